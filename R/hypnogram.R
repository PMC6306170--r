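#' Hypnogram object
#'
#' A hypnogram is a contiguous sequence of fixed-length scoring epochs, each
#' labelled Wake, NREM or REM. Stored as a data.frame with one row per epoch
#' and columns `start` (s), `duration` (s), `state`.
#'
#' @param start,duration Numeric vectors, seconds.
#' @param state Character vector with values in `c("Wake", "NREM", "REM")`.
#' @return A data.frame of class `hypnogram`.
#' @export
hypnogram <- function(start, duration, state) {
  if (length(start) == 0) stop("hypnogram must have at least one epoch",
                               call. = FALSE)
  if (!all(state %in% c("Wake", "NREM", "REM"))) {
    stop("states must be Wake, NREM or REM", call. = FALSE)
  }
  if (any(duration <= 0)) stop("epoch durations must be positive",
                               call. = FALSE)
  if (length(start) > 1) {
    gaps <- abs(start[-1] - (start[-length(start)] + duration[-length(duration)]))
    if (any(gaps > 1e-9)) {
      stop("epochs must be contiguous and non-overlapping", call. = FALSE)
    }
  }
  structure(
    data.frame(start = start, duration = duration, state = state,
               stringsAsFactors = FALSE),
    class = c("hypnogram", "data.frame")
  )
}

#' Generate a randomized bout-structured hypnogram
#'
#' Produces a seed-reproducible hypnogram realising exactly the requested
#' number of epochs per vigilance state. Epochs are grouped into bouts with
#' geometric-like lengths and physiological transition preferences
#' (Wake -> NREM; NREM -> REM or Wake; REM -> Wake or NREM), so that state
#' runs resemble real rodent sleep architecture rather than an i.i.d.
#' shuffle. The defaults mirror a scored session with 195 NREM and 110 REM
#' 15-second epochs (4575 s of scored sleep); 55 Wake epochs are added so
#' that all three classes occur.
#'
#' @param n_wake,n_nrem,n_rem Epoch counts per state (non-negative integers).
#' @param epoch_length Epoch duration, seconds, > 0.
#' @param seed Integer seed; identical seeds give identical hypnograms.
#' @return A [hypnogram()].
#' @export
#' @examples
#' h <- build_hypnogram(n_wake = 2, n_nrem = 4, n_rem = 2, seed = 1)
#' table(h$state)
build_hypnogram <- function(n_wake = 55, n_nrem = 195, n_rem = 110,
                            epoch_length = 15, seed = 1) {
  counts <- c(Wake = n_wake, NREM = n_nrem, REM = n_rem)
  if (any(counts < 0) || any(counts %% 1 != 0)) {
    stop("state counts must be non-negative integers", call. = FALSE)
  }
  if (sum(counts) == 0) {
    stop("all state counts are zero: cannot build an empty session",
         call. = FALSE)
  }
  if (epoch_length <= 0) stop("`epoch_length` must be positive", call. = FALSE)

  mean_bout <- c(Wake = 3, NREM = 8, REM = 5)  # epochs per bout
  prefs <- list(
    Wake = c("NREM", "REM"),
    NREM = c("REM", "Wake"),
    REM  = c("Wake", "NREM")
  )
  states <- with_seed(seed, {
    remaining <- counts
    out <- character(0)
    current <- if (remaining["Wake"] > 0) "Wake" else
      names(remaining)[which(remaining > 0)[1]]
    while (sum(remaining) > 0) {
      if (remaining[current] == 0) {
        avail <- names(remaining)[remaining > 0]
        current <- avail[1]
      }
      len <- min(1 + stats::rpois(1, mean_bout[current] - 1),
                 remaining[current])
      out <- c(out, rep(current, len))
      remaining[current] <- remaining[current] - len
      if (sum(remaining) == 0) break
      cand <- prefs[[current]]
      cand <- cand[remaining[cand] > 0]
      if (length(cand) == 0) {
        cand <- names(remaining)[remaining > 0]
      }
      w <- remaining[cand] + 1
      current <- sample(cand, 1, prob = w)
    }
    out
  })
  n <- length(states)
  hypnogram(start = (seq_len(n) - 1) * epoch_length,
            duration = rep(epoch_length, n),
            state = states)
}

#' Total duration covered by a hypnogram
#' @param h A [hypnogram()].
#' @return Seconds.
#' @export
hypnogram_duration <- function(h) {
  stopifnot(inherits(h, "hypnogram"))
  sum(h$duration)
}

# 0/1 sample mask of the epochs in `state`, at sampling rate fs over n
# samples, with optional raised-cosine ramps (seconds) inside epoch edges.
state_mask <- function(h, state, fs, n, ramp = 0) {
  mask <- numeric(n)
  rows <- h[h$state == state, , drop = FALSE]
  if (nrow(rows) == 0) return(mask)
  for (i in seq_len(nrow(rows))) {
    i0 <- floor(rows$start[i] * fs) + 1
    i1 <- min(n, floor((rows$start[i] + rows$duration[i]) * fs))
    if (i0 > n || i1 < i0) next
    mask[i0:i1] <- 1
  }
  if (ramp > 0) {
    k <- max(2L, as.integer(ramp * fs))
    w <- (1 - cos(pi * seq_len(k) / k)) / 2
    mask <- stats::filter(c(rep(mask[1], k), mask, rep(mask[n], k)),
                          rep(1 / k, k), sides = 2)
    mask <- as.numeric(mask[(k + 1):(k + n)])
  }
  mask
}
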