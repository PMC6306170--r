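#' Detect band-limited oscillatory bursts
#'
#' Isolates sporadic 10-14 Hz events (REM inter-areal bursts, NREM sleep
#' spindles) from a single trace. Pipeline: zero-phase 4th-order Butterworth
#' band-pass -> analytic-signal envelope -> 0.1 s moving-average smoothing
#' -> detection where the envelope stays above its mean + `threshold_k` SD
#' for at least `min_duration` -> surviving events closer than `merge_gap`
#' merged -> reported edges refined outward to where the envelope falls
#' back below mean + `edge_k` SD, so onsets track the true event start to
#' within roughly the envelope correlation time (the reciprocal of the
#' band width). Envelope statistics (and detections) can be restricted to
#' the epochs of one state via `epochs`.
#'
#' @param x Numeric trace, microvolts.
#' @param fs Sampling rate, Hz.
#' @param band Length-2 numeric, Hz; upper edge must be below Nyquist.
#' @param threshold_k Detection threshold in envelope SDs above the mean
#'   (default 2).
#' @param edge_k Boundary threshold in SDs (default 1).
#' @param min_duration Minimum event duration, seconds (default 0.4).
#' @param merge_gap Events separated by less than this are merged, seconds
#'   (default 0.2).
#' @param smooth_s Envelope smoothing window, seconds (default 0.1).
#' @param epochs Optional [epochize()] result (or data.frame with
#'   `start`/`duration`): restricts both the envelope statistics and the
#'   detections to those slices.
#' @return A data.frame of class `burst_events` with columns `start`, `end`,
#'   `duration` (s), `peak_amplitude` (microvolts, envelope peak) and
#'   `center_freq` (Hz, spectral peak of the band-passed event). Attributes
#'   record the band and threshold used.
#' @export
detect_bursts <- function(x, fs, band = c(10, 14), threshold_k = 2,
                          edge_k = 1, min_duration = 0.4, merge_gap = 0.2,
                          smooth_s = 0.1, epochs = NULL) {
  if (length(band) != 2 || band[1] <= 0 || band[2] <= band[1]) {
    stop("`band` must be an increasing positive frequency pair", call. = FALSE)
  }
  if (band[2] >= fs / 2) {
    stop("band upper edge must lie below the Nyquist frequency", call. = FALSE)
  }
  n <- length(x)
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  xb <- signal::filtfilt(bf, x)
  env <- smooth_ma(Mod(analytic_signal(xb)), max(1L, round(smooth_s * fs)))

  mask <- rep(TRUE, n)
  if (!is.null(epochs) && nrow(epochs) > 0) {
    mask <- rep(FALSE, n)
    for (i in seq_len(nrow(epochs))) {
      i0 <- round(epochs$start[i] * fs) + 1L
      i1 <- min(n, i0 + round(epochs$duration[i] * fs) - 1L)
      if (i0 <= n && i1 >= i0) mask[i0:i1] <- TRUE
    }
  }
  mu <- mean(env[mask])
  sdev <- stats::sd(env[mask])
  thr <- mu + threshold_k * sdev
  thr_edge <- mu + edge_k * sdev

  core <- env > thr & mask
  if (!any(core)) {
    return(empty_bursts(band, thr))
  }
  r <- rle(core)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ev <- cbind(starts[r$values], ends[r$values])

  # gate on the core duration first -- sustained supra-threshold power is
  # what defines an event -- then merge survivors across short gaps
  gap <- round(merge_gap * fs)
  keep <- (ev[, 2] - ev[, 1] + 1) / fs >= min_duration
  ev <- ev[keep, , drop = FALSE]
  if (nrow(ev) == 0) return(empty_bursts(band, thr))
  merged <- ev[1, , drop = FALSE]
  for (k in seq_len(nrow(ev))[-1]) {
    last <- nrow(merged)
    if (ev[k, 1] - merged[last, 2] <= gap) {
      merged[last, 2] <- max(merged[last, 2], ev[k, 2])
    } else {
      merged <- rbind(merged, ev[k, , drop = FALSE])
    }
  }

  # refine the reported boundaries outward to the edge threshold (within
  # the mask) so onsets track the true event start, then re-merge overlaps
  low <- env <= thr_edge | !mask
  for (k in seq_len(nrow(merged))) {
    i <- merged[k, 1]
    while (i > 1 && !low[i - 1]) i <- i - 1
    merged[k, 1] <- i
    j <- merged[k, 2]
    while (j < n && !low[j + 1]) j <- j + 1
    merged[k, 2] <- j
  }
  if (nrow(merged) > 1) {
    out2 <- merged[1, , drop = FALSE]
    for (k in seq_len(nrow(merged))[-1]) {
      last <- nrow(out2)
      if (merged[k, 1] - out2[last, 2] <= gap) {
        out2[last, 2] <- max(out2[last, 2], merged[k, 2])
      } else {
        out2 <- rbind(out2, merged[k, , drop = FALSE])
      }
    }
    merged <- out2
  }

  out <- data.frame(
    start = (merged[, 1] - 1) / fs,
    end = merged[, 2] / fs
  )
  out$duration <- out$end - out$start
  out$peak_amplitude <- vapply(seq_len(nrow(merged)), function(k) {
    max(env[merged[k, 1]:merged[k, 2]])
  }, numeric(1))
  out$center_freq <- vapply(seq_len(nrow(merged)), function(k) {
    snip <- xb[merged[k, 1]:merged[k, 2]]
    m <- stats::nextn(max(length(snip) * 4L, 4L * as.integer(fs)), 2)
    sp <- Mod(stats::fft(c(snip, numeric(m - length(snip)))))^2
    f <- (seq_len(m) - 1) * fs / m
    sel <- f >= band[1] & f <= band[2]
    f[sel][which.max(sp[sel])]
  }, numeric(1))
  structure(out, class = c("burst_events", "data.frame"),
            band = band, threshold = thr)
}

empty_bursts <- function(band, thr) {
  structure(
    data.frame(start = numeric(0), end = numeric(0), duration = numeric(0),
               peak_amplitude = numeric(0), center_freq = numeric(0)),
    class = c("burst_events", "data.frame"), band = band, threshold = thr
  )
}

#' Match detected events against a ground-truth schedule
#'
#' An event matches a scheduled one when their midpoints are within
#' `tol` + half the scheduled duration; each true event is matched at most
#' once.
#'
#' @param detected A [detect_bursts()] result (columns `start`, `end`).
#' @param truth Data.frame with `onset` and `duration` columns (the
#'   generator's ground-truth schedule).
#' @param tol Midpoint tolerance, seconds (default 0.25).
#' @return List with `sensitivity`, `precision`, `n_detected`, `n_true`.
#' @export
match_events <- function(detected, truth, tol = 0.25) {
  n_det <- nrow(detected)
  n_true <- nrow(truth)
  if (n_true == 0) {
    return(list(sensitivity = NA_real_,
                precision = if (n_det == 0) NA_real_ else 0,
                n_detected = n_det, n_true = 0))
  }
  mid_det <- (detected$start + detected$end) / 2
  mid_true <- truth$onset + truth$duration / 2
  used <- rep(FALSE, n_true)
  hits <- 0L
  for (i in seq_len(n_det)) {
    d <- abs(mid_true - mid_det[i])
    ok <- which(!used & d <= truth$duration / 2 + tol)
    if (length(ok)) {
      used[ok[which.min(d[ok])]] <- TRUE
      hits <- hits + 1L
    }
  }
  list(sensitivity = sum(used) / n_true,
       precision = if (n_det == 0) NA_real_ else hits / n_det,
       n_detected = n_det, n_true = n_true)
}
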