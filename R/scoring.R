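#' Per-epoch features for vigilance-state scoring
#'
#' Delta (0.5-4 Hz) and theta (6-10 Hz) band power of the EEG-like trace,
#' their ratio, and the EMG RMS, one row per scoring epoch.
#'
#' @param eeg,emg Equal-length numeric traces, microvolts.
#' @param fs Sampling rate, Hz.
#' @param epoch_length Epoch duration, seconds (default 15).
#' @return A data.frame with columns `start`, `delta`, `theta`, `ratio`,
#'   `emg_rms`.
#' @export
state_features <- function(eeg, emg, fs, epoch_length = 15) {
  if (length(eeg) != length(emg)) {
    stop("`eeg` and `emg` must have equal length", call. = FALSE)
  }
  n_ep <- floor(length(eeg) / (epoch_length * fs))
  if (n_ep < 1) {
    stop("`epoch_length` is longer than the recording", call. = FALSE)
  }
  seg <- as.integer(epoch_length * fs)
  out <- lapply(seq_len(n_ep), function(i) {
    idx <- ((i - 1) * seg + 1):(i * seg)
    ps <- welch_psd(eeg[idx], fs, segment_s = min(5, epoch_length),
                    overlap = 0.5)
    delta <- band_power(ps, c(0.5, 4))
    theta <- band_power(ps, c(6, 10))
    data.frame(start = (i - 1) * epoch_length,
               delta = delta, theta = theta,
               ratio = theta / max(delta, .Machine$double.eps),
               emg_rms = sqrt(mean(emg[idx]^2)))
  })
  do.call(rbind, out)
}

# Deterministic 1-D k-means (Lloyd iterations, quantile initialisation) on
# log-transformed positive data. Returns sorted cluster centres on the log
# scale, or NULL for degenerate input.
kmeans1d_log <- function(x, k) {
  x <- x[is.finite(x) & x > 0]
  if (length(x) < k) return(NULL)
  lx <- log(x)
  ctr <- as.numeric(stats::quantile(lx, seq(0, 1, length.out = k)))
  if (max(lx) - min(lx) < 1e-9 || any(duplicated(ctr))) return(NULL)
  for (it in 1:100) {
    assign_ <- vapply(lx, function(v) which.min(abs(v - ctr)), integer(1))
    if (length(unique(assign_)) < k) return(NULL)
    new_ctr <- vapply(seq_len(k), function(j) mean(lx[assign_ == j]),
                      numeric(1))
    if (max(abs(new_ctr - ctr)) < 1e-12) break
    ctr <- new_ctr
  }
  sort(ctr)
}

# Threshold separating the top cluster from the rest: try a 3-cluster split
# first (features like the EMG RMS take three state-dependent levels), fall
# back to 2 clusters, and return NA when no split is separated by at least
# `min_ratio` on the raw scale (unimodal feature).
upper_threshold <- function(x, min_ratio = 3) {
  for (k in c(3L, 2L)) {
    ctr <- kmeans1d_log(x, k)
    if (is.null(ctr)) next
    top <- ctr[k]; next_ <- ctr[k - 1]
    if (exp(top) / exp(next_) >= min_ratio) {
      return(exp((top + next_) / 2))
    }
  }
  NA_real_
}

# Threshold separating the bottom cluster from the rest (two-means only).
bimodal_threshold <- function(x, min_ratio = 3) {
  ctr <- kmeans1d_log(x, 2L)
  if (is.null(ctr) || exp(ctr[2]) / exp(ctr[1]) < min_ratio) {
    return(NA_real_)
  }
  exp(mean(ctr))
}

#' Rule-based vigilance-state scoring
#'
#' Per-epoch decision rule on the EEG/EMG features: Wake when the EMG RMS
#' exceeds the muscle threshold; otherwise NREM when delta power exceeds the
#' delta threshold; otherwise REM when the theta/delta ratio exceeds the
#' ratio threshold; otherwise NREM. Thresholds default to a per-recording
#' derivation: a deterministic two-means split of each log feature when it
#' is bimodal, with absolute fallbacks when it is not (EMG compared with the
#' overall EEG RMS; delta compared with half the broadband power; ratio
#' compared with 1.5). Single-epoch state islands are absorbed by their
#' neighbours. Scoring is deterministic given the thresholds.
#'
#' @inheritParams state_features
#' @param thresholds Optional list with elements `emg`, `delta`, `ratio`
#'   overriding the automatic derivation.
#' @return A [hypnogram()] covering the scored epochs.
#' @export
score_states <- function(eeg, emg, fs, epoch_length = 15, thresholds = NULL) {
  ft <- state_features(eeg, emg, fs, epoch_length)
  # collapse numerical dust (band leakage many orders below the broadband
  # power) to a common floor so it cannot masquerade as a bimodal feature
  floor_delta <- 1e-9 * max(ft$delta + ft$theta, .Machine$double.eps)
  ft$delta <- pmax(ft$delta, floor_delta)
  ft$ratio <- ft$theta / ft$delta

  thr_emg <- thresholds$emg
  if (is.null(thr_emg)) {
    thr_emg <- upper_threshold(ft$emg_rms)
    if (is.na(thr_emg)) thr_emg <- max(sqrt(mean(eeg^2)), 1e-12)
  }
  thr_delta <- thresholds$delta
  if (is.null(thr_delta)) {
    thr_delta <- bimodal_threshold(ft$delta)
    if (is.na(thr_delta)) {
      broadband <- ft$delta + ft$theta
      thr_delta <- stats::median(broadband) / 2 + .Machine$double.eps
    }
  }
  thr_ratio <- thresholds$ratio
  if (is.null(thr_ratio)) {
    thr_ratio <- bimodal_threshold(ft$ratio)
    if (is.na(thr_ratio)) thr_ratio <- 1.5
  }

  state <- ifelse(ft$emg_rms > thr_emg, "Wake",
           ifelse(ft$delta > thr_delta, "NREM",
           ifelse(ft$ratio > thr_ratio, "REM", "NREM")))

  # absorb single-epoch islands by their neighbours
  n <- length(state)
  if (n >= 3) {
    for (i in 2:(n - 1)) {
      if (state[i] != state[i - 1] && state[i] != state[i + 1] &&
          state[i - 1] == state[i + 1]) {
        state[i] <- state[i - 1]
      }
    }
  }
  hypnogram(start = ft$start, duration = rep(epoch_length, n), state = state)
}

#' Score a simulated session
#'
#' Convenience wrapper applying [score_states()] to a session's `CA1_RR`
#' channel (the EEG stand-in) and its `EMG` channel.
#'
#' @param session An `lfp_session`.
#' @param epoch_length Epoch duration, seconds; defaults to the session's
#'   hypnogram epoch length.
#' @param thresholds Passed to [score_states()].
#' @return A [hypnogram()].
#' @export
score_session <- function(session, epoch_length = NULL, thresholds = NULL) {
  stopifnot(inherits(session, "lfp_session"))
  if (is.null(epoch_length)) epoch_length <- session$hypnogram$duration[1]
  score_states(channel_trace(session, "CA1_RR"),
               channel_trace(session, "EMG"),
               session$fs, epoch_length, thresholds)
}

#' Epoch-wise agreement between two hypnograms
#'
#' @param scored,truth Two [hypnogram()]s over the same epochs (compared on
#'   the overlap).
#' @return Fraction of epochs with identical labels.
#' @export
hypnogram_agreement <- function(scored, truth) {
  n <- min(nrow(scored), nrow(truth))
  mean(scored$state[seq_len(n)] == truth$state[seq_len(n)])
}
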