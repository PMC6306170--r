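# Shared segmentation machinery: cut x into (possibly overlapping) windowed
# segments and return the matrix of one-sided FFTs plus the PSD scale.

make_window <- function(type, n) {
  switch(type,
    hann = 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / n),
    rect = rep(1, n),
    stop(sprintf("unknown window '%s'", type), call. = FALSE)
  )
}

segment_starts <- function(n, seg, overlap) {
  step <- max(1L, as.integer(round(seg * (1 - overlap))))
  starts <- seq(1L, n - seg + 1L, by = step)
  starts
}

# FFT of each windowed segment; rows = frequency bins (one-sided), cols =
# segments.
segment_ffts <- function(x, seg, overlap, window) {
  n <- length(x)
  if (seg > n) stop("segment longer than trace", call. = FALSE)
  w <- make_window(window, seg)
  starts <- segment_starts(n, seg, overlap)
  segm <- vapply(starts, function(s) x[s:(s + seg - 1L)] * w,
                 numeric(seg))
  X <- stats::mvfft(as.matrix(segm))
  nfreq <- floor(seg / 2) + 1L
  X[seq_len(nfreq), , drop = FALSE]
}

#' @importFrom stats mvfft
psd_from_ffts <- function(X, seg, fs, window) {
  w <- make_window(window, seg)
  scale <- fs * sum(w^2)
  p <- rowMeans(Mod(X)^2) / scale
  nfreq <- nrow(X)
  # one-sided: double everything except DC (and Nyquist when seg is even)
  mult <- rep(2, nfreq)
  mult[1] <- 1
  if (seg %% 2 == 0) mult[nfreq] <- 1
  p * mult
}

#' Welch power spectral density
#'
#' Segment-averaged one-sided periodogram with window power correction.
#' Density units are (input unit)^2 per Hz, so for microvolt traces
#' microvolts^2/Hz; the integral over frequency recovers the signal
#' variance (Parseval).
#'
#' @param x Numeric vector.
#' @param fs Sampling rate, Hz.
#' @param segment_s Segment length, seconds (default 5).
#' @param overlap Fractional overlap in `[0, 1)` (default 0.5).
#' @param window `"hann"` (default) or `"rect"`.
#' @return A data.frame of class `power_spectrum` with columns `freq`,
#'   `power`, and attributes `segment_s`, `overlap`, `window`,
#'   `n_segments`.
#' @export
welch_psd <- function(x, fs, segment_s = 5, overlap = 0.5, window = "hann") {
  seg <- as.integer(round(segment_s * fs))
  X <- segment_ffts(x, seg, overlap, window)
  p <- psd_from_ffts(X, seg, fs, window)
  out <- data.frame(freq = (seq_len(nrow(X)) - 1) * fs / seg, power = p)
  structure(out, class = c("power_spectrum", "data.frame"),
            segment_s = seg / fs, overlap = overlap, window = window,
            n_segments = ncol(X))
}

#' Rayleigh frequency resolution of an analysis window
#'
#' The minimum resolvable frequency spacing is the reciprocal of the window
#' duration: a 15 s scoring epoch resolves 1/15 ~ 0.067 Hz, finer than
#' 0.1 Hz.
#'
#' @param duration Window duration, seconds.
#' @return Hz.
#' @export
freq_resolution <- function(duration) {
  stopifnot(duration > 0)
  1 / duration
}

#' Epoch slices of one vigilance state
#'
#' Returns the scoring epochs of the requested state as analysis slices,
#' optionally re-cut to a different slice length inside each scored epoch.
#'
#' @param session An `lfp_session` (must carry a hypnogram).
#' @param state `"Wake"`, `"NREM"` or `"REM"`.
#' @param epoch_length Optional slice length, seconds; defaults to the
#'   hypnogram epoch length.
#' @return A data.frame of class `epoch_set` with columns `start`,
#'   `duration` and attribute `state`. Empty (with a warning) if the state
#'   is absent.
#' @export
epochize <- function(session, state, epoch_length = NULL) {
  stopifnot(inherits(session, "lfp_session"))
  h <- session$hypnogram
  if (is.null(h)) stop("session has no hypnogram", call. = FALSE)
  rows <- h[h$state == state, , drop = FALSE]
  if (nrow(rows) == 0) {
    warning(sprintf("no '%s' epochs in this session", state), call. = FALSE)
    out <- data.frame(start = numeric(0), duration = numeric(0))
    return(structure(out, class = c("epoch_set", "data.frame"),
                     state = state))
  }
  if (is.null(epoch_length)) {
    out <- data.frame(start = rows$start, duration = rows$duration)
  } else {
    pieces <- lapply(seq_len(nrow(rows)), function(i) {
      k <- floor(rows$duration[i] / epoch_length)
      if (k < 1) return(NULL)
      data.frame(start = rows$start[i] + (seq_len(k) - 1) * epoch_length,
                 duration = epoch_length)
    })
    out <- do.call(rbind, pieces)
  }
  structure(out, class = c("epoch_set", "data.frame"), state = state)
}

# Collect windowed segment FFTs of one channel across the epochs of a state.
state_segment_ffts <- function(session, channel, epochs, segment_s, overlap,
                               window) {
  fs <- session$fs
  x <- channel_trace(session, channel)
  seg <- as.integer(round(segment_s * fs))
  mats <- lapply(seq_len(nrow(epochs)), function(i) {
    i0 <- round(epochs$start[i] * fs) + 1L
    i1 <- min(length(x), i0 + round(epochs$duration[i] * fs) - 1L)
    xi <- x[i0:i1]
    if (length(xi) < seg) {
      stop("epoch shorter than the Welch segment; reduce `segment_s`",
           call. = FALSE)
    }
    segment_ffts(xi, seg, overlap, window)
  })
  do.call(cbind, mats)
}

#' State-conditioned average power spectrum
#'
#' Welch estimate per scoring epoch of the requested state, averaged across
#' all epochs, for the referential or differential channel of one area.
#'
#' @inheritParams epochize
#' @param mode `"RR"` or `"DR"`.
#' @param area `"CA1"` or `"PFC"` (any montage area).
#' @param segment_s,overlap,window Welch parameters (defaults 5 s Hann,
#'   50% overlap inside each epoch).
#' @return A `power_spectrum` data.frame; attribute `n_epochs` records how
#'   many epochs were averaged.
#' @export
state_spectrum <- function(session, state, mode = c("RR", "DR"),
                           area = "CA1", segment_s = 5, overlap = 0.5,
                           window = "hann") {
  mode <- match.arg(mode)
  epochs <- epochize(session, state)
  if (nrow(epochs) == 0) {
    stop(sprintf("no '%s' epochs: cannot estimate a spectrum", state),
         call. = FALSE)
  }
  channel <- paste0(area, "_", mode)
  X <- state_segment_ffts(session, channel, epochs, segment_s, overlap,
                          window)
  seg <- as.integer(round(segment_s * session$fs))
  p <- psd_from_ffts(X, seg, session$fs, window)
  out <- data.frame(freq = (seq_len(nrow(X)) - 1) * session$fs / seg,
                    power = p)
  structure(out, class = c("power_spectrum", "data.frame"),
            segment_s = segment_s, overlap = overlap, window = window,
            n_segments = ncol(X), n_epochs = nrow(epochs),
            channel = channel, state = state)
}

#' Band power from a power spectrum
#'
#' Trapezoidal integral of the density over `[band[1], band[2]]`.
#'
#' @param ps A `power_spectrum`.
#' @param band Length-2 numeric, Hz.
#' @return Power in (input unit)^2.
#' @export
band_power <- function(ps, band) {
  sel <- ps$freq >= band[1] & ps$freq <= band[2]
  if (sum(sel) < 2) return(0)
  f <- ps$freq[sel]
  p <- ps$power[sel]
  sum(diff(f) * (head(p, -1) + tail(p, -1)) / 2)
}

#' Short-time Fourier power map
#'
#' Sliding-window power spectrogram, by default max-normalised so the
#' colour scale of each map is relative to its own peak.
#'
#' @param x Numeric trace (or use [channel_trace()] first).
#' @param fs Sampling rate, Hz.
#' @param window_s Window length, seconds (default 1).
#' @param overlap Fractional overlap (default 0.9).
#' @param window Window type.
#' @param normalize Divide by the map maximum (default TRUE).
#' @return A list of class `tf_map`: `time` (s, window centres), `freq`
#'   (Hz), `power` (freq x time matrix).
#' @export
spectrogram <- function(x, fs, window_s = 1, overlap = 0.9,
                        window = "hann", normalize = TRUE) {
  seg <- as.integer(round(window_s * fs))
  if (seg > length(x)) stop("window longer than trace", call. = FALSE)
  X <- segment_ffts(x, seg, overlap, window)
  w <- make_window(window, seg)
  p <- Mod(X)^2 / (fs * sum(w^2))
  starts <- segment_starts(length(x), seg, overlap)
  if (normalize && max(p) > 0) p <- p / max(p)
  structure(
    list(time = (starts - 1 + seg / 2) / fs,
         freq = (seq_len(nrow(X)) - 1) * fs / seg,
         power = p),
    class = "tf_map"
  )
}

#' @export
print.tf_map <- function(x, ...) {
  cat(sprintf("<tf_map> %d frequencies x %d windows, %.1f-%.1f s\n",
              length(x$freq), length(x$time), min(x$time), max(x$time)))
  invisible(x)
}
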