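# Averaged auto- and cross-spectra over aligned segment FFT matrices.
avg_spectra <- function(X, Y) {
  list(
    sxx = rowMeans(Mod(X)^2),
    syy = rowMeans(Mod(Y)^2),
    sxy = rowMeans(X * Conj(Y))
  )
}

coherence_df <- function(freq, value, variant, n_segments) {
  structure(
    data.frame(freq = freq, coherence = value),
    class = c("coherence_spectrum", "data.frame"),
    variant = variant, n_segments = n_segments
  )
}

#' Magnitude-squared coherence
#'
#' Segment-averaged coherence: the squared magnitude of the averaged
#' cross-spectrum divided by the product of the averaged auto-spectra.
#' Values lie in `[0, 1]`; self-coherence is identically 1, and for
#' independent signals the estimator has a positive bias of about one over
#' the number of segments averaged.
#'
#' @param x,y Equal-length numeric traces at the same sampling rate.
#' @param fs Sampling rate, Hz.
#' @param segment_s Segment length, seconds (default 5).
#' @param overlap Fractional overlap (default 0.5).
#' @param window `"hann"` (default) or `"rect"`.
#' @return A data.frame of class `coherence_spectrum` with columns `freq`,
#'   `coherence`; attribute `n_segments` is the number of segments averaged.
#' @export
msc <- function(x, y, fs, segment_s = 5, overlap = 0.5, window = "hann") {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length",
                                   call. = FALSE)
  seg <- as.integer(round(segment_s * fs))
  X <- segment_ffts(x, seg, overlap, window)
  Y <- segment_ffts(y, seg, overlap, window)
  if (ncol(X) < 2) {
    stop("coherence needs at least 2 segments (a single segment gives the ",
         "degenerate estimate C = 1 everywhere)", call. = FALSE)
  }
  s <- avg_spectra(X, Y)
  coherence_df((seq_len(nrow(X)) - 1) * fs / seg,
               Mod(s$sxy)^2 / (s$sxx * s$syy), "magnitude-squared", ncol(X))
}

#' Imaginary coherence
#'
#' Magnitude of the imaginary part of the normalised averaged cross-spectrum
#' (coherency). Instantaneous (zero-lag) coupling -- the signature of volume
#' conduction in an ohmic medium -- has a purely real coherency and is
#' therefore suppressed, while a transmission delay d leaves
#' `|sin(2 pi f d)| * sqrt(C)` at frequency f.
#'
#' @inheritParams msc
#' @return A `coherence_spectrum` with variant `"imaginary"`.
#' @export
imag_coherence <- function(x, y, fs, segment_s = 5, overlap = 0.5,
                           window = "hann") {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length",
                                   call. = FALSE)
  seg <- as.integer(round(segment_s * fs))
  X <- segment_ffts(x, seg, overlap, window)
  Y <- segment_ffts(y, seg, overlap, window)
  if (ncol(X) < 2) stop("coherence needs at least 2 segments", call. = FALSE)
  s <- avg_spectra(X, Y)
  coherence_df((seq_len(nrow(X)) - 1) * fs / seg,
               abs(Im(s$sxy / sqrt(s$sxx * s$syy))), "imaginary", ncol(X))
}

# Coherence between two channels of a session using segments drawn within
# the epochs of one state (sliding-window average restricted to the state).
state_msc <- function(session, state, mode = "DR", areas = c("CA1", "PFC"),
                      segment_s = 5, overlap = 0.5, window = "hann",
                      variant = c("msc", "imaginary")) {
  variant <- match.arg(variant)
  epochs <- epochize(session, state)
  if (nrow(epochs) == 0) stop(sprintf("no '%s' epochs", state), call. = FALSE)
  X <- state_segment_ffts(session, paste0(areas[1], "_", mode), epochs,
                          segment_s, overlap, window)
  Y <- state_segment_ffts(session, paste0(areas[2], "_", mode), epochs,
                          segment_s, overlap, window)
  if (ncol(X) < 2) stop("coherence needs at least 2 segments", call. = FALSE)
  s <- avg_spectra(X, Y)
  seg <- as.integer(round(segment_s * session$fs))
  val <- if (variant == "msc") Mod(s$sxy)^2 / (s$sxx * s$syy)
         else abs(Im(s$sxy / sqrt(s$sxx * s$syy)))
  coherence_df((seq_len(nrow(X)) - 1) * session$fs / seg, val,
               if (variant == "msc") "magnitude-squared" else "imaginary",
               ncol(X))
}

# Event-aligned windows of one channel: one column per event, optionally
# band-passed (on the full trace, before slicing) and Hann-tapered.
event_windows <- function(session, events, channel, window_s, band = NULL,
                          taper = FALSE) {
  fs <- session$fs
  x <- channel_trace(session, channel)
  if (!is.null(band)) {
    bf <- signal::butter(2, band / (fs / 2), type = "pass")
    x <- signal::filtfilt(bf, x)
  }
  len <- as.integer(round(window_s * fs))
  w <- if (taper) make_window("hann", len) else rep(1, len)
  mids <- round((event_onsets(events) + event_ends(events)) / 2 * fs)
  cols <- lapply(mids, function(m) {
    i0 <- m - len %/% 2 + 1L
    idx <- i0:(i0 + len - 1L)
    if (idx[1] < 1 || idx[len] > length(x)) return(NULL)
    x[idx] * w
  })
  keep <- !vapply(cols, is.null, logical(1))
  do.call(cbind, cols[keep])
}

event_onsets <- function(events) {
  if ("start" %in% names(events)) events$start else events$onset
}
event_ends <- function(events) {
  if ("end" %in% names(events)) events$end else events$onset + events$duration
}

#' Burst-triggered coherence
#'
#' Coherence between the two areas computed from event-aligned windows only,
#' instead of a sliding average over the whole recording: one Hann-tapered
#' window per detected burst, centred on the event, averaging in the
#' coherence estimator carried out over those windows. Restricting the
#' average to communication episodes avoids diluting phase-locked transients
#' with the silent majority of the recording.
#'
#' @param session An `lfp_session`.
#' @param events A [detect_bursts()] result or ground-truth schedule
#'   (>= 2 events), typically detected on the trigger area's channel.
#' @param trigger_area `"CA1"` or `"PFC"`; recorded in the output attributes
#'   (the events passed in should come from this area's channel).
#' @param mode `"RR"` or `"DR"`.
#' @param window_s Event window length, seconds (default 1; events longer
#'   than this are cropped about their midpoint).
#' @param variant `"msc"` or `"imaginary"`.
#' @return A `coherence_spectrum`.
#' @export
burst_triggered_coherence <- function(session, events,
                                      trigger_area = c("CA1", "PFC"),
                                      mode = c("DR", "RR"), window_s = 1,
                                      variant = c("msc", "imaginary")) {
  trigger_area <- match.arg(trigger_area)
  mode <- match.arg(mode)
  variant <- match.arg(variant)
  if (nrow(events) < 2) {
    stop("burst-triggered coherence needs at least 2 events", call. = FALSE)
  }
  fs <- session$fs
  len <- as.integer(round(window_s * fs))
  w <- make_window("hann", len)
  Xr <- event_windows(session, events, paste0("CA1_", mode), window_s)
  Yr <- event_windows(session, events, paste0("PFC_", mode), window_s)
  if (is.null(Xr) || ncol(Xr) < 2) {
    stop("fewer than 2 usable event windows", call. = FALSE)
  }
  nfreq <- len %/% 2 + 1L
  X <- stats::mvfft(Xr * w)[seq_len(nfreq), , drop = FALSE]
  Y <- stats::mvfft(Yr * w)[seq_len(nfreq), , drop = FALSE]
  s <- avg_spectra(X, Y)
  val <- if (variant == "msc") Mod(s$sxy)^2 / (s$sxx * s$syy)
         else abs(Im(s$sxy / sqrt(s$sxx * s$syy)))
  out <- coherence_df((seq_len(nfreq) - 1) * fs / len, val,
                      if (variant == "msc") "magnitude-squared" else "imaginary",
                      ncol(X))
  attr(out, "trigger_area") <- trigger_area
  attr(out, "mode") <- mode
  out
}

#' Normalised cross-correlation peak
#'
#' Pearson correlation of the overlapping parts of `x` and lagged `y`,
#' scanned over integer-sample lags in `[-max_lag, max_lag]`; returns the
#' lag of the largest absolute correlation, with its signed correlation.
#' Positive lag means `y` lags (is delayed relative to) `x`.
#'
#' @param x,y Equal-length numeric vectors.
#' @param fs Sampling rate, Hz.
#' @param max_lag Maximum lag scanned, seconds; must be shorter than the
#'   window.
#' @param peak `"abs"` (default) picks the largest absolute correlation,
#'   reported with its sign; `"positive"` picks the largest (signed)
#'   correlation, appropriate when the coupling is known to preserve
#'   polarity, as between two like-oriented montage channels.
#' @return List with `correlation` and `lag` (seconds).
#' @export
xcorr_peak <- function(x, y, fs, max_lag = 0.1, peak = c("abs", "positive")) {
  peak <- match.arg(peak)
  n <- length(x)
  if (length(y) != n) stop("`x` and `y` must have equal length", call. = FALSE)
  L <- as.integer(round(max_lag * fs))
  if (L >= n - 1) stop("`max_lag` must be shorter than the window",
                       call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero-variance input: correlation undefined", call. = FALSE)
  }
  lags <- -L:L
  cc <- vapply(lags, function(l) {
    if (l >= 0) {
      xs <- x[1:(n - l)]
      ys <- y[(1 + l):n]
    } else {
      xs <- x[(1 - l):n]
      ys <- y[1:(n + l)]
    }
    if (stats::sd(xs) == 0 || stats::sd(ys) == 0) return(0)
    stats::cor(xs, ys)
  }, numeric(1))
  k <- if (peak == "abs") which.max(abs(cc)) else which.max(cc)
  list(correlation = cc[k], lag = lags[k] / fs)
}

#' Event-wise cross-correlation peak-lag distribution
#'
#' For each event, takes a band-passed window of the CA1 and PFC channels in
#' the chosen montage mode, finds the cross-correlation peak lag (positive =
#' PFC delayed relative to CA1), and summarises the per-event lags as a
#' kernel probability density, an empirical CDF and the median. Both montage
#' channels share the same contact orientation, so the physiological
#' cross-correlation peak is positive and the per-event peak is taken as the
#' maximum signed correlation (see `peak` in [xcorr_peak()]); this also
#' disambiguates the narrowband half-cycle lobe. In the differential
#' montage the median recovers the true inter-areal conduction delay; in
#' the referential montage a dominant common (volume-conducted) source
#' drags the peak to zero lag and blurs the density.
#'
#' @param session An `lfp_session`.
#' @param events Detected events or ground-truth schedule (>= 2; fewer than
#'   10 triggers a low-confidence warning).
#' @param mode `"DR"` or `"RR"`.
#' @param band Band-pass applied to the windows, Hz (default the 10-14 Hz
#'   event band; NULL for broadband).
#' @param window_s Event window length, seconds (default 1.2).
#' @param max_lag Maximum lag scanned, seconds (default 0.1).
#' @return An object of class `lag_distribution`: list with `lags`,
#'   `correlations` (per event), `pdf` (a [stats::density()] object,
#'   Gaussian kernel, Silverman bandwidth), `cdf` (an [stats::ecdf()]),
#'   `median_lag`, `sd_lag`, `iqr_lag`, `n_events`, `mode`.
#' @export
lag_distribution <- function(session, events, mode = c("DR", "RR"),
                             band = c(10, 14), window_s = 1.2,
                             max_lag = 0.1) {
  mode <- match.arg(mode)
  if (nrow(events) < 2) stop("need at least 2 events", call. = FALSE)
  if (nrow(events) < 10) {
    warning("fewer than 10 events: low-confidence lag distribution",
            call. = FALSE)
  }
  Xw <- event_windows(session, events, paste0("CA1_", mode), window_s, band)
  Yw <- event_windows(session, events, paste0("PFC_", mode), window_s, band)
  ne <- ncol(Xw)
  lags <- numeric(ne)
  cors <- numeric(ne)
  for (i in seq_len(ne)) {
    pk <- xcorr_peak(Xw[, i], Yw[, i], session$fs, max_lag,
                     peak = "positive")
    lags[i] <- pk$lag
    cors[i] <- pk$correlation
  }
  structure(
    list(lags = lags, correlations = cors,
         pdf = stats::density(lags, bw = "nrd0", kernel = "gaussian"),
         cdf = stats::ecdf(lags),
         median_lag = stats::median(lags),
         sd_lag = stats::sd(lags),
         iqr_lag = unname(diff(stats::quantile(lags, c(0.25, 0.75)))),
         n_events = ne, mode = mode),
    class = "lag_distribution"
  )
}

#' @export
print.lag_distribution <- function(x, ...) {
  cat(sprintf(
    "<lag_distribution> %s mode, %d events: median %.1f ms (SD %.1f ms)\n",
    x$mode, x$n_events, 1000 * x$median_lag, 1000 * x$sd_lag))
  invisible(x)
}

#' Coherence versus noise level for a unit sine
#'
#' The canonical coherence-degradation simulation: a unit-amplitude sine
#' placed on an exact DFT bin is compared with itself plus Gaussian white
#' noise of standard deviation `noise_sd` (the noise-to-signal ratio, since
#' the signal has unit amplitude). Coherence is estimated with the pinned
#' configuration -- rectangular window, 400-sample disjoint segments,
#' `n_segments` averages -- under which the per-bin SNR is one when
#' `noise_sd` = 10 and the expected coherence at the sine bin is 0.5.
#'
#' @param noise_sd Positive noise standard deviations (the curve abscissa).
#' @param n_segments Segments averaged per level (default 2000, >= 500 for a
#'   stable estimate).
#' @param segment Segment length in samples (default 400).
#' @param cycles_per_segment Integer number of sine cycles per segment
#'   (default 50), keeping the sine on an exact bin.
#' @param seed Integer seed.
#' @return A data.frame of class `snr_curve` with columns `noise_sd`
#'   (= SNR^-1) and `coherence` at the sine bin.
#' @export
coherence_vs_noise <- function(noise_sd, n_segments = 2000, segment = 400,
                               cycles_per_segment = 50, seed = 1) {
  if (any(noise_sd < 0)) stop("`noise_sd` must be non-negative", call. = FALSE)
  fs <- segment  # one-second segments: bin k is k Hz
  n <- n_segments * segment
  tt <- (seq_len(n) - 1) / fs
  x <- sin(2 * pi * cycles_per_segment * tt)
  cohs <- vapply(seq_along(noise_sd), function(i) {
    y <- x + noise_sd[i] *
      with_seed(derive_seed(seed, paste0("noise", i)), stats::rnorm(n))
    cs <- msc(x, y, fs, segment_s = segment / fs, overlap = 0,
              window = "rect")
    cs$coherence[cs$freq == cycles_per_segment]
  }, numeric(1))
  structure(data.frame(noise_sd = noise_sd, coherence = cohs),
            class = c("snr_curve", "data.frame"),
            n_segments = n_segments, segment = segment)
}

#' Fit a hyperbolic-secant decay to a coherence-vs-noise curve
#'
#' Least-squares fit of `C(n) = sech(a * n)` to the curve, by golden-section
#' minimisation of the residual sum of squares over the scale parameter `a`.
#'
#' @param curve A [coherence_vs_noise()] result, or any data.frame with
#'   columns `noise_sd` and `coherence` (>= 3 points).
#' @return List with `a` (scale, per unit noise SD), `residual_rms`,
#'   `fitted` (values of the fit at the curve abscissae). A warning is
#'   emitted when the input curve is not monotone decreasing.
#' @export
fit_sech <- function(curve) {
  stopifnot(all(c("noise_sd", "coherence") %in% names(curve)))
  if (nrow(curve) < 3) stop("need at least 3 points to fit", call. = FALSE)
  o <- order(curve$noise_sd)
  x <- curve$noise_sd[o]
  y <- curve$coherence[o]
  if (any(diff(y) > 0)) {
    warning("coherence curve is not monotone decreasing; sech fit may be poor",
            call. = FALSE)
  }
  sech <- function(z) 1 / cosh(z)
  ssr <- function(a) sum((y - sech(a * x))^2)
  opt <- stats::optimize(ssr, interval = c(1e-6, 10), tol = 1e-10)
  a <- opt$minimum
  fitted <- sech(a * x)
  list(a = a, residual_rms = sqrt(mean((y - fitted)^2)), fitted = fitted)
}
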