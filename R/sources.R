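#' Generator parameters for the synthetic two-area session
#'
#' Defaults define the study conditions emulated by the generator:
#' \itemize{
#'   \item REM: continuous 7 Hz theta in CA1, plus sporadic 10-14 Hz bursts
#'     present in both areas with a fixed 35 ms inter-areal delay
#'     (PFC lagging CA1).
#'   \item NREM: ~1 Hz slow oscillation in both areas plus 10-14 Hz sleep
#'     spindles in PFC.
#'   \item Always-on per-area pink-noise background and one strong distal
#'     common source driving volume conduction into both referential
#'     channels (75% pink power, 25% REM-gated 7 Hz power, so conducted
#'     theta is shared by the two referential channels).
#'   \item An EMG-like channel whose power depends on state (high in Wake,
#'     moderate in NREM, near zero in REM atonia).
#' }
#' Amplitudes are expressed in microvolts of potential at the nearest
#' own-area electrode (peak envelope for transient events, RMS otherwise);
#' they are converted to source currents through the forward model. The
#' defaults are calibrated so that referential power is about 10 times
#' differential power during REM and the distal common source dominates the
#' referential channels.
#'
#' @param fs Sampling rate, Hz.
#' @param theta_freq,theta_rms REM theta frequency (Hz) and RMS amplitude
#'   (microvolts).
#' @param so_band,so_rms NREM slow-oscillation band (Hz) and RMS amplitude.
#' @param spindle_rate,spindle_band,spindle_duration,spindle_peak NREM PFC
#'   spindle Poisson rate (events/s), frequency band (Hz), duration (s) and
#'   peak envelope amplitude (microvolts).
#' @param burst_rate,burst_band,burst_duration,burst_peak,burst_delay REM
#'   inter-areal burst Poisson rate (events/s), band (Hz), duration (s),
#'   peak envelope amplitude (microvolts) and inter-areal waveform delay
#'   (s; positive = PFC later).
#' @param pink_rms,pink_exponent Per-area background RMS amplitude
#'   (microvolts) and pink-noise spectral exponent.
#' @param common_rms,common_theta_frac Distal common source RMS amplitude
#'   (microvolts, at the CA1 electrode) and the fraction of its power in
#'   the REM-gated 7 Hz component.
#' @param emg_rms Named vector of EMG RMS amplitudes (microvolts) per state.
#' @param local_offset Distance of local sources beyond their pair's first
#'   contact along the pair axis, meters; with the default (= epsilon) a
#'   local source sits at distance epsilon from e1 and 3*epsilon from e2,
#'   so its differential amplitude is 2/3 of its referential amplitude.
#' @param common_position Position of the distal common source, meters.
#' @param medium An [medium()].
#' @return A list of class `source_params`.
#' @export
source_params <- function(fs = 1000,
                          theta_freq = 7, theta_rms = 70,
                          so_band = c(0.5, 2), so_rms = 120,
                          spindle_rate = 6 / 60, spindle_band = c(10, 14),
                          spindle_duration = 1, spindle_peak = 60,
                          burst_rate = 6 / 60, burst_band = c(10, 14),
                          burst_duration = 1, burst_peak = 40,
                          burst_delay = 0.035,
                          pink_rms = 10, pink_exponent = 1,
                          common_rms = 150, common_theta_frac = 0.25,
                          emg_rms = c(Wake = 100, NREM = 30, REM = 5),
                          local_offset = 1e-4,
                          common_position = c(3.25e-3, 2e-3, 0),
                          medium = lfpvc::medium()) {
  p <- as.list(environment())
  if (p$burst_delay >= p$burst_duration) {
    stop("inter-areal delay must be smaller than the burst duration",
         call. = FALSE)
  }
  if (p$fs <= 2 * max(p$burst_band, p$spindle_band, p$theta_freq)) {
    stop("sampling rate must exceed twice the highest oscillator frequency",
         call. = FALSE)
  }
  structure(p, class = "source_params")
}

# Hann-windowed sinusoidal burst train; schedule has columns onset,
# duration, freq, phase. `delay` shifts every burst as an exact waveform
# time shift.
burst_train <- function(n, fs, schedule, delay = 0) {
  x <- numeric(n)
  if (nrow(schedule) == 0) return(x)
  for (i in seq_len(nrow(schedule))) {
    on <- schedule$onset[i] + delay
    len <- round(schedule$duration[i] * fs)
    i0 <- round(on * fs) + 1
    idx <- i0:(i0 + len - 1)
    keep <- idx >= 1 & idx <= n
    if (!any(keep)) next
    tt <- (seq_len(len) - 1) / fs
    w <- sin(pi * tt / schedule$duration[i])^2
    x[idx[keep]] <- x[idx[keep]] +
      (w * sin(2 * pi * schedule$freq[i] * tt + schedule$phase[i]))[keep]
  }
  x
}

# Poisson schedule of transient events inside the epochs of one state.
# Events are kept clear of epoch edges and of each other.
schedule_events <- function(h, state, rate, duration, band, margin) {
  rows <- h[h$state == state, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(rows))) {
    L <- rows$duration[i]
    lo <- margin
    hi <- L - duration - margin
    if (hi <= lo) next
    k <- stats::rpois(1, rate * L)
    if (k == 0) next
    on <- sort(stats::runif(k, lo, hi))
    if (k > 1) {  # enforce clean separation between events
      keep <- c(TRUE, diff(on) > 1.5 * duration)
      on <- on[keep]
    }
    out[[length(out) + 1]] <- data.frame(
      onset = rows$start[i] + on,
      duration = duration,
      freq = stats::runif(length(on), band[1], band[2]),
      phase = stats::runif(length(on), 0, 2 * pi)
    )
  }
  if (length(out) == 0) {
    return(data.frame(onset = numeric(0), duration = numeric(0),
                      freq = numeric(0), phase = numeric(0)))
  }
  do.call(rbind, out)
}

# Convert an amplitude target (microvolts at distance d_ref) into a source
# current in amperes.
amp_to_current <- function(amp_uv, d_ref, medium) {
  amp_uv * 1e-6 * 4 * pi * medium$conductivity * d_ref
}

#' Build the state-conditioned source ensemble
#'
#' Realises every current source of the synthetic session as a sampled
#' waveform driven by the hypnogram: per-area oscillators and backgrounds,
#' the distal common source, and the Poisson schedules of NREM spindles and
#' REM inter-areal bursts (the latter present in both areas, the PFC copy
#' delayed by `params$burst_delay`). Local sources sit `params$local_offset`
#' beyond each pair's first contact along the pair axis, so each is at
#' distance epsilon from its nearest electrode.
#'
#' @param h A [hypnogram()].
#' @param params A [source_params()].
#' @param montage An [electrode_montage()] with pairs `CA1` and `PFC`.
#' @param seed Integer seed; identical inputs and seed give an identical
#'   ensemble.
#' @return An object of class `source_ensemble`: list with `sources` (list
#'   of [current_source()] with role/area tags), `bursts` (the ground-truth
#'   schedule: onset, duration, freq, state, areas, delay), `hypnogram`,
#'   `params`, `fs`, `n`, `seed`.
#' @export
build_sources <- function(h, params = source_params(),
                          montage = default_montage(), seed = 1) {
  stopifnot(inherits(h, "hypnogram"), inherits(params, "source_params"),
            inherits(montage, "electrode_montage"))
  if (!all(c("CA1", "PFC") %in% names(montage$pairs))) {
    stop("montage must contain CA1 and PFC pairs", call. = FALSE)
  }
  fs <- params$fs
  n <- round(hypnogram_duration(h) * fs)
  tt <- (seq_len(n) - 1) / fs
  med <- params$medium

  local_pos <- lapply(montage$pairs, function(p) {
    p$midpoint + (p$half_separation + params$local_offset) * p$axis
  })
  # distance from each local source to its own e1 contact
  d_loc <- vapply(names(montage$pairs), function(nm) {
    e1 <- electrode_positions(montage$pairs[[nm]])["e1", ]
    vnorm(local_pos[[nm]] - e1)
  }, numeric(1))
  d_common <- vnorm(params$common_position -
                      electrode_positions(montage$pairs$CA1)["e1", ])

  with_seed(seed, {
    rem_mask <- state_mask(h, "REM", fs, n, ramp = 0.5)
    nrem_mask <- state_mask(h, "NREM", fs, n, ramp = 0.5)

    # REM theta: narrowband noise process centred on theta_freq (+-0.5 Hz),
    # REM-gated. A stochastic oscillator, not a pure sine: independent
    # theta generators must decorrelate rather than interfere coherently.
    theta_osc <- function() {
      bf <- signal::butter(2, c(params$theta_freq - 0.5,
                                params$theta_freq + 0.5) / (fs / 2),
                           type = "pass")
      x <- signal::filtfilt(bf, stats::rnorm(n))
      x / stats::sd(x)
    }
    theta_ca1 <- theta_osc() * rem_mask

    # NREM slow oscillation: band-limited noise, one independent process per
    # area, NREM-gated
    so_osc <- function() {
      bf <- signal::butter(2, params$so_band / (fs / 2), type = "pass")
      x <- signal::filtfilt(bf, stats::rnorm(n))
      (x / stats::sd(x)) * nrem_mask
    }
    so_ca1 <- so_osc()
    so_pfc <- so_osc()

    # transient schedules (ground truth)
    spindles <- schedule_events(h, "NREM", params$spindle_rate,
                                params$spindle_duration, params$spindle_band,
                                margin = 0.6)
    bursts <- schedule_events(h, "REM", params$burst_rate,
                              params$burst_duration, params$burst_band,
                              margin = 0.6 + params$burst_delay)
    spindle_pfc <- burst_train(n, fs, spindles)
    burst_ca1 <- burst_train(n, fs, bursts)
    burst_pfc <- burst_train(n, fs, bursts, delay = params$burst_delay)

    pink_ca1 <- pink_noise(n, fs, params$pink_exponent)
    pink_pfc <- pink_noise(n, fs, params$pink_exponent)

    common <- sqrt(1 - params$common_theta_frac) * pink_noise(n, fs, params$pink_exponent) +
      sqrt(params$common_theta_frac) * theta_osc() * rem_mask

    mk <- function(pos, amp_uv, d_ref, wave, role, area) {
      current_source(pos, amp_to_current(amp_uv, d_ref, med), wave,
                     role = role, area = area)
    }
    sources <- list(
      mk(local_pos$CA1, params$theta_rms, d_loc["CA1"], theta_ca1,
         "local_CA1", "CA1"),
      mk(local_pos$CA1, params$so_rms, d_loc["CA1"], so_ca1,
         "local_CA1", "CA1"),
      mk(local_pos$CA1, params$burst_peak, d_loc["CA1"], burst_ca1,
         "local_CA1", "CA1"),
      mk(local_pos$CA1, params$pink_rms, d_loc["CA1"], pink_ca1,
         "background", "CA1"),
      mk(local_pos$PFC, params$so_rms, d_loc["PFC"], so_pfc,
         "local_PFC", "PFC"),
      mk(local_pos$PFC, params$spindle_peak, d_loc["PFC"], spindle_pfc,
         "local_PFC", "PFC"),
      mk(local_pos$PFC, params$burst_peak, d_loc["PFC"], burst_pfc,
         "local_PFC", "PFC"),
      mk(local_pos$PFC, params$pink_rms, d_loc["PFC"], pink_pfc,
         "background", "PFC"),
      mk(params$common_position, params$common_rms, d_common, common,
         "distal_common", NA_character_)
    )

    gt <- rbind(
      if (nrow(bursts)) cbind(bursts[c("onset", "duration", "freq")],
                              state = "REM", areas = "both",
                              delay = params$burst_delay),
      if (nrow(spindles)) cbind(spindles[c("onset", "duration", "freq")],
                                state = "NREM", areas = "PFC", delay = 0)
    )
    if (is.null(gt)) {
      gt <- data.frame(onset = numeric(0), duration = numeric(0),
                       freq = numeric(0), state = character(0),
                       areas = character(0), delay = numeric(0))
    }
    structure(
      list(sources = sources, bursts = gt, hypnogram = h, params = params,
           montage = montage, fs = fs, n = n, seed = seed),
      class = "source_ensemble"
    )
  })
}

#' @export
print.source_ensemble <- function(x, ...) {
  cat(sprintf("<source_ensemble> %d sources, %d scheduled events, %.0f s at %g Hz\n",
              length(x$sources), nrow(x$bursts), x$n / x$fs, x$fs))
  invisible(x)
}
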