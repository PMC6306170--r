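#' Render a source ensemble into a recording session
#'
#' Every electrode trace is the superposition, over sources, of the ohmic
#' point-source potential times the source waveform:
#' `V_e(t) = sum_s I_s / (4 pi sigma d(e, s)) * w_s(t)`. Five electrode
#' channels are rendered (`CA1_e1`, `CA1_e2`, `PFC_e1`, `PFC_e2`, `REF`)
#' plus a state-gated broadband `EMG` channel that bypasses the forward
#' model. Referential (RR) and differential (DR) channels are derived, not
#' stored: `CA1_RR = CA1_e1 - REF`, `CA1_DR = CA1_e1 - CA1_e2` (likewise
#' PFC); see [channel_trace()]. Traces are in microvolts.
#'
#' @param ensemble A [build_sources()] result.
#' @param montage,medium Defaults taken from the ensemble.
#' @param seed Seed for the EMG noise; defaults to the ensemble seed.
#' @return An object of class `lfp_session`.
#' @export
render <- function(ensemble, montage = ensemble$montage,
                   medium = ensemble$params$medium,
                   seed = ensemble$seed) {
  stopifnot(inherits(ensemble, "source_ensemble"),
            inherits(montage, "electrode_montage"))
  fs <- ensemble$fs
  n <- ensemble$n
  check_reference_distality(montage, ensemble$sources)

  electrodes <- list()
  for (nm in names(montage$pairs)) {
    ep <- electrode_positions(montage$pairs[[nm]])
    electrodes[[paste0(nm, "_e1")]] <- ep["e1", ]
    electrodes[[paste0(nm, "_e2")]] <- ep["e2", ]
  }
  electrodes[["REF"]] <- montage$reference

  traces <- matrix(0, nrow = n, ncol = length(electrodes) + 1L,
                   dimnames = list(NULL, c(names(electrodes), "EMG")))
  for (src in ensemble$sources) {
    w <- src$waveform
    if (is.null(w)) w <- rep(1, n)
    if (length(w) != n) {
      stop("source waveform length does not match the session length",
           call. = FALSE)
    }
    for (enm in names(electrodes)) {
      d <- vnorm(electrodes[[enm]] - src$position)
      if (d < .Machine$double.eps) {
        stop(sprintf("source '%s' coincides with electrode %s", src$role, enm),
             call. = FALSE)
      }
      gain_uv <- src$amplitude / (4 * pi * medium$conductivity * d) * 1e6
      traces[, enm] <- traces[, enm] + gain_uv * w
    }
  }

  emg_levels <- ensemble$params$emg_rms
  emg_gain <- numeric(n)
  for (st in names(emg_levels)) {
    emg_gain <- emg_gain + emg_levels[[st]] *
      state_mask(ensemble$hypnogram, st, fs, n, ramp = 1)
  }
  traces[, "EMG"] <- with_seed(derive_seed(seed, "emg"),
                               stats::rnorm(n)) * emg_gain

  structure(
    list(traces = traces, fs = fs, montage = montage, medium = medium,
         hypnogram = ensemble$hypnogram, bursts = ensemble$bursts,
         params = ensemble$params, seed = ensemble$seed),
    class = "lfp_session"
  )
}

#' Simulate a full session in one call
#'
#' Convenience wrapper: [build_hypnogram()] (unless one is supplied) ->
#' [build_sources()] -> [render()].
#'
#' @param params A [source_params()].
#' @param montage An [electrode_montage()].
#' @param hypnogram Optional [hypnogram()]; built from `...` defaults
#'   otherwise.
#' @param seed Integer master seed (hypnogram, sources and EMG derive
#'   child seeds from it).
#' @param n_wake,n_nrem,n_rem,epoch_length Passed to [build_hypnogram()]
#'   when `hypnogram` is NULL.
#' @return An `lfp_session`.
#' @export
simulate_session <- function(params = source_params(),
                             montage = default_montage(),
                             hypnogram = NULL, seed = 1,
                             n_wake = 55, n_nrem = 195, n_rem = 110,
                             epoch_length = 15) {
  if (is.null(hypnogram)) {
    hypnogram <- build_hypnogram(n_wake, n_nrem, n_rem, epoch_length,
                                 seed = derive_seed(seed, "hypnogram"))
  }
  ens <- build_sources(hypnogram, params, montage,
                       seed = derive_seed(seed, "sources"))
  render(ens, seed = derive_seed(seed, "render"))
}

#' Extract a stored or derived channel
#'
#' Stored channels are the five electrodes plus EMG; derived channels are
#' the referential (`<area>_RR = <area>_e1 - REF`) and differential
#' (`<area>_DR = <area>_e1 - <area>_e2`) montages recomputed on the fly.
#'
#' @param session An `lfp_session`.
#' @param channel Channel name, e.g. `"CA1_e1"`, `"CA1_RR"`, `"PFC_DR"`,
#'   `"EMG"`.
#' @return Numeric vector, microvolts.
#' @export
channel_trace <- function(session, channel) {
  stopifnot(inherits(session, "lfp_session"))
  tr <- session$traces
  if (channel %in% colnames(tr)) return(tr[, channel])
  m <- regmatches(channel, regexec("^([A-Za-z0-9]+)_(RR|DR)$", channel))[[1]]
  if (length(m) == 3) {
    area <- m[2]
    e1 <- paste0(area, "_e1")
    if (!e1 %in% colnames(tr)) {
      stop(sprintf("unknown area '%s'", area), call. = FALSE)
    }
    if (m[3] == "RR") return(tr[, e1] - tr[, "REF"])
    return(tr[, e1] - tr[, paste0(area, "_e2")])
  }
  stop(sprintf("unknown channel '%s'", channel), call. = FALSE)
}

#' Session duration in seconds
#' @param session An `lfp_session`.
#' @export
session_duration <- function(session) {
  nrow(session$traces) / session$fs
}

#' @export
print.lfp_session <- function(x, ...) {
  st <- table(x$hypnogram$state)
  cat(sprintf("<lfp_session> %.0f s at %g Hz, %d stored channels\n",
              session_duration(x), x$fs, ncol(x$traces)))
  cat("  epochs:", paste(sprintf("%s=%d", names(st), st), collapse = ", "),
      "\n")
  cat(sprintf("  ground-truth events: %d\n", nrow(x$bursts)))
  invisible(x)
}
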