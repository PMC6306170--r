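#' Pipeline configuration
#'
#' A fully serialisable (plain lists and numerics, YAML round-trippable)
#' configuration for the end-to-end pipeline: generator parameters,
#' hypnogram epoch counts, estimator parameters, detection band and the
#' master seed. One global seed is expanded into per-stage child seeds
#' deterministically, so a stored config reproduces every output.
#'
#' @param seed Master seed (integer).
#' @param n_wake,n_nrem,n_rem,epoch_length Hypnogram composition.
#' @param generator Named list overriding [source_params()] defaults.
#' @param band Burst-detection band, Hz.
#' @param coherence_segment_s,coherence_overlap Sliding-window coherence
#'   estimator parameters.
#' @param noise_levels Abscissae of the coherence-vs-noise curve.
#' @param noise_segments Segments averaged per noise level.
#' @param out_dir Optional output directory; NULL keeps everything in
#'   memory.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, n_wake = 55, n_nrem = 195,
                            n_rem = 110, epoch_length = 15,
                            generator = list(), band = c(10, 14),
                            coherence_segment_s = 5,
                            coherence_overlap = 0.5,
                            noise_levels = c(1, 2, 5, 10, 15, 20, 30),
                            noise_segments = 2000,
                            out_dir = NULL) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Save / load a pipeline configuration as YAML
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `save_config` returns `path` invisibly; `load_config` returns a
#'   `pipeline_config`.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- do.call(pipeline_config, raw[setdiff(names(raw), "")])
  cfg
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline on a generated session
#'
#' Chains every stage of the montage comparison on one synthetic session:
#' simulate -> score -> state spectra (RR vs DR) -> sliding-window coherence
#' (NREM and REM) -> spectrogram summary -> burst detection ->
#' burst-triggered coherence and imaginary coherence -> lag distributions
#' (RR vs DR) -> coherence-vs-noise curve with sech fit -> montage theory
#' table. Returns a nested report of scalar results; when
#' `config$out_dir` is set, also writes the session (EDF + sidecars), the
#' per-stage CSV curves and the JSON report there.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_report`.
#' @export
run_all <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  t0 <- Sys.time()
  log_stage <- function(name) {
    message(sprintf("[lfpvc %6.1fs] %s",
                    as.numeric(difftime(Sys.time(), t0, units = "secs")),
                    name))
  }

  log_stage("simulate")
  params <- run_stage("simulate",
                      do.call(source_params, config$generator))
  session <- run_stage("simulate", simulate_session(
    params = params, seed = seed,
    n_wake = config$n_wake, n_nrem = config$n_nrem, n_rem = config$n_rem,
    epoch_length = config$epoch_length))

  log_stage("score")
  scored <- run_stage("score", score_session(session))
  agreement <- hypnogram_agreement(scored, session$hypnogram)

  log_stage("spectra")
  spectra <- run_stage("spectra", {
    st <- list()
    for (state in intersect(c("NREM", "REM"), session$hypnogram$state)) {
      for (area in c("CA1", "PFC")) {
        for (mode in c("RR", "DR")) {
          ps <- state_spectrum(session, state, mode, area,
                               segment_s = config$coherence_segment_s,
                               overlap = config$coherence_overlap)
          sel <- ps$freq > 0.5 & ps$freq <= 30
          st[[paste(state, area, mode, sep = "_")]] <- list(
            total_power = band_power(ps, c(0.5, 100)),
            peak_freq = ps$freq[sel][which.max(ps$power[sel])]
          )
        }
      }
    }
    st
  })
  rr_dr_ratio_rem <- if ("REM_CA1_RR" %in% names(spectra)) {
    spectra$REM_CA1_RR$total_power / spectra$REM_CA1_DR$total_power
  } else NA_real_

  log_stage("coherence")
  coherence <- run_stage("coherence", {
    out <- list()
    for (state in intersect(c("NREM", "REM"), session$hypnogram$state)) {
      for (mode in c("RR", "DR")) {
        cs <- state_msc(session, state, mode,
                        segment_s = config$coherence_segment_s,
                        overlap = config$coherence_overlap)
        sel <- cs$freq > 0.5 & cs$freq <= 30
        out[[paste(state, mode, sep = "_")]] <- list(
          peak_freq = cs$freq[sel][which.max(cs$coherence[sel])],
          peak_coherence = max(cs$coherence[sel]),
          band_mean = mean(cs$coherence[cs$freq >= config$band[1] &
                                          cs$freq <= config$band[2]])
        )
      }
    }
    out
  })

  log_stage("events")
  rem_epochs <- if ("REM" %in% session$hypnogram$state) {
    epochize(session, "REM")
  } else NULL
  bursts_ca1 <- run_stage("events", {
    if (is.null(rem_epochs)) {
      empty_bursts(config$band, NA_real_)
    } else {
      detect_bursts(channel_trace(session, "CA1_DR"), session$fs,
                    band = config$band, epochs = rem_epochs)
    }
  })
  truth_rem <- session$bursts[session$bursts$state == "REM", , drop = FALSE]
  detection <- if (nrow(truth_rem) > 0) {
    match_events(bursts_ca1, truth_rem)
  } else list(sensitivity = NA_real_, precision = NA_real_,
              n_detected = nrow(bursts_ca1), n_true = 0)

  log_stage("burst-triggered coherence")
  btc <- run_stage("burst_coherence", {
    if (nrow(bursts_ca1) >= 2) {
      band_val <- function(cs) {
        mean(cs$coherence[cs$freq >= config$band[1] &
                            cs$freq <= config$band[2]])
      }
      list(
        dr = band_val(burst_triggered_coherence(session, bursts_ca1,
                                                "CA1", "DR")),
        rr = band_val(burst_triggered_coherence(session, bursts_ca1,
                                                "CA1", "RR")),
        ic_rr_theta = {
          ic <- state_msc(session, "REM", "RR", variant = "imaginary",
                          segment_s = config$coherence_segment_s,
                          overlap = config$coherence_overlap)
          ms <- state_msc(session, "REM", "RR",
                          segment_s = config$coherence_segment_s,
                          overlap = config$coherence_overlap)
          sel <- which.min(abs(ic$freq - params$theta_freq))
          list(msc = ms$coherence[sel], ic = ic$coherence[sel])
        }
      )
    } else NULL
  })

  log_stage("lags")
  lag <- run_stage("lags", {
    if (nrow(bursts_ca1) >= 2) {
      dr <- lag_distribution(session, bursts_ca1, "DR", band = config$band)
      rr <- lag_distribution(session, bursts_ca1, "RR", band = config$band)
      list(dr_median_s = dr$median_lag, dr_sd_s = dr$sd_lag,
           rr_median_s = rr$median_lag, rr_sd_s = rr$sd_lag,
           n_events = dr$n_events)
    } else NULL
  })

  log_stage("snr curve")
  curve <- run_stage("snr_curve", coherence_vs_noise(
    config$noise_levels, n_segments = config$noise_segments,
    seed = derive_seed(seed, "snr_curve")))
  fit <- fit_sech(curve)

  theory <- theory_table()

  report <- structure(list(
    schema_version = "1.0",
    seed = seed,
    epochs = as.list(table(session$hypnogram$state)),
    scoring_agreement = agreement,
    spectra = spectra,
    rr_dr_power_ratio_rem = rr_dr_ratio_rem,
    coherence = coherence,
    detection = detection,
    burst_triggered = btc,
    lags = lag,
    snr_curve = list(noise_sd = curve$noise_sd,
                     coherence = curve$coherence,
                     sech_a = fit$a,
                     sech_residual_rms = fit$residual_rms),
    theory = theory
  ), class = "pipeline_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    run_stage("write", {
      write_session(session, file.path(config$out_dir, "session"))
      utils::write.csv(curve, file.path(config$out_dir, "snr_curve.csv"),
                       row.names = FALSE)
      utils::write.csv(bursts_ca1, file.path(config$out_dir, "bursts.csv"),
                       row.names = FALSE)
      writeLines(report_json(report),
                 file.path(config$out_dir, "report.json"))
    })
  }
  report
}

#' Serialise a pipeline report to JSON
#'
#' Deterministic: identical reports give byte-identical JSON, so a stored
#' config + seed reproduces the file exactly.
#'
#' @param report A [run_all()] report.
#' @return A JSON string.
#' @export
report_json <- function(report) {
  as.character(jsonlite::toJSON(unclass(report), auto_unbox = TRUE,
                                digits = NA, dataframe = "columns"))
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(sprintf("  scoring agreement: %.3f\n", x$scoring_agreement))
  cat(sprintf("  RR/DR REM power ratio: %.2f\n", x$rr_dr_power_ratio_rem))
  if (!is.null(x$lags)) {
    cat(sprintf("  DR median lag: %.1f ms, RR median lag: %.1f ms\n",
                1000 * x$lags$dr_median_s, 1000 * x$lags$rr_median_s))
  }
  cat(sprintf("  sech scale a: %.4f\n", x$snr_curve$sech_a))
  invisible(x)
}
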