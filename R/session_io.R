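#' Write a session to disk (EDF + plain-text sidecars)
#'
#' Traces go to `session.edf` (16-bit, one-second records, microvolts), the
#' hypnogram to `hypnogram.csv` (columns `start_s,duration_s,state`) and the
#' ground truth (burst schedule, generator parameters, montage, seed) to
#' `ground_truth.json`.
#'
#' @param session An `lfp_session`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "lfp_session"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_edf(session$traces, session$fs, file.path(dir, "session.edf"))

  h <- session$hypnogram
  utils::write.csv(
    data.frame(start_s = h$start, duration_s = h$duration, state = h$state),
    file.path(dir, "hypnogram.csv"), row.names = FALSE
  )

  mt <- session$montage
  gt <- list(
    seed = session$seed,
    fs = session$fs,
    bursts = session$bursts,
    params = session$params[!vapply(session$params, is.object, logical(1))],
    conductivity = session$medium$conductivity,
    montage = list(
      reference = mt$reference,
      pairs = lapply(mt$pairs, function(p) {
        list(midpoint = p$midpoint, axis = p$axis,
             half_separation = p$half_separation)
      })
    )
  )
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a session written by [write_session()]
#'
#' Traces are recovered to within the 16-bit quantization step. If the
#' hypnogram or ground-truth sidecar is missing, a warning is emitted and
#' the session is returned without the corresponding metadata.
#'
#' @param dir Directory containing `session.edf` and its sidecars.
#' @return An `lfp_session` (with empty hypnogram/ground truth if sidecars
#'   are missing).
#' @export
read_session <- function(dir) {
  edf_path <- file.path(dir, "session.edf")
  if (!file.exists(edf_path)) {
    stop(sprintf("no session.edf in '%s'", dir), call. = FALSE)
  }
  edf <- read_edf(edf_path)

  hyp_path <- file.path(dir, "hypnogram.csv")
  h <- NULL
  if (file.exists(hyp_path)) {
    hd <- utils::read.csv(hyp_path, stringsAsFactors = FALSE)
    h <- hypnogram(hd$start_s, hd$duration_s, hd$state)
  } else {
    warning("hypnogram.csv missing: session has no state labels",
            call. = FALSE)
  }

  gt_path <- file.path(dir, "ground_truth.json")
  bursts <- NULL
  seed <- NA_integer_
  montage <- NULL
  medium_obj <- medium()
  params <- NULL
  if (file.exists(gt_path)) {
    gt <- jsonlite::read_json(gt_path, simplifyVector = TRUE)
    bursts <- as.data.frame(gt$bursts)
    seed <- gt$seed
    medium_obj <- medium(gt$conductivity)
    montage <- electrode_montage(
      pairs = lapply(gt$montage$pairs, function(p) {
        electrode_pair(p$midpoint, p$axis, p$half_separation)
      }),
      reference = gt$montage$reference
    )
    params <- gt$params
  } else {
    warning("ground_truth.json missing: session has no ground truth",
            call. = FALSE)
  }

  if (is.null(bursts) || nrow(bursts) == 0) {
    bursts <- data.frame(onset = numeric(0), duration = numeric(0),
                         freq = numeric(0), state = character(0),
                         areas = character(0), delay = numeric(0))
  }
  structure(
    list(traces = edf$traces, fs = edf$fs, montage = montage,
         medium = medium_obj, hypnogram = h, bursts = bursts,
         params = params, seed = seed),
    class = "lfp_session"
  )
}
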