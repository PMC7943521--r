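#' Pipeline configuration
#'
#' Bundles every tunable of the formants-to-parameters pipeline: the
#' acoustic-to-kinematic map (`alpha` 0.3 and `k` 0.04 mm/Hz by default,
#' the values used for continuous-speech analysis), the resampling step
#' (0.01 s), the extraction settings, evaluation flags and synthesis
#' settings.  Fully serializable to JSON.
#'
#' @param alpha,k map literals (ignored when `anchors` is supplied).
#' @param anchors optional named list `f1a, f1i, f2i, f2u` (Hz).
#' @param L2 /i/-/u/ kinematic distance, mm (with `anchors`).
#' @param dt resampling step, s.
#' @param smooth zero-phase low-pass before differentiation.
#' @param extraction an [extraction_config()].
#' @param conventional_means see [derived_parameters()].
#' @param support_level stroke support level for phoneme matching.
#' @param synthesis a [synth_config()].
#' @param seed integer master seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(alpha = 0.3, k = 0.04, anchors = NULL, L2 = NULL,
                            dt = 0.01, smooth = FALSE,
                            extraction = extraction_config(),
                            conventional_means = FALSE, support_level = 0.05,
                            synthesis = synth_config(), seed = 1L) {
  structure(list(alpha = alpha, k = k, anchors = anchors, L2 = L2, dt = dt,
                 smooth = smooth, extraction = extraction,
                 conventional_means = conventional_means,
                 support_level = support_level, synthesis = synthesis,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

config_json <- function(config) {
  jsonlite::toJSON(unclass_recursive(config), digits = NA, auto_unbox = TRUE,
                   null = "null")
}

unclass_recursive <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    lapply(x, unclass_recursive)
  } else x
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(as.character(config_json(config)), f)
  unname(tools::md5sum(f))
}

#' Run the full formants-to-parameters pipeline
#'
#' Resamples and gap-fills the formant track, maps it to a kinematic
#' trajectory, differentiates, extracts lognormal strokes, and computes the
#' derived neuromotor parameters; when a segmentation is supplied, the
#' lognormal-phoneme match report and timing error are added.
#'
#' @param track a [formant_track()] or path to a track file.
#' @param config a [pipeline_config()].
#' @param segmentation optional [phoneme_segmentation()] or path.
#' @param quiet suppress the run log line.
#' @return A list of class `pipeline_report`: `nblog`, `snr`, `strokes`,
#'   `derived`, `match` (or `NULL`), `alpha`, `k`, `dt`, `seed`,
#'   `config_hash`.
#' @export
run_pipeline <- function(track, config = pipeline_config(),
                         segmentation = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(track)) track <- read_formant_track(track)
  if (is.character(segmentation)) segmentation <- read_segmentation(segmentation)
  params <- kinematic_map_params(alpha = config$alpha, k = config$k,
                                 anchors = config$anchors, L2 = config$L2)
  track <- interpolate_gaps(track)
  track <- resample_track(track, dt = config$dt)
  vel <- kinematic_speed(track, params, smooth = config$smooth)
  fit <- extract_strokes(vel, config$extraction)
  derived <- derived_parameters(fit$strokes, snr = fit$snr,
                                conventional_means = config$conventional_means)
  match <- NULL
  if (!is.null(segmentation) && nrow(fit$strokes) >= 1L)
    match <- match_phonemes(fit$strokes, segmentation,
                            level = config$support_level)
  hash <- config_hash(config)
  if (!quiet)
    message(sprintf("pipeline: config=%s seed=%d NbLog=%d SNR=%.2f dB",
                    hash, config$seed, derived$nblog, fit$snr))
  structure(list(nblog = derived$nblog, snr = fit$snr, strokes = fit$strokes,
                 derived = derived, match = match, alpha = params$alpha,
                 k = params$k, dt = config$dt, seed = config$seed,
                 config_hash = hash, converged = fit$converged),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> NbLog = %d, SNR = %.2f dB (alpha = %g, k = %g)\n",
              x$nblog, x$snr, x$alpha, x$k))
  print(x$derived)
  if (!is.null(x$match)) print(x$match)
  invisible(x)
}

#' Serialize a pipeline report to JSON
#'
#' Deterministic JSON (no timestamps): identical input, configuration and
#' seed produce byte-identical files.
#'
#' @param report a `pipeline_report` from [run_pipeline()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "pipeline_report"))
  out <- list(nblog = report$nblog,
              snr = report$snr,
              converged = report$converged,
              alpha = report$alpha, k = report$k, dt = report$dt,
              seed = report$seed, config_hash = report$config_hash,
              derived = unclass_recursive(report$derived)[
                c("mean_dt0", "mean_vp", "mean_mu", "mean_sigma", "mean_D",
                  "nblog", "snr", "flags")],
              strokes = report$strokes)
  if (!is.null(report$match))
    out$match <- list(tpr = report$match$tpr, tnr = report$match$tnr,
                      eps_t = report$match$eps_t, np = report$match$np,
                      table = report$match$table)
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE,
                       null = "null", na = "string")
  invisible(path)
}
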