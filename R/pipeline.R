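# Cohort drivers binding the asymmetry measures to the regression and ISL
# stages. Bent postures (Adam's, selected forward frame) are realigned to the
# patient frame with realign_sagittal() before index/map computation, since
# the vertical crop and the 17-band segmentation act along the cranial-caudal
# axis.

#' Compute the five posture asymmetry measurements of one subject
#'
#' Runs the full measurement battery: upright asymmetry index, upright
#' asymmetry map (overall index), Adam's forward bending test index, bending
#' forward index (least-inclined frame of the sequence, realigned), and the
#' lateral-bending index. The asymmetry map of the realigned forward frame is
#' returned as well, since its coronal asymmetry differences drive the ISL
#' estimate.
#'
#' @param subject a `synthetic_subject` from [make_subject()], or a bundle
#'   list from [read_subject_bundle()].
#' @param cfg an [analysis_config].
#' @param frames frames per generated dynamic sequence (synthetic subjects
#'   only).
#' @return List with `indices` (named numeric: upright_index, upright_map,
#'   adams, forward, lateral, mm), `forward_map` (the forward-bending
#'   [asymmetry_map()] result), and `results` (the per-posture
#'   [asymmetry_result] objects).
#' @export
measure_subject <- function(subject, cfg = analysis_config(), frames = 6) {
  if (inherits(subject, "synthetic_subject")) {
    adams <- make_adams_scan(subject)
    fwd <- make_forward_sequence(subject, frames)
    lat_l <- make_lateral_sequence(subject, "left", frames)
    lat_r <- make_lateral_sequence(subject, "right", frames)
    subject <- list(scan = subject$scan, spl = subject$spl,
                    landmarks = subject$landmarks, adams = adams,
                    forward = fwd, lateral_left = lat_l, lateral_right = lat_r)
  }
  res <- list()
  res$upright_index <- asymmetry_index(subject$scan, subject$spl, cfg,
                                       posture = "upright")
  res$upright_map <- asymmetry_map(subject$scan, subject$spl, cfg,
                                   posture = "upright")
  ad <- realign_sagittal(subject$adams$scan, subject$adams$spl)
  res$adams <- asymmetry_index(ad$scan, ad$spl, cfg, posture = "adams")
  fi <- select_least_inclined_frame(subject$forward$sequence)
  fw <- realign_sagittal(subject$forward$sequence$scans[[fi]],
                         subject$forward$spls[[fi]])
  res$forward <- asymmetry_index(fw$scan, fw$spl, cfg, posture = "forward")
  forward_map <- asymmetry_map(fw$scan, fw$spl, cfg, posture = "forward")
  res$lateral <- lateral_bending_index(
    subject$lateral_left$sequence, subject$lateral_right$sequence,
    subject$lateral_left$spls, subject$lateral_right$spls,
    subject$landmarks, cfg)
  list(indices = vapply(res, function(r) r$index, numeric(1)),
       forward_map = forward_map,
       results = res)
}

#' Tabulate asymmetry measurements over a cohort
#'
#' @param subjects list of `synthetic_subject`s (or bundle lists with a
#'   `true_cobb` element).
#' @param cfg an [analysis_config].
#' @param frames frames per generated dynamic sequence.
#' @return A data.frame with columns `true_cobb`, `upright_index`,
#'   `upright_map`, `adams`, `forward`, `lateral`; the per-subject
#'   measurement lists are attached as attribute `"measurements"`.
#' @export
cohort_index_table <- function(subjects, cfg = analysis_config(),
                               frames = 6) {
  meas <- lapply(subjects, measure_subject, cfg = cfg, frames = frames)
  tbl <- data.frame(
    true_cobb = vapply(subjects, function(s)
      if (!is.null(s$true_cobb)) s$true_cobb else NA_real_, numeric(1)),
    do.call(rbind, lapply(meas, function(m) m$indices)))
  attr(tbl, "measurements") <- meas
  tbl
}

#' Fit the per-posture index-to-Cobb regressions of a cohort
#'
#' @param tbl a [cohort_index_table()] data.frame with a reference Cobb
#'   column.
#' @param rca_column name of the reference Cobb column (default
#'   `"true_cobb"`; use the radiographic rCA column for clinical tables).
#' @return Named list of `regression_model`s, one per posture.
#' @export
fit_cohort_models <- function(tbl, rca_column = "true_cobb") {
  postures <- c("upright_index", "upright_map", "adams", "forward", "lateral")
  missing <- setdiff(c(postures, rca_column), names(tbl))
  if (length(missing))
    bs_stop("invalid_input", paste0("table lacks column(s): ",
                                    paste(missing, collapse = ", ")))
  setNames(lapply(postures, function(p)
    fit_index_regression(tbl[[p]], tbl[[rca_column]], posture = p)), postures)
}

#' Predict weighted combined Cobb estimates (eCA) for a cohort
#'
#' Applies each posture's regression to its index column and combines the
#' per-posture predictions with the configured weights.
#'
#' @param tbl a [cohort_index_table()] data.frame.
#' @param models per-posture models from [fit_cohort_models()].
#' @param cfg an [analysis_config].
#' @return Numeric vector of combined estimates in degrees, one per row.
#' @export
predict_cohort_eca <- function(tbl, models, cfg = analysis_config()) {
  vapply(seq_len(nrow(tbl)), function(i) {
    est <- lapply(names(models), function(p)
      predict_cobb(models[[p]], tbl[[p]][i]))
    names(est) <- names(models)
    combine_estimates(est, cfg)$angle
  }, numeric(1))
}

#' Serialize fitted regression models to JSON
#'
#' @param models named list of `regression_model`s.
#' @return JSON string.
#' @export
models_to_json <- function(models) {
  jsonlite::toJSON(lapply(models, function(m)
    list(posture = m$posture, slope = m$slope, intercept = m$intercept,
         n = m$n, residual_sd = m$residual_sd)),
    auto_unbox = TRUE, digits = NA)
}

#' Read regression models from JSON
#'
#' @param path JSON file written with [models_to_json()].
#' @return Named list of `regression_model`s.
#' @export
models_from_json <- function(path) {
  raw <- jsonlite::read_json(path)
  lapply(raw, function(m)
    structure(list(posture = m$posture, slope = m$slope,
                   intercept = m$intercept, n = m$n,
                   residual_sd = m$residual_sd),
              class = "regression_model"))
}
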