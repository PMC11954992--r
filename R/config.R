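#' Analysis configuration
#'
#' Collects every tunable constant of the back-shape pipeline. Defaults follow
#' the clinical protocol: arm/border cropping at the 0.1 and 0.9 lateral
#' quantiles with a 75% border factor, 17 vertical regions for the asymmetry
#' map, and posture weights 4 (bending forward), 3 (Adam's forward bending
#' test), 2 (upright asymmetry map), 1 (upright asymmetry index), 1 (lateral
#' bending) for the combined Cobb estimate.
#'
#' @param q_low,q_high lateral quantiles used by the border crop
#'   (defaults 0.1 / 0.9). Quantiles are computed by linear interpolation
#'   between order statistics (type 7); the chosen estimator is part of the
#'   contract because it fixes the crop boundary.
#' @param border_factor fraction of the minimum SPL-to-quantile distance kept
#'   by the border crop (default 0.75).
#' @param n_regions number of uniform vertical bands of the asymmetry map
#'   (default 17, one per vertebra C7-L5).
#' @param icp_max_iterations,icp_tolerance ICP stopping rule: maximum
#'   iterations and minimum RMSE change in mm between iterations.
#' @param weights named numeric posture weights for [combine_estimates()].
#'   Names: forward, adams, upright_map, upright_index, lateral.
#' @param isl_gain SPL-to-ISL adjustment gain in mm of coronal correction per
#'   mm of coronal asymmetry difference; calibrate with [calibrate_isl_gain()].
#' @param depthmap_resolution coronal depth-map pixel size in mm.
#' @param max_shift_segments maximum vertical shift (in 17th-segment units)
#'   allowed by [shifted_shape_correlation()] (default 2).
#' @param map_refine_from_global if `TRUE` the per-segment ICP of the
#'   asymmetry map starts from the whole-cloud-registered state; if `FALSE`
#'   (default) each segment pair is registered independently from the
#'   unregistered mirrored cloud, with centroid pre-alignment. The default
#'   avoids a failure mode of whole-cloud pre-registration on strongly
#'   curved spines, where the global ICP rotates the mirrored S-shape onto
#'   the original (a genuinely lower whole-cloud RMSE) and thereby corrupts
#'   every segment residual.
#' @param random_seed integer seed recorded with results for reproducibility.
#' @return An object of class `analysis_config` (a named list).
#' @examples
#' cfg <- analysis_config(icp_tolerance = 1e-5)
#' cfg$weights
#' @export
analysis_config <- function(q_low = 0.1, q_high = 0.9,
                            border_factor = 0.75,
                            n_regions = 17L,
                            icp_max_iterations = 50L,
                            icp_tolerance = 1e-4,
                            weights = c(forward = 4, adams = 3,
                                        upright_map = 2, upright_index = 1,
                                        lateral = 1),
                            isl_gain = 1,
                            depthmap_resolution = 2,
                            max_shift_segments = 2L,
                            map_refine_from_global = FALSE,
                            random_seed = 1L) {
  cfg <- list(q_low = q_low, q_high = q_high, border_factor = border_factor,
              n_regions = as.integer(n_regions),
              icp_max_iterations = as.integer(icp_max_iterations),
              icp_tolerance = icp_tolerance, weights = weights,
              isl_gain = isl_gain, depthmap_resolution = depthmap_resolution,
              max_shift_segments = as.integer(max_shift_segments),
              map_refine_from_global = isTRUE(map_refine_from_global),
              random_seed = as.integer(random_seed))
  validate_config(cfg)
  structure(cfg, class = "analysis_config")
}

validate_config <- function(cfg) {
  with(cfg, {
    if (!(q_low >= 0 && q_low < q_high && q_high <= 1))
      bs_stop("invalid_input", "need 0 <= q_low < q_high <= 1")
    if (!(border_factor > 0 && border_factor <= 1))
      bs_stop("invalid_input", "border_factor must be in (0, 1]")
    if (n_regions < 1)
      bs_stop("invalid_input", "n_regions must be >= 1")
    if (icp_max_iterations < 1 || icp_tolerance < 0)
      bs_stop("invalid_input", "invalid ICP settings")
    if (max_shift_segments < 0)
      bs_stop("invalid_input", "max_shift_segments must be >= 0")
    needed <- c("forward", "adams", "upright_map", "upright_index", "lateral")
    if (!all(needed %in% names(weights)))
      bs_stop("invalid_input", "weights must name all five postures")
    if (any(weights <= 0))
      bs_stop("invalid_input", "all posture weights must be > 0")
  })
  invisible(cfg)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("analysis_config:\n")
  for (nm in setdiff(names(x), "weights"))
    cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  cat("  weights:", paste(names(x$weights), x$weights, sep = "=",
                          collapse = " "), "\n")
  invisible(x)
}
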