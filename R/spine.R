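#' Fit a per-posture index-to-Cobb regression
#'
#' Ordinary least squares of the radiographic Cobb angle (rCA, degrees) on
#' the asymmetry index (mm) of one posture, the calibration step that turns
#' asymmetry into a clinical angle.
#'
#' @param index numeric vector of asymmetry indices in mm (n >= 3, not all
#'   equal).
#' @param rca numeric vector of radiographic Cobb angles in degrees.
#' @param posture posture label stored with the model.
#' @return An object of class `regression_model` with fields `posture`,
#'   `slope` (deg/mm), `intercept` (deg), `n`, `residual_sd` (deg).
#' @export
fit_index_regression <- function(index, rca, posture = "upright_index") {
  if (length(index) != length(rca))
    bs_stop("invalid_input", "index and rca must have equal length")
  if (length(index) < 3)
    bs_stop("invalid_input", "need at least 3 training pairs")
  if (!all(is.finite(index)) || !all(is.finite(rca)))
    bs_stop("invalid_input", "training pairs must be finite")
  if (sd(index) == 0)
    bs_stop("invalid_input", "degenerate predictor: all indices equal")
  fit <- lm(rca ~ index)
  # exact training relations are legitimate; silence the perfect-fit note
  res_sd <- suppressWarnings(summary(fit)$sigma)
  structure(list(posture = posture,
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 n = length(index),
                 residual_sd = res_sd),
            class = "regression_model")
}

#' @export
print.regression_model <- function(x, ...) {
  cat(sprintf(
    "regression_model (%s): Cobb = %.3f deg/mm * index + %.3f deg (n = %d, residual sd %.3f deg)\n",
    x$posture, x$slope, x$intercept, x$n, x$residual_sd))
  invisible(x)
}

#' Predict a Cobb angle from an asymmetry index
#'
#' @param model a `regression_model` from [fit_index_regression()].
#' @param index asymmetry index in mm.
#' @return An object of class `cobb_estimate`: list with `angle` (degrees),
#'   `posture`, `weight` (filled by [combine_estimates()], `NA` here).
#' @export
predict_cobb <- function(model, index) {
  if (!inherits(model, "regression_model"))
    bs_stop("invalid_input", "model must be a regression_model")
  structure(list(angle = model$slope * index + model$intercept,
                 posture = model$posture, weight = NA_real_),
            class = "cobb_estimate")
}

#' @export
print.cobb_estimate <- function(x, ...) {
  cat(sprintf("cobb_estimate (%s): %.2f deg%s\n", x$posture, x$angle,
              if (is.finite(x$weight)) sprintf(" [weight %g]", x$weight)
              else ""))
  invisible(x)
}

#' Combine per-posture Cobb estimates into the weighted overall estimate
#'
#' The overall estimate eCA is the weighted mean of the available per-posture
#' estimates with weights 4 (forward), 3 (adams), 2 (upright_map),
#' 1 (upright_index), 1 (lateral) by default. Missing postures are excluded
#' and the weights renormalize over those present, so the result is always a
#' convex combination of the contributing angles.
#'
#' @param estimates named list of `cobb_estimate` objects or a named numeric
#'   vector of angles in degrees; names must be posture weight names.
#' @param cfg an [analysis_config] supplying `weights`.
#' @return A `cobb_estimate` with posture `"combined"`.
#' @export
combine_estimates <- function(estimates, cfg = analysis_config()) {
  if (length(estimates) < 1)
    bs_stop("invalid_input", "no estimates to combine")
  angles <- if (is.numeric(estimates)) estimates else
    vapply(estimates, function(e) e$angle, numeric(1))
  if (is.null(names(angles)) || any(names(angles) == ""))
    bs_stop("invalid_input", "estimates must be named by posture")
  bad <- setdiff(names(angles), names(cfg$weights))
  if (length(bad))
    bs_stop("invalid_input", paste0("unknown posture(s): ",
                                    paste(bad, collapse = ", ")))
  w <- cfg$weights[names(angles)]
  structure(list(angle = sum(w * angles) / sum(w), posture = "combined",
                 weight = sum(w)),
            class = "cobb_estimate")
}

#' Estimate the internal spinal alignment from SPL and asymmetry differences
#'
#' The manual SPL is the initial estimate of the ISL; its coronal curvature
#' is then adjusted with the coronal asymmetry differences of the
#' forward-bending asymmetry map. The differences are placed at the 17
#' region mid-heights of the SPL extent, linearly interpolated onto the SPL
#' y-stations, mean-centered (so the adjustment changes shape, not
#' position), scaled by `isl_gain`, and added to the SPL's x profile. The y
#' and z coordinates, sample count and ordering are untouched.
#'
#' @param spl the upright SPL [spinal_curve].
#' @param d numeric vector of `n_regions` coronal asymmetry differences in
#'   mm ([coronal_asymmetry_difference()] of the forward-bending map);
#'   missing entries are interpolated from their neighbors.
#' @param cfg an [analysis_config] supplying `isl_gain` and `n_regions`.
#' @return An object of class `isl_estimate`: list with `curve` (a
#'   [spinal_curve] with role ISL), `gain_used`, and `d_interpolated` (the
#'   centered per-station adjustment before scaling).
#' @export
estimate_isl <- function(spl, d, cfg = analysis_config()) {
  if (!inherits(spl, "spinal_curve") || curve_role(spl) != "SPL")
    bs_stop("invalid_input", "spl must be a spinal_curve with role SPL")
  if (length(d) != cfg$n_regions)
    bs_stop("invalid_input",
            sprintf("d must have %d entries", cfg$n_regions))
  adj <- centered_station_adjustment(spl, d, cfg$n_regions)
  m <- unclass(spl)[, 1:3, drop = FALSE]
  m[, 1] <- m[, 1] + cfg$isl_gain * adj
  structure(list(curve = spinal_curve(m, role = "ISL"),
                 gain_used = cfg$isl_gain, d_interpolated = adj),
            class = "isl_estimate")
}

# interpolate region-wise differences onto the SPL y-stations and center
centered_station_adjustment <- function(spl, d, n_regions) {
  if (all(is.na(d)))
    bs_stop("invalid_input", "all coronal asymmetry differences are missing")
  mid_rel <- (seq_len(n_regions) - 0.5) / n_regions  # 0 = C7, 1 = L5
  if (any(is.na(d)))  # fill missing regions from neighbors
    d <- approx(mid_rel[!is.na(d)], d[!is.na(d)], xout = mid_rel,
                rule = 2)$y
  y <- spl[, 2]
  rel <- (max(y) - y) / (max(y) - min(y))
  adj <- approx(mid_rel, d, xout = rel, rule = 2)$y
  adj - mean(adj)
}

#' @export
print.isl_estimate <- function(x, ...) {
  cat(sprintf("isl_estimate: %d samples, gain %.3f mm/mm\n",
              nrow(x$curve), x$gain_used))
  invisible(x)
}

#' Calibrate the SPL-to-ISL adjustment gain
#'
#' Least-squares gain minimizing the summed squared coronal residuals between
#' adjusted SPL and reference ISL over the training subjects:
#' `gain = sum(a * r) / sum(a^2)` where `a` is the centered interpolated
#' adjustment and `r` the coronal SPL-to-reference residual at the SPL
#' stations. The adjustment model itself (a single global gain on the
#' mean-centered differences) is this package's choice of the simplest
#' shape-only correction; the calibration makes it testable.
#'
#' @param training list of training subjects, each a list with elements
#'   `spl` ([spinal_curve], role SPL), `d` (n_regions coronal asymmetry
#'   differences), and `isl` (reference [spinal_curve], role ISL).
#' @param cfg an [analysis_config] supplying `n_regions`.
#' @return Scalar gain in mm of coronal correction per mm of asymmetry
#'   difference.
#' @export
calibrate_isl_gain <- function(training, cfg = analysis_config()) {
  if (length(training) < 1)
    bs_stop("invalid_input", "need at least one training subject")
  num <- 0
  den <- 0
  for (subj in training) {
    adj <- centered_station_adjustment(subj$spl, subj$d, cfg$n_regions)
    ref_x <- approx(subj$isl[, 2], subj$isl[, 1], xout = subj$spl[, 2],
                    rule = 2)$y
    r <- ref_x - subj$spl[, 1]
    num <- num + sum(adj * r)
    den <- den + sum(adj^2)
  }
  if (den == 0)
    bs_stop("invalid_input",
            "zero-variance asymmetry differences across all subjects")
  num / den
}

#' Cobb angle of a coronal curve
#'
#' Surrogate Cobb angle of a spinal curve when vertebral endplates are
#' unavailable: the curve is projected onto the coronal plane, tangent
#' inclinations are computed from central differences (one-sided at the
#' ends), and the angle is the maximum absolute difference between any two
#' tangent inclinations, in degrees. Used as the ground-truth angle of
#' synthetic subjects and as an evaluation utility.
#'
#' @param curve a [spinal_curve] with at least 5 samples.
#' @return Angle in degrees.
#' @export
cobb_from_curve <- function(curve) {
  if (!inherits(curve, "spinal_curve"))
    bs_stop("invalid_input", "curve must be a spinal_curve")
  n <- nrow(curve)
  if (n < 5)
    bs_stop("invalid_input", "need at least 5 samples")
  x <- curve[, 1]
  y <- curve[, 2]
  if (max(y) - min(y) <= 0)
    bs_stop("invalid_input", "degenerate curve: zero vertical extent")
  ip <- c(2:n, n)      # next sample (one-sided at caudal end)
  im <- c(1, 1:(n - 1))  # previous sample (one-sided at cranial end)
  slope <- (x[ip] - x[im]) / (y[ip] - y[im])
  theta <- atan(slope) * 180 / pi
  max(theta) - min(theta)
}
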