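#' Rigid transform
#'
#' A proper rigid-body transform: 3 x 3 rotation (orthonormal, det +1) plus a
#' translation in mm, applied as `p %*% t(rotation) + translation`.
#'
#' @param rotation 3 x 3 orthonormal matrix with determinant +1.
#' @param translation length-3 numeric vector (mm).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3, 3)))
    bs_stop("invalid_input", "rotation must be 3 x 3")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9)
    bs_stop("invalid_input",
            "rotation must be orthonormal with determinant +1")
  if (length(translation) != 3 || !all(is.finite(translation)))
    bs_stop("invalid_input", "translation must be a finite 3-vector")
  structure(list(rotation = rotation,
                 translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Apply a rigid transform to points
#'
#' @param transform a [rigid_transform].
#' @param points n x 3 matrix or [back_scan].
#' @return Object of the same type as `points`, transformed.
#' @export
apply_transform <- function(transform, points) {
  if (inherits(points, "back_scan")) {
    m <- as_xyz(points)
    return(back_scan(apply_transform(transform, m),
                     frame_time = attr(points, "frame_time")))
  }
  sweep(points %*% t(transform$rotation), 2, -transform$translation)
}

# t2 after t1 (i.e. compose(t2, t1) applies t1 first)
compose_transforms <- function(t2, t1) {
  rigid_transform(t2$rotation %*% t1$rotation,
                  as.numeric(t2$rotation %*% t1$translation) + t2$translation)
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid_transform:\n  rotation:\n")
  print(round(x$rotation, 6))
  cat("  translation (mm):", paste(round(x$translation, 4), collapse = ", "),
      "\n")
  invisible(x)
}

#' Directional nearest-neighbor RMSE between two clouds
#'
#' Root mean square of the distances from every point of `moving` to its
#' exact nearest neighbor in `fixed`. Directional (moving to fixed); this is
#' the residual the asymmetry indices report.
#'
#' @param moving,fixed [back_scan] objects or n x 3 matrices.
#' @return RMSE in mm.
#' @export
nearest_neighbor_rmse <- function(moving, fixed) {
  mm <- if (inherits(moving, "back_scan")) as_xyz(moving) else as.matrix(moving)
  fm <- if (inherits(fixed, "back_scan")) as_xyz(fixed) else as.matrix(fixed)
  if (nrow(mm) < 1 || nrow(fm) < 1)
    bs_stop("invalid_input", "both clouds must be non-empty")
  d <- cpp_kdtree_query(cpp_kdtree_build(fm), mm)$dist
  sqrt(mean(d^2))
}

# Closed-form least-squares rigid fit (Kabsch/SVD) of moving onto fixed for
# known correspondences (row i of moving matches row i of fixed). Reflection
# is corrected via the sign of det(V U'). Degenerate (collinear) geometry is
# reported as a registration failure.
kabsch_fit <- function(moving, fixed) {
  cm <- colMeans(moving)
  cf <- colMeans(fixed)
  H <- crossprod(sweep(moving, 2, cm), sweep(fixed, 2, cf))
  s <- svd(H)
  if (nrow(moving) >= 3 && s$d[2] <= 1e-12 * max(s$d[1], 1))
    bs_stop("registration_failure",
            "degenerate correspondence geometry (points nearly collinear)")
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  rigid_transform(R, cf - as.numeric(R %*% cm))
}

#' Point-to-point ICP rigid registration
#'
#' Aligns `moving` onto `fixed` by alternating exact nearest-neighbor
#' correspondence with a closed-form least-squares rigid fit (Kabsch/SVD),
#' until the nearest-neighbor RMSE changes by less than `icp_tolerance` or
#' `icp_max_iterations` is reached. Rigid only (no scaling), point-to-point,
#' no correspondence trimming: the cropping operations are the pipeline's
#' outlier control. The per-iteration RMSE is non-increasing, so the final
#' RMSE never exceeds the initial nearest-neighbor RMSE.
#'
#' @param moving,fixed [back_scan] objects with >= 3 non-collinear points.
#' @param cfg an [analysis_config] supplying the stopping rule.
#' @return An object of class `registration_result`: list with `transform`
#'   (cumulative [rigid_transform]), `rmse` (final nearest-neighbor RMSE,
#'   mm), `iterations`, `converged`, and `rmse_trace`.
#' @export
icp_align <- function(moving, fixed, cfg = analysis_config()) {
  mm <- if (inherits(moving, "back_scan")) as_xyz(moving) else as.matrix(moving)
  fm <- if (inherits(fixed, "back_scan")) as_xyz(fixed) else as.matrix(fixed)
  if (nrow(mm) < 3 || nrow(fm) < 3)
    bs_stop("invalid_input", "both clouds need at least 3 points")
  tree <- cpp_kdtree_build(fm)
  total <- rigid_transform()
  cur <- mm
  nn <- cpp_kdtree_query(tree, cur)
  rmse <- sqrt(mean(nn$dist^2))
  trace <- rmse
  converged <- FALSE
  iter <- 0L
  while (iter < cfg$icp_max_iterations) {
    iter <- iter + 1L
    step <- kabsch_fit(cur, fm[nn$index, , drop = FALSE])
    cur <- apply_transform(step, cur)
    total <- compose_transforms(step, total)
    nn <- cpp_kdtree_query(tree, cur)
    new_rmse <- sqrt(mean(nn$dist^2))
    trace <- c(trace, new_rmse)
    if (abs(rmse - new_rmse) < cfg$icp_tolerance) {
      rmse <- new_rmse
      converged <- TRUE
      break
    }
    rmse <- new_rmse
  }
  structure(list(transform = total, rmse = rmse, iterations = iter,
                 converged = converged, rmse_trace = trace),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf(
    "registration_result: RMSE %.4g mm after %d iteration(s)%s\n",
    x$rmse, x$iterations, if (x$converged) " (converged)" else ""))
  invisible(x)
}

#' Serialize a registration result to JSON
#'
#' @param result a `registration_result`.
#' @return JSON string (rotation row-major).
#' @export
registration_to_json <- function(result) {
  jsonlite::toJSON(list(
    rotation = as.numeric(t(result$transform$rotation)),
    translation = result$transform$translation,
    rmse = result$rmse,
    iterations = result$iterations,
    converged = result$converged
  ), auto_unbox = TRUE, digits = NA)
}
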