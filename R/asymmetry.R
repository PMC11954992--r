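#' Asymmetry measurement result
#'
#' Container for the scalar asymmetry index of a posture, optionally the
#' 2 x 17 asymmetry map it derives from, and per-stage diagnostics (point
#' counts after each crop, ICP iterations).
#'
#' @param index asymmetry index in mm (>= 0).
#' @param posture one of `"upright"`, `"adams"`, `"forward"`, `"lateral"`.
#' @param map an optional `asymmetry_map`.
#' @param diagnostics named list of per-stage diagnostics.
#' @return An object of class `asymmetry_result`.
#' @export
asymmetry_result <- function(index, posture, map = NULL, diagnostics = list()) {
  if (!is.finite(index) || index < 0)
    bs_stop("invalid_input", "asymmetry index must be finite and >= 0")
  posture <- match.arg(posture, c("upright", "adams", "forward", "lateral"))
  structure(list(index = index, posture = posture, map = map,
                 diagnostics = diagnostics),
            class = "asymmetry_result")
}

#' @export
print.asymmetry_result <- function(x, ...) {
  cat(sprintf("asymmetry_result (%s): index %.4g mm%s\n", x$posture, x$index,
              if (!is.null(x$map)) sprintf(", %d x 2 map",
                                           length(x$map$rmse_left)) else ""))
  invisible(x)
}

# shared preprocessing of every static asymmetry measure:
# mirror at the mean SPL -> vertical crop -> lateral quantile crop
mirror_and_crop <- function(scan, spl, cfg) {
  if (!inherits(spl, "spinal_curve") || curve_role(spl) != "SPL")
    bs_stop("invalid_input", "spl must be a spinal_curve with role SPL")
  x0 <- mean_spl_lateral(spl)
  mirrored <- mirror_about_axis(scan, x0)
  orig_v <- crop_vertical_extent(scan, spl)
  mirr_v <- crop_vertical_extent(mirrored, spl)
  orig_c <- crop_lateral_quantile(orig_v, x0, cfg)
  mirr_c <- crop_lateral_quantile(mirr_v, x0, cfg)
  list(fixed = orig_c, moving = mirr_c, x0 = x0,
       diagnostics = list(
         n_input = nrow(scan),
         n_after_vertical = c(original = nrow(orig_v), mirrored = nrow(mirr_v)),
         n_after_lateral = c(original = nrow(orig_c), mirrored = nrow(mirr_c)),
         mirror_x0 = x0))
}

#' Scalar asymmetry index of a posture
#'
#' The back-shape asymmetry surrogate for the Cobb angle: the scan is
#' duplicated and mirrored about the mean lateral location of the SPL, both
#' clouds are cropped to the SPL's vertical extent (C7-L5) and laterally by
#' the quantile border rule, the mirrored cloud is rigidly registered onto
#' the original by ICP, and the index is the final nearest-neighbor RMSE
#' between them. A perfectly bilaterally symmetric back scores 0.
#'
#' @param scan a [back_scan] in the patient frame.
#' @param spl the matching SPL [spinal_curve].
#' @param cfg an [analysis_config].
#' @param posture posture label stored with the result.
#' @return An [asymmetry_result] with `index` in mm.
#' @export
asymmetry_index <- function(scan, spl, cfg = analysis_config(),
                            posture = "upright") {
  prep <- mirror_and_crop(scan, spl, cfg)
  reg <- icp_align(prep$moving, prep$fixed, cfg)
  diag <- c(prep$diagnostics,
            list(icp_iterations = reg$iterations,
                 icp_converged = reg$converged))
  asymmetry_result(reg$rmse, posture, diagnostics = diag)
}

#' 2 x 17 asymmetry map of a posture
#'
#' After the same mirror-and-crop preprocessing as [asymmetry_index()] (and,
#' by default, the whole-cloud ICP registration), both clouds are partitioned
#' into `n_regions` uniform vertical bands over the SPL extent, each split at
#' the mean SPL into a left and a right segment (left = patient's left,
#' positive x). ICP is run per segment pair and the final RMSEs form the map.
#' Segments with fewer than 3 points on either side are flagged missing.
#'
#' @inheritParams asymmetry_index
#' @return An [asymmetry_result] whose `map` is an `asymmetry_map` (fields
#'   `region_edges`: n_regions+1 y boundaries, cranial to caudal;
#'   `rmse_left`, `rmse_right`: per-region RMSE in mm, `NA` = missing) and
#'   whose `index` is [map_overall_index()] of that map.
#' @export
asymmetry_map <- function(scan, spl, cfg = analysis_config(),
                          posture = "upright") {
  prep <- mirror_and_crop(scan, spl, cfg)
  global_iter <- NA_integer_
  fm <- as_xyz(prep$fixed)
  mm0 <- as_xyz(prep$moving)  # pre-registration coords label band/side
  mm <- mm0
  if (cfg$map_refine_from_global) {
    reg <- icp_align(prep$moving, prep$fixed, cfg)
    mm <- apply_transform(reg$transform, mm0)
    global_iter <- reg$iterations
  }
  edges <- seq(max(spl[, 2]), min(spl[, 2]), length.out = cfg$n_regions + 1)
  band_of <- function(y) {
    # half-open [upper, lower) bands, last band closed, cranial band = 1
    b <- cfg$n_regions + 1L -
      findInterval(y, rev(edges), rightmost.closed = TRUE, all.inside = TRUE)
    b
  }
  fb <- band_of(fm[, 2])
  mb <- band_of(mm0[, 2])
  fleft <- fm[, 1] > prep$x0
  mleft <- mm0[, 1] > prep$x0
  seg_rmse <- function(band, left) {
    fsel <- fb == band & (fleft == left)
    msel <- mb == band & (mleft == left)
    if (sum(fsel) < 3 || sum(msel) < 3) return(NA_real_)
    fs <- fm[fsel, , drop = FALSE]
    ms <- mm[msel, , drop = FALSE]
    if (!cfg$map_refine_from_global) {
      # centroid pre-alignment: standard ICP initialization, needed because
      # an unregistered segment pair can be laterally offset by twice the
      # local spinal deviation
      ms <- sweep(ms, 2, colMeans(ms) - colMeans(fs))
    }
    icp_align(back_scan(ms), back_scan(fs), cfg)$rmse
  }
  rmse_left <- vapply(seq_len(cfg$n_regions), seg_rmse, numeric(1), left = TRUE)
  rmse_right <- vapply(seq_len(cfg$n_regions), seg_rmse, numeric(1),
                       left = FALSE)
  if (all(is.na(rmse_left)) && all(is.na(rmse_right)))
    bs_stop("degenerate_crop", "asymmetry map: every segment is missing")
  map <- structure(list(region_edges = edges, rmse_left = rmse_left,
                        rmse_right = rmse_right),
                   class = "asymmetry_map")
  diag <- c(prep$diagnostics, list(global_icp_iterations = global_iter))
  asymmetry_result(map_overall_index(map), posture, map = map,
                   diagnostics = diag)
}

#' Overall index of an asymmetry map
#'
#' The mean of the non-missing right-side segment RMSEs (by construction the
#' left and right columns carry mirrored information, so one side suffices).
#'
#' @param map an `asymmetry_map`.
#' @return Overall map index in mm.
#' @export
map_overall_index <- function(map) {
  if (!inherits(map, "asymmetry_map"))
    bs_stop("invalid_input", "map must be an asymmetry_map")
  if (all(is.na(map$rmse_right)))
    bs_stop("invalid_input", "all right-side map values are missing")
  mean(map$rmse_right, na.rm = TRUE)
}

#' Coronal asymmetry differences of a map
#'
#' Per-region signed difference `rmse_left - rmse_right`. Because the
#' mirrored cloud is the exact reflection of the original, the left and
#' right segment pairs of a band compare the same two half-surfaces with
#' the moving/fixed roles exchanged; the difference therefore isolates the
#' directional component of the registration residual. A paravertebral
#' prominence at band k produces a negative `d[k]` whichever side it lies
#' on: registering the smoother half onto the prominent half leaves a
#' larger residual than the converse, and the prominent half is the fixed
#' target of the right-column registration. These differences drive the
#' SPL-to-ISL coronal adjustment, scaled by a calibrated gain whose sign
#' absorbs the convention.
#'
#' @param map an `asymmetry_map`.
#' @return Numeric vector of n_regions signed values in mm (NA where either
#'   side is missing).
#' @export
coronal_asymmetry_difference <- function(map) {
  if (!inherits(map, "asymmetry_map"))
    bs_stop("invalid_input", "map must be an asymmetry_map")
  map$rmse_left - map$rmse_right
}

#' @export
print.asymmetry_map <- function(x, ...) {
  n <- length(x$rmse_left)
  cat(sprintf("asymmetry_map: %d regions x {left, right} (mm)\n", n))
  print(data.frame(region = seq_len(n),
                   y_top = round(x$region_edges[-(n + 1)], 1),
                   y_bottom = round(x$region_edges[-1], 1),
                   rmse_left = round(x$rmse_left, 4),
                   rmse_right = round(x$rmse_right, 4)), row.names = FALSE)
  invisible(x)
}

#' Maximum-bending frame of a lateral sequence
#'
#' Per frame, the SPL samples are split at the median y into upper and lower
#' halves; the line between the two half means, projected onto the coronal
#' plane, makes an angle with the horizontal (x) axis. The frame minimizing
#' that angle — the spine most tilted from vertical — is the maximum bend.
#' Ties break to the earliest frame.
#'
#' @param spl_seq list of per-frame SPL [spinal_curve]s (>= 4 samples each).
#' @return 1-based frame index.
#' @export
max_bending_frame <- function(spl_seq) {
  if (length(spl_seq) < 1)
    bs_stop("invalid_input", "empty SPL sequence")
  angles <- vapply(spl_seq, function(spl) {
    if (!inherits(spl, "spinal_curve") || nrow(spl) < 4)
      bs_stop("invalid_input",
              "each SPL needs at least 4 samples for the two-mean split")
    y <- spl[, 2]
    upper <- y > median(y)
    du <- colMeans(unclass(spl)[upper, 1:2, drop = FALSE]) -
      colMeans(unclass(spl)[!upper, 1:2, drop = FALSE])
    atan2(abs(du[2]), abs(du[1])) * 180 / pi  # angle from horizontal, deg
  }, numeric(1))
  which.min(angles)
}

#' Match the mirrored counterpart frame in the opposite bending sequence
#'
#' Mirrors every candidate SPL of the opposite-side sequence in the medial
#' direction — about the midpoint between the target's and the candidate's
#' mean lateral positions — and returns the frame whose mirrored samples
#' have the smallest nearest-neighbor RMSE to the target samples. The
#' midpoint axis makes the match invariant to joint lateral translation and
#' recovers an exact mirror image of the target exactly, whatever plane it
#' was mirrored about. Curve samples only; the point clouds are not touched
#' here. Ties break to the earliest frame.
#'
#' @param target_spl the [spinal_curve] of the selected maximum-bend frame.
#' @param opposite_seq list of [spinal_curve]s from the opposite-side
#'   sequence.
#' @return List with `index` (1-based frame), `rmse` (mm), and `axis` (the
#'   mirror-plane x of the selected frame, mm).
#' @export
match_mirrored_frame <- function(target_spl, opposite_seq) {
  if (!inherits(target_spl, "spinal_curve"))
    bs_stop("invalid_input", "target_spl must be a spinal_curve")
  if (length(opposite_seq) < 1)
    bs_stop("invalid_input", "empty opposite sequence")
  xt <- mean_spl_lateral(target_spl)
  tgt <- unclass(target_spl)[, 1:3, drop = FALSE]
  fits <- vapply(opposite_seq, function(cand) {
    cm <- unclass(cand)[, 1:3, drop = FALSE]
    a <- (xt + mean(cm[, 1])) / 2
    cm[, 1] <- 2 * a - cm[, 1]
    c(nearest_neighbor_rmse(cm, tgt), a)
  }, numeric(2))
  idx <- which.min(fits[1, ])
  list(index = idx, rmse = fits[1, idx], axis = fits[2, idx])
}

#' Lateral-bending asymmetry index
#'
#' For each bending side: the maximum-bend frame is found from the per-frame
#' SPLs, its mirrored counterpart is selected from the opposite sequence by
#' SPL matching, the counterpart's full scan is mirrored about the target
#' SPL mean, both scans are cropped to a radius of half the left-right MSS
#' distance around the target SPL, and ICP yields a nearest-neighbor RMSE.
#' The index is the mean of the left-target and right-target RMSEs.
#'
#' @param left_seq,right_seq [scan_sequence]s of left/right lateral bending.
#' @param left_spls,right_spls lists of per-frame SPL [spinal_curve]s aligned
#'   with the sequences.
#' @param landmarks a [landmark_set] containing MSS_left and MSS_right.
#' @param cfg an [analysis_config].
#' @return An [asymmetry_result] with posture `"lateral"`; diagnostics carry
#'   the crop radius, selected frames, and the two per-side RMSEs.
#' @export
lateral_bending_index <- function(left_seq, right_seq, left_spls, right_spls,
                                  landmarks, cfg = analysis_config()) {
  if (!inherits(left_seq, "scan_sequence") ||
      !inherits(right_seq, "scan_sequence"))
    bs_stop("invalid_input", "left_seq and right_seq must be scan_sequences")
  if (length(left_seq) != length(left_spls) ||
      length(right_seq) != length(right_spls))
    bs_stop("invalid_input", "per-frame SPLs must align with their sequences")
  mss <- get_landmarks(landmarks, c("MSS_left", "MSS_right"))
  radius <- 0.5 * sqrt(sum((mss[1, ] - mss[2, ])^2))
  one_side <- function(tgt_seq, tgt_spls, opp_seq, opp_spls) {
    ti <- max_bending_frame(tgt_spls)
    tgt_spl <- tgt_spls[[ti]]
    match <- match_mirrored_frame(tgt_spl, opp_spls)
    counter <- mirror_about_axis(opp_seq$scans[[match$index]], match$axis)
    tgt_crop <- crop_by_spl_radius(tgt_seq$scans[[ti]], tgt_spl, radius)
    cnt_crop <- crop_by_spl_radius(counter, tgt_spl, radius)
    reg <- icp_align(cnt_crop, tgt_crop, cfg)
    list(rmse = reg$rmse, target_frame = ti, matched_frame = match$index,
         spl_match_rmse = match$rmse, n_target = nrow(tgt_crop),
         n_counterpart = nrow(cnt_crop), icp_iterations = reg$iterations)
  }
  left <- one_side(left_seq, left_spls, right_seq, right_spls)
  right <- one_side(right_seq, right_spls, left_seq, left_spls)
  asymmetry_result((left$rmse + right$rmse) / 2, "lateral",
                   diagnostics = list(radius = radius, left = left,
                                      right = right))
}

#' Serialize an asymmetry result to JSON
#'
#' @param result an [asymmetry_result].
#' @return JSON string with posture, index, map (if present) and diagnostics.
#' @export
asymmetry_to_json <- function(result) {
  out <- list(posture = result$posture, index = result$index,
              diagnostics = result$diagnostics)
  if (!is.null(result$map))
    out$map <- list(region_edges = result$map$region_edges,
                    rmse_left = result$map$rmse_left,
                    rmse_right = result$map$rmse_right)
  jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, na = "null")
}

#' Export an asymmetry map as CSV
#'
#' Writes one row per region: `region, y_top, y_bottom, rmse_left,
#' rmse_right, d` (d = coronal asymmetry difference).
#'
#' @param map an `asymmetry_map`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_asymmetry_map_csv <- function(map, path) {
  n <- length(map$rmse_left)
  df <- data.frame(region = seq_len(n),
                   y_top = map$region_edges[-(n + 1)],
                   y_bottom = map$region_edges[-1],
                   rmse_left = map$rmse_left,
                   rmse_right = map$rmse_right,
                   d = coronal_asymmetry_difference(map))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
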