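#' Mirror a scan about a sagittal plane
#'
#' Reflects every point (x, y, z) to (2*x0 - x, y, z), i.e. mirrors the cloud
#' axis-symmetrically about the vertical plane x = x0. Used with
#' `x0 = mean_spl_lateral(spl)` to build the mirrored copy that the asymmetry
#' measures register against. Mirroring is an involution and preserves point
#' count, ordering, and the y/z coordinates exactly.
#'
#' @param scan a [back_scan].
#' @param x0 mirror-plane lateral position in mm.
#' @return The mirrored [back_scan].
#' @export
mirror_about_axis <- function(scan, x0) {
  if (!inherits(scan, "back_scan"))
    bs_stop("invalid_input", "scan must be a back_scan")
  if (length(x0) != 1 || !is.finite(x0))
    bs_stop("invalid_input", "x0 must be a finite scalar")
  m <- as_xyz(scan)
  m[, 1] <- 2 * x0 - m[, 1]
  back_scan(m, frame_time = attr(scan, "frame_time"))
}

#' Mean lateral position of a spinal curve
#'
#' Arithmetic mean of the x coordinates of all curve samples; the mirror-plane
#' location used by every asymmetry measure.
#'
#' @param spl a [spinal_curve].
#' @return Scalar x position in mm.
#' @export
mean_spl_lateral <- function(spl) {
  if (!inherits(spl, "spinal_curve"))
    bs_stop("invalid_input", "spl must be a spinal_curve")
  mean(spl[, 1])
}

#' Crop a scan to the vertical extent of the SPL
#'
#' Keeps only points whose y lies within the closed interval spanned by the
#' SPL samples, limiting the cloud from C7 to L5 in the cranial and caudal
#' directions.
#'
#' @param scan a [back_scan].
#' @param spl a [spinal_curve] in the same frame.
#' @return The cropped [back_scan].
#' @export
crop_vertical_extent <- function(scan, spl) {
  if (!inherits(spl, "spinal_curve"))
    bs_stop("invalid_input", "spl must be a spinal_curve")
  m <- as_xyz(scan)
  keep <- m[, 2] >= min(spl[, 2]) & m[, 2] <= max(spl[, 2])
  finish_crop(m, keep, attr(scan, "frame_time"), "vertical-extent")
}

#' Crop lateral borders by quantile distance
#'
#' Removes border artefacts such as arms: computes the `q_low` and `q_high`
#' quantiles of all point x coordinates (linear interpolation between order
#' statistics), takes `d` as the minimum distance between the mirror-plane
#' location `x0` and the two quantiles, and keeps points with
#' `|x - x0| <= border_factor * d`.
#'
#' @param scan a [back_scan].
#' @param x0 mirror-plane lateral position in mm (mean SPL location).
#' @param cfg an [analysis_config] supplying `q_low`, `q_high`,
#'   `border_factor`.
#' @return The cropped [back_scan].
#' @export
crop_lateral_quantile <- function(scan, x0, cfg = analysis_config()) {
  if (!inherits(scan, "back_scan"))
    bs_stop("invalid_input", "scan must be a back_scan")
  if (length(x0) != 1 || !is.finite(x0))
    bs_stop("invalid_input", "x0 must be a finite scalar")
  m <- as_xyz(scan)
  q <- quantile(m[, 1], probs = c(cfg$q_low, cfg$q_high), names = FALSE,
                type = 7)
  d <- min(abs(x0 - q))
  if (d == 0)
    bs_stop("degenerate_crop",
            "lateral quantile crop degenerate: quantiles coincide with x0")
  keep <- abs(m[, 1] - x0) <= cfg$border_factor * d
  finish_crop(m, keep, attr(scan, "frame_time"), "lateral-quantile")
}

#' Crop a scan to a radius around the SPL
#'
#' Keeps points whose 3D Euclidean distance to the nearest SPL sample is at
#' most `radius`. In the lateral-bending pipeline the radius is half the
#' distance between the left and right MSS landmarks.
#'
#' @param scan a [back_scan].
#' @param spl a [spinal_curve] in the same frame.
#' @param radius crop radius in mm (> 0).
#' @return The cropped [back_scan].
#' @export
crop_by_spl_radius <- function(scan, spl, radius) {
  if (!inherits(scan, "back_scan") || !inherits(spl, "spinal_curve"))
    bs_stop("invalid_input", "need a back_scan and a spinal_curve")
  if (length(radius) != 1 || !is.finite(radius) || radius <= 0)
    bs_stop("invalid_input", "radius must be a positive scalar")
  m <- as_xyz(scan)
  tree <- cpp_kdtree_build(unclass(spl)[, 1:3, drop = FALSE])
  d <- cpp_kdtree_query(tree, m)$dist
  finish_crop(m, d <= radius, attr(scan, "frame_time"), "SPL-radius")
}

finish_crop <- function(m, keep, frame_time, label) {
  if (sum(keep) < 3)
    bs_stop("degenerate_crop",
            sprintf("%s crop left %d point(s); at least 3 are required",
                    label, sum(keep)))
  back_scan(m[keep, , drop = FALSE], frame_time = frame_time)
}

#' Sagittal inclination of a scan
#'
#' Projects the cloud onto the sagittal (y-z) plane and returns the
#' least-squares slope of y regressed on z, i.e. the inclination of the back
#' relative to the horizontal. A fully upright back (long axis vertical)
#' yields a large |slope|; a horizontally aligned back (maximum forward bend,
#' facing an overhead camera) yields a slope near zero, which is how the
#' maximum-bend frame of a forward-bending sequence is selected.
#'
#' @param scan a [back_scan] with at least 3 points and non-constant z.
#' @return Dimensionless slope dy/dz.
#' @export
sagittal_inclination <- function(scan) {
  if (!inherits(scan, "back_scan"))
    bs_stop("invalid_input", "scan must be a back_scan")
  m <- as_xyz(scan)
  if (nrow(m) < 3)
    bs_stop("invalid_input", "need at least 3 points")
  vz <- sd(m[, 3])
  if (!is.finite(vz) || vz == 0)
    bs_stop("undefined_slope",
            "sagittal inclination undefined: z is constant")
  unname(coef(lsfit(m[, 3], m[, 2]))[2])
}

#' Select the least inclined frame of a sequence
#'
#' Returns the index of the frame minimizing `|sagittal_inclination|`; for a
#' forward-bending sequence this is the frame in which the back is nearest to
#' horizontal alignment (maximum bend). Frames with undefined inclination are
#' skipped; ties are broken by the earliest frame.
#'
#' @param seq a [scan_sequence].
#' @return 1-based frame index.
#' @export
select_least_inclined_frame <- function(seq) {
  if (!inherits(seq, "scan_sequence"))
    bs_stop("invalid_input", "seq must be a scan_sequence")
  slopes <- vapply(seq$scans, function(s) {
    tryCatch(abs(sagittal_inclination(s)),
             backshape_undefined_slope = function(e) NA_real_)
  }, numeric(1))
  if (all(is.na(slopes)))
    bs_stop("undefined_slope", "sagittal inclination undefined in every frame")
  which.min(slopes)  # which.min skips NA and takes the earliest minimum
}

#' Realign a bent posture to the patient frame
#'
#' Rotates a scan and its SPL about the medial-lateral (x) axis so that the
#' SPL chord (C7 to L5) runs cranial-caudal along +y. The vertical crop and
#' the 17-band segmentation act along y, which is the anatomical
#' cranial-caudal axis only in an upright frame; bent-forward frames are
#' realigned with this utility before index or map computation.
#'
#' @param scan a [back_scan].
#' @param spl the matching [spinal_curve].
#' @return List with elements `scan`, `spl` and the applied `angle_deg`.
#' @export
realign_sagittal <- function(scan, spl) {
  if (!inherits(scan, "back_scan") || !inherits(spl, "spinal_curve"))
    bs_stop("invalid_input", "need a back_scan and a spinal_curve")
  chord <- unclass(spl)[1, 2:3] - unclass(spl)[nrow(spl), 2:3]
  theta <- atan2(chord[2], chord[1])  # angle of chord from +y, in y-z plane
  ctr <- colMeans(unclass(spl))[2:3]
  rot_yz <- function(m) {
    u <- m[, 2] - ctr[1]
    v <- m[, 3] - ctr[2]
    m[, 2] <- cos(theta) * u + sin(theta) * v + ctr[1]
    m[, 3] <- -sin(theta) * u + cos(theta) * v + ctr[2]
    m
  }
  sm <- rot_yz(as_xyz(scan))
  cm <- rot_yz(unclass(spl)[, 1:3, drop = FALSE])
  list(scan = back_scan(sm, frame_time = attr(scan, "frame_time")),
       spl = spinal_curve(cm, role = curve_role(spl)),
       angle_deg = theta * 180 / pi)
}

#' Project a scan onto a coronal depth map
#'
#' Rasterizes the cloud onto an (x, y) pixel grid at the configured
#' resolution. Each occupied cell stores the maximum z of its points (the
#' most posterior surface point, nearest a posterior camera); unoccupied
#' cells hold the background sentinel, a reserved value below the physical z
#' range. The affine pixel-to-mm mapping is returned alongside so foreground
#' pixels can be back-projected.
#'
#' @param scan a [back_scan].
#' @param cfg an [analysis_config] supplying `depthmap_resolution` (mm/pixel).
#' @return An object of class `depth_map`: list with `image` (rows indexed by
#'   y, columns by x), `background` sentinel, `origin` (mm position of pixel
#'   centre `[1, 1]`) and `resolution` (mm per pixel).
#' @export
project_coronal_depthmap <- function(scan, cfg = analysis_config()) {
  if (!inherits(scan, "back_scan"))
    bs_stop("invalid_input", "scan must be a back_scan")
  res <- cfg$depthmap_resolution
  if (!is.finite(res) || res <= 0)
    bs_stop("invalid_input", "depthmap_resolution must be > 0")
  m <- as_xyz(scan)
  ix <- floor((m[, 1] - min(m[, 1])) / res) + 1L
  iy <- floor((m[, 2] - min(m[, 2])) / res) + 1L
  nx <- max(ix)
  ny <- max(iy)
  background <- min(m[, 3]) - 1
  img <- matrix(background, nrow = ny, ncol = nx)
  # max-z collision rule; process in increasing z so the last write wins
  ord <- order(m[, 3])
  img[cbind(iy[ord], ix[ord])] <- m[ord, 3]
  structure(list(image = img, background = background,
                 origin = c(x = min(m[, 1]) + res / 2,
                            y = min(m[, 2]) + res / 2),
                 resolution = res),
            class = "depth_map")
}

#' Back-project foreground depth-map pixels to 3D points
#'
#' Inverse of [project_coronal_depthmap()] up to rasterization: each
#' foreground pixel becomes the 3D point at its cell centre with the stored
#' depth, reproducing the original x/y within half a pixel.
#'
#' @param dm a `depth_map`.
#' @return A [back_scan] of foreground cell-centre points.
#' @export
depthmap_to_points <- function(dm) {
  fg <- which(dm$image != dm$background, arr.ind = TRUE)
  if (nrow(fg) < 1)
    bs_stop("invalid_input", "depth map has no foreground pixels")
  back_scan(cbind(
    x = dm$origin[["x"]] + (fg[, 2] - 1) * dm$resolution,
    y = dm$origin[["y"]] + (fg[, 1] - 1) * dm$resolution,
    z = dm$image[fg]))
}
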