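#' Parameters of a synthetic scoliotic subject
#'
#' Controls the deterministic back-surface generator. The torso is a smooth
#' bilaterally structured surface z(x, y) with convex posterior
#' cross-sections, displaced coronally by a windowed sinusoidal spinal curve
#' c(y), with a paravertebral Gaussian hump on the convex side and optional
#' isotropic sensor noise. Ground truth: the internal spinal alignment (ISL)
#' follows c(y) exactly; the spinous process line (SPL) follows
#' `spl_damping * c(y)`, modeling the known lag of the spinous processes
#' behind the vertebral-body deviation; the true Cobb angle is measured from
#' the ISL.
#'
#' @param torso_height C7-to-L5 span in mm (default 450).
#' @param torso_halfwidth lateral half-extent of the scanned back in mm
#'   (default 180).
#' @param curve_amplitude coronal amplitude A of the spinal curve in mm.
#' @param curve_apex_y apex height in mm (default: one quarter wavelength
#'   below C7, giving a single full period over the torso with nodes at C7
#'   and L5).
#' @param curve_wavelength wavelength of the coronal curve in mm (default:
#'   the torso height).
#' @param hump_amplitude height of the paravertebral hump in mm (default 10).
#' @param hump_sigma Gaussian radius of the hump in mm (default 40); must be
#'   at least the grid spacing.
#' @param hump_offset lateral distance of the hump centre from the spine in
#'   mm (default 50).
#' @param hump_side `"auto"` (convex side of the curve, left if the curve is
#'   flat), `"left"` or `"right"`.
#' @param hump_center_y hump centre height in mm (default: the curve apex).
#' @param bend_hump_gain multiplicative prominence of the rib hump at full
#'   forward bend relative to upright (default 2): bending forward rotates
#'   the rib cage into the scanned surface and roughly doubles the visible
#'   hump, the clinical rationale of the Adam's test. Bent-posture frames
#'   scale the hump by `1 + (bend_hump_gain - 1) * sin(bend angle)`, so the
#'   first frame of a forward sequence equals the upright scan exactly.
#' @param spl_damping SPL-to-ISL coronal damping factor in \[0, 1\]
#'   (default 0.6).
#' @param noise_sd isotropic Gaussian sensor noise in mm (default 0.5,
#'   typical of structured-light depth cameras; set 0 for noiseless
#'   fixtures).
#' @param grid_spacing surface sampling grid pitch in mm (default 5,
#'   comparable to structured-light scanner point spacing and fine enough
#'   to resolve the 17 vertical bands of the asymmetry map, each about
#'   26 mm tall).
#' @param depth_amplitude posterior prominence of the torso cross-section in
#'   mm (default 40).
#' @param sagittal_tilt overall sagittal lean of the back (dz/dy,
#'   default 0.12) so the upright posture has a well-defined nonzero
#'   sagittal inclination.
#' @param kyphosis_amplitude sagittal profile amplitude in mm (default 5).
#' @param n_spl_samples number of SPL/ISL samples from C7 to L5 (default 33).
#' @param y_margin extra scanned surface beyond C7/L5 in mm (default 40),
#'   so the vertical crop has material to remove.
#' @param seed integer RNG seed for the sensor noise.
#' @return An object of class `subject_params`.
#' @export
subject_params <- function(torso_height = 450, torso_halfwidth = 180,
                           curve_amplitude = 15, curve_apex_y = NULL,
                           curve_wavelength = NULL,
                           hump_amplitude = 10, hump_sigma = 40,
                           hump_offset = 50, hump_side = "auto",
                           hump_center_y = NULL,
                           bend_hump_gain = 2,
                           spl_damping = 0.6, noise_sd = 0.5,
                           grid_spacing = 5, depth_amplitude = 40,
                           sagittal_tilt = 0.12, kyphosis_amplitude = 5,
                           n_spl_samples = 33, y_margin = 40, seed = 1L) {
  if (is.null(curve_wavelength)) curve_wavelength <- torso_height
  if (is.null(curve_apex_y)) curve_apex_y <- torso_height - curve_wavelength / 4
  p <- list(torso_height = torso_height, torso_halfwidth = torso_halfwidth,
            curve_amplitude = curve_amplitude, curve_apex_y = curve_apex_y,
            curve_wavelength = curve_wavelength,
            hump_amplitude = hump_amplitude, hump_sigma = hump_sigma,
            hump_offset = hump_offset,
            hump_side = match.arg(hump_side, c("auto", "left", "right")),
            hump_center_y = hump_center_y,
            bend_hump_gain = bend_hump_gain,
            spl_damping = spl_damping, noise_sd = noise_sd,
            grid_spacing = grid_spacing, depth_amplitude = depth_amplitude,
            sagittal_tilt = sagittal_tilt,
            kyphosis_amplitude = kyphosis_amplitude,
            n_spl_samples = as.integer(n_spl_samples), y_margin = y_margin,
            seed = as.integer(seed))
  lengths_pos <- c("torso_height", "torso_halfwidth", "hump_sigma",
                   "hump_offset", "grid_spacing", "depth_amplitude",
                   "curve_wavelength", "bend_hump_gain")
  for (nm in lengths_pos)
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0)
      bs_stop("invalid_input", paste(nm, "must be > 0"))
  if (p$curve_amplitude < 0 || p$hump_amplitude < 0 || p$noise_sd < 0)
    bs_stop("invalid_input", "amplitudes and noise_sd must be >= 0")
  if (p$spl_damping < 0 || p$spl_damping > 1)
    bs_stop("invalid_input", "spl_damping must be in [0, 1]")
  if (p$n_spl_samples < 5)
    bs_stop("invalid_input", "n_spl_samples must be >= 5")
  structure(p, class = "subject_params")
}

# coronal spinal-curve deviation c(y); nodes at C7/L5 under the defaults
curve_x <- function(y, p) {
  H <- p$torso_height
  yc <- pmin(pmax(y, 0), H)  # clamp beyond the C7-L5 span
  phi0 <- pi / 2 - 2 * pi * (H - p$curve_apex_y) / p$curve_wavelength
  p$curve_amplitude * sin(2 * pi * (H - yc) / p$curve_wavelength + phi0)
}

# sagittal profile: gentle monotone lean plus a kyphosis/lordosis wave
sag_z <- function(y, p) {
  p$sagittal_tilt * (y - p$torso_height / 2) +
    p$kyphosis_amplitude * sin(2 * pi * pmin(pmax(y, 0), p$torso_height) /
                                 p$torso_height)
}

hump_side_sign <- function(p) {
  switch(p$hump_side,
         left = 1,
         right = -1,
         auto = if (curve_x(p$curve_apex_y, p) < 0) -1 else 1)
}

# full surface height; the hump is optional so the SPL can ride the
# undeformed midline profile, and scalable for bent postures
surface_z <- function(x, y, p, include_hump = TRUE, hump_scale = 1) {
  we <- p$torso_halfwidth + 20  # cross-section vanishes just beyond the grid
  cy <- curve_x(y, p)
  z <- p$depth_amplitude * cos(pi * (x - cy) / (2 * we)) + sag_z(y, p)
  if (include_hump && p$hump_amplitude > 0) {
    yh <- if (is.null(p$hump_center_y)) p$curve_apex_y else p$hump_center_y
    xh <- curve_x(yh, p) + hump_side_sign(p) * p$hump_offset
    z <- z + hump_scale * p$hump_amplitude *
      exp(-((x - xh)^2 + (y - yh)^2) / (2 * p$hump_sigma^2))
  }
  z
}

#' Generate a synthetic scoliotic subject
#'
#' Builds the upright back-surface scan plus ground truth: SPL, ISL, the
#' nine anatomical landmarks, and the true Cobb angle measured from the ISL
#' with [cobb_from_curve()]. Fully reproducible for a given seed.
#'
#' @param params a [subject_params].
#' @return An object of class `synthetic_subject`: list with `scan`
#'   ([back_scan]), `spl`, `isl` ([spinal_curve]s sharing y-stations),
#'   `landmarks` ([landmark_set]), `true_cobb` (degrees), `params`.
#' @examples
#' subj <- make_subject(subject_params(curve_amplitude = 20, noise_sd = 0))
#' subj$true_cobb
#' @export
make_subject <- function(params = subject_params()) {
  p <- params
  if (p$hump_amplitude > 0 && p$hump_sigma < p$grid_spacing)
    bs_stop("invalid_input",
            "grid too coarse to resolve the hump (hump_sigma < grid_spacing)")
  H <- p$torso_height
  pts <- build_scan_points(p)
  ys_s <- seq(H, 0, length.out = p$n_spl_samples)
  spl_x <- p$spl_damping * curve_x(ys_s, p)
  # spinous processes ride the midline profile; the paravertebral hump is
  # lateral to them and excluded from the SPL depth
  spl_z <- surface_z(spl_x, ys_s, p, include_hump = FALSE)
  spl <- spinal_curve(cbind(spl_x, ys_s, spl_z), role = "SPL")
  # the ISL ground truth shares the SPL's sagittal track: the estimation
  # stage adjusts only coronal curvature, so recovery is judged coronally
  isl <- spinal_curve(cbind(curve_x(ys_s, p), ys_s, spl_z), role = "ISL")
  lm_xy <- rbind(C7 = c(spl_x[1], H),
                 MSS_left = c(80, H - 80), MSS_right = c(-80, H - 80),
                 ISA_left = c(95, H - 150), ISA_right = c(-95, H - 150),
                 T12 = c(p$spl_damping * curve_x(0.35 * H, p), 0.35 * H),
                 L5 = c(spl_x[p$n_spl_samples], 0),
                 PSIS_left = c(45, 30), PSIS_right = c(-45, 30))
  lms <- landmark_set(cbind(lm_xy,
                            z = surface_z(lm_xy[, 1], lm_xy[, 2], p,
                                          include_hump = FALSE)))
  structure(list(scan = back_scan(pts), spl = spl, isl = isl,
                 landmarks = lms, true_cobb = cobb_from_curve(isl),
                 params = p),
            class = "synthetic_subject")
}

#' @export
print.synthetic_subject <- function(x, ...) {
  cat(sprintf(
    "synthetic_subject: %d points, true Cobb %.1f deg (amplitude %.1f mm)\n",
    nrow(x$scan), x$true_cobb, x$params$curve_amplitude))
  invisible(x)
}

# curve amplitude achieving a target Cobb angle, by monotone bisection on
# the generated ISL
amplitude_for_cobb <- function(target, base, tol = 0.05) {
  if (target <= 0) return(0)
  f <- function(a) {
    p <- base
    p$curve_amplitude <- a
    ys <- seq(p$torso_height, 0, length.out = p$n_spl_samples)
    cobb_from_curve(spinal_curve(cbind(curve_x(ys, p), ys, 0), role = "ISL"))
  }
  hi <- 10
  while (f(hi) < target) {
    hi <- hi * 2
    if (hi > 4 * base$torso_halfwidth)
      bs_stop("invalid_input",
              sprintf("Cobb target %.1f deg unreachable for this geometry",
                      target))
  }
  lo <- 0
  while (hi - lo > 1e-6) {
    mid <- (lo + hi) / 2
    if (f(mid) < target) lo <- mid else hi <- mid
    if (abs(f(mid) - target) < tol) return(mid)
  }
  (lo + hi) / 2
}

#' Generate a synthetic cohort spanning a Cobb-angle range
#'
#' Draws `n` subjects whose true Cobb angles span `cobb_range` uniformly:
#' per-subject curve amplitudes are found by monotone bisection of
#' [cobb_from_curve()] on the generated ISL. The hump amplitude co-varies
#' with the curve amplitude (scaled relative to a 20 mm reference), so the
#' rib-hump asymmetry grows with the deformity as it does clinically.
#' Per-subject noise seeds derive deterministically from `seed`.
#'
#' @param n number of subjects (>= 1).
#' @param cobb_range length-2 numeric, target Cobb range in degrees
#'   (low < high).
#' @param base a [subject_params] supplying everything except the curve and
#'   hump amplitudes.
#' @param seed cohort seed.
#' @return List of `synthetic_subject`s.
#' @export
make_cohort <- function(n, cobb_range = c(5, 60), base = subject_params(),
                        seed = 1L) {
  if (n < 1)
    bs_stop("invalid_input", "n must be >= 1")
  if (length(cobb_range) != 2 || cobb_range[1] > cobb_range[2])
    bs_stop("invalid_input", "cobb_range must be (low, high) with low <= high")
  targets <- if (n == 1) mean(cobb_range) else
    seq(cobb_range[1], cobb_range[2], length.out = n)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  lapply(seq_len(n), function(i) {
    p <- base
    p$curve_amplitude <- amplitude_for_cobb(targets[i], base)
    p$hump_amplitude <- base$hump_amplitude * p$curve_amplitude / 20
    p$seed <- seeds[i]
    make_subject(p)
  })
}

# sample the surface on the symmetric grid; the sensor-noise pattern is a
# fixed body texture (same seed for every frame), so frame 0 of a dynamic
# sequence is bit-identical to the static scan
build_scan_points <- function(p, hump_scale = 1) {
  half <- seq(0, p$torso_halfwidth, by = p$grid_spacing)
  xs <- sort(unique(c(-half, half)))  # exactly symmetric about x = 0
  ys <- seq(-p$y_margin, p$torso_height + p$y_margin, by = p$grid_spacing)
  g <- expand.grid(x = xs, y = ys)
  pts <- cbind(x = g$x, y = g$y,
               z = surface_z(g$x, g$y, p, hump_scale = hump_scale))
  if (p$noise_sd > 0) {
    set.seed(p$seed)
    pts <- pts + matrix(rnorm(length(pts), sd = p$noise_sd), ncol = 3)
  }
  pts
}

# rotation about a medial-lateral (x) axis: positive angle bends forward
# (cranial end moves anterior, i.e. toward negative z)
rotate_about_x <- function(m, angle_deg, pivot_y, pivot_z) {
  if (angle_deg == 0) return(m)  # keep the identity frame bit-exact
  phi <- angle_deg * pi / 180
  u <- m[, 2] - pivot_y
  v <- m[, 3] - pivot_z
  m[, 2] <- pivot_y + cos(phi) * u + sin(phi) * v
  m[, 3] <- pivot_z - sin(phi) * u + cos(phi) * v
  m
}

#' Generate a forward-bending sequence
#'
#' Rotates the subject about a hip-height medial-lateral axis from 0 to 90
#' degrees in equal steps at 5 Hz; the SPL transforms rigidly with the
#' surface. The rib hump grows with the bend angle (see `bend_hump_gain` in
#' [subject_params()]): bending forward rotates the rib cage into view, so
#' the visible hump is larger in the bent posture than upright. The first
#' frame equals the static upright scan exactly; the final frame is
#' horizontally aligned and therefore has the smallest absolute sagittal
#' inclination.
#'
#' @param subject a `synthetic_subject`.
#' @param frames number of frames (>= 2).
#' @return List with `sequence` (a [scan_sequence]) and `spls` (per-frame
#'   [spinal_curve]s).
#' @export
make_forward_sequence <- function(subject, frames = 6) {
  if (frames < 2)
    bs_stop("invalid_input", "need at least 2 frames")
  p <- subject$params
  pivot_y <- -p$y_margin - 60  # hip height, below the scan
  pivot_z <- mean(subject$scan[, 3])
  angles <- seq(0, 90, length.out = frames)
  scans <- vector("list", frames)
  spls <- vector("list", frames)
  for (i in seq_len(frames)) {
    hs <- 1 + (p$bend_hump_gain - 1) * sin(angles[i] * pi / 180)
    sm <- rotate_about_x(build_scan_points(p, hump_scale = hs), angles[i],
                         pivot_y, pivot_z)
    cm <- rotate_about_x(unclass(subject$spl)[, 1:3, drop = FALSE],
                         angles[i], pivot_y, pivot_z)
    scans[[i]] <- back_scan(sm, frame_time = (i - 1) / 5)
    spls[[i]] <- spinal_curve(cm, role = "SPL")
  }
  list(sequence = scan_sequence(scans, rate_hz = 5), spls = spls)
}

#' Generate a static Adam's forward bending scan
#'
#' The Adam's test posture is emulated as a forward rotation of the upright
#' subject (default 45 degrees) about the hip axis, with the rib hump
#' amplified according to the bend angle (`bend_hump_gain`), as the posture
#' exposes the hump clinically.
#'
#' @param subject a `synthetic_subject`.
#' @param angle_deg forward rotation in degrees.
#' @return List with `scan` and `spl` in the bent frame.
#' @export
make_adams_scan <- function(subject, angle_deg = 45) {
  p <- subject$params
  pivot_y <- -p$y_margin - 60
  pivot_z <- mean(subject$scan[, 3])
  hs <- 1 + (p$bend_hump_gain - 1) * sin(angle_deg * pi / 180)
  sm <- rotate_about_x(build_scan_points(p, hump_scale = hs), angle_deg,
                       pivot_y, pivot_z)
  cm <- rotate_about_x(unclass(subject$spl)[, 1:3, drop = FALSE], angle_deg,
                       pivot_y, pivot_z)
  list(scan = back_scan(sm), spl = spinal_curve(cm, role = "SPL"))
}

#' Generate a lateral-bending sequence
#'
#' Applies a height-graded coronal displacement ramping from zero to the
#' maximum bend toward the requested side (displacement grows quadratically
#' above the pelvis, emulating a lateral spine bend); the last frame is the
#' maximum bend. For a bilaterally symmetric subject the left and right
#' sequences are exact frame-by-frame mirror images.
#'
#' @param subject a `synthetic_subject`.
#' @param side `"left"` or `"right"`.
#' @param frames number of frames (>= 2).
#' @param max_displacement lateral displacement of the cranial end at
#'   maximum bend, in mm (default 250).
#' @return List with `sequence` (a [scan_sequence]) and `spls` (per-frame
#'   [spinal_curve]s).
#' @export
make_lateral_sequence <- function(subject, side = c("left", "right"),
                                  frames = 6, max_displacement = 250) {
  side <- match.arg(side)
  if (frames < 2)
    bs_stop("invalid_input", "need at least 2 frames")
  sgn <- if (side == "left") 1 else -1
  H <- subject$params$torso_height
  bend <- function(m, s) {
    g <- (pmax(m[, 2], 0) / H)^2
    m[, 1] <- m[, 1] + sgn * s * g
    m
  }
  amounts <- seq(0, max_displacement, length.out = frames)
  scans <- vector("list", frames)
  spls <- vector("list", frames)
  for (i in seq_len(frames)) {
    scans[[i]] <- back_scan(bend(as_xyz(subject$scan), amounts[i]),
                            frame_time = (i - 1) / 5)
    spls[[i]] <- spinal_curve(bend(unclass(subject$spl)[, 1:3, drop = FALSE],
                                   amounts[i]), role = "SPL")
  }
  list(sequence = scan_sequence(scans, rate_hz = 5), spls = spls)
}
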