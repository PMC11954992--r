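#' Back-surface point cloud
#'
#' A `back_scan` is an n x 3 numeric matrix of 3D points in the patient
#' coordinate frame, in mm: x medial-lateral (positive toward the patient's
#' left), y caudal-cranial (positive cranial), z anterior-posterior (positive
#' posterior, toward the camera). Members of a dynamic sequence may carry a
#' `frame_time` attribute in seconds.
#'
#' @param points numeric n x 3 matrix (or coercible) of coordinates in mm.
#' @param frame_time optional scalar acquisition time in seconds.
#' @return An object of class `back_scan`.
#' @examples
#' s <- back_scan(cbind(x = 0:2, y = c(10, 20, 30), z = 0))
#' nrow(s)
#' @export
back_scan <- function(points, frame_time = NULL) {
  pts <- as.matrix(points)
  if (ncol(pts) != 3)
    bs_stop("invalid_input", "a back_scan needs an n x 3 coordinate matrix")
  if (nrow(pts) < 1)
    bs_stop("invalid_input", "a back_scan must contain at least one point")
  storage.mode(pts) <- "double"
  if (!all(is.finite(pts)))
    bs_stop("invalid_input", "back_scan coordinates must all be finite")
  colnames(pts) <- c("x", "y", "z")
  structure(pts, class = c("back_scan", "matrix", "array"),
            frame_time = frame_time)
}

# strip class/attributes -> plain coordinate matrix
as_xyz <- function(scan) {
  m <- unclass(scan)
  attr(m, "frame_time") <- NULL
  m
}

#' @export
print.back_scan <- function(x, ...) {
  cat(sprintf("back_scan: %d points (mm)\n", nrow(x)))
  rng <- apply(as_xyz(x), 2, range)
  cat(sprintf("  x [%.1f, %.1f]  y [%.1f, %.1f]  z [%.1f, %.1f]\n",
              rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  invisible(x)
}

#' Ordered sequence of back scans
#'
#' Dynamic captures (forward and lateral bending) are 5 Hz sequences of
#' [back_scan] frames.
#'
#' @param scans list of [back_scan] objects, in acquisition order.
#' @param rate_hz sampling rate in Hz (default 5, the clinical protocol).
#' @return An object of class `scan_sequence`.
#' @export
scan_sequence <- function(scans, rate_hz = 5) {
  if (length(scans) < 1)
    bs_stop("invalid_input", "a scan_sequence must contain at least one frame")
  ok <- vapply(scans, inherits, logical(1), what = "back_scan")
  if (!all(ok))
    bs_stop("invalid_input", "all sequence members must be back_scan objects")
  times <- vapply(scans, function(s) {
    ft <- attr(s, "frame_time")
    if (is.null(ft)) NA_real_ else ft
  }, numeric(1))
  if (any(!is.na(times)) && any(diff(times[!is.na(times)]) <= 0))
    bs_stop("invalid_input", "frame times must be strictly increasing")
  structure(list(scans = scans, rate_hz = rate_hz), class = "scan_sequence")
}

#' @export
length.scan_sequence <- function(x) length(x$scans)

#' @export
print.scan_sequence <- function(x, ...) {
  cat(sprintf("scan_sequence: %d frames at %g Hz\n", length(x$scans), x$rate_hz))
  invisible(x)
}

#' Anatomical landmark set
#'
#' Named 3D positions (mm) of the radiopaque surface markers. Valid names are
#' C7, MSS_left, MSS_right, ISA_left, ISA_right, T12, L5, PSIS_left,
#' PSIS_right (MSS: medial end of the scapular spine; ISA: inferior scapular
#' angle; PSIS: posterior superior iliac spine). Any subset may be present.
#'
#' @param positions numeric k x 3 matrix with rownames drawn from the fixed
#'   nine-name vocabulary.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(positions) {
  m <- as.matrix(positions)
  if (ncol(m) != 3)
    bs_stop("invalid_input", "landmark positions must be a k x 3 matrix")
  storage.mode(m) <- "double"
  nm <- rownames(m)
  if (is.null(nm))
    bs_stop("invalid_input", "landmark positions must have rownames")
  bad <- setdiff(nm, landmark_names())
  if (length(bad))
    bs_stop("invalid_input", paste0("unknown landmark name(s): ",
                                    paste(bad, collapse = ", ")))
  if (anyDuplicated(nm))
    bs_stop("invalid_input", "duplicated landmark names")
  if (!all(is.finite(m)))
    bs_stop("invalid_input", "landmark coordinates must be finite")
  colnames(m) <- c("x", "y", "z")
  structure(m, class = c("landmark_set", "matrix", "array"))
}

#' @rdname landmark_set
#' @export
landmark_names <- function() {
  c("C7", "MSS_left", "MSS_right", "ISA_left", "ISA_right",
    "T12", "L5", "PSIS_left", "PSIS_right")
}

# fetch required landmarks, erroring with the missing names
get_landmarks <- function(lms, names) {
  missing <- setdiff(names, rownames(lms))
  if (length(missing))
    bs_stop("invalid_input", paste0("missing landmark(s): ",
                                    paste(missing, collapse = ", ")))
  unclass(lms)[names, , drop = FALSE]
}

#' Spinal curve (SPL or ISL)
#'
#' An ordered cranial-to-caudal 3D polyline sampled from C7 (first sample) to
#' L5 (last sample), in mm. The role tag distinguishes the spinous process
#' line (SPL, on the back surface) from the internal spinal alignment (ISL,
#' through the vertebral-body centroids).
#'
#' @param samples numeric n x 3 matrix (n >= 3) of curve samples, cranial
#'   first; y must be strictly decreasing.
#' @param role `"SPL"` or `"ISL"`.
#' @return An object of class `spinal_curve`.
#' @export
spinal_curve <- function(samples, role = c("SPL", "ISL")) {
  role <- match.arg(role)
  m <- as.matrix(samples)
  if (ncol(m) != 3)
    bs_stop("invalid_input", "curve samples must be an n x 3 matrix")
  storage.mode(m) <- "double"
  if (nrow(m) < 3)
    bs_stop("invalid_input", "a spinal curve needs at least 3 samples")
  if (!all(is.finite(m)))
    bs_stop("invalid_input", "curve coordinates must be finite")
  if (any(diff(m[, 2]) >= 0))
    bs_stop("invalid_input",
            "curve samples must have strictly decreasing y (cranial first)")
  colnames(m) <- c("x", "y", "z")
  structure(m, class = c("spinal_curve", "matrix", "array"), role = role)
}

curve_role <- function(curve) attr(curve, "role")

#' @export
print.spinal_curve <- function(x, ...) {
  cat(sprintf("spinal_curve (%s): %d samples, y from %.1f to %.1f mm\n",
              curve_role(x), nrow(x), x[1, 2], x[nrow(x), 2]))
  invisible(x)
}
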