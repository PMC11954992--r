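# File formats. Point clouds travel as PLY (ASCII or binary little-endian,
# vertex properties x/y/z in mm); curves and landmarks as CSV; configuration
# and sequence manifests as flat YAML. All units are mm and manifests declare
# it: anything else is rejected rather than silently rescaled.

ply_type_size <- c(char = 1L, int8 = 1L, uchar = 1L, uint8 = 1L,
                   short = 2L, int16 = 2L, ushort = 2L, uint16 = 2L,
                   int = 4L, int32 = 4L, uint = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

#' Read a back scan from a PLY file
#'
#' Accepts ASCII and binary little-endian PLY with `x`, `y`, `z` vertex
#' properties (float or double) in mm; extra vertex properties are ignored,
#' elements after the vertex element are not read.
#'
#' @param path PLY file path.
#' @return A [back_scan].
#' @export
read_scan <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!identical(magic, "ply"))
    bs_stop("format_error", paste0(path, ": not a PLY file"))
  fmt <- NULL
  n_vertex <- NULL
  props <- character()
  types <- character()
  in_vertex <- FALSE
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0)
      bs_stop("format_error", paste0(path, ": truncated PLY header"))
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(tok) == 0 || tok[1] == "comment") next
    if (tok[1] == "format") {
      fmt <- tok[2]
    } else if (tok[1] == "element") {
      if (tok[2] == "vertex") {
        n_vertex <- as.integer(tok[3])
        in_vertex <- TRUE
      } else {
        if (is.null(n_vertex))
          bs_stop("format_error",
                  paste0(path, ": vertex must be the first element"))
        in_vertex <- FALSE
      }
    } else if (tok[1] == "property" && in_vertex) {
      if (tok[2] == "list")
        bs_stop("format_error",
                paste0(path, ": list properties unsupported in vertex"))
      types <- c(types, tok[2])
      props <- c(props, tok[3])
    } else if (tok[1] == "end_header") break
  }
  if (is.null(n_vertex) || n_vertex < 1)
    bs_stop("format_error", paste0(path, ": no vertex element"))
  if (!all(c("x", "y", "z") %in% props))
    bs_stop("format_error",
            paste0(path, ": vertex element lacks x/y/z properties"))
  if (identical(fmt, "ascii")) {
    vals <- scan(con, what = numeric(), n = n_vertex * length(props),
                 quiet = TRUE)
    if (length(vals) < n_vertex * length(props))
      bs_stop("format_error", paste0(path, ": truncated vertex data"))
    m <- matrix(vals, nrow = n_vertex, ncol = length(props), byrow = TRUE)
  } else if (identical(fmt, "binary_little_endian")) {
    unknown <- setdiff(types, names(ply_type_size))
    if (length(unknown))
      bs_stop("format_error", paste0(path, ": unknown property type ",
                                     unknown[1]))
    sizes <- ply_type_size[types]
    raw <- readBin(con, "raw", n = n_vertex * sum(sizes))
    if (length(raw) < n_vertex * sum(sizes))
      bs_stop("format_error", paste0(path, ": truncated vertex data"))
    stride <- sum(sizes)
    offs <- cumsum(c(0L, sizes))[seq_along(sizes)]
    m <- matrix(NA_real_, nrow = n_vertex, ncol = length(props))
    for (j in seq_along(props)) {
      idx <- as.vector(outer(seq_len(sizes[j]),
                             (seq_len(n_vertex) - 1L) * stride + offs[j],
                             "+"))
      bytes <- raw[idx]
      m[, j] <- switch(types[j],
        float = , float32 = readBin(bytes, "double", n = n_vertex, size = 4,
                                    endian = "little"),
        double = , float64 = readBin(bytes, "double", n = n_vertex, size = 8,
                                     endian = "little"),
        readBin(bytes, "integer", n = n_vertex, size = sizes[j],
                endian = "little"))
    }
  } else {
    bs_stop("format_error",
            paste0(path, ": unsupported PLY format '", fmt, "'"))
  }
  xyz <- m[, match(c("x", "y", "z"), props), drop = FALSE]
  if (!all(is.finite(xyz))) {
    bad <- which(!apply(is.finite(xyz), 1, all))[1]
    bs_stop("format_error",
            sprintf("%s: non-finite coordinate in vertex %d", path, bad))
  }
  back_scan(xyz)
}

#' Write a back scan to a PLY file
#'
#' Coordinates are written as doubles so binary round-trips are bit-exact.
#'
#' @param scan a [back_scan].
#' @param path output path.
#' @param binary write binary little-endian (default) or ASCII.
#' @return `path`, invisibly.
#' @export
write_scan <- function(scan, path, binary = TRUE) {
  if (!inherits(scan, "back_scan"))
    bs_stop("invalid_input", "scan must be a back_scan")
  m <- as_xyz(scan)
  con <- file(path, "wb")
  on.exit(close(con))
  header <- c("ply",
              sprintf("format %s 1.0",
                      if (binary) "binary_little_endian" else "ascii"),
              "comment units mm",
              sprintf("element vertex %d", nrow(m)),
              "property double x", "property double y", "property double z",
              "end_header")
  writeLines(header, con)
  if (binary) {
    writeBin(as.vector(t(m)), con, size = 8, endian = "little")
  } else {
    writeLines(apply(m, 1, function(p)
      paste(formatC(p, format = "g", digits = 17), collapse = " ")), con)
  }
  invisible(path)
}

#' Read a spinal curve from CSV
#'
#' Expects the header `index,x,y,z` in mm, cranial-first ordering. A
#' caudal-first file (strictly increasing y) is reversed with a warning.
#'
#' @param path CSV file path.
#' @param role `"SPL"` or `"ISL"`.
#' @return A [spinal_curve].
#' @export
read_curve <- function(path, role = c("SPL", "ISL")) {
  role <- match.arg(role)
  df <- read.csv(path)
  if (!all(c("index", "x", "y", "z") %in% names(df)))
    bs_stop("format_error", paste0(path, ": header must be index,x,y,z"))
  if (nrow(df) < 3)
    bs_stop("format_error", paste0(path, ": fewer than 3 curve samples"))
  df <- df[order(df$index), ]
  m <- as.matrix(df[, c("x", "y", "z")])
  dimnames(m) <- NULL
  if (all(diff(m[, 2]) > 0)) {
    warning(paste0(path, ": caudal-first curve, reversing to cranial-first"),
            call. = FALSE)
    m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  }
  tryCatch(spinal_curve(m, role = role),
           backshape_invalid_input = function(e)
             bs_stop("format_error", paste0(path, ": ", conditionMessage(e))))
}

#' Write a spinal curve to CSV
#'
#' @param curve a [spinal_curve].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  if (!inherits(curve, "spinal_curve"))
    bs_stop("invalid_input", "curve must be a spinal_curve")
  df <- data.frame(index = seq_len(nrow(curve)) - 1L,
                   x = curve[, 1], y = curve[, 2], z = curve[, 3])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a landmark set from CSV (header `name,x,y,z`)
#'
#' @param path CSV file path.
#' @return A [landmark_set].
#' @export
read_landmarks <- function(path) {
  df <- read.csv(path)
  if (!all(c("name", "x", "y", "z") %in% names(df)))
    bs_stop("format_error", paste0(path, ": header must be name,x,y,z"))
  m <- as.matrix(df[, c("x", "y", "z")])
  rownames(m) <- df$name
  tryCatch(landmark_set(m),
           backshape_invalid_input = function(e)
             bs_stop("format_error", paste0(path, ": ", conditionMessage(e))))
}

#' Write a landmark set to CSV
#'
#' @param landmarks a [landmark_set].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(landmarks, path) {
  df <- data.frame(name = rownames(landmarks),
                   x = landmarks[, 1], y = landmarks[, 2], z = landmarks[, 3])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an analysis configuration from a flat YAML file
#'
#' Every [analysis_config()] default is overridable; unknown keys are an
#' error (catching typos rather than silently ignoring them). `weights` is
#' a nested map of the five posture weights.
#'
#' @param path YAML file path.
#' @param base configuration supplying defaults for absent keys.
#' @return An [analysis_config].
#' @export
read_config <- function(path, base = analysis_config()) {
  vals <- yaml::read_yaml(path)
  if (length(vals) == 0) return(base)
  unknown <- setdiff(names(vals), names(base))
  if (length(unknown))
    bs_stop("format_error", paste0(path, ": unknown config key(s): ",
                                   paste(unknown, collapse = ", ")))
  if (!is.null(vals$weights)) vals$weights <- unlist(vals$weights)
  cfg <- modifyList(as.list(base), vals)
  do.call(analysis_config, cfg[setdiff(names(cfg), "")])
}

#' Write an analysis configuration to YAML
#'
#' @param cfg an [analysis_config].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(lapply(as.list(cfg), function(v)
    if (is.numeric(v) && !is.null(names(v))) as.list(v) else v), path)
  invisible(path)
}

#' Write a scan sequence as numbered PLY files plus a manifest
#'
#' @param seq a [scan_sequence].
#' @param dir output directory (created if needed).
#' @param prefix frame-file prefix.
#' @param binary write binary PLY frames.
#' @return Path of the written `manifest.yaml`, invisibly.
#' @export
write_sequence <- function(seq, dir, prefix = "frame", binary = TRUE) {
  if (!inherits(seq, "scan_sequence"))
    bs_stop("invalid_input", "seq must be a scan_sequence")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("%s_%03d.ply", prefix, seq_along(seq$scans))
  for (i in seq_along(seq$scans))
    write_scan(seq$scans[[i]], file.path(dir, files[i]), binary = binary)
  manifest <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(list(units = "mm", rate_hz = seq$rate_hz,
                        frames = as.list(files)), manifest)
  invisible(manifest)
}

#' Read a scan sequence from a manifest
#'
#' The manifest must declare `units: mm`; frame times are reconstructed from
#' `rate_hz`.
#'
#' @param manifest_path path to a `manifest.yaml` written by
#'   [write_sequence()].
#' @return A [scan_sequence].
#' @export
read_sequence <- function(manifest_path) {
  info <- yaml::read_yaml(manifest_path)
  if (!identical(info$units, "mm"))
    bs_stop("format_error",
            paste0(manifest_path, ": units must be declared as mm"))
  if (is.null(info$rate_hz) || length(info$frames) < 1)
    bs_stop("format_error",
            paste0(manifest_path, ": manifest needs rate_hz and frames"))
  dir <- dirname(manifest_path)
  scans <- lapply(seq_along(info$frames), function(i) {
    s <- read_scan(file.path(dir, info$frames[[i]]))
    attr(s, "frame_time") <- (i - 1) / info$rate_hz
    s
  })
  scan_sequence(scans, rate_hz = info$rate_hz)
}

#' Write a complete synthetic subject to a bundle directory
#'
#' Emits everything the pipeline consumes for one subject: the upright and
#' Adam's scans, forward and left/right lateral bending sequences with
#' per-frame SPL CSVs, the upright SPL/ISL curves, landmarks, and a
#' `subject.yaml` manifest recording units and the true Cobb angle.
#'
#' @param subject a `synthetic_subject`.
#' @param dir output directory.
#' @param frames frames per dynamic sequence.
#' @param binary write binary PLY.
#' @return `dir`, invisibly.
#' @export
write_subject_bundle <- function(subject, dir, frames = 6, binary = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_scan(subject$scan, file.path(dir, "upright.ply"), binary = binary)
  adams <- make_adams_scan(subject)
  write_scan(adams$scan, file.path(dir, "adams.ply"), binary = binary)
  write_curve(adams$spl, file.path(dir, "adams_spl.csv"))
  write_curve(subject$spl, file.path(dir, "spl.csv"))
  write_curve(subject$isl, file.path(dir, "isl.csv"))
  write_landmarks(subject$landmarks, file.path(dir, "landmarks.csv"))
  seqs <- list(forward = make_forward_sequence(subject, frames),
               lateral_left = make_lateral_sequence(subject, "left", frames),
               lateral_right = make_lateral_sequence(subject, "right", frames))
  for (nm in names(seqs)) {
    sdir <- file.path(dir, nm)
    write_sequence(seqs[[nm]]$sequence, sdir, binary = binary)
    for (i in seq_along(seqs[[nm]]$spls))
      write_curve(seqs[[nm]]$spls[[i]],
                  file.path(sdir, sprintf("spl_%03d.csv", i)))
  }
  yaml::write_yaml(list(units = "mm", true_cobb = subject$true_cobb,
                        frames = frames), file.path(dir, "subject.yaml"))
  invisible(dir)
}

#' Read a subject bundle directory
#'
#' @param dir a directory written by [write_subject_bundle()].
#' @return A list with `scan`, `spl`, `isl`, `landmarks`, `adams`
#'   (scan + spl), `forward`, `lateral_left`, `lateral_right` (each
#'   sequence + spls), and `true_cobb` (NA if absent).
#' @export
read_subject_bundle <- function(dir) {
  meta_path <- file.path(dir, "subject.yaml")
  meta <- if (file.exists(meta_path)) yaml::read_yaml(meta_path) else
    list(units = "mm")
  if (!identical(meta$units, "mm"))
    bs_stop("format_error", paste0(dir, ": bundle units must be mm"))
  read_seq_dir <- function(nm) {
    sdir <- file.path(dir, nm)
    seq <- read_sequence(file.path(sdir, "manifest.yaml"))
    spls <- lapply(seq_along(seq$scans), function(i)
      read_curve(file.path(sdir, sprintf("spl_%03d.csv", i)), role = "SPL"))
    list(sequence = seq, spls = spls)
  }
  list(scan = read_scan(file.path(dir, "upright.ply")),
       spl = read_curve(file.path(dir, "spl.csv"), role = "SPL"),
       isl = read_curve(file.path(dir, "isl.csv"), role = "ISL"),
       landmarks = read_landmarks(file.path(dir, "landmarks.csv")),
       adams = list(scan = read_scan(file.path(dir, "adams.ply")),
                    spl = read_curve(file.path(dir, "adams_spl.csv"),
                                     role = "SPL")),
       forward = read_seq_dir("forward"),
       lateral_left = read_seq_dir("lateral_left"),
       lateral_right = read_seq_dir("lateral_right"),
       true_cobb = if (is.null(meta$true_cobb)) NA_real_ else meta$true_cobb)
}
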