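# Shared fixtures and independent oracles. Everything is generated in code;
# no fixture files.

# exhaustive O(n^2) nearest-neighbor oracle, independent of the kd-tree
brute_nn_rmse <- function(moving, fixed) {
  d2 <- outer(rowSums(moving^2), rowSums(fixed^2), "+") -
    2 * moving %*% t(fixed)
  sqrt(mean(pmax(apply(d2, 1, min), 0)))
}

# sort-based percentile oracle (linear interpolation between order statistics)
oracle_percentile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# straight vertical SPL along x = 0, z = 0
straight_spl <- function(n = 11, y_top = 100, y_bottom = 0) {
  spinal_curve(cbind(0, seq(y_top, y_bottom, length.out = n), 0),
               role = "SPL")
}

# small random cloud with enough rank for registration
random_cloud <- function(n, scale = 100) {
  back_scan(matrix(runif(3 * n, -scale, scale), ncol = 3))
}

# smooth structured surface patch for ICP recovery tests
surface_patch <- function(n = 500) {
  x <- runif(n, 0, 120)
  y <- runif(n, 0, 120)
  z <- 12 * sin(x / 15) + 9 * cos(y / 18) + 5 * sin((x + y) / 23)
  back_scan(cbind(x, y, z))
}

rot3 <- function(axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}

# noiseless bilaterally symmetric subject (the symmetry-null fixture)
null_subject <- function(...) {
  make_subject(subject_params(curve_amplitude = 0, hump_amplitude = 0,
                              noise_sd = 0, ...))
}

# a moderately scoliotic noiseless subject
scoliotic_subject <- function(amplitude = 20, ...) {
  make_subject(subject_params(curve_amplitude = amplitude, noise_sd = 0, ...))
}
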