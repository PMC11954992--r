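test_that("mirroring reflects x about the axis and is an involution", {
  s <- back_scan(rbind(c(5, 100, 20), c(-3, 50, 10), c(0, 10, 5)))
  m <- mirror_about_axis(s, 0)
  expect_equal(unclass(m)[1, ], c(x = -5, y = 100, z = 20))
  expect_equal(unclass(mirror_about_axis(m, 0)), unclass(s))
  m7 <- mirror_about_axis(s, 7)
  expect_equal(m7[, 1], 14 - s[, 1])
  expect_equal(m7[, 2:3], s[, 2:3])
  # symmetric cloud: mirrored point set equals the original set
  sym <- back_scan(rbind(c(-2, 0, 1), c(2, 0, 1), c(0, 5, 3)))
  ms <- unclass(mirror_about_axis(sym, 0))
  ord <- function(m) m[order(m[, 1], m[, 2], m[, 3]), ]
  expect_equal(ord(ms), ord(unclass(sym)))
  expect_error(mirror_about_axis(s, NA), class = "backshape_invalid_input")
})

test_that("mean SPL lateral position is the arithmetic mean of sample x", {
  mk <- function(x) spinal_curve(cbind(x, seq(100, 0, length.out = length(x)),
                                       0), role = "SPL")
  expect_equal(mean_spl_lateral(mk(c(-2, 0, 2))), 0)
  expect_equal(mean_spl_lateral(mk(c(7, 7, 7))), 7)
  expect_equal(mean_spl_lateral(mk(c(1, 2, 4))), 7 / 3)
})

test_that("vertical crop keeps the closed SPL y-interval", {
  spl <- straight_spl(y_top = 450, y_bottom = 0)
  s <- back_scan(cbind(0, c(-10, 100, 450, 460, 0), 0))
  cropped <- crop_vertical_extent(s, spl)
  expect_equal(sort(cropped[, 2]), c(0, 100, 450))
  inside <- back_scan(cbind(0, c(10, 20, 30), 0))
  expect_equal(unclass(crop_vertical_extent(inside, spl)), unclass(inside))
  outside <- back_scan(cbind(0, c(-5, -6, 470), 0))
  expect_error(crop_vertical_extent(outside, spl),
               class = "backshape_degenerate_crop")
})

test_that("lateral quantile crop follows the enumerated quantile contract", {
  # 11 points x = -5..5: type-7 quantiles are -4 and 4, threshold 0.75*4 = 3
  s <- back_scan(cbind(-5:5, 100, 0))
  cropped <- crop_lateral_quantile(s, 0, analysis_config())
  expect_equal(sort(cropped[, 1]), -3:3)
  # border_factor = 1 retains exactly the min-quantile distance
  all_kept <- crop_lateral_quantile(s, 0, analysis_config(border_factor = 1))
  expect_equal(sort(all_kept[, 1]), -4:4)
  # symmetric input stays symmetric
  expect_setequal(cropped[, 1], -cropped[, 1])
  degenerate <- back_scan(cbind(rep(2, 5), 1:5, 0))
  expect_error(crop_lateral_quantile(degenerate, 2, analysis_config()),
               class = "backshape_degenerate_crop")
})

test_that("SPL-radius crop measures 3D distance to the nearest sample", {
  spl <- straight_spl(n = 11, y_top = 100, y_bottom = 0)
  on_spl <- back_scan(rbind(c(0, 50, 0), c(0, 0, 0), c(0, 100, 0)))
  expect_equal(nrow(crop_by_spl_radius(on_spl, spl, 0.001)), 3)
  # cylinder of radius 5 around the SPL, points at sample heights
  theta <- seq(0, 2 * pi, length.out = 13)[-13]
  cyl <- back_scan(do.call(rbind, lapply(seq(100, 0, length.out = 11),
    function(yy) cbind(5 * cos(theta), yy, 5 * sin(theta)))))
  expect_equal(nrow(crop_by_spl_radius(cyl, spl, 5 + 1e-9)), nrow(cyl))
  expect_error(crop_by_spl_radius(cyl, spl, 4.9),
               class = "backshape_degenerate_crop")
  # brute-force distance oracle agrees with the kd-tree path
  pts <- matrix(runif(60, -30, 130), ncol = 3)
  d_oracle <- apply(pts, 1, function(p)
    sqrt(min(colSums((t(unclass(spl)) - p)^2))))
  kept <- crop_by_spl_radius(back_scan(pts), spl, 60)
  expect_equal(nrow(kept), sum(d_oracle <= 60))
})

test_that("sagittal inclination is the slope of height on depth", {
  # back lying on the line y = 2 z + 1 in the sagittal plane
  z <- seq(0, 50, length.out = 20)
  s <- back_scan(cbind(runif(20, -5, 5), 2 * z + 1, z))
  expect_equal(sagittal_inclination(s), 2, tolerance = 1e-12)
  # translation leaves the slope unchanged
  s2 <- back_scan(sweep(unclass(s), 2, c(10, -40, 25), "+"))
  expect_equal(sagittal_inclination(s2), 2, tolerance = 1e-12)
  # horizontal back (constant height): slope 0
  flat <- back_scan(cbind(runif(10), 5, seq(0, 90, length.out = 10)))
  expect_equal(sagittal_inclination(flat), 0)
  # constant depth: inclination undefined
  vertical <- back_scan(cbind(0, 1:10, 3))
  expect_error(sagittal_inclination(vertical),
               class = "backshape_undefined_slope")
})

test_that("least-inclined frame selection takes the argmin with early ties", {
  mk <- function(slope) {
    z <- seq(0, 50, length.out = 10)
    back_scan(cbind(0, slope * z, z))
  }
  seq1 <- scan_sequence(list(mk(0.5), mk(0.1), mk(-0.3)))
  expect_equal(select_least_inclined_frame(seq1), 2)
  seq2 <- scan_sequence(list(mk(0.2), mk(-0.2)))
  expect_equal(select_least_inclined_frame(seq2), 1)
  expect_equal(select_least_inclined_frame(scan_sequence(list(mk(1)))), 1)
  # frames with undefined inclination are skipped
  bad <- back_scan(cbind(0, 1:10, 3))
  seq3 <- scan_sequence(list(bad, mk(0.4)))
  expect_equal(select_least_inclined_frame(seq3), 2)
  expect_error(select_least_inclined_frame(scan_sequence(list(bad))),
               class = "backshape_undefined_slope")
})

test_that("frame selection is invariant to uniform rigid translation", {
  set.seed(7)
  frames <- lapply(c(0.6, 0.05, -0.4), function(sl) {
    z <- runif(30, 0, 60)
    back_scan(cbind(runif(30, -40, 40), sl * z + rnorm(30, sd = 0.1), z))
  })
  base <- select_least_inclined_frame(scan_sequence(frames))
  shifted <- lapply(frames, function(f)
    back_scan(sweep(unclass(f), 2, c(12, -300, 40), "+")))
  expect_equal(select_least_inclined_frame(scan_sequence(shifted)), base)
})

test_that("coronal depth map keeps the most posterior point per cell", {
  cfg <- analysis_config(depthmap_resolution = 1)
  single <- project_coronal_depthmap(back_scan(cbind(3, 7, 42)), cfg)
  expect_equal(sum(single$image != single$background), 1)
  expect_equal(max(single$image), 42)
  # two points in one cell: max z wins
  two <- project_coronal_depthmap(
    back_scan(rbind(c(0.2, 0.2, 10), c(0.3, 0.4, 12), c(5, 5, 1))), cfg)
  expect_equal(two$image[1, 1], 12)
  expect_true(all(two$image[two$image != two$background] %in% c(12, 1)))
})

test_that("depth-map back-projection reproduces x/y within half a pixel", {
  set.seed(11)
  pts <- cbind(runif(200, -80, 80), runif(200, 0, 300), runif(200, 0, 40))
  cfg <- analysis_config(depthmap_resolution = 2)
  dm <- project_coronal_depthmap(back_scan(pts), cfg)
  bp <- depthmap_to_points(dm)
  # every back-projected foreground pixel is near some original point
  for (i in seq_len(nrow(bp))) {
    dxy <- abs(sweep(pts[, 1:2, drop = FALSE], 2, unclass(bp)[i, 1:2]))
    expect_true(any(dxy[, 1] <= 1 & dxy[, 2] <= 1))
  }
})

test_that("crops are idempotent", {
  set.seed(3)
  s <- back_scan(cbind(runif(300, -150, 150), runif(300, -30, 480),
                       runif(300, 0, 50)))
  spl <- straight_spl(y_top = 450, y_bottom = 0)
  cfg <- analysis_config()
  v1 <- crop_vertical_extent(s, spl)
  expect_equal(unclass(crop_vertical_extent(v1, spl)), unclass(v1))
  q1 <- crop_lateral_quantile(v1, 0, cfg)
  # re-cropping shrinks the quantile span, so idempotence is on the kept set
  r1 <- crop_by_spl_radius(v1, spl, 80)
  expect_equal(unclass(crop_by_spl_radius(r1, spl, 80)), unclass(r1))
  expect_true(nrow(q1) <= nrow(v1))
})

test_that("sagittal realignment turns the SPL chord vertical", {
  subj <- scoliotic_subject(15, grid_spacing = 10)
  ad <- make_adams_scan(subj, 45)
  re <- realign_sagittal(ad$scan, ad$spl)
  chord <- unclass(re$spl)[1, 2:3] - unclass(re$spl)[nrow(re$spl), 2:3]
  expect_equal(chord[["z"]], 0, tolerance = 1e-9)
  expect_gt(chord[["y"]], 0)
  # rigid: pairwise distances preserved
  d0 <- dist(unclass(ad$spl)[1:5, ])
  d1 <- dist(unclass(re$spl)[1:5, ])
  expect_equal(as.numeric(d1), as.numeric(d0), tolerance = 1e-9)
})
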