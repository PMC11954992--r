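# fast fixtures: coarser 10 mm sampling is enough for these unit checks
null10 <- null_subject(grid_spacing = 10)
scol10 <- scoliotic_subject(20, grid_spacing = 10)

test_that("a symmetric noiseless back has zero asymmetry index", {
  res <- asymmetry_index(null10$scan, null10$spl)
  expect_lt(res$index, 1e-6)
  expect_equal(res$posture, "upright")
  expect_true(all(unlist(res$diagnostics[c("n_after_vertical",
                                           "n_after_lateral")]) >= 3))
})

test_that("a unilateral hump produces a positive index", {
  humped <- make_subject(subject_params(curve_amplitude = 0,
                                        hump_amplitude = 10, noise_sd = 0,
                                        grid_spacing = 10))
  expect_gt(asymmetry_index(humped$scan, humped$spl)$index, 0.1)
})

test_that("the asymmetry index is invariant to joint lateral translation", {
  base <- asymmetry_index(scol10$scan, scol10$spl)$index
  shift <- function(m, dx) {
    m[, 1] <- m[, 1] + dx
    m
  }
  scan2 <- back_scan(shift(unclass(scol10$scan)[, 1:3], 50))
  spl2 <- spinal_curve(shift(unclass(scol10$spl)[, 1:3], 50), role = "SPL")
  expect_equal(asymmetry_index(scan2, spl2)$index, base, tolerance = 1e-9)
})

test_that("the asymmetry map has 17 x 2 structure and a consistent index", {
  res <- asymmetry_map(scol10$scan, scol10$spl)
  expect_s3_class(res$map, "asymmetry_map")
  expect_length(res$map$rmse_left, 17)
  expect_length(res$map$rmse_right, 17)
  expect_length(res$map$region_edges, 18)
  expect_true(all(diff(res$map$region_edges) < 0))
  expect_equal(res$index, mean(res$map$rmse_right, na.rm = TRUE))
  expect_equal(res$index, map_overall_index(res$map))
  expect_true(all(res$map$rmse_left >= 0, na.rm = TRUE))
})

test_that("a symmetric noiseless back yields an all-zero asymmetry map", {
  res <- asymmetry_map(null10$scan, null10$spl)
  vals <- c(res$map$rmse_left, res$map$rmse_right)
  expect_false(anyNA(vals))
  expect_lt(max(vals), 1e-6)
})

test_that("map overall index and coronal differences follow their definitions", {
  mk_map <- function(left, right)
    structure(list(region_edges = seq(450, 0, length.out = 18),
                   rmse_left = left, rmse_right = right),
              class = "asymmetry_map")
  expect_equal(map_overall_index(mk_map(rep(5, 17), rep(3, 17))), 3)
  expect_equal(map_overall_index(mk_map(rep(0, 17), 1:17)), 9)
  # left column has no effect on the overall index
  expect_equal(map_overall_index(mk_map(runif(17), 1:17)), 9)
  expect_equal(coronal_asymmetry_difference(mk_map(rep(2, 17), rep(1, 17))),
               rep(1, 17))
  expect_equal(coronal_asymmetry_difference(mk_map(1:17, 1:17)), rep(0, 17))
  # missing values propagate and the all-missing map errors
  m <- mk_map(c(NA, rep(1, 16)), rep(1, 17))
  expect_true(is.na(coronal_asymmetry_difference(m)[1]))
  expect_error(map_overall_index(mk_map(rep(1, 17), rep(NA_real_, 17))),
               class = "backshape_invalid_input")
})

test_that("a localized prominence lights up its own band with negative d", {
  yk <- 450 * (1 - 7.5 / 17)  # centre of band 8
  mk <- function(side) make_subject(subject_params(
    curve_amplitude = 0, hump_amplitude = 10, hump_side = side,
    hump_center_y = yk, noise_sd = 0, grid_spacing = 10))
  right <- asymmetry_map(mk("right")$scan, mk("right")$spl)
  expect_equal(which.max(right$map$rmse_right), 8)
  d_right <- coronal_asymmetry_difference(right$map)
  expect_lt(d_right[8], 0)
  # the mirror metric compares the same two half-surfaces with roles
  # exchanged, so the measurement is invariant to the side of the hump
  left <- asymmetry_map(mk("left")$scan, mk("left")$spl)
  expect_equal(which.max(left$map$rmse_right), 8)
  expect_equal(coronal_asymmetry_difference(left$map), d_right,
               tolerance = 1e-9)
})

test_that("maximum-bending frame minimizes the two-mean coronal angle", {
  mk_spl <- function(bend_deg) {
    y <- seq(100, 0, length.out = 8)
    spinal_curve(cbind(tan(bend_deg * pi / 180) * y, y, 0), role = "SPL")
  }
  expect_equal(max_bending_frame(lapply(c(10, 40, 25), mk_spl)), 2)
  # all-vertical frames tie; earliest wins
  expect_equal(max_bending_frame(lapply(c(0, 0, 0), mk_spl)), 1)
  # monotone synthetic bend: last frame
  expect_equal(max_bending_frame(lapply(c(5, 15, 30, 45), mk_spl)), 4)
  short <- spinal_curve(cbind(0, c(30, 20, 10), 0), role = "SPL")
  expect_error(max_bending_frame(list(short)),
               class = "backshape_invalid_input")
})

test_that("mirrored-frame matching finds the counterpart by curve RMSE", {
  y <- seq(50, 10, by = -10)
  mk <- function(x) spinal_curve(cbind(x, y, 0), role = "SPL")
  target <- mk(c(3, 1, 0, -1, -3))
  # an exact mirror image (about any plane) is recovered with RMSE 0
  mirror_img <- mk(2 * 30 - c(3, 1, 0, -1, -3))
  hit <- match_mirrored_frame(target, list(mk(c(5, 5, 5, 5, 5)), mirror_img))
  expect_equal(hit$index, 2)
  expect_lt(hit$rmse, 1e-12)
  # hand-enumerated RMSEs against target x = (3,1,0,-1,-3): candidates
  # mirror about x = 0 to (-2,0,0,0,2) and (-1,-1,0,1,1); the nearest
  # target sample is always the one at the same height (y steps of 10
  # dominate the x offsets), so the per-sample distances are (5,1,0,1,5)
  # and (4,2,0,2,4)
  candA <- mk(c(2, 0, 0, 0, -2))
  candB <- mk(c(1, 1, 0, -1, -1))
  got <- match_mirrored_frame(target, list(candA, candB))
  expect_equal(got$index, 2)
  expect_equal(got$rmse, sqrt(40 / 5))
  # joint lateral translation does not change the result
  mks <- function(x, dx) spinal_curve(cbind(x + dx, y, 0), role = "SPL")
  got2 <- match_mirrored_frame(mks(c(3, 1, 0, -1, -3), 70),
                               list(mks(c(2, 0, 0, 0, -2), 70),
                                    mks(c(1, 1, 0, -1, -1), 70)))
  expect_equal(got2$index, 2)
  expect_equal(got2$rmse, got$rmse, tolerance = 1e-9)
})

test_that("lateral-bending index is null for a symmetric subject", {
  lat_l <- make_lateral_sequence(null10, "left", frames = 4)
  lat_r <- make_lateral_sequence(null10, "right", frames = 4)
  res <- lateral_bending_index(lat_l$sequence, lat_r$sequence,
                               lat_l$spls, lat_r$spls, null10$landmarks)
  expect_lt(res$index, 1e-3)
  # half the MSS distance is used as crop radius and surfaced in diagnostics
  mss <- unclass(null10$landmarks)[c("MSS_left", "MSS_right"), ]
  expect_equal(res$diagnostics$radius,
               0.5 * sqrt(sum((mss[1, ] - mss[2, ])^2)))
  expect_equal(res$diagnostics$radius, 80)
})

test_that("a scoliotic subject scores higher than a symmetric one laterally", {
  lat_l0 <- make_lateral_sequence(null10, "left", frames = 4)
  lat_r0 <- make_lateral_sequence(null10, "right", frames = 4)
  base <- lateral_bending_index(lat_l0$sequence, lat_r0$sequence,
                                lat_l0$spls, lat_r0$spls,
                                null10$landmarks)$index
  lat_l <- make_lateral_sequence(scol10, "left", frames = 4)
  lat_r <- make_lateral_sequence(scol10, "right", frames = 4)
  res <- lateral_bending_index(lat_l$sequence, lat_r$sequence,
                               lat_l$spls, lat_r$spls, scol10$landmarks)
  expect_gt(res$index, base + 0.1)
  only_c7 <- landmark_set(matrix(c(0, 450, 40), 1, 3,
                                 dimnames = list("C7", NULL)))
  expect_error(lateral_bending_index(lat_l$sequence, lat_r$sequence,
                                     lat_l$spls, lat_r$spls, only_c7),
               class = "backshape_invalid_input")
})

test_that("asymmetry results serialize to JSON and CSV", {
  res <- asymmetry_map(scol10$scan, scol10$spl)
  parsed <- jsonlite::fromJSON(asymmetry_to_json(res))
  expect_equal(parsed$posture, "upright")
  expect_length(parsed$map$rmse_right, 17)
  csv <- tempfile(fileext = ".csv")
  write_asymmetry_map_csv(res$map, csv)
  df <- read.csv(csv)
  expect_equal(nrow(df), 17)
  expect_equal(df$d, df$rmse_left - df$rmse_right)
})
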