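test_that("index regression recovers an exact linear relation", {
  idx <- c(1, 2, 5, 8)
  model <- fit_index_regression(idx, 2 * idx + 1, posture = "forward")
  expect_equal(model$slope, 2)
  expect_equal(model$intercept, 1)
  expect_equal(model$residual_sd, 0, tolerance = 1e-10)
  expect_equal(model$n, 4)
  expect_error(fit_index_regression(c(1, 2), c(3, 4)),
               class = "backshape_invalid_input")
  expect_error(fit_index_regression(rep(2, 5), 1:5),
               class = "backshape_invalid_input")
})

test_that("index regression recovers a noisy slope within 3 standard errors", {
  set.seed(99)
  idx <- runif(100, 0, 10)
  rca <- 3 * idx + 5 + rnorm(100, sd = 2)
  model <- fit_index_regression(idx, rca)
  se <- model$residual_sd / (sd(idx) * sqrt(99))
  expect_lt(abs(model$slope - 3), 3 * se)
})

test_that("Cobb prediction is the affine model evaluation", {
  model <- fit_index_regression(c(0, 5, 10), c(1, 11, 21))  # slope 2, int 1
  expect_equal(predict_cobb(model, 0)$angle, 1)
  expect_equal(predict_cobb(model, 10)$angle, 21)
  # OLS identity: prediction at the training mean equals the mean response
  set.seed(4)
  idx <- runif(30, 0, 12)
  rca <- 2.5 * idx + rnorm(30)
  m2 <- fit_index_regression(idx, rca)
  expect_equal(predict_cobb(m2, mean(idx))$angle, mean(rca))
})

test_that("weighted combination uses the protocol weights and renormalizes", {
  cfg <- analysis_config()
  all_same <- combine_estimates(c(forward = 20, adams = 20, upright_map = 20,
                                  upright_index = 20, lateral = 20), cfg)
  expect_equal(all_same$angle, 20)
  mixed <- combine_estimates(c(forward = 20, adams = 20, upright_map = 10,
                               upright_index = 10, lateral = 10), cfg)
  expect_equal(mixed$angle, 180 / 11)
  partial <- combine_estimates(c(forward = 20, lateral = 10), cfg)
  expect_equal(partial$angle, 18)
  # convex combination property
  set.seed(10)
  for (i in 1:10) {
    angles <- setNames(runif(5, 0, 60), names(cfg$weights))
    present <- sample(names(angles), sample(1:5, 1))
    e <- combine_estimates(angles[present], cfg)$angle
    expect_gte(e, min(angles[present]) - 1e-12)
    expect_lte(e, max(angles[present]) + 1e-12)
  }
  expect_error(combine_estimates(setNames(numeric(0), character(0)), cfg),
               class = "backshape_invalid_input")
  expect_error(combine_estimates(c(sideways = 5), cfg),
               class = "backshape_invalid_input")
})

test_that("ISL estimation adjusts only the centered coronal profile", {
  subj <- scoliotic_subject(15, grid_spacing = 10)
  d <- sin(seq(0, 2 * pi, length.out = 17))
  zero_gain <- estimate_isl(subj$spl, d, analysis_config(isl_gain = 0))
  expect_equal(unclass(zero_gain$curve)[, 1], unname(subj$spl[, 1]))
  # constant d: centered adjustment vanishes at any gain
  const_d <- estimate_isl(subj$spl, rep(3, 17), analysis_config(isl_gain = 5))
  expect_equal(unclass(const_d$curve)[, 1], unname(subj$spl[, 1]),
               tolerance = 1e-12)
  est <- estimate_isl(subj$spl, d, analysis_config(isl_gain = 2))
  expect_equal(est$curve[, 2], subj$spl[, 2])
  expect_equal(est$curve[, 3], subj$spl[, 3])
  expect_equal(nrow(est$curve), nrow(subj$spl))
  expect_equal(attr(est$curve, "role"), "ISL")
  expect_equal(mean(est$curve[, 1] - subj$spl[, 1]), 0, tolerance = 1e-12)
  expect_error(estimate_isl(subj$spl, rep(NA_real_, 17), analysis_config()),
               class = "backshape_invalid_input")
})

test_that("gain calibration inverts an exact construction and scales", {
  subj <- scoliotic_subject(10, grid_spacing = 10)
  d <- cos(seq(0, 3, length.out = 17))
  adj <- backshape:::centered_station_adjustment(subj$spl, d, 17)
  ref <- spinal_curve(cbind(subj$spl[, 1] + 2 * adj, subj$spl[, 2],
                            subj$spl[, 3]), role = "ISL")
  training <- list(list(spl = subj$spl, d = d, isl = ref))
  expect_equal(calibrate_isl_gain(training), 2, tolerance = 1e-10)
  # reference equal to the SPL: gain 0
  same <- list(list(spl = subj$spl, d = d,
                    isl = spinal_curve(unclass(subj$spl)[, 1:3],
                                       role = "ISL")))
  expect_equal(calibrate_isl_gain(same), 0, tolerance = 1e-10)
  # doubling d halves the fitted gain
  doubled <- list(list(spl = subj$spl, d = 2 * d, isl = ref))
  expect_equal(calibrate_isl_gain(doubled), 1, tolerance = 1e-10)
  flat <- list(list(spl = subj$spl, d = rep(1, 17), isl = ref))
  expect_error(calibrate_isl_gain(flat), class = "backshape_invalid_input")
})

test_that("curve Cobb surrogate matches analytic geometry", {
  # straight vertical line: no curvature
  straight <- spinal_curve(cbind(3, seq(400, 0, length.out = 30), 0),
                           role = "ISL")
  expect_equal(cobb_from_curve(straight), 0)
  # circular arc with 30 degrees of total turning
  alpha <- seq(45, 15, length.out = 100) * pi / 180
  arc <- spinal_curve(cbind(300 * cos(alpha), 300 * sin(alpha), 0),
                      role = "ISL")
  expect_equal(cobb_from_curve(arc), 30, tolerance = 0.2)
  # full-period sine: tangent extrema give 2 atan(2 pi A / L)
  A <- 20
  L <- 400
  y <- seq(L, 0, length.out = 400)
  sine <- spinal_curve(cbind(A * sin(2 * pi * (L - y) / L), y, 0),
                       role = "ISL")
  expect_equal(cobb_from_curve(sine), 2 * atan(2 * pi * A / L) * 180 / pi,
               tolerance = 0.1)
  expect_error(cobb_from_curve(spinal_curve(cbind(0, c(3, 2, 1), 0),
                                            role = "ISL")),
               class = "backshape_invalid_input")
})

test_that("curve Cobb is invariant under small in-plane rotation", {
  A <- 15
  L <- 450
  y <- seq(L, 0, length.out = 200)
  m <- cbind(A * sin(2 * pi * (L - y) / L), y, 0)
  base <- cobb_from_curve(spinal_curve(m, role = "ISL"))
  th <- 3 * pi / 180
  rot <- cbind(cos(th) * m[, 1] + sin(th) * m[, 2],
               -sin(th) * m[, 1] + cos(th) * m[, 2], 0)
  expect_equal(cobb_from_curve(spinal_curve(rot, role = "ISL")), base,
               tolerance = 0.15)
})
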