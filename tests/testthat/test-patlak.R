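test_that("cumulative AIF integral: rectangle, triangle, quadrature oracle", {
  tt <- seq(0, 10, by = 0.5)
  const <- concentration_curve(tt, rep(2, length(tt)))
  ci <- cumulative_aif_integral(const, 0)
  expect_equal(ci$values[length(tt)], 20)
  ramp <- concentration_curve(tt, tt)   # 0 -> 10 over 10 s
  expect_equal(cumulative_aif_integral(ramp, 0)$values[length(tt)], 50)
  # zero before arrival
  ci2 <- cumulative_aif_integral(const, 5)
  expect_equal(ci2$values[tt < 5], rep(0, sum(tt < 5)))
  expect_equal(ci2$values[length(tt)], 10)
  expect_error(cumulative_aif_integral(const, 99))
  # gamma-variate AIF vs adaptive quadrature at 0.58 s sampling
  tr <- synthetic_truth()
  aif <- generate_aif(tr)
  ci3 <- cumulative_aif_integral(aif, tr$arrival)
  t_eval <- tr$arrival + 60
  oracle <- integrate(function(u) aif_value(tr, u), tr$arrival, t_eval,
                      rel.tol = 1e-10, subdivisions = 2000L)$value
  got <- approx(ci3$times, ci3$values, xout = t_eval)$y
  expect_lt(abs(got - oracle) / oracle, 0.001)
})

test_that("evaluation window anchors at the second maximum and counts frames", {
  lm <- list(t_arrival = 10, t_aorta_max2 = 32.3)
  expect_equal(evaluation_window(lm), c(32.3, 92.3))
  tt <- seq(0, 150, by = 0.58)
  aorta <- concentration_curve(tt, rep(1, length(tt)))
  win <- evaluation_window(lm, aorta)
  n_in <- floor((win[2] - win[1]) / 0.58) + 1
  expect_gte(n_in, 100)   # more than 100 regression points in a full window
  # truncated window when the series ends early
  short <- concentration_curve(seq(0, 80, by = 0.58),
                               rep(1, length(seq(0, 80, by = 0.58))))
  expect_warning(win2 <- evaluation_window(lm, short),
                 class = "window_truncated")
  expect_lt(win2[2], 92.3)
  # too-short window errors
  tiny <- concentration_curve(seq(0, 44, by = 0.58),
                              rep(1, length(seq(0, 44, by = 0.58))))
  expect_error(suppressWarnings(evaluation_window(lm, tiny)),
               class = "window_too_short")
})

test_that("Patlak points: vascular-only kidney, identity case, denominator guard", {
  tr <- synthetic_truth()
  aif <- generate_aif(tr)
  win <- c(33, 93)   # starts after the second aortic maximum (~32.2 s)
  # purely vascular kidney: y constant = V_vas, slope 0
  # (delta_t = 8 frames keeps the shifted samples on-grid, so exact)
  dt8 <- 8 * 0.58
  vas <- generate_kidney_curve(aif, v_vas = 6, v_kidney = 30, p = 0,
                               delta_t = dt8, t_arrival = tr$arrival)
  pp <- build_patlak_points(aif, vas, delta_t = dt8, v_kidney = 30,
                            t_arrival = tr$arrival, window = win)
  expect_equal(pp$y, rep(6, length(pp$y)), tolerance = 1e-9)
  ft <- fit_patlak(pp)
  expect_equal(ft$slope_m, 0, tolerance = 1e-9)
  expect_equal(ft$intercept_b, 6, tolerance = 1e-9)
  # delta_t = 0, kidney == aorta, V = 1 -> y = 1
  pp2 <- build_patlak_points(aif, aif, delta_t = 0, v_kidney = 1,
                             t_arrival = tr$arrival, window = win)
  expect_equal(pp2$y, rep(1, length(pp2$y)))
  # x is non-negative and non-decreasing while the aorta declines
  expect_true(all(pp2$x >= 0))
  expect_true(all(diff(pp2$x) > -1e-9))
  # degenerate denominator: all frames dropped
  dead <- concentration_curve(aif$times,
                              ifelse(aif$times < tr$arrival + 20,
                                     aif$values, 0))
  expect_error(build_patlak_points(dead, vas, 4, 30, tr$arrival,
                                   window = c(30, 90)),
               class = "degenerate_denominator")
})

test_that("Patlak invariances: aorta rescaling leaves x; y scales with V_kidney", {
  tr <- synthetic_truth()
  aif <- generate_aif(tr)
  kid <- generate_kidney_curve(aif, 6, 30, 0.04, 5, tr$arrival)
  win <- c(32, 92)
  pp <- build_patlak_points(aif, kid, 5, 30, tr$arrival, win)
  aif2 <- curve_with_values(aif, 3.7 * aif$values)
  pp2 <- build_patlak_points(aif2, kid, 5, 30, tr$arrival, win)
  expect_equal(pp2$x, pp$x, tolerance = 1e-12)
  expect_equal(pp2$y, pp$y / 3.7, tolerance = 1e-12)
  pp3 <- build_patlak_points(aif, kid, 5, 60, tr$arrival, win)
  expect_equal(pp3$y, 2 * pp$y, tolerance = 1e-12)
})

test_that("fit_patlak: exact line, guards", {
  tt <- seq(0, 30, by = 0.58)
  x <- seq(1, 20, length.out = 40)
  pts <- structure(list(x = x, y = 3 + 0.5 * x, t = x, window = c(0, 60),
                        v_kidney = 30, delta_t = 5, n_dropped = 0),
                   class = "patlak_points")
  ft <- fit_patlak(pts)
  expect_equal(ft$slope_m, 0.5, tolerance = 1e-12)
  expect_equal(ft$intercept_b, 3, tolerance = 1e-12)
  expect_equal(ft$r_squared, 1)
  pts$x <- rep(2, 40); pts$y <- rnorm(40)
  expect_error(fit_patlak(pts), class = "zero_x_variance")
  pts$x <- 1:5
  expect_error(fit_patlak(pts), class = "too_few_points")
})

test_that("gfr_from_slope is the linear plasma-normalized conversion", {
  s0 <- subject("u", body_weight = 1, hematocrit = 0.5, body_surface = 1)
  expect_equal(gfr_from_slope(1, subject("u", 1, hematocrit = 1e-9,
                                         body_surface = 1)),
               60, tolerance = 1e-6)
  expect_equal(gfr_from_slope(0, s0), 0)
  # back-calculated reference slope reproduces the mean left-kidney value
  dog <- subject("dog", 17.5, hematocrit = 0.47, body_surface = 0.675)
  expect_equal(gfr_from_slope(0.2696, dog), 12.7, tolerance = 0.01)
  # linear and homogeneous in slope
  expect_equal(gfr_from_slope(2 * 0.13, dog), 2 * gfr_from_slope(0.13, dog))
})

test_that("pipeline propagates stage labels on failure", {
  ss <- fx_subject()
  bad <- ss$curves
  bad$aorta_all <- concentration_curve(bad$aorta_all$times,
                                       rep(1, length(bad$aorta_all)))
  err <- tryCatch(
    run_subject_pipeline(curves = bad, geometry = ss$geometry,
                         subj = ss$subject),
    error = function(e) e)
  expect_match(conditionMessage(err), "\\[stage landmarks\\]")
})

test_that("pipeline requires kidney volumes", {
  ss <- fx_subject()
  expect_error(
    run_subject_pipeline(curves = ss$curves, geometry = NULL,
                         subj = ss$subject),
    "volume")
})
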