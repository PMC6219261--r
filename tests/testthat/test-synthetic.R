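test_that("AIF self-checks: peak scaling, landmark phenomenology, invariant guards", {
  tr <- synthetic_truth(peak_conc = 125)
  aif <- generate_aif(tr, seq(0, tr$duration, by = 0.1))
  expect_lt(abs(max(aif$values) - 125) / 125, 0.01)
  # default truth targets the reference landmark means
  tl <- fx_subject()$truth_landmarks
  expect_lt(abs(tl$t_aorta_max1 - 8.5), 0.58)
  expect_lt(abs(tl$t_aorta_min1 - 23.9), 0.58)
  expect_lt(abs(tl$t_aorta_max2 - 32.3), 0.58)
  expect_lt(abs(tl$kidneys$left$t_kidney_max1 - 14.5), 0.58)
  expect_lt(tl$c_aorta_max2, tl$c_aorta_max1)
  # default kidney peaks inside the observed 4-16 umol/mL band
  expect_gt(tl$kidneys$left$c_kidney_max1, 4)
  expect_lt(tl$kidneys$left$c_kidney_max1, 16)
  expect_error(synthetic_truth(v_vas = 30, v_kidney = 30), "v_vas")
  expect_error(synthetic_truth(delta_t = -1))
})

test_that("kidney curve: p = 0 gives a scaled, delayed AIF copy", {
  tr <- synthetic_truth()
  aif <- generate_aif(tr)
  kid <- generate_kidney_curve(aif, v_vas = 6, v_kidney = 30, p = 0,
                               delta_t = 5, t_arrival = tr$arrival)
  shifted <- approx(aif$times + 5, aif$values, xout = aif$times)$y
  ok <- !is.na(shifted) & aif$times >= tr$arrival + 5
  expect_equal(kid$values[ok], (6 / 30) * shifted[ok], tolerance = 1e-9)
  expect_true(all(kid$values[aif$times < tr$arrival + 5] == 0))
})

test_that("noiseless Patlak round trip recovers slope within 0.5%", {
  ss <- fx_subject()
  tr <- ss$truth
  for (side in c("left", "right")) {
    kd <- tr$kidneys[[side]]
    pp <- build_patlak_points(ss$curves$aorta_all,
                              ss$curves[[paste0("kidney_", side)]],
                              delta_t = kd$delta_t, v_kidney = kd$v_kidney,
                              t_arrival = tr$arrival,
                              window = c(ss$truth_landmarks$t_aorta_max2,
                                         ss$truth_landmarks$t_aorta_max2 + 60))
    ft <- fit_patlak(pp)
    expect_lt(abs(ft$slope_m - kd$slope) / kd$slope, 0.005)
    expect_lt(abs(ft$intercept_b - kd$v_vas) / kd$v_vas, 0.02)
    expect_gt(ft$r_squared, 0.999)
  }
})

test_that("measurement noise: identity at zero, seed determinism, smoothable", {
  ss <- fx_subject()
  cv <- ss$curves$kidney_left
  expect_curve_equal(add_measurement_noise(cv, 0, 0, seed = 5), cv)
  n1 <- add_measurement_noise(cv, 0.03, 0.05, 4, seed = 99)
  n2 <- add_measurement_noise(cv, 0.03, 0.05, 4, seed = 99)
  expect_identical(n1$values, n2$values)
  n3 <- add_measurement_noise(cv, 0.03, 0.05, 4, seed = 100)
  expect_false(identical(n1$values, n3$values))
  # RNG state of the caller is untouched
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(add_measurement_noise(cv, 0.03, seed = 7))
  expect_identical(runif(1), before)
  # smoothing recovers most of the high-frequency noise variance
  sm <- smooth_curve(n1, 15, 2)
  interior <- 10:(length(cv) - 9)
  v_in <- var((n1$values - cv$values)[interior])
  v_out <- var((sm$values - cv$values)[interior])
  expect_lt(v_out, 0.3 * v_in)
})

test_that("simulate_subject: forward-model consistency and seeded reproducibility", {
  ss <- fx_subject()
  expect_named(ss$curves,
               c("aorta_all", "kidney_left", "kidney_right", "cortex_left",
                 "cortex_right", "correction_aorta", "correction_left",
                 "correction_right"))
  expect_equal(ss$truth_gfr$total, ss$truth_gfr$left + ss$truth_gfr$right)
  # truth GFR consistent with slope * 60 / BS * (1 - hct)
  kd <- ss$truth$kidneys$left
  expect_equal(kd$gfr,
               kd$p * kd$v_vas * 60 / ss$truth$body_surface *
                 (1 - ss$truth$hematocrit),
               tolerance = 1e-12)
  s1 <- simulate_subject(synthetic_truth(seed = 7), noise = TRUE)
  s2 <- simulate_subject(synthetic_truth(seed = 7), noise = TRUE)
  expect_identical(s1$curves$aorta_all$values, s2$curves$aorta_all$values)
})

test_that("voxel-mixed subject is inverted exactly by the correction", {
  ss_mixed <- simulate_subject(synthetic_truth(), noise = FALSE, mix = TRUE)
  ss_pure <- fx_subject()
  for (nm in c("kidney_left", "aorta_all")) {
    g <- ss_mixed$geometry[[nm]]
    expect_gt(g$v_residual, 0)
    rec <- suppressWarnings(correct_residual_tissue(
      ss_mixed$curves[[nm]],
      ss_mixed$curves[[if (nm == "aorta_all") "correction_aorta"
                       else "correction_left"]], g))
    expect_equal(rec$values, ss_pure$curves[[nm]]$values, tolerance = 1e-9)
  }
})

test_that("rendered dynamic series: structure, zero-subject, full round trip", {
  ss <- fx_subject()
  rd <- suppressWarnings(render_dynamic_series(ss))
  expect_s3_class(rd$series, "dynamic_series")
  expect_s3_class(rd$rois, "roi_set")
  expect_false(rd$series$subtracted)
  expect_true(all(vapply(rd$rois, any, logical(1))))
  expect_equal(dim(rd$series$frames)[3], length(ss$curves$aorta_all))
  # full image pipeline reproduces tissue curves within 1% of peak
  sub <- subtract_baseline(rd$series)
  corr_map <- c(aorta_all = "correction_aorta", kidney_left = "correction_left",
                kidney_right = "correction_right")
  for (nm in names(corr_map)) {
    cc <- suppressWarnings(curve_to_concentration(
      extract_roi_mean(sub, rd$rois[[nm]], roi = nm)))
    cr <- suppressWarnings(curve_to_concentration(
      extract_roi_mean(sub, rd$rois[[corr_map[[nm]]]], roi = "corr")))
    fixed <- suppressWarnings(
      correct_residual_tissue(cc, cr, rd$geometry[[nm]]))
    truth <- ss$curves[[nm]]
    expect_lt(max(abs(fixed$values - truth$values)) / max(truth$values),
              0.01)
  }
  # zero-concentration subject -> all-zero after subtraction
  tr0 <- synthetic_truth(peak_conc = 1)
  ss0 <- simulate_subject(tr0, noise = FALSE)
  for (nm in names(ss0$curves))
    ss0$curves[[nm]]$values <- ss0$curves[[nm]]$values * 0
  rd0 <- suppressWarnings(render_dynamic_series(ss0))
  expect_equal(max(abs(subtract_baseline(rd0$series)$frames)), 0)
})

test_that("generate_dilution_table: determinism and out-of-domain error", {
  m <- default_calibration()
  t1 <- generate_dilution_table(m, sd_frac = 0.02, seed = 3)
  t2 <- generate_dilution_table(m, sd_frac = 0.02, seed = 3)
  expect_identical(t1$mean_si, t2$mean_si)
  t0 <- generate_dilution_table(m, sd_frac = 0)
  expect_equal(t0$mean_si, concentration_to_si(t0$concentration, m))
  expect_error(generate_dilution_table(m, concentrations = c(-3, 1)),
               class = "calibration_domain_error")
})
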