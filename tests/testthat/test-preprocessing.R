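make_series <- function(nx = 4, ny = 3, nt = 25, fill = 0) {
  dynamic_series(array(fill, dim = c(nx, ny, nt)), frame_interval = 0.58)
}

test_that("subtract_baseline zeroes the reference, recovers enhancement, is idempotent", {
  base <- matrix(runif(12, 50, 150), 4, 3)
  enh <- array(0, dim = c(4, 3, 25))
  for (t in 4:25) enh[, , t] <- matrix(t, 4, 3)
  raw <- sweep(enh, c(1, 2), base, `+`)
  raw[, , 1:3] <- array(rep(base, 3), dim = c(4, 3, 3))
  ser <- dynamic_series(raw, frame_interval = 0.58)

  sub <- subtract_baseline(ser)
  expect_true(sub$subtracted)
  expect_equal(sub$frames, enh)
  # series equal to its baseline everywhere -> all-zero output
  flat <- dynamic_series(array(rep(base, 25), dim = c(4, 3, 25)))
  expect_equal(subtract_baseline(flat)$frames, array(0, dim = c(4, 3, 25)))
  # idempotence
  expect_warning(sub2 <- subtract_baseline(sub), class = "already_subtracted")
  expect_equal(sub2$frames, sub$frames)
})

test_that("extract_roi_mean equals a brute-force mean and is linear", {
  set.seed(42)
  arr <- array(rnorm(4 * 3 * 25), dim = c(4, 3, 25))
  ser <- dynamic_series(arr)
  mask <- matrix(FALSE, 4, 3); mask[c(1, 5, 9, 12)] <- TRUE
  got <- extract_roi_mean(ser, mask)
  brute <- sapply(1:25, function(t) {
    vals <- c()
    for (i in 1:4) for (j in 1:3) if (mask[i, j]) vals <- c(vals, arr[i, j, t])
    mean(vals)
  })
  expect_equal(got$values, brute)
  expect_equal(got$times, (0:24) * 0.58)
  # single voxel mask -> that voxel's trace
  m1 <- matrix(FALSE, 4, 3); m1[2, 2] <- TRUE
  expect_equal(extract_roi_mean(ser, m1)$values, arr[2, 2, ])
  # two voxels with traces f and -f -> zero curve
  arr2 <- array(0, dim = c(4, 3, 25))
  arr2[1, 1, ] <- sin(1:25); arr2[2, 1, ] <- -sin(1:25)
  m2 <- matrix(FALSE, 4, 3); m2[1:2, 1] <- TRUE
  expect_equal(extract_roi_mean(dynamic_series(arr2), m2)$values, rep(0, 25))
  # linearity in the series
  serA <- dynamic_series(arr); serB <- dynamic_series(arr2)
  serAB <- dynamic_series(arr + 2 * arr2)
  expect_equal(extract_roi_mean(serAB, m2)$values,
               extract_roi_mean(serA, m2)$values +
                 2 * extract_roi_mean(serB, m2)$values)
  expect_error(extract_roi_mean(ser, matrix(FALSE, 4, 3)))
})

test_that("Savitzky-Golay smoothing reproduces low-order polynomials exactly", {
  tt <- seq(0, 30, by = 0.58)
  for (po in c(2, 3)) {
    v <- 3 - 0.5 * tt + 0.1 * tt^min(po, 2)
    sc <- signal_curve(tt, v)
    sm <- smooth_curve(sc, 15, poly_order = po)
    interior <- 8:(length(tt) - 7)
    expect_equal(sm$values[interior], v[interior], tolerance = 1e-9)
  }
  # constant curve is untouched everywhere (mirror padding included)
  const <- smooth_curve(signal_curve(tt, rep(7, length(tt))), 15, 2)
  expect_equal(const$values, rep(7, length(tt)), tolerance = 1e-12)
  expect_true(const$smoothed)
  # independent oracle: centre value of a local quadratic lm fit
  set.seed(7)
  v <- cumsum(rnorm(length(tt)))
  sm <- smooth_curve(signal_curve(tt, v), 15, 2)
  i <- 20
  fit <- lm(y ~ x + I(x^2), data = data.frame(x = -7:7, y = v[(i - 7):(i + 7)]))
  expect_equal(sm$values[i], unname(coef(fit)[1]), tolerance = 1e-9)
})

test_that("smoothing suppresses high-frequency oscillation on a trend", {
  tt <- seq(0, 60, by = 0.58)
  trend <- 0.5 * tt
  hf <- sin(2 * pi * tt / (3 * 0.58))   # period of 3 frames
  sm <- smooth_curve(signal_curve(tt, trend + hf), 15, 2)
  resid_in <- hf
  resid_out <- sm$values - trend
  interior <- 10:(length(tt) - 9)
  expect_lt(var(resid_out[interior]), 0.2 * var(resid_in[interior]))
})

test_that("smoothing rejects invalid windows and preserves grid", {
  sc <- signal_curve(seq(0, 10, by = 0.5), rnorm(21))
  expect_error(smooth_curve(sc, 14), "odd")
  expect_error(smooth_curve(sc, 3, poly_order = 2), "poly_order")
  expect_error(smooth_curve(sc, 23), "longer")
  sm <- smooth_curve(sc, 7, edge = "fit")
  expect_equal(sm$times, sc$times)
  expect_equal(length(sm), length(sc))
})

test_that("residual-tissue correction implements the mixing formula", {
  tt <- seq(0, 12, by = 0.58)
  organ <- concentration_curve(tt, rep(2, length(tt)))
  res <- concentration_curve(tt, rep(1, length(tt)))
  g <- tissue_geometry(v_voxel = 10, v_tissue = 5)
  expect_equal(g$v_residual, 5)
  out <- correct_residual_tissue(organ, res, g)
  expect_equal(unique(out$values), 2 * 2 - 1 * 1)  # 3 mmol/L
  # no residual tissue -> identity
  gid <- tissue_geometry(8, 8)
  expect_curve_equal(correct_residual_tissue(organ, res, gid), organ)
  # mixture consistency: mixing then correcting returns the truth exactly
  set.seed(11)
  c_true <- abs(rnorm(length(tt), 5))
  c_res <- abs(rnorm(length(tt), 1))
  g2 <- tissue_geometry(v_voxel = 13.7, v_tissue = 6.1)
  c_vox <- (c_true * g2$v_tissue + c_res * g2$v_residual) / g2$v_voxel
  rec <- correct_residual_tissue(concentration_curve(tt, c_vox),
                                 concentration_curve(tt, c_res), g2)
  expect_equal(rec$values, c_true, tolerance = 1e-12)
  # guards
  expect_error(tissue_geometry(10, 0))
  expect_error(tissue_geometry(10, 11))
  expect_error(correct_residual_tissue(
    organ, concentration_curve(tt + 1, res$values), g))
  expect_warning(
    correct_residual_tissue(
      concentration_curve(tt, rep(0.1, length(tt))), res, g),
    class = "negative_concentration")
})

test_that("body surface area and subject metadata", {
  expect_equal(body_surface_area(1), 0.1)
  expect_equal(body_surface_area(14), 0.1 * 14^0.667, tolerance = 1e-12)
  expect_equal(body_surface_area(14), 0.58139, tolerance = 1e-4)
  expect_equal(body_surface_area(22), 0.78595, tolerance = 1e-4)
  expect_error(body_surface_area(0))
  s <- subject("d1", 17.5)
  expect_equal(s$hematocrit, 0.47)
  expect_equal(s$body_surface, body_surface_area(17.5))
  expect_error(subject("d2", 10, hematocrit = 1.2))
})
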