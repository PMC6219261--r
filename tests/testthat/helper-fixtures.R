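# Shared fixtures, memoised so expensive objects are built once per run.
.fx <- new.env(parent = emptyenv())

fx_get <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- build()
  .fx[[name]]
}

# noiseless default synthetic subject + its pipeline result
fx_subject <- function() fx_get("subject", function() {
  simulate_subject(synthetic_truth(), noise = FALSE)
})

fx_result <- function() fx_get("result", function() {
  ss <- fx_subject()
  run_subject_pipeline(curves = ss$curves, geometry = ss$geometry,
                       subj = ss$subject)
})

# absolute-time landmark vectors (aorta max1/min1/max2 + left kidney max1)
abs_landmarks <- function(lm) {
  lm$t_arrival + c(lm$t_aorta_max1, lm$t_aorta_min1, lm$t_aorta_max2,
                   lm$kidneys$left$t_kidney_max1)
}

expect_curve_equal <- function(a, b, tol = 1e-9) {
  expect_equal(a$times, b$times, tolerance = tol)
  expect_equal(a$values, b$values, tolerance = tol)
}
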