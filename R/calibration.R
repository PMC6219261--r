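#' Serial-dilution calibration: signal intensity to gadolinium concentration
#'
#' A serial dilution of Gd-DOTA in saline, scanned with the bolus-track
#' sequence, yields mean signal intensity (SI) per known concentration. Over
#' the working range (0-15 mmol/L, SI 0-1200) concentration is well described
#' by an ascending exponential in SI,
#' \deqn{c(S) = a + b e^{x S},}
#' which this module fits by nonlinear least squares and compares against a
#' third-degree polynomial via AIC. Above ~40 mmol/L T2*-effects make SI
#' non-monotone; that regime is outside the validity range and only warned
#' about, never modelled.
#'
#' @name calibration
NULL

#' Build a serial-dilution table
#'
#' @param concentration numeric, mmol/L per tube, strictly increasing,
#'   non-negative.
#' @param mean_si numeric, mean signal intensity (a.u.) per tube, averaged
#'   over replicate scans.
#' @return A `data.frame` of class `dilution_table` with columns
#'   `concentration` and `mean_si`.
#' @export
dilution_table <- function(concentration, mean_si) {
  concentration <- as.numeric(concentration)
  mean_si <- as.numeric(mean_si)
  stopifnot(length(concentration) == length(mean_si))
  if (anyNA(concentration) || any(concentration < 0))
    stop("concentrations must be finite and non-negative", call. = FALSE)
  if (is.unsorted(concentration, strictly = TRUE))
    stop("concentrations must be strictly increasing (one SI per tube)",
         call. = FALSE)
  structure(data.frame(concentration = concentration, mean_si = mean_si),
            class = c("dilution_table", "data.frame"))
}

#' Read a dilution table from CSV
#'
#' Expects a header with columns `concentration_mmol_per_L` and `mean_si`.
#'
#' @param path file path.
#' @return A [dilution_table()].
#' @export
read_dilution_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("concentration_mmol_per_L", "mean_si")
  if (!all(need %in% names(df)))
    stop_with("schema_error", "dilution CSV needs columns: ",
              paste(need, collapse = ", "))
  dilution_table(df$concentration_mmol_per_L, df$mean_si)
}

#' Construct a calibration model
#'
#' @param a offset, mmol/L.
#' @param b scale, mmol/L; must be > 0.
#' @param x rate, 1/a.u.; must be > 0 so the map is strictly increasing.
#' @param si_valid_max upper end of the validated SI range (a.u.).
#' @param conc_valid_max upper end of the validated concentration range
#'   (mmol/L).
#' @param aic_exponential,aic_cubic optional AIC values recorded by
#'   [fit_si_concentration_models()].
#' @return An object of class `calibration_model`.
#' @export
calibration_model <- function(a, b, x, si_valid_max = 1200,
                              conc_valid_max = 15,
                              aic_exponential = NA_real_,
                              aic_cubic = NA_real_) {
  stopifnot(is.finite(a), is.finite(b), is.finite(x))
  if (b <= 0 || x <= 0)
    stop("calibration requires b > 0 and x > 0 (strictly increasing map)",
         call. = FALSE)
  if (si_valid_max <= 0) stop("si_valid_max must be > 0", call. = FALSE)
  structure(list(a = a, b = b, x = x,
                 si_valid_max = si_valid_max, conc_valid_max = conc_valid_max,
                 aic_exponential = aic_exponential, aic_cubic = aic_cubic),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(
    "<calibration_model> c(S) = %.6g + %.6g * exp(%.6g * S)  [valid SI 0-%g, c <= %g mmol/L]\n",
    x$a, x$b, x$x, x$si_valid_max, x$conc_valid_max))
  if (is.finite(x$aic_exponential))
    cat(sprintf("  AIC exponential %.3f vs cubic %.3f\n",
                x$aic_exponential, x$aic_cubic))
  invisible(x)
}

#' The built-in default calibration model
#'
#' Exponential constants from the reference serial dilution of Gd-DOTA at 3 T
#' with the bolus-track sequence: a = -1.933 mmol/L, b = 1.996 mmol/L,
#' x = 0.001876 per a.u., validated on SI 0-1200 (concentration 0-15 mmol/L).
#' The original dilution tubes are not refittable; these constants ship with
#' the package (`inst/extdata/calibration_default.json`).
#'
#' @return A [calibration_model()].
#' @export
default_calibration <- function() {
  read_calibration_json(system.file("extdata", "calibration_default.json",
                                    package = "patlakGFR", mustWork = TRUE))
}

#' Read / write a calibration model as JSON
#'
#' JSON keys: `a`, `b`, `x`, `si_valid_max`, `conc_valid_max`.
#'
#' @param path file path.
#' @return `read_calibration_json()` returns a [calibration_model()];
#'   `write_calibration_json()` returns `path` invisibly.
#' @export
read_calibration_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  calibration_model(a = j$a, b = j$b, x = j$x,
                    si_valid_max = j$si_valid_max %||% 1200,
                    conc_valid_max = j$conc_valid_max %||% 15)
}

#' @rdname read_calibration_json
#' @param model a [calibration_model()].
#' @export
write_calibration_json <- function(model, path) {
  stopifnot(inherits(model, "calibration_model"))
  jsonlite::write_json(
    model[c("a", "b", "x", "si_valid_max", "conc_valid_max")],
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert signal intensity to concentration
#'
#' Evaluates `a + b * exp(x * si)`. SI above the model's validated range is
#' extrapolated (the bolus peak briefly exceeds it in vivo) and a
#' `calibration_out_of_range` warning is raised; set `clip = TRUE` to clamp at
#' `si_valid_max` instead.
#'
#' @param si numeric, signal intensity in a.u.; must be >= 0.
#' @param model a [calibration_model()].
#' @param clip clamp out-of-range SI to `si_valid_max` instead of
#'   extrapolating.
#' @return Concentration in mmol/L, same length as `si`.
#' @export
si_to_concentration <- function(si, model = default_calibration(),
                                clip = FALSE) {
  stopifnot(inherits(model, "calibration_model"))
  if (anyNA(si) || any(si < 0))
    stop("si must be finite and non-negative", call. = FALSE)
  n_out <- sum(si > model$si_valid_max)
  if (n_out > 0) {
    if (clip) si <- pmin(si, model$si_valid_max)
    warn_with("calibration_out_of_range",
              n_out, " SI value(s) above validity limit ", model$si_valid_max,
              if (clip) " (clipped)" else " (extrapolated)")
  }
  model$a + model$b * exp(model$x * si)
}

#' Convert concentration to signal intensity (inverse map)
#'
#' Strict inverse of [si_to_concentration()]: `log((c - a)/b)/x`. Only defined
#' for `c > a`; physically meaningful (SI >= 0) for `c >= a + b`.
#'
#' @param conc numeric, mmol/L.
#' @inheritParams si_to_concentration
#' @return Signal intensity in a.u.
#' @export
concentration_to_si <- function(conc, model = default_calibration()) {
  stopifnot(inherits(model, "calibration_model"))
  if (anyNA(conc) || any(conc <= model$a))
    stop_with("calibration_domain_error",
              "concentration must exceed the model offset a = ", model$a)
  log((conc - model$a) / model$b) / model$x
}

#' AIC of a least-squares fit (Gaussian residuals)
#'
#' `n * log(RSS/n) + 2k`, with k counting the fitted coefficients plus the
#' residual variance. Used identically for the exponential (k = 4) and the
#' cubic (k = 5) calibration candidates.
#'
#' @param rss residual sum of squares.
#' @param n number of points.
#' @param k number of parameters (coefficients + 1 for sigma^2).
#' @return AIC, unitless.
#' @export
gaussian_aic <- function(rss, n, k) {
  stopifnot(n > 0, rss >= 0)
  n * log(max(rss, .Machine$double.xmin) / n) + 2 * k
}

#' Evidence ratio of two models from their AICs
#'
#' `exp((aic_high - aic_low)/2)`: how many times more probable the lower-AIC
#' model is than the higher-AIC one (relative likelihood).
#'
#' @param aic_low AIC of the preferred (lower-AIC) model.
#' @param aic_high AIC of the other model.
#' @return Evidence ratio >= 1 when `aic_low <= aic_high`.
#' @export
aic_relative_likelihood <- function(aic_low, aic_high) {
  if (!is.finite(aic_low) || !is.finite(aic_high))
    stop("AIC values must be finite", call. = FALSE)
  exp((aic_high - aic_low) / 2)
}

#' Fit the SI-to-concentration calibration models
#'
#' Restricts the table to `mean_si <= si_max`, then fits concentration on SI:
#' the ascending exponential `c = a + b*exp(x*S)` by nonlinear least squares
#' (profiled: for fixed rate x the model is linear in a, b, so a 1-D
#' optimisation over x with an `nls` polish), and a third-degree polynomial on
#' the same points. Records the Gaussian AIC of both (k = 4 exponential,
#' k = 5 cubic).
#'
#' @param table a [dilution_table()].
#' @param si_max upper SI bound of the fit range (a.u.), default 1200.
#' @param conc_valid_max recorded validity limit in mmol/L, default the
#'   largest in-range concentration.
#' @return A [calibration_model()] with `aic_exponential` and `aic_cubic`
#'   filled in.
#' @export
fit_si_concentration_models <- function(table, si_max = 1200,
                                        conc_valid_max = NULL) {
  stopifnot(inherits(table, "dilution_table"))
  keep <- table$mean_si <= si_max
  tab <- table[keep, , drop = FALSE]
  if (nrow(tab) < 5)
    stop_with("insufficient_data",
              "need >= 5 dilution points with mean_si <= ", si_max,
              ", got ", nrow(tab))
  # SI must increase with concentration within the fit range; if it rolls
  # over (T2* regime leaking in), keep the monotone prefix and warn
  if (is.unsorted(tab$mean_si, strictly = TRUE)) {
    up <- which(diff(tab$mean_si) <= 0)
    warn_with("nonmonotone_si",
              "SI not strictly increasing in fit range; using monotone ",
              "prefix of ", up[1], " rows")
    tab <- tab[seq_len(up[1]), , drop = FALSE]
    if (nrow(tab) < 5)
      stop_with("insufficient_data",
                "monotone prefix has fewer than 5 rows")
  }
  conc <- tab$concentration
  si <- tab$mean_si
  if (stats::sd(conc) == 0)
    stop_with("insufficient_signal",
              "constant concentration across tubes: nothing to fit")
  n <- length(conc)

  rss_given_x <- function(xr) {
    e <- exp(xr * si)
    f <- stats::lm.fit(cbind(1, e), conc)
    sum(f$residuals^2)
  }
  # search the rate on a log grid, refine with optimize()
  x_grid <- exp(seq(log(1e-5), log(0.05), length.out = 60))
  r <- vapply(x_grid, rss_given_x, numeric(1))
  i0 <- which.min(r)
  lo <- x_grid[max(1, i0 - 1)]; hi <- x_grid[min(length(x_grid), i0 + 1)]
  opt <- stats::optimize(rss_given_x, c(lo, hi), tol = 1e-14)
  x_hat <- opt$minimum
  ab <- stats::lm.fit(cbind(1, exp(x_hat * si)), conc)$coefficients
  a_hat <- ab[[1]]; b_hat <- ab[[2]]

  # nls polish from the profiled solution (falls back silently if singular)
  fit <- tryCatch(
    stats::nls(conc ~ a + b * exp(x * si),
               start = list(a = a_hat, b = b_hat, x = x_hat),
               control = stats::nls.control(maxiter = 200, tol = 1e-10,
                                            minFactor = 1e-12)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    a_hat <- cf[["a"]]; b_hat <- cf[["b"]]; x_hat <- cf[["x"]]
  }
  if (b_hat <= 0 || x_hat <= 0)
    stop_with("insufficient_signal",
              "degenerate exponential fit (b <= 0 or x <= 0): SI carries no ",
              "ascending signal")
  rss_exp <- sum((conc - (a_hat + b_hat * exp(x_hat * si)))^2)

  cub <- stats::lm(conc ~ poly(si, 3, raw = TRUE))
  rss_cub <- sum(stats::residuals(cub)^2)

  calibration_model(
    a = a_hat, b = b_hat, x = x_hat,
    si_valid_max = si_max,
    conc_valid_max = conc_valid_max %||% max(conc),
    aic_exponential = gaussian_aic(rss_exp, n, 4),
    aic_cubic = gaussian_aic(rss_cub, n, 5))
}

#' Convert a signal curve to a concentration curve
#'
#' Element-wise [si_to_concentration()]. Negative post-subtraction SI (noise)
#' is clipped to 0 with a warning; out-of-range SI warnings are aggregated to
#' one per curve.
#'
#' @param curve a [signal_curve()].
#' @inheritParams si_to_concentration
#' @return A [concentration_curve()] on the same time grid.
#' @export
curve_to_concentration <- function(curve, model = default_calibration(),
                                   clip = FALSE) {
  stopifnot(inherits(curve, "signal_curve"))
  v <- curve$values
  if (any(v < 0)) {
    warn_with("negative_si", sum(v < 0),
              " negative SI value(s) clipped to 0 before conversion")
    v <- pmax(v, 0)
  }
  conc <- si_to_concentration(v, model, clip = clip)
  curve_with_values(curve, conc, units = "mmol/L")
}
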