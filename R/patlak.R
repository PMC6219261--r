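#' Time-shift-modified Rutland-Patlak analysis
#'
#' The Rutland-Patlak plot linearizes a two-compartment tracer model: with
#' \eqn{c_{kidney}} the whole-kidney concentration, \eqn{c_{aorta}} the
#' arterial input, \eqn{V_{kidney}} the kidney volume, \eqn{V_{vas}} the
#' renal vascular volume and \eqn{p} the clearance proportionality constant,
#' \deqn{\frac{c_{kidney}(t+\Delta t)\,V_{kidney}}{c_{aorta}(t)} =
#'   V_{vas} + p V_{vas}\,
#'   \frac{\int_0^{t} c_{aorta}(t')\,dt'}{c_{aorta}(t)}.}
#' The kidney curve is shifted by the aorta-to-kidney delay \eqn{\Delta t} so
#' the model's steady-state assumption holds. Plotting y against x gives a
#' straight line with slope \eqn{m = p V_{vas}} (renal clearance, mL/s) and
#' intercept \eqn{b = V_{vas}} (mL). The line is fitted by ordinary least
#' squares over a 60 s window anchored at the second aortic maximum (the
#' first-pass perfusion transient must have died away), and the slope is
#' converted to plasma GFR per body surface area as
#' \eqn{GFR = m \cdot 60 / BS \cdot (1 - hct)}.
#'
#' @name patlak
NULL

#' Cumulative arterial input integral
#'
#' Cumulative trapezoidal integral of the aortic concentration from bolus
#' arrival (t = 0); identically zero before arrival.
#'
#' @param aorta aortic [concentration_curve()].
#' @param t_arrival arrival time on the curve's time axis (seconds).
#' @return A curve-like object on the same grid whose values are
#'   `integral(c_aorta)` in mmol·s/L.
#' @export
cumulative_aif_integral <- function(aorta, t_arrival) {
  stopifnot(inherits(aorta, "roi_curve"))
  if (t_arrival < aorta$times[1] - 1e-9 ||
      t_arrival > aorta$times[length(aorta$times)] + 1e-9)
    stop("arrival time outside the curve", call. = FALSE)
  i0 <- curve_index_at(aorta, t_arrival)
  v <- aorta$values
  tt <- aorta$times
  inc <- c(0, diff(tt) * (utils::head(v, -1) + utils::tail(v, -1)) / 2)
  cum <- cumsum(inc)
  out <- cum - cum[i0]
  out[seq_len(i0)] <- 0
  curve_with_values(aorta, out, units = aorta$units)
}

#' Patlak evaluation window
#'
#' `[t_aorta_max2, t_aorta_max2 + duration]` in seconds after arrival: the
#' regression starts when the second aortic maximum is reached (first-pass
#' perfusion no longer dominates) and runs 60 s, which at a 0.58 s frame
#' interval provides more than 100 regression points. Truncated with a
#' warning if the series ends earlier; an error if fewer than 10 frames
#' remain.
#'
#' @param landmarks `bolus_landmarks` or `aorta_landmarks` (needs
#'   `t_aorta_max2` and `t_arrival`).
#' @param aorta optional aortic curve used to truncate the window at the end
#'   of the series and to count in-window frames.
#' @param duration window length in seconds, default 60.
#' @return Numeric `c(t_start, t_end)` in seconds after arrival.
#' @export
evaluation_window <- function(landmarks, aorta = NULL, duration = 60) {
  t2 <- landmarks$t_aorta_max2
  if (is.null(t2) || !is.finite(t2))
    stop("second aortic maximum not available", call. = FALSE)
  win <- c(t2, t2 + duration)
  if (!is.null(aorta)) {
    stopifnot(inherits(aorta, "roi_curve"))
    t_end_rel <- aorta$times[length(aorta$times)] - landmarks$t_arrival
    if (win[2] > t_end_rel + 1e-9) {
      win[2] <- t_end_rel
      warn_with("window_truncated",
                "series ends before the full evaluation window; truncated at ",
                signif(t_end_rel, 4), " s after arrival")
    }
    dt <- frame_interval(aorta)
    n_in <- floor((win[2] - win[1]) / dt + 1e-9) + 1
    if (n_in < 10)
      stop_with("window_too_short",
                "evaluation window holds ", n_in, " frames (< 10)")
  }
  win
}

#' Build the Rutland-Patlak points
#'
#' For every frame time t (seconds after arrival) inside the window:
#' `x = integral_0^t c_aorta / c_aorta(t)` and
#' `y = c_kidney(t + delta_t) * v_kidney / c_aorta(t)`, the shifted kidney
#' value obtained by linear interpolation. Frames whose aortic denominator
#' falls below `eps_frac` of the post-arrival aortic peak (or whose shifted
#' kidney sample falls outside the series) are dropped and counted.
#'
#' @param aorta,kidney [concentration_curve()]s on one common grid.
#' @param delta_t aorta-to-kidney delay in seconds (>= 0).
#' @param v_kidney kidney volume in mL (> 0).
#' @param t_arrival arrival time on the curves' time axis (seconds).
#' @param window `c(t_start, t_end)` in seconds after arrival, from
#'   [evaluation_window()].
#' @param eps_frac denominator guard as a fraction of the post-arrival aortic
#'   peak, default 0.01.
#' @param integral_from `"arrival"` (default; the integral's lower bound is
#'   t = 0 as in the model equation) or `"window_start"` for comparison.
#' @return An object of class `patlak_points`: vectors `x` (s), `y` (mL),
#'   `t` (s after arrival), plus `window`, `v_kidney`, `delta_t`,
#'   `n_dropped`.
#' @export
build_patlak_points <- function(aorta, kidney, delta_t, v_kidney, t_arrival,
                                window, eps_frac = 0.01,
                                integral_from = c("arrival", "window_start")) {
  stopifnot(inherits(aorta, "concentration_curve"),
            inherits(kidney, "concentration_curve"))
  integral_from <- match.arg(integral_from)
  if (v_kidney <= 0) stop("v_kidney must be > 0", call. = FALSE)
  if (delta_t < 0) stop("delta_t must be >= 0", call. = FALSE)
  if (length(aorta$times) != length(kidney$times) ||
      max(abs(aorta$times - kidney$times)) > 1e-9)
    stop("aorta and kidney curves must share one time grid", call. = FALSE)

  integ <- cumulative_aif_integral(aorta, aorta$times[curve_index_at(aorta, t_arrival)])
  if (integral_from == "window_start") {
    iw <- which(aorta$times - t_arrival >= window[1] - 1e-9)[1]
    integ$values <- pmax(integ$values - integ$values[iw], 0)
  }

  rel <- aorta$times - t_arrival
  sel <- which(rel >= window[1] - 1e-9 & rel <= window[2] + 1e-9)
  if (length(sel) == 0) stop("window contains no frames", call. = FALSE)

  post <- rel >= -1e-9
  ca_peak <- max(aorta$values[post])
  eps <- eps_frac * ca_peak

  ck_shift <- curve_interp(kidney, aorta$times[sel] + delta_t)
  ca <- aorta$values[sel]
  keep <- !is.na(ck_shift) & ca > eps
  n_dropped <- sum(!keep)
  if (!any(keep))
    stop_with("degenerate_denominator",
              "all frames dropped: aortic denominator below guard everywhere")
  x <- integ$values[sel][keep] / ca[keep]
  y <- ck_shift[keep] * v_kidney / ca[keep]
  structure(list(x = x, y = y, t = rel[sel][keep], window = window,
                 v_kidney = v_kidney, delta_t = delta_t,
                 n_dropped = n_dropped),
            class = "patlak_points")
}

#' @export
print.patlak_points <- function(x, ...) {
  cat(sprintf("<patlak_points> n=%d (%d dropped), window [%.1f, %.1f] s, delta_t=%.2f s\n",
              length(x$x), x$n_dropped, x$window[1], x$window[2], x$delta_t))
  invisible(x)
}

#' Fit the Patlak regression line
#'
#' Ordinary least squares `y = b + m x`. The slope `m` estimates the renal
#' clearance `p * V_vas` (mL/s) and the intercept `b` the vascular volume
#' `V_vas` (mL).
#'
#' @param points a [build_patlak_points()] result.
#' @return An object of class `patlak_fit`: `slope_m` (mL/s), `intercept_b`
#'   (mL), `r_squared`, `n_points`.
#' @export
fit_patlak <- function(points) {
  stopifnot(inherits(points, "patlak_points"))
  n <- length(points$x)
  if (n < 10)
    stop_with("too_few_points", "Patlak fit needs >= 10 points, got ", n)
  if (stats::sd(points$x) <= 1e-12 * max(abs(points$x), 1e-12))
    stop_with("zero_x_variance", "Patlak abscissa has no variance")
  fit <- stats::lm(y ~ x, data = list(x = points$x, y = points$y))
  cf <- stats::coef(fit)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((points$y - mean(points$y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(list(slope_m = unname(cf[2]), intercept_b = unname(cf[1]),
                 r_squared = max(0, min(1, r2)), n_points = n),
            class = "patlak_fit")
}

#' @export
print.patlak_fit <- function(x, ...) {
  cat(sprintf("<patlak_fit> slope %.4g mL/s, intercept %.4g mL, R^2 %.4f (n=%d)\n",
              x$slope_m, x$intercept_b, x$r_squared, x$n_points))
  invisible(x)
}

#' Convert the Patlak slope to plasma GFR
#'
#' `GFR = slope * 60 / BS * (1 - hct)` in mL/min per m^2 body surface: the
#' factor 60 converts per-second clearance to per-minute, division by body
#' surface normalizes between subjects, and `(1 - hct)` converts whole-blood
#' clearance to plasma filtration.
#'
#' @param slope_m Patlak slope in mL/s.
#' @param subj a [subject()].
#' @return GFR in mL/min/m^2 BS.
#' @export
gfr_from_slope <- function(slope_m, subj) {
  stopifnot(inherits(subj, "gfr_subject"), subj$body_surface > 0)
  slope_m * 60 / subj$body_surface * (1 - subj$hematocrit)
}
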