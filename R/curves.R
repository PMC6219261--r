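#' ROI time-series containers
#'
#' Bolus-track analysis operates on uniformly sampled per-ROI mean curves:
#' signal-intensity curves in arbitrary units (a.u.) straight off the scanner,
#' and concentration curves in mmol/L (numerically identical to umol/mL) after
#' calibration. Both are thin S3 records holding a uniform time grid, the
#' values, the ROI label, the unit, and a flag recording whether the curve has
#' been Savitzky-Golay smoothed.
#'
#' @param times numeric vector of acquisition times in seconds, uniformly
#'   spaced and increasing.
#' @param values numeric vector, same length as `times`.
#' @param roi character ROI label (e.g. `"aorta_all"`, `"kidney_left"`).
#' @param smoothed logical; has the curve been smoothed already?
#' @return An object of class `signal_curve` or `concentration_curve`
#'   (both inherit from `roi_curve`).
#' @examples
#' sc <- signal_curve(seq(0, 10, by = 0.58), rnorm(18), roi = "aorta_all")
#' frame_interval(sc)
#' @export
signal_curve <- function(times, values, roi = "roi", smoothed = FALSE) {
  new_roi_curve(times, values, roi, units = "a.u.",
                class = "signal_curve", smoothed = smoothed)
}

#' @rdname signal_curve
#' @export
concentration_curve <- function(times, values, roi = "roi", smoothed = FALSE) {
  new_roi_curve(times, values, roi, units = "mmol/L",
                class = "concentration_curve", smoothed = smoothed)
}

new_roi_curve <- function(times, values, roi, units, class, smoothed = FALSE) {
  times <- as.numeric(times)
  values <- as.numeric(values)
  stopifnot(length(times) == length(values), length(times) >= 2L)
  if (anyNA(times) || is.unsorted(times, strictly = TRUE))
    stop("curve times must be finite and strictly increasing", call. = FALSE)
  dt <- diff(times)
  if (max(dt) - min(dt) > 1e-6 * mean(dt))
    stop("curve time grid must be uniform", call. = FALSE)
  structure(
    list(times = times, values = values, roi = as.character(roi),
         units = units, smoothed = isTRUE(smoothed)),
    class = c(class, "roi_curve"))
}

#' @rdname signal_curve
#' @param curve a `roi_curve`.
#' @export
frame_interval <- function(curve) {
  stopifnot(inherits(curve, "roi_curve"))
  mean(diff(curve$times))
}

#' @export
length.roi_curve <- function(x) length(x$values)

#' @export
print.roi_curve <- function(x, ...) {
  cat(sprintf("<%s> roi=%s  n=%d  dt=%.4g s  range=[%.4g, %.4g] %s%s\n",
              class(x)[1], x$roi, length(x$values), frame_interval(x),
              min(x$values), max(x$values), x$units,
              if (x$smoothed) "  (smoothed)" else ""))
  invisible(x)
}

#' @export
as.data.frame.roi_curve <- function(x, ...) {
  data.frame(time_s = x$times, value = x$values, roi_label = x$roi,
             stringsAsFactors = FALSE)
}

# Replace the values of a curve, keeping grid/label, optionally retagging class
curve_with_values <- function(curve, values, units = curve$units,
                              smoothed = curve$smoothed) {
  cls <- if (identical(units, "mmol/L")) "concentration_curve" else "signal_curve"
  new_roi_curve(curve$times, values, curve$roi, units, cls, smoothed)
}

# Linear interpolation of a curve at arbitrary times; NA outside the grid
curve_interp <- function(curve, at) {
  stats::approx(curve$times, curve$values, xout = at, rule = 1)$y
}

# index of the frame whose time equals t (within half a frame)
curve_index_at <- function(curve, t) {
  i <- which.min(abs(curve$times - t))
  if (abs(curve$times[i] - t) > 0.5 * frame_interval(curve) + 1e-9)
    stop("time ", t, " s does not lie on the curve's grid", call. = FALSE)
  i
}

stop_with <- function(class, ...) {
  stop(errorCondition(paste0(...), class = c(class, "patlakGFR_error")))
}

warn_with <- function(class, ...) {
  warning(warningCondition(paste0(...), class = c(class, "patlakGFR_warning")))
}
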