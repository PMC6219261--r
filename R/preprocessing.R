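#' Dynamic series, ROI sets and tissue geometry
#'
#' The bolus-track acquisition is a rapid single-slab dynamic series (one
#' thick dorsal slice, default 0.58 s between frames). The scanner's
#' subtraction procedure takes the third frame as reference and subtracts it
#' from all subsequent frames, so curves measure enhancement above baseline.
#' Because the 45 mm slab is thicker than the organs, every ROI voxel mixes
#' organ and residual tissue; the residual-tissue correction removes that
#' partial-volume contribution using a nearby correction ROI and the measured
#' volumes.
#'
#' @name preprocessing
NULL

#' Construct a dynamic series
#'
#' @param frames numeric 3-D array `[x, y, t]`: a stack of 2-D frames ordered
#'   by time. At least 20 frames.
#' @param frame_interval seconds between frames (default 0.58).
#' @param baseline_index 1-based ordinal of the subtraction reference frame
#'   (default 3, i.e. the third frame).
#' @param subtracted has the baseline already been subtracted?
#' @return An object of class `dynamic_series`.
#' @export
dynamic_series <- function(frames, frame_interval = 0.58, baseline_index = 3,
                           subtracted = FALSE) {
  stopifnot(is.array(frames), length(dim(frames)) == 3)
  nt <- dim(frames)[3]
  if (nt < 20) stop("dynamic series needs >= 20 frames", call. = FALSE)
  if (frame_interval <= 0) stop("frame_interval must be > 0", call. = FALSE)
  if (baseline_index < 1 || baseline_index > nt)
    stop("baseline_index out of range", call. = FALSE)
  structure(list(frames = frames, frame_interval = frame_interval,
                 baseline_index = as.integer(baseline_index),
                 subtracted = isTRUE(subtracted)),
            class = "dynamic_series")
}

#' @export
print.dynamic_series <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<dynamic_series> %d x %d x %d frames, dt=%.3g s, baseline frame %d%s\n",
              d[1], d[2], d[3], x$frame_interval, x$baseline_index,
              if (x$subtracted) " (subtracted)" else ""))
  invisible(x)
}

#' Construct an ROI set
#'
#' A named list of logical masks over the frame grid. Canonical names are
#' `aorta_all`, `kidney_left`, `kidney_right`, `cortex_left`, `cortex_right`,
#' `correction_aorta`, `correction_left`, `correction_right`; extra aortic
#' variants (`aorta_renalis`, `aorta_highest_si`) are allowed. Organ masks
#' must be disjoint from their own correction masks.
#'
#' @param masks named list of logical matrices, all the same shape.
#' @return An object of class `roi_set`.
#' @export
roi_set <- function(masks) {
  stopifnot(is.list(masks), length(masks) > 0, !is.null(names(masks)))
  shp <- dim(masks[[1]])
  for (nm in names(masks)) {
    m <- masks[[nm]]
    if (!is.logical(m) || !identical(dim(m), shp))
      stop("mask '", nm, "' must be a logical matrix of shape ",
           paste(shp, collapse = "x"), call. = FALSE)
    if (!any(m)) stop("mask '", nm, "' is empty", call. = FALSE)
  }
  pairs <- list(c("aorta_all", "correction_aorta"),
                c("kidney_left", "correction_left"),
                c("kidney_right", "correction_right"))
  for (p in pairs) {
    if (all(p %in% names(masks)) && any(masks[[p[1]]] & masks[[p[2]]]))
      stop("organ mask '", p[1], "' overlaps its correction mask", call. = FALSE)
  }
  structure(masks, class = "roi_set")
}

#' Subtract the baseline reference frame
#'
#' Implements the scanner's subtraction procedure: the baseline frame
#' (default the third) is subtracted voxel-wise from every later frame;
#' frames up to and including the baseline are zeroed. Idempotent: applying
#' it to an already-subtracted series is a no-op with a warning.
#'
#' @param series a [dynamic_series()].
#' @return A [dynamic_series()] with `subtracted = TRUE`.
#' @export
subtract_baseline <- function(series) {
  stopifnot(inherits(series, "dynamic_series"))
  if (series$subtracted) {
    warn_with("already_subtracted", "series already baseline-subtracted; no-op")
    return(series)
  }
  fr <- series$frames
  b <- series$baseline_index
  base <- fr[, , b]
  for (t in seq_len(dim(fr)[3])) {
    fr[, , t] <- if (t <= b) 0 else fr[, , t] - base
  }
  series$frames <- fr
  series$subtracted <- TRUE
  series
}

#' Extract the ROI mean signal curve
#'
#' Per-frame arithmetic mean of the series over the mask voxels;
#' `times = (frame - 1) * frame_interval`.
#'
#' @param series a [dynamic_series()].
#' @param mask logical matrix matching the frame shape.
#' @param roi label for the resulting curve.
#' @return A [signal_curve()].
#' @export
extract_roi_mean <- function(series, mask, roi = "roi") {
  stopifnot(inherits(series, "dynamic_series"))
  d <- dim(series$frames)
  if (!is.logical(mask) || !identical(dim(mask), d[1:2]))
    stop("mask must be a logical matrix matching the frame shape", call. = FALSE)
  if (!any(mask)) stop("empty mask", call. = FALSE)
  flat <- matrix(series$frames, nrow = d[1] * d[2], ncol = d[3])
  v <- colMeans(flat[as.vector(mask), , drop = FALSE])
  signal_curve((seq_len(d[3]) - 1) * series$frame_interval, v, roi = roi)
}

# Savitzky-Golay convolution weights for the window centre
sg_weights <- function(window, poly_order) {
  h <- (window - 1L) / 2L
  A <- outer(seq(-h, h), 0:poly_order, `^`)
  (solve(crossprod(A), t(A)))[1L, ]
}

#' Savitzky-Golay smoothing of a curve
#'
#' Local least-squares polynomial smoothing: the default 15-frame window at a
#' 0.58 s frame interval spans 8.7 s, enough to suppress breathing-motion
#' oscillation while preserving the bolus extrema. Edges are handled by
#' mirror padding (`edge = "mirror"`) or by refitting truncated windows
#' (`edge = "fit"`).
#'
#' @param curve a [signal_curve()] or [concentration_curve()].
#' @param window_frames odd window length in frames, default 15;
#'   must satisfy `poly_order + 2 <= window_frames <= length(curve)`.
#' @param poly_order polynomial order, default 2.
#' @param edge edge handling, `"mirror"` (default) or `"fit"`.
#' @return A curve of the same class on the same grid, flagged `smoothed`.
#' @export
smooth_curve <- function(curve, window_frames = 15, poly_order = 2,
                         edge = c("mirror", "fit")) {
  stopifnot(inherits(curve, "roi_curve"))
  edge <- match.arg(edge)
  w <- as.integer(window_frames)
  n <- length(curve$values)
  if (w %% 2L == 0L) stop("window_frames must be odd", call. = FALSE)
  if (w < poly_order + 2L) stop("window too short for poly_order", call. = FALSE)
  if (w > n) stop("window longer than curve", call. = FALSE)
  h <- (w - 1L) %/% 2L
  v <- curve$values
  if (edge == "mirror") {
    padded <- c(v[(h + 1L):2L], v, v[(n - 1L):(n - h)])
    wt <- sg_weights(w, poly_order)
    sm <- as.numeric(stats::filter(padded, wt, sides = 2))[(h + 1L):(h + n)]
  } else {
    sm <- v
    wt <- sg_weights(w, poly_order)
    for (i in seq_len(n)) {
      if (i > h && i <= n - h) {
        sm[i] <- sum(wt * v[(i - h):(i + h)])
      } else {
        lo <- max(1L, i - h); hi <- min(n, i + h)
        xs <- seq(lo, hi) - i
        fit <- stats::lm.fit(outer(xs, 0:poly_order, `^`), v[lo:hi])
        sm[i] <- fit$coefficients[1]
      }
    }
  }
  curve_with_values(curve, sm, smoothed = TRUE)
}

#' Tissue geometry of a thick-slab ROI
#'
#' @param v_voxel total ROI voxel volume in mL (mask voxels times the voxel
#'   volume; slab thickness 45 mm).
#' @param v_tissue organ volume inside the ROI, mL; `0 < v_tissue <= v_voxel`.
#' @return An object of class `tissue_geometry` with the residual volume
#'   `v_residual = v_voxel - v_tissue` computed exactly.
#' @export
tissue_geometry <- function(v_voxel, v_tissue) {
  stopifnot(is.finite(v_voxel), is.finite(v_tissue))
  if (v_voxel <= 0) stop("v_voxel must be > 0", call. = FALSE)
  if (v_tissue <= 0 || v_tissue > v_voxel)
    stop("need 0 < v_tissue <= v_voxel", call. = FALSE)
  structure(list(v_voxel = v_voxel, v_tissue = v_tissue,
                 v_residual = v_voxel - v_tissue),
            class = "tissue_geometry")
}

#' Residual-tissue (partial-volume) correction
#'
#' The slab is thicker than the organ, so the ROI voxel concentration mixes
#' organ and residual tissue. The true tissue concentration is recovered as
#' \deqn{c_{tissue}(t) = c_{voxel}(t)\frac{V_{voxel}}{V_{tissue}}
#'       - c_{residual}(t)\frac{V_{residual}}{V_{tissue}},}
#' applied pointwise. Negative results (noise) are retained with a warning so
#' the Patlak fit sees unbiased noise; set `clip_negative = TRUE` to clamp.
#'
#' @param organ_curve [concentration_curve()] of the organ ROI (voxel-mixed).
#' @param correction_curve [concentration_curve()] of the correction ROI
#'   (pure residual tissue), same time grid.
#' @param geom a [tissue_geometry()].
#' @param clip_negative clamp negative corrected values to 0.
#' @return A [concentration_curve()] of the true tissue concentration.
#' @export
correct_residual_tissue <- function(organ_curve, correction_curve, geom,
                                    clip_negative = FALSE) {
  stopifnot(inherits(organ_curve, "concentration_curve"),
            inherits(correction_curve, "concentration_curve"),
            inherits(geom, "tissue_geometry"))
  if (length(organ_curve$times) != length(correction_curve$times) ||
      max(abs(organ_curve$times - correction_curve$times)) > 1e-9)
    stop("organ and correction curves must share one time grid", call. = FALSE)
  v <- organ_curve$values * (geom$v_voxel / geom$v_tissue) -
    correction_curve$values * (geom$v_residual / geom$v_tissue)
  if (any(v < 0)) {
    if (clip_negative) v <- pmax(v, 0)
    else warn_with("negative_concentration", sum(v < 0),
                   " negative corrected concentration value(s) retained")
  }
  curve_with_values(organ_curve, v)
}

#' Canine body surface area from body weight
#'
#' Allometric formula `BS = 0.1 * BW^0.667` (m^2, BW in kg).
#'
#' @param bw body weight in kg, > 0.
#' @return Body surface area in m^2.
#' @export
body_surface_area <- function(bw) {
  if (any(!is.finite(bw)) || any(bw <= 0))
    stop("body weight must be > 0", call. = FALSE)
  0.1 * bw^0.667
}

#' Subject metadata
#'
#' @param id subject identifier.
#' @param body_weight kg, > 0.
#' @param hematocrit red-cell volume fraction in (0, 1); the reference value
#'   0.47 for healthy laboratory Beagles is the default when unmeasured.
#' @param body_surface m^2; derived from body weight via
#'   [body_surface_area()] when `NULL`.
#' @return An object of class `gfr_subject`.
#' @export
subject <- function(id, body_weight, hematocrit = 0.47, body_surface = NULL) {
  stopifnot(body_weight > 0)
  if (hematocrit <= 0 || hematocrit >= 1)
    stop("hematocrit must be in (0, 1)", call. = FALSE)
  bs <- body_surface %||% body_surface_area(body_weight)
  stopifnot(bs > 0)
  structure(list(id = as.character(id), body_weight = body_weight,
                 hematocrit = hematocrit, body_surface = bs),
            class = "gfr_subject")
}
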