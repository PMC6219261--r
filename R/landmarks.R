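#' Bolus landmark detection
#'
#' The aortic concentration course shows a characteristic sequence: a steep
#' first-pass maximum, a minimum, and a lower second maximum caused by
#' recirculation of the bolus; the kidneys peak a few seconds after the
#' aorta. The time of the last frame before the aortic ascent defines t = 0,
#' the second aortic maximum anchors the Patlak evaluation window, and the
#' delay between the first aortic and renal maxima is the time shift
#' \eqn{\Delta t} applied to the kidney curve. Detection is always run on
#' smoothed curves.
#'
#' @name landmarks
NULL

# indices of interior local maxima (first index of any plateau)
local_maxima_idx <- function(v) {
  n <- length(v)
  if (n < 3) return(integer(0))
  d <- diff(v)
  idx <- integer(0)
  last_sign <- 0
  for (i in seq_len(n - 1)) {
    s <- sign(d[i])
    if (s != 0) {
      if (last_sign > 0 && s < 0) idx <- c(idx, i - rle_back(d, i))
      last_sign <- s
    }
  }
  # a rise that never turns down (e.g. plateau at the end) closes no maximum
  idx
}

# length of the zero-run in d immediately before position i (for plateaus we
# report the first index of the plateau)
rle_back <- function(d, i) {
  j <- i - 1L
  k <- 0L
  while (j >= 1L && d[j] == 0) { k <- k + 1L; j <- j - 1L }
  k
}

#' Detect bolus arrival (t = 0)
#'
#' Scans the smoothed aortic curve for the first frame exceeding
#' `baseline_mean + k * baseline_sd` and rising for at least `rise_frames`
#' consecutive frames; baseline statistics are taken over all frames before
#' the candidate crossing (at least `min_baseline`). Returns the time of the
#' last frame before that ascent, the t = 0 reference for all downstream
#' times.
#'
#' @param curve smoothed [signal_curve()] or [concentration_curve()].
#' @param k threshold in baseline standard deviations, default 5.
#' @param min_baseline minimum number of baseline frames, default 8.
#' @param rise_frames required consecutive rising frames, default 3.
#' @return Arrival time in seconds (on the curve's own time axis).
#' @export
detect_bolus_arrival <- function(curve, k = 5, min_baseline = 8,
                                 rise_frames = 3) {
  stopifnot(inherits(curve, "roi_curve"))
  v <- curve$values
  n <- length(v)
  eps <- 1e-8 * max(abs(v), 1e-12)
  for (i in seq(min_baseline + 1L, n - rise_frames)) {
    b <- v[seq_len(i - 1L)]
    thr <- mean(b) + k * stats::sd(b) + eps
    if (v[i] > thr && all(diff(v[i:(i + rise_frames)]) >= 0) &&
        all(v[i:(i + rise_frames)] > thr)) {
      return(curve$times[i - 1L])
    }
  }
  stop_with("bolus_not_found",
            "no bolus arrival: curve never exceeds baseline + ", k, " sd")
}

#' Detect the aortic landmarks (first max, first min, second max)
#'
#' On the smoothed aortic concentration curve after arrival: the first
#' maximum is the first local maximum exceeding `prominence_frac` (default
#' 50%) of the post-arrival global maximum; the first minimum is the global
#' minimum between the first maximum and the next qualifying local maximum;
#' the second maximum is the highest local maximum after the minimum within
#' `horizon` seconds of arrival (earliest wins on ties). Local maxima closer
#' than `min_sep_frames` to the previous accepted one are ignored.
#'
#' @param curve smoothed [concentration_curve()] (or [signal_curve()]).
#' @param t_arrival arrival time from [detect_bolus_arrival()] (curve time
#'   axis, seconds).
#' @param horizon search horizon after arrival in seconds, default 60.
#' @param prominence_frac fraction of the global maximum a first peak must
#'   reach, default 0.5.
#' @param min_sep_frames minimum peak-to-peak separation in frames, default 5.
#' @return A list of class `aorta_landmarks`: `t_arrival` plus
#'   `t_aorta_max1`, `t_aorta_min1`, `t_aorta_max2` (seconds after arrival)
#'   and the concentrations `c_aorta_max1`, `c_aorta_min1`, `c_aorta_max2`.
#' @export
detect_aorta_landmarks <- function(curve, t_arrival, horizon = 60,
                                   prominence_frac = 0.5, min_sep_frames = 5) {
  stopifnot(inherits(curve, "roi_curve"))
  post <- curve$times >= t_arrival - 1e-9
  tt <- curve$times[post]
  vv <- curve$values[post]
  if (length(vv) < 10)
    stop("curve too short after arrival", call. = FALSE)
  gmax <- max(vv)
  lm_idx <- local_maxima_idx(vv)
  q1 <- lm_idx[vv[lm_idx] >= prominence_frac * gmax]
  if (length(q1) == 0)
    stop_with("flat_curve", "no qualifying first maximum after arrival")
  i_max1 <- q1[1]
  # second maximum: highest qualifying local maximum after the first peak
  # (separated by >= min_sep_frames) within the horizon; earliest wins on
  # ties via which.max. Selecting it first makes the minimum search robust
  # to residual breathing bumps in the valley.
  nxt <- lm_idx[lm_idx >= i_max1 + min_sep_frames]
  cand <- nxt[tt[nxt] - t_arrival <= horizon]
  if (length(cand) == 0)
    stop_with("recirculation_not_found",
              "no second aortic maximum (recirculation) within ", horizon,
              " s of arrival")
  i_max2 <- cand[which.max(vv[cand])]
  # first minimum: global minimum between the two maxima
  seg <- seq(i_max1, i_max2)
  i_min1 <- seg[which.min(vv[seg])]
  if (i_min1 == i_max1 || i_min1 == i_max2)
    stop_with("recirculation_not_found",
              "no valley between the aortic maxima")
  res <- list(t_arrival = t_arrival,
              t_aorta_max1 = tt[i_max1] - t_arrival,
              t_aorta_min1 = tt[i_min1] - t_arrival,
              t_aorta_max2 = tt[i_max2] - t_arrival,
              c_aorta_max1 = vv[i_max1],
              c_aorta_min1 = vv[i_min1],
              c_aorta_max2 = vv[i_max2])
  class(res) <- "aorta_landmarks"
  res
}

#' Detect the renal first maximum
#'
#' First local maximum after arrival exceeding `prominence_frac` of the
#' post-arrival global maximum. A peak on the final frame is returned with a
#' boundary warning.
#'
#' @inheritParams detect_aorta_landmarks
#' @return A list with `t_kidney_max1` (seconds after arrival) and
#'   `c_kidney_max1`.
#' @export
detect_kidney_peak <- function(curve, t_arrival, prominence_frac = 0.5) {
  stopifnot(inherits(curve, "roi_curve"))
  post <- curve$times >= t_arrival - 1e-9
  tt <- curve$times[post]
  vv <- curve$values[post]
  if (diff(range(vv)) <= 1e-12 * max(abs(vv), 1e-12))
    stop_with("flat_curve", "kidney curve is flat: no peak")
  gmax <- max(vv)
  lm_idx <- local_maxima_idx(vv)
  q <- lm_idx[vv[lm_idx] >= prominence_frac * gmax]
  if (length(q) == 0) {
    # monotone rise to the final frame
    i <- length(vv)
    if (vv[i] == gmax) {
      warn_with("boundary_peak", "kidney peak on the final frame")
      return(list(t_kidney_max1 = tt[i] - t_arrival, c_kidney_max1 = vv[i]))
    }
    stop_with("flat_curve", "no qualifying kidney maximum after arrival")
  }
  i <- q[1]
  if (i == length(vv))
    warn_with("boundary_peak", "kidney peak on the final frame")
  list(t_kidney_max1 = tt[i] - t_arrival, c_kidney_max1 = vv[i])
}

#' Aorta-to-kidney delay
#'
#' `delta_t = t_kidney_max1 - t_aorta_max1`, floored at 0 (with a warning)
#' if the renal peak is detected before the aortic one.
#'
#' @param t_aorta_max1,t_kidney_max1 peak times in seconds (same reference).
#' @return `delta_t` in seconds, >= 0.
#' @export
compute_delta_t <- function(t_aorta_max1, t_kidney_max1) {
  d <- t_kidney_max1 - t_aorta_max1
  if (d < 0) {
    warn_with("negative_delta_t",
              "kidney peak precedes aortic peak; delta_t clamped to 0")
    d <- 0
  }
  d
}

#' Assemble full bolus landmarks for a subject
#'
#' Combines [detect_bolus_arrival()], [detect_aorta_landmarks()],
#' [detect_kidney_peak()] and [compute_delta_t()] for both kidneys and
#' validates the ordering invariant (max1 < min1 < max2, second maximum
#' lower than the first).
#'
#' @param aorta smoothed aortic [concentration_curve()].
#' @param kidneys named list of smoothed renal curves (e.g. `left`, `right`).
#' @inheritParams detect_aorta_landmarks
#' @inheritParams detect_bolus_arrival
#' @return An object of class `bolus_landmarks`: the aortic fields plus a
#'   `kidneys` list of `(t_kidney_max1, c_kidney_max1, delta_t)` per entry.
#' @export
detect_landmarks <- function(aorta, kidneys, k = 5, horizon = 60,
                             prominence_frac = 0.5, min_sep_frames = 5) {
  t0 <- detect_bolus_arrival(aorta, k = k)
  al <- detect_aorta_landmarks(aorta, t0, horizon = horizon,
                               prominence_frac = prominence_frac,
                               min_sep_frames = min_sep_frames)
  kid <- lapply(kidneys, function(kc) {
    kp <- detect_kidney_peak(kc, t0, prominence_frac = prominence_frac)
    kp$delta_t <- compute_delta_t(al$t_aorta_max1, kp$t_kidney_max1)
    kp
  })
  lm <- c(unclass(al), list(kidneys = kid))
  class(lm) <- "bolus_landmarks"
  validate_landmarks(lm)
  lm
}

validate_landmarks <- function(lm) {
  stopifnot(inherits(lm, "bolus_landmarks"))
  if (!(lm$t_aorta_max1 < lm$t_aorta_min1 && lm$t_aorta_min1 < lm$t_aorta_max2))
    stop("landmark ordering violated: need max1 < min1 < max2", call. = FALSE)
  if (lm$c_aorta_max2 >= lm$c_aorta_max1)
    warn_with("second_max_not_lower",
              "second aortic maximum is not lower than the first")
  for (kp in lm$kidneys) stopifnot(kp$delta_t >= 0)
  invisible(lm)
}

#' @export
print.bolus_landmarks <- function(x, ...) {
  cat(sprintf("<bolus_landmarks> arrival at %.2f s (curve time); after arrival:\n",
              x$t_arrival))
  cat(sprintf("  aorta: max1 %.2f s (%.3g), min1 %.2f s (%.3g), max2 %.2f s (%.3g)\n",
              x$t_aorta_max1, x$c_aorta_max1, x$t_aorta_min1, x$c_aorta_min1,
              x$t_aorta_max2, x$c_aorta_max2))
  for (nm in names(x$kidneys)) {
    kp <- x$kidneys[[nm]]
    cat(sprintf("  kidney %s: max1 %.2f s (%.3g), delta_t %.2f s\n",
                nm, kp$t_kidney_max1, kp$c_kidney_max1, kp$delta_t))
  }
  invisible(x)
}

#' Write landmarks to JSON
#'
#' @param lm a `bolus_landmarks` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_landmarks_json <- function(lm, path) {
  stopifnot(inherits(lm, "bolus_landmarks"))
  jsonlite::write_json(unclass(lm), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
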