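#' Pipeline configuration
#'
#' Collects the tunable parameters of [run_subject_pipeline()] with the
#' defaults used throughout: 15-frame order-2 Savitzky-Golay smoothing
#' (8.7 s at 0.58 s/frame), arrival threshold 5 baseline standard
#' deviations, 60 s landmark search horizon and 60 s evaluation window,
#' 1% aortic-peak denominator guard, integral lower bound at bolus arrival.
#'
#' @param smooth logical; apply Savitzky-Golay smoothing (default TRUE).
#' @param smooth_window,smooth_poly Savitzky-Golay window (frames) and
#'   polynomial order.
#' @param arrival_k arrival threshold in baseline sd units.
#' @param horizon landmark search horizon after arrival, s.
#' @param window_duration Patlak evaluation window length, s.
#' @param eps_frac aortic denominator guard, fraction of the aortic peak.
#' @param integral_from `"arrival"` or `"window_start"`.
#' @param delta_t_source `"kidney"` (default) or `"cortex"`: which curve's
#'   peak defines the per-side time shift.
#' @param clip_negative clamp negative SI/concentrations instead of
#'   retaining them.
#' @param clip_si clamp out-of-range SI at the calibration limit instead of
#'   extrapolating.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(smooth = TRUE, smooth_window = 15,
                            smooth_poly = 2, arrival_k = 5, horizon = 60,
                            window_duration = 60, eps_frac = 0.01,
                            integral_from = c("arrival", "window_start"),
                            delta_t_source = c("kidney", "cortex"),
                            clip_negative = FALSE, clip_si = FALSE) {
  structure(list(smooth = isTRUE(smooth), smooth_window = smooth_window,
                 smooth_poly = smooth_poly, arrival_k = arrival_k,
                 horizon = horizon, window_duration = window_duration,
                 eps_frac = eps_frac,
                 integral_from = match.arg(integral_from),
                 delta_t_source = match.arg(delta_t_source),
                 clip_negative = isTRUE(clip_negative),
                 clip_si = isTRUE(clip_si)),
            class = "pipeline_config")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(errorCondition(paste0("[stage ", stage, "] ", conditionMessage(e)),
                        class = c(class(e)[1], "pipeline_stage_error")),
         call. = FALSE)
  })
}

#' Run the full single-subject GFR pipeline
#'
#' Executes subtract -> extract -> smooth -> convert -> residual-tissue
#' correct -> landmark detection -> evaluation window -> Rutland-Patlak fit
#' -> GFR, for both kidneys. Input is either a dynamic image series plus ROI
#' masks, or precomputed per-ROI curves (signal or concentration); the
#' correction step runs whenever a matching `correction_*` curve and a
#' non-trivial geometry are available.
#'
#' @param curves named list of [signal_curve()]s or [concentration_curve()]s
#'   (`aorta_all`, `kidney_left`, `kidney_right`, optionally `cortex_*` and
#'   `correction_*`), or `NULL` when `series` is given.
#' @param series a [dynamic_series()] (used when `curves` is `NULL`).
#' @param rois a [roi_set()] accompanying `series`.
#' @param geometry named list of [tissue_geometry()] per organ ROI; `NULL`
#'   disables the residual-tissue correction.
#' @param subj a [subject()].
#' @param calibration a [calibration_model()]; used to convert signal
#'   curves, ignored for concentration input.
#' @param config a [pipeline_config()].
#' @param aorta_roi name of the aortic ROI to use, default `"aorta_all"`.
#' @return An object of class `gfr_result`: `subject`, `landmarks`,
#'   per-kidney `fits` and `points`, `gfr_left`, `gfr_right`, `gfr_total`
#'   (= left + right exactly), `warnings` (messages collected across
#'   stages), and the processed `curves`.
#' @export
run_subject_pipeline <- function(curves = NULL, series = NULL, rois = NULL,
                                 geometry = NULL, subj,
                                 calibration = default_calibration(),
                                 config = pipeline_config(),
                                 aorta_roi = "aorta_all") {
  stopifnot(inherits(subj, "gfr_subject"), inherits(config, "pipeline_config"))
  warns <- character(0)
  collect <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }

  if (is.null(curves)) {
    stopifnot(inherits(series, "dynamic_series"), inherits(rois, "roi_set"))
    series <- collect(with_stage("subtract", {
      if (series$subtracted) series else subtract_baseline(series)
    }))
    curves <- with_stage("extract", {
      lapply(stats::setNames(names(rois), names(rois)), function(nm) {
        extract_roi_mean(series, rois[[nm]], roi = nm)
      })
    })
  }
  need <- c(aorta_roi, "kidney_left", "kidney_right")
  if (!all(need %in% names(curves)))
    stop("curves must include: ", paste(need, collapse = ", "), call. = FALSE)

  if (config$smooth) {
    curves <- collect(with_stage("smooth", {
      lapply(curves, smooth_curve, window_frames = config$smooth_window,
             poly_order = config$smooth_poly)
    }))
  }
  curves <- collect(with_stage("convert", {
    lapply(curves, function(cv) {
      if (inherits(cv, "signal_curve"))
        curve_to_concentration(cv, calibration, clip = config$clip_si)
      else cv
    })
  }))

  corr_for <- c(aorta_all = "correction_aorta", kidney_left = "correction_left",
                kidney_right = "correction_right",
                cortex_left = "correction_left",
                cortex_right = "correction_right")
  if (!is.null(geometry)) {
    curves <- collect(with_stage("correct", {
      for (nm in intersect(names(corr_for), names(curves))) {
        cr <- corr_for[[nm]]
        g <- geometry[[nm]]
        if (!is.null(g) && cr %in% names(curves) && g$v_residual > 0) {
          curves[[nm]] <- correct_residual_tissue(
            curves[[nm]], curves[[cr]], g,
            clip_negative = config$clip_negative)
        }
      }
      curves
    }))
  }

  shift_src <- if (config$delta_t_source == "kidney")
    c(left = "kidney_left", right = "kidney_right")
  else c(left = "cortex_left", right = "cortex_right")
  lmres <- collect(with_stage("landmarks", {
    detect_landmarks(curves[[aorta_roi]],
                     list(left = curves[[shift_src[["left"]]]],
                          right = curves[[shift_src[["right"]]]]),
                     k = config$arrival_k, horizon = config$horizon)
  }))

  aorta <- curves[[aorta_roi]]
  win <- collect(with_stage("window", {
    evaluation_window(lmres, aorta, duration = config$window_duration)
  }))

  v_kid <- function(side) {
    nm <- paste0("kidney_", side)
    g <- geometry[[nm]]
    if (!is.null(g)) g$v_tissue
    else stop("kidney volume unknown: supply geometry for ", nm,
              call. = FALSE)
  }
  sides <- c("left", "right")
  points <- list(); fits <- list(); gfr <- c(left = NA_real_, right = NA_real_)
  for (side in sides) {
    pts <- collect(with_stage(paste0("patlak_", side), {
      build_patlak_points(aorta, curves[[paste0("kidney_", side)]],
                          delta_t = lmres$kidneys[[side]]$delta_t,
                          v_kidney = v_kid(side),
                          t_arrival = lmres$t_arrival, window = win,
                          eps_frac = config$eps_frac,
                          integral_from = config$integral_from)
    }))
    ft <- collect(with_stage(paste0("fit_", side), fit_patlak(pts)))
    points[[side]] <- pts
    fits[[side]] <- ft
    gfr[[side]] <- gfr_from_slope(ft$slope_m, subj)
  }

  structure(list(subject = subj, landmarks = lmres, window = win,
                 points = points, fits = fits,
                 gfr_left = gfr[["left"]], gfr_right = gfr[["right"]],
                 gfr_total = gfr[["left"]] + gfr[["right"]],
                 warnings = warns, curves = curves),
            class = "gfr_result")
}

#' @export
print.gfr_result <- function(x, ...) {
  cat(sprintf("<gfr_result> subject %s\n", x$subject$id))
  for (side in c("left", "right")) {
    f <- x$fits[[side]]
    cat(sprintf(
      "  %s: GFR %.2f mL/min/m^2 BS  (slope %.4g mL/s, V_vas %.3g mL, R^2 %.3f, n=%d)\n",
      side, if (side == "left") x$gfr_left else x$gfr_right,
      f$slope_m, f$intercept_b, f$r_squared, f$n_points))
  }
  cat(sprintf("  total: %.2f mL/min/m^2 BS;  delta_t L/R %.2f/%.2f s;  %d warning(s)\n",
              x$gfr_total, x$landmarks$kidneys$left$delta_t,
              x$landmarks$kidneys$right$delta_t, length(x$warnings)))
  invisible(x)
}
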