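#' Curve CSV interface
#'
#' Long-format CSV with header `time_s, value, roi_label` and a leading
#' comment line recording the unit (`# units: mmol_per_L` or `# units: si`).
#' Each ROI label must sit on its own uniform time grid.
#'
#' @param path file path.
#' @return `load_curves_csv()` returns a named list of [signal_curve()] /
#'   [concentration_curve()] objects; `write_curves_csv()` returns `path`
#'   invisibly.
#' @export
load_curves_csv <- function(path) {
  first <- readLines(path, n = 1)
  units <- "mmol_per_L"
  if (startsWith(first, "#")) {
    m <- regmatches(first, regexec("units:\\s*(\\S+)", first))[[1]]
    if (length(m) == 2) units <- m[2]
  }
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("time_s", "value", "roi_label")
  if (!all(need %in% names(df)))
    stop_with("schema_error", "curve CSV needs columns: ",
              paste(need, collapse = ", "))
  known <- c("aorta_all", "kidney_left", "kidney_right", "cortex_left",
             "cortex_right", "correction_aorta", "correction_left",
             "correction_right", "aorta_renalis", "aorta_highest_si")
  mk <- if (units == "si") signal_curve else concentration_curve
  out <- lapply(split(df, df$roi_label), function(d) {
    d <- d[order(d$time_s), ]
    mk(d$time_s, d$value, roi = d$roi_label[1])
  })
  unknown <- setdiff(names(out), known)
  if (length(unknown))
    warn_with("unknown_roi_label", "unknown ROI label(s): ",
              paste(unknown, collapse = ", "))
  out[intersect(c(known, unknown), names(out))]
}

#' @rdname load_curves_csv
#' @param curves named list of curves sharing one unit.
#' @export
write_curves_csv <- function(curves, path) {
  stopifnot(length(curves) > 0)
  units <- unique(vapply(curves, function(cv) cv$units, character(1)))
  if (length(units) != 1)
    stop("all curves in one CSV must share a unit", call. = FALSE)
  df <- do.call(rbind, lapply(curves, as.data.frame))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# units: ",
                    if (units == "a.u.") "si" else "mmol_per_L"), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Summarize a cohort of GFR results
#'
#' Arithmetic means and sample (n-1) standard deviations of left, right and
#' total GFR and of the per-fit coefficients of determination, plus landmark
#' time/concentration summaries and an optional paired t-test between left
#' and right kidney GFR.
#'
#' @param results list of `gfr_result` objects.
#' @param paired_test include a left-vs-right paired t-test p-value
#'   (requires >= 2 subjects)?
#' @return A list of class `cohort_summary`: `n`, `gfr` (data frame with
#'   mean/sd per measure), `landmarks` (data frame), `per_subject` (data
#'   frame, one row per kidney), optional `paired_t_p`.
#' @export
summarize_cohort <- function(results, paired_test = FALSE) {
  if (length(results) == 0) stop("no results to summarize", call. = FALSE)
  stopifnot(all(vapply(results, inherits, logical(1), "gfr_result")))
  per <- do.call(rbind, lapply(results, function(r) {
    do.call(rbind, lapply(c("left", "right"), function(side) {
      f <- r$fits[[side]]
      data.frame(subject = r$subject$id, kidney = side,
                 gfr = if (side == "left") r$gfr_left else r$gfr_right,
                 slope_ml_s = f$slope_m, v_vas_ml = f$intercept_b,
                 r_squared = f$r_squared, n_points = f$n_points,
                 delta_t_s = r$landmarks$kidneys[[side]]$delta_t,
                 stringsAsFactors = FALSE)
    }))
  }))
  n <- length(results)
  sd_or_na <- function(x) if (length(x) >= 2) stats::sd(x) else NA_real_
  msd <- function(x) c(mean = mean(x), sd = sd_or_na(x))
  gl <- vapply(results, function(r) r$gfr_left, numeric(1))
  gr <- vapply(results, function(r) r$gfr_right, numeric(1))
  gt <- vapply(results, function(r) r$gfr_total, numeric(1))
  gfr_tab <- as.data.frame(rbind(left = msd(gl), right = msd(gr),
                                 total = msd(gt),
                                 r_squared = msd(per$r_squared),
                                 delta_t_s = msd(per$delta_t_s)))
  lm_field <- function(f)
    vapply(results, function(r) r$landmarks[[f]], numeric(1))
  kid_field <- function(f) unlist(lapply(results, function(r)
    vapply(r$landmarks$kidneys, function(k) k[[f]], numeric(1))))
  lmk <- as.data.frame(rbind(
    t_aorta_max1 = msd(lm_field("t_aorta_max1")),
    t_aorta_min1 = msd(lm_field("t_aorta_min1")),
    t_aorta_max2 = msd(lm_field("t_aorta_max2")),
    t_kidney_max1 = msd(kid_field("t_kidney_max1")),
    c_aorta_max1 = msd(lm_field("c_aorta_max1")),
    c_kidney_max1 = msd(kid_field("c_kidney_max1"))))
  out <- list(n = n, gfr = gfr_tab, landmarks = lmk, per_subject = per)
  if (isTRUE(paired_test)) {
    out$paired_t_p <- if (n >= 2) stats::t.test(gl, gr, paired = TRUE)$p.value
                      else NA_real_
  }
  structure(out, class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> n = %d subjects\n", x$n))
  print(round(x$gfr, 3))
  if (!is.null(x$paired_t_p))
    cat(sprintf("paired left-vs-right t-test p = %.3g\n", x$paired_t_p))
  invisible(x)
}

result_record <- function(r) {
  list(subject = unclass(r$subject),
       landmarks = unclass(r$landmarks),
       window = r$window,
       fits = lapply(r$fits, unclass),
       gfr_left = r$gfr_left, gfr_right = r$gfr_right,
       gfr_total = r$gfr_total,
       n_dropped = lapply(r$points, function(p) p$n_dropped),
       warnings = r$warnings)
}

#' Write a result or cohort summary to disk
#'
#' JSON preserves all numeric fields at double precision (schema-versioned);
#' CSV writes one flat row per kidney per subject.
#'
#' @param x a `gfr_result` or `cohort_summary`.
#' @param path output file.
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (inherits(x, "gfr_result")) {
    if (format == "json") {
      jsonlite::write_json(c(list(schema = "patlakGFR/result/1"),
                             result_record(x)),
                           path, auto_unbox = TRUE, digits = NA, na = "null")
    } else {
      utils::write.csv(summarize_cohort(list(x))$per_subject, path,
                       row.names = FALSE)
    }
  } else if (inherits(x, "cohort_summary")) {
    if (format == "json") {
      jsonlite::write_json(list(schema = "patlakGFR/cohort/1", n = x$n,
                                gfr = x$gfr, landmarks = x$landmarks,
                                per_subject = x$per_subject,
                                paired_t_p = x$paired_t_p),
                           path, auto_unbox = TRUE, digits = NA, na = "null")
    } else {
      utils::write.csv(x$per_subject, path, row.names = FALSE)
    }
  } else stop("unsupported object", call. = FALSE)
  invisible(path)
}

#' Read back a JSON result report
#'
#' @param path file written by [write_report()].
#' @return The parsed list.
#' @export
read_report_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Plot a Rutland-Patlak plot with its trend line
#'
#' @param points a `patlak_points` object.
#' @param fit optional `patlak_fit`; fitted on the fly when `NULL`.
#' @param main plot title.
#' @return The `patlak_fit` used, invisibly.
#' @export
plot_patlak <- function(points, fit = NULL, main = "Rutland-Patlak plot") {
  stopifnot(inherits(points, "patlak_points"))
  fit <- fit %||% fit_patlak(points)
  graphics::plot(points$x, points$y, pch = 16, cex = 0.6,
                 xlab = "x = int c_aorta dt' / c_aorta(t)  [s]",
                 ylab = "y = c_kidney(t + dt) V_kidney / c_aorta(t)  [mL]",
                 main = main)
  graphics::abline(fit$intercept_b, fit$slope_m, lwd = 2)
  graphics::mtext(sprintf("slope %.3g mL/s, R^2 = %.3f",
                          fit$slope_m, fit$r_squared), side = 3, cex = 0.8)
  invisible(fit)
}

#' Save the per-kidney Patlak plots of a result to a file
#'
#' @param result a `gfr_result`.
#' @param path output file; format from the extension (`.pdf` default,
#'   `.png` supported).
#' @return `path`, invisibly.
#' @export
save_patlak_plots <- function(result, path) {
  stopifnot(inherits(result, "gfr_result"))
  if (grepl("\\.png$", path)) grDevices::png(path, 1200, 600, res = 120)
  else grDevices::pdf(path, width = 10, height = 5)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(1, 2))
  for (side in c("left", "right")) {
    plot_patlak(result$points[[side]], result$fits[[side]],
                main = paste("RPP", side, "kidney"))
  }
  invisible(path)
}
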