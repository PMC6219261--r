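#' Synthetic bolus-track subjects
#'
#' No in-vivo scans ship with the package; instead a forward model generates
#' ground-truth subjects against which every pipeline stage is testable. The
#' arterial input function (AIF) is a gamma-variate first pass plus a
#' delayed, broadened, lower second pass (recirculation) plus a slowly
#' decaying systemic washout term; kidney curves follow the two-compartment
#' model the Patlak plot linearizes; measurement noise is zero-mean Gaussian
#' plus a multiplicative breathing sinusoid. Defaults target the reference
#' bolus phenomenology: aortic first maximum ~8.5 s after arrival, first
#' minimum ~24 s, lower second maximum ~32 s, renal peaks ~14.5 s, aortic
#' peak concentration within 17-125 umol/mL and renal peaks within
#' 4-16 umol/mL.
#'
#' @name synthetic_data
NULL

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Ground-truth parameters of a synthetic subject
#'
#' Per-kidney clearance constants `p` are derived from the target plasma GFR
#' values so that the truth slope is `p * v_vas` and
#' `GFR = p * v_vas * 60 / BS * (1 - hct)` holds exactly; the defaults use
#' the reference cohort means (left 12.7, right 12.0 mL/min/m^2 BS, body
#' weight 17.5 kg, hct 0.47).
#'
#' @param arrival bolus arrival time in seconds from series start.
#' @param peak_time time of the aortic first-pass peak, seconds after
#'   arrival.
#' @param peak_conc aortic peak concentration in mmol/L (umol/mL); the
#'   in-vivo range is 17-125.
#' @param shape gamma-variate shape of the first pass.
#' @param recirc_delay,recirc_peak_time,recirc_shape second-pass (delay from
#'   arrival, s; own peak time, s; shape).
#' @param recirc_fraction second-pass amplitude as a fraction of the first
#'   (< 1 so the second maximum is lower).
#' @param washout_fraction,washout_rise,washout_rate systemic washout term:
#'   amplitude fraction, rise time constant (s), decay rate (1/s).
#' @param gfr_left,gfr_right target plasma GFR per kidney, mL/min/m^2 BS.
#' @param v_vas renal vascular volume, mL, per kidney.
#' @param v_kidney kidney volume, mL, per kidney (> v_vas).
#' @param delta_t vascular transit delay aorta -> kidney, seconds.
#' @param body_weight,hematocrit subject metadata used for the truth GFR.
#' @param cortex cortex compartment parameters
#'   (`v_vas`, `v_tissue`, `p_scale`, relative to the kidney `p`).
#' @param correction_amp,correction_delay,correction_tau residual-tissue
#'   enhancement: amplitude as a fraction of the aortic peak, delay (s) and
#'   exponential damping time constant (s).
#' @param tissue_fraction per-ROI organ-volume fraction of the thick-slab
#'   voxel volume, used when rendering voxel-mixed data.
#' @param noise_sd Gaussian noise sd as a fraction of each curve's peak.
#' @param breathing_amp,breathing_period multiplicative breathing sinusoid:
#'   amplitude fraction of the local signal and period in seconds.
#' @param duration,frame_interval time grid of the generated series.
#' @param seed base RNG seed for all stochastic elements.
#' @return An object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(arrival = 10, peak_time = 8.5, peak_conc = 60,
                            shape = 4,
                            recirc_delay = 17.5, recirc_peak_time = 14.8,
                            recirc_shape = 12, recirc_fraction = 0.30,
                            washout_fraction = 0.08, washout_rise = 12,
                            washout_rate = 0.010,
                            gfr_left = 12.7, gfr_right = 12.0,
                            v_vas = 6, v_kidney = 30, delta_t = 5,
                            body_weight = 17.5, hematocrit = 0.47,
                            cortex = list(v_vas = 3, v_tissue = 12,
                                          p_scale = 1.3),
                            correction_amp = 0.05, correction_delay = 2,
                            correction_tau = 6,
                            tissue_fraction = c(aorta = 0.35, kidney = 0.55,
                                                cortex = 0.5),
                            noise_sd = 0.03, breathing_amp = 0.05,
                            breathing_period = 4,
                            duration = 150, frame_interval = 0.58,
                            seed = 1L) {
  if (recirc_fraction >= 1)
    stop("recirc_fraction must be < 1 (second maximum lower than first)",
         call. = FALSE)
  if (v_vas >= v_kidney) stop("need v_vas < v_kidney", call. = FALSE)
  if (delta_t < 0) stop("delta_t must be >= 0", call. = FALSE)
  bs <- body_surface_area(body_weight)
  slope_left <- gfr_left * bs / (60 * (1 - hematocrit))
  slope_right <- gfr_right * bs / (60 * (1 - hematocrit))
  p_left <- slope_left / v_vas
  p_right <- slope_right / v_vas
  if (p_left < 0 || p_right < 0) stop("p must be >= 0", call. = FALSE)
  structure(list(
    arrival = arrival, peak_time = peak_time, peak_conc = peak_conc,
    shape = shape, recirc_delay = recirc_delay,
    recirc_peak_time = recirc_peak_time, recirc_shape = recirc_shape,
    recirc_fraction = recirc_fraction,
    washout_fraction = washout_fraction, washout_rise = washout_rise,
    washout_rate = washout_rate,
    kidneys = list(
      left = list(v_vas = v_vas, v_kidney = v_kidney, p = p_left,
                  delta_t = delta_t, gfr = gfr_left,
                  slope = slope_left),
      right = list(v_vas = v_vas, v_kidney = v_kidney, p = p_right,
                   delta_t = delta_t, gfr = gfr_right,
                   slope = slope_right)),
    cortex = cortex,
    correction_amp = correction_amp, correction_delay = correction_delay,
    correction_tau = correction_tau,
    tissue_fraction = tissue_fraction,
    body_weight = body_weight, hematocrit = hematocrit, body_surface = bs,
    noise = list(sd = noise_sd, breathing_amp = breathing_amp,
                 breathing_period = breathing_period),
    duration = duration, frame_interval = frame_interval,
    seed = as.integer(seed)),
    class = "synthetic_truth")
}

# gamma-variate normalized to peak 1 at s = tp
gamma_variate <- function(s, tp, alpha) {
  out <- numeric(length(s))
  pos <- s > 0
  r <- s[pos] / tp
  out[pos] <- r^alpha * exp(alpha * (1 - r))
  out
}

# continuous unscaled AIF as a function of time-after-arrival
aif_shape <- function(truth, s) {
  gamma_variate(s, truth$peak_time, truth$shape) +
    truth$recirc_fraction *
      gamma_variate(s - truth$recirc_delay, truth$recirc_peak_time,
                    truth$recirc_shape) +
    truth$washout_fraction *
      ifelse(s > 0, (1 - exp(-s / truth$washout_rise)) *
               exp(-truth$washout_rate * s), 0)
}

# peak of the raw shape, for normalization (fine grid once per truth)
aif_scale <- function(truth) {
  s <- seq(0, truth$duration - truth$arrival, by = 0.005)
  truth$peak_conc / max(aif_shape(truth, s))
}

#' Evaluate the noiseless AIF at arbitrary times
#'
#' @param truth a [synthetic_truth()].
#' @param times seconds from series start.
#' @return Concentration values in mmol/L.
#' @export
aif_value <- function(truth, times) {
  aif_scale(truth) * aif_shape(truth, times - truth$arrival)
}

#' Generate the arterial input function
#'
#' @param truth a [synthetic_truth()].
#' @param times optional time grid; defaults to
#'   `seq(0, duration, by = frame_interval)`.
#' @return A noiseless aortic [concentration_curve()].
#' @export
generate_aif <- function(truth, times = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  times <- times %||% seq(0, truth$duration, by = truth$frame_interval)
  concentration_curve(times, aif_value(truth, times), roi = "aorta_all")
}

#' Generate a two-compartment kidney curve
#'
#' Forward model of the Patlak equation:
#' \deqn{c_{kidney}(t) = \frac{V_{vas} c_{aorta}(t - \Delta t) +
#'   p V_{vas} \int_0^{t - \Delta t} c_{aorta}\,dt'}{V_{kidney}},}
#' with a trapezoidal integral starting at bolus arrival; zero before
#' `arrival + delta_t`.
#'
#' @param aif aortic [concentration_curve()] on a uniform grid.
#' @param v_vas vascular volume, mL.
#' @param v_kidney kidney volume, mL.
#' @param p clearance proportionality constant, 1/s (>= 0).
#' @param delta_t vascular delay, s.
#' @param t_arrival bolus arrival on the curve's time axis, s.
#' @param roi label of the output curve.
#' @return A [concentration_curve()] on the AIF's grid.
#' @export
generate_kidney_curve <- function(aif, v_vas, v_kidney, p, delta_t,
                                  t_arrival, roi = "kidney") {
  stopifnot(inherits(aif, "roi_curve"), p >= 0, v_vas > 0, v_kidney > 0)
  integ <- cumulative_aif_integral(aif, aif$times[curve_index_at(aif, t_arrival)])
  s <- aif$times - delta_t
  ca <- curve_interp(aif, s)
  ia <- curve_interp(integ, s)
  ca[is.na(ca) | s < aif$times[1]] <- 0
  ia[is.na(ia)] <- 0
  v <- (v_vas * ca + p * v_vas * ia) / v_kidney
  v[aif$times < t_arrival + delta_t] <- 0
  concentration_curve(aif$times, v, roi = roi)
}

#' Add measurement noise to a curve
#'
#' Zero-mean Gaussian noise with standard deviation `sd_frac` of the curve's
#' peak, plus a multiplicative breathing sinusoid
#' `(1 + amp * sin(2 pi t / period + phase))` with random phase. Reproducible
#' under a fixed seed; the caller's RNG state is untouched.
#'
#' @param curve a [signal_curve()] or [concentration_curve()].
#' @param sd_frac Gaussian sd as a fraction of the curve's peak (>= 0).
#' @param breathing_amp breathing amplitude fraction of the local signal.
#' @param breathing_period breathing period in seconds.
#' @param seed RNG seed (NULL uses the current stream).
#' @return A curve of the same class.
#' @export
add_measurement_noise <- function(curve, sd_frac = 0.03, breathing_amp = 0.05,
                                  breathing_period = 4, seed = NULL) {
  stopifnot(inherits(curve, "roi_curve"), sd_frac >= 0, breathing_amp >= 0)
  peak <- max(abs(curve$values))
  with_seed(seed, {
    v <- curve$values
    if (breathing_amp > 0) {
      phase <- stats::runif(1, 0, 2 * pi)
      v <- v * (1 + breathing_amp *
                  sin(2 * pi * curve$times / breathing_period + phase))
    }
    if (sd_frac > 0) v <- v + stats::rnorm(length(v), 0, sd_frac * peak)
    curve_with_values(curve, v, smoothed = FALSE)
  })
}

# residual-tissue enhancement: a small, delayed, exponentially damped copy
# of the AIF (amplitude relative to the aortic peak)
correction_truth_curve <- function(truth, times) {
  dt <- mean(diff(times))
  base <- aif_value(truth, times - truth$correction_delay)
  lam <- exp(-dt / truth$correction_tau)
  v <- numeric(length(base))
  acc <- 0
  for (i in seq_along(base)) {
    acc <- lam * acc + (1 - lam) * base[i]
    v[i] <- acc
  }
  if (max(v) > 0) v <- v * (truth$correction_amp * truth$peak_conc / max(v))
  concentration_curve(times, v, roi = "correction")
}

# fine-grid truth landmarks (aorta extrema and per-kidney peak times)
truth_landmarks <- function(truth, dt_fine = 0.01) {
  times <- seq(0, truth$duration, by = dt_fine)
  aif <- generate_aif(truth, times)
  s <- times - truth$arrival
  post <- s >= 0
  v <- aif$values[post]; ts <- s[post]
  im <- local_maxima_idx(v)
  if (length(im) == 0) im <- which.max(v)
  i1 <- im[1]
  if (length(im) >= 2) {
    seg <- seq(i1, im[2])
    imin <- seg[which.min(v[seg])]
    rest <- im[im > imin]
    i2 <- rest[which.max(v[rest])]
  } else {
    imin <- NA_integer_; i2 <- NA_integer_  # no recirculation in this truth
  }
  kid <- lapply(truth$kidneys, function(kd) {
    kc <- generate_kidney_curve(aif, kd$v_vas, kd$v_kidney, kd$p, kd$delta_t,
                                truth$arrival)
    vv <- kc$values[post]
    ik <- local_maxima_idx(vv)
    ik <- if (length(ik)) ik[1] else which.max(vv)
    list(t_kidney_max1 = ts[ik], c_kidney_max1 = vv[ik])
  })
  pick <- function(idx, vec) if (is.na(idx)) NA_real_ else vec[idx]
  list(t_arrival = truth$arrival,
       t_aorta_max1 = ts[i1], c_aorta_max1 = v[i1],
       t_aorta_min1 = pick(imin, ts), c_aorta_min1 = pick(imin, v),
       t_aorta_max2 = pick(i2, ts), c_aorta_max2 = pick(i2, v),
       kidneys = kid)
}

#' Simulate a complete synthetic subject
#'
#' Builds noiseless truth curves for the aorta, both kidneys, both cortices
#' and the three correction ROIs, optionally mixes organ and residual tissue
#' into thick-slab voxel curves, and optionally adds measurement noise. The
#' returned object carries the full truth (including fine-grid truth
#' landmark times and the exact truth GFRs) for parameter-recovery studies.
#'
#' @param truth a [synthetic_truth()].
#' @param noise add measurement noise (using `truth$noise` and
#'   `truth$seed`)? Default `TRUE`.
#' @param mix return voxel-mixed organ curves plus real partial-volume
#'   geometry (`TRUE`), or pure tissue curves with trivial geometry
#'   (`FALSE`, default)?
#' @param id subject identifier.
#' @return An object of class `synthetic_subject`: `truth`, `curves` (named
#'   list of [concentration_curve()]s), `geometry` (named
#'   [tissue_geometry()] list), `subject` ([subject()]), `truth_landmarks`,
#'   `truth_gfr` (`left`, `right`, `total`).
#' @export
simulate_subject <- function(truth = synthetic_truth(), noise = TRUE,
                             mix = FALSE, id = "synthetic-01") {
  stopifnot(inherits(truth, "synthetic_truth"))
  times <- seq(0, truth$duration, by = truth$frame_interval)
  aif <- generate_aif(truth, times)
  kl <- truth$kidneys$left
  kr <- truth$kidneys$right
  curves <- list(
    aorta_all = aif,
    kidney_left = generate_kidney_curve(aif, kl$v_vas, kl$v_kidney, kl$p,
                                        kl$delta_t, truth$arrival,
                                        roi = "kidney_left"),
    kidney_right = generate_kidney_curve(aif, kr$v_vas, kr$v_kidney, kr$p,
                                         kr$delta_t, truth$arrival,
                                         roi = "kidney_right"))
  cx <- truth$cortex
  curves$cortex_left <- generate_kidney_curve(
    aif, cx$v_vas, cx$v_tissue, kl$p * cx$p_scale, kl$delta_t, truth$arrival,
    roi = "cortex_left")
  curves$cortex_right <- generate_kidney_curve(
    aif, cx$v_vas, cx$v_tissue, kr$p * cx$p_scale, kr$delta_t, truth$arrival,
    roi = "cortex_right")
  corr <- correction_truth_curve(truth, times)
  curves$correction_aorta <- curve_with_values(corr, corr$values)
  curves$correction_aorta$roi <- "correction_aorta"
  curves$correction_left <- curve_with_values(corr, corr$values)
  curves$correction_left$roi <- "correction_left"
  curves$correction_right <- curve_with_values(corr, corr$values)
  curves$correction_right$roi <- "correction_right"

  tf <- truth$tissue_fraction
  geom <- list(
    aorta_all = tissue_geometry(if (mix) 15 / tf[["aorta"]] else 15, 15),
    kidney_left = tissue_geometry(
      if (mix) kl$v_kidney / tf[["kidney"]] else kl$v_kidney, kl$v_kidney),
    kidney_right = tissue_geometry(
      if (mix) kr$v_kidney / tf[["kidney"]] else kr$v_kidney, kr$v_kidney),
    cortex_left = tissue_geometry(
      if (mix) cx$v_tissue / tf[["cortex"]] else cx$v_tissue, cx$v_tissue),
    cortex_right = tissue_geometry(
      if (mix) cx$v_tissue / tf[["cortex"]] else cx$v_tissue, cx$v_tissue))

  if (mix) {
    for (nm in c("aorta_all", "kidney_left", "kidney_right",
                 "cortex_left", "cortex_right")) {
      g <- geom[[nm]]
      mixed <- (curves[[nm]]$values * g$v_tissue +
                  corr$values * g$v_residual) / g$v_voxel
      curves[[nm]] <- curve_with_values(curves[[nm]], mixed)
    }
  }

  if (isTRUE(noise)) {
    nz <- truth$noise
    for (i in seq_along(curves)) {
      curves[[i]] <- add_measurement_noise(
        curves[[i]], sd_frac = nz$sd, breathing_amp = nz$breathing_amp,
        breathing_period = nz$breathing_period, seed = truth$seed * 131L + i)
    }
  }

  structure(list(
    truth = truth, curves = curves, geometry = geom,
    subject = subject(id, truth$body_weight, truth$hematocrit),
    truth_landmarks = truth_landmarks(truth),
    truth_gfr = list(left = kl$gfr, right = kr$gfr,
                     total = kl$gfr + kr$gfr)),
    class = "synthetic_subject")
}

#' Render a synthetic dynamic image series
#'
#' Inverts the image-analysis pipeline: voxel concentrations are built by
#' mixing organ and residual tissue, converted to signal intensity through
#' the calibration map (concentrations below the calibration domain are
#' clamped to the domain minimum, i.e. SI 0, with a warning), a constant
#' baseline offset is added so the subtraction procedure is exercised, and
#' simple geometric ROIs (a vertical aortic band, renal ellipses with a
#' cortical core, rectangular correction boxes) are painted into the frames.
#' Optional voxel-level Gaussian SI noise supports the ROI-size sensitivity
#' harness. Note the partial-volume geometry is taken from the subject's
#' configuration (as for real data), not from mask voxel counts.
#'
#' @param subj a [simulate_subject()] result built with `mix = FALSE` and
#'   `noise = FALSE` (the renderer mixes and adds noise itself).
#' @param calibration a [calibration_model()].
#' @param baseline_si constant pre-contrast SI offset, a.u.
#' @param noise_sd_si per-voxel Gaussian SI noise sd, a.u. (0 = noiseless).
#' @param seed RNG seed for the voxel noise.
#' @param nx,ny frame dimensions.
#' @return A list: `series` ([dynamic_series()], unsubtracted), `rois`
#'   ([roi_set()]), `geometry` (named [tissue_geometry()] list with
#'   thick-slab mixing fractions).
#' @export
render_dynamic_series <- function(subj, calibration = default_calibration(),
                                  baseline_si = 200, noise_sd_si = 0,
                                  seed = NULL, nx = 64, ny = 48) {
  stopifnot(inherits(subj, "synthetic_subject"))
  truth <- subj$truth
  times <- subj$curves$aorta_all$times
  nt <- length(times)

  ellipse <- function(cx, cy, rx, ry) {
    outer(seq_len(nx), seq_len(ny),
          function(i, j) ((i - cx) / rx)^2 + ((j - cy) / ry)^2 <= 1)
  }
  box <- function(rows, cols) {
    m <- matrix(FALSE, nx, ny); m[rows, cols] <- TRUE; m
  }
  cortex_l <- ellipse(22, 11, 4.5, 3.2)
  cortex_r <- ellipse(22, 38, 4.5, 3.2)
  kidney_l <- ellipse(22, 11, 10, 7) & !cortex_l
  kidney_r <- ellipse(22, 38, 10, 7) & !cortex_r
  aorta <- box(5:40, 23:27)
  masks <- list(
    aorta_all = aorta,
    kidney_left = kidney_l, kidney_right = kidney_r,
    cortex_left = cortex_l, cortex_right = cortex_r,
    correction_aorta = box(44:46, 22:28),
    correction_left = box(38:41, 5:12),
    correction_right = box(38:41, 37:44),
    aorta_renalis = box(30:34, 24:26),
    aorta_highest_si = box(6:10, 24:26))
  rois <- roi_set(masks)

  tf <- truth$tissue_fraction
  geom <- subj$geometry
  for (nm in names(geom)) {
    frac <- if (grepl("aorta", nm)) tf[["aorta"]]
            else if (grepl("cortex", nm)) tf[["cortex"]] else tf[["kidney"]]
    geom[[nm]] <- tissue_geometry(geom[[nm]]$v_tissue / frac,
                                  geom[[nm]]$v_tissue)
  }

  corr <- subj$curves$correction_aorta$values
  organ_names <- c("aorta_all", "kidney_left", "kidney_right",
                   "cortex_left", "cortex_right")
  voxel_conc <- lapply(organ_names, function(nm) {
    g <- geom[[nm]]
    (subj$curves[[nm]]$values * g$v_tissue + corr * g$v_residual) / g$v_voxel
  })
  names(voxel_conc) <- organ_names

  c_min <- calibration$a + calibration$b  # concentration at SI = 0
  clamped <- FALSE
  to_si <- function(conc) {
    if (any(conc < c_min)) clamped <<- TRUE
    concentration_to_si(pmax(conc, c_min), calibration)
  }
  si_org <- lapply(voxel_conc, to_si)
  si_corr <- to_si(corr)
  if (clamped)
    warn_with("below_calibration_domain",
              "concentrations below the calibration domain clamped to ",
              signif(c_min, 3), " mmol/L (SI 0)")

  frames <- array(0, dim = c(nx, ny, nt))
  for (t in seq_len(nt)) {
    f <- matrix(baseline_si + si_corr[t], nx, ny)
    for (nm in organ_names) f[masks[[nm]]] <- baseline_si + si_org[[nm]][t]
    frames[, , t] <- f
  }
  if (noise_sd_si > 0) {
    frames <- with_seed(seed,
      frames + array(stats::rnorm(length(frames), 0, noise_sd_si),
                     dim = dim(frames)))
  }
  list(series = dynamic_series(frames,
                               frame_interval = truth$frame_interval,
                               baseline_index = 3),
       rois = rois, geometry = geom)
}

#' Generate a synthetic serial-dilution table
#'
#' Renders tube signal intensities through the inverse calibration map, adds
#' Gaussian SI noise per replicate scan and averages the replicates (four
#' replicate reads by default, as on the bench).
#'
#' @param model truth [calibration_model()].
#' @param concentrations tube concentrations in mmol/L; must lie inside the
#'   model domain (`> a`, `<= conc_valid_max`). Default 25 tubes spanning
#'   0-15 mmol/L.
#' @param sd_frac replicate SI noise sd as a fraction of the largest tube SI.
#' @param n_replicates replicate scans averaged per tube, default 4.
#' @param seed RNG seed.
#' @return A [dilution_table()].
#' @export
generate_dilution_table <- function(model = default_calibration(),
                                    concentrations = seq(0, 15,
                                                         length.out = 25),
                                    sd_frac = 0, n_replicates = 4,
                                    seed = NULL) {
  stopifnot(inherits(model, "calibration_model"))
  if (any(concentrations <= model$a))
    stop_with("calibration_domain_error",
              "tube concentrations must exceed the model offset a = ",
              model$a, " mmol/L")
  if (any(concentrations > model$conc_valid_max))
    warn_with("calibration_out_of_range",
              "tube concentration(s) above the validated range (",
              model$conc_valid_max, " mmol/L)")
  si_true <- concentration_to_si(concentrations, model)
  si_max <- max(abs(si_true))
  mean_si <- with_seed(seed, {
    vapply(si_true, function(s) {
      mean(s + stats::rnorm(n_replicates, 0, sd_frac * si_max))
    }, numeric(1))
  })
  dilution_table(concentrations, mean_si)
}
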