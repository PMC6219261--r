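# patlakGFR

Single-kidney glomerular filtration rate (GFR) from dynamic
contrast-enhanced MRI bolus tracking, via a time-shift-modified
Rutland–Patlak plot.

## The problem

Blood-sample GFR markers (creatinine, inulin) measure only the combined
filtration of both kidneys. Dynamic contrast-enhanced MRI ("bolus track": one
thick dorsal slab imaged every 0.58 s while a Gd-DOTA bolus passes) sees each
kidney separately, so the filtration of a single kidney can be quantified —
clinically relevant wherever unilateral renal disease is suspected, e.g. in
canine nephropathy work-ups. This package implements the complete analysis
for such a study and a synthetic-data generator standing in for scan data.

## The model

Signal intensity `S` is converted to gadolinium concentration with a
serial-dilution calibration (valid for SI 0–1200, ~0–15 mmol/L):

```
c(S) = a + b·exp(x·S),   a = −1.933, b = 1.996, x = 0.001876
```

Because the imaging slab (45 mm) is thicker than the organs, each ROI voxel
mixes organ and residual tissue; a nearby correction ROI and the measured
volumes undo this:

```
c_tissue = c_voxel · V_voxel/V_tissue − c_residual · V_residual/V_tissue
```

Curves are Savitzky–Golay smoothed (15 frames = 8.7 s, order 2) to suppress
breathing-motion artefacts, and the whole-kidney curve — shifted by the
aorta-to-kidney delay Δt (first renal minus first aortic peak time) — enters
the Rutland–Patlak linearization of the two-compartment tracer model:

```
c_kidney(t+Δt)·V_kidney / c_aorta(t) = V_vas + p·V_vas · ∫₀ᵗ c_aorta dt′ / c_aorta(t)
        y                                  b        m              x
```

An OLS line over the 60 s following the second aortic maximum (first-pass
perfusion has died away; >100 points at 0.58 s spacing) gives slope
`m = p·V_vas` (renal clearance, mL/s) and intercept `V_vas` (renal vascular
volume). Per-kidney plasma GFR normalized to body surface is

```
GFR = m · 60 / BS · (1 − hct),   BS = 0.1·BW^0.667 m²,  hct default 0.47
```

## Worked example

```r
library(patlakGFR)
truth <- synthetic_truth(seed = 42)        # truth GFR: left 12.7, right 12.0
ss    <- simulate_subject(truth, noise = TRUE)
res   <- run_subject_pipeline(curves = ss$curves, geometry = ss$geometry,
                              subj = ss$subject)
res
#> <gfr_result> subject synthetic-01
#>   left: GFR 13.20 mL/min/m^2 BS  (slope 0.28 mL/s, V_vas 4.03 mL, R^2 0.999, n=104)
#>   right: GFR 12.48 mL/min/m^2 BS  (slope 0.2648 mL/s, V_vas 3.5 mL, R^2 0.999, n=104)
#>   total: 25.68 mL/min/m^2 BS;  delta_t L/R 6.38/7.54 s;  0 warning(s)
res$landmarks
#> <bolus_landmarks> arrival at 11.02 s (curve time); after arrival:
#>   aorta: max1 6.96 s (59.3), min1 23.20 s (5.02), max2 31.90 s (19.5)
#>   kidney left: max1 13.34 s (14.6), delta_t 6.38 s
#>   kidney right: max1 14.50 s (14.2), delta_t 7.54 s
```

Reading this: the bolus reaches the aorta at 11.0 s; the aortic course shows
the characteristic first peak (59 mmol/L), valley and lower recirculation
peak; the kidneys peak ~6–7 s later. Each kidney's Patlak line is fitted on
104 points with R² ≈ 0.999, and the recovered GFRs (13.2/12.5) sit within
measurement noise of the generating truth (12.7/12.0 mL/min/m² BS); left +
right = total exactly.

A command-line interface wraps the same pipeline
(`inst/exec/patlak-gfr run --curves curves.csv --config subject.json --out
report.json`, `patlak-gfr simulate --seed 42 --out dir/`).

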