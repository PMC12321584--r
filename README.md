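# vesiclezone

Quantification pipeline for presynaptic vesicle organization around the
active zone (AZ) — in particular the ~20-nm **replacement zone**, the thin
shell of undocked synaptic vesicles held next to release sites for rapid
replenishment. The package is aimed at synapse cell biologists and
electrophysiologists who need the measurement chains behind this construct
as reproducible, testable code, without access to the original raw data:
every analysis stage comes with a synthetic-data generator that plants
exact ground truth.

## What it computes

- **2D STED morphometry** — Gaussian pre-smoothing (1.2 px), two-pass blind
  Richardson–Lucy deconvolution (10 iterations/pass, the second pass reuses
  the refined PSF), punctum detection as local maxima with edge exclusion,
  half-intensity boundary contours, Bassoon-bar midline fitting, and
  punctum distances d(midline), d(midpoint), signed d(boundary). A ~100-nm
  bar yields the ~50-nm classification window
  (`bassoon_window_halfwidth()`).
- **EM vesicle morphometry** — edge distance = min distance from vesicle
  center to the AZ polyline − radius (clamped at 0); docked ⇔ edge distance
  ≤ 0.5 nm; replacement ⇔ undocked and ≤ 20 nm; 2-nm-binned relative
  frequency histogram over [2, 50) nm; pit counts; per-group mean ± SEM.
- **Fluorescence traces** — rolling-ball background subtraction,
  dF/F = (F(t) − F0)/F0 with F0 over ~300 ms before the first stimulus,
  per-stimulus peaks with decay-corrected second pulses,
  PPR = P2/P1 with the printed omission rules (outside [0, 30]; [0, 5] at
  1-s intervals), FRAP one-phase association M·(1 − e^(−t/τ)), condensate
  CV = variance/mean, and activity-driven dispersion time courses.
- **fEPSP trains** — normalization to the first response, first/last-ten
  averages, recovery curves, and RRP ("nq") as the pulse-0 intercept of a
  linear back-extrapolation of cumulative normalized amplitudes over the
  final 20 of 100 pulses at 20 Hz.
- **Statistics** — two-sided t, Mann–Whitney U, Kruskal–Wallis with Dunn's
  post hoc restricted to prespecified pairs; deterministic CSV/SVG report
  bundles.

See `vignettes/methods.Rmd` for the model conventions, defaults and design
decisions.

## Worked example

Simulate two EM cohorts with a planted ~35% deficit in replacement-zone
vesicles, quantify, and compare:

```r
library(vesiclezone)

wt <- gen_em_cohort(em_cohort_config(n_profiles = 40, condition = "wt"), 1)
ko <- gen_em_cohort(em_cohort_config(n_profiles = 40, condition = "ko",
                                     replacement_mean = 1.17), 2)
cs <- summarize_cohort(c(wt$profiles, ko$profiles))
subset(cs$summary, metric %in% c("docked", "replacement"))
#>          group      metric  mean       sem  n
#> 1 ko / no-stim      docked 1.625 0.2198120 40
#> 2 ko / no-stim replacement 1.200 0.1761410 40
#> 7 wt / no-stim      docked 1.400 0.2050641 40
#> 8 wt / no-stim replacement 1.775 0.2306276 40

tab <- data.frame(unit = 1:80, group = cs$per_profile$condition,
                  value = cs$per_profile$replacement)
compare_groups(tab, "mann-whitney")
#>           test group1 group2 statistic    p_value adjust
#> 1 mann-whitney     wt     ko     983.5 0.06776969 none
```

Docked counts are equivalent while the replacement pool drops from 1.78 to
1.20 vesicles/profile (the planted 35% deficit; at n = 40/group this run is
suggestive, p ≈ 0.07 by Mann–Whitney). RRP estimation from a simulated
depressing train:

```r
g <- gen_train(train_config(rrp_true = 10, p_release = 0.3, noise_sd = 0.02), 1)
est <- backextrapolate_rrp(normalize_train(g$record))
sprintf("RRP (nq): %.3f  slope: %.3f  R2: %.4f", est$intercept, est$slope, est$r_squared)
#> "RRP (nq): 2.999  slope: 0.102  R2: 1.0000"
```

The intercept is in units of the first response. For this model the closed
form is (RRP − r/p) · p / (p · RRP) = (10 − 1)/10 · 1/0.3 · 0.3 = 3.0 —
the depletable pool above steady state, recovered here as 2.999 despite 2%
amplitude noise; the slope (0.102 ≈ r/(p·RRP) = 0.1) is the per-pulse
steady-state replenishment.

## Command line

```sh
Rscript inst/cli/vesiclezone run --config run.json
Rscript inst/cli/vesiclezone simulate-em --seed 1 --out out/
Rscript inst/cli/vesiclezone analyze-em --input out/simulate_em --out out/
```

Configs are JSON (or YAML) with `seed`, `outdir` and per-stage parameter
blocks; unknown keys are rejected before any computation and every run
writes a digest manifest.

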