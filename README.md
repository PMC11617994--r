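# sptmsd

Single-particle tracking (SPT) and mean-square-displacement (MSD) analysis
of membrane protein dynamics in R.

Proteins diffusing in the plasma membrane — exocyst subunits, receptors,
lipid-anchored GTPases — are routinely imaged one molecule at a time by
total internal reflection fluorescence (TIRF) microscopy and characterized
by how their mean-square displacement grows with lag time. `sptmsd`
implements that entire measurement chain as a tested, scriptable pipeline:

1. **Detection** — per-frame Laplacian-of-Gaussian (LoG) spot detection
   with 3×3 median pre-filtering, a robust data-driven quality threshold,
   and subpixel refinement (`detect_spots()`, `auto_threshold()`).
2. **Linking** — a two-stage linear-assignment-problem (LAP) tracker:
   globally optimal distance-gated frame-to-frame matching, then a second
   global assignment that closes short blinking gaps, followed by a
   minimum-spots track filter (`link_frames()`, `filter_tracks()`).
3. **MSD analysis** — time-averaged MSD per track over all overlapping
   point pairs (`tamsd()`), pair-count-weighted ensemble curves with SEM
   bands (`ensemble_msd()`), and the anomalous-diffusion power-law fit
   (`fit_powerlaw()`).
4. **Classification and confinement** — motion classes from the fitted
   exponent (`classify_motion()`, `class_fractions()`) and confinement
   radii from plateauing MSD curves (`confinement_radius()`).
5. **Statistics** — Kruskal-Wallis with Dunn-Holm post hoc tests for
   diffusion coefficients, one-way ANOVA with Tukey HSD for exponents,
   and 1.5×IQR box summaries (`kruskal_groups()`, `mean_alpha_summary()`).
6. **Simulation** — ground-truth trajectory generators for all four motion
   regimes plus a TIRF-like movie renderer, so every stage can be
   validated against known truth (`simulate_cohort()`, `render_movie()`).

## The model

The time-averaged MSD of a 2-D trajectory is fit, on log-log axes over the
first 200 ms of lag time, to the anomalous-diffusion power law

```
MSD(τ) = 2 d D τ^α ,  d = 2
log10 MSD(τ) = α·log10 τ + log10(2 d D)
```

where `D` is the generalized diffusion coefficient (µm²/sᵅ, reported also
as −log₁₀D) and `α` the anomalous exponent. Fits with R² ≤ 0.8 on the
log-log regression are gated out. Remaining tracks are classified by α:
below the Brownian band (default 0.9–1.1) as anomalous/confined
subdiffusion, inside it as Brownian, above it as directed transport.
Confined trajectories whose ensemble MSD saturates are additionally fit
with `MSD(τ) = R_c²(1 − exp(−τ/τ_c))`, whose plateau equals the squared
radius `R_c²` of the confining disk.

Default acquisition geometry follows the targeted TIRF regime: 65 nm
pixels, 58.8 Hz frame rate (17 ms interval), 500×500 px fields, 5000-frame
movies.

## Worked example

Simulate a mixed cohort — 60 Brownian tracks (D = 0.10 µm²/s) and 60
subdiffusive fractional-Brownian-motion tracks (D = 0.05 µm²/s^0.5,
α = 0.5) — then fit, classify, and compare:

```r
library(sptmsd)
dt <- 1 / 58.8                               # 17 ms frame interval
cohort <- simulate_cohort(
  list(list(model = brownian_model(0.10),       n = 60),
       list(model = anomalous_model(0.05, 0.5), n = 60)),
  n_steps = 1000, dt = dt, seed = 42)
fits  <- fit_tracks(cohort)                  # TA-MSD + power-law fit
truth <- cohort$model[!duplicated(cohort$track_id)]
aggregate(cbind(alpha, D) ~ truth, cbind(fits, truth),
          function(v) round(mean(v), 3))
#>       truth alpha     D
#> 1 anomalous 0.499 0.050
#> 2  brownian 0.996 0.099
class_fractions(fits)
#>         motion_class count fraction
#> 1 anomalous_confined    60      0.5
#> 2           brownian    60      0.5
#> 3           directed     0      0.0
kruskal_groups(fits$neg_log10_D, truth)$omnibus
#>         H df p
#> 1 89.2562  1 0
```

Both sub-cohorts are recovered at their generating parameters (mean fitted
α of 0.499 and 0.996 against targets 0.5 and 1; mean D of 0.050 and 0.099
against 0.05 and 0.10), every track lands in its true motion class, and
the two conditions separate decisively on −log₁₀D (Kruskal-Wallis
H = 89.3, p < 10⁻¹⁵).

The movie-level pipeline is one call:

```r
res <- run_pipeline(pipeline_config(), "movie.tif", "run1/")
# writes locs.csv, tracks.csv, tracks.xml, fits.csv, ensemble.csv,
# stats.json, manifest.json
```

A command-line driver with `simulate | detect | link | msd | compare |
run` subcommands is installed at `inst/cli/sptmsd.R`
(`Rscript $(Rscript -e 'cat(system.file("cli/sptmsd.R", package="sptmsd"))') run movie.tif --out-dir run1`).

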