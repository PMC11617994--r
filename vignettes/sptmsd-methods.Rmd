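---
title: "Methods: tracking, MSD fitting and motion classification in sptmsd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tracking, MSD fitting and motion classification in sptmsd}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sptmsd)
```

`sptmsd` quantifies the lateral mobility of membrane proteins from
single-particle TIRF movies. This vignette explains each stage's model and
assumptions, the parameters that matter, the numerical choices behind the
implementation, and what the built-in simulator can and cannot tell you
about performance on real data.

## The measurement model

A trajectory is a time-ordered sequence of 2-D positions $r(t)$ sampled at
the frame interval $\Delta t$. Its time-averaged MSD at lag $\tau$,
computed by `tamsd()` over *all* overlapping ordered point pairs separated
by $\tau$, is fit on log-log axes to the anomalous-diffusion power law

$$\mathrm{MSD}(\tau) = 2\,d\,D\,\tau^{\alpha},\qquad d = 2,$$

i.e. $\log_{10}\mathrm{MSD} = \alpha\,\log_{10}\tau + \log_{10}(2dD)$ by
ordinary least squares (`fit_powerlaw()`). The slope is the anomalous
exponent $\alpha$; the intercept gives the generalized diffusion
coefficient $D = 10^{\mathrm{intercept}}/(2d)$ in µm²/s^α, conventionally
reported as $-\log_{10} D$. $d = 2$ throughout: TIRF's evanescent field
restricts imaging to in-plane membrane motion.

Assumptions worth stating: displacement statistics are stationary over a
track's lifetime; localization error is not modeled as an offset term in
the MSD (see *Limitations*); and the fit window is short enough that
confinement has not yet bent the curve for the mobile population.

### Key fitting parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `fit_window_s` | 0.2 | s | short-lag window (~first dozen delays at 58.8 Hz) where the power law holds before confinement saturates the curve; configurable as an absolute window because the lag grid, not track duration, sets where the power law is informative |
| `r2_gate` | 0.8 | — | tracks whose log-log regression explains < 80 % of variance are too noisy to trust an exponent; they are flagged, excluded from class counts, and reported separately |
| `d` | 2 | — | membrane (in-plane) diffusion |
| `band` | (0.9, 1.1) | — | the Brownian class $\alpha = 1$ is measure-zero under noise; the band width ≈ 2 SD of per-track $\hat\alpha$ scatter for 1000-step tracks, and is echoed into every report |

Fits with fewer than three usable delays (after dropping zero-MSD delays,
which have no logarithm) are marked `failed`, never silently passed.

### Motion classes and the $-\log_{10}D$ series

`classify_motion()` maps $\alpha$ below/inside/above the band to
anomalous-confined, Brownian, and directed motion. `logD_vs_time()`
reports the apparent coefficient $D_{app}(\tau) =
\mathrm{MSD}(\tau)/(2d\tau)$ per delay: constant for Brownian motion,
falling (i.e. $-\log_{10}D_{app}$ rising) for subdiffusion — a
model-free visual of anomalousness.

### Confinement radius

For curves that saturate, `confinement_radius()` fits
$\mathrm{MSD}(\tau) = R_c^2\,(1 - e^{-\tau/\tau_c})$ by
Levenberg–Marquardt nonlinear least squares. The identification of the
plateau with $R_c^2$ is a convention tied to the simulator's reflecting
disk: two independent uniform points on a disk of radius $R_c$ have mean
squared separation exactly $R_c^2$, so the fitted $R_c$ *is* the disk
radius. Curves whose late-lag log-log slope is ≥ 0.3 (last third of
delays) are refused with a diagnostic instead of returning a meaningless
radius; the single-exponential form itself is a package convention — the
literature uses several — and is recorded in output.

## Detection

Each frame is optionally median-filtered (3×3; implemented as an exact
pmin/pmax selection network on raw counts), then convolved with a
scale-normalized Laplacian-of-Gaussian at $\sigma =
\mathrm{diameter}/(2\sqrt2)$, the blob-detector convention that matches a
Gaussian spot of the stated diameter. Candidates are strict 3×3 local
maxima of the (sign-flipped) response above a quality threshold, with:

- **auto-threshold**: median + 8·MAD of the response over ≤ 20 evenly
  sampled frames. On pure noise this admits ≲ 0.1 false maxima per frame;
  it is deliberately overridable per movie since real acquisitions differ
  in signal intensity.
- **border policy**: candidates within $\lceil 2\sigma\rceil$ px of the
  edge are discarded (the refinement window must fit).
- **duplicate suppression**: of two maxima closer than diameter/2, the
  higher-quality one survives; ties break lexicographically by
  (frame, y, x) so results are deterministic.
- **subpixel refinement**: per-axis quadratic interpolation of the
  response through the maximum; if the parabola is degenerate or its
  vertex falls outside ±1 px, an intensity-weighted centroid over a
  $(2\lceil2\sigma\rceil+1)^2$ window is used instead.

Coordinates are physical µm under the pixel-center convention: pixel
$(i,j)$ (0-based row, column) has its center at $((j+0.5)\,\mathrm{px},\,
(i+0.5)\,\mathrm{px})$. Frames are 0-based.

## Linking

`link_frames()` is a two-stage LAP tracker. Stage 1 solves, per
consecutive frame pair, a rectangular assignment with cost = squared
distance and pairs beyond `max_link_distance_um` forbidden. Minimizing
total cost with a per-rejection charge of gate² is equivalent to a
maximum-weight bipartite matching with edge benefit gate² − distance²,
which is how it is solved (via igraph's weighted matching); the test suite
checks the solution against an exhaustive enumeration oracle. Stage 2
closes gaps: segment ends may join segment starts 2 to
`max_frame_gap`+1 frames later within `max_gap_distance_um`, again by one
global assignment over all candidate end–start pairs. Gap frames carry no
interpolated positions — TA-MSD delays come from true time differences,
so gaps are handled naturally downstream.

Defaults (`max_link_distance_um` 0.5, `max_gap_distance_um` 0.8,
`max_frame_gap` 2, `min_spots` 10) suit a particle with
$D \le 0.1$ µm²/s at 58.8 Hz, where the RMS frame-to-frame step is
≈ 0.08 µm: the gate is ~6× that, wide enough for tail steps yet far below
typical inter-particle spacing at the densities the detector is meant for
(≤ 0.05 µm⁻²). They are mandatory inputs echoed into all output metadata
because results depend on them. A greedy nearest-neighbour mode exists
solely for sensitivity analysis. Splitting and merging are out of scope
(the simple two-stage formulation excludes them).

The `min_spots` filter (localized points, not bridged frames) discards
blink-dominated fragments whose MSD fits would be dominated by noise.

## Ensemble averaging and group statistics

`ensemble_msd()` averages per-track curves per delay, weighting by each
track's pair count at that delay (default) — the variance-minimizing
choice when tracks contribute unequal information — or uniformly. The SEM
uses reliability weights
($n_\mathrm{eff} = (\sum w)^2/\sum w^2$), reducing to the ordinary SEM
under uniform weights.

Per-track $-\log_{10}D$ distributions are compared with the
Kruskal–Wallis rank-sum test (tie-corrected) followed by Dunn's pairwise
z-tests on the shared ranks with Holm adjustment — the standard rank-based
companion; pairwise Wilcoxon with Bonferroni is available by flag.
Per-track $\alpha$ means are compared parametrically (one-way ANOVA +
Tukey HSD), the family conventionally used for exponent comparisons; the
family used is recorded in the output. Box summaries fix the
linear-interpolation quantile rule (R type 7) and Tukey 1.5×IQR whiskers,
since quartile definitions vary across software. Groups with fewer than
three values are excluded with a warning. Tracks are pooled across cells
within a condition; cell-level nesting is not modeled (a caveat for
hierarchical designs — per-cell medians can be fed in instead).

## The simulator: what it emulates, and what it does not

`simulate_cohort()` + `render_movie()` emulate the targeted acquisition
regime: 65 nm pixels, 58.8 Hz, 500×500 px fields, with four exact motion
models:

- **Brownian**: independent Gaussian increments, variance $2D\Delta t$
  per axis.
- **Anomalous**: fractional Brownian motion per axis with Hurst
  $H = \alpha/2$, synthesized *exactly* via Davies–Harte circulant
  embedding of the increment covariance (Cholesky fallback if the
  embedding spectrum goes negative), scaled so
  $E\,\mathrm{MSD}(\tau) = 4D\tau^\alpha$. Exactness matters because
  $\alpha$ recovery is the package's headline validation.
- **Confined**: Brownian motion radially reflected at a disk of radius
  $R_c$; the frame interval is internally subdivided so the per-substep
  RMS step is ≤ $R_c/8$, keeping the discrete scheme close to continuous
  reflection and the stationary distribution uniform — hence the
  $R_c^2$ plateau used by the tests.
- **Directed**: Brownian increments plus $v\,\Delta t$ drift.

Rendering integrates an isotropic Gaussian PSF over pixel areas (CDF
differences), adds a uniform background, and applies Poisson shot noise
(optional Gaussian read noise). Defaults
(`photons_per_spot` 1000, `background` 100, `psf_sigma_px` 1.3) give a
peak-to-background-shot-noise ratio ≈ 10, and cohort defaults keep spot
density ≤ 0.05 µm⁻² — chosen once as a realistic single-fluorophore TIRF
regime in which the tracker is meant to operate, since spot density and
photon budget are acquisition-specific. Determinism: one root seed with
per-track child streams (separate streams for start position and
increments), so growing a cohort never perturbs existing tracks; rendered
movies are byte-identical given a seed.

Deliberately **not** emulated: depth-dependent evanescent excitation,
EMCCD excess noise, sample drift, astigmatic/3-D PSFs, motion blur within
a frame, and (by default) blinking/bleaching photophysics. Passing the
synthetic validations therefore demonstrates correctness of the
*algorithms* under the stated imaging model — not robustness to every
real-data pathology; the detector threshold and link gates remain per-
dataset judgments on real movies.

## Numerical choices and degenerate inputs

- The LoG second-derivative kernel is re-centered to sum exactly to zero,
  so constant images give an exactly zero response (and the auto-threshold
  is exactly 0 there).
- The log-log fit excludes msd = 0 delays; `D = 0` degenerate tracks are
  representable in simulation but unfittable, by design.
- The confinement fit starts from the empirical plateau and the lag
  nearest $1 - e^{-1}$ of it, with positivity bounds.
- Empty localization tables link to empty track lists (not an error);
  movies with no detectable spots flow through the whole pipeline and
  yield a `"no tracks"` summary.
- Assignment ties (exactly equal costs) have measure zero for continuous
  data; determinism elsewhere is enforced by explicit lexicographic
  tie-breaks.
- The "first 25 % (200 ms)" fitting convention is implemented as an
  absolute 200 ms default window rather than a per-track fraction, the
  only unambiguous reading when track durations vary; both are available
  via `fit_window_s`.
- Whether published $-\log D$ values derive from per-track fits or the
  ensemble curve varies by study; both are computed (`fit_tracks()`,
  `fit_powerlaw(ensemble_msd(...))`).

## Validation scale

The shipped tests validate: exact inversion of noiseless power-law curves
over a 25-point $(D,\alpha)$ grid; Brownian recovery (200 tracks × 1000
steps: mean $\hat\alpha \in [0.95, 1.05]$, mean $\hat D$ within 10 %, R²
gate ≥ 95 % pass); fBm recovery at $\alpha \in \{0.4, 0.6, 0.8\}$ (±0.05);
reflecting-disk plateau and $R_c$ within 10 % (500 tracks × 300 steps);
detector recall ≥ 0.95 and ≥ 99 % link fidelity on a rendered 20-spot,
200-frame movie at 0.05 µm⁻²; exact agreement of TA-MSD and the LAP stage
with brute-force oracles; Kruskal–Wallis null calibration (type-I error
0.05 ± 0.02 over 2000 simulations); and byte-level pipeline determinism.
These sizes were chosen to give stable Monte-Carlo estimates at desk
scale; `scripts/acceptance.R` re-runs them from a single root seed.

## Limitations

- No localization-error offset term in the MSD model: static error
  inflates short-lag MSD and biases $\hat\alpha$ slightly downward on
  tracked (vs. true) trajectories — visible as ≈ 0.03 in the rendered-
  movie validation. Fitting from the second delay onward, or an offset
  term, would be the standard remedies if this matters for an
  application.
- No Kalman/motion-model prediction in the linker; fast directed motion
  beyond the distance gates will fragment.
- No HMM state segmentation or Bayesian classifier: classification is
  per-track, from a single exponent.
- TrackMate XML support covers the simplified "Tracks" export dialect
  (with a `frameInterval`-attribute convention distinguishing frame-index
  from seconds dialects), not full TrackMate session files.
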