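---
title: "Apparent size of bacterial microcompartments: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Apparent size of bacterial microcompartments: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcpsize)
```

Bacterial microcompartments (MCPs) are ~100–150 nm protein organelles. When
the same purified MCP preparation is sized with different techniques —
negative-stain TEM, TEM after HMDS solvent exchange, SEM, cryo-TEM,
ultra-thin-section (UTS) TEM, ensemble dynamic light scattering (DLS) or
nanoparticle tracking analysis (NTA) — the apparent diameters disagree
systematically, because each preparation perturbs the particle (drying
collapse, coating, sectioning) or measures a different physical average.
`mcpsize` packages the quantitative models that explain and reproduce those
disagreements: a stereological sectioning model, a calibrated synthetic
measurement generator, DLS cumulant analysis, and the comparative statistics.

## The stereological sectioning model

An ultramicrotome section at distance $r$ from the centre of a sphere of
diameter $D$ exposes a circle of diameter

$$d(r) = D\sqrt{1 - (2r/D)^2}.$$

Averaging $d(r)$ with the spherical volume element (weight $\propto r^2$ on
$[0, D/2]$) gives the expectation

$$\mathbb{E}[d] \;=\; \frac{1}{V}\int_V d(r)\,\mathrm{d}V \;=\; \frac{3\pi}{16}\,D
\;\approx\; 0.589\,D,$$

i.e. ~41.1% underestimation of the true diameter even for a perfect sphere.
This volume-element weighting is what `scheme = "volume_weighted"`
implements, and it is the model whose prediction the package reproduces. The
classical stereological convention — a uniformly random plane offset — gives
$\mathbb{E}[d] = (\pi/4) D$ (~21.5% underestimation) and is provided
alongside as `scheme = "uniform_plane"`. The two weightings answer different
sampling questions (volume-weighted sampling corresponds to picking a random
point inside the particle, uniform planes to a random section position);
both are exposed and neither is silently substituted for the other.

```{r}
m <- sectioning_model(138)
underestimation_percent(m)
underestimation_percent(sectioning_model(138, "uniform_plane"))
```

`mc_section_sphere()` is the Monte-Carlo counterpart (inverse-CDF draws of
$r$: $r = (D/2)U^{1/3}$ volume-weighted, $r=(D/2)U$ uniform) and agrees with
the closed forms to within Monte-Carlo error; tests assert agreement at
$3\,\mathrm{SE}$ with $10^5$–$10^6$ draws.

### The detection limit

Observed UTS measurements underestimate less than the model predicts
(99 nm recorded against a 138 nm cryo-TEM reference: a ratio of 0.72, not
0.589). The package models this as a *detection limit*: sections smaller
than a threshold $t$ are not recognised during image analysis and are never
recorded, which left-truncates the section-diameter distribution and raises
its mean. The truncated mean is monotone in $t$, so the threshold matching
an observed ratio is found by bracketed root finding (`uniroot`, absolute
tolerance $10^{-6} D$) on the numerically integrated truncated mean.

One subtlety matters. For a *single* sphere of diameter 138 nm the threshold
solving $\mathbb{E}[d \mid d \ge t]/138 = 0.72$ is ~66 nm. But the observed
0.72 is a ratio of *population* means over particles of varying true size
(cryo-TEM spread 21 nm), and both the truncated mean and the probability
that a particle yields a recordable section are nonlinear in $D$; fitting on
a fixed diameter and then simulating a dispersed population overshoots the
target mean by about 2 nm. `fit_detection_limit(..., true_size_sd = 21)`
therefore averages the truncated mean and the acceptance probability over a
normal true-size distribution (numerical integration over $\pm 8$ SD); the
population-consistent threshold is ~62 nm and re-simulation recovers the
99 nm mean within Monte-Carlo error. With `true_size_sd = 0` the
single-sphere behaviour is retained.

```{r}
fit_detection_limit(99 / 138, m)                    # single sphere
(t_pop <- fit_detection_limit(99 / 138, m, true_size_sd = 21))
```

### Irregular particles

Real Pdu MCPs are irregular polyhedra, not spheres. `make_irregular_particle()`
builds a convex particle from a regular icosahedron whose vertices are
radially perturbed by up to ±30%, re-hulled, recentred at the volume
centroid, and rescaled so the max Feret diameter (the largest caliper width,
matching the manual "longest diameter" measurement convention) equals the
target exactly. Facets, edges, volume and centroid come from an incremental
3-D convex-hull builder written for this package (no hull routine is
available in the dependency set); it is cross-checked in the tests against
the icosahedron closed form and against `scipy.spatial.ConvexHull` values
frozen from an independent run. `section_particle()` intersects a plane with
the hull edges and reports the section polygon's max Feret;
`mc_section_particle()` draws isotropic normals (normalised Gaussians) and
per-scheme offsets over the support interval along each normal.

A geometric caveat discovered while validating: a regular icosahedron is
substantially "pointier" than its circumsphere, so its volume-weighted mean
section Feret is ~0.507 of its max Feret — noticeably below the spherical
$3\pi/16 \approx 0.589$, not marginally below it. The test suite asserts the
value verified by two independent implementations rather than a nominal
sphere-like band. Sectioning irregular particles inflates the apparent
coefficient of variation relative to the true-size distribution, which is
the qualitative explanation for UTS being 1.5–1.9× more variable than every
other technique.

## The synthetic measurement generator

The generator replaces manual micrograph tracing: its defaults *are* the
study conditions. Each imaging technique is calibrated to the pooled group
statistics — TEM 102 ± 17, TEM+HMDS 124 ± 17, SEM 126 ± 17, cryo-TEM
138 ± 21, UTS TEM 99 ± 32 nm, each N = 300 as 3 replicates × 100. Design
choices, fixed once:

* **Within-replicate noise is Gaussian** (the published box plots are
  roughly symmetric; no distributional form is stated); negative draws are
  redrawn rather than truncated so the moments stay interpretable
  (vanishingly rare at these calibrations).
* **Between-replicate spread defaults to 5 nm** — replicate-level spread is
  never reported (replicates are pooled), so this is a documented free knob.
* **`exact_moments = TRUE`** affinely standardises each pooled sample so
  mean and SD match the calibration to machine precision; the statistical
  comparisons then test the method, not generator luck. Without it, moments
  converge at $1/\sqrt{N}$.
* **UTS can be generated two ways**: `direct` (from the 99 ± 32 calibration,
  like any technique) or `sectioned` (mechanistically, by sectioning
  cryo-calibrated true sizes through the model above and applying the
  detection limit). The sectioned route is the one that *explains* the UTS
  numbers rather than copying them.
* **DLS/NTA populations are lognormal** (standard for particle sizing, and
  closed under the $d^3$/$d^6$ reweighting algebra). The NTA sample is a
  lognormal mixture: a main population parameterised by the reported mode
  (130.7 nm, log-SD 0.15) plus an aggregate component (3% at 400 ± 100 nm by
  default). Aggregates shift the per-particle *mean* far more than the
  kernel-density *mode* — the qualitative mean > mode signature of NTA.

What the generator does **not** emulate: micrograph pixel data, stain and
coating artefacts, non-Gaussian tails, finite NTA track lengths, or
replicate-level covariance between techniques. Passing tests therefore show
that the analysis pipeline recovers what it should from data with the
published first and second moments — not that real micrographs are Gaussian.

## DLS simulation and cumulant analysis

The intensity autocorrelation of a polydisperse suspension is simulated as

$$g_2(\tau) = 1 + \beta\Big[\textstyle\sum_i w_i e^{-q^2 D_i \tau}\Big]^2 + \varepsilon,$$

with intensity weights $w_i$, Stokes–Einstein diffusion
$D_i = k_B T / (3\pi\eta d_i)$ and scattering vector
$q = (4\pi \hat n/\lambda)\sin(\theta/2)$. Instrument defaults follow the
study conditions: 173° backscatter, 4 °C water ($\eta = 1.567$ mPa·s,
$\hat n = 1.333$), 633 nm (the standard He-Ne line; the source wavelength is
not stated and is configurable), coherence intercept $\beta = 0.8$, noise 0
for analysis-grade curves.

`cumulant_fit()` implements the standard second-order cumulant expansion:
weighted least squares of $\tfrac12\ln[(g_2-1)/\beta]$ on
$-\bar\Gamma\tau + (\mu_2/2)\tau^2$ over the lags where the normalised
amplitude is at least `window_floor` (default 0.1 — the tail of the
logarithm amplifies noise), with amplitude-squared weights. The Z-average is
$\bar\Gamma$ mapped back through $q$ and Stokes–Einstein — the
intensity-weighted *harmonic mean* diameter, the instrument convention — and
PDI $= \mu_2/\bar\Gamma^2$, clamped at zero (with a flag) when the quadratic
term fits marginally negative on monodisperse input.

Calibration to an ensemble target is closed-form: for intensity-weighted
diameters lognormal$(m, s)$, PDI $= e^{s^2}-1$ and the harmonic mean is
$e^{m - s^2/2}$, so `calibrate_intensity_psd(122.04, 0.045)` sets
$s^2 = \ln(1.045)$, $m = \ln(122.04) + s^2/2$.

```{r}
fit <- cumulant_fit(simulate_correlogram(calibrate_intensity_psd(122.04, 0.045)))
fit
```

The ~0.002 shortfall of recovered PDI is the truncation error of the
second-order expansion on a lognormal — within the ±0.015 band the recovery
tests assert. PSD reweighting uses Rayleigh-regime factors (intensity
$\propto$ number $\times d^6$, volume $\propto$ number $\times d^3$); at
122 nm under 633 nm illumination Mie corrections would modify the $d^6$
factor, a known bias accepted by design. `psd_mode()` maximises weight
*density* (weight per unit diameter), so linear and logarithmic grids agree;
ties resolve to the smaller diameter. The ~90 nm number/volume maxima of the
published distributions cannot be pinned without knowing the instrument's
inversion, so only the left-shift ordering (number < volume < intensity
mode) is asserted.

## Statistics

`summarize_diameters()` uses Tukey hinges (`fivenum`) for quartiles — the
convention matters for outlier counts — whiskers at the most extreme points
within 1.5 IQR of the hinges, and Tukey fences for outliers. ANOVA is the
classical fixed-effects F (`oneway.test`, `var.equal = TRUE`). The t-test
variant is not stated in the source analysis; Welch is the default (group
SDs of 17 vs 32 nm are plainly unequal), pooled is selectable, and the
summary-statistic route exists because published tables carry only
(n, mean, SD) — the raw-data p-values of .12/.26 depend on distributional
detail beyond two moments and are deliberately not targets. No
multiple-testing correction is applied, for fidelity to the original
analysis; percent changes are rounded to integers only at the reporting
layer.

## Reproduction driver and problem sizes

`run_reproduction()` chains everything — generation, statistics, stereology,
DLS, NTA — writes CSVs plus a human-readable report, and returns a manifest
(config, master seed, per-stage child seeds, file inventory). One master
seed expands into fixed per-stage child seeds (`child_seed()`), so reruns
are byte-identical and each stage is independently reproducible.

Problem sizes used by the shipped tests and driver: $10^5$–$10^6$ sphere
sections for Monte-Carlo/analytic agreement, $10^4$ particles for the
sectioned-UTS dataset (SE ≈ 0.25 nm on the 99 nm mean), $2\times10^4$ NTA
tracks, 250 log-spaced correlogram lags from 1 µs to 0.1 s, and 500
simulations for the ANOVA type-I-rate property. These give comfortable
3-SE margins for every stochastic assertion while keeping the whole suite
in seconds.

## Known limitations

* The zero-thickness section model ignores finite slice thickness
  (`slice_thickness` is honoured by the Monte-Carlo sampler as a slab
  maximum but is an undocumented-by-the-source extension, default 0).
* The detection limit is a hard threshold; a smooth recognition probability
  would be more realistic but is unidentifiable from a single observed
  ratio.
* Rayleigh weighting, Gaussian imaging noise, and the absence of
  between-technique correlation are simplifications noted above.
* MCP collapse/deflation mechanics are not modelled; the per-technique
  means are calibrated, not derived.
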