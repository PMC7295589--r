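---
title: "Methods: migration kinematics, stable walk models and FCCS binding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: migration kinematics, stable walk models and FCCS binding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellwalk)
```

cellwalk quantifies how a treatment (in the motivating application, a
glucocorticoid acting through its receptor) changes the migratory
behaviour of single cells, and whether the receptor physically engages a
candidate effector in live cells. Four statistical procedures carry the
analysis; this vignette states each model, its assumptions, the tunable
parameters, and the numerical choices made where the design was open.

## 1. Trajectory kinematics

A trajectory is a time-ordered planar path $(t_i, x_i, y_i)$ in minutes
and micrometres, as exported by any single-particle tracking tool. The
per-frame *step length* is the planar Euclidean distance
$c_i = \sqrt{(x_{i+1}-x_i)^2 + (y_{i+1}-y_i)^2}$; only 2-D positions are
used (tracking here is 2-D; any z-drift is not corrected).

Per track we report:

* **total displacement** — the *cumulative path length* $\sum_i c_i$.
  This follows the operational definition used in migration violin
  plots ("the overall distance moved"), not the word's usual
  straight-line meaning; the straight-line start-to-end distance is
  reported separately as **net displacement**, which serves rose plots.
  Path length ≥ net displacement always (triangle inequality; enforced
  by a property test).
* **median step length** and **mean speed** (path length / duration, so
  a gap in acquisition is normalised by the actual elapsed time rather
  than a nominal frame count).

**Speed filter.** Tracking debris is removed by requiring mean speed
strictly above a threshold, default 2.5 µm/min, with the boundary value
rejected. A caveat a user must know: with 10-min frames and step lengths
of a few µm — the regime the defaults emulate — mean speeds are
~0.2–0.3 µm/min, so a 2.5 µm/min cut rejects *every* cell. The
published workflow this package re-implements states the same threshold
alongside step lengths of that scale, which we read as a unit ambiguity
in the upstream tracker's speed field (per-frame rather than per-minute
speeds). We keep the stated default on the function, and set the
threshold explicitly (0.1 µm/min) in the synthetic pipeline configs.
The upstream 25 µm object-size filter is an imaging-side segmentation
setting; it is recorded in `track_filter_config()` for provenance and
never applied, since no pixels are processed here.

**Cumulative-distance matrices** align each track's running path length
on the acquisition grid relative to its own start; tracks of different
lengths are kept ragged rather than truncated or imputed, and a cell
simply drops out of time points beyond its last frame.

## 2. The α-stable step-length model

Pooled step lengths from migrating epithelial cells are heavy-tailed:
mostly small steps, occasionally a long relocating "search" step. The
α-stable family captures this with four parameters — stability exponent
$\alpha \in (0,2]$ (tail weight; 2 = Gaussian, 1 = Cauchy), skewness
$\beta \in [-1,1]$, scale $\gamma > 0$ (µm) and location $\delta$ (µm).
A treatment that suppresses long steps shows up as a reduced $\delta$
(left-shifted frequency curve) and reduced $\gamma$.

**Parameterisation.** Densities have no closed form; everything is
computed from the characteristic function. Internally we use Nolan's
continuous S0 form, which is numerically continuous at $\alpha = 1$;
results carry an explicit tag and convert losslessly to the classical
S1 form (`stable_convert()`), since the upstream MATLAB workflow does
not state which it reports. The two differ only by the location shift
$\delta_1 = \delta_0 - \beta\gamma\tan(\pi\alpha/2)$.

**Density and CDF** are evaluated by adaptive quadrature of the
inversion integral (absolute tolerance 1e-10) on data standardised to
$\gamma = 1, \delta = 0$; beyond $|z| > 80$ standardised units the
first-order power-law tail expansion is used instead, avoiding an
integrand oscillating over hundreds of cycles. At $\alpha = 2$ exactly
the Gaussian branch is taken. Grid evaluation for PDF overlays simply
vectorises the point quadrature: at overlay grid sizes (≤512 points)
this is fast and avoids FFT wrap-around/aliasing choices entirely.

**Estimation** (`fit_alpha_stable()`) is by iterated regression on the
empirical characteristic function $\hat\varphi(t)$, in the spirit of
Koutrouvelis with the fixed 10-point grid of Kogon–Williams on
$t \in [0.1, 1]$ for standardised data:

1. initialise $\delta$ = median, $\gamma$ = IQR/2, $\alpha = 1.5$,
   $\beta = 0$ (a crude but monotone-corrected start; a McCulloch table
   lookup adds nothing once the regression iterates);
2. regress $\log(-\log|\hat\varphi(t)|^2)$ on $\log t$: the slope is
   $\alpha$, the intercept updates $\gamma$;
3. regress the continued ECF phase on $t$ and
   $\tan(\pi\alpha/2)(t^\alpha - t)$ (continuous at $\alpha = 1$):
   coefficients update $\delta$ and give $\beta$;
4. re-standardise and repeat to convergence (≤5 iterations).

Pilot simulation (20 replicates, n = 15,000, $\alpha$ ∈ {1.2, 1.5,
1.8}) shows mean bias in $\hat\alpha$ below 0.01 and $\hat\gamma$
within 0.2% — comfortably inside the package's acceptance tolerances
(±0.03, ±5%). Near $\alpha = 2$, $\tan(\pi\alpha/2) \to 0$ makes
$\beta$ unidentifiable; the phase regression then drops the skewness
regressor and fixes $\beta = 0$. A maximum-likelihood polish
(`refine = "mle"`, Nelder–Mead on a 257-node binned likelihood) is
available but off by default: at these sample sizes it changes
estimates by less than Monte-Carlo error at many times the cost.

**Support mismatch.** Step lengths are non-negative, but the stable law
lives on ℝ. Following the workflow being re-implemented, the fit is
applied to the raw sample with no truncation correction; the fitted CDF
mass below zero is reported as a diagnostic (`mass_below_zero`). The
synthetic walk generator, conversely, rejection-resamples each step to
be ≥ 0 so pooled samples stay i.i.d. The two choices do not cancel:
conditioning away even ~0.4% of negative mass biases $\hat\alpha$
upward by roughly +0.1. The round-trip test asserts exactly this
bounded, upward-only effect rather than pretending the generator and
the fit share a support.

**Uncertainty** follows the published resampling protocol
(`bootstrap_alpha_stable()`): 100 resamples of 15,000 values drawn with
replacement, each refitted; per-parameter mean ± sd is reported. The
whole stream is determined by one integer seed.

**Sampling** uses the Chambers–Mallows–Stuck construction in S1,
shifted into S0 — the standard exact sampler, one uniform and one
exponential variate per draw. Histogram bins for empirical PDFs default
to Freedman–Diaconis (the upstream workflow states no rule; FD is
robust to the heavy tail).

## 3. FCCS binding quantification

Fluorescence cross-correlation spectroscopy measures, at one confocal
spot, the auto-correlation of each spectral channel and their
cross-correlation; co-diffusion of the two labels (binding) produces
cross-correlation amplitude.

**Curve model** (`correlation_model()`): multi-component 3-D diffusion
with structural parameter $S$ fixed at 4 and an optional triplet term,

$$G(\tau) = \Big[1 + \tfrac{T}{1-T}e^{-\tau/\tau_T}\Big]\,
\frac{1}{N}\sum_i f_i\Big(1+\tfrac{\tau}{\tau_{D,i}}\Big)^{-1}
\Big(1+\tfrac{\tau}{S^2\tau_{D,i}}\Big)^{-1/2}.$$

Autocorrelations are fitted with two components plus triplet;
cross-correlations with a single component (the complex is one species)
and no triplet. Fitting is weighted least squares — inverse-variance
across the five 5-s repeat runs when per-run curves are provided,
uniform otherwise — over a fixed multi-start grid of diffusion times
(log-spaced 5×5 over $10^{-5}$–$1$ s; the four best raw starts are
polished by BFGS in transformed coordinates: log N, logit f, log τ).
The zero-lag amplitude $G_0 = 1/N$ is taken from the fitted model, not
the first measured lag, suppressing afterpulsing noise.

**QC** mirrors the published cuts: reject if counts-per-molecule
< 1 kHz in either channel or photobleaching > 10% in either channel;
both strict, so boundary values pass.

**Concentrations.** With the calibrated effective volume
$V_{\mathrm{eff}} = 0.57$ fL,
$[green]_{tot} = 1/(G_{g0} N_A V_{\mathrm{eff}})$, likewise red, and
$[complex] = G_{x0}/(G_{g0} G_{r0} N_A V_{\mathrm{eff}})$. A complex
exceeding either total by more than 5% is rejected as unphysical;
smaller excess (fit noise) is capped at the smaller total.

**RCC.** "Fraction of the red-labelled species bound" equals
$G_{x0}/G_{g0}$ by the standard amplitude relations, so
$\mathrm{RCC} = 100\,G_{x0}/G_{g0}$ — this is the unique amplitude
ratio equal to the quoted quantity. Since the source text cannot
disambiguate the denominator channel, the complementary ratio
$G_{x0}/G_{r0}$ is switchable (`denominator = "red_auto"`). Independent
species give 0%, a tandem fusion of both fluorophores 100%.

**Kd.** The single-site isotherm
$[complex]/[green]_{tot} = x/(K_d + x)$ with
$x = [red]_{tot} - [complex]$ is fitted by least squares in $\log K_d$
(golden-section on a 12-decade bracket — one parameter, no start
sensitivity). Before fitting, measurements whose total green or red
concentration lies more than 3 SD from the condition mean are excluded
in a single pass per channel (no iterative re-exclusion; iteration is
unstated upstream, and a one-pass rule is idempotent on clean data).
The default confidence interval is Wald on $\log K_d$ — positivity is
respected without ad-hoc truncation — with a profile-likelihood
interval behind `ci_method = "profile"`. Note the 3-SD rule only has
teeth at realistic cohort sizes: in a 6-point table a single gross
outlier inflates the SD enough to mask itself; at the ~30-cell scale
the rule behaves as intended. `compare_kd()` grades two conditions by
the highest ladder level (0.95, 0.99, 0.999, 0.9999) at which their
intervals are disjoint.

## 4. Group statistics

**Tertile analysis** of microtubule plus-end growth speeds anchors the
bin edges on the *reference* (vehicle) condition — its 1/3 and 2/3
empirical quantiles (type-7 interpolation, switchable) — and applies
those edges to every other condition. Bins are left-open/right-closed
with ties to the lower bin (tie handling is unstated upstream; any
fixed convention preserves the balanced-to-within-1 property tested).

**Rank-sum scan.** At each shared time point, the cumulative distances
of treated vs vehicle cells still in frame are compared by a two-sided
Mann–Whitney/Wilcoxon test; the *earliest significant time* is the
first point with $p < \alpha$ (default $10^{-4}$) **and** treated
median below vehicle median. The direction requirement is implied but
not explicit upstream; it is on by default and switchable
(`require_reduction = FALSE`). No multiplicity correction is applied
across the scan — the published procedure reports a per-time-point
threshold, which is why it is set so conservatively; this is stated
prominently rather than silently "fixed". The exact null distribution
is used for tie-free groups under 50 cells, the tie-corrected normal
approximation otherwise.

## 5. Synthetic data: what a green test establishes

The generators produce data with the statistical structure each
analysis assumes, at the scale of the experiments they emulate:

* **Walks**: ~100 cells/condition, 145 frames at 10 min (24 h), step
  lengths from condition-specific stable laws (vehicle
  α=1.5, γ=0.9, δ=2.6 µm; treated γ=0.7, δ=2.1 µm — a few-µm median
  step with a heavy tail, and the treated law pulled left/down as the
  drug effect), isotropic headings, optional parameter switch at a
  configurable frame to emulate dosing mid-acquisition. Steps are
  rejection-resampled to ≥ 0 (see §2). Each cell has a deterministic
  RNG substream derived from the cohort seed, so cohorts reproduce
  bit-for-bit regardless of evaluation order.
* **FCCS**: ~30 cells, totals drawn from expression ranges (green
  30–80 nM, red 20–400 nM — transfection-level variation), complex from
  the isotherm at the configured true Kd (or forced to the control
  limits), curves synthesised from the diffusion model with
  multiplicative Gaussian noise (default 2%, lag-independent; real
  photon noise is lag-dependent and is out of scope), QC failures
  injected at a configured rate.
* **Growth speeds**: log-normal base speeds (median ~11 µm/min,
  σ_log = 0.35), 9149/9669 events as in the emulated experiment, with a
  multiplicative shift applied to the reference-defined fast tail only.

What these do **not** emulate: segmentation/tracking errors, spatially
correlated motion, photophysics (blinking statistics, detector
afterpulsing), cross-talk between spectral channels, or cell-cycle
heterogeneity. A green test therefore establishes that the *estimators
and decision rules* behave as specified on data satisfying their model
assumptions — not that the upstream imaging pipeline is recovered.

## 6. Reproducibility and the pipeline

`run_pipeline()` executes any subset of stages from one flat JSON/YAML
config, validates every field up front (listing all offenders at once),
logs per-stage counts, and writes a manifest with the config, seeds and
an MD5 hash of every output; identical config + seed gives
byte-identical outputs. All randomness flows from integer seeds through
one documented path (`with_seed` restores the caller's RNG state, and
per-cell substreams are derived as `seed * 10007 + k` mod 2³¹).

## Known limitations

* The stable fit ignores the non-negative support of step lengths
  (faithful to the re-implemented workflow); `mass_below_zero` is the
  honest flag, typically ~0.1 for migration-scale parameters.
* β is weakly identified near α = 2 and near α = 1 (where
  $\tan(\pi\alpha/2)$ degenerates); migration data live at
  α ≈ 1.4–1.8 where it is well behaved.
* The Kd CI assumes i.i.d. residuals on the bound fraction; per-cell
  heteroscedasticity (brighter cells fit better) is not modelled.
* The scan's earliest significant time is a detection time, not an
  onset time: it is biased late at small cohort sizes and strict α.
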