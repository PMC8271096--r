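---
title: "Methods: personalized oscillator models, grid fitting, and variability analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: personalized oscillator models, grid fitting, and variability analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parcelfit)
```

# The modeling problem

Whole-brain dynamical models represent the cortex as a network of brain
regions (parcels) defined by a parcellation. Each region hosts one
oscillator; the coupling topology comes from diffusion-tractography
structural connectivity (streamline counts, eSC) and the coupling delays
from the corresponding mean path lengths (ePL). The model is *personalized*:
its parameters are derived from a single subject's data, simulated, and the
simulated functional connectivity (sFC, pairwise Pearson correlation of the
simulated signals) is compared against that subject's empirical functional
connectivity (eFC, correlation of parcel-averaged BOLD) and against eSC.
`parcelfit` implements this pipeline end to end, together with a synthetic
cohort generator so every stage can be validated against known ground
truth.

## The two models

The **phase model** is a network of Kuramoto oscillators with pairwise
delays,

$$\dot\varphi_j = 2\pi f_j + \frac{C}{N}\sum_{n=1}^N w_{jn}
  \sin\!\big(\varphi_n(t-\tau_{jn}) - \varphi_j(t)\big) + \eta_j,$$

with the BOLD observable $x_j = \sin\varphi_j$ and $\eta_j$ independent
uniform noise on $[-0.3, 0.3]$.

The **limit-cycle model** is the normal form of the supercritical Hopf
bifurcation,

$$\dot z_j = \big(a_j + i\,2\pi f_j - |z_j|^2\big) z_j
  + \frac{C}{N}\sum_{n=1}^N w_{jn}\big(z_n(t-\tau_{jn}) - z_j(t)\big) + \xi_j,$$

with observable $x_j = \mathrm{Re}\, z_j$ and componentwise uniform complex
noise on $[-0.3, 0.3]$. Without coupling and noise, an oscillator with
$a_j > 0$ settles on a limit cycle of radius $\sqrt{a_j}$ (this is what the
equation implies, and what the package's closed-form tests assert); with
$a_j < 0$ it decays to the origin and is purely noise-driven (subcritical
regime).

The two free *global* parameters are the coupling strength $C$ and the
global delay $\tau$. Pairwise quantities are derived from the subject data:

* weights $w_{jn} = k_{jn} / \langle k_{jn}\rangle$, streamline counts
  normalized by their ensemble average over the entire zero-diagonal
  $N \times N$ matrix (i.e. an $N^2$ denominator — the package's default;
  `convention = "offdiag"` divides by $N(N-1)$ instead, since the phrasing
  admits both readings);
* delays $\tau_{jn} = \tau \cdot L_{jn} / \langle L_{jn}\rangle$ under the
  same averaging convention, so $\tau$ is the network-average delay and
  encodes the propagation velocity $V = \langle L\rangle/\tau$;
* natural frequencies $f_j$: the largest periodogram peak of the
  mean-removed concatenated BOLD signal within 0.01–0.1 Hz. A single
  no-taper FFT periodogram is used — the simplest reading of a "maximal
  spectral peak"; Welch averaging or tapers would trade bin resolution for
  variance and are deliberately not applied;
* Hopf amplitudes $a_j$: per-region BOLD temporal standard deviations
  affinely standardized so that across parcels
  $\langle a_j\rangle = 0.5$ and $\mathrm{std}(a_j) = 0.4$ exactly.
  The *population* (divide-by-$n$) standard deviation is used so the
  moment contract holds exactly, and negative $a_j$ are permitted.
  If all regions have identical SD the calibration is degenerate and all
  $a_j = 0.5$ with a warning.

## Numerical integration

Both models are integrated with a stochastic Heun (predictor–corrector)
scheme at a fixed step $\Delta t = 0.06$ s. Delays are discretized to
integer step counts by round-half-to-even; the delayed state is read from
the stored history, which is held constant at the random initial state
before $t = 0$. Initial phases are uniform on $[0, 2\pi)$ and initial
limit-cycle states uniform in the complex unit disk. The uniform noise
draw is added after the corrector, scaled by $\sqrt{\Delta t}$ by default
(the diffusion reading of an additive noise term); a `noise_convention =
"dt"` switch applies the literal ODE-term scaling instead, since the
printed equations state the noise distribution but not the integration
convention. All random draws come from R's RNG, so a seed fixes the
trajectory bit for bit.

The default protocol simulates 4000 s and discards the first 500 s as
transient; desk-scale analyses in this package use 600 s with a 100 s
transient (problem sizes are stated below).

# Grid fitting

The goodness of fit is

$$\mathrm{Fit}(\mathrm{sFC}, \cdot) = \max_{(C,\tau)}
  \mathrm{corr}(\mathrm{sFC}, \cdot),$$

the maximal Pearson correlation between strictly upper-triangular parts,
taken over an exhaustive grid. The reference grid has 48 equally spaced
delays on $[0, 94]$ s (step 2) by 64 couplings on $[0, 0.945]$ (step
0.015). One simulation per grid point serves all six targets per subject:
the five eFC matrices (four sessions plus their concatenation) and the eSC
matrix. The per-point seed is derived deterministically from the subject,
model, and grid indices, making planes reproducible; argmax ties break by
scan order (delay ascending, then coupling); diverged points are recorded
as missing and excluded from the maximum.

# The synthetic cohort generator

The generator produces subject bundles with the statistical structure the
downstream analyses assume. Its defaults emulate the target acquisition
protocol: 4 sessions of 1200 volumes at TR = 0.72 s; the generating
simulation uses $\Delta t = 0.06$ s and the observable is downsampled by
taking every 12th sample (an exact integer ratio, so no interpolation).

* **Parcellations.** Fine units are drawn uniformly in a
  140 × 180 × 120 mm box (brain-like extents giving plausible distance
  distributions without anatomy) and clustered with Ward linkage; cutting
  one tree at several granularities guarantees nested levels.
* **Structural connectomes.** Counts follow
  $\log k \sim \mathcal N(\log(\text{scale}) - d/\lambda,\ 0.8)$ with
  centroid distance $d$ and decay length $\lambda$ (default 60 mm),
  rounded with floor 0 — a heavy-tailed, distance-decaying law that mimics
  tractography phenomenology. It is a stand-in, not a fit to any empirical
  count distribution. Path lengths are centroid distances under
  multiplicative lognormal noise.
* **Subject random effects.** Per-edge multiplicative lognormal jitter on
  counts (σ = 0.2) and per-region lognormal frequency jitter (σ = 0.05)
  around group base frequencies drawn uniformly in 0.02–0.08 Hz — inside
  the extraction band, with margin. Group Hopf amplitudes are drawn from
  $\mathcal N(0.5, 0.4)$, mirroring the calibration contract.
* **Measurement noise.** Additive Gaussian noise with SD equal to 0.5
  times each region's signal SD — strong enough that recovery is
  nontrivial, weak enough that it remains feasible.

What the generator does **not** emulate: hemodynamics (no
Balloon–Windkessel forward model — the oscillator observable *is* the
modeled BOLD), spatial autocorrelation of measurement noise, scanner
drift, motion, and real atlas geometry. Passing tests therefore validate
the pipeline's statistical machinery and its dynamical models, not claims
about empirical brains.

# Parameter recovery: what is tested and why

A scaled-down recovery experiment fits synthetic subjects generated at a
known $(\tau^*, C^*)$ on a reduced 12 × 16 grid — an exact 4-fold
coarsening of the reference grid (delays $[0, 88]$ s step 8; couplings
$[0, 0.9]$ step 0.06) — with 600 s simulations and N = 40 regions, 20
seeded runs. The ground truth, $(\tau^*, C^*) = (16, 0.48)$ with the
limit-cycle model, sits in the identifiable regime: coupling strong
enough to shape FC, delays comparable to oscillation periods.

The recovery fit uses the *generating* model inputs
(`ground_truth_inputs()`) rather than re-deriving frequencies from the
generated BOLD. This isolates the property under test — that the grid
search locates the generating parameters — from a genuine and separately
documented phenomenon: in a coupled network the observed spectral peak of
a region is pulled away from its natural frequency (synchronization
shifts frequencies), so data-derived $f_j$ are systematically *effective*
rather than natural frequencies, and refitting with them under renewed
coupling shifts the apparent optimum. Frequency extraction itself is
validated on uncoupled multi-sinusoid data, where peak and natural
frequency coincide. The grid steps (8 s in delay, 0.06 in coupling)
match the intrinsic resolution of the fit landscape at this problem
size: simulated FC patterns at delays 4 s apart correlate at 0.97-0.98,
above the attainable fit ceiling under measurement noise, so a finer
delay grid cannot be resolved by 600 s simulations.

# Data variables

Per subject, parcellation, and session scope the package computes 17
scalar indices: mean and spread of per-region BOLD temporal SDs; mean and
spread of the diagonal-excluded column means and SDs of eFC; upper-
triangular correlations among eFC, eSC, ePL; the analogous column
statistics of eSC and ePL after normalizing each matrix by its mean (the
form in which the models consume them); and mean and spread of the natural
frequencies. Column statistics exclude the diagonal because a region's
average connectivity is to the *rest* of the brain, and eFC's unit
diagonal (or eSC's zero diagonal) would bias the column means. Population
SDs are used throughout, consistent with the amplitude calibration.

# Variability statistics

* **Fit-pattern correlations.** Vectors of Fit values over subjects (and
  scans) are Pearson-correlated between parcellations; mean within-atlas
  and between-atlas values go through Fisher's z (transform, average,
  back-transform), with inputs clipped within 1e-15 of ±1. Cells with
  p ≥ 0.05 are masked.
* **Paired signed-rank matrices.** For each ordered parcellation pair the
  one-sided alternative Fit(row) > Fit(column) is tested; zero
  differences are dropped; the null distribution is exact (a shift
  convolution over doubled ranks, which stay integral under mid-ranks)
  for n ≤ 25 and a tie-corrected normal approximation above. Bonferroni
  correction across all ordered pairs is the default (Holm available);
  the matched-pairs rank-biserial correlation is the effect size.
* **Variable–fit correlations and classification.** Each data variable is
  correlated with Fit per parcellation, over pooled rows (joint), and
  across parcellation medians (group-median, requiring at least 3
  levels). Classification uses explicit thresholds (margin δ = 0.1, floor
  0.3, α = 0.05, all configurable and reported): *intra* when the
  Fisher-z mean per-parcellation |r| beats the joint |r| by δ with
  predominant per-parcellation significance, *inter* in the mirrored
  case, *both* when both magnitudes reach the floor and differ by less
  than δ, else *neither*.
* **Multiple linear regression.** OLS of Fit on data variables z-scored
  (population SD) within scope, so coefficients are comparable and the
  intercept equals the mean response; coefficient p-values and R² are
  reported, with non-significant coefficients flagged.
* **Optimal-parameter distances.** Per subject, Euclidean distance
  between optima normalized by the default grid extents
  $(\tau/94,\ C/0.945)$, averaged over subjects per parcellation pair.

# Problem sizes used in the shipped checks

The test-suite experiments run at desk scale, chosen so each validates
the targeted property with margin: unit and closed-form checks use 1–10
oscillators and 60–3000 s of simulated time; the end-to-end pipeline
check uses 3 subjects × 2 nested levels (24 fine units) on a 4 × 4 grid
with 600 s fitting simulations; the recovery experiment uses the sizes
stated above; and the nested-versus-independent contrast uses 10 cohorts
of 4 subjects at two nested levels of a 32-unit hierarchy, fitted on a
4 × 4 grid with 300 s simulations. The reference design's bookkeeping
(48 × 64 grid, 272 subjects, 11 parcellations, 2 models, more than 18
million runs) is checked arithmetically via `plan_jobs()` rather than by
simulation.

# Known limitations

* The lognormal distance-decay connectome is a phenomenological stand-in;
  no claim is made that it matches empirical parcel-level count
  distributions.
* Natural frequencies derived from coupled-network BOLD are effective
  frequencies (see the recovery section); this mirrors the situation with
  empirical data and is inherent to the derivation, not an implementation
  artifact.
* The phase model's fit landscape is shallow in $(\tau, C)$ under strong
  measurement noise at desk scale; quantitative parameter recovery is
  demonstrated with the limit-cycle model.
* Statistical analyses assume aligned subject/scan vectors across
  parcellations and will refuse silently misaligned input rather than
  guess.

# A worked example

```{r example, eval = FALSE}
hier <- make_parcellation_hierarchy(24, c(12, 6), seed = 1)
cohort <- make_bold_cohort(
  3, hier[[1]],
  ground_truth = list(model_kind = "phase", tau = 4, C = 0.6),
  seed = 1
)
grid <- fit_grid(c(0, 2, 4, 6), c(0, 0.2, 0.4, 0.6))
fits <- fit_cohort(cohort, "phase", grid,
  sim_config(duration = 600, transient = 100, seed = 1)
)
dplyr::filter(fits, target == "concatenated")
```

The same flow, including coarsening, data variables, and the statistics
report, is available as one call:

```{r pipeline, eval = FALSE}
run_pipeline("all", pipeline_config(seed = 1), out = "parcelfit_out")
```
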