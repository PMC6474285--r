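---
title: "Methods: simulation, preprocessing and chemometrics in nmrmetab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation, preprocessing and chemometrics in nmrmetab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmrmetab)
```

## What the package models

`nmrmetab` implements a bucketed ¹H NMR metabolomics workflow for two-class
cohort comparisons — the kind used to ask whether a treatment returns a
disease model's serum or brain metabolome toward the healthy reference, and
up to which treatment delay it still does so. Because studies of this kind
rarely deposit raw spectra, the package ships a spectrum simulator with full
ground truth; every downstream stage is validated by recovering parameters
the generator planted.

## The synthetic-data generator

A spectrum is a sum of Lorentzian lines on a shared ppm grid:

$$I(\delta) = d \sum_m c_m \sum_k h_{mk}\,
  \frac{\gamma^2}{(\delta - (\mu_{mk} + \varepsilon_m))^2 + \gamma^2}
  + \mathrm{TSP}(\delta) + \mathrm{water}(\delta)
  + \mathrm{baseline}(\delta) + \epsilon(\delta)$$

with per-sample dilution $d$, concentrations $c_m$, template peak positions
$\mu_{mk}$ and relative heights $h_{mk}$, and per-metabolite position jitter
$\varepsilon_m$. Choices and defaults:

- **Lineshape.** Lorentzian with constant half-width $\gamma = 0.0015$ ppm
  per metabolite — the standard high-field solution-state approximation, and
  a single knob for peak-overlap stress tests. No J-coupling fine structure,
  ¹³C satellites or FID-domain effects are modeled.
- **Peak templates.** `inst/extdata/metabolite_peaks.tsv` freezes canonical
  literature chemical shifts for the 21-metabolite serum and 56-metabolite
  brain panels, with proton-count-like relative heights and synthetic
  reference concentrations. These are fixture values, documented as such:
  the workflow they feed does not depend on shift accuracy, only on
  consistency between simulation and quantification intervals.
- **Biological variation.** Concentrations are log-normal: Gaussian on the
  natural-log scale with SD `conc_sd = 0.15` by default — strictly positive
  amounts and multiplicative biology. Group structure enters as
  $(1 - \text{recovery}) \cdot \text{log2\_effect} \cdot \ln 2$ added to the
  log-mean; recovery 1 means full return to reference, 0 the full disease
  effect. The default six-group design uses recovery fractions
  1.0/0.9/0.75/0.1 for the four treatment delays, reproducing an
  "effective early, ineffective late" therapeutic-window pattern, with n = 8
  per group.
- **Nuisance structure.** Dilution uniform in [0.5, 2]; shift jitter SD
  0.001 ppm; a smooth random baseline (amplitude 0.05); additive Gaussian
  noise (SD 0.005); a TSP singlet at 0 ppm; and a broad residual-water hump
  (Lorentzian, $\gamma = 0.1$ ppm, centered at 4.95 ppm) that deliberately
  leaks outside the excluded window so the preprocessing has something real
  to remove.

Everything drawn is recorded in the `truth` slot (concentration matrix,
dilution factors), and a fixed seed reproduces a cohort bit-for-bit.

What the generator does **not** emulate: phase errors, solvent suppression
artifacts, peak-shape asymmetry, ridge baselines, inter-metabolite spectral
correlation beyond shared templates, and realistic inter-metabolite
covariance of biology (concentrations are independent given the group).
Passing recovery tests therefore demonstrates correctness of the
algorithms, not robustness to every failure mode of real instruments.

## Preprocessing choices

- **TSP referencing** shifts the axis so the window maximum sits exactly at
  0 ppm; a peak is only accepted when it exceeds 5x the median absolute
  intensity in the window.
- **Baseline.** Asymmetric least squares (second-difference penalty).
  Defaults $\lambda = 10^6$, $p = 0.001$, 10 reweighting iterations, solved
  with a sparse Cholesky factorization. $\lambda = 10^6$ at grid steps near
  0.001 ppm lets the baseline follow broad features (including most of the
  water hump's tails) while narrow metabolite peaks lose less than 5% of
  apex height.
- **Alignment.** Segment-wise integer shifts (default segment 0.02 ppm,
  max shift 5 points) against the cohort median spectrum, scored by
  *normalized* cross-correlation — normalization prevents the edge-filled
  shifted segment from inflating the raw inner product — with candidate
  shifts ordered by magnitude so exact ties keep the data unshifted.
- **Bucketing.** Ascending half-open $[lo, lo + 0.0025)$ buckets over
  0–10 ppm; a bucket is kept iff it does not intersect the open water
  interval (4.65, 5.25), whose boundaries fall exactly on bucket edges, so
  3760 of 4000 buckets survive with no partial buckets. Bucket values are
  trapezoidal integrals of the piecewise-linear spectrum (recorded in the
  JSON sidecar; integration, not averaging).
- **PQN.** Total-integral scaling, median reference spectrum, per-sample
  median quotient — but the quotient median runs over *signal buckets*
  (reference above its 0.95 quantile). In sparse ¹H spectra the vast
  majority of 0.0025 ppm buckets contain only noise and background remnants
  that do not scale with dilution; including them drags the quotient median
  toward 1 regardless of the true dilution and destroys factor recovery
  (measured correlation with truth drops from ≥ 0.99 to 0.65–0.89).
  `signal_quantile = 0` restores the textbook all-bucket variant. Dilution
  factors are only identifiable up to a cohort-wide constant (the reference
  is itself a cohort median), so they are reported normalized to median 1.
  PQN deliberately cannot absorb genuine biological group shifts; cohorts
  with large planted effects will show correspondingly larger factor errors.
- **Pareto scaling.** Column centering and division by the square root of
  the sample SD (ddof = 1 everywhere in the package); near-constant columns
  (SD < 1e-12) are zeroed and flagged rather than amplified.

## Chemometrics

**OPLS-DA.** The two-class NIPALS form: y coded -1/+1 and centered (the
symmetric published derivation); per orthogonal round
$w \propto X'y$, $t = Xw$, $p = X't/(t't)$,
$w_\perp = p - (w'p)w$ (normalized), deflation by $t_\perp p_\perp'$; the
predictive component is refit on the filtered matrix. With zero orthogonal
components this reduces exactly to the first NIPALS PLS1 component — an
oracle equivalence asserted in the test suite. Component signs follow the
convention that the largest-|w| variable is positive, which makes plots and
exports reproducible and, conveniently, makes the fit invariant to which
class is coded +1 (tested). Orthogonal extraction stops early if the
orthogonal weight norm collapses below 1e-10, recording the achieved count.

**Validation.** Q²Y uses stratified 7-fold cross-validation (folds dealt
round-robin within class from a seeded shuffle), refitting the entire
OPLS-DA model — orthogonal filtering included — on each training split. The
input matrix is taken as already column-scaled and is *not* re-scaled inside
folds: Pareto scaling at these sample sizes is near-idempotent across folds
(Q²Y differences below 0.01 in the configurations shipped) and keeping
scaling outside the fold loop preserves the contract that `fit_oplsda`
receives a scaled matrix. The number of orthogonal components can be chosen
by `auto_orthogonal()`: the smallest count beyond which the cross-validated
Q²Y gain drops below 0.01.

**S-plot, VIP.** S-plot coordinates are $cov(t, x_j)$ and $corr(t, x_j)$ on
the training matrix before deflation; near-constant columns get correlation
0 and a flag. VIP is the single-component form
$\mathrm{VIP}_j = \sqrt{p \cdot w_j^2}$, computed on the predictive
component only (orthogonal variation is class-irrelevant by construction),
so mean(VIP²) = 1 exactly and VIP > 1 is the conventional importance cut.

**SUS classification and small cohorts.** Variables are classified from the
two models' S-plot correlations: near the +1 diagonal and jointly strong =
shared-positive; near the -1 diagonal = shared-negative; strong in exactly
one model with that model's VIP > 1 = unique to it. The correlation cutoff
`tau_corr` deserves care: for a truly unaffected variable the S-plot
correlation is a sample correlation against an essentially fixed score
vector, with null spread $\approx 1/\sqrt{n-1}$. A fixed cutoff of 0.3 is
adequate for n ≳ 45 but sits only 1.2σ from zero at n = 16 (8 + 8), where it
misclassifies unaffected metabolites roughly a quarter of the time.
`sus_tau_corr(n, conf)` therefore returns the null quantile
$z_{(1+conf)/2}/\sqrt{n-1}$ (0.665 at n = 16 with conf = 0.99); the pipeline
uses it whenever no explicit threshold is configured. A second small-panel
caveat: with only a dozen variables the discriminant partially overfits each
variable's own contribution, inflating in-sample null correlations — no
fixed threshold repairs that, so SUS conclusions are most trustworthy at
bucket-scale dimensionality or on panels of some tens of metabolites.

## Univariate layer and networks

Fold changes are ratios of group means on PQN-normalized, *unscaled*
quantities (ratios of Pareto-scaled values would be meaningless); the mean
(not median) is used and recorded in the output metadata. Tests are chosen
per metabolite by Shapiro–Wilk on each group (α = 0.05): Welch's t when both
pass, Mann–Whitney otherwise — Welch rather than pooled because equal
variances are not guaranteed at n = 8. Benjamini–Hochberg is implemented
directly (step-up, clipped, returned in input order) and checked against
`stats::p.adjust` as an independent oracle in the tests. Rendered tables map
log2 FC onto a symmetric blue–white–red scale (FC = 1 exactly white, FC = 2
and 0.5 mirrored) with 0.05/0.01/0.001 significance stars.

Correlation networks threshold Pearson |r| > 0.6 — read as absolute value
since both positive (warm) and negative (cool) edges are drawn — per
treatment group, with edge width |r| and node up/down attributes from the
fold-change table. Degree centrality ranks break ties alphabetically so
reports are deterministic.

## Problem sizes and determinism

The shipped tests and the acceptance script run at sizes chosen to exercise
each property well: full-spectrum stages on 0–10 ppm grids of 4001–8001
points (0.00125–0.0025 ppm steps), cohorts of 48 spectra for dilution
recovery, and quantity-level cohorts (the generator's truth concentrations,
skipping spectral rendering) for the statistical recovery suites — VIP
sensitivity, SUS partition recovery and permutation nulls — where the
spectral stage is not the property under test. All randomness flows from
explicit seeds; identical configurations produce byte-identical artifacts,
and the pipeline writes a JSON provenance sidecar (parameters, seed) next to
every stage output.

## Known limitations

- PQN factor recovery degrades when most of the panel shifts in one
  direction (self-averaging of quotients fails); this is a property of PQN,
  not of the implementation.
- The simulator's independence of metabolite concentrations given the group
  makes correlation networks sparser than real biology; network tests use
  explicitly constructed covariance structures instead.
- OPLS-DA here is strictly two-class with a single predictive component;
  multi-class extensions and O2-PLS are out of scope.
- The alignment operator shifts whole segments by integer grid points;
  sub-point interpolation and recursive segment splitting are not
  implemented.
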