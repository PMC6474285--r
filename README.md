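# nmrmetab

A simulation-backed ¹H NMR metabolomics pipeline in R, built around the
workflow used to assess multi-compound stroke treatments in rodent cohorts:
spectral preprocessing and bucketing, probabilistic quotient normalization
(PQN) and Pareto scaling, PCA and from-scratch two-class OPLS-DA with
S-plot/VIP/SUS/Venn interpretation, Benjamini–Hochberg-corrected fold-change
tables, and Pearson correlation networks. A Lorentzian spectrum simulator
with known ground truth (true concentrations, dilution factors, planted
group effects) makes every stage verifiable by parameter recovery — no
instrument or animal data required.

It is aimed at metabolomics researchers and methods developers who want a
transparent, fully testable implementation of this common chemometrics stack
rather than a black-box vendor tool.

## The methods

**Preprocessing.** Spectra are referenced to TSP (0 ppm), baseline-corrected
by asymmetric least squares (second-difference penalty λ, asymmetry p),
aligned segment-wise by integer-shift cross-correlation against the cohort
median, and segmented into 0.0025 ppm integrated buckets over 0–10 ppm,
excluding residual water at 4.65–5.25 ppm (3760 buckets retained of 4000).
Dilution is corrected by PQN: after total-integral scaling, each sample is
divided by the median quotient against the median reference spectrum,
computed over signal-carrying buckets. Pareto scaling
(x − x̄)/√s precedes the multivariate models.

**OPLS-DA.** For a two-class vector y coded ±1 and centered, each orthogonal
round computes w ∝ X′y, t = Xw, p = X′t/(t′t), splits off
w⊥ = p − (w′p)w, and deflates X by t⊥p⊥′; the predictive component is fit on
the filtered matrix. Fit quality is R²Y; predictive quality Q²Y = 1 −
PRESS/SS is estimated by stratified 7-fold cross-validation with a full
refit (orthogonal filtering included) inside every fold. The S-plot shows
cov(t, x_j) against corr(t, x_j); VIP_j = √(p·w_j²) so mean(VIP²) = 1 and
VIP > 1 marks influential variables. SUS plots compare the S-plot
correlations of two models sharing a reference class to separate shared from
treatment-unique metabolites; Venn partitions summarize the resulting sets.

**Univariate and network layers.** Per metabolite: fold change of group
means, a Welch t-test or Mann–Whitney test chosen by per-group Shapiro–Wilk
normality, and hand-implemented Benjamini–Hochberg step-up adjustment.
Correlation networks connect metabolites with |r| > 0.6 (signed, weighted
edges; degree centrality with deterministic ranks).

## Worked example

Simulate the default six-group serum study (Sham, disease model, four
treatment delays with recovery fractions 1.0/0.9/0.75/0.1; n = 8 per group),
run the full pipeline, and inspect the models:

```r
library(nmrmetab)

cfg <- pipeline_config(list(sim = list(n_per_group = 8,
                                       ppm_grid = c(0, 10, 8001)),
                            seed = 42))
res <- run_pipeline(cfg, outdir = "demo_out")

res$cohort
#> <nmr_spectrum_set> 48 spectra, groups: Model(8), Sham(8), T0.5(8), T3(8),
#>   T5(8), T7(8) [with ground truth]
res$pqn
#> <pqn_result> 48 samples, dilution factors 0.503-1.925

for (nm in names(res$summaries)) {
  s <- res$summaries[[nm]]
  cat(sprintf("%-14s R2Y = %.3f  Q2Y = %.3f\n", nm, s$R2Y, s$Q2Y))
}
#> Sham vs Model  R2Y = 0.988  Q2Y = 0.970
#> T0.5 vs Model  R2Y = 0.981  Q2Y = 0.930
#> T3 vs Model    R2Y = 0.988  Q2Y = 0.970
#> T5 vs Model    R2Y = 0.954  Q2Y = 0.893
#> T7 vs Model    R2Y = 0.447  Q2Y = -0.057
```

The early treatments restore near-Sham metabolite levels, so they separate
cleanly from the disease model; the latest treatment (recovery fraction 0.1)
is nearly indistinguishable from it — Q²Y ≈ 0 correctly reports a
non-predictive model. The VIP ranking of the Sham-vs-Model comparison
recovers the planted markers:

```r
round(sort(vip(res$models[["Sham vs Model"]]), decreasing = TRUE)[1:6], 2)
#>    Glucose    Leucine  Glutamine     Valine    Alanine Isoleucine
#>       3.10       1.45       1.27       1.07       1.06       0.86

head(subset(res$fc, comparison == "Model vs Sham" & adjusted_p < 0.01))
#>       metabolite    FC log2FC adjusted_p test_used
#>        Glutamine 0.403 -1.310   8.85e-07         t
#>          Glucose 2.018  1.013   1.28e-06         t
#>       Isoleucine 1.564  0.645   3.79e-05         t
```

Fold changes above/below 1 match the planted effect signs (glucose up,
glutamine down in the disease model). `demo_out/` contains the bucket table,
S-plot/SUS coordinates, the colored fold-change CSV, per-group GraphML
networks, JSON provenance sidecars for every stage, and `report.md`.

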