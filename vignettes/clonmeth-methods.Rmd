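---
title: "Methods: methylation signatures of clonal hematopoiesis drivers"
author: "clonmeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: methylation signatures of clonal hematopoiesis drivers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Somatic driver mutations in *TET2* and *DNMT3A* found in the blood of
hematologically healthy individuals (clonal hematopoiesis of
indeterminate potential, CHIP) perturb the enzymes that remove and
deposit DNA methylation. clonmeth implements an epigenome-wide
association pipeline for quantifying those perturbations from
methylation arrays: loss of TET2 function is expected to produce
clone-size-dependent *hyper*methylation concentrated at enhancer
elements and CpG-poor regions, while DNMT3A loss produces
*hypo*methylation. The pipeline covers probe-level quality control,
per-CpG association models, a directionality-based significance rule,
cross-cohort replication, annotation/ontology/motif enrichment and an
elastic-net predictor of mutation status, plus a synthetic-cohort
generator used to validate every stage.

## The association model

Beta values (methylation fractions) are transformed to M values,
`M = log2(beta / (1 - beta))`, clipping beta into `[eps, 1 - eps]`
(`eps = 1e-6`; the transform is undefined at the boundary and the
induced bias is far below array noise). Per CpG, the model is

    M ~ mutation + age + sex + batch + cell fractions + PC1..PC4

with a twin-pair random intercept when the cohort is twin-paired
(compound symmetry), or ordinary least squares for unpaired cohorts.
Carriers of driver genes other than the exposure gene are excluded, so
the contrast is carriers versus samples without any CHIP mutation.
Cell fractions are estimated by constrained projection onto reference
cell-type methylomes (non-negative fractions summing to at most one,
solved exactly as a quadratic program); all but the first cell type
enter the model, the first being absorbed by the intercept. The
principal-component covariates are computed from the centered M matrix
of the analysis samples.

### REML, degrees of freedom, and the small-sample adjustment

The mixed model is fitted by REML with the variance ratio
`theta = sigma2_pair / sigma2_resid` profiled out by golden-section
search on `log(theta)` over `[-12, 12]`: a single variance component
admits a robust 1-D optimization after an orthogonal within-pair
transform (pair sums, pair differences, singletons) that diagonalizes
the covariance.

The Wald test of the exposure coefficient deserves care. A plug-in
Wald test with residual degrees of freedom `n - rank(X)` is sometimes
described as conservative; on simulated null cohorts at this design
size (60 twin pairs, realistic pair variance) it is in fact
*anti-conservative* — the plug-in GLS standard error ignores the
uncertainty in the estimated variance components, giving genomic
inflation around 1.05-1.07 and detectable departures from P-value
uniformity. clonmeth therefore uses the Kenward-Roger small-sample
variance adjustment (cheaply computable here because the covariance is
linear in the two variance parameters and diagonal after the pair
transform) together with Satterthwaite degrees of freedom from the
observed REML information. After the adjustment, zero-effect cohorts
give genomic inflation 0.98-1.03 and pass Kolmogorov-Smirnov
uniformity at alpha = 0.01. At the `theta = 0` boundary the model
collapses to OLS and the exact residual df is used; at the upper
boundary (within-pair variance negligible, e.g. outcomes duplicated
within pairs) the limit model — a weighted regression on pair means and
singletons with `n_pairs + n_singletons - rank(X)` df — is fitted
explicitly.

Empirical-Bayes variance moderation (limma-style) is available for the
OLS path but off by default: the downstream selection logic depends
only on signs and ranks.

## Site selection: the directionality rule

For a one-sided biological signal the proportion of sites whose effect
is positive, among sites with `P <= c`, rises toward 1 as the cutoff
`c` decreases. The significance threshold is the **largest** observed
P value at which that proportion still reaches 95%. Ties in P are
handled inclusively (all sites at the boundary P count), matching how
printed site counts at a threshold behave. When no cutoff qualifies —
the weak-signal situation seen in small tumor cohorts — the fallback
selects the K most significant directional sites (default K = 2000)
and records the rule as `top_k`. Hypomethylation analyses run the same
machinery with direction -1.

## Replication and contingency testing

Cross-cohort checks drop set members absent from the replication
cohort (lost to QC) from both numerator and denominator, then count
members whose effect sign agrees. Association between dichotomous
outcomes uses the Pearson chi-squared test without continuity
correction unless any expected cell count is below five, in which case
a two-sided Fisher exact test (point-probability method; the "doubling"
alternative is not used) is dispatched. P values below 1e-300 are
reported with the sentinel `"<1e-300"` rather than 0.

## Enrichment

Chromatin-state and CpG-island composition compares the selected set
against all other analyzed sites per category with the same
chi-squared/Fisher dispatcher. GREAT-style ontology testing treats
each selected CpG as a 1-bp region: genes receive strand-aware basal
domains (5 kb upstream / 1 kb downstream, the published defaults, since
no parameters are stated elsewhere) extended up to 1 Mb or to the
neighboring basal domain; each term is tested with a region-based
binomial (on the fraction of the genome its domain union covers) and a
gene-based hypergeometric test, both Bonferroni-corrected, and a term
must pass both. The enhancer cell-type-specificity comparison z-scales
effect estimates over all probes and compares A-specific versus
B-specific enhancer sites with Welch's t test by default (group
variances are not guaranteed equal; classical Student's t is available
by flag).

## Ranked motif enrichment

200 bp regions centered on selected CpG sites (`[pos - 100,
pos + 100)`) are ranked by hypermethylation — either one effect
estimate or a composite score, the mean of the two z-normalized effect
estimates when two are available. Each PWM is scanned over both
strands; a region is a hit when its maximum log-odds score is at least
0 bits (the match is likelier under the motif than under the
background). This fixed rule is a documented simplification of AME's
internal threshold optimization; it presumes sharply informative PWMs,
which is why the synthetic PWM generator defaults to consensus
probability 0.97 and widths 10-12 (background regions then hit at rates
around 0.15-0.35 while consensus-bearing regions always hit). For
every partition point (top-i versus rest) a one-sided Fisher
(hypergeometric upper-tail) P value is computed — the one-sided tail is
the enrichment-detection form, and is the only reading consistent with
the two-region worked example giving P = 0.5. The E value corrects the
minimum P for both the motif count and the number of partitions tested
(every rank for up to 1000 regions, 1000 evenly spaced beyond);
correcting for the motif count only is available by flag. Motif-family
summaries test family membership against the enriched flag with the
two-sided Fisher test.

## The predictor

Elastic-net logistic regression is implemented from scratch as cyclic
coordinate descent on the IRLS quadratic approximation with warm starts
along a descending lambda path; the intercept is unpenalized, and
features are standardized inside each training fold only. The mixing
parameter defaults to alpha = 0.5: "elastic net" without qualification
implies both penalties, and the value is exposed in the specification
and reported with outputs. Leave-one-out cross-validation selects
lambda per held-out sample by stratified inner 10-fold CV under the
deviance criterion (`lambda_min` rule), refits, and records the
held-out probability. Classification uses cutoff 0.5 with ties
classified positive. Inner fold assignment is driven by the caller's
RNG state; out-of-fold probabilities are therefore reproducible under a
fixed seed but can shift slightly under sample reordering (confusion
summaries are stable, which is what the tests assert). Convergence is
verified in tests via the KKT conditions and a non-increasing per-sweep
objective trace.

## The synthetic world

The generator emulates the cohorts the analysis was designed for, and
its defaults are the stated world of the validation suite:

* 60 twin pairs (120 samples aged 70-90, twins sharing age and sex),
  TET2 mutation rate 1/3 and DNMT3A 0.15 (at most one driver per
  sample), VAF uniform on (0.1, 0.5).
* A 15-state ChromHMM-style segmentation per cell type tiling a toy
  genome; CpG-island relations are CpG-poor at enhancers and CpG-rich
  at promoters.
* Per-sample beta profiles are Dirichlet-weighted mixtures of four
  reference cell-type methylomes (granulocyte-dominated), with TET2
  carriers receiving a +3 percentage-point monocyte bump — the
  direction is reported for real carriers, the magnitude is a simulator
  assumption.
* Effects are planted additively on the M scale, proportional to VAF
  (shift = effect_size x VAF), at ~1% of probes with a 10:1
  enhancer bias. The default effect size, 0.5/0.3 M units per unit
  VAF, makes the mean planted group difference 0.5 M units at the mean
  VAF of 0.3. No absolute effect magnitudes are reported for the real
  cohorts, so these defaults are calibrated for statistical power, not
  to any cohort.
* Noise structure: probe-level Gaussian M noise (SD 0.2), a pair-shared
  random intercept (SD half the noise SD), per-(probe, batch) shifts
  (SD 0.05), and — importantly — four latent sample-level factors with
  probe loadings of SD 0.15. The latent factors represent the
  structured technical/biological variation (plate chemistry, residual
  cell composition) that principal-component covariates exist to
  absorb. Without them, a synthetic cohort has no structured variance
  and the data-derived PCs can lock onto the planted mutation signature
  itself, absorbing up to half of the planted effect; with them, the
  PCs capture the factors and the planted signal is recovered intact.
  This is a known hazard of outcome-derived PCs in real EWAS too.

### The calibration null versus the planted-effect world

The validation suite uses two variants of this world. The
*null-calibration* cohorts carry zero planted effects, no carrier
monocyte bump, and no latent factors: they contain exactly the
structure the association model accounts for (pair correlation, batch,
cell mixture), and on them the mixed model's P values are uniform and
the inflation factor sits in [0.98, 1.03]. The *planted-effect*
cohorts keep the latent factors on. The distinction matters because
shared latent structure has a chance sample correlation with any finite
exposure draw; principal-component adjustment removes most but not all
of it, and the common residual — although tiny per probe — is detectable
by a Kolmogorov-Smirnov test across 20,000 correlated probes for some
seeds (inflation up to ~1.06, while a permuted-exposure rerun of the
same cohort is perfectly calibrated). No adjustment method achieves
exact uniformity under shared latent structure at this scale; the same
mechanism is one reason real blood EWAS report inflation factors above
1 even for exposures with few true associations. Calibration is
therefore a statement about the inference machinery, tested on the
structure the model claims to handle, while power and recovery are
tested in the richer world.

What a green test does *not* establish: the generator plants linear
VAF effects with homoscedastic M-scale noise and exactly mixing cell
types; real arrays have probe-type chemistry differences, detection
artifacts, correlated probes within regions and non-linear cell-type
effects, none of which are simulated. Cohort-level numbers from the
real studies (site counts, inflation factors, enhancer fractions) are
not reproducible from synthetic data and are exercised as arithmetic
worked examples instead.

## Numerical choices and degenerate inputs

* Golden-section REML tolerance 1e-8 on `log(theta)`; probes with a
  fitted `theta` at the zero boundary are reported, not dropped.
* Deconvolution uses an exact QP solve; a rank-deficient reference
  matrix (reciprocal condition number below 1e-10) is refused.
* `beta_to_m` clips at `eps = 1e-6`; the round trip is exact to 1e-9
  away from the clip.
* Fisher tests sum hypergeometric point probabilities with a 1 + 1e-7
  relative slack on the observed probability, the standard guard
  against floating-point ties.
* Zero-margin contingency tables return P = 1 with a warning.
* Coordinate descent caps IRLS weights below at 1e-5 and errors on
  non-convergence rather than returning a partial fit.
* BED output is 0-based half-open; the probe manifest is 1-based
  (array-manifest convention); both conversions are covered by tests.

## Known limitations

* The AME reimplementation fixes the hit threshold at 0 bits rather
  than optimizing it per motif; weakly informative PWMs will saturate
  as hits and lose power.
* The Satterthwaite/Kenward-Roger machinery assumes the
  compound-symmetry structure; pairs of size three or more are
  rejected.
* The pipeline's QC stage assumes detection/bead matrices are only
  available for the file-based path; simulated cohorts skip
  probe-level QC (they are generated clean) and apply only outlier
  screening and batch centering.
* GREAT-style testing runs on user-supplied term-to-gene and TSS
  tables; no curated ontology ships with the package.
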