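---
title: "MorphoScreen: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MorphoScreen: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MorphoScreen)
```

MorphoScreen quantifies morphological variance across yeast strain
populations profiled with CalMorph-style morphometry and detects
gene-deletion strains whose multivariate morphology lies beyond the
variation of natural isolates. This vignette is the package's own account
of the statistical machinery: the models, every convention that was a
genuine design choice, and what the synthetic-data bench does and does not
establish.

## 1. Trait families and the normalization GLM

The default catalog (`buildDefaultCatalog()`) declares 501 parameters in
four probability families: 220 coefficient-of-variation (CV) traits, 183
positive continuous mean traits (gamma), 37 unit-interval traits (beta),
and 61 cell-ratio traits (overdispersed binomial). The published
identifier-to-family table is not redistributable, so the identifiers are
synthetic but stable, in the CalMorph naming style; a user catalog TSV maps
real exports onto the same machinery. Each CV trait pairs one-to-one with a
mean trait — conveniently, 183 gamma + 37 beta = 220, exactly the number of
CV traits, and the package exploits that correspondence.

**CV uncoupling.** CV traits depend strongly on their paired mean.
`normalizeCV()` regresses CV on the partner mean with `stats::lowess`
(span 0.4, the assay's standard setting) and keeps the residuals, treated
as Gaussian afterwards. Two numerical choices: the smoother is evaluated at
every culture (`delta = 0`) rather than interpolated between anchor points,
so results are independent of the x-spacing of the data; and the trend is
fit on all cultures jointly by default (`scope = "global"`), with
`scope = "reference"` available because fitting on wild-type cultures alone
is equally defensible when mutant panels are small or extreme.

**The strain-effect model.** For every strain and trait,
`fitStrainEffect()` fits η(E[y]) = β₀ + β₁x with x the 0/1
wild-type/mutant indicator: a Gaussian linear model for CV residuals
(identity link), a gamma GLM (log link), a mean-precision beta regression
with a common precision across groups (logit link, via `mgcv`'s `betar`
family — the one installed maximum-likelihood beta-regression
implementation), and a quasi-binomial GLM (logit link) whose standard
errors carry the Pearson-based dispersion estimate. The Wald statistic
z = β₁/se(β₁) is the trait's Z-score. Deletion strains contribute a single
culture, so their dispersion is estimated from the pooled residuals, which
are dominated by the replicated reference — the design the assay
prescribes. Convergence follows the fitters' defaults capped at 100
iterations with relative tolerance 1e-8; non-converged or failed fits mark
the trait, and `zscoreMatrix()` drops any trait that fails for at least one
strain (or contains a missing value), with a logged count. Exactly constant
data are flagged non-converged rather than fit.

Because all strains share one reference panel, Z-scores within a trait are
correlated: the reference-mean error is a common additive component
(standard deviation ≈ se_ref/se_total) and the shared dispersion estimate a
common multiplicative one. The test suite's calibration bands account for
this; treating columns of a Z-matrix as i.i.d. standard normal is only an
approximation.

## 2. Mahalanobis ranking and strain selection

`mahalanobisDistances()` centers on the column means of the wild-type
replicate Z-scores. With hundreds of traits against tens of replicates the
sample covariance is singular, so the default covariance is its diagonal
(floored at 1e-6), with linear shrinkage toward the diagonal or the full
matrix available when replicates outnumber traits. The full-covariance mode
is the one that carries the classical invariance of the distance under
invertible reparameterizations; the diagonal default trades that for
stability in the P ≫ n regime. A non-invertible choice fails loudly with
the condition number.

`selectStrains()` implements the two-tier panel: the top `kTop = 100` by
distance, plus `kEdge = 20` strains from the remainder maximizing their
largest absolute per-component standardized PCA score over PC1–PC20.
"Edge of PC space" has no published formula; the max-|standardized score|
statistic was chosen because it is monotone in each component, unitless
across components, and recovers strains extreme along minor axes that a
global distance underweights. Ties everywhere break by ascending strain
identifier, so selection is reproducible.

## 3. Variance conventions, PCA, ellipses

`perTraitVariance()` implements the three centering conventions the assay
uses, with their exact divisors: own mean (n − 1; 36 for 37 strains, 109
for 110), pooled subgroup means (Σ(n_g − 1); 4 for two triplicates), and an
external reference center (divisor n, the unbiased choice when the center
is known rather than estimated). `varianceRatioProfile()` counts strict
exceedances of the per-trait deletion/natural ratio and excludes
zero-denominator traits with a log.

`pcaZ()` is column-centered, unscaled PCA (`prcomp`) — covariance, not
correlation, because Z-scores are already variance-standardized by
construction. The wild-type reference's own Z-vector is identically zero,
so its position in score space is the projection of the zero vector
(`projectScores()`), not an extra fitted row.

`equiprobabilityEllipse()` fits a bivariate normal (or an equal-weight
two-component mixture when a second point set is supplied, weights
configurable), evaluates the density on a 200 × 200 grid spanning the data
range ± 3 marginal standard deviations, and selects the density level whose
super-level set encloses the requested mass (default 0.95 — the published
figures do not state their contour level, and 0.95 is the conventional
choice). Degenerate (collinear) clouds are an error. The **broadness
ratio** of two populations is defined here as the ratio of
equiprobability-ellipse areas at a common mass level, which for fitted
normals is √(det Σ_A/det Σ_B); per-axis sd ratios are attached because an
area ratio alone can hide strongly anisotropic broadening. Published
"x-fold broader" figures do not define their statistic; outputs are
labelled as area ratios.

## 4. Heteroclite detection and error control

For each deletion strain and component, z = (score − center)/sd_nat, where
`naturalVariancePerPC()` estimates sd_nat from the n natural strains about
the wild-type center with divisor n. Significance is Bonferroni over
m = strains × components (440 for the 110 × 4 design), and a strain
significant on any component is heteroclite.

**Reference distribution.** With the center known and sd_nat estimated
from n strains, the null statistic is *exactly* Student t with n degrees of
freedom. The classical formulation refers z to the standard normal, which
ignores the sd estimation noise; at Bonferroni-scale per-test levels
(α/m ≈ 1.1 × 10⁻⁴) the normal tail understates the t₃₇ tail roughly
four-fold, and simulation at the package's default design (37 natural
strains, 110 deletion strains, 4 components, 1000 replicates — the check in
`test-acceptance.R` and `scripts/acceptance.R`) shows the family-wise error
of the normal version rising to roughly three times the nominal 5%, while
the t version stays at or below it. The package therefore defaults to
`nullDist = "t"` and keeps `nullDist = "normal"` as the classical variant;
this is the one place the package deliberately departs from the textbook
one-sample normal test, precisely so that the Bonferroni guarantee it
advertises actually holds.

**Bonferroni denominator.** `m` scales with the number of components, so
*removing* a component loosens the per-test threshold and can add
detections — subset monotonicity only holds at a fixed denominator. The
`mTests` argument pins the denominator for component-subset comparisons and
for robustness re-runs on a second strain panel at the original correction.

Components default to PC1–PC4; `componentsByRatio()` instead takes the
smallest prefix reaching a cumulative explained-variance target (default
0.6, the level the four-component choice reflects). Degenerate components
(zero natural variance) are an error, not a silent skip.

## 5. Interpretation and annotation statistics

`significantLoadings()` calls a parameter for a component when the Pearson
correlation between its Z column and the score column exceeds 0.6 in
absolute value with correlation-test p < 1.95 × 10⁻³. The p-threshold is
taken as a configurable constant: it is the published Bonferroni-corrected
level, but its correction family is not recoverable from the available
text, so the package does not pretend to re-derive it.
`representativeParameters()` then runs a second PCA on wild-type replicate
Z-scores (the null data), applies the same loading rule there, groups
passing parameters that attach to a common null component (assignment by
largest passing |loading|), and picks each group's representative as the
member with the largest primary-analysis loading, ties by identifier. The
same-rule symmetry between primary and null analyses is a design choice;
the grouping is guaranteed to be a partition of the passing parameters.

`manovaGO()` compares the nested multivariate linear models Y ~ s and
Y ~ s + x by the Pillai trace F-approximation (Wilks available), where Y
holds the analysis components (by convention PC1, PC2, PC4), s the strain
background (two levels by default: natural vs laboratory background —
the source text is ambiguous about finer structure), and x the 0/1 GO
membership. For a single-degree-of-freedom hypothesis the Pillai F is
exact, so null p-values are exactly uniform under Gaussian errors — which
is what the calibration test verifies. Each GO's model uses natural strains
and wild-type (x = 0) with the deletion strains annotated to the GO
(x = 1); unannotated deletion strains are excluded by default
(`includeUnannotated` reverses this, another published ambiguity).
GO filtering keeps sets with < 100 genome-wide annotations hitting ≥ 3
focal genes; GO clustering is complete linkage on 1 − Jaccard distances
(Dice available) — "distance between GOs" is otherwise undefined in the
source assay. `mannWhitney()` uses exact enumeration when both groups have
≤ 8 observations without ties, otherwise the tie- and continuity-corrected
normal approximation. Interaction counting applies the stringent
asymmetric cutoffs (ε < −0.12 or ε > 0.16, each with p < 0.05); values
between the cutoffs never count.

## 6. The synthetic-data generator

`simulateMorphology()` emulates the study conditions: 40 wild-type
cultures, 36 natural strains × 5 cultures, 110 deletion strains × 1
culture, 200 cells scored per culture. Per family: gamma draws with shape
100 (≈10% culture-to-culture CV) around a strain-shifted log mean; beta
draws with precision 200 around a logit-shifted mean; beta-binomial counts
with intra-culture correlation ρ = 0.05 (ρ = 0 recovers plain binomial);
CV values as a decreasing Taylor-law-like function of the partner mean's
culture value (0.5/√(m + 0.05)) plus Gaussian noise (sd 0.05) plus the
strain shift — so the CV–mean coupling exists for the lowess stage to
remove. Strain effects are drawn once per strain on the link scale
(replicates exchangeable within strain) with half their variance carried by
a shared per-block factor (blocks: cell shape, actin, nucleus, noise,
assigned from the identifier prefix), giving the Z-score PCA its block
structure. Natural strains use effect sd 0.2, deletion strains 0.6; these
were fixed once as a plausible "deletions are about three-fold more
variable on the link scale" regime and are the package's study conditions,
not tuning knobs. Planted strains add magnitude × naturalEffectSd ×
direction(block) to their effect vector, and the ground-truth record keeps
every strain's true effects, the block map and the planted labels.

What the generator does *not* emulate: single-cell geometry; genuine
CalMorph trait distributions and their long tails; linkage or genotype
structure among natural strains; missing-data patterns of real exports
(missingness must be injected explicitly); batch or plate effects. Passing
tests therefore demonstrate the statistical machinery under its stated
assumptions, not performance on any real dataset.

## 7. Problem sizes and numerical conventions

The test suite runs scaled-down designs chosen to keep each property
informative: GLM-heavy simulations use gamma-only catalogs of 8–20 traits
and panels of 25–100 strains; the score-level detection studies use the
full 37 natural/110 deletion/4 component design at 200–1000 Monte-Carlo
replicates; calibration checks use 1000 replicates per family at the
assay's 40-reference/5-culture sizes. Calibration bands are derived from
the statistics' actual sampling distributions (including the
shared-reference correlations of Section 1) at roughly ±3σ.

Other conventions, in one place: catalog construction is deterministic;
every simulation is fully determined by its seed (`withr::with_seed`, so
the user's RNG state is untouched); beta draws are clamped away from the
open-interval boundary at 1e-9; the ellipse grid mass is a sub-probability
(truncation beyond ±3 sd is accepted and the contour level is taken on the
observed mass); `hclust` handles the linkage but distances are computed
from the gene sets directly; all tie-breaks are by ascending identifier.

## 8. Known limitations

* The beta-regression Wald z relies on `mgcv`'s maximum-likelihood
  `betar` family; with very few mutant cultures its small-sample behavior
  is approximate (the calibration test bounds it at the default design).
* The diagonal Mahalanobis default ignores trait correlations; rankings
  can differ from a full-covariance analysis where reference replicates
  are plentiful.
* The broadness ratio assumes the fitted (mixture-)normal describes the
  score cloud; heavy-tailed score distributions will inflate it.
* `selectGOs()` treats GO sets as flat gene lists: no ontology
  propagation, no term semantics.
* The published strain lists and headline dataset statistics require the
  original CalMorph datasets and external annotation databases, which the
  package does not ship; it reproduces the *procedure* and its design
  constants, with the synthetic bench standing in for the data.
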