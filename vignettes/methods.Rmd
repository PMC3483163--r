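---
title: "Models and methods: pedigree-based drug-cytotoxicity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: pedigree-based drug-cytotoxicity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`lcltox` implements the analysis chain of a family-based pharmacogenomics
design: lymphoblastoid cell lines from pedigreed donors are dosed with two
drugs (imatinib, a tyrosine kinase inhibitor, and omacetaxine, a protein
synthesis inhibitor), viability is read by a two-wavelength alamarBlue assay,
per-line inhibitory concentrations are extracted from dose-response curves,
their heritability is estimated on the pedigree, and genome-wide expression
fold changes after an IC20-equivalent dose are tested, clustered and
validated by qPCR. This vignette explains each model, its assumptions, the
tunable parameters, and the numerical choices; the package's test suite and
the scripts under `analysis/` compute every number referred to here.

## Viability and dose response

Percent viability of a treated well against the untreated control is

$$ V = 100\,\frac{117216\,A_{570}^{test} - 80586\,A_{600}^{test}}
               {117216\,A_{570}^{untr} - 80586\,A_{600}^{untr}}, $$

the standard two-wavelength percent-reduction form with the molar extinction
coefficients of oxidized alamarBlue. (Published descriptions of this assay
sometimes swap the wavelength labels of the two coefficients in prose; the
equation above is the operative form.) Replicate absorbances are averaged
*before* the ratio — the assay's order of operations — and the ratio is
invariant to common rescaling of all four absorbances.

Dose-response curves are four-parameter logistic (4PL) on
\(x = \log_{10}(\mathrm{dose})\):

$$ V(x) = b + \frac{t - b}{1 + 10^{\,h (x - m)}} $$

with bottom \(b \in [0, 100)\), top \(t \in (50, 150]\), Hill slope
\(h \in (0, 10]\) (positive = inhibitory) and midpoint \(m = \log_{10}
\mathrm{IC}_{50}\). Fitting is bounded Levenberg-Marquardt from a heuristic
start (dose nearest the viability midpoint, \(h = 1\)), falling back to a
deterministic grid of starts over the observed dose range and
\(h \in \{0.5, 1, 2\}\) when the first fit fails or fits poorly; there is no
random restart, so fits are exactly reproducible. The inhibitory
concentration at threshold \(x\%\) solves \(V = 100 - x\) on the fitted
curve in closed form; targets outside the fitted asymptotes are an error
rather than an extrapolation. The sensitivity of drug response (SDR) is the
ordinary least-squares slope of viability on \(\log_{10}\) dose — more
negative means a more sensitive line; changing dose units shifts only the
intercept.

Default dose grids are the study's:
imatinib \(\{2, 10, 50, 75, 100, 150, 200\}\,\mu M\), omacetaxine
\(\{5, 10, 25, 50, 75, 100, 500\}\,nM\). At thresholds of 80-90% inhibition
the target viability approaches the bottom asymptote from sparse coverage at
the top of the grid, so IC estimates there are noticeably noisier — visible
in the heritability table of `analysis/03_heritability.R` as attenuated
estimates at the 80/90 rows.

## Kinship and the polygenic model

Kinship coefficients come from the classical recursion over a
founders-first ordering: \(\Phi_{ii} = \tfrac12 (1 + \Phi_{fm})\),
\(\Phi_{ij} = \tfrac12(\Phi_{fj} + \Phi_{mj})\), with missing parents
contributing 0 (founders unrelated and non-inbred). Monozygotic twins are
declared through an `mz_group` column and collapsed onto one genotype node
before the recursion, so a twin pair has \(\Phi\) equal to self-kinship and
twins' descendants inherit correctly. The relatedness matrix \(2\Phi\) is
exactly block-diagonal across families and is required to be positive
semi-definite at tolerance `1e-8`; a violation is an error because the
recursion cannot produce an indefinite matrix.

The trait model is the additive polygenic mixed model

$$ y = \mu + X\beta + g + e, \qquad
   g \sim N(0, \sigma^2_g\, 2\Phi), \quad e \sim N(0, \sigma^2_e I), $$

fit by maximum likelihood (not REML, matching the twice-log-likelihood
testing convention of the field's reference tool). One eigendecomposition
\(2\Phi = U D U'\) rotates the problem so that for each candidate
\(h^2 = \sigma^2_g / (\sigma^2_g + \sigma^2_e)\) the fixed effects and total
variance have closed-form weighted-least-squares solutions; the 1-D profile
over \(h^2\) is maximized on a deterministic grid (uniform in the interior,
geometrically refined toward the upper boundary) polished by Brent search to
tolerance `1e-8`, with \(h^2\) clamped to \([0, 1 - 10^{-6}]\). The test
suite verifies that this profile likelihood equals a dense
multivariate-normal evaluation (direct solve and determinant) to `1e-6` on
dozens of random pedigrees.

Two numerical points deserve note:

* **Multimodality.** The profile can have several local maxima, including
  narrow ones near \(h^2 = 1\); the grid-plus-refinement search therefore
  polishes the three best brackets rather than a single one.
* **MZ degeneracy.** An MZ pair duplicates a genotype, so \(2\Phi\) has an
  exactly zero eigenvalue. If any covariate differs within the pair (a
  per-line fold change does; age and sex do not), the ML profile diverges as
  \(h^2 \to 1\): the covariate can interpolate the twin contrast while its
  weight vanishes — the classic degenerate-likelihood spike, which inflated
  the type-I error of covariate tests about five-fold in our null
  simulations. Eigenvalues below `1e-8` are therefore floored at `0.05`
  during fitting: twins are modeled as sharing all but a 5% sliver of the
  genetic deviation. Null calibration is restored (measured type-I ~0.06 at
  the 5% level) and heritability estimates are unaffected, since only the
  twin-contrast dimension changes.

### Tests

All traits entering heritability tests are first rank-transformed to normal
scores (Blom offset 3/8, average ranks for ties). The heritability LRT
compares polygenic vs sporadic (fixed-effects-only, \(\sigma^2_g = 0\)) fits;
because the null pins a variance to its boundary, the reference distribution
is the half-half mixture \(\tfrac12\chi^2_0 : \tfrac12\chi^2_1\) — the
statistic 0 gives p = 0.5, not 1, which is the behavior that a null trait
exhibits in roughly half of replicates. Tests of interior parameters use
plain \(\chi^2_1\): the per-probe mean-fold-change test constrains the
intercept to zero, and the FC-SDR association appends the probe's fold
change as a covariate to the polygenic model of SDR and constrains its
coefficient to zero. These two tests run on untransformed traits: the
rank-based normal-scores transform forces the sample mean to zero and
rescales coefficients, which would make a test of the mean (or of a
coefficient's magnitude) meaningless.

The covariate design is fixed: age, sex (0/1, 1 = male), age x sex,
age^2, age^2 x sex, ages uncentered.

**Small-sample bias.** With 17 families (~110-120 individuals), the ML
estimate of \(h^2\) is attenuated: recovery simulations in the test suite
measure a mean of about 0.55-0.58 at truth 0.60 and 0.68-0.70 at truth 0.73
over 200 replicates (per-replicate SD about 0.15). This is the expected
Jensen-curvature effect of the variance ratio plus boundary truncation, not
an optimizer artifact — the same fits pass the dense-likelihood equality
check. Interpret single-study point estimates accordingly.

## Expression preparation and multiple testing

Intensities are quantile normalized across all samples jointly (treated and
untreated together, the standard convention for paired designs), with ties
receiving the mean of the corresponding reference quantiles. Per-line log
fold changes use base 2 — configurable, since only "log fold change" is
conventional — with an intensity floor of 1.0 before the ratio to guard
background-subtracted values at or below zero. Per-probe p-values are
adjusted with the Benjamini-Hochberg step-up rule; `significant` means
q < alpha (default 0.05).

Significant probes are clustered by k-means (Lloyd refinement, Euclidean
distance) in the (mean iFC, mean oFC) plane with k fixed at 4 by
configuration — the study design pre-set four clusters and no selection
criterion is added. Initialization is seeded sampling with 100 restarts,
best within-cluster sum of squares kept, so results are reproducible;
cluster labels are arbitrary and `match_clusters()` relabels them against
reference centers (e.g. published cluster means) by exhaustive permutation.
Cluster geometry is summarized with bivariate confidence ellipses of the
sample mean and covariance, semi-axes \(\sqrt{\lambda_i \chi^2_{2}(0.95)}\)
— the sample-covariance estimator, chosen because the alternative
(model-based) estimator is underdetermined by the published description.
Between-group contrasts use the tie-corrected Kruskal-Wallis test, and
enrichment of an annotated subset (e.g. cis-regulated transcripts) against a
genome-wide reference proportion uses the one-sample goodness-of-fit
chi-square with the subset denominators supplied explicitly by the caller —
they are an input annotation, never inferred.

## qPCR validation

Cycle-threshold triplicates pass QC if their SD is at most 0.3 cycles;
otherwise the duplicate pair with the smallest SD is assessed, and if that
also exceeds 0.3 the sample is excluded. The duplicate choice (minimum-SD
pair) is a deterministic reading of a protocol that does not say which pair
to keep. Relative quantitation is \(2^{-\Delta\Delta C_T}\) with perfect
doubling assumed (no efficiency correction) and HPRT1 as the endogenous
control; excluded inputs propagate. For platform concordance the microarray
log fold changes are first corrected by subtracting the reference gene's
log fold change, then correlated with qPCR \(\log_2\) relative quantities —
Pearson if both margins pass Shapiro-Wilk normality at 0.05, Spearman
otherwise. Pooled and per-gene coefficients are both reported, since the
published description is ambiguous about the pooling.

## The synthetic-data generator

Every pipeline stage is exercised end-to-end on generated data with known
ground truth; all generators are pure functions of the configuration and the
RNG stream.

* **Pedigrees.** 17 families sized 6-10, sizes drawn with weight toward the
  small end so the cohort lands near 110-120 individuals; every fourth
  family is three-generation (grandparent couple, two married sibs, their
  children), providing first-cousin (third-degree) pairs, and one MZ sib
  pair is planted in the first family. The 55-line assayed subset forces in
  the MZ pair and a cousin pair; its realized relationship counts (~60-75
  sibling pairs, a handful of cousin pairs, one MZ pair) match the study's
  reported mix.
* **IC traits.** Per-line true \(\log_{10} IC_{50}\) is polygenic on
  \(2\Phi\) with \(h^2 = 0.60\) for imatinib and \(0\) for omacetaxine
  (the study's contrast), mean \(-3.9\) / \(-7.0\) log10 molar and SD 0.25,
  placing IC20 ranges on the reported scales
  (\(10^{-5}\) M and \(10^{-8}\) M).
* **Plates.** Viability from the true 4PL curve at each grid dose; replicate
  viabilities perturbed by Gaussian noise (SD 2 percent points) and
  converted to well absorbances by inverting the viability equation at fixed
  abs600 = 0.4 against untreated wells (0.8, 0.4) — absorbance-level
  synthesis, so the viability equation itself is exercised, and a zero-noise
  run round-trips exactly.
* **Expression.** Probes are null (91%) or belong to one of four clusters
  with the published (iFC, oFC) centers, cluster fractions proportional to
  the published cluster sizes, per-probe center scatter SD 0.08, per-line
  residual SD 0.4 split between a polygenic part (per-probe \(h^2_r\) drawn
  from [0.2, 0.6], reflecting "measurable heritability" without fabricating
  a distribution) and iid noise. The per-line residual SD is a calibration
  choice: it puts the significant fraction at a few percent of probes at
  n = 55, the reported ballpark. Untreated intensities are lognormal;
  treated = untreated x 2^FC, so recomputed fold changes match the planted
  ones up to the floor.
* **qPCR.** Target CT = baseline − FC (perfect doubling), reference CT
  constant; triplicate noise SD 0.1 cycles. Zero-noise CTs invert exactly
  through the ddCt pipeline.
* **Covariates.** Ages uniform on [20, 70], sex Bernoulli(1/2) (twins share
  both) — the donors' covariate values are not part of the published record.

What the generator does *not* emulate: bead-level Illumina noise, probe
cross-hybridization, batch structure, platform-specific discordance between
microarray and qPCR (our synthetic concordance is far higher than a real
cross-platform comparison), EBV-transformation biology, and annotation
(probe-to-gene, GO, cis-LOD) — the cis-regulated set is an input list.
Passing tests therefore demonstrate correctness of the statistical machinery
under the study's design, not robustness to real-data artifacts.

## Problem sizes

The defaults are desk-scale by design: 2,000 probes (the study's array has
48,803 — all per-probe operations are linear in probe count), 200-replicate
recovery simulations for heritability, and 17-pedigree cohorts of 110-120
individuals. The whole analysis chain in `analysis/` runs in well under a
minute; the test suite, including all recovery and calibration simulations,
runs in under a minute.

## Known limitations

* ML heritability estimates are attenuated at this design scale (above);
  REML would reduce but not remove this, and is deliberately not used.
* The IC ladder above ~70% inhibition extrapolates beyond the dose grids and
  should be read with the corresponding loss of precision.
* The boundary-mixture p-value assumes a single variance component tested at
  the boundary; no dominance or household components are modeled.
* k-means with k = 4 is a design constant, not a model-selection result.
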