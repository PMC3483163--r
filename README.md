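# lcltox

Heritability and kinship-corrected expression analysis of drug cytotoxicity
in pedigreed lymphoblastoid cell lines.

## The problem

When cell lines derived from members of known pedigrees are dosed with a
drug, the concentration that inhibits growth becomes a quantitative trait
whose resemblance among relatives measures the genetic control of drug
toxicity. This package implements that analysis chain for a two-drug design
(imatinib and omacetaxine on 17 pedigrees, 55 expression-assayed lines):

1. **Viability**: alamarBlue two-wavelength absorbances to percent viability,
   `V = 100 (117216 A570_test − 80586 A600_test) / (117216 A570_untr − 80586 A600_untr)`,
   four-parameter logistic dose-response fits, closed-form IC_x extraction
   (IC_x solves fitted viability = 100 − x), and the SDR slope of viability
   on log10 dose.
2. **Heritability**: recursive pedigree kinship Φ (MZ twins collapsed to one
   genotype), the polygenic mixed model
   `y = μ + Xβ + g + e, Cov(g) = σ²g·2Φ, Cov(e) = σ²e·I`
   fit by maximum likelihood through a 1-D profile over
   `h² = σ²g/(σ²g+σ²e)` after one eigendecomposition of 2Φ, and the
   boundary likelihood-ratio test with the ½χ²₀:½χ²₁ mixture null
   (statistic 0 ⇒ p = 0.5).
3. **Differential expression**: quantile normalization, per-line log2 fold
   changes (iFC, oFC), kinship-corrected per-probe mean tests (plain χ²₁),
   Benjamini–Hochberg FDR, k-means (k = 4) clustering in (iFC, oFC) space
   with 95% confidence ellipses, Kruskal–Wallis contrasts, significance-set
   overlaps and a one-sample proportion χ² for annotation enrichment.
4. **qPCR validation**: 0.3-cycle replicate QC, 2^−ΔΔCT relative
   quantitation against HPRT1, and Pearson/Spearman platform concordance
   gated by Shapiro–Wilk normality.
5. **Synthetic data**: seeded generators for pedigrees, heritable IC traits,
   plate absorbances, planted-cluster expression matrices and CT tables, so
   the entire pipeline runs with known ground truth.

For whom: quantitative geneticists and pharmacogenomics analysts who need a
reproducible, tested reference implementation of this family-based toxicity
workflow, or a simulation bench for the boundary-LRT heritability machinery.

## Worked example

```r
library(lcltox)

st  <- simulate_study(sim_config(seed = 20260925))   # full synthetic study
tab <- run_heritability_study(st$pedigree, st$plates, thresholds = c(20, 50))
print(tab, digits = 3)
```

```
         drug threshold mean_dose   n    h2 statistic        p
1    imatinib        20  3.83e-05 122 0.621     14.11 8.62e-05
2    imatinib        50  1.62e-04 122 0.602     15.78 3.57e-05
3 omacetaxine        20  2.95e-08 122 0.000      0.00 5.00e-01
4 omacetaxine        50  1.16e-07 122 0.000      0.00 5.00e-01
```

Imatinib IC20 (mean 3.8×10⁻⁵ M across 122 lines) is strongly heritable
(ĥ² ≈ 0.6, boundary-mixture p < 1e-4) while the omacetaxine trait sits on
the null boundary (ĥ² = 0, p = 0.5) — the generator plants exactly this
contrast (true h² 0.60 vs 0), and the estimates recover it.

The numbered scripts under `analysis/` run the full chain on generated data
and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R                # pedigree, plates, expression, CT
Rscript analysis/02_viability.R               # IC ladder + SDR per line
Rscript analysis/03_heritability.R            # drug x threshold h2 table
Rscript analysis/04_differential_expression.R # volcano, clusters, ellipses, FC-SDR
Rscript analysis/05_qpcr_validation.R         # ddCt, platform concordance
```

Stage 4, for example, reports 56/2000 probes (2.8%) significant after
imatinib and 194 (9.7%) after omacetaxine with 22 (1.1%) shared, then
recovers the four planted fold-change clusters (mean iFC/oFC per cluster
within a few hundredths of the planted centers).

See `vignettes/methods.Rmd` for the models, assumptions, parameter defaults
and numerical choices.

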