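# cuckoomorph

Morphometric analysis of geographic phenotypic variation in Mangrove
Cuckoo (*Coccyzus minor*), built for the taxonomic question behind it:
are any of the 12 historically named subspecies *diagnosable*, or is
variation in bill size and ventral plumage color clinal? The package is
aimed at systematists and ornithologists working with museum specimen
series — one row per specimen, three bill measurements (mm) and four
ordinal color scores — and at anyone who wants the 75% rule with its
machinery exposed rather than buried in a script.

## What it computes

* **Repeatability** of measurements from twice-measured specimens, as
  the intraclass correlation from a one-way ANOVA:
  `r = s²_A / (s²_A + MS_W)` with `s²_A = (MS_A − MS_W)/n₀`.
* **Composite bill size**: PC1 of the correlation matrix of bill
  length, width and depth, oriented to correlate positively with depth.
* **Sex screen**: MANOVA (Pillai's trace, Type II) of sex adjusted for
  subspecies, with a Mahalanobis/χ² outlier screen.
* **Cluster structure**: complete-linkage clustering on Euclidean
  distances with a three-index vote (Calinski–Harabasz, silhouette,
  Duda–Hart) on the number of clusters.
* **Discriminant classification** by region and by named subspecies,
  with resubstitution (or LOO-CV) confusion matrices.
* **Diagnosability under the 75% rule** — the core statistic. For focal
  `f` and reference `r`:
  `D = |x̄_f − x̄_r| − t(0.75, n_f−1)·s_f − t(0.99, n_r−1)·s_r`,
  computed on the PC1 composite for every ordered pair; `D ≥ 0` passes
  in that direction, and a valid subspecies must pass both directions.
  For ordinal color the rule is applied empirically: the fraction of
  focal scores outside the reference sample's observed range.
* **A synthetic specimen generator** emulating the study system — a
  logistic bill-size step between the Greater and Lesser Antilles with
  intermediates on Antigua/Barbuda and the mainland, color darkest at
  Dominica, session-level measurement error with a known target
  repeatability — so every stage is validated against ground truth.

## Worked example

```r
library(cuckoomorph)

cfg <- build_config("clinal_step", seed = 1)   # 274 specimens, 12 taxa
tbl <- sample_specimens(cfg)

bill <- complete_specimens(tbl, bill_traits())$records
pca  <- pca_composite(bill)
round(pca$prop_var[1], 3)
#> [1] 0.802

gs <- group_summaries(pca$composite, bill$region, levels = region_levels())
dm <- d_matrix(gs)
round(dm$D["lesser_antilles", c("greater_antilles", "middle_america")], 2)
#> greater_antilles   middle_america
#>             0.45            -0.99

reciprocal_report(dm)$per_taxon$lesser_antilles
#> [1] "florida_bahamas"  "greater_antilles"
```

PC1 carries 80% of the bill-trait variance, so it is a defensible
composite size score. The Lesser-Antillean sample passes the 75% rule
against the Greater Antilles in this direction (`D = 0.45 ≥ 0`) but not
against the phenotypically intermediate mainland (`D = −0.99`), and the
reciprocal report shows it is reciprocally diagnosable only from the
two small-billed regions — the clinal pattern: distinctive extremes,
no taxon separable from all others.

The numbered scripts under `analysis/` run the same stages as a
narrative workflow (`01_simulate.R` … `05_diagnosability.R`), writing
tables to `results/`. `vignettes/diagnosability-methods.Rmd` documents
the models, parameter choices and limitations.

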