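# isobalance

Alternative splicing lets one gene express several mRNA isoforms, and the
*balance* between isoforms — not just overall expression — is a heritable,
selectable trait. For a gene with exactly two isoforms, that balance in one
individual is summarised by a single number, the **e_T-ratio**:

    e_T = FPKM(isoform 1) / (FPKM(isoform 1) + FPKM(isoform 2))

reported for the isoform with the higher average ratio across all
individuals, so values concentrate in [0.5, 1]. `isobalance` implements a
complete analysis of e_T-ratio *diversity* between two population panels —
a cultivated compartment (CS) and a wild compartment (WS) — of the kind
used to ask whether domestication bottlenecks reduced splicing-ratio
variability in crops. It is aimed at population transcriptomicists working
from isoform-level FPKM tables (e.g. Cufflinks/Cuffdiff output adapted to
a simple TSV schema).

The pipeline:

1. **Masking & filtering** — per-gene read coverage < 5 in an accession
   masks that cell as `NA`; genes are kept only if they have exactly two
   isoforms, no masked cell in either panel, and both isoforms expressed
   (FPKM > 0) in at least one accession of each panel.
2. **e_T-ratios** — per gene and accession, with a deterministic numerator
   convention (union-panel mean ≥ 0.5, lexicographic tie-break).
3. **Dispersion contrast** — per-gene spread (sample variance `sigma_r`,
   inter-quartile range `iq_r`) within each panel; counts of genes by
   direction, the OLS slope of WS spread on CS spread, and paired
   Student-t / Wilcoxon signed-rank tests on per-gene differences.
4. **Ordination** — PCA of accessions using each gene's e_T-ratio as a
   coordinate, with variance-explained fractions.
5. **Outlier genes** — spread contrast `|iq_r(CS) − iq_r(WS)| > 0.2` and
   location contrast `|med_r(CS) − med_r(WS)| > max(0.2,
   (iq_r(CS)+iq_r(WS))/2)`, with consensus across comparisons.
6. **GO enrichment** — hypergeometric Singular Enrichment Analysis with
   Bonferroni control, computed in log-space.
7. **Functional impact** — the alternative isoform's protein is predicted
   from its mRNA (CDS-prefix anchoring, standard genetic code) and the
   event classified: (1) start lost, (2) premature stop before 20% of the
   canonical protein, (3) slightly different protein, (4) identical
   protein; 1–2 roll up to *deleterious*, 3–4 to *functional*.

A synthetic-study generator (`simulation_config()`,
`simulate_expression()`, `simulate_go()`, `simulate_protein_pairs()`)
produces complete studies with known ground truth — Beta-distributed
ratios with per-compartment concentration, log-normal totals, a coverage
model feeding the masking rule, planted median shifts, one planted
enriched GO term, and protein pairs spanning the four impact categories —
for calibration and power assessment.

## Worked example

```r
library(isobalance)

cfg <- simulation_config(seed = 7)      # 2,000 genes, 10 CS + 6 WS accessions
sim <- simulate_expression(cfg)
ratios <- et_ratio_pipeline(sim$table, sim$cs_panel, sim$ws_panel)
ratios
#> e_T-ratio matrix: 1360 genes x 16 accessions
#>   cultivated: CS01, CS02, CS03, CS04, CS05, CS06, CS07, CS08, CS09, CS10
#>   wild:       WS01, WS02, WS03, WS04, WS05, WS06
#>   mean e_T-ratio: 0.7305

compare_panels(ratios, sim$cs_panel, sim$ws_panel, "sigma_r")
#> e_T-ratio spread comparison (sigma_r): popCS_10 vs popWS_6
#>   genes: 1360   CS>WS: 24   CS=WS: 0   CS<WS: 1336
#>   slope (WS ~ CS): 3.446   mean diff (CS-WS): -0.007171
#>   paired t p: 1.52e-267   Wilcoxon p: 9.95e-223
```

Of the 2,000 simulated genes, 1,360 survive the coverage and expression
filters. Under the default regime (ratio concentration 200 in the
cultivated panel vs 20 in the wild panel) 1,336 of 1,360 genes have a
higher e_T-ratio variance in the wild panel, and both paired tests reject
the no-difference null overwhelmingly — the signature of reduced
expression-balance diversity in the cultivated compartment. Downstream:
`pca_accessions()` ordinates the accessions, `iqr_contrast()` /
`median_contrast()` flag outlier genes, `sea()` tests GO terms, and
`classify_pairs()` calls the functional impact of each isoform pair.

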