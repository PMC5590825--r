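---
title: "Methods: isoform expression-balance diversity between populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isoform expression-balance diversity between populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isobalance)
```

## The quantity under study

For a gene expressing exactly two mRNA isoforms, the expression balance in
one accession is the e_T-ratio: the FPKM of one isoform divided by the
summed FPKM of both. The two possible numerators give complementary values
x and 1 − x, so which isoform is used does not affect any within- or
between-population *spread* statistic; for presentation the package fixes
the numerator per gene to the isoform whose unweighted arithmetic mean
ratio over the union of the two panels is ≥ 0.5, so values concentrate in
[0.5, 1]. At an exact tie of 0.5 the lexicographically smaller isoform id
is chosen — an arbitrary but deterministic rule, which matters only for
reproducibility, never for any statistic.

The scientific question is comparative: is the within-population diversity
of this balance smaller in a cultivated compartment (CS) than in a wild
compartment (WS), as a domestication bottleneck would predict, and which
genes deviate most from the genome-wide pattern?

## Filters and their rationale

Isoform-level FPKM estimates are unreliable at low sequencing depth, and
spread statistics are exquisitely sensitive to such noise. Three filters
precede all analysis:

1. **Two isoforms exactly.** The e_T-ratio is only defined for two-isoform
   genes; genes with one or with three or more isoforms are excluded.
2. **Coverage ≥ 5 everywhere.** If a gene's mean mapped read depth is
   *strictly below* 5 in any accession of the compared panels, that cell's
   FPKMs are first masked as `NA` (a coverage of exactly 5 is retained),
   and any gene with a masked cell is excluded — the comparison uses no
   missing data.
3. **Both isoforms expressed in both panels.** Each isoform must have
   FPKM > 0 in at least one accession of each panel. "Expressed" is read
   as strict positivity, the weakest reading consistent with the word;
   this is surfaced in the documentation because upstream quantifiers
   differ in how they emit zeros.

A cell can have adequate coverage yet zero FPKM for *both* isoforms (a
quantifier artefact). Defining the ratio there as `NA` would reintroduce
missing data after filter 2, so such genes are instead rejected with a
logged count (`rejected_zero_total`), keeping the ratio matrix NA-free by
construction.

## Spread statistics and the comparison battery

Per gene and panel the package reports the mean (`avg_r`), median
(`med_r`), sample variance (`sigma_r`, n − 1 denominator) and
inter-quartile range (`iq_r`). Two conventions are fixed explicitly:

* `sigma_r` is a **variance**, not a standard deviation, despite the
  σ-flavoured name — the name follows the field's usage for this quantity
  and the print methods say "variance" throughout.
* Quantiles interpolate order statistics at rank 1 + (n − 1)p
  (`stats::quantile` type 7). At panel sizes of 6–10 the IQR differs
  appreciably between quantile conventions, so the choice is part of the
  method, not a detail.

`compare_panels()` then reports, for variance or IQR: the counts of genes
with CS spread greater than / equal to / less than WS spread (equality
within 1e−12, because ratio ties can be bit-exact, e.g. both accessions at
1.0), the OLS slope of WS spread regressed on CS spread (WS as response —
the orientation in which a genome-wide slope > 1 means the wild panel is
the more dispersed), the mean per-gene difference CS − WS, a paired
Student t-test, and a Wilcoxon signed-rank test (zeros dropped, exact
null distribution for n ≤ 25 without ties, normal approximation with
continuity correction otherwise — `stats::wilcox.test` supplies both
regimes). Tests are two-sided by default: the direction is not assumed,
and a user wanting the directional version can pass `alternative`.
No correction is applied across the handful of panel comparisons; each is
reported raw.

### Unequal panel sizes bias spread comparisons — by construction

A subtlety that shapes the package's own calibration: with equal
underlying dispersion, the *sampling distribution* of a variance estimate
from 6 accessions is more right-skewed than from 10. The difference of the
two estimates is then not symmetric about zero, so the sign counts drift
from 1/2 (the Gaussian analogue is P(F(9,5) < 1) ≈ 0.47) and the Wilcoxon
signed-rank test — which assumes symmetry under the null — rejects far too
often. This is a property of the estimators, not a defect of the pipeline,
and it is exactly why the study design subsamples the larger panel to the
size of the smaller one. `subsample_panel()` provides that operation
(distinct draws without replacement, reproducible, labelled
`popCS_6_1` …), and the package's null-calibration checks are run on the
equal-size subsampled comparison. Users comparing unequal panels should
interpret sign counts and Wilcoxon p-values with this bias in mind; the
paired t-test, which only needs a zero mean difference, is calibrated in
both settings.

## Ordination

`pca_accessions()` treats each gene's e_T-ratio as one coordinate, so
accessions are points in gene-dimensional space, and projects onto the
first two principal axes (centered, unscaled — ratios are already
commensurate on [0, 1]; `scale. = TRUE` is available). Axis signs are
canonicalised by making the largest-magnitude loading positive, so scores
are deterministic and invariant to gene reordering. Degenerate inputs
(all-constant genes, fewer than two non-degenerate dimensions) raise
errors rather than returning arbitrary axes.
`compartment_compactness()` summarises the projection as the mean pairwise
within-compartment score distance.

## Outlier genes

Two per-gene filters, both with strict inequalities at the boundary:

* **Spread contrast**: |iq_r(CS) − iq_r(WS)| > 0.2.
* **Location contrast**: |med_r(CS) − med_r(WS)| > max(0.2,
  (iq_r(CS) + iq_r(WS)) / 2) — the between-compartment shift must exceed
  both a fixed floor and the average within-compartment spread, which is
  what makes the filter stringent (its per-gene false-positive rate under
  the null regime is far below 1%).

`consensus_genes()` intersects call sets across comparisons by gene
identity only; a gene flagged in opposite directions in different
comparisons still counts, but such conflicts are reported in an attribute
so users can exclude them. The choice of which comparisons enter a
consensus is the user's — the function takes an explicit list.

## GO enrichment

`sea()` is a Singular Enrichment Analysis: for every GO term annotating at
least one foreground gene, the upper-tail hypergeometric probability
P(X ≥ k) of drawing k or more term-annotated genes in a foreground of
size n from a background of N genes of which K carry the term. The tail
is computed in log-space (`lchoose` + log-sum-exp) so it remains accurate
when binomial coefficients overflow; the implementation agrees with exact
big-integer rational summation to relative error below 1e−10 over the
problem sizes the package targets (N ≤ 2,000).

Two conventions are explicit and configurable:

* **Background = annotated genes only**; unannotated foreground genes are
  dropped from the draw size with a logged count. This mirrors standard
  SEA practice and keeps K, n, N on one universe.
* **Bonferroni multiplier = number of terms tested** (terms with ≥ 1
  foreground gene) by default; `universe = "background_terms"` switches to
  all terms with ≥ 1 background gene. Web services rarely expose their
  multiplier, which is why reproducing a published adjusted p-value to the
  digit generally requires knowing both the multiplier and the term
  universe; the raw hypergeometric value is the stable quantity.

No GO-graph ancestor propagation is performed, and Bonferroni is the only
correction offered — the analysis this package supports used exactly that.

## Functional-impact classification

`translate_alternative()` anchors the canonical start in the alternative
mRNA by exact match of the canonical CDS prefix (30 nt, falling back to
the longest exact prefix ≥ 12 nt), then translates with the standard
genetic code to the first stop. Anchoring by exact prefix rather than
spliced alignment is deliberate: it is deterministic, testable, and fails
loudly (`start_not_found`) instead of guessing.

`classify_as_impact()` applies a first-match cascade:

1. start not found → **category 1** (start lost);
2. alternative protein shorter than 20% of the canonical (strict < 0.2 of
   the length) → **category 2** (early stop). The cascade classifies by
   stop position only — a frameshift that terminates *after* 20% is not
   category 2, which is flagged here because frameshifts are the usual
   cause of early stops;
3. exact equality → **category 4** (identical; checked before category 3
   since an identical protein satisfies every category-3 rule);
4. otherwise **category 3** (slightly different) if ANY of: indels
   affecting < 10% of canonical residues; identity > 50% with equivalent
   length; an identical contiguous block ≥ 500 aa. "Equivalent length",
   undefined in common usage, is fixed at a length ratio within
   [0.9, 1.1], consistent with the 10% indel tolerance;
5. otherwise the protein matches no rule: reported category 2 with reason
   `major_disruption` — the four categories are not exhaustive for
   arbitrary sequences, and these cases land in the "non-functional
   protein" column of the rollup table rather than being silently forced
   into category 3.

Categories 1–2 roll up to *deleterious*, 3–4 to *functional* (an early
stop can still matter via transcript degradation; the rollup is about the
protein). All alignment-derived evidence comes from one fixed global
alignment — match +1, mismatch 0, gap open −5, gap extend −1, via
`Biostrings::pairwiseAlignment` — chosen so that gaps are strongly
discouraged relative to mismatches and indel counts are conservative;
with the scores fixed, calls are reproducible bit-for-bit.

## The synthetic-study generator

The generator emulates the statistical structure the analysis assumes,
with known ground truth:

* **Ratios**: per gene, a mean μ_g ~ Uniform(0.5, 0.98) (the observed
  concentration of majority-isoform ratios above one half; no stronger
  distributional information is available, so the simplest distribution
  covering that range is used); per accession,
  r ~ Beta(μκ, (1 − μ)κ) with compartment-specific concentration κ. The
  Beta family is a modelling stand-in, not an empirical fit: it lives on
  [0, 1] and κ cleanly encodes the dispersion contrast, with variance
  μ(1 − μ)/(κ + 1) decreasing in κ.
* **Defaults as study conditions**: 2,000 genes, 10 CS + 6 WS accessions,
  κ_CS = 200 vs κ_WS = 20 (dispersion markedly lower in the cultivated
  compartment — the direction the data tables of this analysis design
  report), 2% of genes with a planted median shift of δ = 0.3
  (μ_WS = μ_g − δ), log-normal totals (meanlog 4, sdlog 1), coverage
  = 1.5 × total + N(0, 2) floored at 0, and 2% of cells forced below the
  coverage threshold. These rates were chosen once so that the
  post-filter working set lands near 1,400 genes, the scale of the real
  working sets this design produces; they are conditions, not tuning
  knobs.
* **GO**: 50 terms; one designated enriched term annotates shifted genes
  with probability 0.5 and others with 0.04 (the 0.42-vs-0.04 frequency
  contrast typical of a real positive hit); 49 background terms annotate
  40 genes each uniformly.
* **Proteins**: 4 × n pairs realising the impact categories by
  construction (category 2 via an early stop-codon substitution; category
  3 cycling its three defining sub-rules; category 1 by rejection-sampling
  mRNAs that lack the 12-nt anchor).
* **Determinism**: all randomness flows from one integer seed through
  fixed per-purpose sub-streams (expression / GO / proteins); identical
  configs give byte-identical output, and the RNG state of the calling
  session is left untouched.

What the generator does *not* emulate — and therefore what passing tests
on synthetic data cannot show about real data: mapping and assembly
artefacts, correlated errors between isoforms of one gene, 3-or-more
isoform genes, population structure within compartments, and any
dependence between a gene's expression level and its ratio dispersion
beyond the coverage mask. Conclusions about real studies still require
the real data.

## Validation design and problem sizes

The test suite validates at three levels. Exactness: the whole
mask–filter–ratio pipeline is compared against an independent brute-force
per-cell implementation on randomised messy tables of up to 50 genes, and
the hypergeometric tail against frozen exact-rational reference values and
`stats::phyper`. Calibration: under the null regime (equal κ, no shift;
2,000 genes; 500 replicates; the equal-size subsampled comparison, for
the reason above) the sign proportion stays within the binomial CI of
1/2, both paired tests hold their 5% level within [0.03, 0.07], and the
location-contrast false-positive rate stays below 1%. Power: under the
default contrast regime (100 replicates) both tests reject at p < 1e−6
with the correct direction in ≥ 95% of replicates, the cultivated cluster
is the tighter one in PCA space, planted median shifts are recovered
through the 3-way subsampled consensus in ≥ 90% of cases, and the impact
classifier recovers 100% of planted categories. These replicate counts
keep the estimates' Monte-Carlo error comfortably inside the asserted
bands.

## Known limitations

* Only two-isoform genes; no extension to isoform triples.
* FPKM is consumed as given; no re-normalisation, no uncertainty
  propagation from quantification into the ratios.
* The location/spread filters are fixed-threshold rules, not tests; their
  stringency under other designs should be re-checked with the generator.
* The impact classifier's category 3 rules are permissive for
  substitution-only divergence (a same-length protein with many
  substitutions but no indels satisfies the indel rule); this mirrors the
  rule set it implements, and individual calls should be treated as
  screening annotations, not verdicts.
* Panel files, GO maps and FASTA are the only supported inputs; adapting
  quantifier-specific formats (e.g. `*.fpkm_tracking`) is left to a thin
  external conversion step so the analysis stays decoupled from any one
  upstream tool.
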