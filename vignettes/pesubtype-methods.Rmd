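---
title: "Methods: subtype-stratified placental transcriptome analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: subtype-stratified placental transcriptome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`pesubtype` is a pipeline for bulk placental RNA-seq in preeclampsia (PE),
analyzed separately per clinical subtype: early-onset severe (EOSPE),
late-onset severe (LOSPE) and late-onset mild (LOMPE) against normal
controls. The stages are (i) removal of cord-blood contamination from raw
counts using a blood-exclusive marker gene, (ii) dual-procedure
differential expression per subtype with intersection/union combination,
(iii) PCA and Ward clustering of samples, (iv) hypergeometric gene-set
enrichment and curated-list fraction enrichment with bootstrap errors, and
(v) term-gene and TF-target-pathway bipartite networks. Because cohorts of
this kind are rarely public, the package ships a synthetic-data generator
with known ground truth; all statistical claims made by the test suite are
claims about that generator, a point discussed at the end.

# Marker-based decontamination

Placental tissue cannot be fully washed free of cord blood, so a fraction
of each library derives from blood rather than placenta. The model is
additive: for gene $X$ and sample $j$,

$$\mathrm{obs}_{Xj} = \mathrm{plac}_{Xj} + c_{Xj},$$

where the contaminant $c_{Xj}$ is proportional to a per-gene blood
reference profile $B_X$. A marker gene expressed **only** in blood (a
hemoglobin-subunit-like transcript; red cells are dominated by hemoglobin
mRNA) identifies the per-sample admixture scale

$$s_j = \frac{\mathrm{marker~count~in~sample~}j}{\mathrm{marker~count~in~}B},
\qquad
\widehat{\mathrm{plac}}_{Xj} = \mathrm{obs}_{Xj} - B_X \, s_j .$$

Choices the method itself leaves open, resolved here as package defaults:

* **Negative corrected values are clipped to 0** — downstream NB models
  require non-negative counts.
* **Corrected values are rounded half-up to integers** — both DE
  procedures expect integer counts. `round_half_up()` is used rather than
  banker's rounding so that reported numbers match the everyday
  convention.
* **Several blood references are combined** by scaling each column to the
  mean reference depth, averaging per gene, and rounding; a single
  reference passes through unchanged (`build_blood_profile()`).
* **Several markers** may be supplied; the scale is then the ratio of
  summed marker counts, which reduces single-gene sampling noise. With
  one marker this reduces exactly to the marker-ratio formula.
* **No depth renormalization** is applied between the placental sample and
  the blood profile inside the subtraction; the formula operates on raw
  counts. This mirrors the method as published and is a known limitation:
  if the blood reference is sequenced much deeper or shallower than the
  tissue samples, the marker ratio absorbs that difference, which is
  exactly what makes the subtraction self-calibrating — but it also means
  $s_j$ is a library-relative, not biological, admixture fraction.

Under a deterministic admixture ($c_{Xj} = \mathrm{round}(\alpha_j B_X)$,
marker the most abundant blood gene) the correction recovers true counts
to within ±1 per cell; with Poisson contaminant noise it cannot be exact,
but the mean absolute error against truth drops by roughly an order of
magnitude on default simulations (the test suite checks strict per-sample
improvement on 20 replicate datasets).

# Dual-procedure differential expression

Each subtype is contrasted against normal twice, with two established
negative-binomial frameworks run through their own filters and
normalizations:

* **Procedure A** (DESeq2): genes with at least 1 count in *every* sample
  of the contrast; median-of-ratios size factors; Wald test.
* **Procedure B** (edgeR): genes with CPM > 1 in *at least one* sample
  (strict inequality); TMM scaling; quasi-likelihood F test.

Both sets of p-values are Benjamini–Hochberg adjusted; "adjusted p" and
"FDR" are treated as the same procedure throughout. The final DEG call
combines the two tables:

* **intersect** (default for EOSPE and LOSPE): adjusted p ≤ α in *both*
  procedures. We additionally require the two fold-change signs to agree;
  discordant genes are dropped with a message. The published analysis is
  silent on discordant-sign genes, and a single coherent direction per
  DEG is needed for up/down tallies and TF direction classes, so
  concordance is the default and a `require_concordance = FALSE` switch
  restores the plain intersection.
* **union** (default for LOMPE): adjusted p ≤ α in *either* procedure.
  The mild late-onset contrast has both the smallest case group and by
  far the weakest signal; the union rule trades specificity for power
  there, as in the analysis this package operationalizes.

Reported directions come from procedure A's fold change when the gene was
tested by A, otherwise from B. α defaults to 0.05.

# Sample exploration

All exploration runs on
$\log_2(\text{median-of-ratios-normalized count} + 1)$. The published
figures do not state their transformation (the tooling implies a
variance-stabilizing family); this simpler transform was chosen because it
is monotone, fast, dependency-light and easy to test, and the clustering
conclusions it supports on synthetic data are insensitive to swapping in a
VST. PCA uses the top 500 genes by variance of that transform (ties broken
by gene id), is centered but not scaled, and orients every component so
its largest-absolute loading is positive — a pure sign convention that
makes scores reproducible. Sample clustering uses Euclidean distances on
"expressed" genes (raw count above 1 in every sample), Ward linkage
(`ward.D2`), and an explicit flat cluster count `k` (default 2). `k` is
deliberately a parameter, not inferred: the published reading of two
clusters was made by eye, and the package does not pretend to automate
that judgement.

# Enrichment statistics

Gene-set over-representation is the upper-tail hypergeometric probability
$P(X \ge k)$ for overlap $k$ between a query of size $n$ and a set of size
$K$ in a universe of size $N$, BH-adjusted across sets. Screening cutoffs
follow the conventions of the analysis: q ≤ 0.2 for pathway screens,
q ≤ 0.05 (with adjusted p ≤ 0.05) for GO-style screens. The q-value
estimator behind the published cutoffs is unstated; Benjamini–Hochberg is
the default here, with a Storey-type smoother estimator (`q_method =
"storey"`) available — at typical enrichment scales the two differ by a
factor $\hat\pi_0 \le 1$ and rarely change which sets pass.

Curated-list enrichment is reported as a fraction in **two modes**,
because published fraction statements use both: `of_query`
($|q \cap L| / |q|$, the bar-plot convention) and `of_list`
($|q \cap L| / |L|$, the "x% of transporter genes are DEGs" convention).
Each row records its mode and all four counts. Significance is a
one-sided Fisher's exact test on the 2×2 membership table over the
universe; the uncertainty of the observed fraction is the standard
deviation over 100 bootstrap resamples of the query with replacement
(seeded; `n_boot` configurable). Literature recovery stratifies a curated
list by occurrence count (reported once / twice / three-or-more times)
and reports per-stratum recovery at one decimal percent, rounded half-up
to match printed values.

# Term and TF networks

Enriched terms and their member DEGs form a two-mode graph (term nodes,
gene nodes carrying the DE direction). Terms are compared by the Jaccard
index of their gene memberships and clustered by **average linkage on
1 − J**; the linkage is not stated in the published method, and average
linkage is the standard, reproducible choice for set-overlap similarity.
Terms are sorted lexicographically before clustering so merge order is
deterministic; the flat group count `k` is user-supplied (published group
counts were fixed manually from the network layout), with a silhouette
suggestion printed but never applied.

The TF stage consumes an external motif-scanner hit table (tf, motif,
target). (tf, target) pairs are deduplicated across motifs before any
counting. It reports DEG coverage (fraction of DEGs targeted by ≥ 1 TF,
with numerator/denominator and a rounded percent), classifies each TF as
up-only / down-only / both by its targets' directions, and computes
per-TF pathway enrichment of DEG targets. TF→pathway links are kept at
**raw** p ≤ 0.05 — matching the annotation convention of the display this
reproduces — with an adjusted-p mode behind a flag; TFs with fewer than 5
DEG targets are skipped to avoid degenerate tests. Per-TF
tri-partite graphs (TF–targets–pathways) export as GraphML or TSV.

# The synthetic-data generator

The generator emulates the study design the pipeline expects, and its
defaults *are* those study conditions:

| Parameter | Default | Rationale |
|---|---|---|
| group sizes | normal 32, EOSPE 9, LOSPE 15, LOMPE 9 | the cohort structure the pipeline targets |
| genes | 5,000 | enough for stable normalization/enrichment at desk scale |
| DE fraction | EOSPE 0.12, LOSPE 0.02, LOMPE 0.002 | reproduces the strong many ≫ few ≫ near-none subtype asymmetry |
| log2 FC | ±1.5, 60% up | moderate bulk effect sizes; up-bias as observed in PE placenta |
| dispersion | $\phi(\mu) = 0.05 + 2/\mu$ | decreasing mean–dispersion trend typical of bulk RNA-seq |
| library sizes | 5×10⁵–2×10⁶ | scaled-down depths preserving a 4× spread |
| contamination α | U(0.02, 0.20) | visible but sub-dominant blood admixture |
| blood refs | 2 | two cord-blood reference samples |
| marker blood count | 10,000 at 10⁶ depth | hemoglobin-like dominance of the blood profile |

True placental counts are NB draws with log-normal baseline means
(renormalized to each sample's depth); the marker's placental mean is
exactly 0. The contaminant is Poisson with mean $\alpha_j B_X$, where
$B$ is the expected blood profile at the blood reference depth — i.e. the
additive mixture the decontamination model assumes, with the contaminant
*not* rescaled to the tissue sample's depth, mirroring the raw-count
subtraction it is meant to test. `contaminant_noise = FALSE` freezes the
admixture at its expectation for exactness testing. The non-marker blood
profile is clipped at 0.8× the marker mean so the marker is always the
most abundant blood gene; besides being biologically sensible for
hemoglobin, this bounds the rounding error of the estimated scale so that
deterministic recovery is exact to ±1 per cell. The truth bundle retains
exact bookkeeping (observed = true + contaminant), the implanted DE
labels with signs, the per-sample α, and both NB parameterizations.

Annotation side-inputs are generated with controlled overlap to the
implanted truth: a curated list sampled with configurable odds ratio for
DEG membership, whose occurrence strata (1 / 2 / ≥3) are weighted so
recovery rises with occurrence; a GMT collection in which alternating
sets are DEG-enriched; and a TF hit table covering a configurable
fraction (default 0.79) of one group's true DEGs, with background
non-DEG targets and duplicate motifs included deliberately so that
deduplication and intersection logic is exercised.

What the generator does **not** emulate: batch effects, twin-pregnancy
correlation, isoform structure, GC/length biases, outlier samples, or the
correlation structure of real co-expression networks. Passing tests
therefore demonstrate that the pipeline's statistics behave as designed
under a faithful NB + additive-contamination model — not that any
particular biological conclusion about real placentas is correct.

# Numerical choices and problem sizes

* Percent reporting rounds half-up at the stated precision
  (`percent_of()`), so printed pairs like 296/934 → 31.7% reproduce
  exactly.
* Hypergeometric p-values are validated against brute-force combinatorial
  enumeration for all universe sizes up to 25.
* Ties: variance ranking and loading ranking break ties by gene id; term
  clustering sorts terms lexicographically before linkage.
* Degenerate inputs are errors, not silent results: zero library sizes,
  all-zero blood reference columns, markers absent from a matrix, a zero
  marker count in the blood profile, empty queries or curated lists.
* Problem sizes used by the test suite and acceptance script, chosen to
  keep a full run at desk scale: the DEG-ordering, recovery and
  co-clustering checks run the full generator defaults (5,000 genes,
  32/9/15/9 samples) over 10 seeds; null-calibration runs use 2,000 genes
  at 10 vs 10 samples over 3 seeds; decontamination error checks use 20
  replicate datasets of 400 genes; module-level tests use 120–500 gene
  toys.

# Known limitations

* The decontamination scale is estimated from a single (or few) marker
  gene(s); a lowly-expressed marker would make $s_j$ noisy. The
  multi-marker option mitigates this but the package does not attempt
  full reference-based deconvolution.
* The raw-count subtraction inherits the published method's lack of
  explicit depth renormalization (discussed above).
* The union rule for the low-power subtype inflates its false-discovery
  risk by construction; it is reported with its rule attached so the two
  regimes are never mixed silently.
* Biotype handling expects annotation biotypes reducible to
  protein-coding / lncRNA / microRNA / pseudogene / other.
* `cluster_terms()` and `cluster_samples()` expose `k` rather than
  inferring it; silhouette output is advisory only.
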