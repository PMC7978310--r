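# pesubtype

Subtype-stratified analysis of placental bulk RNA-seq in preeclampsia
(PE). Cohorts of this kind contrast placentas from three clinical
subtypes — early-onset severe (EOSPE), late-onset severe (LOSPE) and
late-onset mild (LOMPE) — against normal pregnancies, and face two
recurring problems: residual **cord-blood contamination** of the tissue
counts, and **very unequal signal** across subtypes (thousands of
differentially expressed genes in EOSPE, a handful in LOMPE). This
package implements the full analysis as tested, reusable R functions:

1. **Decontamination** — per-sample blood admixture is estimated from a
   blood-exclusive marker gene (a hemoglobin-subunit-like transcript) and
   subtracted:
   `corrected(X, j) = observed(X, j) − B(X) · s_j`, with
   `s_j = marker_j / marker_B`, where `B` is a per-gene cord-blood
   reference profile.
2. **Dual-procedure differential expression** — each subtype versus
   normal is tested with two established NB frameworks (DESeq2:
   min-count filter, median-of-ratios, Wald; edgeR: CPM > 1 filter, TMM,
   quasi-likelihood F), combined by **intersection** (both adjusted
   p ≤ 0.05, concordant signs) or **union** (either; used for the
   low-power LOMPE contrast).
3. **Exploration** — PCA on the top-500 variance genes and Ward
   clustering of sample–sample distances on log2 normalized counts.
4. **Enrichment** — upper-tail hypergeometric tests for gene sets
   (`P(X ≥ k)` for overlap `k`, set `K`, query `n`, universe `N`,
   BH-adjusted, q-value cutoffs); curated-list fraction enrichment with
   one-sided Fisher tests and bootstrap standard errors (100 resamples);
   occurrence-stratified literature recovery.
5. **Networks** — term–gene bipartite graphs with Jaccard clustering of
   terms (average linkage on 1 − J), and TF summaries from an external
   motif-hit table: DEG coverage, up/down/both direction classes, per-TF
   pathway enrichment (Sankey rows), TF–target–pathway graphs.

Because raw cohorts of this kind are generally not public, the package
includes a first-class synthetic-data generator (`simulate_dataset()`,
`simulate_annotations()`) whose defaults mirror the target study design
(32/9/15/9 samples, NB counts, implanted subtype-specific DE, a
blood-exclusive marker carried by a Poisson admixture) together with a
ground-truth bundle, so every stage is validated end-to-end against known
truth.

## Worked example

```r
library(pesubtype)

sim <- simulate_dataset(sim_config(seed = 1))     # 5,000 genes, 65 samples
dec <- remove_blood_contamination(sim$observed, sim$blood_refs, "HBM_LIKE")
dec$estimate
#> contamination_estimate over 65 samples; markers: HBM_LIKE
#>   scale: min 0.017  median 0.0928  max 0.152

de <- run_de(dec$corrected, sim$metadata, c("EOSPE", "normal"),
             annotation = sim$annotation)
summarize_de(de)
#>   n_deg n_up n_down n_coding n_noncoding
#> 1   431  263    168      306         125
```

The per-sample scales (0.02–0.15) recover the simulated admixture
fractions; the EOSPE contrast calls 431 DEGs (both procedures significant
at adjusted p ≤ 0.05 with concordant signs), with the up-regulated excess
the generator implants. Curated-list enrichment and TF coverage:

```r
ann <- simulate_annotations(sim, seed = 2)
fraction_enrichment(deg_ids(de), ann$curated_list$gene_id,
                    rownames(dec$corrected), seed = 3)
#>   overlap query_size observed_percent expected_percent    fisher_p    boot_se
#> 1      78        431             18.1                6 1.42057e-20 0.01755719

motif_coverage(ann$motif_hits, de)
#>   n_deg n_covered percent n_tf
#> 1   431       334      77   23
```

18.1% of DEGs are on the curated list against 6% expected (one-sided
Fisher p ≈ 1e-20, bootstrap SE 1.8 points), and 77% of DEGs are targeted
by at least one of the 23 simulated TFs — close to the generator's
configured 79% coverage of true DEGs.

An entire run (decontam → DE per contrast → clustering → enrichment →
networks, with TSV/GraphML/Newick outputs and a checksummed manifest):

```r
run_pipeline(pipeline_config(out_dir = "run1", seed = 1))
```

or from a shell: `Rscript inst/scripts/run-pipeline.R --out run1 --seed 1`.

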