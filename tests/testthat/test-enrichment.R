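# Hypergeometric set enrichment, curated-list fraction enrichment with
# bootstrap errors, and occurrence-stratified literature recovery.

test_that("hypergeometric p matches exact combinatorial values", {
  universe <- sprintf("g%02d", 1:20)
  sets <- list(full = universe[1:5], other = universe[6:10])
  res <- hypergeom_enrich(universe[1:5], sets, universe, q_cutoff = NULL)
  row <- res[res$set == "full", ]
  # N=20, K=5, n=5, k=5: p = 1 / C(20,5) = 1 / 15504
  expect_equal(row$pvalue, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(row[, c("k", "n", "K", "N")], data.frame(k = 5L, n = 5L, K = 5L, N = 20L),
               ignore_attr = TRUE)
  # disjoint set: k = 0 gives p = 1 under the upper tail
  expect_equal(res$pvalue[res$set == "other"], 1)
  expect_equal(res$k[res$set == "other"], 0L)
})

test_that("hypergeometric p equals brute-force enumeration for N <= 25", {
  for (N in c(8, 15, 25)) {
    universe <- sprintf("u%02d", seq_len(N))
    for (K in c(2, floor(N / 3), floor(N / 2))) {
      for (n in c(2, floor(N / 2), N - 1)) {
        set <- universe[seq_len(K)]
        query <- universe[seq_len(n)]
        k <- length(intersect(query, set))
        res <- hypergeom_enrich(query, list(s = set), universe, q_cutoff = NULL)
        expect_equal(res$pvalue, hyper_tail_bruteforce(N, K, n, k),
                     tolerance = 1e-12,
                     label = sprintf("N=%d K=%d n=%d", N, K, n))
      }
    }
  }
})

test_that("saturated query and empty query behave at the boundaries", {
  universe <- sprintf("g%d", 1:10)
  sets <- list(all = universe)
  res <- hypergeom_enrich(universe, sets, universe, q_cutoff = NULL)
  expect_equal(res$pvalue, 1)  # forced full overlap
  expect_equal(res$k, 10L)
  expect_warning(out <- hypergeom_enrich(c("x", "y"), sets, universe,
                                         q_cutoff = NULL),
                 "empty query")
  expect_equal(nrow(out), 0)
})

test_that("BH adjustment is monotone and q-value variants are consistent", {
  set.seed(2)
  universe <- sprintf("g%03d", 1:300)
  sets <- lapply(1:25, function(i) sample(universe, 30))
  names(sets) <- sprintf("S%02d", 1:25)
  query <- sample(universe, 60)
  res <- hypergeom_enrich(query, sets, universe, q_cutoff = NULL)
  ord <- order(res$pvalue)
  expect_true(all(diff(res$padj[ord]) >= -1e-12))
  expect_true(all(res$padj >= res$pvalue - 1e-12))
  res_st <- hypergeom_enrich(query, sets, universe, q_cutoff = NULL,
                             q_method = "storey")
  expect_true(all(res_st$qvalue <= res_st$padj + 1e-12))  # pi0 <= 1
})

test_that("fraction reporters reproduce printed percentages from count pairs", {
  expect_equal(percent_of(205, 1554), 13.2)    # of-list transporter fraction
  expect_equal(percent_of(23, 1554), 1.5)
  expect_equal(percent_of(1554, 19738, 2), 7.87)
  expect_equal(percent_of(296, 934), 31.7)
  expect_equal(percent_of(81, 96), 84.4)
  expect_equal(percent_of(2349, 2977, 0), 79)
  expect_equal(percent_of(301, 375, 2), 80.27)
})

test_that("query = universe gives observed = expected and Fisher p = 1", {
  universe <- sprintf("g%d", 1:50)
  lst <- universe[1:10]
  fr <- fraction_enrichment(universe, lst, universe, n_boot = 10)
  expect_equal(fr$observed_fraction, fr$expected_fraction)
  expect_equal(fr$fisher_p, 1)
})

test_that("both fraction modes report their own denominators", {
  universe <- sprintf("g%03d", 1:200)
  query <- universe[1:40]
  lst <- universe[31:70]   # overlap 10
  a <- fraction_enrichment(query, lst, universe, mode = "of_query", n_boot = 10)
  b <- fraction_enrichment(query, lst, universe, mode = "of_list", n_boot = 10)
  expect_equal(a$observed_fraction, 10 / 40)
  expect_equal(b$observed_fraction, 10 / 40)  # equal sizes here
  expect_equal(a$query_size, 40L)
  expect_equal(b$list_size, 40L)
  expect_error(fraction_enrichment(character(0), lst, universe), "empty query")
  expect_error(fraction_enrichment(query, character(0), universe), "empty curated")
})

test_that("one-sided Fisher p is oriented toward enrichment", {
  set.seed(4)
  universe <- sprintf("g%04d", 1:2000)
  for (i in 1:10) {
    query <- sample(universe, 150)
    # list deliberately overlaps 40 query genes: observed 40/150 > expected 200/2000
    lst <- c(query[1:40], sample(setdiff(universe, query), 160))
    fr <- fraction_enrichment(query, lst, universe, n_boot = 5)
    expect_gt(fr$observed_fraction, fr$expected_fraction)
    expect_lte(fr$fisher_p, 0.5)
  }
})

test_that("bootstrap SE shrinks as the query grows at fixed proportion", {
  set.seed(6)
  universe <- sprintf("g%05d", 1:20000)
  lst <- universe[1:2000]
  q_small <- c(universe[1:10], universe[3000:3089])       # 100 genes, 10% in list
  q_big <- c(universe[1:1000], universe[3000:11999])      # 10000 genes, 10%
  se_small <- fraction_enrichment(q_small, lst, universe, n_boot = 100)$boot_se
  se_big <- fraction_enrichment(q_big, lst, universe, n_boot = 100)$boot_se
  expect_gt(se_small, 3 * se_big)  # expect ~ sqrt(100) ratio
  # and the bootstrap is seeded: identical runs give identical SEs
  again <- fraction_enrichment(q_small, lst, universe, n_boot = 100)$boot_se
  expect_identical(se_small, again)
})

test_that("literature recovery stratifies by occurrence and handles edge cases", {
  curated <- data.frame(
    gene_id = sprintf("g%04d", 1:1177),
    occurrence_count = rep(c(1L, 2L, 3L, 5L), c(934, 147, 50, 46)))
  # DEGs recover 296 of the once-reported, 88 of twice, 81 of >= 3 times
  degs <- c(sprintf("g%04d", 1:296),            # stratum "1" is genes 1..934
            sprintf("g%04d", 935:1022),         # stratum "2" is 935..1081
            sprintf("g%04d", 1082:1162))        # stratum ">=3" is 1082..1177
  rec <- literature_recovery(degs, curated)
  expect_equal(rec$percent, c(31.7, 59.9, 84.4))
  expect_equal(rec$n_genes, c(934L, 147L, 96L))
  expect_equal(rec$n_recovered, c(296L, 88L, 81L))

  none <- literature_recovery(character(0), curated)
  expect_equal(none$percent, c(0, 0, 0))
  empty_stratum <- literature_recovery("g0001", data.frame(
    gene_id = c("g0001", "g0002"), occurrence_count = c(1L, 3L)))
  expect_true(is.na(empty_stratum$percent[empty_stratum$stratum == "2"]))
  expect_error(literature_recovery(degs, data.frame(gene_id = "a",
                                                    occurrence_count = 0L)),
               ">= 1")
})
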