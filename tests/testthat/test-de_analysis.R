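# Dual-procedure differential expression: the two gene filters, the two
# delegated NB tests, and the intersect/union combination rules.

test_that("min-count filter keeps genes with >= 1 count in every sample", {
  # columns are samples: g1=(3,1,0) g2=(1,0,3) g3=(0,2,0) g4=(9,5,1) g5=(0,1,0)
  m <- toy_counts(c(3, 1, 0, 9, 0, 1, 0, 2, 5, 1, 0, 3, 0, 1, 0),
                  genes = sprintf("g%d", 1:5))
  expect_identical(filter_min_count(m), "g4")  # the only all-positive gene
  expect_identical(filter_min_count(toy_counts(c(1, 1, 1), genes = "g1")), "g1")
  expect_identical(filter_min_count(toy_counts(c(3, 0, 5), genes = "g1")),
                   character(0))
})

test_that("CPM filter uses a strict > 1 threshold on count/libsize * 1e6", {
  m <- toy_counts(c(10, 1, 999989, 0, 0, 1e6), genes = c("gA", "gB", "big"),
                  samples = c("s1", "s2"))
  # libsizes are 1e6 each: gA has CPM 10 in s1 -> kept; gB CPM exactly 1 -> dropped
  kept <- filter_cpm(m)
  expect_true("gA" %in% kept)
  expect_false("gB" %in% kept)
  zero <- toy_counts(c(0, 5, 0, 7), genes = c("null", "g"), samples = c("s1", "s2"))
  expect_false("null" %in% filter_cpm(zero))
  allzero <- toy_counts(c(0, 1, 0, 2), genes = c("a", "b"), samples = c("s1", "s2"))
  allzero[, 1] <- 0L
  expect_error(filter_cpm(allzero), "library size")
})

test_that("a gene with identical normalized counts in all samples is null", {
  set.seed(8)
  n <- 60
  m <- matrix(rnbinom(n * 12, mu = 80, size = 5) + 1L, nrow = n)
  dimnames(m) <- list(sprintf("g%02d", 1:n), sprintf("s%02d", 1:12))
  m["g01", ] <- 100L
  m["g02", ] <- 0L
  m["g02", ] <- as.integer(max(colSums(m)) - colSums(m) + 200L)  # equalize depth
  meta <- data.frame(sample_id = colnames(m), group = rep(c("x", "y"), each = 6))
  for (proc in c("deseq2", "edger")) {
    res <- test_de(m, meta, c("y", "x"), proc)
    row <- res[res$gene_id == "g01", ]
    expect_lt(abs(row$log2fc), 0.1)  # TMM/size factors are not exactly 1
    expect_gt(row$pvalue, 0.5)
  }
})

test_that("results are invariant to sample order within groups", {
  sim <- small_sim(seed = 41, n_genes = 150)
  meta <- sim$metadata[sim$metadata$group %in% c("EOSPE", "normal"), ]
  perm <- meta[sample(nrow(meta)), ]
  for (proc in c("deseq2", "edger")) {
    a <- test_de(sim$observed, meta, c("EOSPE", "normal"), proc)
    b <- test_de(sim$observed, perm, c("EOSPE", "normal"), proc)
    a <- a[order(a$gene_id), ]; b <- b[order(b$gene_id), ]
    expect_equal(a$log2fc, b$log2fc, tolerance = 1e-10)
    expect_equal(a$pvalue, b$pvalue, tolerance = 1e-10)
  }
})

test_that("test_de validates its inputs", {
  sim <- small_sim(seed = 41, n_genes = 100)
  expect_error(test_de(sim$observed, sim$metadata, c("EOSPE", "EOSPE")), "distinct")
  expect_error(test_de(sim$observed, sim$metadata, c("nope", "normal")), "missing")
  one <- sim$metadata[c(1, which(sim$metadata$group == "EOSPE")[1]), ]
  one$group[1] <- "normal"
  expect_error(test_de(sim$observed, one, c("EOSPE", "normal")), ">= 2 samples")
  bad <- sim$observed; bad[1, 1] <- -1L
  expect_error(test_de(bad, sim$metadata, c("EOSPE", "normal")), "negative")
})

test_that("combine_de reproduces hand enumeration on a toy table", {
  resA <- data.frame(gene_id = sprintf("g%d", 1:6),
                     log2fc = c(2, -1, 1.5, -2, 1, 0.5),
                     pvalue = c(1e-4, 1e-3, 0.002, 1e-5, 0.2, 0.01),
                     padj = c(0.001, 0.01, 0.20, 0.001, 0.60, 0.04))
  resB <- data.frame(gene_id = sprintf("g%d", 1:6),
                     log2fc = c(1.8, -0.9, 1.2, 2.1, 0.8, 0.4),
                     pvalue = c(2e-4, 5e-3, 0.001, 1e-4, 0.3, 0.20),
                     padj = c(0.002, 0.03, 0.01, 0.002, 0.70, 0.50))
  # hand enumeration at alpha 0.05:
  #  g1: both hit, signs agree          -> intersect DEG, up
  #  g2: both hit, signs agree          -> intersect DEG, down
  #  g3: A padj 0.20 fails              -> union only
  #  g4: both hit but signs disagree    -> dropped under intersect
  #  g5: neither hits                   -> never
  #  g6: A hits, B fails                -> union only
  expect_message(inter <- combine_de(resA, resB, "intersect"), "discordant")
  expect_setequal(deg_ids(inter), c("g1", "g2"))
  expect_identical(inter$direction[inter$gene_id == "g1"], "up")
  expect_identical(inter$direction[inter$gene_id == "g2"], "down")

  uni <- combine_de(resA, resB, "union")
  expect_setequal(deg_ids(uni), c("g1", "g2", "g3", "g4", "g6"))
  expect_true(all(deg_ids(inter) %in% deg_ids(uni)))
  # direction comes from procedure A where available: g4 is down under A
  expect_identical(uni$direction[uni$gene_id == "g4"], "down")

  no_conc <- suppressMessages(
    combine_de(resA, resB, "intersect", require_concordance = FALSE))
  expect_setequal(deg_ids(no_conc), c("g1", "g2", "g4"))
})

test_that("union calls are a superset of intersect calls on real output", {
  sim <- small_sim(seed = 43, n_genes = 300)
  resA <- test_de(sim$observed, sim$metadata, c("EOSPE", "normal"), "deseq2")
  resB <- test_de(sim$observed, sim$metadata, c("EOSPE", "normal"), "edger")
  inter <- suppressMessages(combine_de(resA, resB, "intersect"))
  uni <- combine_de(resA, resB, "union")
  expect_true(all(deg_ids(inter) %in% deg_ids(uni)))
  expect_true(all(inter$padj_A >= inter$pvalue_A, na.rm = TRUE))
  expect_true(all(inter$padj_B >= inter$pvalue_B, na.rm = TRUE))
  # every flagged gene carries a direction consistent with its fold change
  up <- uni[uni$deg & uni$direction == "up", ]
  down <- uni[uni$deg & uni$direction == "down", ]
  lfc_up <- ifelse(is.na(up$log2fc_A), up$log2fc_B, up$log2fc_A)
  lfc_down <- ifelse(is.na(down$log2fc_A), down$log2fc_B, down$log2fc_A)
  expect_true(all(lfc_up > 0) && all(lfc_down < 0))
})

test_that("biotype categories are carried into results and summaries", {
  sim <- small_sim(seed = 47, n_genes = 250)
  de <- suppressMessages(run_de(sim$observed, sim$metadata, c("EOSPE", "normal"),
                                annotation = sim$annotation))
  expect_true(all(c("biotype", "deg", "direction") %in% names(de)))
  s <- summarize_de(de)
  expect_equal(s$n_deg, s$n_up + s$n_down)
  expect_equal(s$n_deg, s$n_coding + s$n_noncoding)
})
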