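# Term-gene bipartite graphs and Jaccard clustering of enriched terms.

# small helper: an enrichment-like row table plus a matching DE result
toy_rows <- function(memberships, category = "GO-BP") {
  data.frame(set = names(memberships), category = category,
             genes = vapply(memberships, paste, "", collapse = ","),
             stringsAsFactors = FALSE)
}
toy_de <- function(genes, direction) {
  structure(data.frame(gene_id = genes, deg = TRUE, direction = direction,
                       stringsAsFactors = FALSE),
            class = c("de_result", "data.frame"))
}

test_that("node and edge counts match hand enumeration", {
  de <- toy_de(c("g1", "g2", "g3", "g4"), c("up", "down", "up", "down"))
  g1 <- build_term_gene_graph(toy_rows(list(T1 = c("g1", "g2", "g3"))), de)
  expect_equal(igraph::vcount(g1), 4)   # 1 term + 3 genes
  expect_equal(igraph::ecount(g1), 3)

  shared <- toy_rows(list(T1 = c("g1", "g2"), T2 = c("g1", "g2")))
  g2 <- build_term_gene_graph(shared, de)
  expect_equal(igraph::vcount(g2), 4)   # gene nodes not duplicated
  expect_equal(igraph::ecount(g2), 4)   # edge count = sum of memberships

  three <- toy_rows(list(T1 = c("g1", "g2"), T2 = c("g2", "g3"), T3 = "g4"))
  g3 <- build_term_gene_graph(three, de)
  expect_equal(igraph::vcount(g3), 7)
  expect_equal(igraph::ecount(g3), 5)
  # strict two-mode structure: every edge joins a term to a gene
  el <- igraph::as_data_frame(g3, "edges")
  types <- stats::setNames(igraph::V(g3)$type, igraph::V(g3)$name)
  expect_true(all(types[el$from] != types[el$to]))
  # gene nodes carry the DE direction
  expect_identical(igraph::V(g3)$direction[igraph::V(g3)$name == "g1"], "up")
})

test_that("rows with direction-less genes are rejected with a message", {
  de <- toy_de(c("g1", "g2"), c("up", "down"))
  rows <- toy_rows(list(good = c("g1", "g2"), bad = c("g1", "gX")))
  expect_message(g <- build_term_gene_graph(rows, de), "rejected")
  expect_false("bad" %in% igraph::V(g)$name)
  expect_error(suppressMessages(
    build_term_gene_graph(toy_rows(list(only = "gX")), de)), "no usable")
})

test_that("Jaccard similarity matches hand counts and metric properties", {
  memb <- list(A = c("g1", "g2", "g3"), B = c("g2", "g3", "g4"),
               C = c("g1", "g2", "g3"), D = c("g8", "g9"))
  J <- jaccard_term_similarity(memb)
  expect_equal(J["A", "B"], 0.5)    # 2 shared / 4 in union
  expect_equal(J["A", "C"], 1)      # identical memberships
  expect_equal(J["A", "D"], 0)      # disjoint
  expect_equal(J, t(J))
  expect_true(all(diag(J) == 1))
  expect_true(all(J >= 0 & J <= 1))
})

test_that("similarity from a graph agrees with similarity from memberships", {
  de <- toy_de(sprintf("g%d", 1:4), c("up", "up", "down", "down"))
  memb <- list(T1 = c("g1", "g2", "g3"), T2 = c("g2", "g3", "g4"))
  g <- build_term_gene_graph(toy_rows(memb), de)
  expect_equal(jaccard_term_similarity(g), jaccard_term_similarity(memb))
})

test_that("perfectly separated blocks are recovered at k = 2", {
  memb <- list(A1 = c("x1", "x2"), A2 = c("x1", "x2"),
               B1 = c("y1", "y2"), B2 = c("y1", "y2"))
  J <- jaccard_term_similarity(memb)
  cl <- suppressMessages(cluster_terms(J, 2))
  expect_equal(cl$labels[["A1"]], cl$labels[["A2"]])
  expect_equal(cl$labels[["B1"]], cl$labels[["B2"]])
  expect_false(cl$labels[["A1"]] == cl$labels[["B1"]])
  singletons <- suppressMessages(cluster_terms(J, 4))
  expect_equal(length(unique(singletons$labels)), 4)
  expect_error(cluster_terms(J, 0), "between")
  expect_error(cluster_terms(J, 5), "between")
})

test_that("average-linkage merge order matches a hand-traced trace", {
  # distances: d(A,B)=0.2, d(C,D)=0.4, all cross pairs 0.9
  J <- matrix(0.1, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(J) <- 1
  J["A", "B"] <- J["B", "A"] <- 0.8
  J["C", "D"] <- J["D", "C"] <- 0.6
  cl <- suppressMessages(cluster_terms(J, 2, suggest_k = FALSE))
  # hand trace: merge {A,B} at 0.2, {C,D} at 0.4, then the two pairs at the
  # average of the four cross distances, 0.9
  expect_equal(cl$hclust$height, c(0.2, 0.4, 0.9), tolerance = 1e-12)
  expect_equal(cl$labels[["A"]], cl$labels[["B"]])
  expect_equal(cl$labels[["C"]], cl$labels[["D"]])
})

test_that("labels are invariant to term order and to duplicated terms", {
  memb <- list(A = c("x1", "x2"), B = c("x1", "x3"), C = c("y1", "y2"),
               D = c("y1", "y2", "y3"))
  J <- jaccard_term_similarity(memb)
  perm <- c("C", "A", "D", "B")
  cl1 <- suppressMessages(cluster_terms(J, 2, suggest_k = FALSE))
  cl2 <- suppressMessages(cluster_terms(J[perm, perm], 2, suggest_k = FALSE))
  # same partition up to label renaming
  part <- function(l) split(names(l), l)[order(vapply(split(names(l), l), `[[`, "", 1))]
  expect_identical(lapply(part(cl1$labels), sort), lapply(part(cl2$labels), sort))

  memb$E <- memb$A  # a term identical to A
  J2 <- jaccard_term_similarity(memb)
  cl3 <- suppressMessages(cluster_terms(J2, 2, suggest_k = FALSE))
  for (nm in names(cl1$labels)) {
    same1 <- cl1$labels == cl1$labels[[nm]]
    same3 <- cl3$labels[names(cl1$labels)] == cl3$labels[[nm]]
    expect_identical(unname(same1), unname(same3))
  }
})

test_that("graph exports round-trip through GraphML and edge tables", {
  de <- toy_de(c("g1", "g2", "g3"), c("up", "down", "up"))
  g <- build_term_gene_graph(toy_rows(list(T1 = c("g1", "g2"), T2 = "g3")), de)
  gml <- tempfile(fileext = ".graphml")
  write_graphml(g, gml)
  back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(back), igraph::vcount(g))
  expect_equal(igraph::ecount(back), igraph::ecount(g))

  tsv <- tempfile(fileext = ".tsv")
  paths <- write_graph_tables(g, tsv)
  edges <- utils::read.delim(paths[1], comment.char = "#")
  nodes <- utils::read.delim(paths[2], comment.char = "#")
  expect_equal(nrow(edges), igraph::ecount(g))
  expect_setequal(nodes$name, igraph::V(g)$name)
})
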