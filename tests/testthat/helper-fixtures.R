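# Shared fixtures built in code.

# a small, fast simulation for module-level tests
small_sim <- function(seed = 7, n_genes = 400, ...) {
  simulate_dataset(sim_config(n_genes = n_genes, seed = seed, ...))
}

# deterministic toy count matrix with named genes/samples
toy_counts <- function(values, genes = NULL, samples = NULL) {
  m <- matrix(as.integer(values), nrow = length(genes) %||% nrow(values))
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(nrow(m)))
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(ncol(m)))
  dimnames(m) <- list(genes, samples)
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force upper-tail hypergeometric probability by direct enumeration
# of all overlap outcomes (independent oracle; no phyper/dhyper)
hyper_tail_bruteforce <- function(N, K, n, k) {
  i <- max(0, k):min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}
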