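# Small in-code fixtures shared across test files.

# tiny planted corpus with known ground truth
tiny_planted <- function(branching = c(2, 2), n_genes = 120, n_cells = 300,
                         parent_share = 0.2, seed = 7,
                         libsize_log_mean = log(400)) {
  spec <- build_tree_spec(branching)
  beta <- make_beta_true(spec, n_genes, parent_share, seed = seed)
  sim <- simulate_planted_tree(spec, beta, n_cells, seed = seed + 1,
                               libsize_log_mean = libsize_log_mean)
  list(spec = spec, beta = beta, counts = sim$counts,
       theta_true = sim$theta_true)
}

# dense count matrix with explicit values, for exact-arithmetic tests
small_counts <- function(values, n_cells, n_genes,
                         genes = paste0("g", seq_len(n_genes))) {
  as_count_matrix(matrix(values, n_cells, n_genes, byrow = TRUE),
                  gene_names = genes,
                  barcodes = paste0("c", seq_len(n_cells)))
}

# 100-cell QC fixture with exactly 10 planted violations:
# 3 cells below the detected-gene floor, 3 above the ceiling,
# 4 with a mitochondrial fraction above 5%
qc_fixture <- function(seed = 42) {
  n_genes <- 3000
  genes <- paste0("GENE", seq_len(n_genes))
  genes[1:10] <- paste0("MT-G", 1:10)
  counts <- matrix(0L, 100, n_genes)
  set.seed(seed)
  for (i in 1:100) {
    on <- sample(11:n_genes, 1000)      # 1000 detected genes, no mito
    counts[i, on] <- 1L
  }
  for (i in 1:3) {                      # too few detected genes
    counts[i, ] <- 0L
    counts[i, sample(11:n_genes, 150)] <- 1L
  }
  for (i in 4:6) {                      # too many detected genes
    counts[i, ] <- 0L
    counts[i, sample(11:n_genes, 2600)] <- 1L
  }
  for (i in 7:10) {                     # mito fraction 100/1100 > 5%
    counts[i, 1:10] <- 10L
  }
  as_count_matrix(counts, gene_names = genes,
                  barcodes = paste0("bc", 1:100))
}
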