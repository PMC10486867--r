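#' Simulate UMI counts with splatter-like marginals
#'
#' Emulates the core of splatter-style scRNA-seq simulation: gene mean
#' expression levels are Gamma distributed, per-cell library sizes are
#' log-normal, and counts are Poisson around the library-scaled gene
#' proportions. Defaults give a median library of roughly 2000 UMIs. No
#' dropout, batch or differential-expression structure is modeled — the goal
#' is realistic count marginals, not biology.
#'
#' @param n_cells,n_genes dimensions.
#' @param libsize_log_mean,libsize_log_sd log-normal library-size
#'   parameters (natural log).
#' @param gene_mean_shape,gene_mean_rate Gamma parameters for gene means.
#' @param seed integer seed; output is a pure function of parameters + seed.
#' @return A cell x gene sparse count matrix.
#' @export
simulate_splatter_like <- function(n_cells, n_genes,
                                   libsize_log_mean = log(2000),
                                   libsize_log_sd = 0.3,
                                   gene_mean_shape = 0.6,
                                   gene_mean_rate = 0.3, seed = 1L) {
  if (n_cells == 0 || n_genes == 0) {
    return(as_count_matrix(Matrix::Matrix(0, n_cells, n_genes, sparse = TRUE)))
  }
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  gene_means <- stats::rgamma(n_genes, shape = gene_mean_shape,
                              rate = gene_mean_rate)
  p <- gene_means / sum(gene_means)
  libsize <- stats::rlnorm(n_cells, libsize_log_mean, libsize_log_sd)
  counts <- poisson_counts(outer(libsize, p))
  as_count_matrix(counts,
                  gene_names = paste0("gene", seq_len(n_genes)),
                  barcodes = paste0("cell", seq_len(n_cells)))
}

# memory-aware Poisson sampling over a (possibly implicit) rate matrix
poisson_counts <- function(rate) {
  D <- nrow(rate); G <- ncol(rate)
  x <- stats::rpois(D * G, as.vector(rate))
  Matrix::Matrix(matrix(x, D, G), sparse = TRUE)
}

#' Planted ground-truth gene distributions over a tree
#'
#' Builds node gene distributions with hierarchical structure: every node
#' owns a reserved, disjoint block of specific genes carrying a sparse
#' random profile; a non-top node's distribution is
#' `parent_share * parent + (1 - parent_share) * specific`, so
#' `parent_share = 0` gives disjoint sibling supports and `parent_share = 1`
#' makes every child equal its parent. Top-level nodes get disjoint anchors.
#'
#' @param spec a `tree_spec`.
#' @param n_genes total vocabulary size (must allow >= 2 specific genes per
#'   node).
#' @param parent_share fraction of each node's mass copied from its parent,
#'   in `[0, 1]`.
#' @param seed integer seed.
#' @return A node x gene matrix with rows on the simplex.
#' @export
make_beta_true <- function(spec, n_genes, parent_share = 0.3, seed = 1L) {
  stopifnot(inherits(spec, "tree_spec"))
  if (parent_share < 0 || parent_share > 1) {
    stop("parent_share must be in [0, 1]")
  }
  K <- spec$n_nodes
  per_node <- n_genes %/% K
  if (per_node < 2L) {
    stop("need at least 2 genes per node; got ", n_genes, " genes for ",
         K, " nodes")
  }
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  beta <- matrix(0, K, n_genes)
  for (k in seq_len(K)) {
    block <- ((k - 1L) * per_node + 1L):(k * per_node)
    prof <- stats::rgamma(per_node, shape = 2, rate = 1)
    specific <- numeric(n_genes)
    specific[block] <- prof / sum(prof)
    p <- spec$parent[k]
    beta[k, ] <- if (is.na(p)) {
      specific
    } else {
      parent_share * beta[p, ] + (1 - parent_share) * specific
    }
  }
  dimnames(beta) <- list(as.character(seq_len(K)),
                         paste0("gene", seq_len(n_genes)))
  beta
}

# one truncated stick-breaking draw over k ordered atoms; remainder folded
# into the last atom
rstick <- function(k, tau) {
  if (k == 1L) return(1)
  br <- stats::rbeta(k - 1L, 1, tau)
  w <- stick_breaking_weights(pmin(pmax(br, 1e-12), 1))$weights
  c(w, 1 - sum(w))
}

#' Simulate a corpus from a planted tree-structured topic model
#'
#' The sampling version of the model's generative story. Per cell: walk from
#' a stick-breaking-chosen top-level node, descending to a
#' stick-breaking-chosen child with probability `gamma_true` at each internal
#' node; distribute the cell's loading over the resulting path by truncated
#' stick breaking (root gets the first stick); then draw counts from the
#' Poisson mixture \eqn{C_{dg} \sim \mathrm{Pois}(L_d \sum_k \theta_{dk}
#' \beta_{kg})} with log-normal library sizes. `gamma_true = 0` puts all
#' loading on level-1 nodes.
#'
#' @param spec a `tree_spec`.
#' @param beta_true node x gene distributions (e.g. [make_beta_true()]).
#' @param n_cells number of cells.
#' @param tau_true stick-breaking concentration for sibling choice and path
#'   loadings (small values concentrate mass on the first atom).
#' @param gamma_true descend probability at internal nodes, in `[0, 1]`.
#' @param libsize_log_mean,libsize_log_sd log-normal library parameters.
#' @param seed integer seed.
#' @return A list with `counts` (cell x gene sparse), `theta_true` (cells x
#'   nodes, rows on the simplex, zero off the sampled path) and `beta_true`.
#' @export
simulate_planted_tree <- function(spec, beta_true, n_cells, tau_true = 1,
                                  gamma_true = 0.75,
                                  libsize_log_mean = log(500),
                                  libsize_log_sd = 0.3, seed = 1L) {
  stopifnot(inherits(spec, "tree_spec"), nrow(beta_true) == spec$n_nodes)
  if (gamma_true < 0 || gamma_true > 1) stop("gamma_true must be in [0, 1]")
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  K <- spec$n_nodes
  G <- ncol(beta_true)
  theta <- matrix(0, n_cells, K)
  for (d in seq_len(n_cells)) {
    top <- level_nodes(spec, 1L)
    node <- top[sample.int(length(top), 1L, prob = rstick(length(top),
                                                          tau_true))]
    path <- node
    while (length(spec$children[[node]]) > 0 &&
             stats::runif(1) < gamma_true) {
      kids <- spec$children[[node]]
      node <- kids[sample.int(length(kids), 1L,
                              prob = rstick(length(kids), tau_true))]
      path <- c(path, node)
    }
    theta[d, path] <- rstick(length(path), tau_true)
  }
  libsize <- stats::rlnorm(n_cells, libsize_log_mean, libsize_log_sd)
  rate <- (theta %*% beta_true) * libsize
  counts <- poisson_counts(rate)
  counts <- as_count_matrix(counts, gene_names = colnames(beta_true),
                            barcodes = paste0("cell", seq_len(n_cells)))
  colnames(theta) <- as.character(seq_len(K))
  rownames(theta) <- rownames(counts)
  list(counts = counts, theta_true = theta, beta_true = beta_true)
}

#' Train/test split plan with nested training sizes
#'
#' For each replicate: a held-out test set of `test_size` cells is sampled,
#' then nested training sets of the requested sizes are drawn from the
#' remaining cells (the larger sets contain the smaller ones, so training-
#' size comparisons differ only by added cells).
#'
#' @param counts cell x gene count matrix (only `nrow` is used).
#' @param test_size held-out cells per replicate.
#' @param train_sizes increasing vector of training-set sizes.
#' @param replicates number of independent replicates.
#' @param seed integer seed.
#' @return A list of `replicates` plans, each with `test` (integer indices)
#'   and `train` (named list of nested index vectors, one per size).
#' @export
split_train_test <- function(counts, test_size, train_sizes,
                             replicates = 3L, seed = 1L) {
  n <- nrow(counts)
  train_sizes <- sort(as.integer(train_sizes))
  if (test_size + max(train_sizes) > n) {
    stop("test_size + max(train_sizes) exceeds the number of cells (", n, ")")
  }
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  lapply(seq_len(replicates), function(r) {
    test <- sort(sample.int(n, test_size))
    pool <- setdiff(seq_len(n), test)
    big <- sample(pool, max(train_sizes))
    train <- lapply(train_sizes, function(s) sort(big[seq_len(s)]))
    names(train) <- as.character(train_sizes)
    list(test = test, train = train)
  })
}
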