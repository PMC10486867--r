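#' Construct a tree-structured GEM model
#'
#' Bundles the tree, the per-node gene distributions and the model
#' hyperparameters. Each row of `beta` is a distribution over genes (a GEM);
#' rows are indexed by node id over the full tree.
#'
#' @param tree a `tree_spec`.
#' @param beta node x gene non-negative matrix; rows are renormalized to sum
#'   to 1 and must be strictly positive after smoothing.
#' @param alpha global DP concentration (> 0).
#' @param tau cell-level DP concentration (> 0); controls how fast sibling
#'   stick weights decay.
#' @param eta symmetric Dirichlet prior weight on gene distributions (> 0).
#' @param gamma_switch depth-switching probability in (0, 1); higher values
#'   encourage cells to express deeper, more specialized nodes.
#' @param gene_names optional character vector overriding `colnames(beta)`.
#' @return A list of class `gem_model`.
#' @export
gem_model <- function(tree, beta, alpha = 1, tau = 1, eta = 0.01,
                      gamma_switch = 0.75, gene_names = NULL) {
  stopifnot(inherits(tree, "tree_spec"))
  beta <- as.matrix(beta)
  if (nrow(beta) != tree$n_nodes) {
    stop("beta must have one row per tree node")
  }
  if (any(beta < 0) || any(!is.finite(beta))) {
    stop("beta entries must be finite and >= 0")
  }
  rs <- rowSums(beta)
  if (any(rs <= 0)) stop("every beta row needs positive mass")
  beta <- beta / rs
  if (!is.null(gene_names)) colnames(beta) <- gene_names
  if (is.null(colnames(beta))) {
    colnames(beta) <- paste0("gene", seq_len(ncol(beta)))
  }
  rownames(beta) <- as.character(seq_len(tree$n_nodes))
  if (alpha <= 0 || tau <= 0 || eta <= 0) {
    stop("alpha, tau and eta must be > 0")
  }
  if (gamma_switch <= 0 || gamma_switch >= 1) {
    stop("gamma_switch must lie strictly in (0, 1)")
  }
  structure(
    list(tree = tree, beta = beta, alpha = alpha, tau = tau, eta = eta,
         gamma_switch = gamma_switch, gene_names = colnames(beta)),
    class = "gem_model"
  )
}

#' @export
print.gem_model <- function(x, ...) {
  cat("gem_model: tree ", paste(x$tree$branching, collapse = "-"),
      " (", x$tree$n_nodes, " GEMs) over ", ncol(x$beta), " genes\n",
      "  alpha=", x$alpha, " tau=", x$tau, " eta=", x$eta,
      " gamma_switch=", x$gamma_switch, "\n", sep = "")
  invisible(x)
}

#' Save / load a GEM model (TSV + JSON sidecar)
#'
#' `beta` is written as a dense TSV (rows = node ids, header = gene names) at
#' full precision and the hyperparameters plus tree as a JSON sidecar; the
#' round-trip is lossless to better than 1e-12.
#'
#' @param model a `gem_model`.
#' @param dir output directory.
#' @return `write_gem_model` returns `dir` invisibly; `read_gem_model` the
#'   restored `gem_model`.
#' @export
write_gem_model <- function(model, dir) {
  stopifnot(inherits(model, "gem_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  beta_chr <- format(model$beta, digits = 17, scientific = TRUE, trim = TRUE)
  utils::write.table(beta_chr, file.path(dir, "beta.tsv"), sep = "\t",
                     quote = FALSE, col.names = NA)
  jsonlite::write_json(
    list(branching = model$tree$branching, alpha = model$alpha,
         tau = model$tau, eta = model$eta, gamma_switch = model$gamma_switch,
         version = 1L),
    file.path(dir, "model.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_gem_model
#' @export
read_gem_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = TRUE)
  beta <- as.matrix(utils::read.table(file.path(dir, "beta.tsv"), sep = "\t",
                                      header = TRUE, row.names = 1,
                                      check.names = FALSE))
  gem_model(build_tree_spec(meta$branching), beta, alpha = meta$alpha,
            tau = meta$tau, eta = meta$eta, gamma_switch = meta$gamma_switch)
}

#' Transfer a pretrained model onto a new gene vocabulary
#'
#' Warm-start support: restricts/extends the pretrained gene distributions to
#' `target_genes`. Genes absent from the pretrained model enter every row at
#' the eta-smoothed minimum mass; rows are then renormalized. The tree and
#' hyperparameters carry over, so the result can be passed as `init` to
#' [fit_gem()] — pretraining on one dataset and transferring to another
#' typically speeds up convergence.
#'
#' @param pretrained a `gem_model`.
#' @param target_genes character vector of gene names for the target data.
#' @return A `gem_model` over `target_genes`, with attribute
#'   `"pretrained_from"` recording the source gene count.
#' @export
warm_start <- function(pretrained, target_genes) {
  stopifnot(inherits(pretrained, "gem_model"))
  target_genes <- as.character(target_genes)
  K <- pretrained$tree$n_nodes
  beta <- matrix(pretrained$eta / ncol(pretrained$beta),
                 K, length(target_genes),
                 dimnames = list(rownames(pretrained$beta), target_genes))
  common <- intersect(target_genes, colnames(pretrained$beta))
  beta[, common] <- pretrained$beta[, common]
  out <- gem_model(pretrained$tree, beta, alpha = pretrained$alpha,
                   tau = pretrained$tau, eta = pretrained$eta,
                   gamma_switch = pretrained$gamma_switch)
  attr(out, "pretrained_from") <- ncol(pretrained$beta)
  out
}
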