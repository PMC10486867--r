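#' Run the end-to-end GEM pipeline
#'
#' Ties the stages together: read (or simulate) counts, QC-filter, normalize,
#' initialize the tree, fit, and evaluate held-out perplexity. Any prefix of
#' the stage list can be run. Every run writes a `manifest.json` capturing
#' all parameters and the seed, so artifact directories are self-describing
#' and reruns are reproducible.
#'
#' @param counts cell x gene count matrix, or a path readable by
#'   [read_10x()] / [read_matrix_tsv()].
#' @param out_dir output directory for artifacts.
#' @param branching tree structure, e.g. `c(5, 4, 3)`.
#' @param config a [fit_config()].
#' @param qc a [qc_params()] or `NULL` to skip filtering.
#' @param train_size cells used for tree initialization (defaults to all).
#' @param test_counts optional held-out count matrix for perplexity.
#' @param stages character subset of
#'   `c("qc", "init", "fit", "eval", "export")` (a prefix is typical).
#' @return A list with the produced objects (`counts`, `init`, `fit`,
#'   `perplexity` where computed), invisibly.
#' @export
run_pipeline <- function(counts, out_dir, branching = c(5, 4, 3),
                         config = fit_config(), qc = qc_params(),
                         train_size = NULL, test_counts = NULL,
                         stages = c("qc", "init", "fit", "eval", "export")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(counts)) {
    counts <- if (dir.exists(counts)) read_10x(counts) else
      read_matrix_tsv(counts)
  }
  counts <- as_count_matrix(counts)
  result <- list()
  manifest <- list(branching = branching, seed = config$seed,
                   mode = config$mode, gamma_switch = config$gamma_switch,
                   n_cells_in = nrow(counts), n_genes = ncol(counts),
                   stages = stages)

  if ("qc" %in% stages && !is.null(qc)) {
    counts <- qc_filter(counts, qc)
    manifest$n_cells_qc <- nrow(counts)
    if (nrow(counts) == 0) stop("no cells left after QC")
  }
  result$counts <- counts

  spec <- build_tree_spec(branching)
  if ("init" %in% stages) {
    props <- normalize_proportions(counts)
    ts <- if (is.null(train_size)) nrow(props) else min(train_size,
                                                        nrow(props))
    init <- initialize_gem_tree(props, spec, train_size = ts,
                                seed = config$seed)
    result$init <- init
    utils::write.table(init$init_beta, file.path(out_dir, "init_beta.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
  }

  if ("fit" %in% stages) {
    if (is.null(result$init)) stop("stage 'fit' requires stage 'init'")
    fitres <- fit_gem(counts, result$init, config)
    result$fit <- fitres
    write_gem_model(fitres$model, file.path(out_dir, "model"))
    utils::write.table(fitres$loadings$theta,
                       file.path(out_dir, "loadings.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    utils::write.table(
      data.frame(epoch = seq_along(fitres$trace$epoch_likelihoods),
                 objective = fitres$trace$epoch_likelihoods),
      file.path(out_dir, "trace.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$converged_at <- fitres$trace$converged_at
  }

  if ("eval" %in% stages && !is.null(result$fit)) {
    eval_counts <- if (is.null(test_counts)) counts else
      as_count_matrix(test_counts)
    th <- infer_loadings(result$fit$model, eval_counts)
    result$perplexity <- perplexity(th, result$fit$model, eval_counts)
    manifest$perplexity <- result$perplexity
  }

  if ("export" %in% stages && !is.null(result$fit)) {
    export_gene_sets(result$fit$model, file.path(out_dir, "gem_top50.gmt"),
                     n = min(50L, ncol(result$fit$model$beta)))
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(result)
}
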