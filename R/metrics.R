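#' Held-out predictive log-likelihood
#'
#' \deqn{L_{test} = \sum_d \sum_g C_{dg} \log \sum_k \theta_{dk} \beta_{kg}}
#' with theta inferred by fold-in ([infer_loadings()]) and beta from the
#' trained model.
#'
#' @param theta a `cell_loadings` or a cells x nodes matrix with rows on the
#'   simplex.
#' @param model a `gem_model` or a nodes x genes matrix of gene
#'   distributions.
#' @param counts cell x gene count matrix, genes matched by name when names
#'   are available.
#' @return The scalar log-likelihood (<= 0 for proper mixtures).
#' @export
test_log_likelihood <- function(theta, model, counts) {
  if (inherits(theta, "cell_loadings")) theta <- theta$theta
  beta <- if (inherits(model, "gem_model")) model$beta else as.matrix(model)
  counts <- as_count_matrix(counts)
  if (!is.null(colnames(beta)) && !is.null(colnames(counts))) {
    if (!all(colnames(counts) %in% colnames(beta))) {
      missing <- setdiff(colnames(counts), colnames(beta))
      stop("genes absent from the model: ", paste(utils::head(missing, 5),
                                                  collapse = ", "))
    }
    beta <- beta[, colnames(counts), drop = FALSE]
  }
  stopifnot(nrow(theta) == nrow(counts), ncol(theta) == nrow(beta),
            ncol(beta) == ncol(counts))
  T3 <- methods::as(counts, "TsparseMatrix")
  if (length(T3@x) == 0) return(0)
  ll <- 0
  chunks <- make_chunks(counts)
  for (ch in chunks) {
    P <- theta[ch$rows, , drop = FALSE] %*% beta
    p_nz <- P[cbind(ch$i, ch$j)]
    if (any(p_nz <= 0)) {
      g <- colnames(counts)[ch$j[which(p_nz <= 0)[1]]]
      stop("observed gene with zero mixture probability: ", g)
    }
    ll <- ll + sum(ch$x * log(p_nz))
  }
  ll
}

#' Held-out perplexity
#'
#' \deqn{\exp(-L_{test} / \sum_{d,g} C_{dg})}: the exponentiated negative
#' predictive log-likelihood per UMI token. Lower is better; a uniform
#' mixture over G genes gives perplexity exactly G.
#'
#' @inheritParams test_log_likelihood
#' @return Scalar perplexity, >= 1 for proper mixtures.
#' @export
perplexity <- function(theta, model, counts) {
  counts <- as_count_matrix(counts)
  total <- sum(counts)
  if (total <= 0) stop("perplexity needs at least one UMI token")
  exp(-test_log_likelihood(theta, model, counts) / total)
}

#' Pointwise mutual information of a gene pair
#'
#' \eqn{\mathrm{PMI}(g_i, g_j) = \log p(g_i, g_j) / (p(g_i) p(g_j))};
#' positive when the genes co-occur more often than independence predicts.
#'
#' @param p_joint joint presence probability (>= 0, possibly smoothed).
#' @param p_i,p_j marginal presence probabilities, > 0.
#' @return Scalar PMI; symmetric in the two genes.
#' @export
pmi <- function(p_joint, p_i, p_j) {
  if (p_i <= 0 || p_j <= 0) stop("marginal probabilities must be > 0")
  if (p_joint < 0) stop("joint probability must be >= 0")
  log(p_joint / (p_i * p_j))
}

#' Coherence configuration
#' @param top_n number of top-weighted genes per GEM entering the score.
#' @param smoothing added to all presence probabilities to avoid log(0).
#' @return A list of class `coherence_config`.
#' @export
coherence_config <- function(top_n = 50L, smoothing = 1e-12) {
  if (top_n < 2L) stop("top_n must be >= 2")
  structure(list(top_n = as.integer(top_n), smoothing = smoothing),
            class = "coherence_config")
}

#' Top-weighted genes of a GEM
#'
#' @param beta_row named numeric vector of gene weights (one model row).
#' @param n how many genes; ties broken by input gene order (stable).
#' @return Character vector of `n` gene names in descending weight order.
#' @export
top_genes <- function(beta_row, n) {
  if (n < 1L || n > length(beta_row)) {
    stop("`n` must be in 1..", length(beta_row))
  }
  nm <- names(beta_row)
  if (is.null(nm)) nm <- paste0("gene", seq_along(beta_row))
  ord <- order(-as.numeric(beta_row), seq_along(beta_row))
  nm[ord[seq_len(n)]]
}

#' PMI topic coherence of a GEM
#'
#' Sums pointwise mutual information over all unordered pairs of the GEM's
#' `top_n` genes. Presence probabilities are document frequencies in the
#' reference corpus: p(g) is the fraction of cells with count > 0 for g, and
#' p(gi, gj) the fraction with both present, each smoothed. Higher scores
#' indicate a more internally consistent gene module.
#'
#' @param beta_row named gene-weight vector (one model row).
#' @param reference_counts cell x gene count matrix used to estimate
#'   co-occurrence (typically the training corpus).
#' @param config a [coherence_config()].
#' @return Scalar coherence (sum over `choose(top_n, 2)` pairs).
#' @export
topic_coherence <- function(beta_row, reference_counts,
                            config = coherence_config()) {
  counts <- as_count_matrix(reference_counts)
  if (nrow(counts) == 0) stop("reference corpus is empty")
  genes <- top_genes(beta_row, config$top_n)
  eps <- config$smoothing
  D <- nrow(counts)
  present <- matrix(0, D, length(genes))
  known <- genes %in% colnames(counts)
  if (!all(known)) {
    message(sum(!known), " top genes absent from the reference corpus; ",
            "their pairs use smoothed probabilities")
  }
  present[, known] <- as.matrix(counts[, genes[known], drop = FALSE] > 0)
  p_marg <- colMeans(present) + eps
  p_joint <- crossprod(present) / D + eps
  total <- 0
  n <- length(genes)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      total <- total + pmi(p_joint[i, j], p_marg[i], p_marg[j])
    }
  }
  total
}

#' Cosine similarity between gene vectors or gene sets
#'
#' \eqn{\cos\theta = a \cdot b / (|a||b|)}. Character vectors are treated as
#' gene sets and embedded as binary indicators over the union vocabulary, so
#' two top-gene lists of size n sharing m genes score \eqn{m/n}.
#'
#' @param a,b non-negative numeric vectors (same length) or character gene
#'   sets.
#' @return Scalar in `[0, 1]` for non-negative input.
#' @export
cosine_similarity <- function(a, b) {
  if (is.character(a) || is.character(b)) {
    vocab <- union(a, b)
    a <- as.numeric(vocab %in% a)
    b <- as.numeric(vocab %in% b)
  }
  if (length(a) != length(b)) stop("length mismatch")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity of a zero vector")
  sum(a * b) / (na * nb)
}

#' Cosine similarities between GEM top genes and marker gene sets
#'
#' Entry (k, s) is the cosine similarity between the top `top_n` genes of
#' GEM k and marker set s (both as binary indicator sets). With
#' `marker_sets = NULL` the GEM x GEM similarity matrix of top-gene lists is
#' returned instead (diagonal 1).
#'
#' @param model a `gem_model`.
#' @param marker_sets named list of character gene vectors, or `NULL`.
#' @param top_n number of top genes per GEM.
#' @return Numeric matrix, rows = node ids.
#' @export
gem_similarity_matrix <- function(model, marker_sets = NULL, top_n = 150L) {
  stopifnot(inherits(model, "gem_model"))
  tops <- lapply(seq_len(nrow(model$beta)),
                 function(k) top_genes(model$beta[k, ], top_n))
  if (is.null(marker_sets)) {
    K <- length(tops)
    out <- matrix(1, K, K, dimnames = list(rownames(model$beta),
                                           rownames(model$beta)))
    for (i in seq_len(K)) {
      for (j in seq_len(K)) {
        if (i < j) out[i, j] <- out[j, i] <- cosine_similarity(tops[[i]],
                                                               tops[[j]])
      }
    }
    return(out)
  }
  if (length(marker_sets) == 0 || is.null(names(marker_sets))) {
    stop("marker_sets must be a named, non-empty list")
  }
  for (s in names(marker_sets)) {
    if (length(marker_sets[[s]]) == 0) stop("empty marker set: ", s)
  }
  out <- matrix(0, length(tops), length(marker_sets),
                dimnames = list(rownames(model$beta), names(marker_sets)))
  for (k in seq_along(tops)) {
    for (s in seq_along(marker_sets)) {
      out[k, s] <- cosine_similarity(tops[[k]], marker_sets[[s]])
    }
  }
  out
}

#' Export per-GEM top gene sets in GMT format
#'
#' Writes one line per tree node: set name (`GEM_<id>`), a description, and
#' the node's top `n` genes tab-separated — the standard input for
#' enrichment tools such as GSVA or fgsea.
#'
#' @param model a `gem_model`.
#' @param path output `.gmt` file.
#' @param n genes per set.
#' @return `path`, invisibly.
#' @export
export_gene_sets <- function(model, path, n = 50L) {
  stopifnot(inherits(model, "gem_model"))
  lines <- vapply(seq_len(nrow(model$beta)), function(k) {
    paste(c(paste0("GEM_", k),
            paste0("top", n, "_genes_node", k, "_level",
                   model$tree$level[k]),
            top_genes(model$beta[k, ], n)), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Parse a GMT gene-set file
#' @param path `.gmt` file.
#' @return Named list of character gene vectors.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  out <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    parts[-(1:2)]
  })
  names(out) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1]][1]
  }, character(1), USE.NAMES = FALSE)
  out
}
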