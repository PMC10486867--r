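#' Training configuration for the tree-structured topic model
#'
#' @param mode `"one-batch"` (full-data updates every epoch; the recorded
#'   objective is then provably non-decreasing) or `"mini-batch"` (stochastic
#'   natural-gradient updates on the gene-distribution statistics).
#' @param batch_size cells per mini-batch.
#' @param learning_rate constant step size for mini-batch updates.
#' @param max_epochs upper bound on passes over the data.
#' @param conv_tol stop when the relative change of the epoch objective falls
#'   below this.
#' @param gamma_switch depth-switching probability in (0, 1). Higher values
#'   encourage cells to traverse down to leaf nodes; lower values are a
#'   conservative search that keeps more mass on higher tree levels.
#' @param alpha,tau,eta DP / Dirichlet hyperparameters (see [gem_model()]).
#' @param seed integer seed controlling subsampling and batch order.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(mode = c("one-batch", "mini-batch"), batch_size = 512L,
                       learning_rate = 0.01, max_epochs = 100L,
                       conv_tol = 1e-4, gamma_switch = 0.75, alpha = 1,
                       tau = 1, eta = 0.01, seed = 1L) {
  mode <- match.arg(mode)
  if (learning_rate <= 0 || learning_rate > 1) {
    stop("learning_rate must be in (0, 1]")
  }
  if (batch_size < 1L) stop("batch_size must be >= 1")
  structure(list(mode = mode, batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs), conv_tol = conv_tol,
                 gamma_switch = gamma_switch, alpha = alpha, tau = tau,
                 eta = eta, seed = as.integer(seed)),
            class = "fit_config")
}

# triplet view of a sparse cell x gene matrix, chunked over cells so the
# dense cell x gene probability block stays below ~5e6 entries
make_chunks <- function(counts, target = 5e6) {
  T3 <- methods::as(counts, "TsparseMatrix")
  D <- nrow(counts); G <- ncol(counts)
  rows_per <- max(1L, floor(target / max(1L, G)))
  starts <- seq(1L, D, by = rows_per)
  ord <- order(T3@i)
  ti <- T3@i[ord] + 1L; tj <- T3@j[ord] + 1L; tx <- T3@x[ord]
  lapply(starts, function(s) {
    e <- min(s + rows_per - 1L, D)
    inn <- ti >= s & ti <= e
    list(rows = s:e, i = ti[inn] - s + 1L, j = tj[inn], x = tx[inn])
  })
}

# one EM pass over the data at fixed (theta, beta): returns the data
# log-likelihood at the current parameters, the expected per-cell node counts
# n (D x K) and, if wanted, the expected per-node gene counts m (K x G)
em_pass <- function(chunks, theta, beta, want_m = TRUE) {
  K <- nrow(beta); G <- ncol(beta)
  n <- matrix(0, nrow(theta), K)
  m <- if (want_m) matrix(0, K, G) else NULL
  loglik <- 0
  bt <- t(beta)
  for (ch in chunks) {
    th <- theta[ch$rows, , drop = FALSE]
    P <- th %*% beta                              # Dc x G dense
    p_nz <- P[cbind(ch$i, ch$j)]
    loglik <- loglik + sum(ch$x * log(p_nz))
    R <- Matrix::sparseMatrix(i = ch$i, j = ch$j, x = ch$x / p_nz,
                              dims = c(length(ch$rows), G))
    n[ch$rows, ] <- th * as.matrix(R %*% bt)
    if (want_m) m <- m + t(th) %*% R              # scaled by beta below
  }
  if (want_m) m <- beta * as.matrix(m)
  list(loglik = loglik, n = n, m = m)
}

row_normalize <- function(M) M / rowSums(M)

# penalized objective: data log-likelihood + Dirichlet pseudo-count terms
penalized_objective <- function(loglik, theta, beta, a, eta) {
  loglik + eta * sum(log(beta)) + sum(log(theta) %*% a)
}

#' Fit the nested tree-structured topic model
#'
#' Estimates per-node gene distributions beta and per-cell node loadings
#' theta for a preset GEM tree by penalized EM on the multinomial mixture
#' \eqn{C_{d\cdot} \sim \mathrm{Mult}(\sum_k \theta_{dk} \beta_{k\cdot})}.
#' The per-cell Dirichlet prior pseudo-counts \eqn{a_k = \tau q_k} follow the
#' tree's expected stick-breaking/switch occupancy ([node_prior_weights()]),
#' so `gamma_switch` controls how strongly cells are pulled toward deep
#' versus shallow nodes. Gene rows carry a symmetric Dirichlet `eta`
#' pseudo-count, keeping all distributions strictly positive.
#'
#' In `"one-batch"` mode every epoch performs a full E step and exact M
#' steps, and the recorded epoch objective (data log-likelihood plus the
#' Dirichlet pseudo-count terms, evaluated at the parameters entering the
#' epoch) never decreases. In `"mini-batch"` mode the gene-distribution
#' statistics follow stochastic natural-gradient updates with a constant
#' learning rate over seeded random batches.
#'
#' @param counts cell x gene UMI count matrix (raw counts, not proportions).
#' @param init starting values: an `init_result` from
#'   [initialize_gem_tree()] or a `gem_model` (e.g. from [warm_start()]).
#' @param config a [fit_config()].
#' @return A list of class `gem_fit` with `model` (a `gem_model`),
#'   `loadings` (a `cell_loadings` for the training cells) and `trace` (a
#'   `fit_trace` with `epoch_likelihoods`, `converged_at`, `settings`).
#' @export
fit_gem <- function(counts, init, config = fit_config()) {
  counts <- as_count_matrix(counts)
  if (nrow(counts) == 0 || sum(counts) == 0) stop("empty count matrix")
  if (inherits(init, "init_result")) {
    spec <- init$spec
    beta0 <- init$init_beta
  } else if (inherits(init, "gem_model")) {
    spec <- init$tree
    beta0 <- init$beta
  } else {
    stop("`init` must be an init_result or gem_model")
  }
  common <- intersect(colnames(counts), colnames(beta0))
  if (length(common) == 0) {
    stop("gene sets of counts and init do not overlap")
  }
  if (length(common) < ncol(counts) || length(common) < ncol(beta0)) {
    warning("restricting to ", length(common), " shared genes")
  }
  counts <- counts[, common, drop = FALSE]
  beta <- row_normalize(beta0[, common, drop = FALSE] + 1e-12)

  rng <- local_rng(config$seed)
  on.exit(rng(), add = TRUE)

  D <- nrow(counts); G <- ncol(counts); K <- spec$n_nodes
  a <- config$tau * node_prior_weights(spec, config$gamma_switch, config$tau)
  theta <- matrix(a / sum(a), D, K, byrow = TRUE)
  chunks <- make_chunks(counts)
  eta <- config$eta

  epoch_obj <- numeric(0)
  converged_at <- NA_integer_

  if (config$mode == "one-batch") {
    for (epoch in seq_len(config$max_epochs)) {
      pass <- em_pass(chunks, theta, beta, want_m = TRUE)
      obj <- penalized_objective(pass$loglik, theta, beta, a, eta)
      epoch_obj <- c(epoch_obj, obj)
      theta <- row_normalize(pass$n + matrix(a, D, K, byrow = TRUE))
      beta <- row_normalize(pass$m + eta)
      if (epoch >= 2 && abs(obj - epoch_obj[epoch - 1]) <
            config$conv_tol * abs(epoch_obj[epoch - 1])) {
        converged_at <- epoch
        break
      }
    }
  } else {
    lambda <- eta + (sum(counts) / K) * beta     # SVI state on gene stats
    rho <- config$learning_rate
    for (epoch in seq_len(config$max_epochs)) {
      perm <- sample.int(D)
      batch_starts <- seq(1L, D, by = config$batch_size)
      for (s in batch_starts) {
        cells <- perm[s:min(s + config$batch_size - 1L, D)]
        sub <- counts[cells, , drop = FALSE]
        th <- theta[cells, , drop = FALSE]
        bch <- make_chunks(sub)
        for (it in 1:10) {                       # fold-in for the batch
          p <- em_pass(bch, th, beta, want_m = FALSE)
          th <- row_normalize(p$n + matrix(a, nrow(th), K, byrow = TRUE))
        }
        p <- em_pass(bch, th, beta, want_m = TRUE)
        theta[cells, ] <- th
        lambda <- (1 - rho) * lambda + rho * (eta + (D / length(cells)) * p$m)
        beta <- row_normalize(lambda)
      }
      pass <- em_pass(chunks, theta, beta, want_m = FALSE)
      obj <- penalized_objective(pass$loglik, theta, beta, a, eta)
      epoch_obj <- c(epoch_obj, obj)
      theta <- row_normalize(pass$n + matrix(a, D, K, byrow = TRUE))
      if (epoch >= 2 && abs(obj - epoch_obj[epoch - 1]) <
            config$conv_tol * abs(epoch_obj[epoch - 1])) {
        converged_at <- epoch
        break
      }
    }
  }

  model <- gem_model(spec, beta, alpha = config$alpha, tau = config$tau,
                     eta = eta, gamma_switch = config$gamma_switch,
                     gene_names = colnames(counts))
  loadings <- make_cell_loadings(theta, spec, rownames(counts))
  trace <- structure(
    list(epoch_likelihoods = epoch_obj, converged_at = converged_at,
         settings = list(mode = config$mode,
                         learning_rate = config$learning_rate,
                         batch_size = config$batch_size,
                         seed = config$seed)),
    class = "fit_trace")
  structure(list(model = model, loadings = loadings, trace = trace),
            class = "gem_fit")
}

make_cell_loadings <- function(theta, spec, barcodes,
                               active_threshold = 1e-3) {
  rownames(theta) <- barcodes
  colnames(theta) <- as.character(seq_len(spec$n_nodes))
  active <- lapply(seq_len(nrow(theta)), function(d) {
    on <- which(theta[d, ] > active_threshold)
    sort(unique(c(on, unlist(lapply(on, ancestors, spec = spec)))))
  })
  names(active) <- barcodes
  structure(list(theta = theta, active_subtree = active),
            class = "cell_loadings")
}

#' Infer per-cell GEM loadings with frozen gene distributions
#'
#' Fold-in inference for held-out cells: only the per-cell loadings theta are
#' updated (by the same penalized EM as [fit_gem()]); the model's beta is
#' never modified. Cells with no counts on the model's genes get a uniform
#' distribution over the top-level nodes and are flagged.
#'
#' @param model a `gem_model`.
#' @param counts cell x gene count matrix; genes are matched by name to the
#'   model's vocabulary.
#' @param gamma_switch optional override of the model's switching parameter
#'   for the fold-in prior.
#' @param max_iter,tol fold-in EM iteration controls.
#' @return A `cell_loadings`: `theta` (cells x nodes, rows on the simplex)
#'   and `active_subtree` (per-cell node sets closed under the parent
#'   relation); attribute `"flagged_cells"` lists cells with no usable
#'   counts.
#' @export
infer_loadings <- function(model, counts, gamma_switch = NULL,
                           max_iter = 200L, tol = 1e-10) {
  stopifnot(inherits(model, "gem_model"))
  counts <- as_count_matrix(counts)
  common <- intersect(colnames(counts), colnames(model$beta))
  if (length(common) == 0) {
    stop("gene sets of model and counts do not overlap")
  }
  counts <- counts[, common, drop = FALSE]
  beta <- row_normalize(model$beta[, common, drop = FALSE])
  spec <- model$tree
  K <- spec$n_nodes
  if (is.null(gamma_switch)) gamma_switch <- model$gamma_switch
  a <- model$tau * node_prior_weights(spec, gamma_switch, model$tau)

  D <- nrow(counts)
  flagged <- as.integer(which(Matrix::rowSums(counts) == 0))
  theta <- matrix(a / sum(a), D, K, byrow = TRUE)
  chunks <- make_chunks(counts)
  A <- matrix(a, D, K, byrow = TRUE)
  prev <- -Inf
  for (it in seq_len(max_iter)) {
    pass <- em_pass(chunks, theta, beta, want_m = FALSE)
    theta <- row_normalize(pass$n + A)
    if (it >= 2 && abs(pass$loglik - prev) <=
          tol * max(1, abs(prev))) break
    prev <- pass$loglik
  }
  if (length(flagged)) {
    top <- level_nodes(spec, 1L)
    theta[flagged, ] <- 0
    theta[flagged, top] <- 1 / length(top)
  }
  out <- make_cell_loadings(theta, spec, rownames(counts))
  attr(out, "flagged_cells") <- flagged
  out
}
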