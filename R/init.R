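#' L1 (k-medians) clustering
#'
#' KMeans under the L1 norm: assignments minimize L1 distance to their
#' centroid and each centroid is the element-wise median of its assigned rows
#' (the exact L1 minimizer). Seeding is kmeans++-style adapted to L1
#' distance. Empty clusters are re-seeded from the row farthest (L1) from its
#' current centroid. The L1 objective is preferred over L2 here because it is
#' less sensitive to the heavy-tailed sparsity of single-cell proportion
#' vectors.
#'
#' @param X numeric matrix, rows are observations.
#' @param k number of clusters, `1 <= k <= nrow(X)`.
#' @param max_iter maximum alternation steps.
#' @param tol stop when the total L1 cost improves by less than `tol`
#'   relative to its magnitude.
#' @param seed integer seed; identical inputs and seed give identical output.
#' @param weights optional non-negative row weights: centroids become
#'   weighted element-wise medians and the objective a weighted L1 cost
#'   (rows with zero weight are still assigned but do not shape centroids).
#' @param nstart number of seeded restarts; the solution with the lowest
#'   cost is kept.
#' @return A list with `centroids` (k x ncol(X)), `assignments` (length
#'   nrow(X)) and `cost` (total L1 distance).
#' @export
l1_kmeans <- function(X, k, max_iter = 50L, tol = 1e-6, seed = 1L,
                      weights = NULL, nstart = 3L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k < 1L) stop("`k` must be >= 1")
  if (k > n) stop("`k` (", k, ") exceeds the number of rows (", n, ")")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0)) {
    stop("`weights` must be non-negative, one per row")
  }
  if (all(weights == 0)) weights <- rep(1, n)
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)

  best <- NULL
  for (start in seq_len(nstart)) {
    centroids <- X[l1pp_seed(X, k, weights), , drop = FALSE]
    prev_cost <- Inf
    assignments <- rep(1L, n)
    cost <- Inf
    for (iter in seq_len(max_iter)) {
      D <- l1_dist(X, centroids)          # n x k
      assignments <- max.col(-D, ties.method = "first")
      # re-seed empty clusters from the worst-fit rows
      taken <- rep(FALSE, n)
      for (j in which(tabulate(assignments, k) == 0L)) {
        cand <- weights * D[cbind(seq_len(n), assignments)]
        cand[taken] <- -Inf
        worst <- which.max(cand)
        assignments[worst] <- j
        taken[worst] <- TRUE
      }
      cost <- sum(weights * D[cbind(seq_len(n), assignments)])
      if (prev_cost - cost < tol * max(1, abs(cost))) break
      prev_cost <- cost
      for (j in seq_len(k)) {
        rows <- which(assignments == j)
        centroids[j, ] <- col_weighted_median(X, rows, weights[rows])
      }
    }
    if (is.null(best) || cost < best$cost) {
      best <- list(centroids = unname(centroids),
                   assignments = assignments, cost = cost)
    }
  }
  best
}

# column-wise weighted median over a row subset (compiled); the weighted L1
# minimizer per coordinate, reducing to stats::median for equal weights
col_weighted_median <- function(M, rows, w) {
  if (sum(w) <= 0) w <- rep(1, length(rows))
  cpp_col_weighted_median(M, as.integer(rows), as.numeric(w))
}

# pairwise L1 distances between rows of X and rows of C (compiled)
l1_dist <- function(X, C) {
  cpp_l1_dist(X, C)
}

# kmeans++ seeding with L1 distances (assumes RNG already set by caller)
l1pp_seed <- function(X, k, weights = rep(1, nrow(X))) {
  n <- nrow(X)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1L, prob = if (sum(weights) > 0) weights else NULL)
  if (k == 1L) return(idx)
  d2 <- l1_dist(X, X[idx[1], , drop = FALSE])[, 1]
  for (j in 2:k) {
    p <- weights * d2
    if (sum(p) <= 0) {
      pool <- setdiff(seq_len(n), idx[seq_len(j - 1L)])
      idx[j] <- pool[sample.int(length(pool), 1L)]
    } else {
      idx[j] <- sample.int(n, 1L, prob = p)
    }
    d2 <- pmin(d2, l1_dist(X, X[idx[j], , drop = FALSE])[, 1])
  }
  idx
}

# run code under a temporary seed, restoring the caller's RNG state
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  set.seed(seed)
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

#' Remove a centroid's explainable mass from a proportion vector
#'
#' The "information breaking" step between tree levels: the centroid is
#' renormalized to the simplex, the overlap coefficient
#' \eqn{c = \sum_g \min(x_g, \hat\Theta_g)} measures how much of the cell the
#' centroid can explain, and the residual
#' \eqn{r = \max(0, x - c\,\hat\Theta)} is renormalized. A residual of all
#' zeros (the centroid explains everything) is returned as zeros with
#' attribute `exhausted = TRUE`.
#'
#' @param x gene-proportion vector (on the simplex, or all zero).
#' @param centroid non-negative gene vector.
#' @return Residual proportion vector, same length as `x`.
#' @export
break_information <- function(x, centroid) {
  if (length(x) != length(centroid)) stop("length mismatch")
  s <- sum(centroid)
  if (s <= 0) {
    r <- x
    attr(r, "exhausted") <- FALSE
    attr(r, "unexplained") <- sum(x)
    return(r)
  }
  ch <- centroid / s
  ovl <- sum(pmin(x, ch))
  r <- pmax(0, x - ovl * ch)
  tot <- sum(r)
  if (tot <= 0) {
    r <- numeric(length(x))
    attr(r, "exhausted") <- TRUE
  } else {
    r <- r / tot
    attr(r, "exhausted") <- FALSE
  }
  attr(r, "unexplained") <- tot
  r
}

#' Initialize per-node gene distributions by recursive L1 k-medians
#'
#' Top-down tree initialization: a seeded subsample of cells is clustered
#' into the top-level nodes with [l1_kmeans()]; within each node, every
#' assigned cell is residualized against the node centroid with
#' [break_information()] and the residuals are clustered into that node's
#' children; this repeats level by level to the leaves (a single top-down
#' pass — residualization makes repeated sweeps ill-defined). Centroids are
#' smoothed and renormalized into strictly positive gene distributions
#' suitable as starting values for [fit_gem()].
#'
#' @param props cell x gene proportion matrix (see
#'   [normalize_proportions()]).
#' @param spec a `tree_spec`.
#' @param train_size number of cells to subsample (<= nrow(props)).
#' @param seed integer seed.
#' @param smoothing small constant added to centroids before renormalizing
#'   (keeps downstream logs finite).
#' @return A list of class `init_result` with `init_beta` (node x gene, rows
#'   on the simplex, strictly positive), `centroids` (raw, node x gene) and
#'   `assignments` (level-indexed list mapping each sampled cell to its node
#'   at that level).
#' @export
initialize_gem_tree <- function(props, spec, train_size = nrow(props),
                                seed = 1L, smoothing = 1e-6) {
  stopifnot(inherits(spec, "tree_spec"))
  props <- as.matrix(props)
  if (train_size > nrow(props)) {
    stop("`train_size` exceeds the number of cells")
  }
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)

  sampled <- sort(sample.int(nrow(props), train_size))
  X <- props[sampled, , drop = FALSE]
  G <- ncol(props)
  L <- length(spec$branching)
  centroids <- matrix(0, spec$n_nodes, G)
  assign_by_level <- vector("list", L)
  # node assignment of each sampled cell at the current level
  node_of <- rep(NA_integer_, nrow(X))
  resid <- X                                # residual proportions, updated
  # fraction of each cell's original mass still unexplained; residualized
  # cells that their centroids explain fully carry no information about
  # deeper structure, so they are down-weighted when clustering children
  resid_mass <- rep(1, nrow(X))

  cluster_into <- function(rows, kids, resid, w) {
    k <- length(kids)
    sub <- resid[rows, , drop = FALSE]
    if (length(rows) < k) {
      # too few cells to split: perturb the parent residual mean
      base <- if (length(rows) > 0) colMeans(sub) else rep(1 / G, G)
      cen <- matrix(rep(base, each = k), k, G)
      cen <- cen * matrix(stats::runif(k * G, 0.5, 1.5), k, G)
      asg <- rep(seq_len(k), length.out = length(rows))
      message("node with ", length(rows), " cells split into ", k,
              " children by perturbation")
      return(list(centroids = cen, assignments = asg))
    }
    km <- l1_kmeans(sub, k, seed = stats::runif(1) * 1e8, weights = w)
    list(centroids = km$centroids, assignments = km$assignments)
  }

  for (l in seq_len(L)) {
    new_node <- rep(NA_integer_, nrow(X))
    if (l == 1L) {
      top <- level_nodes(spec, 1L)
      res <- cluster_into(seq_len(nrow(X)), top, resid, resid_mass)
      centroids[top, ] <- res$centroids
      new_node <- top[res$assignments]
    } else {
      for (parent in level_nodes(spec, l - 1L)) {
        rows <- which(node_of == parent)
        kids <- spec$children[[parent]]
        res <- cluster_into(rows, kids, resid, resid_mass[rows])
        centroids[kids, ] <- res$centroids
        if (length(rows) > 0L) new_node[rows] <- kids[res$assignments]
      }
    }
    # residualize each cell against its newly assigned node's centroid
    for (i in seq_len(nrow(X))) {
      if (!is.na(new_node[i])) {
        r <- break_information(resid[i, ], centroids[new_node[i], ])
        resid_mass[i] <- resid_mass[i] * attr(r, "unexplained")
        resid[i, ] <- r
      }
    }
    node_of <- new_node
    assign_by_level[[l]] <- stats::setNames(node_of, rownames(X))
  }

  init_beta <- centroids + smoothing
  init_beta <- init_beta / rowSums(init_beta)
  colnames(init_beta) <- colnames(props)
  rownames(init_beta) <- as.character(seq_len(spec$n_nodes))
  structure(
    list(init_beta = init_beta, centroids = centroids,
         assignments = assign_by_level, sampled_cells = sampled, spec = spec),
    class = "init_result"
  )
}
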