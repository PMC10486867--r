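#' Stick-breaking weights
#'
#' Turns a vector of break fractions \eqn{\pi_i \in (0, 1]} into Dirichlet
#' process atom weights \eqn{w_i = \pi_i \prod_{j<i} (1 - \pi_j)}. The
#' remainder \eqn{\prod_j (1 - \pi_j)} is the unbroken stick mass left after
#' truncation.
#'
#' @param breaks numeric vector with all entries in (0, 1].
#' @return A list of class `stick_weights` with `breaks`, `weights` and
#'   `remainder`; `sum(weights) + remainder == 1` to machine precision.
#' @examples
#' stick_breaking_weights(c(0.5, 0.5, 0.5))$weights  # 0.5 0.25 0.125
#' @export
stick_breaking_weights <- function(breaks) {
  breaks <- as.numeric(breaks)
  if (length(breaks) == 0 || any(!is.finite(breaks)) ||
      any(breaks <= 0) || any(breaks > 1)) {
    stop("all break fractions must lie in (0, 1]")
  }
  stick_left <- cumprod(c(1, 1 - breaks[-length(breaks)]))
  weights <- breaks * stick_left
  remainder <- prod(1 - breaks)
  structure(list(breaks = breaks, weights = weights, remainder = remainder),
            class = "stick_weights")
}

#' Chinese restaurant process predictive probabilities
#'
#' Predictive distribution of a Dirichlet process after n draws: a new atom is
#' chosen with probability \eqn{\alpha / (\alpha + n)} and existing atom i
#' with probability \eqn{n_i / (\alpha + n)}.
#'
#' @param alpha DP concentration, > 0.
#' @param occupancy named numeric vector of non-negative atom counts.
#' @return Named numeric probability vector; first element `"new"`, then one
#'   entry per existing atom. Sums to 1.
#' @examples
#' crp_next_probabilities(1, c(a = 2, b = 1))  # new 0.25, a 0.5, b 0.25
#' @export
crp_next_probabilities <- function(alpha, occupancy = numeric(0)) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0) {
    stop("`alpha` must be a positive scalar")
  }
  occupancy <- stats::setNames(as.numeric(occupancy), names(occupancy))
  if (any(occupancy < 0)) stop("occupancy counts must be >= 0")
  n <- sum(occupancy)
  p <- c(new = alpha / (alpha + n), occupancy / (alpha + n))
  p
}

#' Expected truncated stick-breaking weights among k siblings
#'
#' Under breaks ~ Beta(1, tau) the expected weight of the i-th stick is
#' (1/(1+tau)) * (tau/(1+tau))^(i-1); truncated to k atoms and renormalized.
#' Sibling order follows node id (the package's fixed tie-break).
#'
#' @keywords internal
expected_sibling_weights <- function(k, tau) {
  w <- (1 / (1 + tau)) * (tau / (1 + tau))^(seq_len(k) - 1)
  w / sum(w)
}

#' Expected node occupancy prior over a tree
#'
#' Distributes unit mass over the tree: each top-level node receives its
#' expected sibling stick weight; an internal node at level l < L keeps a
#' fraction (1 - gamma) of its arriving mass and passes gamma down to its
#' children, again split by expected sibling weights; leaves keep everything
#' that arrives. The result sums to 1 and is the mean of the generative
#' path-plus-stick construction, used as the per-cell Dirichlet prior
#' direction during inference.
#'
#' @param spec a `tree_spec`.
#' @param gamma_switch depth-switching probability in (0, 1); lower values
#'   concentrate prior mass on higher tree levels.
#' @param tau stick-breaking concentration, > 0.
#' @return Numeric vector of length `total_nodes(spec)` summing to 1.
#' @export
node_prior_weights <- function(spec, gamma_switch, tau) {
  stopifnot(inherits(spec, "tree_spec"))
  if (gamma_switch <= 0 || gamma_switch >= 1) {
    stop("`gamma_switch` must lie strictly in (0, 1)")
  }
  if (tau <= 0) stop("`tau` must be > 0")
  L <- length(spec$branching)
  arriving <- numeric(spec$n_nodes)
  top <- level_nodes(spec, 1L)
  arriving[top] <- expected_sibling_weights(length(top), tau)
  q <- numeric(spec$n_nodes)
  for (l in seq_len(L)) {
    ids <- level_nodes(spec, l)
    if (l < L) {
      q[ids] <- arriving[ids] * (1 - gamma_switch)
      for (id in ids) {
        kids <- spec$children[[id]]
        arriving[kids] <- arriving[id] * gamma_switch *
          expected_sibling_weights(length(kids), tau)
      }
    } else {
      q[ids] <- arriving[ids]
    }
  }
  q
}
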