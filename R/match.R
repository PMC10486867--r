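#' Optimal one-to-one matching of fitted and reference topics
#'
#' Solves the linear assignment problem maximizing the total pairwise
#' similarity (Hungarian algorithm, shortest-augmenting-path formulation,
#' O(n^3)). Used to compare a fitted set of gene distributions against a
#' planted ground truth without rewarding two fitted rows for explaining the
#' same reference row.
#'
#' @param similarity square numeric matrix; entry (i, j) scores pairing
#'   fitted row i with reference row j.
#' @return Integer vector `match` with `match[i]` = reference column
#'   assigned to fitted row i; attribute `"total"` holds the achieved total
#'   similarity.
#' @export
match_topics <- function(similarity) {
  similarity <- as.matrix(similarity)
  if (nrow(similarity) != ncol(similarity)) {
    stop("similarity matrix must be square")
  }
  m <- hungarian_min(max(similarity) - similarity)
  attr(m, "total") <- sum(similarity[cbind(seq_along(m), m)])
  m
}

# minimum-cost assignment; returns match[i] = column for row i
hungarian_min <- function(cost) {
  n <- nrow(cost)
  u <- numeric(n)            # row potentials
  v <- numeric(n + 1L)       # column potentials, slot n+1 = virtual column
  p <- integer(n + 1L)       # p[j] = row currently assigned to column j
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[n + 1L] <- i
    j0 <- n + 1L
    minv <- rep(Inf, n)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j]) {
          cur <- cost[i0, j] - u[i0] - v[j]
          if (cur < minv[j]) {
            minv[j] <- cur
            way[j] <- j0
          }
          if (minv[j] < delta) {
            delta <- minv[j]
            j1 <- j
          }
        }
      }
      for (j in seq_len(n + 1L)) {
        if (used[j]) {
          u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == n + 1L) break
    }
  }
  match <- integer(n)
  match[p[seq_len(n)]] <- seq_len(n)
  match
}

#' Mean matched cosine similarity between two sets of gene distributions
#'
#' Convenience wrapper: computes all pairwise cosine similarities between
#' rows of `fitted` and rows of `reference`, finds the optimal one-to-one
#' matching with [match_topics()], and returns the mean similarity of the
#' matched pairs — the package's standard topic-recovery score.
#'
#' @param fitted,reference matrices with the same shape, rows are gene
#'   distributions.
#' @return Scalar mean cosine over matched pairs, with the matching as
#'   attribute `"match"`.
#' @export
mean_matched_cosine <- function(fitted, reference) {
  fitted <- as.matrix(fitted)
  reference <- as.matrix(reference)
  stopifnot(nrow(fitted) == nrow(reference))
  S <- matrix(0, nrow(fitted), nrow(reference))
  for (i in seq_len(nrow(fitted))) {
    for (j in seq_len(nrow(reference))) {
      S[i, j] <- cosine_similarity(as.numeric(fitted[i, ]),
                                   as.numeric(reference[j, ]))
    }
  }
  m <- match_topics(S)
  out <- mean(S[cbind(seq_along(m), m)])
  attr(out, "match") <- m
  out
}
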