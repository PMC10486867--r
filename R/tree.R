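#' Build a preset GEM tree structure
#'
#' Constructs the finite tree on which gene co-expressing modules (GEMs) are
#' organized. `branching` gives the number of children per node at each level:
#' `c(5, 4, 3)` means five top-level GEMs, four children under each of those,
#' and three children under each second-level GEM (85 nodes in total). Node
#' ids are assigned level-by-level, left-to-right, starting at 1, so outputs
#' are stable across runs.
#'
#' @param branching integer vector of per-level branching factors, all >= 1.
#' @return An object of class `tree_spec`: a list with `branching`, `n_nodes`,
#'   `level` (node -> level, 1-based), `parent` (node -> parent id, `NA` for
#'   top-level nodes) and `children` (list of integer vectors per node).
#' @examples
#' spec <- build_tree_spec(c(5, 4, 3))
#' total_nodes(spec)  # 85
#' @export
build_tree_spec <- function(branching) {
  if (length(branching) == 0) {
    stop("`branching` must be a non-empty vector of positive integers")
  }
  branching <- as.integer(branching)
  if (anyNA(branching) || any(branching < 1)) {
    stop("all entries of `branching` must be positive integers")
  }
  L <- length(branching)
  per_level <- as.integer(cumprod(branching))  # nodes on each level
  n_nodes <- as.integer(sum(per_level))
  level_start <- as.integer(cumsum(c(1L, per_level[-L])))  # first id per level

  level <- rep.int(seq_len(L), per_level)
  parent <- rep(NA_integer_, n_nodes)
  children <- vector("list", n_nodes)
  for (l in seq_len(L)) {
    ids <- level_start[l] + seq_len(per_level[l]) - 1L
    if (l > 1L) {
      # children on level l are laid out in blocks of branching[l] per parent
      parent[ids] <- as.integer(level_start[l - 1L] +
        (seq_len(per_level[l]) - 1L) %/% branching[l])
    }
    if (l < L) {
      kids <- level_start[l + 1L] + seq_len(per_level[l + 1L]) - 1L
      children[ids] <- split(kids, (seq_along(kids) - 1L) %/% branching[l + 1L])
    } else {
      children[ids] <- list(integer(0))
    }
  }
  structure(
    list(branching = branching, n_nodes = n_nodes, level = level,
         parent = parent, children = children),
    class = "tree_spec"
  )
}

#' Total number of nodes (GEMs) in a tree
#'
#' @param spec a `tree_spec`.
#' @return Integer node count, \eqn{\sum_l \prod_{m \le l} branching[m]}.
#' @export
total_nodes <- function(spec) {
  stopifnot(inherits(spec, "tree_spec"))
  spec$n_nodes
}

#' Root-to-parent ancestor path of a node
#'
#' @param spec a `tree_spec`.
#' @param node a node id in `1..total_nodes(spec)`.
#' @return Integer vector of ancestor ids ordered from the top-level root down
#'   to the node's parent; empty for top-level nodes.
#' @export
ancestors <- function(spec, node) {
  stopifnot(inherits(spec, "tree_spec"))
  node <- as.integer(node)
  if (length(node) != 1L || is.na(node) || node < 1L || node > spec$n_nodes) {
    stop("unknown node id: ", node)
  }
  path <- integer(0)
  p <- spec$parent[node]
  while (!is.na(p)) {
    path <- c(p, path)
    p <- spec$parent[p]
  }
  path
}

#' Node ids on a given level
#' @param spec a `tree_spec`.
#' @param l level in `1..length(spec$branching)`.
#' @return Integer vector of node ids.
#' @export
level_nodes <- function(spec, l) {
  stopifnot(inherits(spec, "tree_spec"))
  which(spec$level == as.integer(l))
}

#' @export
print.tree_spec <- function(x, ...) {
  cat("GEM tree: ", paste(x$branching, collapse = "-"),
      " (", x$n_nodes, " nodes, ", length(x$branching), " levels)\n", sep = "")
  invisible(x)
}

#' Serialize / restore a tree structure as JSON
#'
#' @param spec a `tree_spec`.
#' @param path file to write.
#' @return `write_tree_spec` returns `path` invisibly; `read_tree_spec`
#'   returns the reconstructed `tree_spec`.
#' @export
write_tree_spec <- function(spec, path) {
  stopifnot(inherits(spec, "tree_spec"))
  jsonlite::write_json(
    list(branching = spec$branching, version = 1L),
    path, auto_unbox = FALSE
  )
  invisible(path)
}

#' @rdname write_tree_spec
#' @export
read_tree_spec <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  build_tree_spec(obj$branching)
}
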