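# independent scalar-loop oracle for the predictive likelihood
loop_loglik <- function(theta, beta, counts) {
  total <- 0
  for (d in seq_len(nrow(counts))) {
    for (g in seq_len(ncol(counts))) {
      if (counts[d, g] > 0) {
        p <- 0
        for (k in seq_len(ncol(theta))) p <- p + theta[d, k] * beta[k, g]
        total <- total + counts[d, g] * log(p)
      }
    }
  }
  total
}

test_that("predictive log-likelihood matches the scalar-loop oracle", {
  # one cell, counts (3, 1), mixture probs (0.8, 0.2)
  theta1 <- matrix(1, 1, 1)
  beta1 <- matrix(c(0.8, 0.2), 1, 2)
  counts1 <- small_counts(c(3, 1), 1, 2)
  expect_equal(test_log_likelihood(theta1, beta1, counts1),
               3 * log(0.8) + 1 * log(0.2))
  # all-zero counts
  expect_equal(test_log_likelihood(theta1, beta1, small_counts(c(0, 0), 1, 2)),
               0)
  # 2-cell worked instance against the oracle
  theta2 <- matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE)
  beta2 <- matrix(c(0.8, 0.2, 0.5, 0.5), 2, 2, byrow = TRUE)
  counts2 <- small_counts(c(3, 1, 2, 2), 2, 2)
  expect_equal(test_log_likelihood(theta2, beta2, counts2),
               loop_loglik(theta2, beta2, counts2), tolerance = 1e-12)
  # random instances against the oracle
  set.seed(8)
  for (i in 1:5) {
    D <- 4; G <- 7; K <- 3
    theta <- matrix(rexp(D * K), D); theta <- theta / rowSums(theta)
    beta <- matrix(rexp(K * G), K); beta <- beta / rowSums(beta)
    counts <- small_counts(rpois(D * G, 2), D, G)
    expect_equal(test_log_likelihood(theta, beta, counts),
                 loop_loglik(theta, beta, as.matrix(counts)),
                 tolerance = 1e-12)
  }
})

test_that("perplexity closed forms: uniform model gives G, perfect gives 1", {
  D <- 5; G <- 12; K <- 3
  set.seed(9)
  counts <- small_counts(rpois(D * G, 3) + 1, D, G)
  theta <- matrix(1 / K, D, K)
  beta_unif <- matrix(1 / G, K, G)
  expect_equal(perplexity(theta, beta_unif, counts), G, tolerance = 1e-12)
  # probability 1 on every observed gene: one gene per cell
  one_gene <- small_counts(c(4, 0, 0, 5), 2, 2)
  th <- matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE)
  be <- matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE)
  expect_equal(perplexity(th, be, one_gene), 1)
  # 2-cell worked instance (8 tokens): exp(-L/8) with L from the oracle
  theta2 <- matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE)
  beta2 <- matrix(c(0.8, 0.2, 0.5, 0.5), 2, 2, byrow = TRUE)
  counts2 <- small_counts(c(3, 1, 2, 2), 2, 2)
  expect_equal(perplexity(theta2, beta2, counts2),
               exp(-loop_loglik(theta2, beta2, counts2) / 8),
               tolerance = 1e-12)
  expect_error(perplexity(theta2, beta2, small_counts(rep(0, 4), 2, 2)),
               "token")
})

test_that("perplexity of a proper mixture lies in [1, G]", {
  fx <- tiny_planted(branching = c(2, 2), n_genes = 90, n_cells = 60)
  model <- gem_model(fx$spec, fx$beta + 1e-8)
  th <- infer_loadings(model, fx$counts)
  p <- perplexity(th, model, fx$counts)
  expect_gte(p, 1)
  expect_lte(p, ncol(fx$counts))
})

test_that("PMI matches its closed form and is symmetric", {
  expect_equal(pmi(0.25, 0.5, 0.5), 0)         # independence
  expect_equal(pmi(0.5, 0.5, 0.5), log(2))     # perfect co-occurrence
  expect_equal(pmi(0.1, 0.4, 0.5), log(0.5))
  expect_equal(pmi(0.1, 0.4, 0.5), pmi(0.1, 0.5, 0.4))
  expect_error(pmi(0.1, 0, 0.5), "> 0")
})

test_that("topic coherence hits the perfectly co-occurring closed form", {
  # top genes present together in exactly half the cells
  n_top <- 6; D <- 40
  counts <- matrix(0L, D, 10)
  counts[1:20, 1:n_top] <- 1L
  counts[, 7:10] <- 1L                           # filler genes everywhere
  counts <- as_count_matrix(counts)
  beta_row <- setNames(c(rep(0.15, n_top), rep(0.001, 4)),
                       colnames(counts))
  co <- topic_coherence(beta_row, counts, coherence_config(top_n = n_top))
  expect_equal(co, choose(n_top, 2) * log(2), tolerance = 1e-6)
  # single pair with p_i = p_j = p_joint = 0.5
  co2 <- topic_coherence(beta_row[1:2], counts[, 1:2],
                         coherence_config(top_n = 2))
  expect_equal(co2, log(2), tolerance = 1e-6)
})

test_that("independent genes give near-zero coherence at large n", {
  set.seed(10)
  D <- 10000
  rates <- runif(8, 0.2, 0.8)
  counts <- sapply(rates, function(r) rbinom(D, 1, r))
  counts <- as_count_matrix(counts)
  beta_row <- setNames(rep(1 / 8, 8), colnames(counts))
  co <- topic_coherence(beta_row, counts, coherence_config(top_n = 8))
  expect_lt(abs(co) / choose(8, 2), 0.05)        # mean |PMI| small
})

test_that("coherence is invariant under cell permutation", {
  fx <- tiny_planted(n_genes = 50, n_cells = 80)
  beta_row <- fx$beta[1, ]
  set.seed(11)
  perm <- sample(nrow(fx$counts))
  expect_equal(
    topic_coherence(beta_row, fx$counts, coherence_config(top_n = 10)),
    topic_coherence(beta_row, fx$counts[perm, ], coherence_config(top_n = 10)))
})

test_that("top_genes sorts by weight with stable tie-breaking", {
  w <- c(a = 0.1, b = 0.7, c = 0.2)
  expect_identical(top_genes(w, 2), c("b", "c"))
  ties <- c(x = 0.25, y = 0.25, z = 0.25, w = 0.25)
  expect_identical(top_genes(ties, 3), c("x", "y", "z"))
  expect_setequal(top_genes(w, 3), names(w))
  expect_error(top_genes(w, 4), "1..3")
})

test_that("cosine similarity handles vectors and gene sets", {
  expect_equal(cosine_similarity(c("a", "b"), c("a", "b")), 1)
  expect_equal(cosine_similarity(c("a", "b"), c("c", "d")), 0)
  s150 <- paste0("g", 1:150)
  t150 <- c(paste0("g", 1:75), paste0("h", 1:75))
  expect_equal(cosine_similarity(s150, t150), 0.5)
  expect_equal(cosine_similarity(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero vector")
})

test_that("GEM similarity matrices behave on planted supports", {
  spec <- build_tree_spec(c(2, 2))
  beta <- make_beta_true(spec, 240, parent_share = 0, seed = 12)
  model <- gem_model(spec, beta + 1e-12)
  gg <- gem_similarity_matrix(model, top_n = 40)
  expect_equal(unname(diag(gg)), rep(1, 6))
  expect_equal(gg, t(gg))
  # marker set equal to a GEM's top genes scores 1
  mk <- list(self = top_genes(model$beta[3, ], 40))
  ms <- gem_similarity_matrix(model, mk, top_n = 40)
  expect_equal(unname(ms["3", "self"]), 1)
  # disjoint-support siblings share exactly the genes neither owns: with
  # parent_share = 0 and 40 = the per-node block size, sibling overlap is 0
  expect_equal(unname(gg["3", "4"]), 0)
  expect_error(gem_similarity_matrix(model, list(bad = character(0))),
               "empty marker set")
})

test_that("GMT export round-trips the top gene lists", {
  spec <- build_tree_spec(c(3, 2, 2))
  beta <- make_beta_true(spec, 210, seed = 13)
  model <- gem_model(spec, beta + 1e-9)
  path <- withr::local_tempfile(fileext = ".gmt")
  export_gene_sets(model, path, n = 5)
  sets <- read_gene_sets(path)
  expect_length(sets, 21)
  for (k in seq_len(21)) {
    expect_identical(sets[[paste0("GEM_", k)]], top_genes(model$beta[k, ], 5))
  }
  export_gene_sets(model, path, n = 1)
  one <- read_gene_sets(path)
  for (k in seq_len(21)) {
    expect_identical(one[[k]],
                     colnames(model$beta)[which.max(model$beta[k, ])])
  }
})

test_that("topic matching recovers a known permutation", {
  set.seed(14)
  ref <- matrix(rexp(8 * 30), 8); ref <- ref / rowSums(ref)
  perm <- sample(8)
  fitted <- ref[perm, ]
  m <- match_topics(outer(1:8, 1:8, Vectorize(function(i, j) {
    cosine_similarity(fitted[i, ], ref[j, ])
  })))
  expect_equal(m, perm, ignore_attr = TRUE)
  expect_equal(as.numeric(mean_matched_cosine(fitted, ref)), 1)
})
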