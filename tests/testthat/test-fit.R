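test_that("single-node model degenerates to the corpus distribution", {
  fx <- tiny_planted(branching = c(1), n_genes = 60, n_cells = 100)
  init <- initialize_gem_tree(normalize_proportions(fx$counts), fx$spec,
                              seed = 1)
  f <- fit_gem(fx$counts, init, fit_config(max_epochs = 50, seed = 2))
  expect_equal(unname(f$loadings$theta[, 1]), rep(1, 100))
  empirical <- Matrix::colSums(fx$counts) / sum(fx$counts)
  # beta is the eta-smoothed empirical corpus distribution
  eta <- 0.01
  smoothed <- (Matrix::colSums(fx$counts) + eta) /
    (sum(fx$counts) + eta * ncol(fx$counts))
  expect_equal(as.numeric(f$model$beta[1, ]), as.numeric(smoothed),
               tolerance = 1e-6)
  expect_gt(cosine_similarity(as.numeric(f$model$beta[1, ]),
                              as.numeric(empirical)), 0.999)
})

test_that("one-batch training objective is non-decreasing on random fixtures", {
  for (s in 1:5) {
    fx <- tiny_planted(branching = c(2, 2), n_genes = 80, n_cells = 120,
                       seed = 30 + s)
    init <- initialize_gem_tree(normalize_proportions(fx$counts), fx$spec,
                                seed = s)
    f <- fit_gem(fx$counts, init,
                 fit_config(max_epochs = 25, conv_tol = 1e-9, seed = s))
    obj <- f$trace$epoch_likelihoods
    expect_true(all(diff(obj) >= -1e-6 * abs(obj[-length(obj)])))
  }
})

test_that("beta and theta rows stay on the simplex after fitting", {
  fx <- tiny_planted()
  init <- initialize_gem_tree(normalize_proportions(fx$counts), fx$spec,
                              seed = 3)
  for (mode in c("one-batch", "mini-batch")) {
    f <- fit_gem(fx$counts, init,
                 fit_config(mode = mode, batch_size = 64, max_epochs = 8,
                            seed = 4))
    expect_equal(rowSums(f$model$beta), rep(1, fx$spec$n_nodes),
                 ignore_attr = TRUE, tolerance = 1e-9)
    expect_equal(rowSums(f$loadings$theta), rep(1, nrow(fx$counts)),
                 ignore_attr = TRUE, tolerance = 1e-9)
    expect_true(all(f$model$beta > 0))
  }
})

test_that("active subtrees are closed under the parent relation", {
  fx <- tiny_planted(branching = c(2, 2))
  init <- initialize_gem_tree(normalize_proportions(fx$counts), fx$spec,
                              seed = 6)
  f <- fit_gem(fx$counts, init, fit_config(max_epochs = 15, seed = 7))
  for (sub in f$loadings$active_subtree[1:50]) {
    for (k in sub) {
      expect_true(all(ancestors(fx$spec, k) %in% sub))
    }
  }
})

test_that("planted gene distributions are recovered on an easy corpus", {
  fx <- tiny_planted(branching = c(2, 2), n_genes = 240, n_cells = 800,
                     parent_share = 0.25, seed = 40)
  init <- initialize_gem_tree(normalize_proportions(fx$counts), fx$spec,
                              seed = 41)
  f <- fit_gem(fx$counts, init,
               fit_config(max_epochs = 80, conv_tol = 1e-6, seed = 42))
  expect_gte(as.numeric(mean_matched_cosine(f$model$beta, fx$beta)), 0.8)
})

test_that("fold-in inference is deterministic and leaves beta frozen", {
  fx <- tiny_planted()
  model <- gem_model(fx$spec, fx$beta + 1e-8)
  beta_before <- model$beta
  a <- infer_loadings(model, fx$counts)
  b <- infer_loadings(model, fx$counts)
  expect_identical(a, b)
  expect_identical(model$beta, beta_before)
  expect_equal(rowSums(a$theta), rep(1, nrow(fx$counts)),
               ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("a cell supported by one leaf path loads that path heavily", {
  spec <- build_tree_spec(c(2, 2))
  # disjoint supports per node so a pure-path cell is unambiguous
  beta <- make_beta_true(spec, 120, parent_share = 0, seed = 50)
  model <- gem_model(spec, beta + 1e-9)
  path <- c(1, 3)
  prob <- 0.5 * beta[1, ] + 0.5 * beta[3, ]
  set.seed(51)
  x <- rmultinom(1, 2000, prob)[, 1]
  counts <- as_count_matrix(matrix(x, 1, 120),
                            gene_names = colnames(beta), barcodes = "cell1")
  th <- infer_loadings(model, counts)
  expect_gte(sum(th$theta[1, path]), 0.99)
})

test_that("zero-overlap cells fall back to uniform top-level loadings", {
  fx <- tiny_planted(branching = c(2, 2))
  model <- gem_model(fx$spec, fx$beta + 1e-8)
  counts <- rbind(fx$counts[1:2, ], 0)
  rownames(counts) <- c("a", "b", "empty")
  th <- infer_loadings(model, as_count_matrix(counts))
  expect_identical(attr(th, "flagged_cells"), 3L)
  expect_equal(unname(th$theta["empty", level_nodes(fx$spec, 1)]),
               c(0.5, 0.5))
  expect_error(infer_loadings(model, small_counts(1:4, 2, 2,
                                                  genes = c("zz1", "zz2"))),
               "do not overlap")
})

test_that("lower gamma_switch shifts loading mass to the top level", {
  fx <- tiny_planted(branching = c(2, 2), n_genes = 160, n_cells = 300,
                     parent_share = 0.4, seed = 60)
  model <- gem_model(fx$spec, fx$beta + 1e-9)
  lev1 <- level_nodes(fx$spec, 1)
  mass <- vapply(c(0.9, 0.5, 0.1), function(g) {
    th <- infer_loadings(model, fx$counts, gamma_switch = g)
    mean(rowSums(th$theta[, lev1]))
  }, numeric(1))
  expect_true(all(diff(mass) > 0))
})

test_that("warm start transfers and extends gene vocabularies", {
  fx <- tiny_planted(branching = c(2, 2), n_genes = 100)
  model <- gem_model(fx$spec, fx$beta + 1e-9)
  # same gene set: unchanged up to renormalization
  same <- warm_start(model, colnames(model$beta))
  expect_equal(same$beta, model$beta, tolerance = 1e-12)
  # one unseen gene enters every row at the smoothed minimum
  ext <- warm_start(model, c(colnames(model$beta), "NOVEL1"))
  expect_identical(ncol(ext$beta), 101L)
  expect_true(all(ext$beta[, "NOVEL1"] > 0))
  # unseen genes enter at the eta-smoothed minimum: eta spread over the
  # pretrained vocabulary, up to row renormalization
  expect_true(all(ext$beta[, "NOVEL1"] <= model$eta / 100 + 1e-12))
  expect_equal(rowSums(ext$beta), rep(1, 6), ignore_attr = TRUE)
})

test_that("mini-batch training improves the objective over its start", {
  fx <- tiny_planted(branching = c(2, 2), n_genes = 120, n_cells = 400,
                     seed = 70)
  init <- initialize_gem_tree(normalize_proportions(fx$counts), fx$spec,
                              seed = 71)
  f <- fit_gem(fx$counts, init,
               fit_config(mode = "mini-batch", batch_size = 100,
                          learning_rate = 0.05, max_epochs = 10, seed = 72))
  obj <- f$trace$epoch_likelihoods
  expect_gt(obj[length(obj)], obj[1])
})

test_that("empty input and disjoint gene sets raise errors", {
  fx <- tiny_planted()
  init <- initialize_gem_tree(normalize_proportions(fx$counts), fx$spec,
                              seed = 1)
  empty <- as_count_matrix(Matrix::Matrix(0, 3, ncol(fx$counts),
                                          sparse = TRUE),
                           gene_names = colnames(fx$counts))
  expect_error(fit_gem(empty, init), "empty")
})
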