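# Small trained run reused across saliency tests.
saliency_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      d <- toy_design(n_nodes = 12, n_per_group = c(10, 10),
                      effect_size = 5, noise = 0.01, seed = 7)
      folds <- make_folds(d$y, k = 5, split_seed = 0)
      run <- run_repeated(d$X, d$y, folds, n_seeds = 3,
                          hidden = c(32, 16, 8), keep_models = TRUE)
      cache <<- list(d = d, folds = folds, run = run)
    }
    cache
  }
})

test_that("gradient collection covers every correct (seed, participant)", {
  fx <- saliency_fixture()
  # separable cohort: everyone correct under every seed
  expect_true(all(vapply(fx$run$results, function(r) all(r$correct),
                         logical(1))))
  gs <- fx$run$gradient_samples
  expect_equal(sum(gs$count), 3 * 20)   # n_seeds x N
  expect_equal(gs$count, c(30L, 30L))   # <= n_seeds x class size, met here
  # streaming accumulation equals collection from retained models
  gs2 <- collect_gradients(fx$run, fx$d$X, fx$d$y)
  expect_equal(gs2$sum, gs$sum)
  expect_equal(gs2$count, gs$count)
})

test_that("misclassified participants contribute no samples", {
  fx <- saliency_fixture()
  cv <- fx$run$results[[1]]
  cv2 <- run_cv(fx$d$X, fx$d$y, fx$folds, init_seed = 0,
                hidden = c(32, 16, 8))
  # force participant 1 to count as misclassified and recollect
  cv2$correct[1] <- FALSE
  gs_all <- collect_gradients(cv2, fx$d$X, fx$d$y)
  cv2$correct[] <- FALSE
  expect_error(
    aggregate_edge_scores(collect_gradients(cv2, fx$d$X, fx$d$y)),
    "no gradient samples")
  expect_equal(sum(gs_all$count), 19)
})

test_that("edge scores are the per-class sample means", {
  fx <- saliency_fixture()
  gs <- collect_gradients(fx$run, fx$d$X, fx$d$y, keep_samples = TRUE)
  es <- aggregate_edge_scores(gs)
  expect_equal(es$class0, colMeans(gs$samples[[1]]))
  expect_equal(es$class1, colMeans(gs$samples[[2]]))
  # a single sample aggregates to itself
  one <- list(gs$samples[[1]][1, , drop = FALSE],
              gs$samples[[2]][1, , drop = FALSE])
  es1 <- aggregate_edge_scores(one)
  expect_equal(es1$class0, gs$samples[[1]][1, ])
  # duplicating every sample leaves the mean unchanged
  dup <- list(rbind(gs$samples[[1]], gs$samples[[1]]),
              rbind(gs$samples[[2]], gs$samples[[2]]))
  expect_equal(aggregate_edge_scores(dup)$class0, es$class0)
  expect_equal(aggregate_edge_scores(dup)$class1, es$class1)
})

test_that("per-sample class gradients are exact negatives in probability mode", {
  fx <- saliency_fixture()
  cv <- run_cv(fx$d$X, fx$d$y, fx$folds, init_seed = 1,
               hidden = c(32, 16, 8))
  for (f in 1:2) {
    sel <- which(fx$folds$fold == f & cv$correct)
    g_true <- mlp_input_gradient(cv$models[[f]],
                                 fx$d$X[sel, , drop = FALSE],
                                 target_class = fx$d$y[sel])
    g_flip <- mlp_input_gradient(cv$models[[f]],
                                 fx$d$X[sel, , drop = FALSE],
                                 target_class = 1L - fx$d$y[sel])
    expect_identical(g_true, -g_flip)
  }
})

test_that("node scores sum incident edge scores (hand example + identity)", {
  expect_equal(node_scores(c(1, 2, 3), 3), c(3, 4, 5))
  set.seed(61)
  for (r in 1:20) {
    n <- sample(4:30, 1)
    g <- rnorm(n * (n - 1) / 2)
    s <- node_scores(g, n)
    expect_equal(sum(s), 2 * sum(g), tolerance = 1e-12)
  }
  # exact on integer-valued scores
  g_int <- as.numeric(sample.int(100, 45))
  expect_identical(sum(node_scores(g_int, 10)), 2 * sum(g_int))
})

test_that("node scores are equivariant under node relabelling", {
  set.seed(62)
  n <- 9
  S <- random_symmetric_matrix(n, density = 1)
  s <- node_scores(vectorize(S), n)
  for (r in 1:10) {
    perm <- sample.int(n)
    s_perm <- node_scores(vectorize(S[perm, perm]), n)
    expect_equal(s_perm, s[perm])
  }
})

test_that("top_k ranks by score with deterministic index tie-breaks", {
  expect_equal(top_k(c(0.1, 0.5, 0.3), 2)$index, c(2, 3))
  full <- top_k(c(0.1, 0.5, 0.3), 3)
  expect_equal(full$index, c(2, 3, 1))
  expect_equal(full$score, c(0.5, 0.3, 0.1))
  ties <- top_k(c(1, 2, 2, 1), 4)
  expect_equal(ties$index, c(2, 3, 1, 4))
  expect_error(top_k(1:3, 4), "exceeds")
})

test_that("ranked edge lists carry names/hemispheres; crossings counted", {
  nt <- toy_node_table(6)  # nodes 1-3 L, 4-6 R
  g <- numeric(15)
  g[edge_index(1, 2, 6)] <- 3   # L-L
  g[edge_index(1, 4, 6)] <- 2   # L-R
  g[edge_index(4, 5, 6)] <- 1   # R-R
  top <- top_k_edges(g, 3, nt)
  expect_equal(top$item[1], "Node01--Node02")
  expect_equal(cross_hemisphere_count(top, nt), 1L)
  # all-within-hemisphere list counts zero
  expect_equal(cross_hemisphere_count(top[c(1, 3), ], nt), 0L)
  # midline endpoints never count as crossing
  nt_m <- nt; nt_m$hemisphere[4] <- "M"
  expect_equal(cross_hemisphere_count(top, nt_m), 0L)
  expect_error(
    cross_hemisphere_count(data.frame(node_i = "Nope", node_j = "Node01"),
                           nt), "unknown node name")
})

test_that("planted edges receive higher group-1 scores than background", {
  d <- toy_design(n_nodes = 16, n_per_group = c(15, 15), effect_size = 2,
                  noise = 0.3, n_planted = 5, n_cross = 2, seed = 41)
  folds <- make_folds(d$y, k = 5, split_seed = 4)
  run <- run_repeated(d$X, d$y, folds, n_seeds = 5, hidden = c(64, 32, 16))
  g1 <- aggregate_edge_scores(run$gradient_samples)$class1
  planted <- d$cohort$ground_truth$edge
  expect_gt(mean(g1[planted]), mean(g1[-planted]))
})

test_that("saliency summary is internally consistent", {
  fx <- saliency_fixture()
  nt <- fx$d$cfg$node_table
  sal <- compute_saliency(fx$run$gradient_samples, nt, k_nodes = 5,
                          k_edges = 10)
  expect_equal(sal$node_scores$class1,
               node_scores(sal$edge_scores$class1, 12))
  expect_equal(sal$top_edges$class1,
               top_k_edges(sal$edge_scores$class1, 10, nt))
  expect_equal(sal$cross_hemisphere[["class1"]],
               cross_hemisphere_count(sal$top_edges$class1, nt))
})

test_that("shared-input aggregation makes class scores exact negatives", {
  fx <- saliency_fixture()
  gs <- collect_gradients(fx$run, fx$d$X, fx$d$y, mode = "probability",
                          aggregation = "shared")
  es <- aggregate_edge_scores(gs)
  expect_equal(gs$count[1], gs$count[2])
  expect_identical(es$class0, -es$class1)
})
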