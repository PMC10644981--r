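test_that("edge indexing is the canonical row-major strict upper triangle", {
  expect_equal(edge_index(1, 2, 84), 1)
  # oracle: enumerate all pairs in canonical order and read off positions
  enum <- expand.grid(j = 1:84, i = 1:84)
  enum <- enum[enum$i < enum$j, c("i", "j")]
  enum <- enum[order(enum$i, enum$j), ]
  expect_equal(nrow(enum), 3486)
  expect_equal(edge_index(83, 84, 84), 3486)
  ks <- c(1, 2, 100, 1000, 3486)
  expect_equal(edge_index(enum$i[ks], enum$j[ks], 84), ks)
  expect_equal(unname(edge_pairs(84)), unname(as.matrix(enum)),
               ignore_attr = TRUE)
})

test_that("edge_pair inverts edge_index for all pairs at n = 10", {
  pairs <- edge_pairs(10)
  k <- edge_index(pairs[, 1], pairs[, 2], 10)
  expect_equal(k, 1:45)
  back <- edge_pair(1:45, 10)
  expect_equal(unname(back), unname(pairs))
})

test_that("edge indexing rejects invalid input", {
  expect_error(edge_index(3, 3, 10), "i < j")
  expect_error(edge_index(5, 2, 10), "i < j")
  expect_error(edge_index(0, 2, 10), "out of range")
  expect_error(edge_pair(46, 10), "out of range")
})

test_that("a 3x3 matrix file parses to the expected weights", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0 2 0", "2 0 1", "0 1 0"), f)
  nt <- toy_node_table(3)
  m <- load_connectome(f, nt)
  expect_equal(m$weights[1, 2], 2)
  expect_equal(m$weights[2, 3], 1)
  expect_equal(m$weights[1, 3], 0)
  # comma-delimited dialect parses identically
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("0,2,0", "2,0,1", "0,1,0"), f2)
  expect_equal(load_connectome(f2, nt)$weights, m$weights)
})

test_that("non-zero diagonal entries are zeroed with a warning", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0 2 0", "2 5 1", "0 1 0"), f)
  expect_warning(m <- load_connectome(f, toy_node_table(3)), "diagonal")
  expect_equal(m$weights[2, 2], 0)
  expect_equal(m$weights[1, 2], 2)
})

test_that("invalid matrix files are rejected with informative errors", {
  nt <- toy_node_table(3)
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0 2", "2 0"), f)        # dimension mismatch vs node table
  expect_error(load_connectome(f, nt), "3 regions")
  writeLines(c("0 2 0", "2 0 -1", "0 -1 0"), f)
  expect_error(load_connectome(f, nt), "negative")
  writeLines(c("0 2 0", "9 0 1", "0 1 0"), f)   # gross asymmetry
  expect_error(load_connectome(f, nt), "asymmetry")
  writeLines(c("0 x 0", "x 0 1", "0 1 0"), f)
  expect_error(load_connectome(f, nt), "non-numeric")
})

test_that("small asymmetry is resolved by averaging", {
  nt <- toy_node_table(3)
  w <- matrix(c(0, 2, 0, 2 + 2e-7, 0, 1, 0, 1, 0), 3, 3)
  m <- connectome(w, nt)
  expect_equal(m$weights[1, 2], 2 + 1e-7)
  expect_identical(m$weights, t(m$weights))
})

test_that("write/read round-trips an 84-node simulated connectome", {
  cfg <- sim_config(n_per_group = c(1L, 1L), seed = 3)
  cohort <- generate_cohort(cfg)
  m <- cohort$connectomes[[1]]
  f <- withr::local_tempfile(fileext = ".txt")
  write_connectome(m, f)
  m2 <- load_connectome(f, cfg$node_table)
  expect_lt(max(abs(m2$weights - m$weights)), 1e-9)
})

test_that("vectorize yields 3486 values for 84 nodes and inverts exactly", {
  cfg <- sim_config(n_per_group = c(1L, 1L), seed = 5)
  m <- generate_cohort(cfg)$connectomes[[1]]
  v <- vectorize(m)
  expect_length(v, 3486)
  expect_identical(devectorize(v, 84), m$weights)
  # element correspondence follows the canonical ordering
  expect_identical(v[edge_index(5, 60, 84)], m$weights[5, 60])
})

test_that("vectorize of an all-ones 4-node matrix is six ones", {
  w <- matrix(1, 4, 4); diag(w) <- 0
  expect_identical(vectorize(w), rep(1, 6))
})

test_that("vectorize/devectorize round-trips 100 random 12-node matrices", {
  set.seed(11)
  for (r in 1:100) {
    w <- random_symmetric_matrix(12)
    expect_identical(devectorize(vectorize(w), 12), w)
  }
})

test_that("min-max normalization maps to [0,1] and preserves order", {
  expect_equal(normalize_edges(c(0, 5, 10)), c(0, 0.5, 1))
  v <- c(0, 0.25, 1, 0.5)
  expect_identical(normalize_edges(v), v)  # idempotent on normalized input
  set.seed(2)
  cfg <- sim_config(n_nodes = 12L, n_per_group = c(25L, 25L), seed = 9,
                    intra_hemisphere_density = 0.8,
                    inter_hemisphere_density = 0.5,
                    n_planted = 4L, n_cross_hemisphere_planted = 2L)
  cohort <- generate_cohort(cfg)$connectomes
  for (m in cohort) {
    out <- normalize_edges(vectorize(m))
    expect_equal(min(out), 0)
    expect_equal(max(out), 1)
    expect_identical(order(out), order(vectorize(m)))
  }
  expect_error(normalize_edges(rep(3, 10)), "degenerate")
})

test_that("the shipped DK table has 84 uniquely named lateralized regions", {
  nt <- dk_node_table()
  expect_equal(nrow(nt), 84)
  expect_identical(nt$index, 0:83)
  expect_false(anyDuplicated(nt$name) > 0)
  expect_equal(sum(nt$hemisphere == "L"), 42)
  expect_equal(sum(nt$hemisphere == "R"), 42)
})

test_that("node tables with gaps, duplicates or bad codes are rejected", {
  nt <- as.data.frame(dk_node_table())
  bad <- nt; bad$index[2] <- 5L
  expect_error(connectomlp:::validate_node_table(bad), "without gaps")
  bad <- nt; bad$name[2] <- bad$name[1]
  expect_error(connectomlp:::validate_node_table(bad), "unique")
  bad <- nt; bad$hemisphere[3] <- "Q"
  expect_error(connectomlp:::validate_node_table(bad), "hemisphere")
})

test_that("manifest reading resolves relative paths and checks labels", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_nodes = 6L, n_per_group = c(2L, 2L), n_planted = 2L,
                    intra_hemisphere_density = 0.9,
                    inter_hemisphere_density = 0.9,
                    n_cross_hemisphere_planted = 0L, seed = 1)
  manifest_path <- write_cohort(generate_cohort(cfg), dir)
  manifest <- read_manifest(manifest_path)
  expect_equal(nrow(manifest), 4)
  expect_true(all(file.exists(manifest$path)))
  cohort <- load_cohort(manifest, cfg$node_table)
  expect_equal(vapply(cohort, `[[`, integer(1), "label"),
               c(0L, 0L, 1L, 1L))
})
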