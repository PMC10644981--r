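# Shared fixtures and oracles for the test suite.

# Random symmetric non-negative zero-diagonal matrix.
random_symmetric_matrix <- function(n, density = 0.7) {
  m <- n * (n - 1) / 2
  v <- ifelse(stats::runif(m) < density, stats::rlnorm(m), 0)
  devectorize(v, n)
}

# Generic two-hemisphere node table for n nodes (L first).
toy_node_table <- function(n) {
  sim_config(n_nodes = n, n_per_group = c(1L, 1L), n_planted = 0L,
             n_cross_hemisphere_planted = 0L)$node_table
}

# Small fast cohort in design-matrix form.
toy_design <- function(n_nodes = 12, n_per_group = c(10, 10),
                       effect_size = 5, noise = 0.01, n_planted = 4,
                       n_cross = 2, seed = 7) {
  # denser than the 84-node default so tiny graphs always have room
  # for the requested planted edges
  cfg <- sim_config(n_nodes = n_nodes, n_per_group = as.integer(n_per_group),
                    intra_hemisphere_density = 0.8,
                    inter_hemisphere_density = 0.5,
                    effect_size = effect_size, subject_noise_sd = noise,
                    n_planted = as.integer(n_planted),
                    n_cross_hemisphere_planted = as.integer(n_cross),
                    seed = seed)
  cohort <- generate_cohort(cfg)
  d <- connectomlp:::cohort_design(cohort$connectomes)
  list(X = d$X, y = d$y, cohort = cohort, cfg = cfg)
}

# Independent oracle: central finite differences of a scalar function.
numeric_gradient <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

# Scalar class output of the model, for finite differencing.
mlp_scalar_output <- function(model, cls, mode) {
  function(x) {
    fw <- mlp_forward(model, x)
    switch(mode,
           probability = fw$prob[1, cls + 1],
           logit = fw$logits[1, cls + 1],
           margin = fw$logits[1, cls + 1] - fw$logits[1, 2 - cls])
  }
}

# A small random trained-or-raw network for gradient checks.
random_small_mlp <- function(input_dim = 8, seed = 1) {
  m <- mlp_init(input_dim, hidden = c(6L, 5L, 4L), init_seed = seed)
  # shift biases so ReLU kinks are away from the evaluation point
  m$b <- lapply(m$b, function(b) b + stats::runif(length(b), 0.05, 0.3))
  m
}
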