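#' Simulation configuration for synthetic connectome cohorts
#'
#' Defines a two-group cohort of synthetic structural connectomes with a
#' controlled, recoverable group difference. A shared backbone of mean edge
#' weights is drawn once: an edge between two regions is present with
#' probability `intra_hemisphere_density` when both regions lie in the same
#' hemisphere and `inter_hemisphere_density` otherwise, and present edges
#' receive log-normal weights (positive and right-skewed, like
#' SIFT2-weighted streamline counts). Each subject multiplies the backbone
#' by i.i.d. log-normal noise per present edge, and group-1 subjects
#' additionally have the planted edges multiplied by `1 + effect_size`.
#'
#' Defaults mirror a small clinical case-control study: 20 group-0 and 28
#' group-1 subjects on the 84-region DK parcellation, denser
#' intra-hemisphere than inter-hemisphere connectivity, 20 planted edges of
#' which 2 cross hemispheres.
#'
#' @param n_nodes Number of regions (default 84).
#' @param n_per_group Integer pair: subjects in group 0 and group 1.
#' @param intra_hemisphere_density,inter_hemisphere_density Probability
#'   that a same-/different-hemisphere region pair is connected.
#' @param base_weight_log_mean,base_weight_log_sd Log-scale mean and sd of
#'   backbone edge weights.
#' @param subject_noise_sd Log-scale sd of per-subject, per-edge
#'   multiplicative noise.
#' @param planted_edges Optional two-column matrix of 1-based node pairs
#'   (i < j) to receive the group effect; if `NULL`, `n_planted` edges are
#'   sampled from the backbone, `n_cross_hemisphere_planted` of them
#'   cross-hemisphere and the rest intra-hemisphere.
#' @param n_planted Number of planted edges when sampling automatically.
#' @param n_cross_hemisphere_planted How many sampled planted edges must
#'   cross hemispheres.
#' @param effect_size Non-negative multiplier: planted edges in group 1 are
#'   scaled by `1 + effect_size`. `0` gives exchangeable groups.
#' @param seed Integer master seed; the backbone uses `seed` and subject
#'   `s` uses `seed + s`, so individual subjects are reproducible
#'   independent of cohort size.
#' @param node_table Node table supplying hemisphere codes; defaults to
#'   the shipped DK table when `n_nodes` is 84, otherwise nodes are split
#'   into two equal hemisphere blocks (L first).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_nodes = 84L,
                       n_per_group = c(20L, 28L),
                       intra_hemisphere_density = 0.35,
                       inter_hemisphere_density = 0.15,
                       base_weight_log_mean = 3,
                       base_weight_log_sd = 1,
                       subject_noise_sd = 0.3,
                       planted_edges = NULL,
                       n_planted = 20L,
                       n_cross_hemisphere_planted = 2L,
                       effect_size = 2,
                       seed = 1L,
                       node_table = NULL) {
  if (is.null(node_table)) {
    node_table <- if (n_nodes == 84L) dk_node_table() else
      validate_node_table(data.frame(
        index = 0:(n_nodes - 1L),
        name = sprintf("Node%02d", 1:n_nodes),
        hemisphere = rep(c("L", "R"), c(ceiling(n_nodes / 2),
                                        floor(n_nodes / 2)))))
  }
  stopifnot(nrow(node_table) == n_nodes,
            length(n_per_group) == 2, all(n_per_group >= 1),
            intra_hemisphere_density > 0, intra_hemisphere_density <= 1,
            inter_hemisphere_density >= 0, inter_hemisphere_density <= 1,
            base_weight_log_sd >= 0, subject_noise_sd >= 0,
            effect_size >= 0, n_planted >= 0,
            n_cross_hemisphere_planted >= 0,
            n_cross_hemisphere_planted <= n_planted)
  if (!is.null(planted_edges)) {
    planted_edges <- as.matrix(planted_edges)
    stopifnot(ncol(planted_edges) == 2,
              all(planted_edges[, 1] < planted_edges[, 2]),
              all(planted_edges >= 1), all(planted_edges <= n_nodes))
  }
  structure(list(
    n_nodes = as.integer(n_nodes), n_per_group = as.integer(n_per_group),
    intra_hemisphere_density = intra_hemisphere_density,
    inter_hemisphere_density = inter_hemisphere_density,
    base_weight_log_mean = base_weight_log_mean,
    base_weight_log_sd = base_weight_log_sd,
    subject_noise_sd = subject_noise_sd,
    planted_edges = planted_edges,
    n_planted = as.integer(n_planted),
    n_cross_hemisphere_planted = as.integer(n_cross_hemisphere_planted),
    effect_size = effect_size, seed = as.integer(seed),
    node_table = node_table), class = "sim_config")
}

# TRUE for edges whose endpoints share a hemisphere (M counts as its own
# side, so M-M is intra and M-L / M-R are inter).
same_hemisphere <- function(pairs, node_table) {
  node_table$hemisphere[pairs[, 1]] == node_table$hemisphere[pairs[, 2]]
}

#' Draw the backbone mean matrix of a simulated cohort
#'
#' @param config A [sim_config()].
#' @return Symmetric non-negative `n_nodes` x `n_nodes` matrix of mean
#'   edge weights; absent edges are 0. Deterministic given `config$seed`.
#' @export
generate_backbone <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_nodes
  pairs <- edge_pairs(n)
  intra <- same_hemisphere(pairs, config$node_table)
  p_edge <- ifelse(intra, config$intra_hemisphere_density,
                   config$inter_hemisphere_density)
  withr_seed(config$seed, {
    present <- stats::runif(nrow(pairs)) < p_edge
    w <- numeric(nrow(pairs))
    w[present] <- stats::rlnorm(sum(present),
                                meanlog = config$base_weight_log_mean,
                                sdlog = config$base_weight_log_sd)
  })
  devectorize(w, n)
}

# Run expr with the RNG seeded to `seed`, restoring prior RNG state after.
# Evaluates in the caller's frame so assignments escape.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed %% .Machine$integer.max)
  eval.parent(substitute(expr))
}

#' Generate a synthetic two-group cohort of connectomes
#'
#' Subject matrices are `backbone * exp(eps)` elementwise on present edges,
#' with `eps ~ Normal(0, subject_noise_sd^2)` i.i.d. per subject per edge;
#' group-1 subjects additionally have planted edges multiplied by
#' `1 + effect_size`. Group 0 subjects come first (`sub-001` ...). The
#' planted edge set and applied multiplier are recorded as ground truth.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_cohort`: `connectomes` (list of labelled
#'   [connectome()] objects), `ground_truth` (data.frame `i`, `j`,
#'   `edge` flat index, `multiplier`), `backbone`, `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_nodes
  backbone <- generate_backbone(config)
  bb_vec <- vectorize(backbone)
  planted <- config$planted_edges
  if (is.null(planted) && config$n_planted > 0L) {
    # own substream, past the last subject's seed
    planted <- withr_seed(config$seed + sum(config$n_per_group) + 1L,
                          sample_planted_edges(config, bb_vec))
  }
  if (!is.null(planted)) {
    k <- edge_index(planted[, 1], planted[, 2], n)
    if (any(bb_vec[k] == 0)) {
      stop("planted edge(s) absent from the backbone: ",
           paste(sprintf("(%d,%d)", planted[bb_vec[k] == 0, 1],
                         planted[bb_vec[k] == 0, 2]), collapse = " "))
    }
  } else {
    planted <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("i", "j")))
    k <- integer(0)
  }
  n0 <- config$n_per_group[1]; n_total <- sum(config$n_per_group)
  labels <- rep(c(0L, 1L), config$n_per_group)
  mult <- 1 + config$effect_size
  present <- bb_vec > 0
  connectomes <- lapply(seq_len(n_total), function(s) {
    withr_seed(config$seed + s, {
      eps <- stats::rnorm(sum(present), sd = config$subject_noise_sd)
    })
    v <- bb_vec
    v[present] <- v[present] * exp(eps)
    if (labels[s] == 1L && length(k)) v[k] <- v[k] * mult
    connectome(devectorize(v, n), config$node_table,
               participant_id = sprintf("sub-%03d", s), label = labels[s])
  })
  gt <- data.frame(i = planted[, 1], j = planted[, 2], edge = k,
                   multiplier = rep(mult, length(k)))
  structure(list(connectomes = connectomes, ground_truth = gt,
                 backbone = backbone, config = config),
            class = "sim_cohort")
}

# Sample planted node pairs from present backbone edges, honouring the
# requested cross-/intra-hemisphere split. Assumes RNG already seeded.
sample_planted_edges <- function(config, bb_vec) {
  pairs <- edge_pairs(config$n_nodes)
  present <- bb_vec > 0
  intra <- same_hemisphere(pairs, config$node_table)
  n_cross <- config$n_cross_hemisphere_planted
  n_intra <- config$n_planted - n_cross
  pool_cross <- which(present & !intra)
  pool_intra <- which(present & intra)
  if (length(pool_cross) < n_cross || length(pool_intra) < n_intra) {
    stop("backbone too sparse to place the requested planted edges")
  }
  k <- c(if (n_cross > 0) pool_cross[sample.int(length(pool_cross), n_cross)],
         if (n_intra > 0) pool_intra[sample.int(length(pool_intra), n_intra)])
  pairs[sort(k), , drop = FALSE]
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("Simulated cohort:", length(x$connectomes), "subjects (",
      x$config$n_per_group[1], "group 0 /", x$config$n_per_group[2],
      "group 1 ),", x$config$n_nodes, "nodes,",
      nrow(x$ground_truth), "planted edges, effect size",
      x$config$effect_size, "\n")
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Emits one plain-text matrix file per subject, a participant manifest
#' TSV (`participant_id  path  label`) and a ground-truth JSON listing
#' planted edges as `(i, j, multiplier)` triples (1-based node ids plus
#' region names).
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nt <- cohort$config$node_table
  rows <- lapply(cohort$connectomes, function(m) {
    fn <- paste0(m$participant_id, "_connectome.txt")
    write_connectome(m, file.path(dir, fn))
    data.frame(participant_id = m$participant_id, path = fn,
               label = m$label)
  })
  manifest <- do.call(rbind, rows)
  manifest_path <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, manifest_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  gt <- cohort$ground_truth
  gt_out <- lapply(seq_len(nrow(gt)), function(r) list(
    i = gt$i[r], j = gt$j[r],
    name_i = nt$name[gt$i[r]], name_j = nt$name[gt$j[r]],
    multiplier = gt$multiplier[r]))
  jsonlite::write_json(gt_out, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest_path)
}
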