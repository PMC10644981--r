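#' Collect input gradients of correctly predicted participants
#'
#' For every participant correctly predicted as a held-out test case, the
#' gradient of the true-class output with respect to the input edges is
#' taken under the model of the fold in which the participant was held
#' out, and assigned to that class's sample set. Applied to a
#' [run_repeated()] result (with retained models) this pools samples over
#' every (seed, participant) combination; [run_repeated()] can also do
#' this on the fly without retaining models.
#'
#' Two aggregations are available. `"per_class"` (default) assigns each
#' correctly predicted participant's true-class gradient to its own
#' class's sample set, so the two classes average over disjoint
#' participant sets. `"shared"` evaluates both class gradients of every
#' correctly predicted participant and feeds them to both sets; with the
#' probability-mode gradient this makes the class-0 and class-1 scores
#' exact negatives of each other, since the per-input class gradients
#' already are.
#'
#' @param run A `cv_result` or a `repeated_run` with `keep_models = TRUE`.
#' @param X,y The design matrix and labels the run was made from.
#' @param mode Gradient target, as in [mlp_input_gradient()].
#' @param aggregation `"per_class"` or `"shared"` (see Details).
#' @param keep_samples Keep the individual gradient rows (per class) in
#'   addition to running sums.
#' @return Object of class `grad_samples`: list with `sum` (list of two
#'   per-edge gradient sums, classes 0 and 1), `count` (samples per
#'   class), `mode`, `n_edges`, and optionally `samples` (list of two
#'   matrices, one gradient per row).
#' @export
collect_gradients <- function(run, X, y, mode = "probability",
                              aggregation = c("per_class", "shared"),
                              keep_samples = FALSE) {
  UseMethod("collect_gradients")
}

#' @export
collect_gradients.cv_result <- function(run, X, y, mode = "probability",
                                        aggregation = c("per_class",
                                                        "shared"),
                                        keep_samples = FALSE) {
  aggregation <- match.arg(aggregation)
  if (is.null(run$models)) {
    stop("cv_result has no retained models; rerun with keep_models = TRUE")
  }
  y <- as.integer(y)
  d <- ncol(X)
  sums <- list(numeric(d), numeric(d))
  count <- c(0L, 0L)
  samples <- if (keep_samples) list(NULL, NULL)
  for (f in seq_len(run$folds$k)) {
    sel <- run$folds$fold == f & run$correct
    if (!any(sel)) next
    Xf <- X[sel, , drop = FALSE]
    for (cl in 0:1) {
      rows <- if (aggregation == "shared") rep(TRUE, sum(sel))
              else y[sel] == cl
      if (!any(rows)) next
      Gc <- mlp_input_gradient(run$models[[f]], Xf[rows, , drop = FALSE],
                               target_class = cl, mode = mode)
      sums[[cl + 1L]] <- sums[[cl + 1L]] + colSums(Gc)
      count[cl + 1L] <- count[cl + 1L] + nrow(Gc)
      if (keep_samples) {
        samples[[cl + 1L]] <- rbind(samples[[cl + 1L]], Gc)
      }
    }
  }
  structure(list(sum = sums, count = count, mode = mode, n_edges = d,
                 samples = samples),
            class = "grad_samples")
}

#' @export
collect_gradients.repeated_run <- function(run, X, y, mode = "probability",
                                           aggregation = c("per_class",
                                                           "shared"),
                                           keep_samples = FALSE) {
  aggregation <- match.arg(aggregation)
  has_models <- all(vapply(run$results, function(r) !is.null(r$models),
                           logical(1)))
  if (!has_models) {
    if (!is.null(run$gradient_samples) &&
        identical(run$gradient_samples$mode, mode) &&
        aggregation == "per_class" && !keep_samples) {
      return(run$gradient_samples)
    }
    stop("repeated_run has no retained models; use keep_models = TRUE or ",
         "the gradients collected during the run")
  }
  gs <- NULL
  for (r in run$results) {
    gs_r <- collect_gradients(r, X, y, mode = mode,
                              aggregation = aggregation,
                              keep_samples = keep_samples)
    gs <- if (is.null(gs)) gs_r else combine_grad_samples(gs, gs_r)
  }
  gs
}

# Merge two gradient accumulators (same mode and edge count).
combine_grad_samples <- function(a, b) {
  stopifnot(identical(a$mode, b$mode), a$n_edges == b$n_edges)
  structure(list(
    sum = list(a$sum[[1]] + b$sum[[1]], a$sum[[2]] + b$sum[[2]]),
    count = a$count + b$count, mode = a$mode, n_edges = a$n_edges,
    samples = if (!is.null(a$samples) && !is.null(b$samples)) {
      list(rbind(a$samples[[1]], b$samples[[1]]),
           rbind(a$samples[[2]], b$samples[[2]]))
    }), class = "grad_samples")
}

#' @export
print.grad_samples <- function(x, ...) {
  cat("Gradient samples (", x$mode, " mode): ",
      x$count[1], " class-0 + ", x$count[2], " class-1 over ",
      x$n_edges, " edges\n", sep = "")
  invisible(x)
}

#' Per-class edge gradient scores
#'
#' The gradient score of an edge for class `c` is the arithmetic mean of
#' that edge's gradient over all collected class-`c` samples — all
#' (seed, correctly-predicted-participant) combinations. A positive score
#' means a stronger connection pushes the classifier toward that group.
#'
#' @param samples A [collect_gradients()] accumulator, or a list of two
#'   matrices of raw gradient rows (classes 0 and 1).
#' @return List of class `edge_scores` with per-class mean-gradient
#'   vectors in `$class0` and `$class1`, and `$count`.
#' @export
aggregate_edge_scores <- function(samples) {
  if (inherits(samples, "grad_samples")) {
    if (any(samples$count == 0L)) {
      stop("no gradient samples for class ",
           paste(which(samples$count == 0L) - 1L, collapse = " and "))
    }
    g0 <- samples$sum[[1]] / samples$count[1]
    g1 <- samples$sum[[2]] / samples$count[2]
    count <- samples$count
  } else if (is.list(samples) && length(samples) == 2L) {
    if (is.null(samples[[1]]) || is.null(samples[[2]]) ||
        nrow(samples[[1]]) == 0L || nrow(samples[[2]]) == 0L) {
      stop("empty class sample set")
    }
    g0 <- colMeans(samples[[1]])
    g1 <- colMeans(samples[[2]])
    count <- c(nrow(samples[[1]]), nrow(samples[[2]]))
  } else {
    stop("samples must be a grad_samples object or a list of two matrices")
  }
  structure(list(class0 = g0, class1 = g1, count = count),
            class = "edge_scores")
}

#' Node strength: summed gradient scores of incident edges
#'
#' The node score of region `v` sums the edge gradient scores of every
#' edge incident to `v`, for one class. Since each edge has two
#' endpoints, the node scores always satisfy the handshake identity
#' `sum(node scores) = 2 * sum(edge scores)`.
#'
#' @param g Per-edge score vector in canonical order (length n(n-1)/2).
#' @param n_nodes Number of regions.
#' @return Numeric vector of length `n_nodes`.
#' @examples
#' node_scores(c(1, 2, 3), 3)  # edges (1,2),(1,3),(2,3) -> 3 4 5
#' @export
node_scores <- function(g, n_nodes) {
  n_nodes <- as.integer(n_nodes)
  if (length(g) != n_nodes * (n_nodes - 1L) / 2L) {
    stop("edge score vector length does not match node count")
  }
  pairs <- edge_pairs(n_nodes)
  ends <- c(pairs[, 1], pairs[, 2])
  as.vector(rowsum(c(g, g), ends, reorder = TRUE))
}

#' Top-k ranked items
#'
#' Ranks scored items in non-increasing score order, ties broken by
#' ascending index, and keeps the top `k`.
#'
#' @param scores Numeric score vector.
#' @param k List length (`k <= length(scores)`).
#' @param items Optional item names (default the indices).
#' @return A data.frame of class `ranked_list` with columns `rank`,
#'   `index`, `item`, `score`, sorted by rank.
#' @export
top_k <- function(scores, k, items = NULL) {
  if (k > length(scores)) stop("k exceeds number of items")
  ord <- order(-scores, seq_along(scores))[seq_len(k)]
  out <- data.frame(rank = seq_len(k), index = ord,
                    item = if (is.null(items)) as.character(ord)
                           else items[ord],
                    score = scores[ord])
  class(out) <- c("ranked_list", "data.frame")
  out
}

#' Top-k nodes and edges by gradient score
#'
#' Convenience wrappers of [top_k()] that attach region names and
#' hemisphere codes from a node table. Edge items are named
#' `"<name_i>--<name_j>"`.
#'
#' @param scores Node- or edge-score vector for one class.
#' @param k List length.
#' @param node_table Node table of the parcellation.
#' @return A `ranked_list` data.frame; the edge version carries columns
#'   `node_i`, `node_j`, `hemisphere_i`, `hemisphere_j`.
#' @export
top_k_nodes <- function(scores, k, node_table) {
  stopifnot(length(scores) == nrow(node_table))
  out <- top_k(scores, k, items = node_table$name)
  out$hemisphere <- node_table$hemisphere[out$index]
  out
}

#' @rdname top_k_nodes
#' @export
top_k_edges <- function(scores, k, node_table) {
  n <- nrow(node_table)
  stopifnot(length(scores) == n * (n - 1L) / 2L)
  pairs <- edge_pairs(n)
  nm <- paste0(node_table$name[pairs[, 1]], "--",
               node_table$name[pairs[, 2]])
  out <- top_k(scores, k, items = nm)
  out$node_i <- node_table$name[pairs[out$index, 1]]
  out$node_j <- node_table$name[pairs[out$index, 2]]
  out$hemisphere_i <- node_table$hemisphere[pairs[out$index, 1]]
  out$hemisphere_j <- node_table$hemisphere[pairs[out$index, 2]]
  out
}

#' Count cross-hemisphere edges in a ranked edge list
#'
#' An edge crosses hemispheres when its two endpoint regions carry
#' different lateral hemisphere codes (`L` vs `R`); edges with a midline
#' (`M`) endpoint never count as crossing.
#'
#' @param ranked_edges A [top_k_edges()] result, or any data.frame with
#'   `node_i`, `node_j` columns of region names.
#' @param node_table Node table resolving names to hemispheres.
#' @return Integer count.
#' @export
cross_hemisphere_count <- function(ranked_edges, node_table) {
  hi <- node_table$hemisphere[node_ids(ranked_edges$node_i, node_table)]
  hj <- node_table$hemisphere[node_ids(ranked_edges$node_j, node_table)]
  sum(hi != hj & hi != "M" & hj != "M")
}

#' Full saliency summary for a repeated cross-validation run
#'
#' Aggregates collected gradients into per-class edge scores and node
#' strengths, and extracts ranked top-k lists with cross-hemisphere
#' counts for each class.
#'
#' @param samples A [collect_gradients()] accumulator (e.g.
#'   `run$gradient_samples`).
#' @param node_table Node table of the parcellation.
#' @param k_nodes,k_edges Lengths of the ranked lists.
#' @return Object of class `saliency_result`: `edge_scores`,
#'   `node_scores` (lists with `class0`/`class1`), `top_nodes`,
#'   `top_edges` (lists of `ranked_list`s), `cross_hemisphere`
#'   (per-class counts within `top_edges`), `count`, `mode`.
#' @export
compute_saliency <- function(samples, node_table, k_nodes = 20L,
                             k_edges = 20L) {
  es <- aggregate_edge_scores(samples)
  n <- nrow(node_table)
  ns <- list(class0 = node_scores(es$class0, n),
             class1 = node_scores(es$class1, n))
  top_n <- lapply(ns, top_k_nodes, k = k_nodes, node_table = node_table)
  top_e <- lapply(list(class0 = es$class0, class1 = es$class1),
                  top_k_edges, k = k_edges, node_table = node_table)
  xh <- vapply(top_e, cross_hemisphere_count, integer(1),
               node_table = node_table)
  structure(list(edge_scores = es[c("class0", "class1")],
                 node_scores = ns, top_nodes = top_n, top_edges = top_e,
                 cross_hemisphere = xh, count = es$count,
                 mode = if (inherits(samples, "grad_samples"))
                   samples$mode else NA_character_,
                 node_table = node_table),
            class = "saliency_result")
}

#' @export
print.saliency_result <- function(x, ...) {
  cat("Saliency over", x$count[1], "class-0 and", x$count[2],
      "class-1 gradient samples (", x$mode, "mode )\n")
  for (cl in c("class0", "class1")) {
    te <- x$top_edges[[cl]]
    cat("  ", cl, "top edge:", te$item[1],
        sprintf("(score %.3g);", te$score[1]),
        x$cross_hemisphere[[cl]], "cross-hemisphere in top",
        nrow(te), "\n")
  }
  invisible(x)
}

#' Write saliency tables
#'
#' Emits per-class edge-score and node-score TSVs. Edge tables are in
#' long, chord-diagram-ready format: `source`, `target`, hemispheres and
#' `weight` (the gradient score).
#'
#' @param sal A [compute_saliency()] result.
#' @param dir Output directory.
#' @param prefix Filename prefix.
#' @return Invisibly, the paths written.
#' @export
write_saliency_tables <- function(sal, dir, prefix = "saliency") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nt <- sal$node_table
  n <- nrow(nt)
  pairs <- edge_pairs(n)
  paths <- character(0)
  for (cl in c("class0", "class1")) {
    edge_df <- data.frame(
      source = nt$name[pairs[, 1]], target = nt$name[pairs[, 2]],
      hemisphere_source = nt$hemisphere[pairs[, 1]],
      hemisphere_target = nt$hemisphere[pairs[, 2]],
      weight = sal$edge_scores[[cl]])
    p1 <- file.path(dir, sprintf("%s_%s_edges.tsv", prefix, cl))
    utils::write.table(edge_df, p1, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    node_df <- data.frame(name = nt$name, hemisphere = nt$hemisphere,
                          score = sal$node_scores[[cl]])
    p2 <- file.path(dir, sprintf("%s_%s_nodes.tsv", prefix, cl))
    utils::write.table(node_df, p2, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p1, p2)
  }
  invisible(paths)
}
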