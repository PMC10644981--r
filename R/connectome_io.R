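#' Edge indexing for strict-upper-triangle vectorization
#'
#' A symmetric zero-diagonal n x n connectome has n(n-1)/2 unique edges.
#' The canonical flattening used throughout this package is the row-major
#' strict upper triangle: pairs (i, j) with i < j, ordered by i then j,
#' 1-based. For the 84-region DK parcellation this yields 3486 edges.
#' `edge_index` maps a node pair to its flat position, `edge_pair` inverts
#' it, and `edge_pairs` enumerates the full ordering.
#'
#' @param i,j Node indices, 1-based, with `i < j`. Vectorized.
#' @param k Flat edge index in `1..n(n-1)/2`. Vectorized.
#' @param n Number of nodes.
#' @return `edge_index`: integer flat indices. `edge_pair`: a two-column
#'   integer matrix with columns `i`, `j`. `edge_pairs`: the
#'   `n(n-1)/2 x 2` matrix of all pairs in canonical order.
#' @examples
#' edge_index(1, 2, 84)    # 1 (first edge)
#' edge_index(83, 84, 84)  # 3486 (last edge)
#' edge_pair(3486, 84)     # c(83, 84)
#' @export
edge_index <- function(i, j, n) {
  i <- as.integer(i); j <- as.integer(j); n <- as.integer(n)
  if (any(i < 1L) || any(j > n)) stop("node indices out of range 1..n")
  if (any(i >= j)) stop("edge_index requires i < j (strict upper triangle)")
  # edges with first node < i occupy sum_{r<i} (n - r) slots
  (i - 1L) * n - (i * (i - 1L)) %/% 2L + (j - i)
}

#' @rdname edge_index
#' @export
edge_pair <- function(k, n) {
  n <- as.integer(n)
  m <- (n * (n - 1L)) %/% 2L
  k <- as.integer(k)
  if (any(k < 1L) || any(k > m)) stop("flat edge index out of range 1..", m)
  # invert the row-major enumeration: find largest i with offset(i) < k
  ii <- integer(length(k)); jj <- integer(length(k))
  for (t in seq_along(k)) {
    i <- 1L
    off <- 0L
    while (off + (n - i) < k[t]) {
      off <- off + (n - i)
      i <- i + 1L
    }
    ii[t] <- i
    jj[t] <- i + (k[t] - off)
  }
  cbind(i = ii, j = jj)
}

#' @rdname edge_index
#' @export
edge_pairs <- function(n) {
  n <- as.integer(n)
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- sequence((n - 1L):1L, from = 2:n)
  cbind(i = i, j = j)
}

#' Connectome matrices
#'
#' A connectome is a symmetric, non-negative, zero-diagonal n x n matrix of
#' edge weights (streamline-weight units, arbitrary scale) over the regions
#' of a node table, optionally carrying a participant id and a binary group
#' label.
#'
#' `connectome()` validates a numeric matrix: the diagonal is zeroed with a
#' warning if non-zero (self-connections are excluded from analysis), and
#' asymmetry within relative tolerance `tol` is resolved by averaging
#' `(w_ij + w_ji)/2`; larger asymmetry is an error, as tractography builders
#' emit symmetric matrices and gross asymmetry indicates a corrupt file.
#'
#' @param weights Numeric n x n matrix, n = `nrow(node_table)`.
#' @param node_table A [dk_node_table()]-style node table.
#' @param participant_id Optional id string.
#' @param label Optional integer group label in `{0, 1}`.
#' @param tol Relative symmetry tolerance (default `1e-6`).
#' @return An object of class `connectome`: a list with elements `weights`,
#'   `participant_id`, `label`, `n_nodes`.
#' @export
connectome <- function(weights, node_table, participant_id = NA_character_,
                       label = NA_integer_, tol = 1e-6) {
  if (!is.matrix(weights) || !is.numeric(weights)) {
    stop("weights must be a numeric matrix")
  }
  n <- nrow(node_table)
  if (nrow(weights) != n || ncol(weights) != n) {
    stop("matrix is ", nrow(weights), "x", ncol(weights),
         " but node table has ", n, " regions")
  }
  if (anyNA(weights) || any(!is.finite(weights))) {
    stop("matrix contains non-finite values")
  }
  if (any(weights < 0)) stop("matrix contains negative edge weights")
  scale <- max(abs(weights), 1)
  asym <- max(abs(weights - t(weights)))
  if (asym > tol * scale) {
    stop("matrix asymmetry ", format(asym),
         " exceeds tolerance; refusing to symmetrize")
  }
  if (asym > 0) weights <- (weights + t(weights)) / 2
  if (any(diag(weights) != 0)) {
    warning("non-zero diagonal entries zeroed (self-connections excluded)")
    diag(weights) <- 0
  }
  if (!is.na(label) && !label %in% c(0L, 1L)) {
    stop("label must be 0, 1 or NA")
  }
  structure(
    list(weights = weights, participant_id = as.character(participant_id),
         label = if (is.na(label)) NA_integer_ else as.integer(label),
         n_nodes = n),
    class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat("Connectome:", x$n_nodes, "nodes,",
      sum(x$weights[upper.tri(x$weights)] > 0), "non-zero edges")
  if (!is.na(x$participant_id)) cat(", participant", x$participant_id)
  if (!is.na(x$label)) cat(", label", x$label)
  cat("\n")
  invisible(x)
}

#' Read and write connectome matrix files
#'
#' Matrix files are plain-text n x n numeric grids, whitespace- or
#' comma-delimited, as emitted by standard tractography connectome
#' builders. Validation and cleanup rules are those of [connectome()].
#'
#' @param path File path.
#' @param node_table Node table defining the expected dimension.
#' @param participant_id,label Optional metadata attached to the result.
#' @param m A `connectome` object (for `write_connectome`).
#' @return `load_connectome`: a validated `connectome`.
#' @export
load_connectome <- function(path, node_table, participant_id = NA_character_,
                            label = NA_integer_) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sep <- if (any(grepl(",", lines, fixed = TRUE))) "," else ""
  rows <- lapply(lines, function(l) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(l),
      if (sep == ",") "\\s*,\\s*" else "\\s+")[[1]]))
    if (anyNA(v)) stop("non-numeric content in ", path)
    v
  })
  n <- length(rows)
  if (any(lengths(rows) != n)) {
    stop("file ", path, " is not a square matrix")
  }
  w <- do.call(rbind, rows)
  connectome(w, node_table, participant_id = participant_id, label = label)
}

#' @rdname load_connectome
#' @export
write_connectome <- function(m, path) {
  w <- if (inherits(m, "connectome")) m$weights else m
  utils::write.table(format(w, digits = 17, scientific = TRUE, trim = TRUE),
                     path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Vectorize and devectorize connectomes
#'
#' `vectorize` flattens the strict upper triangle of a connectome into the
#' canonical edge vector (length n(n-1)/2; 3486 for 84 nodes);
#' `devectorize` rebuilds the symmetric zero-diagonal matrix. The two are
#' exact inverses.
#'
#' @param m A `connectome` or a symmetric numeric matrix.
#' @param v Edge vector of length n(n-1)/2.
#' @param n Number of nodes (for `devectorize`).
#' @return `vectorize`: numeric vector in canonical edge order.
#'   `devectorize`: symmetric n x n matrix.
#' @export
vectorize <- function(m) {
  w <- if (inherits(m, "connectome")) m$weights else m
  # row-major upper triangle of a symmetric matrix == column-major lower
  w[lower.tri(w)]
}

#' @rdname vectorize
#' @export
devectorize <- function(v, n) {
  m_len <- n * (n - 1L) / 2L
  if (length(v) != m_len) {
    stop("edge vector has length ", length(v), ", expected ", m_len)
  }
  w <- matrix(0, n, n)
  w[lower.tri(w)] <- v
  w + t(w)
}

#' Per-participant min-max normalization of an edge vector
#'
#' Rescales edge values to `[0, 1]`:
#' `(v - min(v)) / (max(v) - min(v))`. Applied per participant, so no
#' cohort statistic (and hence no test-set information) enters the
#' scaling. Rank order of edges is preserved.
#'
#' @param v Numeric edge vector with at least two distinct values.
#' @return Vector of the same length with minimum 0 and maximum 1.
#' @examples
#' normalize_edges(c(0, 5, 10))  # 0.0 0.5 1.0
#' @export
normalize_edges <- function(v) {
  if (anyNA(v) || any(!is.finite(v))) stop("edge vector must be finite")
  lo <- min(v); hi <- max(v)
  if (hi == lo) {
    stop("constant edge vector (max == min): degenerate connectome")
  }
  (v - lo) / (hi - lo)
}

#' Participant manifests and cohort loading
#'
#' A manifest is a TSV with header `participant_id  path  label` listing
#' one connectome matrix file per participant with its binary group label.
#' Relative `path` entries are resolved against the manifest's directory.
#'
#' @param path Manifest TSV path.
#' @param manifest A data.frame as returned by `read_manifest`.
#' @param node_table Node table for validation.
#' @return `read_manifest`: data.frame with columns `participant_id`,
#'   `path`, `label`. `load_cohort`: list of validated `connectome`
#'   objects, one per manifest row.
#' @export
read_manifest <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "character", "integer"))
  req <- c("participant_id", "path", "label")
  if (!all(req %in% names(df))) {
    stop("manifest must have columns: ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(df$participant_id)) {
    stop("duplicate participant ids in manifest")
  }
  if (!all(df$label %in% c(0L, 1L))) stop("labels must be 0 or 1")
  rel <- !grepl("^(/|[A-Za-z]:)", df$path)
  df$path[rel] <- file.path(dirname(path), df$path[rel])
  df
}

#' @rdname read_manifest
#' @export
load_cohort <- function(manifest, node_table) {
  lapply(seq_len(nrow(manifest)), function(r) {
    load_connectome(manifest$path[r], node_table,
                    participant_id = manifest$participant_id[r],
                    label = manifest$label[r])
  })
}

# Stack a cohort (list of connectomes) into the design matrix used by the
# classifier: one row per participant, normalized canonical edge vectors.
cohort_design <- function(cohort, normalize = TRUE) {
  X <- t(vapply(cohort, function(m) {
    v <- vectorize(m)
    if (normalize) normalize_edges(v) else v
  }, numeric(cohort[[1]]$n_nodes * (cohort[[1]]$n_nodes - 1L) / 2L)))
  rownames(X) <- vapply(cohort, `[[`, character(1), "participant_id")
  y <- vapply(cohort, `[[`, integer(1), "label")
  list(X = X, y = y)
}
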