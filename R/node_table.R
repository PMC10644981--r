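#' Atlas node tables
#'
#' A node table maps connectome matrix rows/columns to named brain regions
#' with a hemisphere code. The package ships the 84-region Desikan-Killiany
#' (DK) parcellation used by standard tractography connectome builders:
#' 2 x 34 cortical labels, 2 x 7 subcortical labels and the two cerebellar
#' cortices, ordered left hemisphere first.
#'
#' @section File format:
#' Tab-separated with header `index  name  hemisphere`. `index` is the
#' 0-based matrix row/column position (kept 0-based on disk for
#' interoperability with connectome builders); `hemisphere` is one of
#' `L`, `R`, `M` (midline). Inside R, rows are addressed 1-based.
#'
#' @param path Path to a node-table TSV.
#' @return A `data.frame` of class `conn_node_table` with columns
#'   `index` (0-based), `name`, `hemisphere`.
#' @examples
#' nt <- dk_node_table()
#' nrow(nt)   # 84
#' @name node-table
NULL

#' @rdname node-table
#' @export
read_node_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = c("integer", "character", "character"))
  validate_node_table(df)
}

#' @rdname node-table
#' @export
dk_node_table <- function() {
  path <- system.file("extdata", "dk84_nodes.tsv", package = "connectomlp",
                      mustWork = TRUE)
  read_node_table(path)
}

validate_node_table <- function(df) {
  req <- c("index", "name", "hemisphere")
  if (!all(req %in% names(df))) {
    stop("node table must have columns: ", paste(req, collapse = ", "))
  }
  n <- nrow(df)
  if (n < 2L) stop("node table needs at least 2 nodes")
  if (!identical(as.integer(df$index), 0:(n - 1L))) {
    stop("node table 'index' must be exactly 0..", n - 1L,
         " in order, without gaps or duplicates")
  }
  if (anyDuplicated(df$name)) stop("node table names must be unique")
  bad <- setdiff(unique(df$hemisphere), c("L", "R", "M"))
  if (length(bad)) {
    stop("unknown hemisphere code(s): ", paste(bad, collapse = ", "))
  }
  class(df) <- c("conn_node_table", "data.frame")
  df
}

#' @export
print.conn_node_table <- function(x, ...) {
  cat("Node table:", nrow(x), "regions (",
      sum(x$hemisphere == "L"), "L /", sum(x$hemisphere == "R"), "R /",
      sum(x$hemisphere == "M"), "M )\n")
  print.data.frame(utils::head(x, 4))
  if (nrow(x) > 4) cat("  ...", nrow(x) - 4, "more rows\n")
  invisible(x)
}

# Node names for a vector of 1-based node ids.
node_names <- function(ids, node_table) {
  stopifnot(all(ids >= 1L), all(ids <= nrow(node_table)))
  node_table$name[ids]
}

# 1-based node ids for a vector of names; errors on unknown names.
node_ids <- function(names, node_table) {
  idx <- match(names, node_table$name)
  if (anyNA(idx)) {
    stop("unknown node name(s): ",
         paste(unique(names[is.na(idx)]), collapse = ", "))
  }
  idx
}
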