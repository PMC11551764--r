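# Serialization of connectomes to a single self-describing JSON container:
# node table columns, CSR-style edge arrays (row pointers, 0-based column
# indices, weights) and metadata. The layout is canonical (nodes sorted by
# id, edges in CSR order) so re-serialising a loaded connectome is
# byte-identical.

CONNECTOME_FORMAT_VERSION <- 1L

#' Save and load connectomes
#'
#' Writes a connectome to a single JSON container holding the node table,
#' CSR-style edge arrays (row pointers, column indices, weights) and
#' metadata (units, format version).  The round trip is lossless and the
#' serialisation canonical: saving a loaded connectome reproduces the file
#' byte for byte.
#'
#' @param conn A `connectome`.
#' @param path File path (conventionally `.json`).
#' @return `load_connectome()` returns a `connectome`;
#'   `save_connectome()` returns `path` invisibly.
#' @export
save_connectome <- function(conn, path) {
  ord <- order(conn$nodes$neuron_id)
  nodes <- conn$nodes[ord, , drop = FALSE]
  adj <- conn$adj[ord, ord, drop = FALSE]
  csr <- methods::as(Matrix::t(adj), "CsparseMatrix")  # CSC of t = CSR
  payload <- list(
    format = "neurotopo-connectome",
    version = CONNECTOME_FORMAT_VERSION,
    units = conn$meta$units %||% "um",
    n_nodes = nrow(nodes),
    nodes = as.list(nodes),
    edges = list(indptr = csr@p, indices = csr@i, weights = csr@x))
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           null = "null")
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname save_connectome
#' @export
load_connectome <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(payload$format, "neurotopo-connectome")) {
    abort("Not a neurotopo connectome container.")
  }
  if (!identical(as.integer(payload$version), CONNECTOME_FORMAT_VERSION)) {
    abort(paste0("Connectome container version ", payload$version,
                 " is not supported (expected ",
                 CONNECTOME_FORMAT_VERSION, ")."))
  }
  nodes <- tibble::as_tibble(payload$nodes)
  nodes$neuron_id <- as.numeric(nodes$neuron_id)
  n <- payload$n_nodes
  indptr <- as.integer(payload$edges$indptr)
  indices <- as.integer(payload$edges$indices)
  weights <- as.numeric(payload$edges$weights)
  if (length(weights) == 0L) weights <- numeric(0)
  adj <- Matrix::sparseMatrix(i = rep(seq_len(n), diff(indptr)),
                              j = indices + 1L, x = weights, dims = c(n, n),
                              dimnames = list(as.character(nodes$neuron_id),
                                              as.character(nodes$neuron_id)))
  new_connectome(nodes, methods::as(adj, "CsparseMatrix"),
                 meta = list(units = payload$units))
}
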