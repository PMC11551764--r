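#' Neuron and synapse tables
#'
#' A *neuron table* is a tibble with one row per neuron and columns
#' `neuron_id` (unique identifier), `x`, `y`, `z` (soma position in
#' micrometres), `synapse_class` (`"E"` or `"I"`), and optionally
#' `cell_type`, `proofreading_axon` and `proofreading_dendrite`.  A
#' *synapse table* is a tibble with columns `pre_id`, `post_id` and
#' optionally `synapse_count` (defaults to one synapse per row, so
#' per-synapse tables work unchanged).
#'
#' `as_neuron_table()` validates and normalises a data frame into this
#' shape; `read_neuron_table()` / `read_synapse_table()` read CSV (or
#' Parquet, when the arrow package is installed) files, renaming columns
#' according to `columns`.  Defaults match the MICrONS-style column names
#' (`pt_root_id`, `pre_pt_root_id`, `post_pt_root_id`).  Coordinates can be
#' converted from voxel indices with `voxel_resolution` (in nanometres per
#' voxel; positions are stored in micrometres).
#'
#' `dedupe_neurons()` drops *all* rows whose `neuron_id` occurs more than
#' once: duplicated ids typically indicate erroneously merged cells, so no
#' row of such an id can be trusted.
#'
#' @param x A data frame.
#' @param path Path to a `.csv` or `.parquet` file.
#' @param columns Named character vector mapping the canonical column names
#'   to the names used in the file, e.g.
#'   `c(neuron_id = "pt_root_id", x = "x", ...)`.
#' @param voxel_resolution Optional numeric length-3 vector of nanometres
#'   per voxel (e.g. `c(4, 4, 40)`); if supplied, coordinates are
#'   multiplied by it and converted to micrometres.
#' @param neurons A neuron table.
#' @return A tibble.
#' @name neuron_table
NULL

#' @rdname neuron_table
#' @export
as_neuron_table <- function(x) {
  x <- tibble::as_tibble(x)
  needed <- c("neuron_id", "x", "y", "z", "synapse_class")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols) > 0L) {
    abort(paste0("Neuron table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(x) == 0L) abort("Neuron table is empty.")
  coords <- as.matrix(x[, c("x", "y", "z")])
  bad <- which(!apply(is.finite(coords), 1L, all))
  if (length(bad) > 0L) {
    abort(paste0("Non-finite coordinates in neuron table row(s): ",
                 paste(head(bad, 5L), collapse = ", ")))
  }
  if (anyNA(x$synapse_class) || !all(x$synapse_class %in% c("E", "I"))) {
    abort("`synapse_class` must be 'E' or 'I' for every neuron.")
  }
  x$neuron_id <- as.numeric(x$neuron_id)
  x
}

#' @rdname neuron_table
#' @export
dedupe_neurons <- function(neurons) {
  neurons <- tibble::as_tibble(neurons)
  dup_ids <- unique(neurons$neuron_id[duplicated(neurons$neuron_id)])
  if (length(dup_ids) > 0L) {
    rlang::inform(paste0("Dropping ", sum(neurons$neuron_id %in% dup_ids),
                         " rows with ", length(dup_ids),
                         " duplicated neuron id(s)."))
    neurons <- neurons[!neurons$neuron_id %in% dup_ids, , drop = FALSE]
  }
  neurons
}

read_table_file <- function(path) {
  if (grepl("\\.parquet$", path, ignore.case = TRUE)) {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      abort("Reading Parquet requires the arrow package.")
    }
    tibble::as_tibble(arrow::read_parquet(path))
  } else {
    tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  }
}

rename_by_map <- function(x, columns) {
  for (canon in names(columns)) {
    src <- columns[[canon]]
    if (src %in% names(x) && !identical(src, canon)) {
      names(x)[names(x) == src] <- canon
    }
  }
  x
}

#' @rdname neuron_table
#' @export
read_neuron_table <- function(path,
                              columns = c(neuron_id = "pt_root_id",
                                          x = "x", y = "y", z = "z",
                                          synapse_class = "synapse_class"),
                              voxel_resolution = NULL) {
  x <- rename_by_map(read_table_file(path), columns)
  if (!is.null(voxel_resolution)) {
    stopifnot(length(voxel_resolution) == 3L)
    x$x <- x$x * voxel_resolution[1] / 1000
    x$y <- x$y * voxel_resolution[2] / 1000
    x$z <- x$z * voxel_resolution[3] / 1000
  }
  as_neuron_table(dedupe_neurons(x))
}

#' @rdname neuron_table
#' @export
read_synapse_table <- function(path,
                               columns = c(pre_id = "pre_pt_root_id",
                                           post_id = "post_pt_root_id",
                                           synapse_count = "synapse_count")) {
  x <- rename_by_map(read_table_file(path), columns)
  if (!all(c("pre_id", "post_id") %in% names(x))) {
    abort("Synapse table must have `pre_id` and `post_id` columns.")
  }
  if (!"synapse_count" %in% names(x)) x$synapse_count <- 1L
  tibble::as_tibble(x)
}

new_connectome <- function(nodes, adj, meta = list()) {
  structure(list(nodes = nodes, adj = adj, meta = meta),
            class = "connectome")
}

#' Build a connectome from neuron and synapse tables
#'
#' Aggregates synapse rows into a directed simple graph with integer
#' synapse-count edge weights.  Synapse rows whose `pre_id` or `post_id`
#' is absent from the neuron table are dropped (unmatched fragments), as
#' are self-loop rows (autapses); the number of rows dropped for each
#' reason is recorded in the `drop_log` element of the result's metadata.
#'
#' @param neurons A neuron table (see [as_neuron_table()]).  Duplicate
#'   `neuron_id` rows should already have been removed with
#'   [dedupe_neurons()]; any remaining duplicates are dropped with a
#'   warning.
#' @param synapses A synapse table with columns `pre_id`, `post_id` and
#'   optionally `synapse_count`.
#' @return A `connectome` object: node tibble plus a sparse adjacency
#'   matrix whose entry \eqn{(u, v)} is the total synapse count of the
#'   connection \eqn{u \to v}.
#' @examples
#' neurons <- tibble::tibble(neuron_id = 1:3, x = 0, y = 0, z = 0,
#'                           synapse_class = "E")
#' synapses <- tibble::tibble(pre_id = c(1, 1, 2), post_id = c(2, 2, 3))
#' conn <- build_connectome(neurons, synapses)
#' connectome_edges(conn)
#' @export
build_connectome <- function(neurons, synapses) {
  neurons <- as_neuron_table(neurons)
  if (anyDuplicated(neurons$neuron_id)) {
    warn("Neuron table has duplicated ids; dropping all their rows.")
    neurons <- dedupe_neurons(neurons)
    if (nrow(neurons) == 0L) abort("Neuron table is empty after deduplication.")
  }
  synapses <- tibble::as_tibble(synapses)
  if (!"synapse_count" %in% names(synapses)) synapses$synapse_count <- 1L
  if (nrow(synapses) > 0L &&
      any(!is.finite(synapses$synapse_count) | synapses$synapse_count < 1)) {
    abort("`synapse_count` must be a positive integer for every row.")
  }
  n_total <- nrow(synapses)
  known <- synapses$pre_id %in% neurons$neuron_id &
    synapses$post_id %in% neurons$neuron_id
  n_unknown <- sum(!known)
  synapses <- synapses[known, , drop = FALSE]
  loop <- synapses$pre_id == synapses$post_id
  n_loops <- sum(loop)
  synapses <- synapses[!loop, , drop = FALSE]

  ids <- neurons$neuron_id
  n <- length(ids)
  if (nrow(synapses) > 0L) {
    agg <- synapses |>
      dplyr::group_by(.data$pre_id, .data$post_id) |>
      dplyr::summarise(weight = sum(.data$synapse_count), .groups = "drop")
    adj <- Matrix::sparseMatrix(
      i = match(agg$pre_id, ids), j = match(agg$post_id, ids),
      x = as.numeric(agg$weight), dims = c(n, n),
      dimnames = list(as.character(ids), as.character(ids)))
  } else {
    adj <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                dims = c(n, n),
                                dimnames = list(as.character(ids),
                                                as.character(ids)))
  }
  drop_log <- tibble::tibble(
    reason = c("unknown_endpoint", "self_loop"),
    n_rows = c(n_unknown, n_loops))
  new_connectome(neurons, adj,
                 meta = list(units = "um", drop_log = drop_log,
                             n_synapse_rows = n_total))
}

#' Connectome accessors
#'
#' `connectome_nodes()` returns the node (neuron) table,
#' `connectome_edges()` the directed weighted edge list as a tibble with
#' columns `pre_id`, `post_id` and `count`, and `as_igraph()` an igraph
#' representation (edge attribute `weight` carries the synapse count).
#' `induced_connectome()` restricts a connectome to a subset of neuron
#' ids, keeping the edges among them.
#'
#' @param conn A `connectome`.
#' @param ids Neuron ids to keep.
#' @name connectome-accessors
NULL

#' @rdname connectome-accessors
#' @export
connectome_nodes <- function(conn) conn$nodes

#' @rdname connectome-accessors
#' @export
connectome_edges <- function(conn) {
  tm <- methods::as(conn$adj, "TsparseMatrix")
  ids <- conn$nodes$neuron_id
  tibble::tibble(pre_id = ids[tm@i + 1L], post_id = ids[tm@j + 1L],
                 count = tm@x) |>
    dplyr::arrange(.data$pre_id, .data$post_id)
}

#' @rdname connectome-accessors
#' @export
as_igraph <- function(conn) {
  g <- igraph::graph_from_adjacency_matrix(conn$adj, mode = "directed",
                                           weighted = TRUE)
  igraph::set_vertex_attr(g, "synapse_class",
                          value = conn$nodes$synapse_class)
}

#' @rdname connectome-accessors
#' @export
induced_connectome <- function(conn, ids) {
  keep <- conn$nodes$neuron_id %in% ids
  if (!any(keep)) abort("No requested ids are present in the connectome.")
  new_connectome(conn$nodes[keep, , drop = FALSE],
                 conn$adj[keep, keep, drop = FALSE], conn$meta)
}

#' @rdname connectome-accessors
#' @export
excitatory_ids <- function(conn) {
  conn$nodes$neuron_id[conn$nodes$synapse_class == "E"]
}

#' @rdname connectome-accessors
#' @export
inhibitory_ids <- function(conn) {
  conn$nodes$neuron_id[conn$nodes$synapse_class == "I"]
}

n_nodes <- function(conn) nrow(conn$nodes)
n_edges <- function(conn) length(conn$adj@x)

#' @exportS3Method base::print
print.connectome <- function(x, ...) {
  cat("<connectome> ", nrow(x$nodes), " neurons (",
      sum(x$nodes$synapse_class == "E"), " E / ",
      sum(x$nodes$synapse_class == "I"), " I), ",
      n_edges(x), " connections, ", sum(x$adj@x), " synapses\n", sep = "")
  invisible(x)
}

#' @exportS3Method base::format
format.connectome <- function(x, ...) {
  paste0("<connectome: ", nrow(x$nodes), " nodes, ", n_edges(x), " edges>")
}
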