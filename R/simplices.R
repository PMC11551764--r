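#' Enumerate directed simplices (directed flag complex)
#'
#' A directed simplex of dimension \eqn{d} is a motif of \eqn{d + 1}
#' distinct neurons admitting a numbering from 0 (*source position*) to
#' \eqn{d} (*target position*) such that a connection runs from every
#' lower- to every higher-numbered member.  Enumeration extends ordered
#' cliques by the intersection of the out-neighbourhoods of all current
#' members, so each simplex is produced exactly once; reciprocal edges
#' yield distinct simplices for each valid ordering.  The motif dimension
#' is conventionally computed on the excitatory subgraph — pass the
#' subgraph of interest ([induced_connectome()]).
#'
#' Listing (rather than counting) simplex tuples can exhaust memory in
#' dense graphs; listing above `list_guard` therefore requires raising
#' that limit explicitly.
#'
#' @param graph A `connectome`, or a square (sparse) adjacency matrix
#'   whose nonzero entries are directed edges.  Self-loops are not
#'   allowed.
#' @param max_dim Largest dimension to enumerate (`NULL`: until no
#'   simplices remain).
#' @param list_tuples Record the node tuples (needed by all downstream
#'   per-simplex statistics), or only count.
#' @param list_guard Largest dimension whose tuples may be recorded
#'   without an explicit opt-in.
#' @return A `simplex_table`: per-dimension counts and (optionally) one
#'   integer matrix of node ids per dimension, rows = simplices, columns
#'   = positions 0..dim.
#' @examples
#' conn <- transitive_tournament(4)
#' st <- enumerate_simplices(conn)
#' simplex_counts(st)  # 4, 6, 4, 1
#' @export
enumerate_simplices <- function(graph, max_dim = NULL, list_tuples = TRUE,
                                list_guard = 10L) {
  if (inherits(graph, "connectome")) {
    adj <- graph$adj
    ids <- graph$nodes$neuron_id
  } else {
    adj <- methods::as(graph, "CsparseMatrix")
    ids <- if (!is.null(rownames(adj))) as.numeric(rownames(adj))
           else seq_len(nrow(adj))
  }
  n <- nrow(adj)
  if (n > 0 && any(Matrix::diag(adj) != 0)) {
    abort("Graph must not contain self-loops.")
  }
  if (list_tuples && !is.null(max_dim) && max_dim > list_guard) {
    abort(paste0("Listing simplices above dimension ", list_guard,
                 " requires raising `list_guard` explicitly."))
  }
  csr <- methods::as(Matrix::t(adj), "CsparseMatrix")  # CSC of t = out-CSR
  md <- if (is.null(max_dim)) -1L else as.integer(max_dim)
  ld <- if (!list_tuples) -1L else if (is.null(max_dim)) list_guard
        else as.integer(max_dim)
  res <- flag_complex_cpp(csr@p, csr@i, n, md, ld)
  counts <- res$counts
  names(counts) <- as.character(seq_along(counts) - 1L)
  tuples <- NULL
  if (list_tuples) {
    tuples <- lapply(res$tuples, function(m) {
      m[] <- ids[m + 1L]
      m
    })
    names(tuples) <- as.character(seq_along(tuples) - 1L)
  }
  structure(list(counts = counts, tuples = tuples, node_ids = ids),
            class = "simplex_table")
}

#' @exportS3Method base::print
print.simplex_table <- function(x, ...) {
  cat("<simplex_table> counts by dimension:\n")
  print(x$counts)
  invisible(x)
}

#' Simplex table accessors
#'
#' `simplex_counts()` returns the per-dimension simplex counts as a
#' tibble, `simplex_tuples()` the matrix of node ids for one dimension
#' (rows = simplices, columns = positions 0..dim), and
#' `max_simplex_dim()` the largest dimension with a nonzero count.
#'
#' @param st A `simplex_table`.
#' @param dim Dimension.
#' @name simplex_table-accessors
#' @export
simplex_counts <- function(st) {
  tibble::tibble(dim = as.integer(names(st$counts)),
                 count = as.numeric(st$counts))
}

#' @rdname simplex_table-accessors
#' @export
simplex_tuples <- function(st, dim) {
  st$tuples[[as.character(dim)]]
}

#' @rdname simplex_table-accessors
#' @export
max_simplex_dim <- function(st) {
  nz <- which(st$counts > 0)
  if (length(nz) == 0L) return(NA_integer_)
  as.integer(names(st$counts)[max(nz)])
}

#' @export
tidy.simplex_table <- function(x, ...) simplex_counts(x)

#' @export
glance.simplex_table <- function(x, ...) {
  tibble::tibble(n_nodes = length(x$node_ids),
                 n_edges = as.numeric(x$counts["1"] %||% 0),
                 max_dim = max_simplex_dim(x))
}

# Long view of one dimension's tuples: (simplex, position, node_id).
melt_simplices <- function(tuples) {
  if (is.null(tuples) || nrow(tuples) == 0L) {
    return(tibble::tibble(simplex = integer(), position = integer(),
                          node_id = numeric()))
  }
  tibble::tibble(simplex = rep(seq_len(nrow(tuples)), ncol(tuples)),
                 position = rep(seq_len(ncol(tuples)) - 1L,
                                each = nrow(tuples)),
                 node_id = as.vector(tuples))
}

#' Fraction of unique neurons by simplex position
#'
#' Because a neuron can sit in the same position of many simplices, the
#' number of *unique* neurons at a position, divided by the simplex
#' count, measures how concentrated that position is.  A profile rising
#' from source to target reveals divergent feed-forward flow: few shared
#' sources feeding many distinct targets.  The profile is also returned
#' normalised to its value at the source position.
#'
#' @param st A `simplex_table` with tuples.
#' @param dim Dimension to profile.
#' @return A tibble with columns `position`, `fraction`, `normalized`
#'   (all `NA` with a warning when there are no simplices at `dim`).
#' @export
unique_fraction_by_position <- function(st, dim) {
  tuples <- simplex_tuples(st, dim)
  if (is.null(tuples) || nrow(tuples) == 0L) {
    warn(paste0("No simplices of dimension ", dim, "."))
    return(tibble::tibble(position = 0:dim, fraction = NA_real_,
                          normalized = NA_real_))
  }
  frac <- apply(tuples, 2, function(col) length(unique(col))) / nrow(tuples)
  tibble::tibble(position = 0:dim, fraction = frac,
                 normalized = frac / frac[1])
}

#' Node participation counts
#'
#' Counts, for every (dimension, position, node), the number of simplices
#' containing the node at that position.  Only nonzero counts are
#' returned.
#'
#' @param st A `simplex_table` with tuples.
#' @param dims Dimensions to include (default: all listed).
#' @return A tibble with columns `dim`, `position`, `node_id`,
#'   `n_simplices`.
#' @export
node_participation <- function(st, dims = NULL) {
  dims <- dims %||% as.integer(names(st$tuples))
  purrr::map_dfr(dims, function(d) {
    melt_simplices(simplex_tuples(st, d)) |>
      dplyr::count(.data$position, .data$node_id, name = "n_simplices") |>
      dplyr::mutate(dim = d, .before = 1L)
  })
}

#' Maximal simplex dimension of each edge
#'
#' An edge \eqn{(u, v)} participates in a simplex if \eqn{u} occupies
#' position \eqn{i} and \eqn{v} position \eqn{j} with \eqn{i < j} in that
#' simplex.  Every edge is itself a 1-simplex, so the minimum is 1.
#'
#' @param st A `simplex_table` with tuples (the 1-dimensional tuples must
#'   be present; they define the edge set).
#' @return A tibble with columns `pre_id`, `post_id`, `dim`.
#' @export
edge_max_dimension <- function(st) {
  edges <- simplex_tuples(st, 1L)
  if (is.null(edges)) abort("Simplex table has no 1-dimensional tuples.")
  out <- tibble::tibble(pre_id = edges[, 1], post_id = edges[, 2],
                        dim = 1L)
  listed <- as.integer(names(st$tuples))
  for (d in sort(listed[listed >= 2L], decreasing = TRUE)) {
    tuples <- simplex_tuples(st, d)
    if (is.null(tuples) || nrow(tuples) == 0L) next
    pairs <- which(upper.tri(diag(d + 1L)), arr.ind = TRUE)
    pe <- unique(tibble::tibble(pre_id = as.vector(tuples[, pairs[, 1]]),
                                post_id = as.vector(tuples[, pairs[, 2]])))
    idx <- match(paste(out$pre_id, out$post_id),
                 paste(pe$pre_id, pe$post_id))
    out$dim[!is.na(idx) & out$dim < d] <- d
  }
  out
}

#' Nodes participating in at least one simplex of a dimension
#'
#' The simplex `k`-core of a network (e.g. the "6-core") is the set of
#' neurons participating in at least one directed simplex of dimension
#' `k`.
#'
#' @param st A `simplex_table` with tuples.
#' @param dim Dimension.
#' @return A numeric vector of node ids (empty above the maximal
#'   dimension).
#' @export
simplex_core <- function(st, dim) {
  tuples <- simplex_tuples(st, dim)
  if (is.null(tuples) || nrow(tuples) == 0L) return(numeric(0))
  sort(unique(as.vector(tuples)))
}

#' Transitive tournament connectome
#'
#' The complete directed acyclic graph on `n` nodes (edge \eqn{i \to j}
#' for every \eqn{i < j}); its directed simplex count at dimension `d` is
#' `choose(n, d + 1)`.  A convenient closed-form fixture.
#'
#' @param n Number of nodes.
#' @return A `connectome` of `n` excitatory nodes.
#' @export
transitive_tournament <- function(n) {
  neurons <- tibble::tibble(neuron_id = seq_len(n), x = seq_len(n),
                            y = 0, z = 0, synapse_class = "E")
  pairs <- which(upper.tri(diag(n)), arr.ind = TRUE)
  build_connectome(neurons, tibble::tibble(pre_id = pairs[, 1],
                                           post_id = pairs[, 2]))
}
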