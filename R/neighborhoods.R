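#' Neighborhood subgraph of a node
#'
#' The induced subgraph on a node together with all its afferents and
#' efferents (in- and out-neighbours) and the connections between them.
#'
#' @param conn A `connectome`.
#' @param node A neuron id.
#' @return A `connectome` restricted to the neighbourhood.
#' @export
neighborhood_subgraph <- function(conn, node) {
  idx <- match(node, conn$nodes$neuron_id)
  if (is.na(idx)) abort(paste0("Node ", node, " is not in the connectome."))
  nbr <- union(which(conn$adj[idx, ] > 0), which(conn$adj[, idx] > 0))
  induced_connectome(conn, conn$nodes$neuron_id[union(idx, nbr)])
}

#' First Wasserstein distance between two empirical distributions
#'
#' \eqn{W_1 = \int |F_x(t) - F_y(t)|\,dt} over the empirical CDFs.  For
#' samples of equal size this reduces to the mean absolute difference of
#' the sorted samples; unequal sizes are handled by the general
#' CDF-difference integral.
#'
#' @param x,y Numeric samples.
#' @return A nonnegative number.
#' @export
wasserstein1 <- function(x, y) {
  stopifnot(length(x) > 0L, length(y) > 0L)
  if (length(x) == length(y)) {
    return(mean(abs(sort(x) - sort(y))))
  }
  grid <- sort(unique(c(x, y)))
  if (length(grid) == 1L) return(0)
  fx <- stats::ecdf(x)(grid)
  fy <- stats::ecdf(y)(grid)
  sum(abs(fx - fy)[-length(grid)] * diff(grid))
}

#' Neighborhood complexity of a node
#'
#' Compares the neighbourhood of a neuron in the observed graph with the
#' neighbourhood of the same neuron in a degree-preserving
#' (configuration-model) control: the W1 (Wasserstein) distance between
#' the distributions of node degrees within the two neighbourhood
#' subgraphs.  Because the control preserves every neuron's in- and
#' out-degree, both neighbourhoods have (essentially) the same size but
#' can differ in internal structure; a large distance marks a
#' neighbourhood whose internal wiring deviates from degree-matched
#' chance.
#'
#' @param conn A `connectome`.
#' @param control A degree-preserving control of `conn`
#'   ([configuration_model()]).
#' @param nodes Neuron ids to score (default: all).
#' @param degree Degree flavour inside the neighbourhood subgraph:
#'   total (in + out), in, or out.
#' @return A tibble with columns `node_id`, `size_graph`,
#'   `size_control`, `w1` (`NA` for nodes with no neighbours).
#' @export
neighborhood_complexity <- function(conn, control, nodes = NULL,
                                    degree = c("total", "in", "out")) {
  degree <- match.arg(degree)
  nodes <- nodes %||% conn$nodes$neuron_id
  deg_of <- function(sub) {
    a <- sub$adj > 0
    switch(degree,
           total = Matrix::rowSums(a) + Matrix::colSums(a),
           `in` = Matrix::colSums(a),
           out = Matrix::rowSums(a))
  }
  purrr::map_dfr(nodes, function(v) {
    sg <- neighborhood_subgraph(conn, v)
    sc <- neighborhood_subgraph(control, v)
    if (n_nodes(sg) <= 1L || n_nodes(sc) <= 1L) {
      return(tibble::tibble(node_id = v, size_graph = n_nodes(sg),
                            size_control = n_nodes(sc), w1 = NA_real_))
    }
    tibble::tibble(node_id = v, size_graph = n_nodes(sg),
                   size_control = n_nodes(sc),
                   w1 = wasserstein1(deg_of(sg), deg_of(sc)))
  })
}

#' Mean neighborhood complexity per simplex dimension and position
#'
#' Averages [neighborhood_complexity()] scores over the distinct nodes
#' participating at each (dimension, position); nodes in no simplex of a
#' dimension are excluded from that dimension's rows.
#'
#' @param records A [neighborhood_complexity()] result.
#' @param st A `simplex_table` with tuples.
#' @param dims Dimensions to include (default: all listed with
#'   simplices).
#' @return A tibble with columns `dim`, `position`, `mean_w1`,
#'   `n_nodes`.
#' @export
complexity_by_position <- function(records, st, dims = NULL) {
  listed <- as.integer(names(st$tuples))
  dims <- dims %||% listed[vapply(st$tuples, nrow, 1L) > 0]
  purrr::map_dfr(dims, function(d) {
    melt_simplices(simplex_tuples(st, d)) |>
      dplyr::distinct(.data$position, .data$node_id) |>
      dplyr::inner_join(records, by = "node_id") |>
      dplyr::group_by(.data$position) |>
      dplyr::summarise(mean_w1 = mean(.data$w1, na.rm = TRUE),
                       n_nodes = dplyr::n(), .groups = "drop") |>
      dplyr::mutate(dim = d, .before = 1L)
  })
}
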