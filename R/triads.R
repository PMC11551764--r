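# Triad census: the 13 connected directed triad classes, estimated by
# uniform sampling of connected triads and linear scaling to the exact
# connected-triad total.

# igraph triad_census order; the first three classes (003, 012, 102) have
# an isolated node and are not connected triads.
TRIAD_CLASSES <- c("003", "012", "102", "021D", "021U", "021C", "111D",
                   "111U", "030T", "030C", "201", "120D", "120U", "120C",
                   "210", "300")
CONNECTED_TRIADS <- TRIAD_CLASSES[-(1:3)]

# Classify a triad by the 6 ordered-edge bits (uv, vu, uw, wu, vw, wv)
# against a lookup table built once from igraph's own census.
triad_class_table <- local({
  tbl <- NULL
  function() {
    if (!is.null(tbl)) return(tbl)
    out <- character(64)
    pairs <- rbind(c(1, 2), c(2, 1), c(1, 3), c(3, 1), c(2, 3), c(3, 2))
    for (code in 0:63) {
      bits <- as.integer(intToBits(code))[1:6]
      el <- pairs[bits == 1L, , drop = FALSE]
      g <- igraph::make_empty_graph(3, directed = TRUE)
      if (nrow(el) > 0L) g <- igraph::add_edges(g, as.vector(t(el)))
      out[code + 1] <- TRIAD_CLASSES[which(igraph::triad_census(g) == 1)]
    }
    tbl <<- out
    tbl
  }
})

#' Estimate the census of connected triad motifs
#'
#' Counts the 13 connected three-node motif classes of a directed graph.
#' The exact number of connected triads is computed in closed form
#' (wedges of the underlying undirected graph minus twice its triangle
#' count).  When that total is at most `n_samples` the census is exact
#' (via [igraph::triad_census()]); otherwise connected triads are sampled
#' uniformly — an undirected edge and a third node are drawn at random
#' and the triad is accepted with probability inversely proportional to
#' its undirected edge count — classified, and class frequencies scaled
#' linearly to the total.
#'
#' @param conn A `connectome` or igraph graph.
#' @param n_samples Number of sampled triads.
#' @param seed Optional RNG seed.
#' @return A tibble with columns `class` (MAN label), `count` (estimate),
#'   `exact` (logical).
#' @export
triad_census_estimate <- function(conn, n_samples = 10000L, seed = NULL) {
  g <- if (inherits(conn, "connectome")) as_igraph(conn) else conn
  ug <- igraph::as_undirected(g, mode = "collapse")
  deg <- igraph::degree(ug)
  wedges <- sum(choose(deg, 2))
  n_tri <- sum(igraph::count_triangles(ug)) / 3
  total <- wedges - 2 * n_tri
  if (total <= 0) {
    return(tibble::tibble(class = CONNECTED_TRIADS, count = 0,
                          exact = TRUE))
  }
  if (total <= n_samples) {
    census <- igraph::triad_census(g)
    return(tibble::tibble(class = CONNECTED_TRIADS,
                          count = as.numeric(census[-(1:3)]),
                          exact = TRUE))
  }
  el <- igraph::as_edgelist(ug, names = FALSE)
  n <- igraph::vcount(g)
  adj_dir <- igraph::as_adjacency_matrix(g, sparse = TRUE) > 0
  has_edge <- function(a, b) adj_dir[a, b]
  counts <- setNames(numeric(length(CONNECTED_TRIADS)), CONNECTED_TRIADS)
  tbl <- triad_class_table()
  with_rng_seed(seed, {
    accepted <- 0L
    while (accepted < n_samples) {
      e <- el[sample.int(nrow(el), 1L), ]
      w <- sample.int(n, 1L)
      if (w == e[1] || w == e[2]) next
      u <- e[1]; v <- e[2]
      uw <- has_edge(u, w) || has_edge(w, u)
      vw <- has_edge(v, w) || has_edge(w, v)
      if (!uw && !vw) next  # disconnected triad
      n_und <- 1L + uw + vw
      if (runif(1) >= 1 / n_und) next  # uniformity correction
      bits <- c(has_edge(u, v), has_edge(v, u), has_edge(u, w),
                has_edge(w, u), has_edge(v, w), has_edge(w, v))
      code <- sum(2^(0:5) * bits)
      cls <- tbl[code + 1]
      counts[cls] <- counts[cls] + 1
      accepted <- accepted + 1L
    }
  })
  tibble::tibble(class = CONNECTED_TRIADS,
                 count = as.numeric(counts) / n_samples * total,
                 exact = FALSE)
}
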