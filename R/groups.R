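#' Louvain grouping of simplices by overlap
#'
#' Clusters simplices on the weighted graph whose adjacency is an overlap
#' matrix (diagonal zeroed — self-overlap is not affinity), using the
#' Louvain modularity algorithm.  Clustering the source-side overlap
#' yields *source groups* (simplices sharing source neurons, i.e. driven
#' together); the target-side overlap yields *target groups*.
#'
#' @param overlap A symmetric nonnegative overlap matrix
#'   ([overlap_matrix()]).
#' @param resolution Louvain resolution parameter (default 2.2; larger
#'   values produce more, smaller groups).
#' @param seed Optional RNG seed (Louvain is greedy and order-dependent).
#' @param n_restarts Number of runs; the partition with the best
#'   modularity is kept.
#' @return A `group_assignment`: tibble with columns `simplex` and
#'   `group` (contiguous labels from 0), carrying the resolution and
#'   modularity as attributes.
#' @export
cluster_simplices <- function(overlap, resolution = 2.2, seed = NULL,
                              n_restarts = 1L) {
  m <- methods::as(overlap, "CsparseMatrix")
  stopifnot(nrow(m) == ncol(m))
  Matrix::diag(m) <- 0
  m <- Matrix::drop0(m)
  s <- nrow(m)
  if (length(m@x) == 0L) {
    warn("All-zero overlap matrix; every simplex forms its own group.")
    assign <- tibble::tibble(simplex = seq_len(s), group = seq_len(s) - 1L)
    return(structure(assign, class = c("group_assignment", class(assign)),
                     resolution = resolution, modularity = NA_real_))
  }
  g <- igraph::graph_from_adjacency_matrix(m, mode = "undirected",
                                           weighted = TRUE)
  with_rng_seed(seed, {
    best <- NULL
    for (r in seq_len(max(1L, n_restarts))) {
      cl <- igraph::cluster_louvain(g, resolution = resolution)
      q <- max(igraph::modularity(cl))
      if (is.null(best) || q > best$q) best <- list(cl = cl, q = q)
    }
    memb <- igraph::membership(best$cl)
    # contiguous labels from 0, ordered by first appearance
    lab <- as.integer(factor(memb, levels = unique(memb))) - 1L
    assign <- tibble::tibble(simplex = seq_len(s), group = lab)
    structure(assign, class = c("group_assignment", class(assign)),
              resolution = resolution, modularity = best$q)
  })
}

#' @export
tidy.group_assignment <- function(x, ...) tibble::as_tibble(unclass(x))

#' Group size distribution
#'
#' @param assignment A [cluster_simplices()] result.
#' @return A tibble with columns `group` and `size`, sorted by
#'   decreasing size.
#' @export
group_sizes <- function(assignment) {
  dplyr::count(tibble::as_tibble(assignment), .data$group,
               name = "size") |>
    dplyr::arrange(dplyr::desc(.data$size))
}

#' Ensemble of column-shuffled disynaptic inhibition matrices
#'
#' Convenience wrapper generating `n` controls: each shuffles the
#' interneuron columns of the reduced tensors independently
#' ([shuffle_inhibition_columns()]) and recomputes the disynaptic
#' matrix, preserving every simplex's inhibitory in- and out-totals.
#'
#' @param tensors An [inhibition_tensors()] result.
#' @param n Number of controls.
#' @param seed Optional RNG seed.
#' @inheritParams disynaptic_inhibition
#' @return A list of matrices.
#' @export
shuffled_disynaptic <- function(tensors, n = 20L, seed = NULL,
                                binarize = FALSE) {
  with_rng_seed(seed, {
    lapply(seq_len(n), function(k) {
      sh <- shuffle_inhibition_columns(tensors$m_ei, tensors$m_ie)
      disynaptic_inhibition(sh, binarize = binarize)
    })
  })
}

#' Excitation and inhibition between source and target groups
#'
#' Reduces the simplex-level network to a bipartite group-level one.  For
#' every (source group, target group) pair, over all cross pairs of
#' simplices \eqn{(s, t)}, \eqn{s \neq t}: *excitation* is the mean
#' any-position overlap (shared neurons), and *inhibition* the fraction
#' of pairs whose disynaptic inhibition exceeds the 95th percentile of
#' the shuffled-control ensemble — per pair by default, or of the pooled
#' control distribution with `pooled = TRUE` (useful for small shuffle
#' budgets).
#'
#' @param src_groups,tgt_groups [cluster_simplices()] results for the
#'   source-side and target-side overlap.
#' @param o_any Any-position overlap matrix ([overlap_matrix()] over
#'   positions `0:dim`).
#' @param inh Disynaptic inhibition matrix.
#' @param shuffles List of shuffled control matrices
#'   ([shuffled_disynaptic()]).
#' @param percentile Exceedance percentile of the control distribution.
#' @param pooled Compare each pair against the pooled control
#'   distribution instead of its own.
#' @return A `group_network`: list with `excitation` and `inhibition`
#'   matrices (source groups x target groups) and the two group size
#'   tables.
#' @export
group_network <- function(src_groups, tgt_groups, o_any, inh, shuffles,
                          percentile = 0.95, pooled = FALSE) {
  stopifnot(length(shuffles) >= 1L)
  s <- nrow(o_any)
  gs <- src_groups$group
  gt <- tgt_groups$group
  stopifnot(length(gs) == s, length(gt) == s)
  o_any <- as.matrix(o_any)
  inh <- as.matrix(inh)
  diag_overlap <- diag(o_any)
  if (pooled) {
    thr <- quantile(unlist(lapply(shuffles, off_diagonal)), percentile)
    exceed <- 1 * (inh > thr)
  } else {
    arr <- simplify2array(shuffles)
    thr <- apply(arr, c(1, 2), quantile, probs = percentile)
    exceed <- 1 * (inh > thr)
  }
  ms <- Matrix::sparseMatrix(i = seq_len(s), j = gs + 1L, x = 1,
                             dims = c(s, max(gs) + 1L))
  mt <- Matrix::sparseMatrix(i = seq_len(s), j = gt + 1L, x = 1,
                             dims = c(s, max(gt) + 1L))
  # cross-pair sums exclude s == t, handled via the joint membership counts
  common <- as.matrix(Matrix::t(ms) %*% mt)       # |{s : s in g and h}|
  n_pairs <- outer(Matrix::colSums(ms), Matrix::colSums(mt)) - common
  sum_overlap <- as.matrix(Matrix::t(ms) %*% o_any %*% mt) -
    as.matrix(Matrix::t(ms * diag_overlap) %*% mt)
  sum_exceed <- as.matrix(Matrix::t(ms) %*% exceed %*% mt) -
    as.matrix(Matrix::t(ms * diag(exceed)) %*% mt)
  excitation <- ifelse(n_pairs > 0, sum_overlap / n_pairs, NA_real_)
  inhibition <- ifelse(n_pairs > 0, sum_exceed / n_pairs, NA_real_)
  structure(list(excitation = excitation, inhibition = inhibition,
                 src_sizes = group_sizes(src_groups),
                 tgt_sizes = group_sizes(tgt_groups),
                 percentile = percentile, pooled = pooled),
            class = "group_network")
}

#' @exportS3Method base::print
print.group_network <- function(x, ...) {
  cat("<group_network> ", nrow(x$excitation), " source groups x ",
      ncol(x$excitation), " target groups\n", sep = "")
  invisible(x)
}
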