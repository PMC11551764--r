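#' Fit an exponential distance-dependent connection model
#'
#' For one synapse-class pathway, bins all ordered neuron pairs by soma
#' distance (default 20 um bins up to the 99th percentile pair distance)
#' and fits the decay \eqn{P(d) = a e^{-d/b}} to the per-bin empirical
#' connection probabilities by nonlinear least squares with positivity
#' constraints, weighting bins by their pair counts.
#'
#' @param conn A `connectome`.
#' @param pathway One of `"ee"`, `"ei"`, `"ie"`, `"ii"`.
#' @param bin_width Distance bin width in micrometres.
#' @param max_quantile Upper quantile of pair distances defining the
#'   fitting range.
#' @return A `fitted_distance_model`: the parameters plus per-bin
#'   diagnostics (`tidy()` gives the parameters, `glance()` the fit
#'   summary, `autoplot()` the binned probabilities with the fitted
#'   curve).
#' @export
fit_distance_model <- function(conn, pathway = "ee", bin_width = 20,
                               max_quantile = 0.99) {
  stopifnot(pathway %in% PATHWAYS)
  nodes <- conn$nodes
  cls_pre <- toupper(substr(pathway, 1, 1))
  cls_post <- toupper(substr(pathway, 2, 2))
  pre_idx <- which(nodes$synapse_class == cls_pre)
  post_idx <- which(nodes$synapse_class == cls_post)
  if (length(pre_idx) == 0L || length(post_idx) == 0L) {
    warn(paste0("No neurons for pathway ", pathway, "; returning a = 0."))
    return(new_fitted_distance_model(pathway, 0, bin_width, NULL))
  }
  pos <- as.matrix(nodes[, c("x", "y", "z")])
  d2 <- outer(rowSums(pos[pre_idx, , drop = FALSE]^2),
              rowSums(pos[post_idx, , drop = FALSE]^2), "+") -
    2 * pos[pre_idx, , drop = FALSE] %*% t(pos[post_idx, , drop = FALSE])
  d <- sqrt(pmax(d2, 0))
  conn_flag <- as.matrix(conn$adj[pre_idx, post_idx, drop = FALSE] > 0)
  same <- outer(pre_idx, post_idx, "==")
  keep <- !same
  d <- d[keep]; conn_flag <- conn_flag[keep]
  dmax <- quantile(d, max_quantile)
  breaks <- seq(0, dmax + bin_width, by = bin_width)
  bin <- cut(d, breaks, include.lowest = TRUE, labels = FALSE)
  ok <- !is.na(bin)
  bins <- tibble::tibble(bin = bin[ok], connected = conn_flag[ok]) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(n_pairs = dplyr::n(), n_conn = sum(.data$connected),
                     .groups = "drop") |>
    dplyr::mutate(mid = breaks[.data$bin] + bin_width / 2,
                  p_hat = .data$n_conn / .data$n_pairs)
  if (all(bins$n_conn == 0)) {
    warn(paste0("No connections in pathway ", pathway, "; returning a = 0."))
    return(new_fitted_distance_model(pathway, 0, bin_width, bins))
  }
  a0 <- max(min(max(bins$p_hat), 1), 1e-4)
  b0 <- max(dmax / 3, bin_width)
  fit <- tryCatch(
    minpack.lm::nlsLM(p_hat ~ a * exp(-mid / b), data = bins,
                      start = list(a = a0, b = b0),
                      lower = c(1e-8, 1e-3), upper = c(1, 1e7),
                      weights = bins$n_pairs),
    error = function(e) NULL)
  if (is.null(fit)) {
    warn("Distance-model fit failed to converge; returning bin maximum.")
    return(new_fitted_distance_model(pathway, a0, b0, bins))
  }
  cf <- stats::coef(fit)
  bins$fitted <- cf["a"] * exp(-bins$mid / cf["b"])
  bins$resid <- bins$p_hat - bins$fitted
  new_fitted_distance_model(pathway, cf["a"], cf["b"], bins)
}

new_fitted_distance_model <- function(pathway, a, b, bins) {
  structure(list(pathway = pathway, a = unname(a), b = unname(b),
                 bins = bins),
            class = "fitted_distance_model")
}

#' @exportS3Method base::print
print.fitted_distance_model <- function(x, ...) {
  cat("<fitted_distance_model> ", x$pathway, ": a = ", signif(x$a, 4),
      ", b = ", signif(x$b, 4), " um\n", sep = "")
  invisible(x)
}

#' @export
tidy.fitted_distance_model <- function(x, ...) {
  tibble::tibble(pathway = x$pathway, a = x$a, b = x$b)
}

#' @export
glance.fitted_distance_model <- function(x, ...) {
  rss <- if (!is.null(x$bins$resid)) sum(x$bins$resid^2) else NA_real_
  tibble::tibble(pathway = x$pathway, n_bins = nrow(x$bins) %||% 0L,
                 rss = rss)
}

#' @rdname fit_distance_model
#' @export
fit_distance_models <- function(conn, bin_width = 20, max_quantile = 0.99) {
  fits <- lapply(PATHWAYS, function(p) {
    fit_distance_model(conn, p, bin_width, max_quantile)
  })
  params <- distance_model_params(
    ee = c(fits[[1]]$a, fits[[1]]$b %||% bin_width),
    ei = c(fits[[2]]$a, fits[[2]]$b %||% bin_width),
    ie = c(fits[[3]]$a, fits[[3]]$b %||% bin_width),
    ii = c(fits[[4]]$a, fits[[4]]$b %||% bin_width))
  attr(params, "fits") <- fits
  params
}

#' Stochastic instance of a fitted distance-dependent model
#'
#' Shares its implementation with [sample_distance_connectome()]: each
#' ordered pair is connected independently with the fitted pathway
#' probability at its soma distance.
#'
#' @inheritParams sample_distance_connectome
#' @export
instantiate_distance_model <- function(neurons, params, seed = NULL) {
  sample_distance_connectome(neurons, params, seed = seed)
}

#' Configuration-model control
#'
#' Degree-preserving randomisation of a directed simple graph by repeated
#' directed double-edge swaps (rejecting swaps that would create
#' self-loops or parallel edges), so every neuron keeps its exact in- and
#' out-degree while all other structure is randomised.  Synapse counts
#' are not preserved; control edges carry weight 1.
#'
#' @param conn A `connectome`.
#' @param seed Optional RNG seed.
#' @param n_swaps_per_edge Number of attempted swaps per edge.
#' @return A `connectome` with identical node table and degree sequences.
#' @export
configuration_model <- function(conn, seed = NULL, n_swaps_per_edge = 10) {
  if (n_edges(conn) < 2L) {
    warn("Fewer than 2 edges; returning the graph unchanged.")
    return(conn)
  }
  g <- as_igraph(conn)
  with_rng_seed(seed, {
    g2 <- igraph::rewire(
      g, igraph::keeping_degseq(loops = FALSE,
                                niter = n_swaps_per_edge *
                                  igraph::ecount(g)))
    el <- igraph::as_edgelist(g2, names = FALSE)
    adj <- Matrix::sparseMatrix(i = el[, 1], j = el[, 2],
                                x = rep(1, nrow(el)), dims = dim(conn$adj),
                                dimnames = dimnames(conn$adj))
    new_connectome(conn$nodes, methods::as(adj, "CsparseMatrix"), conn$meta)
  })
}

#' Directed Erdos-Renyi control graph
#'
#' Exactly `m_edges` distinct ordered pairs drawn uniformly without
#' replacement, no self-loops.  Node positions are synthetic placeholders
#' (all zero): this control is purely structural, independent of
#' distance.
#'
#' @param n Number of nodes.
#' @param m_edges Number of directed edges.
#' @param seed Optional RNG seed.
#' @return A `connectome` of `n` excitatory nodes.
#' @export
erdos_renyi_directed <- function(n, m_edges, seed = NULL) {
  stopifnot(n >= 1, m_edges >= 0, m_edges <= n * (n - 1))
  neurons <- tibble::tibble(neuron_id = seq_len(n), x = 0, y = 0, z = 0,
                            synapse_class = "E")
  with_rng_seed(seed, {
    k <- sample(n * (n - 1), m_edges)  # ordered non-diagonal cells
    pre <- floor((k - 1) / (n - 1)) + 1
    off <- (k - 1) %% (n - 1) + 1
    post <- ifelse(off >= pre, off + 1, off)
    build_connectome(neurons, tibble::tibble(pre_id = pre, post_id = post))
  })
}

#' Column-shuffle control for simplex-interneuron matrices
#'
#' Applies an independent uniform permutation to the interneuron columns
#' of the reduced E-to-I and I-to-E matrices.  Per-simplex inhibitory
#' in- and out-totals (row sums) are preserved exactly; which interneuron
#' provides them is randomised, which is the null used for disynaptic
#' inhibition.
#'
#' @param m_ei,m_ie Matrices (simplices x interneurons) with equal column
#'   counts.
#' @param seed Optional RNG seed.
#' @return A list with elements `m_ei`, `m_ie`, `perm_ei`, `perm_ie`.
#' @export
shuffle_inhibition_columns <- function(m_ei, m_ie, seed = NULL) {
  if (ncol(m_ei) != ncol(m_ie)) {
    abort("Matrices must have the same number of interneuron columns.")
  }
  with_rng_seed(seed, {
    perm_ei <- sample.int(ncol(m_ei))
    perm_ie <- sample.int(ncol(m_ie))
    list(m_ei = m_ei[, perm_ei, drop = FALSE],
         m_ie = m_ie[, perm_ie, drop = FALSE],
         perm_ei = perm_ei, perm_ie = perm_ie)
  })
}
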