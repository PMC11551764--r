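#' Synthesize activity traces with simplex-graded pairwise correlation
#'
#' Generates a nonnegative activity trace per node such that the expected
#' Pearson correlation of a connected pair equals the profile value for
#' the maximal simplex dimension of the connecting edge — emulating the
#' observation that activity correlations of connected neurons rise with
#' the dimension of the simplices their connection participates in.
#'
#' Two constructions are available.  `"factor"` (default) gives each edge
#' a shared latent Gaussian factor: node \eqn{u}'s trace is
#' \eqn{\sqrt{1 - \sum_e r_e}\, z_u + \sum_e \sqrt{r_e} f_e} over its
#' incident edges, so a connected pair's covariance is exactly its edge's
#' target correlation.  If a node's incident targets sum above 1 its
#' loadings are rescaled (with a warning), lowering realised correlations.
#' `"gaussian"` builds the full target correlation matrix and samples from
#' it directly, erroring if the matrix is not positive definite (the
#' factor construction is the fallback for such profiles).  Traces are
#' shifted to be nonnegative, which leaves Pearson correlations unchanged.
#'
#' @param nodes Vector of node ids.
#' @param edge_dims Tibble with columns `pre_id`, `post_id`, `dim`: the
#'   maximal simplex dimension per edge (see [edge_max_dimension()]).
#' @param corr_profile Named numeric vector mapping dimension to target
#'   correlation in `[0, 1)`, e.g. `c("1" = 0.05, "5" = 0.3)`.  Edges take
#'   the value of the largest profile dimension not exceeding their own.
#' @param t_samples Number of time samples.
#' @param seed Optional RNG seed.
#' @param method `"factor"` or `"gaussian"`.
#' @return A numeric matrix (`t_samples` rows) with one column per node,
#'   column names = node ids.
#' @export
synth_activity <- function(nodes, edge_dims, corr_profile, t_samples = 1000L,
                           seed = NULL, method = c("factor", "gaussian")) {
  method <- match.arg(method)
  stopifnot(t_samples >= 2L)
  prof_dims <- sort(as.numeric(names(corr_profile)))
  prof_vals <- as.numeric(corr_profile[as.character(prof_dims)])
  if (any(prof_vals < 0 | prof_vals >= 1)) {
    abort("Target correlations must lie in [0, 1).")
  }
  if (is.unsorted(prof_vals)) {
    abort("`corr_profile` must be monotone non-decreasing in dimension.")
  }
  edge_dims <- tibble::as_tibble(edge_dims)
  lookup <- function(d) {
    idx <- findInterval(d, prof_dims)
    prof_vals[pmax(idx, 1L)]
  }
  edges <- edge_dims |>
    dplyr::filter(.data$pre_id %in% nodes, .data$post_id %in% nodes,
                  .data$pre_id != .data$post_id)
  # collapse reciprocal pairs to one undirected latent factor (max dim)
  key <- paste(pmin(edges$pre_id, edges$post_id),
               pmax(edges$pre_id, edges$post_id))
  edges <- edges |>
    dplyr::mutate(key = key) |>
    dplyr::group_by(key) |>
    dplyr::summarise(u = .data$pre_id[1], v = .data$post_id[1],
                     dim = max(.data$dim), .groups = "drop") |>
    dplyr::mutate(r = lookup(.data$dim))
  n <- length(nodes)
  with_rng_seed(seed, {
    if (method == "gaussian") {
      cmat <- diag(n)
      iu <- match(edges$u, nodes); iv <- match(edges$v, nodes)
      cmat[cbind(iu, iv)] <- edges$r
      cmat[cbind(iv, iu)] <- edges$r
      ch <- tryCatch(chol(cmat), error = function(e) NULL)
      if (is.null(ch)) {
        abort(paste0("Target correlation matrix is not positive definite; ",
                     "use method = 'factor'."))
      }
      x <- matrix(rnorm(t_samples * n), t_samples, n) %*% ch
    } else {
      loading <- edges$r
      overloaded <- 0L
      for (id in nodes) {
        inc <- which(edges$u == id | edges$v == id)
        s <- sum(loading[inc])
        if (s > 0.99) {
          overloaded <- overloaded + 1L
          loading[inc] <- loading[inc] * 0.99 / s
        }
      }
      if (overloaded > 0L) {
        warn(paste0("Incident target correlations of ", overloaded,
                    " node(s) sum above 1; their factor loadings were ",
                    "rescaled and realised correlations will be lower."))
      }
      x <- matrix(0, t_samples, n)
      resid_var <- rep(1, n)
      if (nrow(edges) > 0L) {
        f <- matrix(rnorm(t_samples * nrow(edges)), t_samples, nrow(edges))
        iu <- match(edges$u, nodes); iv <- match(edges$v, nodes)
        for (e in seq_len(nrow(edges))) {
          lam <- sqrt(loading[e])
          x[, iu[e]] <- x[, iu[e]] + lam * f[, e]
          x[, iv[e]] <- x[, iv[e]] + lam * f[, e]
          resid_var[iu[e]] <- resid_var[iu[e]] - loading[e]
          resid_var[iv[e]] <- resid_var[iv[e]] - loading[e]
        }
      }
      x <- x + sweep(matrix(rnorm(t_samples * n), t_samples, n), 2,
                     sqrt(pmax(resid_var, 0)), "*")
    }
    x <- sweep(x, 2, apply(x, 2, min))  # nonnegative; Pearson unchanged
    colnames(x) <- as.character(nodes)
    x
  })
}
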