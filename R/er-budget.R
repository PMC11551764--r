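#' Reconstruction-error control for simplex counts
#'
#' Could the observed high-dimensional simplices be a residue of a much
#' denser unstructured graph thinned by reconstruction errors?  In an
#' undirected Erdos-Renyi graph on \eqn{n} nodes with connection
#' probability \eqn{p}, the expected maximal simplicial dimension is
#' approximately \eqn{-2\log(n)/\log(p)}.  Solving for the \eqn{p} that
#' would make a target dimension expected gives the directed edge budget
#' \eqn{n(n-1)p} such a graph would need; comparing with the observed
#' edge count gives the fraction of edges a reconstruction would have had
#' to lose.  Independently, a simplex of dimension \eqn{d} has
#' \eqn{\binom{d+1}{2}} edges, so the probability that one survives
#' thinning at a given recall is \eqn{recall^{\binom{d+1}{2}}}.
#'
#' @param n Number of nodes (>= 2).
#' @param target_dim Dimension the control graph must be able to reach.
#' @param observed_edges Observed number of directed edges.
#' @param recall Optional synapse-detection recall in `[0, 1]` for the
#'   survival probability.
#' @return An object of class `er_budget` with elements `n`, `p`,
#'   `target_dim`, `required_directed_edges`, `removal_fraction`, and
#'   (when `recall` is given) `survival_probability`.
#' @examples
#' b <- er_simplex_budget(14559, 7, 819869, recall = 0.06)
#' round(100 * b$removal_fraction)  # 94
#' @export
er_simplex_budget <- function(n, target_dim, observed_edges, recall = NULL) {
  stopifnot(target_dim >= 1, observed_edges >= 0)
  if (n < 2) abort("`n` must be at least 2.")
  p <- n^(-2 / target_dim)
  if (p >= 1) abort("Implied connection probability is not below 1.")
  required <- n * (n - 1) * p
  removal <- max(0, 1 - observed_edges / required)
  out <- list(n = n, target_dim = target_dim, p = p,
              observed_edges = observed_edges,
              required_directed_edges = required,
              removal_fraction = removal)
  if (!is.null(recall)) {
    stopifnot(recall >= 0, recall <= 1)
    out$recall <- recall
    out$survival_probability <- recall^choose(target_dim + 1, 2)
  }
  structure(out, class = "er_budget")
}

#' @rdname er_simplex_budget
#' @param p Connection probability.
#' @export
expected_max_dimension <- function(n, p) {
  stopifnot(n >= 2, p > 0, p < 1)
  -2 * log(n) / log(p)
}

#' @exportS3Method base::print
print.er_budget <- function(x, ...) {
  cat("<er_budget> n = ", x$n, ", target dim = ", x$target_dim,
      ", p = ", signif(x$p, 4), "\n  required directed edges = ",
      format(round(x$required_directed_edges), big.mark = ","),
      "; observed = ", format(x$observed_edges, big.mark = ","),
      "\n  removal fraction = ", signif(x$removal_fraction, 4), "\n",
      sep = "")
  if (!is.null(x$survival_probability)) {
    cat("  survival probability at recall ", x$recall, " = ",
        signif(x$survival_probability, 3), "\n", sep = "")
  }
  invisible(x)
}

#' @export
tidy.er_budget <- function(x, ...) {
  tibble::tibble(n = x$n, target_dim = x$target_dim, p = x$p,
                 required_directed_edges = x$required_directed_edges,
                 observed_edges = x$observed_edges,
                 removal_fraction = x$removal_fraction,
                 survival_probability = x$survival_probability %||% NA_real_)
}
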