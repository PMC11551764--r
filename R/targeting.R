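#' Hypergeometric test for inhibitory-targeting interneurons
#'
#' Disinhibitory interneurons preferentially innervate other
#' interneurons.  For each interneuron \eqn{j} with total out-degree
#' \eqn{d_j^{ttl}} and out-degree onto interneurons \eqn{d_j^{inh}}, the
#' null keeps every neuron's total out-degree and the population-wide
#' fraction of connections onto interneurons: \eqn{j}'s targets are
#' drawn without replacement from the pooled \eqn{\sum_i d_i^{ttl}}
#' target slots, of which \eqn{\sum_i d_i^{inh}} are inhibitory (sums
#' over all interneurons).  The p-value is the hypergeometric survival
#' probability of observing \eqn{\ge d_j^{inh}} inhibitory targets in
#' \eqn{d_j^{ttl}} draws; neurons with \eqn{p_j \le} `threshold` are
#' flagged as inhibitory-targeting.
#'
#' @param conn A `connectome` with inhibitory neurons.
#' @param threshold Flagging threshold on the p-value (default `1e-6`,
#'   chosen to isolate the clearly disinhibitory tail).
#' @return A `targeting_test`: tibble with columns `neuron_id`, `d_ttl`,
#'   `d_inh`, `p_value`, `flagged`, carrying the threshold and flagged
#'   fraction as attributes (`glance()` reports both).
#' @export
inhibitory_targeting_test <- function(conn, threshold = 1e-6) {
  i_ids <- inhibitory_ids(conn)
  if (length(i_ids) == 0L) abort("Connectome has no inhibitory neurons.")
  edges <- connectome_edges(conn) |>
    dplyr::distinct(.data$pre_id, .data$post_id)
  mine <- edges[edges$pre_id %in% i_ids, ]
  deg <- tibble::tibble(neuron_id = i_ids) |>
    dplyr::left_join(dplyr::count(mine, .data$pre_id, name = "d_ttl"),
                     by = c(neuron_id = "pre_id")) |>
    dplyr::left_join(
      dplyr::count(mine[mine$post_id %in% i_ids, ], .data$pre_id,
                   name = "d_inh"),
      by = c(neuron_id = "pre_id")) |>
    tidyr::replace_na(list(d_ttl = 0L, d_inh = 0L))
  m_total <- sum(deg$d_ttl)
  if (m_total == 0L) abort("No outgoing connections from interneurons.")
  k_inh <- sum(deg$d_inh)
  deg$p_value <- ifelse(
    deg$d_inh == 0L, 1,
    phyper(deg$d_inh - 1L, k_inh, m_total - k_inh, deg$d_ttl,
           lower.tail = FALSE))
  deg$flagged <- deg$p_value <= threshold
  structure(deg, class = c("targeting_test", class(deg)),
            threshold = threshold,
            flagged_fraction = mean(deg$flagged))
}

#' @export
tidy.targeting_test <- function(x, ...) tibble::as_tibble(unclass(x))

#' @export
glance.targeting_test <- function(x, ...) {
  tibble::tibble(n_interneurons = nrow(x),
                 threshold = attr(x, "threshold"),
                 n_flagged = sum(x$flagged),
                 flagged_fraction = attr(x, "flagged_fraction"))
}

#' Simplex in- and out-degrees of interneurons
#'
#' The *simplex indegree* of an interneuron is its number of connections
#' from excitatory neurons occupying source-side positions of the given
#' dimension's simplices; the *simplex outdegree* its number of
#' connections onto neurons in target-side positions.  A neuron occupying
#' an eligible position in several simplices contributes once per
#' (simplex, position) occurrence, so interneurons attached to heavily
#' reused simplex members score correspondingly higher.
#'
#' @param st A `simplex_table` with tuples.
#' @param conn The full `connectome`.
#' @param dim Simplex dimension (default: largest with simplices).
#' @param source_positions,target_positions Eligible position sets;
#'   defaults are the first and last three positions.
#' @return A tibble with columns `neuron_id`, `simplex_indegree`,
#'   `simplex_outdegree` (one row per interneuron).
#' @export
simplex_degrees_of_inhibitory <- function(st, conn, dim = NULL,
                                          source_positions = NULL,
                                          target_positions = NULL) {
  dim <- dim %||% max_simplex_dim(st)
  tuples <- simplex_tuples(st, dim)
  if (is.null(tuples) || nrow(tuples) == 0L) {
    abort(paste0("No simplices of dimension ", dim, "."))
  }
  source_positions <- source_positions %||% 0:min(2L, dim)
  target_positions <- target_positions %||% (max(dim - 2L, 0L):dim)
  i_ids <- inhibitory_ids(conn)
  memb <- melt_simplices(tuples)
  edges <- connectome_edges(conn) |>
    dplyr::distinct(.data$pre_id, .data$post_id)
  indeg <- memb[memb$position %in% source_positions, ] |>
    dplyr::inner_join(edges[edges$post_id %in% i_ids, ],
                      by = c(node_id = "pre_id"),
                      relationship = "many-to-many") |>
    dplyr::count(.data$post_id, name = "simplex_indegree")
  outdeg <- memb[memb$position %in% target_positions, ] |>
    dplyr::inner_join(edges[edges$pre_id %in% i_ids, ],
                      by = c(node_id = "post_id"),
                      relationship = "many-to-many") |>
    dplyr::count(.data$pre_id, name = "simplex_outdegree")
  tibble::tibble(neuron_id = i_ids) |>
    dplyr::left_join(indeg, by = c(neuron_id = "post_id")) |>
    dplyr::left_join(outdeg, by = c(neuron_id = "pre_id")) |>
    tidyr::replace_na(list(simplex_indegree = 0L, simplex_outdegree = 0L))
}

#' Disinhibition profile over simplex-degree bins
#'
#' Stacks, for interneurons binned by their simplex degree, the mean
#' inhibitory in-degree received from inhibitory-targeting
#' (disinhibitory) interneurons versus the remaining inhibitory
#' population.  A rising targeting share with simplex degree shows that
#' disinhibition concentrates on the interneurons most engaged with the
#' simplicial network.
#'
#' @param conn A `connectome`.
#' @param targeting A [inhibitory_targeting_test()] result.
#' @param simplex_degrees A [simplex_degrees_of_inhibitory()] result.
#' @param degree Which simplex degree to bin by: `"indegree"` or
#'   `"outdegree"`.
#' @param n_bins Number of equal-width bins over the degree range.
#' @return A tibble with columns `bin`, `bin_mid`, `n_neurons`,
#'   `from_targeting`, `from_other` (mean in-degrees) and
#'   `share_targeting`.
#' @export
disinhibition_profile <- function(conn, targeting, simplex_degrees,
                                  degree = c("indegree", "outdegree"),
                                  n_bins = 5L) {
  degree <- match.arg(degree)
  flagged_ids <- targeting$neuron_id[targeting$flagged]
  i_ids <- inhibitory_ids(conn)
  edges <- connectome_edges(conn) |>
    dplyr::distinct(.data$pre_id, .data$post_id)
  ii <- edges[edges$pre_id %in% i_ids & edges$post_id %in% i_ids, ]
  recv <- tibble::tibble(neuron_id = i_ids) |>
    dplyr::left_join(
      ii |>
        dplyr::group_by(.data$post_id) |>
        dplyr::summarise(
          from_targeting = sum(.data$pre_id %in% flagged_ids),
          from_other = sum(!.data$pre_id %in% flagged_ids),
          .groups = "drop"),
      by = c(neuron_id = "post_id")) |>
    tidyr::replace_na(list(from_targeting = 0L, from_other = 0L))
  deg_col <- paste0("simplex_", degree)
  recv$deg <- simplex_degrees[[deg_col]][
    match(recv$neuron_id, simplex_degrees$neuron_id)]
  breaks <- seq(0, max(recv$deg, 1), length.out = n_bins + 1L)
  recv$bin <- cut(recv$deg, breaks, include.lowest = TRUE, labels = FALSE)
  recv |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      bin_mid = (breaks[.data$bin[1]] + breaks[.data$bin[1] + 1L]) / 2,
      n_neurons = dplyr::n(),
      from_targeting = mean(.data$from_targeting),
      from_other = mean(.data$from_other), .groups = "drop") |>
    dplyr::mutate(share_targeting = ifelse(
      .data$from_targeting + .data$from_other > 0,
      .data$from_targeting / (.data$from_targeting + .data$from_other),
      NA_real_))
}
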