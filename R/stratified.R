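#' Connection probability with simplex positions, stratified by class
#'
#' Interneuron populations differ in size, so absolute degree profiles
#' conflate class size with connection preference.  This profile divides
#' the mean number of class members connected to/from the simplex neuron
#' at each position by the class size, giving the probability that a
#' class member makes that connection.  Used to compare proofreading
#' strata or inhibitory subtypes (e.g. DTC/ITC/PTC/STC) on an equal
#' footing.
#'
#' @param st A `simplex_table` with tuples.
#' @param conn The full `connectome`.
#' @param dim Simplex dimension (default: largest with simplices).
#' @param class_col Name of the node-table column holding the class
#'   labels (e.g. `"cell_type"` or `"proofreading_axon"`); only
#'   inhibitory neurons are stratified.
#' @param direction `"onto_simplex"` for class-member-to-simplex-neuron
#'   connections, `"from_simplex"` for the reverse.
#' @param normalize Also return each profile divided by its value at the
#'   source position.
#' @return A tibble with columns `class`, `position`, `probability` and
#'   (optionally) `normalized`.
#' @export
position_profile_stratified <- function(st, conn, dim = NULL,
                                        class_col = "cell_type",
                                        direction = c("onto_simplex",
                                                      "from_simplex"),
                                        normalize = TRUE) {
  direction <- match.arg(direction)
  dim <- dim %||% max_simplex_dim(st)
  tuples <- simplex_tuples(st, dim)
  if (is.null(tuples) || nrow(tuples) == 0L) {
    abort(paste0("No simplices of dimension ", dim, "."))
  }
  nodes <- conn$nodes
  if (!class_col %in% names(nodes)) {
    abort(paste0("Node table has no column `", class_col, "`."))
  }
  strata <- nodes[nodes$synapse_class == "I", c("neuron_id", class_col)]
  names(strata) <- c("member_id", "class")
  class_sizes <- dplyr::count(strata, .data$class, name = "class_size")
  if (any(is.na(strata$class))) {
    warn("Interneurons with missing class labels are excluded.")
    strata <- strata[!is.na(strata$class), ]
  }
  memb <- melt_simplices(tuples)
  edges <- connectome_edges(conn) |>
    dplyr::distinct(.data$pre_id, .data$post_id)
  joined <- if (direction == "onto_simplex") {
    memb |>
      dplyr::inner_join(edges, by = c(node_id = "post_id"),
                        relationship = "many-to-many") |>
      dplyr::inner_join(strata, by = c(pre_id = "member_id"))
  } else {
    memb |>
      dplyr::inner_join(edges, by = c(node_id = "pre_id"),
                        relationship = "many-to-many") |>
      dplyr::inner_join(strata, by = c(post_id = "member_id"))
  }
  s <- nrow(tuples)
  grid <- tidyr::expand_grid(class = class_sizes$class, position = 0:dim)
  out <- joined |>
    dplyr::count(.data$class, .data$position) |>
    dplyr::right_join(grid, by = c("class", "position")) |>
    tidyr::replace_na(list(n = 0L)) |>
    dplyr::left_join(class_sizes, by = "class") |>
    dplyr::mutate(probability = ifelse(.data$class_size > 0,
                                       .data$n / s / .data$class_size,
                                       NA_real_)) |>
    dplyr::arrange(.data$class, .data$position) |>
    dplyr::select("class", "position", "probability")
  if (any(class_sizes$class_size == 0)) {
    warn("Empty class encountered; probabilities reported as missing.")
  }
  if (normalize) {
    out <- out |>
      dplyr::group_by(.data$class) |>
      dplyr::mutate(normalized = .data$probability /
                      .data$probability[.data$position == 0]) |>
      dplyr::ungroup()
  }
  out
}

#' Mean synapses per connection by simplex position
#'
#' For the neuron at each position of the given dimension's simplices,
#' the mean synapse count of its existing E-to-I and I-to-E connections.
#' Values above 1 indicate multi-synapse (strengthened) connections;
#' biased pathways around simplices tend to carry more synapses per
#' connection.
#'
#' @inheritParams inhibition_tensors
#' @return A tibble with columns `position`, `mean_syn_ei`,
#'   `mean_syn_ie`.
#' @export
synapses_per_connection_by_position <- function(st, conn, dim = NULL) {
  dim <- dim %||% max_simplex_dim(st)
  tuples <- simplex_tuples(st, dim)
  if (is.null(tuples) || nrow(tuples) == 0L) {
    abort(paste0("No simplices of dimension ", dim, "."))
  }
  i_ids <- inhibitory_ids(conn)
  memb <- melt_simplices(tuples)
  edges <- connectome_edges(conn)
  ei <- memb |>
    dplyr::inner_join(edges[edges$post_id %in% i_ids, ],
                      by = c(node_id = "pre_id"),
                      relationship = "many-to-many") |>
    dplyr::group_by(.data$position) |>
    dplyr::summarise(mean_syn_ei = mean(.data$count), .groups = "drop")
  ie <- memb |>
    dplyr::inner_join(edges[edges$pre_id %in% i_ids, ],
                      by = c(node_id = "post_id"),
                      relationship = "many-to-many") |>
    dplyr::group_by(.data$position) |>
    dplyr::summarise(mean_syn_ie = mean(.data$count), .groups = "drop")
  tibble::tibble(position = 0:dim) |>
    dplyr::left_join(ei, by = "position") |>
    dplyr::left_join(ie, by = "position")
}
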