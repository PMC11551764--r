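#' Synapse-count tensors between simplices and interneurons
#'
#' For the \eqn{S} simplices of one dimension and the \eqn{N_{inh}}
#' interneurons of the connectome, builds the sparse tensors
#' \eqn{M_{ei}[i, j, k]} = number of synapses from the neuron at position
#' \eqn{j} of simplex \eqn{i} to interneuron \eqn{k}, and
#' \eqn{M_{ie}[i, j, k]} = number of synapses from interneuron \eqn{k} to
#' the neuron at position \eqn{j} of simplex \eqn{i}; plus their
#' reductions over position, the simplex-by-interneuron matrices
#' \eqn{M'_{ei}} and \eqn{M'_{ie}}.
#'
#' @param st A `simplex_table` with tuples.
#' @param conn The full `connectome` (excitatory and inhibitory neurons).
#' @param dim Simplex dimension (default: largest with a nonzero count).
#' @return An `inhibition_tensors` object: long sparse tensors `t_ei`,
#'   `t_ie` (tibbles with `simplex`, `position`, `interneuron_id`,
#'   `count`) and sparse reductions `m_ei`, `m_ie`
#'   (simplices x interneurons; columns cover every interneuron).
#' @export
inhibition_tensors <- function(st, conn, dim = NULL) {
  dim <- dim %||% max_simplex_dim(st)
  tuples <- simplex_tuples(st, dim)
  if (is.null(tuples) || nrow(tuples) == 0L) {
    abort(paste0("No simplices of dimension ", dim, "."))
  }
  i_ids <- inhibitory_ids(conn)
  if (length(i_ids) == 0L) abort("Connectome has no inhibitory neurons.")
  memb <- melt_simplices(tuples)
  edges <- connectome_edges(conn)
  e2i <- edges[edges$post_id %in% i_ids, ]
  i2e <- edges[edges$pre_id %in% i_ids, ]
  t_ei <- memb |>
    dplyr::inner_join(e2i, by = c(node_id = "pre_id"),
                      relationship = "many-to-many") |>
    dplyr::select(simplex = "simplex", position = "position",
                  interneuron_id = "post_id", count = "count")
  t_ie <- memb |>
    dplyr::inner_join(i2e, by = c(node_id = "post_id"),
                      relationship = "many-to-many") |>
    dplyr::select(simplex = "simplex", position = "position",
                  interneuron_id = "pre_id", count = "count")
  reduce <- function(t_long) {
    red <- t_long |>
      dplyr::group_by(.data$simplex, .data$interneuron_id) |>
      dplyr::summarise(count = sum(.data$count), .groups = "drop")
    Matrix::sparseMatrix(i = red$simplex,
                         j = match(red$interneuron_id, i_ids),
                         x = red$count,
                         dims = c(nrow(tuples), length(i_ids)),
                         dimnames = list(NULL, as.character(i_ids)))
  }
  structure(list(dim = dim, n_simplices = nrow(tuples),
                 interneuron_ids = i_ids,
                 t_ei = t_ei, t_ie = t_ie,
                 m_ei = reduce(t_ei), m_ie = reduce(t_ie)),
            class = "inhibition_tensors")
}

#' @exportS3Method base::print
print.inhibition_tensors <- function(x, ...) {
  cat("<inhibition_tensors> dim ", x$dim, ": ", x$n_simplices,
      " simplices x ", length(x$interneuron_ids), " interneurons; ",
      sum(x$m_ei), " E->I and ", sum(x$m_ie), " I->E synapses\n", sep = "")
  invisible(x)
}

#' Mean inhibitory in/out-degree by simplex position
#'
#' For each position of the given dimension's simplices, the mean (over
#' simplices) number of *distinct* interneurons innervating the neuron at
#' that position (`in_degree`) and innervated by it (`out_degree`).
#' Source-side neurons of cortical simplices tend to excite many
#' interneurons while target-side neurons receive from many, so the
#' out-profile falls and the in-profile rises with position.
#'
#' @inheritParams inhibition_tensors
#' @return A tibble with columns `position`, `in_degree`, `out_degree`.
#' @export
inhibitory_degree_by_position <- function(st, conn, dim = NULL) {
  dim <- dim %||% max_simplex_dim(st)
  tuples <- simplex_tuples(st, dim)
  if (is.null(tuples) || nrow(tuples) == 0L) {
    abort(paste0("No simplices of dimension ", dim, "."))
  }
  i_ids <- inhibitory_ids(conn)
  memb <- melt_simplices(tuples)
  edges <- connectome_edges(conn)
  in_deg <- edges[edges$pre_id %in% i_ids, ] |>
    dplyr::distinct(.data$pre_id, .data$post_id) |>
    dplyr::count(.data$post_id, name = "deg")
  out_deg <- edges[edges$post_id %in% i_ids, ] |>
    dplyr::distinct(.data$pre_id, .data$post_id) |>
    dplyr::count(.data$pre_id, name = "deg")
  s <- nrow(tuples)
  memb |>
    dplyr::left_join(in_deg, by = c(node_id = "post_id")) |>
    dplyr::rename(ideg = "deg") |>
    dplyr::left_join(out_deg, by = c(node_id = "pre_id")) |>
    dplyr::rename(odeg = "deg") |>
    dplyr::group_by(.data$position) |>
    dplyr::summarise(
      in_degree = sum(.data$ideg, na.rm = TRUE) / s,
      out_degree = sum(.data$odeg, na.rm = TRUE) / s, .groups = "drop")
}

#' Aggregate per-subnetwork profiles into mean and standard deviation
#'
#' @param profiles A list of tibbles sharing grouping column(s) and value
#'   columns (e.g. outputs of [inhibitory_degree_by_position()] for each
#'   subnetwork).
#' @param by Name(s) of the grouping column(s).
#' @return A tibble with, per value column, its mean and sd across the
#'   supplied profiles.
#' @export
aggregate_profiles <- function(profiles, by = "position") {
  dplyr::bind_rows(profiles, .id = "subnetwork") |>
    tidyr::pivot_longer(-dplyr::all_of(c("subnetwork", by)),
                        names_to = "metric") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(by, "metric")))) |>
    dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value),
                     .groups = "drop")
}

#' Disynaptic inhibition between simplices
#'
#' The simplex-by-simplex matrix \eqn{I = M'_{ei} M_{ie}'^{\top}}: entry
#' \eqn{(i, j)} is the synapse-weighted number of E-to-I-to-E paths
#' leaving simplex \eqn{i}, passing through one interneuron, and ending
#' in simplex \eqn{j}.  With `binarize = TRUE` the reductions are
#' binarised first, counting interneuron partners rather than
#' synapse-weighted paths.
#'
#' @param tensors An [inhibition_tensors()] result, or a list with
#'   elements `m_ei` and `m_ie`.
#' @param binarize Count connections instead of synapses.
#' @return A dense base matrix (simplices x simplices).
#' @export
disynaptic_inhibition <- function(tensors, binarize = FALSE) {
  m_ei <- tensors$m_ei
  m_ie <- tensors$m_ie
  if (binarize) {
    m_ei <- 1 * (m_ei > 0)
    m_ie <- 1 * (m_ie > 0)
  }
  as.matrix(m_ei %*% Matrix::t(m_ie))
}

#' Symmetry score of a square interaction matrix
#'
#' \eqn{\mathbb{S} = var(I - I^{\top}) / var(I)} over off-diagonal
#' entries (population variances).  Perfect symmetry gives 0; entries at
#' \eqn{(i,j)} and \eqn{(j,i)} statistically independent give an expected
#' value of 2.  The diagonal is excluded because it is identically zero
#' in the difference and measures self-interaction in \eqn{I}.
#'
#' @param mat A square matrix, at least 2 x 2.
#' @return A single number (`NA` with a warning if `var(I)` is zero).
#' @export
symmetry_score <- function(mat) {
  mat <- as.matrix(mat)
  stopifnot(nrow(mat) == ncol(mat), nrow(mat) >= 2L)
  v <- pop_var(off_diagonal(mat))
  if (!is.finite(v) || v == 0) {
    warn("Matrix has zero off-diagonal variance; symmetry score undefined.")
    return(NA_real_)
  }
  pop_var(off_diagonal(mat - t(mat))) / v
}

#' Overlap of simplices within a position range
#'
#' Entry \eqn{(s, t)} counts the neurons that simplices \eqn{s} and
#' \eqn{t} share within positions `j..k`, ignoring order inside the
#' range.  Positions 0–2 give the *source-side* overlap, positions
#' dim-2..dim the *target-side* overlap, and the full range the
#' any-position overlap.
#'
#' @param st A `simplex_table` with tuples.
#' @param dim Simplex dimension.
#' @param positions Integer range of positions, e.g. `0:2`.
#' @return A symmetric sparse matrix (simplices x simplices) with
#'   diagonal `length(positions)`.
#' @export
overlap_matrix <- function(st, dim, positions) {
  tuples <- simplex_tuples(st, dim)
  if (is.null(tuples) || nrow(tuples) == 0L) {
    abort(paste0("No simplices of dimension ", dim, "."))
  }
  stopifnot(all(positions >= 0), all(positions <= dim))
  sub <- tuples[, positions + 1L, drop = FALSE]
  node_lvls <- sort(unique(as.vector(sub)))
  b <- Matrix::sparseMatrix(
    i = rep(seq_len(nrow(sub)), ncol(sub)),
    j = match(as.vector(sub), node_lvls),
    x = 1, dims = c(nrow(sub), length(node_lvls)))
  o <- b %*% Matrix::t(b)
  attr(o, "positions") <- positions
  o
}

#' Correlations between overlap and disynaptic inhibition
#'
#' Pearson correlations, over off-diagonal simplex pairs, between
#' source-side overlap, target-side overlap and disynaptic inhibition
#' strength.  A larger source-side correlation indicates that simplices
#' sharing sources inhibit each other — lateral competition between
#' targets driven by a common source.
#'
#' @param o_source,o_target Overlap matrices ([overlap_matrix()]).
#' @param inh Disynaptic inhibition matrix ([disynaptic_inhibition()]).
#' @return A one-row tibble with `r_source_inh`, `r_target_inh`,
#'   `r_source_target`.
#' @export
overlap_inhibition_correlation <- function(o_source, o_target, inh) {
  os <- off_diagonal(as.matrix(o_source))
  ot <- off_diagonal(as.matrix(o_target))
  ii <- off_diagonal(as.matrix(inh))
  stopifnot(length(os) == length(ii), length(ot) == length(ii))
  safe_cor <- function(x, y) {
    if (sd(x) == 0 || sd(y) == 0) {
      warn("Constant input; correlation undefined.")
      return(NA_real_)
    }
    cor(x, y)
  }
  tibble::tibble(r_source_inh = safe_cor(os, ii),
                 r_target_inh = safe_cor(ot, ii),
                 r_source_target = safe_cor(os, ot))
}
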