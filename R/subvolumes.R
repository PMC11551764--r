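#' Grid of overlapping analysis subvolumes
#'
#' Cortical-slab connectomes are analysed in a grid of overlapping
#' rectangular subvolumes in the horizontal plane: excitatory neurons are
#' admitted to a subnetwork only if their soma falls inside the rectangle,
#' while inhibitory neurons are kept regardless of position (they are
#' analysed relative to the excitatory simplices, and restricting them
#' would create edge artefacts).  The default is a 5 x 3 grid of
#' 500 x 300 um rectangles shifted by 50 um between neighbours.
#'
#' @param width,depth Rectangle extent in micrometres along the first and
#'   second horizontal axis.
#' @param grid_shape Integer length-2: number of rectangles along each
#'   horizontal axis.
#' @param shift Shift between neighbouring rectangles in micrometres.
#' @param origin Optional numeric length-2 anchor (minimum corner of the
#'   first rectangle).  When `NULL`, the grid footprint is centred on the
#'   neuron cloud at selection time.
#' @param axes Which coordinate columns span the horizontal plane.
#' @return An object of class `subvolume_grid`.
#' @seealso [select_subnetworks()]
#' @export
subvolume_grid <- function(width = 500, depth = 300, grid_shape = c(5L, 3L),
                           shift = 50, origin = NULL,
                           axes = c("x", "y")) {
  stopifnot(width > 0, depth > 0, shift > 0, length(grid_shape) == 2L,
            all(grid_shape >= 1L), length(axes) == 2L)
  structure(list(width = width, depth = depth,
                 grid_shape = as.integer(grid_shape), shift = shift,
                 origin = origin, axes = axes),
            class = "subvolume_grid")
}

#' @exportS3Method base::print
print.subvolume_grid <- function(x, ...) {
  cat("<subvolume_grid> ", x$grid_shape[1], "x", x$grid_shape[2],
      " rectangles of ", x$width, "x", x$depth, " um, shift ", x$shift,
      " um\n", sep = "")
  invisible(x)
}

#' Select excitatory subnetworks on a grid of subvolumes
#'
#' Returns one selection per grid rectangle.  Excitatory neurons are
#' admitted if their soma lies inside the rectangle, with half-open bounds
#' `[min, max)` on each horizontal axis so that a grid tiling the volume
#' with `shift = width` assigns every neuron to exactly one rectangle; the
#' vertical axis is unbounded.  The inhibitory set is, by default, all
#' inhibitory neurons regardless of position (`i_margin = Inf`); a finite
#' `i_margin` instead admits inhibitory neurons inside the rectangle
#' enlarged by that many micrometres in each of the four horizontal
#' directions (the convention used for volumes where the full inhibitory
#' population would be disproportionate).
#'
#' @param neurons A neuron table.
#' @param grid A [subvolume_grid()].
#' @param i_margin Enlargement of the rectangle for inhibitory neurons in
#'   micrometres; `Inf` admits all inhibitory neurons.
#' @return A tibble with one row per rectangle: grid indices, rectangle
#'   bounds, and list-columns `e_ids` and `i_ids` of admitted neuron ids.
#' @export
select_subnetworks <- function(neurons, grid = subvolume_grid(),
                               i_margin = Inf) {
  neurons <- as_neuron_table(neurons)
  u <- neurons[[grid$axes[1]]]
  v <- neurons[[grid$axes[2]]]
  span_u <- grid$width + (grid$grid_shape[1] - 1L) * grid$shift
  span_v <- grid$depth + (grid$grid_shape[2] - 1L) * grid$shift
  origin <- grid$origin
  if (is.null(origin)) {
    origin <- c(mean(range(u)) - span_u / 2, mean(range(v)) - span_v / 2)
  }
  if (grid$width > diff(range(u)) || grid$depth > diff(range(v))) {
    warn("Subvolume rectangle is larger than the extent of the neuron cloud.")
  }
  is_e <- neurons$synapse_class == "E"
  is_i <- !is_e
  all_i <- neurons$neuron_id[is_i]
  out <- tidyr::expand_grid(gi = seq_len(grid$grid_shape[1]),
                            gj = seq_len(grid$grid_shape[2]))
  out$umin <- origin[1] + (out$gi - 1L) * grid$shift
  out$vmin <- origin[2] + (out$gj - 1L) * grid$shift
  out$umax <- out$umin + grid$width
  out$vmax <- out$vmin + grid$depth
  sel_e <- vector("list", nrow(out))
  sel_i <- vector("list", nrow(out))
  for (r in seq_len(nrow(out))) {
    inside <- u >= out$umin[r] & u < out$umax[r] &
      v >= out$vmin[r] & v < out$vmax[r]
    sel_e[[r]] <- neurons$neuron_id[inside & is_e]
    if (is.infinite(i_margin)) {
      sel_i[[r]] <- all_i
    } else {
      inside_i <- u >= out$umin[r] - i_margin & u < out$umax[r] + i_margin &
        v >= out$vmin[r] - i_margin & v < out$vmax[r] + i_margin
      sel_i[[r]] <- neurons$neuron_id[inside_i & is_i]
    }
  }
  out$e_ids <- sel_e
  out$i_ids <- sel_i
  out
}

#' Pairwise connection probabilities between two neuron groups
#'
#' Over all ordered cross pairs \eqn{(a, b)}, \eqn{a \in A}, \eqn{b \in
#' B}, \eqn{a \neq b}, whose somata lie within `max_distance` of each
#' other, computes the probability of a connection \eqn{a \to b}
#' (`p_ab`), \eqn{b \to a} (`p_ba`), of a reciprocal pair
#' (`p_bidirectional`), and the overexpression of bidirectionality
#' `p_bidirectional / (p_ab * p_ba)` (reported as `NA` when a denominator
#' is zero).
#'
#' @param conn A `connectome`.
#' @param group_a,group_b Neuron id vectors (disjoint or identical).
#' @param max_distance Maximum soma distance in micrometres (default
#'   `Inf`: all pairs).
#' @return A one-row tibble with columns `p_ab`, `p_ba`,
#'   `p_bidirectional`, `overexpression` and `n_pairs`.
#' @export
pairwise_connection_stats <- function(conn, group_a, group_b,
                                      max_distance = Inf) {
  nodes <- conn$nodes
  ia <- match(intersect(group_a, nodes$neuron_id), nodes$neuron_id)
  ib <- match(intersect(group_b, nodes$neuron_id), nodes$neuron_id)
  empty <- tibble::tibble(p_ab = NA_real_, p_ba = NA_real_,
                          p_bidirectional = NA_real_,
                          overexpression = NA_real_, n_pairs = 0L)
  if (length(ia) == 0L || length(ib) == 0L) {
    warn("No eligible pairs for pairwise connection statistics.")
    return(empty)
  }
  pairs <- tidyr::expand_grid(a = ia, b = ib)
  pairs <- pairs[pairs$a != pairs$b, , drop = FALSE]
  if (is.finite(max_distance)) {
    pa <- as.matrix(nodes[pairs$a, c("x", "y", "z")])
    pb <- as.matrix(nodes[pairs$b, c("x", "y", "z")])
    d <- sqrt(rowSums((pa - pb)^2))
    pairs <- pairs[d <= max_distance, , drop = FALSE]
  }
  if (nrow(pairs) == 0L) {
    warn("No eligible pairs for pairwise connection statistics.")
    return(empty)
  }
  ab <- conn$adj[cbind(pairs$a, pairs$b)] > 0
  ba <- conn$adj[cbind(pairs$b, pairs$a)] > 0
  p_ab <- mean(ab)
  p_ba <- mean(ba)
  p_bi <- mean(ab & ba)
  over <- if (p_ab > 0 && p_ba > 0) p_bi / (p_ab * p_ba) else NA_real_
  tibble::tibble(p_ab = p_ab, p_ba = p_ba, p_bidirectional = p_bi,
                 overexpression = over, n_pairs = nrow(pairs))
}
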