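#' Specification of planted simplicial structure
#'
#' Describes the divergent feed-forward motifs to plant into a synthetic
#' excitatory connectome and the positioning bias of the inhibitory wiring
#' around them.  Divergence means that the planted simplices reuse a small
#' pool of source neurons while drawing their target-side neurons from a
#' much larger pool, so the fraction of unique neurons rises from the
#' source position towards the target position.
#'
#' @param dim Motif dimension (>= 2); a dim-`d` motif has `d + 1` neurons.
#' @param n_motifs Number of motifs to plant.
#' @param source_pool,target_pool Sizes of the excitatory source and
#'   target pools.
#' @param in_bias Strength of the excitatory-to-inhibitory wiring bias
#'   towards source positions (0 = unbiased).
#' @param out_bias Strength of the inhibitory-to-excitatory wiring bias
#'   towards target positions.
#' @param disinhibitory_fraction Fraction of inhibitory neurons wired
#'   preferentially onto other inhibitory neurons.
#' @param p_ei,p_ie Baseline connection probabilities for E->I and I->E
#'   wiring of simplex members.
#' @param p_ii_base,p_ii_target I->I connection probability for ordinary
#'   and for disinhibitory interneurons.
#' @param reciprocity Probability that a sampled E->I connection is
#'   mirrored by the reciprocal I->E connection.  Interneurons
#'   preferentially inhibit the pyramidal cells that innervate them, so
#'   biased excitation from source-side neurons returns as inhibition
#'   onto the same motifs; this couples disynaptic inhibition to shared
#'   sources.
#' @param weight_bias Nonnegative scale of extra synapses per connection
#'   on strongly biased edges (0 keeps all synapse counts at 1).
#' @return An object of class `plant_spec`.
#' @export
plant_spec <- function(dim = 5L, n_motifs = 25L, source_pool = 4L,
                       target_pool = 120L, in_bias = 3, out_bias = 3,
                       disinhibitory_fraction = 0.15,
                       p_ei = 0.08, p_ie = 0.08,
                       p_ii_base = 0.02, p_ii_target = 0.35,
                       reciprocity = 0.4, weight_bias = 0) {
  stopifnot(dim >= 2L, n_motifs >= 1L, source_pool >= 1L, target_pool >= 1L,
            in_bias >= 0, out_bias >= 0,
            disinhibitory_fraction >= 0, disinhibitory_fraction <= 1,
            p_ei >= 0, p_ei <= 1, p_ie >= 0, p_ie <= 1,
            reciprocity >= 0, reciprocity <= 1, weight_bias >= 0)
  structure(list(dim = as.integer(dim), n_motifs = as.integer(n_motifs),
                 source_pool = as.integer(source_pool),
                 target_pool = as.integer(target_pool),
                 in_bias = in_bias, out_bias = out_bias,
                 disinhibitory_fraction = disinhibitory_fraction,
                 p_ei = p_ei, p_ie = p_ie, p_ii_base = p_ii_base,
                 p_ii_target = p_ii_target, reciprocity = reciprocity,
                 weight_bias = weight_bias),
            class = "plant_spec")
}

#' Plant divergent feed-forward simplices into a connectome
#'
#' Adds the edges of `n_motifs` ordered all-to-all motifs of dimension
#' `dim` to the excitatory subgraph.  The neuron at position `k` of a
#' motif is drawn from the small source pool with probability
#' `1 - k / dim` (with reuse across motifs) and otherwise from the large
#' target pool (cycling through a permutation, so targets are mostly
#' unique until the pool is exhausted).  Only missing edges are added;
#' planting the same motif twice is idempotent.
#'
#' @param base A `connectome` whose excitatory population is large enough
#'   for the requested pools.
#' @param spec A [plant_spec()].
#' @param seed Optional RNG seed.
#' @return The augmented `connectome`; the planted motifs and added edges
#'   are attached as attributes `"plant_motifs"` (matrix, one motif per
#'   row, columns = positions) and `"plant_edges"` (tibble).
#' @export
plant_divergent_simplices <- function(base, spec, seed = NULL) {
  stopifnot(inherits(base, "connectome"), inherits(spec, "plant_spec"))
  e_ids <- excitatory_ids(base)
  if (length(e_ids) < spec$source_pool + spec$target_pool) {
    abort("Excitatory population too small for the requested pools.")
  }
  if (spec$dim + 1L > spec$source_pool + spec$target_pool) {
    abort("Pools exhausted: a motif needs more neurons than the pools hold.")
  }
  with_rng_seed(seed, {
    pool_ids <- sample(e_ids, spec$source_pool + spec$target_pool)
    src_pool <- pool_ids[seq_len(spec$source_pool)]
    tgt_pool <- pool_ids[-seq_len(spec$source_pool)]
    tgt_seq <- sample(tgt_pool)
    tgt_ptr <- 0L
    next_target <- function() {
      tgt_ptr <<- tgt_ptr + 1L
      if (tgt_ptr > length(tgt_seq)) {  # pool exhausted: recycle
        tgt_seq <<- sample(tgt_pool)
        tgt_ptr <<- 1L
      }
      tgt_seq[tgt_ptr]
    }
    d <- spec$dim
    motifs <- matrix(NA_real_, nrow = spec$n_motifs, ncol = d + 1L)
    for (m in seq_len(spec$n_motifs)) {
      nodes <- numeric(0)
      from_pool <- logical(d + 1L)
      for (k in 0:d) {
        for (try in 1:1000) {
          use_pool <- runif(1) < 1 - k / d
          cand <- if (use_pool) sample(src_pool, 1L) else next_target()
          if (!cand %in% nodes) break
          if (try == 1000L) abort("Pools exhausted while planting a motif.")
        }
        nodes <- c(nodes, cand)
        from_pool[k + 1L] <- use_pool
      }
      # source-pool members take their positions in canonical pool order,
      # so two motifs never order a pool pair oppositely (which would
      # plant reciprocal edges and duplicate whole simplex suffixes)
      nodes[from_pool] <- nodes[from_pool][
        order(match(nodes[from_pool], src_pool))]
      motifs[m, ] <- nodes
    }
    pairs <- which(upper.tri(diag(d + 1L)), arr.ind = TRUE)
    new_edges <- tibble::tibble(
      pre_id = as.vector(motifs[, pairs[, 1]]),
      post_id = as.vector(motifs[, pairs[, 2]])) |>
      dplyr::distinct()
    out <- add_edges_to_connectome(base, new_edges, weight = 1)
    attr(out, "plant_motifs") <- motifs
    attr(out, "plant_edges") <- new_edges
    out
  })
}

# Add missing edges (weight applied only to edges not already present).
add_edges_to_connectome <- function(conn, edges, weight = 1) {
  if (nrow(edges) == 0L) return(conn)
  ids <- conn$nodes$neuron_id
  i <- match(edges$pre_id, ids)
  j <- match(edges$post_id, ids)
  if (anyNA(i) || anyNA(j)) abort("Edge endpoints absent from connectome.")
  w <- if (length(weight) == 1L) rep(weight, length(i)) else weight
  present <- conn$adj[cbind(i, j)] > 0
  if (all(present)) return(conn)
  add <- Matrix::sparseMatrix(i = i[!present], j = j[!present],
                              x = as.numeric(w[!present]),
                              dims = dim(conn$adj),
                              dimnames = dimnames(conn$adj))
  new_connectome(conn$nodes, methods::as(conn$adj + add, "CsparseMatrix"),
                 conn$meta)
}

#' Wire inhibition with simplex-position bias
#'
#' Samples excitatory-to-inhibitory edges with probability increasing
#' towards the source positions of the supplied simplices, and
#' inhibitory-to-excitatory edges with probability increasing towards the
#' target positions — the positioning observed around cortical simplex
#' motifs, where interneurons are excited by source-side neurons and
#' inhibit target-side neurons.  A configured fraction of interneurons is
#' made disinhibitory: wired onto other interneurons with elevated
#' probability.
#'
#' For a simplex member with mean normalised position \eqn{\rho \in [0,
#' 1]} (0 = source, 1 = target), the E->I probability is
#' `p_ei * (1 + in_bias * (1 - rho))` and the I->E probability
#' `p_ie * (1 + out_bias * rho)`, both capped at 1.  With `weight_bias >
#' 0`, sampled biased edges carry `1 + rpois(weight_bias * bias_factor)`
#' synapses, emulating the stronger (multi-synapse) connections seen on
#' biased pathways.
#'
#' @param base A `connectome` containing inhibitory neurons.
#' @param simplices A `simplex_table` for the excitatory subgraph of
#'   `base` (see [enumerate_simplices()]).
#' @param dim Dimension whose simplices define the positions (defaults to
#'   the largest enumerated dimension with at least one simplex).
#' @param spec A [plant_spec()].
#' @param seed Optional RNG seed.
#' @return The augmented `connectome`, with attribute
#'   `"disinhibitory_ids"` naming the interneurons wired as disinhibitory.
#' @export
wire_biased_inhibition <- function(base, simplices, spec, dim = NULL,
                                   seed = NULL) {
  stopifnot(inherits(base, "connectome"), inherits(spec, "plant_spec"))
  i_ids <- inhibitory_ids(base)
  if (length(i_ids) == 0L) abort("Connectome has no inhibitory neurons.")
  dim <- dim %||% max_simplex_dim(simplices)
  tuples <- simplex_tuples(simplices, dim)
  if (is.null(tuples) || nrow(tuples) == 0L) {
    abort("Simplex table has no simplices at the requested dimension.")
  }
  # mean normalised position per participating excitatory neuron
  memb <- melt_simplices(tuples)
  rho <- memb |>
    dplyr::group_by(.data$node_id) |>
    dplyr::summarise(rho = mean(.data$position / dim), .groups = "drop")
  with_rng_seed(seed, {
    n_dis <- round(spec$disinhibitory_fraction * length(i_ids))
    dis_ids <- if (n_dis > 0) sample(i_ids, n_dis) else numeric(0)

    grid <- tidyr::expand_grid(e = rho$node_id, i = i_ids) |>
      dplyr::left_join(rho, by = c(e = "node_id"))
    p_ei <- pmin(1, spec$p_ei * (1 + spec$in_bias * (1 - grid$rho)))
    p_ie <- pmin(1, spec$p_ie * (1 + spec$out_bias * grid$rho))
    ei_hit <- runif(nrow(grid)) < p_ei
    ie_hit <- runif(nrow(grid)) < p_ie
    # reciprocal loops: inhibition returns onto the neurons driving it
    mirror <- ei_hit & runif(nrow(grid)) < spec$reciprocity
    ie_hit <- ie_hit | mirror
    w_ei <- rep(1, sum(ei_hit))
    w_ie <- rep(1, sum(ie_hit))
    if (spec$weight_bias > 0) {
      w_ei <- 1 + stats::rpois(sum(ei_hit),
                               spec$weight_bias * (1 - grid$rho[ei_hit]))
      w_ie <- 1 + stats::rpois(sum(ie_hit),
                               spec$weight_bias * grid$rho[ie_hit])
    }
    edges <- dplyr::bind_rows(
      tibble::tibble(pre_id = grid$e[ei_hit], post_id = grid$i[ei_hit],
                     w = w_ei),
      tibble::tibble(pre_id = grid$i[ie_hit], post_id = grid$e[ie_hit],
                     w = w_ie))
    # inhibitory-to-inhibitory wiring; disinhibitory cells target I densely
    ii <- tidyr::expand_grid(pre_id = i_ids, post_id = i_ids) |>
      dplyr::filter(.data$pre_id != .data$post_id)
    p_ii <- ifelse(ii$pre_id %in% dis_ids, spec$p_ii_target, spec$p_ii_base)
    ii_hit <- runif(nrow(ii)) < p_ii
    edges <- dplyr::bind_rows(edges,
                              tibble::tibble(pre_id = ii$pre_id[ii_hit],
                                             post_id = ii$post_id[ii_hit],
                                             w = 1))
    out <- add_edges_to_connectome(base, edges, weight = edges$w)
    attr(out, "disinhibitory_ids") <- dis_ids
    out
  })
}
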