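#' Activity correlation grouped by edge simplex dimension
#'
#' Groups pairwise activity correlations of connected neurons by the
#' maximal simplex dimension of the connecting edge — in the "all"
#' variant over every edge, in the "last" variant over the final
#' (position dim-1 to dim) connections of each dimension's simplices,
#' counted with repetition.  Correlations are z-scored within each
#' session against all valid pairs of that session, then averaged per
#' group across sessions.  Connected- and unconnected-pair baselines are
#' reported alongside.
#'
#' @param corr A correlation matrix with node ids as dimnames, or a list
#'   of such matrices (one per session).
#' @param edge_dims Tibble with columns `pre_id`, `post_id`, `dim`
#'   ([edge_max_dimension()]).
#' @param last_edges Optional tibble with columns `dim`, `pre_id`,
#'   `post_id` ([last_simplex_edges()]); enables the "last" variant.
#' @return A tibble with columns `variant` (`all`, `last`, `connected`,
#'   `unconnected`), `dim` (`NA` for baselines), `mean_z`, `se`, `n`.
#' @export
correlation_by_edge_dimension <- function(corr, edge_dims,
                                          last_edges = NULL) {
  sessions <- if (is.list(corr) && !is.matrix(corr)) corr else list(corr)
  per_session <- purrr::imap(sessions, function(cm, si) {
    ids <- as.numeric(rownames(cm))
    if (length(ids) < 2L) {
      warn(paste0("Session ", si, " has fewer than 2 nodes; skipped."))
      return(NULL)
    }
    ut <- upper.tri(cm)
    vals <- cm[ut]
    mu <- mean(vals, na.rm = TRUE)
    sigma <- sd(vals, na.rm = TRUE)
    if (!is.finite(sigma) || sigma == 0) sigma <- 1
    z <- (cm - mu) / sigma
    ed <- edge_dims[edge_dims$pre_id %in% ids & edge_dims$post_id %in% ids, ]
    iu <- match(ed$pre_id, ids); iv <- match(ed$post_id, ids)
    rows <- list(
      tibble::tibble(variant = "all", dim = ed$dim, z = z[cbind(iu, iv)]))
    if (!is.null(last_edges)) {
      le <- last_edges[last_edges$pre_id %in% ids &
                         last_edges$post_id %in% ids, ]
      rows <- c(rows, list(
        tibble::tibble(variant = "last", dim = le$dim,
                       z = z[cbind(match(le$pre_id, ids),
                                   match(le$post_id, ids))])))
    }
    conn_mask <- matrix(FALSE, nrow(cm), ncol(cm))
    conn_mask[cbind(iu, iv)] <- TRUE
    pair_mask <- ut | t(ut)
    rows <- c(rows, list(
      tibble::tibble(variant = "connected", dim = NA_integer_,
                     z = z[conn_mask]),
      tibble::tibble(variant = "unconnected", dim = NA_integer_,
                     z = z[pair_mask & !conn_mask & !t(conn_mask)])))
    dplyr::bind_rows(rows)
  })
  dplyr::bind_rows(per_session) |>
    dplyr::group_by(.data$variant, .data$dim) |>
    dplyr::summarise(mean_z = mean(.data$z, na.rm = TRUE),
                     se = sd(.data$z, na.rm = TRUE) /
                       sqrt(sum(is.finite(.data$z))),
                     n = sum(is.finite(.data$z)), .groups = "drop")
}

#' Last connections of each dimension's simplices
#'
#' The edges from position `dim - 1` to position `dim`, listed with
#' repetition (one row per simplex).
#'
#' @param st A `simplex_table` with tuples.
#' @return A tibble with columns `dim`, `pre_id`, `post_id`.
#' @export
last_simplex_edges <- function(st) {
  listed <- as.integer(names(st$tuples))
  purrr::map_dfr(listed[listed >= 1L], function(d) {
    tuples <- simplex_tuples(st, d)
    if (is.null(tuples) || nrow(tuples) == 0L) return(NULL)
    tibble::tibble(dim = d, pre_id = tuples[, d], post_id = tuples[, d + 1L])
  })
}

#' Select the target dimension of a network
#'
#' The *target dimension* is the dimension whose source-normalised
#' unique-neuron fraction at the target position is maximal — where the
#' divergent feed-forward trend is strongest.  Ties break towards the
#' lower dimension (the more conservative, smaller motif).
#'
#' @param profiles A tibble with columns `dim`, `position`, `normalized`
#'   (e.g. rows of [unique_fraction_by_position()] bound with a `dim`
#'   column), or a `simplex_table` from which profiles are computed for
#'   every dimension with simplices.
#' @param min_dim Smallest dimension considered (default 1).
#' @return A single integer dimension.
#' @export
select_target_dimension <- function(profiles, min_dim = 1L) {
  if (inherits(profiles, "simplex_table")) {
    st <- profiles
    dims <- as.integer(names(st$tuples))
    dims <- dims[dims >= min_dim &
                   vapply(st$tuples, nrow, 1L)[as.character(dims)] > 0]
    profiles <- purrr::map_dfr(dims, function(d) {
      dplyr::mutate(unique_fraction_by_position(st, d), dim = d)
    })
  }
  at_target <- profiles |>
    dplyr::filter(.data$dim >= min_dim) |>
    dplyr::group_by(.data$dim) |>
    dplyr::summarise(value = .data$normalized[which.max(.data$position)],
                     .groups = "drop") |>
    dplyr::filter(is.finite(.data$value))
  if (nrow(at_target) == 0L) abort("No usable divergence profiles.")
  best <- max(at_target$value)
  min(at_target$dim[at_target$value >= best - 1e-12])
}

#' Configuration of a full synthetic analysis run
#'
#' Bundles the generator settings, analysis thresholds and the root seed
#' for [run_analysis()].  Every random stage derives its own seed from
#' `seed`, so a configuration determines the outputs exactly.
#'
#' @param n_e,n_i Neuron counts.
#' @param volume Slab extent in micrometres.
#' @param params A [distance_model_params()].
#' @param plant A [plant_spec()].
#' @param grid A [subvolume_grid()] or `NULL` to analyse the full volume
#'   as a single subnetwork.
#' @param n_shuffles Size of the column-shuffle control ensemble.
#' @param targeting_threshold Flagging threshold of the disinhibition
#'   test.
#' @param percentile Exceedance percentile for the group network.
#' @param resolution Louvain resolution.
#' @param n_neighborhood_nodes Number of nodes scored for neighbourhood
#'   complexity (sampled from the simplex core outward); `Inf` scores
#'   all.
#' @param rewiring Optional tibble with columns `d_max`, `m` to run a
#'   rewiring schedule.
#' @param activity Logical: synthesize traces and compute the
#'   correlation-by-dimension analysis.
#' @param t_samples Trace length when `activity` is `TRUE`.
#' @param corr_profile Named dimension-to-correlation profile for the
#'   synthetic traces.
#' @param seed Root seed.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(n_e = 300L, n_i = 80L,
                            volume = c(400, 300, 400),
                            params = distance_model_params(),
                            plant = plant_spec(),
                            grid = NULL,
                            n_shuffles = 20L,
                            targeting_threshold = 1e-6,
                            percentile = 0.95,
                            resolution = 2.2,
                            n_neighborhood_nodes = 60L,
                            rewiring = NULL,
                            activity = FALSE,
                            t_samples = 2000L,
                            corr_profile = c("1" = 0.05, "3" = 0.15,
                                             "5" = 0.3),
                            seed = 1L) {
  structure(as.list(environment()), class = "analysis_config")
}

#' Run the full synthetic analysis pipeline
#'
#' Generates a synthetic connectome with planted divergent simplices and
#' position-biased inhibition, then runs every analysis stage: simplex
#' enumeration, divergence profiles and target-dimension selection,
#' inhibitory degree profiles, disynaptic inhibition with its symmetry
#' and shuffled controls, overlap correlations, the disinhibition
#' targeting test and profile, source/target grouping with the
#' group-level network, neighbourhood complexity, and optionally
#' rewiring and the structure-activity correlation.  Each stage's output
#' is hashed into a manifest so identical configurations are verifiably
#' reproducible.
#'
#' @param config An [analysis_config()].
#' @return A list of stage outputs plus `manifest` (tibble of stage
#'   hashes) and the echoed `config`.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  res <- list()
  sd_ <- function(k) derive_seed(config$seed, k)

  neurons <- make_neurons(config$n_e, config$n_i, config$volume,
                          seed = sd_(1))
  base <- sample_distance_connectome(neurons, config$params, seed = sd_(2))
  planted <- plant_divergent_simplices(base, config$plant, seed = sd_(3))
  e_st <- enumerate_simplices(induced_connectome(planted,
                                                 excitatory_ids(planted)))
  conn <- wire_biased_inhibition(planted, e_st, config$plant,
                                 dim = config$plant$dim, seed = sd_(4))
  res$connectome <- conn

  if (!is.null(config$grid)) {
    res$subnetworks <- select_subnetworks(conn$nodes, config$grid)
    central <- res$subnetworks[ceiling(nrow(res$subnetworks) / 2), ]
    keep <- c(central$e_ids[[1]], central$i_ids[[1]])
    conn_a <- induced_connectome(conn, keep)
  } else {
    conn_a <- conn
  }
  esub <- induced_connectome(conn_a, excitatory_ids(conn_a))
  st <- enumerate_simplices(esub)
  res$simplex_counts <- simplex_counts(st)
  dims <- as.integer(names(st$tuples))
  dims <- dims[dims >= 1L & vapply(st$tuples, nrow, 1L) > 0]
  res$divergence <- purrr::map_dfr(dims, function(d) {
    dplyr::mutate(unique_fraction_by_position(st, d), dim = d)
  })
  target_dim <- select_target_dimension(res$divergence, min_dim = 2L)
  res$target_dim <- target_dim

  res$degree_profile <- inhibitory_degree_by_position(st, conn_a, target_dim)
  tensors <- inhibition_tensors(st, conn_a, target_dim)
  inh <- disynaptic_inhibition(tensors)
  res$symmetry <- symmetry_score(inh)
  shuffles <- shuffled_disynaptic(tensors, config$n_shuffles, seed = sd_(5))
  res$symmetry_shuffled <- vapply(shuffles, symmetry_score, numeric(1))

  o_src <- overlap_matrix(st, target_dim, 0:min(2L, target_dim))
  o_tgt <- overlap_matrix(st, target_dim,
                          max(target_dim - 2L, 0L):target_dim)
  o_any <- overlap_matrix(st, target_dim, 0:target_dim)
  res$overlap_correlation <- overlap_inhibition_correlation(o_src, o_tgt,
                                                            inh)

  targeting <- inhibitory_targeting_test(conn_a,
                                         config$targeting_threshold)
  res$targeting <- tibble::as_tibble(unclass(targeting))
  sdeg <- simplex_degrees_of_inhibitory(st, conn_a, target_dim)
  res$simplex_degrees <- sdeg
  res$disinhibition <- disinhibition_profile(conn_a, targeting, sdeg)

  src_groups <- cluster_simplices(o_src, config$resolution, seed = sd_(6))
  tgt_groups <- cluster_simplices(o_tgt, config$resolution, seed = sd_(7))
  res$group_network <- group_network(src_groups, tgt_groups, o_any, inh,
                                     shuffles,
                                     percentile = config$percentile)
  res$source_group_sizes <- group_sizes(src_groups)
  res$target_group_sizes <- group_sizes(tgt_groups)

  control <- configuration_model(conn_a, seed = sd_(8))
  core <- simplex_core(st, target_dim)
  score_nodes <- if (is.finite(config$n_neighborhood_nodes) &&
                     length(core) > config$n_neighborhood_nodes) {
    with_rng_seed(sd_(9), sample(core, config$n_neighborhood_nodes))
  } else core
  res$neighborhood <- neighborhood_complexity(conn_a, control, score_nodes)
  res$complexity_by_position <- complexity_by_position(res$neighborhood, st,
                                                       dims = target_dim)

  if (!is.null(config$rewiring)) {
    res$rewiring <- rewiring_schedule(conn_a, config$rewiring,
                                      seed = sd_(10))
  }
  if (isTRUE(config$activity)) {
    ed <- edge_max_dimension(st)
    e_ids <- esub$nodes$neuron_id
    traces <- synth_activity(e_ids, ed, config$corr_profile,
                             config$t_samples, seed = sd_(11))
    cm <- cor(traces)
    rownames(cm) <- colnames(cm) <- as.character(e_ids)
    res$correlation_by_dim <- correlation_by_edge_dimension(
      cm, ed, last_simplex_edges(st))
  }

  manifest <- tibble::tibble(stage = names(res),
                             hash = vapply(res, rlang::hash, character(1)))
  c(res, list(manifest = manifest, config = config))
}
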