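#' Plasticity-inspired rewiring of excitatory connectivity
#'
#' A rewiring step removes excitatory edges that participate only in
#' low-dimensional simplices and adds edges between neurons that
#' participate strongly in high-dimensional ones, emulating structural
#' plasticity that favours connections inside large feed-forward motifs.
#'
#' One step, with dimension threshold `d_max` and step size `m`:
#' \enumerate{
#'   \item On the pre-step excitatory graph, compute each edge's maximal
#'     simplex dimension and each node's participation counts
#'     \eqn{Par_{dim,pos}}.
#'   \item Remove `m` edges chosen uniformly among edges with maximal
#'     dimension \eqn{\le} `d_max`.
#'   \item Add `m` edges among currently unconnected ordered excitatory
#'     pairs (after the removals), sampled without replacement with
#'     probability \eqn{P(a \to b) \propto \sum_{dim > d\_max}
#'     \sum_{i < j \in pos} Par_{dim,i}(a)\, Par_{dim,j}(b)}.
#' }
#' Participation and edge dimensions are computed once on the pre-step
#' graph (removal does not feed back into the addition probabilities
#' within a step); pairs disconnected by this step's removals are
#' eligible for addition.  Edge count is conserved exactly.
#'
#' `rewiring_schedule()` applies a sequence of steps and logs per-step
#' simplex counts and edge-dimension histograms.
#'
#' @param conn A `connectome`; only excitatory-to-excitatory edges are
#'   rewired.
#' @param d_max Dimension threshold: removed edges have maximal simplex
#'   dimension at or below it; addition probabilities use participation
#'   strictly above it.
#' @param m Number of edges removed and added.
#' @param pos Eligible position set for the addition rule (default
#'   `c(0, 1)`: the source side).
#' @param seed Optional RNG seed.
#' @return `rewiring_step()`: list with elements `connectome` and `log`
#'   (tibble of removed/added edges).
#' @export
rewiring_step <- function(conn, d_max, m, pos = c(0, 1), seed = NULL) {
  stopifnot(m >= 0, d_max >= 1)
  if (m == 0L) {
    return(list(connectome = conn,
                log = tibble::tibble(action = character(),
                                     pre_id = numeric(),
                                     post_id = numeric())))
  }
  e_ids <- excitatory_ids(conn)
  esub <- induced_connectome(conn, e_ids)
  st <- enumerate_simplices(esub)
  edim <- edge_max_dimension(st)
  eligible <- edim[edim$dim <= d_max, ]
  if (nrow(eligible) < m) {
    abort(paste0("Only ", nrow(eligible), " edges with maximal dimension <= ",
                 d_max, " exist; ", m, " removals requested (deficit ",
                 m - nrow(eligible), ")."))
  }
  par <- node_participation(st)
  dims_above <- sort(unique(par$dim[par$dim > d_max]))
  n_e <- length(e_ids)
  w <- matrix(0, n_e, n_e)
  pos_pairs <- expand.grid(i = pos, j = pos)
  pos_pairs <- pos_pairs[pos_pairs$i < pos_pairs$j, , drop = FALSE]
  for (d in dims_above) {
    pd <- par[par$dim == d, ]
    for (r in seq_len(nrow(pos_pairs))) {
      pi <- pd[pd$position == pos_pairs$i[r], ]
      pj <- pd[pd$position == pos_pairs$j[r], ]
      if (nrow(pi) == 0L || nrow(pj) == 0L) next
      vi <- numeric(n_e); vi[match(pi$node_id, e_ids)] <- pi$n_simplices
      vj <- numeric(n_e); vj[match(pj$node_id, e_ids)] <- pj$n_simplices
      w <- w + outer(vi, vj)
    }
  }
  with_rng_seed(seed, {
    rm_rows <- eligible[sample.int(nrow(eligible), m), ]
    ids_all <- conn$nodes$neuron_id
    adj <- conn$adj
    adj[cbind(match(rm_rows$pre_id, ids_all),
              match(rm_rows$post_id, ids_all))] <- 0
    adj <- Matrix::drop0(adj)
    # addition candidates: unconnected ordered E pairs after removal
    e_adj <- adj[match(e_ids, ids_all), match(e_ids, ids_all)] > 0
    w[as.matrix(e_adj)] <- 0
    diag(w) <- 0
    if (sum(w) <= 0) {
      abort("Addition probability mass is zero for all unconnected pairs.")
    }
    flat_idx <- which(w > 0)
    picks <- flat_idx[sample.int(length(flat_idx), m,
                                 prob = w[flat_idx])]
    add_pre <- e_ids[(picks - 1) %% n_e + 1]
    add_post <- e_ids[(picks - 1) %/% n_e + 1]
    adj[cbind(match(add_pre, ids_all), match(add_post, ids_all))] <- 1
    out <- new_connectome(conn$nodes, methods::as(adj, "CsparseMatrix"),
                          conn$meta)
    log <- dplyr::bind_rows(
      tibble::tibble(action = "remove", pre_id = rm_rows$pre_id,
                     post_id = rm_rows$post_id),
      tibble::tibble(action = "add", pre_id = add_pre, post_id = add_post))
    list(connectome = out, log = log)
  })
}

#' @rdname rewiring_step
#' @param schedule A tibble or data frame with columns `d_max` and `m`,
#'   one row per step, applied in order.  The reference schedule is one
#'   step at the middle dimension threshold (`d_max = 3`, `m = 2000`)
#'   followed by three source-side steps (`d_max = 2`, `m = 10000`).
#' @return `rewiring_schedule()`: list with the final `connectome`,
#'   per-step `metrics` (simplex counts and edge-dimension histograms),
#'   the combined change `log`, and `fraction_rewired`.
#' @export
rewiring_schedule <- function(conn, schedule, pos = c(0, 1), seed = NULL) {
  schedule <- tibble::as_tibble(schedule)
  stopifnot(nrow(schedule) >= 1L, all(c("d_max", "m") %in% names(schedule)))
  n_e_edges <- function(cc) {
    eidx <- which(cc$nodes$synapse_class == "E")
    length(Matrix::drop0(cc$adj[eidx, eidx])@x)
  }
  initial_edges <- n_e_edges(conn)
  metric_row <- function(cc, step) {
    esub <- induced_connectome(cc, excitatory_ids(cc))
    st <- enumerate_simplices(esub)
    tibble::tibble(step = step,
                   counts = list(simplex_counts(st)),
                   edge_dims = list(dplyr::count(edge_max_dimension(st),
                                                 .data$dim)))
  }
  metrics <- metric_row(conn, 0L)
  logs <- list()
  for (k in seq_len(nrow(schedule))) {
    res <- rewiring_step(conn, schedule$d_max[k], schedule$m[k], pos = pos,
                         seed = derive_seed(seed, k))
    conn <- res$connectome
    logs[[k]] <- dplyr::mutate(res$log, step = k, .before = 1L)
    metrics <- dplyr::bind_rows(metrics, metric_row(conn, k))
  }
  list(connectome = conn, metrics = metrics,
       log = dplyr::bind_rows(logs),
       fraction_rewired = sum(schedule$m) / initial_edges)
}
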