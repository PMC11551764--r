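# Shared fixtures and independent oracles. Fixtures are memoized in this
# environment so the suite builds each one once.

fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(fixture_env[[key]])) fixture_env[[key]] <- builder()
  fixture_env[[key]]
}

# --- independent oracles ----------------------------------------------------

all_perms <- function(v) {
  if (length(v) <= 1L) return(matrix(v, 1L))
  do.call(rbind, lapply(seq_along(v), function(i) {
    cbind(v[i], all_perms(v[-i]), deparse.level = 0)
  }))
}

# Exhaustive directed-simplex counts over all ordered node subsets.
brute_force_simplex_counts <- function(adj, max_dim) {
  a <- as.matrix(adj) > 0
  n <- nrow(a)
  counts <- numeric(max_dim + 1L)
  counts[1] <- n
  for (d in seq_len(max_dim)) {
    k <- d + 1L
    if (k > n) break
    combs <- utils::combn(n, k)
    perms <- all_perms(seq_len(k))
    tot <- 0
    for (p in seq_len(nrow(perms))) {
      tuples <- t(combs[perms[p, ], , drop = FALSE])
      ok <- rep(TRUE, nrow(tuples))
      for (i in 1:(k - 1)) {
        for (j in (i + 1):k) {
          ok <- ok & a[cbind(tuples[, i], tuples[, j])]
        }
      }
      tot <- tot + sum(ok)
    }
    counts[d + 1L] <- tot
  }
  counts
}

# Direct hypergeometric tail by summing the mass function.
hyper_tail <- function(k, n_pos, n_total, n_draws) {
  if (k <= 0) return(1)
  sum(stats::dhyper(k:min(n_draws, n_pos), n_pos, n_total - n_pos, n_draws))
}

random_connectome <- function(n, p, seed, n_i = 0L) {
  withr::with_seed(seed, {
    neurons <- tibble::tibble(neuron_id = seq_len(n), x = runif(n, 0, 100),
                              y = runif(n, 0, 100), z = runif(n, 0, 100),
                              synapse_class = rep(c("E", "I"),
                                                  c(n - n_i, n_i)))
    pairs <- expand.grid(pre_id = seq_len(n), post_id = seq_len(n))
    pairs <- pairs[pairs$pre_id != pairs$post_id, ]
    pairs <- pairs[runif(nrow(pairs)) < p, ]
    build_connectome(neurons, tibble::as_tibble(pairs))
  })
}

# --- memoized fixtures ------------------------------------------------------

# Planted synthetic connectome: divergent dim-5 motifs on a
# distance-dependent excitatory background, position-biased inhibition,
# and a disinhibitory interneuron subclass.
planted_fixture <- function() {
  memo("planted", function() {
    spec <- plant_spec(dim = 5L, n_motifs = 25L, source_pool = 4L,
                       target_pool = 120L, in_bias = 3, out_bias = 3,
                       disinhibitory_fraction = 0.15, weight_bias = 2)
    neurons <- make_neurons(300, 80, c(400, 300, 400), seed = 101)
    base <- sample_distance_connectome(neurons, distance_model_params(),
                                       seed = 102)
    planted <- plant_divergent_simplices(base, spec, seed = 103)
    est <- enumerate_simplices(induced_connectome(planted,
                                                  excitatory_ids(planted)))
    conn <- wire_biased_inhibition(planted, est, spec, dim = 5L,
                                   seed = 104)
    st <- enumerate_simplices(induced_connectome(conn,
                                                 excitatory_ids(conn)))
    list(spec = spec, neurons = neurons, conn = conn, st = st,
         dim = 5L, disinhibitory_ids = attr(conn, "disinhibitory_ids"),
         plant_motifs = attr(planted, "plant_motifs"))
  })
}

# Distance-model parameter recovery fixture: known (a, b), n = 2000.
dd_fixture <- function() {
  memo("dd", function() {
    params <- distance_model_params(ee = c(a = 0.1, b = 100),
                                    ei = c(a = 0.12, b = 90),
                                    ie = c(a = 0.12, b = 90),
                                    ii = c(a = 0.1, b = 80))
    neurons <- make_neurons(1600, 400, c(500, 300, 500), seed = 201)
    conn <- sample_distance_connectome(neurons, params, seed = 202)
    list(params = params, neurons = neurons, conn = conn)
  })
}

# Two disjoint transitive tournaments: planted two-block overlap
# structure for clustering recovery.
two_block_fixture <- function() {
  memo("two_block", function() {
    n <- 7L
    neurons <- tibble::tibble(neuron_id = 1:(2 * n), x = 0, y = 0, z = 0,
                              synapse_class = "E")
    pairs <- which(upper.tri(diag(n)), arr.ind = TRUE)
    synapses <- tibble::tibble(
      pre_id = c(pairs[, 1], pairs[, 1] + n),
      post_id = c(pairs[, 2], pairs[, 2] + n))
    conn <- build_connectome(neurons, synapses)
    st <- enumerate_simplices(conn)
    list(conn = conn, st = st, block = rep(0:1, each = n))
  })
}
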