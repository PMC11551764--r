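test_that("make_neurons respects counts, seed and uniformity", {
  only_i <- make_neurons(0, 5, seed = 1)
  expect_equal(nrow(only_i), 5L)
  expect_true(all(only_i$synapse_class == "I"))

  a <- make_neurons(50, 10, seed = 42)
  b <- make_neurons(50, 10, seed = 42)
  expect_identical(a, b)
  expect_error(make_neurons(10, 0, volume = c(0, 10, 10)), "positive")

  # octant occupancy within 5% of uniform at n = 10^4
  big <- make_neurons(10000, 0, volume = c(100, 100, 100), seed = 7)
  oct <- table(paste(big$x > 50, big$y > 50, big$z > 50))
  expect_equal(length(oct), 8L)
  expect_true(all(abs(oct / 10000 - 1 / 8) < 0.05 / 8 * 8))
  expect_true(all(abs(oct - 1250) / 1250 < 0.05))
})

test_that("distance-dependent sampling obeys its closed-form limits", {
  # a = 0: empty edge set
  params0 <- distance_model_params(ee = c(0, 100), ei = c(0, 100),
                                   ie = c(0, 100), ii = c(0, 100))
  neurons <- make_neurons(30, 10, seed = 2)
  conn0 <- sample_distance_connectome(neurons, params0, seed = 3)
  expect_equal(nrow(connectome_edges(conn0)), 0L)

  # coincident points with a = 1: the complete digraph
  tight <- make_neurons(12, 4, volume = c(1e-9, 1e-9, 1e-9) + 1e-12,
                        seed = 4)
  params1 <- distance_model_params(ee = c(1, 100), ei = c(1, 100),
                                   ie = c(1, 100), ii = c(1, 100))
  conn1 <- sample_distance_connectome(tight, params1, seed = 5)
  expect_equal(nrow(connectome_edges(conn1)), 16 * 15)

  # amplitudes above 1 are rejected at construction
  expect_error(distance_model_params(ee = c(1.2, 100)), "0, 1")
})

test_that("empirical connection probability tracks the decay curve", {
  fx <- dd_fixture()
  nodes <- fx$conn$nodes
  e_idx <- which(nodes$synapse_class == "E")
  pos <- as.matrix(nodes[e_idx, c("x", "y", "z")])
  d <- as.matrix(dist(pos))
  adj <- as.matrix(fx$conn$adj[e_idx, e_idx] > 0)
  diag(adj) <- NA
  bins <- cut(d, c(0, 50, 100, 150, 200), labels = FALSE)
  for (b in 1:4) {
    sel <- which(bins == b & !is.na(adj))
    p_emp <- mean(adj[sel])
    p_true <- mean(0.1 * exp(-d[sel] / 100))
    se <- sqrt(p_true * (1 - p_true) / length(sel))
    expect_lt(abs(p_emp - p_true), 4 * se + 1e-12)
  }
})

test_that("planting adds exactly the motif edges and is idempotent", {
  neurons <- make_neurons(60, 0, seed = 6)
  base <- build_connectome(neurons,
                           tibble::tibble(pre_id = numeric(),
                                          post_id = numeric()))
  spec <- plant_spec(dim = 2L, n_motifs = 1L, source_pool = 2L,
                     target_pool = 10L)
  planted <- plant_divergent_simplices(base, spec, seed = 7)
  expect_equal(nrow(connectome_edges(planted)), 3L)

  again <- plant_divergent_simplices(planted, spec, seed = 7)
  expect_equal(connectome_edges(again), connectome_edges(planted))

  tiny <- make_neurons(3, 0, seed = 8)
  tiny_conn <- build_connectome(tiny, tibble::tibble(pre_id = numeric(),
                                                     post_id = numeric()))
  expect_error(plant_divergent_simplices(tiny_conn,
                                         plant_spec(dim = 5L,
                                                    source_pool = 2L,
                                                    target_pool = 1L)),
               "small|exhaust")
})

test_that("planted divergence is recovered downstream", {
  neurons <- make_neurons(80, 0, seed = 9)
  base <- build_connectome(neurons,
                           tibble::tibble(pre_id = numeric(),
                                          post_id = numeric()))
  spec <- plant_spec(dim = 4L, n_motifs = 10L, source_pool = 3L,
                     target_pool = 50L)
  planted <- plant_divergent_simplices(base, spec, seed = 10)
  st <- enumerate_simplices(planted)
  uf <- unique_fraction_by_position(st, 4)
  # strictly increasing until the unique fraction saturates at 1 (late
  # positions are drawn fully from the large target pool), never falling
  expect_true(all(diff(uf$fraction) >= 0))
  unsat <- uf$fraction < 1
  expect_true(all(diff(uf$fraction[unsat]) > 0))
  expect_equal(uf$fraction[5], 1)
  expect_gt(uf$normalized[5], 3)
})

test_that("unbiased inhibitory wiring yields a flat position profile", {
  fx <- planted_fixture()
  spec_flat <- plant_spec(dim = 5L, in_bias = 0, out_bias = 0,
                          disinhibitory_fraction = 0)
  est <- enumerate_simplices(induced_connectome(fx$conn,
                                                excitatory_ids(fx$conn)))
  neurons <- fx$neurons
  empty <- build_connectome(neurons,
                            tibble::tibble(pre_id = numeric(),
                                           post_id = numeric()))
  wired <- wire_biased_inhibition(empty, est, spec_flat, dim = 5L,
                                  seed = 11)
  prof <- inhibitory_degree_by_position(est, wired, 5L)
  trend_in <- cor.test(prof$position, prof$in_degree, method = "spearman")
  trend_out <- cor.test(prof$position, prof$out_degree,
                        method = "spearman")
  expect_gt(trend_in$p.value, 0.01)
  expect_gt(trend_out$p.value, 0.01)
})

test_that("empty simplex tables are rejected by the inhibition wiring", {
  neurons <- make_neurons(20, 5, seed = 12)
  conn <- build_connectome(neurons,
                           tibble::tibble(pre_id = numeric(),
                                          post_id = numeric()))
  st <- enumerate_simplices(induced_connectome(conn,
                                               excitatory_ids(conn)))
  expect_error(wire_biased_inhibition(conn, st, plant_spec(), dim = 5L),
               "No simplices|no simplices")
})

test_that("synthetic traces reproduce the target correlation profile", {
  # disjoint pairs at two dimensions
  nodes <- 1:40
  edge_dims <- tibble::tibble(pre_id = seq(1, 39, by = 2),
                              post_id = seq(2, 40, by = 2),
                              dim = rep(c(1L, 5L), each = 10))
  profile <- c("1" = 0.05, "5" = 0.3)
  x <- synth_activity(nodes, edge_dims, profile, t_samples = 10000,
                      seed = 13)
  expect_true(all(x >= 0))
  cors <- vapply(seq_len(nrow(edge_dims)), function(i) {
    cor(x[, as.character(edge_dims$pre_id[i])],
        x[, as.character(edge_dims$post_id[i])])
  }, numeric(1))
  expect_lt(abs(mean(cors[1:10]) - 0.05), 0.02)
  expect_lt(abs(mean(cors[11:20]) - 0.3), 0.02)

  # zero profile: mean absolute pairwise correlation near zero
  x0 <- synth_activity(nodes, edge_dims, c("1" = 0, "5" = 0),
                       t_samples = 5000, seed = 14)
  cm <- cor(x0)
  expect_lt(mean(abs(cm[upper.tri(cm)])), 0.03)

  # reproducibility
  x1 <- synth_activity(nodes, edge_dims, profile, t_samples = 100,
                       seed = 15)
  x2 <- synth_activity(nodes, edge_dims, profile, t_samples = 100,
                       seed = 15)
  expect_identical(x1, x2)

  # invalid profiles are rejected
  expect_error(synth_activity(nodes, edge_dims, c("1" = 1.2)), "0, 1")
  expect_error(synth_activity(nodes, edge_dims, c("1" = 0.3, "5" = 0.1)),
               "monotone")
})
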