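# A small hand-built scene: one 2-simplex (1 -> 2 -> 3, 1 -> 3) plus two
# interneurons (ids 4, 5); interneuron 4 receives 3 synapses from the
# source and sends 2 to the target, interneuron 5 is unconnected.
scene <- function() {
  neurons <- tibble::tibble(neuron_id = 1:5, x = 0, y = 0, z = 0,
                            synapse_class = c("E", "E", "E", "I", "I"))
  syn <- tibble::tibble(
    pre_id = c(1, 1, 2, 1, 4),
    post_id = c(2, 3, 3, 4, 3),
    synapse_count = c(1, 1, 1, 3, 2))
  conn <- build_connectome(neurons, syn)
  st <- enumerate_simplices(induced_connectome(conn, 1:3))
  list(conn = conn, st = st)
}

test_that("tensors count synapses per simplex, position and interneuron", {
  sc <- scene()
  tn <- inhibition_tensors(sc$st, sc$conn, dim = 2)
  expect_equal(dim(tn$m_ei), c(1L, 2L))
  expect_equal(as.matrix(tn$m_ei), matrix(c(3, 0), 1),
               ignore_attr = TRUE)
  expect_equal(as.matrix(tn$m_ie), matrix(c(2, 0), 1),
               ignore_attr = TRUE)
  expect_equal(tn$t_ei$position, 0L)     # synapses leave the source
  expect_equal(tn$t_ie$position, 2L)     # and arrive at the target
  expect_equal(as.matrix(disynaptic_inhibition(tn)), matrix(6, 1, 1),
               ignore_attr = TRUE)
  expect_error(inhibition_tensors(sc$st, sc$conn, dim = 5),
               "No simplices")
})

test_that("tensors equal a triple-loop recomputation on the fixture", {
  fx <- planted_fixture()
  tn <- inhibition_tensors(fx$st, fx$conn, fx$dim)
  tuples <- simplex_tuples(fx$st, fx$dim)
  adj <- as.matrix(fx$conn$adj)
  ids <- fx$conn$nodes$neuron_id
  i_ids <- tn$interneuron_ids
  take_s <- head(seq_len(nrow(tuples)), 20)
  take_k <- head(seq_along(i_ids), 15)
  for (s in take_s) {
    for (k in take_k) {
      ei <- 0; ie <- 0
      for (p in 1:(fx$dim + 1)) {
        v <- match(tuples[s, p], ids)
        ki <- match(i_ids[k], ids)
        ei <- ei + adj[v, ki]
        ie <- ie + adj[ki, v]
      }
      expect_equal(unname(tn$m_ei[s, k]), ei)
      expect_equal(unname(tn$m_ie[s, k]), ie)
    }
  }
})

test_that("degree-by-position profiles are exact on edge cases", {
  sc <- scene()
  prof <- inhibitory_degree_by_position(sc$st, sc$conn, 2)
  expect_equal(prof$in_degree, c(0, 0, 1))   # I->E only onto the target
  expect_equal(prof$out_degree, c(1, 0, 0))  # E->I only from the source

  # 1-simplices give the two-point (source, target) profile
  prof1 <- inhibitory_degree_by_position(sc$st, sc$conn, 1)
  expect_equal(nrow(prof1), 2L)
})

test_that("the planted inhibition bias is recovered in the profiles", {
  fx <- planted_fixture()
  prof <- inhibitory_degree_by_position(fx$st, fx$conn, fx$dim)
  expect_gt(prof$in_degree[fx$dim + 1], prof$in_degree[1])
  expect_gt(prof$out_degree[1], prof$out_degree[fx$dim + 1])
  expect_true(all(prof$in_degree <=
                    length(inhibitory_ids(fx$conn))))
})

test_that("aggregation over subnetworks returns means and deviations", {
  p1 <- tibble::tibble(position = 0:2, in_degree = c(1, 2, 3),
                       out_degree = c(3, 2, 1))
  p2 <- tibble::tibble(position = 0:2, in_degree = c(3, 4, 5),
                       out_degree = c(5, 4, 3))
  agg <- aggregate_profiles(list(p1, p2))
  got <- agg$mean[agg$metric == "in_degree"]
  expect_equal(got, c(2, 3, 4))
  expect_equal(agg$sd[agg$metric == "in_degree"],
               rep(sd(c(1, 3)), 3))
})

test_that("disynaptic inhibition equals the explicit path-sum oracle", {
  withr::with_seed(41, {
    m_ei <- matrix(rpois(30, 1), 6, 5)
    m_ie <- matrix(rpois(30, 1), 6, 5)
  })
  i_mat <- disynaptic_inhibition(list(m_ei = m_ei, m_ie = m_ie))
  oracle <- matrix(0, 6, 6)
  for (i in 1:6) for (j in 1:6) {
    oracle[i, j] <- sum(m_ei[i, ] * m_ie[j, ])
  }
  expect_equal(i_mat, oracle, ignore_attr = TRUE)
  # binarised variant counts interneuron partners
  i_bin <- disynaptic_inhibition(list(m_ei = m_ei, m_ie = m_ie),
                                 binarize = TRUE)
  expect_true(all(i_bin <= 5))
})

test_that("the symmetry score matches its closed-form cases", {
  withr::with_seed(42, a <- matrix(runif(100), 10, 10))
  expect_equal(symmetry_score(a + t(a)), 0)
  expect_equal(symmetry_score(matrix(c(0, 1, 3, 0), 2, 2, byrow = TRUE)),
               4)
  expect_warning(s0 <- symmetry_score(matrix(1, 3, 3)), "undefined")
  expect_true(is.na(s0))
})

test_that("iid matrices give a symmetry score near 2", {
  scores <- vapply(1:100, function(k) {
    withr::with_seed(5000 + k, symmetry_score(matrix(runif(200 * 200),
                                                     200, 200)))
  }, numeric(1))
  expect_lt(abs(mean(scores) - 2) / 2, 0.02)
})

test_that("overlap matrices equal the set-intersection oracle", {
  fx <- two_block_fixture()
  o <- overlap_matrix(fx$st, 2, 0:2)
  expect_true(Matrix::isSymmetric(o))
  expect_true(all(Matrix::diag(o) == 3))
  tuples <- simplex_tuples(fx$st, 2)
  for (s in seq_len(min(nrow(tuples), 15))) {
    for (t in seq_len(min(nrow(tuples), 15))) {
      expect_equal(o[s, t],
                   length(intersect(tuples[s, 1:3], tuples[t, 1:3])))
    }
  }
  # simplices from different blocks never overlap
  blocks <- (tuples[, 1] > 7) + 1L
  cross <- outer(blocks, blocks, "!=")
  expect_true(all(o[cross] == 0))
})

test_that("overlap-inhibition correlations behave at their limits", {
  fx <- planted_fixture()
  st <- fx$st
  o_src <- overlap_matrix(st, fx$dim, 0:2)
  o_tgt <- overlap_matrix(st, fx$dim, (fx$dim - 2):fx$dim)
  # inhibition proportional to source overlap correlates perfectly
  fake_i <- as.matrix(o_src) * 2.5
  r <- overlap_inhibition_correlation(o_src, o_tgt, fake_i)
  expect_equal(r$r_source_inh, 1)
  # independent random matrices decorrelate
  s <- nrow(o_src)
  withr::with_seed(43, {
    r0 <- overlap_inhibition_correlation(
      matrix(runif(s^2), s), matrix(runif(s^2), s), matrix(runif(s^2), s))
  })
  n_pairs <- s * (s - 1)
  expect_true(all(abs(unlist(r0)) < 3 / sqrt(n_pairs)))
  # the planted structure shares sources, not targets
  tn <- inhibition_tensors(st, fx$conn, fx$dim)
  r_real <- overlap_inhibition_correlation(o_src, o_tgt,
                                           disynaptic_inhibition(tn))
  expect_gt(r_real$r_source_inh, r_real$r_target_inh)
})

test_that("synapses per connection resolve weights by position", {
  sc <- scene()
  spc <- synapses_per_connection_by_position(sc$st, sc$conn, 2)
  expect_equal(spc$mean_syn_ei, c(3, NA, NA))
  expect_equal(spc$mean_syn_ie, c(NA, NA, 2))
  # all-unit weights give a constant profile of 1 on the fixture
  fx <- two_block_fixture()
  neurons2 <- dplyr::bind_rows(
    fx$conn$nodes,
    tibble::tibble(neuron_id = 100, x = 0, y = 0, z = 0,
                   synapse_class = "I"))
  syn2 <- dplyr::bind_rows(
    connectome_edges(fx$conn) |>
      dplyr::rename(synapse_count = "count"),
    tibble::tibble(pre_id = c(1, 2), post_id = 100, synapse_count = 1),
    tibble::tibble(pre_id = 100, post_id = c(3, 4), synapse_count = 1))
  conn2 <- build_connectome(neurons2, syn2)
  st2 <- enumerate_simplices(induced_connectome(conn2, 1:14))
  spc2 <- synapses_per_connection_by_position(st2, conn2, 2)
  expect_true(all(spc2$mean_syn_ei %in% c(1, NA)))
  expect_true(all(spc2$mean_syn_ie %in% c(1, NA)))
})

test_that("stratified position profiles separate planted classes", {
  fx <- planted_fixture()
  conn <- fx$conn
  nodes <- conn$nodes
  nodes$cell_type <- ifelse(nodes$synapse_class == "I",
                            ifelse(nodes$neuron_id %in%
                                     fx$disinhibitory_ids, "ITC", "PTC"),
                            NA)
  conn2 <- conn
  conn2$nodes <- nodes
  prof <- position_profile_stratified(fx$st, conn2, fx$dim,
                                      class_col = "cell_type",
                                      direction = "from_simplex")
  expect_setequal(unique(prof$class), c("ITC", "PTC"))
  expect_true(all(prof$probability >= 0 & prof$probability <= 1,
                  na.rm = TRUE))
  # single-class stratification reduces to the degree profile / size
  nodes$cell_type[nodes$synapse_class == "I"] <- "ALL"
  conn3 <- conn
  conn3$nodes <- nodes
  prof3 <- position_profile_stratified(fx$st, conn3, fx$dim,
                                       class_col = "cell_type",
                                       direction = "onto_simplex")
  deg <- inhibitory_degree_by_position(fx$st, conn3, fx$dim)
  n_i <- length(inhibitory_ids(conn3))
  expect_equal(prof3$probability, deg$in_degree / n_i, tolerance = 1e-10)
})
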