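test_that("targeting p-values equal direct hypergeometric enumeration", {
  # interneuron A: 4 of 4 targets inhibitory; B: 1 of 6.
  # pool: 10 target slots, 5 inhibitory -> p_A = C(5,4)/C(10,4) = 5/210
  neurons <- tibble::tibble(
    neuron_id = 1:11, x = 0, y = 0, z = 0,
    synapse_class = c(rep("I", 6), rep("E", 5)))
  syn <- tibble::tibble(
    pre_id = c(rep(1, 4), rep(2, 6)),
    post_id = c(3, 4, 5, 6, 3, 7, 8, 9, 10, 11))
  conn <- build_connectome(neurons, syn)
  res <- inhibitory_targeting_test(conn, threshold = 0.05)
  a <- res[res$neuron_id == 1, ]
  expect_equal(a$d_ttl, 4L)
  expect_equal(a$d_inh, 4L)
  expect_equal(a$p_value, 5 / 210)
  expect_equal(a$p_value, hyper_tail(4, 5, 10, 4))
  b <- res[res$neuron_id == 2, ]
  expect_equal(b$p_value, hyper_tail(1, 5, 10, 6))
  expect_true(a$flagged)
  # untouched interneurons have p = 1
  expect_true(all(res$p_value[res$d_inh == 0] == 1))
  expect_true(all(res$d_inh <= res$d_ttl))
})

test_that("degenerate targeting inputs error or saturate", {
  neurons <- tibble::tibble(neuron_id = 1:3, x = 0, y = 0, z = 0,
                            synapse_class = c("I", "I", "E"))
  conn <- build_connectome(neurons,
                           tibble::tibble(pre_id = 3, post_id = 1))
  expect_error(inhibitory_targeting_test(conn), "outgoing")
})

test_that("the planted disinhibitory class is recovered", {
  fx <- planted_fixture()
  # at a loose threshold the flagged set covers the planted class
  res <- inhibitory_targeting_test(fx$conn, threshold = 1e-3)
  flagged <- res$neuron_id[res$flagged]
  planted <- fx$disinhibitory_ids
  expect_true(all(planted %in% flagged))
  # flagged fraction stays close to the planted fraction
  expect_lt(abs(attr(res, "flagged_fraction") - 0.15), 0.08)
  # non-planted false positives stay rare
  fp <- setdiff(flagged, planted)
  expect_lt(length(fp) / nrow(res), 0.05)
})

test_that("simplex degrees count per-occurrence multiplicity", {
  # one 2-simplex (1,2,3); interneuron 4 receives from positions 0 and 2
  neurons <- tibble::tibble(neuron_id = 1:4, x = 0, y = 0, z = 0,
                            synapse_class = c("E", "E", "E", "I"))
  syn <- tibble::tibble(pre_id = c(1, 1, 2, 1, 3),
                        post_id = c(2, 3, 3, 4, 4))
  conn <- build_connectome(neurons, syn)
  st <- enumerate_simplices(induced_connectome(conn, 1:3))
  deg <- simplex_degrees_of_inhibitory(st, conn, 2,
                                       source_positions = c(0, 2),
                                       target_positions = 0:2)
  expect_equal(deg$simplex_indegree[deg$neuron_id == 4], 2L)

  # a neuron reused in two simplices contributes once per simplex
  fx <- two_block_fixture()
  neurons2 <- dplyr::bind_rows(
    fx$conn$nodes,
    tibble::tibble(neuron_id = 50, x = 0, y = 0, z = 0,
                   synapse_class = "I"))
  syn2 <- dplyr::bind_rows(
    connectome_edges(fx$conn) |> dplyr::rename(synapse_count = "count"),
    tibble::tibble(pre_id = 1, post_id = 50, synapse_count = 1))
  conn2 <- build_connectome(neurons2, syn2)
  st2 <- enumerate_simplices(induced_connectome(conn2, 1:14))
  n_occurrences <- sum(simplex_tuples(st2, 2)[, 1:3] == 1)
  deg2 <- simplex_degrees_of_inhibitory(st2, conn2, 2)
  expect_equal(deg2$simplex_indegree[deg2$neuron_id == 50],
               n_occurrences)
})

test_that("simplex degrees equal a loop oracle on the fixture", {
  fx <- planted_fixture()
  deg <- simplex_degrees_of_inhibitory(fx$st, fx$conn, fx$dim)
  tuples <- simplex_tuples(fx$st, fx$dim)
  adj <- as.matrix(fx$conn$adj) > 0
  ids <- fx$conn$nodes$neuron_id
  for (k_id in head(deg$neuron_id, 10)) {
    ki <- match(k_id, ids)
    indeg <- 0
    for (s in seq_len(nrow(tuples))) {
      for (p in 1:3) {  # source positions 0..2
        v <- match(tuples[s, p], ids)
        indeg <- indeg + adj[v, ki]
      }
    }
    expect_equal(deg$simplex_indegree[deg$neuron_id == k_id], indeg)
  }
})

test_that("disinhibition profiles stack targeting and other inhibition", {
  fx <- planted_fixture()
  targeting <- inhibitory_targeting_test(fx$conn, 1e-6)
  sdeg <- simplex_degrees_of_inhibitory(fx$st, fx$conn, fx$dim)
  prof <- disinhibition_profile(fx$conn, targeting, sdeg, n_bins = 4)
  expect_true(all(prof$share_targeting >= 0 & prof$share_targeting <= 1,
                  na.rm = TRUE))

  # no flagged neurons: targeting share identically zero
  none <- targeting
  none$flagged <- FALSE
  prof0 <- disinhibition_profile(fx$conn, none, sdeg, n_bins = 4)
  expect_true(all(prof0$from_targeting == 0))
  # all inhibition flagged: share one wherever inhibition exists
  all_f <- targeting
  all_f$flagged <- TRUE
  prof1 <- disinhibition_profile(fx$conn, all_f, sdeg, n_bins = 4)
  expect_true(all(prof1$share_targeting[prof1$from_targeting > 0] == 1))
})
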