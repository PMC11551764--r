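test_that("transitive tournaments have binomial simplex counts", {
  for (k in 4:7) {
    st <- enumerate_simplices(transitive_tournament(k))
    expect_equal(unname(st$counts), choose(k, seq_len(k)),
                 info = paste("tournament on", k, "nodes"))
  }
})

test_that("a directed 3-cycle has no 2-simplices", {
  neurons <- tibble::tibble(neuron_id = 1:3, x = 0, y = 0, z = 0,
                            synapse_class = "E")
  conn <- build_connectome(neurons, tibble::tibble(pre_id = c(1, 2, 3),
                                                   post_id = c(2, 3, 1)))
  st <- enumerate_simplices(conn)
  expect_equal(unname(st$counts), c(3, 3))
})

test_that("reciprocal edges yield one simplex per valid ordering", {
  neurons <- tibble::tibble(neuron_id = 1:2, x = 0, y = 0, z = 0,
                            synapse_class = "E")
  conn <- build_connectome(neurons, tibble::tibble(pre_id = c(1, 2),
                                                   post_id = c(2, 1)))
  st <- enumerate_simplices(conn)
  expect_equal(unname(st$counts["1"]), 2)
})

test_that("enumeration matches brute force over ordered subsets", {
  for (seed in c(11, 12)) {
    conn <- random_connectome(10, 0.35, seed = seed)
    st <- enumerate_simplices(conn)
    # the factorial oracle is tractable up to dimension 4; these graphs
    # hold nothing above it (asserted against the enumeration itself)
    expect_lte(max_simplex_dim(st), 4L)
    bf <- brute_force_simplex_counts(conn$adj, max_dim = 4)
    expect_equal(unname(st$counts), bf[seq_along(st$counts)])
    expect_true(all(bf[-seq_along(st$counts)] == 0))
  }
  # denser mid-size graph, counts up to dimension 3
  conn <- random_connectome(30, 0.3, seed = 13)
  st <- enumerate_simplices(conn, max_dim = 3)
  bf <- brute_force_simplex_counts(conn$adj, max_dim = 3)
  expect_equal(unname(st$counts), bf[seq_along(st$counts)])
})

test_that("every listed simplex re-validates against the graph", {
  fx <- planted_fixture()
  adj <- induced_connectome(fx$conn, excitatory_ids(fx$conn))$adj
  ids <- as.numeric(rownames(adj))
  for (d in 2:fx$dim) {
    tuples <- simplex_tuples(fx$st, d)
    if (is.null(tuples) || nrow(tuples) == 0L) next
    take <- head(seq_len(nrow(tuples)), 200)
    for (r in take) {
      tup <- match(tuples[r, ], ids)
      expect_false(anyDuplicated(tup) > 0)
      pairs <- which(upper.tri(diag(d + 1L)), arr.ind = TRUE)
      expect_true(all(adj[cbind(tup[pairs[, 1]], tup[pairs[, 2]])] > 0))
    }
  }
})

test_that("unique-neuron fractions and normalization are exact", {
  # a single simplex: all fractions 1
  st1 <- enumerate_simplices(transitive_tournament(3))
  expect_equal(unique_fraction_by_position(st1, 2)$fraction, rep(1, 3))

  # two 2-simplices (a,b,c), (a,d,e): fractions (0.5, 1, 1)
  neurons <- tibble::tibble(neuron_id = 1:5, x = 0, y = 0, z = 0,
                            synapse_class = "E")
  syn <- tibble::tibble(pre_id = c(1, 1, 2, 1, 1, 4),
                        post_id = c(2, 3, 3, 4, 5, 5))
  st2 <- enumerate_simplices(build_connectome(neurons, syn))
  uf <- unique_fraction_by_position(st2, 2)
  expect_equal(uf$fraction, c(0.5, 1, 1))
  expect_equal(uf$normalized, c(1, 2, 2))

  # no simplices at the requested dimension: missing values with warning
  expect_warning(uf0 <- unique_fraction_by_position(st2, 4), "No simplices")
  expect_true(all(is.na(uf0$fraction)))
})

test_that("the planted divergent profile increases towards the target", {
  fx <- planted_fixture()
  uf <- unique_fraction_by_position(fx$st, fx$dim)
  # monotone towards the target, with a strong overall rise; background
  # simplices allow plateaus but never a decrease
  expect_true(all(diff(uf$normalized) >= 0))
  expect_gt(uf$normalized[fx$dim + 1], 3)
  # and the set sizes recompute directly from the tuples
  tuples <- simplex_tuples(fx$st, fx$dim)
  manual <- apply(tuples, 2, function(col) length(unique(col))) /
    nrow(tuples)
  expect_equal(uf$fraction, manual)
})

test_that("participation counts satisfy their sum rules", {
  fx <- planted_fixture()
  par <- node_participation(fx$st)
  cnt <- simplex_counts(fx$st)
  for (d in unique(par$dim)) {
    s_d <- cnt$count[cnt$dim == d]
    per_pos <- par[par$dim == d, ] |>
      dplyr::group_by(position) |>
      dplyr::summarise(total = sum(n_simplices))
    expect_true(all(per_pos$total == s_d))
    expect_equal(sum(par$n_simplices[par$dim == d]), (d + 1) * s_d)
  }

  # single 2-simplex: all participations are 1
  st <- enumerate_simplices(transitive_tournament(3))
  p2 <- node_participation(st, dims = 2L)
  expect_equal(p2$n_simplices, rep(1L, 3))
  expect_equal(p2$node_id[p2$position == 0], 1)
})

test_that("edge maximal dimension matches a scan of the simplex list", {
  st <- enumerate_simplices(transitive_tournament(3))
  ed <- edge_max_dimension(st)
  expect_equal(ed$dim[ed$pre_id == 1 & ed$post_id == 3], 2L)

  # an edge in no triangle has dimension 1
  neurons <- tibble::tibble(neuron_id = 1:4, x = 0, y = 0, z = 0,
                            synapse_class = "E")
  conn <- build_connectome(neurons, tibble::tibble(pre_id = c(1, 3),
                                                   post_id = c(2, 4)))
  ed1 <- edge_max_dimension(enumerate_simplices(conn))
  expect_true(all(ed1$dim == 1L))

  # random graph against an R scan over tuples
  conn_r <- random_connectome(12, 0.35, seed = 21)
  st_r <- enumerate_simplices(conn_r)
  ed_r <- edge_max_dimension(st_r)
  for (row in sample.int(nrow(ed_r), min(40, nrow(ed_r)))) {
    u <- ed_r$pre_id[row]; v <- ed_r$post_id[row]
    best <- 1L
    for (d in as.integer(names(st_r$tuples))) {
      if (d < 2) next
      tuples <- simplex_tuples(st_r, d)
      if (nrow(tuples) == 0) next
      for (r2 in seq_len(nrow(tuples))) {
        iu <- match(u, tuples[r2, ]); iv <- match(v, tuples[r2, ])
        if (!is.na(iu) && !is.na(iv) && iu < iv) best <- max(best, d)
      }
    }
    expect_equal(ed_r$dim[row], best)
  }
})

test_that("the simplex core is the union over the simplex list", {
  st <- enumerate_simplices(transitive_tournament(7))
  expect_equal(simplex_core(st, 6), 1:7)
  expect_equal(simplex_core(st, 9), numeric(0))
  fx <- planted_fixture()
  expect_equal(simplex_core(fx$st, fx$dim),
               sort(unique(as.vector(simplex_tuples(fx$st, fx$dim)))))
})

test_that("listing above the memory guard needs an explicit opt-in", {
  conn <- transitive_tournament(4)
  expect_error(enumerate_simplices(conn, max_dim = 12), "list_guard")
  expect_silent(enumerate_simplices(conn, max_dim = 12, list_guard = 12))
  expect_silent(enumerate_simplices(conn, max_dim = 12,
                                    list_tuples = FALSE))
})

test_that("ER edge budget reproduces its closed forms", {
  b <- er_simplex_budget(1000, 4, observed_edges = 0)
  p <- 1000^(-2 / 4)
  expect_equal(b$p, p)
  expect_equal(b$required_directed_edges, 1000 * 999 * p)
  expect_equal(b$removal_fraction, 1)
  b2 <- er_simplex_budget(1000, 4,
                          observed_edges = 1000 * 999 * p)
  expect_equal(b2$removal_fraction, 0)
  # expected maximal dimension is increasing in p
  dims <- vapply(c(0.05, 0.1, 0.2, 0.4), function(p) {
    expected_max_dimension(500, p)
  }, numeric(1))
  expect_true(all(diff(dims) > 0))
  expect_error(er_simplex_budget(1, 4, 10), "at least 2")
})
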