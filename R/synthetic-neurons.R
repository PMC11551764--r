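#' Synthetic neuron tables
#'
#' Places `n_e` excitatory and `n_i` inhibitory somata uniformly at random
#' in a rectangular slab of cortical tissue.  Positions are in
#' micrometres; the default slab (500 x 300 x 500 um) matches the
#' footprint of one analysis subvolume.
#'
#' @param n_e,n_i Numbers of excitatory and inhibitory neurons.
#' @param volume Numeric length-3 slab extent in micrometres.
#' @param origin Minimum corner of the slab.
#' @param seed Optional RNG seed; the global RNG state is restored.
#' @return A neuron table.
#' @export
make_neurons <- function(n_e, n_i, volume = c(500, 300, 500),
                         origin = c(0, 0, 0), seed = NULL) {
  stopifnot(n_e >= 0, n_i >= 0, length(volume) == 3L)
  if (any(volume <= 0)) abort("`volume` must be positive in every direction.")
  n <- n_e + n_i
  if (n == 0L) abort("At least one neuron is required.")
  with_rng_seed(seed, {
    tibble::tibble(
      neuron_id = seq_len(n),
      x = runif(n, origin[1], origin[1] + volume[1]),
      y = runif(n, origin[2], origin[2] + volume[2]),
      z = runif(n, origin[3], origin[3] + volume[3]),
      synapse_class = rep(c("E", "I"), c(n_e, n_i)))
  })
}

PATHWAYS <- c("ee", "ei", "ie", "ii")

#' Distance-dependent connectivity model parameters
#'
#' Connection probability between two neurons at soma distance \eqn{d}
#' (micrometres) follows an exponential decay \eqn{P(d) = a e^{-d/b}} with
#' amplitude \eqn{a \in (0, 1]} and length constant \eqn{b > 0} um, one
#' pair per synapse-class pathway (E\eqn{\to}E, E\eqn{\to}I, I\eqn{\to}E,
#' I\eqn{\to}I).  With this convention \eqn{P(d) \le a \le 1} for every
#' distance, so the parameters always define a valid probability.
#'
#' @param ee,ei,ie,ii Numeric length-2 vectors `c(a, b)` per pathway.
#' @return A tibble of class `distance_model_params` with columns
#'   `pathway`, `a`, `b`.
#' @export
distance_model_params <- function(ee = c(a = 0.1, b = 120),
                                  ei = c(a = 0.15, b = 110),
                                  ie = c(a = 0.15, b = 110),
                                  ii = c(a = 0.1, b = 100)) {
  m <- rbind(ee, ei, ie, ii)
  params <- tibble::tibble(pathway = PATHWAYS, a = m[, 1], b = m[, 2])
  if (any(params$a < 0 | params$a > 1)) {
    abort("Amplitude `a` must lie in [0, 1] for every pathway.")
  }
  if (any(params$b <= 0)) abort("Length constant `b` must be positive.")
  class(params) <- c("distance_model_params", class(params))
  params
}

#' @rdname distance_model_params
#' @param params A `distance_model_params`.
#' @param d Distances in micrometres.
#' @param pathway One of `"ee"`, `"ei"`, `"ie"`, `"ii"`.
#' @export
connection_probability <- function(params, d, pathway) {
  row <- params[params$pathway == pathway, ]
  if (nrow(row) != 1L) abort(paste0("Unknown pathway: ", pathway))
  row$a * exp(-d / row$b)
}

#' Sample a distance-dependent random connectome
#'
#' Connects each ordered pair of neurons independently with probability
#' \eqn{a e^{-d/b}} of its synapse-class pathway.  Synapse counts per
#' connection are 1 by default, or `1 + Geometric(count_prob)` for a
#' heavier-tailed count distribution.
#'
#' @param neurons A neuron table.
#' @param params A [distance_model_params()].
#' @param seed Optional RNG seed.
#' @param count_dist `"constant"` (one synapse per connection) or
#'   `"geometric"`.
#' @param count_prob Success probability of the geometric count
#'   distribution.
#' @return A `connectome`.
#' @export
sample_distance_connectome <- function(neurons, params, seed = NULL,
                                       count_dist = c("constant", "geometric"),
                                       count_prob = 0.5) {
  neurons <- as_neuron_table(neurons)
  count_dist <- match.arg(count_dist)
  stopifnot(inherits(params, "distance_model_params"))
  n <- nrow(neurons)
  pos <- as.matrix(neurons[, c("x", "y", "z")])
  cls <- neurons$synapse_class
  # pathway index: 1 = ee, 2 = ei, 3 = ie, 4 = ii
  a_vec <- setNames(params$a, params$pathway)[PATHWAYS]
  b_vec <- setNames(params$b, params$pathway)[PATHWAYS]
  is_i <- as.integer(cls == "I")
  with_rng_seed(seed, {
    pre <- integer(0); post <- integer(0)
    block <- max(1L, floor(2e6 / n))
    for (start in seq(1L, n, by = block)) {
      rows <- start:min(start + block - 1L, n)
      d <- sqrt(pmax(outer(rowSums(pos[rows, , drop = FALSE]^2),
                           rowSums(pos^2), "+") -
                       2 * pos[rows, , drop = FALSE] %*% t(pos), 0))
      idx <- outer(2L * is_i[rows], is_i, "+") + 1L
      p <- a_vec[idx] * exp(-d / b_vec[idx])
      dim(p) <- dim(d)
      hit <- which(matrix(runif(length(p)), nrow = nrow(p)) < p,
                   arr.ind = TRUE)
      keep <- rows[hit[, 1]] != hit[, 2]
      pre <- c(pre, rows[hit[, 1]][keep])
      post <- c(post, hit[, 2][keep])
    }
    counts <- if (count_dist == "constant") {
      rep(1L, length(pre))
    } else {
      1L + rgeom(length(pre), count_prob)
    }
    build_connectome(neurons,
                     tibble::tibble(pre_id = neurons$neuron_id[pre],
                                    post_id = neurons$neuron_id[post],
                                    synapse_count = counts))
  })
}
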