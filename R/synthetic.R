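#' Synthetic cohort configuration
#'
#' Defines the generative law for a synthetic cohort of weighted, undirected
#' connectomes with a planted densely interconnected core, bi-hemispheric
#' spherical region coordinates, and per-task brain-state pairs with a
#' designed stability asymmetry. Defaults describe a desk-scale cohort whose
#' planted core is recoverable by rich-club detection.
#'
#' @param n_subjects number of subjects (default 10).
#' @param n_nodes number of regions, even (default 100).
#' @param core_size size of the planted dense core (default 10).
#' @param base_density baseline edge probability before distance decay
#'   (default 0.15).
#' @param core_density edge probability within the core (default 0.9).
#' @param weight_low,weight_high FA-like weight bounds (defaults 0.1, 1.0).
#' @param core_weight_boost multiplicative boost on core-core weights,
#'   capped at `weight_high` (default 1.5).
#' @param distance_decay rate of the exponential distance penalty on edge
#'   probability, per radian of great-circle distance (default 0.5).
#' @param degree_heterogeneity shape of the gamma distribution (mean 1)
#'   of per-node connection propensities; smaller values give a heavier
#'   right tail of degree beyond the planted core's own. `Inf` (the
#'   default) disables propensity heterogeneity: multiplicative hubs form
#'   their own densely interconnected sets that compete with the planted
#'   core as ground truth, so the default leaves the degree tail's right
#'   mass to the core alone.
#' @param subject_jitter fraction of edge weights independently resampled
#'   per subject; half that fraction of node pairs have their presence
#'   toggled (default 0.1).
#' @param n_tasks number of synthetic tasks (default 2).
#' @param state_gap weight of the fast-mode component mixed into the less
#'   stable state of each pair (default 1).
#' @param state_noise_sd Gaussian noise on state vectors (default 0.05).
#' @param n_state_modes number of eigenmodes combined per state (default 5).
#' @param core_activation attenuation factor on the planted core's state
#'   amplitude (default 0.2): task-like activation concentrates in the
#'   periphery, making the dense core a passive backbone rather than a
#'   carrier of state content.
#' @param seed integer RNG seed.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 10, n_nodes = 100, core_size = 10,
                          base_density = 0.15, core_density = 1.0,
                          weight_low = 0.1, weight_high = 1.0,
                          core_weight_boost = 1.5, distance_decay = 0.5,
                          degree_heterogeneity = Inf, subject_jitter = 0.2,
                          n_tasks = 2,
                          state_gap = 1, state_noise_sd = 0.05,
                          n_state_modes = 5, core_activation = 0.2,
                          seed = 1) {
  cfg <- list(n_subjects = n_subjects, n_nodes = n_nodes,
              core_size = core_size, base_density = base_density,
              core_density = core_density, weight_low = weight_low,
              weight_high = weight_high,
              core_weight_boost = core_weight_boost,
              distance_decay = distance_decay,
              degree_heterogeneity = degree_heterogeneity,
              subject_jitter = subject_jitter, n_tasks = n_tasks,
              state_gap = state_gap, state_noise_sd = state_noise_sd,
              n_state_modes = n_state_modes,
              core_activation = core_activation, seed = as.integer(seed))
  stopifnot(cfg$n_nodes %% 2 == 0, cfg$core_size < cfg$n_nodes,
            cfg$weight_low > 0, cfg$weight_high >= cfg$weight_low,
            cfg$base_density > 0, cfg$base_density <= 1,
            cfg$core_density >= cfg$base_density, cfg$core_density <= 1,
            cfg$core_weight_boost >= 1, cfg$distance_decay >= 0,
            cfg$degree_heterogeneity > 0,
            cfg$subject_jitter >= 0, cfg$subject_jitter <= 1,
            cfg$state_gap >= 0, cfg$state_noise_sd >= 0,
            cfg$core_activation >= 0, cfg$core_activation <= 1)
  class(cfg) <- "cohort_config"
  cfg
}

#' Bi-hemispheric unit-sphere coordinates
#'
#' Draws n/2 points uniformly on the left (x < 0) half of the unit sphere
#' and mirrors them across the sagittal (x = 0) plane, so the two
#' hemispheres are exact reflections — the symmetry the spin-rotation null
#' model preserves.
#'
#' @param n_nodes even number of regions.
#' @param seed integer RNG seed.
#' @return list with `coordinates` (n x 3, unit rows) and `hemisphere`
#'   (character, "left" then "right").
#' @export
generate_coordinates <- function(n_nodes, seed = 1) {
  if (n_nodes %% 2 != 0) stop("n_nodes must be even")
  half <- n_nodes / 2
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  left <- matrix(stats::rnorm(half * 3), half, 3)
  left <- left / sqrt(rowSums(left^2))
  left[, 1] <- -abs(left[, 1])
  right <- left
  right[, 1] <- -right[, 1]
  list(coordinates = rbind(left, right),
       hemisphere = rep(c("left", "right"), each = half))
}

# save/restore global RNG state so generators are pure in their seed
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

great_circle_distance <- function(coords) {
  dp <- tcrossprod(coords)
  dp[dp > 1] <- 1; dp[dp < -1] <- -1
  acos(dp)
}

#' Template connectome with a planted dense core
#'
#' Edge probability is
#' `base_density * theta_i * theta_j * exp(-distance_decay * d)` (capped at
#' 1) for great-circle distance d and gamma-distributed node propensities
#' theta (mean 1, shape `degree_heterogeneity`), which produce the heavy
#' right tail of degree seen in empirical connectomes. Within the planted
#' core the probability is overridden to `core_density`. Weights are
#' uniform in `[weight_low, weight_high]` with core-core weights multiplied
#' by `core_weight_boost` (capped at `weight_high`). Disconnected draws are
#' rejected and regenerated (up to 100 attempts).
#'
#' @param config a [cohort_config].
#' @return a [connectome] with attribute `core_nodes` (planted core indices).
#' @export
generate_template_connectome <- function(config) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  geom <- generate_coordinates(config$n_nodes, seed = config$seed)
  n <- config$n_nodes
  dist <- great_circle_distance(geom$coordinates)
  core <- sort(sample.int(n, max(config$core_size, 1)))
  if (config$core_size == 0) core <- integer(0)
  in_core <- logical(n); in_core[core] <- TRUE
  theta <- if (is.finite(config$degree_heterogeneity)) {
    stats::rgamma(n, shape = config$degree_heterogeneity,
                  rate = config$degree_heterogeneity)
  } else rep(1, n)
  prob <- pmin(config$base_density * tcrossprod(theta) *
                 exp(-config$distance_decay * dist), 1)
  prob[in_core, in_core] <- config$core_density
  for (attempt in seq_len(100)) {
    ut <- upper.tri(prob)
    present <- matrix(FALSE, n, n)
    present[ut] <- stats::runif(sum(ut)) < prob[ut]
    w <- matrix(0, n, n)
    w[present] <- stats::runif(sum(present), config$weight_low,
                               config$weight_high)
    boost <- in_core %o% in_core & present
    w[boost] <- pmin(w[boost] * config$core_weight_boost, config$weight_high)
    w <- w + t(w)
    g <- igraph::graph_from_adjacency_matrix(w > 0, mode = "undirected")
    if (igraph::is_connected(g)) {
      c <- connectome(w, coordinates = geom$coordinates,
                      hemisphere = geom$hemisphere)
      attr(c, "core_nodes") <- core
      return(c)
    }
  }
  stop("failed to generate a connected template in 100 attempts")
}

#' Synthetic cohort of connectomes
#'
#' Derives `n_subjects` connectomes from one template: a `subject_jitter`
#' fraction of present edges have their weight independently resampled, and
#' a `subject_jitter / 2` fraction of node pairs have their presence toggled
#' (present edges dropped, absent ones added with a fresh weight), always
#' preserving symmetry. Per-subject seeds are `config$seed + 1000 * i`.
#'
#' @param config a [cohort_config].
#' @return list of [connectome]s, with attributes `template` and
#'   `core_nodes`.
#' @export
generate_cohort <- function(config) {
  template <- generate_template_connectome(config)
  n <- config$n_nodes
  ut_idx <- which(upper.tri(template$weights))
  cohort <- vector("list", config$n_subjects)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  for (i in seq_len(config$n_subjects)) {
    set.seed(config$seed + 1000L * i)
    w <- template$weights
    if (config$subject_jitter > 0) {
      present <- ut_idx[w[ut_idx] > 0]
      n_rew <- round(config$subject_jitter * length(present))
      if (n_rew > 0) {
        pick <- sample(present, n_rew)
        w[pick] <- stats::runif(n_rew, config$weight_low, config$weight_high)
      }
      n_tog <- round(config$subject_jitter / 2 * length(present))
      if (n_tog > 0) {
        pick <- sample(ut_idx, n_tog)
        on_now <- w[pick] > 0
        w[pick[on_now]] <- 0
        w[pick[!on_now]] <- stats::runif(sum(!on_now), config$weight_low,
                                         config$weight_high)
      }
      w[lower.tri(w)] <- 0
      w <- w + t(w)
    }
    cohort[[i]] <- connectome(w, coordinates = template$coordinates,
                              hemisphere = template$hemisphere)
    attr(cohort[[i]], "core_nodes") <- attr(template, "core_nodes")
  }
  attr(cohort, "template") <- template
  attr(cohort, "core_nodes") <- attr(template, "core_nodes")
  cohort
}

#' Brain-state pair with designed stability asymmetry
#'
#' State A is a unit-norm combination of the `n_state_modes` slowest
#' eigenmodes of the stabilized system (largest, least-negative
#' eigenvalues) plus Gaussian noise; state B adds the same number of
#' fastest modes weighted by `state_gap` before renormalization. Both are
#' rescaled to exactly equal Euclidean norm, so A decays more slowly under
#' the dynamics and is cheaper to maintain (higher stability).
#'
#' When the connectome carries planted-core indices (attribute
#' `core_nodes`), both states' amplitudes on core nodes are attenuated by
#' `config$core_activation` before the final normalization: the planted
#' core is a passive backbone whose regions carry little task-like
#' activation, mirroring how empirical task contrasts concentrate outside
#' the densely interconnected hub core.
#'
#' @param connectome a [connectome].
#' @param config a [cohort_config].
#' @param task_index task number (enters the seed).
#' @param seed base RNG seed.
#' @return list with elements `A` and `B`, numeric length-N vectors.
#' @export
generate_state_pair <- function(connectome, config, task_index = 1,
                                seed = config$seed) {
  sys <- stabilize(connectome)
  es <- eigen(sys$S, symmetric = TRUE)
  n <- nrow(sys$S)
  s <- min(config$n_state_modes, n)
  slow <- es$vectors[, seq_len(s), drop = FALSE]          # least negative
  fast <- es$vectors[, n - seq_len(s) + 1, drop = FALSE]  # most negative
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed + 97L * as.integer(task_index))
  mix <- stats::rnorm(s)
  mix <- mix / sqrt(sum(mix^2))
  base <- drop(slow %*% mix)
  a <- base + stats::rnorm(n, sd = config$state_noise_sd)
  b <- base + config$state_gap * drop(fast %*% mix) +
    stats::rnorm(n, sd = config$state_noise_sd)
  core <- attr(connectome, "core_nodes")
  if (!is.null(core) && length(core)) {
    a[core] <- config$core_activation * a[core]
    b[core] <- config$core_activation * b[core]
  }
  a <- a / sqrt(sum(a^2))
  b <- b / sqrt(sum(b^2))
  list(A = a, B = b)
}

#' Spatially contiguous network labels
#'
#' Assigns each region to one of `n_networks` labels by k-means clustering
#' of its coordinates, a stand-in for resting-state network assignments.
#'
#' @param coordinates N x 3 matrix of region coordinates.
#' @param n_networks number of networks (<= N).
#' @param seed integer RNG seed.
#' @return integer vector of labels in `1..n_networks`, each used at least
#'   once.
#' @export
generate_network_labels <- function(coordinates, n_networks, seed = 1) {
  n <- nrow(coordinates)
  if (n_networks > n) stop("n_networks must not exceed the number of nodes")
  if (n_networks == n) return(seq_len(n))
  if (n_networks == 1) return(rep(1L, n))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  km <- stats::kmeans(coordinates, centers = n_networks, nstart = 5,
                      iter.max = 50)
  as.integer(km$cluster)
}
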