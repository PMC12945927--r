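#' Spin-rotation spatial permutations
#'
#' Generates hemisphere-preserving permutations of regions by rotating
#' their unit-sphere coordinates: each draw applies a uniform random 3D
#' rotation to the left-hemisphere points and its sagittal mirror
#' conjugate to the right-hemisphere points, then matches rotated to
#' original positions within each hemisphere by greedy nearest-distance
#' assignment (closest pair first), which guarantees a bijection. This is
#' the parcel-centroid adaptation of surface-rotation nulls; parcel
#' contiguity is not representable at centroid level.
#'
#' @param coordinates N x 3 unit-sphere coordinates.
#' @param hemisphere character vector, "left"/"right" per region.
#' @param n_perm number of permutations (default 50).
#' @param seed integer RNG seed.
#' @param identity_hook if TRUE, use the identity rotation for every draw
#'   (test hook; yields identity permutations).
#' @return object of class `spin_ensemble`: list with `permutations` (list
#'   of integer vectors; entry i of a permutation is the source region
#'   whose value region i receives), `n_perm`, `seed`.
#' @export
spin_rotations <- function(coordinates, hemisphere, n_perm = 50, seed = 1,
                           identity_hook = FALSE) {
  if (is.null(coordinates) || is.null(hemisphere))
    stop("coordinates and hemisphere labels are required for spin nulls")
  n <- nrow(coordinates)
  stopifnot(length(hemisphere) == n)
  left <- which(hemisphere == "left")
  right <- which(hemisphere == "right")
  mirror <- diag(c(-1, 1, 1))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  perms <- vector("list", n_perm)
  for (i in seq_len(n_perm)) {
    rot <- if (identity_hook) diag(3) else random_rotation()
    rot_r <- mirror %*% rot %*% mirror
    perm <- integer(n)
    perm[left] <- left[greedy_match(coordinates[left, , drop = FALSE],
                                    coordinates[left, , drop = FALSE] %*%
                                      t(rot))]
    perm[right] <- right[greedy_match(coordinates[right, , drop = FALSE],
                                      coordinates[right, , drop = FALSE] %*%
                                        t(rot_r))]
    perms[[i]] <- perm
  }
  structure(list(permutations = perms, n_perm = n_perm, seed = seed),
            class = "spin_ensemble")
}

# uniform random rotation (Haar) via QR of a Gaussian matrix, det +1
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  d <- sign(diag(qr.R(qr_)))
  q <- q %*% diag(d)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# For each original point, which rotated point lands on it: repeatedly take
# the globally closest (original, rotated) pair, assign, remove both.
# Returns m[i] = index of the rotated (source) point matched to original i.
greedy_match <- function(orig, rotated) {
  k <- nrow(orig)
  d <- 2 - 2 * tcrossprod(orig, rotated)  # squared chordal distance
  m <- integer(k)
  for (step in seq_len(k)) {
    idx <- arrayInd(which.min(d), dim(d))
    m[idx[1]] <- idx[2]
    d[idx[1], ] <- Inf
    d[, idx[2]] <- Inf
  }
  m
}

#' Spun images of a node set
#'
#' @param target integer vector of node indices (non-empty).
#' @param ens a [spin_rotations] ensemble.
#' @return list of integer vectors, each of size `length(target)`: the
#'   image of the target under each permutation (the regions that receive
#'   the target's labels).
#' @export
spun_sets <- function(target, ens) {
  if (!length(target)) stop("target set must be non-empty")
  lapply(ens$permutations, function(p) which(p %in% target))
}

#' Connectivity-profile-matched reference set
#'
#' Draws `n_candidates` random size-matched node sets and returns the one
#' whose mean pairwise correlation of connectivity rows is closest to the
#' target set's; ties go to the earliest sampled candidate.
#'
#' @param c a [connectome].
#' @param target integer vector of node indices.
#' @param n_candidates candidate pool size (default 500).
#' @param seed integer RNG seed.
#' @param include_target test hook: prepend the target itself to the pool.
#' @return integer vector of node indices, `length(target)` of them, with
#'   attributes `criterion` and `criterion_target`.
#' @export
profile_matched_set <- function(c, target, n_candidates = 500, seed = 1,
                                include_target = FALSE) {
  matched_set(c, target, n_candidates, seed, include_target,
              criterion = profile_criterion)
}

#' Connection-sum-matched reference set
#'
#' As [profile_matched_set] but matching on the summed weight of
#' within-set edges.
#'
#' @inheritParams profile_matched_set
#' @export
sum_matched_set <- function(c, target, n_candidates = 500, seed = 1,
                            include_target = FALSE) {
  matched_set(c, target, n_candidates, seed, include_target,
              criterion = sum_criterion)
}

profile_criterion <- function(c, set) {
  rows <- c$weights[set, , drop = FALSE]
  cors <- stats::cor(t(rows))
  mean(cors[upper.tri(cors)])
}

sum_criterion <- function(c, set) {
  sub <- c$weights[set, set, drop = FALSE]
  sum(sub[upper.tri(sub)])
}

matched_set <- function(c, target, n_candidates, seed, include_target,
                        criterion) {
  n <- n_nodes(c)
  k <- length(target)
  if (k >= n) stop("target set must be smaller than the network")
  crit_t <- criterion(c, target)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  best <- NULL
  best_d <- Inf
  pool <- vector("list", n_candidates + include_target)
  if (include_target) pool[[1]] <- sort(target)
  for (i in seq_len(n_candidates))
    pool[[i + include_target]] <- sort(sample.int(n, k))
  for (cand in pool) {
    d <- abs(criterion(c, cand) - crit_t)
    if (d < best_d) { best_d <- d; best <- cand }
  }
  structure(best, criterion = criterion(c, best), criterion_target = crit_t)
}

#' Permutation p-value from a null distribution
#'
#' Plug-in exceedance probability: for `alternative = "greater"`,
#' `p = #{null >= empirical} / n` (ties count as exceedance, and p = 0 is
#' attainable); "less" mirrors it; "two-sided" doubles the smaller side,
#' capped at 1.
#'
#' @param empirical scalar empirical statistic.
#' @param null_values numeric vector of null statistics (non-empty).
#' @param alternative one of "greater", "less", "two-sided".
#' @return scalar p-value in `[0, 1]`.
#' @export
spin_pvalue <- function(empirical,
                        null_values,
                        alternative = c("greater", "less", "two-sided")) {
  alternative <- match.arg(alternative)
  null_values <- null_values[is.finite(null_values)]
  if (!length(null_values)) stop("need at least one finite null value")
  n <- length(null_values)
  p_g <- sum(null_values >= empirical) / n
  p_l <- sum(null_values <= empirical) / n
  switch(alternative,
         greater = p_g,
         less = p_l,
         `two-sided` = min(1, 2 * min(p_g, p_l)))
}
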