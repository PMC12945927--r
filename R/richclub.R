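#' Weighted rich-club coefficient curve
#'
#' For each degree level k, let V_k be the nodes with degree > k, E_k the
#' number of edges among them and W_k their summed weight. The weighted
#' rich-club coefficient is
#' \deqn{\phi^w(k) = W_k / \sum_{e=1}^{E_k} w^{rank}_e,}
#' the ratio of W_k to the sum of the E_k strongest weights anywhere in the
#' network. Levels where E_k = 0 are undefined (NA).
#'
#' @param c a [connectome].
#' @return data.frame with columns `k`, `phi` (NA where undefined), `n_edges`.
#' @export
weighted_rich_club_curve <- function(c) {
  w <- c$weights
  deg <- rowSums(w > 0)
  ut <- which(upper.tri(w) & w > 0)
  ew <- w[ut]
  # an edge survives at level k iff both endpoints have degree > k,
  # i.e. iff min(deg_u, deg_v) > k
  ij <- arrayInd(ut, dim(w))
  mdeg <- pmin(deg[ij[, 1]], deg[ij[, 2]])
  kmax <- max(deg)
  ks <- seq_len(kmax)
  cnt <- tabulate(mdeg, nbins = kmax)
  wsum <- vapply(split(ew, factor(mdeg, levels = ks)), sum, numeric(1))
  # reverse cumulative: edges with min degree > k
  e_k <- rev(cumsum(rev(cnt)))
  e_k <- c(e_k[-1], 0)               # strictly greater than k
  w_k <- rev(cumsum(rev(wsum)))
  w_k <- c(w_k[-1], 0)
  top <- cumsum(sort(ew, decreasing = TRUE))
  phi <- ifelse(e_k > 0, w_k / top[pmax(e_k, 1)], NA_real_)
  data.frame(k = ks, phi = phi, n_edges = e_k)
}

#' Degree-preserving rewired null network
#'
#' Maslov-Sneppen double-edge swaps: `iters_per_edge * E` attempted swaps,
#' each exchanging the endpoints of two randomly chosen edges, rejected when
#' a self-loop or multi-edge would arise. Weights travel with their edges,
#' so the degree sequence and the weight multiset are preserved exactly.
#'
#' @param c a [connectome].
#' @param iters_per_edge attempted swaps per edge (default 10).
#' @param seed integer RNG seed.
#' @return a [connectome] with the same degree sequence.
#' @export
rewire_preserving_degree <- function(c, iters_per_edge = 10, seed = 1) {
  w <- c$weights
  n <- nrow(w)
  ut <- which(upper.tri(w) & w > 0)
  if (length(ut) < 2) return(c)
  ij <- arrayInd(ut, dim(w))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  edges <- rewire_edges_cpp(ij, n, as.integer(iters_per_edge * length(ut)))
  w2 <- matrix(0, n, n)
  w2[cbind(edges[, 1], edges[, 2])] <- w[ut]
  w2[cbind(edges[, 2], edges[, 1])] <- w[ut]
  out <- c
  out$weights <- w2
  out
}

#' Normalized rich-club curve against a rewired null ensemble
#'
#' Computes the empirical weighted rich-club curve, the mean curve over
#' `n_nulls` degree-preserving rewired networks, the normalized coefficient
#' \eqn{\Phi(k) = \phi_{emp}(k) / \bar\phi_{null}(k)}, a one-sided
#' exceedance p-value per k, and the cutoff `k_max_phi`: the k maximizing
#' \eqn{\Phi} within the significant regime `{k : p < alpha}` (ties broken
#' toward smaller k). When no level is significant, `k_max_phi` is NA and
#' downstream code must fall back to the top-k rich-club definition.
#'
#' @param c a [connectome].
#' @param n_nulls size of the null ensemble (>= 20; default 200).
#' @param iters_per_edge swaps per edge in each null (default 10).
#' @param alpha per-k significance level (default 0.05).
#' @param seed integer RNG seed.
#' @return an object of class `rich_club_curve`: data.frame columns `k`,
#'   `phi_emp`, `phi_null_mean`, `phi_norm`, `p`, plus attributes
#'   `k_max_phi` (may be NA) and `n_nulls`.
#' @export
normalized_rich_club <- function(c, n_nulls = 200, iters_per_edge = 10,
                                 alpha = 0.05, seed = 1) {
  if (n_nulls < 20) stop("n_nulls must be at least 20")
  emp <- weighted_rich_club_curve(c)
  kmax <- nrow(emp)
  null_phi <- matrix(NA_real_, n_nulls, kmax)
  for (i in seq_len(n_nulls)) {
    nc <- rewire_preserving_degree(c, iters_per_edge, seed = seed + i)
    ph <- weighted_rich_club_curve(nc)$phi
    null_phi[i, seq_along(ph)] <- ph
  }
  null_mean <- colMeans(null_phi, na.rm = TRUE)
  null_mean[is.nan(null_mean)] <- NA_real_
  # one-sided exceedance over the whole ensemble: nulls where the level is
  # undefined (no surviving edges) cannot exceed the empirical value
  p <- vapply(seq_len(kmax), function(k) {
    if (is.na(emp$phi[k])) return(NA_real_)
    sum(null_phi[, k] >= emp$phi[k], na.rm = TRUE) / n_nulls
  }, numeric(1))
  phi_norm <- emp$phi / null_mean
  curve <- data.frame(k = emp$k, phi_emp = emp$phi,
                      phi_null_mean = null_mean, phi_norm = phi_norm,
                      p = p, n_edges = emp$n_edges)
  sig <- which(!is.na(p) & p < alpha & !is.na(phi_norm))
  k_max_phi <- if (length(sig)) {
    best <- sig[phi_norm[sig] == max(phi_norm[sig])]
    curve$k[min(best)]
  } else NA_integer_
  structure(curve, class = c("rich_club_curve", "data.frame"),
            k_max_phi = k_max_phi, n_nulls = n_nulls, alpha = alpha)
}

#' Rich-club membership from an individual curve
#'
#' Members are the nodes with degree strictly greater than the curve's
#' `k_max_phi` cutoff.
#'
#' @param curve a `rich_club_curve` from [normalized_rich_club].
#' @param c the [connectome] the curve was computed on.
#' @return a `rich_club_assignment`: list with `member_flags` (logical N),
#'   `k_cutoff`, `source`.
#' @export
individual_rich_club <- function(curve, c) {
  k_cut <- attr(curve, "k_max_phi")
  if (is.na(k_cut))
    stop("no significant rich-club regime: k_max_phi undefined; ",
         "use individual_topk_rich_club() instead")
  flags <- node_degree(c) > k_cut
  structure(list(member_flags = unname(flags), k_cutoff = k_cut,
                 source = "individual-curve"),
            class = "rich_club_assignment")
}

#' Top-k rich-club membership
#'
#' The `size` highest-degree nodes; degree ties broken by higher strength,
#' then by lower node index, so membership is deterministic and has exactly
#' `size` members.
#'
#' @param c a [connectome].
#' @param size number of members (<= N).
#' @return a `rich_club_assignment`.
#' @export
individual_topk_rich_club <- function(c, size) {
  n <- n_nodes(c)
  if (size > n) stop("size exceeds the number of nodes")
  ord <- order(-node_degree(c), -node_strength(c), seq_len(n))
  flags <- logical(n)
  flags[ord[seq_len(size)]] <- TRUE
  structure(list(member_flags = flags, k_cutoff = NA_integer_,
                 source = "individual-topk"),
            class = "rich_club_assignment")
}

#' Group-level rich club
#'
#' The group size is `round(f * n_nodes)` (half away from zero) where f is
#' the mean individual membership fraction (overridable via `fraction`);
#' members are the nodes that qualified most consistently across subjects.
#' Frequency ties are broken by higher mean degree, then lower node index.
#'
#' @param assignments list of `rich_club_assignment`s (one per subject).
#' @param n_nodes number of regions.
#' @param fraction override for the membership fraction f (default: mean
#'   over assignments).
#' @param mean_degree optional per-node mean degree across subjects, used
#'   only to break frequency ties.
#' @return a `rich_club_assignment` with `source = "group"` and attribute
#'   `frequency` (per-node membership frequency).
#' @export
group_rich_club <- function(assignments, n_nodes, fraction = NULL,
                            mean_degree = NULL) {
  if (!length(assignments)) stop("need at least one assignment")
  flags <- vapply(assignments, function(a) a$member_flags,
                  logical(n_nodes))
  freq <- rowMeans(flags)
  f <- if (is.null(fraction)) mean(colMeans(flags)) else fraction
  size <- floor(f * n_nodes + 0.5)   # round half away from zero
  if (is.null(mean_degree)) mean_degree <- numeric(n_nodes)
  ord <- order(-freq, -mean_degree, seq_len(n_nodes))
  members <- logical(n_nodes)
  if (size > 0) members[ord[seq_len(size)]] <- TRUE
  structure(list(member_flags = members, k_cutoff = NA_integer_,
                 source = "group"),
            class = "rich_club_assignment", frequency = freq, fraction = f,
            size = size)
}

#' @export
print.rich_club_assignment <- function(x, ...) {
  cat(sprintf("rich-club assignment (%s): %d members%s\n", x$source,
              sum(x$member_flags),
              if (!is.na(x$k_cutoff)) sprintf(", k > %d", x$k_cutoff) else ""))
  invisible(x)
}
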