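#' Activation-difference covariate
#'
#' Mean over regions of the target-minus-initial activation difference,
#' entered as a per-subject covariate in the repeated-measures model so
#' that control-metric differences are not mere activation differences.
#'
#' @param x0,xT initial and target brain states (equal length).
#' @param absolute take the absolute value of the mean difference.
#' @return scalar covariate.
#' @export
activation_covariate <- function(x0, xT, absolute = FALSE) {
  stopifnot(length(x0) == length(xT))
  v <- mean(xT - x0)
  if (absolute) abs(v) else v
}

#' Two-level repeated-measures comparison with a covariate
#'
#' Fits the model `metric ~ condition + covariate` with subjects as the
#' repeated-measures blocking factor, for a two-level within-subject
#' condition (e.g. rich-club-excluded vs. mean over reference-set-excluded
#' runs). With two levels the within-subject condition effect is the
#' covariate-adjusted paired comparison: the per-subject difference d is
#' regressed on the centered covariate and the condition F is the squared
#' t of the intercept, on (1, n-2) degrees of freedom.
#'
#' @param a,b per-subject metric under condition a and b (length >= 3).
#' @param covariate per-subject continuous covariate (default all zero).
#' @return list with `F`, `p`, `df`, `direction` (sign of mean(a - b)),
#'   `mean_diff`.
#' @export
rm_anova_covariate <- function(a, b, covariate = NULL) {
  n <- length(a)
  stopifnot(length(b) == n, n >= 3, all(is.finite(a)), all(is.finite(b)))
  if (stats::var(a) == 0 && stats::var(b) == 0 && !all(a == b))
    stop("zero variance in both conditions")
  if (is.null(covariate)) covariate <- numeric(n)
  stopifnot(length(covariate) == n, all(is.finite(covariate)))
  d <- a - b
  if (all(d == 0))
    return(list(F = 0, p = 1, df = c(1, n - 2), direction = 0, mean_diff = 0))
  cv <- covariate - mean(covariate)
  fit <- if (stats::var(cv) > 0) stats::lm(d ~ cv) else stats::lm(d ~ 1)
  sm <- summary(fit)$coefficients
  tval <- sm["(Intercept)", "t value"]
  df2 <- fit$df.residual
  f <- tval^2
  p <- stats::pf(f, 1, df2, lower.tail = FALSE)
  list(F = f, p = p, df = c(1, df2), direction = sign(mean(d)),
       mean_diff = mean(d))
}

#' One-tailed paired t-test
#'
#' @param a,b paired samples (length >= 2).
#' @param direction "greater" tests mean(a - b) > 0, "less" the reverse.
#' @return list with `t`, `p`, `df`.
#' @export
paired_t_one_tailed <- function(a, b, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  if (stats::sd(d) == 0) stop("zero-variance differences")
  tt <- stats::t.test(a, b, paired = TRUE, alternative = direction)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter))
}

#' Regional control-impact ranks from lesion scans
#'
#' Converts per-task lesion deltas into ranks: the impact score is the
#' energy increase (energy measure) or the stability decrease (stability
#' measure) upon removing the region from the control set; rank 1 is the
#' largest impact. Ties get average ranks, then are resolved to an integer
#' permutation by node index. Regions with missing deltas (failed lesions)
#' are ranked last, with a warning.
#'
#' @param scans list (one element per task) of lesion-scan data.frames
#'   from [regional_lesion_scan] (columns `energy_delta`,
#'   `stability_delta`).
#' @return object of class `regional_rank_table`: list with `ranks`
#'   (N x task x measure array), `mean_rank` (length N).
#' @export
rank_regions <- function(scans) {
  stopifnot(length(scans) >= 1)
  n <- nrow(scans[[1]])
  measures <- c("energy", "stability")
  ranks <- array(NA_integer_, dim = c(n, length(scans), 2),
                 dimnames = list(NULL, names(scans), measures))
  any_missing <- FALSE
  for (t in seq_along(scans)) {
    sc <- scans[[t]]
    stopifnot(nrow(sc) == n)
    impact <- list(energy = sc$energy_delta,
                   stability = -sc$stability_delta)
    for (m in 1:2) {
      x <- impact[[m]]
      if (anyNA(x)) { any_missing <- TRUE; x[is.na(x)] <- -Inf }
      avg <- rank(-x, ties.method = "average")
      ord <- order(avg, seq_len(n))
      r <- integer(n)
      r[ord] <- seq_len(n)
      ranks[, t, m] <- r
    }
  }
  if (any_missing)
    warning("regions with failed lesions were ranked last")
  structure(list(ranks = ranks,
                 mean_rank = apply(ranks, 1, mean)),
            class = "regional_rank_table")
}

#' Spin test of a node set's mean control rank
#'
#' Compares the mean of `mean_rank` over a node set with the same
#' statistic over the set's spin-rotated images. With
#' `alternative = "greater"` the test asks whether the set ranks higher
#' (contributes less to control) than expected by chance.
#'
#' @param table a [rank_regions] table.
#' @param set integer vector of node indices (non-empty).
#' @param ens a [spin_rotations] ensemble.
#' @param alternative passed to [spin_pvalue] (default "greater").
#' @return list with `mean_rank`, `p`, `null_values`.
#' @export
set_mean_rank_test <- function(table, set, ens, alternative = "greater") {
  stopifnot(length(set) >= 1)
  emp <- mean(table$mean_rank[set])
  nulls <- vapply(spun_sets(set, ens),
                  function(s) mean(table$mean_rank[s]), numeric(1))
  list(mean_rank = emp,
       p = spin_pvalue(emp, nulls, alternative),
       null_values = nulls)
}

#' Spin-tested correlation between control ranks and a regional map
#'
#' Product-moment correlation between the rank table's `mean_rank` (or one
#' per-measure rank column) and a regional map, with significance from
#' spin permutations of the map.
#'
#' @param table a [rank_regions] table.
#' @param map numeric regional map of length N.
#' @param ens a [spin_rotations] ensemble.
#' @param measure "mean" (default) or "energy"/"stability" for per-measure
#'   ranks (averaged over tasks).
#' @param alternative passed to [spin_pvalue] (default "two-sided").
#' @return list with `r`, `p`, `null_values`.
#' @export
map_rank_correlation <- function(table, map, ens, measure = "mean",
                                 alternative = "two-sided") {
  ranks <- rank_vector(table, measure)
  stopifnot(length(map) == length(ranks))
  if (stats::sd(map) == 0) stop("zero-variance map")
  emp <- stats::cor(ranks, map)
  nulls <- vapply(ens$permutations,
                  function(p) stats::cor(ranks, map[p]), numeric(1))
  list(r = emp, p = spin_pvalue(emp, nulls, alternative),
       null_values = nulls)
}

rank_vector <- function(table, measure) {
  if (measure == "mean") return(table$mean_rank)
  stopifnot(measure %in% dimnames(table$ranks)[[3]])
  apply(table$ranks[, , measure, drop = FALSE], 1, mean)
}

#' Per-network mean control ranks with spin inference
#'
#' Mean regional rank per network label, each tested in both directions
#' against spin permutations of the rank map (lower-than-chance mean rank
#' means the network contributes more to control than chance).
#'
#' @param table a [rank_regions] table.
#' @param labels network label vector of length N.
#' @param ens a [spin_rotations] ensemble.
#' @return data.frame with columns `network`, `n_regions`, `mean_rank`,
#'   `p_low`, `p_high`.
#' @export
network_mean_ranks <- function(table, labels, ens) {
  stopifnot(length(labels) == length(table$mean_rank))
  labs <- sort(unique(labels))
  mr <- table$mean_rank
  null_mat <- vapply(ens$permutations, function(p) mr[p],
                     numeric(length(mr)))
  res <- lapply(labs, function(l) {
    idx <- which(labels == l)
    if (!length(idx)) {
      warning(sprintf("network %s has no members; skipped", l))
      return(NULL)
    }
    emp <- mean(mr[idx])
    nulls <- colMeans(null_mat[idx, , drop = FALSE])
    data.frame(network = l, n_regions = length(idx), mean_rank = emp,
               p_low = spin_pvalue(emp, nulls, "less"),
               p_high = spin_pvalue(emp, nulls, "greater"))
  })
  do.call(rbind, res)
}

#' Paired Cohen's d
#'
#' Effect size for a paired comparison: `mean(a - b) / sd(a - b)`.
#' Zero-variance differences yield the signed sentinel `Inf`.
#'
#' @param a,b paired samples (length >= 2).
#' @return scalar d.
#' @export
paired_effect_size <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  s <- stats::sd(d)
  if (s == 0) return(sign(mean(d)) * Inf)
  mean(d) / s
}
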