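#' Construct a connectome object
#'
#' A connectome is a symmetric, nonnegative, zero-diagonal weight matrix over
#' N brain regions, optionally carrying unit-sphere region coordinates and
#' hemisphere labels used by the spatial (spin) null models.
#'
#' @param weights N x N numeric matrix; symmetric within `tol`, nonnegative,
#'   zero diagonal. Weights are FA-like in `[0, 1]` for the synthetic cohorts
#'   but any nonnegative weighting (e.g. streamline counts, binary) is valid.
#' @param node_ids optional character vector of region identifiers.
#' @param coordinates optional N x 3 matrix of unit-sphere points.
#' @param hemisphere optional character vector with entries "left"/"right".
#' @param tol symmetry tolerance (default 1e-10).
#' @return an object of class `connectome`: a list with elements `weights`,
#'   `node_ids`, `coordinates`, `hemisphere`.
#' @export
connectome <- function(weights, node_ids = NULL, coordinates = NULL,
                       hemisphere = NULL, tol = 1e-10) {
  weights <- as.matrix(weights)
  n <- nrow(weights)
  if (ncol(weights) != n) stop("weights must be square")
  if (any(!is.finite(weights))) stop("weights must be finite")
  asym <- abs(weights - t(weights))
  if (max(asym) > tol) {
    idx <- which(asym == max(asym), arr.ind = TRUE)[1, ]
    stop(sprintf("weights not symmetric: max asymmetry %.3g at cell (%d, %d)",
                 max(asym), idx[1], idx[2]))
  }
  weights <- (weights + t(weights)) / 2
  if (any(diag(weights) != 0)) stop("diagonal must be exactly zero")
  if (any(weights < 0)) stop("weights must be nonnegative")
  if (is.null(node_ids)) node_ids <- sprintf("region_%03d", seq_len(n))
  if (!is.null(coordinates)) {
    coordinates <- as.matrix(coordinates)
    stopifnot(nrow(coordinates) == n, ncol(coordinates) == 3)
  }
  if (!is.null(hemisphere)) {
    stopifnot(length(hemisphere) == n, all(hemisphere %in% c("left", "right")))
  }
  structure(list(weights = weights, node_ids = node_ids,
                 coordinates = coordinates, hemisphere = hemisphere),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  n <- nrow(x$weights)
  e <- sum(x$weights[upper.tri(x$weights)] > 0)
  cat(sprintf("connectome: %d regions, %d edges, density %.3f%s\n",
              n, e, e / choose(n, 2),
              if (!is.null(x$coordinates)) ", with coordinates" else ""))
  invisible(x)
}

n_nodes <- function(c) nrow(c$weights)

#' Nodal degree
#'
#' Per-region count of strictly positive connections.
#'
#' @param c a [connectome].
#' @return named numeric vector of length N.
#' @export
node_degree <- function(c) {
  d <- rowSums(c$weights > 0)
  names(d) <- c$node_ids
  d
}

#' Nodal strength
#'
#' Per-region sum of connection weights.
#'
#' @param c a [connectome].
#' @return named numeric vector of length N.
#' @export
node_strength <- function(c) {
  s <- rowSums(c$weights)
  names(s) <- c$node_ids
  s
}

#' Participation coefficient
#'
#' How evenly a region's connection weight is spread across modules:
#' \deqn{P_i = 1 - \sum_m (s_{im}/s_i)^2} where \eqn{s_{im}} is node i's
#' summed weight to module m and \eqn{s_i} its strength. Zero-strength
#' nodes get \eqn{P_i = 0}.
#'
#' @param c a [connectome].
#' @param labels integer/factor vector of module assignments, length N.
#' @param binary compute on the binarized network instead of weights.
#' @return numeric vector in `[0, 1 - 1/M]`.
#' @export
participation_coefficient <- function(c, labels, binary = FALSE) {
  w <- c$weights
  if (binary) w <- (w > 0) + 0
  stopifnot(length(labels) == nrow(w))
  labels <- as.integer(factor(labels))
  s <- rowSums(w)
  # N x M matrix of per-module strengths via indicator multiplication
  mm <- outer(labels, seq_len(max(labels)), `==`) + 0
  sm <- w %*% mm
  p <- 1 - rowSums((sm / ifelse(s > 0, s, 1))^2)
  p[s == 0] <- 0
  names(p) <- c$node_ids
  p
}

#' Regional communicability
#'
#' Weighted sum of walks of all lengths between regions, via the matrix
#' exponential of the strength-normalized adjacency
#' \eqn{G = \exp(D^{-1/2} W D^{-1/2})}, \eqn{D = diag(strength)}. The
#' regional value is the off-diagonal row sum \eqn{\sum_{j \ne i} G_{ij}};
#' self-communicability is excluded. Zero-strength nodes are excluded from
#' the normalization and reported as 0, with a warning.
#'
#' @param c a [connectome].
#' @return numeric vector of length N.
#' @export
communicability <- function(c) {
  w <- c$weights
  s <- rowSums(w)
  out <- numeric(length(s))
  names(out) <- c$node_ids
  keep <- s > 0
  if (!all(keep)) {
    if (!any(keep)) return(out)
    warning(sprintf("%d zero-strength node(s) assigned communicability 0",
                    sum(!keep)))
  }
  wk <- w[keep, keep, drop = FALSE]
  dk <- 1 / sqrt(s[keep])
  a <- wk * tcrossprod(dk)   # D^{-1/2} W D^{-1/2}, stays symmetric
  es <- eigen(a, symmetric = TRUE)
  g <- es$vectors %*% (exp(es$values) * t(es$vectors))
  out[keep] <- rowSums(g) - diag(g)
  out
}

#' Cohort outlier detection
#'
#' Flags subjects whose connectome deviates from the group, using the group
#' edge-prevalence matrix (per-edge count of subjects in which the edge is
#' present). Each subject's score is the summed prevalence over its own
#' present edges; subjects scoring more than 2 IQR above Q3 or below Q1
#' (quartiles by linear interpolation, type 7) are flagged.
#'
#' @param cohort list of [connectome] objects (>= 4) on the same regions.
#' @param iqr_factor multiplier on the interquartile range (default 2).
#' @return logical vector, one flag per subject.
#' @export
cohort_outliers <- function(cohort, iqr_factor = 2) {
  if (length(cohort) < 4) stop("need at least 4 subjects")
  pres <- lapply(cohort, function(c) c$weights > 0)
  prevalence <- Reduce(`+`, pres)
  ut <- upper.tri(prevalence)
  scores <- vapply(pres, function(p) sum(prevalence[ut & p]), numeric(1))
  q <- stats::quantile(scores, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  scores > q[2] + iqr_factor * iqr | scores < q[1] - iqr_factor * iqr
}

#' Reweight a connectome
#'
#' @param c a [connectome].
#' @param scheme "fa" and "nos" are pass-through tags on an already-weighted
#'   matrix; "binary" sets every positive weight to exactly 1.
#' @return a [connectome].
#' @export
reweight <- function(c, scheme = c("fa", "nos", "binary")) {
  scheme <- match.arg(scheme)
  if (scheme == "binary") c$weights <- (c$weights > 0) + 0
  c
}
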