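matrix_power <- function(m, k) {
  out <- diag(nrow(m))
  base <- m
  while (k > 0) {
    if (k %% 2 == 1) out <- out %*% base
    k <- k %/% 2
    if (k > 0) base <- base %*% base
  }
  out
}

#' Stabilized linear system from a connectome
#'
#' Builds the Hurwitz-stable system matrix
#' \deqn{S = A / (1 + \lambda_{max}(A)) - I}
#' where \eqn{\lambda_{max}} is the largest eigenvalue of the weight matrix
#' A. All eigenvalues of S then lie in (-2, 0), so the uncontrolled
#' dynamics \eqn{\dot x = S x} decay to the origin.
#'
#' @param c a [connectome] (or a plain symmetric nonnegative matrix).
#' @return object of class `stabilized_system`: list with `S` (N x N) and
#'   `lambda_max`.
#' @export
stabilize <- function(c) {
  a <- if (inherits(c, "connectome")) c$weights else as.matrix(c)
  if (max(abs(a - t(a))) > 1e-10) stop("weight matrix must be symmetric")
  if (any(a < 0)) stop("weights must be nonnegative")
  lambda_max <- max(eigen(a, symmetric = TRUE, only.values = TRUE)$values)
  s <- a / (1 + lambda_max) - diag(nrow(a))
  structure(list(S = s, lambda_max = lambda_max),
            class = "stabilized_system")
}

#' Control problem specification
#'
#' @param x0,xT initial and target activation vectors (length N).
#' @param control_set logical mask of length N: which nodes may exert
#'   control. Default: all nodes.
#' @param T time horizon (default 1).
#' @param rho control-energy penalization weight (default 1).
#' @param n_steps trajectory discretization count (default 1000).
#' @return a `control_problem` list.
#' @export
control_problem <- function(x0, xT, control_set = NULL, T = 1, rho = 1,
                            n_steps = 1000) {
  n <- length(x0)
  stopifnot(length(xT) == n, all(is.finite(x0)), all(is.finite(xT)),
            T > 0, rho > 0, n_steps >= 10)
  if (is.null(control_set)) control_set <- rep(TRUE, n)
  stopifnot(length(control_set) == n, is.logical(control_set))
  if (!any(control_set)) stop("control set must contain at least one node")
  structure(list(x0 = as.numeric(x0), xT = as.numeric(xT),
                 control_set = control_set, T = T, rho = rho,
                 n_steps = as.integer(n_steps)),
            class = "control_problem")
}

#' Solve the two-point optimal control problem
#'
#' Minimizes
#' \deqn{J = \int_0^T (x_T - x)^\top (x_T - x) + \rho\, u^\top u \; dt}
#' subject to \eqn{\dot x = S x + B u}, hard endpoints \eqn{x(0) = x_0},
#' \eqn{x(T) = x_T}, where B selects the control nodes (excluded nodes keep
#' evolving under S but receive no input). Pontryagin's conditions give
#' \eqn{u^*(t) = -B^\top p(t) / (2\rho)} and the linear-affine Hamiltonian
#' system
#' \deqn{\frac{d}{dt}\begin{pmatrix}x\\p\end{pmatrix} =
#'   \begin{pmatrix}S & -BB^\top/(2\rho)\\ -2I & -S^\top\end{pmatrix}
#'   \begin{pmatrix}x\\p\end{pmatrix} + \begin{pmatrix}0\\2x_T\end{pmatrix},}
#' solved exactly with one matrix exponential; the unknown initial costate
#' follows from a linear solve on the endpoint condition. The trajectory is
#' then propagated on an `n_steps` grid by exact stepping.
#'
#' Per-node energy is \eqn{\int_0^T u_i(t)^2 dt} (trapezoid rule) divided
#' by `n_steps`, the time normalization that makes values comparable
#' across horizons; `mean_energy` averages over all N nodes, controllers
#' and non-controllers alike (the latter contribute exactly 0).
#'
#' @param sys a [stabilize]d system.
#' @param prob a [control_problem].
#' @param rcond_min minimum acceptable reciprocal condition number of the
#'   endpoint solve (default 1e-12); below it the control set is reported
#'   as uncontrollable/ill-conditioned.
#' @param endpoint_tol maximum relative endpoint error (default 1e-4).
#' @return object of class `control_solution`: list with `t_grid`,
#'   `x_traj` ((n_steps+1) x N), `u_traj` ((n_steps+1) x N, zero columns
#'   for non-controllers), `nodal_energy`, `mean_energy`, `endpoint_error`.
#' @export
solve_optimal_control <- function(sys, prob, rcond_min = 1e-12,
                                  endpoint_tol = 1e-4) {
  s <- sys$S
  n <- nrow(s)
  stopifnot(length(prob$x0) == n)
  mask <- prob$control_set
  nc <- sum(mask)
  rho <- prob$rho
  # BB' is diagonal: 1 on controlled nodes
  bbt <- diag(as.numeric(mask), n)
  m <- rbind(cbind(s, -bbt / (2 * rho)),
             cbind(-2 * diag(n), -t(s)))
  b_aff <- c(numeric(n), 2 * prob$xT)
  m_aug <- rbind(cbind(m, b_aff), 0)
  # one matrix exponential for the grid step; the horizon propagator is its
  # exact n_steps-th power so the endpoint solve and the trajectory
  # propagation share one operator and stay mutually consistent
  dt <- prob$T / prob$n_steps
  step <- as.matrix(Matrix::expm(Matrix::Matrix(m_aug * dt)))
  big <- matrix_power(step, prob$n_steps)
  phi <- big[seq_len(2 * n), seq_len(2 * n), drop = FALSE]
  part <- big[seq_len(2 * n), 2 * n + 1]
  phi11 <- phi[seq_len(n), seq_len(n), drop = FALSE]
  phi12 <- phi[seq_len(n), n + seq_len(n), drop = FALSE]
  rhs <- prob$xT - phi11 %*% prob$x0 - part[seq_len(n)]
  rc <- rcond(phi12)
  if (!is.finite(rc) || rc < rcond_min)
    stop(sprintf(
      "uncontrollable/ill-conditioned control set (%d of %d nodes): rcond %.2e",
      nc, n, rc))
  p0 <- solve(phi12, rhs)
  z <- c(prob$x0, p0, 1)
  x_traj <- matrix(0, prob$n_steps + 1, n)
  p_traj <- matrix(0, prob$n_steps + 1, n)
  x_traj[1, ] <- prob$x0
  p_traj[1, ] <- p0
  for (k in seq_len(prob$n_steps)) {
    z <- step %*% z
    x_traj[k + 1, ] <- z[seq_len(n)]
    p_traj[k + 1, ] <- z[n + seq_len(n)]
  }
  u_traj <- matrix(0, prob$n_steps + 1, n)
  u_traj[, mask] <- -p_traj[, mask, drop = FALSE] / (2 * rho)
  # trapezoid integral of u_i^2 over [0, T], then the per-step normalization
  u2 <- u_traj^2
  trap_w <- c(0.5, rep(1, prob$n_steps - 1), 0.5) * dt
  nodal_energy <- as.numeric(crossprod(u2, trap_w)) / prob$n_steps
  endpoint_error <- sqrt(sum((x_traj[prob$n_steps + 1, ] - prob$xT)^2)) /
    max(sqrt(sum(prob$xT^2)), 1)
  if (endpoint_error > endpoint_tol)
    stop(sprintf("endpoint not reached: relative error %.3g > %.3g",
                 endpoint_error, endpoint_tol))
  structure(list(t_grid = seq(0, prob$T, length.out = prob$n_steps + 1),
                 x_traj = x_traj, u_traj = u_traj,
                 nodal_energy = nodal_energy,
                 mean_energy = mean(nodal_energy),
                 endpoint_error = endpoint_error),
            class = "control_solution")
}

#' Optimal transition energy between two brain states
#'
#' The mean per-node control energy of the optimal transition from `x0` to
#' `xT` (see [solve_optimal_control] for the cost and normalization).
#'
#' @inheritParams control_problem
#' @param sys a [stabilize]d system.
#' @param ... passed to [solve_optimal_control].
#' @return scalar mean energy.
#' @export
transition_energy <- function(sys, x0, xT, control_set = NULL, T = 1,
                              rho = 1, n_steps = 1000, ...) {
  prob <- control_problem(x0, xT, control_set, T, rho, n_steps)
  solve_optimal_control(sys, prob, ...)$mean_energy
}

#' Stability of a brain state
#'
#' The inverse of the control energy needed to maintain a state, i.e. of
#' the transition energy with the state as both origin and target. States
#' whose maintenance energy is below 1e-12 (notably the zero state, an
#' equilibrium of the stable dynamics) get the sentinel `Inf`.
#'
#' @inheritParams transition_energy
#' @param x the state to maintain.
#' @return scalar stability (possibly `Inf`).
#' @export
state_stability <- function(sys, x, control_set = NULL, T = 1, rho = 1,
                            n_steps = 1000, ...) {
  e <- transition_energy(sys, x, x, control_set, T, rho, n_steps, ...)
  if (e < 1e-12) return(Inf)
  1 / e
}

#' Single-region lesion scan of the control set
#'
#' Removes one region at a time from the (otherwise full) control set and
#' records the change in transition energy (for `x0 -> xT`) and in the
#' stability of `x0`, relative to the full-control baselines. Removal can
#' only increase optimal energy, so energy deltas are nonnegative up to
#' numerical noise. Regions whose removal makes the endpoint solve
#' ill-conditioned are returned as NA with a warning.
#'
#' @inheritParams transition_energy
#' @return data.frame with columns `node`, `energy_delta`,
#'   `stability_delta`, plus attributes `energy_full`, `stability_full`.
#' @export
regional_lesion_scan <- function(sys, x0, xT, T = 1, rho = 1,
                                 n_steps = 1000, ...) {
  n <- nrow(sys$S)
  if (n < 2) stop("need at least 2 regions")
  full <- rep(TRUE, n)
  e_full <- transition_energy(sys, x0, xT, full, T, rho, n_steps, ...)
  s_full <- state_stability(sys, x0, full, T, rho, n_steps, ...)
  e_delta <- s_delta <- rep(NA_real_, n)
  failed <- integer(0)
  for (r in seq_len(n)) {
    mask <- full
    mask[r] <- FALSE
    res <- tryCatch({
      e_r <- transition_energy(sys, x0, xT, mask, T, rho, n_steps, ...)
      s_r <- state_stability(sys, x0, mask, T, rho, n_steps, ...)
      c(e_r - e_full, s_r - s_full)
    }, error = function(err) NULL)
    if (is.null(res)) failed <- c(failed, r)
    else { e_delta[r] <- res[1]; s_delta[r] <- res[2] }
  }
  if (length(failed))
    warning(sprintf("lesion of region(s) %s ill-conditioned; recorded as NA",
                    paste(failed, collapse = ", ")))
  structure(data.frame(node = seq_len(n), energy_delta = e_delta,
                       stability_delta = s_delta),
            energy_full = e_full, stability_full = s_full)
}

#' Control metrics with a set of regions barred from control
#'
#' The control set is the complement of `excluded`; excluded regions stay
#' in the dynamics (they are still steered by the others) but receive no
#' input. Returns the transition energy `x0 -> xT` and the stability of
#' both states under that restricted control set.
#'
#' @inheritParams transition_energy
#' @param excluded a `rich_club_assignment`, a logical mask, or an integer
#'   vector of node indices to bar from control.
#' @return list with `energy`, `stability_x0`, `stability_xT`,
#'   `n_excluded`.
#' @export
excluded_set_metrics <- function(sys, x0, xT, excluded, T = 1, rho = 1,
                                 n_steps = 1000, ...) {
  n <- nrow(sys$S)
  mask <- rep(TRUE, n)
  if (inherits(excluded, "rich_club_assignment")) {
    mask[excluded$member_flags] <- FALSE
  } else if (is.logical(excluded)) {
    stopifnot(length(excluded) == n)
    mask[excluded] <- FALSE
  } else {
    mask[as.integer(excluded)] <- FALSE
  }
  if (!any(mask)) stop("cannot exclude every node from the control set")
  list(energy = transition_energy(sys, x0, xT, mask, T, rho, n_steps, ...),
       stability_x0 = state_stability(sys, x0, mask, T, rho, n_steps, ...),
       stability_xT = state_stability(sys, xT, mask, T, rho, n_steps, ...),
       n_excluded = sum(!mask))
}
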