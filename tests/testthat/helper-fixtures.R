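# deterministic fixtures and independent numerical oracles used across tests

# weighted Erdos-Renyi connectome, resampled until connected
random_connectome <- function(n, p = 0.3, seed = 1, wmin = 0.1, wmax = 1,
                              with_coords = FALSE) {
  set.seed(seed)
  repeat {
    w <- matrix(0, n, n)
    ut <- upper.tri(w)
    on <- runif(sum(ut)) < p
    w[ut][on] <- runif(sum(on), wmin, wmax)
    w <- w + t(w)
    deg <- rowSums(w > 0)
    g <- igraph::graph_from_adjacency_matrix(w > 0, mode = "undirected")
    if (all(deg > 0) && igraph::is_connected(g)) break
  }
  if (with_coords) {
    geom <- generate_coordinates(n, seed = seed + 1)
    connectome(w, coordinates = geom$coordinates,
               hemisphere = geom$hemisphere)
  } else connectome(w)
}

# classic fourth-order Runge-Kutta on dx/dt = S x + B u(t) with u linearly
# interpolated on the solver grid; independent check that the returned
# control actually steers x0 to xT
rk4_endpoint <- function(sys, sol, x0) {
  tg <- sol$t_grid
  u <- sol$u_traj
  n_steps <- length(tg) - 1
  uf <- function(t) {
    # linear interpolation between grid rows
    pos <- min(max(t / tg[length(tg)] * n_steps, 0), n_steps)
    i <- floor(pos)
    frac <- pos - i
    if (i >= n_steps) return(u[n_steps + 1, ])
    (1 - frac) * u[i + 1, ] + frac * u[i + 2, ]
  }
  f <- function(t, x) drop(sys$S %*% x) + uf(t)
  x <- x0
  h <- tg[2] - tg[1]
  for (k in seq_len(n_steps)) {
    t0 <- tg[k]
    k1 <- f(t0, x)
    k2 <- f(t0 + h / 2, x + h / 2 * k1)
    k3 <- f(t0 + h / 2, x + h / 2 * k2)
    k4 <- f(t0 + h, x + h * k3)
    x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  x
}

# independent scalar boundary-value oracle: shooting on the 2x2 Hamiltonian
# ODE with deSolve + uniroot, then trapezoid energy of u = -p/(2 rho).
# Entirely separate from the matrix-exponential path under test.
scalar_bvp_energy <- function(s, x0, xT, T = 1, rho = 1, n_steps = 1000) {
  rhs <- function(t, y, parms) {
    list(c(s * y[1] - y[2] / (2 * rho),
           2 * (xT - y[1]) - s * y[2]))
  }
  times <- seq(0, T, length.out = n_steps + 1)
  shoot <- function(p0) {
    out <- deSolve::ode(c(x0, p0), times, rhs, NULL, method = "ode45",
                        atol = 1e-12, rtol = 1e-12)
    out[nrow(out), 2] - xT
  }
  p0 <- uniroot(shoot, c(-1e3, 1e3), tol = 1e-12)$root
  out <- deSolve::ode(c(x0, p0), times, rhs, NULL, method = "ode45",
                      atol = 1e-12, rtol = 1e-12)
  u <- -out[, 3] / (2 * rho)
  h <- T / n_steps
  sum((u[-1]^2 + u[-length(u)]^2) / 2 * h) / n_steps
}
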