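test_that("stabilization yields a Hurwitz system with the expected spectrum", {
  # empty graph: S = -I
  s0 <- stabilize(connectome(matrix(0, 4, 4)))
  expect_equal(s0$S, -diag(4))

  # 2-node unit edge: lambda_max = 1, eigenvalues of S are -0.5 and -1.5
  w <- matrix(c(0, 1, 1, 0), 2, 2)
  s2 <- stabilize(connectome(w))
  expect_equal(s2$lambda_max, 1)
  expect_equal(sort(eigen(s2$S)$values), c(-1.5, -0.5))

  for (s in 1:50) {
    con <- random_connectome(12, seed = 800 + s)
    ev <- eigen(stabilize(con)$S, only.values = TRUE)$values
    expect_lt(max(Re(ev)), 0)
  }
  expect_error(stabilize(matrix(c(0, 1, 0, 0), 2, 2)), "symmetric")
})

test_that("maintaining the origin costs exactly nothing", {
  con <- random_connectome(10, seed = 1)
  sys <- stabilize(con)
  e <- transition_energy(sys, rep(0, 10), rep(0, 10), n_steps = 100)
  expect_identical(e, 0)
  expect_equal(state_stability(sys, rep(0, 10), n_steps = 100), Inf)
})

test_that("solver agrees with the independent scalar BVP oracle", {
  skip_if_not_installed("deSolve")
  sysS <- structure(list(S = matrix(-1, 1, 1), lambda_max = 0),
                    class = "stabilized_system")
  oracle <- scalar_bvp_energy(-1, 1, 0, T = 1, rho = 1)
  solver <- transition_energy(sysS, 1, 0, T = 1, rho = 1)
  expect_lt(abs(solver - oracle) / oracle, 1e-6)

  # a second, asymmetric instance
  oracle2 <- scalar_bvp_energy(-0.6, -0.4, 1.2, T = 2, rho = 0.5,
                               n_steps = 1000)
  sys2 <- structure(list(S = matrix(-0.6, 1, 1), lambda_max = 0),
                    class = "stabilized_system")
  solver2 <- transition_energy(sys2, -0.4, 1.2, T = 2, rho = 0.5)
  expect_lt(abs(solver2 - oracle2) / oracle2, 1e-6)
})

test_that("returned controls steer the system to the target (RK4 oracle)", {
  for (s in 1:20) {
    set.seed(900 + s)
    n <- sample(5:12, 1)
    con <- random_connectome(n, p = 0.5, seed = 900 + s)
    sys <- stabilize(con)
    x0 <- rnorm(n); xT <- rnorm(n)
    mask <- rep(TRUE, n)
    if (s %% 2 == 0) mask[sample(n, floor(n / 3))] <- FALSE
    prob <- control_problem(x0, xT, mask, n_steps = 4000)
    sol <- solve_optimal_control(sys, prob)
    xe <- rk4_endpoint(sys, sol, x0)
    expect_lt(sqrt(sum((xe - xT)^2)) / max(sqrt(sum(xT^2)), 1), 1e-3)
  }
})

test_that("nodal energy is nonnegative and zero outside the control set", {
  con <- random_connectome(10, p = 0.5, seed = 77)
  sys <- stabilize(con)
  set.seed(77)
  x0 <- rnorm(10); xT <- rnorm(10)
  mask <- rep(TRUE, 10); mask[c(2, 5, 9)] <- FALSE
  sol <- solve_optimal_control(sys, control_problem(x0, xT, mask,
                                                    n_steps = 200))
  expect_true(all(sol$nodal_energy >= 0))
  expect_equal(sol$nodal_energy[c(2, 5, 9)], rep(0, 3))
  expect_equal(sol$mean_energy, mean(sol$nodal_energy))
})

test_that("restricting the control set never lowers optimal energy", {
  viol <- 0
  for (s in 1:20) {
    set.seed(1000 + s)
    n <- 10
    con <- random_connectome(n, p = 0.5, seed = 1000 + s)
    sys <- stabilize(con)
    x0 <- rnorm(n); xT <- rnorm(n)
    small <- rep(TRUE, n); small[sample(n, 4)] <- FALSE
    e_full <- transition_energy(sys, x0, xT, n_steps = 200)
    e_small <- transition_energy(sys, x0, xT, small, n_steps = 200)
    if (e_full > e_small + 1e-9) viol <- viol + 1
    s_full <- state_stability(sys, x0, n_steps = 200)
    s_small <- state_stability(sys, x0, small, n_steps = 200)
    if (s_full < s_small - 1e-9) viol <- viol + 1
  }
  expect_equal(viol, 0)
})

test_that("time normalization makes energies grid-convergent", {
  con <- random_connectome(12, p = 0.5, seed = 55)
  sys <- stabilize(con)
  set.seed(55)
  x0 <- rnorm(12); xT <- rnorm(12)
  e1 <- transition_energy(sys, x0, xT, n_steps = 500)
  e2 <- transition_energy(sys, x0, xT, n_steps = 1000)
  # nodal integral scales with 1/n_steps by the chosen normalization
  expect_lt(abs(e2 * 1000 - e1 * 500) / (e1 * 500), 0.01)
})

test_that("lesion scan deltas are nonnegative and permutation-equivariant", {
  n <- 8
  con <- random_connectome(n, p = 0.5, seed = 66)
  sys <- stabilize(con)
  set.seed(66)
  x0 <- rnorm(n); xT <- rnorm(n)
  scan <- regional_lesion_scan(sys, x0, xT, n_steps = 150)
  expect_true(all(scan$energy_delta >= -1e-9))
  expect_gt(attr(scan, "energy_full"), 0)

  # relabeling nodes consistently permutes the deltas
  perm <- sample(n)
  w2 <- con$weights[perm, perm]
  sys2 <- stabilize(connectome(w2))
  scan2 <- regional_lesion_scan(sys2, x0[perm], xT[perm], n_steps = 150)
  expect_equal(scan2$energy_delta, scan$energy_delta[perm],
               tolerance = 1e-8)
})

test_that("excluded-set metrics reduce to full control for the empty set", {
  n <- 10
  con <- random_connectome(n, p = 0.5, seed = 88)
  sys <- stabilize(con)
  set.seed(88)
  x0 <- rnorm(n); xT <- rnorm(n)
  m0 <- excluded_set_metrics(sys, x0, xT, integer(0), n_steps = 200)
  expect_equal(m0$energy, transition_energy(sys, x0, xT, n_steps = 200))
  expect_equal(m0$n_excluded, 0)

  m1 <- excluded_set_metrics(sys, x0, xT, c(1, 4), n_steps = 200)
  m2 <- excluded_set_metrics(sys, x0, xT, c(1, 4), n_steps = 200)
  expect_identical(m1, m2)
  expect_gte(m1$energy, m0$energy - 1e-9)
  expect_error(excluded_set_metrics(sys, x0, xT, 1:n), "every node")
})

test_that("ill-conditioned and unreachable problems fail loudly", {
  con <- random_connectome(6, p = 0.6, seed = 5)
  sys <- stabilize(con)
  expect_error(control_problem(rnorm(6), rnorm(6),
                               control_set = rep(FALSE, 6)),
               "at least one")
})
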