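test_that("activation covariate is the signed mean difference", {
  x <- rnorm(20)
  expect_equal(activation_covariate(x, x), 0)
  expect_equal(activation_covariate(rep(0, 10), rep(1, 10)), 1)
  y <- rnorm(20)
  expect_equal(activation_covariate(x, y), -activation_covariate(y, x))
  expect_equal(activation_covariate(x, y, absolute = TRUE),
               abs(activation_covariate(x, y)))
})

test_that("repeated-measures model degenerates correctly and detects effects", {
  a <- rnorm(10)
  res <- rm_anova_covariate(a, a, covariate = rnorm(10))
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)

  expect_error(rm_anova_covariate(rep(1, 5), rep(0, 5)), "zero variance")

  # power at delta = 1 sd, n = 50
  set.seed(21)
  rej <- replicate(200, {
    b <- rnorm(50)
    a <- b + 1 + rnorm(50)
    rm_anova_covariate(a, b, covariate = rnorm(50))$p < 0.05
  })
  expect_gt(mean(rej), 0.9)
})

test_that("repeated-measures model keeps nominal type-I error", {
  set.seed(31)
  ps <- replicate(1000, {
    a <- rnorm(30)
    b <- rnorm(30)
    rm_anova_covariate(a, b, covariate = rnorm(30))$p
  })
  rate <- mean(ps < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("one-tailed paired t matches a hand-computed oracle", {
  a <- c(5.1, 4.8, 6.0, 5.5, 5.9, 6.2)
  b <- c(4.9, 4.4, 5.6, 5.6, 5.3, 5.8)
  d <- a - b
  t_hand <- mean(d) / (sd(d) / sqrt(length(d)))
  p_hand <- pt(t_hand, length(d) - 1, lower.tail = FALSE)
  res <- paired_t_one_tailed(a, b, "greater")
  expect_equal(res$t, t_hand, tolerance = 1e-10)
  expect_equal(res$p, p_hand, tolerance = 1e-10)

  # direction reversal complements the p-value
  res_l <- paired_t_one_tailed(a, b, "less")
  expect_equal(res$p + res_l$p, 1, tolerance = 1e-12)

  # constant positive difference with tiny noise: p below any fixed bound
  set.seed(41)
  a2 <- 1:10 + 1
  b2 <- 1:10 + rnorm(10, sd = 1e-6)
  expect_lt(paired_t_one_tailed(a2, b2, "greater")$p, 1e-10)
  expect_error(paired_t_one_tailed(1:5 + 1, 1:5, "greater"),
               "zero-variance")
})

test_that("regional ranks order lesioned impact correctly", {
  # single task, strictly ordered deltas: ranks equal the sort order
  scan <- data.frame(node = 1:6,
                     energy_delta = c(0.5, 0.1, 0.9, 0.3, 0.7, 0.05),
                     stability_delta = -c(0.5, 0.1, 0.9, 0.3, 0.7, 0.05))
  tab <- rank_regions(list(task1 = scan))
  expect_equal(tab$ranks[, 1, "energy"], rank(-scan$energy_delta))
  expect_equal(tab$ranks[, 1, "stability"], rank(-scan$energy_delta))
  expect_true(all(tab$mean_rank >= 1 & tab$mean_rank <= 6))
  # each slice is a permutation of 1..N
  expect_setequal(tab$ranks[, 1, "energy"], 1:6)

  # permuting regions permutes ranks identically
  perm <- c(3, 1, 6, 2, 5, 4)
  tabp <- rank_regions(list(task1 = scan[perm, ]))
  expect_equal(tabp$mean_rank, tab$mean_rank[perm])

  # missing lesions rank last with a warning
  scan2 <- scan
  scan2$energy_delta[2] <- NA
  expect_warning(tab2 <- rank_regions(list(t = scan2)), "ranked last")
  expect_equal(tab2$ranks[2, 1, "energy"], 6)
})

test_that("set mean-rank spin test behaves at its extremes", {
  g <- generate_coordinates(40, seed = 3)
  ens <- spin_rotations(g$coordinates, g$hemisphere, n_perm = 50, seed = 4)
  scan <- data.frame(node = 1:40, energy_delta = rnorm(40),
                     stability_delta = rnorm(40))
  tab <- rank_regions(list(t1 = scan))

  # the whole-network set is rotation invariant: p must be 1 (ties)
  res_all <- set_mean_rank_test(tab, 1:40, ens)
  expect_equal(res_all$mean_rank, mean(tab$mean_rank))
  expect_equal(res_all$p, 1)

  # identity-only ensemble gives degenerate p in {0, 1}... here 1 by ties
  id <- spin_rotations(g$coordinates, g$hemisphere, n_perm = 1, seed = 1,
                       identity_hook = TRUE)
  res_id <- set_mean_rank_test(tab, c(1, 5, 9), id)
  expect_true(res_id$p %in% c(0, 1))
})

test_that("planted rank structure is detected by the spin tests", {
  set.seed(51)
  g <- generate_coordinates(60, seed = 5)
  ens <- spin_rotations(g$coordinates, g$hemisphere, n_perm = 200, seed = 6)
  core <- c(1, 7, 13, 22, 35, 48)
  # construct lesion deltas that disfavor the core: tiny impact there
  delta <- runif(60, 0.5, 1)
  delta[core] <- runif(6, 0, 0.05)
  scan <- data.frame(node = 1:60, energy_delta = delta,
                     stability_delta = -delta)
  tab <- rank_regions(list(t1 = scan))
  res <- set_mean_rank_test(tab, core, ens, "greater")
  expect_lt(res$p, 0.05)

  # rank-degree style correlation with a planted aligned map
  map <- -delta + rnorm(60, sd = 0.05)
  mr <- map_rank_correlation(tab, map, ens)
  expect_gt(mr$r, 0)
  expect_lt(mr$p, 0.05)
})

test_that("map-rank correlation hits its closed-form extremes", {
  g <- generate_coordinates(30, seed = 7)
  ens <- spin_rotations(g$coordinates, g$hemisphere, n_perm = 20, seed = 8)
  scan <- data.frame(node = 1:30, energy_delta = runif(30),
                     stability_delta = runif(30))
  tab <- rank_regions(list(t1 = scan))
  expect_equal(map_rank_correlation(tab, tab$mean_rank, ens)$r, 1)
  expect_equal(map_rank_correlation(tab, -tab$mean_rank, ens)$r, -1)
  expect_error(map_rank_correlation(tab, rep(1, 30), ens), "zero-variance")
})

test_that("network mean ranks aggregate and test both directions", {
  g <- generate_coordinates(40, seed = 9)
  ens <- spin_rotations(g$coordinates, g$hemisphere, n_perm = 50, seed = 10)
  scan <- data.frame(node = 1:40, energy_delta = runif(40),
                     stability_delta = runif(40))
  tab <- rank_regions(list(t1 = scan))

  res1 <- network_mean_ranks(tab, rep(1, 40), ens)
  expect_equal(res1$mean_rank, mean(tab$mean_rank))

  labels <- rep(1:4, each = 10)
  res <- network_mean_ranks(tab, labels, ens)
  expect_equal(nrow(res), 4)
  expect_true(all(res$p_low >= 0 & res$p_low <= 1))
  expect_true(all(res$p_high >= 0 & res$p_high <= 1))

  # label permutation equivariance of the mean-rank vector
  perm <- sample(40)
  resp <- network_mean_ranks(
    structure(list(ranks = tab$ranks[perm, , , drop = FALSE],
                   mean_rank = tab$mean_rank[perm]),
              class = "regional_rank_table"),
    labels[perm], ens)
  expect_equal(sort(resp$mean_rank), sort(res$mean_rank))
})

test_that("paired effect size matches its definition and limits", {
  a <- rnorm(30)
  b <- rnorm(30)
  expect_equal(paired_effect_size(a, b), mean(a - b) / sd(a - b))
  expect_equal(paired_effect_size(a, b), -paired_effect_size(b, a))
  shift_base <- c(1, 2, 3, 4, 5)
  expect_equal(paired_effect_size(shift_base + 1, shift_base), Inf)
  set.seed(61)
  big_b <- rnorm(1e4)
  big_a <- big_b + rnorm(1e4, mean = 1)
  expect_lt(abs(paired_effect_size(big_a, big_b) - 1), 0.05)
})
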