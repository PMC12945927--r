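#' Study run configuration
#'
#' Bundles every knob of the end-to-end analysis: the synthetic cohort (or
#' a directory of inputs), the control-solver parameters, the rich-club
#' and reference-set definitions, and the permutation counts.
#'
#' @param cohort a [cohort_config] (simulate mode) or a directory path
#'   written by [write_cohort] (load mode).
#' @param T_values time horizons to analyze (default 1).
#' @param rho control penalization weight (default 1).
#' @param n_steps trajectory discretization (default 1000).
#' @param weighting connectome weighting scheme: "fa", "nos" or "binary".
#' @param richclub_mode "group", "individual-curve" or "individual-topk".
#' @param null_mode "spin", "profile-matched" or "sum-matched".
#' @param n_perm_network reference sets per subject for the network-level
#'   comparison (default 50).
#' @param n_perm_regional permutations for regional spin tests
#'   (default 1000; the full-scale analysis uses 10000).
#' @param n_nulls_richclub rewired nulls per rich-club curve (default 100).
#' @param alpha significance level (default 0.05).
#' @param seed master seed; all stage seeds derive from it.
#' @return a `run_config` list.
#' @export
run_config <- function(cohort = cohort_config(), T_values = 1, rho = 1,
                       n_steps = 1000,
                       weighting = c("fa", "nos", "binary"),
                       richclub_mode = c("group", "individual-curve",
                                         "individual-topk"),
                       null_mode = c("spin", "profile-matched",
                                     "sum-matched"),
                       n_perm_network = 50, n_perm_regional = 1000,
                       n_nulls_richclub = 100, alpha = 0.05, seed = 1) {
  stopifnot(all(T_values > 0), rho > 0, n_perm_network >= 1,
            n_perm_regional >= 1, n_nulls_richclub >= 20)
  structure(list(cohort = cohort, T_values = T_values, rho = rho,
                 n_steps = as.integer(n_steps),
                 weighting = match.arg(weighting),
                 richclub_mode = match.arg(richclub_mode),
                 null_mode = match.arg(null_mode),
                 n_perm_network = as.integer(n_perm_network),
                 n_perm_regional = as.integer(n_perm_regional),
                 n_nulls_richclub = as.integer(n_nulls_richclub),
                 alpha = alpha, seed = as.integer(seed)),
            class = "run_config")
}

# steps grow with the horizon (fixed step size), so the per-step energy
# normalization keeps magnitudes comparable across T settings
horizon_steps <- function(config, T) {
  max(50L, as.integer(round(config$n_steps * T)))
}

config_hash <- function(x) {
  # stable content hash without external digest dependencies
  raw <- serialize(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                    force = TRUE),
                   connection = NULL, version = 2)
  sprintf("%08x", sum(as.integer(raw) * (seq_along(raw) %% 251 + 1)) %%
            .Machine$integer.max)
}

load_or_simulate_cohort <- function(config) {
  cc <- config$cohort
  if (inherits(cc, "cohort_config")) {
    cohort <- generate_cohort(cc)
    list(cohort = cohort, cohort_config = cc,
         core_nodes = attr(cohort, "core_nodes"))
  } else if (is.character(cc)) {
    manifest <- jsonlite::read_json(file.path(cc, "manifest.json"),
                                    simplifyVector = TRUE)
    cfg <- do.call(cohort_config, manifest$config)
    cohort <- generate_cohort(cfg)   # regeneration is bit-identical
    list(cohort = cohort, cohort_config = cfg,
         core_nodes = manifest$core_nodes)
  } else stop("cohort must be a cohort_config or a directory path")
}

detect_rich_club <- function(cohort, config) {
  cc <- attr(cohort, "template")
  n <- n_nodes(cohort[[1]])
  assignments <- vector("list", length(cohort))
  sizes <- integer(length(cohort))
  for (i in seq_along(cohort)) {
    curve <- normalized_rich_club(cohort[[i]],
                                  n_nulls = config$n_nulls_richclub,
                                  alpha = config$alpha,
                                  seed = config$seed + 13L * i)
    assignments[[i]] <- if (!is.na(attr(curve, "k_max_phi"))) {
      individual_rich_club(curve, cohort[[i]])
    } else {
      # fallback when no significant regime: top-k at the cohort's
      # running mean size (or 10% of nodes before any size is known)
      k <- max(1L, round(mean(sizes[seq_len(i - 1)])))
      if (i == 1 || !is.finite(k) || k < 1) k <- max(1L, round(0.1 * n))
      individual_topk_rich_club(cohort[[i]], k)
    }
    sizes[i] <- sum(assignments[[i]]$member_flags)
  }
  mean_deg <- rowMeans(vapply(cohort, node_degree, numeric(n)))
  group <- group_rich_club(assignments, n, mean_degree = mean_deg)
  list(assignments = assignments, group = group,
       group_size = attr(group, "size"))
}

subject_rich_club <- function(det, i, con, config) {
  switch(config$richclub_mode,
         group = det$group,
         `individual-curve` = det$assignments[[i]],
         `individual-topk` = individual_topk_rich_club(
           con, max(1L, det$group_size)))
}

reference_sets <- function(connectome, members, config, subject_seed) {
  target <- which(members)
  switch(config$null_mode,
    spin = {
      ens <- spin_rotations(connectome$coordinates, connectome$hemisphere,
                            n_perm = config$n_perm_network,
                            seed = config$seed)
      spun_sets(target, ens)
    },
    `profile-matched` = lapply(seq_len(config$n_perm_network), function(j)
      profile_matched_set(connectome, target, seed = subject_seed + j)),
    `sum-matched` = lapply(seq_len(config$n_perm_network), function(j)
      sum_matched_set(connectome, target, seed = subject_seed + j)))
}

#' Within-task control analysis of the rich club
#'
#' The study's main loop: per subject and task, compute full-control state
#' stabilities and transition energies in both directions, repeat with the
#' rich club barred from control and with each of `n_perm_network`
#' size-matched reference sets barred, then compare rich-club-excluded
#' metrics against the per-subject mean over reference sets with the
#' repeated-measures model (activation-difference covariate) and one-tailed
#' paired post hocs. Subjects with a failed solve are excluded listwise and
#' counted in the provenance block.
#'
#' @param config a [run_config].
#' @return a `run_report` list: `subject_metrics` (long data.frame),
#'   `tests` (per task x measure), `rich_club` (detection results),
#'   `provenance`.
#' @export
run_within_task <- function(config) {
  inp <- load_or_simulate_cohort(config)
  cohort <- lapply(inp$cohort, reweight, scheme = config$weighting)
  attributes(cohort) <- attributes(inp$cohort)
  cc <- inp$cohort_config
  det <- detect_rich_club(cohort, config)
  T <- config$T_values[1]
  rows <- list()
  failed_subjects <- integer(0)
  for (i in seq_along(cohort)) {
    res <- tryCatch(
      subject_within_task(cohort[[i]], i, cc, config, det),
      error = function(e) NULL)
    if (is.null(res)) failed_subjects <- c(failed_subjects, i)
    else rows[[length(rows) + 1]] <- res
  }
  if (!length(rows)) stop("all subjects failed the control solve")
  metrics <- do.call(rbind, rows)
  tests <- within_task_tests(metrics, cc)
  structure(list(subject_metrics = metrics, tests = tests,
                 rich_club = det,
                 provenance = list(config_hash = config_hash(config),
                                   seed = config$seed,
                                   n_failed = length(failed_subjects),
                                   failed_subjects = failed_subjects,
                                   version = as.character(
                                     utils::packageVersion("richclubnct")))),
            class = "run_report")
}

subject_within_task <- function(con, i, cc, config, det) {
  sys <- stabilize(con)
  rc <- subject_rich_club(det, i, con, config)
  refs <- reference_sets(con, rc$member_flags, config,
                         subject_seed = config$seed + 1000L * i)
  T <- config$T_values[1]
  config$n_steps <- horizon_steps(config, T)
  out <- list()
  for (t in seq_len(cc$n_tasks)) {
    st <- generate_state_pair(con, cc, task_index = t,
                              seed = cc$seed + 1000L * i)
    cv <- activation_covariate(st$A, st$B)
    full <- list(
      stability_A = state_stability(sys, st$A, T = T, rho = config$rho,
                                    n_steps = config$n_steps),
      stability_B = state_stability(sys, st$B, T = T, rho = config$rho,
                                    n_steps = config$n_steps),
      energy_AB = transition_energy(sys, st$A, st$B, T = T,
                                    rho = config$rho,
                                    n_steps = config$n_steps),
      energy_BA = transition_energy(sys, st$B, st$A, T = T,
                                    rho = config$rho,
                                    n_steps = config$n_steps))
    rc_m <- condition_metrics(sys, st, which(rc$member_flags), T, config)
    ref_m <- lapply(refs, function(s)
      condition_metrics(sys, st, s, T, config))
    ref_mean <- colMeans(do.call(rbind, lapply(ref_m, unlist)))
    for (meas in names(full)) {
      out[[length(out) + 1]] <- data.frame(
        subject = i, task = t, measure = meas, covariate = cv,
        full = full[[meas]], rc_excluded = rc_m[[meas]],
        ref_excluded = unname(ref_mean[meas]))
    }
  }
  do.call(rbind, out)
}

condition_metrics <- function(sys, st, excluded, T, config) {
  n <- nrow(sys$S)
  mask <- rep(TRUE, n)
  mask[excluded] <- FALSE
  list(
    stability_A = state_stability(sys, st$A, mask, T, config$rho,
                                  config$n_steps),
    stability_B = state_stability(sys, st$B, mask, T, config$rho,
                                  config$n_steps),
    energy_AB = transition_energy(sys, st$A, st$B, mask, T, config$rho,
                                  config$n_steps),
    energy_BA = transition_energy(sys, st$B, st$A, mask, T, config$rho,
                                  config$n_steps))
}

within_task_tests <- function(metrics, cc) {
  combos <- unique(metrics[, c("task", "measure")])
  res <- lapply(seq_len(nrow(combos)), function(r) {
    sub <- metrics[metrics$task == combos$task[r] &
                     metrics$measure == combos$measure[r], ]
    an <- if (nrow(sub) >= 3) {
      rm_anova_covariate(sub$rc_excluded, sub$ref_excluded, sub$covariate)
    } else {
      # too few subjects for inference; report descriptives only
      list(F = NA_real_, p = NA_real_,
           direction = sign(mean(sub$rc_excluded - sub$ref_excluded)),
           mean_diff = mean(sub$rc_excluded - sub$ref_excluded))
    }
    dir <- if (an$direction >= 0) "greater" else "less"
    post <- tryCatch(
      paired_t_one_tailed(sub$rc_excluded, sub$ref_excluded, dir),
      error = function(e) list(t = NA_real_, p = NA_real_))
    data.frame(task = combos$task[r], measure = combos$measure[r],
               F = an$F, p = an$p, direction = an$direction,
               mean_diff = an$mean_diff, t_post = post$t, p_post = post$p,
               effect_size = paired_effect_size(sub$rc_excluded,
                                                sub$ref_excluded),
               n = nrow(sub))
  })
  do.call(rbind, res)
}

#' Between-task transition analysis
#'
#' Takes one representative state per task (state A by default) and
#' evaluates every ordered pair of tasks: transition energy with the rich
#' club vs. reference sets barred from control, the per-transition paired
#' effect size (positive when reference-set exclusion costs more), the
#' per-target-state mean effect size, and its correlation with the
#' target-state stability difference between the two exclusion conditions.
#'
#' @param config a [run_config]; the cohort must have >= 2 tasks.
#' @param representative "A" or "B": which state of each pair represents
#'   its task.
#' @return a `run_report` list with `transitions`, `by_target`,
#'   `stability_effect_correlation`, `provenance`.
#' @export
run_between_task <- function(config, representative = "A") {
  inp <- load_or_simulate_cohort(config)
  cohort <- lapply(inp$cohort, reweight, scheme = config$weighting)
  attributes(cohort) <- attributes(inp$cohort)
  cc <- inp$cohort_config
  if (cc$n_tasks < 2) stop("between-task analysis needs at least 2 tasks")
  det <- detect_rich_club(cohort, config)
  T <- config$T_values[1]
  config$n_steps <- horizon_steps(config, T)
  pairs <- expand.grid(from = seq_len(cc$n_tasks), to = seq_len(cc$n_tasks))
  pairs <- pairs[pairs$from != pairs$to, ]
  per_subj <- list()
  stab <- list()
  for (i in seq_along(cohort)) {
    con <- cohort[[i]]
    sys <- stabilize(con)
    rc <- subject_rich_club(det, i, con, config)
    refs <- reference_sets(con, rc$member_flags, config,
                           subject_seed = config$seed + 1000L * i)
    states <- lapply(seq_len(cc$n_tasks), function(t) {
      st <- generate_state_pair(con, cc, task_index = t,
                                seed = cc$seed + 1000L * i)
      st[[representative]]
    })
    mask_rc <- !rc$member_flags
    for (t in seq_len(cc$n_tasks)) {
      s_rc <- state_stability(sys, states[[t]], mask_rc, T, config$rho,
                              config$n_steps)
      s_ref <- mean(vapply(refs, function(s) {
        m <- rep(TRUE, length(mask_rc)); m[s] <- FALSE
        state_stability(sys, states[[t]], m, T, config$rho, config$n_steps)
      }, numeric(1)))
      stab[[length(stab) + 1]] <- data.frame(subject = i, task = t,
                                             stab_rc = s_rc,
                                             stab_ref = s_ref)
    }
    for (r in seq_len(nrow(pairs))) {
      x0 <- states[[pairs$from[r]]]
      xT <- states[[pairs$to[r]]]
      e_rc <- transition_energy(sys, x0, xT, mask_rc, T, config$rho,
                                config$n_steps)
      e_ref <- mean(vapply(refs, function(s) {
        m <- rep(TRUE, length(mask_rc)); m[s] <- FALSE
        transition_energy(sys, x0, xT, m, T, config$rho, config$n_steps)
      }, numeric(1)))
      per_subj[[length(per_subj) + 1]] <- data.frame(
        subject = i, from = pairs$from[r], to = pairs$to[r],
        energy_rc = e_rc, energy_ref = e_ref)
    }
  }
  trans <- do.call(rbind, per_subj)
  stab <- do.call(rbind, stab)
  by_pair <- lapply(seq_len(nrow(pairs)), function(r) {
    sub <- trans[trans$from == pairs$from[r] & trans$to == pairs$to[r], ]
    data.frame(from = pairs$from[r], to = pairs$to[r],
               effect_size = paired_effect_size(sub$energy_ref,
                                                sub$energy_rc),
               mean_energy_rc = mean(sub$energy_rc),
               mean_energy_ref = mean(sub$energy_ref))
  })
  by_pair <- do.call(rbind, by_pair)
  by_target <- stats::aggregate(effect_size ~ to, by_pair, mean)
  stab_by_task <- stats::aggregate(cbind(stab_rc, stab_ref) ~ task, stab,
                                   mean)
  stab_diff <- stab_by_task$stab_rc - stab_by_task$stab_ref
  corr <- if (nrow(by_target) >= 3 && stats::sd(stab_diff) > 0 &&
              stats::sd(by_target$effect_size) > 0) {
    ct <- stats::cor.test(by_target$effect_size,
                          stab_diff[by_target$to])
    list(r = unname(ct$estimate), p = ct$p.value)
  } else list(r = NA_real_, p = NA_real_)
  structure(list(transitions = by_pair, by_target = by_target,
                 subject_transitions = trans, stability = stab_by_task,
                 stability_effect_correlation = corr,
                 rich_club = det,
                 provenance = list(config_hash = config_hash(config),
                                   seed = config$seed)),
            class = "run_report")
}

#' Parameter sweep over time horizons and weighting schemes
#'
#' Repeats the within-task analysis per setting and tabulates the
#' time-normalized energies and the test outcomes side by side.
#'
#' @param config a [run_config]; the sweep covers `config$T_values` and
#'   `weightings`.
#' @param weightings weighting schemes to include (default: the config's).
#' @return a `run_report` list with one `tests` table per setting and a
#'   combined `summary` data.frame.
#' @export
run_parameter_sweep <- function(config, weightings = config$weighting) {
  settings <- expand.grid(T = config$T_values, weighting = weightings,
                          stringsAsFactors = FALSE)
  runs <- vector("list", nrow(settings))
  for (s in seq_len(nrow(settings))) {
    cfg_s <- config
    cfg_s$T_values <- settings$T[s]
    cfg_s$weighting <- settings$weighting[s]
    runs[[s]] <- run_within_task(cfg_s)
  }
  summaries <- lapply(seq_len(nrow(settings)), function(s) {
    tests <- runs[[s]]$tests
    cbind(T = settings$T[s], weighting = settings$weighting[s], tests)
  })
  structure(list(settings = settings, runs = runs,
                 summary = do.call(rbind, summaries),
                 provenance = list(config_hash = config_hash(config),
                                   seed = config$seed)),
            class = "run_report")
}
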