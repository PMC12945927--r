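#!/usr/bin/env Rscript
# Between-task transitions: one representative state per task, every
# ordered task pair, rich-club vs reference-set exclusion, per-transition
# paired effect sizes, and the correlation between per-target mean effect
# size and the target state's stability difference.

suppressPackageStartupMessages(library(richclubnct))

cfg <- run_config(
  cohort = cohort_config(n_subjects = 5, n_nodes = 60, core_size = 6,
                         n_tasks = 3, seed = 42),
  n_steps = 300, n_perm_network = 10, n_nulls_richclub = 100, seed = 42)

rep <- run_between_task(cfg)
dir.create("results/between_task", showWarnings = FALSE, recursive = TRUE)
utils::write.table(rep$transitions, "results/between_task/transitions.tsv",
                   sep = "\t", row.names = FALSE, quote = FALSE)
utils::write.table(rep$by_target, "results/between_task/by_target.tsv",
                   sep = "\t", row.names = FALSE, quote = FALSE)

cat("ordered between-task transitions (effect size > 0: reference-set\n")
cat("exclusion costs more energy than rich-club exclusion):\n")
print(rep$transitions, digits = 3)
cat(sprintf("\npositive effect sizes: %d of %d transitions\n",
            sum(rep$transitions$effect_size > 0), nrow(rep$transitions)))
cat(sprintf("per-target mean effect size vs stability difference: r = %.2f (p = %.3f)\n",
            rep$stability_effect_correlation$r,
            rep$stability_effect_correlation$p))
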