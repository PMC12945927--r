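#!/usr/bin/env Rscript
# The study's main question at desk scale: per subject and task, state
# stabilities and transition energies under full control, with the detected
# rich club barred from control, and with spin-rotated size-matched
# reference sets barred. Rich-club-excluded metrics are compared to the
# per-subject mean over reference sets with the repeated-measures model
# (activation-difference covariate) and one-tailed paired post hocs.

suppressPackageStartupMessages(library(richclubnct))

cfg <- run_config(
  cohort = cohort_config(n_subjects = 6, n_nodes = 60, core_size = 6,
                         n_tasks = 2, seed = 42),
  n_steps = 400, n_perm_network = 20, n_nulls_richclub = 100, seed = 42)

rep <- run_within_task(cfg)
dir.create("results/within_task", showWarnings = FALSE, recursive = TRUE)
utils::write.table(rep$subject_metrics,
                   "results/within_task/subject_metrics.tsv",
                   sep = "\t", row.names = FALSE, quote = FALSE)
utils::write.table(rep$tests, "results/within_task/tests.tsv",
                   sep = "\t", row.names = FALSE, quote = FALSE)
jsonlite::write_json(rep$provenance, "results/within_task/provenance.json",
                     auto_unbox = TRUE, digits = NA)

cat("per-task, per-measure comparison (rich club vs reference sets):\n")
print(rep$tests, digits = 3)
en <- rep$tests[grepl("energy", rep$tests$measure), ]
st <- rep$tests[grepl("stability", rep$tests$measure), ]
cat(sprintf(
  "\nenergy rows with rc-excluded < ref-excluded: %d of %d\n",
  sum(en$direction < 0), nrow(en)))
cat(sprintf(
  "stability rows with rc-excluded > ref-excluded: %d of %d\n",
  sum(st$direction > 0), nrow(st)))
cat("negative energy direction / positive stability direction reproduce\n")
cat("the passive-core expectation: barring the club from control perturbs\n")
cat("the system less than barring a size-matched reference set.\n")
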