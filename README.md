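# richclubnct

Does the structural connectome's rich club — the densely interconnected
set of high-degree hub regions — actually *drive* the control of brain
states, or is it a passive backbone that other regions steer? This package
implements the full analysis needed to answer that question with linear
network control theory, for researchers working on connectome topology and
brain-state dynamics:

* **Optimal control energy and state stability.** Linear dynamics
  `dx/dt = S x + B u` on a stabilized connectivity matrix
  `S = A/(1 + lambda_max(A)) - I`; the two-point optimal control problem

      min J = ∫₀ᵀ (x_T − x)ᵀ(x_T − x) + ρ uᵀu dt,  x(0) = x₀, x(T) = x_T

  solved exactly via the matrix exponential of the Hamiltonian system.
  Energy is the per-node integral of squared input, normalized by the
  number of timesteps and averaged over all N regions; stability of a
  state is the inverse of the energy needed to maintain it. The control
  matrix `B` is manipulable: full control, single-region lesions, or
  whole node sets barred from control (they stay in the dynamics).
* **Rich-club detection.** Weighted rich-club coefficient φʷ(k), nulls by
  Maslov–Sneppen rewiring with weights travelling on edges, normalized
  coefficient Φ(k), per-level exceedance p-values, the kmaxΦ cutoff, and
  individual, top-k, and frequency-based group-level club definitions.
* **Spatial null models.** Spin-rotation permutations of spherical region
  centroids (hemisphere-preserving bijections), spun size-matched
  reference sets, and connectivity-profile- or connection-sum-matched
  reference sets.
* **Inference.** Two-level repeated-measures comparison with an
  activation-difference covariate, one-tailed paired post hocs, paired
  Cohen's d, regional lesion ranks, and spin-tested rank–map correlations
  and per-network mean ranks.
* **A synthetic cohort generator** that plants a fully interconnected,
  *passive* core in distance-decayed random connectomes, with
  bi-hemispheric spherical coordinates and per-task state pairs of
  designed stability asymmetry — so the entire workflow runs, and is
  tested, without any neuroimaging data.

## Worked example

Detect the rich club of a synthetic cohort and ask whether barring it from
control hurts less than barring matched reference sets:

```r
library(richclubnct)

cfg <- run_config(
  cohort = cohort_config(n_subjects = 6, n_nodes = 60, core_size = 6,
                         n_tasks = 2, seed = 42),
  n_steps = 400, n_perm_network = 20, n_nulls_richclub = 100, seed = 42)
rep <- run_within_task(cfg)
rep$tests[, c("task", "measure", "F", "p", "direction", "effect_size")]
```

```
  task     measure     F      p direction effect_size
1    1 stability_A 0.514 0.5130         1       0.309
2    1 stability_B 8.749 0.0416        -1      -1.150
3    1   energy_AB 2.578 0.1836        -1      -0.703
4    1   energy_BA 4.791 0.0938        -1      -0.979
5    2 stability_A 0.251 0.6430         1       0.217
6    2 stability_B 2.401 0.1962        -1      -0.635
7    2   energy_AB 2.113 0.2197        -1      -0.599
8    2   energy_BA 4.451 0.1025        -1      -0.724
```

Every energy row has `direction = -1`: transitions cost *less* energy
when the rich club is barred from control than when a size-matched spun
reference set is barred — the club contributes less to control than
equally many peripheral regions. `F` and `p` come from the
repeated-measures model with the activation-difference covariate; at six
subjects only the strongest rows reach significance, which is the
expected behavior at this cohort size.

The regional view tells the same story. On a 60-region connectome with a
planted 6-region core (`analysis/04_regional_ranks.R`):

```
planted core mean rank 50.3 (grand mean 30.5), spin p = 0.0000

              map     r p_spin
1          degree 0.356  0.002
2   participation 0.268  0.040
3 communicability 0.257  0.032
```

Core regions occupy high ranks (rank 1 = most control impact, so high
rank = little impact), and regional degree correlates positively with
rank under spin permutation — high-degree regions contribute *less* to
state maintenance and transitions.

## The analysis workflow

Numbered drivers under `analysis/` run the study end to end at desk scale
and write their tables under `results/`:

| script | what it does |
|---|---|
| `01_simulate_cohort.R` | simulate and write the synthetic cohort |
| `02_detect_rich_club.R` | per-subject curves, group club, planted-core recovery |
| `03_within_task_control.R` | the main rich-club vs reference-set comparison |
| `04_regional_ranks.R` | lesion ranks, map correlations, network mean ranks |
| `05_between_task.R` | transitions across tasks, effect sizes by target state |
| `06_parameter_sweep.R` | robustness across time horizons and weightings |

Each is a thin narrative over the package's functions; everything they do
is callable directly.

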