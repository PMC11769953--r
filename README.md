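# dynstates

Dynamic brain-state analysis of resting-state fMRI with variational Bayes
hidden Markov models.

Parcellated rs-fMRI gives each subject a `T × N` matrix (volumes × regions;
e.g. 190 volumes at TR = 2 s over the 116 AAL regions). `dynstates` models
all subjects jointly with a K-state HMM whose states carry full-covariance
multivariate Gaussian observation models,

    z_t | z_{t-1} ~ A[z_{t-1}, ·],    x_t | z_t = k ~ N(μ_k, Σ_k),

fitted by variational Bayes under conjugate Dirichlet / Normal–Wishart
priors. One model is shared by the whole cohort (chains restart at each
subject's first volume), the number of states is selected by the minimum
variational free energy over K = 2…15, and each state is summarised by its
activation map (μ_k, in z-units), functional-connectivity matrix
(cov2cor(Σ_k), with 10-network block summaries), and per-subject temporal
profile:

* **FO** – fractional occupancy (posterior time fraction per state),
* **LT** – mean lifetime of Viterbi-path visits (TRs and seconds),
* **SR** – switching rate (state changes per TR),
* per-subject empirical transition matrices.

Two-group contrasts (e.g. patients vs controls) use nonparametric
permutation tests (5,000 label shuffles, difference of means) with
Benjamini–Hochberg FDR within each metric family, plus Spearman
correlations between state metrics and clinical scales (IBS-SSS, PHQ-9,
PASS) over patients. A synthetic-cohort generator with a known
ground-truth HMM — group-differential occupancy in two designated states,
one elevated transition entry, and symptom scores linked to occupancy —
backs every stage with recoverable truth. It is intended for researchers
studying disorders of gut–brain interaction (and any group-comparison
rs-fMRI design) who want a self-validating, scriptable state-dynamics
pipeline.

## Worked example

Generate the default synthetic cohort (35 patients + 31 controls,
190 × 20 series, 6 generating states), fit the 6-state model, and test the
group differences:

```r
library(dynstates)

co  <- generate_cohort(cohort_config(seed = 42))
co
#> <state_cohort> 35 patients + 31 controls, 190 x 20 series, K = 6 states

fit <- vb_fit(co$series, n_states = 6, n_init = 2, seed = 42)
fit
#> <vbhmm> K = 6 states, N = 20 regions, 66 subjects; free energy
#> 374222.2097 (converged after 6 iterations, init 1/2)

metrics <- temporal_metrics(fit$posterior)
res <- run_group_analysis(metrics, co$clinical, n_perm = 5000, seed = 42)
res
#> <group_analysis> 43 tests (11 significant at p_fdr < 0.05),
#> 36 correlations, 5000 permutations

dplyr::filter(tidy(res), significant)[1:5, ]
#>   family     state from_state to_state estimate   p_perm    p_fdr significant
#> 1 fo             4         NA       NA   0.119  0.000200 0.000600 TRUE
#> 2 fo             6         NA       NA  -0.147  0.000200 0.000600 TRUE
#> 3 lt             4         NA       NA   1.99   0.000400 0.00120  TRUE
#> 4 lt             6         NA       NA  -4.00   0.000200 0.00120  TRUE
#> 5 transition    NA          3        4   0.0700 0.000200 0.00150  TRUE
```

Reading the output: fitted state labels are arbitrary
(`match_states(fit, co$truth)` resolves them — here fitted state 4 is the
generator's raised state and fitted state 6 its lowered state). Patients
occupy the raised state ~12 percentage points more (FO +0.119, dwelling
~2 TRs = 4 s longer), occupy the lowered state less (−0.147), and show the
designed elevated transition into the raised state (entry +0.070 from the
generator's source state, fitted label 3). The raised state's occupancy
also correlates with symptom severity over patients:

```r
dplyr::filter(tidy(res, "correlations"), significant)
#>   clinical metric state   rho r_squared   p_value    p_fdr significant  n
#> 1 ibs_sss  fo         4 0.666     0.443 0.0000127 0.000152 TRUE        35
#> 2 ibs_sss  lt_tr      4 0.439     0.193 0.00831   0.0499   TRUE        35
```

`autoplot(res)`, `plot_metric_by_group(metrics, co$clinical, "fo")`,
`plot_state_fc(fit, k, load_network_table())` and
`plot_activation_maps(fit)` draw the standard figures;
`select_model_order(co$series, 2:15)` produces the free-energy curve
(`autoplot()`) behind the choice of K.

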