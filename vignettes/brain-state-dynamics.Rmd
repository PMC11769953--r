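---
title: "Dynamic brain-state analysis with variational Bayes HMMs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic brain-state analysis with variational Bayes HMMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynstates)
```

## The model

Resting-state fMRI signal, averaged within the regions of a parcellation,
yields one $T \times N$ matrix per subject (here $T = 190$ volumes at
TR = 2 s over $N$ regions of the 116-region AAL atlas, or a reduced region
count for desk-scale work). dynstates models these multivariate time series
with a hidden Markov model whose $K$ states each carry a full-covariance
multivariate Gaussian observation distribution:

$$z_t \mid z_{t-1} \sim A_{z_{t-1},\cdot},\qquad
  x_t \mid z_t = k \sim \mathcal N(\mu_k, \Sigma_k),$$

with initial distribution $\pi$. One model is shared by all subjects: the
series are concatenated, the forward--backward recursion restarts from
$\pi$ at every subject's first volume, and no transition is counted across
a subject boundary, so the states are group-level objects while every
subject retains an individual state time course. The state mean $\mu_k$ is
read as the state's activation map (in the z-units of the standardized
data, positive = above the region's temporal mean) and the correlation
matrix $D^{-1/2}\Sigma_k D^{-1/2}$ as its functional-connectivity pattern.

### Inference and model selection

Fitting is variational Bayes under conjugate priors: Dirichlet on $\pi$ and
on each row of $A$ (concentration 1 with a +10 "sticky" diagonal bonus that
discourages degenerate fast switching), and Normal--Wishart on
$(\mu_k, \Lambda_k = \Sigma_k^{-1})$ with mean-precision scale
$\beta_0 = 0.01$, degrees of freedom $N + 2$ (the smallest supporting a
finite expected covariance) and prior expected covariance equal to the
identity, matching standardized data. The E-step runs forward--backward
under the expected-log parameters; the M-step applies the conjugate count
updates; covariance updates add $10^{-6} I$ before inversion for numerical
safety.

The objective is the variational free energy
$F = -\log \tilde Z + \mathrm{KL}(q \,\|\, \text{prior})$, where
$\log \tilde Z$ is the chain evidence under the expected-log parameters.
$F$ is non-increasing across iterations (asserted for every fit in the test
suite), and at $K = 1$ the optimum attains the exact Normal--Wishart
marginal likelihood because the variational family then contains the true
posterior — the suite checks this against the closed form and an
independent sequential Student-t predictive product to $10^{-6}$.

The number of states is chosen by fitting every $K$ in 2–15 and taking the
minimum final free energy, ties toward smaller $K$ for parsimony. Each $K$
runs 5 deterministic initializations: greedy farthest-point center seeding
started from the observation maximizing a seeded random projection, refined
by 10 Lloyd iterations, then converted to soft responsibilities. This
initialization is invariant to subject order (all reductions are
row-order-free), which makes the whole fit reproducible bit-for-bit under a
fixed seed and invariant to subject permutation up to floating-point
summation order. Convergence is declared at a relative free-energy change
below $10^{-5}$ (at most 500 iterations). A simpler first-principal-
component quantile initialization was tried and discarded: with six
near-orthogonal state directions it routinely stalled in local optima and
distorted the model-order curve.

### State summaries

Per subject, the fitted posterior yields

* **Fractional occupancy (FO)** — fraction of time in each state, computed
  from the soft responsibilities (column means of $\gamma$);
* **Lifetime (LT)** — mean length of maximal constant runs of the hard
  Viterbi path, reported in TRs and seconds (TR = 2 s); states never
  visited are missing, not imputed;
* **Switching rate (SR)** — state changes per transition opportunity,
  $\#\{z_t \neq z_{t-1}\}/(T-1)$;
* **Empirical transition matrix** — normalized successor counts of the
  Viterbi path, rows of unvisited source states missing.

FO uses soft responsibilities because occupancy has a natural posterior
mean; LT, SR and transitions presuppose discrete runs and therefore use the
hard path. Both conventions are available (`true_path_posterior()` wraps
any hard path as one-hot responsibilities, where the two FO definitions
coincide exactly).

Group comparisons of transition probabilities use these per-subject
empirical matrices rather than the shared model's $A$ — a single shared
matrix admits no between-group test. Diagonal entries are excluded from
transition testing: self-persistence is lifetime's domain, and testing it
twice would double-count a nearly collinear quantity.

### Group statistics

Between-group differences (patients minus controls) are tested with a
nonparametric permutation test: difference of means, labels shuffled 5,000
times by default, two-sided $p = (1 + \#\{|T^\ast| \ge |T|\})/(n_{\rm perm}+1)$.
The pooled sample is sorted and the smaller group size is always the one
drawn, which makes the permutation stream invariant to within-group
ordering and to label swaps. Benjamini–Hochberg FDR is applied *within each
metric family* — FO across states, LT across states, transitions across
off-diagonal entries — a conservative, clearly delineated correction scope.
Spearman correlations between each state's FO/LT and the clinical scales
(IBS-SSS, PHQ-9, PASS) are computed over patients only (controls carry no
scale scores), with the large-sample t approximation for $p$ and FDR within
each clinical variable. Scale severity bands are provided as helpers:
IBS-SSS &lt;75 none / 75–175 mild / 176–300 moderate / &gt;300 severe;
PHQ-9 band floors 5/10/15/20.

## The synthetic cohort generator

Because subject-level data of the motivating study design are not publicly
deposited, the package ships a generator that emulates its conditions with
known ground truth: 35 patients and 31 controls, $T = 190$, TR = 2 s, a
6-state generating HMM, and 20 regions by default (116 available by
configuration; the model is dimension-agnostic, and 20 regions keep the
full model-order sweep at minutes on one CPU).

* **State means** lie on random orthogonal directions scaled so their
  per-region RMS equals `mean_separation` (default 1, in units of the
  unit observation noise) — orthogonality guarantees identifiability at
  moderate separation.
* **State covariances** are $I + vv^\top$ with a random unit-ish $v$ per
  state, so each state also has a distinct correlation structure.
* **Control dynamics**: diagonal stickiness 0.8 (expected dwell 5 TRs =
  10 s, a typical fMRI state timescale), off-diagonal mass uniform.
* **Group effect**: the patient matrix lowers one designated state's
  occupancy and raises another's. Its two designated rows are solved
  analytically so the patient chain's stationary distribution equals the
  control's *exactly* in every other state (occupancy $1/6 - 0.14$ and
  $1/6 + 0.14$ in the designated pair, $1/6$ elsewhere). The designated
  dwell times move with the row diagonals (0.20 and 0.87 versus 0.8).
* **Transition effect**: one entry (state 2 → state 6 by default) is
  elevated by 0.06. The extra mass is taken from the source row's other
  off-diagonal entries — depleting the entry into the lowered state first,
  then pro-rata — *not* from the diagonal: a diagonal source would shorten
  the source state's dwell time and leak a spurious occupancy difference
  into a state that is supposed to be null. The row is modified before the
  designated rows are solved, so the stationary guarantee includes it.
* **Clinical link**: patient IBS-SSS is a linear map of the normalized
  ranks of the raised state's true FO plus Gaussian noise
  (`clinical_effect` = 0.7 ≈ the induced Spearman correlation), rescaled to
  224 ± 50 and clipped to 0–500; any monotone link reproduces a positive
  rank correlation, and ranks are the least committal choice. PHQ-9
  (5 ± 4) and PASS (29 ± 16) share a latent anxiety factor so they
  correlate with each other; IBS-QOL is independent noise. Controls carry
  missing scores.

Effect magnitudes were fixed from an analytic power computation at
$n = 35/31$, $T = 190$ (per-subject FO standard deviation ≈ 0.07–0.13
under these autocorrelations), targeting ≥ 0.99 detection for the
designated FO/LT differences and ≈ 0.98 for the transition entry at the
FDR-adjusted thresholds. One caveat is inherent to FDR itself: with two
genuine effects among six FO tests, the chance that some null state slips
under the Benjamini–Hochberg step-up threshold is ≈ 10% per cohort, so
"exactly the designated states and nothing else" holds in about 90% of
cohorts — a ceiling no effect size can raise.

What the generator does *not* emulate: voxel-level imaging, physiological
noise, head motion, scanner drift, hemodynamic smoothing, or any
preprocessing upstream of parcellated series. Passing tests therefore
demonstrate correctness of the modelling and inference pipeline on data
that satisfy its assumptions, not robustness to real-world artefacts.

## Preprocessing conventions

File-based inputs are processed in a fixed order: discard the first 10
volumes (steady-state guard: 200 acquired → 190 analyzed), zero-phase
band-pass 0.01–0.08 Hz (4th-order Butterworth applied forward and backward
over a reflection-padded series — zero phase so state timing is not
displaced), then per-subject, per-region standardization using the sample
(n−1) standard deviation. Standardization is a documented convention, not a
given: it fixes the scale the Gaussian observation model and the activation
maps live on. Constant regions are centred, left at zero, and warned about.
Atlas and functional grids must already match; no resampling is performed.

Synthetic-mode runs skip all three steps by default: the generator emits
stationary series of exactly the target length on a common unit-noise
scale, filtering would smear the ground-truth state boundaries, and
per-subject standardization would distort the known state means that
recovery is judged against (its column scalings depend on realized state
occupancy).

## Numerical choices and edge cases

* Forward–backward and Viterbi run in compiled code with per-step scaling
  (stable beyond $T = 10{,}000$); both match exhaustive path enumeration to
  $10^{-10}$ on hundreds of random small instances in the suite.
* Expected-log parameters make the E-step's effective transition matrix
  sub-normalized; the chain log-normalizer absorbs this, which is the
  standard construction for a monotone free energy.
* Model-order ties break toward smaller $K$; a candidate that fails to fit
  is recorded as missing, warned about, and excluded from the argmin.
* Label switching between fits is resolved by `match_states()`: exact
  branch-and-bound assignment maximizing total correlation between matched
  state means.
* States never visited propagate missing values into group statistics;
  subjects missing a state are dropped from that state's LT test with a
  reported count.
* Degenerate inputs error early: all-constant regions (singular
  covariance), $K$ exceeding the total number of volumes, bands outside
  the Nyquist range, transition/occupancy targets that would require
  negative probability mass.

## Problem sizes used in validation

The test-suite and acceptance-script sizes are the package's chosen
desk-scale study conditions: the full selection sweep ($K = 2..15$, 5
initializations, 66 subjects × 190 × 20) runs in a few minutes; parameter
recovery uses 20 seeds at 16 subjects × 190 × 12; statistical calibration
uses 1,000 null permutation tests and 50 null cohorts; designed-effect
detection uses 20 cohorts analysed from their ground-truth paths plus one
full fit–decode–test run. Every empirical number quoted anywhere in the
documentation is computed by those tests or by `scripts/acceptance.R`.

## Known limitations

* The Gaussian observation model ignores temporal autocorrelation within
  states (no autoregressive observation model).
* One shared model across groups means group contrasts live entirely in
  the per-subject metrics, not in group-specific parameters.
* Free-energy model selection inherits variational bias; it is validated
  here by recovery, not against the exact evidence.
* The packaged AAL network assignment is a curated default for block
  summaries, standing in for study-specific assignments that are rarely
  published in full.
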