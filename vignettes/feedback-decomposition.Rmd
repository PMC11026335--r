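---
title: "Decomposing cortical feedback signals: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing cortical feedback signals: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(feedbackRSA)
```

## The problem this package addresses

When part of the visual field is occluded, the retinotopically
corresponding voxels in early visual cortex (V1/V2) receive no informative
feedforward input, yet their activity patterns still carry information:
*contextual* information about the visible surround arriving through
lateral connections, and *mnemonic* information about associated content
retrieved from memory and fed back from higher areas. In an occlusion
paradigm, participants view rooms whose lower corner is masked and retrieve
the object that belongs there, either via a newly learned arbitrary pairing
(episodic route) or via prior knowledge (semantic route). The analytic
question is how much of each signal component is present in the occluded
voxels, and how the composition differs between groups (e.g. age groups).

feedbackRSA implements the full analysis chain for this question —
multivariate decoding with cross-classification, representational
similarity analysis (RSA) with cross-validated Mahalanobis distances, and
differentiation-index statistics — together with a generative simulator
that produces cohorts whose contextual and mnemonic signal content is known
ground truth, so every estimator can be validated against what was planted.

## The experimental design

The design pairs 4 objects with 16 rooms. Eight rooms carry semantically
unrelated pairings (episodic trials) and eight carry congruent pairings
(semantic trials); each object appears in exactly two rooms of each half,
which is what makes the "same object, different room" and "different
object, different room" contrasts possible. `make_stimulus_set()`
randomizes the assignment under these constraints, emulating
counterbalancing across participants.

Two schedules are generated:

* **Occlusion task** (`make_occlusion_schedule()`): 4 runs, every room 6
  times per run in shuffled order, 4 s stimulus + 2 s inter-trial interval,
  i.e. 96 trials and 576 s per run.
* **Sensory template** (`make_sensory_schedule()`): one run showing all 16
  correct pairings unoccluded, 12 times each at 1.5 s + 1 s, i.e. 192
  trials and 480 s. It provides the feedforward reference patterns.

Trial order is a seeded uniform shuffle. Design-efficiency optimization of
the order matters only when estimating betas from real BOLD time series;
the default simulator works at the beta level and bypasses it. The episodic
and semantic rooms are shuffled jointly within each run, the simplest
reading of an intermixed presentation.

## The generative model

For trial $t$ with room $r(t)$ and object $o(t)$, the simulated voxel
pattern is

$$x_t = w_{\mathrm{ctx}}\, s_{r(t)} + w_{\mathrm{mne}}(\mathrm{type}(t))\,
s_{o(t)} + \varepsilon_t, \qquad \varepsilon_t \sim \mathcal N(0,
\sigma^2 I),$$

where $s_r$ and $s_o$ are unit-norm voxel signatures drawn once per
subject and ROI. On sensory-template trials both room and object are
physically on screen, so a single feedforward amplitude $w_{\mathrm{ff}}$
replaces both feedback amplitudes. Because signatures have unit norm, the
amplitudes are interpretable directly as per-component SNR against
$\sigma = 1$.

Signatures are Gram–Schmidt orthogonalized within type by default
(`orthogonalize = TRUE`) so that recovery tests are not confounded by
accidental collinearity between, say, two room signatures; raw Gaussian
directions are available behind the flag. With fewer voxels than
signatures, only the first `n_voxels` directions of a type can be mutually
orthogonal; the remainder are unit-norm only.

The default group presets (`inst/extdata/group_presets.json`, read by
`default_group_params()`) encode the qualitative contrast the package's
demo cohort emulates: the "older" preset has a weaker contextual amplitude
(0.45 vs 0.9), an equal episodic mnemonic amplitude (0.3), a stronger
semantic mnemonic amplitude (0.3 vs 0.15), a weaker feedforward amplitude
(0.6 vs 1.0) and more noise (1.2 vs 1.0). These are modelling choices, not
fitted values; they live in a config file rather than code so users can
swap presets without touching the package.

What the simulator deliberately does **not** emulate: spatial
autocorrelation between voxels, physiological (cardiac/respiratory) noise,
scanner drift at the pattern level, trial-order adaptation, or any
retinotopic structure — an ROI is an abstract voxel set. Tests that pass on
this simulator therefore validate the estimators' statistical behaviour
under the additive-signal model, not their robustness to every property of
real BOLD data.

## Single-trial estimation (optional realistic path)

`simulate_bold()` turns beta patterns into BOLD runs: each voxel's series
is the sum of HRF-convolved boxcars weighted by the trial betas, plus
low-frequency cosine drift and white noise. The HRF is the canonical
double-gamma (`hrf_kernel()`, peak near 5 s, undershoot near 15 s),
constructed on a 0.1 s grid and resampled to the scan grid by linear
interpolation, so a repetition time that does not divide the design
resolution is resampled rather than truncated.

`fit_lss()` recovers single-trial betas with a least-squares-separate
scheme: one GLM per trial, whose design contains the target trial's own
regressor, one regressor per room built from all of that room's onsets
**with the target trial removed from its room's regressor**, the nuisance
columns, a cosine high-pass basis (cutoff 128 s) and an intercept. Keeping
the target inside its room regressor would make the design exactly
collinear; removing it is the standard estimable formulation. Drift
columns and the intercept are additions relative to a minimal
motion-plus-compartment nuisance model; they make the beta contract a
single well-posed linear solve. Rank deficiency is detected via the QR
decomposition and reported with the names of the collinear columns.
Real-data nuisance regressors are accepted as a precomputed table
(`nuisance_set()`); they are never computed from images here.

## Decoding

Two families of binary problems are built from the stimulus set:

* **Contextual** (`build_contextual_scheme()`): per object, the two rooms
  paired with it within a trial type form the two classes. Train and test
  cells are identical; since both classes share the object, only room
  (contextual) information can support classification. Four problems per
  trial type.
* **Mnemonic cross-classification** (`build_mnemonic_scheme()`): per
  unordered object pair, training opposes one room of each object and
  testing opposes each object's *other* room. Train and test rooms are
  disjoint while the object pair is shared, so above-chance transfer can
  only ride on retrieved object information. Both room assignments are
  emitted: 12 problems per trial type.

`run_loro_cv()` evaluates a problem with leave-one-run-out
cross-validation: a binary linear max-margin classifier (fixed
regularization C = 1, no feature scaling by default since beta maps share
units; per-fold z-scoring behind a flag) is trained on the train cells of
all-but-one run and tested on the held-out run, each run serving as test
once. The default classifier is a compiled dual coordinate-descent solver
for the linear L1-loss SVM with an augmented bias term, with a
liblinear-style stopping rule; `engine = "libsvm"` switches to
`e1071::svm` with the identical contract, and the two engines are
cross-checked against each other in the test suite. A subject-level
accuracy is the unweighted mean over the problems of a scheme
(`decode_subject()`); the per-problem accuracies are retained so any other
aggregation can be computed downstream.

Group-level inference uses the two-step permutation/bootstrap approach:
`permutation_null()` permutes trial labels *within run* — the
exchangeability that run-wise cross-validation actually relies on — and
recomputes the full cross-validated subject accuracy per permutation
(default 100); `group_bootstrap_test()` then draws one null accuracy per
subject with replacement, averages across subjects (default 1000 draws)
and compares the observed group mean against the 99.9th percentile of this
null (p < 0.001 decision rule; the quantile is configurable). A one-sided
one-sample t test against chance (`accuracy_ttest()`) is provided
alongside.

## Representational similarity analysis

`crossnobis_rdm()` computes cross-validated Mahalanobis distances for the
occlusion task. For conditions (rooms) $i, j$ and run pair $(A, B)$ the
contribution is

$$d_{ij}^{(A,B)} = (\hat\mu_{Ai} - \hat\mu_{Aj})^\top \Sigma^{-1}
(\hat\mu_{Bi} - \hat\mu_{Bj}) / P,$$

averaged over all unordered run pairs, where $\hat\mu$ are per-run
condition means and $P$ the voxel count. Because the two factors carry
independent noise, the estimator is unbiased: its expectation is zero when
the true patterns are equal, and entries can legitimately be negative.
The noise covariance $\Sigma$ is estimated from within-run, within-condition
residuals and shrunk toward its diagonal with an analytically chosen
intensity (a Schäfer–Strimmer-style estimator, written here because no
installed package provides one); `noise_cov = "diag"` and `"identity"`
(cross-validated Euclidean) are available, the latter mainly for tests
where the metric must reduce to a closed form.

Pairing *individual trials* while cross-validating over runs requires a
choice, since a trial exists in only one run: the package uses
condition-matched fold estimates (the per-run condition mean) assigned
back to trial pairs. A 96 × 96 trial-wise matrix (`mode = "trial"`,
labelled by a reference run's trial order) is therefore the condition
matrix expanded to trials — same-condition pairs sit at exactly zero — and
`mode = "condition"` returns the compact 16 × 16 form. Both modes are
exposed and the mode used is recorded in the result.

`pearson_rdm()` computes 1 − Pearson correlation between trial patterns
for the single-run sensory template.

Model RDMs (`build_model_rdm()`) are binary ideal patterns with exclusion
masks. The contextual model expects minimal dissimilarity (0) for
same-object–same-room pairs and maximal (1) elsewhere. The mnemonic model
expects 0 for same-object–different-room pairs and 1 for
different-object–different-room pairs, and *excludes*
same-object–same-room pairs so that room similarity cannot artificially
deflate an object-driven correlation. The diagonal is always excluded, as
are pairs involving trials outside the requested trial type.
`fit_model()` Spearman-correlates neural and model dissimilarities over
the included upper triangle (the matrices are symmetric, so the full
matrix would double-count) and Fisher-z-transforms the coefficient;
$\rho = \pm 1$ is capped at $\mathrm{atanh}(1 - 10^{-12})$ to keep z
finite. Group-level fits are tested against zero with Wilcoxon signed-rank
tests.

## Differentiation indices

`differentiation_index()` is mean between-object dissimilarity minus mean
within-object dissimilarity: higher values mean more distinct object
representations. For feedback (crossnobis) RDMs the default `pair_policy =
"different_room"` counts only same-object pairs from *different* rooms as
"within", mirroring the mnemonic model's exclusion — under the
condition-matched crossnobis convention same-room pairs are exactly zero
and would otherwise deflate the within mean mechanically. The literal
"all same-object pairs" reading is available as `pair_policy = "all"`, and
the policy used is recorded in the output tables. Feedback DIs are
computed per trial type; the feedforward DI used for cross-pathway
correlation is computed once per subject and ROI (the sensory run does not
distinguish trial types), though per-type feedforward DIs are also
emitted.

DIs are z-scored within group × ROI × pathway × trial type strata
(`zscore_and_flag_outliers()`; group-pooled strata behind the `by`
argument) and records beyond 3.29 SD — the most extreme 0.1% of a normal —
are flagged and excluded from correlations. `ff_fb_correlation()` then
Spearman-correlates (one-sided, positive direction, per the hypothesis
that a shared mechanism degrades both pathways) feedforward against
episodic and semantic feedback DIs per group × ROI, adjusting the family
of p-values with Benjamini–Hochberg (`bh_adjust()`, a wrapper around
`p.adjust`).

## Exact small-sample tests

`wilcoxon_vs_zero()` computes the signed-rank null exactly for up to 25
non-zero values via a generating-function convolution over the doubled
(hence integer) average ranks — equivalent to enumerating all $2^n$ sign
patterns, ties included — and switches to a tie-corrected normal
approximation with continuity correction above. `spearman_test()`
enumerates all $n!$ rank permutations for $n \le 8$ (configurable up to
10) and otherwise uses the t approximation on $n - 2$ degrees of freedom.
Both are validated in the test suite against naive brute-force enumeration
and against the corresponding `stats` functions where those are exact.

## Pipeline and reproducibility

`pipeline_config()` validates every setting up front (unknown keys are
rejected; invalid sizes fail before any simulation starts) and
`run_pipeline()` executes simulate → (optional BOLD + LSS) → decode → RSA
→ DI in dependency order, producing tidy one-row-per-observation tables
ready for external mixed-model fitting, plus a manifest with the config
fingerprint, seed, package version and timestamp. Seeding is hierarchical
and counter-based (`derive_seed()`): master seed → per-subject → per-stage
streams, so adding subjects or stages never perturbs existing streams, and
two runs with the same config and seed produce identical tables in
direct-beta mode. A thin command-line wrapper
(`inst/scripts/feedback-pipeline.R`, verbs `run-all` and `simulate`)
exposes the pipeline to shell users; the remaining stages are plain
function calls on saved intermediates.

```{r, eval = FALSE}
cfg <- pipeline_config(n_per_group = 10,
                       groups = default_group_params(n_voxels = 20),
                       seed = 1, output_dir = "results")
res <- run_pipeline(cfg)
summary(res)
```

## Problem sizes, calibration and power

The test suite validates the statistical machinery at the design's scale
where that is cheap (schedule arithmetic, chance-level decoding with 50
voxels and the full 4 × 96 schedule) and at deliberately reduced scale
where a property needs hundreds of Monte-Carlo repetitions. The sizes are
the package's own choices, recorded here:

* **Type-I calibration** of the permutation/bootstrap test: 200 replicate
  zero-signal cohorts of 20 subjects, 16 voxels, 3 repetitions per room
  per run, 40 permutations, 500 bootstrap draws, at an α = 0.05 analogue
  of the decision rule. The acceptance bound (≤ 7.5%) is the binomial 99%
  upper bound for a nominal 5% rate at 200 repetitions.
* **Selectivity dissociation**: 20 subjects per scenario at 50 voxels and
  full schedule, 30 permutations, 500 bootstrap draws.
* **Crossnobis unbiasedness**: 1000 simulated subjects at 8 voxels,
  3 runs × 32 trials.
* **Parameter recovery**: 3-point amplitude grids × 20 seeds for the
  monotonicity of model-fit z in the generating amplitudes; and 200
  repetitions of a 40-subject cohort for the feedforward–feedback DI
  correlation.

For the DI-correlation recovery, per-subject amplitudes are log-normal,
$w_{\mathrm{mne,epi}} = 0.8\,e^{a}$ and $w_{\mathrm{ff}} = 1.0\,e^{b}$
with $(a, b)$ standard bivariate normal with correlation
$2\sin(\pi/12) \approx 0.518$, which makes the generating *Spearman*
correlation exactly 0.5. The amplitude base levels and unit log-spread
were fixed by a design-stage reliability analysis: the episodic feedback
DI is estimated from only four within-object room pairs, so weaker
mnemonic amplitudes leave its between-subject ranking too noisy for the
rank correlation, once attenuated by both DIs' measurement error, to reach
the targeted 80% power at n = 40.

## Numerical choices and edge cases

* Crossnobis requires ≥ 2 runs with every room present in each run;
  a singular covariance (even after shrinkage) is reported with advice to
  increase the shrinkage intensity.
* `pearson_rdm()` refuses zero-variance pattern rows, naming the trial.
* `fit_model()` requires ≥ 3 included cells and identical trial orderings.
* Spearman ties use average ranks everywhere; the exact permutation null
  is conditional on the observed tie pattern.
* A stratum of identical DIs yields z = 0 for all members and no outlier
  flags.
* The compiled SVM solver shuffles coordinate order with a private
  generator, so results are bit-reproducible and independent of R's RNG
  state.

## Known limitations

* The simulator's additive, spatially white model understates the
  difficulty of real-data decoding; absolute accuracies here do not
  transfer to real cohorts.
* The condition-matched crossnobis convention pins same-room pairs at
  exactly zero in trial mode; analyses that need within-condition trial
  variability should use the beta patterns directly.
* Group contrasts (mixed models etc.) are out of scope by design; the
  tidy tables are the hand-off point.
* The BOLD path models drift and white noise only — no motion, spikes or
  autocorrelated noise — and is intended for validating the LSS estimator,
  not for realistic power studies.
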