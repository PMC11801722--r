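---
title: "Methods: salient-distractor population analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: salient-distractor population analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(salpop)
```

This vignette documents the statistical models, the synthetic-data
generator, the numerical choices, and the known limitations of `salpop`. It
is the companion to the function reference: the reference says *what* each
function computes, this document says *why* it is computed that way.

## The task and the data model

The package analyses trial-based population recordings from a free-viewing
visual search task: after fixation and a cue, an array of 8 stimuli appears
on a rhombus (positions indexed 0–7, position 0 at the right horizontal
meridian, counterclockwise), one stimulus is the target, and on
singleton-present and mixed-colour displays one non-target stimulus is a
colour oddball. The subject scans freely until fixating the target; search
time is the interval from array onset to the start of target fixation.
Units are labelled per trial by what their receptive field (RF) contained
(target, salient distractor, non-salient distractor) and by whether the
first saccade went toward or away from the RF. All analyses of stimulus
encoding use only trials with the first saccade away from the RF, so that
presaccadic activity reflects the RF stimulus rather than saccade
preparation.

## Synthetic sessions with planted ground truth

`make_unit_population()` + `simulate_session()` generate sessions in which
every downstream quantity has a known planted value. The rate of unit *i*
on a 1-ms grid is

```
lambda_i(t) = b_i * (1 + (g_i - 1) * a(t)) * s_i(t)  +  r * a(t) * (wT_i[target] + wS_i[singleton])
```

with baseline `b_i` (uniform 20–40 spikes/s), visual gain `g_i` (uniform
2.5–3.5), visual onset profile `a(t)` ramping 0→1 over 40–60 ms, the
archetype singleton-gain `s_i(t)` applied only when the singleton occupies
the RF, and additive location tuning scaled by `r` (40 spikes/s per tuning
unit, tuning weights with SD 0.5). Spikes are drawn per 1-ms bin as
independent Poisson counts, which makes window counts exactly Poisson (the
Fano-factor property test). Rates are floored at 0.5 spikes/s; with the
default parameters the floor essentially never binds, which matters for the
geometry guarantees below.

Choices worth recording:

- **Tuning strength.** The defaults give spatial modulation of roughly
  15–20% of the visual response. This is the regime in which a population of
  ~100 units decodes 5 locations at well above 80% — the regime reported for
  these areas — while single-trial counts remain realistically noisy.
- **Archetype gain shapes.** Four temporal archetypes: `suppression` (gain
  dips to 0.7 from 60 ms), `early_enh_late_supp` (gain >1 over 25–100 ms,
  <1 over 125–300 ms), `enhancement` (gain >1 from 85 ms), and
  `nonselective` (gain 1). All profiles equal 1 outside 0–300 ms. The onset
  latencies are free parameters chosen to qualitatively match the cluster
  shapes these analyses are meant to separate.
- **Planted geometry.** Target- and singleton-location tuning matrices are
  `W = U A`, with `U` an orthonormal `N x d_true` basis and `A` location
  coefficients that are (i) centred across positions, so row-centring a
  condition matrix does not change the planted span, and (ii) isotropic
  within the span (random orthonormal rows), so every direction of the
  planted subspace carries equal variance. The singleton basis is rotated
  against the target basis so that all principal angles equal
  `acos(sqrt(overlap))`: the planted shared-variance fraction equals
  `overlap` exactly, with `overlap = 0` giving fully orthogonal subspaces
  and `overlap = 1` identical ones. `planted_condition_patterns()` exposes
  the exact noiseless patterns for recovery tests.
- **Behaviour.** First-saccade destinations follow configurable
  probabilities (default: 60% to the target, 1.5% to the singleton —
  singleton avoidance — remainder uniform). Search time is log-normal per
  display type (medians 340/380/360 ms for singleton-present / absent /
  mixed); on singleton-bearing displays its location parameter decreases
  with a per-trial latent efficacy that simultaneously deepens the
  singleton gain modulation (`coupling = 0.6`, `search_beta = 0.25`). This
  plants the fast/slow median-split effect: trials with stronger distractor
  suppression end sooner. No generative behavioural model is claimed beyond
  this coupling.
- **Trial counts** are configurable per display type (default 40 each).
  Analyses that need per-location trial depth (decoding, subspaces,
  median splits) are run on sessions with more singleton-present trials
  (100–320 in the tests); those problem sizes are stated in the test files
  themselves.
- **Eye traces** are sampled at 120 Hz, the rate of the recording system
  being emulated: fixational Gaussian jitter (SD 0.02 deg per sample) plus
  sigmoidal saccade displacements whose duration scales with amplitude
  (`10 + 2*amplitude` ms), so a 1-degree saccade still crosses the 50 deg/s
  detection threshold at 120-Hz central differences.

What the generator does **not** emulate: noise correlations between units
(each unit's spikes are conditionally independent given the trial), cue and
delay-period dynamics, realistic saccade kinematics beyond threshold
crossing, drift or nonstationarity across a session, and multi-saccade scan
paths (one corrective saccade at most). Passing recovery tests on this
generator therefore shows the estimators are correct and calibrated, not
that real cortical data will show any particular effect size; in
particular, decoding results on correlated populations can differ
substantially from the independent-unit case.

## Preprocessing conventions

- All analysis windows are half-open `[a, b)` in ms relative to array onset
  (so adjacent windows never double-count a bin), except the subspace
  window, which is the inclusive 51-point grid 150–200 ms (below).
- Spike-density functions convolve spike trains with a Gaussian
  (`sigma = 10` ms, truncated at 4 sigma, no edge renormalisation);
  smoothing is linear and conserves spike mass up to truncation error.
- Saccade detection uses central differences on the position samples —
  the simplest unbiased velocity estimate at 120 Hz; no additional
  filtering. An event requires speed > 50 deg/s, start-to-end displacement
  ≥ 0.4 deg, duration ≥ 8 ms; suprathreshold runs separated by ≤ 10 ms are
  merged. The merge gap and minimum duration are conventions (configurable),
  not measurements.
- Normalisation divides a unit's rates by the maximum of its condition-mean
  rate over 40–200 ms, making it idempotent; all-zero units are flagged and
  excluded rather than producing NaNs.
- Units enter an analysis only with ≥ 10 trials per condition, and the
  responsiveness screen is a paired t test of 40–120 ms versus −150–0 ms at
  α = 0.05.

## Per-unit statistics

**AUROC.** The ROC curve is built by sweeping an integer spike-count
criterion and plotting the per-condition exceedance proportions; ties at
the criterion contribute one half, which makes the area identical to the
Mann–Whitney `U/(n1*n2)` statistic. The package keeps both routes: the
sweep is the estimator, the rank identity is verified exhaustively in the
tests, and the (mathematically identical) rank form is used inside the
500-shuffle permutation nulls where the sweep would be needlessly slow.
Population inference draws one null value per unit and averages across
units, 1,000 times, giving a two-sided permutation p per time bin,
corrected with Benjamini–Hochberg across bins at q = 0.05.

**Effect size.** For Wilcoxon tests the package uses `r = z / sqrt(n)`.

**ω² (percent explained variance).** One-way ANOVA across the 5
contralateral locations per 50-ms window (10-ms steps):
`ω² = (SS_between − df·MSE)/(SS_total + MSE)`. Being unbiased, ω² can be
negative under the null; values are deliberately not clipped, because the
permutation z-score (200 label shuffles; z = (ω² − null mean)/null SD)
relies on the unclipped distribution. A unit is selective at z > 1.645
(one-tailed) within 150–200 ms, strictly: a z exactly at the threshold does
not count. **Caveat:** because the singleton never occupies the target's
position, the two location factors are not independent; strong tuning for
one factor leaks a small amount of explained variance into the other,
slightly inflating the mixed-selective count. This is a property of the
task design itself, visible on synthetic data with planted single-factor
tuning.

**Latency.** The first of 5 consecutive significant 5-ms bins, per-bin
one-sample t tests Bonferroni-corrected over the bins at or after 0 ms
(the family size is the bin count in the analysis window — a convention,
configurable). Latency differences between groups are tested by permuting
group labels and comparing median latencies.

## Profile clustering

Profiles are per-millisecond two-sample t values (pooled variance;
degenerate bins get t = 0) for singleton versus non-salient distractor in
the RF. Inclusion requires ≥ 10 consecutive individually significant 1-ms
bins (α = 0.05, uncorrected — the screen is deliberately liberal and,
because the smoothed rates are autocorrelated over ~2 kernel widths, it
passes an appreciable minority of null units; the clustering step is what
separates structure from noise). Units with baseline differences between
the conditions (t test at α = 0.1 on −150–0 ms) are excluded as unstable.

Clustering follows the PhenoGraph recipe: K = 40 nearest neighbours by
Euclidean distance, edges weighted by the Jaccard index of neighbour sets,
Louvain modularity maximisation at resolution 1 with a fixed seed. The
cluster count is emergent. Two safeguards: communities smaller than 3 units
are merged into the nearest-centroid cluster, and a degenerate input with
all profiles identical returns a single cluster directly. Labels are
0-based and ordered by decreasing cluster size.

## Decoding

A linear SVM (cost 1 — the conventional default; the margin scale matters
little after min-max scaling) with stratified 5-fold cross-validation on
balanced pseudo-trials (10 per label, 50 resamples). Features are scaled to
\[0, 1\] using the range over *all* samples, with the same scaling applied
to train and test folds. This joint scaling leaks range information across
the train/test split; it is implemented this way because it is the stated
procedure of the analyses being reproduced, and `scale_train_only = TRUE`
provides the leakage-free variant. One practical consequence, visible in
the calibration tests: with strongly structured data and few samples,
label-permuted accuracy sits slightly above chance (permutations partially
realign with the true structure, and accuracy is convex in that overlap),
so chance calibration is tested at 40+ samples where the effect is within
±1%.

Significance over time uses a two-sided cluster-based permutation test:
per-bin one-sample t statistics of paired differences across resamples,
cluster-forming threshold at the two-sided α = 0.05 t quantile, cluster
statistic = summed t, and a max-|cluster| null from random sign flips of
the per-resample difference series. Fold assignment within a resample is
stratified with a logged seed.

## Subspace geometry

The condition matrix stacks per-location mean rates on the inclusive
150–200 ms 1-ms grid (5 locations × 51 time points = 255 rows × N units),
column-centred. Covariances are computed from these condition means —
single trials enter only through projected decoding. All captured-variance
quantities are alignment indices, `Tr(QᵀCQ)` normalised by the top-d
eigenvalue sum of `C` (the most any d-dimensional subspace can capture, so
`A ∈ [0, 1]` by the Poincaré separation theorem; this bound is asserted on
every fit).

Three fits, all on the Stiefel manifold of orthonormal frames:

1. **Orthogonal pair**: a joint `N x 2d` frame whose two d-blocks maximise
   the summed normalised variances; block orthogonality is inherited from
   the frame constraint rather than penalised.
2. **Exclusive**: maximise one context's normalised variance subject to the
   other's staying below `v = 0.01`. The constraint is handled by an
   exterior quadratic penalty `mu * max(0, A_limit - v)^2` with `mu`
   raised 10× per continuation step (10² to 10⁸) until the returned point
   satisfies `A_limit ≤ v + 1e-4`; feasibility is verified post hoc and
   infeasible problems (the limit covariance dominating every direction)
   are reported with the minimal achievable limit variance. A finite
   penalty weight leaves the solution a hair outside the boundary, which is
   why the post-hoc tolerance exists.
3. **Shared**: within the orthogonal complement of both exclusive bases,
   the objective is a single quadratic trace, so the optimum is computed
   exactly as the top-d eigenvectors of the complement-projected sum of
   normalised covariances — no iteration, and the orthogonality residual is
   machine precision.

The optimiser itself is projected Riemannian gradient ascent with QR
retraction (sign-fixed R diagonal for determinism), Armijo backtracking
(objective is non-decreasing by construction), a doubling/halving step
heuristic, convergence at gradient norm ≤ 1e-6 or 500 iterations, and
principal-component initialisation plus 5 random restarts with the best
objective kept. For `d = 1` at small N it matches an exhaustive grid search
to within 1% of the objective (tested); `fit_shared`'s closed form is exact.

Whether projected-activity decoding should fit `Q` on held-out data is left
to the caller: the tests fit on planted (noiseless) covariances or held-out
sessions, because an in-sample fit lets condition-mean noise leak decodable
information into the cross-projection. A related subtlety on *any* fit: on
singleton-present trials the singleton's position itself carries
information about the target's position (they never coincide), so
cross-context decoding is tested on singleton-absent trials where that
channel is absent.

`d = 5` is the conventional dimension (and the planted `d_true` default);
it is a configuration parameter, not an estimate — no dimensionality
selection is performed.

## Behaviour

First-saccade-to-singleton rates are tested against the 1/8 random-search
expectation by chi-squared; search times compared across display types by
Wilcoxon rank-sum. The fast/slow median split is computed within each
display type (search-time distributions differ by display, so pooling would
confound display with speed; a pooled option exists). Trials tied at the
median are assigned alternately to the smaller side, keeping the imbalance
at most 1; an all-tied condition is an error rather than an arbitrary
split.

## Pipeline

`run_pipeline()` chains simulate → preprocess → unit stats → clustering →
decoding → subspaces → behaviour, writes every table plus `config.json` and
`report.md`, and is byte-deterministic given a seed (each stage derives its
own child seed). Stage failures abort with the stage name, keeping completed
outputs. The `stages` argument exposes the same surface a subcommand CLI
would; the package deliberately ships functions rather than a shell tool,
since its users drive analyses from R.

## Problem sizes and limitations

The shipped tests run on deliberately small problems (tens of units,
100–320 singleton-present trials, single windows where a time course is not
the point); these sizes are the package's chosen trade-off between
statistical resolution and a test suite that runs in minutes, and each test
states its own sizes. Known limitations: no noise-correlation-aware
decoding; no time-resolved (sliding-window) subspaces; no Leiden refinement
or consensus clustering; the AUROC is the plain empirical estimator (no
bias correction); and the exclusive-subspace solution is only guaranteed
feasible to the stated post-hoc tolerance, not exactly on the boundary.
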