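---
title: "Methods: the torsadex TdP-risk pipeline"
author: "torsadex authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the torsadex TdP-risk pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`torsadex` implements a CiPA-style in-silico pipeline for classifying the
torsades de pointes (TdP) risk of drugs, together with a Shapley-value
explainability layer. This vignette documents the models and procedures, the
parameters that matter, the numerical choices, and what the synthetic-data
generators do and do not emulate.

## 1. Dose–response stage

Fractional block of an ionic current at drug concentration $D$ follows the
Hill equation

$$\mathrm{block}(D) = \frac{1}{1 + (IC_{50}/D)^h},$$

with the zero-dose limit defined as 0. Conductances are rescaled as
$g_i = g_{i,\mathrm{control}}\,(1-\mathrm{block})$ at a configurable multiple
(1–4×) of the drug's free plasma Cmax.

**Posterior sampling.** `fitHillMCMC()` samples $(\log IC_{50}, \log h)$ —
and $\log\sigma$ when the measurement noise is not supplied — by
random-walk Metropolis:

- *Likelihood*: Gaussian on fractional block. Assay protocols rarely report
  a noise model, so a Gaussian on the (clipped) fraction is the least
  structured choice; $\sigma$ can be fixed or given a half-normal(0.1) prior
  and sampled.
- *Priors*: log-uniform $IC_{50}$ on $[10^{-3}, 10^{7}]$ nM and uniform $h$
  on $(0, 10]$. Both are wide enough to be data-dominated for any plausible
  assay; the $IC_{50}$ range spans sub-pM to 10 mM.
- *Adaptation*: the proposal scale is multiplied by 0.7 / 1.4 every 100
  burn-in iterations when the window acceptance rate leaves [0.2, 0.5], then
  frozen, so the post-burn-in chain is a valid fixed-kernel chain. Burn-in
  is 2000 iterations; the chain is thinned (default 5) to return exactly the
  requested number of draws (default 2000). A chain whose post-burn-in
  acceptance falls below 1% aborts with a diagnostic rather than returning a
  frozen posterior.

Tests compare the sampler against a dense $200\times200$ grid evaluation of
the same posterior; the posterior mean $IC_{50}$ agrees within 5% and the
median recovers a known truth within 25% at the 6-concentration ×
3-replicate, $\sigma = 0.03$ design.

## 2. Myocyte simulation stage

`bundledModel()` returns a reduced Hodgkin–Huxley-style human ventricular
model written for this package: seven drug-scalable currents (INa, INaL,
ICaL, IKr, IKs, IK1, Ito), a fixed background leak, and a two-compartment
calcium subsystem (cytosol + sarcoplasmic reticulum) in which SR release is
graded by the instantaneous ICaL magnitude above a small threshold — so a
fully blocked ICaL collapses the calcium transient, and at rest the release
flux is exactly zero. It is **not** a reproduction of the O'Hara–Rudy or
CiPAORdv1.0 parameterizations: it is a desk-scale model with plausible
morphology (resting ≈ −88 mV, APD90 ≈ 190 ms at cycle length 2000 ms,
upstroke ≈ 195 mV/ms, calcium transient amplitude ≈ 8×10⁻⁴ mM with
monotone decay). Anything implementing the `IonicModel` contract — state,
right-hand side with named current outputs, conductance multipliers — can be
passed to `runPacing()` instead, including a full ORd port.

Two properties are engineered rather than tuned:

- *Exact resting equilibrium.* Gates are initialized at their steady state
  for the resting potential and the leak reversal is solved so the total
  membrane current vanishes there; the right-hand-side norm at the initial
  state is below 10⁻⁶, so an unstimulated cell holds its resting potential
  indefinitely.
- *Fast quasi-steady pacing.* Calcium does not feed back on the membrane
  currents, so the voltage trajectory settles within a few beats;
  beat-to-beat RMS difference after 20 beats is ≈ 2×10⁻⁶ mV. The
  paper-scale protocol (1000 prepace + 1000 drug beats, 250 recorded)
  remains the default of `pacingProtocol()`; tests use 2–20-beat protocols,
  which this model's fast settling makes representative.

**Numerics.** Stiff adaptive integration (`deSolve::lsoda`) with relative
tolerance 10⁻⁶ and absolute tolerance 10⁻⁸; each beat is integrated in two
segments (stimulus on, stimulus off) so the rectangular −80 A/F, 0.5 ms
stimulus never sits inside a solver step; recorded beats are emitted on a
uniform 0.1 ms grid.

**Beat selection.** Per recorded beat, the maximum dVm/dt is taken inside a
window set by repolarization extent — [30%, 90%] crossings for full
repolarizers, 30% crossing to beat end for partial (≥30%, <90%), peak to
beat end for minimal (<30%) — and the non-failed beat with the highest
windowed rate is selected, ties to the earliest beat. The wording of the
selection rule mixes "depolarization" and "repolarization"; we read it as
the repolarization-phase maximum, which is the quantity that spikes when an
early afterdepolarization intrudes on repolarization, making the selected
beat the most proarrhythmic of the recorded ones. Depolarization failure is
defined as peak Vm < 0 mV or amplitude < 30 mV; failed beats are omitted,
and a trace with no analyzable AP raises an explicit error that upstream
code converts to a dropped sample.

## 3. Biomarkers

All durations are measured from the signal peak to the linear-interpolated
crossing of peak − f·(peak − baseline), baseline being the pre-stimulus
value of the same beat. APD_tri and Ca_tri are implemented as the
differences APD90 − APD50 and CaD90 − CaD50 — the standard triangulation
metrics; the geometric phrase "triangle area" admits no other closed
formula at fixed units. Vm_resting averages the 10 ms up to the stimulus;
Ca_diastole is the beat's calcium minimum. qNet is the trapezoidal integral
of INaL + ICaL + IKr + IKs + IK1 + Ito from stimulus onset over exactly one
cycle length (A/F·ms). qInward is the sum (no ½ factor) of the drug/control
AUC ratios of ICaL and INaL, so a drug beat identical to control scores
exactly 2; `qinwardHalved` switches to the averaged variant used elsewhere
in the CiPA literature. Any missing component (threshold never crossed,
depolarization failure) drops the whole sample, mirroring the AP-omission
rule.

Feature rows are computed at a single configurable Cmax multiple (default
2×): how the four concentration multiples map to the per-drug sample pool is
not fixed by the study design we follow, and a single mid-range multiple
keeps one row per MCMC sample.

## 4. Classifier stage

Features are z-score normalized with means and sds from training rows only;
the parameters are stored and reapplied at prediction time (inside
cross-validation, normalization is refit per fold). Grid search is
exhaustive over the printed grids (see `defaultGrid()`) with stratified
5-fold CV on the training split; the score is mean validation accuracy
(the study records accuracy scores; no other scoring metric is stated), with
ties broken by grid order.

Family internals delegate to established implementations where one exists:
ranger (random forest), xgboost, e1071 (RBF-kernel SVM with C = 1 and
gamma = "scale"). Three components are written in-package because no
installed implementation matches the contract: the ANN (a 12→6·6·6→3
multilayer perceptron, ReLU hidden layers, softmax output, categorical
cross-entropy, Adam or RMSprop, batch 32/64, up to 200 epochs), the RBF
network (a Gaussian radial-basis layer with uniform-random centers over the
training feature ranges and grid-tuned gamma, followed by a multinomial
softmax layer fitted with `nnet::multinom`), and the KNN probability
classifier (vote fractions over the k nearest neighbours; Euclidean or
Manhattan metric — `class::knn` supports neither the Manhattan grid entry
nor probability output). One mapping is approximate: the sklearn-style RF
grid entries `max_features {'log2','auto','sqrt'}` and criterion
`{gini, entropy}` become `mtry {log2(p), sqrt(p)}` ('auto' equals 'sqrt'
for classification) with ranger's Gini-family splitting, since ranger
exposes no entropy criterion; tree counts and depths are kept as printed.

Every randomized component receives its seed from the single pipeline seed
through `deriveSeed(seed, stage)`, a fixed linear-congruential mix of the
seed with the stage label modulo $2^{31}-1$; whole runs are bit-reproducible
and individual stages can be re-run in isolation.

## 5. Shapley attribution and elimination

The coalition value $V_S(x_S)$ is the interventional marginal expectation:
features in $S$ take the explained row's values, features outside $S$ are
replaced by each background row's values, and predictions are averaged over
the background (the KernelSHAP convention; the defining equation leaves
$V_S$ abstract). The background defaults to the training split capped at 100
rows by deterministic subsampling. Exact mode enumerates all $2^p$
coalitions with the exact weights $|S|!(p-|S|-1)!/p!$ and is limited to
p ≤ 14; sampled mode averages marginal contributions over m random feature
permutations. One attribution vector is produced per class probability.
Exact-mode values satisfy efficiency, dummy and symmetry to 10⁻⁹ against an
independent brute-force enumeration in the tests.

Per class, importance is the mean absolute attribution over explained rows;
the overall score sums the three per-class means (a `max` aggregate is
available) — the study ranks by an "overall importance level" without
defining the aggregate, and the sum is the convention its per-class bar
charts imply. `shapGuidedElimination()` loops train → explain → rank → drop
the lowest-ranked feature → re-evaluate, from 12 features down to a floor of
6, re-using the grid-search winner's hyperparameters at each step (the grid
is searched once; re-searching per step would confound the feature effect
with hyperparameter drift). Explanations are computed on training rows
(which split feeds the attribution summaries is not stated; a parameter
exposes the choice), subsampled to `nExplain` rows (default 64) with
`nPerm` = 16 permutations — precision settings chosen so that a
label-independent feature lands at the bottom of the ranking in ≥ 19 of 20
seeded replicates of the synthetic elimination diagnostic.

## 6. Evaluation

Each bootstrap drug set draws one row per test drug, uniformly and
independently across sets (10,000 sets at paper scale). Per set: multiclass
accuracy; per class one-vs-rest sensitivity, specificity, LR+ =
sens/(1−spec), LR− = (1−sens)/spec with 0-denominators giving +∞ and 0/0
giving NaN; and one-vs-rest AUC using the class's predicted probability as
the score — a hard-label AUC on a 16-point set would be a single ROC corner,
so the continuous score is the only faithful option. Trapezoidal ROC
integration groups tied scores and therefore equals the Mann–Whitney
statistic with half credit for ties (asserted to 10⁻¹² in tests). Metrics
are summarized as median and 2.5–97.5 percentiles with linear interpolation
between order statistics; NaNs are excluded with counts reported, and
infinities participate in the ordering (the percentile routine returns the
order statistic itself at integer ranks, so `Inf` never produces `0·∞`
artifacts).

## 7. Synthetic data: what it emulates, what it does not

- `genDoseResponse()` — Hill curves plus clipped Gaussian noise, with the
  generating parameters returned so recovery tests never re-estimate truth.
- `genWaveform()` — a parametric beat whose 50%/90% crossings land exactly
  on the requested APD/CaD targets: piecewise-linear Vm (the crossings are
  kink points, so linear-interpolated extraction recovers them to within one
  0.1 ms grid step), a double-exponential calcium transient whose shape
  parameter is solved by root-finding to match the CaD90/CaD50 ratio
  (attainable range ≈ 2.3–3.3), and constant current templates whose qNet
  is analytic and trapezoid-exact.
- `genFeatureTable()` — per-drug Gaussian clusters: class mean + per-drug
  offset, diagonal within-drug covariance, optional label noise and
  appended pure-noise features. The drug allocation mirrors the 12-train /
  16-test, three-class design; 200 samples per drug at desk scale
  (`paperScale = TRUE` gives 2000). Class means and dispersions are fixed
  plausible biomarker values (e.g. longer APD90 and lower qNet with rising
  risk); the `separation` and `noiseScale` multipliers scale the
  between-class contrasts and within-drug spread.

What passing tests on these fixtures shows: the machinery — fitting,
extraction, normalization, CV, attribution, bootstrap — is correct and
reproducible. What it does not show: real CiPA drugs are not Gaussian
clusters, their biomarker covariances are not diagonal, and class overlap is
far larger; the headline discriminations reported on the real data (and the
published AUC levels) are therefore not reproduced here, by design. Problem
sizes used throughout the tests — 200 samples/drug, 1000 bootstrap sets,
2–20-beat pacing — are the package's desk-scale defaults; all paper-scale
settings (2000 samples/drug, 10,000 sets, 1000/1000/250 beats) are plain
parameter changes.

## 8. Known limitations

- The bundled myocyte model is phenomenological; absolute biomarker values
  (qNet scale, CaD ratios) are model-specific and should not be compared
  numerically against ORd-based studies without plugging in an ORd-class
  model.
- The MCMC sampler is a single adaptive random-walk chain; no convergence
  diagnostics beyond the acceptance-rate guard are computed. Hierarchical
  pooling across drugs and HMC-style samplers are out of scope.
- KNN probability estimates are vote fractions and therefore coarse
  (k + 1 levels), which limits per-set AUC resolution for that family.
- Exact Shapley mode is exponential in the feature count (capped at 14);
  sampled mode's Monte Carlo error decreases with the permutation count but
  rankings of near-zero-importance features remain noisy at small m.
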