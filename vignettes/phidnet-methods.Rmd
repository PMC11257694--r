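---
title: "Information decomposition, the synergistic workspace, and shared-effect statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Information decomposition, the synergistic workspace, and shared-effect statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phidnet)
```

phidnet analyses multivariate neural timeseries through the lens of
information decomposition: which pairs of brain regions carry information
*synergistically* (only their joint state is informative about the future),
which carry it *redundantly* (each region alone suffices), and how these two
interaction networks organise into a "workspace" of globally integrative
regions. This vignette explains the models and estimators, the choices made
where the design was genuinely open, and what the synthetic validation does
and does not establish.

## The Gaussian model and its information quantities

All estimators assume the data are (approximately) stationary and jointly
Gaussian, so that every information quantity is a function of covariances
alone. For a region pair $(i, j)$ at lag $\tau$ we form the joint Gaussian
vector $(x_i(t-\tau), x_j(t-\tau), x_i(t), x_j(t))$ and compute, in nats:

* **TDMI**, the time-delayed mutual information
  $I(\text{past pair};\, \text{future pair})$ — the total information the
  pair's past carries about its future;
* **redundancy**, the minimum over the four single-past
  $\to$ single-future mutual informations (the minimum-mutual-information,
  MMI, convention for Gaussian variables) — information about the future
  that *either* region's past supplies on its own, persistently in past and
  future;
* **synergy**, TDMI minus the larger of the two single-past
  $\to$ joint-future informations — what the joint past adds over the best
  single region;
* **whole-minus-sum integrated information** $\Phi$, TDMI minus the two
  self-predictive informations. $\Phi$ can be negative when the pair is
  dominated by shared (redundant) input — a well-known interpretive
  shortcoming;
* **$\Phi_R$**, the revised integrated information, $\Phi$ plus the
  redundancy. Adding the double-counted redundancy back makes the measure
  non-negative while preserving its "whole beyond the parts" reading.

Two properties are enforced to numerical tolerance throughout the test
suite: the four forward-PID atoms (redundancy, two uniques, synergy, with
the joint future as target) sum *exactly* to the joint mutual information,
and $\Phi_R = \Phi + \mathrm{Red} \ge 0$.

A subtlety worth knowing: under the MMI convention two *independent*
self-predicting AR(1) regions have zero redundancy and zero $\Phi$, but a
synergy equal to the weaker region's self-information. MMI synergy
therefore has a floor set by self-predictability; all
rank-based downstream analyses are unaffected by a uniform floor, but the
raw synergy matrix should not be read as "zero means independent".

## Estimation

`estimate_lagged_model()` removes each region's mean, aligns the $T - \tau$
past/future sample pairs, and estimates the contemporaneous covariance
(pooled over the past and future segments) and the lag-$\tau$
cross-covariance with a single shared normalisation $T - \tau - 1$. The
convention is `sigma_tau[i, j]` $= \mathrm{Cov}(x_i(t-\tau),\, x_j(t))$, so
for a VAR(1) process `sigma_tau` converges to $\Sigma_0 A^\top$. No
shrinkage is applied by default: shrinkage would bias every mutual
information downward, and the regimes of interest here have $T \gg n$.

The lag defaults to $\tau = 1$ sample and is recorded in every output; it
is a free parameter of the method, not an estimated quantity.

Near-singular joint covariances receive one diagonal jitter of
$10^{-10} \times$ the mean variance; anything still degenerate raises an
error naming the offending pair — a duplicated or constant signal is a data
problem that should not be silently smoothed over.
`pairwise_networks()` evaluates all pairs through closed-form determinants
(vectorised over pairs), falling back to the conditioned per-pair route for
numerically awkward pairs; the two routes are tested against each other and
against an independent eigendecomposition-based oracle.

## From networks to the workspace

Following the group-analysis convention, per-subject matrices are averaged
(`group_average()`) before ranking. Each region's **nodal strength** (row
sum) is ranked ascending, separately on the synergy and redundancy
networks, with average ranks on ties so that no ordering of the input can
influence the result. The **gradient** is rank(synergy) − rank(redundancy):
a relative, not absolute, balance. Regions with strictly positive gradient
form the **synergistic workspace**; a percentile rule is available as an
alternative cut, but the sign rule is the default because zero is the only
scale-free reference point of a rank difference.

Workspace regions are subdivided by the same construction applied to the
**participation coefficient** $P_i = 1 - \sum_s (\kappa_{is}/k_i)^2$
computed against a module partition (own-module strength included in both
$\kappa$ and $k$, the canonical form; negative entries — possible only for
$\Phi$ networks — are excluded as the definition concerns positive
connection strengths). Within the workspace only, regions whose
synergy-based participation outranks their redundancy-based participation
are **gateways** (synergistic interactions spread over many modules);
the converse are **broadcasters** (redundant interactions spread over many
modules); exact ties are left unclassified rather than forced.

## Condition contrasts and the composite test

Edgewise condition effects are scored with a two-sided F (the squared
two-sample pooled-variance t for unpaired designs, the squared paired t for
within-subject designs), with the direction of effect carried separately.
Familywise error over the ~$n^2/2$ edges is controlled with the
network-based statistic: edges with $F > 9$ (the conventional threshold,
exposed as a parameter) form a supra-threshold graph, connected components
are scored by intensity (sum of F; extent is available), and component
significance comes from a permutation null of the maximum component score —
group-label permutations or within-subject sign flips, matching the design.
Permutation p-values use $(1 + b)/(1 + B)$, which cannot return zero.

To identify effects *shared* across several contrasts, the composite test
takes the edgewise **minimum** of the per-contrast F scores as its
statistic, and samples its null by reshuffling exactly one contrast's data
— chosen uniformly at random per permutation — and recomputing the minimum.
This is a least-favourable-configuration construction: a rejection requires
every contrast to show an effect, and the false-positive rate is controlled
whenever at least one contrast is truly null, because reaching the observed
minimum requires the reshuffled dataset itself to reach it. Component
correction is applied to the min-F matrix exactly as in the NBS.
Sign-consistency across all contrasts (all increases, or all decreases) is
applied *after* the component step, as a separately labelled filter
defining the common-increase and common-decrease edge sets; the minimum and
the sign filter are kept distinct so each can be inspected on its own.

## What the synthetic generator emulates — and what it does not

`simulate_mvar()` realises stable VAR(1) dynamics
$x_t = A x_{t-1} + \varepsilon_t$: cross-coupling in $A$ is the synergy
control, correlated innovations in $\Sigma_\varepsilon$ the redundancy
control, exactly the two axes of the classic two-parameter two-node
illustration (`make_two_node_system(a, c)`). `make_modular_system()` adds
resting-state-network-like block structure; `simulate_group_dataset()` adds
subject-level coupling jitter (innovation covariance is held fixed across
subjects so that redundancy structure is not confounded with subject
variability) and condition effects that rescale coupling on chosen edges.
Systems destabilised by jitter are rescaled to spectral radius 0.95 with a
warning. Burn-in defaults to 100 samples, ample for transient decay at
spectral radii $\le 0.95$.

What this does *not* emulate: hemodynamic convolution and its
deconvolution, physiological and scanner noise, non-Gaussian or
non-stationary dynamics, and the spatial autocorrelation of real parcel
data. Passing the synthetic recovery studies therefore demonstrates that
the estimators and the rank pipeline are *internally correct and
statistically calibrated* — not that real fMRI data satisfy their
assumptions.

### Planted-role benchmarks

Designing a system whose gateway and broadcaster are knowable *a priori* is
less obvious than it sounds, because in linear dynamics any strong
reciprocal coupling produces lagged correlation — hence redundancy — in
exactly the places it produces synergy. `make_planted_roles_system()`
therefore dissociates the two with three mechanisms whose information
signatures we verified analytically: one-way driving (synergy with little
redundancy, because redundancy takes the minimum over both lagged
directions and the reverse path is weak), common drivers with self-memory
(their targets become mutually redundant copies), and weak reciprocal edges
(a localised balanced anchor). The planted gateway drives one region in
each module and keeps its redundancy inside its own module; the planted
broadcaster drives only its own module while listening to two foreign
module drivers, which spreads its redundancy across modules. Ground truth
is the population (analytic-covariance) profile; the validation study asks
the full estimation pipeline, run on 20 independently seeded groups of 10
jittered subjects at $T = 5000$ samples (the gradient is computed on
group-averaged matrices, as in the main analysis convention), to recover
both labels — it succeeds in $\ge 90\%$ of runs. The workspace-recovery
benchmark uses the same system with single runs, scoring balanced accuracy
of workspace membership for two synergy hubs against two driver-fed
redundancy hubs.

### Statistical calibration studies

The test suite re-derives, at full scale: the NBS familywise error under a
global null (500 replicates of 20-node networks, 15 subjects per group, 500
permutations each — the edge values are exchangeable Gaussians, which is
the regime the permutation argument addresses); and the composite test's
false-positive rate when exactly one of three MVAR-simulated contrast
datasets is null (300 replicates of the full simulate → decompose →
$\Phi_R$ edges → composite pipeline at 20 nodes, $T = 1000$, 15 subjects
per group, 500 permutations, with the null dataset's position rotating so
every least-favourable configuration is exercised). Both rates must stay
within two binomial standard errors of the nominal 0.05. Power against a
shared planted effect is checked to increase with effect size. The
`scripts/acceptance.R` entry point re-runs the composite false-positive
study from scratch and writes the rate as JSON.

Problem sizes in the routine suite (network sizes 6–20, $T$ up to $10^5$,
300–500 replicates for the calibration studies) were chosen so the whole
validation runs comfortably on a single CPU; all seeds are explicit and
every simulation is bit-reproducible under its seed.

## Numerical choices, degenerate inputs, limitations

* Natural logarithms throughout; `nats_to_bits()` converts for display.
* Ranks ascending, average on ties; the gradient of an untied ranking sums
  to zero over regions, which is asserted in tests.
* Zero-variance regions, duplicated labels, ragged files: hard errors with
  the offending region, label or line named. Masked pair failures (optional
  `on_error = "mask"`) propagate as missing values excluded from strengths
  with a reported count.
* Edges with zero within-group variance get $F = \infty$ if the means
  differ (warned), $F = 0$ otherwise.
* VAR order is fixed at 1 — the framework relates one past to one future
  lag; higher-order memory is out of scope. The lag $\tau$ and the
  two-node self-coupling default ($s = 0.2$) are configuration, not
  science: both are surfaced in outputs.
* The workspace cut (sign of the gradient) and the component-forming
  threshold ($F = 9$) are conventions; both are parameters, and provenance
  sidecars record the values used.
* The composite test is derived for three contrasts; `composite_min_f()`
  accepts other counts but flags the generalisation.

## A worked pipeline

```{r pipeline, eval = FALSE}
cfg <- read_pipeline_config(
  system.file("extdata", "demo_config.yaml", package = "phidnet"))
cfg$out_dir <- tempfile("phidnet_demo_")
run <- run_pipeline(cfg)

run$profiles          # per-region strengths, gradient, workspace, roles
glance(run$nbs)       # component-level contrast summary
autoplot(run$profiles)
```

Every artefact is written under `out_dir` with a JSON provenance sidecar
(measure, lag, units, sample count, configuration hash, seed), and the
manifest's checksums are identical across re-runs of the same
configuration.
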