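---
title: "Discrete neural states from population spike trains: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discrete neural states from population spike trains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuroethogram)
```

## The problem

During naturalistic behavior — here, a rat playing hide-and-seek with an
experimenter — prefrontal population activity is hypothesized to move
through a finite repertoire of discrete states, an "ethogram of the
brain". The package infers those states without using the behavioral
annotations, then asks post hoc how well the inferred states line up with
what a human tagged from video: game-phase time points (start, box open,
jump out, interaction, return transit, jump in, end) and free behaviors
such as darting.

## The generative model and its inference mirror

The analysis assumes a three-layer generative process per trial:

1. a discrete state sequence $s_t \in \{1..K\}$ with Markovian, sticky
   dynamics;
2. latent factors $x_t \in \mathbb{R}^d$ that are stereotyped per state
   and vary smoothly in time;
3. per-neuron firing rates $r_t$ driven linearly by $x_t$, with Poisson
   spike counts in 250 ms bins.

Inference inverts the stack with two standard tools:

* **GPFA** (Gaussian-process factor analysis): binned counts
  $y_t = C x_t + d + \varepsilon_t$, $\varepsilon_t \sim N(0, R)$
  diagonal, with each latent an independent Gaussian process over the
  bin grid under a squared-exponential kernel
  $k(\Delta) = (1-\sigma_n^2)\exp(-\Delta^2/2\tau^2) + \sigma_n^2
  \delta_\Delta$. EM alternates exact Gaussian conditioning per trial
  with closed-form updates of $C, d, R$ and a bounded 1-D search for
  each $\tau$. Counts enter untransformed (a square-root flag exists but
  defaults off).
* **Sticky Gaussian HMM** on the GPFA factors: emissions
  $y_t \mid s_t = k \sim N(\mu_k, \Sigma_k)$ with full covariances, a
  Dirichlet transition prior with concentration $\alpha = 1$ plus
  $\kappa = 100$ extra mass on the diagonal, MAP-EM (M-step row $i$
  proportional to expected counts $+\,\alpha - 1 + \kappa\,\delta_{ij}$,
  floored at $10^{-8}$), 40 restarts seeded `base_seed + r - 1`, best
  final MAP objective wins. Segmentations are decoded by Viterbi;
  probability timecourses use the forward-backward posteriors
  $\gamma_t(k)$, which is also the convention used for cross-session
  matching. The choice of Viterbi for segmentations and $\gamma$ for
  timecourses is a genuine design decision: both decoders are exposed.

The latent dimensionality is chosen in two steps: cross-validated factor
analysis picks the likelihood-maximizing candidate $d^*$, and the
smallest dimensionality whose leading eigenvalues of the shared
covariance (the Gram matrix of the loadings) capture 95% of its variance
is kept. The Gram form $C^\top C$ and the scatter form $C C^\top$ share
their nonzero spectrum, so the 95% rule is identical either way; the
Gram form is what the implementation computes. The number of HMM states
is chosen by 10-fold cross-validation over trials on the held-out
log-likelihood per bin; defaults of $K = 11$ for play-only sessions and
$K = 18$ when observing trials are present reflect the regimes the
method was designed for, and both are overridable.

## Correspondence statistics

Two segmentations of the same trials — inferred states and tagged
behavior — are compared as clusterings of time bins with plug-in mutual
information in nats. Significance never relies on asymptotics:

* **Segment-shuffle null**: within each trial the order of the HMM
  segmentation's run-length segments is permuted (labels and lengths
  preserved), 10,000 times by default; `p` is the fraction of null MI at
  or above the observed MI, with zero counts reported as the bound
  `1/n_null` plus a `below_resolution` flag.
* **Cyclic-rotation null**: all nonzero rotations of the concatenated
  labels, which additionally preserves transition statistics and tests
  timing alone.
* **Conditional probabilities** $P(\text{behavior}\mid\text{state})$ and
  $P(\text{state}\mid\text{behavior})$ get per-cell bootstrap p-values
  from the same shuffle ensemble, cells with observed probability at or
  below 0.001 are excluded, and Holm-Bonferroni runs across all included
  cells of both matrices at $\alpha = 0.05$.
* **Role separation**: with playing and observing trials,
  $P(\text{observing}\mid\text{state})$ per state, the fraction of time
  in "mixed" states (conditional probability strictly between 0.3 and
  0.7), and the MI between states and the binary role labeling, whose
  null redraws each segment's label uniformly from $\{1..K\}$ keeping
  all boundaries.

## Time stretching and cross-session matching

Trials differ in duration, so all trial-averaged views live on a
reference timeline: per game phase, the median offset from trial start
("global" anchors pool every trial of every session, the default for
matching; per-session anchors are available, since the two conventions
are both defensible for single-session figures). A piecewise-linear
time map sends each trial's anchors onto the reference anchors; rates
and probabilities are resampled by linear interpolation, discrete labels
by nearest-time lookup with ties to the earlier bin. If medians come out
non-monotone (possible with very few trials) they are isotonically
corrected and minimally separated — the warp needs increasing knots.

States of independently fitted sessions are matched by correlating their
stretched occupancy timecourses per role, averaging the hide and seek
correlation matrices, and solving the assignment problem on the negated
average with the Hungarian algorithm (an authored
shortest-augmenting-path implementation, brute-force-verified; no
installed package provides weighted linear assignment). The reference
session maximizes the mean matched correlation to all partners; all
other sessions are relabeled through their assignment. Pearson
correlation is scale-invariant, so raw timecourses are used.

## The synthetic-data generator

Because the method must be testable without recordings, the generator
emulates the study conditions end to end: 5-31 neurons per session (10
by default), 250 ms bins, trials around 60 s, hide/seek roles (seek has
the extra "box open" phase), latent states that follow the game phases
in order, GP-smooth factors (timescale 0.5 s, marginal SD 0.3) driving
softplus rates around a ~5 spikes/s baseline, Poisson counts, and
imperfect tags: Gaussian jitter (SD 0.5 s) on phase points and a 5%
mislabeling rate on behavior intervals. The tagging-noise defaults are
the package's own choice of a plausible human-annotation error scale;
no quantitative tagging-noise model was available to copy, and both
knobs are exposed.

Two dwell regimes coexist deliberately. Phase-state dwell inside a trial
scales with the trial length (each phase occurs exactly once, which is
what makes "one tag per phase per trial" well defined), while the
`stickiness` parameter (expected dwell, 8 bins = 2 s by default) governs
everything whose duration is not tied to the trial: inserted free states
("darting"-like, not phase-locked, insertion probability 0.3) and
free-running chains sampled with `cyclic = TRUE`, whose long-run
self-transition frequency is $1 - 1/\text{stickiness}$. The softplus
link keeps rates positive and near-linear at high drive; the generative
account it mirrors names no link function, so this is a package choice.

What the generator does **not** emulate: inter-trial activity, slow
nonstationarities (electrode drift, satiety), non-Poisson spiking
(refractoriness, bursting), neuron-specific latencies, and correlated
tagging errors. Passing tests therefore certify the pipeline's
correctness and calibration under the assumed model class, not its
adequacy for any particular real recording.

## Numerical choices

* EM stopping: relative objective change below $10^{-8}$ (500 iteration
  cap) for factor analysis; $10^{-6}$ with a 100-iteration cap for GPFA
  and a 200-iteration cap for the HMM, whose objectives plateau much
  earlier at these problem sizes.
* Degenerate inputs: zero-variance channels get a logged ridge;
  emission-covariance collapse is caught by a PD-enforcing ridge floor;
  constant rows in correlation-based steps get maximal distance
  (ordering) or zero correlation (matching), with a message.
* Ties: Viterbi breaks toward the lower state index; nearest-time
  lookup toward the earlier bin; kneedle toward the smallest candidate;
  reference selection toward the earlier session.
* The Gaussian smoothing window interprets "half-width" as half-width at
  half-maximum ($\sigma = 0.5/\sqrt{2\ln 2}$ s), truncates at
  $4\sigma$, and renormalizes at trial edges so constant rates stay
  constant.
* K-means uses 10 restarts with a config seed; cross-validated K uses
  forward-chained ordered splits scored by held-out inertia per point,
  with the knee of the (negated, normalized) test-score curve.
* Failed trials carry an optional `failed` flag that no statistic uses;
  spikes outside every trial are stored but never analyzed.

## Problem sizes in the examples and tests

The bundled analysis scripts and the test suite run on deliberately
moderate sizes — cohorts of three sessions, 8-15 trials per role, tens
of seconds per trial, 10-20 neurons — chosen so that every stage (GPFA
EM, 40-restart HMM fits, 10,000-draw permutation nulls) completes in
minutes while remaining in the regime where the method's behavior is
representative. The statistical calibration check uses 200 simulated
independence datasets with 199-draw nulls, the smallest ensemble at
which a rejection-rate band of [0.02, 0.10] at $\alpha = 0.05$ is
meaningful.

One subtlety deserves a note. Cross-validated selection of $K$ by
held-out likelihood can only be expected to recover the generating
state count when the emission model is well specified: if the latent
noise is temporally correlated within states (the generator's default
GP noise), additional states soak up that structure and the held-out
curve keeps creeping upward — the same reason one should be cautious
about reading the cross-validated $K$ as a ground truth on real data.
The K-recovery check therefore uses short trials and latent noise whose
GP timescale is well below the bin width (effectively white), the
regime where the argmax is informative.

## Known limitations

* The HMM assumes Gaussian emissions on GPFA factors; a Poisson-emission
  HMM on raw counts is a natural variant the package does not implement.
* $K$ is imposed, not inferred; nonparametric alternatives (HDP-HMM) and
  switching linear dynamical systems are out of scope.
* Cross-session matching aligns labels, not latent spaces; there is no
  joint multi-session model.
* UMAP embeddings and video-derived summaries are visualization-only
  concerns and are not reproduced here.
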