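---
title: "Methods: from spike trains to corrected small-world-ness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from spike trains to corrected small-world-ness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikesw)
```

This vignette documents the models behind `spikesw`, the choices we made
where the design was genuinely open, and what the synthetic benchmarks do
and do not establish. It states no number that the test suite or the
acceptance script does not itself compute.

## The estimation model

Spike trains are treated as binary time series on a regular grid. The
conditional intensity of output neuron $i$ is modelled linearly in the
recent spiking history of all $N$ recorded neurons,

$$\lambda_i(t) = k_0 + \sum_{n=1}^{N} \sum_{\tau} k^{(n)}(\tau)\,
x_n(t - \tau),$$

with first-order kernels only. Each kernel is expanded in $J$ discrete
Laguerre basis functions, $k^{(n)}(\tau) = \sum_j c_j^{(n)} b_j(\tau)$,
which reduces the parameter count per input from the memory length $M$ to
$J$. The basis decay is governed by $\alpha \in (0,1)$; smaller $\alpha$
gives faster decay. Estimation is penalised least squares (Gaussian
likelihood with identity link on the binary targets) with an L1 constraint,
so that only inputs genuinely predictive of the output retain nonzero
coefficients. The penalty $\zeta$ is selected from a grid of 20 log-spaced
values on $[10^{-5}, 10^{-1}]$ by 5-fold cross-validated deviance;
$\alpha$ is selected on the grid $\{0.2, \dots, 0.9\}$ jointly with
$\zeta$. Cross-validation folds are contiguous time blocks, not shuffled
bins, because the regressors are serially dependent.

Choices the data sources leave open, and what we chose:

* **Bin width 10 ms, memory 50 bins (0.5 s).** Typical interaction latencies
  in hippocampal microcircuits are a few milliseconds to tens of
  milliseconds; 10 ms bins keep per-bin spike probabilities small (so the
  Gaussian approximation to the Bernoulli likelihood is benign) while 0.5 s
  of memory comfortably covers kernel support. Both are configurable
  (`analysis_config()`).
* **Self-history.** The output's own lagged spikes enter the design like any
  other input (an autoregressive term that absorbs refractoriness), but a
  self-group never produces a graph edge.
* **Strict causality.** Regressors at bin $t$ involve bins strictly before
  $t$ (the convolution is lagged one bin). The generative model in
  `simulate_spike_trains()` uses exactly the same convention and the same
  kernel-evaluation code path, which a test verifies to $10^{-10}$.

## From coefficients to edges

The edge rule is where we deviated from the most literal reading
("any nonzero coefficient is an edge"). Cross-validated lasso minimises
prediction error, and at its optimum it habitually retains a few tiny
noise coefficients; with an any-nonzero rule those become false edges and
dominate the graph's precision on small networks. We therefore read
"selected as significant" literally: after the penalty is chosen, the
retained columns are refit by ordinary least squares (a standard debiasing
step), and the directed edge $n \to i$ is drawn only when input $n$'s
group contains a coefficient significant at level 0.05 with a Bonferroni
correction across *all* candidate coefficients of the network — the
reconstructed graph is treated as a single family of hypotheses. The
any-nonzero rule remains available
(`build_functional_network(edge_criterion = "nonzero")`). Isolated nodes
are removed, as are neurons below the 0.5 Hz firing-rate floor before
fitting.

## Model validation

Three diagnostics are provided per fitted neuron:

* **Time-rescaling K-S test.** If the fitted intensity is correct, the
  integrated intensity between consecutive spikes is unit-exponential and
  $z_k = 1 - e^{-\Delta\Lambda_k}$ is uniform. The K-S plot's 95% band is
  $\pm 1.36/\sqrt{n}$ around the diagonal — the asymptotic K-S envelope,
  since no construction is canonical here. For continuous spike times the
  piecewise-constant intensity is integrated exactly. For binned trains we
  use the discrete-hazard form with per-bin contribution
  $-\log(1 - \lambda\Delta)$ and a uniform draw within the spike bin's
  atom, which makes $z$ exactly uniform under the true model and removes
  the discreteness bias a rectangle rule incurs as per-bin probabilities
  grow. Negative intensities from the identity link are floored at
  $10^{-8}$ before integration.
* **Autocorrelation of rescaled intervals** at lags 1..20 against
  $\pm 1.96/\sqrt{n}$; constant sequences are flagged undefined.
* **ROC accuracy.** The spike/no-spike threshold on the predicted intensity
  maximises Youden's $J$; TP is sensitivity (spike bins predicted as
  spikes), TN specificity.

## Graph metrics and their references

All small-world quantities use the binarised, symmetrised graph; direction
is retained only for controllability. Average path length $\bar L$ is
taken over unordered pairs of the largest connected component (isolates
were already removed upstream; disconnected random references are
flagged). Average clustering $\bar C$ counts degree-<2 nodes as zero.
Two metrics are reported:

$$S_w = \frac{\bar C / C_r}{\bar L / L_r}, \qquad
\omega = \frac{L_r}{\bar L} - \frac{\bar C}{C_l},$$

with $C_r, L_r$ averaged over 20 Erdős–Rényi $G(N, E)$ replicates (the
replicate count is a package default; it is not prescribed anywhere) and
$C_l$ from a deterministic ring lattice built by filling nearest-neighbour
offsets ring-wise until exactly $E$ edges exist. A lattice too sparse to
contain any triangle gives $C_l = 0$ and an NaN $\omega$ with a flag,
rather than a silent number.

## The 3D simulator

Neurons are placed uniformly in a cuboid of 780 × 320 × 100 µm — the
extent of tissue a 4-shank probe with ~200 µm shank spacing and ~50 µm
recording columns samples. Three connectivity models are provided:

* **Distance threshold:** pairs within $l$ connect with probability
  $P_{in}$, others with $P_{out}$ ($P_{in} \ge P_{out}$). The threshold
  $l$ is nowhere stated in the sources this package draws on, so it is
  *calibrated*: the expected density is
  $P_{out} + (P_{in} - P_{out}) F(l)$ with $F$ the empirical CDF of pair
  distances, so the quantile of the pair distances at
  $(d^\ast - P_{out})/(P_{in} - P_{out})$ hits a target density
  $d^\ast$ exactly (the closed-form solution of the bisection this
  calibration would otherwise perform). `calibrate_radius()` records the
  result.
* **Model 1 (geometric decay):** $P(d) = P_0 + \alpha \lambda^{d/d_u}$ —
  probability $\alpha$ at contact, decaying to the bias $P_0$; larger
  $\lambda$ lengthens the range.
* **Model 2 (hyperbolic decay):** $P(d) = P_1 + \gamma/(1 + \beta d/d_u)$ —
  initial state $\gamma$, heavy tail that tolerates long-range
  connections; larger $\beta$ lowers the curve everywhere.

The exact functional forms of the two parametric models are not published
in a readable form; the forms above were chosen to reproduce every stated
qualitative behaviour (initial states, monotonicity in each parameter,
final states) and are isolated behind one function each
(`connection_prob_model1/2`). The distance unit $d_u$ defaults to 50 µm,
the recording-column radius; biases $P_0, P_1$ default to 0.

**Electrode subsampling.** Six electrodes (the typical per-session count)
are placed uniformly; neurons within $l'$ of any electrode are sampled and
the sampled network is the vertex-induced subgraph. When a target sample
size is wanted, $l'$ is set to the $n$-th smallest neuron-to-electrode
distance, which is deterministic given the geometry.

**Pattern fitting.** `fit_pattern_ga()` searches $(P_{in}, P_{out})$ by a
real-coded genetic algorithm (population 40, 60 generations, tournament
selection of size 3, blend crossover, Gaussian mutation with SD 0.08,
elitism), scoring each candidate by the mean $(\bar L, \bar C)$ over 5
fixed spatial realizations and minimising the squared pattern distance.
With only two free probabilities the threshold must be pinned: we fix it
at the distance quantile that makes half of all pairs local, which leaves
density (via $P_{in} + P_{out}$) and clustering excess (via their spread)
independently adjustable — enough to span the session patterns the GA is
asked to match. The winner is re-scored on 20 fresh realizations so the
reported pattern is not an optimistic selection artefact.

## Subsampling bias and its correction

Subsampled networks systematically *overstate* small-world-ness: the
sampled $\omega$ sits below the original network's. The bias is summarised
by the percentage error $\sigma = (\omega_{ON} - \omega_{SN}) /
\omega_{SN}$ as a function of the number of sampled neurons $N$, modelled
as $\sigma(N) = a e^{bN} + c e^{dN}$ and inverted as
$\hat\omega_{ON} = \omega_{SN}(1 + \sigma(N))$. Both candidate inversion
forms (multiplication by $1 + \sigma$ versus division by $1 - \sigma$)
were evaluated against the published per-session adjustment endpoints;
only the multiplicative form reproduces them, so it is the one
implemented. Three degenerate cases are handled explicitly: $\omega_{SN}
= 0$ adjusts to 0; negative $\omega_{SN}$ is adjusted on magnitude with
its sign preserved and a warning (the error curve was characterised on
positive $\omega$, and the published treatment of the one negative
session is not explained); and $\sigma$ is undefined at $\omega_{SN} = 0$
(NaN with a warning).

The curve is fitted by Levenberg–Marquardt nonlinear least squares with
$b, d$ constrained non-positive and ten starts (one near the reference
coefficients, nine log-normally perturbed); the best residual sum of
squares wins, and RMSE is reported on $n - 4$ degrees of freedom.
`error_curve_reference()` carries the published reference coefficients
$(1.564, -0.080, 0.279, -0.006)$ for use when no fresh simulation is
wanted; `adjust_range()` spans an adjustment interval across fits at
several edge densities (default sweep 5.8%–23%, bracketing cortical
connectivity estimates, plus the 8.32% working density).

## Controllability

For the directed graph, the minimum number of driver nodes is
$\max(N - M^\ast, 1)$ where $M^\ast$ is the maximum matching of the
digraph — computed by splitting each node into an out- and an in-copy and
running Hopcroft–Karp on the resulting bipartite graph. Self-loops are
kept as matchable edges by default (a node with self-dynamics can match
itself); a flag removes them. The driver set reported is the sorted set of
unmatched in-copies, so output is deterministic.

## The synthetic generator, and what the tests show

`make_ground_truth()` draws a directed graph at a chosen density and gives
every edge a kernel in the *same* Laguerre basis the estimator uses, with
the leading coefficient dominant, 80% excitatory, and baselines of 5 Hz at
10 ms bins (inside the observed range of retained units in the recordings
this workflow emulates, and safely above the 0.5 Hz floor).
`simulate_spike_trains()` emits Bernoulli spikes from the clipped linear
intensity — deliberately the estimator's own model family, so that
benchmark failures indicate estimation defects rather than model
mismatch. What passing benchmarks therefore show is *internal*
consistency: correct kernels, correct selection behaviour, calibrated
validation statistics. They do not show robustness to the features real
recordings add — non-Poisson bursting, theta modulation, common drive from
unobserved neurons, spike-sorting errors — and edge precision on real data
should be expected to be lower than on these benchmarks.

## Problem sizes and numerical tolerances

The shipped tests use sizes chosen to make the statistical properties they
assert stable at modest cost: 500-neuron spatial networks (30 seeds per
probability combination) for the overestimation property, 20 seeds for the
density calibration, 10-neuron / 10 000-bin ground truths (10 seeds) for
end-to-end recovery, 100 repetitions for K-S calibration, and a full-budget
GA run for the pattern fit. Exact identities are asserted to $10^{-10}$ or
tighter; orthonormality of the basis to $10^{-6}$ over 100 lags;
stochastic properties at the rates stated in each test. Degenerate inputs
(empty samples, one-class targets, constant rescaled values, zero-variance
designs, lattices without triangles) raise errors or flagged NaNs rather
than numbers.

## Known limitations

* The Gaussian/identity likelihood on binary targets is an approximation;
  a logistic variant is a natural extension but is not the default
  anywhere in the pipeline.
* $S_w$ is not corrected for subsampling — only $\omega$ has a
  characterised error curve.
* The correction curve was characterised on distance-threshold networks
  near 8.3% density; applying it far outside that regime extrapolates.
* Community structure, weighted/directed small-world variants, and
  control-energy analyses are out of scope.
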