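---
title: "Connectome-informed reservoir computing: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectome-informed reservoir computing: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connrc)
```

## The question the package addresses

Descriptive connectomics can correlate network features with function, but
it does not say what a given wiring diagram can *compute*. Reservoir
computing offers a direct probe: impose the connectome as the fixed
recurrent weight matrix of a dynamical system, drive it with the input
stream of a cognitive task, and train nothing but a linear readout. Because
the recurrent weights are never adjusted, differences in task performance
across networks, dynamical regimes, or readout node sets are attributable
to the imposed structure and dynamics rather than to learning inside the
network.

The pipeline has five stages: fetch (generate) the task dataset, set the
connectivity matrix, simulate the reservoir dynamics, fit the readout, and
assess performance — typically as a curve against the spectral radius
`alpha` that tunes the global dynamical regime.

## Dynamics

### Echo-state (rate) reservoir

The discrete-time update is

$$x(t) = f\bigl(x(t-1)\,W + u(t)\,M\,g\bigr), \qquad x(0) = x_0,$$

with row-vector states, `W[i, j]` the connection from node $i$ to node $j$
(one orientation convention, stated once, used by every simulator), input
map $M$ and gain $g$. The trace records the state *after* consuming input
row $t$, so trace row $t$ aligns with input row $t$; $x(0)$ is not recorded.
Input is injected pre-activation, the standard echo-state construction.
There is no leak term in the default update — "leaky ReLU" names an
activation, not leaky integration — but a leak-rate hook
$x(t) = (1-a)x(t-1) + a f(\cdot)$ is exposed for users who want it
(`leak_rate`, default 1 = off).

Supported activations: `linear`, `tanh`, `sigmoid` ($1/(1+e^{-z})$),
`relu`, `leaky_relu` (slope in $(0,1)$). Note that the sigmoid has
$f(0) = 0.5$, so its zero-input equilibrium is nonzero; the zero fixed-point
property tested for the other activations does not apply to it. With
unbounded activations the simulator aborts with a diagnostic (first
offending timestep) once any state magnitude exceeds $10^6$, rather than
silently overflowing.

`alpha` is defined against the spectral radius (largest absolute
*eigenvalue*, not singular value): `scale_to_alpha()` computes
$W' = \alpha W / \rho(W)$, which retargets rather than compounds when
applied repeatedly. Dynamics are stable (fading memory) for
$\alpha < 1$, approximately critical at $\alpha = 1$ and chaotic beyond;
nilpotent graphs such as a pure delay line have $\rho = 0$ and cannot be
spectrally scaled, which the package reports as a degenerate input rather
than guessing a scale.

### Input routing

At the simulator level the default input map broadcasts every channel with
weight 1 onto every selected input node — the simplest stated convention.
The workflow layer (`run_experiment()`) instead defaults to a seeded
uniform-random map, drawn once per experiment: with the broadcast map every
input node receives the channel *sum*, and for the decision tasks below the
two stimulus streams sum to a constant by construction, which would cancel
the discriminative signal before it enters the network. The random map
keeps distinct channels distinguishable while remaining fixed and
reproducible.

### Spiking (LIF) reservoir

The continuous-time option integrates, with the forward Euler method,

$$\tau_m \frac{dV_i}{dt} = -(V_i - v_{rest}) + I_{syn,i} + I_{ext,i},$$

with threshold-reset firing and an absolute refractory period during which
the membrane is clamped at the reset potential. Each presynaptic spike
drives the double-exponential synaptic kernel

$$w_{ji}\,\frac{e^{-t/\tau_{decay}} - e^{-t/\tau_{rise}}}{\tau_{decay} - \tau_{rise}},$$

implemented with two auxiliary exponential state variables updated by exact
decay factors per step, so the kernel's tail decays at exactly
$e^{-dt/\tau_{decay}}$ per step. Time constants may be vectors, giving
heterogeneous synapses per neuron. Defaults (`dt` 0.1 ms, $\tau_m$ 20 ms,
$v_{rest}$ = $v_{reset}$ = −65 mV, $v_{thresh}$ −50 mV, $t_{ref}$ 2 ms,
$\tau_{rise}$ 0.5 ms, $\tau_{decay}$ 5 ms) are standard cortical LIF
figures and fully configurable. The constraint $dt < \tau_{rise}$ is
enforced so the kernel is resolved. External channels are injected as
currents into input nodes; each task timestep is held for
`steps_per_input` integration steps (default 100, i.e. 10 ms per task
step), and filtered synaptic traces (or windowed rates) serve as the
continuous states the readout consumes. An `inhibitory_mask` flips the sign
of flagged neurons' outgoing weights; richer interneuron semantics are out
of scope.

Two closed forms anchor the implementation: the constant-current interspike
interval $\tau_m \ln\frac{I-(v_{reset}-v_{rest})}{I-(v_{thresh}-v_{rest})} + t_{ref}$
and the kernel peak time
$\frac{\tau_{rise}\tau_{decay}}{\tau_{decay}-\tau_{rise}}\ln\frac{\tau_{decay}}{\tau_{rise}}$;
both are verified to within $2\,dt$ by the test suite and the acceptance
script.

## Tasks

All generators are pure functions of their parameters and a seed.

* **Perceptual decision making** — two-alternative forced choice. Channels:
  x1 constant bias (1 within the trial), x2/x3 noisy streams with
  generating means $b \pm \delta$ during the stimulus epoch; the label (1
  if x2's generating mean is higher, else 2) is emitted during the decision
  epoch and 0 (fixation) elsewhere. The trial's $\delta$ is drawn from the
  signed coherence set.
* **Context-dependent decision making** — seven channels: bias, a one-hot
  two-channel context cue active throughout the trial, and two stimulus
  pairs (one per modality), both present every trial; the label follows the
  cued modality only. Note the label is an exclusive-or of cue and
  coherence sign, so it is *not* a linear function of the raw channel
  means — solving it requires the nonlinear mixing the reservoir provides,
  and the solvability ceiling is checked on the cued decision variable.
* **Memory capacity** — a single uniform $[-1, 1]$ stream with `max_lag`
  targets $y_k(t) = u(t-k)$; the first `washout + max_lag` steps are masked
  from scoring. $MC = \sum_k \text{corr}(y_k, \hat y_k)^2$ (squared Pearson
  per lag, summed — the standard definition in the echo-state literature),
  bounded by `max_lag`; the per-lag curve and its mean are both reported,
  since published capacity curves are sometimes drawn on either scale.

Defaults the task descriptions leave open were fixed once as follows:
epochs of 3 (fixation), 10 (stimulus), 3 (decision) timesteps; coherence
set $\{\pm 0.1, \pm 0.2, \pm 0.4\}$ around baseline 0.5 with noise sd 0.25
(large enough that accuracy is not saturated at every alpha); memory-task
`max_lag` 20 and `washout` 100. Scoring uses decision-epoch timesteps only
(the `decision_mask`); trial-level predictions are the majority vote over a
trial's decision timesteps, ties resolving to the lower label, and both
trial-level and per-timestep scores are reported. Splits are 70/30 by
trial, never cutting a trial; the single-trial memory task splits the time
axis contiguously, training first.

## Readout

The readout is a ridge model on z-scored features (training-set statistics)
with an unpenalized intercept, default $\lambda = 1$: classification is
ridge regression onto $\pm 1$ indicators ("ridge classifier": the task
names a ridge classifier without specifying a loss, and ridge-on-labels
matches that name; one-vs-rest with argmax beyond two classes). The solver
uses the augmented-QR route ($[X; \sqrt\lambda I]$), which the tests check
against an independent normal-equations brute force to $10^{-8}$; with
$\lambda = 0$ and a rank-deficient design it falls back to the
pseudoinverse with a warning.

## Null models and inference

`rewire_null()` produces degree-preserving surrogates by Maslov–Sneppen
double-edge swaps (10 swap trials per edge by default, the common figure
for this family of nulls), rejecting self-loops and multi-edges; the swap
core is delegated to igraph. Weighted networks are rewired on their binary
topology and the original weight multiset is permuted onto the surviving
edges, so density, degree sequence and the weight distribution are
preserved exactly. Undirected networks are rewired as undirected. A
replicate on which no swap is possible (e.g. a complete graph) is returned
as a weight-permuted copy, flagged, with a warning — degenerate inputs are
surfaced, not papered over.

`null_comparison()` runs the identical pipeline on the empirical network
and every surrogate with matched datasets (the same master seed drives all
networks — a paired design that removes dataset-to-dataset variance from
the contrast). The statistic is the realization-mean metric at a fixed
alpha or its peak over the grid, and
$p = (1 + \#\{\text{null} \ge \text{emp}\})/(1 + R)$, whose minimum with
$R = 500$ nulls is $1/501 \approx 0.002$. The calibration of this procedure
is itself under test: when the "empirical" network is drawn from the same
null generator, the rejection rate at the 0.05 level over 200 miniature
experiments must stay near nominal.

`stratified_readout()` fits an independent readout per partition label on
the *same* simulated trace, so modules are compared on identical dynamics,
and summarizes the module contrast with a one-way ANOVA across realizations
(realizations, not trials, are the exchangeable unit here: each realization
is an independent dataset draw, while trials within a realization share a
simulation). $MS_{within} = 0$ yields $F = +\infty$, reported explicitly
with a note rather than as NaN.

## Randomness and determinism

Every source of randomness derives from one master seed through a
deterministic integer-hash fan-out (iterated Lehmer steps modulo
$2^{31}-1$), one stream per realization/replicate. Consequences: reruns are
bit-identical, growing `n_realizations` leaves earlier realizations
unchanged, and null replicates are independent given the ensemble seed.
Library functions save and restore R's global RNG state, so calling them
does not perturb user code.

## What the synthetic generators do and do not emulate

The fixture generators (`random`, `modular`, `delay_line`, `ring`) stand in
for empirical connectomes in every test: they reproduce the *formal*
properties the pipeline relies on (square weighted adjacency, directedness,
modular partitions, known spectral radii, known memory depth). They do not
reproduce the heavy-tailed weight distributions, geometric wiring cost,
hub concentration or community structure of real connectomes — so green
tests certify the machinery (scaling, simulation, learning, inference
logic), not any claim that a particular brain's topology outperforms its
nulls. Running the same workflow on empirical matrices is exactly what the
package is for, but those matrices are external downloads and no test
depends on them.

## Problem sizes

The test suite and acceptance script run at deliberately modest scales,
chosen as the smallest sizes at which each property is unambiguous: 100
networks of 50–200 nodes for scaling exactness, a 100-node network with 100
rewired replicates for null integrity, 200-step horizons for the
echo-state/chaos contrast, a 2000-step series for the delay-line oracle,
200 miniature experiments of 20 nulls each (24-node networks, 150-step
memory task) for calibration, and 20 realizations of a 100-node network for
the stable-versus-chaotic trend. All of these are configuration values, not
limits of the implementation.

## Known limitations

* Readouts are open-loop: no output feedback into the reservoir, and no
  training of recurrent weights (deliberately — that is the paradigm's
  point).
* Conduction delays, plasticity, conductance-based synapses and
  spike-train input encodings are out of scope; external input to the LIF
  reservoir is a current injection.
* Negative weights are rejected unless explicitly allowed; how signed
  empirical connectomes should be preprocessed before spectral scaling
  (e.g. log-transformation of streamline counts) is left to the user, as a
  config choice upstream of the pipeline.
* The connectome loader reads dense plain-text matrices (CSV/TSV, optional
  id header); binary array formats should be converted upstream.
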