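---
title: "Fitting Markov models of channel gating: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fitting Markov models of channel gating: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gatefit)
```

## The model

A gating model is a continuous-time Markov chain on a small set of
conformational states. The occupancy vector $x(t)$ evolves under the master
equation

$$\frac{dx}{dt} = Q(v)\,x,$$

where the generator $Q(v)$ collects the voltage-dependent transition rates:
`Q[i, j]` holds the rate from state $j$ to state $i$ for connected pairs and
each diagonal entry is minus the sum of the rates leaving that state, so
columns sum to zero and total occupancy is conserved. Whole-cell conductance
is the dot product of the occupancy with a per-state relative conductance
vector $G$, and current is conductance times the driving force
$v - E_\mathrm{rev}$.

### Rates that respect microscopic reversibility

Most channels satisfy detailed balance: at equilibrium the probability flux
balances on every edge, $r_{ij} s_i = r_{ji} s_j$, equivalently the product
of rates around any cycle is equal in both directions at every voltage.
Rather than constraining rates after the fact, `gatefit` *generates* them
from independent parameters. Every state carries a vector $\alpha_i$ and
every edge a vector $\beta_{ij}$, both of the basis dimension $F$, with

$$s_i(v) = e^{f(v)\cdot\alpha_i}, \qquad
  k_{ij}(v) = r_{ij} r_{ji} = e^{f(v)\cdot\beta_{ij}},$$

where $f(v)$ is a small feature vector of voltage. The per-edge pair
(balance equation, product equation) is a linear system in
$(\ln r_{ij}, \ln r_{ji})$ whose closed-form solution

$$r_{ij} = \sqrt{k_{ij}\, s_j / s_i}, \qquad
  r_{ji} = \sqrt{k_{ij}\, s_i / s_j}$$

satisfies detailed balance identically in $v$, for any parameter values.
The equivalent stacked-matrix solve (a $2E \times 2E$ block system with
blocks $[[1,-1],[1,1]]$) is retained as an independent oracle in the test
suite; the two routes agree to $10^{-12}$ on the log scale.

Because $s$ enters only through differences $\alpha_j - \alpha_i$, one state
row is not identifiable; state 1's $\alpha$ is pinned to the zero vector
(gauge fix). A useful corollary of the construction: the normalized $s(v)$
*is* the stationary distribution of $Q(v)$, which the tests verify to
$10^{-8}$.

### Voltage bases

Three bases are provided (`voltage_basis()`):

* **linear** — $f(v) = (1, v)$, the constant-temperature Eyring form
  $r = e^{\theta_1 + \theta_2 v}$. Works well, but rates grow exponentially
  in $|v|$, which invites stiffness.
* **polynomial** — $f(v) = (1, v, \dots, v^n)$. More expressive; prone to
  overfitting and even stiffer.
* **sigmoid** — $f(v) = (1, \mathrm{sig}((v - a)/b))$ with the logistic
  function and fixed midpoint $a$ and slope $b$ shared across all rates.
  Rates are bounded in voltage, which limits stiffness by construction.
  The defaults $a = -40$ mV, $b = 15$ mV place the transition in the
  mid-physiological range; both are configurable.

Units are fixed throughout: time in ms, voltage in mV, rates in 1/ms.

## Protocol simulation by matrix exponential

Voltage-clamp protocols are sequences of constant-voltage steps, so the
master equation is piecewise linear-time-invariant and the exact solution of
each step is $x(t) = e^{tQ} x_0$ — no ODE integrator is needed. Unrecorded
steps cost one matrix exponential; recorded steps precompute
$H = e^{Q\,\Delta t}$ once and sample occupancy by repeated application
("powering up"). An adaptive-step ODE backend (`deSolve::lsoda`, with a
`radau` retry and a compiled right-hand side) is kept as an independent
reference; the two backends agree to better than $10^{-6}$ in occupancy
across the packaged Na$^+$ protocol suite.

### Numerics of the exponential

Pade scaling-and-squaring (the textbook algorithm) loses probability
conservation catastrophically once $\lVert tQ \rVert$ exceeds roughly
$10^9$: tens of repeated squarings amplify roundoff without bound. The
generators built here are reversible, which admits a stable alternative:
with $D = \mathrm{diag}(\sqrt{\pi})$, the matrix $A = D^{-1} Q D$ is
symmetric with off-diagonals $\sqrt{Q_{ij} Q_{ji}}$, and

$$e^{tQ} = D\, U e^{t\Lambda} U^{\!\top} D^{-1}$$

from the orthogonal eigendecomposition of $A$. The null mode is known
exactly (eigenvector $\sqrt{\pi}$) and is deflated and re-added exactly, so
the stationary direction carries no eigenvalue error; the result is then
projected back onto the column-stochastic manifold (roundoff negatives
zeroed, columns renormalized) so that repeated powering conserves mass to
machine precision. Non-reversible inputs fall back to Pade
(`arma::expmat`).

Even this route has a limit: for $\lVert Q \rVert \gtrsim 10^{12}$ /ms the
absolute eigenvalue error $\varepsilon\,\lVert A\rVert$ swamps slow modes
and *no* double-precision method (including stiff ODE solvers, whose
right-hand sides suffer the same flux cancellation) can deliver the
dynamics. `gatefit` refuses to pretend otherwise: a strict conservation
gate raises a typed stiffness-overflow error, the cost function maps it to
an infinite cost, and the annealer rejects the model. The same reasoning
motivates the guard $|\ln r| \le 700$ on individual rates. Clipping rates
instead was rejected because dependent rates would silently violate
microscopic reversibility; the sanctioned mitigation is the stiffness
penalty below.

The steady state is likewise computed from the detailed-balance structure
when present (log-domain spanning-tree potentials, exact for rate ratios
spanning hundreds of log units), because the generic ones-row linear solve
and eigen fallback lose the small occupancy components once rates span more
than ~12 orders of magnitude. The generic routes remain for non-reversible
input generators.

## Protocols, features, and cost

A `protocol()` is a holding potential, an ordered list of steps (each a
voltage and duration, either of which may be the sweep placeholder), a list
of sweep values, a reversal potential, and one feature specification. The
packaged Na$^+$ suite (reversal +50 mV) encodes: activation G-V from a
$-100$ mV resting potential with pulses $-120$ to $+20$ mV in 10 mV steps;
steady-state inactivation with 200 ms conditioning pulses from a $-120$ mV
hold followed by a $-20$ mV test pulse; recovery from inactivation with a
200 ms conditioning pulse and recovery intervals of 1–1000 ms at $-120$ mV;
10–90% rise and 90–20% fall times of the activation pulses; and a 5 ms
normalized conductance trace at $-10$ mV. The K$^+$ suite (reversal
$-90$ mV) encodes activation from $-100$ to $+60$ mV in 20 mV steps, a
deactivation protocol (2 ms pulse to $+60$ mV, then 4 ms conditioning
pulses from $-120$ to 0 mV, scored by minimum absolute current over driving
force), rise times, and 4 ms traces at $-20/0/+40$ mV from a $-80$ mV
rest. Where the experimental descriptions leave pulse lengths or sampling
unstated, the package uses 20 ms pulses at $\Delta t = 0.005$ ms for Na-style
and $\Delta t = 0.01$ ms for K-style recordings.

Design notes on features:

* Peaks are taken as the maximum of the sampled conductance trace; within
  one sweep the driving force is constant, so peak current over driving
  force reduces to peak conductance.
* Rise and fall times interpolate threshold crossings linearly between
  samples; a trace that never crosses its thresholds yields a *missing*
  feature, which contributes a fixed squared-error of $10^2$ per affected
  row instead of aborting, so the optimizer can walk out of pathological
  regions.
* Sweep voltages within 1 mV of the reversal potential are rejected at
  protocol validation (the driving force vanishes there).
* Each protocol extracts exactly one feature, so rise and fall times are
  two protocol objects sharing one step definition, and the three K$^+$
  traces are one protocol object per pulse voltage. Cost rows join on
  (protocol, x).

The cost of a model against a dataset is
$\sum_r w_r (\hat y_r - y_r)^2 + \lambda\, S(m)$, where $S(m)$ is the
**stiffness penalty**: the largest-magnitude eigenvalue of $Q(v)$ over the
grid $-120, -110, \dots, +20$ mV. Stiff models force tiny steps on any ODE
integrator that later consumes the fitted model (e.g. in action-potential
simulation) and are physically implausible; a small penalty
($\lambda = 10^{-4}$ per ms$^{-1}$ by default, 0 disables) demonstrably
steers fits toward models whose spectral radius is an order of magnitude
smaller, at slightly higher data cost. Each data row has unit weight by
default; per-row weights are in the dataset format.

## Optimization: synchronous multi-chain simulated annealing

`anneal()` maintains `n_chains` independent models sharing one exponential
temperature schedule $T(t) = T_0 \gamma^t$. Per iteration and chain, a
proposal is drawn, its cost evaluated, and Metropolis acceptance applied:
downhill always, uphill with probability $e^{-\Delta e / T}$. Chains never
exchange information; each owns an RNG stream derived from the master seed,
so results are bit-reproducible and independent of the order in which
chains are advanced.

Every proposal applies a **rate update**: each parameter entry is touched
with probability $p$ by adding zero-mean normal noise. The kernel is scaled
per basis column by the typical magnitude of the corresponding voltage
feature over $[-120, 60]$ mV — a linear-basis slope entry acts multiplied
by ~100 mV, so its proposals are ~100-fold smaller than offset proposals.
Without this scaling, slope proposals are effectively catastrophic jumps
and chains freeze far from any optimum. Passing vectors for `p`/`sigma`
defines a mixture kernel (one component drawn per proposal). Structural
moves fire independently with their configured probabilities: state
addition (new non-conducting state joined by one random edge, parameters
from the initialization distributions), state removal (with random
spanning-tree reconnection of any disconnected components and re-gauging of
$\alpha$), edge addition, edge removal (with reconnection), and an optional
conductance flip that relocates the single conducting state (off by
default; the conductivity vector is otherwise fixed at initialization).
Inapplicable moves are skipped. Every visited model passes structural
validation and keeps detailed balance by construction.

Initialization draws connected graphs by a first-entry random walk (the
entering edge is added whenever an unvisited state is first reached),
optionally adds extra edges with a fixed probability, and draws offset
parameter entries from $N(0, 1)$ and voltage-dependent entries with
standard deviation 0.2 — the latter keeps initial rates within numerical
range across physiological voltages under the linear basis. $T_0$ defaults
to the median initial chain cost (a scale-free start).

### The recovery benchmark

The package's end-to-end benchmark generates synthetic targets from the
fixed 3-state closed–open–inactivated ground truth (`ground_truth_model("na3")`)
over the reduced Na$^+$ suite, adds 1% Gaussian feature noise, and anneals
8 chains for 5,000 iterations. Configuration choices, made once and
documented here:

* **Suite**: the four everywhere-defined curves — activation G-V, SSI,
  recovery, and the normalized trace. Rise/fall-time features are undefined
  wherever a candidate trace fails to cross the 10/90/20% thresholds, which
  makes them flat +100-per-row plateaus over large regions of model space;
  features that cannot guide the search are poor recovery targets (they are
  validated separately against closed forms). Reduced variants use every
  other sweep value, 50 ms conditioning, 10 ms pulses and
  $\Delta t = 0.05$ ms, sized so the full benchmark runs in minutes on one
  CPU.
* **Penalty off** ($\lambda = 0$): the benchmark compares the achieved cost
  to the pure noise floor $\sum_r w_r\,\mathrm{noise}_r^2$, so the cost must
  measure the same quantity; the stiffness penalty gets its own dedicated
  penalized-vs-unpenalized comparison.
* **Schedule**: $T_0 = 20$ (roughly the initial data-cost scale),
  $\gamma = (10^{-5}/20)^{1/5000}$ so the end temperature sits well below
  the per-row noise scale and the final ~third of the run is pure
  refinement.
* **Kernel**: $\sigma = 0.35$, $p = 0.25$; structural moves at 0.02 each
  with conductance flips at 0.05; chains start as random 3-state spanning
  trees.

The packaged acceptance checks assert, for a fixed seed, that the best of
8 chains lands within 5 times the noise floor with the G-V half-activation
voltage within 2 mV of the truth; `scripts/acceptance.R` re-runs the same
benchmark from scratch at an arbitrary seed and reports both quantities.

## What the synthetic generator does and does not emulate

`synth_dataset()` adds i.i.d. Gaussian noise to *features* (scaled by each
protocol's feature magnitude), not to raw current traces, because the cost
operates on features and no noise model for the source recordings is
available. Real voltage-clamp data additionally carry leak and capacitance
artifacts, series-resistance error, non-stationary noise, sweep-to-sweep
drift, and cell-to-cell variability — none of which are modeled. Passing
the recovery benchmark therefore demonstrates that the optimizer can invert
the forward model under honest noise; it does not certify performance on
real Nav1.5/KCNQ1 recordings, whose published values exist only in figure
form. Feature rows that are undefined for the ground-truth model (e.g. a
fall time at a voltage where the channel barely opens) are dropped — an
experimenter could not have measured them either.

## Known limitations

* No continuous-voltage (action-potential) simulation, state aggregation,
  identifiability analysis, or single-channel stochastic trajectories.
* One-way (irreversible) transitions are unsupported by design: the rate
  construction presumes detailed balance.
* Models whose rates exceed double precision's simulable range raise typed
  errors rather than producing approximate dynamics; fits avoid such
  regions via the infinite-cost sentinel and the stiffness penalty.
* The annealing defaults are tuned for the packaged benchmark scale;
  fitting larger models or richer datasets will need schedule and kernel
  adjustments through `anneal_config()`.
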