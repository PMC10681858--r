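---
title: "Models, numerics and design choices in stochcirc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, numerics and design choices in stochcirc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stochcirc)
```

This vignette is the package's account of its science: the models it
implements, the assumptions behind them, the numerical choices that matter,
and the points where the design was genuinely open and we had to commit to
one option.

## 1. The circuit model

A gene regulatory circuit couples $N$ genes through the two-stage expression
network: transcription at rate $k_{m_i} c_i(X)$, translation at
$k_{x_i}\,\mathrm{mRNA}_i$, and first-order degradation of mRNA
($\gamma_{m_i}$) and protein ($\gamma_{x_i}$). All regulation enters through
the dimensionless promoter activity $c_i$, for which we use the leaky
product of Hill functions

$$c_i(X) = \varepsilon_i + (1 - \varepsilon_i)
  \prod_{j:\,T_{ij} \neq 0} h_{ij}(X_j), \qquad
  h_{ij}(x) = \frac{x^{n_{ij}}}{K_{ij}^{n_{ij}} + x^{n_{ij}}}
  \ \text{or}\ \frac{K_{ij}^{n_{ij}}}{K_{ij}^{n_{ij}} + x^{n_{ij}}},$$

increasing for activation ($T_{ij} = +1$), decreasing for repression
($T_{ij} = -1$). The product form means co-regulators act as an AND gate on
the promoter; $\varepsilon_i \in [0, 1)$ is the residual activity of a fully
repressed promoter. The literature uses several algebraically different
input-function families (sums of Hills, thermodynamic occupancy models); we
committed to the product form because it is the convention of the
semi-Lagrangian solver lineage this package follows, and kept the edge
response pluggable (`evaluate_input_gene(hill_override = )`) so a different
family can be registered without touching the solvers. Time-varying or
extrinsic-noise inputs are *not* implemented; the override hook is the
extension point for them.

Parameters live in molecules and reciprocal model time units. Two derived
quantities organize everything downstream: the burst size
$b_i = k_{x_i}/\gamma_{m_i}$ (mean proteins per mRNA lifetime) and the burst
frequency $a_i = k_{m_i}/\gamma_{x_i}$ (transcription events per protein
lifetime).

## 2. Exact simulation (SSA)

`ssa_simulate()` is Gillespie's direct method over the $4N$ reactions:
exponential waiting time in the total propensity, linear candidate scan
(fine at this reaction count), implemented in C++ with a self-contained
xoshiro256++ generator. Each ensemble member seeds its own stream from
`(master seed, run index)` through a splitmix64 mix, so `ssa_ensemble()` is
bitwise reproducible and independent of execution order — R's own RNG
cannot be split per run this way, which is why the generator is internal.
Trajectories are recorded by piecewise-constant sampling onto a requested
time grid (the state at the largest event time $\le t$), avoiding event-list
blowup on long runs; the full event list remains available with
`record = "events"` for structural checks.

## 3. The PIDE approximation and its solver

Solving the chemical master equation directly is hopeless beyond toy state
spaces. In the bursty regime — mRNA much shorter-lived than protein,
$\gamma_m \gg \gamma_x$ — mRNA can be eliminated and protein production
becomes a compound point process: transcription events at rate
$k_m c(X)$, each injecting an exponentially distributed protein burst of
mean $b$. The density $P(t, X)$ over continuous protein levels then obeys a
degradation-drift plus jump-integral equation, which `pide_solve()` /
`pide_stationary()` integrate on a uniform tensor grid (up to 3 genes;
higher dimensions are refused rather than attempted on dense grids).

Two modeling commitments deserve a flag. First, the jump term is
implemented **with** its loss part $-k_m c(X) P$; probability conservation
requires it even though compact statements of the equation often leave it
implicit in the gain integral. Second, the burst kernel is exponential with
mean $b_i$ — the fast-mRNA limit of the two-stage network; the kernel's
mean is the only place mRNA kinetics survive in the PIDE.

The numerical scheme, per time step and dimension in fixed index order
(first-order operator splitting):

1. **Advection.** $\partial_t P = \partial_x(\gamma_x x P)$ is solved
   exactly along characteristics: $P(x) \leftarrow e^{\gamma_x \Delta t}
   P(x e^{\gamma_x \Delta t})$, with linear interpolation at the
   characteristic foot and zero extension beyond the grid (the truncation
   $x_{\max} = 4\times$ the full-activity stationary mean makes the tail
   negligible by construction). Because pure decay transports no mass
   through either boundary, each interpolation column is rescaled to carry
   exactly its basis function's integral; this makes the half-step exactly
   conservative at a $1 + O(h^2)$ correction that cannot break positivity.
2. **Bursts.** The gain integral is evaluated by *product integration*:
   the exponential kernel is integrated in closed form against the
   piecewise-linear interpolant of $c \cdot P$, giving a lower-triangular
   matrix whose row $k$ sums to exactly $1 - e^{-x_k/b}$, the true kernel
   mass on $[0, x_k]$. (Plain trapezoid weights were measurably worse: at
   the fixture grid resolutions the per-step mass drift violated our own
   $10^{-3}$ conservation budget.) Gain minus loss is applied by explicit
   Euler.
3. **Cleanup.** Negative values (roundoff-level by construction) are
   clipped, and the field is renormalized to unit trapezoidal mass unless
   `renormalize = FALSE` — the flag exists so conservation tests can watch
   the raw drift, which the diagnostics `mass_pre` and `clipped` expose on
   every step.

**Time step.** A semi-Lagrangian scheme has no advective CFL limit, and
*smaller is not better*: every step re-interpolates, so interpolation
diffusion accumulates proportionally to the number of steps, while the
explicit jump update contributes $O(\Delta t)$ error. The default,
`pide_default_dt()`, takes a two-cell characteristic displacement at the
domain edge, $2/\max_i(\gamma_{x_i}(n_i - 1))$, capped by the positivity
bound $0.25/\max_i k_{m_i}$ for the Euler jump; on the analytically
solvable constitutive circuit this balance point minimizes the L1 error
against the closed-form stationary law (the acceptance script recomputes
that error). Steps larger than the cap are subdivided automatically with a
warning.

**Oracles.** For a single unregulated gene the stationary law is the Gamma
density with shape $a = k_m/\gamma_x$ and scale $b = k_x/\gamma_m$. The
test suite verifies the closed form by residual substitution (one solver
step started *at* the discretized Gamma must barely move it) before using
it as the accuracy oracle, checks grid-refinement convergence toward it,
and cross-checks the toggle-switch PIDE solution against a $10^4$-run SSA
ensemble by KL divergence on shared bins.

## 4. Calibration

Model identification fixes the topology and estimates free kinetic
parameters from distribution-valued data. The cost is the summed
Kullback–Leibler divergence $\sum_t D(p_t^{\text{data}} \|
q_t^{\text{model}})$ — for histogram data with large counts, minimizing it
is maximum-likelihood estimation up to an additive constant, which is the
sense in which `calibrate_circuit()` is an ML fitter. Numerical choices:

* model bins are floored at $10^{-12}$ mass (then renormalized) so empty
  bins cannot produce infinities; the bias is negligible at fixture scale;
* model densities are aggregated onto the data bins by exact integration
  of the grid interpolant over each bin (matrix contraction per axis); the
  SSA backend instead counts ensemble samples per bin;
* rate constants and thresholds are searched in log space by default (they
  span decades); leakages and cooperativities linearly;
* parameter vectors whose simulation fails or returns non-finite values
  get a finite penalty ($10^6$ plus a centre-pulling term) rather than an
  exception, keeping the landscape informative for the global optimizer;
* raw sample data are expected to be binned onto a stated grid before
  fitting — no kernel density estimation.

A caution from our own recovery experiments: transcription rate and burst
size compensate each other strongly (both scale the mean), so the cost
surface has a curved valley in $(\log k_m, \log k_x)$. The optimizer's
Nelder–Mead polish phase exists precisely because axis-aligned coordinate
search stalls in that valley.

## 5. Automated design

`design_problem()` encodes a circuit family as one decision vector:
topology entries as ternary integers, cooperativities as bounded integers
(default 1–4, the MINLP framing of regulation steepness), rates and
thresholds as bounded reals. Switching an edge on attaches default
$(K, n)$ regulation parameters; switching it off drops them. Objectives
are pure functions of the decision vector:

* **target stationary / target dynamics** — KL divergence from target
  histograms to the solved distribution (shared machinery with
  calibration);
* **bimodality** — $\sum_{\text{domains}} |\text{mass} - \text{target}|$
  plus a hinge penalty on the distance between the two largest strict
  local maxima of the stationary field (grid-neighbor comparison;
  unimodal fields take the full hinge);
* **oscillation** — minus the height of the *second peak* of the protein
  autocorrelation, defined as the first strict local maximum at positive
  lag (the $R(0) = 1$ peak being the first), with a 0.01 prominence
  threshold to skip noise wiggles. The objective simulates a single
  fixed-seed SSA trajectory (defaults: 20000 recorded samples after 2000
  burn-in) — cheap and deterministic, at the price of a noisier estimate
  than an ensemble average would give; that tradeoff is deliberate.

An adaptation-to-external-signals objective is intentionally absent — no
formula pinned it down — but `design_problem()` accepts any user function
of a circuit, which is the registry for such extensions.

The autocorrelation estimator (`autocorr()`) computes the standard biased
normalized estimator via FFT; a direct double-loop implementation of the
same sum is kept as an independent oracle and the two agree to $10^{-10}$
in the tests. For small problems `enumerate_topologies()` brute-forces
every assignment of the free topology slots, which is how the design search
is validated end-to-end: on the two-gene bimodality problem (all $3^4 = 81$
topologies) the scatter search must return the enumeration optimum —
mutual repression.

## 6. The global optimizer

`minlp_minimize()` is a compact scatter-search heuristic in the enhanced
scatter search mold, not a re-creation of any specific implementation:
Latin-hypercube diversification ($10\times$ dimension), a reference set of
$\max(6, \dim)$ members balancing quality and maximin diversity, pairwise
hyper-rectangle combinations (25% extension beyond the pair's box) with
stochastic rounding of integer slots, greedy replacement, regeneration of
the worst half after 20 stagnant rounds, and a final derivative-free polish
of the incumbent over the real slots only (restarted Nelder–Mead for two or
more real dimensions, shrinking-step line search for one). Two details earn
their keep:

* **exact budget accounting** — the evaluation counter is the contract:
  reported `n_eval` equals the number of objective calls, errors included
  (they count and cost $10^6$);
* **duplicate avoidance** — a combination child identical to an existing
  member has one random slot perturbed (±1 on integer slots) before
  evaluation. On small integer lattices the reference set otherwise
  collapses onto a local optimum and recombines it with itself forever;
  with the perturbation the design benchmark above is solved reliably
  across seeds.

Determinism is end-to-end: one `set.seed()` at entry drives the LHS draws,
combinations and perturbations, and stochastic objectives carry their own
fixed seeds.

## 7. Fixtures and the synthetic-data generator

The three bundled circuits are chosen inside the PIDE's validity regime —
fast mRNA turnover ($\gamma_m/\gamma_x = 10$) and substantial bursts
($b = 5$–$10$) — so that SSA-vs-PIDE comparisons test the *solver*, not the
reduction's asymptotics:

* *constitutive*: $a = 4$, $b = 10$, stationary mean 40 — the analytic
  workhorse (Gamma law, moment formulas);
* *toggle switch*: symmetric mutual repression, cooperativity 3,
  $K = 6$, leakage 0.02 — cooperativity 2 at these rates leaves a shallow
  central ridge between the two states, while 3 gives a cleanly bimodal
  stationary field with anticorrelated modes;
* *repressilator*: three-gene ring, cooperativity 4, $K = 20$, $k_m = 8$ —
  parameters picked so the noisy oscillation is coherent enough for a
  second autocorrelation peak above 0.1 across seeds.

`make_pseudo_data()` emulates distribution-valued observations by binning
SSA ensembles at stated times, optionally after a recorded multiplicative
parameter perturbation (uniform in $[1 \pm \text{perturbation}]$) that
serves as ground truth for recovery experiments. What the generator does
*not* emulate: measurement noise, autofluorescence background, gating
artifacts, or arbitrary-unit scaling of real cytometry data. Passing
recovery tests therefore demonstrate identifiability and correctness of
the fitting machinery under the model's own sampling noise — not
robustness to instrument effects.

## 8. Problem sizes and degenerate inputs

The shipped tests and the acceptance script run at desk scale, chosen to
exercise every claim in minutes on one CPU: 200-point grids for 1-D
stationary accuracy, $61^2$–$81^2$ for the toggle, $64^3$ for three-gene
conservation checks, $10^4$-run ensembles for distribution comparisons,
optimizer budgets of 60 (one free parameter), 300 (three free parameters)
and 250 (topology design over 81 candidates, with memoized objective
values since the objective is pure).

Degenerate inputs are rejected at validation rather than limited through:
zero rates, $K = 0$, $\varepsilon \ge 1$, cooperativity below 1, edge
parameters without a topology edge, grids under 16 points, more than 3
genes on dense grids. Self-regulation is allowed ($T_{ii} \neq 0$); design
problems can exclude it by not freeing the diagonal.

## 9. Known limitations

* The PIDE is the protein-only bursting reduction; it degrades when
  $\gamma_m \not\gg \gamma_x$ or bursts are small (the Fano factor of the
  two-stage network is $1 + k_x/(\gamma_m + \gamma_x)$ versus $b$ for the
  continuous Gamma law — close only in the bursty regime).
* Dense tensor grids cap the PIDE at 3 genes; larger circuits must use the
  SSA backend.
* The gain integral is $O(n^2)$ per grid line; an FFT path would need the
  kernel to be convolutional, which $c_i(y)$ inside the integrand
  prevents in general.
* Calibration reports point estimates only — no confidence intervals or
  profile likelihoods — and weights all histogram bins equally rather than
  by multinomial counting noise.
* The design search is a heuristic: outside the small lattices where we
  can enumerate, there is no optimality certificate.
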