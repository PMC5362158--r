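---
title: "Designing embedded biomolecular tracking controllers with crncontrol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing embedded biomolecular tracking controllers with crncontrol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crncontrol)
```

## The problem

Synthetic biology aims to build feedback controllers out of chemistry
itself: circuits of abstract chemical reactions, later implementable in
DNA strand-displacement chemistry, that force the output of a biomolecular
process to track a prescribed reference concentration. `crncontrol`
implements a complete design workflow for one such architecture — an
inverse-feedforward controller combined with a proportional–integral (PI)
feedback loop around an enzymatic reaction process — together with the
compiler, simulator and analysis machinery needed to evaluate it.

A chemical reaction network (CRN) with $n$ species and $m$ reactions
compiles, under generalised mass-action kinetics, to

$$\frac{dx}{dt} = P\, f(x),$$

where $P \in \mathbb{Z}^{n \times m}$ is the stoichiometric matrix and
$f_j(x) = k_j \prod_s x_s^{\nu_{js}}$ the rate of reaction $j$ with
reactant multiplicities $\nu_{js}$. All reactions are unimolecular or
bimolecular (the substrate that DNA strand displacement can express);
termolecular input is rejected unless explicitly overridden. Species such
as the reference $r$ are *clamped*: they enter rate laws catalytically at
a held concentration and carry no state equation.

## Why feedback alone fails: one-sided subtraction

A tracking controller needs the error $e = r - y$. Concentrations cannot
be negative, and no standard single-rail CRN motif realises the term
$-\gamma x_{i,2}$ that two-sided subtraction would require: placing a
species on the reactant side always multiplies it into the rate, never
negates it alone. The standard four-reaction subtraction motif
(`make_subtraction_onesided()`) therefore computes

$$x_o \to \max(0,\; x_{i,1} - x_{i,2}),$$

and when the difference is non-positive it has *no finite fixed point*:
the intermediate species grows without settling. This package treats that
regime as a first-class outcome — `steady_state()` flags it as
non-converged rather than erroring, and the Monte Carlo analysis excludes
the subtraction intermediates from its instability bound (see below).

The dual-rail encoding (`make_dualrail()`) works around the limitation by
representing every signal as the difference of two species
($u = u^+ - u^-$) with a fast annihilation reaction ($\eta \gg \gamma$;
default $\eta = 1000\gamma$, warning below $100\gamma$). The signed
difference of the output rails then satisfies an exact linear ODE, so
subtraction of any sign is computable — at the price of nine reactions
per operator, which motivates the feedforward architecture instead.

## The plant and its inversion

The controlled process is the minimal enzymatic reaction scheme:
substrate + enzyme $\xrightarrow{k_{r1}}$ complex
$\xrightarrow{k_{r2}}$ product + enzyme, product
$\xrightarrow{k_{r3}} \varnothing$, with conserved total enzyme
$x_T = x_e + x_i$. Its steady-state input–output map inverts in closed
form: with $\alpha = k_{r2}k_{r3}$, $\beta = k_{r1}k_{r2}x_T$,
$\delta = k_{r1}k_{r3}$, the input that holds the output at $r$ is

$$u = \frac{\alpha r}{\beta - \delta r}, \qquad 0 \le r < \beta/\delta.$$

`build_full_ff()` realises this law as a ten-reaction cascade (two gains,
a one-sided subtraction computing $\beta - \delta r$ — always positive in
the feasible range, which is why one-sided suffices — and a division).
The PI chain (`build_pi_chain()`, 13 reactions) supplies an integral and
proportional correction from the one-sided error $\max(0, r - y)$, and
the assembled loop (`assemble_closed_loop()`) has 26 reactions; a
first-order Taylor approximation $u \approx (\alpha/\beta)\, r$ reduces
the feedforward branch to a single gain and the loop to 18 reactions.
Because the feedforward carries the load, the PI loop only needs to trim
transients — the configuration in which a one-sided error signal is
harmless.

## Tunable parameters

Defaults are the nominal design values (dimensionless-consistent units;
concentrations and times are left abstract, consistent with the source
design):

| group | parameter | default | meaning |
|---|---|---|---|
| process | `kr1`, `kr2`, `kr3` | 0.005, 1.6, 8e-4 | binding, catalytic, degradation rates |
| process | `xT` | 5.5 | total enzyme |
| feedforward | `gGa`, `gGd`, `gSbI`, `gD` | 1.0 | operator rates |
| PI | `KP`, `KI` | 0.02, 2.5e-8 | proportional / integral gains |
| PI | `gGKP`, `gSmI` | 1.0, 4e-4 | gain-operator and Summation I rates |
| wiring | `gSbII`, `gSmII` | 3.0, 1.0 | Subtraction II / Summation II rates |
| reference | — | 4 on [0, 40000) s, 1 after | benchmark tracking task |

The benchmark experiment evaluates the signed relative steady-state error
$100\,(\hat y(t_k) - r_k)/\hat y(t_k)$ at $t = 40{,}000$ s (step-up) and
$t = 80{,}000$ s (step-down).

## Numerical choices

* **Integrator.** No stiff ODE solver package is available in the target
  environment, so the package ships its own: a Rosenbrock 2(3) scheme
  (the `ode23s` linearly implicit method) with the analytic mass-action
  Jacobian, compiled in C++. Rosenbrock methods need one LU
  factorisation and three linear solves per step and are A/L-stable,
  which matters here: the circuits mix annihilation rates up to $10^3$,
  binding rates up to $10^6$ and an integral gain of $2.5\times10^{-8}$
  in the same system. Default tolerances are `rtol = 1e-8`,
  `atol = 1e-10`; the Monte Carlo analysis relaxes to `1e-6`/`1e-9`
  (the envelope is a min/max statistic; we verified the nominal
  steady-state errors agree to seven digits between the two settings).
* **Discontinuous inputs.** Piecewise-constant inputs restart the
  integrator at each breakpoint, so reference steps are handled exactly
  and the evaluation times fall on segment ends.
* **Steady-state detection** is long-horizon integration plus a
  derivative test (`max |dx/dt|` relative to the state scale), never
  root-finding — the one-sided motifs have no root to find in their
  deficit regime.
* **Non-negativity.** Mass-action dynamics preserve non-negativity;
  solver undershoot is clipped to zero on output and the largest clipped
  magnitude is logged in the trajectory metadata.
* **Initial conditions.** All circuit species start at zero except the
  free enzyme at $x_T$ — the natural unexcited state; the source design
  does not state its initial conditions, and the handful of published
  sensitivity maxima that depend on the transient (e.g. 29.58% for the
  first Subtraction II term) are reproduced to within ~0.15 percentage
  points under this choice.

## Perturbation analyses

Robustness and sensitivity perturb every *occurrence* of a rate constant
in the closed-loop ODEs independently (`perturbation_targets()`): the
Subtraction II rate appears in five ODE terms, so it contributes five
independent parameters, even though the motif has only four reactions —
one bimolecular reaction contributes a term to two state equations. This
is implemented as per-(species, reaction) multipliers on the
stoichiometric matrix rather than on rate constants. The PI gains and
the three process rates are single parameters; the controller's design
constants ($\alpha, \beta, \delta$, $\Gamma_1$) stay at their nominal
values while the process is perturbed — that is precisely the model
mismatch the feedback must absorb.

Steady-state errors under perturbation arise because summation and
subtraction motifs are only exact when their internal rates are
identical: scaling all terms of an operator together leaves the
equilibrium untouched, while scaling one term alone biases the computed
sum or difference — a property the test suite checks directly.

* **Monte Carlo** (`monte_carlo_robustness()`): $N$ draws of
  $\theta(1 + s\Delta)$, $\Delta \sim U[-1,1]$, with
  $N = 1060 = \lceil \ln(2/(1-c))/(2\varepsilon^2) \rceil$ at accuracy
  $\varepsilon = 0.05$ and confidence $c = 0.99$ (additive
  Chernoff–Hoeffding bound). A run is flagged divergent if any state
  exceeds $10^6$ — *except* the one-sided subtraction intermediates,
  which grow without bound by design whenever output exceeds reference
  and whose magnitude therefore says nothing about loop stability; their
  bound crossings are reported separately
  (`n_unbounded_intermediate`). At scales 0.1 and 1.0 no run diverges.
* **Sensitivity** (`sensitivity_sweep()`): one parameter at a time,
  factors 0.5–2.0 in steps of 0.1, reporting the maximum *signed* error
  per evaluation time. Signed maxima were chosen (over `max |e|`)
  because upward output bias cannot be corrected by the one-sided error
  and dominates, matching the published non-negative tables.
* **Process regimes** (`process_regime_sweep()`): the eight sign
  patterns of $(k_{r1}, k_{r2}, k_{r3})$ at their literature range
  endpoints ($10^{-9}..10^6$, $10^{-2}..10^2$, $10^{-5}..10^{-3}$), with
  a 10% tracking verdict threshold (the source reports only Y/N). Slow
  product degradation ($k_{r3} = 10^{-5}$) defeats both controllers:
  the output decays more slowly than the 40,000 s segments, so the
  one-sided error is pinned at zero. The design remarks prescribe only
  directions for the remedies; the package calibrates the magnitudes
  once: "increase $\gamma$" multiplies the Subtraction I and Division
  rates by $10^6$ and $10^8$ respectively (the division's effective rate
  is $\gamma_D(\beta - \delta r)$, catastrophically small when $k_{r1}$
  is tiny; the two gain blocks are already fast and gain nothing from
  scaling), and "decrease/increase $K_P, K_I$" uses factors $10^{-12}$ /
  $10^8$ (with $k_{r1} = 10^6$ the process small-signal gain is so large
  that any visible PI leakage saturates the output — the remedy is
  effectively feedforward-only control). With these choices the
  package's verdict table matches the published one in all sixteen
  rows.

## Retroactivity

Ideal modularity is the default: the plant reads the control species
catalytically (`x5 + xe -> xi + x5`), so the controller's output ODE is
untouched. With `retroactivity = TRUE` the binding reaction consumes
`x5`, adding the loading term $-k_{r1} x_5 x_e$ to its dynamics — same
reaction count, different products. Neither controller can observe this
loss, so a small steady-state error appears (about 1.6% / 2.3% at the
two evaluation times at nominal parameters, below the 5% band the
analysis asserts).

## DNA strand-displacement compilation

`compile_dsd()` maps every abstract reaction to its strand-displacement
implementation: a unimolecular reaction becomes two steps with
auxiliaries $G, O, T$; a bimolecular one becomes three steps (the first
reversible with backward rate $q_{max}$) with auxiliaries
$L, H, B, O, T$. Fuel species start at $C_{max}$ (default $10^4 \times$
the signal scale), intermediates at zero; the unimolecular first-step
constant is $k/C_{max}$ and the bimolecular forward constant is $k$ with
the back-strand buffered at $C_{max}$ — the choices for which the
emulated kinetics converge to the source kinetics as $C_{max}$ grows,
which the tests verify over $C_{max} \in \{10^2, 10^3, 10^4\}$. The
waste strand is not tracked. Fuel depletion below 50% of $C_{max}$ is
flagged (`check_depletion()`) as a regime violation. Sequence design,
toehold selection and crosstalk are out of scope.

## What the analyses do and do not establish

Everything here is deterministic mass-action simulation of the stated
circuits. A green suite establishes: the compiled ODEs equal the
published closed forms term by term; the operator motifs meet their
equilibrium contracts; the closed loops track the benchmark reference to
within 2% while PI-only control fails the step-down by more than 50%;
and the perturbation analyses reproduce the published sensitivity maxima
and regime verdicts. It does not establish anything about stochastic
(low-copy) behaviour, crosstalk between DNA species, wet-lab rate
feasibility, or references outside the inversion-feasible range
$r < \beta/\delta$.

One behavioural caveat: with the nominal (deliberately small) PI gains,
the PI-only failure demonstration undershoots — its step-down error is
large and *negative* — whereas a PI-only loop tuned aggressively enough
to reach the reference overshoots and fails positively. The failure
magnitude, not its sign, is the robust property, and that is what the
acceptance test asserts.

## A worked example

```{r example, eval = FALSE}
library(crncontrol)

circuit <- assemble_closed_loop("full_ff")
circuit$reaction_count        # 26
traj <- run_tracking(circuit)
relative_ess(traj)            # e_U ~ 0.098%, e_D ~ 0.332%

simp <- assemble_closed_loop("simplified_ff")
percent_reduction(circuit$reaction_count, simp$reaction_count)  # 31

sensitivity_sweep(circuit, parameters = "gSbII_1")$e_U          # ~29.54
```
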