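---
title: "SEDPNR: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SEDPNR: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sedpnr)
```

# The model

SEDPNR is a six-compartment model of how a rumor (or piece of
misinformation) moves through an online population. At any time the
population of size $N$ is split into

* $s$ — **Susceptible**: users who have not seen the rumor;
* $e$ — **Exposed**: users who have seen it but not yet reacted;
* $d$ — **Doubtful**: users who saw it and are undecided;
* $p$ — **Positively infected**: users actively spreading the rumor;
* $n$ — **Negatively infected**: users actively countering it;
* $r$ — **Restrained**: users who have stopped engaging.

The dynamics are a *linear* (constant-hazard) system of ordinary
differential equations:

$$
\begin{aligned}
\dot s &= \mu_1 e + \mu_2 d - \alpha s \\
\dot e &= \alpha s - (\beta_1+\beta_2+\gamma+\mu_1)\,e \\
\dot d &= \gamma e - (\beta_3+\beta_4+\mu_2)\,d \\
\dot p &= \beta_1 e + \beta_3 d - \lambda_1 p \\
\dot n &= \beta_2 e + \beta_4 d - \lambda_2 n \\
\dot r &= \lambda_1 p + \lambda_2 n
\end{aligned}
$$

All ten rates have units of 1/day (one model step is one day).
$\alpha$ is the exposure rate, $\gamma$ the exposed-to-doubtful rate,
$\beta_1,\beta_2$ ($\beta_3,\beta_4$) the rates at which exposed
(doubtful) users become positive/negative spreaders, $\lambda_1,
\lambda_2$ the restraining rates, and $\mu_1,\mu_2$ the rates at which
exposed and doubtful users revert to susceptible. Defaults in
`sedpnr_params()` are all zero; every rate must be supplied explicitly
for a meaningful run.

Two consequences of linearity are load-bearing for the whole package:

1. **Mass conservation.** The six derivatives sum to zero identically,
   so $N$ is invariant. Every integrator and the network simulator are
   tested against this invariant.
2. **Hazards, not mass action.** Flows are proportional to the *source*
   compartment only (e.g. $\alpha s$, not $\alpha s p / N$). This is
   deliberate: it is the form under which the model's published
   benchmark values — the day-100 baseline table and the country-level
   runs — are exactly reproducible, which we verified against closed
   forms before committing to it. The baseline module exposes a
   `mass_action` toggle for comparison, but the constant-hazard form is
   the canonical one.

```{r rhs}
p <- fixtures("sensitivity_a01")$params
sedpnr_rhs(sedpnr_state(s = 299990, p = 5, n = 5), p)
```

# Integration

`sedpnr_integrate()` supports two schemes:

* **adaptive** (default): `deSolve::ode()` with `lsoda`,
  `rtol = atol = 1e-8`, sampled on the integer grid `0..t_end`. This is
  the reference scheme; at these tolerances the conservation drift over
  100 days of a 300,000-person run is below $10^{-9}$.
* **euler**: forward Euler with a `step_size` that must divide 1 evenly,
  so integer days stay on the grid. Euler with step 1 is the
  deterministic skeleton of the network simulation (the per-node
  expectation obeys the Euler recursion exactly), which is why it is
  kept as a first-class scheme rather than an afterthought.

Values in $(-10^{-12}, 0)$ are clipped to zero as floating-point
underflow. A *genuinely* negative compartment under Euler aborts with an
error naming the compartment and step, because it means the per-step
outflow exceeded the compartment — the fix is a smaller step, not
silent clipping. Correspondingly, `sedpnr_params()` warns (it does not
error) when any compartment's total outflow rate exceeds 1/day: such
parameter sets are perfectly valid for the adaptive scheme but unsafe
for unit-step Euler and for the network simulator.

`check_decay_bounds()` verifies the exponential lower bounds implied by
the outflow structure ($s(t) \ge s(0)e^{-\alpha t}$, etc.) and that $r$
is nondecreasing; together these give positivity of solutions.

# Stability analysis

## Basic reproduction number

With linear flows, only the spreading compartments $p$ and $n$ are
"infectious", and the next-generation construction reduces to the
$2\times 2$ block $F V^{-1} = \mathrm{diag}(\beta_1/\lambda_1,\,
\beta_2/\lambda_2)$, so

$$R_0 = \max\!\left(\frac{\beta_1}{\lambda_1},
                    \frac{\beta_2}{\lambda_2}\right).$$

`basic_reproduction_number()` returns both the closed form and the
spectral radius of the computed next-generation matrix, plus an
`agreement` flag; the identity holds to $10^{-12}$ across random
parameter draws in the test suite. The function also exposes the full
$6$-state-inspired $5\times5$ $F$/$V$ layout for inspection. A wider
layout in which the exposed and doubtful compartments are also treated
as infected states does not produce a consistent $FV^{-1}$ for this
model (the product is identically zero), which is why the $(p,n)$-block
alignment is the one the package computes.

## Jacobian

`sedpnr_jacobian()` has two variants. `"corrected"` is the exact
Jacobian of the right-hand side (verified against central finite
differences in the tests). `"as_printed"` reproduces a historically
circulated variant whose only difference is a *positive* $\lambda_2$ on
the $n$-diagonal; that sign is inconsistent with the $\dot n$ equation,
but the variant is retained so the discrepancy is inspectable rather
than papered over.

## Eigenvalue conditions and die-out

Because $(p,n,r)$ are driven by $(s,e,d)$, asymptotics are governed by
the $3\times3$ linear block in $(s,e,d)$. `eigenvalue_conditions()`
returns the closed-form quantities $\delta_1,\delta_2,\delta_3$ built
from that block, the numeric eigenvalues, and two verdicts:

* `dies_out_printed`: the literal inequality
  $\alpha - \sqrt{\alpha^2 + 4\mu_1(\beta_1+\beta_2+\gamma)} > 0$. For
  any $\mu_1 > 0$ this is unsatisfiable (the radicand exceeds
  $\alpha^2$), so the flag is essentially always `FALSE`; it is kept for
  transparency.
* `dies_out_numeric`: `max(Re(eigenvalues)) < 0`, the practical verdict
  the rest of the package relies on.

```{r eig}
ec <- eigenvalue_conditions(p)
round(Re(ec$numeric_eigenvalues), 4)
ec$dies_out_numeric
```

## Equilibria

`sedpnr_equilibrium()` reports two things side by side. The
`closed_form` entry evaluates the circulated endemic-equilibrium
expressions verbatim, with zero denominators flagged and the
corresponding values withheld as `NA`. Those expressions for $p^*$ and
$n^*$ are mutually self-referential; solved as the homogeneous
$2\times2$ system they are, the generic solution is $p^* = n^* = 0$.
The `numeric_fixed_point` is computed independently from the null space
of the system matrix (via SVD), scaled to the requested total. For
strictly positive rates it is the all-Restrained state
$(0,0,0,0,0,N)$ — the rumor always burns out and everyone ends up
disengaged — and the long-run trajectory limit agrees with it:

```{r equil}
eq <- sedpnr_equilibrium(p, total = 3e5)
as.numeric(eq$numeric_fixed_point)
```

Both residuals (`rhs_residual_at_closed_form`,
`rhs_residual_at_numeric`) are reported so the user can see which
candidate actually solves the system.

## Lyapunov diagnostic

A sum-of-squares function $V = \sum_i x_i^2$ has been proposed as a
Lyapunov certificate with $\dot V = 0$ along trajectories. That claim
does not hold algebraically for this system, so
`lyapunov_diagnostic()` *records* $V(t)$ along a supplied trajectory
and reports whether it was empirically constant — it never asserts
constancy. On any genuine epidemic trajectory it is not constant.

# Network simulation

## Generator

`generate_scale_free(n, m, seed)` is a hand-rolled Barabási–Albert
generator: an $m$-clique seed, then each new node attaches $m$ edges by
preferential attachment implemented with a repeated-nodes target list.
The construction is deterministic given `seed`, has no self-loops or
duplicate edges, and produces exactly $m(n-m) + \binom{m}{2}$ edges. We
deliberately did not reuse an off-the-shelf BA generator because the
package's tests and acceptance runs pin the exact edge count and
per-seed determinism of *this* construction; `igraph` is still used
where it is the right tool (see below).

Degree-tail estimation uses `fit_power_law()`, a thin wrapper over
`igraph::fit_power_law(implementation = "plfit")` (Clauset-style
$x_{\min}$ selection). Its calibration test uses an exact
zeta-distribution sampler as the oracle: draws with exponent 2.5 are
recovered within $\pm 0.15$. BA graphs themselves have tails near 3 at
these sizes, and finite-size estimates between roughly 2 and 3.5 are
expected and accepted.

## Dynamics

`simulate_network()` runs a synchronous discrete-time process: each
step, every node draws one uniform variate and moves according to a
categorical distribution whose probabilities are the model rates
interpreted per-step (E: $\gamma, \beta_1, \beta_2, \mu_1$; D:
$\beta_3, \beta_4, \mu_2$). Two hazard modes are provided:

* `"constant"`: S→E fires at rate $\alpha$ regardless of neighbors.
  This is the stochastic counterpart of the ODE: the expected counts
  obey the unit-step Euler recursion *exactly*, which the tests exploit
  by comparing ensemble means against the Euler trajectory at full
  scale (200,020 nodes) under a 3-standard-error binomial band.
* `"neighbor"`: S→E fires only if the node has at least one spreading
  (P or N) neighbor. This reintroduces contact structure; with
  `initial_node_states(..., placement = "superspreader")` seeds can be
  placed on the highest-degree hubs.

Because transitions use rates as probabilities, the simulator rejects
parameter sets with per-step outflow above 1 (the same condition the
Euler scheme needs).

# Baselines and scenarios

`run_baseline()` provides constant-hazard SI, SIR, SIS and the
four-compartment SEDIS precursor, integrated with `lsoda` at
`rtol = 1e-10` so the rounded day-0/10/100 summaries are exact against
the closed forms ($S(t) = S_0 e^{-\beta t}$ and friends).
`comparison_table()` lays several baseline runs side by side after
checking they share a population.

`run_intervention()` integrates the model piecewise with the windowed
rates multiplied by $1-\text{reduction}$, so the rate switch is exact at
the window boundaries; a zero reduction returns the baseline trajectory
identically. Peak reduction is monotone in the reduction fraction.

`distrust_params()` / `run_distrust()` implement the seven-compartment
distrust extension, with a distrustful class $v$ fed from $s$ and
bilinear $(1-\tau)\,v\,e$ infection terms. As written this system is
**not** mass-conserving (the $\nu s$ inflow has no matching outflow and
the bilinear terms inject mass), so `run_distrust()` reports the
running total per step instead of asserting conservation.

`country_rates()` maps a Human Development Index $h \in [0,1]$ and
internet penetration $i \in [0,100]$ (percent) to a recovery constant
$\phi$ and infection constant $\omega$. The default `"table"` convention
($\phi = h/100$, $\omega = (i/100)/10$, rounded to 3 decimals)
reproduces all published country constants; the `"literal"` convention
applies the circulated formula text with the symbols swapped and is
kept for fidelity. `stiffness_run()` turns these into constant-hazard
SIR runs and summarizes depletion times.

# Known discrepancies

The published sensitivity benchmarks (peak total infection 116,354 at
step 31 for $\alpha=0.1$ and 141,874 at step 25 for $\alpha=0.2$, from
initial state $(299990,0,0,5,5,0)$) are **not** reproducible from the
stated parameters under any integration scheme we tried — adaptive,
fixed-step Euler at several step sizes, RK4, sequential updates, and
probability-transform discretizations all land 9–18% high. Swapping
$\mu_1 \leftrightarrow \mu_2$ reproduces both peaks to within 1.2% and
0.4%, which strongly suggests a transcription error in the original
values; the package nevertheless implements the rates exactly as
stated, and its acceptance test for those two peaks fails honestly
rather than adopting the swap.

# Limitations

* The deterministic model is linear; it cannot exhibit
  prevalence-dependent saturation unless the baseline `mass_action`
  toggle is used, and that toggle exists only in the baseline module.
* The network simulator is synchronous with one transition per node per
  step; event-driven (Gillespie) dynamics are out of scope.
* The distrust extension is reported as specified, including its
  non-conservation; no corrected variant is provided.
* Country parameterization is a two-index heuristic, not a fitted
  model.
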