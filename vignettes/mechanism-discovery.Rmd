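---
title: "Discovering parsimonious mass-action mechanisms from concentration-time data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering parsimonious mass-action mechanisms from concentration-time data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Given an overall reaction (say 4A &rarr; B + C) and concentration--time
measurements of the species that can actually be observed, which network of
elementary steps produced the data?  Manual mechanism building is slow and
subjective; purely combinatorial generators drown the modeller in candidates.
`kinmech` takes a data-first middle road: it enumerates *every* physically
sensible mechanism at a given complexity, fits each one, scores them with an
information criterion, and only moves to a more complex mechanism class when
the data rewards the extra parameters.

The pipeline has four phases, plus an optional experiment designer:

1. **Enumeration.**  A mechanism is an integer matrix: one row per elementary
   step, one column per species, negative entries for consumed species,
   positive for produced (net coefficients).  A backtracking search composes
   candidate rows and prunes partial matrices that can no longer satisfy the
   constraints.
2. **Translation.**  Each matrix becomes a mass-action ODE system: step $j$
   has rate $r_j = k_j \prod_i C_i^{|\nu_{ji}|}$ over its reactants
   ($\nu_{ji} < 0$), and $\dot C_i = \sum_j \nu_{ji} r_j$.
3. **Estimation.**  Rate constants minimise the sum of squared errors between
   simulated and observed concentrations over all experiments, by multistart
   L-BFGS-B inside the box $[0, 10]$.
4. **Selection.**  Candidates are ranked by
   $\mathrm{AIC} = 2\,\mathrm{NLL} + 2d$ with $d$ the number of steps.  The
   ladder grows by one step and one hidden intermediate per iteration and
   terminates when the best AIC stops improving strictly; the previous
   winner is returned.

## Feasibility rules

A matrix is feasible when all of the following hold:

* every entry lies in `[entry_min, entry_max]` (default $[-2, 2]$);
* every step has at least one reactant and one product, with at most
  `max_reactant_molecules` (default 2) consumed and
  `max_product_molecules` (default 2) produced, counting multiplicity --
  the four classical archetypes A&rarr;B, A+B&rarr;C, A&rarr;B+C,
  A+B&rarr;C+D.  Termolecular chemistry is admitted simply by raising the
  caps;
* each species column sums to its overall coefficient (zero for
  intermediates), so the mechanism telescopes to the overall reaction;
* an overall reactant is never produced and an overall product is never
  consumed by any step.  These species have a fixed net role in the overall
  reaction; a step regenerating feedstock or consuming product would encode
  that role into a hidden cycle invisible to the column sums;
* intermediates obey *cumulative availability*: scanning steps top to
  bottom, the running sum of an intermediate column never goes negative.
  This is deliberately stronger than only requiring the first production to
  precede the first consumption -- a step consuming two units of an
  intermediate of which only one has been produced is rejected even though
  production came first;
* every declared intermediate column is used by at least one step.
  Complexity classes stay disjoint: a mechanism ignoring its intermediate is
  exactly an earlier, simpler class member and would only duplicate work.

Under these rules the three bundled systems have exactly 2, 31 and 10
feasible matrices at their smallest interesting sizes, which the test suite
pins down both against a brute-force Cartesian filter and as regression
values.  Matrices differing only by row order are distinct outputs (no
canonicalisation), and identical duplicate rows are allowed -- one of the 31
matrices above contains the same 2A&rarr;D step twice, i.e. the step class
"two at rate $k_1$, again at rate $k_2$".

The search is deterministic (lexicographic emit order), can be partitioned
over worker processes by first-row candidate with a result provably
independent of the worker count, and honours a wall-clock budget: on expiry
the partial set is returned flagged `complete = FALSE` rather than blocking.

## Numerical choices

**Integration.**  Candidate mechanisms can be stiff, so the public simulator
`simulate_model()` uses `deSolve::lsoda` (rtol $10^{-6}$, atol $10^{-8}$).
The fitting objective is evaluated hundreds of thousands of times per
iteration, so `model_sse()` defaults to a compiled adaptive Cash--Karp
Runge--Kutta engine with the same tolerance semantics.
A failed integration (step-size underflow, step budget,
non-finite state) contributes a large finite penalty ($10^{10}$) to the SSE
instead of raising, so the optimiser can retreat from blow-up regions.
The suite asserts agreement between the two engines on the case-study
models at random rate constants (to 1e-5 relative).

**Likelihood bridge.**  Estimation minimises the SSE; selection needs a
likelihood.  We use the concentrated Gaussian form with the pooled
maximum-likelihood variance $\hat\sigma^2 = \mathrm{SSE}/N$ substituted in
and additive constants dropped: $\mathrm{NLL} = (N/2)\log(\mathrm{SSE}/N)$,
where $N$ is the total number of observed values.  Constants cancel in every
within-dataset comparison the algorithm makes, which is all the AIC is used
for; absolute AIC values are therefore convention-dependent and only AIC
*differences* are meaningful.  A zero SSE is floored at machine epsilon
times $N$ before the logarithm.

**Multistart.**  Start points are uniform in the bounds box from a seeded
generator, five starts by default, drawn row-wise so that the first start of
an $n$-start fit equals the single start of a 1-start fit (adding starts can
only improve the result).  Within a discovery iteration every candidate gets
its own deterministic seed derived from the master seed, the iteration index
and the candidate index; whole runs are reproducible from one `--seed`.

**Ties and termination.**  All candidates of an iteration share $d$, so AIC
ties are SSE ties; the lexicographically smallest matrix wins (the first
minimum in enumeration order).  Termination treats an *equal* AIC as
worsening: complexity must pay for itself strictly.  A `max_iterations` cap
(default 6) and an optional global wall-clock budget guard against unbounded
ladders.

**Screening large iterations.**  Later ladder rungs can hold thousands of
candidates.  `run_iteration()` optionally fits every candidate at a reduced
budget (fewer starts, fewer optimiser iterations), then refits the
best-screening `top` candidates at the full budget before selecting; the
default remains a full-budget fit of every candidate.  Enumeration is never
truncated and the winner always comes from a full-budget fit; only the
effort spent on clearly poor candidates is reduced.

## What the generators emulate

The three bundled generators reproduce the benchmark study conditions: five
experiments each, thirty samples over the stated horizon, additive zero-mean
Gaussian noise on the observed species only, hidden intermediates started at
zero:

| case | overall | true mechanism | k (true) | noise sd | horizon |
|---|---|---|---|---|---|
| hypothetical | 4A &rarr; B + C | 2A&rarr;D, D&rarr;B, E&rarr;C, 2A&rarr;E | 0.1, 0.2, 0.13, 0.25 | 0.15 on A--C | 10 h |
| aldol | A + B &rarr; C + D | A&rarr;E, E+B&rarr;F, F&rarr;C+D | 0.759, 0.293, 0.681 | 0.15 on A--D | 10 h |
| fructose | A &rarr; 3B + C | pseudo-first-order, $r = k C_A C_\mathrm{acid}$ | 0.9 (1/M/min), $C_\mathrm{acid} = 0.033$ M | 0.2 on A--C | 90 min |

The fructose generator follows the experimentally validated rate law rather
than a hidden-intermediate microkinetic simulation: with constant acid and
isothermal operation at 410.15 K (where the Arrhenius factor is 1 and
$k = k_\mathrm{ref}$) the kinetics are exactly pseudo-first-order with
$k_\mathrm{eff} = k\,C_\mathrm{acid} = 0.0297\,\mathrm{min}^{-1}$.  Noise is
drawn one stream per experiment in column-major order (all times of the
first observed species, then the next), so fixtures are stable across
releases; negative noisy concentrations are retained, because clipping would
bias the zero-mean noise model and hence the fits.

What passing on these datasets does **not** show: the generators are
homoscedastic, isothermal, isochoric and noise-only -- no drift, no
calibration error, no unmodelled side reactions, no missing samples.  Real
datasets violate most of these, and mechanisms recovered from them remain
hypotheses consistent with the data, not guaranteed chemistry.

## Problem sizes used by the tests

The suite exercises the enumeration ladder exactly (2, 31, 10 and a
brute-force equivalence up to $5^8$-sized instances) and the full recovery
of all three true mechanisms from seeded noisy data.  For the discovery
ladder the suite runs the aldol system through its winning third iteration
with every candidate fitted at full budget, the hypothetical system through
its first two rungs, and the fructose system's first two rungs (the
783-candidate second rung screened: 1 start / 25 optimiser iterations for
every candidate, top 15 refitted fully).  On the fructose system the first
two rungs both fit to the noise floor and are separated by a fraction of a
percent of the SSE, so their AIC ordering genuinely depends on the noise
realization.  The terminating rungs of the hypothetical (5x6) and fructose
(5x7) ladders hold $10^5$--$10^6$ candidate fits and are out of desk scale
-- the termination rule itself is instead exercised end-to-end on a small
self-consistency instance whose generating mechanism sits on rung 1.

## The experiment designer

When two rival fitted mechanisms survive, the Hunter--Reiner criterion
picks the next experiment's initial conditions to maximise
$\sum_t \sum_{i \in \mathrm{obs}} (\hat y^{(\nu)}_{ti} - \hat y^{(\mu)}_{ti})^2$,
the squared divergence between their predicted observed trajectories.  Only
initial concentrations of observed species are designable; intermediates
start at zero, matching the experimental setting.  The maximisation reuses
the seeded multistart L-BFGS-B machinery on the negated divergence (ten
starts by default).  The closed loop -- design, run or simulate the new
experiment, merge, rediscover -- is deliberately left as a documented
two-command workflow rather than automated: the modeller decides whether
the budget is better spent discriminating or validating.

## Known limitations

* Net-coefficient rows cannot express catalytic steps like A + B &rarr; 2B;
  rate laws derive from negative entries only.
* Intermediates are kinetic placeholders; nothing identifies their
  chemistry.
* No reversible-step notation (a reverse step must be enumerated as its own
  row), no temperature dependence inside candidate models, no
  heteroscedastic weighting, no uncertainty quantification on the
  estimates.
* Concentration and time units are carried as metadata, never converted;
  rate-constant units follow from the data's units.
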