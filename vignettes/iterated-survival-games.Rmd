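---
title: "Iterated survival games: model, cutoffs, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Iterated survival games: model, cutoffs, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(survgame)
```

## The model

Two players face an environment for `n` discrete steps. In each step a player
either cooperates (`C`) or defects (`D`), and survives the step with a
probability set by the pair of behaviors: `a` when both cooperate, `b` when
the player cooperates against a defector, `c` when the player defects on a
cooperator, and `d` when both defect. Survival events are independent across
players and steps. A player whose partner has died finishes the game alone,
surviving each remaining step with the loner probability `a0`, whatever their
strategy. The only payoff is survival: the value of an `n`-step strategy is
the probability of being alive after step `n`, so per-step payoffs accrue
multiplicatively rather than additively — which is exactly why the usual
backward-induction argument for defecting everywhere fails here.

Strategies are restricted to the switch-once family `S_i`: cooperate for the
first `n - i` steps, defect for the final `i`. The single number `i` — the
count of end-game defections — is the whole strategy. From the focal player's
perspective the game is an absorbing Markov chain on three states (paired,
alone, dead), with one 3×3 transition matrix per behavior pair. The matrices
are triangular, so their powers have closed forms, and the payoff
`A(S_j; S_i)` of `S_j` against `S_i` is a short sum of products of the pair
eigenvalues `a^2`, `bc`, `d^2` and the loner rate `a0`. The ordering of those
four eigenvalues governs everything: every payoff difference in the game is a
two-term exponential in `i` whose sign pattern is decided by ratios of
eigenvalues.

We focus on the canonical Prisoner's Dilemma (`c > a > d > b` and
`a^2 > bc`): defecting is individually better in every single step, yet a
pair of cooperators outlives any other pair, and a large enough threat of
ending up alone can hold defection in check.

## The cutoffs and what they mean

All of the qualitative structure is carried by a handful of analytic
quantities, all available through `threshold_set()`:

* `a0_star` — the largest `a0` for which a *finite* optimal number of
  defections against an all-C partner exists. It is the average of `a^2` and
  `a` weighted by `c - a` (gain in own survival from defecting on a
  cooperator) and `a^2 - bc` (loss in pair survival). Below it, `j_opt` and
  its integer version `J_opt` give the optimum; above it, ever more defection
  pays and only the game length caps it.
* `a0_prime` and `i_D` — against a partner defecting for the final `i` steps,
  one *more* defection stops paying once `i > i_D`. The cutoff `i_D` exists
  exactly when `a0 < a0_prime`, the same weighted average transplanted to the
  `d^2`–`d` bracket, and grows without bound as `a0` approaches it.
* `a0_double_prime` and `i_C` — one more *cooperation* starts paying once
  `i > i_C`. This requires `bc > d^2` (adding the first cooperator to a DD
  pair must help pair survival) and `a0 < a0_double_prime`.
* `a0_triple_prime` — in the regime `a0_prime < a0_double_prime` the curves
  `i_D(a0)` and `i_C(a0)` cross here; above it the interval between them
  inverts and *disequilibria* appear: strategies from which both deviating up
  and deviating down beat staying put.

Locally stable strategies (no better one-step deviation) occupy the integer
stretch from `ceiling(i_D)` to `floor(i_C)`, intersected with the game; for
the strict dilemma local and global (strict Nash / ESS) stability coincide,
which `is_globally_stable()` verifies by brute force rather than by trusting
the theory. The ten possible configurations of the cutoffs bin into five
qualitative incentive types (`classify_incentives()`); `response_walk()`
iterates simultaneous best replies, which either converge into an
equilibrium stretch or, across a disequilibrium stretch, settle into a
multi-state cycle.

One finite-`n` subtlety deserves emphasis: at `i = n` there is no further
defection available, so `S_n` is stable whenever one more cooperation does
not pay there — even in parameter regions whose large-`n` description is
"defection always favored". `classify_incentives(g, large_n = FALSE)`
reports the concrete game (its equilibrium stretch is exactly the locally
stable set), while `large_n = TRUE` reports the idealized description the
five types are named after.

## Parameters, defaults, and the survey

All seven model parameters are dimensionless: five per-step survival
probabilities in (0, 1), the loner rate `a0`, and the integer game length
`n`. The worked examples in the documentation use the classic dilemma
`(a, b, c, d) = (0.97, 0.94, 0.99, 0.95)` — a linear rescaling of the
textbook (3, 0, 5, 1) payoffs — with `n = 20` or `n = 50` and `a0` chosen to
land in the regime being illustrated, plus small perturbations of `b`, `c`
or `d` that flip the ordering of `a0_prime` and `a0_double_prime`.

The parameter-space census (`run_survey()`) samples single-step dilemmas by
sorting four uniforms into `c > a > d > b`, discarding draws with
`a^2 <= bc`, and attaching an independent uniform `a0`. Two models are
standard: the full range (everything uniform on (0, 1)) and a narrow range
((0.9, 1) for the pair payoffs, (0.7, 1) for `a0`) describing mild single
steps with loners at a plausible disadvantage. Classification treats `n` as
unbounded, since the type definitions are `n`-free. Quantiles of `i_D` and
`i_C` are reported conditioned on the quantity's own existence, and — because
the alternative reading is defensible — also conditioned on at least one of
the two existing; the two differ noticeably for `i_D`, whose existence region
is the smaller one. The census in the test suite and acceptance script uses
1–2 × 10^5 draws, which puts a binomial standard error of at most ~0.16
percentage points on each reported percentage — ample for percentages quoted
to two decimals from 10^6-draw studies.

What the generator deliberately does *not* emulate: correlated survival
within a step, mid-game strategy revision, opting out, mixed or reactive
strategies, and population dynamics. Passing tests therefore certify the
switch-once, independent-survival model only.

## Numerical choices

**One code path for the removable singularities.** Every closed form in this
model contains quotients of the shape `(x^k - y^k) / (x - y)`, which are
indeterminate when `a0` collides with `a^2`, `bc` or `d^2`. All of them are
evaluated by `geometric_ratio_sum()`, the explicit `k`-term sum, which is
exact for all arguments including `x = y`. This removes every special-case
branch (the degenerate variants of the payoff, gain and cutoff formulas fold
into the generic ones) at an `O(n)` cost per term that is irrelevant at the
game lengths of interest. The cutoffs `i_D` and `i_C` keep one explicit
limit branch at `a0 = d^2`, where the logarithm quotient itself — not just a
geometric sum — degenerates; the tests check that the branch sits on the
continuous curve.

**Dual routes everywhere.** The closed-form `payoff()` is checked against
`payoff_oracle()`, which multiplies the `n` single-step matrices numerically;
the suite requires agreement below 1e-12 over hundreds of random parameter
sets with the singular collisions engineered exactly. A Monte-Carlo
simulator (`estimate_payoff()`) provides a third, stochastic route. The
best-response search is brute force over the `n + 1` candidates; the
analytic shortcuts (`j_star`, `k_star`) are *assertions* checked against it,
not shortcuts taken on faith — their preconditions have genuine edge cases
(see below).

**Ties.** The analysis assumes `A(S_j; S_i) != A(S_i; S_i)` for `j != i`.
Payoff differences within 1e-12 of zero raise a classed tie error rather
than silently picking a sign, because a silently mis-signed gain would
corrupt the stability scan and the classifier near regime boundaries. Ties
have probability zero under continuous sampling; the survey tallies them
(`tie_count`) rather than branching.

**Existence near cutoffs.** A cutoff within 1e-12 of the game's `a0` is
reported nonexistent: the boundary itself behaves like the always-defect
side (the gain converges to a nonzero constant there), and treating the
measure-zero boundary this way keeps existence flags boolean. Nonexistence
is always a value (`+Inf` plus a flag), never an exception, because the
classifier treats it as a regime.

**`k_star` edge cases.** The defection-side optimum solves
`H + C (a0/bc)^k = 0`. When `a0 >= a0_star` the bracket never changes sign;
the implementation detects this by a sign check around the candidate root
and returns `+Inf` (meaning: defect to the cap) instead of a spurious
finite root. At `a0 = bc` the equation degenerates entirely — the bracket
loses its `k`-dependence, the analogue of the linear-in-`j` special forms —
so `k_star` returns `NA` with a warning there and the brute-force search
(which is canonical anyway) stands alone; a bisection fallback was
considered and rejected because no finite bracket exists at the degeneracy.
`j_star` needs no such care: it reduces to `i_C - 1` identically, and the
implementation uses the `(d - b, bc - d^2)`-weighted form that makes that
identity exact.

**Integer boundaries.** Incentive structures depend on `ceiling(i_D)` and
`floor(i_C)`, not on the reals; the classifier's final split (cases 8–10)
compares integer floors exactly as the decision table prescribes, and the
single-point and switching cases are distinguished by those integers, not by
`a0_triple_prime`.

## Problem sizes

The suite exercises exhaustive payoff-oracle equivalence up to `n = 12`
(where the `(n+1)^2` table is still cheap for the matrix-product route),
stability brute force up to `n = 15`, best-response properties up to
`n = 25`, and the worked `n = 20` and `n = 50` examples. Monte-Carlo checks
use 10^5–2×10^5 replicates, putting ~3σ bands of about 0.004 on estimated
survival probabilities; the census uses 10^5–2×10^5 draws per model. These
sizes were chosen so that every statistical check has comfortable power
while the whole suite runs in well under a minute.

## Limitations

Only switch-once strategies are analyzed — the model's own restriction, and
the reason closed forms exist. The equality case `A(S_j; S_i) = A(S_i; S_i)`
is deliberately out of scope (hence the tie errors), as are finite-population
dynamics, correlated within-step survival, and reactive or mixed strategies.
The `j_opt` formula is exposed for non-dilemma games but characterized and
tested only in the strict-dilemma regime.
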