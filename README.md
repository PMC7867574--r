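# survgame

Exact analysis of two-player **iterated survival games** with switch-once
strategies, for researchers in evolutionary game theory and the mathematical
biology of cooperation.

Two players face an environment for *n* steps. In each step each player
cooperates (*C*) or defects (*D*) and survives the step with probability *a*
(both cooperate), *b* (cooperate against a defector), *c* (defect on a
cooperator) or *d* (both defect); a player whose partner has died survives
each remaining step with the loner probability *a₀*, regardless of strategy.
The payoff of a strategy is the probability of surviving all *n* steps, so
payoffs accrue multiplicatively. Strategy *Sᵢ* cooperates for the first
*n − i* steps and defects for the final *i*: the number of end-game
defections is the whole strategy.

From the focal player's side the game is an absorbing Markov chain on
{paired, alone, dead}, and the *n*-step payoff has a closed form,

> A(S_j; S_i) = (A_CC^{n−j} · A_DC^{j−i} · A_DD^i)₍₁,₁₎ + (·)₍₁,₂₎  for j ≥ i,

a four-term sum over the ways the partner can die, built from the pair
eigenvalues *a²*, *bc*, *d²* and *a₀*. For the canonical Prisoner's Dilemma
(*c > a > d > b*, *a² > bc*) the package computes the loner-survival cutoffs
that organize all incentives — *a₀\** (finite optimal defection count
against all-C), *a₀′* (existence of the defection cutoff *i_D*), *a₀″*
(existence of the cooperation cutoff *i_C*), *a₀‴* (crossing *i_D = i_C*) —
classifies the ten possible incentive structures into five types (stretches
of equilibria, stretches of disequilibria, or defection favored throughout),
finds strict Nash equilibria locally and by brute force globally, iterates
best-response walks to their terminal fixed points or cycles, and surveys
the whole parameter space by Monte Carlo.

Every closed form is cross-checked by an independent route: a matrix-product
oracle (`payoff_oracle()`), a game simulator (`estimate_payoff()`), and
brute-force searches behind every analytic shortcut.

## Worked example

The classic dilemma payoffs (a rescaling of the textbook 3/0/5/1 values)
with a moderately safe loner rate:

```r
library(survgame)
g <- survival_game(0.97, 0.94, 0.99, 0.95, a0 = 0.86, n = 20, require_pd = TRUE)
threshold_set(g)
#> Loner-survival cutoffs and optimal responses
#>   a0 = 0.86 (game), n = 20
#>   a0*   = 0.950792   (finite optimum vs all-C exists iff a0 < a0*)
#>   a0'   = 0.918647   (i_D exists iff a0 < a0')
#>   a0''  = 0.937533   (i_C exists iff bc > d^2 and a0 < a0'')
#>   a0''' = 0.432115   (crossing i_D = i_C; shrinking-stretch case only)
#>   j_opt = 9.622125, J_opt = 10
#>   i_D   = 13.49043
#>   i_C   = 4.220318
#>   j*    = 3.220318, k*(0) = 9.12633
```

Against a fully cooperative partner the best reply is to defect in the last
10 steps (`J_opt`). One more defection pays only while the partner defects
fewer than `i_D = 13.49` end steps; one more cooperation starts paying once
the partner defects more than `i_C = 4.22`. Because `i_C < i_D` the interval
between them is a stretch of **disequilibria** — both deviations beat
staying put:

```r
classify_incentives(g)
#> Incentive structure: case 8 of 10, type 5a
#>   bounded stretch of disequilibria
#>   disequilibrium stretch: [[5, 13]]

response_walk(g, 0)
#> Best-response walk from i = 0
#>   trajectory: 0 -> 10 -> 4 -> 11 -> 4
#>   terminal cycle of length 2: {4, 11}
```

Simultaneous best replies never settle: defection incentives push the pair
up through the stretch while the cooperation side leaps back over it, giving
a permanent two-state cycle between 4 and 11 end-game defections. Lowering
`b` and `c` by 0.01 flips the ordering of `a₀′` and `a₀″` and the same
machinery yields a stretch of true equilibria, ⟦4, 15⟧, instead.

## Command line

A thin wrapper over the same functions lives at `inst/cli/survgame`:

```sh
Rscript inst/cli/survgame classify --a 0.97 --b 0.94 --c 0.99 --d 0.95 --a0 0.86 --n 20
Rscript inst/cli/survgame survey --model full --samples 100000 --seed 1 --out census.json
```

Subcommands: `surface`, `thresholds`, `classify`, `walk`, `simulate`,
`survey`; flags may come from a YAML/JSON file via `--config`, and every
JSON artifact carries a provenance block (parameters, seed, version).

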