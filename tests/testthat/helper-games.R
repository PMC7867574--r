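# Reference games used throughout the suite. The (0.97, 0.94, 0.99, 0.95)
# Prisoner's Dilemma is a linear transformation of the classic (R, S, T, P) =
# (3, 0, 5, 1) payoffs; the variants perturb b, c or d to move the game
# across the qualitative regimes.

pd_classic <- function(a0 = 0.8, n = 50) {
  survival_game(0.97, 0.94, 0.99, 0.95, a0, n, require_pd = TRUE)
}

# bounded stretch of equilibria [[4, 15]]
game_eq_stretch <- function(a0 = 0.86, n = 20) {
  survival_game(0.97, 0.93, 0.98, 0.95, a0, n, require_pd = TRUE)
}

# bounded stretch of disequilibria [[5, 13]], two-state cycle {4, 11}
game_diseq_stretch <- function(a0 = 0.86, n = 20) {
  survival_game(0.97, 0.94, 0.99, 0.95, a0, n, require_pd = TRUE)
}

# bc < d^2 and a0 > a0': defection always favored
game_defect_always <- function() {
  survival_game(0.97, 0.91, 0.98, 0.95, 0.95, 20, require_pd = TRUE)
}

# unbounded stretch capped by n: stable for all i >= 12
game_capped_stretch <- function() {
  survival_game(0.97, 0.93, 0.98, 0.95, 0.92, 20, require_pd = TRUE)
}

# single equilibrium point at i = 4
game_single_point <- function() {
  survival_game(0.97, 0.93, 0.99, 0.949, 0.78, 20, require_pd = TRUE)
}

# Random strict Prisoner's Dilemma: sorted uniforms labelled c > a > d > b,
# rejecting a^2 <= bc (uses the caller's RNG state).
random_pd <- function(lo = 0.5, hi = 1, a0 = NULL, n = NULL) {
  repeat {
    p <- sort(runif(4, lo, hi), decreasing = TRUE)
    if (p[2]^2 > p[1] * p[4]) break
  }
  if (is.null(a0)) a0 <- runif(1)
  if (is.null(n)) n <- sample(3:12, 1)
  survival_game(p[2], p[4], p[1], p[3], a0, n, require_pd = TRUE)
}

# The set of locally stable strategies by direct scan.
stable_scan <- function(g) {
  which(vapply(0:g$n, function(i) is_locally_stable(g, i), logical(1))) - 1L
}
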