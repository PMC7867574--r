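# Game parameters and single-step classification.

.tie_tol <- 1e-12

.tie_error <- function(msg) {
  stop(errorCondition(msg, class = c("survgame_tie_error", "error")))
}

#' Define a two-player iterated survival game
#'
#' Constructs and validates the parameter set of an `n`-step iterated survival
#' game. In each step both players are either cooperating (`C`) or defecting
#' (`D`); an individual survives the step with probability `a` (both
#' cooperate), `b` (individual cooperates, partner defects), `c` (individual
#' defects, partner cooperates) or `d` (both defect). A player whose partner
#' has died survives each remaining step with the loner probability `a0`,
#' regardless of strategy. The overall payoff of a strategy is the probability
#' of being alive after all `n` steps.
#'
#' Strategies are restricted to the switch-once family: `S_i` plays `C` for
#' the first `n - i` steps and `D` for the final `i` steps, so `S_0` is all-C
#' and `S_n` is all-D.
#'
#' The pair-survival probabilities `a^2`, `bc` and `d^2` are the leading
#' eigenvalues of the four single-step transition matrices (see
#' [step_matrix()]); together with `a0` their ordering governs every payoff
#' difference in the game, so they are cached on the returned object.
#'
#' @param a,b,c,d Single-step survival probabilities, each strictly in (0,1).
#'   `a > d` is required: `C` is the more cooperative behavior.
#' @param a0 Loner survival probability, strictly in (0,1).
#' @param n Game length (number of steps), a positive integer.
#' @param require_pd If `TRUE`, additionally enforce the canonical strict
#'   Prisoner's Dilemma conditions `c > a > d > b` and `a^2 > bc`.
#' @return An object of class `"survival_game"`: a list with the five
#'   probabilities, `n`, and cached eigenvalues `aa = a^2`, `bc`, `dd = d^2`.
#' @examples
#' g <- survival_game(0.97, 0.94, 0.99, 0.95, a0 = 0.8, n = 50, require_pd = TRUE)
#' g$aa  # 0.9409
#' g$bc  # 0.9306
#' @export
survival_game <- function(a, b, c, d, a0, n, require_pd = FALSE) {
  probs <- list(a = a, b = b, c = c, d = d, a0 = a0)
  for (nm in names(probs)) {
    p <- probs[[nm]]
    if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p <= 0 || p >= 1)
      stop(sprintf("parameter '%s' must be a single number strictly in (0, 1), got %s",
                   nm, format(p)))
  }
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 1 || n != round(n))
    stop(sprintf("parameter 'n' must be a positive integer, got %s", format(n)))
  if (a <= d)
    stop(sprintf("parameter 'a' must exceed 'd' (C is the more cooperative behavior); a = %s, d = %s",
                 format(a), format(d)))
  if (isTRUE(require_pd)) {
    if (!(c > a && a > d && d > b))
      stop(sprintf("strict Prisoner's Dilemma requires c > a > d > b; got c = %s, a = %s, d = %s, b = %s",
                   format(c), format(a), format(d), format(b)))
    if (!(a^2 > b * c))
      stop(sprintf("strict Prisoner's Dilemma requires a^2 > bc; got a^2 = %s, bc = %s",
                   format(a^2), format(b * c)))
  }
  structure(
    list(a = a, b = b, c = c, d = d, a0 = a0, n = as.integer(n),
         aa = a^2, bc = b * c, dd = d^2,
         strict_pd = (c > a && a > d && d > b && a^2 > b * c)),
    class = "survival_game"
  )
}

.check_game <- function(g) {
  if (!inherits(g, "survival_game"))
    stop("expected a 'survival_game' object; see survival_game()")
  invisible(g)
}

.check_pd <- function(g) {
  .check_game(g)
  if (!g$strict_pd)
    stop("this quantity is defined for the strict Prisoner's Dilemma only (c > a > d > b and a^2 > bc)")
  invisible(g)
}

.check_index <- function(g, x, name) {
  if (!is.numeric(x) || length(x) != 1L || x != round(x) || x < 0 || x > g$n)
    stop(sprintf("strategy index '%s' must be an integer in [0, %d], got %s",
                 name, g$n, format(x)))
  as.integer(x)
}

#' Classify the single-step game
#'
#' The sign pattern of `(c - a, d - b)` places the single-step game in one of
#' the four classical symmetric two-player game families: both positive gives
#' the Prisoner's Dilemma, both negative the Harmony Game, and the mixed signs
#' give the Stag Hunt (`a > c`, `b < d`) and the Hawk-Dove game (`a < c`,
#' `b > d`).
#'
#' @param g A [survival_game()].
#' @return One of `"PrisonersDilemma"`, `"StagHunt"`, `"HawkDove"`,
#'   `"Harmony"`.
#' @examples
#' classify_single_step(survival_game(0.97, 0.94, 0.99, 0.95, 0.8, 10))
#' @export
classify_single_step <- function(g) {
  .check_game(g)
  if (abs(g$c - g$a) < .tie_tol || abs(g$d - g$b) < .tie_tol)
    .tie_error("single-step payoffs are equal within tolerance; game class is ambiguous")
  if (g$c > g$a) {
    if (g$d > g$b) "PrisonersDilemma" else "HawkDove"
  } else {
    if (g$d > g$b) "StagHunt" else "Harmony"
  }
}

#' @export
print.survival_game <- function(x, ...) {
  cat(sprintf("Iterated survival game (n = %d steps)\n", x$n))
  cat(sprintf("  single-step survival: a = %g, b = %g, c = %g, d = %g, loner a0 = %g\n",
              x$a, x$b, x$c, x$d, x$a0))
  cat(sprintf("  pair eigenvalues:     a^2 = %g, bc = %g, d^2 = %g\n", x$aa, x$bc, x$dd))
  cls <- tryCatch(classify_single_step(x), survgame_tie_error = function(e) "ambiguous (tied payoffs)")
  cat(sprintf("  single-step class:    %s%s\n", cls,
              if (x$strict_pd) " (strict: c > a > d > b, a^2 > bc)" else ""))
  invisible(x)
}
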