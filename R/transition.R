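# Single-step transition matrices over {paired, alone, dead} and their
# closed-form powers.

.pair_states <- c("CC", "DC", "CD", "DD")
.player_states <- c("paired", "alone", "dead")

# Individual/partner single-step survival probabilities for a pair state
# (individual's behavior listed first).
.pair_probs <- function(g, pair) {
  switch(pair,
         CC = c(g$a, g$a),
         DC = c(g$c, g$b),
         CD = c(g$b, g$c),
         DD = c(g$d, g$d),
         stop(sprintf("unknown pair state '%s'; expected one of %s",
                      pair, paste(.pair_states, collapse = ", "))))
}

#' Sum of a two-parameter geometric series
#'
#' Computes `sum_{m=0}^{k-1} x^m * y^(k-1-m)`, the value of
#' `(x^k - y^k) / (x - y)` extended continuously to `x == y` (where it equals
#' `k * x^(k-1)`). The empty sum (`k = 0`) is 0.
#'
#' Every quotient of this form that appears in the closed-form matrix powers
#' and payoff expressions is routed through this function, so the removable
#' singularities `a0 = a^2`, `a0 = bc` and `a0 = d^2` need no special-case
#' branches: the summation form is exact for all arguments.
#'
#' @param x,y Real numbers in \[0, 1\].
#' @param k Number of terms, a non-negative integer.
#' @return The value of the sum (a single number).
#' @examples
#' geometric_ratio_sum(0.9, 0.8, 4)      # (0.9^4 - 0.8^4) / 0.1
#' geometric_ratio_sum(0.5, 0.5, 3)      # 3 * 0.5^2
#' @export
geometric_ratio_sum <- function(x, y, k) {
  if (!is.numeric(k) || length(k) != 1L || k != round(k) || k < 0)
    stop("'k' must be a non-negative integer")
  if (k == 0) return(0)
  sum(x^(0:(k - 1)) * y^((k - 1):0))
}

#' Single-step transition matrix
#'
#' The 3x3 row-stochastic transition matrix of the focal player's Markov
#' chain over the states paired / alone / dead, for one step in which the
#' individual-partner behavior pair is `pair`. With `x` the individual's and
#' `y` the partner's single-step survival probability, the first row is
#' `[x*y, x*(1-y), 1-x]`: both survive, the individual survives alone, the
#' individual dies. The second and third rows are `[0, a0, 1-a0]` and
#' `[0, 0, 1]` for every pair state: a lone player survives with the loner
#' probability regardless of strategy, the alone state cannot return to
#' paired, and death is absorbing.
#'
#' @param g A [survival_game()].
#' @param pair One of `"CC"`, `"DC"`, `"CD"`, `"DD"` (individual first).
#' @return A 3x3 matrix with dimnames `paired`, `alone`, `dead`.
#' @examples
#' step_matrix(survival_game(0.97, 0.94, 0.99, 0.95, 0.8, 10), "CC")
#' @export
step_matrix <- function(g, pair) {
  .check_game(g)
  p <- .pair_probs(g, pair)
  x <- p[1]; y <- p[2]
  m <- rbind(c(x * y, x * (1 - y), 1 - x),
             c(0, g$a0, 1 - g$a0),
             c(0, 0, 1))
  dimnames(m) <- list(.player_states, .player_states)
  m
}

#' Closed-form power of a single-step transition matrix
#'
#' The k-step transition matrix for a phase of the game in which the behavior
#' pair stays fixed. The matrices are triangular with eigenvalues
#' `(x*y, a0, 1)`; the first row of the k-th power is
#' `[(x*y)^k, x*(1-y) * S, 1 - (x*y)^k - x*(1-y) * S]` where
#' `S = geometric_ratio_sum(a0, x*y, k)`, which is exact even when `a0`
#' coincides with the pair eigenvalue. Equals the k-fold product of
#' [step_matrix()].
#'
#' @inheritParams step_matrix
#' @param k Number of steps, a non-negative integer (`k = 0` gives the
#'   identity).
#' @return A 3x3 matrix with dimnames `paired`, `alone`, `dead`.
#' @export
step_matrix_power <- function(g, pair, k) {
  .check_game(g)
  if (!is.numeric(k) || length(k) != 1L || k != round(k) || k < 0)
    stop("'k' must be a non-negative integer")
  p <- .pair_probs(g, pair)
  x <- p[1]; y <- p[2]
  lam <- x * y
  s <- geometric_ratio_sum(g$a0, lam, k)
  r1 <- c(lam^k, x * (1 - y) * s, 1 - lam^k - x * (1 - y) * s)
  m <- rbind(r1, c(0, g$a0^k, 1 - g$a0^k), c(0, 0, 1))
  dimnames(m) <- list(.player_states, .player_states)
  m
}
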