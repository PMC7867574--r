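# Exact n-step survival payoffs A(S_j; S_i).

#' Exact n-step survival payoff A(S_j; S_i)
#'
#' The probability that the focal individual, playing switch-once strategy
#' `S_j`, is alive after all `n` steps against a partner playing `S_i`. For
#' `j >= i` the game passes through three phases (CC for `n-j` steps, DC for
#' `j-i`, DD for `i`) and the payoff decomposes into four terms: the partner
#' survives the whole game, or dies during the CC, DC or DD phase after which
#' the individual survives alone at rate `a0` per step. Each term is a product
#' of pair eigenvalues and a geometric sum; all quotients with removable
#' singularities are computed via [geometric_ratio_sum()], so parameter sets
#' with `a0` equal to `a^2`, `bc` or `d^2` need no special handling. The case
#' `j <= i` is the same expression with `b` and `c` (and `i` and `j`)
#' interchanged.
#'
#' @param g A [survival_game()].
#' @param j Focal player's number of end-game defections, in `0:n`.
#' @param i Partner's number of end-game defections, in `0:n`.
#' @return A survival probability in (0, 1).
#' @seealso [payoff_oracle()] for the independent matrix-product route,
#'   [payoff_surface()] for the full table.
#' @examples
#' g <- survival_game(0.97, 0.94, 0.99, 0.95, 0.8, n = 1)
#' payoff(g, 1, 0)  # c: a single step, defecting on a cooperator
#' payoff(g, 1, 1)  # d: one DD step; the partner's fate no longer matters
#' @export
payoff <- function(g, j, i) {
  .check_game(g)
  j <- .check_index(g, j, "j")
  i <- .check_index(g, i, "i")
  a <- g$a; b <- g$b; c <- g$c; d <- g$d; a0 <- g$a0; n <- g$n
  bc <- g$bc
  if (j >= i) {
    a^(2 * (n - j)) * bc^(j - i) * d^(2 * i) +
      a * (1 - a) * a0^j * geometric_ratio_sum(a0, g$aa, n - j) +
      c * (1 - b) * a^(2 * (n - j)) * a0^i * geometric_ratio_sum(a0, bc, j - i) +
      d * (1 - d) * a^(2 * (n - j)) * bc^(j - i) * geometric_ratio_sum(a0, g$dd, i)
  } else {
    a^(2 * (n - i)) * bc^(i - j) * d^(2 * j) +
      a * (1 - a) * a0^i * geometric_ratio_sum(a0, g$aa, n - i) +
      b * (1 - c) * a^(2 * (n - i)) * a0^j * geometric_ratio_sum(a0, bc, i - j) +
      d * (1 - d) * a^(2 * (n - i)) * bc^(i - j) * geometric_ratio_sum(a0, g$dd, j)
  }
}

#' Matrix-product oracle for the n-step payoff
#'
#' Computes the same survival probability as [payoff()] by explicitly
#' multiplying the `n` single-step transition matrices in game order
#' (`n - max(i,j)` CC steps, `|j - i|` DC or CD steps, `min(i,j)` DD steps)
#' and summing the first-row paired and alone entries of the product. No
#' closed forms are used, so this serves as an independent cross-check of the
#' analytic route; the two must agree to machine precision.
#'
#' @inheritParams payoff
#' @return A survival probability in (0, 1).
#' @export
payoff_oracle <- function(g, j, i) {
  .check_game(g)
  j <- .check_index(g, j, "j")
  i <- .check_index(g, i, "i")
  mid <- if (j > i) "DC" else "CD"
  P <- diag(3)
  counts <- c(CC = g$n - max(i, j), mid = abs(j - i), DD = min(i, j))
  pairs <- c("CC", mid, "DD")
  for (ph in 1:3) {
    m <- step_matrix(g, pairs[ph])
    for (t in seq_len(counts[ph])) P <- P %*% m
  }
  P[1, 1] + P[1, 2]
}

#' Full payoff surface A(S_j; S_i)
#'
#' Evaluates [payoff()] for all pairs of switch-once strategies, returning the
#' `(n+1) x (n+1)` table with rows indexed by the focal player's strategy `j`
#' and columns by the partner's strategy `i` (both labelled `0:n`). Swapping
#' `b` and `c` transposes the surface; the `i = 0` column does not depend on
#' `d` (no step is ever DD against an all-C partner); the diagonal is strictly
#' decreasing in `i`.
#'
#' @param g A [survival_game()].
#' @return A matrix of class `"payoff_surface"` with the game attached as
#'   attribute `"game"`.
#' @examples
#' A <- payoff_surface(survival_game(0.97, 0.94, 0.99, 0.95, 0.8, n = 5))
#' A["3", "1"]
#' @export
payoff_surface <- function(g) {
  .check_game(g)
  n <- g$n
  A <- matrix(NA_real_, n + 1, n + 1, dimnames = list(j = 0:n, i = 0:n))
  for (j in 0:n) for (i in 0:n) A[j + 1, i + 1] <- payoff(g, j, i)
  structure(A, game = g, class = c("payoff_surface", "matrix", "array"))
}

.surface_of <- function(g, surface = NULL) {
  if (is.null(surface)) payoff_surface(g) else surface
}

#' @export
print.payoff_surface <- function(x, digits = 4, ...) {
  g <- attr(x, "game")
  cat(sprintf("Payoff surface A(S_j; S_i), n = %d (rows j = focal, cols i = partner)\n", g$n))
  print(round(unclass(x), digits), ...)
  invisible(x)
}

#' Plot a payoff surface
#'
#' Draws the survival payoff `A(S_j; S_i)` either as curves in `j` (one per
#' partner strategy `i`) or as a perspective surface.
#'
#' @param x A [payoff_surface()].
#' @param type `"curves"` or `"persp"`.
#' @param ... Passed to [graphics::matplot()] or [graphics::persp()].
#' @return `x`, invisibly.
#' @export
plot.payoff_surface <- function(x, type = c("curves", "persp"), ...) {
  type <- match.arg(type)
  g <- attr(x, "game")
  n <- g$n
  if (type == "curves") {
    graphics::matplot(0:n, unclass(x), type = "l", lty = 1,
                      xlab = "focal end-game defections j",
                      ylab = "survival probability A(S_j; S_i)", ...)
  } else {
    graphics::persp(0:n, 0:n, unclass(x), xlab = "j (focal)", ylab = "i (partner)",
                    zlab = "A(S_j; S_i)", theta = 40, phi = 25, ...)
  }
  invisible(x)
}
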