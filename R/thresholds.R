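# Analytic loner-survival cutoffs and optimal-response quantities for the
# strict Prisoner's Dilemma.
#
# Nonexistence of a cutoff is a regime, not an error: real-valued cutoffs
# report +Inf when they do not exist, and threshold_set() carries explicit
# existence flags. A cutoff within 1e-12 of its critical a0 is reported
# nonexistent (the boundary itself behaves like the always-defect side).

.exists_tol <- 1e-12

#' Cutoff a0* for an optimal defection count against all-C
#'
#' The largest loner survival probability for which a finite optimal number
#' of end-game defections against a fully cooperative partner exists. It is
#' the weighted average of `a^2` and `a` with weights `c - a` (the
#' single-step gain in individual survival from defecting on a cooperator)
#' and `a^2 - bc` (the loss in pair survival), so it always lies strictly
#' between `a^2` and `a`. For `a0 >= a0_star`, ever more defection is favored
#' against all-C regardless of game length.
#'
#' @param g A strict Prisoner's Dilemma [survival_game()].
#' @return A probability in `(a^2, a)`.
#' @examples
#' a0_star(survival_game(0.97, 0.94, 0.99, 0.95, 0.8, 50))  # 0.9508
#' @export
a0_star <- function(g) {
  .check_pd(g)
  w1 <- g$c - g$a
  w2 <- g$aa - g$bc
  (w1 * g$aa + w2 * g$a) / (w1 + w2)
}

#' Real-valued optimal defection count against all-C
#'
#' The real `j` maximizing the continuous extension of `A(S_j; S_0)`. Exists
#' (is finite) exactly when `a0 < a0_star(g)`; reported as `+Inf` otherwise,
#' meaning the payoff keeps growing with `j` and only the cap `n` limits
#' defection. The degenerate case `a0 = a^2` is evaluated from the derivative
#' of the corresponding linear-in-`j` form instead of the generic logarithm
#' quotient.
#'
#' @inheritParams a0_star
#' @return A non-negative real, or `+Inf` when no finite optimum exists.
#' @seealso [J_opt()] for the integer optimum.
#' @export
j_opt_real <- function(g) {
  .check_pd(g)
  if (g$a0 >= a0_star(g) - .exists_tol) return(Inf)
  a <- g$a; b <- g$b; c <- g$c; a0 <- g$a0; aa <- g$aa; bc <- g$bc
  if (abs(a0 - aa) < .exists_tol) {
    # slope of A(S_j;S_0) in j when a0 = a^2: exponential term balances the
    # linear loner term
    rhs <- (1 - a) / a * (aa - bc) / ((aa - c) * log(bc / aa))
    return(log(rhs) / log(bc / aa))
  }
  arg <- (a * (1 - a) * (a0 - bc) / ((a0 - c) * (a0 - aa)) - c * (1 - b) / (a0 - c)) *
    log(a0 / aa) / log(bc / aa)
  log(arg) / log(bc / a0)
}

#' Integer-optimal number of end-game defections against all-C
#'
#' The best integer response to a fully cooperative partner. When
#' [j_opt_real()] is finite and less than `n`, it is whichever of its floor
#' and ceiling gives the larger payoff `A(S_j; S_0)`; when `n <= j_opt` the
#' cap binds and all-D (`j = n`) is best; when no finite optimum exists the
#' result is `+Inf` (for any concrete game the best response is then `n`).
#'
#' @inheritParams a0_star
#' @return A positive integer, `n`, or `+Inf`.
#' @export
J_opt <- function(g) {
  jr <- j_opt_real(g)
  if (!is.finite(jr)) return(Inf)
  if (g$n <= jr) return(g$n)
  cand <- unique(pmin(pmax(c(floor(jr), ceiling(jr)), 0), g$n))
  vals <- vapply(cand, function(j) payoff(g, j, 0), numeric(1))
  as.integer(cand[which.max(vals)])
}

#' Cutoff a0' for the existence of i_D
#'
#' The loner-survival cutoff below which additional defection eventually
#' becomes disfavored as the partner's defection count grows. It is the
#' average of `d^2` and `d` with the same weights `c - a` and `a^2 - bc` as
#' [a0_star()] (the switch being contemplated is the same, C to D against a
#' C-playing partner; only the surrounding DD phase changes the anchors), so
#' it lies strictly between `d^2` and `d`. For `a0 >= a0_prime`, one more
#' defection is favored against every partner strategy.
#'
#' @inheritParams a0_star
#' @return A probability in `(d^2, d)`.
#' @examples
#' a0_prime(survival_game(0.97, 0.94, 0.99, 0.95, 0.8, 50))  # 0.9186
#' @export
a0_prime <- function(g) {
  .check_pd(g)
  w1 <- g$c - g$a
  w2 <- g$aa - g$bc
  (w1 * g$dd + w2 * g$d) / (w1 + w2)
}

#' Defection cutoff i_D
#'
#' The real partner-defection level above which defecting one more time
#' becomes disadvantageous. Exists (is finite) exactly when
#' `a0 < a0_prime(g)`; `+Inf` otherwise. Strictly increasing in `a0` on its
#' existence interval, from 0 (as `a0 -> 0`) to `+Inf` (as `a0 -> a0_prime`).
#' The removable singularity at `a0 = d^2` is evaluated by its continuous
#' limit.
#'
#' @inheritParams a0_star
#' @return A non-negative real, or `+Inf`.
#' @examples
#' i_D_real(survival_game(0.97, 0.93, 0.98, 0.95, 0.86, 20))  # 3.08
#' @export
i_D_real <- function(g) {
  .check_pd(g)
  if (g$a0 >= a0_prime(g) - .exists_tol) return(Inf)
  a <- g$a; c <- g$c; d <- g$d; a0 <- g$a0; aa <- g$aa; bc <- g$bc; dd <- g$dd
  if (abs(a0 - dd) < .exists_tol)
    return((c - a) * d / ((aa - bc) * (1 - d)))
  log(1 + (c - a) / (aa - bc) * (a0 - dd) / (a0 - d)) / log(dd / a0)
}

#' Cutoff a0'' for the existence of i_C
#'
#' The loner-survival cutoff below which additional cooperation eventually
#' becomes favored as the partner's defection count grows. Defined only when
#' `bc > d^2` (otherwise adding the first cooperator to a DD pair does not
#' improve pair survival and more cooperation is never favored); then it is
#' the average of `d^2` and `d` with weights `d - b` (individual cost of
#' cooperating against a defector) and `bc - d^2` (gain in pair survival),
#' lying strictly between `d^2` and `d`.
#'
#' @inheritParams a0_star
#' @return A probability in `(d^2, d)`, or `NA` when `bc <= d^2`.
#' @export
a0_double_prime <- function(g) {
  .check_pd(g)
  if (g$bc <= g$dd) return(NA_real_)
  w1 <- g$d - g$b
  w2 <- g$bc - g$dd
  (w1 * g$dd + w2 * g$d) / (w1 + w2)
}

#' Cooperation cutoff i_C
#'
#' The real partner-defection level above which cooperating one more time
#' becomes advantageous. Exists (is finite) exactly when `bc > d^2` and
#' `a0 < a0_double_prime(g)`; `+Inf` otherwise. Strictly increasing in `a0`
#' on its existence interval, from 1 (as `a0 -> 0`) to `+Inf` (as
#' `a0 -> a0_double_prime`). The removable singularity at `a0 = d^2` is
#' evaluated by its continuous limit.
#'
#' @inheritParams a0_star
#' @return A real `>= 1`, or `+Inf`.
#' @examples
#' i_C_real(survival_game(0.97, 0.94, 0.99, 0.95, 0.86, 20))  # 4.22
#' @export
i_C_real <- function(g) {
  .check_pd(g)
  app <- a0_double_prime(g)
  if (is.na(app) || g$a0 >= app - .exists_tol) return(Inf)
  b <- g$b; d <- g$d; a0 <- g$a0; bc <- g$bc; dd <- g$dd
  if (abs(a0 - dd) < .exists_tol)
    return(1 + (d - b) * d / ((bc - dd) * (1 - d)))
  1 + log(1 + (d - b) / (bc - dd) * (a0 - dd) / (a0 - d)) / log(dd / a0)
}

#' Crossing cutoff a0''' where i_D = i_C
#'
#' In the shrinking-stretch regime (`bc > d^2` with
#' `a0_prime < a0_double_prime`), the curves `i_D(a0)` and `i_C(a0)` cross at
#' this value of `a0`. Below it at most a single locally stable strategy
#' exists; above it the continuous interval inverts and stretches of
#' disequilibria appear, where both one more defection and one more
#' cooperation beat keeping one's strategy.
#'
#' @inheritParams a0_star
#' @return A probability.
#' @examples
#' a0_triple_prime(survival_game(0.97, 0.94, 0.99, 0.95, 0.8, 50))  # ~0.43
#' @export
a0_triple_prime <- function(g) {
  .check_pd(g)
  if (g$bc <= g$dd)
    stop("a0_triple_prime requires bc > d^2 (otherwise i_C never exists)")
  app <- a0_double_prime(g)
  if (a0_prime(g) >= app)
    stop("a0_triple_prime requires a0_prime < a0_double_prime (the crossing case)")
  a <- g$a; b <- g$b; c <- g$c; d <- g$d
  b * d * (c - d) * (g$aa - g$bc) / ((g$aa - g$bc + c - a) * (g$bc - g$dd))
}

#' Best response from the cooperative side
#'
#' For partner strategies at or above `ceiling(i_C)`, the payoff-maximizing
#' reply is to defect only in the final `ceiling(j_star)` steps; `j_star`
#' equals `i_C - 1` identically, so the reply is `floor(i_C)` regardless of
#' `i`. Requires `i_C` to exist.
#'
#' @inheritParams a0_star
#' @return A real number (`i_C - 1`).
#' @export
j_star <- function(g) {
  .check_pd(g)
  if (!is.finite(i_C_real(g)))
    stop("j_star requires i_C to exist (bc > d^2 and a0 < a0_double_prime)")
  b <- g$b; d <- g$d; a0 <- g$a0; bc <- g$bc; dd <- g$dd
  # weights (d - b) and (bc - d^2): the same decomposition as a0_double_prime
  log((bc - dd) / (d - b + bc - dd) * (a0 - d) / (a0 - a0_double_prime(g))) /
    log(a0 / dd)
}

# Eq.-51-style auxiliary for the defection-side best response; does not
# depend on the number of additional defections considered.
.H_aux <- function(g, i) {
  a0 <- g$a0
  (g$aa - g$bc) * (g$c * (1 - g$b) / (a0 - g$bc) -
                     g$d * (1 - g$d) / (a0 - g$dd) -
                     (a0 - g$d) / (a0 - g$dd) * (g$dd / a0)^i)
}

#' Best-response increment from the defection side
#'
#' For partner strategies with `i <= floor(i_D)` (or whenever `i_D` does not
#' exist), the payoff-maximizing reply is to defect `ceiling(k_star(g, i))`
#' more times than the partner, capped at `n`. `k_star(0)` recovers the
#' optimal defection count against all-C: `ceiling(k_star(g, 0)) == J_opt(g)`.
#' When the underlying gain never turns negative (the `a0 >= a0_star` side),
#' there is no finite root and `+Inf` is returned: more defection pays at
#' every distance and only the cap `n` stops it. The formula degenerates when
#' `a0 = bc` (the root equation loses its dependence on the increment); `NA`
#' is returned there with a warning and callers fall back to the brute-force
#' search.
#'
#' @inheritParams a0_star
#' @param i Partner's defection count, an integer in `0:n` with
#'   `i <= floor(i_D)` (or `i_D` nonexistent).
#' @return A positive real, or `NA` at the `a0 = bc` degeneracy.
#' @export
k_star <- function(g, i) {
  .check_pd(g)
  i <- .check_index(g, i, "i")
  iD <- i_D_real(g)
  if (is.finite(iD) && i > floor(iD))
    stop(sprintf("k_star is defined for i <= floor(i_D) = %d (or i_D nonexistent); got i = %d",
                 floor(iD), i))
  a0 <- g$a0
  if (abs(a0 - g$bc) < 1e-8) {
    warning("k_star is degenerate at a0 = bc; returning NA (use the brute-force best response)")
    return(NA_real_)
  }
  # stable product form: H * (a0 - bc) avoids the cancelling 1/(a0 - bc)
  Hx <- (g$aa - g$bc) *
    (g$c * (1 - g$b) -
       (g$d * (1 - g$d) + (a0 - g$d) * (g$dd / a0)^i) * (a0 - g$bc) / (a0 - g$dd))
  Cx <- (g$c - g$a + g$aa - g$bc) * (a0 - a0_star(g))
  arg <- -Hx / Cx
  if (!is.finite(arg) || arg <= 0) return(Inf)
  ks <- log(arg) / log(a0 / g$bc)
  # accept only a genuine descending crossing: the defection gain (whose sign
  # is sign(Hx + Cx (a0/bc)^k) * sign(a0 - bc)) is positive below the root and
  # negative above it; otherwise more defection pays at every distance and
  # only the cap n stops it
  gain_sign <- function(k) sign(Hx + Cx * (a0 / g$bc)^k) * sign(a0 - g$bc)
  if (ks <= 0 || gain_sign(ks + 0.5) >= 0) return(Inf)
  ks
}

#' All analytic cutoffs of a game
#'
#' Evaluates every loner-survival cutoff and optimal-response quantity for a
#' strict Prisoner's Dilemma game, with explicit existence flags: `a0_star`,
#' `a0_prime`, `a0_double_prime`, `a0_triple_prime`, `j_opt`, `J_opt`, `i_D`,
#' `i_C`, `j_star`, `k_star0 = k_star(g, 0)` and the auxiliary `H` at
#' `i = 0`. Nonexistent real cutoffs are `+Inf` with their flag `FALSE`;
#' cutoffs whose defining precondition fails (`a0_double_prime` when
#' `bc <= d^2`, `a0_triple_prime` outside the crossing case) are `NA`.
#'
#' @inheritParams a0_star
#' @return A list of class `"threshold_set"`.
#' @examples
#' threshold_set(survival_game(0.97, 0.94, 0.99, 0.95, 0.86, 20))
#' @export
threshold_set <- function(g) {
  .check_pd(g)
  as <- a0_star(g)
  ap <- a0_prime(g)
  app <- a0_double_prime(g)
  appp <- tryCatch(a0_triple_prime(g), error = function(e) NA_real_)
  jo <- j_opt_real(g)
  iD <- i_D_real(g)
  iC <- i_C_real(g)
  js <- if (is.finite(iC)) j_star(g) else NA_real_
  ks0 <- if (!is.finite(iD) || floor(iD) >= 0)
    tryCatch(suppressWarnings(k_star(g, 0)), error = function(e) NA_real_) else NA_real_
  structure(
    list(a0_star = as, a0_prime = ap, a0_double_prime = app, a0_triple_prime = appp,
         j_opt = jo, j_opt_exists = is.finite(jo),
         J_opt = J_opt(g),
         i_D = iD, i_D_exists = is.finite(iD),
         i_C = iC, i_C_exists = is.finite(iC),
         j_star = js, k_star0 = ks0, H = .H_aux(g, 0),
         a0 = g$a0, n = g$n),
    class = "threshold_set"
  )
}

#' @export
print.threshold_set <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else if (!is.finite(v)) "+Inf" else format(round(v, 6))
  cat("Loner-survival cutoffs and optimal responses\n")
  cat(sprintf("  a0 = %s (game), n = %d\n", format(x$a0), x$n))
  cat(sprintf("  a0*   = %s   (finite optimum vs all-C exists iff a0 < a0*)\n", fmt(x$a0_star)))
  cat(sprintf("  a0'   = %s   (i_D exists iff a0 < a0')\n", fmt(x$a0_prime)))
  cat(sprintf("  a0''  = %s   (i_C exists iff bc > d^2 and a0 < a0'')\n", fmt(x$a0_double_prime)))
  cat(sprintf("  a0''' = %s   (crossing i_D = i_C; shrinking-stretch case only)\n", fmt(x$a0_triple_prime)))
  cat(sprintf("  j_opt = %s, J_opt = %s\n", fmt(x$j_opt), fmt(x$J_opt)))
  cat(sprintf("  i_D   = %s%s\n", fmt(x$i_D), if (x$i_D_exists) "" else "  (defection always favored)"))
  cat(sprintf("  i_C   = %s%s\n", fmt(x$i_C), if (x$i_C_exists) "" else "  (cooperation never favored)"))
  cat(sprintf("  j*    = %s, k*(0) = %s\n", fmt(x$j_star), fmt(x$k_star0)))
  invisible(x)
}
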