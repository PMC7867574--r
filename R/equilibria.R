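# One-step payoff gains, local/global stability, stretches of equilibria and
# disequilibria, and the ten-case incentive-structure classifier.

#' Integer interval
#'
#' A closed interval of integers, possibly empty (`lo > hi`). Used for
#' stretches of equilibria and disequilibria.
#'
#' @param lo,hi Integer bounds.
#' @return A list of class `"int_interval"` with fields `lo`, `hi`, `empty`.
#' @export
int_interval <- function(lo, hi) {
  structure(list(lo = lo, hi = hi, empty = lo > hi), class = "int_interval")
}

#' @export
print.int_interval <- function(x, ...) {
  if (x$empty) cat("[empty]\n") else cat(sprintf("[[%s, %s]]\n", format(x$lo), format(x$hi)))
  invisible(x)
}

#' @rdname int_interval
#' @param x An `int_interval`.
#' @return `interval_members()`: the integer members (possibly none).
#' @export
interval_members <- function(x) {
  if (x$empty) integer(0) else seq(x$lo, x$hi)
}

#' One-step payoff gain from defecting once more
#'
#' The closed-form difference `A(S_{i+1}; S_i) - A(S_i; S_i)`: what the focal
#' player gains by defecting one step earlier than a partner who defects for
#' the final `i` steps. Positive for small `i` in a Prisoner's Dilemma
#' (at `i = 0` it equals `a^(2(n-1)) (c - a) > 0`) and changes sign at most
#' once, at `i = i_D` when that cutoff exists. Written with
#' [geometric_ratio_sum()] so the removable singularity at `a0 = d^2` needs
#' no branch; agrees with the same difference computed from [payoff()] to
#' machine precision.
#'
#' @param g A [survival_game()].
#' @param i Partner's defection count, an integer in `0:(n-1)`.
#' @return The payoff difference (a real number).
#' @export
defect_gain <- function(g, i) {
  .check_game(g)
  i <- .check_index(g, i, "i")
  if (i > g$n - 1) stop(sprintf("defect_gain requires i <= n - 1 = %d", g$n - 1))
  a <- g$a; c <- g$c; d <- g$d; a0 <- g$a0; aa <- g$aa; bc <- g$bc; dd <- g$dd
  a^(2 * (g$n - 1)) *
    ((c - a) * (a0 / aa)^i +
       (aa - bc) * (a0 - d) * geometric_ratio_sum(a0, dd, i) / aa^i)
}

#' One-step payoff gain from cooperating once more
#'
#' The closed-form difference `A(S_{i-1}; S_i) - A(S_i; S_i)`: what the focal
#' player gains by defecting one step later than a partner who defects for
#' the final `i` steps. Negative for small `i` in a Prisoner's Dilemma
#' (at `i = 1` it equals `a^(2(n-1)) (b - d) < 0`) and changes sign at most
#' once, at `i = i_C` when that cutoff exists.
#'
#' @param g A [survival_game()].
#' @param i Partner's defection count, an integer in `1:n`.
#' @return The payoff difference (a real number).
#' @export
cooperate_gain <- function(g, i) {
  .check_game(g)
  i <- .check_index(g, i, "i")
  if (i < 1) stop("cooperate_gain requires i >= 1")
  a <- g$a; b <- g$b; d <- g$d; a0 <- g$a0; aa <- g$aa; bc <- g$bc; dd <- g$dd
  a^(2 * (g$n - 1)) *
    ((b - d) * (a0 / aa)^(i - 1) -
       (bc - dd) * (a0 - d) * geometric_ratio_sum(a0, dd, i - 1) / aa^(i - 1))
}

#' One-step difference along the diagonal
#'
#' The closed-form difference `A(S_{i+1}; S_{i+1}) - A(S_i; S_i)` between
#' adjacent states in which both players share the same strategy. Always
#' negative when `a > d` (even at `a0 = 1`), so the diagonal payoff is
#' strictly decreasing in `i`: all-C is the best common strategy.
#'
#' @inheritParams defect_gain
#' @return The payoff difference (a negative real for `a > d`).
#' @export
diagonal_difference <- function(g, i) {
  .check_game(g)
  i <- .check_index(g, i, "i")
  if (i > g$n - 1) stop(sprintf("diagonal_difference requires i <= n - 1 = %d", g$n - 1))
  a <- g$a; d <- g$d; a0 <- g$a0
  a^(2 * (g$n - i - 1)) * (d - a) *
    (a0^i - (a + d) * (a0 - d) * geometric_ratio_sum(a0, g$dd, i))
}

.check_tie <- function(delta, what) {
  if (any(abs(delta) < .tie_tol))
    .tie_error(sprintf("payoff tie within tolerance while evaluating %s; the analysis assumes no ties", what))
  invisible(delta)
}

#' Local stability of a strategy
#'
#' `S_i` is locally stable when neither one more defection nor one more
#' cooperation by the focal player improves on `A(S_i; S_i)`. At `i = 0` only
#' the defection condition applies and at `i = n` only the cooperation
#' condition (the other deviation does not exist), so `S_n` can be stabilized
#' by the cap `n` alone.
#'
#' @param g A [survival_game()].
#' @param i Strategy index in `0:n`.
#' @return `TRUE` or `FALSE`. A gain within `1e-12` of zero raises a tie
#'   error rather than silently choosing a sign.
#' @export
is_locally_stable <- function(g, i) {
  .check_game(g)
  i <- .check_index(g, i, "i")
  ok <- TRUE
  if (i < g$n) {
    dg <- defect_gain(g, i)
    .check_tie(dg, sprintf("defect gain at i = %d", i))
    ok <- ok && dg < 0
  }
  if (i > 0) {
    cg <- cooperate_gain(g, i)
    .check_tie(cg, sprintf("cooperate gain at i = %d", i))
    ok <- ok && cg < 0
  }
  ok
}

#' Global stability of a strategy
#'
#' `S_i` is globally stable (a strict Nash equilibrium, hence an ESS) when
#' `A(S_i; S_i) > A(S_j; S_i)` for every `j != i`, checked by brute force
#' over the payoff surface. For the strict Prisoner's Dilemma, globally and
#' locally stable strategies coincide.
#'
#' @inheritParams is_locally_stable
#' @param surface Optional precomputed [payoff_surface()] for `g`.
#' @return `TRUE` or `FALSE`; ties raise a tie error.
#' @export
is_globally_stable <- function(g, i, surface = NULL) {
  .check_game(g)
  i <- .check_index(g, i, "i")
  A <- .surface_of(g, surface)
  delta <- A[, i + 1] - A[i + 1, i + 1]
  delta <- delta[-(i + 1)]
  .check_tie(delta, sprintf("global stability at i = %d", i))
  all(delta < 0)
}

#' Stretch of locally stable strategies
#'
#' The integer interval of locally stable strategies,
#' `[[ceiling(i_D), floor(i_C)]]` intersected with `[[1, n]]`, using the
#' existence conventions of the cutoffs: when `i_C` does not exist the upper
#' bound is `n`; when `i_D` does not exist (or exceeds `n`) no interior state
#' is stable and only `S_n` remains a candidate, stabilized by the cap
#' whenever one more cooperation does not pay there. The result equals the
#' set `{i : is_locally_stable(g, i)}` exactly.
#'
#' @param g A strict Prisoner's Dilemma [survival_game()].
#' @return An [int_interval()] (possibly empty).
#' @examples
#' stable_stretch(survival_game(0.97, 0.93, 0.98, 0.95, 0.86, 20))  # [[4, 15]]
#' @export
stable_stretch <- function(g) {
  .check_pd(g)
  iD <- i_D_real(g)
  iC <- i_C_real(g)
  hi <- if (is.finite(iC)) min(floor(iC), g$n) else g$n
  lo <- if (is.finite(iD)) min(max(ceiling(iD), 1), g$n) else g$n
  int_interval(as.integer(lo), as.integer(hi))
}

.type_description <- c(
  "1"  = "additional defection always favored",
  "2"  = "unbounded stretch of equilibria (capped by n)",
  "3a" = "bounded stretch of equilibria",
  "3b" = "single equilibrium point",
  "4"  = "unbounded stretch of disequilibria (capped by n)",
  "5a" = "bounded stretch of disequilibria",
  "5b" = "incentives switch between adjacent states"
)

#' Classify the incentive structure of a game
#'
#' Evaluates the decision tree over the ten parameter regions that determine
#' the incentives for a player to defect once more or cooperate once more
#' against a partner with the same strategy: first `bc` versus `d^2`, then
#' `a0_prime` versus `a0_double_prime`, then `a0` against the cutoffs, and
#' finally the integer floors of `i_D` and `i_C`. The ten cases bin into five
#' qualitative types: (1) defection always favored, (2) unbounded stretch of
#' equilibria, (3) bounded stretch of equilibria (including the
#' single-point case), (4) unbounded stretch of disequilibria, (5) bounded
#' stretch of disequilibria (including the adjacent-state switching case).
#'
#' @param g A strict Prisoner's Dilemma [survival_game()].
#' @param large_n If `TRUE` (default), stretches are reported under the
#'   assumption that `n` is large enough to contain them (the regime in which
#'   the ten descriptions hold). If `FALSE`, the report describes the
#'   concrete finite game: the equilibrium stretch is the exact locally
#'   stable set ([stable_stretch()]), which separates cap-induced stability
#'   of `S_n` from the large-n description, and disequilibrium stretches are
#'   intersected with `[[0, n]]` (possibly empty).
#' @return A list of class `"incentive_class"` with fields `case_id` (1-10),
#'   `type_id` (1-5), `type_label` (`"1"`, `"2"`, `"3a"`, `"3b"`, `"4"`,
#'   `"5a"`, `"5b"`), `description`, `equilibrium_stretch`,
#'   `disequilibrium_stretch`, `switch_pair`, and the game's [threshold_set()].
#' @examples
#' classify_incentives(survival_game(0.97, 0.94, 0.99, 0.95, 0.86, 20))
#' @export
classify_incentives <- function(g, large_n = TRUE) {
  .check_pd(g)
  ts <- threshold_set(g)
  a0 <- g$a0
  ap <- ts$a0_prime
  app <- ts$a0_double_prime
  iD <- ts$i_D
  iC <- ts$i_C
  eq <- diseq <- int_interval(1L, 0L)   # empty
  switch_pair <- NULL
  if (g$bc <= g$dd) {
    if (a0 >= ap) { case_id <- 1L; type_label <- "1" }
    else { case_id <- 2L; type_label <- "2"; eq <- int_interval(max(1L, ceiling(iD)), g$n) }
  } else if (ap >= app) {
    if (a0 >= ap) { case_id <- 3L; type_label <- "1" }
    else if (a0 >= app) { case_id <- 4L; type_label <- "2"; eq <- int_interval(max(1L, ceiling(iD)), g$n) }
    else { case_id <- 5L; type_label <- "3a"; eq <- int_interval(max(1L, ceiling(iD)), floor(iC)) }
  } else {
    if (a0 >= app) { case_id <- 6L; type_label <- "1" }
    else if (a0 >= ap) { case_id <- 7L; type_label <- "4"; diseq <- int_interval(ceiling(iC), g$n) }
    else if (floor(iD) > floor(iC)) {
      case_id <- 8L; type_label <- "5a"; diseq <- int_interval(ceiling(iC), floor(iD))
    } else if (floor(iD) == floor(iC)) {
      case_id <- 9L; type_label <- "5b"; switch_pair <- c(floor(iD), ceiling(iD))
    } else {
      case_id <- 10L; type_label <- "3b"; eq <- int_interval(ceiling(iD), floor(iC))
    }
  }
  if (!large_n) {
    # report the concrete finite game: the equilibrium stretch becomes the
    # exact locally stable set (which includes the cap-induced stability of
    # S_n even when Table-2 logic says defection is always favored), and the
    # disequilibrium stretch is intersected with [[0, n]]
    eq <- stable_stretch(g)
    if (!diseq$empty) {
      diseq <- int_interval(diseq$lo, min(diseq$hi, g$n))
      if (diseq$lo > g$n) diseq <- int_interval(1L, 0L)
    }
  }
  structure(
    list(case_id = case_id,
         type_id = as.integer(substr(type_label, 1, 1)),
         type_label = type_label,
         description = unname(.type_description[type_label]),
         equilibrium_stretch = eq,
         disequilibrium_stretch = diseq,
         switch_pair = switch_pair,
         thresholds = ts,
         large_n = isTRUE(large_n),
         n = g$n),
    class = "incentive_class"
  )
}

#' @export
print.incentive_class <- function(x, ...) {
  cat(sprintf("Incentive structure: case %d of 10, type %s\n", x$case_id, x$type_label))
  cat(sprintf("  %s\n", x$description))
  if (!x$equilibrium_stretch$empty) {
    cat("  equilibrium stretch:    "); print(x$equilibrium_stretch)
  }
  if (!x$disequilibrium_stretch$empty) {
    cat("  disequilibrium stretch: "); print(x$disequilibrium_stretch)
  }
  if (!is.null(x$switch_pair))
    cat(sprintf("  incentives switch between i = %d and i = %d\n",
                x$switch_pair[1], x$switch_pair[2]))
  invisible(x)
}
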