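# Monte-Carlo simulation of game play: an independent stochastic oracle for
# the closed-form payoffs.

# Simulate `reps` games and return the number in which the focal player is
# alive after step n. Uses the current RNG state. Tracks the focal player's
# three-state chain plus the partner's aliveness; a dead partner sends the
# focal player to the loner phase for all remaining steps.
.simulate_alive <- function(g, j, i, reps) {
  n <- g$n
  paired <- rep(TRUE, reps)
  alone <- rep(FALSE, reps)
  for (t in seq_len(n)) {
    ind_defects <- t > n - j
    par_defects <- t > n - i
    # individual's survival prob given the two behaviors, and the partner's
    # (same matrix with the roles swapped)
    p_ind <- if (!ind_defects) (if (!par_defects) g$a else g$b) else (if (!par_defects) g$c else g$d)
    p_par <- if (!par_defects) (if (!ind_defects) g$a else g$b) else (if (!ind_defects) g$c else g$d)
    # players already alone at the start of the step face the loner draw;
    # players widowed during this step have survived it as part of a pair
    # and only start their loner phase next step
    was_alone <- which(alone)
    np <- sum(paired)
    if (np > 0) {
      ind_lives <- stats::runif(np) < p_ind
      par_lives <- stats::runif(np) < p_par
      idx <- which(paired)
      paired[idx] <- ind_lives & par_lives
      alone[idx[ind_lives & !par_lives]] <- TRUE
    }
    if (length(was_alone) > 0) {
      lives <- stats::runif(length(was_alone)) < g$a0
      alone[was_alone[!lives]] <- FALSE
    }
  }
  sum(paired | alone)
}

#' Simulate one play of the game
#'
#' Plays a single `n`-step game between `S_j` (focal) and `S_i` (partner) by
#' drawing every survival event, and reports whether the focal player is alive
#' at the end. While both players live, each survives the step independently
#' with the probability set by the two scheduled behaviors; once the partner
#' dies, the focal player survives each remaining step with `a0` regardless of
#' either schedule. Uses the current RNG state (seed with [set.seed()] for
#' reproducibility).
#'
#' @inheritParams payoff
#' @return `TRUE` if the focal player survives the game.
#' @export
play_once <- function(g, j, i) {
  .check_game(g)
  j <- .check_index(g, j, "j")
  i <- .check_index(g, i, "i")
  .simulate_alive(g, j, i, 1L) == 1L
}

#' Monte-Carlo estimate of a survival payoff
#'
#' Estimates `A(S_j; S_i)` as the proportion of simulated games in which the
#' focal player survives, with a normal-approximation 95% confidence
#' half-width `1.96 * sqrt(p(1-p)/reps)`. The estimate is an independent
#' stochastic check on the closed-form [payoff()].
#'
#' @inheritParams payoff
#' @param reps Number of simulated games (at least 1).
#' @param seed Integer seed; recorded in the result so reports are
#'   bit-reproducible.
#' @return A list of class `"payoff_estimate"`: `estimate`, `half_width`,
#'   `reps`, `seed`.
#' @examples
#' g <- survival_game(0.97, 0.94, 0.99, 0.95, 0.8, n = 1)
#' estimate_payoff(g, 1, 0, reps = 2000, seed = 1)$estimate  # near c = 0.99
#' @export
estimate_payoff <- function(g, j, i, reps, seed) {
  .check_game(g)
  if (!is.numeric(reps) || length(reps) != 1L || reps < 1 || reps != round(reps))
    stop("'reps' must be a positive integer")
  set.seed(seed)
  alive <- .simulate_alive(g, j, i, as.integer(reps))
  p <- alive / reps
  structure(
    list(estimate = p,
         half_width = 1.96 * sqrt(p * (1 - p) / reps),
         reps = as.integer(reps),
         seed = as.integer(seed)),
    class = "payoff_estimate"
  )
}

#' @export
print.payoff_estimate <- function(x, ...) {
  cat(sprintf("Monte-Carlo payoff estimate: %.5f +/- %.5f (95%% CI, %d reps, seed %d)\n",
              x$estimate, x$half_width, x$reps, x$seed))
  invisible(x)
}
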