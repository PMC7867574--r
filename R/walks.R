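# Best responses and deterministic best-response walks on the payoff surface.

#' Best response to a partner strategy
#'
#' The strategy `j` maximizing `A(S_j; S_i)` over `j` in `0:n`, found by
#' brute force over the payoff surface (the canonical route). When the
#' analytic fast paths apply they are asserted against the brute-force
#' answer: inside a stable stretch the best response is `i` itself; for
#' `i >= ceiling(i_C)` it is `floor(i_C)` (the cooperative side always jumps
#' straight over the stretch); for `i <= floor(i_D)` it is
#' `min(i + ceiling(k_star(g, i)), n)` (the defection side advances
#' incrementally).
#'
#' @param g A [survival_game()].
#' @param i Partner strategy index in `0:n`.
#' @param surface Optional precomputed [payoff_surface()] for `g`.
#' @param verify If `TRUE` (default), assert agreement with the closed-form
#'   fast paths wherever they are defined (strict PD games only; skipped near
#'   the `a0 = bc` degeneracy of `k_star`).
#' @return The best-response strategy index (integer). A payoff tie among
#'   candidate responses raises a tie error.
#' @examples
#' g <- survival_game(0.97, 0.94, 0.99, 0.95, 0.86, 20)
#' best_response(g, 4)   # 11
#' best_response(g, 11)  # 4 = floor(i_C)
#' @export
best_response <- function(g, i, surface = NULL, verify = TRUE) {
  .check_game(g)
  i <- .check_index(g, i, "i")
  A <- .surface_of(g, surface)
  col <- unname(A[, i + 1])
  j <- which.max(col) - 1L
  gaps <- col[j + 1] - col[-(j + 1)]
  if (any(gaps < .tie_tol))
    .tie_error(sprintf("payoff tie among best responses to i = %d; the walk is not well defined", i))
  if (verify && g$strict_pd) {
    iD <- i_D_real(g)
    iC <- i_C_real(g)
    # candidate replies from the two analytic sides; in a disequilibrium
    # stretch both apply and the better one wins (the walk's vertical arrow)
    cand <- integer(0)
    if (is.finite(iC) && i >= ceiling(iC))
      cand <- c(cand, as.integer(floor(iC)))
    if ((!is.finite(iD) || i <= floor(iD)) && abs(g$a0 - g$bc) >= 1e-8) {
      ks <- suppressWarnings(k_star(g, i))
      if (!is.na(ks))
        cand <- c(cand, if (is.finite(ks)) as.integer(min(i + ceiling(ks), g$n)) else g$n)
    }
    if (length(cand) == 0 && is.finite(iD) && is.finite(iC) && i > iD && i < iC)
      cand <- i  # interior of a stable stretch: staying put is optimal
    if (length(cand) > 0) {
      expected <- cand[which.max(col[cand + 1])]
      if (expected != j)
        stop(sprintf("closed-form best response (%d) disagrees with brute force (%d) at i = %d",
                     expected, j, i))
    }
  }
  j
}

#' Best-response walk from a common starting strategy
#'
#' Both players start at the same strategy `i0`; the focal player adopts the
#' best response to `i`, the partner follows suit, and the process repeats
#' from the new common strategy. The walk is deterministic on a finite state
#' space, so it ends in a cycle: a fixed point (a globally stable strategy)
#' or a longer cycle (as happens across a stretch of disequilibria, where the
#' defection side walks into the stretch and the cooperation side leaps back
#' over it).
#'
#' @param g A [survival_game()].
#' @param i0 Starting strategy index in `0:n`.
#' @param surface Optional precomputed [payoff_surface()] for `g`.
#' @return A list of class `"response_walk"`: `start`, `trajectory` (states
#'   visited, ending at the first revisited state) and `cycle` (the terminal
#'   cycle in order of traversal; length 1 is a fixed point).
#' @examples
#' response_walk(survival_game(0.97, 0.94, 0.99, 0.95, 0.86, 20), 0)$cycle  # 4, 11
#' @export
response_walk <- function(g, i0, surface = NULL) {
  .check_game(g)
  i0 <- .check_index(g, i0, "i0")
  A <- .surface_of(g, surface)
  traj <- i0
  repeat {
    nxt <- best_response(g, traj[length(traj)], surface = A, verify = FALSE)
    traj <- c(traj, nxt)
    first <- match(nxt, traj)
    if (first < length(traj)) break
  }
  cycle <- traj[first:(length(traj) - 1L)]
  structure(list(start = i0, trajectory = traj, cycle = cycle),
            class = "response_walk")
}

#' @export
print.response_walk <- function(x, ...) {
  cat(sprintf("Best-response walk from i = %d\n", x$start))
  cat("  trajectory:", paste(x$trajectory, collapse = " -> "), "\n")
  if (length(x$cycle) == 1L)
    cat(sprintf("  fixed point at i = %d\n", x$cycle))
  else
    cat(sprintf("  terminal cycle of length %d: {%s}\n", length(x$cycle),
                paste(sort(x$cycle), collapse = ", ")))
  invisible(x)
}

#' All terminal cycles of the best-response walk
#'
#' Runs [response_walk()] from every diagonal start `0:n` and returns the
#' distinct terminal cycles (each normalized to start at its smallest state).
#' Fixed points coincide with the globally stable strategies when any exist.
#'
#' @param g A [survival_game()].
#' @param surface Optional precomputed [payoff_surface()] for `g`.
#' @return A list of integer vectors, one per distinct cycle.
#' @export
terminal_cycles <- function(g, surface = NULL) {
  .check_game(g)
  A <- .surface_of(g, surface)
  cycles <- list()
  for (i0 in 0:g$n) {
    cyc <- response_walk(g, i0, surface = A)$cycle
    k <- which.min(cyc)
    if (k > 1L) cyc <- c(cyc[k:length(cyc)], cyc[seq_len(k - 1L)])
    key <- paste(cyc, collapse = ",")
    cycles[[key]] <- cyc
  }
  unname(cycles)
}
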