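# The reference values here are the published ones for the classic
# (0.97, 0.94, 0.99, 0.95) Prisoner's Dilemma and its b,c-perturbed variant.

test_that("the loner-survival cutoffs evaluate to their published values", {
  g <- pd_classic()
  expect_equal(a0_star(g), 0.9508, tolerance = 1e-4)
  expect_equal(a0_prime(g), 0.9186, tolerance = 1e-4)
  expect_equal(a0_double_prime(g), 0.9375, tolerance = 1e-4)
  expect_equal(a0_triple_prime(g), 0.43, tolerance = 0.005)
  # each is the stated weighted average, so it falls inside its bracket
  expect_true(g$aa < a0_star(g) && a0_star(g) < g$a)
  expect_true(g$dd < a0_prime(g) && a0_prime(g) < g$d)
  expect_true(g$dd < a0_double_prime(g) && a0_double_prime(g) < g$d)
})

test_that("cutoffs respond to parameter changes as the averages predict", {
  # bc -> a^2 (b up, c down at the same rate) drives a0_star toward a^2
  g1 <- survival_game(0.97, 0.94, 0.99, 0.95, 0.8, 10, require_pd = TRUE)
  g2 <- survival_game(0.97, 0.945, 0.995, 0.95, 0.8, 10, require_pd = TRUE)
  expect_lt(a0_star(g2), a0_star(g1))
  expect_lt(a0_star(g2) - g2$aa, 0.002)
  # non-PD games are outside the domain
  hd <- survival_game(0.97, 0.95, 0.98, 0.94, 0.8, 10)
  expect_error(a0_star(hd), "Prisoner's Dilemma")
  expect_error(i_D_real(hd), "Prisoner's Dilemma")
})

test_that("j_opt brackets the brute-force argmax and has the right limits", {
  g <- pd_classic(a0 = 0.8, n = 50)
  jo <- j_opt_real(g)
  expect_equal(jo, 6.10, tolerance = 0.005)
  vals <- vapply(0:50, function(j) payoff(g, j, 0), numeric(1))
  expect_equal(J_opt(g), which.max(vals) - 1L)
  expect_true(floor(jo) <= J_opt(g) && J_opt(g) <= ceiling(jo))
  # a0 -> 0: j_opt -> 0 and J_opt -> 1
  g_small <- pd_classic(a0 = 1e-4, n = 50)
  expect_lt(j_opt_real(g_small), 0.5)
  expect_equal(J_opt(g_small), 1L)
  # a0 -> a0_star from below: j_opt diverges; beyond it, nonexistent
  g_near <- pd_classic(a0 = a0_star(g) - 1e-6, n = 50)
  expect_gt(j_opt_real(g_near), 100)
  expect_identical(j_opt_real(pd_classic(a0 = 0.96, n = 50)), Inf)
  # the degenerate a0 = a^2 case still brackets the argmax
  g_eq <- pd_classic(a0 = 0.9409, n = 50)
  vals_eq <- vapply(0:50, function(j) payoff(g_eq, j, 0), numeric(1))
  expect_equal(J_opt(g_eq), which.max(vals_eq) - 1L)
  # when n caps the optimum, all-D is best
  g_cap <- pd_classic(a0 = 0.8, n = 4)
  expect_equal(J_opt(g_cap), 4L)
})

test_that("i_D and i_C match the published worked examples", {
  expect_equal(i_D_real(game_eq_stretch()), 3.08, tolerance = 0.005)
  expect_equal(i_C_real(game_eq_stretch()), 15.99, tolerance = 0.005)
  expect_equal(i_C_real(game_diseq_stretch()), 4.22, tolerance = 0.005)
  expect_equal(i_D_real(game_diseq_stretch()), 13.49, tolerance = 0.005)
})

test_that("i_D and i_C exist exactly below their cutoffs and diverge there", {
  g <- pd_classic(n = 20)
  ap <- a0_prime(g); app <- a0_double_prime(g)
  mk <- function(a0) pd_classic(a0 = a0, n = 20)
  # i_D -> 0 and i_C -> 1 as a0 -> 0 (logarithmically slowly)
  iD_seq <- vapply(c(1e-2, 1e-4, 1e-8), function(a0) i_D_real(mk(a0)), numeric(1))
  expect_true(all(diff(iD_seq) < 0) && iD_seq[3] < 0.1)
  iC_seq <- vapply(c(1e-2, 1e-4, 1e-8), function(a0) i_C_real(mk(a0)), numeric(1))
  expect_true(all(diff(iC_seq) < 0) && abs(iC_seq[3] - 1) < 0.1)
  expect_gt(i_D_real(mk(ap - 1e-7)), 100)              # divergence at a0'
  expect_gt(i_C_real(mk(app - 1e-7)), 100)             # divergence at a0''
  expect_identical(i_D_real(mk(ap + 1e-7)), Inf)
  expect_identical(i_C_real(mk(app + 1e-7)), Inf)
  # the a0 = d^2 special case sits on the continuous curve
  eps <- 1e-7
  expect_equal(i_D_real(mk(g$dd)),
               (i_D_real(mk(g$dd - eps)) + i_D_real(mk(g$dd + eps))) / 2,
               tolerance = 1e-4)
  expect_equal(i_C_real(mk(g$dd)),
               (i_C_real(mk(g$dd - eps)) + i_C_real(mk(g$dd + eps))) / 2,
               tolerance = 1e-4)
})

test_that("i_D, i_C and J_opt increase with a0 on their existence intervals", {
  g <- pd_classic(n = 50)
  ap <- a0_prime(g); app <- a0_double_prime(g); as_ <- a0_star(g)
  grid_D <- seq(0.01, ap - 1e-4, length.out = 200)
  iD <- vapply(grid_D, function(a0) i_D_real(pd_classic(a0 = a0, n = 50)), numeric(1))
  expect_true(all(diff(iD) > 0))
  grid_C <- seq(0.01, app - 1e-4, length.out = 200)
  iC <- vapply(grid_C, function(a0) i_C_real(pd_classic(a0 = a0, n = 50)), numeric(1))
  expect_true(all(diff(iC) > 0))
  grid_J <- seq(0.01, as_ - 1e-4, length.out = 100)
  Jo <- vapply(grid_J, function(a0) J_opt(pd_classic(a0 = a0, n = 50)), numeric(1))
  expect_true(all(diff(Jo) >= 0))
})

test_that("a0_triple_prime is where the i_D and i_C curves cross", {
  g <- pd_classic()
  x <- a0_triple_prime(g)
  g_at <- pd_classic(a0 = x, n = 20)
  expect_lt(abs(i_D_real(g_at) - i_C_real(g_at)), 1e-9)
  # the shrinking-stretch criterion is equivalent to the survival-ratio form
  expect_identical(a0_prime(g) < a0_double_prime(g),
                   (g$aa - g$bc) / (g$c - g$a) < (g$bc - g$dd) / (g$d - g$b))
  # outside the crossing case the quantity is not defined
  expect_error(a0_triple_prime(game_eq_stretch()), "a0_prime < a0_double_prime")
})

test_that("sign of the one-step gains flips exactly at i_D and i_C", {
  set.seed(6)
  for (r in 1:100) {
    g <- random_pd(lo = 0.6, n = 30)
    iD <- i_D_real(g); iC <- i_C_real(g)
    for (i in 0:(g$n - 1)) {
      dg <- defect_gain(g, i)
      if (i < iD) expect_gt(dg, 0) else expect_lt(dg, 0)
    }
    for (i in 1:g$n) {
      cg <- cooperate_gain(g, i)
      if (i < iC) expect_lt(cg, 0) else expect_gt(cg, 0)
    }
  }
})

test_that("j_star and k_star reduce to the cooperation and defection optima", {
  set.seed(7)
  n_checked <- 0
  for (r in 1:100) {
    g <- random_pd(lo = 0.6, n = 30)
    if (is.finite(i_C_real(g))) {
      expect_equal(j_star(g), i_C_real(g) - 1, tolerance = 1e-9)
      n_checked <- n_checked + 1
    }
    if (abs(g$a0 - g$bc) > 1e-8) {
      ks0 <- suppressWarnings(k_star(g, 0))
      Jo <- J_opt(g)
      if (is.finite(ks0) && is.finite(Jo) && Jo < g$n)
        expect_equal(ceiling(ks0), Jo)
    }
  }
  expect_gt(n_checked, 10)   # the identity was actually exercised
  # k_star outside its domain is an error
  g <- game_eq_stretch()     # i_D = 3.08
  expect_error(k_star(g, 5), "i <= floor\\(i_D\\)")
})

test_that("threshold_set gathers values and existence flags consistently", {
  ts <- threshold_set(game_diseq_stretch())
  expect_true(ts$i_D_exists && ts$i_C_exists)
  expect_equal(ts$i_D, i_D_real(game_diseq_stretch()))
  expect_equal(ts$j_star, ts$i_C - 1, tolerance = 1e-9)
  ts2 <- threshold_set(pd_classic(a0 = 0.96, n = 20))  # above a0* > a0' > a0''...
  expect_false(ts2$i_D_exists || ts2$i_C_exists || ts2$j_opt_exists)
  expect_identical(ts2$i_D, Inf)
  expect_output(print(ts), "a0'")
})
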