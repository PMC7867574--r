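test_that("closed-form gains equal the payoff differences", {
  set.seed(8)
  worst <- 0
  for (r in 1:30) {
    p <- sort(runif(4, 0.5, 1), decreasing = TRUE)
    a0 <- if (r %% 3 == 0) p[3]^2 else runif(1)   # include a0 = d^2 exactly
    g <- survival_game(p[2], p[4], p[1], p[3], a0, sample(2:12, 1))
    for (i in 0:(g$n - 1)) {
      worst <- max(worst, abs(defect_gain(g, i) - (payoff(g, i + 1, i) - payoff(g, i, i))))
      worst <- max(worst, abs(diagonal_difference(g, i) -
                                (payoff(g, i + 1, i + 1) - payoff(g, i, i))))
    }
    for (i in 1:g$n)
      worst <- max(worst, abs(cooperate_gain(g, i) - (payoff(g, i - 1, i) - payoff(g, i, i))))
  }
  expect_lt(worst, 1e-12)
})

test_that("endpoint gains have their simple closed forms and signs", {
  set.seed(9)
  for (r in 1:20) {
    g <- random_pd()
    pref <- g$a^(2 * (g$n - 1))
    expect_equal(defect_gain(g, 0), pref * (g$c - g$a), tolerance = 1e-13)
    expect_gt(defect_gain(g, 0), 0)
    expect_equal(cooperate_gain(g, 1), pref * (g$b - g$d), tolerance = 1e-13)
    expect_lt(cooperate_gain(g, 1), 0)
    # cooperating all the way down never beats one defection
    i <- sample(1:g$n, 1)
    expect_equal(payoff(g, 0, i) - payoff(g, 1, i),
                 g$a^(2 * (g$n - i)) * g$bc^(i - 1) * (g$b - g$d), tolerance = 1e-13)
    expect_equal(diagonal_difference(g, 0), pref * (g$d - g$a), tolerance = 1e-13)
  }
})

test_that("the diagonal payoff decreases in i even for a0 near 1", {
  g <- survival_game(0.97, 0.94, 0.99, 0.95, 0.999999, 30)
  for (i in 0:29) expect_lt(diagonal_difference(g, i), 0)
})

test_that("local stability reproduces the worked stretch examples", {
  expect_identical(stable_scan(game_eq_stretch()), 4:15)       # [[4, 15]]
  expect_identical(stable_scan(game_capped_stretch()), 12:20)  # all i >= 12
  expect_identical(stable_scan(game_single_point()), 4L)
  # defection always favored in the large-n sense, but the cap still
  # stabilizes S_n: only the cooperate condition applies at i = n
  expect_identical(stable_scan(game_defect_always()), 20L)
  # all-C is never stable in a Prisoner's Dilemma
  set.seed(10)
  for (r in 1:10) expect_false(is_locally_stable(random_pd(), 0))
})

test_that("a payoff tie raises a tie error instead of choosing a sign", {
  g <- survival_game(0.97, 0.94, 0.97, 0.95, 0.8, 10)  # c = a: defect gain 0 at i = 0
  expect_error(is_locally_stable(g, 0), class = "survgame_tie_error")
})

test_that("locally and globally stable strategies coincide", {
  set.seed(11)
  for (r in 1:50) {
    g <- random_pd(n = sample(3:15, 1))
    A <- payoff_surface(g)
    for (i in 0:g$n)
      expect_identical(is_locally_stable(g, i), is_globally_stable(g, i, A))
  }
})

test_that("stable_stretch equals the stability scan in every regime", {
  games <- list(
    game_eq_stretch(), game_diseq_stretch(), game_defect_always(),
    game_capped_stretch(), game_single_point(),
    pd_classic(a0 = 0.93, n = 20),    # i_D nonexistent, i_C = 23.4 beyond n: only S_n
    pd_classic(a0 = 0.01, n = 20),    # a0 -> 0 with bc > d^2: only S_1
    game_eq_stretch(a0 = 0.93),      # i_D = 20.9 beyond n, i_C nonexistent
    survival_game(0.97, 0.91, 0.98, 0.95, 0.5, 12, require_pd = TRUE)  # bc < d^2
  )
  set.seed(12)
  for (r in 1:30) games[[length(games) + 1]] <- random_pd(n = sample(3:15, 1))
  for (g in games)
    expect_identical(interval_members(stable_stretch(g)), as.integer(stable_scan(g)))
})

test_that("the classifier reproduces the published worked examples", {
  cl <- classify_incentives(game_defect_always())
  expect_identical(cl$case_id, 1L)
  expect_identical(cl$type_label, "1")

  cl <- classify_incentives(game_eq_stretch())
  expect_identical(cl$case_id, 5L)
  expect_identical(cl$type_label, "3a")
  expect_identical(interval_members(cl$equilibrium_stretch), 4:15)

  cl <- classify_incentives(game_diseq_stretch())
  expect_identical(cl$case_id, 8L)
  expect_identical(cl$type_label, "5a")
  expect_identical(interval_members(cl$disequilibrium_stretch), 5:13)

  cl <- classify_incentives(game_capped_stretch())
  expect_identical(cl$case_id, 4L)
  expect_identical(cl$type_label, "2")
  expect_identical(interval_members(cl$equilibrium_stretch), 12:20)

  cl <- classify_incentives(game_single_point())
  expect_identical(cl$case_id, 10L)
  expect_identical(cl$type_label, "3b")
  expect_identical(interval_members(cl$equilibrium_stretch), 4L)

  # the switching interval between single points: floor(i_D) == floor(i_C)
  cl <- classify_incentives(pd_classic(a0 = 0.45, n = 20))
  expect_identical(cl$case_id, 9L)
  expect_identical(cl$type_label, "5b")
  expect_identical(cl$switch_pair, c(1, 2))

  expect_error(classify_incentives(survival_game(0.97, 0.95, 0.98, 0.94, 0.8, 10)),
               "Prisoner's Dilemma")
})

test_that("inside a disequilibrium stretch both deviations beat staying put", {
  g <- game_diseq_stretch()
  cl <- classify_incentives(g)
  for (i in interval_members(cl$disequilibrium_stretch)) {
    expect_gt(defect_gain(g, i), 0)
    expect_gt(cooperate_gain(g, i), 0)
  }
})

test_that("the large_n flag separates idealized stretches from finite-game stability", {
  # same parameters as the capped-stretch game but a very short game:
  # i_D = 11.47 exceeds n = 5, so the interior stretch is gone and only the
  # cap-stabilized S_n remains
  g <- survival_game(0.97, 0.93, 0.98, 0.95, 0.92, 5, require_pd = TRUE)
  cl_large <- classify_incentives(g, large_n = TRUE)
  cl_small <- classify_incentives(g, large_n = FALSE)
  expect_identical(cl_large$case_id, cl_small$case_id)
  expect_identical(interval_members(cl_small$equilibrium_stretch), 5L)
  expect_identical(interval_members(cl_small$equilibrium_stretch),
                   as.integer(stable_scan(g)))
  # Type 1: no stretch in the large-n description, yet S_n is still stable
  cl1 <- classify_incentives(game_defect_always(), large_n = FALSE)
  expect_identical(cl1$type_label, "1")
  expect_identical(interval_members(cl1$equilibrium_stretch), 20L)
  expect_true(classify_incentives(game_defect_always())$equilibrium_stretch$empty)
})
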