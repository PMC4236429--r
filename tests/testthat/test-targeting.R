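test_that("correct targeting ratio matches the m = 1 closed form", {
  p <- 5e-3; astar <- 5e-3; t0 <- 1e4
  r <- correct_targeting_ratio(p, astar, t0)
  expect_equal(r, p * exp(astar * t0) / ((1 - p) * astar), tolerance = 1e-10)
  expect_equal(r, 5.21e21, tolerance = 1e-3)
  expect_gt(r, 1e20)

  # log-space accessor agrees with the linear value
  expect_equal(correct_targeting_ratio(p, astar, t0, log = TRUE), log(r),
               tolerance = 1e-12)

  # a sub-threshold pathogen is invisible: R = 0
  expect_equal(correct_targeting_ratio(1e-3, astar, t0), 0)
  expect_identical(correct_targeting_ratio(1e-3, astar, t0, log = TRUE), -Inf)

  # divergence as a* -> 0 at fixed p
  expect_gt(correct_targeting_ratio(0.5, 1e-9, 10), 1e8)

  expect_error(correct_targeting_ratio(0, 1e-3, 100), "0, 1")
  expect_error(correct_targeting_ratio(1, 1e-3, 100), "0, 1")
})

test_that("ratio computations survive regimes where exp overflows", {
  # a* t0 = 500: R ~ e^500 overflows linear doubles but not the log path
  lr <- correct_targeting_ratio(1e-2, 1e-2, 50000, log = TRUE)
  expect_true(is.finite(lr))
  expect_equal(lr, log(1e-2) - log(1 - 1e-2) - log(1e-2) + 500,
               tolerance = 1e-9)
  expect_equal(lower_bound_ratio(1000, 0.5, 1000, log = TRUE), 500000)
})

test_that("truncated form is exact at m = 1 and tracks the quotient", {
  expect_equal(truncated_targeting_ratio(1e-2, 5e-3, 1000),
               correct_targeting_ratio(1e-2, 5e-3, 1000), tolerance = 1e-12)
  # for m > 1 the truncation keeps the leading order in exp(a* t0)
  lr_exact <- correct_targeting_ratio(1e-2, 5e-3, 4000, m = 2, log = TRUE)
  lr_trunc <- truncated_targeting_ratio(1e-2, 5e-3, 4000, m = 2, log = TRUE)
  expect_equal(lr_exact, lr_trunc, tolerance = 1e-3)
})

test_that("lower bound e^{K s n*} matches the full ratio and its limits", {
  r <- lower_bound_ratio(K = 200, s = 0.05, n_star = 5)
  expect_equal(r, exp(50))
  expect_gt(r, 1e20)
  expect_equal(lower_bound_ratio(100, 1e-9, 1), 1, tolerance = 1e-6)

  # algebraic identity a* t0 = K s n*: the exact quotient at p = a* equals
  # the bound up to its (1 - p) factor
  K <- 200; s <- 0.05; n_star <- 5; N <- 1000
  t0 <- K * N * s; astar <- n_star / N
  expect_equal(correct_targeting_ratio(astar, astar, t0) * (1 - astar),
               lower_bound_ratio(K, s, n_star), tolerance = 1e-9)
})

test_that("the ratio grows with pathogen abundance", {
  astar <- 5e-3; t0 <- 1000
  p_grid <- seq(astar, 0.99, length.out = 200)
  r <- vapply(p_grid, correct_targeting_ratio, numeric(1),
              a_star = astar, t0 = t0, log = TRUE)
  expect_true(all(diff(r) > 0))
})

test_that("a self antigen raised from a_max to a* is hit once per ~3 responses", {
  t0 <- 1e4; astar <- 5e-3
  r <- raised_self_targeting_ratio(p = astar, a_basal = 1 / t0,
                                   a_new = astar, t0 = t0)
  expect_equal(r, exp(1) / (1 - astar), tolerance = 1e-12)
  expect_equal(round(r), 3)  # round-half-even integer convention

  # consistency: unchanged abundance reduces to the correct targeting ratio
  expect_equal(
    raised_self_targeting_ratio(0.05, astar, astar, t0),
    correct_targeting_ratio(0.05, astar, t0), tolerance = 1e-12)

  # never-tolerated limit: f -> 0 gives p / ((1-p) a_new) -> 1 / (1 - p)
  expect_equal(raised_self_targeting_ratio(0.05, 0, 0.05, t0),
               1 / 0.95, tolerance = 1e-12)

  # sub-threshold self antigen stays invisible
  expect_identical(
    raised_self_targeting_ratio(0.05, 1e-4, 1e-3, t0, a_star = astar), Inf)
})

test_that("fold-change targeting follows the threshold branches", {
  params <- default_params()  # t0 = 1000, N = 1000, n* = 5, a* = 5e-3
  amax <- riskiest_abundance(params$t0)  # 1e-3

  expect_equal(fold_change_targeting_prob(amax, 4.9, params), 0)
  expect_equal(fold_change_targeting_prob(amax, 5, params),
               5e-3 * exp(-1), tolerance = 1e-12)
  expect_equal(fold_change_targeting_prob(amax, 5, params), 1.839e-3,
               tolerance = 1e-3)

  # k = 1 is the plain targeting probability
  a <- c(1e-3, 6e-3, 2e-2)
  expect_equal(fold_change_targeting_prob(a, 1, params),
               targeting_probability(a, params))

  expect_error(fold_change_targeting_prob(0.5, 3, params), "exceeds 1")
  expect_error(fold_change_targeting_prob(1e-3, -1, params), "positive")
})

test_that("minimum detectable increment agrees across parameterizations", {
  expect_equal(minimum_detectable_increment(K = 200, s = 0.05, n_star = 5), 50)
  expect_equal(minimum_detectable_increment(K = 1000, s = 0.05, n_star = 10),
               500)
  expect_equal(minimum_detectable_increment(a_star = 5e-3, t0 = 1e4), 50)

  # full parameter set: both routes agree by the identity a* t0 = K s n*
  params <- model_params(N = 1000, n_star = 5, K = 200, s = 0.05)
  expect_equal(minimum_detectable_increment(params), 50)

  expect_error(minimum_detectable_increment(a_star = 5e-3, t0 = 100,
                                            K = 100, s = 0.5, n_star = 5),
               "inconsistent")
  expect_error(minimum_detectable_increment(a_star = 5e-3), "insufficient")
})

test_that("discrimination ability: closed form, gap, and monotonicity", {
  expect_equal(discrimination_ability(1), 0)
  expect_equal(discrimination_ability(10), 0.99975, tolerance = 1e-4)
  expect_equal(discrimination_ability(10),
               (exp(9) - 1) / (exp(9) + 1), tolerance = 1e-14)

  # 1 - Delta without catastrophic cancellation
  expect_equal(discrimination_gap(50), 2 / (exp(49) + 1), tolerance = 1e-12)
  expect_lt(discrimination_gap(50), 1e-20)
  expect_equal(discrimination_gap(1), 1)

  # strictly increasing in the MDI (Delta saturates to 1.0 in double
  # precision past MDI ~ 35; the gap form stays strictly ordered far longer)
  set.seed(47)
  mdi <- sort(runif(100, 1, 30))
  expect_true(all(diff(discrimination_ability(mdi)) > 0))
  mdi_wide <- sort(runif(100, 1, 300))
  expect_true(all(diff(discrimination_gap(mdi_wide)) < 0))

  # m = 1 special case of the odds-ratio form equals the compact form
  delta_odds <- function(MDI) {
    d <- exp(MDI - 1)
    (d - 1) / (d + 1)
  }
  expect_equal(discrimination_ability(c(2, 7, 30)),
               delta_odds(c(2, 7, 30)), tolerance = 1e-14)

  expect_error(discrimination_ability(0.5), ">= 1")
  expect_error(discrimination_gap(0.5), ">= 1")
})

test_that("first-principles discrimination agrees with the closed form", {
  # the defining probability quotient, rebuilt from the targeting
  # probabilities at a_max (raised MDI-fold) and at a*, matches the compact
  # m = 1 expression to high relative accuracy for small a*
  for (astar in c(1e-3, 1e-4)) {
    for (mdi in c(2, 5, 10, 20)) {
      fp <- discrimination_ability(mdi, method = "first_principles",
                                   a_star = astar)
      cf <- discrimination_ability(mdi)
      expect_equal(fp, cf, tolerance = 1e-6)
    }
  }
  # and is insensitive to how a* and t0 split their fixed product
  vals <- sapply(c(1e-5, 1e-4, 1e-3), function(astar) {
    discrimination_ability(12, method = "first_principles", a_star = astar)
  })
  expect_lt(diff(range(vals)), 1e-9)
})

test_that("operating regions of the MDI trade-off classify correctly", {
  expect_equal(classify_region(100), 3L)
  expect_equal(classify_region(1), 1L)
  expect_equal(classify_region(3), 2L)    # lower bound inclusive
  expect_equal(classify_region(20), 3L)
  expect_equal(classify_region(c(1, 5, 50)), c(1L, 2L, 3L))
  expect_equal(classify_region(5, boundaries = c(2, 4)), 3L)
  expect_error(classify_region(5, boundaries = c(4, 2)), "increasing")
})

test_that("the smallest detecting fold is the threshold ratio a*/a_basal", {
  params <- default_params()
  expect_equal(minimum_detecting_fold(1e-3, params), 5L)
  expect_equal(minimum_detecting_fold(5e-3, params), 1L)
  expect_true(is.na(minimum_detecting_fold(1e-9, params, k_max = 10L)))
})
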