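test_that("central tolerance probability matches its closed form and limits", {
  expect_equal(tolerance_probability(0, t0 = 1000), 0)
  expect_equal(tolerance_probability(1e-3, t0 = 1000), 1 - exp(-1))
  expect_equal(tolerance_probability(1e-3, t0 = 1000, m = 2), (1 - exp(-1))^2)

  # exp underflow regime returns the exact limit, no NaN
  expect_identical(tolerance_probability(1, t0 = 1000), 1)

  expect_error(tolerance_probability(-0.1, 1000), "\\[0, 1\\]")
  expect_error(tolerance_probability(1.5, 1000), "\\[0, 1\\]")
  expect_error(tolerance_probability(0.5, t0 = 0), "count")
})

test_that("presentation count pmf: binomial exact, Poisson approximation", {
  expect_equal(presentation_count_pmf(0.5, 2, 0, "binomial"), 0.25)
  expect_equal(presentation_count_pmf(1e-3, 1000, 0, "poisson"), exp(-1))

  # independent small-t0 oracle: direct binomial formula
  t0 <- 7; a <- 0.3
  for (k in 0:t0) {
    expect_equal(presentation_count_pmf(a, t0, k, "binomial"),
                 choose(t0, k) * a^k * (1 - a)^(t0 - k))
  }

  # total-variation distance binomial vs Poisson for rare antigens
  k <- 0:1000
  tv <- sum(abs(presentation_count_pmf(1e-3, 1000, k, "binomial") -
                presentation_count_pmf(1e-3, 1000, k, "poisson")))
  expect_lt(tv, 1e-3)
  # ... and pointwise, across the small-abundance regime
  for (a in c(1e-3, 5e-3, 1e-2)) {
    expect_lt(max(abs(presentation_count_pmf(a, 500, 0:500, "binomial") -
                      presentation_count_pmf(a, 500, 0:500, "poisson"))),
              1e-3)
  }

  expect_error(presentation_count_pmf(0.5, 10, 11, "binomial"),
               "exceed t0")
})

test_that("central-only targeting peaks at 1/t0 and collapses m = 1 forms", {
  expect_equal(targeting_probability_central(0, 1000), 0)
  t0 <- 1000
  expect_equal(targeting_probability_central(1 / t0, t0), exp(-1) / t0)

  # brute-force grid search confirms the riskiest abundance
  grid <- 10^seq(-6, -1, length.out = 5000)
  vals <- targeting_probability_central(grid, t0)
  expect_equal(grid[which.max(vals)], 1e-3, tolerance = 5e-3)

  # the compact m = 1 form a * exp(-a t0) equals the general expression
  set.seed(23)
  a <- runif(50); t0s <- sample(1:5000, 50, replace = TRUE)
  expect_equal(targeting_probability_central(a, t0s[1], m = 1),
               a * exp(-a * t0s[1]), tolerance = 1e-12)
  for (i in 1:50) {
    expect_equal(targeting_probability_central(a[i], t0s[i]),
                 a[i] * exp(-a[i] * t0s[i]), tolerance = 1e-12)
  }
})

test_that("riskiest abundance is 1/(t0 m); m > 1 argmax shifts by an O(1) factor", {
  expect_equal(riskiest_abundance(1000), 1e-3)
  expect_equal(riskiest_abundance(2000), 5e-4)  # doubling t0 halves it
  expect_equal(riskiest_abundance(1000, m = 2), 5e-4)

  # for m = 2 the numeric maximizer of the m-clone targeting probability sits
  # near 1.21/t0, not at 1/(t0 m): the compact formula is a scale, not the
  # exact argmax, once m > 1
  grid <- 10^seq(-6, -1, length.out = 5000)
  amax2 <- grid[which.max(targeting_probability_central(grid, 1000, m = 2))]
  expect_gt(amax2 * 1000, 1.1)
  expect_lt(amax2 * 1000, 1.35)
})

test_that("efficient presentation is Poisson survival rising at a* = n*/N", {
  expect_equal(efficient_presentation_prob(0, 1000, 5), 0)
  # n* = 1 reduces to 1 - exp(-a N)
  a <- c(1e-4, 1e-3, 1e-2)
  expect_equal(efficient_presentation_prob(a, 1000, 1),
               1 - exp(-a * 1000))

  # independent oracle: cumulative Poisson sum built from the raw series
  lambda <- 10; n_star <- 5
  series <- sum(lambda^(0:(n_star - 1)) / factorial(0:(n_star - 1)))
  expect_equal(efficient_presentation_prob(1e-2, 1000, n_star),
               1 - exp(-lambda) * series)
  expect_equal(efficient_presentation_prob(1e-2, 1000, n_star), 0.9707473,
               tolerance = 1e-7)

  expect_equal(presentation_threshold(1000, 5), 5e-3)
  expect_equal(presentation_threshold(100, 100), 1.0)
  expect_error(presentation_threshold(100, 101), "exceed")

  # at the threshold itself the exact probability is near one half
  for (N in c(100, 1000, 10000)) {
    n_star <- as.integer(0.05 * N)
    p_at <- efficient_presentation_prob(0.05, N, n_star)
    expect_gt(p_at, 0.3); expect_lt(p_at, 0.7)
  }
})

test_that("step mode converges to exact mode as N grows at fixed a*", {
  astar <- 0.05
  devs <- sapply(c(100, 1000, 10000), function(N) {
    n_star <- as.integer(astar * N)
    a <- 10^seq(-3, 0, length.out = 500)
    outside <- a < 0.8 * astar | a > 1.2 * astar
    max(abs(efficient_presentation_prob(a, N, n_star, "exact") -
            efficient_presentation_prob(a, N, n_star, "step"))[outside])
  })
  expect_true(all(diff(devs) < 0))
  expect_lt(devs[3], 1e-4)
})

test_that("tolerance and presentation probabilities are proper and monotone", {
  set.seed(31)
  for (i in 1:25) {
    t0 <- sample(10:5000, 1); m <- sample(1:3, 1)
    N <- sample(100:2000, 1); n_star <- sample(1:10, 1)
    a <- sort(runif(20))
    f <- tolerance_probability(a, t0, m)
    pres <- efficient_presentation_prob(a, N, n_star)
    tp <- targeting_probability_central(a, t0, m)
    expect_true(all(f >= 0 & f <= 1))
    expect_true(all(pres >= 0 & pres <= 1))
    expect_true(all(tp >= 0 & tp <= 1))
    expect_true(all(diff(f) >= 0))     # monotone in abundance
    expect_true(all(diff(pres) >= 0))
  }
  # monotone increasing in t0; decreasing in m (all m clones must be deleted)
  expect_true(all(diff(sapply(c(10, 100, 1000),
                              function(t0) tolerance_probability(1e-3, t0))) > 0))
  expect_true(all(diff(sapply(1:4, function(m)
    tolerance_probability(1e-3, 1000, m))) < 0))
})

test_that("combined targeting honors the threshold in step and exact modes", {
  params <- default_params()
  astar <- a_star(params)  # 5e-3

  expect_equal(targeting_probability(0.5 * astar, params, mode = "step"), 0)
  expect_equal(
    targeting_probability(2 * astar, params, mode = "step"),
    targeting_probability_central(2 * astar, params$t0))

  # below threshold the exact mode damps the central probability by the
  # Poisson survival factor; above threshold step and exact nearly agree
  a_lo <- astar / 10
  damp <- targeting_probability(a_lo, params, mode = "exact") /
    targeting_probability_central(a_lo, params$t0)
  expect_equal(damp, efficient_presentation_prob(a_lo, 1000, 5))
  expect_lt(damp, 2e-4)
  a_hi <- 4 * astar
  expect_equal(targeting_probability(a_hi, params, mode = "exact"),
               targeting_probability(a_hi, params, mode = "step"),
               tolerance = 0.03)
})

test_that("derive() evaluates tolerance at basal abundances", {
  env <- antigen_environment(c(1e-3, 1 - 1e-3))
  env_inf <- add_pathogen(env, p = 0.2)
  params <- default_params()
  dq <- derive(env_inf, params)

  expect_equal(dq$a_star, 5e-3)
  expect_equal(dq$a_max, 1e-3)
  expect_equal(dq$mdi, 5)
  # self tolerance computed from pre-infection abundances
  expect_equal(dq$table$f_i[1], tolerance_probability(1e-3, 1000))
  # pathogen antigens are never tolerated
  expect_equal(dq$table$f_i[3], 0)
  expect_true(all(dq$table$targeting_prob >= 0 &
                  dq$table$targeting_prob <= 1))

  out <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  write_derived(dq, out, js)
  expect_equal(nrow(utils::read.delim(out)), 3)
  expect_equal(jsonlite::fromJSON(js)$mdi, 5)
})
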