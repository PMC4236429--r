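# shared fixtures: a small mammalian-ish parameter set and random environments

default_params <- function(...) {
  model_params(t0 = 1000, N = 1000, n_star = 5, ...)
}

random_environment <- function(n = 10L) {
  antigen_environment(stats::runif(n, min = 1e-6, max = 1))
}

# binomial SE of an empirical frequency
binom_se <- function(phat, n) sqrt(phat * (1 - phat) / n)

expect_within_3se <- function(phat, p_true, n) {
  se <- max(binom_se(p_true, n), .Machine$double.eps)
  expect_lt(abs(phat - p_true), 3 * se)
}
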