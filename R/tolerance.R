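#' Probability that a self antigen is centrally tolerated
#'
#' Central tolerance is modeled as thymic negative selection: a naive
#' self-reactive clone is deleted if it encounters its cognate antigen at
#' least once among the `t0` presentations of maturation. An antigen with
#' effective abundance `a_i` therefore escapes one clone with probability
#' `exp(-a_i * t0)` (Poisson zero-count), and is tolerated — all `m` of its
#' reactive clones deleted — with probability
#'
#' \deqn{f_i = (1 - e^{-a_i t_0})^m.}
#'
#' Abundant self antigens are almost surely tolerated; rare ones retain
#' reactive clones in the repertoire.
#'
#' @param a_i effective abundance(s), in \[0, 1\] (vectorized).
#' @param t0 number of presentations during maturation, >= 1.
#' @param m number of naive self-reactive clones per antigen, >= 1.
#' @return Tolerance probability/ies in \[0, 1\], monotone increasing in all
#'   three arguments.
#' @examples
#' tolerance_probability(1e-3, t0 = 1000)       # 1 - exp(-1)
#' tolerance_probability(1e-3, t0 = 1000, m = 2) # (1 - exp(-1))^2
#' @export
tolerance_probability <- function(a_i, t0, m = 1L) {
  check_abundance(a_i)
  check_count(t0, "t0"); check_count(m, "m")
  # (1 - e^-x)^m via expm1 for small x; exact limit 1 when e^-x underflows
  (-expm1(-a_i * t0))^m
}

#' Distribution of presentation counts during maturation
#'
#' During maturation an antigen with effective abundance `a_i` occupies each
#' of the `t0` presentation slots independently, so its total count is
#' binomial; for large `t0` and small `a_i` the Poisson law with rate
#' `a_i * t0` is an excellent approximation (and the one the closed forms
#' build on).
#'
#' @param a_i effective abundance in \[0, 1\].
#' @param t0 number of presentations, >= 1.
#' @param k count(s) at which to evaluate the pmf (vectorized).
#' @param count_model `"binomial"` (exact) or `"poisson"` (approximation).
#' @return Pr\{antigen presented exactly `k` times\}.
#' @export
presentation_count_pmf <- function(a_i, t0, k,
                                   count_model = c("binomial", "poisson")) {
  count_model <- match.arg(count_model)
  check_abundance(a_i)
  check_count(t0, "t0")
  if (any(k < 0) || any(k != round(k))) {
    stop("k must be a non-negative integer count", call. = FALSE)
  }
  if (count_model == "binomial") {
    if (any(k > t0)) {
      stop("binomial counts cannot exceed t0 presentations", call. = FALSE)
    }
    stats::dbinom(k, size = t0, prob = a_i)
  } else {
    stats::dpois(k, lambda = a_i * t0)
  }
}

#' Probability of erroneously targeting a self antigen (central tolerance only)
#'
#' In a danger context (innate system activated), a non-tolerated self
#' antigen can be targeted with probability proportional to its effective
#' abundance. With `m` reactive clones per antigen the probability is
#'
#' \deqn{\Pr\{A_i \mathrm{targeted}\} = 1 - (1 - a_i (1 - f_i))^m,}
#'
#' which for `m = 1` reduces to the compact form `a_i * exp(-a_i * t0)`.
#' The risk is maximal at the abundance [riskiest_abundance()] — rare
#' antigens are hardly presented, abundant ones are tolerated.
#'
#' Tolerance `f_i` is always evaluated at the *basal* abundance (the one in
#' force during maturation); pass `a_basal` when the current abundance has
#' since changed.
#'
#' @param a_i current effective abundance(s) in \[0, 1\] (vectorized).
#' @param t0 presentations during maturation.
#' @param m reactive clones per antigen.
#' @param a_basal abundance at tolerance induction; defaults to `a_i`.
#' @return Targeting probability/ies in \[0, 1\].
#' @export
targeting_probability_central <- function(a_i, t0, m = 1L, a_basal = a_i) {
  check_abundance(a_i); check_abundance(a_basal)
  check_count(t0, "t0"); check_count(m, "m")
  # 1 - f = 1 - (1 - e^-x)^m computed without the cancellation that a
  # literal subtraction would suffer once e^-x is small
  not_tol <- -expm1(m * log1p(-exp(-a_basal * t0)))
  -expm1(m * log1p(-a_i * not_tol))
}

#' Self abundance at maximal risk of erroneous targeting
#'
#' The targeting probability under central tolerance alone peaks at
#' `a_max = 1 / (t0 * m)`: below it presentation is too rare, above it
#' tolerance takes over.
#'
#' @param t0 presentations during maturation.
#' @param m reactive clones per antigen.
#' @return The abundance `1 / (t0 * m)`.
#' @examples
#' riskiest_abundance(1000)  # 1e-3
#' @export
riskiest_abundance <- function(t0, m = 1L) {
  check_count(t0, "t0"); check_count(m, "m")
  1 / (t0 * m)
}

#' Probability of efficient presentation (peripheral tolerance)
#'
#' Lymphocyte activation requires at least `n_star` MHC-peptide-TCR
#' complexes on one APC. An antigen occupying each of the `N` complexes
#' independently with probability `a_i` reaches that count with the Poisson
#' survival probability
#'
#' \deqn{\Pr\{\ge n^*\} = 1 - e^{-a_i N} \sum_{j=0}^{n^*-1} (a_i N)^j / j!,}
#'
#' which rises sharply from 0 to 1 around the threshold abundance
#' `a_star = n_star / N`. `mode = "step"` replaces the rise by a Heaviside
#' step at `a_star` (the approximation used by the downstream closed forms).
#'
#' @param a_i effective abundance(s) in \[0, 1\] (vectorized).
#' @param N MHC-peptide complexes per APC.
#' @param n_star activation threshold, 1 <= n_star <= N.
#' @param mode `"exact"` (Poisson survival) or `"step"` (Heaviside).
#' @return Probability/ies of efficient presentation.
#' @examples
#' efficient_presentation_prob(1e-2, N = 1000, n_star = 5)  # ~0.971
#' @export
efficient_presentation_prob <- function(a_i, N, n_star,
                                        mode = c("exact", "step")) {
  mode <- match.arg(mode)
  check_abundance(a_i)
  check_count(N, "N"); check_count(n_star, "n_star")
  if (n_star > N) stop("n_star cannot exceed N", call. = FALSE)
  if (mode == "step") {
    as.numeric(a_i >= n_star / N)
  } else {
    stats::ppois(n_star - 1, lambda = a_i * N, lower.tail = FALSE)
  }
}

#' Probability of targeting a self antigen under central + peripheral tolerance
#'
#' Combines negative selection with the efficient-presentation requirement.
#' In `"step"` mode (the default closed-form convention),
#'
#' \deqn{\Pr\{A_i\} = 0 \quad (a_i < a^*); \qquad
#'       1 - (1 - a_i(1 - f_i))^m \quad (a_i \ge a^*),}
#'
#' while `"exact"` mode multiplies the central-tolerance targeting
#' probability by the Poisson efficient-presentation probability. With
#' peripheral tolerance in force (`a_star > a_max`) the riskiest self
#' antigens are those sitting just at the threshold `a_star`.
#'
#' @param a_i current effective abundance(s) (vectorized).
#' @param params a [model_params()] supplying `t0`, `N`, `n_star`, `m` and
#'   the default `presentation_mode`.
#' @param a_basal abundance(s) at tolerance induction; defaults to `a_i`.
#' @param mode override of `params$presentation_mode`.
#' @return Targeting probability/ies in \[0, 1\].
#' @export
targeting_probability <- function(a_i, params, a_basal = a_i, mode = NULL) {
  stopifnot(inherits(params, "model_params"))
  require_param(params, "t0", "N", "n_star", "m")
  if (is.null(mode)) mode <- params$presentation_mode
  central <- targeting_probability_central(a_i, params$t0, params$m, a_basal)
  central * efficient_presentation_prob(a_i, params$N, params$n_star, mode)
}

#' Per-antigen derived quantities for an environment
#'
#' Evaluates, for every antigen in an environment, the tolerance probability
#' (at basal abundance), the efficient-presentation probability and the
#' targeting probability (at current abundance), together with the scalar
#' model summaries `a_star`, `a_max` and MDI.
#'
#' @param env an [antigen_environment()].
#' @param params a [model_params()] with `t0`, `N`, `n_star`, `m`.
#' @param mode presentation mode override.
#' @return A list of class `"derived_quantities"`: `table` (one row per
#'   antigen) and scalars `a_star`, `a_max`, `mdi`.
#' @export
derive <- function(env, params, mode = NULL) {
  stopifnot(inherits(env, "antigen_environment"))
  require_param(params, "t0", "N", "n_star", "m")
  if (is.null(mode)) mode <- params$presentation_mode
  # pathogen antigens have basal abundance zero, hence tolerance zero
  f <- tolerance_probability(env$basal_abundances, params$t0, params$m)
  pres <- efficient_presentation_prob(env$abundances, params$N, params$n_star,
                                      mode)
  central <- targeting_probability_central(env$abundances, params$t0,
                                           params$m, env$basal_abundances)
  tab <- data.frame(
    antigen_id = env$ids,
    category = env$categories,
    abundance = env$abundances,
    basal_abundance = env$basal_abundances,
    f_i = f,
    efficient_presentation_prob = pres,
    targeting_prob = central * pres,
    stringsAsFactors = FALSE
  )
  astar <- a_star(params)
  structure(
    list(table = tab,
         a_star = astar,
         a_max = riskiest_abundance(params$t0, params$m),
         mdi = astar * params$t0,
         params = params),
    class = "derived_quantities"
  )
}

#' @export
print.derived_quantities <- function(x, ...) {
  cat(sprintf(
    "Derived quantities: a_star = %g, a_max = %g, MDI = %g\n",
    x$a_star, x$a_max, x$mdi))
  print(utils::head(x$table, 10L), row.names = FALSE)
  if (nrow(x$table) > 10L) cat("... and", nrow(x$table) - 10L, "more rows\n")
  invisible(x)
}

# ---- argument checks shared across the analytic layer ----

check_abundance <- function(a, name = "effective abundance") {
  if (!is.numeric(a) || anyNA(a) || any(a < 0) || any(a > 1)) {
    stop(name, " must lie in [0, 1]", call. = FALSE)
  }
  invisible(a)
}

check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1) {
    stop(name, " must be a count >= 1", call. = FALSE)
  }
  invisible(x)
}

check_fraction <- function(x, name, lo = 0, hi = 1,
                           lo_open = TRUE, hi_open = TRUE) {
  bad <- !is.numeric(x) || length(x) != 1L || is.na(x) ||
    (if (lo_open) x <= lo else x < lo) ||
    (if (hi_open) x >= hi else x > hi)
  if (bad) {
    stop(name, " must lie in ", if (lo_open) "(" else "[", lo, ", ", hi,
         if (hi_open) ")" else "]", call. = FALSE)
  }
  invisible(x)
}
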