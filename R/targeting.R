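#' Correct targeting ratio R: pathogen versus riskiest self antigen
#'
#' In an infection with pathogen effective abundance `p`, the probability of
#' targeting the pathogen is `p` itself (abundances are normalized), while
#' the riskiest self antigen — the one sitting at the presentation threshold
#' `a_star` — is targeted with probability
#' `(1 - p) * [1 - (1 - a_star (1 - f_star))^m]`, with tolerance `f_star`
#' evaluated at the basal abundance `a_star`. Their quotient,
#'
#' \deqn{R = \frac{p}{(1-p)\,[1 - (1 - a^*(1-f^*))^m]},}
#'
#' measures how much more likely the adaptive system is to hit the pathogen
#' than a self antigen; for `m = 1` it equals
#' `p * exp(a_star * t0) / ((1 - p) * a_star)`. A pathogen below the
#' presentation threshold (`p < a_star`) is invisible to the adaptive
#' system, which corresponds to `R = 0`: any response then hits self.
#'
#' `R` can reach `exp(50)`–`exp(500)` at realistic parameters, so the
#' computation is carried in log space; request `log = TRUE` to retrieve
#' `log(R)` without overflow.
#'
#' When `N` and `n_star` are supplied the Heaviside presentation step is
#' replaced by the exact Poisson efficient-presentation probabilities for
#' both antigens (pathogen at abundance `p`, self at `(1 - p) * a_star`) —
#' the form the Monte-Carlo simulator converges to.
#'
#' @param p pathogen effective abundance, in (0, 1).
#' @param a_star efficient-presentation threshold.
#' @param t0 presentations during maturation.
#' @param m reactive clones per antigen.
#' @param N,n_star optional: include exact presentation probabilities.
#' @param log return `log(R)` instead of `R`?
#' @return The ratio `R` (or its log); `0` (`-Inf`) when `p < a_star`.
#' @examples
#' correct_targeting_ratio(p = 5e-3, a_star = 5e-3, t0 = 1e4)  # ~5.2e21
#' @export
correct_targeting_ratio <- function(p, a_star, t0, m = 1L,
                                    N = NULL, n_star = NULL, log = FALSE) {
  check_fraction(p, "p")
  check_fraction(a_star, "a_star")
  check_count(t0, "t0"); check_count(m, "m")
  if (p < a_star) {
    # pathogen invisible to the adaptive system
    return(if (log) -Inf else 0)
  }
  log_r <- log(p) - log1p(-p) - log_self_targeting(a_star, a_star, t0, m)
  if (!is.null(N) && !is.null(n_star)) {
    log_r <- log_r +
      stats::ppois(n_star - 1, p * N, lower.tail = FALSE, log.p = TRUE) -
      stats::ppois(n_star - 1, (1 - p) * a_star * N, lower.tail = FALSE,
                   log.p = TRUE)
  }
  if (log) log_r else exp(log_r)
}

#' Truncated (order-of-magnitude) form of the correct targeting ratio
#'
#' The leading-order approximation obtained by discarding terms of lower
#' order in `exp(a_star * t0)`:
#' `R ~ p * exp(a_star * t0) / ((1 - p) * a_star * m^2)`. Exact for `m = 1`;
#' exposed for comparison with [correct_targeting_ratio()], which is the
#' default everywhere.
#'
#' @inheritParams correct_targeting_ratio
#' @return The approximate ratio (or its log).
#' @export
truncated_targeting_ratio <- function(p, a_star, t0, m = 1L, log = FALSE) {
  check_fraction(p, "p"); check_fraction(a_star, "a_star")
  check_count(t0, "t0"); check_count(m, "m")
  if (p < a_star) return(if (log) -Inf else 0)
  log_r <- log(p) + a_star * t0 - log1p(-p) - log(a_star) - 2 * log(m)
  if (log) log_r else exp(log_r)
}

#' Lower bound on the correct targeting ratio, exp(K s n*)
#'
#' In the least favorable scenario — pathogen abundance as low as the
#' detection threshold, `p = a_star`, and `a_star` much smaller than one —
#' the ratio reduces to `R ~ exp(a_star * t0) = exp(K * s * n_star)`, using
#' `t0 = K N s` and `a_star = n_star / N`. With `n_star` of 5–10, `K` of a
#' few hundred to several thousand and lymphocytes scanning only 5% of the
#' APC surface, this bound already exceeds 1e20: antigen targeting is
#' extremely reliable.
#'
#' @param K APCs scanned during maturation.
#' @param s fraction of APC surface scanned, in (0, 1].
#' @param n_star activation threshold in complexes.
#' @param log return `log(R)` (i.e. `K * s * n_star`) instead of `R`?
#' @return The bound `exp(K s n_star)` (overflows to `Inf` past ~`exp(709)`;
#'   use `log = TRUE` then).
#' @examples
#' lower_bound_ratio(K = 200, s = 0.05, n_star = 5)  # exp(50) ~ 5.2e21
#' @export
lower_bound_ratio <- function(K, s, n_star, log = FALSE) {
  check_count(K, "K"); check_count(n_star, "n_star")
  check_fraction(s, "s", hi_open = FALSE)
  log_r <- K * s * n_star
  if (log) log_r else exp(log_r)
}

#' Targeting ratio against a self antigen whose abundance has risen
#'
#' Bystander autoimmunity risk: a self antigen with basal abundance
#' `a_basal` (at which tolerance was induced) whose effective abundance has
#' risen to `a_new` during an infection. The ratio of the pathogen-targeting
#' probability to this antigen's targeting probability is
#'
#' \deqn{\frac{p}{(1-p)\,[1 - (1 - a_{new}(1 - f(a_{basal})))^m]}.}
#'
#' If the antigen was rarely presented during maturation (`a_basal` near the
#' riskiest abundance `1/t0`) and now reaches the presentation threshold,
#' the ratio collapses from ~1e20 to order `e` — i.e. roughly one erroneous
#' self response for every three correct pathogen responses.
#'
#' If `a_new` is below the presentation threshold `a_star` the antigen
#' remains invisible and the ratio is reported as `Inf`.
#'
#' @param p pathogen effective abundance, in (0, 1).
#' @param a_basal self abundance at tolerance induction.
#' @param a_new self abundance during the infection.
#' @param t0 presentations during maturation.
#' @param m reactive clones per antigen.
#' @param a_star presentation threshold used for the visibility check;
#'   `NULL` skips the check (the caller asserts `a_new` is detectable).
#' @param log return the log ratio?
#' @return The ratio (or its log); `Inf` when the self antigen is below
#'   threshold (undetectable).
#' @examples
#' # basal at a_max = 1/t0, raised to a_star, pathogen at a_star:
#' raised_self_targeting_ratio(5e-3, a_basal = 1e-4, a_new = 5e-3, t0 = 1e4)
#' @export
raised_self_targeting_ratio <- function(p, a_basal, a_new, t0, m = 1L,
                                        a_star = NULL, log = FALSE) {
  check_fraction(p, "p")
  check_abundance(a_basal, "a_basal"); check_abundance(a_new, "a_new")
  check_count(t0, "t0"); check_count(m, "m")
  if (!is.null(a_star) && a_new < a_star) {
    return(if (log) Inf else Inf)  # self antigen undetectable
  }
  log_r <- log(p) - log1p(-p) - log_self_targeting(a_new, a_basal, t0, m)
  if (log) log_r else exp(log_r)
}

# log of 1 - (1 - a_new (1 - f(a_basal)))^m, stable for a_basal * t0 large
log_self_targeting <- function(a_new, a_basal, t0, m) {
  x <- a_basal * t0
  # log(1 - f) with f = (1 - e^-x)^m; asymptotic once e^-x underflows
  log_not_tol <- if (x > 700) log(m) - x else log(-expm1(m * log1p(-exp(-x))))
  log_anf <- log(a_new) + log_not_tol          # a_new * (1 - f)
  if (log_anf < -30) {
    # 1 - (1 - y)^m ~ m y to double precision
    log(m) + log_anf
  } else {
    log(-expm1(m * log1p(-exp(log_anf))))
  }
}

#' Targeting probability after a k-fold abundance increase
#'
#' If antigen `A_i` (basal abundance `a_i`, at which tolerance `f_i` was
#' induced) is over-expressed by a factor `k` — the elementary model of a
#' tumor-associated antigen — its targeting probability becomes
#'
#' \deqn{\Pr\{A_i(\times k)\} = 0 \quad (k a_i < a^*); \qquad
#'       1 - (1 - k a_i (1 - f_i))^m \quad (k a_i \ge a^*).}
#'
#' For `k = 1` this is the ordinary targeting probability. Sensitivity to
#' fold changes is maximal for antigens with basal abundance near `1/t0`,
#' which become detectable once `k` reaches the minimum detectable
#' increment [minimum_detectable_increment()].
#'
#' @param a_i basal effective abundance(s) (vectorized).
#' @param k fold factor(s), > 0; `k * a_i` must not exceed 1.
#' @param params a [model_params()] with `t0`, `N`, `n_star`, `m`.
#' @param mode presentation mode override (`"step"` default per params).
#' @return Targeting probability/ies after the increase.
#' @export
fold_change_targeting_prob <- function(a_i, k, params, mode = NULL) {
  stopifnot(inherits(params, "model_params"))
  require_param(params, "t0", "N", "n_star", "m")
  check_abundance(a_i)
  if (any(k <= 0)) stop("fold factor k must be positive", call. = FALSE)
  if (any(k * a_i > 1)) {
    stop("k * a_i exceeds 1: not a valid effective abundance", call. = FALSE)
  }
  targeting_probability(k * a_i, params, a_basal = a_i, mode = mode)
}

#' Minimum detectable increment (MDI)
#'
#' The fold increase required for the self antigen the system is most
#' sensitive to (basal abundance `a_max = 1/t0`) to reach the presentation
#' threshold: `MDI = a_star / a_max = a_star * t0`. Via `t0 = K N s` and
#' `a_star = n_star / N` this equals `K * s * n_star` — an identity, so both
#' parameterizations agree whenever both are available (checked). At the
#' conservative mammalian estimates the MDI is of order 100 (50 to 500): a
#' tumor antigen must rise ~100-fold to become detectable.
#'
#' @param params a [model_params()]; needs either (`t0` and `N`, `n_star`)
#'   or (`K`, `s`, `n_star`). Individual arguments override.
#' @param a_star,t0,K,s,n_star explicit values overriding `params`.
#' @return The dimensionless fold factor `MDI`.
#' @examples
#' minimum_detectable_increment(K = 200, s = 0.05, n_star = 5)   # 50
#' minimum_detectable_increment(K = 1000, s = 0.05, n_star = 10) # 500
#' @export
minimum_detectable_increment <- function(params = NULL, a_star = NULL,
                                         t0 = NULL, K = NULL, s = NULL,
                                         n_star = NULL) {
  if (!is.null(params)) {
    stopifnot(inherits(params, "model_params"))
    if (is.null(t0)) t0 <- params$t0
    if (is.null(K)) K <- params$K
    if (is.null(s)) s <- params$s
    if (is.null(n_star)) n_star <- params$n_star
    if (is.null(a_star) && !is.null(params$N) && !is.null(n_star)) {
      a_star <- n_star / params$N
    }
  }
  via_t0 <- if (!is.null(a_star) && !is.null(t0)) a_star * t0 else NULL
  via_k <- if (!is.null(K) && !is.null(s) && !is.null(n_star)) {
    K * s * n_star
  } else NULL
  if (is.null(via_t0) && is.null(via_k)) {
    stop("insufficient parameters: need (a_star, t0) or (K, s, n_star)",
         call. = FALSE)
  }
  if (!is.null(via_t0) && !is.null(via_k) &&
      abs(via_t0 - via_k) > 1e-8 * max(via_t0, via_k)) {
    stop("inconsistent parameters: a_star * t0 = ", via_t0,
         " but K * s * n_star = ", via_k, call. = FALSE)
  }
  if (!is.null(via_t0)) via_t0 else via_k
}

#' Discrimination ability of self-change detection
#'
#' When a self antigen is detected, was its abundance genuinely raised, or
#' was the detection chance presentation of an unchanged antigen? The
#' discrimination ability compares the probability of targeting the
#' most-sensitive antigen (basal `1/t0`) after an MDI-fold rise against the
#' probability of targeting an unchanged antigen at the threshold `a_star`:
#'
#' \deqn{\Delta = \frac{\Pr\{a^{max}(\times MDI)\} - \Pr\{a^*\}}
#'                     {\Pr\{a^{max}(\times MDI)\} + \Pr\{a^*\}}.}
#'
#' For `m = 1` this is exactly
#' `(exp(MDI - 1) - 1) / (exp(MDI - 1) + 1) = tanh((MDI - 1) / 2)`,
#' independent of every other model parameter. For `m > 1` it is computed
#' through the odds
#' `delta = (1 - (1 - e^-1)^m) / (1 - (1 - e^-MDI)^m)` as
#' `Delta = (delta - 1)/(delta + 1)` (terms of order `a_star^2` discarded).
#' `Delta` runs from 0 (detection uninformative) towards 1 (detection
#' certain to reflect a true change), and is already ~1 for MDI just over
#' 10: strong discrimination only requires responding to large changes.
#'
#' `method = "first_principles"` evaluates the defining probability quotient
#' directly from [fold_change_targeting_prob()] and [targeting_probability()]
#' at a concrete `a_star` (and `t0 = MDI / a_star`), as an independent
#' construction of the same quantity.
#'
#' @param MDI minimum detectable increment, >= 1.
#' @param m reactive clones per antigen.
#' @param method `"closed_form"` (default) or `"first_principles"`.
#' @param a_star threshold used by the first-principles construction.
#' @return Discrimination ability in \[0, 1).
#' @examples
#' discrimination_ability(1)   # 0
#' discrimination_ability(10)  # ~0.99975
#' @export
discrimination_ability <- function(MDI, m = 1L,
                                   method = c("closed_form",
                                              "first_principles"),
                                   a_star = 1e-3) {
  method <- match.arg(method)
  if (!is.numeric(MDI) || anyNA(MDI) || any(MDI < 1)) {
    stop("MDI must be >= 1 (an increment below 1 is not an increment)",
         call. = FALSE)
  }
  check_count(m, "m")
  if (method == "closed_form") {
    if (m == 1L) {
      tanh((MDI - 1) / 2)
    } else {
      num <- -expm1(m * log1p(-exp(-1)))
      den <- -expm1(m * log1p(-(-expm1(-MDI))))
      delta <- num / den
      (delta - 1) / (delta + 1)
    }
  } else {
    vapply(MDI, function(mdi) {
      t0 <- max(1L, round(mdi / a_star))
      astar_eff <- mdi / t0  # keep a_star * t0 = MDI exactly after rounding
      a_max <- 1 / t0
      # both antigens sit at/above the threshold by construction, so the
      # step factor is 1 and the defining quotient uses the second branches
      # of the fold-change and baseline targeting probabilities
      p_changed <- targeting_probability_central(astar_eff, t0, m,
                                                 a_basal = a_max)
      p_chance <- targeting_probability_central(astar_eff, t0, m,
                                                a_basal = astar_eff)
      if (p_changed + p_chance == 0) return(0)
      (p_changed - p_chance) / (p_changed + p_chance)
    }, numeric(1))
  }
}

#' One minus the discrimination ability, computed without cancellation
#'
#' `1 - Delta` is of order `1e-21` at MDI = 50; the direct difference would
#' lose it to rounding. For `m = 1`, `1 - Delta = 2 / (exp(MDI - 1) + 1)`.
#'
#' @inheritParams discrimination_ability
#' @return `1 - Delta`, accurate for large MDI.
#' @export
discrimination_gap <- function(MDI, m = 1L) {
  if (!is.numeric(MDI) || anyNA(MDI) || any(MDI < 1)) {
    stop("MDI must be >= 1", call. = FALSE)
  }
  check_count(m, "m")
  if (m == 1L) {
    2 / (exp(MDI - 1) + 1)
  } else {
    num <- -expm1(m * log1p(-exp(-1)))
    den <- -expm1(m * log1p(-(-expm1(-MDI))))
    delta <- num / den
    2 / (delta + 1)
  }
}

#' Classify the operating region of the MDI–discrimination trade-off
#'
#' Region 1: the system responds to small abundance changes but with poor
#' discrimination — elevated autoimmunity risk. Region 2: moderate changes,
#' high discrimination — optimal for detecting tumors. Region 3: only large
#' increases become detectable; vertebrate immune systems appear to operate
#' here. The boundaries are conventional (the region-2/3 border especially
#' so) and default to (3, 20), placing "just over 10-fold" in region 2 and
#' MDI ~ 100 in region 3.
#'
#' @param MDI minimum detectable increment(s) (vectorized).
#' @param boundaries increasing pair `(b1, b2)`; region 1 is `MDI < b1`,
#'   region 2 is `b1 <= MDI < b2`, region 3 the rest.
#' @return Integer region label(s) in \{1, 2, 3\}.
#' @export
classify_region <- function(MDI, boundaries = c(3, 20)) {
  if (length(boundaries) != 2L || !is.numeric(boundaries) ||
      boundaries[1] >= boundaries[2]) {
    stop("boundaries must be an increasing pair (b1, b2)", call. = FALSE)
  }
  if (!is.numeric(MDI) || anyNA(MDI) || any(MDI < 0)) {
    stop("MDI must be non-negative", call. = FALSE)
  }
  ifelse(MDI < boundaries[1], 1L, ifelse(MDI < boundaries[2], 2L, 3L))
}

#' Smallest integer fold increase that makes an antigen detectable
#'
#' Scans fold factors `k = 1, 2, ...` for the first at which
#' [fold_change_targeting_prob()] becomes positive, i.e. at which
#' `k * a_i` crosses the presentation threshold.
#'
#' @param a_i basal effective abundance.
#' @param params a [model_params()] with `t0`, `N`, `n_star`, `m`.
#' @param k_max scan limit.
#' @return The smallest detecting integer `k`, or `NA` if none `<= k_max`.
#' @export
minimum_detecting_fold <- function(a_i, params, k_max = 1000L) {
  for (k in seq_len(k_max)) {
    if (k * a_i > 1) return(NA_integer_)
    if (fold_change_targeting_prob(a_i, k, params, mode = "step") > 0) {
      return(k)
    }
  }
  NA_integer_
}
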