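#' Simulate repertoire maturation (negative selection)
#'
#' Maturation is modeled as `t0` antigen presentations per clone, each slot
#' showing antigen `A_i` with probability equal to its *basal* effective
#' abundance. A self-reactive clone is deleted the moment it sees its
#' cognate antigen, so it survives negative selection iff its antigen's
#' presentation count is zero. Every self antigen starts with `m` naive
#' reactive clones; pathogen-category antigens were absent during maturation
#' (basal abundance zero), so their clones always survive — the naive
#' repertoire can recognize virtually everything.
#'
#' Counts are drawn per clone as exact binomial marginals of the
#' presentation multinomial; the Poisson form used by the closed forms is an
#' approximation this simulator can validate.
#'
#' @param env an [antigen_environment()]; basal abundances are used.
#' @param params a [model_params()] with `t0` and `m`.
#' @param n_reps number of independent maturations to simulate.
#' @return An integer matrix of class `"repertoire"`, `n_reps` rows by one
#'   column per antigen: surviving reactive clones, in `[0, m]`.
#' @examples
#' env <- antigen_environment(c(1e-3, 1 - 1e-3))
#' params <- model_params(t0 = 1000)
#' set.seed(1)
#' rep1 <- simulate_maturation(env, params)
#' @export
simulate_maturation <- function(env, params, n_reps = 1L) {
  stopifnot(inherits(env, "antigen_environment"))
  require_param(params, "t0", "m")
  n_reps <- as.integer(n_reps)
  stopifnot(n_reps >= 1L)
  m <- params$m
  n_ag <- length(env$ids)
  surv <- matrix(0L, nrow = n_reps, ncol = n_ag,
                 dimnames = list(NULL, env$ids))
  for (i in seq_len(n_ag)) {
    a <- env$basal_abundances[i]
    if (a == 0) {
      surv[, i] <- m  # never presented during maturation
    } else {
      counts <- stats::rbinom(n_reps * m, size = params$t0, prob = a)
      surv[, i] <- as.integer(rowSums(matrix(counts == 0L, n_reps, m)))
    }
  }
  structure(surv, class = c("repertoire", "matrix", "array"), m = m)
}

#' @export
print.repertoire <- function(x, ...) {
  cat("Surviving self-reactive clones (", nrow(x), " maturation(s), m = ",
      attr(x, "m"), "):\n", sep = "")
  print(utils::head(unclass(x), 5L))
  if (nrow(x) > 5L) cat("... and", nrow(x) - 5L, "more rows\n")
  invisible(x)
}

#' Sample the MHC-peptide complexes of one or more APCs
#'
#' One antigen-presenting cell carries `N` MHC-peptide complexes; each is
#' occupied independently by antigen `A_i` with probability equal to its
#' current effective abundance, so per-APC slot counts are multinomial and
#' sum exactly to `N`.
#'
#' @param env an [antigen_environment()]; current abundances are used.
#' @param N complexes per APC surface.
#' @param n_draws number of APCs to sample.
#' @return Integer matrix, one row per antigen (named), one column per APC.
#' @export
sample_apc <- function(env, N, n_draws = 1L) {
  stopifnot(inherits(env, "antigen_environment"))
  check_count(N, "N")
  prob <- env$abundances / sum(env$abundances)
  out <- stats::rmultinom(n_draws, size = N, prob = prob)
  rownames(out) <- env$ids
  out
}

#' Simulate adaptive response decisions (danger context assumed)
#'
#' Each replicate models one activation opportunity of the adaptive system,
#' given that the innate system has already detected danger:
#'
#' 1. a candidate antigen is engaged with probability equal to its current
#'    effective abundance (one random presentation slot);
#' 2. the candidate must be *efficiently presented*: in `"exact"` mode its
#'    slot count on a freshly sampled APC must reach `n_star`; in `"step"`
#'    mode its abundance must reach the threshold `a_star = n_star / N`;
#' 3. a surviving reactive clone must exist for the candidate.
#'
#' If any condition fails the replicate produces no response. Exactly one
#' antigen (or none) is targeted per replicate, and the per-antigen marginal
#' probabilities reproduce the analytic targeting probabilities (for `m = 1`
#' exactly; for `m > 1` the closed forms compose clone multiplicity
#' analytically and agree to first order in the abundances).
#'
#' @param env an [antigen_environment()] with current (possibly
#'   pathogen-bearing or over-expressed, renormalized) abundances.
#' @param repertoire a `"repertoire"` from [simulate_maturation()]; either a
#'   single row (recycled across replicates) or one row per replicate.
#' @param params a [model_params()] with `N`, `n_star`, `m` and
#'   `presentation_mode`.
#' @param n_reps number of independent response decisions.
#' @param mode presentation mode override.
#' @return Integer vector of length `n_reps`: index of the targeted antigen
#'   in `env$ids`, or `NA` for no response; antigen ids as an attribute.
#' @export
simulate_response <- function(env, repertoire, params, n_reps = 1L,
                              mode = NULL) {
  stopifnot(inherits(env, "antigen_environment"))
  require_param(params, "N", "n_star")
  if (is.null(mode)) mode <- params$presentation_mode
  n_reps <- as.integer(n_reps)
  rep_mat <- unclass(repertoire)
  if (is.null(dim(rep_mat))) rep_mat <- matrix(rep_mat, nrow = 1L)
  if (!nrow(rep_mat) %in% c(1L, n_reps)) {
    stop("repertoire must have one row, or one row per replicate",
         call. = FALSE)
  }
  n_ag <- length(env$ids)
  prob <- env$abundances / sum(env$abundances)
  cand <- sample.int(n_ag, n_reps, replace = TRUE, prob = prob)
  if (mode == "step") {
    eligible <- prob[cand] >= params$n_star / params$N
  } else {
    slots <- stats::rmultinom(n_reps, size = params$N, prob = prob)
    eligible <- slots[cbind(cand, seq_len(n_reps))] >= params$n_star
  }
  rep_rows <- if (nrow(rep_mat) == 1L) rep(1L, n_reps) else seq_len(n_reps)
  has_clone <- rep_mat[cbind(rep_rows, cand)] > 0L
  out <- ifelse(eligible & has_clone, cand, NA_integer_)
  attr(out, "antigen_ids") <- env$ids
  out
}

#' Run a named immune scenario end to end
#'
#' Composes maturation (on the basal environment), an environmental change,
#' and repeated response decisions, with all randomness derived from one
#' master seed. Scenarios:
#'
#' * `"healthy"` — no change; responses, if any, are natural autoimmunity.
#' * `"infection"` — a pathogen of abundance `p >= a_star` is added; self
#'   abundances rescale by `1 - p`.
#' * `"pathogen_below_threshold"` — as infection but `p < a_star`: the
#'   innate system is danger-activated yet the pathogen is invisible to the
#'   adaptive system, so any response is a bystander hit on self.
#' * `"tumor"` — one self antigen is over-expressed `k`-fold (renormalized
#'   before sampling); tolerance remains that of the basal abundances.
#'
#' @param scenario a list with `name` (one of the above) and its knobs:
#'   `p` and optionally `n_pathogen_ags` for the infection scenarios,
#'   `target` (antigen id) and `k` for the tumor scenario.
#' @param env the basal [antigen_environment()].
#' @param params a [model_params()] with `t0`, `N`, `n_star`, `m`.
#' @param n_reps replicates (one maturation + one response decision each).
#' @param seed master RNG seed; `NULL` continues the current RNG stream.
#' @param mode presentation mode override.
#' @return An object of class `"scenario_result"`: per-antigen targeting
#'   frequencies with binomial standard errors, tolerance fractions,
#'   no-response frequency, replicate count and seed.
#' @examples
#' env <- antigen_environment(c(5e-3, 1 - 5e-3))
#' params <- model_params(t0 = 500, N = 1000, n_star = 4)
#' run_scenario(list(name = "infection", p = 0.05), env, params,
#'              n_reps = 1000, seed = 42)
#' @export
run_scenario <- function(scenario, env, params, n_reps = 10000L,
                         seed = NULL, mode = NULL) {
  stopifnot(is.list(scenario), !is.null(scenario$name))
  stopifnot(inherits(env, "antigen_environment"))
  require_param(params, "t0", "N", "n_star", "m")
  name <- match.arg(scenario$name,
                    c("healthy", "infection", "pathogen_below_threshold",
                      "tumor"))
  if (!is.null(seed)) set.seed(seed)
  astar <- a_star(params)
  changed <- switch(
    name,
    healthy = env,
    infection = {
      p <- scenario$p
      check_fraction(p, "p")
      if (p < astar) {
        stop("infection scenario requires p >= a_star; use ",
             "'pathogen_below_threshold' for sub-threshold pathogens",
             call. = FALSE)
      }
      add_pathogen(env, p, n_pathogen_ags = scenario$n_pathogen_ags %||% 1L)
    },
    pathogen_below_threshold = {
      p <- scenario$p
      check_fraction(p, "p")
      if (p >= astar) {
        stop("'pathogen_below_threshold' requires p < a_star", call. = FALSE)
      }
      add_pathogen(env, p, n_pathogen_ags = scenario$n_pathogen_ags %||% 1L)
    },
    tumor = {
      if (is.null(scenario$target) || is.null(scenario$k)) {
        stop("tumor scenario needs 'target' antigen id and fold factor 'k'",
             call. = FALSE)
      }
      overexpress(env, scenario$target, scenario$k, renormalize = TRUE)
    }
  )
  # maturation always precedes the abundance change: tolerance is basal
  repertoire <- simulate_maturation(changed, params, n_reps = n_reps)
  hits <- simulate_response(changed, repertoire, params, n_reps = n_reps,
                            mode = mode)
  n_ag <- length(changed$ids)
  counts <- tabulate(hits, nbins = n_ag)
  freq <- counts / n_reps
  se <- sqrt(freq * (1 - freq) / n_reps)
  is_self <- changed$categories == "self"
  tol_frac <- colMeans(unclass(repertoire) == 0L)
  tol_frac[!is_self] <- 0
  structure(
    list(scenario = name,
         n_reps = n_reps,
         seed = seed,
         table = data.frame(
           antigen_id = changed$ids,
           category = changed$categories,
           abundance = changed$abundances,
           basal_abundance = changed$basal_abundances,
           targeting_freq = freq,
           targeting_se = se,
           tolerance_fraction = as.numeric(tol_frac),
           stringsAsFactors = FALSE),
         no_response_freq = 1 - sum(freq),
         environment = changed,
         params = params),
    class = "scenario_result"
  )
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("Scenario '%s': %d replicates%s\n", x$scenario, x$n_reps,
              if (!is.null(x$seed)) sprintf(" (seed %d)", x$seed) else ""))
  print(utils::head(x$table, 12L), row.names = FALSE, digits = 4)
  if (nrow(x$table) > 12L) cat("... and", nrow(x$table) - 12L, "more rows\n")
  cat(sprintf("no response: %.4f of replicates\n", x$no_response_freq))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
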