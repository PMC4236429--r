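#' Construct a normalized antigenic environment
#'
#' An antigenic environment is the set of antigens visible to the immune
#' system, each carrying an *effective abundance*: the normalized product of
#' concentration, accessibility to antigen-presenting cells and MHC-peptide
#' affinity. Effective abundances behave like molar fractions: they are
#' non-negative and sum to one, and `a_i` is the probability that a randomly
#' chosen presentation slot displays antigen `i`.
#'
#' Each antigen carries a category, `"self"` or `"pathogen"`, and a *basal*
#' abundance: the abundance it had when central tolerance was induced. At
#' construction basal equals current; transformations such as [add_pathogen()]
#' and [overexpress()] update the current abundances while preserving the
#' basal ones, because tolerance computations must always refer to the
#' environment as it was during repertoire maturation.
#'
#' @param abundances numeric vector of non-negative raw abundances; they are
#'   normalized to sum to one. Must contain at least one positive entry.
#' @param ids optional character vector of antigen identifiers; defaults to
#'   `"A1"`, `"A2"`, ... Must be unique.
#' @param categories per-antigen category, `"self"` or `"pathogen"`; recycled
#'   if length one. Defaults to all-self.
#' @param basal_abundances optional vector of abundances at tolerance
#'   induction, normalized likewise; defaults to the (normalized) current
#'   abundances.
#'
#' @return An object of class `"antigen_environment"`: a list with elements
#'   `ids`, `abundances`, `categories`, `basal_abundances`.
#'
#' @examples
#' env <- antigen_environment(c(2, 8))
#' env$abundances  # 0.2 0.8
#' @export
antigen_environment <- function(abundances, ids = NULL, categories = "self",
                                basal_abundances = NULL) {
  if (length(abundances) == 0L) {
    stop("environment must contain at least one antigen", call. = FALSE)
  }
  abundances <- as.numeric(abundances)
  if (anyNA(abundances)) stop("abundances contain NA", call. = FALSE)
  if (any(abundances < 0)) {
    stop("effective abundances must be non-negative", call. = FALSE)
  }
  total <- sum(abundances)
  if (total <= 0) {
    stop("all abundances are zero; cannot normalize", call. = FALSE)
  }
  n <- length(abundances)
  if (is.null(ids)) ids <- paste0("A", seq_len(n))
  ids <- as.character(ids)
  if (length(ids) != n) stop("ids and abundances differ in length", call. = FALSE)
  if (anyDuplicated(ids)) stop("antigen ids must be unique", call. = FALSE)
  if (length(categories) == 1L) categories <- rep(categories, n)
  categories <- match.arg(as.character(categories), c("self", "pathogen"),
                          several.ok = TRUE)
  if (length(categories) != n) {
    stop("categories and abundances differ in length", call. = FALSE)
  }
  abundances <- abundances / total
  if (is.null(basal_abundances)) {
    basal_abundances <- abundances
  } else {
    basal_abundances <- as.numeric(basal_abundances)
    if (length(basal_abundances) != n || any(basal_abundances < 0) ||
        sum(basal_abundances) <= 0) {
      stop("invalid basal_abundances", call. = FALSE)
    }
    basal_abundances <- basal_abundances / sum(basal_abundances)
  }
  structure(
    list(ids = ids, abundances = abundances, categories = categories,
         basal_abundances = basal_abundances),
    class = "antigen_environment"
  )
}

#' @export
print.antigen_environment <- function(x, ...) {
  n <- length(x$ids)
  cat("Antigenic environment:", n, "antigen(s),",
      sum(x$categories == "pathogen"), "pathogen-derived\n")
  df <- as.data.frame(x)
  print(utils::head(df, 10L), row.names = FALSE)
  if (n > 10L) cat("... and", n - 10L, "more\n")
  invisible(x)
}

#' @export
as.data.frame.antigen_environment <- function(x, ...) {
  data.frame(antigen_id = x$ids, abundance = x$abundances,
             category = x$categories, basal_abundance = x$basal_abundances,
             stringsAsFactors = FALSE)
}

#' @export
length.antigen_environment <- function(x) length(x$ids)

# internal validator used by property tests and I/O
validate_environment <- function(env, tol = 1e-12) {
  stopifnot(inherits(env, "antigen_environment"))
  with(env, {
    stopifnot(
      all(abundances >= 0),
      abs(sum(abundances) - 1) <= tol,
      abs(sum(basal_abundances) - 1) <= tol,
      length(ids) == length(abundances),
      all(categories %in% c("self", "pathogen"))
    )
  })
  invisible(env)
}

#' Introduce a pathogen into an antigenic environment
#'
#' A pathogen adds its own antigens with total effective abundance `p`;
#' because abundances are normalized, every pre-existing self abundance is
#' rescaled to `(1 - p) * a_i`. Basal abundances are left untouched: central
#' tolerance was induced before the infection.
#'
#' When the pathogen contributes more than one antigen, `p` is interpreted as
#' the pathogen's total effective abundance, split equally among its antigens.
#'
#' @param env an [antigen_environment()].
#' @param p pathogen effective abundance, strictly inside (0, 1).
#' @param n_pathogen_ags number of pathogen-derived antigens (default 1).
#' @param ids optional identifiers for the new antigens.
#' @return A new `antigen_environment` containing the pathogen antigens.
#' @examples
#' env <- antigen_environment(c(0.5, 0.5))
#' add_pathogen(env, p = 0.2)$abundances  # 0.4 0.4 0.2
#' @export
add_pathogen <- function(env, p, n_pathogen_ags = 1L, ids = NULL) {
  stopifnot(inherits(env, "antigen_environment"))
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p >= 1) {
    stop("pathogen abundance p must lie strictly in (0, 1)", call. = FALSE)
  }
  n_pathogen_ags <- as.integer(n_pathogen_ags)
  if (n_pathogen_ags < 1L) stop("need at least one pathogen antigen", call. = FALSE)
  if (is.null(ids)) ids <- paste0("P", seq_len(n_pathogen_ags))
  if (any(ids %in% env$ids)) stop("pathogen ids clash with existing ids", call. = FALSE)
  new_ab <- c(env$abundances * (1 - p), rep(p / n_pathogen_ags, n_pathogen_ags))
  # pathogen antigens were absent during maturation: basal abundance zero,
  # kept on the original normalized scale
  new_basal <- c(env$basal_abundances, rep(0, n_pathogen_ags))
  structure(
    list(ids = c(env$ids, as.character(ids)),
         abundances = new_ab,
         categories = c(env$categories, rep("pathogen", n_pathogen_ags)),
         basal_abundances = new_basal),
    class = "antigen_environment"
  )
}

#' Over-express one antigen by a fold factor
#'
#' Multiplies the current effective abundance of one antigen by `k`, the
#' elementary model of a tumor-associated antigen whose expression rises
#' during tumor progression. Basal abundances are preserved, so tolerance
#' remains that of the pre-change environment.
#'
#' With `renormalize = FALSE` (the analytic convention) the other abundances
#' are left unchanged and the vector no longer sums to one; closed forms for
#' fold-change detection use the raw `k * a_i`. With `renormalize = TRUE` the
#' whole vector is rescaled to sum to one, which a sampler requires. The two
#' conventions differ by a relative factor `1 + (k - 1) a_i`, negligible when
#' `k * a_i` is small.
#'
#' @param env an [antigen_environment()].
#' @param antigen_id identifier of the antigen to over-express.
#' @param k fold factor, > 0.
#' @param renormalize rescale abundances to sum to one afterwards?
#' @return A new `antigen_environment`.
#' @export
overexpress <- function(env, antigen_id, k, renormalize = FALSE) {
  stopifnot(inherits(env, "antigen_environment"))
  if (!is.numeric(k) || length(k) != 1L || k <= 0) {
    stop("fold factor k must be a positive number", call. = FALSE)
  }
  idx <- match(antigen_id, env$ids)
  if (is.na(idx)) {
    stop("unknown antigen id: ", antigen_id, call. = FALSE)
  }
  ab <- env$abundances
  ab[idx] <- ab[idx] * k
  if (renormalize) ab <- ab / sum(ab)
  structure(
    list(ids = env$ids, abundances = ab, categories = env$categories,
         basal_abundances = env$basal_abundances),
    class = "antigen_environment"
  )
}

#' Renormalize an environment's current abundances to sum to one
#'
#' @param env an [antigen_environment()].
#' @return The environment with abundances rescaled.
#' @export
renormalize <- function(env) {
  stopifnot(inherits(env, "antigen_environment"))
  env$abundances <- env$abundances / sum(env$abundances)
  env
}

#' Drop antigens from an environment
#'
#' Removes the named antigens and optionally renormalizes what remains;
#' used e.g. to model pathogen clearance.
#'
#' @param env an [antigen_environment()].
#' @param antigen_ids identifiers to remove.
#' @param renormalize rescale remaining abundances to sum to one?
#' @return A new `antigen_environment`.
#' @export
drop_antigens <- function(env, antigen_ids, renormalize = TRUE) {
  stopifnot(inherits(env, "antigen_environment"))
  keep <- !(env$ids %in% antigen_ids)
  if (!any(keep)) stop("cannot drop every antigen", call. = FALSE)
  ab <- env$abundances[keep]
  basal <- env$basal_abundances[keep]
  if (renormalize) {
    ab <- ab / sum(ab)
    if (sum(basal) > 0) basal <- basal / sum(basal)
  }
  structure(
    list(ids = env$ids[keep], abundances = ab,
         categories = env$categories[keep], basal_abundances = basal),
    class = "antigen_environment"
  )
}
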