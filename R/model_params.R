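#' Model parameters for probabilistic immune communication
#'
#' Bundles the scalar parameters of the model:
#'
#' * `t0` — number of antigen presentations a maturing lymphocyte witnesses
#'   during negative selection. When the lymphocyte scans `K` antigen-
#'   presenting cells and a fraction `s` of each cell's `N` MHC-peptide
#'   complexes, `t0 = K * N * s`.
#' * `N` — number of MHC-peptide complexes on one APC surface.
#' * `n_star` — minimum number of MHC-peptide-TCR complexes on a single APC
#'   required to activate a lymphocyte; induces the efficient-presentation
#'   threshold `a_star = n_star / N` (the model's peripheral tolerance).
#' * `K` — number of APCs scanned during maturation.
#' * `s` — fraction of an APC surface scanned, in (0, 1].
#' * `m` — number of naive self-reactive lymphocyte clones per self antigen.
#' * `presentation_mode` — `"step"` approximates efficient presentation by a
#'   Heaviside step at `a_star`; `"exact"` uses the Poisson survival
#'   probability of at least `n_star` complexes.
#' * `count_model` — distribution of per-antigen presentation counts during
#'   maturation: exact `"binomial"` or its large-`t0` `"poisson"`
#'   approximation.
#'
#' Any of `t0`, `N`, `n_star`, `K`, `s` may be omitted where a computation
#' does not need it. With `enforce_consistency = TRUE` the identity
#' `t0 = K * N * s` is required (within rounding) when all four are supplied;
#' by default it is not enforced, and [minimum_detectable_increment()] etc.
#' check agreement themselves when both parameterizations are available.
#'
#' @param t0 presentations during maturation (positive count), or `NULL`
#'   to derive from `K * N * s` when those are given.
#' @param N MHC-peptide complexes per APC (positive count).
#' @param n_star activation threshold in complexes (1 <= n_star <= N).
#' @param K APCs scanned during maturation (positive count).
#' @param s fraction of APC surface scanned, in (0, 1].
#' @param m self-reactive clones per antigen (positive count, default 1).
#' @param presentation_mode `"step"` or `"exact"`.
#' @param count_model `"binomial"` or `"poisson"`.
#' @param enforce_consistency require `t0 == K * N * s` when determinable?
#' @return An object of class `"model_params"`.
#' @examples
#' params <- model_params(N = 1000, n_star = 5, K = 200, s = 0.05)
#' params$t0      # 10000 = K N s
#' a_star(params) # 0.005
#' @export
model_params <- function(t0 = NULL, N = NULL, n_star = NULL, K = NULL,
                         s = NULL, m = 1L,
                         presentation_mode = c("step", "exact"),
                         count_model = c("binomial", "poisson"),
                         enforce_consistency = FALSE) {
  presentation_mode <- match.arg(presentation_mode)
  count_model <- match.arg(count_model)
  chk_count <- function(x, name) {
    if (!is.null(x)) {
      if (!is.numeric(x) || length(x) != 1L || x < 1 || x != round(x)) {
        stop(name, " must be a positive integer", call. = FALSE)
      }
    }
    x
  }
  N <- chk_count(N, "N"); n_star <- chk_count(n_star, "n_star")
  K <- chk_count(K, "K"); m <- chk_count(m, "m")
  if (!is.null(s) && (!is.numeric(s) || length(s) != 1L || s <= 0 || s > 1)) {
    stop("s must lie in (0, 1]", call. = FALSE)
  }
  if (!is.null(n_star) && !is.null(N) && n_star > N) {
    stop("n_star cannot exceed N", call. = FALSE)
  }
  derived_t0 <- if (!is.null(K) && !is.null(N) && !is.null(s)) K * N * s else NULL
  if (is.null(t0)) {
    t0 <- derived_t0
    if (!is.null(t0)) t0 <- round(t0)
  } else {
    t0 <- chk_count(t0, "t0")
    if (enforce_consistency && !is.null(derived_t0) &&
        abs(t0 - derived_t0) > 0.5) {
      stop("t0 inconsistent with K * N * s (", derived_t0, ")", call. = FALSE)
    }
  }
  structure(
    list(t0 = t0, N = N, n_star = n_star, K = K, s = s, m = m,
         presentation_mode = presentation_mode, count_model = count_model),
    class = "model_params"
  )
}

#' @export
print.model_params <- function(x, ...) {
  cat("Model parameters:\n")
  for (nm in c("t0", "N", "n_star", "K", "s", "m")) {
    if (!is.null(x[[nm]])) cat(sprintf("  %-7s %g\n", nm, x[[nm]]))
  }
  if (!is.null(x$N) && !is.null(x$n_star)) {
    cat(sprintf("  a_star  %g (= n_star/N, efficient-presentation threshold)\n",
                x$n_star / x$N))
  }
  if (!is.null(x$t0) && !is.null(x$m)) {
    cat(sprintf("  a_max   %g (= 1/(t0 m), riskiest self abundance)\n",
                1 / (x$t0 * x$m)))
  }
  cat("  presentation:", x$presentation_mode, "| counts:", x$count_model, "\n")
  invisible(x)
}

#' Efficient-presentation threshold a* = n*/N
#'
#' The effective abundance above which an antigen is likely to occupy at
#' least `n_star` of the `N` MHC-peptide complexes on one APC, and hence to
#' activate a lymphocyte.
#'
#' @param params a [model_params()] with `N` and `n_star`, or `NULL` if the
#'   explicit arguments are given.
#' @param N,n_star explicit values overriding `params`.
#' @return The threshold abundance `n_star / N`.
#' @export
a_star <- function(params = NULL, N = params$N, n_star = params$n_star) {
  if (is.null(N) || is.null(n_star)) {
    stop("need both N and n_star for the presentation threshold", call. = FALSE)
  }
  if (n_star > N) stop("n_star cannot exceed N", call. = FALSE)
  n_star / N
}

#' @rdname a_star
#' @export
presentation_threshold <- function(N, n_star) a_star(N = N, n_star = n_star)

require_param <- function(params, ...) {
  nms <- c(...)
  missing <- nms[vapply(nms, function(nm) is.null(params[[nm]]), logical(1))]
  if (length(missing)) {
    stop("model_params missing required field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(params)
}
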