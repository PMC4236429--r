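#' Generate a synthetic antigenic environment
#'
#' Real antigenic microenvironments contain effective abundances spanning
#' several orders of magnitude. This generator draws raw abundances either
#' log-uniformly over a decade range (every decade equally populated) or
#' log-normally (centered on the range midpoint, sd a quarter of the range),
#' then normalizes them to sum to one.
#'
#' @param n_antigens number of self antigens, >= 1.
#' @param log10_range increasing pair of decade exponents for the raw draw;
#'   default `c(-6, -2)`.
#' @param distribution `"log-uniform"` or `"log-normal"`.
#' @return An [antigen_environment()] of self antigens. Deterministic under
#'   `set.seed()`. Note normalization shifts the realized decades when the
#'   raw draws do not sum to one.
#' @examples
#' set.seed(7)
#' env <- generate_environment(100)
#' @export
generate_environment <- function(n_antigens, log10_range = c(-6, -2),
                                 distribution = c("log-uniform",
                                                  "log-normal")) {
  distribution <- match.arg(distribution)
  check_count(n_antigens, "n_antigens")
  if (length(log10_range) != 2L || !is.numeric(log10_range) ||
      log10_range[1] >= log10_range[2]) {
    stop("log10_range must be an increasing pair of exponents", call. = FALSE)
  }
  if (n_antigens == 1L) return(antigen_environment(1))
  lg <- switch(distribution,
    "log-uniform" = stats::runif(n_antigens, log10_range[1], log10_range[2]),
    "log-normal" = stats::rnorm(n_antigens,
                                mean = mean(log10_range),
                                sd = diff(log10_range) / 4))
  antigen_environment(10^lg)
}

#' Tabulate the tolerance, presentation and targeting curves
#'
#' Emits the data behind the model's three summary pictures:
#'
#' * `"fig2"` — over a log grid of effective abundances: the remaining
#'   self-reactivity `1 - f`, the exact efficient-presentation probability,
#'   and the targeting probability with and without peripheral tolerance.
#'   The no-peripheral curve peaks at `a = 1/t0`.
#' * `"fig3"` — the baseline targeting curve (step and no-peripheral
#'   variants) plus user-supplied over-expression points `(a_basal, k)` with
#'   their fold-change targeting probabilities and detectability flags.
#' * `"fig4"` — discrimination ability and operating region over an MDI
#'   grid.
#'
#' @param which `"fig2"`, `"fig3"` or `"fig4"`.
#' @param params a [model_params()]; fig2/fig3 need `t0`, `N`, `n_star`,
#'   `m`; fig4 needs nothing beyond `m`.
#' @param log10_range abundance decade range of the fig2/fig3 grid.
#' @param n_grid points on the curve grid.
#' @param points for fig3: data.frame or list with columns/elements
#'   `a_basal` and `k`.
#' @param mdi_grid for fig4: MDI values; default 200 log-spaced in
#'   \[1, 1000\].
#' @param region_boundaries for fig4: passed to [classify_region()].
#' @return A data.frame; for fig3 a list of `curve` and `points` tables.
#' @export
figure_data <- function(which = c("fig2", "fig3", "fig4"), params = NULL,
                        log10_range = c(-6, -1), n_grid = 200L,
                        points = NULL, mdi_grid = NULL,
                        region_boundaries = c(3, 20)) {
  which <- match.arg(which)
  if (which == "fig4") {
    m <- if (is.null(params)) 1L else params$m %||% 1L
    if (is.null(mdi_grid)) {
      mdi_grid <- 10^seq(0, 3, length.out = n_grid)
    }
    return(data.frame(
      MDI = mdi_grid,
      delta = discrimination_ability(mdi_grid, m = m),
      region = classify_region(mdi_grid, region_boundaries)))
  }
  if (is.null(params)) stop("fig2/fig3 need model params", call. = FALSE)
  require_param(params, "t0", "N", "n_star", "m")
  a <- 10^seq(log10_range[1], log10_range[2], length.out = n_grid)
  a <- a[a <= 1]
  if (which == "fig2") {
    return(data.frame(
      abundance = a,
      untolerated = 1 - tolerance_probability(a, params$t0, params$m),
      efficient_presentation =
        efficient_presentation_prob(a, params$N, params$n_star, "exact"),
      targeting_no_peripheral =
        targeting_probability_central(a, params$t0, params$m),
      targeting = targeting_probability(a, params, mode = "exact")))
  }
  # fig3: baseline curve + over-expressed points
  curve <- data.frame(
    abundance = a,
    targeting_no_peripheral =
      targeting_probability_central(a, params$t0, params$m),
    targeting_step = targeting_probability(a, params, mode = "step"))
  pts <- NULL
  if (!is.null(points)) {
    pts <- as.data.frame(points)
    stopifnot(all(c("a_basal", "k") %in% names(pts)))
    astar <- a_star(params)
    pts$a_new <- pts$a_basal * pts$k
    pts$detectable <- pts$a_new >= astar
    pts$targeting_prob <- mapply(function(ab, k) {
      fold_change_targeting_prob(ab, k, params, mode = "step")
    }, pts$a_basal, pts$k)
    pts$targeting_no_peripheral <- targeting_probability_central(
      pts$a_new, params$t0, params$m, a_basal = pts$a_basal)
  }
  list(curve = curve, points = pts)
}
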