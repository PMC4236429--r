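#' Read / write antigenic environments as TSV
#'
#' The tabular interchange format is tab-separated with a header row,
#' columns `antigen_id`, `abundance`, and optionally `category` (default
#' `"self"`) and `basal_abundance`. Abundances are normalized on read.
#'
#' @param path file path.
#' @return `read_environment_tsv()` returns an [antigen_environment()];
#'   `write_environment_tsv()` returns `path` invisibly.
#' @export
read_environment_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("antigen_id", "abundance") %in% names(df))) {
    stop("environment TSV needs columns 'antigen_id' and 'abundance'",
         call. = FALSE)
  }
  antigen_environment(
    abundances = df$abundance,
    ids = df$antigen_id,
    categories = if ("category" %in% names(df)) df$category else "self",
    basal_abundances = if ("basal_abundance" %in% names(df)) {
      df$basal_abundance
    } else NULL
  )
}

#' @rdname read_environment_tsv
#' @param env an [antigen_environment()].
#' @export
write_environment_tsv <- function(env, path) {
  stopifnot(inherits(env, "antigen_environment"))
  write_tsv(as.data.frame(env), path)
  invisible(path)
}

#' JSON round-trip of an antigenic environment
#'
#' @param env an [antigen_environment()].
#' @return `environment_to_json()` returns a JSON string;
#'   `environment_from_json()` its inverse.
#' @export
environment_to_json <- function(env) {
  stopifnot(inherits(env, "antigen_environment"))
  jsonlite::toJSON(unclass(env), digits = NA, auto_unbox = FALSE)
}

#' @rdname environment_to_json
#' @param json JSON string or path as accepted by [jsonlite::fromJSON()].
#' @export
environment_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  antigen_environment(x$abundances, ids = x$ids, categories = x$categories,
                      basal_abundances = x$basal_abundances)
}

# locale-free TSV writer: tab separator, header, '.' decimal
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, dec = ".")
  invisible(path)
}

#' Write per-antigen derived quantities to TSV + JSON
#'
#' Emits the [derive()] table as TSV and the scalar summary (`a_star`,
#' `a_max`, `MDI`, and the resolved parameters) as a JSON sidecar.
#'
#' @param dq a `"derived_quantities"` object from [derive()].
#' @param tsv_path,json_path output paths (`NULL` skips that output).
#' @return Invisibly, the list written to JSON.
#' @export
write_derived <- function(dq, tsv_path = NULL, json_path = NULL) {
  stopifnot(inherits(dq, "derived_quantities"))
  if (!is.null(tsv_path)) write_tsv(dq$table, tsv_path)
  summary <- list(a_star = dq$a_star, a_max = dq$a_max, mdi = dq$mdi,
                  params = Filter(Negate(is.null), unclass(dq$params)))
  if (!is.null(json_path)) {
    jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(summary)
}

#' Write a scenario result to TSV + JSON
#'
#' The per-antigen table goes to TSV; the full result (scenario name,
#' replicate count, seed, frequencies, resolved parameters) to JSON, so
#' every output records the configuration that produced it.
#'
#' @param result a `"scenario_result"` from [run_scenario()].
#' @param tsv_path,json_path output paths (`NULL` skips that output).
#' @return Invisibly, the list written to JSON.
#' @export
write_scenario_result <- function(result, tsv_path = NULL, json_path = NULL) {
  stopifnot(inherits(result, "scenario_result"))
  if (!is.null(tsv_path)) write_tsv(result$table, tsv_path)
  out <- list(scenario = result$scenario, n_reps = result$n_reps,
              seed = result$seed,
              no_response_freq = result$no_response_freq,
              table = result$table,
              params = Filter(Negate(is.null), unclass(result$params)))
  if (!is.null(json_path)) {
    jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(out)
}

#' Read and validate a YAML run configuration
#'
#' A run configuration holds a `params` block ([model_params()] fields), an
#' `environment` block with exactly one source — `abundances` (inline
#' vector, with optional `ids`/`categories`), `tsv` (path), or `generator`
#' (fields of [generate_environment()]) — plus optional `scenario` and
#' `seed` entries.
#'
#' @param path YAML file path.
#' @return A list of class `"run_config"` with elements `params`
#'   (a [model_params()]), `environment_source`, `scenario`, `seed`, and a
#'   `resolve_environment()` already applied as `environment` when the
#'   source is inline or a generator with a seed available.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$params)) stop("config missing 'params' block", call. = FALSE)
  # YAML 1.1 parses a bare key `N` as boolean FALSE; restore the field name
  names(cfg$params)[names(cfg$params) == "FALSE"] <- "N"
  allowed <- c("t0", "N", "n_star", "K", "s", "m",
               "presentation_mode", "count_model")
  unknown <- setdiff(names(cfg$params), allowed)
  if (length(unknown)) {
    stop("unknown params field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  params <- do.call(model_params, cfg$params)
  env_block <- cfg$environment
  if (!is.null(env_block)) {
    sources <- intersect(names(env_block), c("abundances", "tsv", "generator"))
    if (length(sources) != 1L) {
      stop("environment block must name exactly one source: ",
           "'abundances', 'tsv' or 'generator'", call. = FALSE)
    }
    if (identical(sources, "tsv") && !file.exists(env_block$tsv)) {
      stop("environment TSV not found: ", env_block$tsv, call. = FALSE)
    }
  }
  seed <- cfg$seed
  if (!is.null(seed) &&
      (!is.numeric(seed) || length(seed) != 1L || seed < 0 ||
       seed != round(seed))) {
    stop("seed must be a nonnegative integer", call. = FALSE)
  }
  structure(
    list(params = params, environment_source = env_block,
         scenario = cfg$scenario, seed = seed, path = path),
    class = "run_config"
  )
}

#' Materialize the environment named by a run configuration
#'
#' @param config a `"run_config"` from [read_run_config()].
#' @return An [antigen_environment()]. Generator sources consume the
#'   config's seed (if any) via `set.seed()` first.
#' @export
resolve_environment <- function(config) {
  stopifnot(inherits(config, "run_config"))
  src <- config$environment_source
  if (is.null(src)) stop("config has no environment block", call. = FALSE)
  if (!is.null(src$abundances)) {
    antigen_environment(unlist(src$abundances),
                        ids = src$ids,
                        categories = src$categories %||% "self")
  } else if (!is.null(src$tsv)) {
    read_environment_tsv(src$tsv)
  } else {
    if (!is.null(config$seed)) set.seed(config$seed)
    do.call(generate_environment, src$generator)
  }
}
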