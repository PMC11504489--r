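# Structured run reports: machine-readable JSON with a stable key schema,
# carrying enough (config + seed) to regenerate deterministic stages
# bit-for-bit.

# Tiny FNV-1a content hash (hex) so reports can record a config fingerprint
# without external dependencies.
fnv1a_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

#' Run configuration
#'
#' Validated bundle of inputs, design overrides, fit options and seed for
#' a pipeline run. Unknown keys are rejected; every run writes the
#' resolved configuration beside its results.
#'
#' @param titration_table,competition_table,decay_table,plate_table
#'   optional input file paths.
#' @param anomer_fraction_alpha anomeric fraction used when reading
#'   titration/competition tables.
#' @param weighted inverse-variance weighting in [fit_titration()]?
#' @param fit_r_free co-fit free-state rates?
#' @param seed integer seed.
#' @param out_dir output directory.
#' @return An object of class `run_config`.
#' @export
run_config <- function(titration_table = NULL, competition_table = NULL,
                       decay_table = NULL, plate_table = NULL,
                       anomer_fraction_alpha = 0.4,
                       weighted = FALSE, fit_r_free = FALSE,
                       seed = 1L, out_dir = ".") {
  structure(list(titration_table = titration_table,
                 competition_table = competition_table,
                 decay_table = decay_table,
                 plate_table = plate_table,
                 anomer_fraction_alpha = anomer_fraction_alpha,
                 weighted = weighted, fit_r_free = fit_r_free,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from JSON
#'
#' @param path JSON file path.
#' @return A [run_config()]. Unknown keys in the file are an error.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(run_config, raw)
}

#' Assemble a structured report
#'
#' @param config a [run_config()].
#' @param titration_fit optional `fit_result` from [fit_titration()].
#' @param competition_fit optional `competition_fit`.
#' @param rate_estimates optional list of `rate_estimate`s.
#' @param dose_response optional `dose_response_fit`.
#' @return List of class `cpmg_report` with a stable key schema
#'   (`version`, `config`, `config_hash`, result blocks).
#' @export
build_report <- function(config, titration_fit = NULL,
                         competition_fit = NULL, rate_estimates = NULL,
                         dose_response = NULL) {
  stopifnot(inherits(config, "run_config"))
  cfg <- unclass(config)
  rep <- list(
    version = as.character(utils::packageVersion("cpmgbind")),
    config = cfg,
    config_hash = fnv1a_hash(jsonlite::toJSON(cfg, auto_unbox = TRUE,
                                              digits = NA))
  )
  if (!is.null(titration_fit)) {
    p <- titration_fit$params
    rep$titration <- list(
      k_alpha = p$k_alpha, k_beta = p$k_beta, r_bound = p$r_bound,
      r_free_alpha = p$r_free_alpha, r_free_beta = p$r_free_beta,
      stderr = as.list(titration_fit$stderr),
      converged = titration_fit$converged,
      at_bound = as.list(titration_fit$at_bound),
      rss = titration_fit$rss, n = titration_fit$n)
  }
  if (!is.null(competition_fit))
    rep$competition <- list(kd = competition_fit$kd,
                            kd_lower = competition_fit$kd_lower,
                            verdict = competition_fit$verdict)
  if (!is.null(rate_estimates))
    rep$rates <- lapply(rate_estimates, function(r)
      list(sample_id = r$sample_id, anomer = r$anomer, r2 = r$r2,
           stderr = r$stderr, flagged = r$flagged))
  if (!is.null(dose_response))
    rep$dose_response <- list(ic50 = dose_response$ic50,
                              hill = dose_response$hill,
                              upper = dose_response$upper,
                              lower = dose_response$lower,
                              extrapolated = dose_response$extrapolated,
                              mode = dose_response$mode)
  structure(rep, class = "cpmg_report")
}

#' Write / read a report as JSON
#'
#' @param report a `cpmg_report`.
#' @param path JSON file path.
#' @return `read_report()` returns the report as a plain list.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
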