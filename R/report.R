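#' Run a study design from a validated configuration
#'
#' Dispatches a configuration (typically parsed from a JSON or YAML file,
#' see [read_design_config]) to the matching design function and wraps the
#' outcome in a report carrying the echoed inputs, every intermediate
#' quantity (point estimates, z-quantiles, unrounded n), the computed sizes,
#' warnings, and provenance. Sample size calculation is one component of a
#' trial protocol; the report states only what it computes.
#'
#' Supported `design_kind` values:
#' * `"noncomparative"` — single new test vs reference, CI inversion
#'   ([size_noncomparative]); parameters `target_lower_primary`,
#'   `target_lower_alternative`, `level`, `prevalence`, optional
#'   `override_n` (length 2), `primary_metric`, `inflate_pct`.
#' * `"diag-sup"`, `"rct-sup"` — superiority on two proportions
#'   ([size_superiority]); parameters `p_control`, `p_new`, `alpha`,
#'   `power`, optional `rates`, `inflate_pct`.
#' * `"diag-noninf"`, `"rct-noninf"` — non-inferiority
#'   ([size_noninferiority]); additionally `margin`.
#'
#' The `diag-*` kinds use the paired-diagnostic framing (all tests applied
#' to one patient sample), the `rct-*` kinds the two-arm framing (total =
#' twice the per-group size).
#'
#' @param config A list with elements `design_kind`, `parameters` (a named
#'   list), and optionally `percent_convention` (logical; when `TRUE`,
#'   proportion-scale parameters — `p_control`, `p_new`, `margin`, `alpha`,
#'   `power`, `level`, `prevalence` — are read as percentages and divided
#'   by 100; metric floors are always in percent).
#' @return An object of class `"design_report"`.
#' @examples
#' cfg <- list(design_kind = "rct-noninf",
#'             parameters = list(p_control = 0.80, p_new = 0.80,
#'                               margin = 0.05, alpha = 0.05, power = 0.90))
#' run_design(cfg)
#' @export
run_design <- function(config) {
  config <- validate_design_config(config)
  pars <- config$parameters
  kind <- config$design_kind

  result <- if (kind == "noncomparative") {
    do.call(size_noncomparative, pars)
  } else {
    pars$framing <- if (startsWith(kind, "rct")) "two-arm-rct" else
      "paired-diagnostic"
    fn <- if (grepl("noninf", kind)) size_noninferiority else size_superiority
    do.call(fn, pars)
  }

  new_design_report(kind, pars, result)
}

new_design_report <- function(kind, pars, result) {
  numbers <- if (inherits(result, "noncomp_design")) {
    list(
      point_primary = result$point_primary,
      point_alternative = result$point_alternative,
      n_primary = result$n_primary,
      n_alternative = result$n_alternative,
      ci_primary_lower = result$ci_primary$lower,
      ci_primary_upper = result$ci_primary$upper,
      ci_alternative_lower = result$ci_alternative$lower,
      ci_alternative_upper = result$ci_alternative$upper,
      n_total = result$n_total,
      n_cases = result$n_cases,
      n_controls = result$n_controls,
      n_inflated = result$n_inflated)
  } else {
    list(
      z_alpha = result$z_alpha,
      z_power = result$z_power,
      variance_term = result$variance,
      n_unrounded = result$n_unrounded,
      n_per_group = result$n_per_group,
      n_total = result$n_total,
      n_inflated = result$n_inflated)
  }
  warnings <- if (!is.null(result$warnings)) result$warnings else character(0)
  structure(
    list(design_kind = kind,
         inputs = pars,
         numbers = numbers,
         warnings = warnings,
         result = result,
         provenance = list(
           tool = "diagsize",
           version = as.character(utils::packageVersion("diagsize")),
           timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))),
    class = "design_report"
  )
}

#' Render a design report as text or JSON
#'
#' Produces a deterministic serialization of a [run_design] report. The two
#' formats carry identical numbers: the text report is generated from the
#' same field list the JSON serializes, and the JSON round-trips losslessly
#' through [jsonlite::fromJSON].
#'
#' @param report A `"design_report"`.
#' @param format `"text"` or `"json"`.
#' @return A character scalar holding the rendered report.
#' @export
render_report <- function(report, format = c("text", "json")) {
  if (!inherits(report, "design_report")) {
    stop("`report` must be a design_report", call. = FALSE)
  }
  format <- match.arg(format)
  if (format == "json") {
    payload <- list(design_kind = report$design_kind,
                    inputs = report$inputs,
                    numbers = report$numbers,
                    warnings = report$warnings,
                    provenance = report$provenance)
    return(as.character(jsonlite::toJSON(payload, auto_unbox = TRUE,
                                         digits = NA, null = "null",
                                         na = "null")))
  }
  lines <- c(
    sprintf("diagsize design report (%s)", report$design_kind),
    sprintf("generated by %s %s at %s", report$provenance$tool,
            report$provenance$version, report$provenance$timestamp),
    "", "inputs:",
    sprintf("  %s = %s", names(report$inputs),
            vapply(report$inputs, function(v) paste(format(v), collapse = ","),
                   character(1))),
    "", "computed:",
    sprintf("  %s = %s", names(report$numbers),
            vapply(report$numbers, format_report_number, character(1))))
  if (length(report$warnings)) {
    lines <- c(lines, "", "warnings:",
               paste0("  - ", report$warnings))
  }
  lines <- c(lines, "",
             paste("note: sample size is one component of a trial protocol;",
                   "this report covers sizing only."))
  paste(lines, collapse = "\n")
}

# identical digits in text and JSON: both use full-precision representation
format_report_number <- function(v) {
  if (is.na(v)) "NA" else
    as.character(jsonlite::toJSON(v, auto_unbox = TRUE, digits = NA))
}

#' @export
print.design_report <- function(x, ...) {
  cat(render_report(x, "text"), "\n")
  invisible(x)
}

#' Read a design configuration from a JSON or YAML file
#'
#' The file must contain an object with `design_kind` and `parameters`
#' fields as described in [run_design]. The format is chosen by extension
#' (`.json` vs `.yml`/`.yaml`).
#'
#' @param path Path to the configuration file.
#' @return A validated config list ready for [run_design].
#' @export
read_design_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  config <- if (ext == "json") {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required to read YAML configs",
           call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    stop(sprintf("unsupported config extension '.%s' (use .json or .yaml)",
                 ext), call. = FALSE)
  }
  validate_design_config(config)
}

design_kinds <- c("noncomparative", "diag-sup", "diag-noninf",
                  "rct-sup", "rct-noninf")

validate_design_config <- function(config) {
  if (!is.list(config) || is.null(config$design_kind)) {
    stop("config must be a list with a `design_kind` field", call. = FALSE)
  }
  if (!config$design_kind %in% design_kinds) {
    stop(sprintf("unknown design_kind '%s' (expected one of: %s)",
                 config$design_kind, paste(design_kinds, collapse = ", ")),
         call. = FALSE)
  }
  pars <- config$parameters
  if (!is.list(pars)) {
    stop("config must carry a `parameters` list", call. = FALSE)
  }
  if (isTRUE(config$percent_convention)) {
    for (f in c("p_control", "p_new", "margin", "alpha", "power",
                "level", "prevalence")) {
      if (!is.null(pars[[f]])) pars[[f]] <- pars[[f]] / 100
    }
  }
  required <- if (config$design_kind == "noncomparative") {
    c("target_lower_primary", "target_lower_alternative", "prevalence")
  } else if (grepl("noninf", config$design_kind)) {
    c("p_control", "p_new", "margin")
  } else {
    c("p_control", "p_new")
  }
  missing <- setdiff(required, names(pars))
  if (length(missing)) {
    stop(sprintf("config for design_kind '%s' is missing field(s): %s",
                 config$design_kind, paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  for (f in intersect(c("prevalence", "p_control", "p_new", "alpha",
                        "power", "level"), names(pars))) {
    v <- pars[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) ||
        v <= 0 || v >= 1) {
      stop(sprintf("invalid value for `%s`: must be a proportion in (0, 1)",
                   f), call. = FALSE)
    }
  }
  config$parameters <- pars
  config
}
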