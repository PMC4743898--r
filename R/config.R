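# YAML case configuration, validation, the run driver and run-directory
# reporting.  The CLI script (inst/cli/ifem2d.R) is a thin wrapper over
# validate_case() / run_case() / report_case().

#' Validate a case configuration
#'
#' Checks a configuration list (or YAML file) field by field and returns the
#' problems found (empty character vector when valid).
#'
#' @param config path to a YAML file or a configuration list.
#' @return character vector of problems; `character(0)` if valid.
#' @export
validate_case <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  errs <- character(0)
  add <- function(msg) errs <<- c(errs, msg)
  if (is.null(config$case) ||
      !config$case %in% c("bifurcation", "folds"))
    add("case: must be 'bifurcation' or 'folds'")
  if (!is.null(config$algorithm) &&
      !config$algorithm %in% c("ifem", "semi_implicit", "mifem"))
    add("algorithm: must be one of ifem, semi_implicit, mifem")
  if (!is.null(config$dt) && (!is.numeric(config$dt) || config$dt <= 0))
    add("dt: must be a positive number (seconds)")
  if (!is.null(config$n_steps) &&
      (!is.numeric(config$n_steps) || config$n_steps < 1))
    add("n_steps: must be a positive integer")
  if (!is.null(config$seed) && !is.numeric(config$seed))
    add("seed: must be an integer")
  if (identical(config$case, "bifurcation")) {
    g <- config$geometry
    if (!is.null(g$r_d) && (!is.numeric(g$r_d) || g$r_d <= 0))
      add("geometry.r_d: must be a positive number")
    if (!is.null(g$flow_ratio) &&
        (!is.numeric(g$flow_ratio) || g$flow_ratio <= 0))
      add("geometry.flow_ratio: must be a positive number")
  }
  if (identical(config$case, "folds")) {
    if (!is.null(config$geometry$scale) &&
        (!is.numeric(config$geometry$scale) || config$geometry$scale <= 0))
      add("geometry.scale: must be a positive number")
  }
  errs
}

#' Run a demo case from a configuration
#'
#' Reads the configuration (YAML path or list), runs the corresponding case
#' and writes diagnostics (`diagnostics.csv`), a machine-readable summary
#' (`summary.json`) and VTU states into the run directory.
#'
#' @param config YAML file path or configuration list; see
#'   [validate_case()] for the schema.
#' @param out_dir run directory (created; defaults to `runs/<case>`).
#' @return the case diagnostics object, invisibly.
#' @export
run_case <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  errs <- validate_case(config)
  if (length(errs))
    stop("configuration errors:\n  ", paste(errs, collapse = "\n  "))
  if (!is.null(config$seed)) set.seed(as.integer(config$seed))
  if (is.null(out_dir)) out_dir <- file.path("runs", config$case)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  ok <- FALSE
  res <- NULL
  reason <- ""
  tryCatch({
    if (config$case == "bifurcation") {
      g <- config$geometry %||% list()
      res <- rbc_bifurcation_case(
        r_d = g$r_d %||% 1, flow_ratio = g$flow_ratio %||% 1,
        n_steps = config$n_steps %||% 900L,
        dt = config$dt %||% 2e-5)
      utils::write.csv(res$history, file.path(out_dir, "diagnostics.csv"),
                       row.names = FALSE)
      write_state(out_dir, nrow(res$history), res$sim)
      summary <- list(case = "bifurcation", branch = res$branch,
                      apex_x_cm = res$apex_x,
                      Q1 = res$Q1, Q2 = res$Q2,
                      steps = nrow(res$history))
    } else {
      g <- config$geometry %||% list()
      res <- flapping_fold_case(scale = g$scale %||% 0.02,
                                n_steps = config$n_steps %||% 60L,
                                dt = config$dt %||% 1e-5,
                                out_dir = out_dir)
      utils::write.csv(res$series, file.path(out_dir, "diagnostics.csv"),
                       row.names = FALSE)
      sp <- spectrum(res$series$Gw_up, config$dt %||% 1e-5)
      summary <- list(case = "folds", P_in = res$Pin,
                      density_ratio = res$density_ratio,
                      dominant_freq_hz = sp$freq_hz,
                      steps = nrow(res$series))
    }
    ok <- TRUE
  }, error = function(e) reason <<- conditionMessage(e))
  if (!ok) {
    jsonlite::write_json(list(status = "aborted", reason = reason),
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE)
    stop("run aborted: ", reason)
  }
  summary$status <- "completed"
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}

#' Summarize a completed run directory
#'
#' @param run_dir directory written by [run_case()].
#' @return the parsed summary list (printed as a short report).
#' @export
report_case <- function(run_dir) {
  sf <- file.path(run_dir, "summary.json")
  if (!file.exists(sf)) stop("no summary.json in ", run_dir)
  s <- jsonlite::read_json(sf)
  dg <- file.path(run_dir, "diagnostics.csv")
  cat("run:", run_dir, "\n")
  for (nm in names(s)) cat(sprintf("  %s: %s\n", nm, format(s[[nm]])))
  if (file.exists(dg)) {
    d <- utils::read.csv(dg)
    cat(sprintf("  diagnostics: %d rows, columns %s\n", nrow(d),
                paste(names(d), collapse = ", ")))
  }
  invisible(s)
}
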