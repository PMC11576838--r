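# Study configuration schema, validation and output writers.

#' Validate a study configuration file
#'
#' Parses a study YAML, resolves and loads every referenced compound /
#' population file and reports the full list of problems (not fail-fast).
#'
#' @param path study configuration YAML
#' @return a `study_config` (with loaded objects under `$objects` and md5
#'   hashes of every input file under `$file_hashes`) or an error listing
#'   every problem found
#' @export
validate_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  x <- yaml::read_yaml(path)
  errs <- character(0)
  note <- function(msg) errs <<- c(errs, msg)

  if (!identical(x$schema, "study_config/1"))
    note("schema: must be 'study_config/1'")
  if (is.null(x$label)) note("label: missing")
  if (is.null(x$compounds$mmae)) note("compounds.mmae: missing")
  if (is.null(x$scenario$type) ||
      !x$scenario$type %in% c("exposure", "ddi"))
    note("scenario.type: must be 'exposure' or 'ddi'")
  if (is.null(x$population$master_seed))
    note("population.master_seed: seed is mandatory for population runs")

  resolve <- function(ref) {
    if (is.null(ref)) return(NULL)
    if (file.exists(ref)) return(ref)
    p <- try(default_compound_file(ref), silent = TRUE)
    if (inherits(p, "try-error")) {
      note(sprintf("compound reference '%s': no such file or shipped stem",
                   ref))
      return(NULL)
    }
    p
  }
  paths <- list(adc = resolve(x$compounds$adc),
                mmae = resolve(x$compounds$mmae),
                perpetrator = resolve(x$compounds$perpetrator),
                victim = resolve(x$compounds$victim))
  load_checked <- function(p, kind) {
    if (is.null(p)) return(NULL)
    obj <- try(load_compound(p, kind = kind), silent = TRUE)
    if (inherits(obj, "try-error")) {
      note(sprintf("%s (%s): %s", kind, p,
                   conditionMessage(attr(obj, "condition"))))
      return(NULL)
    }
    obj
  }
  objects <- list(
    adc = load_checked(paths$adc, "adc"),
    mmae = load_checked(paths$mmae, "smallmol"),
    perp = load_checked(paths$perpetrator, "perpetrator"),
    victim = load_checked(paths$victim, "victim"))

  pop_args <- x$population
  pop_src <- pop_args$source %||% "cancer"
  pop_args$source <- NULL
  objects$population <- if (file.exists(pop_src)) {
    cfg <- try(load_population_config(pop_src), silent = TRUE)
    if (inherits(cfg, "try-error")) {
      note(sprintf("population file %s invalid", pop_src)); NULL
    } else {
      do.call(population_config, modifyList(
        cfg[setdiff(names(cfg), "population")], pop_args))
    }
  } else if (pop_src %in% c("cancer", "healthy")) {
    do.call(population_config, c(list(population = pop_src), pop_args))
  } else {
    note(sprintf("population.source '%s': not a file or known population",
                 pop_src)); NULL
  }

  mk_regimen <- function(r, name) {
    if (is.null(r)) return(NULL)
    if (!is.null(r$qd))
      return(do.call(qd_regimen, r$qd))
    reg <- try(do.call(dose_regimen, r), silent = TRUE)
    if (inherits(reg, "try-error")) {
      note(sprintf("regimens.%s: %s", name,
                   conditionMessage(attr(reg, "condition"))))
      return(NULL)
    }
    reg
  }
  objects$adc_regimen <- mk_regimen(x$regimens$adc, "adc")
  objects$perp_regimen <- mk_regimen(x$regimens$perpetrator, "perpetrator")
  objects$victim_regimen <- mk_regimen(x$regimens$victim, "victim")

  if (identical(x$scenario$type, "ddi") &&
      identical(x$scenario$victim_analyte %||% "mmae", "victim") &&
      is.null(objects$victim))
    note("scenario: victim compound required for victim_analyte 'victim'")

  if (length(errs))
    stop("invalid study config:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)

  used <- c(path, unlist(paths))
  cfg <- list(label = x$label, scenario = x$scenario, objects = objects,
              file_hashes = as.list(tools::md5sum(used[file.exists(used)])))
  class(cfg) <- "study_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.scenario_from_config <- function(config) {
  sc <- config$scenario
  o <- config$objects
  ddi_scenario(
    victim_analyte = sc$victim_analyte %||% "mmae",
    adc = o$adc, adc_regimen = o$adc_regimen, mmae = o$mmae,
    perp = o$perp, perp_regimen = o$perp_regimen,
    victim = o$victim, victim_regimen = o$victim_regimen,
    end_h = sc$end_h %||% 672, nca_start_h = sc$nca_start_h %||% 0,
    f_bile = sc$f_bile, label = config$label)
}

#' Write study results to a directory
#'
#' Deterministic file names: `timeseries.csv`, `pk_summary.csv`,
#' `ddi_summary.csv` (DDI runs only), `subjects.csv` and `manifest.json`
#' (every input hash and seed).
#'
#' @param results a `study_result` from [run_virtual_study()]
#' @param out_dir output directory (created if needed)
#' @return invisible character vector of the files written
#' @export
write_outputs <- function(results, out_dir) {
  stopifnot(inherits(results, "study_result"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  written <- character(0)
  put <- function(df, name) {
    if (is.null(df)) return()
    f <- file.path(out_dir, name)
    write.csv(df, f, row.names = FALSE)
    written <<- c(written, f)
  }
  put(results$timeseries, "timeseries.csv")
  put(results$pk_summary, "pk_summary.csv")
  put(results$ddi_summary, "ddi_summary.csv")
  put(results$subjects, "subjects.csv")
  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(results$manifest, mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  written <- c(written, mf)
  invisible(written)
}
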