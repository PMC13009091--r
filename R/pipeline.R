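# Pipeline commands tying the stages together: simulate inputs, base-case
# comparison, PSA, population impact, validation. Each command writes
# headed CSV outputs plus a machine-readable JSON run manifest, and is
# callable from R or from the thin command-line wrapper shipped in
# inst/scripts/strokecea.

#' Assemble a pipeline run configuration
#'
#' Reads an optional JSON or YAML configuration file (versioned schema) and
#' applies overrides; unspecified fields fall back to documented defaults.
#'
#' @param path Optional JSON/YAML config file.
#' @param ... Named overrides of config fields: `parameter_file`,
#'   `life_table_file`, `arms` (ordered pair: intervention, comparator),
#'   `discount_rate`, `cycle_correction`, `max_age`, `wtp_thresholds`,
#'   `n_psa_draws`, `master_seed`, `rounding_mode`, `output_dir`,
#'   `n_patients`, `population` (list: `n_procedures`, `p_incomplete`,
#'   `p_accessible`).
#' @return List of class `"run_config"`.
#' @export
run_config <- function(path = NULL, ...) {
  cfg <- list(
    schema_version = 1L,
    parameter_file = NULL, life_table_file = NULL,
    arms = c("etici2c3", "etici2b_accessible"),
    discount_rate = 0.03, cycle_correction = "half_cycle", max_age = NULL,
    wtp_thresholds = c(50000, 100000), n_psa_draws = 10000L,
    master_seed = 1L, rounding_mode = "exact", output_dir = ".",
    n_patients = 1105L,
    population = list(n_procedures = 39000, p_incomplete = 0.539,
                      p_accessible = 0.332)
  )
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    fromfile <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stop("YAML configs require the yaml package")
      }
      yaml::read_yaml(path)
    } else jsonlite::read_json(path, simplifyVector = TRUE)
    unknown <- setdiff(names(fromfile), names(cfg))
    if (length(unknown)) {
      stop("run_config: unknown config key(s): ",
           paste(unknown, collapse = ", "))
    }
    cfg[names(fromfile)] <- fromfile
  }
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown)) {
    stop("run_config: unknown config key(s): ",
         paste(unknown, collapse = ", "))
  }
  cfg[names(overrides)] <- overrides
  if (length(cfg$arms) != 2L || cfg$arms[1L] == cfg$arms[2L]) {
    stop("run_config: arms must be two distinct labels")
  }
  structure(cfg, class = "run_config")
}

# internal: cea_config slice of a run_config
as_cea_config <- function(cfg) {
  cea_config(discount_rate = cfg$discount_rate,
             cycle_correction = cfg$cycle_correction,
             max_age = cfg$max_age,
             wtp_thresholds = cfg$wtp_thresholds,
             n_psa_draws = cfg$n_psa_draws,
             master_seed = cfg$master_seed,
             rounding_mode = cfg$rounding_mode)
}

# internal: load inputs named in a run_config (defaults when unset)
load_inputs <- function(cfg) {
  ps <- if (is.null(cfg$parameter_file)) {
    default_parameter_set()
  } else load_parameter_set(cfg$parameter_file)
  lt <- if (is.null(cfg$life_table_file)) {
    generate_life_table()
  } else load_life_table(cfg$life_table_file)
  list(ps = ps, lt = lt)
}

# internal: write a JSON run manifest next to the outputs
write_manifest <- function(cfg, command, files) {
  files <- files[file.exists(files)]
  manifest <- list(
    command = command,
    package_version = as.character(utils::packageVersion("strokeCEA")),
    config = unclass(cfg),
    master_seed = cfg$master_seed,
    currency_note = "all monetary outputs in USD of the parameter file's currency_year",
    outputs = as.list(stats::setNames(as.character(tools::md5sum(files)),
                                      basename(files))))
  path <- file.path(cfg$output_dir, paste0("manifest_", command, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  message("[", command, "] wrote ", length(files), " file(s) to ",
          cfg$output_dir, " (seed ", cfg$master_seed, ")")
  invisible(path)
}

#' Pipeline command: generate synthetic inputs
#'
#' Writes a synthetic cohort CSV, a life-table CSV and a parameter table
#' JSON to the configured output directory; re-invocation with the same
#' seed is byte-identical.
#'
#' @param cfg A [run_config()].
#' @return Character vector of the files written, invisibly.
#' @export
cmd_simulate <- function(cfg = run_config()) {
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(cfg$output_dir)) {
    stop("cmd_simulate: cannot create output directory ", cfg$output_dir)
  }
  sc <- synthetic_config(n_patients = cfg$n_patients,
                         seed = cfg$master_seed)
  cohort_path <- file.path(cfg$output_dir, "cohort.csv")
  write_cohort(generate_cohort(sc), cohort_path)
  lt_path <- file.path(cfg$output_dir, "life_table.csv")
  write_life_table(generate_life_table(), lt_path)
  ps_path <- file.path(cfg$output_dir, "parameters.json")
  save_parameter_set(default_parameter_set(), ps_path)
  files <- c(cohort_path, lt_path, ps_path)
  write_manifest(cfg, "simulate", files)
  invisible(files)
}

#' Pipeline command: deterministic base-case comparison
#'
#' Runs both configured arms on the point estimates and writes an
#' incremental cost-effectiveness table (one block per perspective, with
#' dominance flags and ICERs where defined).
#'
#' @param cfg A [run_config()].
#' @return The `"cea_comparison"`, invisibly; the CSV is the side effect.
#' @export
cmd_basecase <- function(cfg = run_config()) {
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  inputs <- load_inputs(cfg)
  cc <- as_cea_config(cfg)
  a <- run_lifetime(cfg$arms[1L], inputs$ps, inputs$lt, cc)
  b <- run_lifetime(cfg$arms[2L], inputs$ps, inputs$lt, cc)
  cmp <- compare_arms(a, b)
  tab <- data.frame(
    quantity = c("qalys", "cost_healthcare", "cost_societal"),
    intervention = c(a$qalys, a$cost_healthcare, a$cost_societal),
    comparator = c(b$qalys, b$cost_healthcare, b$cost_societal),
    difference = c(cmp$delta_qalys, cmp$healthcare$delta_cost,
                   cmp$societal$delta_cost),
    dominance = c("", cmp$healthcare$dominance, cmp$societal$dominance),
    icer = c(NA, cmp$healthcare$icer, cmp$societal$icer))
  names(tab)[2:3] <- cfg$arms
  path <- file.path(cfg$output_dir, "basecase.csv")
  utils::write.csv(tab, path, row.names = FALSE, na = "")
  write_manifest(cfg, "basecase", path)
  invisible(cmp)
}

#' Pipeline command: probabilistic sensitivity analysis
#'
#' Runs the PSA for the configured arm pair, writes per-perspective scatter
#' CSVs (one row per draw) and an acceptability table at every configured
#' willingness-to-pay threshold.
#'
#' @param cfg A [run_config()].
#' @return The `"cea_psa"` samples, invisibly.
#' @export
cmd_psa <- function(cfg = run_config()) {
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  inputs <- load_inputs(cfg)
  cc <- as_cea_config(cfg)
  samples <- run_psa(inputs$ps, cfg$arms, config = cc,
                     life_table = inputs$lt)
  files <- character()
  acc <- list()
  for (p in c("healthcare", "societal")) {
    sc <- export_scatter(samples, p)
    f <- file.path(cfg$output_dir, paste0("psa_scatter_", p, ".csv"))
    utils::write.csv(sc, f, row.names = FALSE)
    files <- c(files, f)
    for (l in cfg$wtp_thresholds) {
      r <- acceptability(samples, l, p)
      acc[[length(acc) + 1L]] <- data.frame(
        perspective = p, wtp_usd_per_qaly = l, acceptability = r$fraction,
        n_draws = r$n_draws)
    }
  }
  f <- file.path(cfg$output_dir, "acceptability.csv")
  utils::write.csv(do.call(rbind, acc), f, row.names = FALSE)
  files <- c(files, f)
  write_manifest(cfg, "psa", files)
  invisible(samples)
}

#' Pipeline command: population-level impact
#'
#' Scales per-patient incremental outcomes to the configured national EVT
#' volume and writes the impact table under both rounding modes. Deltas
#' are either supplied directly or computed by running the base case for
#' the two incomplete-pattern comparisons.
#'
#' @param cfg A [run_config()].
#' @param deltas Optional list with `delta_qaly`,
#'   `delta_cost_healthcare`, `delta_cost_societal`, each
#'   `c(accessible, non_accessible)` (savings positive).
#' @return List of the two `"population_impact"` objects, invisibly.
#' @export
cmd_population <- function(cfg = run_config(), deltas = NULL) {
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(deltas)) {
    inputs <- load_inputs(cfg)
    cc <- as_cea_config(cfg)
    ref <- run_lifetime("etici2c3", inputs$ps, inputs$lt, cc)
    acc <- run_lifetime("etici2b_accessible", inputs$ps, inputs$lt, cc)
    non <- run_lifetime("etici2b_non_accessible", inputs$ps, inputs$lt, cc)
    deltas <- list(
      delta_qaly = c(ref$qalys - acc$qalys, ref$qalys - non$qalys),
      delta_cost_healthcare = c(acc$cost_healthcare - ref$cost_healthcare,
                                non$cost_healthcare - ref$cost_healthcare),
      delta_cost_societal = c(acc$cost_societal - ref$cost_societal,
                              non$cost_societal - ref$cost_societal))
  }
  pop <- cfg$population
  out <- lapply(c("exact", "paper"), function(mode) {
    population_impact(pop$n_procedures, pop$p_incomplete, pop$p_accessible,
                      deltas$delta_qaly, deltas$delta_cost_healthcare,
                      deltas$delta_cost_societal, mode)
  })
  names(out) <- c("exact", "paper")
  rows <- do.call(rbind, lapply(out, function(x) {
    data.frame(rounding_mode = x$rounding_mode,
               pattern = names(x$qalys_gained),
               patients_per_year = as.numeric(x$n_patients),
               qalys_gained_per_year = as.numeric(x$qalys_gained),
               healthcare_savings_musd = as.numeric(x$savings_healthcare_musd),
               societal_savings_musd = as.numeric(x$savings_societal_musd))
  }))
  path <- file.path(cfg$output_dir, "population_impact.csv")
  utils::write.csv(rows, path, row.names = FALSE)
  write_manifest(cfg, "population", path)
  invisible(out)
}

#' Pipeline command: validate configured inputs
#'
#' Loads the configured parameter set and life table and reports validator
#' findings; errors raise a condition (nonzero exit from the CLI wrapper).
#'
#' @param cfg A [run_config()].
#' @return The findings data.frame, invisibly.
#' @export
cmd_validate <- function(cfg = run_config()) {
  inputs <- load_inputs(cfg)
  findings <- validate_parameter_set(inputs$ps)
  if (nrow(findings)) {
    apply(findings, 1L, function(r) {
      message(sprintf("[%s] %s: %s", r[["level"]], r[["field"]],
                      r[["message"]]))
    })
  } else message("parameter set: no findings")
  if (any(findings$level == "error")) {
    stop("cmd_validate: parameter set has errors")
  }
  invisible(findings)
}

#' Write the long-run Markov trace to CSV
#'
#' @param outcome A `"lifetime_outcome"`.
#' @param path Output CSV.
#' @return `path`, invisibly.
#' @export
write_trace <- function(outcome, path) {
  utils::write.csv(outcome$trace, path, row.names = FALSE)
  invisible(path)
}
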