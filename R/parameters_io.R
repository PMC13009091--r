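# Parameter table serialization: nested JSON and a flat CSV that mirrors a
# supplementary-table layout (key,value,distribution,dist_params columns).

COST_FIELDS <- c("cost_evt", "cost_ivt", "cost_acute_other",
                 "cost_annual_care", "cost_informal_care")

# internal: dist spec -> short string like "beta(rel_se=0.2)"
format_dist_spec <- function(spec) {
  if (is.null(spec)) return("")
  switch(spec$family,
         fixed = "fixed",
         dirichlet = sprintf("dirichlet(ess=%g)", spec$ess),
         sprintf("%s(rel_se=%g)", spec$family, spec$rel_se))
}

parse_dist_spec <- function(txt) {
  txt <- trimws(txt)
  if (txt == "" || is.na(txt)) return(NULL)
  if (txt == "fixed") return(dist_spec("fixed"))
  m <- regmatches(txt, regexec("^([a-z]+)\\((rel_se|ess)=([0-9.eE+-]+)\\)$",
                               txt))[[1L]]
  if (length(m) != 4L) stop("cannot parse distribution spec: ", txt)
  if (m[3L] == "ess") dist_spec(m[2L], ess = as.numeric(m[4L]))
  else dist_spec(m[2L], rel_se = as.numeric(m[4L]))
}

# internal: parameter set -> flat data frame
flatten_parameter_set <- function(ps) {
  rows <- list()
  add <- function(key, value, spec = NULL) {
    rows[[length(rows) + 1L]] <<- data.frame(
      key = key, value = value,
      distribution = format_dist_spec(spec), stringsAsFactors = FALSE)
  }
  for (arm in names(ps$mrs90_dist)) {
    spec <- ps$psa$mrs90_dist[[arm]]
    for (k in names(ps$mrs90_dist[[arm]])) {
      add(sprintf("mrs90_dist.%s.%s", arm, k), ps$mrs90_dist[[arm]][[k]], spec)
    }
  }
  vec_fields <- c("utility", "post_stroke_mrs", "mortality_hr",
                  "cost_annual_care", "cost_informal_care", "return_to_work",
                  "p_ivt", "employment_rate")
  for (f in vec_fields) {
    for (k in names(ps[[f]])) {
      add(paste(f, k, sep = "."), ps[[f]][[k]], ps$psa[[f]])
    }
  }
  scalar_fields <- c("p_recurrent_annual", "case_fatality_recurrent",
                     "cost_evt", "cost_ivt", "cost_acute_other",
                     "annual_wage", "retirement_age", "start_age",
                     "inflation_factor", "currency_year")
  for (f in scalar_fields) add(f, ps[[f]], ps$psa[[f]])
  do.call(rbind, rows)
}

# internal: flat data frame -> parameter set (no inflation applied here)
unflatten_parameter_set <- function(df) {
  ps <- default_parameter_set()
  known_prefix <- setdiff(names(ps), "psa")
  seen <- character()
  for (i in seq_len(nrow(df))) {
    key <- df$key[i]
    parts <- strsplit(key, ".", fixed = TRUE)[[1L]]
    top <- parts[1L]
    if (!top %in% known_prefix) {
      stop("load_parameter_set: unknown parameter name: ", key)
    }
    val <- as.numeric(df$value[i])
    if (is.na(val)) stop("load_parameter_set: non-numeric value for ", key)
    if (top == "mrs90_dist") {
      if (length(parts) != 3L || !parts[2L] %in% names(ps$mrs90_dist) ||
          !parts[3L] %in% names(ps$mrs90_dist[[parts[2L]]])) {
        stop("load_parameter_set: unknown parameter name: ", key)
      }
      ps$mrs90_dist[[parts[2L]]][[parts[3L]]] <- val
    } else if (length(parts) == 2L) {
      if (!parts[2L] %in% names(ps[[top]])) {
        stop("load_parameter_set: unknown parameter name: ", key)
      }
      ps[[top]][[parts[2L]]] <- val
    } else if (length(parts) == 1L) {
      if (length(ps[[top]]) != 1L) {
        stop("load_parameter_set: ", key, " requires an element suffix")
      }
      ps[[top]] <- val
    } else {
      stop("load_parameter_set: unknown parameter name: ", key)
    }
    seen <- c(seen, top)
    if (nzchar(df$distribution[i]) && !is.na(df$distribution[i])) {
      spec <- parse_dist_spec(df$distribution[i])
      if (top == "mrs90_dist") ps$psa$mrs90_dist[[parts[2L]]] <- spec
      else ps$psa[[top]] <- spec
    }
  }
  required <- setdiff(known_prefix, c("inflation_factor", "currency_year"))
  missing <- setdiff(required, unique(seen))
  if (length(missing)) {
    stop("load_parameter_set: missing required parameter(s): ",
         paste(missing, collapse = ", "))
  }
  ps
}

#' Save a parameter set to JSON or CSV
#'
#' JSON is nested (one object per field); CSV is the flat
#' `key,value,distribution` layout with dotted keys such as
#' `mrs90_dist.etici2c3.mrs0`, diff-able and editable in a spreadsheet.
#'
#' @param ps A `"parameter_set"`.
#' @param path Output file; format inferred from the extension unless given.
#' @param file_format `"auto"`, `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
save_parameter_set <- function(ps, path, file_format = c("auto", "json",
                                                         "csv")) {
  file_format <- match.arg(file_format)
  if (file_format == "auto") {
    file_format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
                   else "csv"
  }
  if (file_format == "json") {
    out <- unclass(ps)
    out$psa <- lapply(out$psa, function(x) {
      if (inherits(x, "dist_spec")) format_dist_spec(x)
      else lapply(x, format_dist_spec)
    })
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    utils::write.csv(flatten_parameter_set(ps), path, row.names = FALSE)
  }
  invisible(path)
}

#' Load and validate a parameter set
#'
#' Reads a parameter table (nested JSON or flat CSV, see
#' [save_parameter_set()]), validates it with [validate_parameter_set()]
#' (errors stop with the offending field named; warnings are attached as an
#' attribute), and applies the file's inflation factor to all cost fields at
#' load time, resetting the factor to 1 so the returned object is expressed
#' in the file's index `currency_year`. Loading, saving and re-loading is
#' therefore value-identical.
#'
#' @param path Parameter file.
#' @param file_format `"auto"`, `"json"` or `"csv"`.
#' @return A validated `"parameter_set"`.
#' @export
load_parameter_set <- function(path, file_format = c("auto", "json", "csv")) {
  file_format <- match.arg(file_format)
  if (!file.exists(path)) stop("parameter file not found: ", path)
  if (file_format == "auto") {
    file_format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
                   else "csv"
  }
  if (file_format == "json") {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
    unknown <- setdiff(names(raw), names(default_parameter_set()))
    if (length(unknown)) {
      stop("load_parameter_set: unknown parameter name: ",
           paste(unknown, collapse = ", "))
    }
    ps <- default_parameter_set()
    required <- setdiff(names(ps), c("psa", "inflation_factor",
                                     "currency_year"))
    missing <- setdiff(required, names(raw))
    if (length(missing)) {
      stop("load_parameter_set: missing required parameter(s): ",
           paste(missing, collapse = ", "))
    }
    for (f in setdiff(names(raw), "psa")) {
      if (f == "mrs90_dist") {
        for (arm in names(raw$mrs90_dist)) {
          if (!arm %in% names(ps$mrs90_dist)) {
            stop("load_parameter_set: unknown arm: ", arm)
          }
          ps$mrs90_dist[[arm]][] <- unlist(raw$mrs90_dist[[arm]])
        }
      } else if (is.list(raw[[f]]) || length(raw[[f]]) > 1L) {
        v <- unlist(raw[[f]])
        bad <- setdiff(names(v), names(ps[[f]]))
        if (length(bad)) {
          stop("load_parameter_set: unknown parameter name: ",
               paste(paste(f, bad, sep = "."), collapse = ", "))
        }
        ps[[f]][names(v)] <- v
      } else {
        ps[[f]] <- as.numeric(raw[[f]])
      }
    }
    if (!is.null(raw$psa)) {
      for (f in names(raw$psa)) {
        if (f == "mrs90_dist") {
          for (arm in names(raw$psa$mrs90_dist)) {
            ps$psa$mrs90_dist[[arm]] <- parse_dist_spec(raw$psa$mrs90_dist[[arm]])
          }
        } else {
          ps$psa[[f]] <- parse_dist_spec(raw$psa[[f]])
        }
      }
    }
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character")
    if (!all(c("key", "value") %in% names(df))) {
      stop("load_parameter_set: CSV must have key and value columns")
    }
    if (is.null(df$distribution)) df$distribution <- ""
    ps <- unflatten_parameter_set(df)
  }
  findings <- validate_parameter_set(ps)
  errs <- findings[findings$level == "error", , drop = FALSE]
  if (nrow(errs)) {
    stop("invalid parameter set: ",
         paste(sprintf("%s (%s)", errs$field, errs$message), collapse = "; "))
  }
  if (ps$inflation_factor != 1) {
    for (f in COST_FIELDS) {
      ps[[f]] <- adjust_for_inflation(ps[[f]], ps$inflation_factor)
    }
    ps$inflation_factor <- 1
  }
  warn <- findings[findings$level == "warning", , drop = FALSE]
  if (nrow(warn)) attr(ps, "warnings") <- warn
  ps
}
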