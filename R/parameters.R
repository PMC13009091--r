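#' Distribution specification for probabilistic sensitivity analysis
#'
#' Each model parameter carries a second-order distribution used by
#' [run_psa()]. Families follow standard cost-effectiveness conventions:
#' `beta` for quantities bounded in \[0, 1\] (probabilities, utilities),
#' `gamma` for non-negative quantities (costs), `lognormal` for positive
#' ratios (mortality hazard ratios), `dirichlet` for probability vectors
#' (90-day mRS distributions), `fixed` for parameters held at their point
#' estimate. Beta, gamma and lognormal are moment-matched to the point
#' estimate with a relative standard error `rel_se`; dirichlet
#' concentrations are `point estimate x ess` (effective sample size).
#'
#' @param family One of `"beta"`, `"gamma"`, `"lognormal"`, `"dirichlet"`,
#'   `"fixed"`.
#' @param rel_se Relative standard error (sd / mean), required for beta,
#'   gamma and lognormal. Default 0.2.
#' @param ess Effective sample size for dirichlet.
#' @return A list of class `"dist_spec"`.
#' @export
#' @examples
#' dist_spec("beta", rel_se = 0.2)
#' dist_spec("dirichlet", ess = 506)
dist_spec <- function(family = c("beta", "gamma", "lognormal", "dirichlet",
                                 "fixed"),
                      rel_se = 0.2, ess = NULL) {
  family <- match.arg(family)
  if (family %in% c("beta", "gamma", "lognormal")) {
    if (!is.numeric(rel_se) || length(rel_se) != 1L || rel_se <= 0) {
      stop("dist_spec: rel_se must be a positive number for family '",
           family, "'")
    }
  }
  if (family == "dirichlet") {
    if (is.null(ess) || !is.numeric(ess) || ess <= 0) {
      stop("dist_spec: dirichlet requires a positive effective sample size")
    }
  }
  structure(list(family = family,
                 rel_se = if (family %in% c("beta", "gamma", "lognormal"))
                   rel_se else NULL,
                 ess = if (family == "dirichlet") as.numeric(ess) else NULL),
            class = "dist_spec")
}

#' Default model parameter set
#'
#' Returns the packaged base-case parameter table for the two-phase Markov
#' model. Values printed in the source data are used directly: the acute EVT
#' procedure cost (15,510 USD), the cost of intravenous alteplase
#' (7,421 USD), per-arm IVT rates (0.621 / 0.558 / 0.585 for eTICI 2c3 /
#' EVT-accessible 2b / EVT-non-accessible 2b) and the cohort start age
#' (70 years). All remaining inputs — per-arm 90-day mRS distributions,
#' utility weights, recurrence and excess-mortality parameters, long-term
#' and societal costs — are synthetic defaults chosen from standard
#' stroke cost-effectiveness conventions; they are plausible, internally
#' consistent stand-ins, not transcriptions of any trial supplement, so
#' absolute lifetime outcomes computed from them are illustrative rather
#' than a replication.
#'
#' @param seed Optional seed; the default set is deterministic and ignores
#'   it, but [generate_parameter_table()] uses it to jitter values.
#' @return An object of class `"parameter_set"`: a named list, see Details.
#' @details Fields:
#' \describe{
#'   \item{mrs90_dist}{named list, arm -> probability vector over mRS 0-6
#'     (mRS 6 = dead at 90 days).}
#'   \item{utility}{QALY weight per year for mRS 0-5, in \[0,1\].}
#'   \item{p_recurrent_annual, case_fatality_recurrent}{annual recurrent
#'     stroke probability and its case fatality.}
#'   \item{post_stroke_mrs}{mRS distribution after a non-fatal recurrent
#'     stroke, truncated at run time to states at least as bad as the
#'     current one (see [recurrence_matrix()]).}
#'   \item{mortality_hr}{hazard ratio on the life-table annual death
#'     probability for mRS 0-5.}
#'   \item{cost_evt, cost_ivt, cost_acute_other}{acute-phase costs, USD.}
#'   \item{p_ivt}{per-arm probability of intravenous alteplase.}
#'   \item{cost_annual_care}{annual direct healthcare cost per mRS state.}
#'   \item{cost_informal_care}{annual uncompensated informal-care cost per
#'     mRS state (societal perspective).}
#'   \item{employment_rate}{employment probability per 5-year age band
#'     (named by band start age).}
#'   \item{return_to_work}{probability of returning to work per mRS state.}
#'   \item{annual_wage, retirement_age, start_age}{human-capital inputs.}
#'   \item{inflation_factor, currency_year}{cost indexing (see
#'     [load_parameter_set()]).}
#'   \item{psa}{named list of [dist_spec()] per parameter.}
#' }
#' @export
default_parameter_set <- function(seed = NULL) {
  mrs_names <- paste0("mrs", 0:6)
  mk <- function(x) stats::setNames(x, mrs_names)
  ps <- list(
    mrs90_dist = list(
      etici2c3               = mk(c(0.22, 0.20, 0.13, 0.13, 0.11, 0.07, 0.14)),
      etici2b_accessible     = mk(c(0.10, 0.13, 0.12, 0.16, 0.18, 0.11, 0.20)),
      etici2b_non_accessible = mk(c(0.17, 0.18, 0.13, 0.14, 0.14, 0.08, 0.16)),
      etici2c3_single_pass   = mk(c(0.23, 0.20, 0.13, 0.13, 0.11, 0.06, 0.14)),
      etici2c3_multi_pass    = mk(c(0.21, 0.20, 0.14, 0.13, 0.11, 0.07, 0.14)),
      other                  = mk(c(0.06, 0.10, 0.11, 0.16, 0.20, 0.14, 0.23))
    ),
    utility = stats::setNames(c(0.95, 0.93, 0.83, 0.62, 0.42, 0.11),
                              paste0("mrs", 0:5)),
    p_recurrent_annual = 0.04,
    case_fatality_recurrent = 0.15,
    post_stroke_mrs = stats::setNames(c(0.10, 0.15, 0.15, 0.20, 0.25, 0.15),
                                      paste0("mrs", 0:5)),
    mortality_hr = stats::setNames(c(1.54, 1.52, 2.17, 3.18, 4.55, 6.55),
                                   paste0("mrs", 0:5)),
    cost_evt = 15510,
    cost_ivt = 7421,
    cost_acute_other = 21500,
    p_ivt = c(etici2c3 = 0.621, etici2b_accessible = 0.558,
              etici2b_non_accessible = 0.585,
              etici2c3_single_pass = 0.621, etici2c3_multi_pass = 0.621,
              other = 0.59),
    cost_annual_care = stats::setNames(
      c(2100, 4200, 6600, 14500, 28500, 46000), paste0("mrs", 0:5)),
    cost_informal_care = stats::setNames(
      c(0, 1600, 5200, 12500, 26000, 36000), paste0("mrs", 0:5)),
    employment_rate = c("45" = 0.81, "50" = 0.79, "55" = 0.72,
                        "60" = 0.56, "65" = 0.32),
    return_to_work = stats::setNames(c(0.88, 0.72, 0.50, 0.20, 0.05, 0),
                                     paste0("mrs", 0:5)),
    annual_wage = 54000,
    retirement_age = 67,
    start_age = 70,
    inflation_factor = 1,
    currency_year = 2021,
    psa = list(
      mrs90_dist = list(
        etici2c3               = dist_spec("dirichlet", ess = 506),
        etici2b_accessible     = dist_spec("dirichlet", ess = 147),
        etici2b_non_accessible = dist_spec("dirichlet", ess = 296),
        etici2c3_single_pass   = dist_spec("dirichlet", ess = 300),
        etici2c3_multi_pass    = dist_spec("dirichlet", ess = 206),
        other                  = dist_spec("dirichlet", ess = 149)
      ),
      utility = dist_spec("beta", rel_se = 0.1),
      p_recurrent_annual = dist_spec("beta", rel_se = 0.2),
      case_fatality_recurrent = dist_spec("beta", rel_se = 0.2),
      post_stroke_mrs = dist_spec("dirichlet", ess = 500),
      mortality_hr = dist_spec("lognormal", rel_se = 0.2),
      cost_evt = dist_spec("gamma", rel_se = 0.2),
      cost_ivt = dist_spec("gamma", rel_se = 0.2),
      cost_acute_other = dist_spec("gamma", rel_se = 0.2),
      p_ivt = dist_spec("beta", rel_se = 0.1),
      cost_annual_care = dist_spec("gamma", rel_se = 0.2),
      cost_informal_care = dist_spec("gamma", rel_se = 0.2),
      return_to_work = dist_spec("beta", rel_se = 0.2),
      employment_rate = dist_spec("fixed"),
      annual_wage = dist_spec("gamma", rel_se = 0.1)
    )
  )
  structure(ps, class = "parameter_set")
}

#' Generate a complete synthetic parameter table
#'
#' Produces a valid [default_parameter_set()] whose continuous inputs are
#' jittered around the defaults (multiplicative lognormal noise for costs,
#' Dirichlet resampling for probability vectors), preserving the structural
#' constraints the validator checks: utilities non-increasing in mRS, care
#' costs non-decreasing, all costs non-negative. Useful for property-style
#' testing over many parameter sets.
#'
#' @param seed Integer seed; identical seeds give identical tables.
#' @param jitter Relative spread of the multiplicative noise (0 = defaults).
#' @param schema_defaults Base parameter set to perturb.
#' @return A `"parameter_set"` object passing [validate_parameter_set()]
#'   with no errors.
#' @export
generate_parameter_table <- function(seed = 1L, jitter = 0.1,
                                     schema_defaults = default_parameter_set()) {
  ps <- schema_defaults
  required <- setdiff(names(default_parameter_set()), "psa")
  missing <- setdiff(required, names(ps))
  if (length(missing)) {
    stop("generate_parameter_table: missing required parameters: ",
         paste(missing, collapse = ", "))
  }
  if (jitter == 0) return(ps)
  with_seed(seed, {
    jig <- function(x) x * stats::rlnorm(length(x), -jitter^2 / 2, jitter)
    for (arm in names(ps$mrs90_dist)) {
      a <- ps$mrs90_dist[[arm]] * 200
      g <- stats::rgamma(length(a), shape = pmax(a, 1e-8))
      ps$mrs90_dist[[arm]][] <- g / sum(g)
    }
    # jitter a base utility level, keep the monotone profile
    ps$utility <- pmin(pmax(ps$utility * stats::rlnorm(1, 0, jitter), 0), 1)
    ps$utility <- stats::setNames(rev(cummax(rev(ps$utility))),
                                  names(ps$utility))
    ps$p_recurrent_annual <- min(jig(ps$p_recurrent_annual), 0.5)
    ps$case_fatality_recurrent <- min(jig(ps$case_fatality_recurrent), 0.9)
    ps$mortality_hr <- pmax(jig(ps$mortality_hr), 1)
    ps$mortality_hr <- stats::setNames(cummax(ps$mortality_hr),
                                       names(ps$mortality_hr))
    for (f in c("cost_evt", "cost_ivt", "cost_acute_other", "annual_wage")) {
      ps[[f]] <- jig(ps[[f]])
    }
    ps$cost_annual_care <- stats::setNames(cummax(jig(ps$cost_annual_care)),
                                           names(ps$cost_annual_care))
    ps$cost_informal_care <- stats::setNames(
      cummax(jig(ps$cost_informal_care)), names(ps$cost_informal_care))
    ps$p_ivt <- pmin(pmax(jig(ps$p_ivt), 0), 1)
    ps
  })
}

#' Recurrence deterioration matrix
#'
#' On a non-fatal recurrent stroke the patient's new mRS grade is drawn from
#' the post-stroke mRS distribution truncated to grades at least as bad as
#' the current one and renormalised, implementing "deteriorate to a worse
#' (or equal) health state" without inventing per-state transition data.
#'
#' @param ps A `"parameter_set"`.
#' @return A 6 x 6 row-stochastic matrix; rows index the current mRS grade
#'   0-5, columns the grade after a non-fatal recurrence.
#' @export
recurrence_matrix <- function(ps) {
  base <- ps$post_stroke_mrs
  W <- matrix(0, N_LIVING, N_LIVING,
              dimnames = list(paste0("mrs", 0:5), paste0("mrs", 0:5)))
  for (s in seq_len(N_LIVING)) {
    tail <- base
    tail[seq_len(s - 1)] <- 0
    tot <- sum(tail)
    W[s, ] <- if (tot > 0) tail / tot else c(rep(0, N_LIVING - 1), 1)
  }
  W
}

#' Inflation adjustment of a cost
#'
#' Multiplies a cost by an inflation factor (e.g. the medical-care component
#' of the consumer price index between the source year and the index year).
#'
#' @param cost Non-negative cost in USD.
#' @param factor Positive multiplier to the index year.
#' @return `cost * factor`.
#' @export
#' @examples
#' adjust_for_inflation(15510, 1.0384)
adjust_for_inflation <- function(cost, factor) {
  if (any(!is.finite(cost)) || any(cost < 0)) {
    stop("adjust_for_inflation: cost must be non-negative")
  }
  if (!is.finite(factor) || factor <= 0) {
    stop("adjust_for_inflation: factor must be positive")
  }
  cost * factor
}

# internal: employment probability at a given age (5-year bands keyed by
# band start age; zero at or beyond retirement age)
employment_rate_at <- function(ps, age) {
  if (age >= ps$retirement_age) return(0)
  starts <- as.numeric(names(ps$employment_rate))
  if (age < min(starts)) return(unname(ps$employment_rate[1L]))
  band <- max(which(starts <= age))
  unname(ps$employment_rate[band])
}

#' Validate a parameter set
#'
#' Checks the structural invariants of a `"parameter_set"` and returns a
#' data frame of findings, one row per violation, with severity `"error"`
#' (the model cannot run correctly) or `"warning"` (unusual but admissible,
#' e.g. non-monotone utilities). The input is never modified; an empty
#' result means the set is clean.
#'
#' @param ps A `"parameter_set"`.
#' @return data.frame with columns `level`, `field`, `message`.
#' @export
validate_parameter_set <- function(ps) {
  findings <- list()
  add <- function(level, field, message) {
    findings[[length(findings) + 1L]] <<-
      data.frame(level = level, field = field, message = message,
                 stringsAsFactors = FALSE)
  }
  req <- setdiff(names(default_parameter_set()), "psa")
  missing <- setdiff(req, names(ps))
  for (m in missing) add("error", m, "required parameter missing")
  if (length(missing) == 0L) {
    for (arm in names(ps$mrs90_dist)) {
      v <- ps$mrs90_dist[[arm]]
      if (length(v) != 7L || any(v < 0) || any(!is.finite(v))) {
        add("error", paste0("mrs90_dist.", arm),
            "must be 7 non-negative finite probabilities (mRS 0-6)")
      } else if (abs(sum(v) - 1) > 1e-9) {
        add("error", paste0("mrs90_dist.", arm),
            sprintf("probabilities sum to %.6f, not 1", sum(v)))
      }
    }
    if (any(ps$utility < 0 | ps$utility > 1)) {
      add("error", "utility", "utilities must lie in [0, 1]")
    } else if (is.unsorted(rev(ps$utility))) {
      add("warning", "utility", "utilities are not non-increasing in mRS")
    }
    for (f in c("p_recurrent_annual", "case_fatality_recurrent")) {
      if (ps[[f]] < 0 || ps[[f]] > 1) {
        add("error", f, "probability outside [0, 1]")
      }
    }
    check_prob <- try(check_prob_vector(ps$post_stroke_mrs,
                                        "post_stroke_mrs"), silent = TRUE)
    if (inherits(check_prob, "try-error")) {
      add("error", "post_stroke_mrs", "not a probability vector")
    }
    if (any(ps$mortality_hr < 1)) {
      add("warning", "mortality_hr",
          "hazard ratio below 1 (protective relative to general population)")
    }
    if (any(ps$mortality_hr < 0)) add("error", "mortality_hr", "negative")
    for (f in c("cost_evt", "cost_ivt", "cost_acute_other", "annual_wage")) {
      if (ps[[f]] < 0) add("error", f, "cost must be non-negative")
    }
    for (f in c("cost_annual_care", "cost_informal_care")) {
      bad <- which(ps[[f]] < 0)
      for (b in bad) {
        add("error", sprintf("%s[%d]", f, b - 1L), "cost must be non-negative")
      }
    }
    if (any(ps$p_ivt < 0 | ps$p_ivt > 1)) {
      add("error", "p_ivt", "probability outside [0, 1]")
    }
    if (any(ps$employment_rate < 0 | ps$employment_rate > 1)) {
      add("error", "employment_rate", "probability outside [0, 1]")
    }
    if (any(ps$return_to_work < 0 | ps$return_to_work > 1)) {
      add("error", "return_to_work", "probability outside [0, 1]")
    }
    if (ps$inflation_factor <= 0) {
      add("error", "inflation_factor", "must be positive")
    }
    if (ps$start_age < 18 || ps$start_age > 99) {
      add("error", "start_age", "implausible cohort start age")
    }
  }
  if (length(findings) == 0L) {
    return(data.frame(level = character(), field = character(),
                      message = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, findings)
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("Model parameter set (", length(x$mrs90_dist), " arms)\n", sep = "")
  cat("  start age:", x$start_age, " currency year:", x$currency_year, "\n")
  cat("  acute costs: EVT", format(x$cost_evt, big.mark = ","),
      "+ IVT", format(x$cost_ivt, big.mark = ","),
      "+ other", format(x$cost_acute_other, big.mark = ","), "USD\n")
  cat("  utilities mRS0-5:", paste(format(x$utility), collapse = " "), "\n")
  f <- validate_parameter_set(x)
  if (nrow(f)) {
    cat("  findings:", sum(f$level == "error"), "error(s),",
        sum(f$level == "warning"), "warning(s)\n")
  } else cat("  findings: none\n")
  invisible(x)
}
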