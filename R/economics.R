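# Costing under healthcare and societal (human-capital) perspectives.
# The healthcare perspective counts direct medical spending only; the
# societal perspective adds informal (uncompensated) care, productivity
# lost while disabled, and foregone earnings after premature death.

#' Direct healthcare cost of one cycle in a health state
#'
#' @param state Health state (label or index 1-7); Dead accrues nothing.
#' @param ps A `"parameter_set"`.
#' @param cycle_length Cycle length in years.
#' @return Cost in USD, `cost_annual_care[state] * cycle_length`.
#' @export
cycle_healthcare_cost <- function(state, ps, cycle_length = 1) {
  s <- as_state_index(state)
  ifelse(s == DEAD, 0, ps$cost_annual_care[pmin(s, N_LIVING)] *
           cycle_length)
}

#' Informal care cost of one cycle in a health state
#'
#' Uncompensated care provided by family and friends, priced per mRS state
#' per year from the parameter table.
#'
#' @inheritParams cycle_healthcare_cost
#' @return Cost in USD; Dead accrues nothing.
#' @export
informal_care_cost <- function(state, ps, cycle_length = 1) {
  s <- as_state_index(state)
  ifelse(s == DEAD, 0, ps$cost_informal_care[pmin(s, N_LIVING)] *
           cycle_length)
}

#' Productivity loss of one cycle in a health state
#'
#' Human-capital valuation of work lost to stroke disability: the age
#' band's employment rate times the probability of *not* returning to work
#' at the patient's mRS grade times the annual wage, accrued only below the
#' retirement age. Dead states accrue nothing here; earnings foregone after
#' death are valued separately by [premature_death_loss()].
#'
#' @inheritParams cycle_healthcare_cost
#' @param age Age in years during the cycle.
#' @return Cost in USD.
#' @export
productivity_loss <- function(state, age, ps, cycle_length = 1) {
  s <- as_state_index(state)
  if (s == DEAD || age >= ps$retirement_age) return(0)
  unname(employment_rate_at(ps, age) * (1 - ps$return_to_work[[s]]) *
           ps$annual_wage * cycle_length)
}

#' Foregone earnings from premature death
#'
#' Discounted sum of expected earnings (employment rate x annual wage) from
#' the age at death to the retirement age; zero for deaths at or beyond
#' retirement. Attributed as a lump sum at the cycle of death.
#'
#' @param age_at_death Age in years at death.
#' @param ps A `"parameter_set"`.
#' @param discount_rate Annual discount rate applied to years after death.
#' @return Cost in USD; non-increasing in `age_at_death`.
#' @export
premature_death_loss <- function(age_at_death, ps, discount_rate = 0) {
  if (age_at_death >= ps$retirement_age) return(0)
  yrs <- seq.int(age_at_death, ps$retirement_age - 1L)
  emp <- vapply(yrs, function(a) employment_rate_at(ps, a), numeric(1))
  sum(emp * ps$annual_wage / (1 + discount_rate)^(yrs - age_at_death))
}

#' Acute-phase (first 90 days) cost components of a strategy arm
#'
#' Direct healthcare spending is the EVT procedure plus the arm's expected
#' intravenous alteplase cost plus other acute hospital costs; societal
#' components (informal care, productivity loss over the 3-month phase, and
#' foregone earnings of patients dead by 90 days) are weighted by the arm's
#' 90-day mRS distribution.
#'
#' @param arm Arm label (see [arm_labels()]).
#' @param ps A `"parameter_set"`.
#' @return List of class `"cost_components"`: `direct_healthcare`,
#'   `informal_care`, `productivity_loss`, `premature_death_loss`,
#'   `total_healthcare`, `total_societal`.
#' @export
#' @examples
#' acute_phase_cost("etici2c3", default_parameter_set())
acute_phase_cost <- function(arm, ps) {
  if (!arm %in% names(ps$mrs90_dist)) {
    stop("acute_phase_cost: unknown arm label: ", arm)
  }
  occ <- ps$mrs90_dist[[arm]]
  direct <- ps$cost_evt + ps$p_ivt[[arm]] * ps$cost_ivt + ps$cost_acute_other
  living <- seq_len(N_LIVING)
  informal <- sum(occ[living] * ps$cost_informal_care) * 0.25
  prod <- sum(occ[living] * vapply(living, function(s) {
    productivity_loss(s, ps$start_age, ps, 0.25)
  }, numeric(1)))
  death <- occ[[7L]] * premature_death_loss(ps$start_age, ps)
  structure(list(direct_healthcare = direct, informal_care = informal,
                 productivity_loss = prod, premature_death_loss = death,
                 total_healthcare = direct,
                 total_societal = direct + informal + prod + death),
            class = "cost_components")
}

#' @export
print.cost_components <- function(x, ...) {
  cat("Acute-phase cost components (USD)\n")
  for (f in c("direct_healthcare", "informal_care", "productivity_loss",
              "premature_death_loss")) {
    cat(sprintf("  %-22s %12.2f\n", f, x[[f]]))
  }
  cat(sprintf("  %-22s %12.2f\n", "societal total", x$total_societal))
  invisible(x)
}
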