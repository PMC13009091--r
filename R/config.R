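#' Run configuration for lifetime and PSA analyses
#'
#' Collects the run-level constants shared by all model evaluations.
#' Defaults follow US health-economic convention: 3%/year discounting of
#' both costs and QALYs, half-cycle correction of annual accruals, a
#' lifetime horizon to the end of the life table, and willingness-to-pay
#' thresholds of 50,000 and 100,000 USD/QALY.
#'
#' @param discount_rate Annual discount rate (0 disables discounting).
#' @param cycle_correction `"half_cycle"` (accruals use the mean of the
#'   state occupancy before and after each annual transition) or `"none"`
#'   (end-of-cycle occupancy, the exact expectation of a
#'   transition-at-cycle-start process).
#' @param max_age Optional cap on the modelled age; default is the life
#'   table's last age, where the death probability is 1, so the cohort is
#'   extinct at the horizon.
#' @param wtp_thresholds Willingness-to-pay thresholds, USD per QALY.
#' @param n_psa_draws Number of second-order Monte Carlo draws.
#' @param master_seed Seed governing all PSA randomness.
#' @param rounding_mode `"exact"` or `"paper"`-style rounding for
#'   population impact reports (see [population_impact()]).
#' @return List of class `"cea_config"`.
#' @export
cea_config <- function(discount_rate = 0.03,
                       cycle_correction = c("half_cycle", "none"),
                       max_age = NULL,
                       wtp_thresholds = c(50000, 100000),
                       n_psa_draws = 10000L,
                       master_seed = 1L,
                       rounding_mode = c("exact", "paper")) {
  cycle_correction <- match.arg(cycle_correction)
  rounding_mode <- match.arg(rounding_mode)
  if (any(wtp_thresholds <= 0)) stop("cea_config: WTP thresholds must be > 0")
  if (n_psa_draws < 1L) stop("cea_config: n_psa_draws must be >= 1")
  if (discount_rate < 0) stop("cea_config: discount_rate must be >= 0")
  structure(list(discount_rate = discount_rate,
                 cycle_correction = cycle_correction,
                 max_age = max_age,
                 wtp_thresholds = wtp_thresholds,
                 n_psa_draws = as.integer(n_psa_draws),
                 master_seed = as.integer(master_seed),
                 rounding_mode = rounding_mode),
            class = "cea_config")
}
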