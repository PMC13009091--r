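# Two-phase cohort model: a 3-month short-run phase that lands the cohort
# on its 90-day mRS distribution, then annual Markov cycles with recurrent
# stroke, functional deterioration and age-dependent background mortality
# until cohort extinction at the end of the life table.

#' Annual transition matrix of the long-run model
#'
#' For each living mRS state the three competing events of a cycle are
#' combined multiplicatively (independence within the cycle):
#' death `P(D) = 1 - (1 - qx * hr_s) * (1 - p_rec * cf)` where `qx` is the
#' life-table annual death probability, `hr_s` the state's mortality hazard
#' ratio (`qx * hr_s` capped at 1), `p_rec` the annual recurrent-stroke
#' probability and `cf` its case fatality; deterioration to a strictly
#' worse state `s'` among survivors of background mortality,
#' `P(s -> s') = (1 - qx * hr_s) * p_rec * (1 - cf) * W(s, s')` with `W`
#' the truncated recurrence matrix ([recurrence_matrix()]); and remaining
#' in state with the residual probability (which also absorbs non-fatal
#' recurrences that leave the grade unchanged). Conditioning the
#' deterioration flow on surviving the cycle keeps every row feasible up
#' to the terminal age, where `qx = 1` sends all living states to Dead
#' with probability 1. Dead is absorbing.
#'
#' @param ps A `"parameter_set"`.
#' @param age Age in years (looked up in the life table, clamped to its
#'   range).
#' @param life_table data.frame `age`, `qx` (default
#'   [generate_life_table()]).
#' @param W Optional precomputed recurrence matrix.
#' @return 7 x 7 row-stochastic matrix over [health_states()].
#' @export
build_transition_matrix <- function(ps, age,
                                    life_table = generate_life_table(),
                                    W = recurrence_matrix(ps)) {
  qx <- qx_at(life_table, age)
  p_rec <- ps$p_recurrent_annual
  cf <- ps$case_fatality_recurrent
  M <- matrix(0, N_STATES, N_STATES,
              dimnames = list(health_states(), health_states()))
  for (s in seq_len(N_LIVING)) {
    qd <- min(qx * ps$mortality_hr[s], 1)
    p_death <- 1 - (1 - qd) * (1 - p_rec * cf)
    worse <- rep(0, N_LIVING)
    if (s < N_LIVING) {
      worse[(s + 1):N_LIVING] <- (1 - qd) * p_rec * (1 - cf) *
        W[s, (s + 1):N_LIVING]
    }
    stay <- 1 - p_death - sum(worse)
    if (stay < -1e-12) {
      stop(sprintf(paste0("build_transition_matrix: negative stay ",
                          "probability (%.4g) for state %s at age %s; ",
                          "parameter combination infeasible"),
                   stay, health_states()[s], age))
    }
    M[s, ] <- c(worse, p_death)
    M[s, s] <- max(stay, 0)
  }
  M[DEAD, DEAD] <- 1
  M
}

# internal: list of transition matrices for cycles 1..n (ages start..)
build_matrix_sequence <- function(ps, start_age, n_cycles, life_table) {
  W <- recurrence_matrix(ps)
  lapply(seq_len(n_cycles), function(t) {
    build_transition_matrix(ps, start_age + t - 1L, life_table, W)
  })
}

#' Short-run (first 90 days) phase of a strategy arm
#'
#' Collapses the acute phase to the arm's 90-day mRS distribution (mRS 6
#' maps to Dead), accruing a quarter-year of utility over surviving states
#' and the acute cost components.
#'
#' @param arm Arm label resolving in `ps$mrs90_dist`.
#' @param ps A `"parameter_set"`.
#' @return List: `state` (probability vector over the 7 health states),
#'   `qalys`, `cost_healthcare`, `cost_societal`, `components`
#'   (the [acute_phase_cost()] breakdown).
#' @export
run_short_run <- function(arm, ps) {
  if (!arm %in% names(ps$mrs90_dist)) {
    stop("run_short_run: unknown arm label: ", arm)
  }
  occ <- stats::setNames(as.numeric(ps$mrs90_dist[[arm]]), health_states())
  check_prob_vector(occ, paste0("mrs90_dist.", arm))
  living <- seq_len(N_LIVING)
  qalys <- 0.25 * sum(occ[living] * ps$utility)
  comp <- acute_phase_cost(arm, ps)
  care <- 0.25 * sum(occ[living] * ps$cost_annual_care)
  list(state = occ, qalys = qalys,
       cost_healthcare = comp$direct_healthcare + care,
       cost_societal = comp$total_societal + care,
       components = comp)
}

#' Long-run annual Markov phase
#'
#' Iterates the cohort distribution through annual cycles from the 90-day
#' state, accruing (discounted and undiscounted) QALYs, life-years and
#' costs per perspective. Cycle `t` covers ages `start_age + t - 1` and is
#' discounted by `(1 + discount_rate)^-t`. Accruals use end-of-cycle
#' occupancy (`cycle_correction = "none"`) or the mean of start and end
#' occupancy (`"half_cycle"`, the default). Earnings foregone through death
#' enter as a lump sum ([premature_death_loss()]) against the cohort's
#' incremental deaths each cycle.
#'
#' @param start Probability vector over the 7 health states at cycle 0.
#' @param start_age Age at model start, years.
#' @param ps A `"parameter_set"`.
#' @param life_table data.frame `age`, `qx`.
#' @param discount_rate Annual discount rate.
#' @param horizon Optional maximum number of annual cycles; default runs to
#'   the life-table maximum age.
#' @param cycle_correction `"half_cycle"` or `"none"`.
#' @param matrices Optional precomputed list of transition matrices (one
#'   per cycle), e.g. shared across arms in a PSA draw.
#' @return List with the Markov `trace` (data.frame: cycle, age, the 7
#'   occupancy columns, per-cycle and cumulative discounted/undiscounted
#'   QALYs and costs per perspective, survival) and scalar totals
#'   `qalys_disc`, `qalys`, `cost_hc_disc`, `cost_soc_disc`, `life_years`.
#' @export
run_long_run <- function(start, start_age, ps,
                         life_table = generate_life_table(),
                         discount_rate = 0.03, horizon = NULL,
                         cycle_correction = c("half_cycle", "none"),
                         matrices = NULL) {
  cycle_correction <- match.arg(cycle_correction)
  check_prob_vector(start, "start distribution")
  max_age <- max(life_table$age)
  # horizon, when given, may extend past the table: qx is clamped to the
  # last row (normally 1, guaranteeing extinction)
  n_cycles <- if (is.null(horizon)) {
    max(max_age - start_age + 1L, 1L)
  } else as.integer(horizon)
  if (is.null(matrices)) {
    matrices <- build_matrix_sequence(ps, start_age, n_cycles, life_table)
  }
  living <- seq_len(N_LIVING)
  u <- as.numeric(ps$utility)
  care <- as.numeric(ps$cost_annual_care)
  informal <- as.numeric(ps$cost_informal_care)
  occ <- as.numeric(start)
  rows <- vector("list", n_cycles)
  tot <- c(qalys = 0, qalys_disc = 0, hc = 0, hc_disc = 0, soc = 0,
           soc_disc = 0, ly = 0)
  for (t in seq_len(n_cycles)) {
    age_t <- start_age + t - 1L
    occ_new <- as.numeric(occ %*% matrices[[t]])
    occ_eff <- if (cycle_correction == "half_cycle") {
      (occ + occ_new) / 2
    } else occ_new
    prod_vec <- if (age_t >= ps$retirement_age) rep(0, N_LIVING) else
      employment_rate_at(ps, age_t) * (1 - as.numeric(ps$return_to_work)) *
      ps$annual_wage
    q_cyc <- sum(occ_eff[living] * u)
    ly_cyc <- sum(occ_eff[living])
    hc_cyc <- sum(occ_eff[living] * care)
    new_dead <- occ_new[DEAD] - occ[DEAD]
    soc_cyc <- hc_cyc + sum(occ_eff[living] * informal) +
      sum(occ_eff[living] * prod_vec) +
      new_dead * premature_death_loss(age_t, ps, discount_rate)
    disc <- (1 + discount_rate)^(-t)
    tot <- tot + c(q_cyc, q_cyc * disc, hc_cyc, hc_cyc * disc,
                   soc_cyc, soc_cyc * disc, ly_cyc)
    rows[[t]] <- c(cycle = t, age = age_t, occ_new,
                   qalys = q_cyc, qalys_disc = q_cyc * disc,
                   cost_hc = hc_cyc, cost_hc_disc = hc_cyc * disc,
                   cost_soc = soc_cyc, cost_soc_disc = soc_cyc * disc,
                   survival = 1 - occ_new[DEAD])
    occ <- occ_new
    if (occ[DEAD] >= 1 - 1e-14) {
      rows <- rows[seq_len(t)]
      break
    }
  }
  trace <- as.data.frame(do.call(rbind, rows))
  names(trace)[3:9] <- health_states()
  trace$cum_qalys_disc <- cumsum(trace$qalys_disc)
  trace$cum_cost_hc_disc <- cumsum(trace$cost_hc_disc)
  trace$cum_cost_soc_disc <- cumsum(trace$cost_soc_disc)
  list(trace = trace,
       qalys = unname(tot["qalys"]), qalys_disc = unname(tot["qalys_disc"]),
       cost_hc_disc = unname(tot["hc_disc"]),
       cost_soc_disc = unname(tot["soc_disc"]),
       life_years = unname(tot["ly"]))
}

#' Lifetime outcome of a strategy arm
#'
#' Composes the short-run 90-day phase and the long-run annual Markov phase
#' into cumulative discounted lifetime QALYs, life-years and costs per
#' perspective. Deterministic for fixed inputs.
#'
#' @param arm Arm label (see [arm_labels()]).
#' @param ps A `"parameter_set"`.
#' @param life_table data.frame `age`, `qx`.
#' @param config A [cea_config()].
#' @param matrices Optional precomputed transition-matrix list.
#' @return Object of class `"lifetime_outcome"`: `arm`, `qalys`,
#'   `cost_healthcare`, `cost_societal` (discounted totals, USD),
#'   `life_years`, `acute` (short-run piece), `trace` (long-run Markov
#'   trace), `settings`.
#' @export
#' @examples
#' ps <- default_parameter_set()
#' run_lifetime("etici2c3", ps)
run_lifetime <- function(arm, ps, life_table = generate_life_table(),
                         config = cea_config(), matrices = NULL) {
  if (!is.null(config$max_age)) {
    life_table <- life_table[life_table$age <= config$max_age, , drop = FALSE]
    life_table$qx[nrow(life_table)] <- 1
  }
  short <- run_short_run(arm, ps)
  long <- run_long_run(short$state, ps$start_age, ps, life_table,
                       config$discount_rate,
                       cycle_correction = config$cycle_correction,
                       matrices = matrices)
  structure(list(
    arm = arm,
    qalys = short$qalys + long$qalys_disc,
    cost_healthcare = short$cost_healthcare + long$cost_hc_disc,
    cost_societal = short$cost_societal + long$cost_soc_disc,
    life_years = 0.25 * (1 - short$state[[DEAD]]) + long$life_years,
    acute = short, trace = long$trace,
    settings = list(discount_rate = config$discount_rate,
                    cycle_correction = config$cycle_correction,
                    start_age = ps$start_age,
                    max_age = max(life_table$age))),
    class = "lifetime_outcome")
}

#' @export
print.lifetime_outcome <- function(x, ...) {
  cat("Lifetime outcome -", x$arm, "\n")
  cat(sprintf("  QALYs (discounted)          %10.3f\n", x$qalys))
  cat(sprintf("  life-years                  %10.3f\n", x$life_years))
  cat(sprintf("  cost, healthcare (USD)      %10.0f\n", x$cost_healthcare))
  cat(sprintf("  cost, societal (USD)        %10.0f\n", x$cost_societal))
  cat(sprintf("  discount %.1f%%/yr, %s correction, ages %d-%d\n",
              100 * x$settings$discount_rate, x$settings$cycle_correction,
              x$settings$start_age, x$settings$max_age))
  invisible(x)
}

#' @export
plot.lifetime_outcome <- function(x, ...) {
  tr <- x$trace
  graphics::matplot(tr$age, as.matrix(tr[, health_states()]), type = "l",
                    lty = 1, xlab = "Age (years)", ylab = "State occupancy",
                    main = paste("Markov trace -", x$arm), ...)
  graphics::legend("right", legend = health_states(), col = 1:7, lty = 1,
                   cex = 0.8)
  invisible(x)
}

#' Individual-level microsimulation oracle
#'
#' Brute-force cross-check of the cohort (matrix) model: simulates
#' `n_patients` individual trajectories by sampling the 90-day state and
#' each annual transition, accruing QALYs and costs with the same
#' conventions as [run_lifetime()]. Means converge to the cohort model's
#' expectations; standard errors quantify the Monte Carlo noise.
#'
#' @inheritParams run_lifetime
#' @param n_patients Number of simulated patients.
#' @param seed Integer seed (explicit; identical seed, identical result).
#' @return List: `qalys`, `cost_healthcare`, `cost_societal`, `life_years`
#'   (means), `se` (named standard errors), `n_patients`.
#' @export
microsim_oracle <- function(arm, ps, life_table = generate_life_table(),
                            config = cea_config(), n_patients = 10000L,
                            seed = 1L) {
  if (n_patients < 1L) stop("microsim_oracle: n_patients must be >= 1")
  if (!is.null(config$max_age)) {
    life_table <- life_table[life_table$age <= config$max_age, , drop = FALSE]
    life_table$qx[nrow(life_table)] <- 1
  }
  half <- config$cycle_correction == "half_cycle"
  r <- config$discount_rate
  start_age <- ps$start_age
  n_cycles <- max(max(life_table$age) - start_age + 1L, 1L)
  matrices <- build_matrix_sequence(ps, start_age, n_cycles, life_table)
  u <- c(as.numeric(ps$utility), 0)
  care <- c(as.numeric(ps$cost_annual_care), 0)
  informal <- c(as.numeric(ps$cost_informal_care), 0)
  with_seed(seed, {
    n <- as.integer(n_patients)
    state <- sample.int(7L, n, replace = TRUE,
                        prob = ps$mrs90_dist[[arm]])
    ivt <- stats::runif(n) < ps$p_ivt[[arm]]
    qaly <- 0.25 * u[state]
    direct0 <- ps$cost_evt + ivt * ps$cost_ivt + ps$cost_acute_other
    hc <- direct0 + 0.25 * care[state]
    pdl0 <- premature_death_loss(start_age, ps)
    soc <- hc + 0.25 * informal[state] +
      0.25 * vapply(pmin(state, 6L), function(s)
        productivity_loss(s, start_age, ps, 1), numeric(1)) *
        (state != 7L) +
      (state == 7L) * pdl0
    ly <- 0.25 * (state != 7L)
    for (t in seq_len(n_cycles)) {
      alive <- which(state != 7L)
      if (!length(alive)) break
      age_t <- start_age + t - 1L
      M <- matrices[[t]]
      new_state <- state
      for (s in unique(state[alive])) {
        idx <- alive[state[alive] == s]
        new_state[idx] <- sample.int(7L, length(idx), replace = TRUE,
                                     prob = M[s, ])
      }
      eff_u <- if (half) (u[state] + u[new_state]) / 2 else u[new_state]
      eff_care <- if (half) {
        (care[state] + care[new_state]) / 2
      } else care[new_state]
      eff_inf <- if (half) {
        (informal[state] + informal[new_state]) / 2
      } else informal[new_state]
      prod_rate <- if (age_t >= ps$retirement_age) rep(0, 7L) else
        c(employment_rate_at(ps, age_t) *
            (1 - as.numeric(ps$return_to_work)) * ps$annual_wage, 0)
      eff_prod <- if (half) {
        (prod_rate[state] + prod_rate[new_state]) / 2
      } else prod_rate[new_state]
      died <- (state != 7L) & (new_state == 7L)
      lump <- premature_death_loss(age_t, ps, r)
      disc <- (1 + r)^(-t)
      # dead-before-cycle patients accrue nothing: their eff_* are 0
      qaly <- qaly + eff_u * disc
      hc <- hc + eff_care * disc
      soc <- soc + (eff_care + eff_inf + eff_prod + died * lump) * disc
      ly <- ly + (if (half) ((state != 7L) + (new_state != 7L)) / 2
                  else (new_state != 7L))
      state <- new_state
    }
    se <- function(x) stats::sd(x) / sqrt(n)
    list(qalys = mean(qaly), cost_healthcare = mean(hc),
         cost_societal = mean(soc), life_years = mean(ly),
         se = c(qalys = se(qaly), cost_healthcare = se(hc),
                cost_societal = se(soc), life_years = se(ly)),
         n_patients = n)
  })
}
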