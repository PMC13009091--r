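# Shared fixtures: small parameter sets and degenerate life tables built
# in code so every test is self-contained.

# life table with constant annual death probability (not forced to 1 at
# the end, so horizons beyond the table keep the same hazard)
const_life_table <- function(qx, min_age = 70L, max_age = 80L) {
  data.frame(age = seq.int(min_age, max_age),
             qx = rep(qx, max_age - min_age + 1L))
}

# parameter set reduced to a single living start state with no recurrence
# and unit hazard ratio: the long-run phase is then a pure survival process
single_state_ps <- function(u = 0.75, state = 1L) {
  ps <- default_parameter_set()
  for (arm in names(ps$mrs90_dist)) {
    v <- rep(0, 7)
    v[state] <- 1
    ps$mrs90_dist[[arm]][] <- v
  }
  ps$utility[] <- 0
  ps$utility[state] <- u
  ps$p_recurrent_annual <- 0
  ps$case_fatality_recurrent <- 0
  ps$mortality_hr[] <- 1
  ps$cost_annual_care[] <- 0
  ps$cost_informal_care[] <- 0
  ps$annual_wage <- 0
  ps$cost_evt <- 0
  ps$cost_ivt <- 0
  ps$cost_acute_other <- 0
  ps
}

# a handful of randomized but valid parameter sets for property tests
random_parameter_sets <- function(seeds = 1:5, jitter = 0.15) {
  lapply(seeds, function(s) generate_parameter_table(seed = s,
                                                     jitter = jitter))
}
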