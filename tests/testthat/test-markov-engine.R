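test_that("short-run phase maps the 90-day distribution onto states", {
  ps <- single_state_ps(u = 0.8)
  # extinct cohort: all mass on mRS 6
  ps$mrs90_dist$etici2c3[] <- c(0, 0, 0, 0, 0, 0, 1)
  sr <- run_short_run("etici2c3", ps)
  expect_equal(sr$state[["Dead"]], 1)
  expect_equal(sr$qalys, 0)
  # zero utilities give zero acute QALYs regardless of distribution
  ps2 <- default_parameter_set()
  ps2$utility[] <- 0
  expect_equal(run_short_run("etici2b_accessible", ps2)$qalys, 0)
  # uniform over living states, graded utilities: 0.25 * mean(u)
  ps3 <- default_parameter_set()
  ps3$mrs90_dist$etici2c3[] <- c(rep(1 / 6, 6), 0)
  ps3$utility[] <- c(1.0, 0.9, 0.8, 0.6, 0.4, 0.2)
  expect_equal(run_short_run("etici2c3", ps3)$qalys, 0.1625)
  expect_error(run_short_run("nope", ps3), "unknown arm")
})

test_that("transition matrix limits: no events, terminal age, row sums", {
  ps <- default_parameter_set()
  ps$p_recurrent_annual <- 0
  ps$mortality_hr[] <- 1
  lt0 <- const_life_table(0)
  M <- build_transition_matrix(ps, 75, lt0)
  expect_equal(M, diag(7), ignore_attr = TRUE)
  lt1 <- const_life_table(1)
  M1 <- build_transition_matrix(default_parameter_set(), 75, lt1)
  expect_equal(unname(M1[1:6, 7]), rep(1, 6))
  # row-stochastic at every age of the synthetic life table
  lt <- generate_life_table()
  for (ps_i in random_parameter_sets(1:3)) {
    for (age in lt$age) {
      M <- build_transition_matrix(ps_i, age, lt)
      expect_true(all(abs(rowSums(M) - 1) < 1e-9))
      expect_true(all(M >= 0))
      expect_equal(unname(M[7, ]), c(rep(0, 6), 1))
    }
  }
})

test_that("long-run phase from an extinct cohort accrues nothing", {
  ps <- default_parameter_set()
  start <- c(rep(0, 6), 1)
  lr <- run_long_run(start, 70, ps, generate_life_table())
  expect_equal(lr$qalys_disc, 0)
  expect_equal(lr$cost_hc_disc, 0)
  expect_equal(lr$cost_soc_disc, 0)
  expect_true(all(lr$trace$survival == 0))
  expect_error(run_long_run(c(rep(0.2, 6), 0), 70, ps), "sum")
})

test_that("constant-hazard single-state QALYs match the geometric series", {
  p <- 0.2
  u <- 0.75
  ps <- single_state_ps(u = u)
  lt <- const_life_table(p)
  start <- c(1, rep(0, 6))
  lr <- run_long_run(start, 70, ps, lt, discount_rate = 0,
                     horizon = 1000, cycle_correction = "none")
  expect_equal(lr$qalys, u * (1 - p) / p, tolerance = 1e-6 / (u * (1 - p) / p))
  # half-cycle correction adds half the first-cycle deaths' utility:
  # sum u * ((1-p)^(t-1) + (1-p)^t)/2 = u * (1 - p/2)/p
  lr2 <- run_long_run(start, 70, ps, lt, discount_rate = 0,
                      horizon = 1000, cycle_correction = "half_cycle")
  expect_equal(lr2$qalys, u * (1 - p / 2) / p,
               tolerance = 1e-6)
})

test_that("extreme discounting leaves only the first cycle", {
  ps <- single_state_ps(u = 1)
  lt <- const_life_table(0.1)
  start <- c(1, rep(0, 6))
  lr <- run_long_run(start, 70, ps, lt, discount_rate = 1e6, horizon = 50,
                     cycle_correction = "none")
  # cycles beyond the first are suppressed by a further factor of 1e-6
  expect_equal(lr$qalys_disc, lr$trace$qalys_disc[1L], tolerance = 1e-5)
})

test_that("probability is conserved and death absorbing on random sets", {
  lt <- generate_life_table()
  for (ps in random_parameter_sets(1:5)) {
    o <- run_lifetime("etici2b_non_accessible", ps, lt)
    occ <- as.matrix(o$trace[, health_states()])
    expect_true(all(abs(rowSums(occ) - 1) < 1e-9))
    expect_true(all(diff(o$trace$Dead) >= -1e-12))
    expect_true(all(diff(o$trace$survival) <= 1e-12))
    expect_true(all(diff(o$trace$cum_qalys_disc) >= -1e-12))
    expect_true(all(diff(o$trace$cum_cost_hc_disc) >= -1e-12))
    # cohort extinct at the end of the life table
    expect_lt(o$trace$survival[nrow(o$trace)], 1e-12)
    expect_lte(o$qalys, o$life_years * max(ps$utility))
    expect_gte(o$cost_healthcare, o$acute$cost_healthcare)
  }
})

test_that("QALYs rise with utilities and fall with mortality", {
  lt <- generate_life_table()
  ps <- default_parameter_set()
  base <- run_lifetime("etici2c3", ps, lt)
  up <- ps
  up$utility[["mrs4"]] <- min(up$utility[["mrs4"]] + 0.2, 1)
  expect_gte(run_lifetime("etici2c3", up, lt)$qalys, base$qalys)
  worse <- ps
  worse$mortality_hr[] <- worse$mortality_hr * 1.5
  expect_lte(run_lifetime("etici2c3", worse, lt)$life_years,
             base$life_years)
})

test_that("first-order dominant 90-day distributions yield more QALYs", {
  lt <- generate_life_table()
  ps <- default_parameter_set()
  better <- ps
  # shift 10% of mass from mRS5 and Dead to mRS0/1
  d <- ps$mrs90_dist$etici2b_accessible
  shift <- 0.05
  d[c("mrs5", "mrs6")] <- d[c("mrs5", "mrs6")] - shift
  d[c("mrs0", "mrs1")] <- d[c("mrs0", "mrs1")] + shift
  better$mrs90_dist$etici2b_accessible <- d
  expect_gte(run_lifetime("etici2b_accessible", better, lt)$qalys,
             run_lifetime("etici2b_accessible", ps, lt)$qalys)
})

test_that("cohort model agrees with the microsimulation oracle", {
  lt <- generate_life_table()
  ps <- default_parameter_set()
  for (mode in c("half_cycle", "none")) {
    cfg <- cea_config(cycle_correction = mode)
    a <- run_lifetime("etici2c3", ps, lt, cfg)
    m <- microsim_oracle("etici2c3", ps, lt, cfg, n_patients = 20000L,
                         seed = 99L)
    expect_lt(abs(m$qalys - a$qalys), 3 * m$se[["qalys"]])
    expect_lt(abs(m$cost_healthcare - a$cost_healthcare),
              3 * m$se[["cost_healthcare"]])
    expect_lt(abs(m$cost_societal - a$cost_societal),
              3 * m$se[["cost_societal"]])
    expect_lt(abs(m$life_years - a$life_years), 3 * m$se[["life_years"]])
  }
})

test_that("microsimulation is deterministic and degenerates correctly", {
  lt <- generate_life_table()
  ps <- default_parameter_set()
  m1 <- microsim_oracle("etici2b_accessible", ps, lt, n_patients = 500L,
                        seed = 4L)
  m2 <- microsim_oracle("etici2b_accessible", ps, lt, n_patients = 500L,
                        seed = 4L)
  expect_identical(m1, m2)
  # no mortality, no recurrence, single state, certain IVT: variance 0
  ps0 <- single_state_ps(u = 1)
  ps0$p_ivt[] <- 1
  lt0 <- const_life_table(0, 70L, 79L)
  m <- microsim_oracle("etici2c3", ps0, lt0,
                       cea_config(discount_rate = 0,
                                  cycle_correction = "none"),
                       n_patients = 200L, seed = 1L)
  expect_equal(unname(m$se[["qalys"]]), 0)
  expect_equal(m$qalys, 0.25 + 10)   # 3 months + 10 whole years alive
})

test_that("lifetime outcome of an all-dead arm is acute costs only", {
  ps <- default_parameter_set()
  ps$mrs90_dist$etici2c3[] <- c(rep(0, 6), 1)
  o <- run_lifetime("etici2c3", ps, generate_life_table())
  expect_equal(o$qalys, 0)
  expect_equal(o$cost_healthcare, o$acute$components$direct_healthcare)
  expect_equal(o$life_years, 0)
})
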