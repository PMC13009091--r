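# minimal lifetime_outcome stub for comparison arithmetic
stub_outcome <- function(arm, qalys, hc, soc = hc) {
  structure(list(arm = arm, qalys = qalys, cost_healthcare = hc,
                 cost_societal = soc, life_years = qalys,
                 settings = list(discount_rate = 0.03,
                                 cycle_correction = "half_cycle",
                                 start_age = 70, max_age = 100)),
            class = "lifetime_outcome")
}

test_that("incremental analysis reproduces published table arithmetic", {
  a <- stub_outcome("etici2c3", 5.17, 154640, 185800)
  b <- stub_outcome("etici2b_accessible", 4.03, 160828, 195117)
  cmp <- compare_arms(a, b)
  expect_equal(cmp$delta_qalys, 1.14)
  expect_equal(cmp$healthcare$delta_cost, -6188)
  expect_equal(cmp$societal$delta_cost, -9317)
  expect_equal(cmp$healthcare$dominance, "intervention_dominant")
  expect_equal(cmp$societal$dominance, "intervention_dominant")
  expect_true(is.na(cmp$healthcare$icer))   # suppressed when dominant
  # single- vs multi-pass block: positive deltas, ICER defined
  sp <- stub_outcome("etici2c3_single_pass", 5.25, 154407)
  mp <- stub_outcome("etici2c3_multi_pass", 5.19, 149680)
  cmp2 <- compare_arms(sp, mp)
  expect_equal(cmp2$healthcare$delta_cost, 4727)
  expect_equal(cmp2$delta_qalys, 0.06)
  expect_equal(cmp2$healthcare$dominance, "icer_defined")
  expect_gt(cmp2$healthcare$icer, 0)
  expect_equal(cmp2$healthcare$icer, 4727 / 0.06)
})

test_that("identical outcomes are equivalent with undefined ICER", {
  a <- stub_outcome("etici2c3", 5, 100)
  b <- stub_outcome("etici2b_accessible", 5, 100)
  cmp <- compare_arms(a, b)
  expect_equal(cmp$healthcare$dominance, "equivalent")
  expect_true(is.na(cmp$healthcare$icer))
})

test_that("mismatched settings and identical arms are rejected", {
  a <- stub_outcome("etici2c3", 5, 100)
  b <- stub_outcome("etici2b_accessible", 4, 120)
  b$settings$discount_rate <- 0
  expect_error(compare_arms(a, b), "different settings")
  expect_error(compare_arms(a, a), "distinct")
})

test_that("dominance classification covers the sign quadrants exhaustively", {
  classes <- c("intervention_dominant", "comparator_dominant", "equivalent",
               "icer_defined")
  for (dq in c(-1, 0, 1)) {
    for (dc in c(-1, 0, 1)) {
      a <- stub_outcome("etici2c3", 5 + dq, 100 + dc, 100 + dc)
      b <- stub_outcome("etici2b_accessible", 5, 100, 100)
      got <- compare_arms(a, b)$healthcare$dominance
      expect_true(got %in% classes)
      want <- if (dq > 0 && dc < 0) "intervention_dominant"
      else if (dq < 0 && dc > 0) "comparator_dominant"
      else if (dq == 0 && dc == 0) "equivalent"
      else "icer_defined"
      expect_identical(got, want)
    }
  }
})

test_that("net monetary benefit transform and its NMB/ICER equivalence", {
  expect_equal(net_monetary_benefit(c(2, 50000), 0), -50000)
  expect_equal(net_monetary_benefit(c(2, 50000), 50000), 50000)
  o <- stub_outcome("etici2c3", 2, 50000, 70000)
  expect_equal(net_monetary_benefit(o, 50000), 50000)
  expect_equal(net_monetary_benefit(o, 50000, "societal"), 30000)
  expect_error(net_monetary_benefit(c(2, 1), -1), "lambda")
  # incremental NMB > 0 iff dominant, or positive dq with ICER < lambda,
  # or cheaper at equal effect
  lambda <- 50000
  for (dq in c(-0.5, 0, 0.5)) {
    for (dc in c(-10000, 0, 10000)) {
      inmb <- lambda * dq - dc
      dom <- dq > 0 && dc < 0
      icer_ok <- dq > 0 && dc >= 0 && dc / dq < lambda
      cheaper_equal <- dq == 0 && dc < 0
      loses <- dq < 0 && dc <= 0 && abs(dc) / abs(dq) > lambda
      expect_identical(inmb > 0, dom || icer_ok || cheaper_equal || loses)
    }
  }
})

test_that("a fully fixed PSA degenerates to the base case", {
  ps <- default_parameter_set()
  for (f in names(ps$psa)) {
    if (f == "mrs90_dist") {
      for (a in names(ps$psa$mrs90_dist)) {
        ps$psa$mrs90_dist[[a]] <- dist_spec("fixed")
      }
    } else ps$psa[[f]] <- dist_spec("fixed")
  }
  lt <- generate_life_table()
  cfg <- cea_config()
  s <- run_psa(ps, c("etici2c3", "etici2b_accessible"), n_draws = 5,
               master_seed = 1, cfg, lt)
  a <- run_lifetime("etici2c3", ps, lt, cfg)
  b <- run_lifetime("etici2b_accessible", ps, lt, cfg)
  expect_true(all(abs(s$inc_qalys - (a$qalys - b$qalys)) < 1e-12))
  expect_true(all(abs(s$inc_cost_healthcare -
                        (a$cost_healthcare - b$cost_healthcare)) < 1e-9))
  sc <- export_scatter(s)
  expect_equal(nrow(unique(sc)), 1L)
})

test_that("PSA is reproducible under the master seed", {
  ps <- default_parameter_set()
  s1 <- run_psa(ps, c("etici2c3", "etici2b_non_accessible"), n_draws = 20,
                master_seed = 123)
  s2 <- run_psa(ps, c("etici2c3", "etici2b_non_accessible"), n_draws = 20,
                master_seed = 123)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  s3 <- run_psa(ps, c("etici2c3", "etici2b_non_accessible"), n_draws = 20,
                master_seed = 124)
  expect_false(identical(as.data.frame(s1), as.data.frame(s3)))
  expect_error(run_psa(ps, c("etici2c3", "etici2c3")), "distinct")
})

test_that("a parameter without a distribution spec is reported by name", {
  ps <- default_parameter_set()
  ps$psa$cost_evt <- NULL
  expect_error(run_psa(ps, c("etici2c3", "etici2b_accessible"),
                       n_draws = 2, master_seed = 1),
               "cost_evt")
})

test_that("sampled parameter means match their distribution means", {
  ps <- default_parameter_set()
  n <- 2000L
  draws <- strokeCEA:::with_seed(5L, {
    vapply(seq_len(n), function(i) {
      psi <- sample_parameter_set(ps)
      c(psi$cost_evt, psi$p_recurrent_annual, psi$mrs90_dist$etici2c3[[1L]])
    }, numeric(3))
  })
  # gamma: mean 15510, rel SE 0.2
  se <- 0.2 * 15510 / sqrt(n)
  expect_lt(abs(mean(draws[1, ]) - 15510), 3 * se)
  # beta: mean 0.04
  se2 <- 0.2 * 0.04 / sqrt(n)
  expect_lt(abs(mean(draws[2, ]) - 0.04), 3 * se2)
  # dirichlet component: mean 0.22, sd sqrt(m(1-m)/(ess+1))
  se3 <- sqrt(0.22 * 0.78 / 507) / sqrt(n)
  expect_lt(abs(mean(draws[3, ]) - 0.22), 3 * se3)
})

test_that("acceptability is a brute-force count over draws", {
  s <- data.frame(draw = 1:4, inc_qalys = c(1, 1, -1, -1),
                  inc_cost_healthcare = c(-5, -5, 5, 5),
                  inc_cost_societal = c(-5, -5, 5, 5))
  class(s) <- c("cea_psa", "data.frame")
  r <- acceptability(s, 50000)
  expect_equal(r$fraction, 0.5)
  # all dominant draws: 1.0 at any lambda
  s2 <- s
  s2$inc_qalys <- abs(s2$inc_qalys)
  s2$inc_cost_healthcare <- -abs(s2$inc_cost_healthcare)
  expect_equal(acceptability(s2, 0)$fraction, 1.0)
  expect_equal(acceptability(s2, 1e6)$fraction, 1.0)
  # independent recount with a second NMB implementation
  ps <- default_parameter_set()
  samples <- run_psa(ps, c("etici2c3", "etici2b_non_accessible"),
                     n_draws = 100, master_seed = 9)
  for (l in c(50000, 100000)) {
    for (p in c("healthcare", "societal")) {
      dc <- if (p == "healthcare") samples$inc_cost_healthcare else
        samples$inc_cost_societal
      recount <- sum(samples$inc_qalys - dc / l > 0) / nrow(samples)
      expect_equal(acceptability(samples, l, p)$fraction, recount)
    }
  }
})

test_that("acceptability never falls as lambda rises when dq >= 0", {
  ps <- default_parameter_set()
  samples <- run_psa(ps, c("etici2c3", "etici2b_accessible"),
                     n_draws = 100, master_seed = 2)
  keep <- samples$inc_qalys >= 0
  s <- samples[keep, ]
  class(s) <- c("cea_psa", "data.frame")
  lambdas <- c(0, 2e4, 5e4, 1e5, 5e5)
  fr <- vapply(lambdas, function(l) acceptability(s, l)$fraction,
               numeric(1))
  expect_true(all(diff(fr) >= 0))
})

test_that("scatter export has one row per draw with faithful columns", {
  ps <- default_parameter_set()
  samples <- run_psa(ps, c("etici2c3", "etici2b_accessible"),
                     n_draws = 10, master_seed = 3)
  sc <- export_scatter(samples, "societal")
  expect_equal(nrow(sc), 10L)
  expect_equal(mean(sc$inc_qalys), mean(samples$qalys_a - samples$qalys_b))
  expect_equal(mean(sc$inc_cost),
               mean(samples$cost_soc_a - samples$cost_soc_b))
})

test_that("population impact reproduces the published annual figures", {
  imp <- population_impact(39000, 0.539, 0.332,
                           delta_qaly = c(1.14, 0.45),
                           delta_cost_healthcare = c(6188, 6156),
                           delta_cost_societal = c(9317, 6473),
                           rounding_mode = "paper")
  expect_equal(unname(imp$qalys_gained), c(7956, 6319, 14275))
  expect_equal(unname(imp$savings_healthcare_musd), c(43, 86, 129))
  expect_equal(unname(imp$savings_societal_musd), c(65, 91, 156))
})

test_that("population impact is linear and zero at zero volume", {
  z <- population_impact(0, 0.539, 0.332, c(1.14, 0.45), c(6188, 6156),
                         c(9317, 6473))
  expect_equal(unname(z$qalys_gained), c(0, 0, 0))
  one <- population_impact(10000, 0.5, 0.4, c(1, 2), c(100, 200),
                           c(300, 400))
  two <- population_impact(20000, 0.5, 0.4, c(1, 2), c(100, 200),
                           c(300, 400))
  expect_equal(2 * one$qalys_gained, two$qalys_gained)
  expect_equal(2 * one$savings_societal_musd, two$savings_societal_musd)
  dbl <- population_impact(10000, 0.5, 0.4, c(2, 4), c(100, 200),
                           c(300, 400))
  expect_equal(2 * one$qalys_gained, dbl$qalys_gained)
  # brute-force per-patient summation oracle
  n_acc <- 10000 * 0.5 * 0.4
  n_non <- 10000 * 0.5 * 0.6
  expect_equal(unname(one$qalys_gained[["total"]]),
               sum(rep(1, n_acc)) + sum(rep(2, n_non)))
  expect_error(population_impact(100, 1.5, 0.5, c(1, 1), c(1, 1), c(1, 1)),
               "proportions")
})

test_that("exact and paper rounding differ only by documented rounding", {
  ex <- population_impact(39000, 0.539, 0.332, c(1.14, 0.45),
                          c(6188, 6156), c(9317, 6473), "exact")
  pa <- population_impact(39000, 0.539, 0.332, c(1.14, 0.45),
                          c(6188, 6156), c(9317, 6473), "paper")
  expect_equal(round(ex$qalys_gained[1:2]), pa$qalys_gained[1:2])
  expect_equal(round(ex$savings_healthcare_musd[1:2]),
               pa$savings_healthcare_musd[1:2])
  # exact totals are sums of unrounded components
  expect_equal(unname(ex$savings_healthcare_musd[["total"]]),
               sum(ex$savings_healthcare_musd[1:2]))
})
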