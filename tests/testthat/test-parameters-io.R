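test_that("parameter sets survive JSON and CSV round trips", {
  ps <- default_parameter_set()
  for (ext in c("json", "csv")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    save_parameter_set(ps, path)
    ps2 <- load_parameter_set(path)
    for (f in setdiff(names(ps), "psa")) {
      expect_equal(ps2[[f]], ps[[f]], tolerance = 1e-12, label = f)
    }
    # load -> save -> load is value-identical
    path2 <- withr::local_tempfile(fileext = paste0(".", ext))
    save_parameter_set(ps2, path2)
    ps3 <- load_parameter_set(path2)
    expect_equal(ps3[setdiff(names(ps3), "psa")],
                 ps2[setdiff(names(ps2), "psa")], tolerance = 1e-12)
    # distribution specs survive too
    expect_equal(ps2$psa$cost_evt$family, "gamma")
    expect_equal(ps2$psa$mrs90_dist$etici2c3$ess, 506)
  }
})

test_that("published acute costs load as stated", {
  path <- withr::local_tempfile(fileext = ".json")
  save_parameter_set(default_parameter_set(), path)
  ps <- load_parameter_set(path)
  expect_equal(ps$cost_evt, 15510)
})

test_that("a non-normalised arm distribution is rejected naming the arm", {
  ps <- default_parameter_set()
  ps$mrs90_dist$etici2b_accessible[1] <-
    ps$mrs90_dist$etici2b_accessible[1] - 0.02
  path <- withr::local_tempfile(fileext = ".json")
  save_parameter_set(ps, path)
  expect_error(load_parameter_set(path), "etici2b_accessible")
})

test_that("unknown and missing parameter names are reported", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{"not_a_parameter": 1}', path)
  expect_error(load_parameter_set(path), "not_a_parameter")
  df <- data.frame(key = "cost_evt", value = "15510", distribution = "")
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  expect_error(load_parameter_set(path), "missing required")
})

test_that("inflation is applied to costs at load time and then cleared", {
  ps <- default_parameter_set()
  ps$inflation_factor <- 1.05
  path <- withr::local_tempfile(fileext = ".json")
  save_parameter_set(ps, path)
  ps2 <- load_parameter_set(path)
  expect_equal(ps2$cost_evt, 15510 * 1.05)
  expect_equal(ps2$cost_annual_care,
               default_parameter_set()$cost_annual_care * 1.05)
  expect_equal(ps2$inflation_factor, 1)
  # wages are not medical costs and are not CPI-indexed
  expect_equal(ps2$annual_wage, ps$annual_wage)
})

test_that("inflation adjustment is plain multiplication with guards", {
  expect_equal(adjust_for_inflation(100, 1.0), 100)
  expect_equal(adjust_for_inflation(100, 1.1), 110)
  expect_equal(adjust_for_inflation(15510, 1.0384), 16105.58,
               tolerance = 0.01 / 16105)
  expect_error(adjust_for_inflation(-1, 1), "non-negative")
  expect_error(adjust_for_inflation(1, 0), "positive")
})

test_that("validator distinguishes warnings from errors, never mutates", {
  ps <- default_parameter_set()
  expect_identical(nrow(validate_parameter_set(ps)), 0L)
  ps$utility[["mrs3"]] <- ps$utility[["mrs2"]] + 0.05
  snapshot <- ps
  f <- validate_parameter_set(ps)
  expect_identical(ps, snapshot)
  expect_true(any(f$level == "warning" & f$field == "utility"))
  expect_false(any(f$level == "error"))
  ps2 <- default_parameter_set()
  ps2$cost_annual_care[[5]] <- -100
  f2 <- validate_parameter_set(ps2)
  expect_true(any(f2$level == "error" & grepl("cost_annual_care", f2$field)))
})

test_that("cohort summary reproduces the enrolment flowchart exactly", {
  co <- flowchart_cohort()
  s <- summarize_cohort(co)
  expect_equal(s$n_enrolled, 1105L)
  expect_equal(s$n_etici2b, 450L)
  expect_equal(s$n_assessable, 443L)
  expect_equal(s$n_accessible, 147L)
  expect_equal(s$n_non_accessible, 296L)
  expect_equal(s$proportions[["accessible_of_assessable"]], 147 / 443)
  expect_equal(round(100 * s$proportions[["accessible_of_assessable"]], 1),
               33.2)
})

test_that("single-record and empty strata are handled", {
  one <- flowchart_cohort(1L, 1L, 0L, 0L, 0L)
  s <- summarize_cohort(one)
  expect_equal(s$n_etici2b, 0L)
  expect_equal(s$n_accessible, 0L)
  expect_equal(s$n_non_accessible, 0L)
  expect_error(summarize_cohort(one[0, ]), "empty")
})

test_that("summary counts match an independent brute-force recount", {
  co <- generate_cohort(synthetic_config(n_patients = 800L, seed = 5L))
  s <- summarize_cohort(co)
  # independent predicate-based recount
  expect_equal(s$n_etici2b, sum(vapply(seq_len(nrow(co)), function(i)
    co$etici_grade[i] == "2b", logical(1))))
  expect_equal(s$n_accessible, sum(vapply(seq_len(nrow(co)), function(i)
    co$pattern_class[i] == "accessible", logical(1))))
  expect_equal(s$n_assessable, s$n_accessible + s$n_non_accessible)
  expect_lte(s$n_assessable, s$n_etici2b)
  for (a in names(s$mrs90_empirical)) {
    expect_equal(sum(s$mrs90_empirical[[a]]), 1, tolerance = 1e-12)
  }
})

test_that("inconsistent records are rejected with the patient id", {
  co <- flowchart_cohort(10L, 5L, 5L, 5L, 2L)
  co$pattern_class[1L] <- "accessible"   # an eTICI 2c/3 patient
  expect_error(summarize_cohort(co), co$patient_id[1L])
  co2 <- flowchart_cohort(10L, 5L, 5L, 5L, 2L)
  co2$mrs90[3L] <- 9L
  expect_error(summarize_cohort(co2), co2$patient_id[3L])
})

test_that("cohort and life-table files round-trip through CSV", {
  co <- generate_cohort(synthetic_config(n_patients = 50L, seed = 2L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  co2 <- read_cohort(path)
  expect_equal(as.data.frame(co2), as.data.frame(co))
  lt <- generate_life_table()
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_life_table(lt, path2)
  expect_equal(load_life_table(path2), lt)
})
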