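#' Configuration for the synthetic trial cohort generator
#'
#' Describes a trial-like EVT population: arm mix (reperfusion patterns),
#' per-arm 90-day mRS outcome profiles, demographics, and the fraction of
#' eTICI 2b angiograms whose reperfusion pattern cannot be read. Defaults
#' emulate the margins of the ESCAPE-NA1 EVT population: 1105 patients,
#' 450/1105 with final eTICI 2b, 443/450 of those assessable, 147/443 with
#' an EVT-accessible residual occlusion, mean age 70.7 (SD 13.6), 48.8%
#' female.
#'
#' @param n_patients Cohort size (>= 1).
#' @param arm_proportions Named probabilities over [arm_labels()]; must sum
#'   to 1.
#' @param p_not_assessable Probability that an eTICI 2b angiogram cannot be
#'   pattern-classified (default 7/450).
#' @param mrs90_profiles Named list of 7-element probability vectors
#'   (mRS 0-6) per arm; defaults from [default_parameter_set()].
#' @param p_ivt Named per-arm probability of intravenous alteplase.
#' @param age_mean,age_sd Age distribution in years (normal, clamped to
#'   18-100).
#' @param female_fraction Probability of female sex.
#' @param seed Integer seed; generation is a pure function of
#'   (config, seed).
#' @return A list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_patients = 1105L,
                             arm_proportions = NULL,
                             p_not_assessable = 7 / 450,
                             mrs90_profiles = NULL,
                             p_ivt = NULL,
                             age_mean = 70.7, age_sd = 13.6,
                             female_fraction = 0.488,
                             seed = 1L) {
  p2b <- 450 / 1105
  if (is.null(arm_proportions)) {
    arm_proportions <- c(
      etici2c3_single_pass = 300 / 1105,
      etici2c3_multi_pass = 206 / 1105,
      etici2b_accessible = p2b * 147 / 443,
      etici2b_non_accessible = p2b * 296 / 443,
      other = 149 / 1105
    )
  }
  ps <- default_parameter_set()
  if (is.null(mrs90_profiles)) {
    mrs90_profiles <- ps$mrs90_dist[names(arm_proportions)]
    # collapsed 2c3 profile covers configs keyed on the pooled arm
    mrs90_profiles[vapply(mrs90_profiles, is.null, TRUE)] <- NULL
    for (a in setdiff(names(arm_proportions), names(mrs90_profiles))) {
      mrs90_profiles[[a]] <- ps$mrs90_dist$etici2c3
    }
  }
  if (is.null(p_ivt)) {
    p_ivt <- ps$p_ivt
    p_ivt[setdiff(names(arm_proportions), names(p_ivt))] <- 0.6
  }
  cfg <- structure(list(n_patients = as.integer(n_patients),
                        arm_proportions = arm_proportions,
                        p_not_assessable = p_not_assessable,
                        mrs90_profiles = mrs90_profiles,
                        p_ivt = p_ivt,
                        age_mean = age_mean, age_sd = age_sd,
                        female_fraction = female_fraction,
                        seed = as.integer(seed)),
                   class = "synthetic_config")
  validate_synthetic_config(cfg)
  cfg
}

# internal
validate_synthetic_config <- function(cfg) {
  if (cfg$n_patients < 1L) stop("synthetic_config: n_patients must be >= 1")
  if (any(cfg$arm_proportions < 0)) {
    stop("synthetic_config: arm_proportions must be non-negative")
  }
  check_prob_vector(cfg$arm_proportions, "arm_proportions")
  for (a in names(cfg$arm_proportions)) {
    prof <- cfg$mrs90_profiles[[a]]
    if (is.null(prof) || length(prof) != 7L) {
      stop("synthetic_config: mrs90_profiles missing 7-element vector for ",
           "arm ", a)
    }
    check_prob_vector(prof, paste0("mrs90_profiles.", a))
  }
  if (cfg$p_not_assessable < 0 || cfg$p_not_assessable > 1 ||
      cfg$female_fraction < 0 || cfg$female_fraction > 1) {
    stop("synthetic_config: probabilities must lie in [0, 1]")
  }
  invisible(TRUE)
}

#' Generate a synthetic trial cohort
#'
#' Draws per-patient records: arm (reperfusion pattern) from the configured
#' multinomial, 90-day mRS from the arm's outcome profile, demographics,
#' number of EVT passes and IVT status. Pattern class is consistent with
#' the eTICI grade (only eTICI 2b patients carry an
#' accessible/non-accessible/not-assessable label). Identical
#' (config, seed) gives identical output.
#'
#' @param config A [synthetic_config()].
#' @return data.frame of class `"cea_cohort"`, one row per patient, columns
#'   `patient_id`, `age`, `sex`, `etici_grade`, `pattern_class`, `n_passes`,
#'   `mrs90`, `received_ivt`, `arm`.
#' @export
generate_cohort <- function(config = synthetic_config()) {
  validate_synthetic_config(config)
  n <- config$n_patients
  with_seed(config$seed, {
    arms <- names(config$arm_proportions)
    arm <- sample(arms, n, replace = TRUE, prob = config$arm_proportions)
    is2b <- grepl("^etici2b", arm)
    is2c3 <- grepl("^etici2c3", arm)
    etici <- character(n)
    etici[is2c3] <- sample(c("2c", "3"), sum(is2c3), replace = TRUE)
    etici[is2b] <- "2b"
    etici[!is2b & !is2c3] <- sample(c("0", "1", "2a"), sum(!is2b & !is2c3),
                                    replace = TRUE, prob = c(0.2, 0.2, 0.6))
    pattern <- rep("not_applicable", n)
    pattern[arm == "etici2b_accessible"] <- "accessible"
    pattern[arm == "etici2b_non_accessible"] <- "non_accessible"
    lost <- is2b & stats::runif(n) < config$p_not_assessable
    pattern[lost] <- "not_assessable"
    passes <- 1L + stats::rpois(n, 0.7)
    passes[arm == "etici2c3_single_pass"] <- 1L
    multi <- arm == "etici2c3_multi_pass"
    passes[multi] <- 2L + stats::rpois(sum(multi), 0.8)
    mrs90 <- integer(n)
    for (a in arms) {
      idx <- which(arm == a)
      if (length(idx)) {
        mrs90[idx] <- sample(0:6, length(idx), replace = TRUE,
                             prob = config$mrs90_profiles[[a]])
      }
    }
    ivt <- stats::runif(n) < config$p_ivt[arm]
    age <- pmin(pmax(round(stats::rnorm(n, config$age_mean, config$age_sd)),
                     18), 100)
    sex <- ifelse(stats::runif(n) < config$female_fraction, "female", "male")
    structure(data.frame(patient_id = sprintf("P%04d", seq_len(n)),
                         age = age, sex = sex, etici_grade = etici,
                         pattern_class = pattern, n_passes = passes,
                         mrs90 = mrs90, received_ivt = ivt, arm = arm,
                         stringsAsFactors = FALSE),
              class = c("cea_cohort", "data.frame"))
  })
}

#' Write / read a cohort CSV
#' @param cohort A cohort data.frame from [generate_cohort()].
#' @param path CSV path.
#' @return `path` (write) or the cohort data.frame (read).
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("patient_id", "age", "etici_grade", "pattern_class", "mrs90")
  miss <- setdiff(needed, names(df))
  if (length(miss)) stop("cohort file missing columns: ",
                         paste(miss, collapse = ", "))
  structure(df, class = c("cea_cohort", "data.frame"))
}

#' Deterministic cohort with fixed flowchart margins
#'
#' Builds a cohort whose label counts are exact (no sampling): useful for
#' checking the enrolment flowchart arithmetic. Defaults reproduce the
#' ESCAPE-NA1 margins: 1105 enrolled, 506 with eTICI 2c/3, 450 with eTICI
#' 2b of which 7 not assessable and the remaining 443 split into 147
#' EVT-accessible and 296 EVT-non-accessible patterns.
#'
#' @param n_enrolled,n_etici2c3,n_etici2b,n_assessable,n_accessible Exact
#'   counts; remaining patients get eTICI grades 0-2a.
#' @return A `"cea_cohort"` data.frame with exactly those label counts.
#' @export
flowchart_cohort <- function(n_enrolled = 1105L, n_etici2c3 = 506L,
                             n_etici2b = 450L, n_assessable = 443L,
                             n_accessible = 147L) {
  if (n_assessable > n_etici2b || n_etici2b + n_etici2c3 > n_enrolled ||
      n_accessible > n_assessable) {
    stop("flowchart_cohort: inconsistent counts")
  }
  n_non <- n_assessable - n_accessible
  n_lost <- n_etici2b - n_assessable
  n_other <- n_enrolled - n_etici2c3 - n_etici2b
  grade <- c(rep(c("2c", "3"), length.out = n_etici2c3),
             rep("2b", n_etici2b),
             rep(c("0", "1", "2a"), length.out = n_other))
  pattern <- c(rep("not_applicable", n_etici2c3),
               rep("accessible", n_accessible),
               rep("non_accessible", n_non),
               rep("not_assessable", n_lost),
               rep("not_applicable", n_other))
  arm <- c(rep(c("etici2c3_single_pass", "etici2c3_multi_pass"),
               length.out = n_etici2c3),
           rep("etici2b_accessible", n_accessible),
           rep("etici2b_non_accessible", n_non),
           rep("etici2b_non_accessible", n_lost),
           rep("other", n_other))
  n <- n_enrolled
  structure(data.frame(patient_id = sprintf("P%04d", seq_len(n)),
                       age = rep(70L, n), sex = rep("female", n),
                       etici_grade = grade, pattern_class = pattern,
                       n_passes = ifelse(arm == "etici2c3_multi_pass", 2L, 1L),
                       mrs90 = rep_len(0:6, n), received_ivt = rep(TRUE, n),
                       arm = arm, stringsAsFactors = FALSE),
            class = c("cea_cohort", "data.frame"))
}
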