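#' Summarise a cohort along the enrolment flowchart
#'
#' Applies the study's filter cascade — enrolled, final eTICI 2b, angiogram
#' assessable, EVT-accessible vs non-accessible pattern — and reports counts
#' and proportions together with per-arm empirical 90-day mRS
#' distributions.
#'
#' @param records A `"cea_cohort"` data.frame (see [generate_cohort()],
#'   [read_cohort()]).
#' @return List of class `"flowchart_summary"` with counts `n_enrolled`,
#'   `n_etici2c3`, `n_etici2b`, `n_assessable`, `n_accessible`,
#'   `n_non_accessible`, derived `proportions`, and `mrs90_empirical` (per
#'   arm, each summing to 1).
#' @export
summarize_cohort <- function(records) {
  if (is.null(records) || nrow(records) == 0L) {
    stop("summarize_cohort: empty cohort")
  }
  bad <- which(!(records$mrs90 %in% 0:6))
  if (length(bad)) {
    stop("summarize_cohort: mrs90 outside 0-6 for patient ",
         records$patient_id[bad[1L]])
  }
  is2b <- records$etici_grade == "2b"
  labelled <- records$pattern_class %in%
    c("accessible", "non_accessible", "not_assessable")
  bad <- which(is2b != labelled)
  if (length(bad)) {
    stop("summarize_cohort: pattern_class inconsistent with eTICI grade ",
         "for patient ", records$patient_id[bad[1L]])
  }
  n_acc <- sum(records$pattern_class == "accessible")
  n_non <- sum(records$pattern_class == "non_accessible")
  counts <- list(
    n_enrolled = nrow(records),
    n_etici2c3 = sum(records$etici_grade %in% c("2c", "3")),
    n_etici2b = sum(is2b),
    n_assessable = n_acc + n_non,
    n_accessible = n_acc,
    n_non_accessible = n_non
  )
  props <- c(
    etici2b_of_enrolled = counts$n_etici2b / counts$n_enrolled,
    etici2c3_of_enrolled = counts$n_etici2c3 / counts$n_enrolled,
    assessable_of_etici2b = if (counts$n_etici2b > 0)
      counts$n_assessable / counts$n_etici2b else NA_real_,
    accessible_of_assessable = if (counts$n_assessable > 0)
      counts$n_accessible / counts$n_assessable else NA_real_,
    non_accessible_of_assessable = if (counts$n_assessable > 0)
      counts$n_non_accessible / counts$n_assessable else NA_real_
  )
  emp <- list()
  if (!is.null(records$arm)) {
    for (a in unique(records$arm)) {
      tab <- tabulate(records$mrs90[records$arm == a] + 1L, nbins = 7L)
      emp[[a]] <- stats::setNames(tab / sum(tab), paste0("mrs", 0:6))
    }
  }
  structure(c(counts, list(proportions = props, mrs90_empirical = emp)),
            class = "flowchart_summary")
}

#' @export
print.flowchart_summary <- function(x, ...) {
  cat("Enrolment flowchart\n")
  cat(sprintf("  enrolled                 %6d\n", x$n_enrolled))
  cat(sprintf("  final eTICI 2c/3         %6d (%.1f%%)\n", x$n_etici2c3,
              100 * x$proportions[["etici2c3_of_enrolled"]]))
  cat(sprintf("  final eTICI 2b           %6d (%.1f%%)\n", x$n_etici2b,
              100 * x$proportions[["etici2b_of_enrolled"]]))
  cat(sprintf("  pattern assessable       %6d\n", x$n_assessable))
  cat(sprintf("  EVT-accessible           %6d (%.1f%% of assessable)\n",
              x$n_accessible,
              100 * x$proportions[["accessible_of_assessable"]]))
  cat(sprintf("  EVT-non-accessible       %6d (%.1f%% of assessable)\n",
              x$n_non_accessible,
              100 * x$proportions[["non_accessible_of_assessable"]]))
  invisible(x)
}
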