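# Incremental cost-effectiveness analysis: dominance classification, ICER
# and net monetary benefit for a pair of lifetime outcomes.

# internal: 4-way dominance classification on the incremental quadrant.
# dq > 0 & dc < 0: intervention dominates (more effect, less cost);
# dq < 0 & dc > 0: comparator dominates; both zero: equivalent; otherwise
# the ICER is the relevant statistic (dq == 0 with dc != 0 yields an
# infinite ICER and is reported as icer_defined).
classify_dominance <- function(dq, dc) {
  if (dq > 0 && dc < 0) return("intervention_dominant")
  if (dq < 0 && dc > 0) return("comparator_dominant")
  if (dq == 0 && dc == 0) return("equivalent")
  "icer_defined"
}

#' Compare two strategy arms
#'
#' Computes incremental QALYs and costs (intervention minus comparator),
#' classifies dominance per perspective and reports the ICER where it is
#' defined. When the intervention is dominant (more QALYs at lower cost)
#' the ICER is suppressed and the dominance flag reported instead, the
#' conventional rendering in cost-effectiveness tables.
#'
#' @param a `"lifetime_outcome"` of the intervention arm.
#' @param b `"lifetime_outcome"` of the comparator arm, computed under the
#'   same settings (discount rate, cycle correction, start age) — mismatch
#'   is an error.
#' @param perspective `"both"`, `"healthcare"` or `"societal"`.
#' @return Object of class `"cea_comparison"`: `delta_qalys`, per
#'   perspective `delta_cost`, `icer` (NA when suppressed or undefined) and
#'   `dominance`.
#' @export
#' @examples
#' ps <- default_parameter_set()
#' lt <- generate_life_table()
#' compare_arms(run_lifetime("etici2c3", ps, lt),
#'              run_lifetime("etici2b_accessible", ps, lt))
compare_arms <- function(a, b, perspective = c("both", "healthcare",
                                               "societal")) {
  perspective <- match.arg(perspective)
  if (!inherits(a, "lifetime_outcome") || !inherits(b, "lifetime_outcome")) {
    stop("compare_arms: inputs must be lifetime_outcome objects")
  }
  if (!identical(a$settings, b$settings)) {
    stop("compare_arms: outcomes were computed under different settings")
  }
  if (identical(a$arm, b$arm)) stop("compare_arms: arms must be distinct")
  dq <- a$qalys - b$qalys
  persp <- if (perspective == "both") {
    c("healthcare", "societal")
  } else perspective
  res <- list(intervention = a$arm, comparator = b$arm, delta_qalys = dq)
  for (p in persp) {
    field <- if (p == "healthcare") "cost_healthcare" else "cost_societal"
    dc <- a[[field]] - b[[field]]
    dom <- classify_dominance(dq, dc)
    icer <- if (dom == "icer_defined" && dq != 0) dc / dq else NA_real_
    res[[p]] <- list(delta_cost = dc, dominance = dom, icer = icer)
  }
  res$settings <- a$settings
  structure(res, class = "cea_comparison")
}

#' @export
print.cea_comparison <- function(x, ...) {
  cat("Incremental analysis:", x$intervention, "vs", x$comparator, "\n")
  cat(sprintf("  incremental QALYs %18.3f\n", x$delta_qalys))
  for (p in intersect(c("healthcare", "societal"), names(x))) {
    r <- x[[p]]
    lab <- sprintf("  %s: %s cost %.0f USD, ", p,
                   if (r$delta_cost < 0) "saves" else "adds",
                   abs(r$delta_cost))
    tail <- switch(r$dominance,
                   intervention_dominant = "intervention dominant",
                   comparator_dominant = "comparator dominant",
                   equivalent = "strategies equivalent",
                   sprintf("ICER %.2f USD/QALY", r$icer))
    cat(lab, tail, "\n", sep = "")
  }
  invisible(x)
}

#' Net monetary benefit
#'
#' `NMB = lambda x QALYs - cost` at willingness-to-pay `lambda`. For a
#' `"lifetime_outcome"` the cost of the chosen perspective is used; a
#' two-element numeric `c(qalys, cost)` is also accepted.
#'
#' @param outcome `"lifetime_outcome"` or numeric `c(qalys, cost)`.
#' @param lambda Willingness-to-pay threshold, USD per QALY (>= 0).
#' @param perspective `"healthcare"` or `"societal"`.
#' @return NMB in USD.
#' @export
#' @examples
#' net_monetary_benefit(c(2, 50000), 50000)
net_monetary_benefit <- function(outcome, lambda,
                                 perspective = c("healthcare", "societal")) {
  if (lambda < 0) stop("net_monetary_benefit: lambda must be >= 0")
  perspective <- match.arg(perspective)
  if (inherits(outcome, "lifetime_outcome")) {
    cost <- if (perspective == "healthcare") {
      outcome$cost_healthcare
    } else outcome$cost_societal
    return(lambda * outcome$qalys - cost)
  }
  if (is.numeric(outcome) && length(outcome) == 2L) {
    return(lambda * outcome[[1L]] - outcome[[2L]])
  }
  stop("net_monetary_benefit: outcome must be a lifetime_outcome or ",
       "c(qalys, cost)")
}
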