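#' Health states of the long-run Markov model
#'
#' The model tracks a stroke cohort over seven mutually exclusive health
#' states: modified Rankin Scale (mRS) grades 0 (no symptoms) through 5
#' (severe disability), plus an absorbing Dead state. mRS 6 in a 90-day
#' outcome distribution maps onto Dead.
#'
#' @return Character vector of the seven state labels, in model order.
#' @export
#' @examples
#' health_states()
health_states <- function() {
  c("mRS0", "mRS1", "mRS2", "mRS3", "mRS4", "mRS5", "Dead")
}

# index of the absorbing state
DEAD <- 7L
N_STATES <- 7L
N_LIVING <- 6L

#' Strategy arm labels understood by the model
#'
#' Arms correspond to final reperfusion patterns after endovascular
#' thrombectomy: near-/complete reperfusion (eTICI 2c/3, also split into
#' single-pass and multi-pass), incomplete reperfusion (eTICI 2b) with an
#' EVT-accessible residual occlusion, incomplete reperfusion without an
#' EVT-accessible target, and a remainder category (eTICI 0-2a).
#'
#' @return Character vector of arm labels.
#' @export
arm_labels <- function() {
  c("etici2c3", "etici2b_accessible", "etici2b_non_accessible",
    "etici2c3_single_pass", "etici2c3_multi_pass", "other")
}

# internal: coerce a state given as label or index to an integer index 1..7
as_state_index <- function(state) {
  if (is.character(state)) {
    idx <- match(state, health_states())
    if (anyNA(idx)) stop("unknown health state: ", state[is.na(idx)][1L])
    return(idx)
  }
  state <- as.integer(state)
  if (any(state < 1L | state > N_STATES)) {
    stop("state index out of range 1..", N_STATES)
  }
  state
}

# internal: validate a probability vector; returns invisibly or stops
check_prob_vector <- function(p, name, tol = 1e-9) {
  if (any(!is.finite(p)) || any(p < -tol)) {
    stop(name, ": entries must be finite and non-negative")
  }
  if (abs(sum(p) - 1) > tol) {
    stop(name, ": probabilities sum to ", format(sum(p), digits = 12),
         ", not 1")
  }
  invisible(TRUE)
}

# internal: run code under a temporary RNG seed, restoring global RNG state.
# Generators take seeds as explicit arguments and never leak global state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}
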