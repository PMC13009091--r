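# Second-order Monte Carlo: joint sampling of all model parameters from
# their assigned distributions, both arms evaluated on each sampled set.

# internal samplers, moment-matched to (mean, relative SE) ---------------

r_beta_mm <- function(n, mean, rel_se) {
  out <- numeric(length(mean) * n)
  dim(out) <- c(n, length(mean))
  for (j in seq_along(mean)) {
    m <- mean[j]
    if (m <= 0 || m >= 1) { out[, j] <- m; next }
    s <- min(rel_se * m, 0.95 * sqrt(m * (1 - m)))
    nu <- m * (1 - m) / s^2 - 1
    out[, j] <- stats::rbeta(n, m * nu, (1 - m) * nu)
  }
  if (length(mean) == 1L) as.numeric(out) else out
}

r_gamma_mm <- function(n, mean, rel_se) {
  shape <- 1 / rel_se^2
  out <- vapply(mean, function(m) {
    if (m <= 0) rep(0, n) else stats::rgamma(n, shape, scale = m / shape)
  }, numeric(n))
  if (length(mean) == 1L) as.numeric(out) else out
}

r_lnorm_mm <- function(n, mean, rel_se) {
  sdlog <- sqrt(log(1 + rel_se^2))
  out <- vapply(mean, function(m) {
    if (m <= 0) rep(0, n) else
      stats::rlnorm(n, log(m) - sdlog^2 / 2, sdlog)
  }, numeric(n))
  if (length(mean) == 1L) as.numeric(out) else out
}

# Dirichlet via normalized gammas
r_dirichlet <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = pmax(alpha, 1e-12))
  g / sum(g)
}

# internal: one elementwise draw of a (possibly vector) parameter
sample_field <- function(value, spec) {
  if (is.null(spec) || spec$family == "fixed") return(value)
  drawn <- switch(spec$family,
                  beta = r_beta_mm(1L, as.numeric(value), spec$rel_se),
                  gamma = r_gamma_mm(1L, as.numeric(value), spec$rel_se),
                  lognormal = r_lnorm_mm(1L, as.numeric(value), spec$rel_se),
                  dirichlet = r_dirichlet(as.numeric(value) * spec$ess),
                  stop("unknown distribution family: ", spec$family))
  value[] <- drawn
  value
}

#' Draw one joint parameter sample for the PSA
#'
#' Samples every parameter from its [dist_spec()] (probability vectors from
#' Dirichlet, probabilities and utilities from moment-matched betas, costs
#' from gammas, hazard ratios from lognormals); parameters marked `fixed`
#' keep their point estimate. Uses the current RNG stream — call inside a
#' seeded context, as [run_psa()] does.
#'
#' @param ps Base `"parameter_set"` (point estimates + `psa` specs).
#' @return A sampled `"parameter_set"`.
#' @export
sample_parameter_set <- function(ps) {
  out <- ps
  for (arm in names(ps$mrs90_dist)) {
    spec <- ps$psa$mrs90_dist[[arm]]
    if (is.null(spec)) {
      stop("run_psa: parameter mrs90_dist.", arm,
           " lacks a distribution spec and is not marked fixed")
    }
    out$mrs90_dist[[arm]] <- sample_field(ps$mrs90_dist[[arm]], spec)
  }
  sampled_fields <- c("utility", "p_recurrent_annual",
                      "case_fatality_recurrent", "post_stroke_mrs",
                      "mortality_hr", "cost_evt", "cost_ivt",
                      "cost_acute_other", "p_ivt", "cost_annual_care",
                      "cost_informal_care", "return_to_work",
                      "employment_rate", "annual_wage")
  for (f in sampled_fields) {
    spec <- ps$psa[[f]]
    if (is.null(spec)) {
      stop("run_psa: parameter ", f,
           " lacks a distribution spec and is not marked fixed")
    }
    out[[f]] <- sample_field(ps[[f]], spec)
  }
  out
}

#' Probabilistic sensitivity analysis
#'
#' Runs `n_draws` second-order Monte Carlo simulations: per draw, one joint
#' sample of all model parameters, both arms evaluated on the same sampled
#' set (sharing one set of transition matrices), incremental costs and
#' QALYs recorded per perspective. Reproducible under `master_seed`.
#'
#' @param ps Base `"parameter_set"`.
#' @param arms Ordered pair of arm labels: `c(intervention, comparator)`.
#' @param n_draws Number of draws (default from `config`).
#' @param master_seed Seed for all PSA randomness (default from `config`).
#' @param config A [cea_config()].
#' @param life_table data.frame `age`, `qx`.
#' @return data.frame of class `"cea_psa"`, one row per draw: per-arm
#'   QALYs/costs, `inc_qalys`, `inc_cost_healthcare`, `inc_cost_societal`.
#'   Attributes: `arms`, `master_seed`, `wtp_thresholds`.
#' @export
run_psa <- function(ps, arms, n_draws = NULL, master_seed = NULL,
                    config = cea_config(),
                    life_table = generate_life_table()) {
  if (length(arms) != 2L || arms[1L] == arms[2L]) {
    stop("run_psa: arms must be two distinct labels")
  }
  if (is.null(n_draws)) n_draws <- config$n_psa_draws
  if (is.null(master_seed)) master_seed <- config$master_seed
  if (n_draws < 1L) stop("run_psa: n_draws must be >= 1")
  if (!is.null(config$max_age)) {
    life_table <- life_table[life_table$age <= config$max_age, , drop = FALSE]
    life_table$qx[nrow(life_table)] <- 1
  }
  n_cycles <- max(max(life_table$age) - ps$start_age + 1L, 1L)
  rows <- with_seed(master_seed, {
    lapply(seq_len(n_draws), function(i) {
      psi <- sample_parameter_set(ps)
      mats <- build_matrix_sequence(psi, psi$start_age, n_cycles, life_table)
      a <- run_lifetime(arms[1L], psi, life_table, config, matrices = mats)
      b <- run_lifetime(arms[2L], psi, life_table, config, matrices = mats)
      c(draw = i,
        qalys_a = a$qalys, cost_hc_a = a$cost_healthcare,
        cost_soc_a = a$cost_societal,
        qalys_b = b$qalys, cost_hc_b = b$cost_healthcare,
        cost_soc_b = b$cost_societal,
        inc_qalys = a$qalys - b$qalys,
        inc_cost_healthcare = a$cost_healthcare - b$cost_healthcare,
        inc_cost_societal = a$cost_societal - b$cost_societal)
    })
  })
  out <- as.data.frame(do.call(rbind, rows))
  attr(out, "arms") <- arms
  attr(out, "master_seed") <- master_seed
  attr(out, "wtp_thresholds") <- config$wtp_thresholds
  class(out) <- c("cea_psa", "data.frame")
  out
}

#' Acceptability at a willingness-to-pay threshold
#'
#' Fraction of PSA draws in which the intervention has positive incremental
#' net monetary benefit, `lambda x inc_QALYs - inc_cost > 0`, counted by
#' brute force over the draws.
#'
#' @param samples A `"cea_psa"` data.frame.
#' @param lambda Willingness-to-pay, USD per QALY.
#' @param perspective `"healthcare"` or `"societal"`.
#' @return List of class `"acceptability_result"`: `lambda`, `perspective`,
#'   `fraction`, `n_draws`.
#' @export
acceptability <- function(samples, lambda,
                          perspective = c("healthcare", "societal")) {
  perspective <- match.arg(perspective)
  if (nrow(samples) == 0L) stop("acceptability: no PSA samples")
  dc <- if (perspective == "healthcare") {
    samples$inc_cost_healthcare
  } else samples$inc_cost_societal
  nmb <- lambda * samples$inc_qalys - dc
  structure(list(lambda = lambda, perspective = perspective,
                 fraction = mean(nmb > 0), n_draws = nrow(samples)),
            class = "acceptability_result")
}

#' @export
print.acceptability_result <- function(x, ...) {
  cat(sprintf("Acceptability at %s USD/QALY (%s): %.2f%% of %d draws\n",
              format(x$lambda, big.mark = ","), x$perspective,
              100 * x$fraction, x$n_draws))
  invisible(x)
}

#' Export the PSA scatter (incremental QALYs vs incremental cost)
#'
#' @param samples A `"cea_psa"` data.frame.
#' @param perspective `"healthcare"` or `"societal"`.
#' @return data.frame with one row per draw: `inc_qalys`, `inc_cost`.
#' @export
export_scatter <- function(samples,
                           perspective = c("healthcare", "societal")) {
  perspective <- match.arg(perspective)
  if (nrow(samples) == 0L) stop("export_scatter: no PSA samples")
  dc <- if (perspective == "healthcare") {
    samples$inc_cost_healthcare
  } else samples$inc_cost_societal
  data.frame(inc_qalys = samples$inc_qalys, inc_cost = dc)
}

#' @export
summary.cea_psa <- function(object, ...) {
  arms <- attr(object, "arms")
  wtp <- attr(object, "wtp_thresholds")
  cat("PSA:", arms[1L], "vs", arms[2L], "-", nrow(object), "draws\n")
  cat(sprintf("  mean incremental QALYs  %8.3f\n",
              mean(object$inc_qalys)))
  cat(sprintf("  mean incremental cost   %8.0f (healthcare) / %8.0f ",
              mean(object$inc_cost_healthcare),
              mean(object$inc_cost_societal)))
  cat("(societal) USD\n")
  for (l in wtp) {
    for (p in c("healthcare", "societal")) {
      a <- acceptability(object, l, p)
      cat(sprintf("  acceptability @ %7s USD/QALY (%-10s) %6.2f%%\n",
                  format(l, big.mark = ","), p, 100 * a$fraction))
    }
  }
  invisible(object)
}

#' @export
plot.cea_psa <- function(x, perspective = c("healthcare", "societal"), ...) {
  perspective <- match.arg(perspective)
  sc <- export_scatter(x, perspective)
  arms <- attr(x, "arms")
  graphics::plot(sc$inc_qalys, sc$inc_cost, pch = 16, cex = 0.4,
                 col = grDevices::adjustcolor("steelblue", 0.4),
                 xlab = "Incremental QALYs",
                 ylab = "Incremental cost (USD)",
                 main = sprintf("PSA scatter: %s vs %s (%s)", arms[1L],
                                arms[2L], perspective), ...)
  graphics::abline(h = 0, v = 0, col = "grey60")
  for (l in attr(x, "wtp_thresholds")) {
    graphics::abline(0, l, lty = 2, col = "grey40")
  }
  invisible(x)
}
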