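#' Define a simulated yes-no observer
#'
#' A synthetic participant whose yes/no responses are Bernoulli draws from
#' one of the two psychometric-function families. Observer family and
#' measurement procedure are deliberately decoupled: a d-prime-family
#' observer can be measured by QUEST and vice versa, which reproduces the
#' model-mismatch situation responsible for systematic threshold offsets
#' between procedures.
#'
#' @param model A [quest_model()] (responses follow the Weibull-type yes-no
#'   function of log10 concentration) or a [qyn_model()] (responses follow
#'   the d-prime/criterion function of linear concentration).
#' @return An object of class `sim_observer`.
#' @seealso [respond()], [run_session()]
#' @export
sim_observer <- function(model) {
  if (!inherits(model, "quest_model") && !inherits(model, "qyn_model")) {
    stop("model must be a quest_model or qyn_model")
  }
  if (inherits(model, "quest_model") && is.na(model$epsilon)) {
    model$epsilon <- solve_epsilon(model)
  }
  structure(
    list(family = if (inherits(model, "quest_model")) "quest" else "qyn",
         model = model),
    class = "sim_observer"
  )
}

#' Draw a yes/no response from a simulated observer
#'
#' One Bernoulli draw with success probability given by the observer's true
#' psychometric function at the presented concentration. Consumes exactly one
#' RNG step, so a fixed seed fully determines the response sequence.
#'
#' @param observer A [sim_observer()].
#' @param c_log10 Presented concentration, log10 mM.
#' @return `1L` ("yes") or `0L` ("no").
#' @export
respond <- function(observer, c_log10) {
  stopifnot(inherits(observer, "sim_observer"))
  p <- if (observer$family == "quest") {
    psi_quest(c_log10, observer$model)
  } else {
    psi_qyn(10^c_log10, observer$model)
  }
  stats::rbinom(1L, 1L, p)
}

#' Run one adaptive threshold session against a simulated observer
#'
#' Plays a full adaptive run: propose a stimulus, draw the observer's
#' response, update the posterior, and repeat until the procedure's
#' termination rule fires. QUEST sessions terminate dynamically (at most 20
#' trials); qYN sessions always run exactly 20 trials.
#'
#' @param procedure `"quest"` or `"qyn"`.
#' @param observer A [sim_observer()].
#' @param grid A [build_log_grid()] tastant ladder.
#' @param seed Integer RNG seed for the response draws.
#' @param ... Passed to [quest_init()] or [qyn_init()] (e.g.
#'   `tau_range_override`).
#' @return A list of class `session_result`: `trials` (a data frame with one
#'   row per trial: `trial`, `proposed_log10_mM`, `presented_log10_mM`,
#'   `response`, plus running estimates — `posterior_mean` and `ci90_width`
#'   for QUEST, `tau_hat`, `far_hat` and `slope_hat` for qYN), `estimates`,
#'   `n_trials`, `terminated_early`, `procedure`, and `seed`.
#' @export
run_session <- function(procedure = c("quest", "qyn"), observer, grid,
                        seed, ...) {
  procedure <- match.arg(procedure)
  stopifnot(inherits(observer, "sim_observer"))
  set.seed(seed)
  state <- if (procedure == "quest") quest_init(grid, ...) else
    qyn_init(grid, ...)
  rows <- list()
  repeat {
    idx <- if (procedure == "quest") quest_propose(state, grid) else
      qyn_propose(state, grid)
    c_pres <- grid$levels_log10[idx]
    resp <- respond(observer, c_pres)
    if (procedure == "quest") {
      state <- quest_update(state, c_pres, resp)
      rows[[length(rows) + 1L]] <- data.frame(
        trial = nrow(state$history),
        proposed_log10_mM = c_pres, presented_log10_mM = c_pres,
        response = resp,
        posterior_mean = sum(state$tau_grid * state$posterior),
        ci90_width = .ci_width(state$tau_grid, state$posterior))
      if (quest_should_stop(state, grid)) break
    } else {
      state <- qyn_update(state, c_pres, resp)
      est <- qyn_estimates(state, grid)
      rows[[length(rows) + 1L]] <- data.frame(
        trial = nrow(state$history),
        proposed_log10_mM = c_pres, presented_log10_mM = c_pres,
        response = resp,
        tau_hat = est$threshold_log10_mM,
        far_hat = est$far, slope_hat = est$slope)
      if (qyn_should_stop(state)) break
    }
  }
  trials <- do.call(rbind, rows)
  estimates <- if (procedure == "quest") {
    list(threshold_log10_mM = quest_estimate(state, grid))
  } else {
    qyn_estimates(state, grid)
  }
  structure(
    list(trials = trials, estimates = estimates, n_trials = nrow(trials),
         terminated_early = nrow(trials) < 20L,
         procedure = procedure, seed = seed, state = state),
    class = "session_result"
  )
}

#' Specify a simulated test-retest cohort
#'
#' Describes a population of simulated observers for a paired test-retest
#' experiment. True thresholds are drawn from a normal distribution in log10
#' mM (clipped to the stimulus range); for d-prime-family observers, slopes
#' are drawn log-uniformly over `slope_range` and criteria uniformly over
#' `lambda_range`. Between sessions, thresholds and criteria can drift:
#' `retest_jitter_*` are the SDs of zero-mean normal perturbations, and
#' `retest_shift_lambda` adds a systematic criterion shift in the retest
#' (positive = more conservative, i.e. lower false-alarm rate).
#'
#' @param n_observers Number of observers (>= 2).
#' @param family `"qyn"` or `"quest"` observer family.
#' @param tau_mean,tau_sd True-threshold distribution, log10 mM.
#' @param lambda_range Criterion range (z-units) for qyn-family observers.
#' @param slope_range Slope range for qyn-family observers.
#' @param retest_jitter_tau,retest_jitter_lambda SDs of between-session
#'   perturbations of threshold (log10 units) and criterion (z-units).
#' @param retest_shift_lambda Systematic criterion shift in the retest.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_observers, family = c("qyn", "quest"),
                        tau_mean, tau_sd,
                        lambda_range = c(0.75, 2.50),
                        slope_range = c(0.5, 3.0),
                        retest_jitter_tau = 0, retest_jitter_lambda = 0,
                        retest_shift_lambda = 0) {
  family <- match.arg(family)
  stopifnot(n_observers >= 2, tau_sd >= 0,
            retest_jitter_tau >= 0, retest_jitter_lambda >= 0)
  structure(
    list(n_observers = as.integer(n_observers), family = family,
         tau_mean = tau_mean, tau_sd = tau_sd,
         lambda_range = lambda_range, slope_range = slope_range,
         retest_jitter_tau = retest_jitter_tau,
         retest_jitter_lambda = retest_jitter_lambda,
         retest_shift_lambda = retest_shift_lambda),
    class = "cohort_spec"
  )
}

.clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# build the observer model for one session given sampled true parameters
.cohort_observer <- function(cohort, tau_log10, lam, slope) {
  if (cohort$family == "quest") {
    sim_observer(quest_model(tau = tau_log10))
  } else {
    sim_observer(qyn_model(tau = 10^tau_log10, gamma_slope = slope, lam = lam))
  }
}

#' Run a paired test-retest simulation over a cohort
#'
#' Samples true observer parameters from a [cohort_spec()], measures every
#' observer twice with the chosen procedure (independent response noise per
#' session; optional parameter drift between sessions), and returns one row
#' per observer with both estimates and the ground truth. All randomness is
#' derived from `seed`, so the output is fully reproducible.
#'
#' @param cohort A [cohort_spec()].
#' @param procedure `"quest"` or `"qyn"`.
#' @param grid A [build_log_grid()] tastant ladder.
#' @param seed Integer master seed.
#' @param ... Passed to [run_session()] (hence to the engine init).
#' @return A data frame with columns `id`, `true_tau_log10`, `true_lambda`,
#'   `true_slope`, `test`, `retest` (threshold estimates, log10 mM), and for
#'   qYN additionally `far_test`, `far_retest`, `slope_test`, `slope_retest`.
#' @export
run_test_retest <- function(cohort, procedure = c("quest", "qyn"), grid,
                            seed, ...) {
  procedure <- match.arg(procedure)
  stopifnot(inherits(cohort, "cohort_spec"))
  n <- cohort$n_observers
  lv <- grid$levels_log10
  set.seed(seed)
  tau_true <- .clip(stats::rnorm(n, cohort$tau_mean, cohort$tau_sd),
                    min(lv), max(lv))
  lam_true <- stats::runif(n, cohort$lambda_range[1], cohort$lambda_range[2])
  slope_true <- 10^stats::runif(n, log10(cohort$slope_range[1]),
                                log10(cohort$slope_range[2]))
  d_tau <- stats::rnorm(n, 0, cohort$retest_jitter_tau)
  d_lam <- stats::rnorm(n, cohort$retest_shift_lambda,
                        cohort$retest_jitter_lambda)
  session_seeds <- matrix(sample.int(.Machine$integer.max - 1L, 2L * n),
                          ncol = 2L)
  rows <- lapply(seq_len(n), function(i) {
    tau2 <- .clip(tau_true[i] + d_tau[i], min(lv), max(lv))
    lam2 <- .clip(lam_true[i] + d_lam[i], 0.05, 4)
    obs1 <- .cohort_observer(cohort, tau_true[i], lam_true[i], slope_true[i])
    obs2 <- .cohort_observer(cohort, tau2, lam2, slope_true[i])
    s1 <- run_session(procedure, obs1, grid, seed = session_seeds[i, 1], ...)
    s2 <- run_session(procedure, obs2, grid, seed = session_seeds[i, 2], ...)
    row <- data.frame(
      id = i, true_tau_log10 = tau_true[i], true_lambda = lam_true[i],
      true_slope = slope_true[i],
      test = s1$estimates$threshold_log10_mM,
      retest = s2$estimates$threshold_log10_mM)
    if (procedure == "qyn") {
      row$far_test <- s1$estimates$far
      row$far_retest <- s2$estimates$far
      row$slope_test <- s1$estimates$slope
      row$slope_retest <- s2$estimates$slope
    }
    row
  })
  do.call(rbind, rows)
}
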