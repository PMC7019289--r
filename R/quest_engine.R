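#' Initialize a QUEST yes-no threshold session
#'
#' Sets up the Bayesian state for the single-parameter QUEST procedure: a
#' dense threshold candidate grid (`tau_grid`, granularity 0.01 log10 mM,
#' extended one physical step beyond the stimulus range so the posterior is
#' not artificially truncated) carrying a normal prior centered on the start
#' concentration with a wide standard deviation (default 20 log10 units,
#' effectively flat over any tastant range). The lateral shift of the
#' psychometric function is solved once so that threshold performance is the
#' model's target yes-proportion (default 0.80).
#'
#' @param grid A [build_log_grid()] tastant ladder.
#' @param model A [quest_model()]; defaults to the standard parameterization
#'   beta 3.5, gamma = delta = 0.01, threshold at 80% "yes".
#' @param granularity Spacing of the threshold candidate grid, log10 units.
#' @param prior_sd Prior standard deviation, log10 units.
#' @param margin_steps Physical steps to extend `tau_grid` beyond the
#'   stimulus range on each side.
#' @return An object of class `quest_state`: fields `tau_grid`, `posterior`
#'   (sums to 1), `history` (0-row data frame), `model`, `grid`, and a
#'   precomputed likelihood matrix.
#' @export
quest_init <- function(grid, model = quest_model(), granularity = 0.01,
                       prior_sd = 20, margin_steps = 1) {
  stopifnot(inherits(grid, "tastant_grid"))
  if (is.na(model$epsilon)) model$epsilon <- solve_epsilon(model)
  lv <- grid$levels_log10
  margin <- margin_steps * grid$step_width
  tau_grid <- seq(min(lv) - margin, max(lv) + margin, by = granularity)
  prior <- stats::dnorm(tau_grid, mean = grid$start_level, sd = prior_sd)
  prior <- prior / sum(prior)
  # likelihood of "yes" for every (physical level, tau candidate) pair;
  # psi depends on tau only through c - tau, so shift the model once per tau
  lik <- outer(lv, tau_grid, function(c, tau) {
    arg <- model$beta * (c - tau + model$epsilon)
    model$delta * model$gamma +
      (1 - model$delta) * (1 - (1 - model$gamma) * .weibull_tail(arg))
  })
  structure(
    list(tau_grid = tau_grid, posterior = prior,
         history = .empty_history(), model = model, grid = grid, lik = lik),
    class = "quest_state"
  )
}

.empty_history <- function() {
  data.frame(trial = integer(), level_index = integer(),
             c_log10 = numeric(), response = integer())
}

.match_level <- function(c_log10, grid) {
  idx <- snap_to_physical(c_log10, grid)
  if (abs(grid$levels_log10[idx] - c_log10) > 1e-9) {
    stop("concentration ", c_log10, " is not a physical grid level")
  }
  idx
}

#' Bayesian posterior update for a QUEST session
#'
#' Multiplies the current posterior over threshold candidates by the
#' likelihood of the observed response at the presented concentration and
#' renormalizes; the trial is appended to the history. The update depends on
#' the entire response history only through the posterior, so yes/no updates
#' at fixed stimuli commute.
#'
#' @param state A `quest_state` from [quest_init()].
#' @param c_log10 Presented concentration, log10 mM; must be a physical level.
#' @param response 1/TRUE for "yes", 0/FALSE for "no".
#' @return The updated `quest_state`.
#' @export
quest_update <- function(state, c_log10, response) {
  stopifnot(inherits(state, "quest_state"))
  idx <- .match_level(c_log10, state$grid)
  yes <- as.integer(response)
  stopifnot(yes %in% c(0L, 1L))
  p_yes <- state$lik[idx, ]
  lik <- if (yes == 1L) p_yes else 1 - p_yes
  post <- state$posterior * lik
  total <- sum(post)
  if (total <= 0 || !is.finite(total)) stop("degenerate posterior")
  state$posterior <- post / total
  state$history <- rbind(
    state$history,
    data.frame(trial = nrow(state$history) + 1L, level_index = idx,
               c_log10 = c_log10, response = yes))
  state
}

#' Propose the next QUEST stimulus
#'
#' The first trial is always the grid's predefined supra-threshold start
#' level. Thereafter the posterior-mean threshold is snapped to the nearest
#' physical level; if that would repeat the previously presented level, the
#' proposal is shifted one physical step up after a "no" and one step down
#' after a "yes" (clamped to the grid ends), avoiding tiring repeats.
#'
#' @param state A `quest_state`.
#' @param grid The tastant ladder in use.
#' @return Integer index of the physical level to present.
#' @export
quest_propose <- function(state, grid) {
  stopifnot(inherits(state, "quest_state"))
  n_tr <- nrow(state$history)
  if (n_tr == 0L) return(grid$start_index)
  est <- sum(state$tau_grid * state$posterior)
  idx <- snap_to_physical(est, grid)
  last <- state$history[n_tr, ]
  if (idx == last$level_index) {
    idx <- if (last$response == 0L) {
      min(idx + 1L, length(grid$levels_log10))
    } else {
      max(idx - 1L, 1L)
    }
  }
  idx
}

# central credible-interval width via linear interpolation of the discrete
# CDF; only mass-carrying points enter, so the CDF is strictly increasing
# there and zero-posterior runs cannot distort the quantiles
.ci_width <- function(tau_grid, posterior, level = 0.90) {
  keep <- posterior > 0
  cdf <- cumsum(posterior)[keep]
  tau <- tau_grid[keep]
  # fp-tied CDF values (negligible increments): keep the first occurrence,
  # matching the inverse-CDF convention Q(p) = inf{tau : F(tau) >= p}
  first <- !duplicated(cdf)
  cdf <- cdf[first]
  tau <- tau[first]
  if (length(tau) == 1L) return(0)
  p <- c((1 - level) / 2, 1 - (1 - level) / 2)
  q <- stats::approx(cdf, tau, xout = p, rule = 2)$y
  q[2] - q[1]
}

#' QUEST termination rule
#'
#' A session ends after at most 20 trials; it may end earlier once more than
#' 10 trials have been run and the central 90% credible interval of the
#' threshold posterior is narrower than half a physical concentration step.
#'
#' @param state A `quest_state`.
#' @param grid The tastant ladder in use.
#' @param max_trials Hard trial cap. Default 20.
#' @param min_trials Trials that must be exceeded before the credible-interval
#'   rule applies. Default 10.
#' @param ci_level Credible-interval mass. Default 0.90.
#' @return `TRUE` if the session should stop.
#' @export
quest_should_stop <- function(state, grid, max_trials = 20L,
                              min_trials = 10L, ci_level = 0.90) {
  n_tr <- nrow(state$history)
  if (n_tr >= max_trials) return(TRUE)
  if (n_tr <= min_trials) return(FALSE)
  .ci_width(state$tau_grid, state$posterior, ci_level) < grid$step_width / 2
}

#' QUEST threshold estimate
#'
#' The mean of the threshold candidates weighted by the posterior (an
#' unbiased threshold estimator for this procedure family), clamped to the
#' range of physically available stimulus concentrations.
#'
#' @param state A `quest_state`.
#' @param grid The tastant ladder in use.
#' @return Threshold estimate, log10 mM.
#' @export
quest_estimate <- function(state, grid) {
  est <- sum(state$tau_grid * state$posterior)
  lv <- grid$levels_log10
  min(max(est, min(lv)), max(lv))
}
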