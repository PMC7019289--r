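#' Initialize a quick Yes-No session
#'
#' Sets up the 3-D Bayesian state of the quick Yes-No (qYN) procedure, which
#' estimates threshold, sensitivity-function slope, and decision criterion
#' simultaneously. The parameter lattice is:
#' * threshold candidates: the tastant ladder refined with virtual midpoint
#'   levels ([insert_midpoints()]), log10 mM, optionally range-restricted;
#' * slope: `n_gamma` values evenly spaced on a decadic logarithmic grid over
#'   `gamma_range` (default 10 values in `[0.5, 3.0]`);
#' * criterion: `n_lambda` evenly spaced values over `lambda_range` (default
#'   8 values in `[0.75, 2.50]`, i.e. false-alarm rates from ~22.7% down to
#'   below 1%).
#'
#' The upper d-prime asymptote is fixed (default 5.0) and the lapse rate set
#' to 0; the prior is uniform over every parameter combination. Yes-response
#' likelihoods are floored at 1e-12 per cell so that a lapse-free model can
#' never zero out the whole posterior.
#'
#' @param grid A [build_log_grid()] tastant ladder.
#' @param tau_range_override Optional `c(lo, hi)` in log10 mM restricting the
#'   threshold candidates (some tastants use a truncated range).
#' @param n_gamma,gamma_range Slope grid size and interval.
#' @param n_lambda,lambda_range Criterion grid size and interval (z-units).
#' @param beta_asymptote Fixed upper d-prime asymptote.
#' @param epsilon_lapse Fixed lapse rate.
#' @return An object of class `qyn_state` with the flattened posterior (tau
#'   varies fastest, then gamma, then lambda), the parameter grids, history,
#'   and a precomputed likelihood matrix (physical levels x lattice cells).
#' @export
qyn_init <- function(grid, tau_range_override = NULL,
                     n_gamma = 10, gamma_range = c(0.5, 3.0),
                     n_lambda = 8, lambda_range = c(0.75, 2.50),
                     beta_asymptote = 5.0, epsilon_lapse = 0) {
  stopifnot(inherits(grid, "tastant_grid"))
  tau_grid <- insert_midpoints(grid)$levels_log10
  if (!is.null(tau_range_override)) {
    tau_grid <- tau_grid[tau_grid >= tau_range_override[1] - 1e-9 &
                         tau_grid <= tau_range_override[2] + 1e-9]
    if (length(tau_grid) == 0) stop("tau_range_override leaves no candidates")
  }
  gamma_grid <- 10^seq(log10(gamma_range[1]), log10(gamma_range[2]),
                       length.out = n_gamma)
  lambda_grid <- seq(lambda_range[1], lambda_range[2], length.out = n_lambda)

  cells <- expand.grid(tau = tau_grid, gamma = gamma_grid, lam = lambda_grid,
                       KEEP.OUT.ATTRS = FALSE)
  n_cells <- nrow(cells)
  # likelihood of "yes" at each physical level for every lattice cell;
  # d' is evaluated on linear concentrations, candidates stored in log10
  lv_lin <- 10^grid$levels_log10
  b <- beta_asymptote
  ratio_pow <- outer(lv_lin, 10^cells$tau, "/")^
    matrix(cells$gamma, nrow = length(lv_lin), ncol = n_cells, byrow = TRUE)
  dp <- b * ratio_pow / sqrt((b^2 - 1) + ratio_pow^2)
  lam_m <- matrix(cells$lam, nrow = length(lv_lin), ncol = n_cells, byrow = TRUE)
  lik <- epsilon_lapse + (1 - epsilon_lapse) *
    stats::pnorm(lam_m - dp, lower.tail = FALSE)
  lik <- pmin(pmax(lik, 1e-12), 1 - 1e-12)

  structure(
    list(tau_grid = tau_grid, gamma_grid = gamma_grid,
         lambda_grid = lambda_grid,
         dims = c(length(tau_grid), n_gamma, n_lambda),
         posterior = rep(1 / n_cells, n_cells),
         history = .empty_history(), grid = grid, lik = lik,
         beta_asymptote = beta_asymptote, epsilon_lapse = epsilon_lapse),
    class = "qyn_state"
  )
}

#' Bayesian posterior update for a qYN session
#'
#' Cellwise Bayes over the (threshold, slope, criterion) lattice: the
#' posterior is multiplied by the yes-likelihood (or its complement for a
#' "no") at the presented concentration and renormalized; the trial is
#' appended to the history.
#'
#' @param state A `qyn_state` from [qyn_init()].
#' @param c_log10 Presented concentration, log10 mM; must be a physical level.
#' @param response 1/TRUE for "yes", 0/FALSE for "no".
#' @return The updated `qyn_state`.
#' @export
qyn_update <- function(state, c_log10, response) {
  stopifnot(inherits(state, "qyn_state"))
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

# Shannon entropy (nats) of a probability mass vector; 0 log 0 := 0
.entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' One-step-ahead expected posterior entropy for a candidate stimulus
#'
#' The expected Shannon entropy (nats) of the posterior after presenting the
#' candidate: `p_yes * H(posterior | yes) + (1 - p_yes) * H(posterior | no)`,
#' where `p_yes` is the posterior-predictive yes-probability. Minimizing this
#' over candidates maximizes the expected knowledge gain about the three
#' parameters; by construction it never exceeds the current entropy.
#'
#' @param state A `qyn_state`.
#' @param candidate_log10 Candidate concentration, log10 mM; a physical level.
#' @return Expected entropy in nats.
#' @export
qyn_expected_entropy <- function(state, candidate_log10) {
  stopifnot(inherits(state, "qyn_state"))
  idx <- .match_level(candidate_log10, state$grid)
  p_cell <- state$lik[idx, ]
  v_yes <- state$posterior * p_cell
  v_no <- state$posterior * (1 - p_cell)
  p_yes <- sum(v_yes)
  h_yes <- if (p_yes > 0) .entropy(v_yes / p_yes) else 0
  h_no <- if (p_yes < 1) .entropy(v_no / (1 - p_yes)) else 0
  p_yes * h_yes + (1 - p_yes) * h_no
}

#' Propose the next qYN stimulus
#'
#' The first trial is the grid's predefined supra-threshold start level.
#' Subsequent trials present the physical level minimizing the one-step-ahead
#' expected posterior entropy ([qyn_expected_entropy()]); ties are broken
#' toward the lower concentration. No anti-repeat rule is applied: the
#' entropy criterion itself interleaves near-threshold placements with very
#' low concentrations that probe the false-alarm rate.
#'
#' @param state A `qyn_state`.
#' @param grid The tastant ladder in use.
#' @return Integer index of the physical level to present.
#' @export
qyn_propose <- function(state, grid) {
  stopifnot(inherits(state, "qyn_state"))
  if (nrow(state$history) == 0L) return(grid$start_index)
  eh <- vapply(grid$levels_log10,
               function(cc) qyn_expected_entropy(state, cc), numeric(1))
  which(eh <= min(eh) + 1e-12)[1L]
}

#' qYN termination rule
#'
#' qYN runs a fixed number of trials (default 20); no dynamic stopping is
#' applied, ensuring enough data for the simultaneous estimation of
#' threshold, slope, and criterion.
#'
#' @param state A `qyn_state`.
#' @param max_trials Fixed trial count. Default 20.
#' @return `TRUE` once `max_trials` trials have been run.
#' @export
qyn_should_stop <- function(state, max_trials = 20L) {
  nrow(state$history) >= max_trials
}

#' qYN parameter estimates
#'
#' Marginal-posterior-weighted means: the threshold estimate is the weighted
#' mean of the log10 threshold candidates, clamped to the physical stimulus
#' range; the criterion estimate is the weighted mean of the lambda marginal,
#' reported as a false-alarm rate `1 - pnorm(lambda_hat)`; the slope estimate
#' is the weighted mean of the gamma marginal.
#'
#' @param state A `qyn_state`.
#' @param grid The tastant ladder in use.
#' @param far_method How to report the false-alarm rate: `"transform_mean"`
#'   (default; transform of the averaged criterion, matching the analysis
#'   pipeline's transformation order) or `"mean_transform"` (weighted mean of
#'   the per-cell false-alarm rates).
#' @return A list with `threshold_log10_mM`, `far`, `slope`, and `lambda_hat`.
#' @export
qyn_estimates <- function(state, grid,
                          far_method = c("transform_mean", "mean_transform")) {
  far_method <- match.arg(far_method)
  arr <- array(state$posterior, dim = state$dims)
  tau_marg <- apply(arr, 1, sum)
  gamma_marg <- apply(arr, 2, sum)
  lambda_marg <- apply(arr, 3, sum)
  lv <- grid$levels_log10
  tau_hat <- sum(state$tau_grid * tau_marg)
  tau_hat <- min(max(tau_hat, min(lv)), max(lv))
  lambda_hat <- sum(state$lambda_grid * lambda_marg)
  far <- if (far_method == "transform_mean") {
    far_from_lambda(lambda_hat)
  } else {
    sum(far_from_lambda(state$lambda_grid) * lambda_marg)
  }
  list(threshold_log10_mM = tau_hat,
       far = far,
       slope = sum(state$gamma_grid * gamma_marg),
       lambda_hat = lambda_hat)
}
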