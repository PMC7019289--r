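#' Weibull-type yes-no psychometric model (QUEST parameterization)
#'
#' Parameter record for the yes-no psychometric function used by the QUEST
#' threshold procedure,
#' \deqn{\Psi_{yes}(c) = \delta\gamma + (1-\delta)\,[1 - (1-\gamma)\,
#'   e^{-10^{\beta (c - \tau + \epsilon)}}],}
#' where \eqn{c} and \eqn{\tau} are log10 concentrations (log10 mM).
#' \eqn{\gamma} is the false-alarm/guess rate (the lower asymptote),
#' \eqn{\delta} the lapse rate (the upper asymptote is
#' \eqn{\delta\gamma + 1 - \delta}), \eqn{\beta} the slope, and
#' \eqn{\epsilon} a lateral shift chosen so that
#' \eqn{\Psi_{yes}(\tau)} equals `threshold_performance`.
#'
#' @param tau Threshold, log10 mM. The concentration at which the expected
#'   proportion of "yes" responses equals `threshold_performance`.
#' @param beta Slope steepness (dimensionless). Default 3.5.
#' @param gamma False-alarm / guess rate in `[0, 1]`. Default 0.01.
#' @param delta Lapse rate in `[0, 1]`. Default 0.01.
#' @param epsilon Lateral shift in log10 units, or `NA` to have it solved by
#'   [solve_epsilon()] on first use.
#' @param threshold_performance Target "yes" proportion at `tau`. Default 0.80.
#' @return An object of class `quest_model`.
#' @seealso [psi_quest()], [solve_epsilon()]
#' @export
#' @examples
#' m <- quest_model(tau = 0)
#' m$epsilon <- solve_epsilon(m)
#' psi_quest(0, m)  # 0.80
quest_model <- function(tau = 0, beta = 3.5, gamma = 0.01, delta = 0.01,
                        epsilon = NA_real_,
                        threshold_performance = 0.80) {
  stopifnot(is.finite(tau), is.finite(beta), beta > 0,
            gamma >= 0, gamma <= 1, delta >= 0, delta <= 1)
  upper <- delta * gamma + (1 - delta)
  if (!(threshold_performance > gamma && threshold_performance < upper)) {
    stop("threshold_performance must lie strictly between the lower asymptote ",
         "gamma (", gamma, ") and the upper asymptote (", upper, ")")
  }
  structure(
    list(tau = tau, beta = beta, gamma = gamma, delta = delta,
         epsilon = epsilon, threshold_performance = threshold_performance),
    class = "quest_model"
  )
}

#' d-prime-based yes-no psychometric model (qYN parameterization)
#'
#' Parameter record for the signal-detection psychometric function used by the
#' quick Yes-No procedure,
#' \deqn{\Psi_{yes}(c) = \epsilon + (1-\epsilon)\,
#'   [1 - \Phi(\lambda - d'(c))],}
#' with the sensitivity function
#' \deqn{d'(c) = \frac{\beta (c/\tau)^{\gamma}}
#'   {\sqrt{(\beta^2 - 1) + (c/\tau)^{2\gamma}}}.}
#' \eqn{c} and \eqn{\tau} are linear concentrations (mM); the threshold
#' \eqn{\tau} is the concentration at which \eqn{d' = 1}. \eqn{\lambda} is the
#' decision criterion in z-units (false-alarm rate \eqn{1 - \Phi(\lambda)}),
#' \eqn{\gamma} the slope of the sensitivity function, \eqn{\beta} its upper
#' asymptote, and \eqn{\epsilon} the lapse rate.
#'
#' @param tau Threshold in linear mM; must be positive.
#' @param gamma_slope Slope of the d-prime function (dimensionless).
#' @param lam Decision criterion in z-units.
#' @param beta_asymptote Upper d-prime asymptote; must exceed 1. Default 5.
#' @param epsilon_lapse Lapse proportion in `[0, 1]`. Default 0.
#' @return An object of class `qyn_model`.
#' @seealso [dprime()], [psi_qyn()], [far_from_lambda()]
#' @export
#' @examples
#' m <- qyn_model(tau = 1, gamma_slope = 1.5, lam = 1)
#' dprime(1, m)      # 1 by definition of threshold
#' psi_qyn(1, m)     # 0.5: criterion sits exactly at d'(tau)
qyn_model <- function(tau, gamma_slope, lam, beta_asymptote = 5.0,
                      epsilon_lapse = 0) {
  stopifnot(is.finite(tau), is.finite(gamma_slope), is.finite(lam))
  if (tau <= 0) stop("tau must be positive (linear mM)")
  if (beta_asymptote <= 1) stop("beta_asymptote must exceed 1")
  if (epsilon_lapse < 0 || epsilon_lapse > 1) {
    stop("epsilon_lapse must lie in [0, 1]")
  }
  structure(
    list(tau = tau, gamma_slope = gamma_slope, lam = lam,
         beta_asymptote = beta_asymptote, epsilon_lapse = epsilon_lapse),
    class = "qyn_model"
  )
}

# exp(-10^x) with the exponent argument clipped so 10^x never overflows;
# clip at 700 is far beyond any value reachable on the grids used.
.weibull_tail <- function(x) {
  exp(-10^pmin(pmax(x, -700), 700))
}

#' QUEST yes-no psychometric function
#'
#' Probability of a "yes" response at log10 concentration `c_log10` under a
#' [quest_model()].
#'
#' @param c_log10 Concentration(s), log10 mM. Vectorized.
#' @param model A [quest_model()]; its `epsilon` must be set (see
#'   [solve_epsilon()]) or `NA` is propagated.
#' @return Probability in `[0, 1]`, same length as `c_log10`.
#' @export
psi_quest <- function(c_log10, model) {
  stopifnot(inherits(model, "quest_model"))
  eps <- if (is.na(model$epsilon)) 0 else model$epsilon
  arg <- model$beta * (c_log10 - model$tau + eps)
  model$delta * model$gamma +
    (1 - model$delta) * (1 - (1 - model$gamma) * .weibull_tail(arg))
}

#' Solve the lateral shift of the QUEST psychometric function
#'
#' Finds the shift `epsilon` such that `psi_quest(tau, model)` equals the
#' model's `threshold_performance` (default 0.80), i.e. such that "threshold"
#' means the concentration yielding the target yes-proportion. A scalar root
#' find (monotone in epsilon) to within 1e-8.
#'
#' @param model A [quest_model()].
#' @return The shift in log10 units.
#' @export
solve_epsilon <- function(model) {
  stopifnot(inherits(model, "quest_model"))
  target <- model$threshold_performance
  f <- function(e) {
    m <- model
    m$epsilon <- e
    psi_quest(model$tau, m) - target
  }
  # psi at tau is strictly increasing in epsilon from gamma to the upper
  # asymptote; widen the bracket until it straddles the root
  lo <- -5; hi <- 5
  while (f(lo) > 0 && lo > -60) lo <- lo * 2
  while (f(hi) < 0 && hi < 60) hi <- hi * 2
  if (f(lo) > 0 || f(hi) < 0) {
    stop("threshold_performance not attainable for these asymptotes")
  }
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Signal-detection sensitivity function d-prime
#'
#' Concentration-dependent sensitivity under a [qyn_model()]:
#' `d'(c) = beta * (c/tau)^gamma / sqrt((beta^2 - 1) + (c/tau)^(2*gamma))`.
#' Equals 0 at `c = 0`, exactly 1 at `c = tau`, and approaches the upper
#' asymptote `beta` as concentration grows.
#'
#' @param c Concentration(s) in linear mM; non-negative. Vectorized.
#' @param model A [qyn_model()].
#' @return Sensitivity in d-prime units.
#' @export
dprime <- function(c, model) {
  stopifnot(inherits(model, "qyn_model"))
  if (any(c < 0)) stop("concentrations must be non-negative")
  b <- model$beta_asymptote
  r <- (c / model$tau)^model$gamma_slope
  b * r / sqrt((b^2 - 1) + r^2)
}

#' qYN yes-no psychometric function
#'
#' Probability of a "yes" response at linear concentration `c` under a
#' [qyn_model()]: `epsilon + (1 - epsilon) * (1 - pnorm(lambda - d'(c)))`.
#' At `c = 0` (blank stimulus) this reduces to the false-alarm rate
#' `1 - pnorm(lambda)` when the lapse rate is zero.
#'
#' @inheritParams dprime
#' @return Probability in `[0, 1]`.
#' @export
psi_qyn <- function(c, model) {
  e <- model$epsilon_lapse
  e + (1 - e) * stats::pnorm(model$lam - dprime(c, model), lower.tail = FALSE)
}

#' Convert between decision criterion and false-alarm rate
#'
#' The criterion `lambda` (z-units) and the false-alarm rate are linked by
#' `FAR = 1 - pnorm(lambda)`, equivalently `lambda = qnorm(1 - FAR)`. The two
#' functions are mutually inverse bijections; `far_from_lambda()` is strictly
#' decreasing.
#'
#' @param lam Criterion value(s) in z-units.
#' @return `far_from_lambda`: false-alarm proportion(s) in (0, 1).
#' @export
#' @examples
#' far_from_lambda(0.75)   # ~0.227: the most liberal criterion on the grid
#' far_from_lambda(2.50)   # < 0.01
far_from_lambda <- function(lam) {
  stats::pnorm(lam, lower.tail = FALSE)
}

#' @rdname far_from_lambda
#' @param far False-alarm proportion(s), strictly inside (0, 1).
#' @return `lambda_from_far`: criterion in z-units.
#' @export
lambda_from_far <- function(far) {
  if (any(far <= 0 | far >= 1)) stop("far must lie strictly in (0, 1)")
  stats::qnorm(far, lower.tail = FALSE)
}
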