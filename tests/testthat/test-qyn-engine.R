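# a small qYN state: 3 physical levels -> 5 threshold candidates, and a
# reduced slope/criterion lattice for hand calculations
small_qyn <- function(n_gamma = 1, gamma_range = c(1.5, 1.5),
                      n_lambda = 1, lambda_range = c(1, 1)) {
  g <- toy_grid3()
  list(grid = g,
       state = qyn_init(g, n_gamma = n_gamma, gamma_range = gamma_range,
                        n_lambda = n_lambda, lambda_range = lambda_range))
}

test_that("the uninformative prior covers the printed lattice sizes", {
  st <- qyn_init(citric())
  expect_equal(st$dims, c(27L, 10L, 8L))
  expect_equal(st$posterior, rep(1 / 2160, 2160))
  expect_equal(sum(st$posterior), 1, tolerance = 1e-12)
  st2 <- qyn_init(tastant_grid("nacl"))
  expect_equal(st2$dims[1], 23L)
  # slope grid is log-spaced over [0.5, 3], criterion grid linear [0.75, 2.5]
  expect_equal(range(st$gamma_grid), c(0.5, 3.0))
  expect_equal(diff(log10(st$gamma_grid)), rep(log10(3 / 0.5) / 9, 9),
               tolerance = 1e-12)
  expect_equal(st$lambda_grid, seq(0.75, 2.50, length.out = 8))
  # threshold candidates can be range-restricted
  g <- citric()
  st3 <- qyn_init(g, tau_range_override = c(-1, 1))
  expect_true(all(st3$tau_grid >= -1 - 1e-9 & st3$tau_grid <= 1 + 1e-9))
  expect_lt(st3$dims[1], 27L)
  expect_error(qyn_init(g, tau_range_override = c(50, 60)), "no candidates")
})

test_that("posterior updates match hand Bayes on a tiny lattice", {
  sq <- small_qyn()
  st <- sq$state; g <- sq$grid
  expect_equal(st$dims, c(5L, 1L, 1L))
  # likelihood of "yes" at the lowest level for each threshold candidate
  psi <- vapply(st$tau_grid, function(tau) {
    psi_qyn(10^g$levels_log10[1],
            qyn_model(tau = 10^tau, gamma_slope = 1.5, lam = 1))
  }, numeric(1))
  st_yes <- qyn_update(st, g$levels_log10[1], 1)
  expect_equal(st_yes$posterior, psi / sum(psi), tolerance = 1e-9)
  st_no <- qyn_update(st, g$levels_log10[1], 0)
  expect_equal(st_no$posterior, (1 - psi) / sum(1 - psi), tolerance = 1e-9)
  # repeated "no" at the top concentration pushes mass to high thresholds
  st2 <- st
  for (i in 1:6) st2 <- qyn_update(st2, g$levels_log10[3], 0)
  expect_gt(sum(st2$posterior[4:5]), 0.95)
  # a single-cell lattice is inert
  one <- qyn_init(build_log_grid(1, 10, 2))
  one$posterior <- 1; one$dims <- c(1L, 1L, 1L)
  one$lik <- one$lik[, 1, drop = FALSE]
  one$tau_grid <- one$tau_grid[1]
  upd <- qyn_update(one, 0, 1)
  expect_equal(upd$posterior, 1)
})

test_that("expected entropy matches brute-force enumeration and conditioning bounds", {
  sq <- small_qyn(n_lambda = 2, lambda_range = c(0.75, 2.5))
  st <- sq$state; g <- sq$grid
  # shape the posterior so the check is not at the uniform special case
  st$posterior <- seq_along(st$posterior)
  st$posterior <- st$posterior / sum(st$posterior)
  # cell order: threshold varies fastest, then slope, then criterion
  cells <- expand.grid(tau = st$tau_grid, gamma = st$gamma_grid,
                       lam = st$lambda_grid)
  for (cand in g$levels_log10) {
    # brute force: enumerate both outcomes with explicit Bayes + entropy,
    # recomputing the likelihood from the psychometric function itself
    p_cell <- mapply(function(tau, gam, lam) {
      psi_qyn(10^cand, qyn_model(tau = 10^tau, gamma_slope = gam, lam = lam))
    }, cells$tau, cells$gamma, cells$lam)
    p_cell <- pmin(pmax(p_cell, 1e-12), 1 - 1e-12)
    h <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
    py <- sum(st$posterior * p_cell)
    post_y <- st$posterior * p_cell / py
    post_n <- st$posterior * (1 - p_cell) / (1 - py)
    eh_oracle <- py * h(post_y) + (1 - py) * h(post_n)
    expect_equal(qyn_expected_entropy(st, cand), eh_oracle, tolerance = 1e-10)
    # conditioning can only reduce expected entropy
    expect_lte(qyn_expected_entropy(st, cand), h(st$posterior) + 1e-12)
  }
  # point-mass posterior: zero expected entropy everywhere
  st$posterior <- rep(0, length(st$posterior)); st$posterior[3] <- 1
  for (cand in g$levels_log10) {
    expect_equal(qyn_expected_entropy(st, cand), 0, tolerance = 1e-12)
  }
})

test_that("stimulus selection minimizes expected entropy with lower-tie-break", {
  sq <- small_qyn(n_lambda = 2, lambda_range = c(0.75, 2.5))
  st <- sq$state; g <- sq$grid
  # first trial is the predefined start level
  expect_equal(qyn_propose(st, g), g$start_index)
  # afterwards: exhaustive-search oracle over all physical levels
  set.seed(3)
  st <- qyn_update(st, g$start_level, 1)
  eh <- vapply(g$levels_log10, function(cc) {
    idx <- snap_to_physical(cc, g)
    p_cell <- st$lik[idx, ]
    h <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
    py <- sum(st$posterior * p_cell)
    py * h(st$posterior * p_cell / py) +
      (1 - py) * h(st$posterior * (1 - p_cell) / (1 - py))
  }, numeric(1))
  expect_equal(qyn_propose(st, g), which.min(eh))
  # all-tied candidates (point mass) resolve to the lowest concentration
  st$posterior <- rep(0, length(st$posterior)); st$posterior[2] <- 1
  expect_equal(qyn_propose(st, g), 1L)
})

test_that("qYN always runs exactly its fixed trial count", {
  sq <- small_qyn()
  st <- sq$state
  expect_false(qyn_should_stop(st))
  for (i in 1:19) st <- push_history(st, 1L, sq$grid, 0)
  expect_false(qyn_should_stop(st))
  st <- push_history(st, 1L, sq$grid, 0)
  expect_true(qyn_should_stop(st))
})

test_that("marginal estimates recover point masses and grid means", {
  g <- citric()
  st <- qyn_init(g)
  # point mass at a known cell
  i_tau <- 13L; i_gam <- 4L; i_lam <- 6L
  post <- array(0, dim = st$dims)
  post[i_tau, i_gam, i_lam] <- 1
  st$posterior <- as.vector(post)
  est <- qyn_estimates(st, g)
  expect_equal(est$threshold_log10_mM, st$tau_grid[i_tau])
  expect_equal(est$slope, st$gamma_grid[i_gam])
  expect_equal(est$lambda_hat, st$lambda_grid[i_lam])
  expect_equal(est$far, 1 - pnorm(st$lambda_grid[i_lam]))
  # uniform criterion marginal averages to the grid midpoint, 1.625
  st2 <- qyn_init(g)
  est2 <- qyn_estimates(st2, g)
  expect_equal(est2$lambda_hat, 1.625, tolerance = 1e-12)
  # the averaged-transform alternative differs from the default pathway
  est3 <- qyn_estimates(st2, g, far_method = "mean_transform")
  expect_equal(est3$far, mean(1 - pnorm(st2$lambda_grid)), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(est2$far, est3$far)))
  # a symmetric threshold marginal estimates its center
  post <- array(0, dim = st$dims)
  post[10, 1, 1] <- 0.5; post[16, 1, 1] <- 0.5
  st$posterior <- as.vector(post)
  expect_equal(qyn_estimates(st, g)$threshold_log10_mM,
               mean(st$tau_grid[c(10, 16)]))
})
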