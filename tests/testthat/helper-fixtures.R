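# shared fixtures: tiny grids and hand-built engine states

toy_grid3 <- function() build_log_grid(1, 100, 3, name = "toy3")  # levels 0,1,2

citric <- function() tastant_grid("citric_acid")

# minimal quest_state with an explicit tau grid, for hand-Bayes oracles
make_quest_state <- function(grid, tau_grid, posterior = NULL,
                             model = quest_model()) {
  if (is.na(model$epsilon)) model$epsilon <- solve_epsilon(model)
  if (is.null(posterior)) posterior <- rep(1 / length(tau_grid), length(tau_grid))
  lik <- outer(grid$levels_log10, tau_grid, function(cc, tau) {
    vapply(seq_along(cc), function(i) {
      m <- model; m$tau <- tau[i]
      psi_quest(cc[i], m)
    }, numeric(1))
  })
  structure(
    list(tau_grid = tau_grid, posterior = posterior,
         history = data.frame(trial = integer(), level_index = integer(),
                              c_log10 = numeric(), response = integer()),
         model = model, grid = grid, lik = lik),
    class = "quest_state")
}

# append a fake trial to an engine state's history without updating
push_history <- function(state, level_index, grid, response) {
  state$history <- rbind(
    state$history,
    data.frame(trial = nrow(state$history) + 1L,
               level_index = level_index,
               c_log10 = grid$levels_log10[level_index],
               response = as.integer(response)))
  state
}
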