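# shared fixtures: a faster mesh for routine tests (the default 401-node
# mesh is exercised in the solver and acceptance files)
fast_config <- function(...) {
  sed_config(solver = list(n = 201), ...)
}

# cache expensive reference solves within one test run
.fixture_env <- new.env(parent = emptyenv())

fixture_fit <- function(gamma0 = 3.9, da_star = 3.7, psi0 = 10,
                        config = fast_config()) {
  key <- paste(gamma0, da_star, psi0, config_hash(config), sep = "|")
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- solve_profile(
      nondim_params(gamma0, da_star, psi0, config = config), config
    )
  }
  .fixture_env[[key]]
}

fixture_grid <- function(seed = 42, n_cells = 120) {
  key <- paste("grid", seed, n_cells, sep = "|")
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- synthesize_grid(seed = seed, n_cells = n_cells)
  }
  .fixture_env[[key]]
}
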