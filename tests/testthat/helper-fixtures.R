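# shared builders for small test problems

tiny_grid <- function(n = 10, cell = 1) make_grid(n * cell, n * cell, cell)

# scenario scaled down for fast generator tests; any argument can be
# overridden
small_scenario <- function(...) {
  args <- list(window_km = c(10, 10), pop_per_agegroup = 2e4,
               target_total_cases = 300, target_birth_cases = 200)
  do.call(scenario_config, utils::modifyList(args, list(...)))
}

# intercept-only Poisson data on a small grid with flat offset
flat_model <- function(n = 10, E_per_cell = 50, mesh_spacing = 2.5,
                       buffer = 5) {
  grid <- tiny_grid(n)
  mesh <- build_mesh(grid, mesh_spacing, buffer)
  A <- make_projector(mesh, grid$cells)
  K <- nrow(grid$cells)
  E <- rep(E_per_cell, K)
  list(grid = grid, mesh = mesh, A = A, E = E, K = K)
}
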