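# Shared fixtures: coarse solver settings keep single simulations around a
# second, and a cache avoids re-running identical cycles across test files.

coarse_control <- function(...) {
  solver_control(nodes_per_branch = 8, steps_per_cycle = 100,
                 max_cycles = 60, ...)
}

tiny_control <- function(...) {
  solver_control(nodes_per_branch = 6, steps_per_cycle = 60,
                 max_cycles = 60, periodicity_tol = 1e-5, ...)
}

.cycle_cache <- new.env(parent = emptyenv())

cached_cycle <- function(key, expr) {
  if (!exists(key, envir = .cycle_cache))
    assign(key, force(expr), envir = .cycle_cache)
  get(key, envir = .cycle_cache)
}

# relative-error expectation: robust for quantities of small magnitude (mol/s),
# where expect_equal's tolerance would be interpreted absolutely
expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual / expected - 1), tol)
}

rest_cycle_coarse <- function() {
  cached_cycle("rest_coarse", {
    run_to_periodic(lung_model(), ventilation_pattern(1, 5),
                    control = coarse_control())
  })
}
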