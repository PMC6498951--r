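test_that("u = 0 steady state reproduces the closed-form conductive profile", {
  tree <- airway_tree(conductive = 17, acinar = 0)
  for (gas in list(o2_species(), co2_species(150))) {
    for (M in c(6, 12)) {
      num <- steady_state_profile(tree, gas, P_sink = 40, nodes_per_branch = M)
      ref <- conductive_profile(tree, gas$P_air, 40, nodes_per_branch = M)
      expect_lt(max(abs(num$pressure_mmHg - ref$pressure_mmHg)), 1e-9)
    }
  }
})

test_that("closed-form profile collapses correctly at h = 1/2", {
  tree <- airway_tree(h = 0.5, conductive = 5, acinar = 0)
  prof <- conductive_profile(tree, 100, 0, nodes_per_branch = 2)
  # 1/(2h) = 1: drop is linear in cumulative depth, 1/(N+1) per generation
  ends <- prof$pressure_mmHg[prof$x_m > 0]
  expect_equal(ends, 100 - 100 * (1:5) / 5)
  starts <- prof$pressure_mmHg[seq(1, 9, by = 2)]
  expect_equal(starts, 100 - 100 * (0:4) / 5)
})

test_that("initial state starts at the inlet pressure and decreases inward", {
  model <- lung_model()
  st <- initialize_state(model)
  prof <- conductive_profile(model$tree, model$o2$P_air,
                             model$blood$Pa_o2_eff, 10)
  expect_equal(prof$pressure_mmHg[1], 150)          # trachea inlet exactly
  expect_true(all(diff(prof$pressure_mmHg[1:10]) < 0))
  # root-to-leaf monotone toward the blood pressure for O2
  expect_true(all(diff(st$x_o2) <= 1e-12))
  expect_equal(st$x_o2[length(st$x_o2)], model$blood$Pa_o2_eff)
  # CO2 rises from ambient toward the arterial value
  expect_true(all(diff(st$x_co2) >= -1e-12))
})

test_that("a uniform field with closed ends is a fixed point of the stepper", {
  # conductive-only tree: no exchange anywhere, closed distal end
  tree <- airway_tree(conductive = 5, acinar = 0)
  gas <- o2_species(P_air = 120)
  model <- lung_model(tree = tree, o2 = gas, co2 = co2_species(120),
                      solver = solver_control(nodes_per_branch = 7,
                                              distal_bc = "closed"))
  st <- initialize_state(model)
  st$x_o2[] <- 120
  st$x_co2[] <- 120
  pat <- ventilation_pattern(0.8, 4)
  for (i in 1:5) st <- advance_timestep(st, model, pat, dt = 0.05)
  # round-off only (the junction rows are volume-scaled, so the linear solves
  # leave ~1e-10 mmHg residue)
  expect_equal(st$x_o2, rep(120, length(st$x_o2)), tolerance = 1e-8)
  expect_equal(st$x_co2, rep(120, length(st$x_co2)), tolerance = 1e-8)
})

test_that("near-constant advection translates a front at the right speed", {
  # single wide branch, fine grid; u ~ A around the crest of the sine
  tree <- airway_tree(r0 = 0.02, conductive = 1, acinar = 0)
  gas <- gas_species("O2", D_air = 1e-9, D_water = 3.3e-9,
                     sigma_blood = 1.34e-3, henry = 2.592e-2, P_air = 100)
  M <- 80
  model <- lung_model(tree = tree, o2 = gas, co2 = co2_species(0.3),
                      solver = solver_control(nodes_per_branch = M,
                                              distal_bc = "closed"))
  st <- initialize_state(model)
  l <- tree$generations$length_m[1]
  x <- seq(0, l, length.out = M)[-1]          # unknowns are nodes 2..M
  # front decreasing from the inlet value (consistent with the Dirichlet BC)
  sig <- function(z) 100 / (1 + exp((z - 0.4 * l) / (0.03 * l)))
  st$x_o2 <- sig(x); st$x_co2 <- sig(x)

  Tlong <- 400
  u <- 0.01                                    # ~ A sin(pi/2)
  pat <- ventilation_pattern(u, Tlong)
  st$time <- Tlong / 4                          # crest of the sine
  dt <- 0.05
  nstep <- 40
  for (i in seq_len(nstep)) st <- advance_timestep(st, model, pat, dt = dt)

  # the mid-value crossing advances by ~ u * t (tolerate upwind smearing)
  crossing <- function(vals) {
    i <- max(which(vals > 50))
    x[i] + (vals[i] - 50) / (vals[i] - vals[i + 1]) * (x[i + 1] - x[i])
  }
  shift <- crossing(st$x_o2) - crossing(sig(x))
  expect_gt(shift / (u * dt * nstep), 0.75)
  expect_lt(shift / (u * dt * nstep), 1.25)
})

test_that("rest ventilation reaches a periodic regime with physiological flows", {
  cyc <- rest_cycle_coarse()
  expect_true(cyc$converged)
  expect_lt(cyc$residuals[length(cyc$residuals)], 1e-6)
  # oxygen uptake in the physiological band 1-2e-4 mol/s
  expect_gt(cyc$flows$vo2, 1e-4)
  expect_lt(cyc$flows$vo2, 2e-4)
  expect_gt(cyc$flows$vco2, 0.5e-4)
  expect_lt(cyc$flows$vco2, 2e-4)
  expect_gt(cyc$flows$rer, 0.4)
  expect_lt(cyc$flows$rer, 1.0)

  expect_equal(species_flux_per_cycle(cyc, "o2"), cyc$flows$vo2)
  expect_equal(species_flux_per_cycle(cyc, "co2"), cyc$flows$vco2)
  expect_equal(respiratory_exchange_ratio(cyc), cyc$flows$rer)
  expect_error(respiratory_exchange_ratio(list(vo2 = 0, vco2 = 1)), "VO2")

  # pressure bounds: O2 within [efficace arterial, ambient]; CO2 within
  # [ambient, arterial]
  expect_gt(min(cyc$hist_o2), 88 - 1e-6)
  expect_lt(max(cyc$hist_o2), 150 + 1e-6)
  expect_gt(min(cyc$hist_co2), 0.3 - 1e-6)
  expect_lt(max(cyc$hist_co2), 47 + 1e-6)
})

test_that("cycle flows are grid-stable and warm starts agree", {
  cyc <- rest_cycle_coarse()
  finer <- run_to_periodic(lung_model(), ventilation_pattern(1, 5),
                           control = solver_control(nodes_per_branch = 8,
                                                    steps_per_cycle = 200,
                                                    max_cycles = 60))
  expect_rel(cyc$flows$vo2, finer$flows$vo2, 0.05)

  warm <- run_to_periodic(lung_model(), ventilation_pattern(1, 5),
                          control = coarse_control(), init = cyc$state)
  expect_rel(warm$flows$vo2, cyc$flows$vo2, 2e-3)
  expect_lte(warm$cycles, 3)
})

test_that("periodic O2 uptake balances the trachea influx", {
  cyc <- rest_cycle_coarse()
  infl_o2 <- trachea_influx(cyc, "o2")
  expect_rel(infl_o2, cyc$flows$vo2, 0.10)
  infl_co2 <- trachea_influx(cyc, "co2")
  expect_rel(-infl_co2, cyc$flows$vco2, 0.10)
})

test_that("no-ventilation limit converges to the diffusion steady state", {
  # diffusive relaxation of the conductive tree is slow (hundreds of seconds),
  # so the tolerance here tracks steadiness of the field, not machine zero
  ctl <- solver_control(nodes_per_branch = 6, steps_per_cycle = 30,
                        max_cycles = 200, periodicity_tol = 1e-7)
  cyc <- run_to_periodic(lung_model(solver = ctl), ventilation_pattern(0, 5))
  expect_true(cyc$converged)
  # the O2 field is time-independent: first and last step of the cycle agree
  expect_equal(cyc$hist_o2[1, ], cyc$hist_o2[30, ], tolerance = 1e-5)
  # uptake equals the steady diffusive flux through the tree (small, positive)
  expect_gt(cyc$flows$vo2, 0)
  expect_lt(cyc$flows$vo2, 2e-5)
})

test_that("adimensional numbers follow their scalings", {
  tree <- airway_tree()
  pat <- ventilation_pattern(1, 5)
  ad <- adimensional_profile(tree, pat, o2_species(), blood_params())
  expect_equal(nrow(ad), 23)
  # Peclet ratio between consecutive conductive generations = 1/(2h)
  pe <- ad$Pe[1:17]
  expect_equal(pe[-1] / pe[-17], rep(1 / (2 * 0.7937), 16), tolerance = 1e-12)
  # gamma defined on the acinus only, of order 1
  expect_true(all(is.na(ad$gamma[1:17])))
  expect_true(all(ad$gamma[18:23] > 0.3 & ad$gamma[18:23] < 10))
  # Pe linear in the amplitude
  ad2 <- adimensional_profile(tree, ventilation_pattern(2, 5), o2_species(),
                              blood_params())
  expect_equal(ad2$Pe, 2 * ad$Pe)
  # alpha = l^2/(DT)
  expect_equal(ad$alpha[1], 0.06^2 / (0.2e-4 * 5))
})

test_that("pressure profile extraction is shaped correctly", {
  cyc <- rest_cycle_coarse()
  pp <- pressure_profiles(cyc)
  expect_named(pp, c("generation", "x_m", "P_O2_mmHg", "P_CO2_mmHg"))
  expect_equal(nrow(pp), 23 * 8)
  expect_equal(pp$P_O2_mmHg[1], 150)    # inlet node at ambient
  expect_error(pressure_profiles(cyc, step = 1e5), "out of range")
})
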