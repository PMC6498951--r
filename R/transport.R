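#' Closed-form steady conductive profile
#'
#' The explicit steady solution of the diffusion problem (u = 0, no acinar
#' exchange) in the conductive tree, P_air at the trachea inlet and `P_blood`
#' at the distal end of the last conductive generation. Per generation i
#' (0-based) the profile is linear in x with
#'   P_i(x) = P_air + (P_blood - P_air)/sum_k (1/2h)^k *
#'            (sum_{k<i} (1/2h)^k + (1/2h)^i x/l_i),
#' the normalizing sum running over the conductive generations.
#'
#' @param tree an [airway_tree()].
#' @param P_air inlet partial pressure (mmHg).
#' @param P_blood distal pressure (mmHg).
#' @param nodes_per_branch grid nodes per branch at which to evaluate.
#' @return data frame with `generation` (0-based), `x_m` (position along the
#'   branch), `pressure_mmHg`.
#' @export
conductive_profile <- function(tree, P_air, P_blood, nodes_per_branch = 10) {
  M <- as.integer(nodes_per_branch)
  prof <- conductive_profile_matrix(tree, P_air, P_blood, M)
  nc <- tree$conductive
  len <- tree$generations$length_m[seq_len(nc)]
  data.frame(
    generation = rep(seq_len(nc) - 1L, each = M),
    x_m = as.vector(vapply(len, function(l) seq(0, l, length.out = M),
                           numeric(M))),
    pressure_mmHg = as.vector(prof)
  )
}

#' Steady-state pressure field with no ventilation
#'
#' Direct solve of the spatially discretized system with u = 0 and no acinar
#' reaction term, a Dirichlet inlet at `P_air` and a Dirichlet distal sink.
#' This exercises the same assembly as the time stepper (with the time
#' derivative dropped) and is the numerical counterpart of
#' [conductive_profile()] on a purely conductive tree.
#'
#' @param tree an [airway_tree()].
#' @param gas a [gas_species()].
#' @param P_sink distal sink pressure (mmHg).
#' @param nodes_per_branch grid nodes per branch.
#' @return data frame `generation`, `x_m`, `pressure_mmHg` over all nodes.
#' @export
steady_state_profile <- function(tree, gas, P_sink, nodes_per_branch = 10) {
  control <- solver_control(nodes_per_branch = nodes_per_branch,
                            distal_bc = "dirichlet", distal_sink = P_sink)
  disc <- discretize(tree, nodes_per_branch)
  gs <- gas_static(disc, gas, blood_params(), control)
  gs$beta_gen[] <- 0
  gs$jun_sink[] <- 0
  bands <- assemble_bands(disc, gs, control, u0val = 0, inv_dt = 0)
  rhs <- numeric(disc$n)
  rhs[1L] <- bands$d1
  rhs[disc$robin_idx] <- P_sink
  x <- as.numeric(Matrix::solve(band_matrix(bands, disc$n), rhs))
  field_to_frame(disc, tree, expand_field(disc, x, gas$P_air))
}

field_to_frame <- function(disc, tree, P) {
  M <- disc$M
  ngen <- disc$ngen
  data.frame(
    generation = rep(seq_len(ngen) - 1L, each = M),
    x_m = as.vector(vapply(tree$generations$length_m,
                           function(l) seq(0, l, length.out = M), numeric(M))),
    pressure_mmHg = as.vector(P)
  )
}

#' Initialize the transport state
#'
#' Conductive generations start on the closed-form steady profile toward the
#' arterial pressure of the gas (the efficace pressure for O2), acinar
#' pressures start constant at the profile's distal value, and junction
#' pressures at the matching branch-end values.
#'
#' @param model a [lung_model()].
#' @param control optional [solver_control()] override.
#' @return An object of class `transport_state`: unknown vectors `x_o2`,
#'   `x_co2` and the `time` (s).
#' @export
initialize_state <- function(model, control = NULL) {
  control <- control %||% model$solver
  disc <- discretize(model$tree, control$nodes_per_branch)
  structure(list(
    x_o2 = initial_unknowns(disc, model$tree, model$o2$P_air,
                            model$blood$Pa_o2_eff),
    x_co2 = initial_unknowns(disc, model$tree, model$co2$P_air,
                             model$blood$Pa_co2),
    time = 0
  ), class = "transport_state")
}

#' Advance the coupled transport system by one implicit time step
#'
#' One backward-Euler step of the fully coupled tridiagonal system for both
#' gases: centered diffusion, first-order upwind convection (direction
#' following the sign of the trachea velocity at the new time level),
#' bifurcation mass-balance rows, Dirichlet inlet and the configured distal
#' boundary. Blood-side pressures are evaluated from the previous time level.
#'
#' @param state a `transport_state` (see [initialize_state()]).
#' @param model a [lung_model()].
#' @param pattern a [ventilation_pattern()].
#' @param dt time step (s), positive.
#' @param control optional [solver_control()] override.
#' @return the advanced `transport_state`.
#' @export
advance_timestep <- function(state, model, pattern, dt, control = NULL) {
  if (!is.numeric(dt) || dt <= 0) stop("dt must be positive")
  control <- control %||% model$solver
  disc <- discretize(model$tree, control$nodes_per_branch)
  gs_o2 <- gas_static(disc, model$o2, model$blood, control)
  gs_co2 <- gas_static(disc, model$co2, model$blood, control)
  t_new <- state$time + dt
  u0 <- pattern$u0(t_new)

  step <- step_once(state$x_o2, state$x_co2, disc, model, control,
                    gs_o2, gs_co2,
                    fac_o2 = NULL, fac_co2 = NULL, u0 = u0, dt = dt,
                    pb_init = NULL)
  structure(list(x_o2 = step$x_o2, x_co2 = step$x_co2, time = t_new),
            class = "transport_state")
}

# Blood coupling + one linear solve for both gases. If factors are NULL the
# bands are assembled and factorized on the fly (single-step use); the cycle
# driver passes pre-factorized operators.
step_once <- function(x_o2, x_co2, disc, model, control, gs_o2, gs_co2,
                      fac_o2, fac_co2, u0, dt, pb_init) {
  ex <- blood_coupling(x_o2, x_co2, disc, model, gs_o2, gs_co2, control,
                       pb_init)
  inv_dt <- 1 / dt
  if (is.null(fac_o2)) {
    b_o2 <- assemble_bands(disc, gs_o2, control, u0, inv_dt)
    b_co2 <- assemble_bands(disc, gs_co2, control, u0, inv_dt)
    fac_o2 <- factor_bands(b_o2, disc$n)
    fac_co2 <- factor_bands(b_co2, disc$n)
    w_o2 <- b_o2$w; w_co2 <- b_co2$w; d1_o2 <- b_o2$d1; d1_co2 <- b_co2$d1
  } else {
    w_o2 <- fac_o2$w; w_co2 <- fac_co2$w
    d1_o2 <- fac_o2$d1; d1_co2 <- fac_co2$d1
    fac_o2 <- fac_o2$fac; fac_co2 <- fac_co2$fac
  }

  rhs <- w_o2 * x_o2
  rhs[1L] <- rhs[1L] + d1_o2
  rhs[gs_o2$ex_pos] <- rhs[gs_o2$ex_pos] + gs_o2$ex_coef * ex$pb_o2
  if (identical(control$distal_bc, "dirichlet"))
    rhs[disc$robin_idx] <- control$distal_sink
  x_o2_new <- as.numeric(Matrix::solve(fac_o2, rhs))

  rhs <- w_co2 * x_co2
  rhs[1L] <- rhs[1L] + d1_co2
  rhs[gs_co2$ex_pos] <- rhs[gs_co2$ex_pos] + gs_co2$ex_coef * ex$pb_co2
  if (identical(control$distal_bc, "dirichlet"))
    rhs[disc$robin_idx] <- control$distal_sink
  x_co2_new <- as.numeric(Matrix::solve(fac_co2, rhs))

  # cycle-flux bookkeeping consistent with the implicit equations: exchange
  # uses the new field against the lagged blood pressure
  flux_o2 <- sum(gs_o2$flux_w * (x_o2_new[gs_o2$ex_pos] - ex$pb_o2))
  flux_co2 <- sum(gs_co2$flux_w * (x_co2_new[gs_co2$ex_pos] - ex$pb_co2))

  list(x_o2 = x_o2_new, x_co2 = x_co2_new,
       flux_o2 = flux_o2, flux_co2 = flux_co2, pb_o2 = ex$pb_o2)
}

blood_coupling <- function(x_o2, x_co2, disc, model, gs_o2, gs_co2, control,
                           pb_init) {
  pos <- gs_o2$ex_pos
  if (length(pos) == 0L)
    return(list(pb_o2 = numeric(0), pb_co2 = numeric(0)))
  pb_o2 <- solve_blood_o2(x_o2[pos], model$blood, model$o2, gs_o2$mem,
                          init = pb_init)
  so2 <- hill_fraction(pb_o2)
  pb_co2 <- solve_blood_co2(x_co2[gs_co2$ex_pos], model$blood, model$co2,
                            gs_co2$mem, SO2 = so2)
  list(pb_o2 = pb_o2, pb_co2 = pb_co2)
}

#' March the transport model to the periodic breathing regime
#'
#' Runs whole ventilation cycles of the implicit solver until the relative L2
#' difference of both pressure fields between consecutive cycle starts falls
#' below the periodicity tolerance, then reports the final cycle: per-step
#' exchange-rate series, cycle-averaged molar flows, the respiratory exchange
#' ratio and the full pressure history of the last cycle.
#'
#' The linear operators are periodic in time, so one factorization per time
#' step of the cycle is computed up front and reused across cycles.
#'
#' @param model a [lung_model()].
#' @param pattern a [ventilation_pattern()].
#' @param control optional [solver_control()] override.
#' @param init optional initial `transport_state` (warm start); defaults to
#'   [initialize_state()].
#' @param verbose print per-cycle residuals.
#' @return An object of class `periodic_cycle`: `flows` (list `vo2`, `vco2`
#'   in mol/s, both positive into their physiological direction, and `rer`),
#'   `converged`, `cycles`, `residuals`, per-step `flux_o2`/`flux_co2` series
#'   (air-to-blood, mol/s), `time` grid, pressure histories `hist_o2`,
#'   `hist_co2` (steps x unknowns), and the final `state`.
#' @export
run_to_periodic <- function(model, pattern, control = NULL, init = NULL,
                            verbose = FALSE) {
  control <- control %||% model$solver
  disc <- discretize(model$tree, control$nodes_per_branch)
  gs_o2 <- gas_static(disc, model$o2, model$blood, control)
  gs_co2 <- gas_static(disc, model$co2, model$blood, control)
  K <- control$steps_per_cycle
  dt <- pattern$period / K
  inv_dt <- 1 / dt

  ops_o2 <- vector("list", K)
  ops_co2 <- vector("list", K)
  for (k in seq_len(K)) {
    u0 <- pattern$u0(k * dt)
    b1 <- assemble_bands(disc, gs_o2, control, u0, inv_dt)
    b2 <- assemble_bands(disc, gs_co2, control, u0, inv_dt)
    ops_o2[[k]] <- list(fac = factor_bands(b1, disc$n), w = b1$w, d1 = b1$d1)
    ops_co2[[k]] <- list(fac = factor_bands(b2, disc$n), w = b2$w, d1 = b2$d1)
  }
  u0k <- pattern$u0(seq_len(K) * dt)

  state <- init %||% initialize_state(model, control)
  if (length(state$x_o2) != disc$n)
    stop("initial state does not match the discretization (",
         length(state$x_o2), " vs ", disc$n, " unknowns)")
  x_o2 <- state$x_o2
  x_co2 <- state$x_co2

  hist_o2 <- matrix(NA_real_, K, disc$n)
  hist_co2 <- matrix(NA_real_, K, disc$n)
  flux_o2 <- numeric(K)
  flux_co2 <- numeric(K)
  residuals <- numeric(0)
  converged <- FALSE
  pb_warm <- NULL
  cycles <- 0L

  for (cyc in seq_len(control$max_cycles)) {
    x0_o2 <- x_o2; x0_co2 <- x_co2
    for (k in seq_len(K)) {
      st <- step_once(x_o2, x_co2, disc, model, control, gs_o2, gs_co2,
                      ops_o2[[k]], ops_co2[[k]], u0 = u0k[k], dt = dt,
                      pb_init = pb_warm)
      x_o2 <- st$x_o2; x_co2 <- st$x_co2
      pb_warm <- st$pb_o2
      hist_o2[k, ] <- x_o2
      hist_co2[k, ] <- x_co2
      flux_o2[k] <- st$flux_o2
      flux_co2[k] <- st$flux_co2
    }
    cycles <- cyc
    res <- max(
      sqrt(sum((x_o2 - x0_o2)^2) / max(sum(x0_o2^2), 1e-300)),
      sqrt(sum((x_co2 - x0_co2)^2) / max(sum(x0_co2^2), 1e-300))
    )
    residuals <- c(residuals, res)
    if (verbose)
      message(sprintf("cycle %3d: residual %.3e", cyc, res))
    if (res < control$periodicity_tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf(
      "periodic regime not reached in %d cycles (last residual %.3e)",
      control$max_cycles, residuals[length(residuals)]))
  if (min(hist_o2) < -1e-6 || min(hist_co2) < -1e-6)
    warning("negative partial pressures detected; the time step or grid is ",
            "too coarse for this ventilation pattern")

  vo2 <- mean(flux_o2)
  vco2 <- -mean(flux_co2)
  structure(list(
    flows = list(vo2 = vo2, vco2 = vco2,
                 rer = if (vo2 > 0) vco2 / vo2 else NA_real_),
    converged = converged, cycles = cycles, residuals = residuals,
    flux_o2 = flux_o2, flux_co2 = flux_co2,
    time = seq_len(K) * dt,
    hist_o2 = hist_o2, hist_co2 = hist_co2,
    state = structure(list(x_o2 = x_o2, x_co2 = x_co2,
                           time = cycles * pattern$period),
                      class = "transport_state"),
    pattern = pattern, control = control, disc = disc, tree = model$tree,
    P_air = c(o2 = model$o2$P_air, co2 = model$co2$P_air),
    D_air = c(o2 = model$o2$D_air, co2 = model$co2$D_air)
  ), class = "periodic_cycle")
}

#' @export
print.periodic_cycle <- function(x, ...) {
  cat(sprintf(
    "Periodic ventilation cycle (A = %.3g m/s, T = %.3g s): %s in %d cycles\n",
    x$pattern$amplitude, x$pattern$period,
    if (x$converged) "converged" else "NOT converged", x$cycles))
  cat(sprintf("  VO2 = %.4g mol/s, VCO2 = %.4g mol/s, RER = %.3f\n",
              x$flows$vo2, x$flows$vco2, x$flows$rer))
  invisible(x)
}

#' Cycle-averaged molar gas flow
#'
#' Average over the final cycle of the instantaneous molar exchange between
#' acinar air and blood (distributed reaction term plus the distal membrane
#' flux), converted from mmHg-volume to moles with the ideal-gas factor at
#' body temperature. Positive in the physiological direction: air-to-blood
#' for O2, blood-to-air for CO2.
#'
#' @param cycle a `periodic_cycle` from [run_to_periodic()].
#' @param gas `"o2"` or `"co2"`.
#' @return molar flow (mol/s).
#' @export
species_flux_per_cycle <- function(cycle, gas = c("o2", "co2")) {
  gas <- match.arg(gas)
  if (!cycle$converged)
    warning("flux evaluated on a non-periodic history (residual ",
            format(cycle$residuals[length(cycle$residuals)], digits = 3), ")")
  if (gas == "o2") mean(cycle$flux_o2) else -mean(cycle$flux_co2)
}

#' Respiratory exchange ratio
#'
#' RER = VCO2 / VO2 of a flow result.
#'
#' @param flows either the `flows` element of a `periodic_cycle` (or the cycle
#'   itself), or a list/vector with elements `vo2` and `vco2` in mol/s.
#' @return dimensionless ratio.
#' @export
respiratory_exchange_ratio <- function(flows) {
  if (inherits(flows, "periodic_cycle")) flows <- flows$flows
  vo2 <- flows[["vo2"]]; vco2 <- flows[["vco2"]]
  if (!is.finite(vo2) || vo2 <= 0)
    stop("RER undefined: VO2 must be positive, got ", format(vo2))
  vco2 / vo2
}

#' Net molar influx of a gas through the trachea inlet
#'
#' Cycle-averaged advective plus diffusive flux through the inlet face,
#' upwinding the advected value (ambient air during inspiration, the
#' near-inlet field during expiration). At the periodic regime this balances
#' the net acinar uptake up to the discretization error of the upwind scheme.
#'
#' @param cycle a `periodic_cycle`.
#' @param gas `"o2"` or `"co2"`.
#' @return molar flow into the tree (mol/s).
#' @export
trachea_influx <- function(cycle, gas = c("o2", "co2")) {
  gas <- match.arg(gas)
  hist <- if (gas == "o2") cycle$hist_o2 else cycle$hist_co2
  P_air <- cycle$P_air[[gas]]
  disc <- cycle$disc
  u0 <- cycle$pattern$u0(cycle$time)
  S0 <- disc$S[1L]
  dx1 <- disc$dx[1L]
  D <- cycle$D_air[[gas]]
  P2 <- hist[, 1L]                       # first interior node of generation 0
  adv <- ifelse(u0 >= 0, u0 * P_air, u0 * P2)
  dif <- -D * (P2 - P_air) / dx1
  mean(S0 * (adv + dif)) / .K_AIR
}

#' Pressure profiles of the final cycle
#'
#' Extracts the full pressure field of one time step of the converged cycle
#' as a tidy table, one row per grid node and gas.
#'
#' @param cycle a `periodic_cycle`.
#' @param step time-step index in 1..steps_per_cycle; default the peak
#'   inspiratory flow (a quarter period).
#' @return data frame `generation`, `x_m`, `P_O2_mmHg`, `P_CO2_mmHg`.
#' @export
pressure_profiles <- function(cycle, step = NULL) {
  K <- nrow(cycle$hist_o2)
  step <- step %||% max(1L, round(K / 4))
  if (step < 1L || step > K) stop("step index out of range 1..", K)
  disc <- cycle$disc
  f_o2 <- field_to_frame(disc, cycle$tree,
                         expand_field(disc, cycle$hist_o2[step, ],
                                      cycle$P_air[["o2"]]))
  f_co2 <- field_to_frame(disc, cycle$tree,
                          expand_field(disc, cycle$hist_co2[step, ],
                                       cycle$P_air[["co2"]]))
  data.frame(f_o2[, c("generation", "x_m")],
             P_O2_mmHg = f_o2$pressure_mmHg,
             P_CO2_mmHg = f_co2$pressure_mmHg)
}

#' Adimensional transport numbers per generation
#'
#' alpha_i = l_i^2/(D T) (transitory vs diffusion), Pe_i = l_i u_i/D
#' (convection vs diffusion, at the peak velocity of the generation), and
#' gamma_i = beta l_i^2/D (blood absorption vs diffusion, acinar generations
#' only).
#'
#' @param tree an [airway_tree()].
#' @param pattern a [ventilation_pattern()].
#' @param gas a [gas_species()].
#' @param blood a [blood_params()].
#' @return data frame `generation`, `zone`, `alpha`, `Pe`, `gamma`.
#' @export
adimensional_profile <- function(tree, pattern, gas, blood) {
  g <- tree$generations
  vf <- velocity_factors(tree)
  D <- gas$D_air
  r_A <- g$radius_m[nrow(g)]
  beta <- exchange_beta(gas, blood, r_A)$beta
  gamma <- ifelse(g$zone == "acinar", beta * g$length_m^2 / D, NA_real_)
  data.frame(
    generation = g$generation,
    zone = g$zone,
    alpha = g$length_m^2 / (D * pattern$period),
    Pe = g$length_m * vf * pattern$amplitude / D,
    gamma = gamma
  )
}

#' Run one ventilation pattern to its periodic regime
#'
#' Convenience wrapper building the pattern and returning the converged cycle.
#'
#' @param model a [lung_model()].
#' @param amplitude trachea velocity amplitude (m/s).
#' @param period breathing period (s).
#' @param control optional [solver_control()] override.
#' @param init optional warm-start `transport_state`.
#' @return a `periodic_cycle`.
#' @export
simulate_ventilation <- function(model, amplitude, period, control = NULL,
                                 init = NULL) {
  run_to_periodic(model, ventilation_pattern(amplitude, period),
                  control = control, init = init)
}
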