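#' Reference activity table
#'
#' Oxygen consumption of increasing physical activities (mL O2 per kg per
#' minute) for a 70 kg subject, used by the exercise series.
#'
#' @return data frame `activity`, `ml_o2_per_kg_min`.
#' @export
activity_demands <- function() {
  data.frame(
    activity = c("walking_5kmh", "bicycling_15kmh", "jogging_9kmh",
                 "basketball", "ice_hockey"),
    ml_o2_per_kg_min = c(11.2, 20.65, 30.80, 38.85, 45.15)
  )
}

#' Altitude table
#'
#' Ambient oxygen partial pressure as a percentage of the sea-level value.
#'
#' @return data frame `altitude_m`, `o2_fraction_pct`.
#' @export
altitude_table <- function() {
  data.frame(
    altitude_m = c(0, 1000, 2000, 3000, 4000),
    o2_fraction_pct = c(100, 89, 79, 69, 60)
  )
}

#' Convert a metabolic oxygen demand to a molar flow
#'
#' mL O2 per kg per minute to mol/s via the ideal-gas molar volume at body
#' temperature and 1 atm.
#'
#' @param ml_per_kg_min demand (mL O2 kg^-1 min^-1).
#' @param mass_kg body mass (kg), default 70.
#' @return oxygen flow (mol/s).
#' @export
metabolic_demand_mol_s <- function(ml_per_kg_min, mass_kg = 70) {
  stopifnot(ml_per_kg_min > 0, mass_kg > 0)
  ml_per_kg_min * mass_kg * 1e-6 / 60 / .V_MOLAR
}

#' Reference rest oxygen demand
#'
#' The resting metabolic rate of 3.5 mL O2 per kg per minute (1 MET) for a
#' 70 kg subject, converted with the same ideal-gas convention as the activity
#' table: about 1.6e-4 mol/s. This is the demand under which the constrained
#' power optimization reproduces the reference rest ventilation (optimal
#' period near 8 s, amplitude near 0.9 m/s). An alternative anchor is the
#' oxygen uptake of the calibrated rest simulation itself (`calibrated`,
#' 1.32e-4 mol/s).
#'
#' @param convention `"met"` (default, 3.5 mL/kg/min x 70 kg) or
#'   `"calibrated"` (the rest-simulation uptake).
#' @return oxygen flow (mol/s).
#' @export
rest_oxygen_demand <- function(convention = c("met", "calibrated")) {
  convention <- match.arg(convention)
  if (convention == "met") metabolic_demand_mol_s(3.5, 70) else 1.32e-4
}

#' Optimal ventilation across exercise intensities
#'
#' Runs the constrained power optimization once per metabolic demand and
#' collects the optimum, its power decomposition and the respiratory exchange
#' ratio (the underlying data of the RER-vs-oxygen-flow response).
#'
#' @param model a [lung_model()].
#' @param demands data frame like [activity_demands()], sorted ascending, or a
#'   numeric vector of demands in mol/s (then used as-is).
#' @param mass_kg body mass for the unit conversion (kg).
#' @param T_bracket,n_grid,control,tol_rel passed to [optimal_ventilation()].
#' @return data frame, one row per demand, with the optimum (T*, A*), powers,
#'   flows, RER and a feasibility flag.
#' @export
run_exercise_series <- function(model, demands = activity_demands(),
                                mass_kg = 70, T_bracket = c(1, 12),
                                n_grid = 9, control = NULL, tol_rel = 1e-3) {
  if (is.data.frame(demands)) {
    F_vals <- metabolic_demand_mol_s(demands$ml_o2_per_kg_min, mass_kg)
    labels <- demands$activity
  } else {
    F_vals <- as.numeric(demands)
    labels <- sprintf("demand_%g", F_vals)
  }
  if (is.unsorted(F_vals)) stop("demands must be sorted ascending")
  rows <- lapply(seq_along(F_vals), function(i) {
    opt <- optimal_ventilation(model, F_vals[i], T_bracket = T_bracket,
                               n_grid = n_grid, control = control,
                               tol_rel = tol_rel)
    optimum_row(labels[i], F_vals[i], opt)
  })
  do.call(rbind, rows)
}

optimum_row <- function(label, F, opt) {
  if (!isTRUE(opt$feasible)) {
    return(data.frame(scenario = label, F_mol_per_s = F, feasible = FALSE,
                      T_star_s = NA_real_, A_star_m_per_s = NA_real_,
                      P_total_W = NA_real_, P_elastic_W = NA_real_,
                      P_viscous_W = NA_real_, VO2_mol_per_s = NA_real_,
                      VCO2_mol_per_s = NA_real_, RER = NA_real_,
                      band_lo_s = NA_real_, band_hi_s = NA_real_))
  }
  data.frame(scenario = label, F_mol_per_s = F, feasible = TRUE,
             T_star_s = opt$T_star, A_star_m_per_s = opt$A_star,
             P_total_W = opt$P_total_W, P_elastic_W = opt$P_elastic_W,
             P_viscous_W = opt$P_viscous_W,
             VO2_mol_per_s = opt$flows$vo2, VCO2_mol_per_s = opt$flows$vco2,
             RER = opt$rer, band_lo_s = opt$band_5pct[1],
             band_hi_s = opt$band_5pct[2])
}

#' Optimal ventilation under altitude hypoxia
#'
#' Scales the ambient oxygen partial pressure by the altitude fraction while
#' holding the demanded oxygen flow at its rest value, and re-optimizes the
#' ventilation at each altitude. Infeasible altitudes (the demand cannot be
#' met at any amplitude) are flagged rather than failing.
#'
#' @param model a [lung_model()] (its `o2$P_air` is the sea-level pressure).
#' @param fractions percentages of the sea-level O2 pressure, default the
#'   altitude table.
#' @param F demanded oxygen flow (mol/s), default the rest demand.
#' @param T_bracket,n_grid,control,tol_rel passed to [optimal_ventilation()].
#' @return data frame, one row per altitude.
#' @export
run_altitude_series <- function(model, fractions = altitude_table(),
                                F = rest_oxygen_demand(),
                                T_bracket = c(1, 15), n_grid = 9,
                                control = NULL, tol_rel = 1e-3) {
  if (is.data.frame(fractions)) {
    pct <- fractions$o2_fraction_pct
    labels <- sprintf("altitude_%gm", fractions$altitude_m)
  } else {
    pct <- as.numeric(fractions)
    labels <- sprintf("o2_%g_pct", pct)
  }
  if (any(pct <= 0 | pct > 100)) stop("fractions must lie in (0, 100] percent")
  rows <- lapply(seq_along(pct), function(i) {
    m <- model
    m$o2$P_air <- model$o2$P_air * pct[i] / 100
    opt <- optimal_ventilation(m, F, T_bracket = T_bracket, n_grid = n_grid,
                               control = control, tol_rel = tol_rel)
    cbind(data.frame(o2_fraction_pct = pct[i]),
          optimum_row(labels[i], F, opt))
  })
  do.call(rbind, rows)
}

#' Optimal ventilation across resistance changes
#'
#' Two modes. `"lumped"`: only the mechanical resistance R is multiplied, the
#' geometry (hence the constraint curve) is unchanged — the optimum then
#' depends on the product RC only. `"h_linked"`: the homothety ratio h is
#' adjusted so the Poiseuille resistance of the conductive tree changes by the
#' same factor; geometry, transport and lumped R are all updated consistently,
#' so both the power profile and the constraint curve move.
#'
#' @param model a [lung_model()].
#' @param multipliers resistance multipliers (>0), e.g. c(0.7, 1, 1.3).
#' @param mode `"h_linked"` (default) or `"lumped"`.
#' @param F demanded oxygen flow (mol/s), default the rest demand.
#' @param T_bracket,n_grid,control,tol_rel passed to [optimal_ventilation()].
#' @return data frame, one row per multiplier, including the homothety ratio
#'   used.
#' @export
run_resistance_sweep <- function(model, multipliers = c(0.7, 1, 1.3),
                                 mode = c("h_linked", "lumped"),
                                 F = rest_oxygen_demand(),
                                 T_bracket = c(2, 15), n_grid = 9,
                                 control = NULL, tol_rel = 1e-3) {
  mode <- match.arg(mode)
  if (any(multipliers <= 0)) stop("resistance multipliers must be positive")
  rows <- lapply(multipliers, function(mult) {
    m <- model
    h_used <- model$tree$h
    if (mode == "h_linked") {
      if (abs(mult - 1) > 1e-12) {
        h_used <- h_for_resistance_ratio(model$tree, mult)
        m$tree <- airway_tree(model$tree$r0, h_used,
                              model$tree$conductive, model$tree$acinar)
      }
      m$mechanics <- mechanics_params(R = model$mechanics$R * mult,
                                      C = model$mechanics$C)
    } else {
      m$mechanics <- mechanics_params(R = model$mechanics$R * mult,
                                      C = model$mechanics$C)
    }
    opt <- optimal_ventilation(m, F, T_bracket = T_bracket, n_grid = n_grid,
                               control = control, tol_rel = tol_rel)
    cbind(data.frame(R_multiplier = mult, mode = mode, h = h_used,
                     R_Pa_s_per_m3 = m$mechanics$R),
          optimum_row(sprintf("R_x%g", mult), F, opt))
  })
  do.call(rbind, rows)
}

#' Oxygen flow under membrane thickening (oedema sweep)
#'
#' Holds the rest ventilation pattern fixed and recomputes the oxygen uptake
#' as the alveolo-capillary membrane thickness tau is multiplied. The exchange
#' coefficient beta scales as 1/tau, so the flow is non-increasing; thanks to
#' screening the flow barely changes at first and collapses once the spare
#' exchange surface is used up.
#'
#' @param model a [lung_model()].
#' @param tau_multipliers thickness multipliers (>= 1 typically).
#' @param pattern ventilation pattern held fixed (default rest).
#' @param control optional [solver_control()] override.
#' @return data frame `tau_multiplier`, `tau_m`, `VO2_mol_per_s`,
#'   `VCO2_mol_per_s`, `RER`.
#' @export
run_oedema_sweep <- function(model, tau_multipliers = 2^(0:9),
                             pattern = ventilation_pattern(1, 5),
                             control = NULL) {
  if (any(tau_multipliers <= 0)) stop("tau multipliers must be positive")
  rows <- lapply(tau_multipliers, function(mult) {
    m <- model
    m$blood$tau <- model$blood$tau * mult
    cyc <- run_to_periodic(m, pattern, control = control)
    data.frame(tau_multiplier = mult, tau_m = m$blood$tau,
               VO2_mol_per_s = cyc$flows$vo2, VCO2_mol_per_s = cyc$flows$vco2,
               RER = cyc$flows$rer)
  })
  do.call(rbind, rows)
}
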