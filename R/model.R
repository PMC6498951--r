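#' Physical constants of one transported gas
#'
#' @param name "O2" or "CO2".
#' @param D_air diffusion coefficient in air (m^2 s^-1).
#' @param D_water diffusion coefficient in water (m^2 s^-1).
#' @param sigma_blood solubility in blood (mol m^-3 mmHg^-1).
#' @param henry dimensionless Henry solubility (aqueous over gas-phase
#'   concentration).
#' @param P_air ambient partial pressure at the trachea inlet (mmHg).
#' @return An object of class `gas_species`.
#' @export
gas_species <- function(name, D_air, D_water, sigma_blood, henry, P_air) {
  vals <- c(D_air = D_air, D_water = D_water, sigma_blood = sigma_blood,
            henry = henry, P_air = P_air)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all gas constants must be positive and finite")
  structure(c(list(name = name), as.list(vals)), class = "gas_species")
}

#' @rdname gas_species
#' @details `o2_species()` and `co2_species()` carry the reference constants:
#'   O2 D_air 0.2e-4, D_water 3.3e-9, sigma 1.34e-3, Henry 2.592e-2; CO2
#'   D_air 0.14e-4, D_water 2.505e-9, sigma 3.07e-2, Henry 0.594. The ambient
#'   partial pressures default to 150 mmHg (O2, humidified tracheal air at sea
#'   level) and 0.3 mmHg (CO2); both are scenario inputs (altitude scales the
#'   O2 value).
#' @export
o2_species <- function(P_air = 150) {
  gas_species("O2", D_air = 0.2e-4, D_water = 3.3e-9,
              sigma_blood = 1.34e-3, henry = 2.592e-2, P_air = P_air)
}

#' @rdname gas_species
#' @export
co2_species <- function(P_air = 0.3) {
  gas_species("CO2", D_air = 0.14e-4, D_water = 2.505e-9,
              sigma_blood = 3.07e-2, henry = 0.594, P_air = P_air)
}

#' Numerical controls of the transport solver
#'
#' @param nodes_per_branch grid nodes per branch (>= 3).
#' @param steps_per_cycle implicit time steps per breathing cycle.
#' @param max_cycles maximum number of cycles marched toward the periodic
#'   regime.
#' @param periodicity_tol relative L2 change of the pressure fields between
#'   consecutive cycle starts below which the regime is declared periodic.
#' @param distal_bc boundary condition at the distal end of the last
#'   generation: `"robin"` (membrane flux into blood, the physical model),
#'   `"dirichlet"` (fixed pressure `distal_sink`, used for validation against
#'   the closed-form steady profile) or `"closed"` (zero flux).
#' @param distal_sink sink pressure (mmHg) for the `"dirichlet"` case.
#' @return An object of class `solver_control`.
#' @export
solver_control <- function(nodes_per_branch = 10, steps_per_cycle = 200,
                           max_cycles = 50, periodicity_tol = 1e-6,
                           distal_bc = c("robin", "dirichlet", "closed"),
                           distal_sink = NULL) {
  nodes_per_branch <- as.integer(nodes_per_branch)
  steps_per_cycle <- as.integer(steps_per_cycle)
  max_cycles <- as.integer(max_cycles)
  if (nodes_per_branch < 3L) stop("need at least 3 nodes per branch")
  if (steps_per_cycle < 4L) stop("need at least 4 time steps per cycle")
  if (max_cycles < 1L) stop("max_cycles must be at least 1")
  if (periodicity_tol <= 0) stop("periodicity tolerance must be positive")
  distal_bc <- match.arg(distal_bc)
  if (distal_bc == "dirichlet" && is.null(distal_sink))
    stop("distal_bc = \"dirichlet\" requires a distal_sink pressure")
  structure(list(nodes_per_branch = nodes_per_branch,
                 steps_per_cycle = steps_per_cycle,
                 max_cycles = max_cycles,
                 periodicity_tol = periodicity_tol,
                 distal_bc = distal_bc, distal_sink = distal_sink),
            class = "solver_control")
}

#' Lumped lung mechanics
#'
#' @param R hydrodynamic resistance of the lung (Pa m^-3 s), default 2e5.
#' @param C compliance (m^3 Pa^-1), default 5e-7.
#' @return An object of class `mechanics_params`.
#' @export
mechanics_params <- function(R = 2e5, C = 5e-7) {
  if (!is.numeric(R) || R <= 0 || !is.numeric(C) || C <= 0)
    stop("resistance and compliance must be positive")
  structure(list(R = R, C = C), class = "mechanics_params")
}

#' Assemble a full lung model
#'
#' Bundles geometry, gas constants, blood parameters, lumped mechanics and
#' solver controls into one context passed to the transport and optimization
#' routines.
#'
#' @param tree an [airway_tree()].
#' @param o2,co2 [gas_species()] objects.
#' @param blood a [blood_params()].
#' @param mechanics a [mechanics_params()].
#' @param solver a [solver_control()].
#' @return An object of class `lung_model`.
#' @export
lung_model <- function(tree = airway_tree(), o2 = o2_species(),
                       co2 = co2_species(), blood = blood_params(),
                       mechanics = mechanics_params(),
                       solver = solver_control()) {
  stopifnot(inherits(tree, "airway_tree"), inherits(blood, "blood_params"),
            inherits(mechanics, "mechanics_params"),
            inherits(solver, "solver_control"))
  structure(list(tree = tree, o2 = o2, co2 = co2, blood = blood,
                 mechanics = mechanics, solver = solver),
            class = "lung_model")
}

#' @export
print.lung_model <- function(x, ...) {
  cat("Lung gas-transport model\n")
  print(x$tree)
  cat(sprintf("  ambient P_O2 %.4g mmHg, P_CO2 %.4g mmHg\n",
              x$o2$P_air, x$co2$P_air))
  cat(sprintf("  efficace arterial P_O2 %.4g mmHg, arterial P_CO2 %.4g mmHg\n",
              x$blood$Pa_o2_eff, x$blood$Pa_co2))
  cat(sprintf("  mechanics R = %.3g Pa.s/m^3, C = %.3g m^3/Pa\n",
              x$mechanics$R, x$mechanics$C))
  invisible(x)
}
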