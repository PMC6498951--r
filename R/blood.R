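#' Blood-side parameters
#'
#' Hemoglobin, plasma, membrane and arterial-pressure parameters governing the
#' gas exchange between alveolar air and capillary blood. Defaults are the
#' reference human values: hemoglobin 9.93 mol/m^3, blood velocity 5e-4 m/s,
#' pH 7.4, pK 6.09072, membrane thickness 1e-6 m, mixed-venous (pulmonary
#' arterial) pressures P_aO2 = 40 mmHg and P_aCO2 = 47 mmHg. `Pa_o2_eff` is the
#' "efficace" arterial oxygen pressure, a calibrated effective value (88 mmHg)
#' that absorbs the unknown upstream exchange history of capillary blood and is
#' used in place of P_aO2 in the oxygen balance; set it equal to `Pa_o2` to
#' recover the uncalibrated model.
#'
#' @param Z0 hemoglobin concentration (mol m^-3).
#' @param v_s blood velocity (m s^-1).
#' @param pH blood pH.
#' @param pK dissociation coefficient of the CO2/bicarbonate system.
#' @param tau alveolo-capillary membrane thickness (m).
#' @param Pa_o2 pulmonary arterial O2 partial pressure (mmHg).
#' @param Pa_co2 pulmonary arterial CO2 partial pressure (mmHg).
#' @param Pa_o2_eff efficace arterial O2 pressure used in the O2 balance (mmHg).
#' @return An object of class `blood_params`.
#' @export
blood_params <- function(Z0 = 9.93, v_s = 5e-4, pH = 7.4, pK = 6.09072,
                         tau = 1e-6, Pa_o2 = 40, Pa_co2 = 47,
                         Pa_o2_eff = 88) {
  vals <- c(Z0 = Z0, v_s = v_s, pH = pH, pK = pK, tau = tau,
            Pa_o2 = Pa_o2, Pa_co2 = Pa_co2, Pa_o2_eff = Pa_o2_eff)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all blood parameters must be positive and finite")
  if (pH <= 6.8 || pH >= 7.8)
    stop("blood pH outside the physiological range (6.8, 7.8): ", pH)
  structure(as.list(vals), class = "blood_params")
}

#' Oxyhemoglobin saturation (Hill equation)
#'
#' f(P) = P^2.6 / (P^2.6 + 26^2.6): the equilibrium fraction of hemoglobin
#' sites occupied at O2 partial pressure P, with half saturation at 26 mmHg.
#'
#' @param P O2 partial pressure (mmHg), vectorized, nonnegative.
#' @return saturation fraction in [0, 1).
#' @export
hill_fraction <- function(P) {
  if (any(P < 0)) stop("O2 partial pressure must be nonnegative")
  x <- P^2.6
  x / (x + 26^2.6)
}

# Derivative of the Hill saturation, used by the Newton blood solver.
hill_fraction_deriv <- function(P) {
  P <- pmax(P, 1e-12)
  f <- hill_fraction(P)
  2.6 * f * (1 - f) / P
}

#' Membrane exchange coefficients for one gas
#'
#' Computes the permeability of the alveolo-capillary membrane
#' alpha = D_water * sigma / tau, the pressure-to-concentration ratio in water
#' k = R T_body / henry (the dimensionless Henry solubility is the ratio of
#' aqueous to gas-phase concentration), the volumetric exchange rate of the
#' acinar reaction term beta = 2 k alpha / r_A, and the distal flux
#' coefficient kappa = alpha * k (m/s).
#'
#' @param gas a [gas_species()].
#' @param blood a [blood_params()] (supplies the membrane thickness tau).
#' @param r_A acinar branch radius (m).
#' @return list with `alpha` (mol m^-2 s^-1 mmHg^-1), `k` (mmHg m^3 mol^-1),
#'   `beta` (s^-1), `kappa` (m s^-1).
#' @export
exchange_beta <- function(gas, blood, r_A) {
  if (blood$tau <= 0) stop("membrane thickness tau must be positive")
  if (r_A <= 0) stop("acinar radius must be positive")
  alpha <- gas$D_water * gas$sigma_blood / blood$tau
  k <- .K_AIR / gas$henry
  list(alpha = alpha, k = k, beta = 2 * k * alpha / r_A, kappa = alpha * k)
}

#' Blood-equilibrium O2 partial pressure
#'
#' Solves the local balance between the membrane flux and the blood uptake,
#'   alpha (P_alv - Pb) = 4 Z0 (f(Pb) - f(Pa)) v_s + sigma v_s (Pb - Pa),
#' for the blood-side pressure Pb. The left side decreases and the right side
#' increases in Pb, so the root is unique and lies between Pa and P_alv.
#' By default Pa is the efficace arterial pressure.
#'
#' @param P_alv alveolar O2 partial pressure (mmHg), vectorized.
#' @param blood a [blood_params()].
#' @param gas the O2 [gas_species()] (supplies sigma).
#' @param membrane coefficients from [exchange_beta()] (supplies alpha).
#' @param Pa arterial O2 pressure entering the balance; defaults to
#'   `blood$Pa_o2_eff`.
#' @param init optional warm start for the Newton iteration.
#' @param tol absolute tolerance on Pb (mmHg).
#' @return blood O2 partial pressure(s), same length as `P_alv`.
#' @export
solve_blood_o2 <- function(P_alv, blood, gas, membrane,
                           Pa = blood$Pa_o2_eff, init = NULL, tol = 1e-10) {
  if (any(P_alv < 0)) stop("alveolar O2 pressure must be nonnegative")
  alpha <- membrane$alpha
  sv <- gas$sigma_blood * blood$v_s
  zv <- 4 * blood$Z0 * blood$v_s
  fPa <- hill_fraction(Pa)
  lo <- pmin(Pa, P_alv)
  hi <- pmax(Pa, P_alv)

  # residual g(Pb) = alpha (P_alv - Pb) - 4 Z0 v_s (f(Pb) - f(Pa))
  #                 - sigma v_s (Pb - Pa); strictly decreasing in Pb.
  g <- function(Pb) alpha * (P_alv - Pb) - zv * (hill_fraction(Pb) - fPa) -
    sv * (Pb - Pa)

  Pb <- if (is.null(init)) (lo + hi) / 2 else pmin(pmax(init, lo), hi)
  for (iter in 1:60) {
    gv <- g(Pb)
    dg <- -alpha - zv * hill_fraction_deriv(Pb) - sv
    step <- gv / dg
    Pb_new <- pmin(pmax(Pb - step, lo), hi)
    if (max(abs(Pb_new - Pb)) < tol) return(Pb_new)
    Pb <- Pb_new
  }
  # Newton safeguarded by bracket clamping always converges here; keep a
  # bisection fallback for pathological parameter sets.
  vapply(seq_along(P_alv), function(i) {
    if (abs(hi[i] - lo[i]) < tol) return(P_alv[i])
    stats::uniroot(function(p) alpha * (P_alv[i] - p) -
                     zv * (hill_fraction(p) - fPa) - sv * (p - Pa),
                   lower = lo[i], upper = hi[i], tol = tol)$root
  }, numeric(1))
}

#' Blood-equilibrium CO2 partial pressure
#'
#' Solves the linear balance
#'   alpha (P_alv - Pb) = (Pb - Pa_co2) sigma v_s (1 + 10^(pH - pK))
#'        (1 - 0.0289 Z0 (3.352 - 0.456 SO2) (8.142 - pH))
#' in closed form. SO2 is the local oxygen-hemoglobin saturation as a
#' fraction in [0, 1].
#'
#' @param P_alv alveolar CO2 partial pressure (mmHg), vectorized.
#' @param blood a [blood_params()].
#' @param gas the CO2 [gas_species()].
#' @param membrane coefficients from [exchange_beta()] for CO2.
#' @param SO2 oxygen saturation fraction(s) in [0, 1].
#' @return blood CO2 partial pressure(s), between `blood$Pa_co2` and `P_alv`.
#' @export
solve_blood_co2 <- function(P_alv, blood, gas, membrane, SO2) {
  if (any(P_alv < 0)) stop("alveolar CO2 pressure must be nonnegative")
  if (any(SO2 < 0 | SO2 > 1)) stop("SO2 must be a fraction in [0, 1]")
  slope <- gas$sigma_blood * blood$v_s * (1 + 10^(blood$pH - blood$pK)) *
    (1 - 0.0289 * blood$Z0 * (3.352 - 0.456 * SO2) * (8.142 - blood$pH))
  if (any(slope <= 0))
    stop("CO2 blood balance slope is nonpositive; check the ",
         "(3.352 - 0.456 SO2)(8.142 - pH) hemoglobin factor and pH")
  (membrane$alpha * P_alv + slope * blood$Pa_co2) / (membrane$alpha + slope)
}

#' Calibrate the efficace arterial O2 pressure
#'
#' Finds the efficace arterial pressure at which the simulated respiratory
#' exchange ratio of the reference (rest) ventilation equals `target_rer`.
#' RER increases with the efficace pressure, so a bracketed root find over
#' full periodic simulations is used. Each evaluation is one
#' [run_to_periodic()] call.
#'
#' @param model a [lung_model()].
#' @param pattern ventilation pattern of the reference state (default rest:
#'   amplitude 1 m/s, period 5 s).
#' @param target_rer target respiratory exchange ratio, in (0.4, 1).
#' @param bracket search interval for the efficace pressure (mmHg).
#' @param tol absolute tolerance on the pressure (mmHg).
#' @param control optional [solver_control()] override.
#' @return list with `Pa_o2_eff`, achieved `rer`, and the evaluated
#'   `curve` (data frame of pressure vs RER).
#' @export
calibrate_arterial_pressure <- function(model,
                                        pattern = ventilation_pattern(1, 5),
                                        target_rer = 0.8,
                                        bracket = c(40, 100), tol = 0.25,
                                        control = NULL) {
  if (target_rer <= 0.4 || target_rer >= 1)
    stop("target RER must lie in (0.4, 1)")
  control <- control %||% model$solver
  evals <- new.env()
  evals$tab <- data.frame(Pa_o2_eff = numeric(0), rer = numeric(0))
  rer_at <- function(p) {
    m <- model
    m$blood$Pa_o2_eff <- p
    cyc <- run_to_periodic(m, pattern, control = control)
    r <- cyc$flows$rer
    evals$tab <- rbind(evals$tab, data.frame(Pa_o2_eff = p, rer = r))
    r
  }
  r_lo <- rer_at(bracket[1])
  r_hi <- rer_at(bracket[2])
  if (target_rer <= r_lo) {
    warning(sprintf("target RER %.3g at or below the value %.3g reached at ",
                    target_rer, r_lo), bracket[1], " mmHg; returning the bracket end")
    return(list(Pa_o2_eff = bracket[1], rer = r_lo, curve = evals$tab))
  }
  if (target_rer >= r_hi)
    stop(sprintf("target RER %.3g unattainable: achieved range [%.3g, %.3g] on the bracket",
                 target_rer, r_lo, r_hi))
  root <- stats::uniroot(function(p) rer_at(p) - target_rer,
                         lower = bracket[1], upper = bracket[2],
                         f.lower = r_lo - target_rer,
                         f.upper = r_hi - target_rer, tol = tol)
  list(Pa_o2_eff = root$root, rer = root$f.root + target_rer,
       curve = evals$tab[order(evals$tab$Pa_o2_eff), ])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
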