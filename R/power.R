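#' Ventilation power components
#'
#' Closed forms for a sinusoidal trachea velocity u0(t) = A sin(2 pi t / T)
#' through a lumped resistance R and compliance C: elastic power
#' P_e = A^2 S0^2 T / (2 pi^2 C) (elastic energy stored during inspiration,
#' dissipated during passive expiration), viscous power P_v = R A^2 S0^2 / 2
#' (independent of T), and total P = P_e (1 + pi^2 R C / T).
#'
#' @param A trachea velocity amplitude (m/s).
#' @param T_period breathing period (s).
#' @param S0 trachea cross-section (m^2).
#' @param C compliance (m^3/Pa).
#' @return power (W).
#' @export
elastic_power <- function(A, T_period, S0, C) {
  stopifnot(A >= 0, T_period > 0, S0 > 0, C > 0)
  A^2 * S0^2 * T_period / (2 * pi^2 * C)
}

#' @rdname elastic_power
#' @param R lumped hydrodynamic resistance (Pa s m^-3). The viscous power does
#'   not depend on the period; `T_period` is accepted for interface symmetry.
#' @export
viscous_power <- function(A, T_period = NULL, S0, R) {
  stopifnot(A >= 0, S0 > 0, R > 0)
  R * A^2 * S0^2 / 2
}

#' @rdname elastic_power
#' @param mech a [mechanics_params()].
#' @export
total_power <- function(A, T_period, mech, S0) {
  elastic_power(A, T_period, S0, mech$C) + viscous_power(A, S0 = S0, R = mech$R)
}

#' Tidal volume of the sinusoidal pattern
#'
#' V_T = integral over inspiration of u0 S0 = S0 A T / pi.
#'
#' @param A amplitude (m/s).
#' @param T_period period (s).
#' @param S0 trachea cross-section (m^2).
#' @return tidal volume (m^3).
#' @export
tidal_volume <- function(A, T_period, S0) {
  stopifnot(A >= 0, T_period > 0, S0 > 0)
  S0 * A * T_period / pi
}

#' @rdname tidal_volume
#' @param V_T tidal volume (m^3); the inverse relation A = pi V_T / (S0 T).
#' @export
amplitude_for_tidal_volume <- function(V_T, T_period, S0) {
  stopifnot(V_T >= 0, T_period > 0, S0 > 0)
  pi * V_T / (S0 * T_period)
}

#' Cycle-averaged oxygen flow of one ventilation pattern
#'
#' @param model a [lung_model()].
#' @param A amplitude (m/s).
#' @param T_period period (s).
#' @param control optional [solver_control()] override.
#' @param init optional warm-start state.
#' @return VO2 (mol/s) with the full `periodic_cycle` as attribute `cycle`.
#' @export
oxygen_flow <- function(model, A, T_period, control = NULL, init = NULL) {
  cyc <- simulate_ventilation(model, A, T_period, control = control,
                              init = init)
  structure(cyc$flows$vo2, cycle = cyc)
}

#' Amplitude satisfying the oxygen-flow constraint at one period
#'
#' Finds the smallest amplitude A such that the simulated cycle-averaged
#' oxygen uptake equals the demanded flow `F` at period `T_period`. The flow
#' is monotone increasing in A, so a bracketed secant/bisection iteration is
#' used; every evaluation is a full [run_to_periodic()], warm-started from the
#' previous evaluation's periodic state.
#'
#' @param model a [lung_model()].
#' @param T_period breathing period (s).
#' @param F demanded oxygen flow (mol/s).
#' @param control optional [solver_control()] override.
#' @param A_guess starting guess for the amplitude (m/s).
#' @param tol_rel relative tolerance on the flow.
#' @param A_max amplitude above which the demand is declared unattainable.
#' @return list `A`, `vo2`, `vco2`, `rer`, `feasible`, `evals`, and `cycle`
#'   (the periodic cycle at the returned amplitude). When infeasible, `A` is
#'   NA and `vo2_sup` carries the flow reached at `A_max`.
#' @export
amplitude_for_flow <- function(model, T_period, F, control = NULL,
                               A_guess = 1, tol_rel = 1e-3, A_max = 40) {
  stopifnot(T_period > 0, F > 0)
  control <- control %||% model$solver
  state <- NULL
  n_eval <- 0L
  flow_at <- function(A) {
    cyc <- simulate_ventilation(model, A, T_period, control = control,
                                init = state)
    state <<- cyc$state
    n_eval <<- n_eval + 1L
    cyc
  }

  # bracket the demand
  A_lo <- 0; f_lo <- 0
  A_hi <- max(A_guess, 1e-3)
  cyc_hi <- flow_at(A_hi); f_hi <- cyc_hi$flows$vo2
  while (f_hi < F && A_hi < A_max) {
    A_lo <- A_hi; f_lo <- f_hi
    A_hi <- min(2 * A_hi, A_max)
    cyc_hi <- flow_at(A_hi); f_hi <- cyc_hi$flows$vo2
  }
  if (f_hi < F) {
    return(list(A = NA_real_, vo2 = NA_real_, vco2 = NA_real_,
                rer = NA_real_, feasible = FALSE, vo2_sup = f_hi,
                evals = n_eval, cycle = NULL))
  }

  cyc <- cyc_hi
  A <- A_hi
  for (iter in 1:40) {
    if (abs(cyc$flows$vo2 - F) <= tol_rel * F) break
    # secant step within the bracket, bisection fallback
    A_new <- A_hi + (F - f_hi) * (A_hi - A_lo) / (f_hi - f_lo)
    if (!is.finite(A_new) || A_new <= A_lo || A_new >= A_hi)
      A_new <- (A_lo + A_hi) / 2
    cyc <- flow_at(A_new)
    f_new <- cyc$flows$vo2
    if (f_new < F) { A_lo <- A_new; f_lo <- f_new }
    else { A_hi <- A_new; f_hi <- f_new }
    A <- A_new
  }
  list(A = A, vo2 = cyc$flows$vo2, vco2 = cyc$flows$vco2,
       rer = cyc$flows$rer, feasible = TRUE, evals = n_eval, cycle = cyc)
}

#' Oxygen-flow constraint curve A(T)
#'
#' Samples the amplitude satisfying the oxygen-flow constraint over a grid of
#' periods, warm-starting each root find from its neighbour. A(T) is a
#' positive decreasing function: longer periods internalize a larger tidal
#' volume per breath, so a smaller velocity amplitude sustains the same flow.
#'
#' @param model a [lung_model()].
#' @param F demanded oxygen flow (mol/s).
#' @param T_grid periods (s) at which to solve for A.
#' @param control optional [solver_control()] override.
#' @param tol_rel relative flow tolerance of each root find.
#' @return data frame `T_s`, `A_m_per_s`, `vo2_mol_per_s`, `vco2_mol_per_s`,
#'   `rer`, `feasible`, plus power columns from the model mechanics.
#' @export
constraint_curve <- function(model, F, T_grid, control = NULL,
                             tol_rel = 1e-3) {
  control <- control %||% model$solver
  S0 <- model$tree$generations$area_m2[1L]
  T_grid <- sort(T_grid)
  out <- vector("list", length(T_grid))
  A_guess <- 1
  for (i in seq_along(T_grid)) {
    res <- amplitude_for_flow(model, T_grid[i], F, control = control,
                              A_guess = A_guess, tol_rel = tol_rel)
    if (res$feasible) A_guess <- res$A
    out[[i]] <- data.frame(
      T_s = T_grid[i],
      A_m_per_s = res$A,
      vo2_mol_per_s = res$vo2,
      vco2_mol_per_s = res$vco2,
      rer = res$rer,
      feasible = res$feasible
    )
  }
  curve <- do.call(rbind, out)
  curve$P_elastic_W <- ifelse(curve$feasible,
    elastic_power(curve$A_m_per_s, curve$T_s, S0, model$mechanics$C), NA)
  curve$P_viscous_W <- ifelse(curve$feasible,
    viscous_power(curve$A_m_per_s, S0 = S0, R = model$mechanics$R), NA)
  curve$P_total_W <- curve$P_elastic_W + curve$P_viscous_W
  curve
}

#' Power-minimizing ventilation under an oxygen-flow constraint
#'
#' Minimizes the total ventilation power P(A(T), T) along the constraint
#' curve A(T) that keeps the simulated oxygen uptake at the demanded flow.
#' A(T) is sampled on a period grid and interpolated with a cubic spline; the
#' optimum is located as the zero of
#'   G(T) = A'(T) (1 + T/(pi^2 R C)) + A(T)/(2 pi^2 R C),
#' with A'(T) from central finite differences (step `dT`), and cross-checked
#' against a direct minimization of the interpolated power. The returned
#' optimum re-runs the transport model at (A(T*), T*) for its flows.
#'
#' @param model a [lung_model()].
#' @param F demanded oxygen flow (mol/s).
#' @param T_bracket period search interval (s).
#' @param n_grid number of period samples of the constraint curve.
#' @param control optional [solver_control()] override.
#' @param dT central-difference step for A'(T) (s).
#' @param tol_rel relative flow tolerance of the constraint root finds.
#' @return An object of class `optimization_result`: `T_star`, `A_star`,
#'   power decomposition at the optimum, `flows` and `rer` at the optimum,
#'   the sampled `curve`, the `band_5pct` period interval within +5% of the
#'   optimal power, `T_star_direct` (direct spline minimizer), `G` samples,
#'   and `feasible`.
#' @export
optimal_ventilation <- function(model, F, T_bracket = c(1, 15), n_grid = 9,
                                control = NULL, dT = 0.1, tol_rel = 1e-3) {
  control <- control %||% model$solver
  S0 <- model$tree$generations$area_m2[1L]
  RC <- model$mechanics$R * model$mechanics$C
  T_grid <- exp(seq(log(T_bracket[1]), log(T_bracket[2]), length.out = n_grid))
  curve <- constraint_curve(model, F, T_grid, control = control,
                            tol_rel = tol_rel)
  ok <- curve$feasible
  if (sum(ok) < 4)
    return(structure(list(feasible = FALSE, curve = curve, F = F),
                     class = "optimization_result"))
  if (!all(ok))
    curve_fit <- curve[ok, ] else curve_fit <- curve
  A_fun <- stats::splinefun(curve_fit$T_s, curve_fit$A_m_per_s,
                            method = "natural")
  P_fun <- function(Tv) total_power(A_fun(Tv), Tv, model$mechanics, S0)
  lo <- min(curve_fit$T_s); hi <- max(curve_fit$T_s)

  G_fun <- function(Tv) {
    Ap <- (A_fun(Tv + dT) - A_fun(Tv - dT)) / (2 * dT)
    Ap * (1 + Tv / (pi^2 * RC)) + A_fun(Tv) / (2 * pi^2 * RC)
  }
  Ts <- seq(lo + dT, hi - dT, length.out = 60)
  Gs <- vapply(Ts, G_fun, numeric(1))
  sign_change <- which(diff(sign(Gs)) != 0)

  direct <- stats::optimize(P_fun, lower = lo, upper = hi)
  boundary_opt <- FALSE
  if (length(sign_change) > 0) {
    i <- sign_change[1]
    T_star <- stats::uniroot(G_fun, lower = Ts[i], upper = Ts[i + 1],
                             tol = 1e-4)$root
  } else {
    warning("G(T) has no sign change in the period bracket; ",
            "returning the boundary minimizer of the interpolated power")
    T_star <- direct$minimum
    boundary_opt <- TRUE
  }

  at_opt <- amplitude_for_flow(model, T_star, F, control = control,
                               A_guess = A_fun(T_star), tol_rel = tol_rel)
  A_star <- at_opt$A
  P_e <- elastic_power(A_star, T_star, S0, model$mechanics$C)
  P_v <- viscous_power(A_star, S0 = S0, R = model$mechanics$R)

  # +5% iso-power band of the interpolated power curve around the optimum
  P_opt <- P_fun(T_star)
  Tb <- seq(lo, hi, length.out = 400)
  inband <- Tb[vapply(Tb, P_fun, numeric(1)) <= 1.05 * P_opt]
  band <- if (length(inband)) range(inband) else c(NA_real_, NA_real_)

  structure(list(
    feasible = TRUE, F = F,
    T_star = T_star, A_star = A_star,
    P_total_W = P_e + P_v, P_elastic_W = P_e, P_viscous_W = P_v,
    tidal_volume_m3 = tidal_volume(A_star, T_star, S0),
    flows = at_opt$cycle$flows, rer = at_opt$rer,
    curve = curve, A_fun = A_fun, G = data.frame(T_s = Ts, G = Gs),
    band_5pct = band, T_star_direct = direct$minimum,
    boundary_optimum = boundary_opt
  ), class = "optimization_result")
}

#' @export
print.optimization_result <- function(x, ...) {
  if (!x$feasible) {
    cat(sprintf("Oxygen demand %.3g mol/s infeasible on the sampled periods\n",
                x$F))
    return(invisible(x))
  }
  cat(sprintf("Optimal ventilation for F = %.4g mol O2/s:\n", x$F))
  cat(sprintf("  T* = %.3g s, A* = %.3g m/s, tidal volume %.3g L\n",
              x$T_star, x$A_star, 1e3 * x$tidal_volume_m3))
  cat(sprintf("  power %.4g W (elastic %.4g, viscous %.4g), RER %.3f\n",
              x$P_total_W, x$P_elastic_W, x$P_viscous_W, x$rer))
  cat(sprintf("  +5%% power band: T in [%.3g, %.3g] s\n",
              x$band_5pct[1], x$band_5pct[2]))
  invisible(x)
}
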