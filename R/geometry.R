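#' Build a symmetric dichotomous airway tree
#'
#' Constructs the idealized lung geometry: `conductive` generations whose
#' radius and length shrink by a constant homothety ratio `h` at each
#' bifurcation, followed by `acinar` generations that all keep the size of the
#' last conductive generation. Branch length is tied to the radius by
#' l = 6 r (length over diameter of 3), so the whole tree derives from the
#' trachea radius `r0` and `h`.
#'
#' @param r0 trachea radius (m), positive.
#' @param h homothety ratio between successive conductive generations,
#'   0 < h <= 1 (`h = 1` gives a degenerate tree of identical branches).
#' @param conductive number of conductive generations (default 17, i.e.
#'   generations 0..16).
#' @param acinar number of acinar (gas-exchanging) generations (default 6).
#'
#' @return An object of class `airway_tree`: a list with a per-generation
#'   data frame `generations` (columns `generation` 0-based, `zone`,
#'   `radius_m`, `length_m`, `area_m2`, `count`, `bifurcation_volume_m3` of the
#'   junction downstream of the generation, NA for the last) plus the scalar
#'   parameters.
#' @export
airway_tree <- function(r0 = 0.01, h = 0.7937, conductive = 17, acinar = 6) {
  if (!is.numeric(r0) || length(r0) != 1L || !is.finite(r0) || r0 <= 0)
    stop("trachea radius r0 must be a positive number, got ", format(r0))
  if (!is.numeric(h) || length(h) != 1L || !is.finite(h) || h <= 0 || h > 1)
    stop("homothety ratio h must lie in (0, 1], got ", format(h))
  conductive <- as.integer(conductive)
  acinar <- as.integer(acinar)
  if (conductive < 1L) stop("need at least one conductive generation")
  if (acinar < 0L) stop("acinar generation count cannot be negative")

  l0 <- 6 * r0
  ic <- seq_len(conductive) - 1L                  # 0-based conductive indices
  r_c <- r0 * h^ic
  l_c <- l0 * h^ic
  n_c <- 2^ic

  r_a <- r0 * h^(conductive - 1L)                 # acinar branches keep the
  l_a <- l0 * h^(conductive - 1L)                 # last conductive size
  ja <- seq_len(acinar)                           # 1-based acinar position
  n_a <- 2^(conductive - 1L + ja)

  radius <- c(r_c, rep(r_a, acinar))
  len <- c(l_c, rep(l_a, acinar))
  count <- c(n_c, n_a)
  ngen <- conductive + acinar

  # Junction q sits between generation q-1 and q (1-based: between g and g+1);
  # its volume is three tubular stubs: parent radius r_g over length r_g/2 and
  # two daughters r_{g+1} over r_{g+1}/2.
  vbif <- rep(NA_real_, ngen)
  if (ngen > 1L) {
    g <- seq_len(ngen - 1L)
    vbif[g] <- pi * (radius[g]^3 / 2 + radius[g + 1L]^3)
  }

  generations <- data.frame(
    generation = seq_len(ngen) - 1L,
    zone = c(rep("conductive", conductive), rep("acinar", acinar)),
    radius_m = radius,
    length_m = len,
    area_m2 = pi * radius^2,
    count = count,
    bifurcation_volume_m3 = vbif
  )

  structure(
    list(generations = generations, r0 = r0, h = h,
         conductive = conductive, acinar = acinar),
    class = "airway_tree"
  )
}

#' @export
print.airway_tree <- function(x, ...) {
  cat(sprintf(
    "Symmetric airway tree: %d conductive + %d acinar generations\n",
    x$conductive, x$acinar))
  cat(sprintf("  trachea radius %.3g m, homothety ratio %.4g\n", x$r0, x$h))
  g <- x$generations
  cat(sprintf("  acinar branch radius %.3g m, length %.3g m\n",
              g$radius_m[nrow(g)], g$length_m[nrow(g)]))
  invisible(x)
}

#' Sinusoidal ventilation pattern
#'
#' Air velocity at the trachea inlet: u0(t) = A sin(2 pi t / T). Inspiration is
#' the first half-period (u0 > 0).
#'
#' @param amplitude trachea velocity amplitude A (m/s), nonnegative.
#' @param period breathing period T (s), positive.
#' @return An object of class `ventilation_pattern` with fields `amplitude`,
#'   `period` and a function `u0(t)`.
#' @export
ventilation_pattern <- function(amplitude, period) {
  if (!is.numeric(amplitude) || length(amplitude) != 1L || amplitude < 0)
    stop("ventilation amplitude must be a nonnegative number")
  if (!is.numeric(period) || length(period) != 1L || period <= 0)
    stop("ventilation period must be positive")
  force(amplitude); force(period)
  structure(
    list(amplitude = amplitude, period = period,
         u0 = function(t) amplitude * sin(2 * pi * t / period)),
    class = "ventilation_pattern"
  )
}

# Velocity scale factor per generation (1-based index over the whole tree):
# u_g(t) = factor[g] * u0(t). Conductive: (1/(2 h^2))^i from incompressible
# mass conservation u_i S_i = 2 u_{i+1} S_{i+1}. Acinar: halves at every
# bifurcation (constant cross-section), including the conductive-to-acinar
# transition, so u_{A,j} = (1/(2h^2))^G u0 / 2^(j+1) with j 0-based.
velocity_factors <- function(tree) {
  h <- tree$h
  ic <- seq_len(tree$conductive) - 1L
  fc <- (1 / (2 * h^2))^ic
  if (tree$acinar > 0L) {
    ja <- seq_len(tree$acinar)
    fa <- fc[tree$conductive] / 2^ja
    c(fc, fa)
  } else fc
}

#' Mean air velocity in a branch of one generation
#'
#' @param tree an [airway_tree()].
#' @param pattern a [ventilation_pattern()].
#' @param generation 0-based generation index over the whole tree
#'   (0 .. conductive + acinar - 1).
#' @param t time (s), vectorized.
#' @return mean air velocity (m/s) in one branch of that generation.
#' @export
branch_velocity <- function(tree, pattern, generation, t) {
  g <- as.integer(generation) + 1L
  ngen <- tree$conductive + tree$acinar
  if (any(g < 1L) || any(g > ngen))
    stop("generation index out of range 0..", ngen - 1L)
  velocity_factors(tree)[g] * pattern$u0(t)
}

#' Poiseuille hydrodynamic resistance of the conductive tree
#'
#' Series sum over conductive generations of the parallel Poiseuille
#' resistances, R = sum_i 8 mu l_i / (pi r_i^4 n_i). Used to translate
#' homothety-ratio changes into resistance changes for the geometry-linked
#' sweeps; the lumped mechanical resistance of [mechanics_params()] remains
#' the value used in the power model.
#'
#' @param tree an [airway_tree()].
#' @param viscosity dynamic viscosity of air (Pa s).
#' @return resistance (Pa s m^-3).
#' @export
poiseuille_resistance <- function(tree, viscosity = .MU_AIR) {
  if (!is.numeric(viscosity) || viscosity <= 0)
    stop("viscosity must be positive")
  g <- tree$generations
  cond <- g$zone == "conductive"
  sum(8 * viscosity * g$length_m[cond] /
        (pi * g$radius_m[cond]^4 * g$count[cond]))
}

#' Homothety ratio matching a target resistance ratio
#'
#' Finds h such that the Poiseuille resistance of the conductive tree equals
#' `ratio` times the resistance of the reference tree, keeping the trachea
#' radius and generation counts fixed. Resistance decreases monotonically
#' with h.
#'
#' @param tree reference [airway_tree()].
#' @param ratio target resistance ratio (>0), e.g. 1.3 for +30%.
#' @return the new homothety ratio.
#' @export
h_for_resistance_ratio <- function(tree, ratio) {
  if (!is.numeric(ratio) || ratio <= 0) stop("resistance ratio must be positive")
  r_ref <- poiseuille_resistance(tree)
  f <- function(h) {
    poiseuille_resistance(
      airway_tree(tree$r0, h, tree$conductive, tree$acinar)) / r_ref - ratio
  }
  stats::uniroot(f, lower = 0.55, upper = 0.999, tol = 1e-10)$root
}
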