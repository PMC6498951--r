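# Internal discretization and assembly of the coupled branch/junction system.
#
# The symmetric tree collapses to one representative branch per generation, so
# the global implicit system is a single tridiagonal chain. Unknown ordering
# along the root-to-leaf path, for M nodes per branch and N generations:
#   gen 1 interior nodes 2..M-1, junction 1, gen 2 interiors, junction 2, ...,
#   gen N interiors, distal node M of gen N.
# Node 1 of gen 1 is the Dirichlet trachea inlet (P = P_air); node 1 of gen g>1
# and node M of gen g<N are identified with the junction scalars (paper-style
# bifurcation volumes obeying a mass balance ODE).

discretize <- function(tree, M) {
  g <- tree$generations
  ngen <- nrow(g)
  M <- as.integer(M)
  dx <- g$length_m / (M - 1)
  n <- ngen * (M - 1L)
  base <- (seq_len(ngen) - 1L) * (M - 1L)
  int_idx <- as.vector(outer(seq_len(M - 2L), base, `+`))  # grouped by gen
  int_idx <- sort(int_idx)
  gen_of_int <- rep(seq_len(ngen), each = M - 2L)
  jun_idx <- if (ngen > 1L) seq_len(ngen - 1L) * (M - 1L) else integer(0)
  robin_idx <- n

  # acinar exchange positions: interior nodes of acinar generations, then the
  # distal node (membrane flux boundary)
  acin <- which(g$zone == "acinar")
  ac_int <- int_idx[gen_of_int %in% acin]
  ac_gen <- gen_of_int[gen_of_int %in% acin]

  # junctions adjoining acinar branches: the branch-end half-cells absorbed
  # into the junction control volume keep their exchange term, so the full
  # acinar branch length l_A contributes to the reaction quadrature
  S <- g$area_m2
  q <- seq_len(max(ngen - 1L, 0L))
  half_par <- ifelse(q %in% acin, S[q] * dx[q] / 2, 0)
  half_dau <- ifelse((q + 1L) %in% acin, 2 * S[q + 1L] * dx[q + 1L] / 2, 0)
  V_ex_jun <- half_par + half_dau
  ac_jun <- which(V_ex_jun > 0)

  list(M = M, ngen = ngen, n = n, dx = dx, V_ex_jun = V_ex_jun,
       ac_jun = ac_jun,
       S = g$area_m2, count = g$count, length = g$length_m,
       V_jun = g$bifurcation_volume_m3[seq_len(max(ngen - 1L, 0L))],
       int_idx = int_idx, gen_of_int = gen_of_int,
       jun_idx = jun_idx, robin_idx = robin_idx,
       acin_gens = acin, ac_int = ac_int, ac_gen = ac_gen,
       vf = velocity_factors(tree))
}

# Per-gas static pieces reused at every time step: exchange coefficients,
# positions with a reaction term, molar flux weights (mmHg-volume to mol via
# the ideal-gas factor at body temperature).
gas_static <- function(disc, gas, blood, control) {
  ngen <- disc$ngen
  has_acinus <- length(disc$acin_gens) > 0L
  mem <- exchange_beta(gas, blood, disc$S[ngen] |> sqrt_area_radius())
  beta_gen <- numeric(ngen)
  if (has_acinus) beta_gen[disc$acin_gens] <- mem$beta

  robin_coef <- switch(control$distal_bc,
    robin = mem$kappa,
    dirichlet = NA_real_,   # handled as a fixed-value row
    closed = 0)

  # positions whose equations carry an exchange term, and the matching
  # blood-coupling coefficients and cycle-flux quadrature weights; junction
  # rows are volume-scaled, so their sink coefficient is beta * V_ex
  aj <- disc$ac_jun
  ex_pos <- c(disc$ac_int, disc$jun_idx[aj],
              if (identical(control$distal_bc, "robin")) disc$robin_idx)
  ex_coef <- c(rep(mem$beta, length(disc$ac_int)),
               mem$beta * disc$V_ex_jun[aj],
               if (identical(control$distal_bc, "robin")) mem$kappa)
  fw <- c(disc$count[disc$ac_gen] * disc$S[disc$ac_gen] * disc$dx[disc$ac_gen] *
            mem$beta,
          disc$count[aj] * disc$V_ex_jun[aj] * mem$beta,
          if (identical(control$distal_bc, "robin"))
            disc$count[ngen] * disc$S[ngen] * mem$kappa) / .K_AIR

  list(D = gas$D_air, P_air = gas$P_air, mem = mem, beta_gen = beta_gen,
       jun_sink = mem$beta * disc$V_ex_jun,
       robin_coef = robin_coef, ex_pos = ex_pos, ex_coef = ex_coef,
       flux_w = fw)
}

sqrt_area_radius <- function(S) sqrt(S / pi)

# Tridiagonal system (lower a, diagonal b, upper cc) for one gas at trachea
# velocity u0val, implicit weight inv_dt (0 gives the steady problem). Returns
# the three bands, the RHS weight w multiplying the previous field, and the
# constant RHS entry at position 1 from the Dirichlet inlet.
assemble_bands <- function(disc, gs, control, u0val, inv_dt) {
  n <- disc$n; M <- disc$M; ngen <- disc$ngen
  D <- gs$D; dx <- disc$dx
  a <- numeric(n); b <- numeric(n); cc <- numeric(n); w <- numeric(n)

  u <- disc$vf * u0val
  dcoef <- D / dx^2
  up <- pmax(u, 0) / dx
  um <- pmin(u, 0) / dx
  gi <- disc$gen_of_int
  a[disc$int_idx] <- (-dcoef - up)[gi]
  b[disc$int_idx] <- (inv_dt + 2 * dcoef + up - um + gs$beta_gen)[gi]
  cc[disc$int_idx] <- (-dcoef + um)[gi]
  w[disc$int_idx] <- inv_dt

  if (ngen > 1L) {
    q <- seq_len(ngen - 1L)
    Sg <- disc$S[q]; Sg1 <- disc$S[q + 1L]
    aj <- -Sg * D / dx[q]
    cj <- -2 * Sg1 * D / dx[q + 1L]
    bj <- disc$V_jun * inv_dt + Sg * D / dx[q] + 2 * Sg1 * D / dx[q + 1L] +
      gs$jun_sink
    if (u0val >= 0) {            # inflow face upwinds from the parent branch
      aj <- aj - Sg * u[q]
      bj <- bj + 2 * Sg1 * u[q + 1L]
    } else {                     # inflow face upwinds from the daughter branch
      bj <- bj - Sg * u[q]
      cj <- cj + 2 * Sg1 * u[q + 1L]
    }
    a[disc$jun_idx] <- aj
    b[disc$jun_idx] <- bj
    cc[disc$jun_idx] <- cj
    w[disc$jun_idx] <- disc$V_jun * inv_dt
  }

  rn <- disc$robin_idx
  if (identical(control$distal_bc, "dirichlet")) {
    a[rn] <- 0; b[rn] <- 1; w[rn] <- 0
  } else {
    a[rn] <- -D / dx[ngen]
    b[rn] <- D / dx[ngen] + gs$robin_coef
    w[rn] <- 0
  }

  # Dirichlet inlet: the missing left neighbour of gen-1 node 2
  d1 <- (dcoef[1] + up[1]) * gs$P_air

  list(a = a, b = b, cc = cc, w = w, d1 = d1)
}

band_matrix <- function(bands, n) {
  Matrix::bandSparse(n, n, k = c(-1L, 0L, 1L),
                     diagonals = list(bands$a[-1L], bands$b, bands$cc[-n]))
}

factor_bands <- function(bands, n) {
  Matrix::lu(methods::as(band_matrix(bands, n), "CsparseMatrix"))
}

# Closed-form initial field mapped onto the unknown vector: conductive
# generations follow the explicit steady profile toward `P_distal`, acinar
# generations and the distal node start constant at `P_distal`.
initial_unknowns <- function(disc, tree, P_air, P_distal) {
  M <- disc$M; ngen <- disc$ngen
  prof <- conductive_profile_matrix(tree, P_air, P_distal, M)
  x <- numeric(disc$n)
  nc <- tree$conductive
  for (g in seq_len(ngen)) {
    base <- (g - 1L) * (M - 1L)
    if (g <= nc) {
      x[base + seq_len(M - 2L)] <- prof[2:(M - 1L), g]
      if (g < ngen)
        x[g * (M - 1L)] <- if (g < nc) prof[M, g] else P_distal
    } else {
      x[base + seq_len(M - 2L)] <- P_distal
      if (g < ngen) x[g * (M - 1L)] <- P_distal
    }
  }
  x[disc$robin_idx] <- P_distal
  x
}

# Explicit steady conductive profile (u = 0): linear per branch, with slope
# set by flux conservation through the branching; node values as an
# M x conductive matrix.
conductive_profile_matrix <- function(tree, P_air, P_blood, M) {
  nc <- tree$conductive
  r <- 1 / (2 * tree$h)
  terms <- r^(0:(nc - 1))
  total <- sum(terms)
  cum <- c(0, cumsum(terms))[seq_len(nc)]   # sum_{k<i} r^k for gen i (0-based)
  xi <- seq(0, 1, length.out = M)
  sapply(seq_len(nc), function(g) {
    P_air + (P_blood - P_air) / total * (cum[g] + terms[g] * xi)
  })
}

# Expand an unknown vector to the full M x ngen node matrix (junction values
# duplicated onto the adjoining branch ends, inlet node set to P_air).
expand_field <- function(disc, x, P_air) {
  M <- disc$M; ngen <- disc$ngen
  P <- matrix(NA_real_, M, ngen)
  for (g in seq_len(ngen)) {
    base <- (g - 1L) * (M - 1L)
    P[2:(M - 1L), g] <- x[base + seq_len(M - 2L)]
    P[1L, g] <- if (g == 1L) P_air else x[(g - 1L) * (M - 1L)]
    P[M, g] <- if (g < ngen) x[g * (M - 1L)] else x[disc$robin_idx]
  }
  P
}
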