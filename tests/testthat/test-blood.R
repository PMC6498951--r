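test_that("Hill saturation has the right anchors and shape", {
  expect_identical(hill_fraction(26), 0.5)
  expect_identical(hill_fraction(0), 0)
  expect_equal(hill_fraction(100), 100^2.6 / (100^2.6 + 26^2.6))
  expect_equal(hill_fraction(100), 0.9707, tolerance = 1e-4)

  p <- seq(0, 600, by = 2)
  f <- hill_fraction(p)
  expect_true(all(diff(f) > 0))
  expect_true(all(f < 1))
  expect_error(hill_fraction(-1), "nonnegative")
})

test_that("membrane coefficients match their defining products", {
  blood <- blood_params()
  o2 <- o2_species()
  r_a <- 1e-2 * 0.7937^16
  mem <- exchange_beta(o2, blood, r_a)

  expect_equal(mem$alpha, 3.3e-9 * 1.34e-3 / 1e-6)   # 4.422e-6
  expect_equal(mem$beta, 2 * mem$k * mem$alpha / r_a)
  expect_equal(mem$kappa, mem$alpha * mem$k)

  # doubling tau halves alpha and beta
  blood2 <- blood_params(tau = 2e-6)
  mem2 <- exchange_beta(o2, blood2, r_a)
  expect_equal(mem2$alpha, mem$alpha / 2)
  expect_equal(mem2$beta, mem$beta / 2)

  # acinar gamma = beta l_A^2 / D of order one at the default geometry
  l_a <- 6 * r_a
  gamma <- mem$beta * l_a^2 / o2$D_air
  expect_gt(gamma, 0.3)
  expect_lt(gamma, 10)

  expect_error(blood_params(tau = 0), "positive")
})

test_that("O2 blood balance root matches a bisection oracle", {
  blood <- blood_params()
  o2 <- o2_species()
  mem <- exchange_beta(o2, blood, 2.48e-4)

  balance <- function(pb, p_alv, pa) {
    mem$alpha * (p_alv - pb) -
      4 * blood$Z0 * blood$v_s * (hill_fraction(pb) - hill_fraction(pa)) -
      o2$sigma_blood * blood$v_s * (pb - pa)
  }
  bisect <- function(p_alv, pa) {
    lo <- min(pa, p_alv); hi <- max(pa, p_alv)
    if (hi - lo < 1e-12) return(p_alv)
    for (i in 1:80) {
      mid <- (lo + hi) / 2
      if (balance(mid, p_alv, pa) > 0) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }

  for (p_alv in c(0, 20, 60, 88, 100, 150)) {
    ours <- solve_blood_o2(p_alv, blood, o2, mem)
    expect_equal(ours, bisect(p_alv, blood$Pa_o2_eff), tolerance = 1e-7)
    expect_gte(ours, min(blood$Pa_o2_eff, p_alv) - 1e-9)
    expect_lte(ours, max(blood$Pa_o2_eff, p_alv) + 1e-9)
  }

  # vectorized call agrees with scalar calls and warm starts converge
  pv <- c(5, 50, 95, 140)
  expect_equal(solve_blood_o2(pv, blood, o2, mem),
               vapply(pv, solve_blood_o2, numeric(1),
                      blood = blood, gas = o2, membrane = mem),
               tolerance = 1e-9)
  expect_equal(solve_blood_o2(pv, blood, o2, mem, init = pv),
               solve_blood_o2(pv, blood, o2, mem), tolerance = 1e-8)

  # fixed point at the efficace pressure, monotone response
  expect_equal(solve_blood_o2(blood$Pa_o2_eff, blood, o2, mem),
               blood$Pa_o2_eff)
  roots <- solve_blood_o2(c(90, 110, 130), blood, o2, mem)
  expect_true(all(diff(roots) > 0))
  expect_error(solve_blood_o2(-5, blood, o2, mem), "nonnegative")
})

test_that("CO2 blood balance is the closed-form linear solution", {
  blood <- blood_params()
  co2 <- co2_species()
  mem <- exchange_beta(co2, blood, 2.48e-4)

  balance <- function(pb, p_alv, so2) {
    mem$alpha * (p_alv - pb) -
      (pb - blood$Pa_co2) * co2$sigma_blood * blood$v_s *
        (1 + 10^(blood$pH - blood$pK)) *
        (1 - 0.0289 * blood$Z0 * (3.352 - 0.456 * so2) * (8.142 - blood$pH))
  }
  bisect <- function(p_alv, so2) {
    lo <- min(blood$Pa_co2, p_alv); hi <- max(blood$Pa_co2, p_alv)
    if (hi - lo < 1e-12) return(p_alv)
    for (i in 1:80) {
      mid <- (lo + hi) / 2
      if (balance(mid, p_alv, so2) > 0) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }

  for (p_alv in c(0.3, 10, 40, 47)) {
    ours <- solve_blood_co2(p_alv, blood, co2, mem, SO2 = 0.97)
    expect_equal(ours, bisect(p_alv, 0.97), tolerance = 1e-7)
    expect_gte(ours, min(blood$Pa_co2, p_alv) - 1e-9)
    expect_lte(ours, max(blood$Pa_co2, p_alv) + 1e-9)
  }

  expect_equal(solve_blood_co2(47, blood, co2, mem, SO2 = 0.5), 47)

  # affine in the alveolar pressure
  p <- c(0, 10, 20, 30, 40)
  v <- solve_blood_co2(p, blood, co2, mem, SO2 = 0.9)
  expect_equal(diff(v, differences = 2), rep(0, 3), tolerance = 1e-12)

  expect_error(solve_blood_co2(40, blood, co2, mem, SO2 = 1.5), "fraction")
  # degenerate hemoglobin factor flagged
  blood_bad <- blood_params(Z0 = 100)
  expect_error(solve_blood_co2(40, blood_bad, co2, mem, SO2 = 0),
               "slope|factor")
})

test_that("calibration rejects unattainable targets early", {
  expect_error(calibrate_arterial_pressure(lung_model(), target_rer = 0.2),
               "target RER")
  expect_error(calibrate_arterial_pressure(lung_model(), target_rer = 1.1),
               "target RER")
})
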