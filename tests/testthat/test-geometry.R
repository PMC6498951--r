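test_that("tree construction follows the homothety recursions", {
  tree <- airway_tree(r0 = 1e-2, h = 0.7937)
  g <- tree$generations

  expect_equal(g$radius_m[2], 7.937e-3)
  expect_equal(g$area_m2[1], pi * 1e-4)
  expect_equal(g$length_m[1], 6e-2)
  expect_equal(g$count, c(2^(0:16), 2^(17:22)))

  # acinar radius oracle: iterated multiplication, 16 times
  r_a <- 1e-2
  for (i in 1:16) r_a <- r_a * 0.7937
  expect_equal(g$radius_m[18], r_a, tolerance = 1e-14)
  expect_true(all(g$radius_m[18:23] == g$radius_m[18]))
  expect_true(all(g$length_m[18:23] == g$length_m[18]))

  # area ratio h^2 across conductive generations
  expect_equal(g$area_m2[2:17] / g$area_m2[1:16], rep(0.7937^2, 16))

  # bifurcation volume: three tubular stubs
  expect_equal(g$bifurcation_volume_m3[1],
               pi * ((1e-2)^3 / 2 + (7.937e-3)^3))
  expect_true(all(g$bifurcation_volume_m3[-23] > 0))
  expect_true(is.na(g$bifurcation_volume_m3[23]))
})

test_that("degenerate and invalid morphometry are handled", {
  tree <- airway_tree(h = 1)
  expect_true(all(tree$generations$radius_m == 1e-2))
  expect_error(airway_tree(h = 1.2), "homothety")
  expect_error(airway_tree(h = 0), "homothety")
  expect_error(airway_tree(r0 = -1), "radius")
})

test_that("branch velocities conserve mass at every bifurcation", {
  tree <- airway_tree()
  pat <- ventilation_pattern(1.3, 4)
  ts <- seq(0, 4, length.out = 7)
  g <- tree$generations

  expect_equal(branch_velocity(tree, pat, 0, ts), pat$u0(ts))

  for (i in 0:21) {
    ui <- branch_velocity(tree, pat, i, ts)
    ui1 <- branch_velocity(tree, pat, i + 1, ts)
    expect_equal(ui * g$area_m2[i + 1], 2 * ui1 * g$area_m2[i + 2],
                 tolerance = 1e-13)
  }

  # conductive scaling against the mass-balance oracle u1 = u0 S0/(2 S1)
  u1 <- branch_velocity(tree, pat, 1, 1)
  expect_equal(u1, pat$u0(1) * g$area_m2[1] / (2 * g$area_m2[2]),
               tolerance = 1e-14)
  expect_equal(u1 / pat$u0(1), 1 / (2 * 0.7937^2), tolerance = 1e-14)

  # acinar halving and total acinar flow independent of depth
  ua <- vapply(17:22, function(i) branch_velocity(tree, pat, i, 1), numeric(1))
  expect_equal(ua[-1] / ua[-6], rep(0.5, 5))
  tot <- ua * g$count[18:23] * g$area_m2[18:23]
  expect_equal(max(tot) - min(tot), 0, tolerance = 1e-18)

  expect_error(branch_velocity(tree, pat, 23, 0), "out of range")
})

test_that("per-generation branch volume scales as (2 h^3)^i", {
  tree <- airway_tree(h = 0.82)
  g <- tree$generations[tree$generations$zone == "conductive", ]
  vol <- g$count * g$area_m2 * g$length_m
  expect_equal(vol / vol[1], (2 * 0.82^3)^(0:16), tolerance = 1e-12)
})

test_that("Poiseuille resistance follows the series formula and h-link", {
  # single generation: R = 8 mu l / (pi r^4), with l = 6 r0
  tree1 <- airway_tree(r0 = 1, conductive = 1, acinar = 0)
  expect_equal(poiseuille_resistance(tree1, viscosity = 1), 8 * 6 / pi)

  # r^4 scaling: doubling r0 (lengths double too) divides R by 2^4/2 = 8
  tree2 <- airway_tree(r0 = 2, conductive = 1, acinar = 0)
  expect_equal(poiseuille_resistance(tree2, viscosity = 1),
               poiseuille_resistance(tree1, viscosity = 1) / 8)

  # monotone decreasing in h, by direct series evaluation
  ref <- airway_tree()
  expect_gt(poiseuille_resistance(airway_tree(h = 0.7937 * 0.9)),
            poiseuille_resistance(ref))

  # h_for_resistance_ratio round trip
  h13 <- h_for_resistance_ratio(ref, 1.3)
  expect_lt(h13, ref$h)
  tree13 <- airway_tree(ref$r0, h13, 17, 6)
  expect_equal(poiseuille_resistance(tree13) / poiseuille_resistance(ref),
               1.3, tolerance = 1e-6)

  expect_error(poiseuille_resistance(ref, viscosity = 0), "viscosity")
})

test_that("ventilation pattern is a sine starting at zero flow", {
  pat <- ventilation_pattern(2, 6)
  expect_equal(pat$u0(0), 0)
  expect_equal(pat$u0(1.5), 2)
  # antisymmetric about T/2
  expect_equal(pat$u0(3 - 0.7), -pat$u0(3 + 0.7))
  expect_error(ventilation_pattern(-1, 5), "amplitude")
  expect_error(ventilation_pattern(1, 0), "period")
})
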