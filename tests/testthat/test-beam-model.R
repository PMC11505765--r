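test_that("Bragg curve range follows the Bragg-Kleeman calibration", {
  cv <- ref_curve()
  # independent range oracle: R = alpha E^p in water
  oracle <- 10 * 0.0022 * 250^1.77
  expect_lt(abs(cv$range_80 - oracle), 8)     # distal-80% near nominal range
  expect_lt(abs(cv$range_80 - oracle), 0.5)   # calibration contract
  expect_gt(max(cv$dose) / cv$dose[1], 2)     # peak-to-entrance ratio

  # shape contract at several energies
  for (e in c(70, 150, 250)) {
    b <- bragg_curve(e, depth_step = 0.5)
    expect_true(all(b$dose >= 0))
    imax <- which.max(b$dose)
    expect_equal(sum(b$dose == max(b$dose)), 1)
    distal <- b$dose[b$depth > b$range_80]
    expect_true(all(diff(distal) <= 1e-12))
    expect_lt(utils::tail(b$dose, 1), 1e-3)
  }
  expect_error(bragg_curve(0.5), "energy")
  expect_error(bragg_curve(400), "energy")
})

test_that("pullback is an exact translation and composes additively", {
  cv <- ref_curve()
  p50 <- pullback(cv, 50)
  k <- 50 / cv$depth_step
  n <- length(cv$dose)
  expect_identical(p50$dose[1:(n - k)], cv$dose[(k + 1):n])
  expect_equal(p50$range_80, cv$range_80 - 50)

  # equivariance: t then s equals t + s (exact on the grid)
  p_a <- pullback(pullback(cv, 12.5), 7.5)
  p_b <- pullback(cv, 20)
  expect_equal(p_a$dose, p_b$dose, tolerance = 1e-12)
  expect_error(pullback(cv, -1), "wet")
})

test_that("water-equivalent thickness scales with stopping power", {
  expect_equal(wet_of_slab(rm_materials("water"), 10), 10)
  pmma <- rm_materials("pmma")
  expect_equal(wet_of_slab(pmma, 200), 200 * 1.16)  # hand product oracle
  expect_equal(wet_of_slab(pmma, 0), 0)
  expect_error(wet_of_slab(pmma, -3), ">= 0")
  expect_error(material("x", density = -1, relative_stopping_power = 1))
  expect_error(material("x", density = 1, relative_stopping_power = 0))
})

test_that("two-point deflection reproduces spot positions at the isocenter", {
  bl <- beamline()
  # planar geometry oracles
  expect_equal(spot_direction(scan_spot(40, 0), bl)$kick_x, atan(40 / 2000))
  expect_equal(spot_direction(scan_spot(0, 40), bl)$kick_y, atan(40 / 2560))
  axial <- spot_direction(scan_spot(0, 0), bl)
  expect_equal(axial$direction, c(0, 0, 1))

  # every spot of the 80 x 80 grid lands on (x, y) at z = 0
  plan <- uniform_field_plan(c(80, 80), 5)
  for (i in seq(1, nrow(plan), by = 37)) {
    sd <- spot_direction(plan[i, ], bl)
    p <- sd$vertices[3, ] + sd$direction * (-bl$x_magnet_z) / sd$direction[3]
    expect_lt(max(abs(p[1:2] - c(plan$x[i], plan$y[i]))), 1e-9)
  }
  pos0 <- spot_position_at(plan$x, plan$y, bl, 0)
  expect_lt(max(abs(pos0 - cbind(plan$x, plan$y))), 1e-12)
})

test_that("lateral sigma combines source, divergence and scattering", {
  bl <- beamline()
  # at the source plane only the spot size remains
  expect_equal(lateral_sigma(0, 0, bl, drift = 0), 3 / (2 * sqrt(2 * log(2))))

  # pure free drift: quadrature closed form, and exact divergence doubling
  s1 <- lateral_sigma(0, 0, bl, drift = 2000)
  sig0 <- 3 / (2 * sqrt(2 * log(2)))
  expect_equal(s1, sqrt(sig0^2 + (0.001 * 2000)^2), tolerance = 1e-12)
  bl2 <- beamline(divergence_sigma = 2)
  s2 <- lateral_sigma(0, 0, bl2, drift = 2000)
  expect_equal(s2, sqrt(sig0^2 + (0.002 * 2000)^2), tolerance = 1e-12)

  # monotone non-decreasing in depth and upstream WET
  depths <- seq(0, 200, by = 20)
  expect_true(all(diff(lateral_sigma(depths, 100, bl)) >= 0))
  wets <- seq(0, 230, by = 23)
  sig_w <- vapply(wets, function(w) lateral_sigma(50, w, bl), 0)
  expect_true(all(diff(sig_w) >= 0))
  expect_gt(lateral_sigma(50, 232, bl), lateral_sigma(50, 0, bl))
})

test_that("beamline and material configs round-trip through files", {
  tf <- tempfile(fileext = ".yaml")
  writeLines(c("energy: 250", "momentum_spread: 0",
               "source_plane_z: -2560", "x_magnet_z: -2000",
               "y_magnet_z: -2560", "initial_fwhm: 3",
               "divergence_sigma: 1"), tf)
  bl <- beamline_from_config(tf)
  expect_s3_class(bl, "rm3d_beamline")
  expect_equal(bl$x_magnet_z, -2000)

  tm <- tempfile(fileext = ".yaml")
  writeLines(c("rigur:", "  density: 1.2",
               "  relative_stopping_power: 1.165",
               "  radiation_length: 337"), tm)
  mats <- materials_from_config(tm)
  expect_equal(mats$rigur$relative_stopping_power, 1.165)
  expect_error(beamline(x_magnet_z = -3000, y_magnet_z = -2000))
})
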