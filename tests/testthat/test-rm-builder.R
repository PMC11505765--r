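test_that("axial rays intersect the rotated cube analytically", {
  tg <- cube_target(center_depth = 130)
  iv <- target_depth_interval(tg, 0, 0)
  # chord oracle: 60 / max |beam-axis component in the cube frame|
  expect_equal(iv[2] - iv[1], 60 / (sqrt(2) / 2), tolerance = 1e-9)
  expect_equal(mean(iv), 130, tolerance = 1e-9)

  expect_true(all(is.na(target_depth_interval(tg, 100, 0))))
  expect_false(cube_silhouette_contains(tg, 60, 0))
  expect_true(cube_silhouette_contains(tg, 0, 0))

  # support-function oracle for the total axial extent
  g <- expand.grid(x = seq(-55, 55, by = 0.5), y = seq(-45, 45, by = 0.5))
  ivg <- target_depth_interval(tg, g$x, g$y)
  extent <- max(ivg[, 2], na.rm = TRUE) - min(ivg[, 1], na.rm = TRUE)
  expect_equal(extent, 60 * (sqrt(2) / 2 + 1 / 2 + 1 / 2), tolerance = 0.05)
})

test_that("uniform raster plans have the expected spot grids", {
  p <- uniform_field_plan(c(80, 80), 5, mu = 1)
  expect_equal(nrow(p), 17 * 17)
  expect_equal(nrow(uniform_field_plan(c(5, 5), 5)), 4)
  p0 <- uniform_field_plan(c(10, 10), 5, mu = 0)
  expect_true(all(p0$mu == 0))
  expect_error(uniform_field_plan(c(7, 7), 5), "divide")

  # serpentine path: consecutive rows scan in opposite x directions
  rows <- split(p$x, p$y)
  expect_true(all(diff(rows[[1]]) > 0))
  expect_true(all(diff(rows[[2]]) < 0))
})

test_that("range-shifter layers collapse by per-spot MU summation", {
  g <- expand.grid(x = c(0, 5), y = c(0, 5))
  l1 <- list(wet = 0, spots = data.frame(g, mu = 1))
  l2 <- list(wet = 3, spots = data.frame(g, mu = 2.5))
  p <- plan_from_layers(list(l1, l2))
  expect_equal(p$mu, rep(3.5, 4))
  expect_equal(plan_from_layers(list(l1))$mu, rep(1, 4))
  # permutation invariance in layer order
  expect_equal(plan_from_layers(list(l2, l1))$mu,
               plan_from_layers(list(l1, l2))$mu)
  bad <- list(wet = 3, spots = data.frame(x = c(0, 1), y = c(0, 0),
                                          mu = 1))
  expect_error(plan_from_layers(list(l1, bad)), "match")
})

test_that("cube modulator pins land their distal peaks on the target", {
  fx <- cube_fixture("desk")
  mod <- fx$modulator
  expect_gt(nrow(mod$pins), 500)
  expect_equal(mod$base_layer, 8)
  expect_equal(mod$period, 3)

  # no pin outside the silhouette + margin
  far <- sqrt(mod$pins$x^2 + mod$pins$y^2)
  expect_false(any(!cube_silhouette_contains(fx$target, mod$pins$x,
                                             mod$pins$y) & far > 60))

  # per-pin range arithmetic: offset + absorber + base place the deepest
  # Bragg peak on the pin's own distal edge (quantized to 1 mm)
  rsp <- mod$material$relative_stopping_power
  reached <- fx$curve$range_80 - fx$scene$absorber_wet -
    mod$base_layer * rsp - mod$pins$offset_wet
  expect_lt(max(abs(reached - mod$pins$distal_q)), 1e-6)
  expect_lt(max(abs(mod$pins$distal_q - mod$pins$distal)), 1)

  # the deepest-reaching pin uses (almost) no compensator offset
  expect_lt(min(mod$pins$offset_wet), 1)
  # center pin carries the longest modulation
  hts <- vapply(mod$pins$contour, function(p) max(p$levels$height), 0)
  ic <- which(mod$pins$x == 0 & mod$pins$y == 0)
  expect_gt(hts[ic], 0.95 * max(hts))
})

test_that("per-pin SOBPs are flat over their own depth intervals", {
  fx <- cube_fixture("desk")
  mod <- fx$modulator
  keep <- mod$pins$distal_q - mod$pins$proximal_q > 10
  idx <- which(keep)
  set.seed(11)
  idx <- sample(idx, 40)
  flat <- vapply(idx, function(i) {
    w <- optimize_sobp_weights(fx$curve, mod$pins$proximal_q[i],
                               mod$pins$distal_q[i], wet_step = 3)
    sobp_flatness(w, fx$curve)
  }, 0)
  expect_gte(mean(flat <= 2), 0.95)
})

test_that("cube plan covers the silhouette with positive MU", {
  fx <- cube_fixture("desk")
  plan <- fx$plan
  expect_true(all(plan$mu > 0))
  expect_equal(attr(plan, "spacing"), 5)
  inside <- cube_silhouette_contains(fx$target, plan$x, plan$y)
  # spots cover at least the silhouette interior
  g <- expand.grid(x = seq(-40, 40, by = 10), y = seq(-30, 30, by = 10))
  gin <- cube_silhouette_contains(fx$target, g$x, g$y)
  near <- vapply(which(gin), function(i)
    min(abs(plan$x - g$x[i]) + abs(plan$y - g$y[i])), 0)
  expect_lt(max(near), 5.1)
  expect_gt(mean(inside), 0.5)
})

test_that("unreachable targets are rejected", {
  cv <- ref_curve()
  deep <- cube_target(center_depth = 250)   # distal corner beyond range
  expect_error(build_cube_modulator(deep, ref_scene(), cv), "reachable")
})
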