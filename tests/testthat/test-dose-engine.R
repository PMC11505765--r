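small_open_field <- function(mu = 1) {
  p <- uniform_field_plan(c(20, 20), 5, mu = mu)
  p
}

test_that("dose is linear in MU and invariant to spot order", {
  scene <- scene_config("baseline")
  smp <- run_profile("desk")
  d1 <- compute_dose(small_open_field(1), scene, sampling = smp)
  d2 <- compute_dose(small_open_field(2), scene, sampling = smp)
  expect_equal(d2$values, 2 * d1$values, tolerance = 1e-12)

  p <- small_open_field(1)
  set.seed(3)
  pp <- p[sample(nrow(p)), ]
  d3 <- compute_dose(pp, scene, sampling = smp)
  expect_equal(d3$values, d1$values, tolerance = 1e-12)
})

test_that("baseline peak depth follows range arithmetic", {
  # oracle: range in water minus the absorber WET (200 mm PMMA)
  scene <- scene_config("baseline")
  d <- compute_dose(uniform_field_plan(c(40, 40), 5), scene,
                    sampling = run_profile("desk"))
  pr <- sobp_profile(d, c(0, 0))
  oracle <- ref_curve()$range_80 - wet_of_slab(rm_materials("pmma"), 200)
  expect_lt(abs(pr$z[which.max(pr$dose)] - oracle), 5)
})

test_that("2D modulator pencil beam yields a flat integrated SOBP", {
  b <- full_2drm("step")
  d <- compute_dose(single_spot_plan(), pencil_scene_small(),
                    modulator = b$modulator, sampling = pencil_sampling())
  idd <- integrated_depth_dose(d)
  sel <- idd$z >= b$proximal + 5 & idd$z <= b$weights$plateau_distal
  flat <- 100 * max(abs(idd$dose[sel] / mean(idd$dose[sel]) - 1))
  expect_lte(flat, 1.5)
})

test_that("mesh and analytic modulator paths agree above the 20% isodose", {
  b <- full_2drm("step")
  mesh <- tessellate(b$modulator)
  smp <- pencil_sampling()
  da <- compute_dose(single_spot_plan(), pencil_scene_small(),
                     modulator = b$modulator, sampling = smp)
  dm <- compute_dose(single_spot_plan(), pencil_scene_small(),
                     mod_mesh = mesh, sampling = smp)
  hi <- da$values > 0.2 * max(da$values)
  rel <- abs(dm$values[hi] - da$values[hi]) / da$values[hi]
  expect_lt(max(rel), 0.005)
})

test_that("translating the modulator by one pin period is equivariant", {
  b <- full_2drm("step")
  mesh <- tessellate(b$modulator)
  smp <- pencil_sampling()
  d0 <- compute_dose(single_spot_plan(), pencil_scene_small(),
                     mod_mesh = mesh, sampling = smp)
  d3 <- compute_dose(single_spot_plan(), pencil_scene_small(),
                     mod_mesh = apply_transform(
                       mesh, rigid_transform(translation = c(3, 0, 0))),
                     sampling = smp)
  i0 <- integrated_depth_dose(d0)
  i3 <- integrated_depth_dose(d3)
  sel <- i0$z >= b$proximal + 5 & i0$z <= b$weights$plateau_distal
  m <- mean(i0$dose[sel])
  expect_lt(100 * max(abs(i3$dose[sel] - i0$dose[sel])) / m, 0.2)
})

test_that("depth profiles extract columns with lateral averaging", {
  x <- seq(-5, 5, by = 2.5)
  z <- seq(0.5, 9.5, by = 1)
  lat <- outer(exp(-x^2 / 20), exp(-x^2 / 30))
  dep <- seq_len(10)
  vals <- array(as.vector(lat) %o% dep, c(5, 5, 10))
  d <- dose_grid(x, x, z, vals)
  pr <- sobp_profile(d, c(0, 0))
  expect_equal(pr$dose, lat[3, 3] * dep)          # separable construction
  pr3 <- sobp_profile(d, c(0, 0), window = 3)
  expect_equal(pr3$dose, apply(vals[2:4, 2:4, ], 3, mean))
  expect_error(sobp_profile(d, c(50, 0)), "outside")
})

test_that("fluence stays smooth when no modulator is present", {
  scene <- scene_config("reference")
  plan <- uniform_field_plan(c(30, 30), 5)
  f1 <- score_fluence(plan, scene, plane_z = scene$absorber_z,
                      extent = 20, sampling = run_profile("desk"))
  f2 <- score_fluence(plan, scene, plane_z = scene$phantom_entrance_z,
                      extent = 20, sampling = run_profile("desk"))
  expect_lt(fluence_cov(f1, 8), 0.06)
  expect_lt(fluence_cov(f2, 8), 0.06)
  expect_true(all(f1$counts >= 0))
})

test_that("dose grids round-trip through JSON and slice CSV", {
  x <- seq(-5, 5, by = 2.5)
  z <- seq(0.5, 4.5, by = 1)
  vals <- array(runif(5 * 5 * 5), c(5, 5, 5))
  d <- dose_grid(x, x, z, vals)
  tf <- tempfile(fileext = ".json")
  write_dose_json(d, tf)
  back <- read_dose_json(tf)
  expect_equal(back$values, d$values, tolerance = 1e-6)
  expect_equal(back$z, d$z)

  tc <- tempfile(fileext = ".csv")
  write_dose_slice_csv(d, 2.5, tc)
  m <- utils::read.csv(tc, row.names = 1)
  expect_equal(unname(as.matrix(m)), d$values[, , 3], tolerance = 1e-9)
  expect_error(dose_slice(d, 50), "outside")
})
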