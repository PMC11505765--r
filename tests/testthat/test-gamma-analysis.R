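grid2d <- function(v, spacing = 2.5) {
  n <- nrow(v)
  ax <- (seq_len(n) - (n + 1) / 2) * spacing
  list(x = ax, y = ax, values = v)
}

test_that("identical distributions pass everywhere with gamma zero", {
  set.seed(21)
  v <- smooth_field_2d(seq(-10, 10, 2.5), seq(-10, 10, 2.5),
                       random_blobs())
  g <- gamma_index(grid2d(v), grid2d(v))
  expect_equal(g$passing_rate, 100)
  expect_true(all(g$gamma < 1e-9))
})

test_that("a uniform 5% rescale gives gamma 2.5 with no spatial rescue", {
  v <- matrix(1, 11, 11)
  g <- gamma_index(grid2d(v), grid2d(1.05 * v))
  expect_equal(g$passing_rate, 0)
  expect_equal(unname(g$gamma), rep(2.5, g$n_evaluated), tolerance = 1e-6)
})

test_that("sub-dta spatial shifts pass fully under local 2%/2mm", {
  ax <- seq(-15, 15, by = 2.5)
  # smooth field (gentle bumps on a plateau) with a taper that drops the
  # frame boundary below the 20% threshold: a 1 mm shift (< dta) must then
  # be fully rescued spatially
  fld <- function(x, y) {
    blob <- 1 + 0.3 * outer(exp(-(x - 3)^2 / 200), exp(-(y + 2)^2 / 260)) +
      0.25 * outer(exp(-(x + 4)^2 / 260), exp(-(y - 3)^2 / 200))
    r <- sqrt(outer(x^2, rep(1, length(y))) +
                outer(rep(1, length(x)), y^2))
    blob / (1 + exp((r - 10) / 1.2))
  }
  ref <- list(x = ax, y = ax, values = fld(ax, ax))
  ev <- list(x = ax, y = ax, values = fld(ax - 1.0, ax))
  g <- gamma_index(ref, ev)
  expect_equal(g$passing_rate, 100)
  gb <- gamma_index_brute(ref, ev, sample_step = 0.25)
  expect_equal(gb$passing_rate, 100)
})
test_that("optimized gamma matches the brute-force dense search", {
  set.seed(33)
  ax <- seq(-8, 8, by = 2)
  for (i in 1:20) {
    blobs <- random_blobs(3)
    ref <- grid2d(smooth_field_2d(ax, ax, blobs), spacing = 2)
    ev <- ref
    ev$values <- ref$values * (1 + runif(1, -0.03, 0.03)) +
      matrix(rnorm(length(ax)^2, 0, 0.004), length(ax))
    ev$values <- pmax(ev$values, 0)
    g1 <- gamma_index(ref, ev)
    g2 <- gamma_index_brute(ref, ev)
    expect_lt(max(abs(g1$gamma - g2$gamma)), 0.01)
  }
})

test_that("gamma agrees with brute force on a small 3D grid", {
  set.seed(55)
  ax <- seq(-5, 5, by = 2.5)
  z <- seq(0.5, 8.5, by = 2)
  base <- array(0, c(5, 5, 5))
  for (k in 1:5)
    base[, , k] <- smooth_field_2d(ax, ax, random_blobs(2)) + 0.4
  ref <- dose_grid(ax, ax, z, base)
  ev <- dose_grid(ax, ax, z, base * 1.015)
  # identical probe lattices: both searches step 0.25 mm
  g1 <- gamma_index(ref, ev, search_step = 0.25)
  g2 <- gamma_index_brute(ref, ev, sample_step = 0.25)
  expect_lt(max(abs(g1$gamma - g2$gamma)), 0.01)
})

test_that("local gamma is scale invariant and monotone in the criteria", {
  set.seed(13)
  ax <- seq(-10, 10, 2.5)
  blobs <- random_blobs()
  ref <- grid2d(smooth_field_2d(ax, ax, blobs))
  ev <- ref
  ev$values <- smooth_field_2d(ax - 0.8, ax, blobs) * 1.012
  g <- gamma_index(ref, ev)
  ref2 <- ref; ev2 <- ev
  ref2$values <- ref$values * 7.3
  ev2$values <- ev$values * 7.3
  expect_equal(gamma_index(ref2, ev2)$gamma, g$gamma, tolerance = 1e-9)

  tighter_dc <- gamma_index(ref, ev, gamma_criteria(dose_criterion = 0.01))
  tighter_dta <- gamma_index(ref, ev, gamma_criteria(dta = 1))
  expect_lte(tighter_dc$passing_rate, g$passing_rate)
  expect_lte(tighter_dta$passing_rate, g$passing_rate)
})

test_that("slice gamma extracts the requested depth planes", {
  ax <- seq(-10, 10, by = 2.5)
  z <- seq(0.5, 199.5, by = 1)
  set.seed(2)
  blobs <- random_blobs()
  lat <- smooth_field_2d(ax, ax, blobs) + 0.3
  depth <- exp(-(z - 120)^2 / (2 * 60^2))
  vals <- array(as.vector(lat) %o% depth, c(9, 9, length(z)))
  ref <- dose_grid(ax, ax, z, vals)
  gs <- gamma_slices(ref, ref, depths = c(110, 160))
  expect_equal(gs$z110$passing_rate, 100)
  expect_equal(gs$z160$passing_rate, 100)
  expect_error(gamma_slices(ref, ref, depths = 500), "outside")

  # slice result equals an independent 2D evaluation of the same plane
  ev <- ref
  ev$values <- vals * 1.011
  gs2 <- gamma_slices(ref, ev, depths = 160)
  sl_r <- dose_slice(ref, 160)
  sl_e <- dose_slice(ev, 160)
  # slice extraction matches a direct 2D evaluation of the same plane
  expect_equal(gs2[[1]]$gamma, gamma_index(sl_r, sl_e)$gamma)
  gb <- gamma_index_brute(sl_r, sl_e, sample_step = 0.25)
  g25 <- gamma_index(sl_r, sl_e, search_step = 0.25)
  expect_lt(max(abs(g25$gamma - gb$gamma)), 0.01)
})

test_that("empty reference distributions are rejected", {
  v <- matrix(0, 5, 5)
  expect_error(gamma_index(grid2d(v), grid2d(v)), "no dose")
})

test_that("SOBP metrics reproduce their closed forms", {
  z <- seq(50, 150, by = 1)
  p1 <- data.frame(z = z, dose = rep(1.002, length(z)))
  p0 <- data.frame(z = z, dose = rep(1.000, length(z)))
  m <- sobp_metrics(p1, c(60, 140), reference = p0)
  expect_equal(m$flatness, 0)
  expect_equal(m$max_deviation, 0.2)
  expect_equal(sobp_metrics(p0, c(60, 140), reference = p0)$max_deviation, 0)

  set.seed(99)
  for (i in 1:5) {
    d <- 1 + 0.05 * sin(z / runif(1, 5, 20)) + rnorm(length(z), 0, 0.01)
    pr <- data.frame(z = z, dose = d)
    sel <- z >= 70 & z <= 130
    m2 <- sobp_metrics(pr, c(70, 130))
    expect_equal(m2$flatness,
                 100 * max(abs(d[sel] - mean(d[sel]))) / mean(d[sel]))
  }
  expect_error(sobp_metrics(p0, c(500, 600)), "plateau")
})
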