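manual_weights <- function(weights, wet_step = 3) {
  structure(list(pullbacks = (seq_along(weights) - 1) * wet_step,
                 weights = weights / sum(weights), wet_step = wet_step,
                 proximal = NA_real_, distal = NA_real_),
            class = "rm3d_weights")
}

test_that("optimized weights produce a flat 10 cm SOBP", {
  cv <- ref_curve()
  distal <- cv$range_80 - ref_scene()$absorber_wet - 8 * 1.165
  w <- optimize_sobp_weights(cv, distal - 100, distal, wet_step = 3)
  expect_equal(sum(w$weights), 1)
  expect_true(all(w$weights >= 0))
  expect_lte(sobp_flatness(w, cv), 1)

  # deepest layer dominates; weights decrease towards the proximal side
  expect_equal(which.max(w$weights), 1L)
  n <- length(w$weights)
  expect_gt(mean(w$weights[1:(n %/% 2)]), mean(w$weights[(n %/% 2 + 1):n]))

  # degenerate interval: single layer
  w1 <- optimize_sobp_weights(cv, distal - 2, distal, wet_step = 3)
  expect_equal(w1$weights, 1)
  expect_equal(w1$pullbacks, 0)

  expect_error(optimize_sobp_weights(cv, 100, cv$range_80 + 50), "range_80")
  expect_error(optimize_sobp_weights(cv, 120, 100), "proximal")
})

test_that("step contour areas are proportional to the weights", {
  w <- manual_weights(c(0.25, 0.25, 0.25, 0.25))
  pin <- weights_to_step_contour(w)
  expect_equal(pin$levels$area_fraction, rep(0.25, 4))
  expect_equal(sum(pin$levels$area_fraction), 1)
  # adjacent level height difference: one WET step over the material RSP
  expect_equal(unique(round(diff(pin$levels$height), 9)),
               round(3 / 1.165, 9))

  # zero-weight layers are dropped
  wz <- manual_weights(c(0.5, 0, 0.5))
  pz <- weights_to_step_contour(wz)
  expect_equal(nrow(pz$levels), 2)
  expect_equal(pz$levels$wet, c(0, 6))
})

test_that("stepless contour keeps the valley atom and ramps linearly", {
  w <- manual_weights(c(0.5, 0.5))
  pin <- step_to_stepless(w)
  # deepest layer stays a flat valley floor of area 0.5
  expect_equal(pin_height_at(pin, 1.4, 0), 0)
  a <- seq(0.55, 0.95, by = 0.05)   # cumulative area inside the ramp
  wet <- stats::approx(pin$knot_cum, pin$knot_wet, xout = a,
                       ties = "ordered")$y
  # exact linearity of the single ramp
  expect_lt(max(abs(diff(diff(wet)))), 1e-9)
  expect_true(all(diff(pin$profile$wet) >= 0))
  expect_error(step_to_stepless(w, grid_resolution = 2), "resolution")
})

test_that("WET distribution round-trips both contour kinds", {
  set.seed(41)
  for (i in 1:15) {
    n <- sample(3:20, 1)
    wv <- runif(n)
    wv[sample(n, 1)] <- 0           # allow dropped layers
    wv[1] <- max(wv) + 0.2          # deepest usually dominant
    w <- manual_weights(wv)
    ps <- weights_to_step_contour(w)
    rt <- contour_wet_distribution(ps)
    expect_equal(rt$weights[match(ps$levels$wet, rt$pullbacks)],
                 ps$levels$area_fraction, tolerance = 1e-12)
    pc <- step_to_stepless(w)
    rc <- contour_wet_distribution(pc)
    m <- seq_len(min(length(rc$weights), n))
    expect_lt(max(abs(rc$weights[m] - w$weights[m])), 1e-3)
  }
})

test_that("flat slab pin has a delta WET distribution", {
  pin <- structure(list(kind = "step", base_period = 3,
                        material = rm_materials("rigur"),
                        levels = data.frame(wet = 6, height = 6 / 1.165,
                                            area_fraction = 1),
                        wet_step = 3),
                   class = "rm3d_pin")
  d <- contour_wet_distribution(pin)
  expect_equal(d$weights[d$pullbacks == 6], 1)
  expect_equal(sum(d$weights), 1)
})

test_that("contours are invariant under weight rescaling", {
  set.seed(7)
  wv <- runif(8)
  w1 <- manual_weights(wv)
  w2 <- manual_weights(wv * 17.3)
  expect_equal(weights_to_step_contour(w1)$levels,
               weights_to_step_contour(w2)$levels)
  expect_equal(step_to_stepless(w1)$knot_cum, step_to_stepless(w2)$knot_cum)
})

test_that("pin contours serialize to JSON and back", {
  w <- manual_weights(c(0.4, 0.3, 0.2, 0.1))
  for (pin in list(weights_to_step_contour(w), step_to_stepless(w))) {
    tf <- tempfile(fileext = ".json")
    write_pin_json(pin, tf)
    back <- read_pin_json(tf)
    expect_equal(back$kind, pin$kind)
    x <- seq(-1.45, 1.45, by = 0.05)
    expect_equal(pin_height_at(back, x, 0), pin_height_at(pin, x, 0),
                 tolerance = 1e-9)
  }
})

test_that("concentric-ring heights integrate back to the area fractions", {
  w <- manual_weights(c(0.35, 0.3, 0.2, 0.15))
  pin <- weights_to_step_contour(w)
  # fine area sampling of the cell recovers each level's area fraction
  u <- seq(-1.5 + 0.0005, 1.5 - 0.0005, by = 0.001)
  h <- pin_height_at(pin, rep(u, length(u)), rep(u, each = length(u)))
  for (k in seq_len(nrow(pin$levels)))
    expect_equal(mean(abs(h - pin$levels$height[k]) < 1e-9),
                 pin$levels$area_fraction[k], tolerance = 2e-3)
})
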