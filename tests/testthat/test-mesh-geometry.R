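test_that("tessellated modulators are watertight with the analytic volume", {
  b <- tiny_2drm("step")
  mesh <- tessellate(b$modulator)
  expect_true(mesh_is_watertight(mesh))
  va <- attr(mesh, "analytic_volume")
  expect_lt(abs(mesh_volume(mesh) - va) / va, 0.005)

  # flat-slab geometry: volume is exactly footprint x height
  slab <- modulator(data.frame(x = 0, y = 0, offset_wet = 3 * 1.165,
                               raw_sum = 1,
                               contour = I(list(structure(list(
                                 kind = "step", base_period = 3,
                                 material = rm_materials("rigur"),
                                 levels = data.frame(wet = 0, height = 0,
                                                     area_fraction = 1),
                                 wet_step = 3), class = "rm3d_pin")))),
                   period = 3, base_layer = 8, z_base = -225)
  ms <- tessellate(slab)
  expect_true(mesh_is_watertight(ms))
  expect_equal(mesh_volume(ms), 3 * 3 * (8 + 3), tolerance = 1e-9)

  bc <- tiny_2drm("stepless")
  mc <- tessellate(bc$modulator, tolerance = 0.2)
  expect_true(mesh_is_watertight(mc))
  vc <- attr(mc, "analytic_volume")
  expect_lt(abs(mesh_volume(mc) - vc) / vc, 0.005)
})

test_that("rigid transforms move vertices exactly and rigidly", {
  mesh <- tessellate(tiny_2drm("step")$modulator)
  idt <- apply_transform(mesh, rigid_transform())
  expect_identical(idt$vertices, mesh$vertices %*% diag(3))

  tr <- apply_transform(mesh, rigid_transform(translation = c(1.5, 0, 0)))
  expect_equal(tr$vertices[, 1], mesh$vertices[, 1] + 1.5)
  expect_equal(tr$vertices[, 2:3], mesh$vertices[, 2:3])

  # hand-rotation oracle: vertex at the origin, 1.5 deg about Y around
  # pivot (-200, 0, -180)
  th <- 1.5 * pi / 180
  vx <- 0 - (-200); vz <- 0 - (-180)
  exp_x <- cos(th) * vx + sin(th) * vz - 200
  exp_z <- -sin(th) * vx + cos(th) * vz - 180
  m0 <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                      matrix(c(1, 2, 3), 1))
  rot <- apply_transform(m0, rigid_transform(1.5, "y", c(-200, 0, -180)))
  expect_equal(rot$vertices[1, ], c(exp_x, 0, exp_z), tolerance = 1e-12)

  # pairwise distances preserved to < 1e-9 relative
  set.seed(5)
  pick <- sample(nrow(mesh$vertices), 30)
  d0 <- stats::dist(mesh$vertices[pick, ])
  rt <- apply_transform(mesh, rigid_transform(37, "y", c(10, -4, 2),
                                              c(3, 1, -2)))
  d1 <- stats::dist(rt$vertices[pick, ])
  expect_lt(max(abs(d1 - d0) / pmax(d0, 1e-9)), 1e-9)

  # composition about a shared pivot
  p <- c(4, 0, -7)
  a <- apply_transform(apply_transform(m0, rigid_transform(10, "y", p)),
                       rigid_transform(23, "y", p))
  b <- apply_transform(m0, rigid_transform(33, "y", p))
  expect_equal(a$vertices, b$vertices, tolerance = 1e-12)
})

test_that("STL round-trips in both dialects at float32 precision", {
  mesh <- tessellate(tiny_2drm("step")$modulator)
  soup <- function(m) m$vertices[as.vector(t(m$triangles)), ]

  tb <- tempfile(fileext = ".stl")
  write_stl(mesh, tb, "binary")
  mb <- read_stl(tb)
  expect_equal(nrow(mb$triangles), nrow(mesh$triangles))
  expect_lt(max(abs(soup(mb) - soup(mesh))), 1e-4)   # float32
  expect_true(mesh_is_watertight(mb))

  ta <- tempfile(fileext = ".stl")
  write_stl(mesh, ta, "ascii")
  ma <- read_stl(ta)
  expect_equal(nrow(ma$triangles), nrow(mesh$triangles))
  expect_lt(max(abs(soup(ma) - soup(mb))), 1e-4)

  # malformed files fail with a byte diagnosis
  tt <- tempfile(fileext = ".stl")
  raw_all <- readBin(tb, "raw", n = file.size(tb))
  writeBin(raw_all[1:200], tt)
  expect_error(read_stl(tt), "ends at")
  writeBin(raw_all[1:10], tt)
  expect_error(read_stl(tt), "small")
})

test_that("analytic and ray-cast heightfields agree off step edges", {
  b <- tiny_2drm("step")
  mesh <- tessellate(b$modulator)
  hf_a <- heightfield_of(b$modulator, 0.1)
  hf_m <- heightfield_of(mesh, 0.1)
  ix <- match(round(hf_m$x, 6), round(hf_a$x, 6))
  iy <- match(round(hf_m$y, 6), round(hf_a$y, 6))
  D <- abs(hf_m$H[!is.na(ix), !is.na(iy)] -
             hf_a$H[ix[!is.na(ix)], iy[!is.na(iy)]])
  # identical everywhere except exactly on ring edges
  expect_gt(mean(D < 1e-6), 0.97)
  expect_equal(stats::median(D), 0)

  # ray through the valley between pins sees the base layer only
  # (pin centers sit at +-1.5/+-4.5 mm, so the origin is a cell corner)
  slab_h <- heightfield_lookup(hf_a, 0.05, 0.05)
  expect_equal(slab_h, 8, tolerance = 0.2)
})

test_that("heightfields of flat slabs are constant", {
  pin <- structure(list(kind = "step", base_period = 3,
                        material = rm_materials("rigur"),
                        levels = data.frame(wet = 0, height = 0,
                                            area_fraction = 1),
                        wet_step = 3), class = "rm3d_pin")
  slab <- modulator(data.frame(x = 0, y = 0, offset_wet = 4 * 1.165,
                               raw_sum = 1, contour = I(list(pin))),
                    period = 3, base_layer = 8, z_base = -225)
  hf <- modulator_heightfield(slab, 0.25)
  inner <- hf$H[abs(hf$x) < 1.2, abs(hf$y) < 1.2]
  expect_true(all(abs(inner - 12) < 1e-9))
})
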