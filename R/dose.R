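# Deterministic pencil-beam dose engine.
#
# Each scan spot is decomposed into sub-rays on a stratified lattice over
# the spot's Gaussian fluence at the modulator plane.  A sub-ray looks up
# its material path through the modulator (analytic heightfield for the
# nominal device, ray-cast heightfield for a transformed mesh), converts it
# to water-equivalent thickness, and deposits the correspondingly
# pulled-back Bragg curve along depth.  Sub-rays are binned by quantized
# modulator WET; the dose is composed as (fluence map per WET class) x
# (depth-dose per class), then blurred laterally with the depth-dependent
# Gaussian scattering kernel accrued downstream of the modulator (absorber
# and phantom scattering dominate; in-pin scattering is neglected for dose,
# but modelled for fluence scoring).  Everything is deterministic; dose is
# linear in MU.

#' Engine sampling configuration
#'
#' @param cell_size lateral cell size of the WET class field in mm (must
#'   divide the pin period).
#' @param subsamples sub-rays per class-field cell and axis used when
#'   rasterizing a transformed mesh.
#' @param window_sigmas half-width of the per-spot fluence window in units
#'   of the beam sigma at the modulator plane.
#' @param wet_quant quantization of the WET classes in mm.
#' @param stepless_tolerance ring height tolerance for tessellating
#'   stepless pins in mm.
#' @param kernel_cut lateral kernel cutoff in sigmas.
#' @return list of class `rm3d_sampling`.
#' @export
sampling_config <- function(cell_size = 0.5, subsamples = 25,
                            window_sigmas = 3, wet_quant = 0.25,
                            stepless_tolerance = 0.2, kernel_cut = 4) {
  structure(list(cell_size = cell_size, subsamples = subsamples,
                 window_sigmas = window_sigmas, wet_quant = wet_quant,
                 stepless_tolerance = stepless_tolerance,
                 kernel_cut = kernel_cut),
            class = "rm3d_sampling")
}

#' Scored dose grid
#'
#' Depths are relative to the water-phantom surface, not absolute z.
#'
#' @param x,y lateral voxel centers in mm.
#' @param z depth voxel centers in mm below the phantom surface.
#' @param values array `length(x) x length(y) x length(z)`, relative dose.
#' @return object of class `rm3d_dose`.
#' @export
dose_grid <- function(x, y, z, values) {
  stopifnot(all(dim(values) == c(length(x), length(y), length(z))),
            all(values >= 0))
  structure(list(x = x, y = y, z = z, values = values,
                 spacing = c(x[2] - x[1], y[2] - y[1], z[2] - z[1])),
            class = "rm3d_dose")
}

#' @export
print.rm3d_dose <- function(x, ...) {
  cat(sprintf("<dose grid %d x %d x %d, %.2g x %.2g x %.2g mm voxels, max %.3g>\n",
              length(x$x), length(x$y), length(x$z), x$spacing[1],
              x$spacing[2], x$spacing[3], max(x$values)))
  invisible(x)
}

scene_grid_axes <- function(scene) {
  sp <- scene$grid_lateral_spacing
  ext <- scene$grid_lateral_extent
  lat <- seq(-ext, ext, by = sp)
  z <- seq(scene$grid_depth_spacing / 2, scene$grid_depth_extent,
           by = scene$grid_depth_spacing)
  list(lat = lat, z = z)
}

# Gaussian resampling matrix between two sets of uniform centers (mass of a
# unit Gaussian at source center j integrated over target cell i).
gauss_smear_matrix <- function(centers, sigma, cut = 4) {
  s <- centers[2] - centers[1]
  if (sigma < 0.05 * s) return(diag(length(centers)))
  d <- outer(centers, centers, "-")
  M <- stats::pnorm((d + s / 2) / sigma) - stats::pnorm((d - s / 2) / sigma)
  M[abs(d) > cut * sigma + s] <- 0
  M
}

# lateral scattering kernel sigma at depth z (mm) accrued downstream of the
# modulator plane: residual divergence drift, absorber MCS with the full
# slab lever arm, and in-water MCS.
kernel_sigma <- function(z, scene, bl) {
  drift <- z + (scene$phantom_entrance_z - scene$mod_plane_z)
  sig_div <- (bl$divergence_sigma / 1000) * drift
  R0 <- bragg_kleeman_range(bl$energy)
  xa <- scene$absorber_thickness
  e_mid <- energy_from_range(max(R0 - scene$absorber_wet / 2, 1))
  th_a <- highland_theta0(xa, scene$absorber$radiation_length, e_mid)
  La <- scene$air_gap + z
  var_a <- th_a^2 * (xa^2 / 3 + xa * La + La^2)
  e_w <- energy_from_range(pmax(R0 - scene$absorber_wet - z / 2, 1))
  th_w <- highland_theta0(z, rm_materials("water")$radiation_length, e_w)
  var_w <- th_w^2 * z^2 / 3
  sqrt(sig_div^2 + var_a + var_w)
}

# beam sigma at the modulator plane (source size + divergence drift)
sigma_at_modulator <- function(scene, bl) {
  sig0 <- bl$initial_fwhm / (2 * sqrt(2 * log(2)))
  drift <- scene$mod_plane_z - bl$source_plane_z
  sqrt(sig0^2 + ((bl$divergence_sigma / 1000) * drift)^2)
}

# resolve the modulator description to a WET class field (or NULL)
resolve_class_field <- function(modulator, mod_mesh, sampling) {
  if (!is.null(mod_mesh)) {
    mesh_class_field(mod_mesh, cell_size = sampling$cell_size,
                     subsamples = sampling$subsamples,
                     q = sampling$wet_quant)
  } else if (!is.null(modulator)) {
    analytic_class_field(modulator, cell_size = sampling$cell_size,
                         q = sampling$wet_quant)
  } else NULL
}

#' Compute the 3D dose in the water phantom
#'
#' @param plan an `rm3d_plan`.
#' @param scene an [scene_config()].
#' @param modulator optional `rm3d_modulator` (analytic heightfield path).
#' @param mod_mesh optional `rm3d_mesh` of the (possibly transformed)
#'   modulator; takes precedence over `modulator`.
#' @param bl an [beamline()].
#' @param sampling an [sampling_config()].
#' @return an `rm3d_dose`; attribute `escaped` holds the weight fraction of
#'   sub-rays that left the scoring grid (logged, not raised, below 0.1%).
#' @export
compute_dose <- function(plan, scene, modulator = NULL, mod_mesh = NULL,
                         bl = beamline(), sampling = sampling_config()) {
  stopifnot(inherits(scene, "rm3d_scene"), nrow(plan) >= 1)
  axes <- scene_grid_axes(scene)
  lat <- axes$lat; zv <- axes$z
  nx <- length(lat); nz <- length(zv)
  sp <- scene$grid_lateral_spacing

  cf <- resolve_class_field(modulator, mod_mesh, sampling)
  curve <- bragg_curve(bl$energy, depth_step = 0.5)

  sig_mod <- sigma_at_modulator(scene, bl)
  q <- sampling$wet_quant
  zm <- scene$mod_plane_z
  pe <- scene$phantom_entrance_z
  pos_mod <- spot_position_at(plan$x, plan$y, bl, zm)
  pos_ent <- spot_position_at(plan$x, plan$y, bl, pe)

  idx_list <- vector("list", nrow(plan))
  escaped <- 0; total_w <- 0
  air_cf <- is.null(cf)
  for (s in seq_len(nrow(plan))) {
    if (plan$mu[s] <= 0) next
    if (air_cf) {
      ent <- list(px = pos_mod[s, 1], py = pos_mod[s, 2], cls = 0L, w = 1)
    } else {
      ent <- spot_window_entries(cf, pos_mod[s, 1], pos_mod[s, 2],
                                 sig_mod, nsig = sampling$window_sigmas)
    }
    # carry the window cells to the phantom entrance along the spot axis
    rx <- ent$px + (pos_ent[s, 1] - pos_mod[s, 1])
    ry <- ent$py + (pos_ent[s, 2] - pos_mod[s, 2])
    w <- ent$w * plan$mu[s]
    cls <- ent$cls
    total_w <- total_w + sum(w)
    fx <- (rx - lat[1]) / sp; fy <- (ry - lat[1]) / sp
    i0 <- floor(fx); j0 <- floor(fy)
    ok <- i0 >= 0 & i0 <= nx - 2 & j0 >= 0 & j0 <= nx - 2
    if (!all(ok)) {
      escaped <- escaped + sum(w[!ok])
      i0 <- i0[ok]; j0 <- j0[ok]
      fx <- fx[ok]; fy <- fy[ok]; w <- w[ok]
      cl <- cls[ok]
    } else cl <- cls
    tx <- fx - i0; ty <- fy - j0
    cell <- rep(i0 + 1L + j0 * nx, 4) +
      c(rep(0L, length(i0)), rep(1L, length(i0)),
        rep(nx, length(i0)), rep(nx + 1L, length(i0)))
    wb <- c(w * (1 - tx) * (1 - ty), w * tx * (1 - ty),
            w * (1 - tx) * ty, w * tx * ty)
    idx_list[[s]] <- cbind(key = (rep(cl, 4) * (nx * nx + 1)) + cell - 1,
                           w = wb)
  }
  allm <- do.call(rbind, idx_list)
  acc <- rowsum(allm[, "w"], allm[, "key"])
  keys <- as.numeric(rownames(acc))
  cls_u <- sort(unique(floor(keys / (nx * nx + 1))))
  ncls <- length(cls_u)
  Fm <- matrix(0, nx * nx, ncls)
  ci <- match(floor(keys / (nx * nx + 1)), cls_u)
  cell <- keys %% (nx * nx + 1) + 1
  Fm[cbind(cell, ci)] <- acc[, 1]

  # depth-dose per WET class (absorber + modulator pullback)
  A <- vapply(cls_u, function(cl)
    bragg_dose_at(curve, zv + scene$absorber_wet + cl * q),
    numeric(nz))
  if (scene$fluence_attenuation > 0) {
    lam <- scene$fluence_attenuation
    att <- exp(-lam * (outer(zv, scene$absorber_wet + cls_u * q, "+")))
    A <- A * att
  }
  D <- Fm %*% t(A)                     # (cells x nz)

  sigk <- kernel_sigma(zv, scene, bl)
  # without a modulator the beam profile is not realized by window cells,
  # so the source/divergence width at the modulator plane joins the kernel
  if (air_cf) sigk <- sqrt(sigk^2 + sig_mod^2)
  vals <- array(0, c(nx, nx, nz))
  for (k in seq_len(nz)) {
    if (all(D[, k] == 0)) next
    S <- gauss_smear_matrix(lat, sigk[k], cut = sampling$kernel_cut)
    vals[, , k] <- S %*% matrix(D[, k], nx, nx) %*% t(S)
  }
  out <- dose_grid(lat, lat, zv, vals)
  frac <- if (total_w > 0) escaped / total_w else 0
  attr(out, "escaped") <- frac
  if (frac > 0.001)
    warning(sprintf("%.2f%% of sub-ray weight left the scoring grid",
                    100 * frac), call. = FALSE)
  out
}

#' Score the lateral particle fluence at a plane
#'
#' Sub-rays are generated as in [compute_dose()]; each is spread with the
#' Gaussian displacement accumulated up to `plane_z` (in-pin scattering
#' with its lever arm, then absorber scattering for planes downstream of
#' the absorber) and histogrammed on a fine lateral grid.
#'
#' @inheritParams compute_dose
#' @param plane_z scoring plane in mm (between source and phantom).
#' @param resolution lateral bin size in mm.
#' @param extent half-extent of the scoring grid in mm.
#' @return object of class `rm3d_fluence`: `x`, `y`, `counts`.
#' @export
score_fluence <- function(plan, scene, modulator = NULL, mod_mesh = NULL,
                          bl = beamline(), plane_z = NULL,
                          resolution = 0.5, extent = 45,
                          sampling = sampling_config()) {
  if (is.null(plane_z)) plane_z <- scene$absorber_z
  stopifnot(plane_z >= scene$mod_plane_z,
            plane_z <= scene$phantom_entrance_z)
  cf <- resolve_class_field(modulator, mod_mesh, sampling)
  mat_mod <- if (!is.null(modulator)) modulator$material
             else attr(mod_mesh, "material") %||% rm_materials("rigur")
  rsp_mod <- mat_mod$relative_stopping_power
  sig_mod <- sigma_at_modulator(scene, bl)
  zm <- scene$mod_plane_z
  R0 <- bragg_kleeman_range(bl$energy)

  grid <- seq(-extent, extent, by = resolution)
  ng <- length(grid)
  pos_mod <- spot_position_at(plan$x, plan$y, bl, zm)
  pos_pl <- spot_position_at(plan$x, plan$y, bl, plane_z)

  var_a <- 0
  if (plane_z > scene$absorber_z) {
    xa <- min(plane_z, scene$absorber_exit_z) - scene$absorber_z
    La <- max(plane_z - scene$absorber_exit_z, 0)
    e_mid <- energy_from_range(
      max(R0 - wet_of_slab(scene$absorber, xa) / 2, 1))
    th_a <- highland_theta0(xa, scene$absorber$radiation_length, e_mid)
    var_a <- th_a^2 * (xa^2 / 3 + xa * La + La^2)
  }
  drift <- plane_z - zm
  lx <- vector("list", nrow(plan)); ly <- lx; lw <- lx; ls_ <- lx
  for (s in seq_len(nrow(plan))) {
    if (plan$mu[s] <= 0) next
    if (is.null(cf)) {
      ent <- list(px = pos_mod[s, 1], py = pos_mod[s, 2], cls = 0L, w = 1)
    } else {
      ent <- spot_window_entries(cf, pos_mod[s, 1], pos_mod[s, 2],
                                 sig_mod, nsig = sampling$window_sigmas)
    }
    lmod <- ent$cls * sampling$wet_quant / rsp_mod  # physical path in pins
    # in-pin scattering, lever = remaining pin + drift to the plane
    th_p <- highland_theta0(lmod, mat_mod$radiation_length, bl$energy)
    var_p <- th_p^2 * (lmod^2 / 3 + lmod * drift + drift^2)
    lx[[s]] <- ent$px + (pos_pl[s, 1] - pos_mod[s, 1])
    ly[[s]] <- ent$py + (pos_pl[s, 2] - pos_mod[s, 2])
    lw[[s]] <- ent$w * plan$mu[s]
    ls_[[s]] <- sqrt(var_p + var_a + if (is.null(cf)) sig_mod^2 else 0)
  }
  px <- unlist(lx); py <- unlist(ly)
  pw <- unlist(lw); psig <- unlist(ls_)
  counts <- matrix(0, ng, ng)
  scls <- round(psig / 0.05)
  for (sc in sort(unique(scls))) {
    sel <- scls == sc
    h <- matrix(0, ng, ng)
    fx <- (px[sel] - grid[1]) / resolution
    fy <- (py[sel] - grid[1]) / resolution
    i0 <- floor(fx); j0 <- floor(fy)
    ok <- i0 >= 0 & i0 <= ng - 2 & j0 >= 0 & j0 <= ng - 2
    i0 <- i0[ok]; j0 <- j0[ok]
    tx <- fx[ok] - i0; ty <- fy[ok] - j0; w <- pw[sel][ok]
    idx <- c(i0 + 1L + j0 * ng, i0 + 2L + j0 * ng,
             i0 + 1L + (j0 + 1L) * ng, i0 + 2L + (j0 + 1L) * ng)
    wb <- c(w * (1 - tx) * (1 - ty), w * tx * (1 - ty),
            w * (1 - tx) * ty, w * tx * ty)
    acc <- rowsum(wb, idx)
    h[as.integer(rownames(acc))] <- acc[, 1]
    sig <- sc * 0.05
    if (sig > 0.05 * resolution) {
      S <- gauss_smear_matrix(grid, sig)
      h <- S %*% h %*% t(S)
    }
    counts <- counts + h
  }
  structure(list(x = grid, y = grid, counts = counts, plane_z = plane_z),
            class = "rm3d_fluence")
}

#' Coefficient of variation of a fluence map over a central region
#' @param fl an `rm3d_fluence`.
#' @param half_extent half-size of the central square region in mm.
#' @return sd/mean of the counts in the region.
#' @export
fluence_cov <- function(fl, half_extent = 15) {
  ix <- abs(fl$x) <= half_extent
  v <- fl$counts[ix, ix]
  stats::sd(v) / mean(v)
}

#' Depth-dose profile along a lateral point
#'
#' @param dose an `rm3d_dose`.
#' @param point lateral (x, y) in mm.
#' @param window lateral averaging window in voxels (odd integer).
#' @return data.frame with `z` (depth, mm) and `dose`.
#' @export
sobp_profile <- function(dose, point = c(0, 0), window = 1) {
  i <- which.min(abs(dose$x - point[1]))
  j <- which.min(abs(dose$y - point[2]))
  if (abs(dose$x[i] - point[1]) > dose$spacing[1] ||
      abs(dose$y[j] - point[2]) > dose$spacing[2])
    stop("point outside the dose grid", call. = FALSE)
  half <- (window - 1) %/% 2
  ii <- max(1, i - half):min(length(dose$x), i + half)
  jj <- max(1, j - half):min(length(dose$y), j + half)
  prof <- apply(dose$values[ii, jj, , drop = FALSE], 3, mean)
  data.frame(z = dose$z, dose = prof)
}

#' Laterally integrated depth dose
#'
#' Sums the dose over the lateral plane per depth (optionally within a
#' radius).  For a single pencil beam this is the quantity whose plateau is
#' flat for a well-designed modulator: the central-axis dose of a pencil
#' falls with depth simply because scattering dilutes it laterally.
#'
#' @param dose an `rm3d_dose`.
#' @param radius optional lateral integration radius in mm.
#' @return data.frame with `z` and `dose`.
#' @export
integrated_depth_dose <- function(dose, radius = NULL) {
  v <- dose$values
  if (!is.null(radius)) {
    sel <- outer(dose$x^2, dose$y^2, "+") <= radius^2
    prof <- apply(v, 3, function(m) sum(m[sel]))
  } else prof <- apply(v, 3, sum)
  data.frame(z = dose$z, dose = prof)
}

#' Dose-grid JSON I/O
#' @param dose an `rm3d_dose`.
#' @param path file path.
#' @rdname dose_io
#' @export
write_dose_json <- function(dose, path) {
  jsonlite::write_json(
    list(x = dose$x, y = dose$y, z = dose$z,
         values = as.vector(dose$values)),
    path, digits = 8)
  invisible(path)
}

#' @rdname dose_io
#' @export
read_dose_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  dose_grid(obj$x, obj$y, obj$z,
            array(obj$values, c(length(obj$x), length(obj$y),
                                length(obj$z))))
}

#' Extract a transverse slice
#' @param dose an `rm3d_dose`.
#' @param depth slice depth in mm (must lie inside the grid).
#' @return list with `x`, `y`, `values` (matrix), `depth` (actual voxel
#'   depth).
#' @export
dose_slice <- function(dose, depth) {
  if (depth < min(dose$z) - dose$spacing[3] / 2 ||
      depth > max(dose$z) + dose$spacing[3] / 2)
    stop("depth ", depth, " mm outside the scored grid", call. = FALSE)
  k <- which.min(abs(dose$z - depth))
  list(x = dose$x, y = dose$y, values = dose$values[, , k],
       depth = dose$z[k])
}

#' @rdname dose_io
#' @param depth slice depth in mm for the CSV export.
#' @export
write_dose_slice_csv <- function(dose, depth, path) {
  sl <- dose_slice(dose, depth)
  m <- sl$values
  dimnames(m) <- list(sprintf("x_%g", sl$x), sprintf("y_%g", sl$y))
  utils::write.csv(m, path)
  invisible(path)
}
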