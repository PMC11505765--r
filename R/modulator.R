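# Modulator assembly: a lateral grid of pins on a base layer with
# protective side walls.  Pins sit on the upstream face of the base and
# point towards the source; the base's downstream face is `mod_gap` mm
# upstream of the absorber.  Each pin of a target-specific (3D) modulator
# carries, in addition to its modulation steps, a uniform compensator
# offset that places its deepest Bragg peak on the target's distal surface.

#' Modulator object
#'
#' Usually constructed by [build_cube_modulator()] or [build_2drm()].
#'
#' @param pins data.frame with one row per pin: `x`, `y` (cell centers, mm),
#'   `offset_wet` (compensator WET, mm), `raw_sum` (unnormalized fluence
#'   weight used by the MU heuristic), and list-column `contour` of
#'   `rm3d_pin` objects.
#' @param period pin cell size in mm.
#' @param base_layer base layer thickness in mm.
#' @param material modulator material.
#' @param wall list with `thickness` and `height` (mm); `NULL` for none.
#' @param z_base downstream face of the base layer (mm).
#' @return object of class `rm3d_modulator`.
#' @export
modulator <- function(pins, period = 3, base_layer = 8,
                      material = rm_materials("rigur"), wall = NULL,
                      z_base = NULL) {
  stopifnot(base_layer >= 0)
  structure(list(pins = pins, period = period, base_layer = base_layer,
                 material = material, wall = wall, z_base = z_base),
            class = "rm3d_modulator")
}

#' @export
print.rm3d_modulator <- function(x, ...) {
  hmax <- if (nrow(x$pins)) max(modulator_pin_heights(x)) else 0
  cat(sprintf(
    "<modulator: %d pins, period %.1f mm, base %.1f mm, max height %.1f mm, %s>\n",
    nrow(x$pins), x$period, x$base_layer, hmax, x$material$name))
  invisible(x)
}

# total physical height (offset + modulation) per pin
modulator_pin_heights <- function(mod) {
  rsp <- mod$material$relative_stopping_power
  vapply(seq_len(nrow(mod$pins)), function(i) {
    pin <- mod$pins$contour[[i]]
    hmax <- if (pin$kind == "step") max(pin$levels$height)
            else max(pin$profile$height)
    hmax + mod$pins$offset_wet[i] / rsp
  }, 0)
}

# lateral footprint of the pin field (not including walls)
modulator_footprint <- function(mod) {
  p2 <- mod$period / 2
  list(x = range(mod$pins$x) + c(-p2, p2),
       y = range(mod$pins$y) + c(-p2, p2))
}

#' Build the target-conformal cube modulator
#'
#' For every pin cell whose center lies inside the rotated-cube silhouette
#' (plus `margin`), computes the SOBP depth interval of the axial ray,
#' solves the layer weights with [optimize_sobp_weights()], converts them to
#' a step contour, and adds the compensator offset that places the pin's
#' deepest Bragg peak on its own distal edge.  If the target's
#' `center_depth` is unset, the cube is placed so that its deepest point
#' needs exactly zero compensator offset (deepest reachable placement).
#'
#' @param target an [cube_target()].
#' @param scene an [scene_config()] (reference geometry).
#' @param curve pristine [bragg_curve()] at the plan energy.
#' @param margin silhouette margin in mm (default one pin period).
#' @param wet_step WET layer spacing in mm.
#' @param period pin cell size in mm.
#' @param base_layer base layer thickness in mm.
#' @param material modulator material.
#' @param interval_quantum quantization of the per-pin (proximal, distal)
#'   intervals in mm used to cache weight solves.
#' @return list with `modulator` (an `rm3d_modulator`), `target` (with
#'   resolved center depth) and `available_range` (max distal depth, mm).
#' @export
build_cube_modulator <- function(target, scene, curve, margin = NULL,
                                 wet_step = 3, period = 3, base_layer = 8,
                                 material = rm_materials("rigur"),
                                 interval_quantum = 1) {
  stopifnot(inherits(target, "rm3d_cube"), inherits(scene, "rm3d_scene"))
  if (is.null(margin)) margin <- period
  rsp <- material$relative_stopping_power
  base_wet <- base_layer * rsp
  available <- curve$range_80 - scene$absorber_wet - base_wet
  if (is.null(target$center_depth))
    target$center_depth <- available - cube_z_extent(target) / 2
  if (target$center_depth + cube_z_extent(target) / 2 > available + 1e-6)
    stop("target distal corner beyond the reachable range", call. = FALSE)

  # candidate pin centers (a pin centered on the beam axis)
  half_lat <- target$side * sqrt(3) / 2 + margin + period
  ks <- seq(-ceiling(half_lat / period), ceiling(half_lat / period))
  centers <- expand.grid(x = ks * period, y = ks * period)
  # a cell is occupied when its center is inside the silhouette + margin:
  # probe the interval at the center and at 4 pulled-in margin probes
  iv <- target_depth_interval(target, centers$x, centers$y)
  inside <- !is.na(iv[, 1])
  if (margin > 0) {
    for (dd in list(c(margin, 0), c(-margin, 0), c(0, margin), c(0, -margin))) {
      iv2 <- target_depth_interval(target, centers$x + dd[1],
                                   centers$y + dd[2])
      grow <- !is.na(iv2[, 1]) & !inside
      inside <- inside | !is.na(iv2[, 1])
      iv[grow, ] <- iv2[grow, ]
    }
  }
  centers <- centers[inside, , drop = FALSE]
  iv <- iv[inside, , drop = FALSE]

  q <- interval_quantum
  prox_q <- pmax(round(iv[, 1] / q) * q, 1)
  dist_q <- pmin(round(iv[, 2] / q) * q, available)
  dist_q <- pmax(dist_q, prox_q + 0.5)

  cache <- new.env(parent = emptyenv())
  contours <- vector("list", nrow(centers))
  offsets <- numeric(nrow(centers))
  raw_sums <- numeric(nrow(centers))
  for (i in seq_len(nrow(centers))) {
    key <- sprintf("%.3f_%.3f", prox_q[i], dist_q[i])
    ent <- cache[[key]]
    if (is.null(ent)) {
      w <- optimize_sobp_weights(curve, prox_q[i], dist_q[i],
                                 wet_step = wet_step)
      ent <- list(contour = weights_to_step_contour(w, base_period = period,
                                                    material = material),
                  raw_sum = attr(w, "raw_sum"))
      cache[[key]] <- ent
    }
    contours[[i]] <- ent$contour
    raw_sums[i] <- ent$raw_sum
    offsets[i] <- available - dist_q[i]
    if (offsets[i] < -1e-6)
      stop(sprintf("pin at (%g, %g): distal depth %.1f mm unreachable",
                   centers$x[i], centers$y[i], dist_q[i]), call. = FALSE)
  }

  pins <- data.frame(x = centers$x, y = centers$y,
                     proximal = iv[, 1], distal = iv[, 2],
                     proximal_q = prox_q, distal_q = dist_q,
                     offset_wet = pmax(offsets, 0), raw_sum = raw_sums)
  pins$contour <- contours
  hmax <- max(offsets / rsp +
                vapply(contours, function(p) max(p$levels$height), 0))
  wall <- list(thickness = period, height = hmax)
  mod <- modulator(pins, period = period, base_layer = base_layer,
                   material = material, wall = wall,
                   z_base = scene$mod_plane_z)
  list(modulator = mod, target = target, available_range = available)
}

#' Build a uniform (2D) range-modulator
#'
#' All pins identical, optimized for a flat SOBP of length `sobp_length`
#' ending at the deepest reachable depth behind the absorber and base layer.
#'
#' @param curve pristine [bragg_curve()].
#' @param scene an [scene_config()].
#' @param sobp_length SOBP modulation length in mm of water (default 100).
#' @param kind `"step"` or `"stepless"` pin contour.
#' @param n_pins pins per side of the square pin field.
#' @param wet_step WET layer spacing in mm.
#' @param period pin cell size in mm.
#' @param base_layer base layer thickness in mm.
#' @param material modulator material.
#' @param wall add protective side walls?
#' @return list with `modulator`, `weights`, `proximal`, `distal`.
#' @export
build_2drm <- function(curve, scene, sobp_length = 100,
                       kind = c("step", "stepless"), n_pins = 10,
                       wet_step = 3, period = 3, base_layer = 8,
                       material = rm_materials("rigur"), wall = FALSE) {
  kind <- match.arg(kind)
  rsp <- material$relative_stopping_power
  distal <- curve$range_80 - scene$absorber_wet - base_layer * rsp
  proximal <- distal - sobp_length
  if (proximal <= 0) stop("SOBP longer than the reachable range",
                          call. = FALSE)
  w <- optimize_sobp_weights(curve, proximal, distal, wet_step = wet_step)
  pin <- if (kind == "step")
    weights_to_step_contour(w, base_period = period, material = material)
  else step_to_stepless(w, base_period = period, material = material)

  ks <- seq_len(n_pins) - (n_pins + 1) / 2
  centers <- expand.grid(x = ks * period, y = ks * period)
  pins <- data.frame(x = centers$x, y = centers$y, offset_wet = 0,
                     raw_sum = attr(w, "raw_sum"))
  pins$contour <- rep(list(pin), nrow(pins))
  wl <- if (wall) {
    hmax <- if (kind == "step") max(pin$levels$height)
            else max(pin$profile$height)
    list(thickness = period, height = hmax)
  } else NULL
  mod <- modulator(pins, period = period, base_layer = base_layer,
                   material = material, wall = wl,
                   z_base = scene$mod_plane_z)
  list(modulator = mod, weights = w, proximal = proximal, distal = distal)
}

#' Raster plan for a cube modulator
#'
#' Heuristic monitor units: the per-spot MU is the average, over sample
#' points in the spot's cell, of the unnormalized per-pin weight total of
#' the pin covering the point (zero outside the pin field).  This delivers
#' an approximately flat lateral plateau dose inside the silhouette.
#'
#' @param mod an `rm3d_modulator` built by [build_cube_modulator()].
#' @param spacing scan spot spacing in mm.
#' @param energy beam energy in MeV.
#' @return an `rm3d_plan`.
#' @export
cube_plan <- function(mod, spacing = 5, energy = 250) {
  fp <- modulator_footprint(mod)
  kx <- seq(floor(fp$x[1] / spacing), ceiling(fp$x[2] / spacing))
  ky <- seq(floor(fp$y[1] / spacing), ceiling(fp$y[2] / spacing))
  spots <- expand.grid(x = kx * spacing, y = ky * spacing)
  half <- spacing / 2 - 0.5
  probe <- expand.grid(px = seq(-half, half, by = 1),
                       py = seq(-half, half, by = 1))
  ox <- min(mod$pins$x); oy <- min(mod$pins$y)
  stack <- function(x, y) {
    i <- match(paste(round((x - ox) / mod$period),
                     round((y - oy) / mod$period)),
               paste(round((mod$pins$x - ox) / mod$period),
                     round((mod$pins$y - oy) / mod$period)))
    out <- mod$pins$raw_sum[i]
    out[is.na(out)] <- 0
    out
  }
  mu <- vapply(seq_len(nrow(spots)), function(s)
    mean(stack(spots$x[s] + probe$px, spots$y[s] + probe$py)), 0)
  keep <- mu > 0
  sp <- data.frame(x = spots$x[keep], y = spots$y[keep], mu = mu[keep])
  sp <- sp[order(sp$y, sp$x), ]
  new_plan(sp, energy = energy,
           field = c(diff(range(sp$x)), diff(range(sp$y))),
           spacing = spacing)
}

#' Analytic heightfield of an untransformed modulator
#'
#' Physical material column length along +z per lateral sample: base layer
#' plus the local pin height (modulation plus compensator offset) plus the
#' side walls.  Sample points are offset half a sample from cell
#' boundaries.
#'
#' @param mod an `rm3d_modulator`.
#' @param lateral_resolution sample spacing in mm.
#' @param pad extra margin around the footprint in mm.
#' @return list of class `rm3d_heightfield`: `x`, `y` (sample centers),
#'   `H` (matrix, mm of material), `resolution`.
#' @export
modulator_heightfield <- function(mod, lateral_resolution = 0.25, pad = NULL) {
  wallt <- if (is.null(mod$wall)) 0 else mod$wall$thickness
  if (is.null(pad)) pad <- wallt + lateral_resolution
  fp <- modulator_footprint(mod)
  res <- lateral_resolution
  x <- seq(fp$x[1] - pad + res / 2, fp$x[2] + pad - res / 2, by = res)
  y <- seq(fp$y[1] - pad + res / 2, fp$y[2] + pad - res / 2, by = res)
  H <- matrix(0, length(x), length(y))
  rsp <- mod$material$relative_stopping_power

  # index pin cells relative to the pin-grid origin (pin centers may sit on
  # half-period offsets of the lab frame)
  ox <- min(mod$pins$x); oy <- min(mod$pins$y)
  key_all <- paste(round((mod$pins$x - ox) / mod$period),
                   round((mod$pins$y - oy) / mod$period))
  gx <- round((rep(x, length(y)) - ox) / mod$period)
  gy <- round((rep(y, each = length(x)) - oy) / mod$period)
  pin_idx <- match(paste(gx, gy), key_all)
  ux <- rep(x, length(y)) - (ox + gx * mod$period)
  uy <- rep(y, each = length(x)) - (oy + gy * mod$period)

  hs <- numeric(length(pin_idx))
  for (i in unique(pin_idx[!is.na(pin_idx)])) {
    sel <- which(!is.na(pin_idx) & pin_idx == i)
    hs[sel] <- pin_height_at(mod$pins$contour[[i]], ux[sel], uy[sel]) +
      mod$pins$offset_wet[i] / rsp
  }
  H[] <- hs
  inside_fp <- outer(x >= fp$x[1] & x <= fp$x[2],
                     y >= fp$y[1] & y <= fp$y[2], "&")
  H[inside_fp] <- H[inside_fp] + mod$base_layer
  if (!is.null(mod$wall)) {
    wx <- x >= fp$x[1] - wallt & x <= fp$x[2] + wallt
    wy <- y >= fp$y[1] - wallt & y <= fp$y[2] + wallt
    in_wall <- outer(wx, wy, "&") & !inside_fp
    H[in_wall] <- mod$base_layer + mod$wall$height
  }
  structure(list(x = x, y = y, H = H, resolution = res),
            class = "rm3d_heightfield")
}

#' Bilinear lookup in a heightfield
#'
#' Positions outside the sampled area return 0 (no material).
#'
#' @param hf an `rm3d_heightfield`.
#' @param x,y query positions in mm (vectors).
#' @return material column lengths in mm.
#' @export
heightfield_lookup <- function(hf, x, y) {
  nx <- length(hf$x); ny <- length(hf$y)
  fx <- (x - hf$x[1]) / hf$resolution
  fy <- (y - hf$y[1]) / hf$resolution
  i0 <- floor(fx); j0 <- floor(fy)
  tx <- fx - i0; ty <- fy - j0
  out <- numeric(length(x))
  ok <- i0 >= 0 & i0 <= nx - 2 & j0 >= 0 & j0 <= ny - 2
  if (any(ok)) {
    i <- i0[ok] + 1L; j <- j0[ok] + 1L
    txo <- tx[ok]; tyo <- ty[ok]
    H <- hf$H
    out[ok] <-
      H[cbind(i, j)] * (1 - txo) * (1 - tyo) +
      H[cbind(i + 1L, j)] * txo * (1 - tyo) +
      H[cbind(i, j + 1L)] * (1 - txo) * tyo +
      H[cbind(i + 1L, j + 1L)] * txo * tyo
  }
  out
}
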