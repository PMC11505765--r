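# Scanned-beam source geometry and lateral beam widths for a
# ProBeam-like beamline: two-point magnetic deflection (Y magnet upstream of
# the X magnet), a Gaussian source spot, Gaussian angular divergence, and
# Highland multiple-Coulomb-scattering growth in traversed material.

#' Beamline description
#'
#' Defaults describe a 250 MeV scanned proton beamline with the X scanning
#' magnet 200 cm and the Y magnet 256 cm upstream of the isocenter, a 3 mm
#' FWHM source spot at the Y-magnet plane and 1 mrad Gaussian angular
#' divergence, zero momentum spread.  All positions in mm, isocenter at
#' z = 0, beam travels towards +z.
#'
#' @param energy kinetic energy in MeV.
#' @param momentum_spread relative momentum spread (0 here; range straggling
#'   of the monoenergetic beam is modelled inside [bragg_curve()]).
#' @param source_plane_z z of the source plane (mm, negative).
#' @param x_magnet_z,y_magnet_z z of the deflection points (mm, negative).
#' @param initial_fwhm source spot FWHM in mm.
#' @param divergence_sigma Gaussian angular divergence sigma in mrad.
#' @return object of class `rm3d_beamline`.
#' @export
beamline <- function(energy = 250, momentum_spread = 0,
                     source_plane_z = -2560, x_magnet_z = -2000,
                     y_magnet_z = -2560, initial_fwhm = 3,
                     divergence_sigma = 1) {
  if (!(source_plane_z <= y_magnet_z && y_magnet_z <= x_magnet_z &&
        x_magnet_z < 0))
    stop("require source_plane_z <= y_magnet_z <= x_magnet_z < 0",
         call. = FALSE)
  if (initial_fwhm <= 0) stop("initial_fwhm must be > 0", call. = FALSE)
  structure(list(energy = energy, momentum_spread = momentum_spread,
                 source_plane_z = source_plane_z, x_magnet_z = x_magnet_z,
                 y_magnet_z = y_magnet_z, initial_fwhm = initial_fwhm,
                 divergence_sigma = divergence_sigma),
            class = "rm3d_beamline")
}

#' Read a beamline from a flat key-value config file
#'
#' YAML file whose keys are exactly the arguments of [beamline()].
#' @param path config file path.
#' @return `rm3d_beamline`.
#' @export
beamline_from_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(beamline, cfg)
}

#' A scan spot
#'
#' @param x,y lateral position at the isocenter plane (mm).
#' @param mu monitor units (>= 0).
#' @return one-row data.frame with columns `x`, `y`, `mu`.
#' @export
scan_spot <- function(x, y, mu = 1) {
  if (any(mu < 0)) stop("mu must be >= 0", call. = FALSE)
  data.frame(x = x, y = y, mu = mu)
}

#' Central trajectory of a scan spot
#'
#' The spot is deflected in Y at `y_magnet_z` and in X at `x_magnet_z` such
#' that the trajectory passes through (x, y) at the isocenter plane z = 0.
#' The two kick angles are the unique solution of this two-point geometry.
#'
#' @param spot a [scan_spot()] row (or list with `x`, `y`).
#' @param bl an [beamline()] object.
#' @return list with `kick_x`, `kick_y` (radians), `direction` (unit vector
#'   after both kicks) and `vertices` (4 x 3 matrix of the piecewise-linear
#'   trajectory: source, Y kick, X kick, isocenter).
#' @export
spot_direction <- function(spot, bl) {
  stopifnot(inherits(bl, "rm3d_beamline"))
  kx <- atan(spot$x / -bl$x_magnet_z)
  ky <- atan(spot$y / -bl$y_magnet_z)
  d <- c(spot$x / -bl$x_magnet_z, spot$y / -bl$y_magnet_z, 1)
  d <- d / sqrt(sum(d^2))
  y_at_xmag <- spot$y * (bl$x_magnet_z - bl$y_magnet_z) / -bl$y_magnet_z
  vertices <- rbind(
    c(0, 0, bl$source_plane_z),
    c(0, 0, bl$y_magnet_z),
    c(0, y_at_xmag, bl$x_magnet_z),
    c(spot$x, spot$y, 0))
  list(kick_x = kx, kick_y = ky, direction = d, vertices = vertices)
}

#' Lateral position of spot centers at a given plane
#'
#' Vectorized over spots.  Valid for planes downstream of both magnets.
#'
#' @param x,y spot coordinates at the isocenter plane (mm).
#' @param bl an [beamline()] object.
#' @param z plane position in mm (z >= x_magnet_z).
#' @return matrix with columns `x`, `y`.
#' @export
spot_position_at <- function(x, y, bl, z) {
  stopifnot(all(z >= bl$x_magnet_z))
  cbind(x = x * (z - bl$x_magnet_z) / -bl$x_magnet_z,
        y = y * (z - bl$y_magnet_z) / -bl$y_magnet_z)
}

# momentum x velocity (MeV) for a proton of kinetic energy E (MeV)
pv_of_energy <- function(energy) {
  mp <- 938.272
  pc2 <- energy^2 + 2 * energy * mp
  pc2 / (energy + mp)
}

#' Highland multiple-scattering angle
#'
#' theta0 = 14.1 MeV / pv * sqrt(x/X0) * (1 + 1/9 log10(x/X0)).
#'
#' @param thickness physical path length in the material (mm).
#' @param radiation_length radiation length of the material (mm).
#' @param energy proton kinetic energy in MeV at which pv is evaluated.
#' @return scattering angle sigma in radians (0 for zero thickness).
#' @export
highland_theta0 <- function(thickness, radiation_length, energy) {
  t <- thickness / radiation_length
  th <- ifelse(t > 0,
               14.1 / pv_of_energy(energy) * sqrt(t) *
                 (1 + log10(pmax(t, 1e-12)) / 9),
               0)
  pmax(th, 0)
}

#' Lateral beam sigma at depth
#'
#' Combines, in quadrature: the Gaussian source size (FWHM/2.355), the
#' free-drift growth of the angular divergence over the source-to-point
#' distance, Highland scattering in the upstream absorber (with the full
#' lever-arm integral for scattering distributed along the slab followed by
#' a drift), and Highland scattering in the water already traversed.  The
#' upstream absorber is taken as PMMA whose downstream face sits `air_gap`
#' mm before the phantom surface; `upstream_wet` is its water-equivalent
#' thickness.  Monotone non-decreasing in both `depth_in_water` and
#' `upstream_wet`.
#'
#' @param depth_in_water depth of the point below the phantom surface (mm).
#' @param upstream_wet water-equivalent thickness of upstream material (mm).
#' @param bl an [beamline()] object.
#' @param air_gap air gap between absorber exit and phantom surface (mm).
#' @param drift total source-to-point distance in mm, or `NULL` for the
#'   default geometry (phantom surface at the isocenter).
#' @param absorber absorber material (default PMMA).
#' @return sigma in mm (vectorized over `depth_in_water`).
#' @export
lateral_sigma <- function(depth_in_water, upstream_wet, bl = beamline(),
                          air_gap = 50, drift = NULL,
                          absorber = rm_materials("pmma")) {
  stopifnot(all(depth_in_water >= 0), all(upstream_wet >= 0))
  sig0 <- bl$initial_fwhm / (2 * sqrt(2 * log(2)))
  if (is.null(drift)) drift <- -bl$source_plane_z + depth_in_water
  sig_div <- (bl$divergence_sigma / 1000) * drift

  R0 <- bragg_kleeman_range(bl$energy)
  x_abs <- upstream_wet / absorber$relative_stopping_power
  e_mid_abs <- energy_from_range(pmax(R0 - upstream_wet / 2, 1))
  th_abs <- highland_theta0(x_abs, absorber$radiation_length, e_mid_abs)
  lever_abs <- air_gap + depth_in_water
  var_abs <- th_abs^2 * (x_abs^2 / 3 + x_abs * lever_abs + lever_abs^2)

  water <- rm_materials("water")
  e_mid_w <- energy_from_range(pmax(R0 - upstream_wet - depth_in_water / 2, 1))
  th_w <- highland_theta0(depth_in_water, water$radiation_length, e_mid_w)
  var_w <- th_w^2 * depth_in_water^2 / 3

  sqrt(sig0^2 + sig_div^2 + var_abs + var_w)
}
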