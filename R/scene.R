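# Scene geometry: phantom, pre-absorber and modulator placement along the
# beam axis (mm, isocenter at z = 0, beam towards +z).
#
# Two study variants are built in:
#  * "reference": 170 mm PMMA absorber, 50 mm air gap to the water phantom,
#    phantom entrance at the isocenter, modulator 5 mm upstream of the
#    absorber.  This is the geometry used for all modulator runs.
#  * "baseline":  200 mm PMMA, 50 mm air gap, isocenter 90 mm inside the
#    phantom (phantom entrance at z = -90), no modulator.

#' Scene configuration
#'
#' @param variant `"reference"` or `"baseline"` preset, or `"custom"`.
#' @param absorber_thickness physical PMMA thickness in mm.
#' @param air_gap absorber exit to phantom entrance air gap in mm.
#' @param mod_gap modulator exit to absorber entrance gap in mm.
#' @param phantom_entrance_z phantom entrance position in mm.
#' @param absorber absorber material.
#' @param grid_lateral_extent half-extent of the lateral scoring grid in mm.
#' @param grid_lateral_spacing lateral voxel size in mm.
#' @param grid_depth_extent scored depth range in mm below the surface.
#' @param grid_depth_spacing depth voxel size in mm.
#' @param fluence_attenuation optional linear fluence attenuation per mm of
#'   WET (nuclear-interaction stand-in, default 0 = off).
#' @return object of class `rm3d_scene` with derived positions:
#'   `absorber_z` (entrance face), `mod_plane_z` (modulator downstream
#'   face), `absorber_wet`.
#' @export
scene_config <- function(variant = c("reference", "baseline", "custom"),
                         absorber_thickness = NULL, air_gap = 50,
                         mod_gap = 5, phantom_entrance_z = NULL,
                         absorber = rm_materials("pmma"),
                         grid_lateral_extent = 62.5,
                         grid_lateral_spacing = 2.5,
                         grid_depth_extent = 220,
                         grid_depth_spacing = 1,
                         fluence_attenuation = 0) {
  variant <- match.arg(variant)
  if (is.null(absorber_thickness))
    absorber_thickness <- switch(variant, reference = 170, baseline = 200,
                                 custom = 170)
  if (is.null(phantom_entrance_z))
    phantom_entrance_z <- switch(variant, reference = 0, baseline = -90,
                                 custom = 0)
  absorber_exit_z <- phantom_entrance_z - air_gap
  absorber_z <- absorber_exit_z - absorber_thickness
  structure(list(
    variant = variant,
    absorber_thickness = absorber_thickness,
    air_gap = air_gap, mod_gap = mod_gap,
    phantom_entrance_z = phantom_entrance_z,
    absorber = absorber,
    absorber_z = absorber_z,
    absorber_exit_z = absorber_exit_z,
    absorber_wet = wet_of_slab(absorber, absorber_thickness),
    mod_plane_z = absorber_z - mod_gap,
    grid_lateral_extent = grid_lateral_extent,
    grid_lateral_spacing = grid_lateral_spacing,
    grid_depth_extent = grid_depth_extent,
    grid_depth_spacing = grid_depth_spacing,
    fluence_attenuation = fluence_attenuation),
    class = "rm3d_scene")
}

#' @export
print.rm3d_scene <- function(x, ...) {
  cat(sprintf(
    "<scene '%s': %g mm %s @ z=%g, air gap %g mm, phantom @ z=%g, mod plane z=%g>\n",
    x$variant, x$absorber_thickness, x$absorber$name, x$absorber_z,
    x$air_gap, x$phantom_entrance_z, x$mod_plane_z))
  invisible(x)
}

#' Scene JSON I/O
#' @param scene an `rm3d_scene`.
#' @param path file path.
#' @rdname scene_io
#' @export
write_scene_json <- function(scene, path) {
  obj <- scene[c("variant", "absorber_thickness", "air_gap", "mod_gap",
                 "phantom_entrance_z", "grid_lateral_extent",
                 "grid_lateral_spacing", "grid_depth_extent",
                 "grid_depth_spacing", "fluence_attenuation")]
  obj$absorber <- scene$absorber$name
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname scene_io
#' @export
read_scene_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  scene_config(variant = obj$variant,
               absorber_thickness = obj$absorber_thickness,
               air_gap = obj$air_gap, mod_gap = obj$mod_gap,
               phantom_entrance_z = obj$phantom_entrance_z,
               absorber = rm_materials(obj$absorber),
               grid_lateral_extent = obj$grid_lateral_extent,
               grid_lateral_spacing = obj$grid_lateral_spacing,
               grid_depth_extent = obj$grid_depth_extent,
               grid_depth_spacing = obj$grid_depth_spacing,
               fluence_attenuation = obj$fluence_attenuation)
}
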