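#' Beamline materials
#'
#' A material is described by its mass density, its relative stopping power
#' (RSP, also called the water-equivalent ratio) and, for multiple-scattering
#' calculations, its radiation length.  Water is the reference medium
#' (RSP = 1).  The mean excitation energy is carried as metadata only: the
#' depth-dose model is calibrated directly against the Bragg-Kleeman range
#' power law in water, which subsumes the I-value.
#'
#' @param name material name.
#' @param density mass density in g/cm^3 (must be > 0).
#' @param relative_stopping_power stopping power relative to water (> 0).
#' @param radiation_length radiation length in mm of physical path.
#' @param excitation_energy mean excitation energy in eV (metadata).
#' @return An object of class `rm3d_material`.
#' @examples
#' pmma <- material("pmma", density = 1.19, relative_stopping_power = 1.16,
#'                  radiation_length = 340.7)
#' wet_of_slab(pmma, 200)  # 232 mm water-equivalent
#' @export
material <- function(name, density, relative_stopping_power,
                     radiation_length = NA_real_,
                     excitation_energy = NA_real_) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.finite(density) || density <= 0)
    stop("material density must be > 0", call. = FALSE)
  if (!is.finite(relative_stopping_power) || relative_stopping_power <= 0)
    stop("relative_stopping_power must be > 0", call. = FALSE)
  structure(
    list(name = name, density = density,
         relative_stopping_power = relative_stopping_power,
         radiation_length = radiation_length,
         excitation_energy = excitation_energy),
    class = "rm3d_material")
}

#' @export
print.rm3d_material <- function(x, ...) {
  cat(sprintf("<material %s: density %.3f g/cm^3, RSP %.4f, X0 %.1f mm>\n",
              x$name, x$density, x$relative_stopping_power,
              x$radiation_length))
  invisible(x)
}

#' Built-in material table
#'
#' Water is the dose-scoring reference (I = 78 eV is recorded as the water
#' calibration label).  The printable polymer used for modulators
#' ("rigur", density 1.2 g/cm^3) has no published RSP; the default of 1.165
#' is a PMMA-like value and is configurable through [material()].
#'
#' @param name one of `"water"`, `"pmma"`, `"rigur"`, `"air"`, or `NULL` to
#'   return the whole table as a named list.
#' @return An `rm3d_material`, or a named list of them.
#' @export
rm_materials <- function(name = NULL) {
  tab <- list(
    water = material("water", 1.000, 1.000, radiation_length = 360.8,
                     excitation_energy = 78),
    pmma  = material("pmma",  1.190, 1.160, radiation_length = 340.7),
    rigur = material("rigur", 1.200, 1.165, radiation_length = 337.0),
    air   = material("air", 1.205e-3, 1.064e-3, radiation_length = 3.039e5))
  if (is.null(name)) return(tab)
  m <- tab[[tolower(name)]]
  if (is.null(m)) stop("unknown material: ", name, call. = FALSE)
  m
}

#' Water-equivalent thickness of a slab
#'
#' WET = physical thickness x relative stopping power.  A slab of WET t pulls
#' a Bragg curve back (towards the surface) by exactly t mm of water.
#'
#' @param material an [material()] object.
#' @param physical_thickness slab thickness in mm (>= 0).
#' @return water-equivalent thickness in mm.
#' @export
wet_of_slab <- function(material, physical_thickness) {
  stopifnot(inherits(material, "rm3d_material"))
  if (any(physical_thickness < 0))
    stop("physical_thickness must be >= 0", call. = FALSE)
  physical_thickness * material$relative_stopping_power
}

#' Read materials from a flat key-value config file
#'
#' The file is YAML with one block per material; keys are exactly the fields
#' of [material()]: `density`, `relative_stopping_power`,
#' `radiation_length`, `excitation_energy`.
#'
#' @param path config file path.
#' @return named list of `rm3d_material`.
#' @export
materials_from_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- lapply(names(cfg), function(nm) {
    m <- cfg[[nm]]
    material(nm, density = m$density,
             relative_stopping_power = m$relative_stopping_power,
             radiation_length = m$radiation_length %||% NA_real_,
             excitation_energy = m$excitation_energy %||% NA_real_)
  })
  names(out) <- names(cfg)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
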