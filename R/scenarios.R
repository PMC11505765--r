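# Scenario layer: builds the study fixtures (reference cube modulator,
# uniform 2D modulators), runs misalignment scenarios against the cached
# reference dose, and the step-vs-stepless tilt sweep.
#
# All scenario transforms are applied to the tessellated mesh and
# re-rasterized by ray casting (mirroring an STL-transform workflow); the
# reference dose itself is computed through the identical mesh path with an
# identity transform, so mesh discretization effects cancel in every
# comparison.

#' Run profiles
#'
#' `"desk"` is the default reduced-resolution profile (coarser sub-ray
#' lattice and ray casting); `"full"` the fine-sampling profile.
#'
#' @param profile profile name.
#' @return an [sampling_config()].
#' @export
run_profile <- function(profile = c("desk", "full")) {
  profile <- match.arg(profile)
  switch(profile,
         desk = sampling_config(cell_size = 0.5, subsamples = 15,
                                wet_quant = 0.25),
         full = sampling_config(cell_size = 0.5, subsamples = 30,
                                wet_quant = 0.25))
}

#' Misalignment scenario
#'
#' @param name scenario name.
#' @param field_shift lateral shift of every scan spot in mm, length 2.
#' @param rm_transform an [rigid_transform()] applied to the modulator
#'   mesh, or `NULL`.  For rotations whose pivot is specified relative to
#'   the modulator isocenter, give `pivot_relative = c(x, y, z)` instead of
#'   an absolute pivot (resolved against the footprint center at the
#'   pin-base plane at run time).
#' @param pivot_relative optional pivot offset from the modulator
#'   isocenter in mm (used with `rotation`/`axis`).
#' @param rotation,axis rotation in degrees about the named axis (used
#'   with `pivot_relative`).
#' @param geometry_variant scene preset name.
#' @return object of class `rm3d_scenario`.
#' @export
scenario <- function(name, field_shift = c(0, 0), rm_transform = NULL,
                     pivot_relative = NULL, rotation = 0, axis = "y",
                     geometry_variant = "reference") {
  structure(list(name = name, field_shift = field_shift,
                 rm_transform = rm_transform,
                 pivot_relative = pivot_relative, rotation = rotation,
                 axis = axis, geometry_variant = geometry_variant),
            class = "rm3d_scenario")
}

#' The five misalignment scenarios of the robustness study
#'
#' Treatment field shifted +1 mm in X; modulator shifted +1.5 mm in X;
#' modulator shifted +1.5 mm in X and Y; modulator rotated 0.5 deg about Y;
#' modulator rotated 1.5 deg about Y.  The rotation pivot sits 200 mm
#' upstream-left in X and 180 mm upstream in Z of the modulator isocenter
#' (the mechanical mounting point).
#'
#' @return named list of [scenario()] objects.
#' @export
study_scenarios <- function() {
  piv <- c(-200, 0, -180)
  list(
    field_x_1mm = scenario("field +1 mm X", field_shift = c(1, 0)),
    rm_x_1p5mm = scenario(
      "RM +1.5 mm X",
      rm_transform = rigid_transform(translation = c(1.5, 0, 0))),
    rm_xy_1p5mm = scenario(
      "RM +1.5 mm X/Y",
      rm_transform = rigid_transform(translation = c(1.5, 1.5, 0))),
    rot_y_0p5deg = scenario("RM 0.5 deg Y", pivot_relative = piv,
                            rotation = 0.5, axis = "y"),
    rot_y_1p5deg = scenario("RM 1.5 deg Y", pivot_relative = piv,
                            rotation = 1.5, axis = "y"))
}

# modulator isocenter: footprint center at the pin-base plane
modulator_isocenter <- function(mod) {
  fp <- modulator_footprint(mod)
  c(mean(fp$x), mean(fp$y), mod$z_base - mod$base_layer)
}

#' Build (and cache) the rotated-cube study fixture
#'
#' Reference scene, 250 MeV curve, cube target, target-conformal modulator,
#' raster plan and tessellated mesh.
#'
#' @param profile run profile name (see [run_profile()]).
#' @return list with `scene`, `curve`, `target`, `modulator`, `plan`,
#'   `mesh`, `beamline`, `sampling`, `available_range`.
#' @export
cube_fixture <- function(profile = "desk") {
  key <- paste0("cube_fixture_", profile)
  if (!is.null(.rm3d_cache[[key]])) return(.rm3d_cache[[key]])
  sampling <- run_profile(profile)
  bl <- beamline()
  scene <- scene_config("reference")
  curve <- bragg_curve(bl$energy, depth_step = 0.5)
  built <- build_cube_modulator(cube_target(), scene, curve)
  mesh <- tessellate(built$modulator)
  plan <- cube_plan(built$modulator)
  fx <- list(scene = scene, curve = curve, target = built$target,
             modulator = built$modulator, plan = plan, mesh = mesh,
             beamline = bl, sampling = sampling,
             available_range = built$available_range)
  .rm3d_cache[[key]] <- fx
  fx
}

#' Reference dose of the nominal cube-modulator setup
#'
#' Deterministic and cached per profile; computed through the mesh ray-cast
#' path with an identity transform.
#'
#' @param profile run profile name.
#' @return an `rm3d_dose`.
#' @export
run_reference <- function(profile = "desk") {
  key <- paste0("reference_dose_", profile)
  if (!is.null(.rm3d_cache[[key]])) return(.rm3d_cache[[key]])
  fx <- cube_fixture(profile)
  d <- compute_dose(fx$plan, fx$scene, mod_mesh = fx$mesh,
                    bl = fx$beamline, sampling = fx$sampling)
  .rm3d_cache[[key]] <- d
  d
}

# lateral displacement of the distal 80% isodose surface along one axis:
# depth map of the distal crossing of 80% of the per-column plateau dose,
# matched between reference and evaluated by a 1D shift search
distal_surface_shift <- function(reference, evaluated, axis = 1,
                                 level = 0.8) {
  z80_map <- function(d) {
    nx <- length(d$x); ny <- length(d$y)
    m <- matrix(NA_real_, nx, ny)
    gmax <- max(d$values)
    for (i in seq_len(nx)) for (j in seq_len(ny)) {
      col <- d$values[i, j, ]
      cmax <- max(col)
      if (cmax < 0.5 * gmax) next
      lev <- level * cmax
      k <- which(col >= lev)
      if (!length(k)) next
      k <- max(k)
      if (k >= length(col)) { m[i, j] <- d$z[k]; next }
      m[i, j] <- stats::approx(col[c(k, k + 1)], d$z[c(k, k + 1)],
                               xout = lev)$y
    }
    m
  }
  mr <- z80_map(reference)
  me <- z80_map(evaluated)
  if (axis == 2) { mr <- t(mr); me <- t(me) }
  xs <- if (axis == 1) reference$x else reference$y
  dx <- xs[2] - xs[1]
  # local displacement per column: me(x) = mr(x - s) on the sloped flanks
  # of the distal surface, so s = -(me - mr) / (dmr/dx); pool as a median
  # over columns with a well-defined slope
  n <- nrow(mr)
  slope <- (mr[c(2:n, n), ] - mr[c(1, 1:(n - 1)), ]) / (2 * dx)
  slope[c(1, n), ] <- NA
  dzm <- me - mr
  ok <- !is.na(dzm) & !is.na(slope) & abs(slope) > 0.3 & abs(slope) < 5
  if (!any(ok)) return(0)
  stats::median(-dzm[ok] / slope[ok])
}

#' Run one misalignment scenario against the reference dose
#'
#' Applies the field shift to the plan and/or the rigid transform to the
#' modulator mesh, recomputes the dose with otherwise identical settings,
#' and evaluates the 2D gamma index (2%/2 mm, local, 20% threshold) on the
#' proximal (110 mm) and distal (160 mm) slices plus center-line SOBP
#' metrics and the distal-surface displacement.
#'
#' @param s an [scenario()].
#' @param reference reference `rm3d_dose`, or `NULL` to use
#'   [run_reference()].
#' @param profile run profile name.
#' @param depths gamma slice depths in mm.
#' @return object of class `rm3d_scenario_report`.
#' @export
run_scenario <- function(s, reference = NULL, profile = "desk",
                         depths = c(110, 160)) {
  stopifnot(inherits(s, "rm3d_scenario"))
  fx <- cube_fixture(profile)
  if (is.null(reference)) reference <- run_reference(profile)

  plan <- shift_plan(fx$plan, s$field_shift[1], s$field_shift[2])
  mesh <- fx$mesh
  tr <- s$rm_transform
  if (!is.null(s$pivot_relative)) {
    piv <- modulator_isocenter(fx$modulator) + s$pivot_relative
    tr <- rigid_transform(angle = s$rotation, axis = s$axis, pivot = piv)
  }
  if (!is.null(tr)) mesh <- apply_transform(mesh, tr)
  d <- compute_dose(plan, fx$scene, mod_mesh = mesh, bl = fx$beamline,
                    sampling = fx$sampling)

  gs <- gamma_slices(reference, d, depths = depths)
  iv0 <- target_depth_interval(fx$target, 0, 0)
  prof_r <- sobp_profile(reference, c(0, 0))
  prof_e <- sobp_profile(d, c(0, 0))
  # plateau of the widest (center-line) SOBP: from just inside the proximal
  # edge to where the reference rolls below 95% of its plateau level (the
  # distal shoulder of the center line is rounded by lateral mixing with
  # shallower neighboring pins)
  lo <- iv0[1] + 5
  m0 <- stats::median(prof_r$dose[prof_r$z >= lo & prof_r$z <= lo + 40])
  in_pl <- prof_r$z >= lo & prof_r$dose >= 0.95 * m0
  hi <- max(prof_r$z[in_pl])
  met <- sobp_metrics(prof_e, plateau = c(lo, hi), reference = prof_r)
  shift <- distal_surface_shift(reference, d, axis = 1)
  structure(list(scenario = s,
                 proximal_gi = gs[[1]]$passing_rate,
                 distal_gi = gs[[2]]$passing_rate,
                 gamma = gs,
                 center_sobp_max_dev = met$max_deviation,
                 distal_surface_shift = shift,
                 dose = d),
            class = "rm3d_scenario_report")
}

#' @export
print.rm3d_scenario_report <- function(x, ...) {
  cat(sprintf(
    "<scenario '%s': GI proximal %.1f%%, distal %.1f%%, center dev %.2f%%, distal shift %.2f mm>\n",
    x$scenario$name, x$proximal_gi, x$distal_gi, x$center_sobp_max_dev,
    x$distal_surface_shift))
  invisible(x)
}

# compact scene for single-pencil 2D RM studies
pencil_scene <- function() {
  scene_config("reference", grid_lateral_extent = 30,
               grid_lateral_spacing = 1, grid_depth_extent = 200,
               grid_depth_spacing = 1)
}

#' Tilt sweep of the uniform 2D range-modulators
#'
#' Builds the step and stepless 2D modulators for a 10 cm SOBP, simulates
#' a single axial pencil beam through each at every tilt angle (rotation
#' about Y through the modulator isocenter), and extracts the center-line
#' SOBP with its deviation metrics.
#'
#' @param angles tilt angles in degrees.
#' @param kinds pin contour kinds to run.
#' @param sobp_length SOBP length in mm.
#' @param n_pins pins per side of the modulator patch.
#' @param sampling an [sampling_config()]; the default uses a finer
#'   lattice than the scanned-field profiles (single-spot runs are cheap).
#' @return list with `profiles` (per kind, per angle data.frames),
#'   `metrics` (data.frame: kind, angle, flatness, deviation from the 0
#'   degree curve), `mutual` (per-angle max deviation between kinds),
#'   `plateau`.
#' @export
run_tilt_sweep <- function(angles = c(0, 0.5, 1, 2),
                           kinds = c("step", "stepless"),
                           sobp_length = 100, n_pins = 12,
                           sampling = sampling_config(subsamples = 25,
                                                      wet_quant = 0.1)) {
  scene <- pencil_scene()
  bl <- beamline()
  curve <- bragg_curve(bl$energy, depth_step = 0.5)
  plan <- new_plan(data.frame(x = 0, y = 0, mu = 1), energy = bl$energy,
                   field = c(0, 0), spacing = NA)
  profiles <- list(); metrics <- NULL
  plateau <- NULL
  for (kind in kinds) {
    built <- build_2drm(curve, scene, sobp_length = sobp_length,
                        kind = kind, n_pins = n_pins)
    plateau <- c(built$proximal + 5, built$distal - 5)
    mesh <- tessellate(built$modulator,
                       tolerance = sampling$stepless_tolerance)
    iso <- modulator_isocenter(built$modulator)
    profs <- list()
    for (a in angles) {
      m <- if (a == 0) mesh
           else apply_transform(mesh, rigid_transform(angle = a,
                                                      axis = "y",
                                                      pivot = iso))
      d <- compute_dose(plan, scene, mod_mesh = m, bl = bl,
                        sampling = sampling)
      profs[[sprintf("a%g", a)]] <- integrated_depth_dose(d)
    }
    profiles[[kind]] <- profs
    ref0 <- profs[[1]]
    for (i in seq_along(angles)) {
      met <- sobp_metrics(profs[[i]], plateau, reference = ref0)
      metrics <- rbind(metrics,
                       data.frame(kind = kind, angle = angles[i],
                                  flatness = met$flatness,
                                  deviation_from_0 = met$max_deviation))
    }
  }
  mutual <- NULL
  if (length(kinds) == 2) {
    mutual <- vapply(seq_along(angles), function(i) {
      p1 <- profiles[[kinds[1]]][[i]]
      p2 <- profiles[[kinds[2]]][[i]]
      sobp_metrics(p2, plateau, reference = p1)$max_deviation
    }, 0)
    mutual <- data.frame(angle = angles, max_mutual_deviation = mutual)
  }
  list(profiles = profiles, metrics = metrics, mutual = mutual,
       plateau = plateau)
}

# tiny rolling hex digest for provenance records (not cryptographic)
config_digest <- function(x) {
  bytes <- as.integer(serialize(x, NULL))
  h <- 5381
  for (b in bytes) h <- (h * 69069 + b) %% 4294967296
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Write a provenance record next to an output
#'
#' JSON with a config hash, the seed and package version.
#'
#' @param path output JSON path.
#' @param config arbitrary serializable configuration.
#' @param seed RNG seed used (if any).
#' @export
write_provenance <- function(path, config, seed = NA) {
  jsonlite::write_json(
    list(config_hash = config_digest(config), seed = seed,
         package = as.character(utils::packageVersion("rm3d")),
         r_version = R.version.string,
         timestamp = format(Sys.time(), tz = "UTC")),
    path, auto_unbox = TRUE)
  invisible(path)
}

#' Clear cached fixtures and reference doses
#' @export
clear_rm3d_cache <- function() {
  rm(list = ls(.rm3d_cache), envir = .rm3d_cache)
  invisible(NULL)
}
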