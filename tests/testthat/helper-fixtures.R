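# Shared fixtures, memoized so expensive objects are built once per run.
# Everything is generated in code; no data files.

.fix <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fix[[key]])) .fix[[key]] <- force(expr)
  .fix[[key]]
}

ref_curve <- function() memo("curve", bragg_curve(250))

ref_scene <- function() memo("scene", scene_config("reference"))

# small single-pencil scene for 2D-RM work
pencil_scene_small <- function()
  memo("pencil_scene",
       scene_config("reference", grid_lateral_extent = 30,
                    grid_lateral_spacing = 1, grid_depth_extent = 200,
                    grid_depth_spacing = 1))

# a tiny uniform modulator (short SOBP, few pins) for geometry tests
tiny_2drm <- function(kind = "step")
  memo(paste0("tiny2drm_", kind),
       build_2drm(ref_curve(), ref_scene(), sobp_length = 30, kind = kind,
                  n_pins = 4))

# the full 10 cm SOBP 2D modulator used for dose-level checks
full_2drm <- function(kind = "step")
  memo(paste0("full2drm_", kind),
       build_2drm(ref_curve(), pencil_scene_small(), sobp_length = 100,
                  kind = kind, n_pins = 12))

single_spot_plan <- function()
  memo("pencil_plan", {
    p <- scan_spot(0, 0, 1)
    structure(p, energy = 250, field = c(0, 0), spacing = NA,
              class = c("rm3d_plan", "data.frame"))
  })

pencil_sampling <- function() sampling_config(subsamples = 25,
                                              wet_quant = 0.1)

# smooth 2D test field for gamma work: sum of Gaussian blobs
smooth_field_2d <- function(x, y, blobs) {
  v <- matrix(0, length(x), length(y))
  for (b in seq_len(nrow(blobs)))
    v <- v + blobs[b, "a"] *
      outer(exp(-(x - blobs[b, "x0"])^2 / (2 * blobs[b, "s"]^2)),
            exp(-(y - blobs[b, "y0"])^2 / (2 * blobs[b, "s"]^2)))
  v
}

random_blobs <- function(n = 3) {
  cbind(a = runif(n, 0.5, 1), x0 = runif(n, -6, 6), y0 = runif(n, -6, 6),
        s = runif(n, 4, 9))
}
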