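# Raster scan plans: regular grids of scan spots with monitor-unit weights.
# A plan is a data.frame with columns x, y, mu (mm at the isocenter plane,
# MU >= 0) and attributes energy, field, spacing.

new_plan <- function(spots, energy, field, spacing) {
  stopifnot(all(c("x", "y", "mu") %in% names(spots)), all(spots$mu >= 0))
  structure(spots, energy = energy, field = field, spacing = spacing,
            class = c("rm3d_plan", "data.frame"))
}

#' Uniform-MU raster plan
#'
#' Regular spot grid centered on the beam axis with equal monitor units and
#' serpentine (boustrophedon) scan ordering.
#'
#' @param field field size in mm, length-2 vector (x, y).
#' @param spacing scan spot spacing in mm (must divide the field).
#' @param mu monitor units per spot (>= 0).
#' @param energy beam energy in MeV.
#' @return an `rm3d_plan` data.frame in scan order.
#' @export
uniform_field_plan <- function(field = c(80, 80), spacing = 5, mu = 1,
                               energy = 250) {
  if (length(field) == 1) field <- c(field, field)
  n <- field / spacing
  if (any(abs(n - round(n)) > 1e-9))
    stop("spacing must divide the field size", call. = FALSE)
  xs <- seq(-field[1] / 2, field[1] / 2, by = spacing)
  ys <- seq(-field[2] / 2, field[2] / 2, by = spacing)
  rows <- lapply(seq_along(ys), function(j) {
    xr <- if (j %% 2 == 1) xs else rev(xs)       # serpentine path
    data.frame(x = xr, y = ys[j], mu = mu)
  })
  new_plan(do.call(rbind, rows), energy = energy, field = field,
           spacing = spacing)
}

#' Collapse range-shifter layers into a single-energy plan
#'
#' Sums, per scan spot, the monitor units over all range-shifter layers.
#' All layers must share the same spot grid.
#'
#' @param layer_plans list of layers, each a list with elements `wet` (mm)
#'   and `spots` (data.frame with `x`, `y`, `mu`).
#' @param energy beam energy of the collapsed plan.
#' @return an `rm3d_plan` with per-spot MU summed over layers.
#' @export
plan_from_layers <- function(layer_plans, energy = 250) {
  stopifnot(length(layer_plans) >= 1)
  key <- function(s) paste(s$x, s$y, sep = "/")
  ref <- layer_plans[[1]]$spots
  ref <- ref[order(ref$y, ref$x), ]
  mu <- ref$mu
  for (lp in layer_plans[-1]) {
    s <- lp$spots[order(lp$spots$y, lp$spots$x), ]
    if (nrow(s) != nrow(ref) || !identical(key(s), key(ref)))
      stop("layer spot grids do not match", call. = FALSE)
    mu <- mu + s$mu
  }
  sp <- unique(diff(sort(unique(ref$x))))
  new_plan(data.frame(x = ref$x, y = ref$y, mu = mu), energy = energy,
           field = c(diff(range(ref$x)), diff(range(ref$y))),
           spacing = if (length(sp)) sp[1] else NA_real_)
}

#' Shift all scan spots laterally
#' @param plan an `rm3d_plan`.
#' @param dx,dy shift in mm at the isocenter plane.
#' @return shifted plan.
#' @export
shift_plan <- function(plan, dx = 0, dy = 0) {
  plan$x <- plan$x + dx
  plan$y <- plan$y + dy
  plan
}

#' Plan I/O: CSV (x_mm, y_mm, mu) and JSON with header
#' @param plan an `rm3d_plan`.
#' @param path output file.
#' @rdname plan_io
#' @export
write_plan_csv <- function(plan, path) {
  utils::write.csv(data.frame(x_mm = plan$x, y_mm = plan$y, mu = plan$mu),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname plan_io
#' @param energy,field,spacing plan metadata for CSV reading (CSV carries
#'   spots only).
#' @export
read_plan_csv <- function(path, energy = 250, field = NA, spacing = NA) {
  d <- utils::read.csv(path)
  stopifnot(all(c("x_mm", "y_mm", "mu") %in% names(d)))
  new_plan(data.frame(x = d$x_mm, y = d$y_mm, mu = d$mu),
           energy = energy, field = field, spacing = spacing)
}

#' @rdname plan_io
#' @export
write_plan_json <- function(plan, path) {
  jsonlite::write_json(
    list(energy = attr(plan, "energy"), field = attr(plan, "field"),
         spacing = attr(plan, "spacing"),
         spots = data.frame(x = plan$x, y = plan$y, mu = plan$mu)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname plan_io
#' @export
read_plan_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_plan(as.data.frame(obj$spots), energy = obj$energy,
           field = obj$field, spacing = obj$spacing)
}
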