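# Spread-out Bragg peak (SOBP) weight optimization and pin contours.
#
# A flat SOBP on [proximal, distal] is a non-negative superposition of
# range-shifted Bragg curves on a uniform WET grid.  The weights are then
# encoded geometrically into a modulator pin: each WET layer occupies a
# partial area of the pin cell directly proportional to its weight ("step"
# contour), or the cumulative area-vs-WET staircase is interpolated into a
# quasi-continuous "stepless" contour that preserves the modulation
# function.

#' Optimize Bragg-peak weights for a flat SOBP
#'
#' Solves a non-negative least-squares problem for the layer weights of a
#' spread-out Bragg peak that is flat on `[proximal, distal]` (depths in mm
#' of water).  Layer k is the pristine curve pulled back by
#' `(k-1) * wet_step`; the deepest layer (pullback 0) is positioned so that
#' its distal 80% falloff lands exactly at `distal`.  The plateau is sampled
#' every 1 mm and the target dose is 1.
#'
#' @param curve an [bragg_curve()] object.
#' @param proximal,distal plateau limits in mm, `0 < proximal < distal <=
#'   curve$range_80`.
#' @param wet_step WET spacing of the layers in mm (> 0).
#' @return object of class `rm3d_weights`: `pullbacks` (mm WET, increasing
#'   from 0), `weights` (normalized to sum 1), `wet_step`, `proximal`,
#'   `distal`, and attribute `raw_sum` (unnormalized weight total for a
#'   plateau dose of 1).
#' @export
optimize_sobp_weights <- function(curve, proximal, distal, wet_step = 3) {
  stopifnot(inherits(curve, "rm3d_bragg"))
  if (!(wet_step > 0)) stop("wet_step must be > 0", call. = FALSE)
  if (!(proximal > 0 && proximal < distal))
    stop("require 0 < proximal < distal", call. = FALSE)
  if (distal > curve$range_80 + 1e-6)
    stop("distal (", distal, " mm) beyond the curve range_80 (",
         round(curve$range_80, 1), " mm)", call. = FALSE)

  span <- distal - proximal
  if (span < wet_step) {
    w <- structure(list(pullbacks = 0, weights = 1, wet_step = wet_step,
                        proximal = proximal, distal = distal,
                        plateau_distal =
                          distal - (curve$range_80 - curve$peak_depth)),
                   class = "rm3d_weights")
    attr(w, "raw_sum") <- 1
    return(w)
  }
  n <- floor(span / wet_step + 1e-9) + 1L
  pullbacks <- (seq_len(n) - 1L) * wet_step
  shift0 <- curve$range_80 - distal
  # the flat region ends where the deepest pristine peak culminates; the
  # remaining (range_80 - peak_depth) mm are the SOBP's own distal falloff
  plateau_distal <- distal - (curve$range_80 - curve$peak_depth)

  zfit <- seq(proximal - wet_step / 2, plateau_distal, by = 0.5)
  A <- vapply(pullbacks, function(pb)
    bragg_dose_at(curve, zfit + shift0 + pb), numeric(length(zfit)))
  sol <- pracma::lsqnonneg(A, rep(1, length(zfit)))
  wraw <- sol$x
  s <- sum(wraw)
  if (s <= 0) stop("weight optimization failed (all-zero solution)",
                   call. = FALSE)
  out <- structure(list(pullbacks = pullbacks, weights = wraw / s,
                        wet_step = wet_step, proximal = proximal,
                        distal = distal, plateau_distal = plateau_distal),
                   class = "rm3d_weights")
  attr(out, "raw_sum") <- s
  out
}

#' @export
print.rm3d_weights <- function(x, ...) {
  cat(sprintf("<SOBP weights: %d layers, step %.2f mm, plateau [%.1f, %.1f] mm>\n",
              length(x$weights), x$wet_step, x$proximal, x$distal))
  invisible(x)
}

#' Evaluate the SOBP produced by a weight vector
#'
#' Superposes the pulled-back Bragg curves; the deepest layer's distal 80%
#' falloff is placed at `w$distal`.
#'
#' @param w an [optimize_sobp_weights()] object (weights may be normalized
#'   or not; the shape is what matters).
#' @param curve the pristine [bragg_curve()].
#' @param z depths in mm at which to evaluate.
#' @return dose values (same normalization as the weights).
#' @export
sobp_dose_at <- function(w, curve, z) {
  shift0 <- curve$range_80 - w$distal
  d <- numeric(length(z))
  for (k in seq_along(w$weights))
    d <- d + w$weights[k] * bragg_dose_at(curve, z + shift0 + w$pullbacks[k])
  d
}

#' SOBP plateau flatness
#'
#' max |D - mean(D)| / mean(D) over the plateau interior (one `wet_step`
#' excluded at the proximal edge; the distal end of the flat region is
#' where the deepest pristine peak culminates), in percent.
#'
#' @inheritParams sobp_dose_at
#' @param dz sampling step in mm.
#' @return flatness in percent.
#' @export
sobp_flatness <- function(w, curve, dz = 0.5) {
  pd <- w$plateau_distal %||%
    (w$distal - (curve$range_80 - curve$peak_depth))
  lo <- min(w$proximal + w$wet_step, pd)
  z <- seq(lo, pd, by = dz)
  d <- sobp_dose_at(w, curve, z)
  100 * max(abs(d - mean(d))) / mean(d)
}

#' Convert SOBP weights to a step pin contour
#'
#' Each layer k becomes one step whose partial area fraction equals its
#' weight and whose physical height is `pullback_k / RSP(material)`: the
#' WET the pin must remove for that layer, relative to the deepest layer.
#' Zero-weight layers are dropped.  Within the square cell the steps are
#' arranged as concentric square rings, widest (deepest) level outermost
#' and the pin tip at the cell center.
#'
#' @param w an [optimize_sobp_weights()] object.
#' @param base_period lateral pin cell size in mm.
#' @param material pin material (for the WET-to-height conversion).
#' @return object of class `rm3d_pin` with `kind = "step"` and a `levels`
#'   data.frame (`wet`, `height`, `area_fraction`).
#' @export
weights_to_step_contour <- function(w, base_period = 3,
                                    material = rm_materials("rigur")) {
  stopifnot(inherits(w, "rm3d_weights"))
  keep <- w$weights > 0
  rsp <- material$relative_stopping_power
  levels <- data.frame(wet = w$pullbacks[keep],
                       height = w$pullbacks[keep] / rsp,
                       area_fraction = w$weights[keep] / sum(w$weights[keep]))
  structure(list(kind = "step", base_period = base_period,
                 material = material, levels = levels,
                 wet_step = w$wet_step),
            class = "rm3d_pin")
}

#' Convert SOBP weights to a stepless pin contour
#'
#' The cumulative area-vs-WET staircase is replaced by a monotone
#' interpolant through its bin edges: within the WET bin of width
#' `wet_step` centered on layer k (k >= 2) the cumulative area rises
#' linearly by exactly that layer's weight, so re-binning the contour at
#' the original step recovers the weights exactly and every interior
#' layer's mean pullback is preserved.  The deepest layer cannot ramp below
#' zero removable material, so it stays a flat valley floor (an atom at
#' WET 0), exactly as in the step contour; this keeps the distal edge of
#' the SOBP identical between the two pin kinds.
#'
#' @param w an [optimize_sobp_weights()] object.
#' @param grid_resolution WET sampling resolution of the stored profile in
#'   mm; must be much smaller than `wet_step`.
#' @param base_period lateral pin cell size in mm.
#' @param material pin material.
#' @return object of class `rm3d_pin` with `kind = "stepless"`, interpolation
#'   knots (`knot_wet`, `knot_cum`) and a sampled `profile` data.frame
#'   (`cum_area`, `wet`, `height`).
#' @export
step_to_stepless <- function(w, grid_resolution = 0.05, base_period = 3,
                             material = rm_materials("rigur")) {
  stopifnot(inherits(w, "rm3d_weights"))
  if (grid_resolution > w$wet_step / 2)
    stop("grid_resolution must be well below wet_step", call. = FALSE)
  cum <- cumsum(w$weights) / sum(w$weights)
  if (any(diff(c(0, cum)) < -1e-12))
    stop("internal error: non-monotone cumulative weights", call. = FALSE)
  # knots: valley-floor atom at WET 0 carrying the deepest layer's weight,
  # then one linear ramp per bin edge interval
  edges <- w$pullbacks + w$wet_step / 2
  kwet <- c(0, edges)
  kcum <- c(cum[1], cum[1], cum[-1])
  keep <- !duplicated(kwet)
  kwet <- kwet[keep]; kcum <- kcum[keep]

  wet_grid <- seq(0, max(kwet), by = grid_resolution)
  cum_grid <- stats::approx(kwet, kcum, xout = wet_grid, rule = 2)$y
  rsp <- material$relative_stopping_power
  structure(list(kind = "stepless", base_period = base_period,
                 material = material,
                 knot_wet = kwet, knot_cum = kcum,
                 profile = data.frame(cum_area = cum_grid, wet = wet_grid,
                                      height = wet_grid / rsp),
                 wet_step = w$wet_step,
                 pullbacks = w$pullbacks),
            class = "rm3d_pin")
}

#' @export
print.rm3d_pin <- function(x, ...) {
  if (x$kind == "step")
    cat(sprintf("<%s pin: %d levels, period %.1f mm, max height %.2f mm>\n",
                x$kind, nrow(x$levels), x$base_period, max(x$levels$height)))
  else
    cat(sprintf("<%s pin: period %.1f mm, max height %.2f mm>\n",
                x$kind, x$base_period, max(x$profile$height)))
  invisible(x)
}

# cumulative area fraction with WET <= t (the contour's modulation CDF)
pin_cum_area <- function(pin, t) {
  if (pin$kind == "step") {
    lv <- pin$levels
    vapply(t, function(ti) sum(lv$area_fraction[lv$wet <= ti + 1e-12]), 0)
  } else {
    y <- stats::approx(pin$knot_wet, pin$knot_cum, xout = t, rule = 2)$y
    y[t < 0] <- 0
    y
  }
}

#' WET distribution of a pin contour
#'
#' Area-weighted histogram of the WET removed by the pin, binned at the
#' design `wet_step` (bins centered on the layer pullback values).  This is
#' the exact inverse of the two contour constructors: a step pin returns its
#' weights exactly, a stepless pin within the interpolation resolution.
#'
#' @param pin an `rm3d_pin`.
#' @param wet_step bin width in mm; default the pin's design step.
#' @return an `rm3d_weights` object (without plateau metadata).
#' @export
contour_wet_distribution <- function(pin, wet_step = pin$wet_step) {
  tmax <- if (pin$kind == "step") max(pin$levels$wet) else max(pin$knot_wet)
  centers <- seq(0, tmax + wet_step / 2, by = wet_step)
  lo <- centers - wet_step / 2
  hi <- centers + wet_step / 2
  mass <- pin_cum_area(pin, hi) - pin_cum_area(pin, lo)
  keep <- seq_len(max(which(mass > 1e-12)))
  structure(list(pullbacks = centers[keep], weights = mass[keep] / sum(mass),
                 wet_step = wet_step, proximal = NA_real_,
                 distal = NA_real_),
            class = "rm3d_weights")
}

#' Pin height at lateral positions within the cell
#'
#' The pin is a stack of concentric square rings (tip at the cell center):
#' the region removing at least WET t is the central square of area fraction
#' `1 - F(t)` where F is the contour's cumulative WET distribution.  The
#' height at Chebyshev radius r from the cell center follows by inversion.
#'
#' @param pin an `rm3d_pin`.
#' @param dx,dy offsets from the pin cell center in mm (vectors).
#' @return physical heights in mm.
#' @export
pin_height_at <- function(pin, dx, dy) {
  r <- pmax(abs(dx), abs(dy))
  a <- pmin((2 * r / pin$base_period)^2, 1)   # area of square with half-width r
  rsp <- pin$material$relative_stopping_power
  if (pin$kind == "step") {
    lv <- pin$levels[order(-pin$levels$wet), ]
    cum_in <- cumsum(lv$area_fraction)        # area with WET >= lv$wet
    # height at the point: tallest level whose inner square covers radius r
    idx <- findInterval(a, c(0, cum_in), rightmost.closed = TRUE,
                        left.open = TRUE)
    idx <- pmin(pmax(idx, 1L), nrow(lv))
    lv$height[idx]
  } else {
    # wet(r) solves 1 - F(wet) = a; the CDF may hold an atom (repeated
    # cumulative value) at the valley floor, so interpolate the ordered
    # knots without tie collapsing
    f <- stats::approx(pin$knot_cum, pin$knot_wet, xout = 1 - a, rule = 2,
                       ties = "ordered")$y
    f / rsp
  }
}

#' Serialize a pin contour to JSON
#' @param pin an `rm3d_pin`.
#' @param path output file.
#' @export
write_pin_json <- function(pin, path) {
  obj <- list(kind = pin$kind, base_period = pin$base_period,
              material = pin$material$name,
              rsp = pin$material$relative_stopping_power,
              wet_step = pin$wet_step)
  if (pin$kind == "step") obj$levels <- pin$levels
  else { obj$knot_wet <- pin$knot_wet; obj$knot_cum <- pin$knot_cum }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a pin contour from JSON
#' @param path file written by [write_pin_json()].
#' @return an `rm3d_pin`.
#' @export
read_pin_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  mat <- material(obj$material, density = 1.2,
                  relative_stopping_power = obj$rsp)
  if (obj$kind == "step") {
    structure(list(kind = "step", base_period = obj$base_period,
                   material = mat, levels = as.data.frame(obj$levels),
                   wet_step = obj$wet_step), class = "rm3d_pin")
  } else {
    rsp <- obj$rsp
    wet_grid <- seq(0, max(obj$knot_wet), by = 0.05)
    cum_grid <- stats::approx(obj$knot_wet, obj$knot_cum, xout = wet_grid,
                              rule = 2)$y
    structure(list(kind = "stepless", base_period = obj$base_period,
                   material = mat, knot_wet = obj$knot_wet,
                   knot_cum = obj$knot_cum,
                   profile = data.frame(cum_area = cum_grid, wet = wet_grid,
                                        height = wet_grid / rsp),
                   wet_step = obj$wet_step), class = "rm3d_pin")
  }
}

#' Plot a pin cross-section
#'
#' Height versus lateral position through the cell center.
#'
#' @param pin an `rm3d_pin`.
#' @param ... passed to [graphics::plot()].
#' @export
plot_pin_contour <- function(pin, ...) {
  x <- seq(-pin$base_period / 2, pin$base_period / 2, length.out = 601)
  h <- pin_height_at(pin, x, 0)
  graphics::plot(x, h, type = "l", xlab = "lateral position [mm]",
                 ylab = "pin height [mm]",
                 main = sprintf("%s pin contour", pin$kind), ...)
  invisible(NULL)
}
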