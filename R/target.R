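# The rotated-cube target: a cube rotated 45 degrees about both the x and
# the y axis inside the water phantom, one corner pointing towards the
# nozzle.  In beam's eye view it presents a wide range of laterally varying
# SOBP depths and lengths (up to ~85 mm on the central chord), which makes
# it a worst-case study object for modulator misalignment.

rot_mat_deg <- function(axis, deg) {
  th <- deg * pi / 180
  c_ <- cos(th); s_ <- sin(th)
  switch(axis,
         x = matrix(c(1, 0, 0, 0, c_, s_, 0, -s_, c_), 3, 3),
         y = matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3, 3),
         z = matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3),
         stop("axis must be x, y or z", call. = FALSE))
}

#' Rotated-cube target volume
#'
#' @param side cube side length in mm.
#' @param rot_x,rot_y rotation in degrees, applied about x first, then y.
#' @param center_depth depth of the cube center below the phantom surface
#'   (mm); `NULL` lets [build_cube_modulator()] place the distal corner at
#'   the deepest reachable depth.
#' @return object of class `rm3d_cube` with the lab-frame rotation matrix
#'   `R` (columns = cube axes in lab coordinates).
#' @export
cube_target <- function(side = 60, rot_x = 45, rot_y = 45,
                        center_depth = NULL) {
  if (side <= 0) stop("side must be > 0", call. = FALSE)
  R <- rot_mat_deg("y", rot_y) %*% rot_mat_deg("x", rot_x)
  structure(list(side = side, rot_x = rot_x, rot_y = rot_y,
                 center_depth = center_depth, R = R),
            class = "rm3d_cube")
}

#' @export
print.rm3d_cube <- function(x, ...) {
  cat(sprintf("<cube target: side %.0f mm, rotated %g/%g deg, center %s mm>\n",
              x$side, x$rot_x, x$rot_y,
              if (is.null(x$center_depth)) "(unset)"
              else sprintf("%.1f", x$center_depth)))
  invisible(x)
}

# total z-extent of the rotated cube (support function along the beam axis)
cube_z_extent <- function(target) {
  dz <- t(target$R) %*% c(0, 0, 1)
  target$side * sum(abs(dz))
}

#' Entry/exit depths of the axial ray through a lateral point
#'
#' Analytic slab intersection of the axial (+z) ray through
#' `(x, y)` with the rotated cube, in the cube's own frame.  Returns `NA`
#' rows outside the silhouette.
#'
#' @param target an [cube_target()] with resolved `center_depth`.
#' @param x,y lateral coordinates in mm (vectors of equal length).
#' @return matrix with columns `proximal`, `distal` (depths in mm below the
#'   phantom surface), `NA` where the ray misses the cube.
#' @export
target_depth_interval <- function(target, x, y) {
  stopifnot(inherits(target, "rm3d_cube"))
  if (is.null(target$center_depth))
    stop("target center_depth is not set", call. = FALSE)
  Rt <- t(target$R)
  d <- as.numeric(Rt %*% c(0, 0, 1))
  n <- length(x)
  stopifnot(length(y) == n)
  # ray origin (x, y, 0) relative to the cube center, in the cube frame
  ox <- cbind(x, y, -target$center_depth) %*% t(Rt)
  h <- target$side / 2
  tmin <- rep(-Inf, n); tmax <- rep(Inf, n)
  for (i in 1:3) {
    oi <- ox[, i]
    if (abs(d[i]) < 1e-12) {
      miss <- abs(oi) > h
      tmin[miss] <- Inf
    } else {
      t1 <- (-h - oi) / d[i]
      t2 <- (h - oi) / d[i]
      tmin <- pmax(tmin, pmin(t1, t2))
      tmax <- pmin(tmax, pmax(t1, t2))
    }
  }
  hit <- tmax > tmin + 1e-9
  out <- cbind(proximal = ifelse(hit, tmin, NA_real_),
               distal = ifelse(hit, tmax, NA_real_))
  out
}

#' Does the silhouette contain a lateral point?
#' @inheritParams target_depth_interval
#' @return logical vector.
#' @export
cube_silhouette_contains <- function(target, x, y) {
  tg <- target
  if (is.null(tg$center_depth)) tg$center_depth <- 0
  !is.na(target_depth_interval(tg, x, y)[, 1])
}
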