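# WET class fields: the engine's area-integrating view of a modulator.
#
# A class field partitions the modulator plane into square cells (default
# 0.5 mm) and stores, per cell, the exact area fraction occupied by each
# quantized total-WET class (pin modulation + compensator offset + base
# layer + walls, all in water-equivalent mm).  Point sampling cannot
# resolve the thinnest pin rings (down to a few hundredths of a mm), so
# the per-cell fractions are computed analytically for the nominal device
# and by dense scanline rasterization of the mesh for transformed devices.

new_class_field <- function(x, y, spacing, cell, class, frac, q) {
  cellsum <- numeric(length(x) * length(y))
  cs <- rowsum(frac, cell)
  cellsum[as.integer(rownames(cs))] <- cs[, 1]
  o <- order(cell)
  structure(list(x = x, y = y, spacing = spacing,
                 cell = cell[o], class = class[o], frac = frac[o],
                 cellsum = cellsum, q = q,
                 csr = c(0, cumsum(tabulate(cell[o],
                                            length(x) * length(y))))),
            class = "rm3d_class_field")
}

#' @export
print.rm3d_class_field <- function(x, ...) {
  cat(sprintf("<WET class field %d x %d cells @ %.2f mm, %d entries, q = %.2f mm>\n",
              length(x$x), length(x$y), x$spacing, length(x$cell), x$q))
  invisible(x)
}

#' Analytic WET class field of an untransformed modulator
#'
#' Exact per-cell area fractions: the intersection of a square cell with
#' the Chebyshev ball of radius r centered on the pin is a product of two
#' interval overlaps, so ring areas within a cell are closed-form.
#'
#' @param mod an `rm3d_modulator`.
#' @param cell_size lateral cell size in mm (the pin period must be a
#'   multiple of it).
#' @param q WET quantization in mm.
#' @return an `rm3d_class_field`.
#' @export
analytic_class_field <- function(mod, cell_size = 0.5, q = 0.25) {
  stopifnot(abs(mod$period / cell_size - round(mod$period / cell_size))
            < 1e-9)
  fp <- modulator_footprint(mod)
  wallt <- if (is.null(mod$wall)) 0 else mod$wall$thickness
  rsp <- mod$material$relative_stopping_power
  base_cls <- as.integer(round(mod$base_layer * rsp / q))
  x0 <- fp$x[1] - wallt; x1 <- fp$x[2] + wallt
  y0 <- fp$y[1] - wallt; y1 <- fp$y[2] + wallt
  nx <- as.integer(round((x1 - x0) / cell_size))
  ny <- as.integer(round((y1 - y0) / cell_size))
  cx <- x0 + (seq_len(nx) - 0.5) * cell_size
  cy <- y0 + (seq_len(ny) - 0.5) * cell_size

  cells <- list(); clss <- list(); frcs <- list(); nb <- 0L
  push <- function(cell, cls, frac) {
    nb <<- nb + 1L
    cells[[nb]] <<- cell; clss[[nb]] <<- cls; frcs[[nb]] <<- frac
  }

  # walls and the footprint cells not covered by a pin: uniform classes
  in_fpx <- cx > fp$x[1] & cx < fp$x[2]
  in_fpy <- cy > fp$y[1] & cy < fp$y[2]
  covered <- matrix(FALSE, nx, ny)

  kpc <- as.integer(round(mod$period / cell_size))
  half <- mod$period / 2
  for (p in seq_len(nrow(mod$pins))) {
    px <- mod$pins$x[p]; py <- mod$pins$y[p]
    rings <- pin_rings(mod$pins$contour[[p]], mod$pins$offset_wet[p],
                       period = mod$period)
    i0 <- as.integer(round((px - half - x0) / cell_size))
    j0 <- as.integer(round((py - half - y0) / cell_size))
    ii <- i0 + seq_len(kpc); jj <- j0 + seq_len(kpc)
    stopifnot(all(ii >= 1), all(ii <= nx), all(jj >= 1), all(jj <= ny))
    covered[ii, jj] <- TRUE
    cell_ids <- outer(ii, (jj - 1L) * nx, "+")
    if (is.null(rings)) {                      # bare base under this pin
      push(as.vector(cell_ids), rep(base_cls, kpc * kpc),
           rep(1, kpc * kpc))
      next
    }
    clv <- as.integer(round((rings$h * rsp + mod$base_layer * rsp) / q))
    # cell x-interval overlaps with [-r, r] around the pin center
    xlo <- x0 + (ii - 1L) * cell_size - px
    ylo <- y0 + (jj - 1L) * cell_size - py
    bs <- c(rings$b, 0)                        # ring outer radii + center
    # A[cell_x, r] = overlap length of [xlo, xlo+cs] with [-r, r]
    ovl <- function(lo, r) pmin(lo + cell_size, r) - pmax(lo, -r)
    area_r <- function(r) {                    # nx_cells x ny_cells
      lx <- pmax(ovl(xlo, r), 0)
      ly <- pmax(ovl(ylo, r), 0)
      outer(lx, ly)
    }
    Aprev <- area_r(bs[1])
    # area beyond the outermost ring (height 0, bare base)
    rem <- cell_size^2 - Aprev
    sel <- rem > 1e-12
    if (any(sel))
      push(cell_ids[sel], rep(base_cls, sum(sel)),
           rem[sel] / cell_size^2)
    for (r in seq_len(nrow(rings))) {
      Anext <- area_r(bs[r + 1])
      da <- Aprev - Anext
      sel <- da > 1e-12
      if (any(sel))
        push(cell_ids[sel], rep(clv[r], sum(sel)), da[sel] / cell_size^2)
      Aprev <- Anext
    }
  }
  # footprint cells without a pin: base only
  basecells <- which(outer(in_fpx, in_fpy, "&") & !covered)
  if (length(basecells))
    push(basecells, rep(base_cls, length(basecells)),
         rep(1, length(basecells)))
  if (!is.null(mod$wall)) {
    wall_cls <- as.integer(round((mod$base_layer + mod$wall$height) *
                                   rsp / q))
    wallcells <- which(!outer(in_fpx, in_fpy, "&"))
    push(wallcells, rep(wall_cls, length(wallcells)),
         rep(1, length(wallcells)))
  }
  new_class_field(cx, cy, cell_size, unlist(cells),
                  as.integer(unlist(clss)), unlist(frcs), q)
}

#' WET class field of a (possibly transformed) modulator mesh
#'
#' Scanline-rasterizes the mesh onto a dense sub-ray lattice
#' (`cell_size / subsamples` pitch) and pools sub-rays into per-cell WET
#' class fractions.
#'
#' @param mesh an `rm3d_mesh` (union of closed solids; the `material`
#'   attribute provides the RSP).
#' @param cell_size lateral cell size in mm.
#' @param subsamples sub-rays per cell and axis.
#' @param q WET quantization in mm.
#' @return an `rm3d_class_field`.
#' @export
mesh_class_field <- function(mesh, cell_size = 0.5, subsamples = 25,
                             q = 0.25) {
  mat <- attr(mesh, "material") %||% rm_materials("rigur")
  V <- mesh$vertices
  xr <- range(V[, 1]); yr <- range(V[, 2])
  x0 <- floor(xr[1] / cell_size) * cell_size
  y0 <- floor(yr[1] / cell_size) * cell_size
  nx <- as.integer(ceiling((xr[2] - x0) / cell_size))
  ny <- as.integer(ceiling((yr[2] - y0) / cell_size))
  res <- cpp_raycast_class_field(V, mesh$triangles, x0, y0, nx, ny,
                                 cell_size, as.integer(subsamples),
                                 mat$relative_stopping_power, q)
  if (res$skipped > 0.001 * (as.double(nx) * ny * subsamples^2))
    warning(sprintf("%d sub-rays skipped (unbalanced crossings)",
                    res$skipped), call. = FALSE)
  cx <- x0 + (seq_len(nx) - 0.5) * cell_size
  cy <- y0 + (seq_len(ny) - 0.5) * cell_size
  # drop the all-air class-0 entries outside the device: they are implied
  keep <- res$class > 0L
  new_class_field(cx, cy, cell_size, res$cell[keep], res$class[keep],
                  res$frac[keep], q)
}

# entries of a class field for one spot window: positions (mm, modulator
# plane), class, and Gaussian-weighted fluence fraction
spot_window_entries <- function(cf, sx, sy, sigma, nsig = 3) {
  s <- cf$spacing
  half <- nsig * sigma
  nx <- length(cf$x); ny <- length(cf$y)
  kx <- seq(floor((sx - half - cf$x[1]) / s), ceiling((sx + half - cf$x[1]) / s))
  ky <- seq(floor((sy - half - cf$y[1]) / s), ceiling((sy + half - cf$y[1]) / s))
  cxs <- cf$x[1] + kx * s
  cys <- cf$y[1] + ky * s
  wx <- stats::pnorm((cxs + s / 2 - sx) / sigma) -
    stats::pnorm((cxs - s / 2 - sx) / sigma)
  wy <- stats::pnorm((cys + s / 2 - sy) / sigma) -
    stats::pnorm((cys - s / 2 - sy) / sigma)
  inx <- kx >= 0 & kx <= nx - 1
  iny <- ky >= 0 & ky <= ny - 1

  W <- outer(wx, wy)
  PX <- matrix(cxs, length(kx), length(ky))
  PY <- matrix(cys, length(kx), length(ky), byrow = TRUE)
  inside <- outer(inx, iny, "&")
  cellid <- outer(kx + 1L, ky * nx, "+")

  # air outside the device grid
  out_px <- PX[!inside]; out_py <- PY[!inside]; out_w <- W[!inside]
  # covered cells: modulated entries + class-0 remainder
  ids <- cellid[inside]
  n_ent <- cf$csr[ids + 1L] - cf$csr[ids]
  has <- n_ent > 0L
  ent_idx <- sequence(n_ent[has], from = cf$csr[ids[has]] + 1L)
  rep_i <- rep(which(inside)[has], n_ent[has])
  px <- c(PX[rep_i], out_px)
  py <- c(PY[rep_i], out_py)
  cls <- c(cf$class[ent_idx], integer(length(out_w)))
  w <- c(W[rep_i] * cf$frac[ent_idx], out_w)
  rem <- 1 - cf$cellsum[ids]
  remsel <- rem > 1e-9
  if (any(remsel)) {
    ii <- which(inside)[remsel]
    px <- c(px, PX[ii]); py <- c(py, PY[ii])
    cls <- c(cls, integer(sum(remsel)))
    w <- c(w, W[ii] * rem[remsel])
  }
  list(px = px, py = py, cls = cls, w = w)
}
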