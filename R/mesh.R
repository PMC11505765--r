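# Triangle meshes: tessellation of modulators, rigid-body transforms, STL
# I/O (binary and ASCII) and heightfield extraction by vertical ray
# casting.  Generated modulator meshes are unions of closed, outward-
# oriented solids (base slab, wall boxes, one "wedding-cake" solid per
# pin), so every edge is shared by exactly two triangles and the axial
# material path length of a ray is recovered by signed crossing summation.

#' Triangle mesh
#'
#' @param vertices n x 3 numeric matrix (mm).
#' @param triangles m x 3 integer matrix of 1-based vertex indices.
#' @param provenance free-text origin tag.
#' @return object of class `rm3d_mesh`.
#' @export
triangle_mesh <- function(vertices, triangles, provenance = "") {
  vertices <- as.matrix(vertices)
  storage.mode(triangles) <- "integer"
  stopifnot(ncol(vertices) == 3, ncol(triangles) == 3,
            max(triangles) <= nrow(vertices), min(triangles) >= 1)
  structure(list(vertices = vertices, triangles = triangles,
                 provenance = provenance),
            class = "rm3d_mesh")
}

#' @export
print.rm3d_mesh <- function(x, ...) {
  cat(sprintf("<mesh: %d vertices, %d triangles%s>\n", nrow(x$vertices),
              nrow(x$triangles),
              if (nzchar(x$provenance)) paste0(", ", x$provenance) else ""))
  invisible(x)
}

merge_meshes <- function(meshes, provenance = "") {
  offs <- cumsum(c(0, vapply(meshes, function(m) nrow(m$vertices), 0)))
  V <- do.call(rbind, lapply(meshes, `[[`, "vertices"))
  Tr <- do.call(rbind, lapply(seq_along(meshes), function(i)
    meshes[[i]]$triangles + offs[i]))
  triangle_mesh(V, Tr, provenance)
}

# closed axis-aligned box with outward-oriented triangles
box_mesh <- function(xr, yr, zr) {
  v <- rbind(c(xr[1], yr[1], zr[1]), c(xr[2], yr[1], zr[1]),
             c(xr[2], yr[2], zr[1]), c(xr[1], yr[2], zr[1]),
             c(xr[1], yr[1], zr[2]), c(xr[2], yr[1], zr[2]),
             c(xr[2], yr[2], zr[2]), c(xr[1], yr[2], zr[2]))
  f <- rbind(c(1, 3, 2), c(1, 4, 3),     # bottom (-z)
             c(5, 6, 7), c(5, 7, 8),     # top (+z)
             c(1, 2, 6), c(1, 6, 5),     # south (-y)
             c(3, 4, 8), c(3, 8, 7),     # north (+y)
             c(4, 1, 5), c(4, 5, 8),     # west (-x)
             c(2, 3, 7), c(2, 7, 6))     # east (+x)
  triangle_mesh(v, f)
}

# concentric-square "wedding cake" solid in a local frame (z up, sitting on
# z = 0): rings with outer half-widths b (outermost first, strictly
# decreasing) and heights h (strictly increasing).  Closed, outward-
# oriented.
cake_mesh <- function(b, h, cx = 0, cy = 0) {
  m <- length(b)
  stopifnot(length(h) == m, m >= 1)
  csx <- c(1, -1, -1, 1)           # corner order, ccw seen from +z
  csy <- c(1, 1, -1, -1)
  corners <- function(bb, hh)      # 4*length(bb) rows
    cbind(cx + rep(bb, each = 4) * csx, cy + rep(bb, each = 4) * csy,
          rep(hh, each = 4))
  # vertex layout: bottom ring (b1, 0) | wall tops (b_j, h_j) | inner ring
  # bottoms (b_{j+1}, h_j) for j < m
  V <- rbind(corners(b[1], 0), corners(b, h),
             if (m > 1) corners(b[-1], h[-m]))
  idx_top <- matrix(4L + seq_len(4 * m), m, 4, byrow = TRUE)
  idx_bot <- rbind(1:4,
                   if (m > 1) matrix(4L + 4L * m + seq_len(4 * (m - 1)),
                                     m - 1, 4, byrow = TRUE))
  nxt <- c(2L, 3L, 4L, 1L)
  PB <- idx_bot; PT <- idx_top
  PBn <- PB[, nxt, drop = FALSE]; PTn <- PT[, nxt, drop = FALSE]
  Tr <- rbind(
    c(1L, 3L, 2L), c(1L, 4L, 3L),                     # bottom (-z)
    cbind(as.vector(PB), as.vector(PBn), as.vector(PTn)),  # walls
    cbind(as.vector(PB), as.vector(PTn), as.vector(PT)))
  if (m > 1) {                                        # top annuli (+z)
    PO <- idx_top[-m, , drop = FALSE]; PI <- idx_bot[-1, , drop = FALSE]
    POn <- PO[, nxt, drop = FALSE]; PIn <- PI[, nxt, drop = FALSE]
    Tr <- rbind(Tr,
                cbind(as.vector(PO), as.vector(POn), as.vector(PIn)),
                cbind(as.vector(PO), as.vector(PIn), as.vector(PI)))
  }
  pc <- idx_top[m, ]                                  # top cap (+z)
  Tr <- rbind(Tr, pc[c(1, 2, 3)], pc[c(1, 3, 4)])
  triangle_mesh(V, Tr)
}

# ring decomposition of a pin (with compensator offset), outermost first
pin_rings <- function(pin, offset_wet = 0, period = pin$base_period,
                      tolerance = 0.2) {
  rsp <- pin$material$relative_stopping_power
  off_h <- offset_wet / rsp
  if (pin$kind == "step") {
    lv <- pin$levels[order(pin$levels$height), ]
    inner_cum <- rev(cumsum(rev(lv$area_fraction)))  # area with height >= h_i
    b <- period / 2 * sqrt(inner_cum)
    h <- lv$height + off_h
  } else {
    hstep <- max(tolerance, 1e-3)
    hmax <- max(pin$profile$height)
    edges <- seq(0, hmax, by = hstep)
    if (edges[length(edges)] < hmax) edges <- c(edges, hmax)
    mids <- (edges[-1] + edges[-length(edges)]) / 2
    # area with height >= edge: 1 - F(wet(edge))
    fa <- 1 - pin_cum_area(pin, edges * rsp - 1e-9)
    b <- period / 2 * sqrt(fa[-length(fa)])
    h <- mids + off_h
  }
  keep <- h > 1e-9 & b > 1e-9
  b <- b[keep]; h <- h[keep]
  if (!length(b)) return(NULL)
  # merge rings with (numerically) identical boundaries
  keep <- c(abs(diff(b)) > 1e-9, TRUE)
  data.frame(b = b[keep], h = h[keep])
}

#' Tessellate a modulator into a watertight triangle mesh
#'
#' The mesh is the union of closed solids: the base slab, four wall boxes
#' and one concentric-square stepped solid per pin.  Stepless pins are
#' discretized into rings no taller than `tolerance` (midpoint heights, so
#' the enclosed volume matches the analytic volume to well below 0.5%).
#' The analytic volume is attached as attribute `analytic_volume`.
#'
#' @param mod an `rm3d_modulator`.
#' @param tolerance ring discretization tolerance for stepless pins (mm).
#' @return an `rm3d_mesh` with attributes `material` and `analytic_volume`.
#' @export
tessellate <- function(mod, tolerance = 0.2) {
  stopifnot(inherits(mod, "rm3d_modulator"))
  fp <- modulator_footprint(mod)
  z_pin_base <- mod$z_base - mod$base_layer   # pins seat here, point to -z
  parts <- list()
  vol <- 0
  wallt <- if (is.null(mod$wall)) 0 else mod$wall$thickness
  # base slab (extends under the walls)
  bx <- fp$x + c(-wallt, wallt); by <- fp$y + c(-wallt, wallt)
  parts[[1]] <- box_mesh(bx, by, c(z_pin_base, mod$z_base))
  vol <- vol + diff(bx) * diff(by) * mod$base_layer
  if (!is.null(mod$wall)) {
    wh <- mod$wall$height
    zr <- c(z_pin_base - wh, z_pin_base)
    for (w in list(list(x = c(fp$x[1] - wallt, fp$x[1]), y = by),
                   list(x = c(fp$x[2], fp$x[2] + wallt), y = by),
                   list(x = fp$x, y = c(fp$y[1] - wallt, fp$y[1])),
                   list(x = fp$x, y = c(fp$y[2], fp$y[2] + wallt)))) {
      parts[[length(parts) + 1]] <- box_mesh(w$x, w$y, zr)
      vol <- vol + diff(w$x) * diff(w$y) * wh
    }
  }
  rsp <- mod$material$relative_stopping_power
  for (i in seq_len(nrow(mod$pins))) {
    rings <- pin_rings(mod$pins$contour[[i]], mod$pins$offset_wet[i],
                       period = mod$period, tolerance = tolerance)
    if (is.null(rings)) next
    cake <- cake_mesh(rings$b, rings$h, cx = mod$pins$x[i],
                      cy = mod$pins$y[i])
    # map local "up" frame to lab (pins point upstream) and flip winding
    cake$vertices[, 3] <- z_pin_base - cake$vertices[, 3]
    cake$triangles <- cake$triangles[, c(1, 3, 2)]
    parts[[length(parts) + 1]] <- cake
    b_out <- c(rings$b, 0)
    vol <- vol + sum((2 * rings$b)^2 * rings$h) -
      sum((2 * b_out[-1])^2 * rings$h)
  }
  out <- merge_meshes(parts, provenance = "rm3d modulator")
  attr(out, "material") <- mod$material
  attr(out, "analytic_volume") <- vol
  out
}

#' Signed enclosed volume of a mesh
#'
#' Divergence-theorem sum over triangles; positive for consistently
#' outward-oriented closed meshes.
#'
#' @param mesh an `rm3d_mesh`.
#' @return volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  V <- mesh$vertices; Tr <- mesh$triangles
  a <- V[Tr[, 1], , drop = FALSE]
  b <- V[Tr[, 2], , drop = FALSE]
  c_ <- V[Tr[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
      a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

#' Watertightness check
#'
#' TRUE when every undirected edge is shared by exactly two triangles and
#' every directed edge appears exactly once (consistent orientation).
#'
#' @param mesh an `rm3d_mesh`.
#' @return logical.
#' @export
mesh_is_watertight <- function(mesh) {
  Tr <- mesh$triangles
  e <- rbind(Tr[, c(1, 2)], Tr[, c(2, 3)], Tr[, c(3, 1)])
  n <- nrow(mesh$vertices) + 1
  directed <- e[, 1] * n + e[, 2]
  if (anyDuplicated(directed) > 0) return(FALSE)
  undirected <- pmin(e[, 1], e[, 2]) * n + pmax(e[, 1], e[, 2])
  all(tabulate(match(undirected, unique(undirected))) == 2L)
}

#' Rigid-body transform
#'
#' Rotation by `angle` degrees about a named axis through `pivot`, followed
#' by `translation`: v -> R (v - pivot) + pivot + translation.
#'
#' @param angle rotation angle in degrees (right-handed about the +axis).
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param pivot rotation point, length-3 mm.
#' @param translation length-3 mm.
#' @return object of class `rm3d_transform`.
#' @export
rigid_transform <- function(angle = 0, axis = "y", pivot = c(0, 0, 0),
                            translation = c(0, 0, 0)) {
  R <- rot_mat_deg(axis, angle)
  stopifnot(max(abs(t(R) %*% R - diag(3))) < 1e-12)
  structure(list(angle = angle, axis = axis, pivot = pivot,
                 translation = translation, R = R),
            class = "rm3d_transform")
}

#' Apply a rigid transform to a mesh
#'
#' Vertices are mapped by v -> R (v - pivot) + pivot + translation; the
#' triangle topology is unchanged.
#'
#' @param mesh an `rm3d_mesh`.
#' @param transform an [rigid_transform()].
#' @return transformed `rm3d_mesh` (attributes preserved).
#' @export
apply_transform <- function(mesh, transform) {
  stopifnot(inherits(mesh, "rm3d_mesh"), inherits(transform, "rm3d_transform"))
  V <- sweep(mesh$vertices, 2, transform$pivot)
  V <- V %*% t(transform$R)
  V <- sweep(V, 2, transform$pivot + transform$translation, "+")
  out <- mesh
  out$vertices <- V
  out
}

#' Write a mesh to STL
#'
#' Binary STL (80-byte header, little-endian, 50-byte triangle records) or
#' ASCII.  Units are mm.
#'
#' @param mesh an `rm3d_mesh`.
#' @param path output file.
#' @param dialect `"binary"` (default) or `"ascii"`.
#' @export
write_stl <- function(mesh, path, dialect = c("binary", "ascii")) {
  dialect <- match.arg(dialect)
  V <- mesh$vertices; Tr <- mesh$triangles
  a <- V[Tr[, 1], , drop = FALSE]
  b <- V[Tr[, 2], , drop = FALSE]
  c_ <- V[Tr[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- c_ - a
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(nrm^2))
  nrm <- nrm / ifelse(len > 0, len, 1)
  nt <- nrow(Tr)
  if (dialect == "binary") {
    con <- file(path, "wb")
    on.exit(close(con))
    header <- charToRaw(sprintf("%-80s", "rm3d binary STL"))[1:80]
    writeBin(header, con)
    writeBin(as.integer(nt), con, size = 4, endian = "little")
    rec <- t(cbind(nrm, a, b, c_))          # 12 floats per triangle
    dat <- writeBin(as.numeric(rec), raw(), size = 4, endian = "little")
    dat <- matrix(dat, nrow = 48)
    out <- rbind(dat, matrix(as.raw(0), 2, nt))
    writeBin(as.vector(out), con)
  } else {
    fmt <- paste0(
      " facet normal %.9g %.9g %.9g\n  outer loop\n",
      "   vertex %.9g %.9g %.9g\n   vertex %.9g %.9g %.9g\n",
      "   vertex %.9g %.9g %.9g\n  endloop\n endfacet")
    body <- sprintf(fmt, nrm[, 1], nrm[, 2], nrm[, 3],
                    a[, 1], a[, 2], a[, 3], b[, 1], b[, 2], b[, 3],
                    c_[, 1], c_[, 2], c_[, 3])
    writeLines(c("solid rm3d", body, "endsolid rm3d"), path)
  }
  invisible(path)
}

#' Read an STL file
#'
#' Detects the dialect automatically.  Returns the triangle soup with
#' duplicate vertices merged (exact float32 match), so closed solids remain
#' watertight.
#'
#' @param path STL file (binary or ASCII).
#' @param merge merge coincident vertices (default TRUE).
#' @return an `rm3d_mesh`.
#' @export
read_stl <- function(path, merge = TRUE) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 15) stop("malformed STL: file too small (",
                                 sz %||% 0, " bytes)", call. = FALSE)
  con <- file(path, "rb")
  head <- readBin(con, "raw", n = min(sz, 512))
  close(con)
  is_ascii <- identical(rawToChar(head[1:5]), "solid") &&
    !any(head == as.raw(0)) &&
    grepl("facet", rawToChar(head), fixed = TRUE)
  if (is_ascii) {
    txt <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex", txt, value = TRUE)
    if (length(vl) == 0 || length(vl) %% 3 != 0)
      stop("malformed ASCII STL: vertex count ", length(vl),
           " not a multiple of 3", call. = FALSE)
    nums <- t(vapply(strsplit(trimws(vl), "\\s+"),
                     function(p) as.numeric(p[2:4]), numeric(3)))
    V <- nums
    Tr <- matrix(seq_len(nrow(V)), ncol = 3, byrow = TRUE)
  } else {
    if (sz < 84) stop("malformed binary STL: truncated header at byte ",
                      sz, call. = FALSE)
    con <- file(path, "rb")
    on.exit(close(con))
    invisible(readBin(con, "raw", n = 80))
    nt <- readBin(con, "integer", n = 1, size = 4, endian = "little")
    need <- 84 + 50 * nt
    if (sz < need)
      stop("malformed binary STL: expected ", need, " bytes, file ends at ",
           sz, call. = FALSE)
    dat <- readBin(con, "raw", n = 50 * nt)
    dat <- matrix(dat, nrow = 50)
    fl <- readBin(as.vector(dat[1:48, ]), "numeric", n = 12 * nt, size = 4,
                  endian = "little")
    fl <- matrix(fl, nrow = 12)
    V <- matrix(as.vector(fl[4:12, ]), ncol = 3, byrow = TRUE)
    Tr <- matrix(seq_len(nrow(V)), ncol = 3, byrow = TRUE)
  }
  if (merge && nrow(V)) {
    key <- paste(V[, 1], V[, 2], V[, 3], sep = "/")
    uk <- !duplicated(key)
    map <- match(key, key[uk])
    V <- V[uk, , drop = FALSE]
    Tr <- matrix(map[Tr], ncol = 3)
  }
  triangle_mesh(V, Tr, provenance = paste("read from", basename(path)))
}

#' Heightfield of a mesh or modulator
#'
#' Total material path length of axial (+z) rays on a regular lateral grid.
#' For an untransformed `rm3d_modulator` the heightfield is analytic; for a
#' mesh it is computed by signed ray casting (the mesh must be a union of
#' closed solids).  Sample points sit half a sample off cell boundaries.
#'
#' @param x an `rm3d_modulator` or `rm3d_mesh`.
#' @param lateral_resolution sample spacing in mm.
#' @param ... unused.
#' @return an `rm3d_heightfield` (see [modulator_heightfield()]).
#' @export
heightfield_of <- function(x, lateral_resolution = 0.25, ...) {
  UseMethod("heightfield_of")
}

#' @export
heightfield_of.rm3d_modulator <- function(x, lateral_resolution = 0.25, ...) {
  modulator_heightfield(x, lateral_resolution)
}

#' @export
heightfield_of.rm3d_mesh <- function(x, lateral_resolution = 0.25, ...) {
  V <- x$vertices
  res <- lateral_resolution
  xr <- range(V[, 1]); yr <- range(V[, 2])
  gx <- seq(xr[1] + res / 2, xr[2], by = res)
  gy <- seq(yr[1] + res / 2, yr[2], by = res)
  H <- cpp_raycast_heightfield(V, x$triangles, gx, gy,
                               bucket = max(1.5, 4 * res))
  nb <- attr(H, "unbalanced")
  if (!is.null(nb) && nb > 0) {
    if (nb > 0.001 * length(H))
      stop("ray casting found ", nb, " unbalanced crossings; ",
           "mesh is not a union of closed solids", call. = FALSE)
    H[is.na(H)] <- 0
  }
  structure(list(x = gx, y = gy, H = H, resolution = res),
            class = "rm3d_heightfield")
}

#' Export a heightfield as a plain-text matrix
#' @param hf an `rm3d_heightfield`.
#' @param path output TSV file (first row/column are the axes).
#' @export
write_heightfield_tsv <- function(hf, path) {
  m <- rbind(c(NA, hf$y), cbind(hf$x, hf$H))
  utils::write.table(m, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
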