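## Isosurface extraction by marching tetrahedra. Each grid cube is split into
## six tetrahedra sharing the main diagonal; the split is translation
## invariant, so shared cube faces carry matching diagonals and the surface is
## watertight by construction. On binary masks the field is first smoothed
## with one pass of a separable 3-voxel box filter (optional), which places
## interpolated vertices at sub-voxel positions instead of on the voxel
## staircase and removes most of the staircase area bias.

CUBE_OFFSETS <- matrix(c(0, 0, 0,  1, 0, 0,  1, 1, 0,  0, 1, 0,
                         0, 0, 1,  1, 0, 1,  1, 1, 1,  0, 1, 1),
                       ncol = 3L, byrow = TRUE)

## six tetrahedra around the v1-v7 diagonal (1-based corner ids)
CUBE_TETS <- matrix(c(1, 2, 3, 7,
                      1, 3, 4, 7,
                      1, 4, 8, 7,
                      1, 8, 5, 7,
                      1, 5, 6, 7,
                      1, 6, 2, 7), ncol = 4L, byrow = TRUE)

box_smooth3 <- function(a) {
  for (ax in 1:3) {
    a <- (shift3_num(a, ax, 1L) + a + shift3_num(a, ax, -1L)) / 3
  }
  a
}

shift3_num <- function(a, axis, s) {
  sh <- c(0L, 0L, 0L)
  sh[axis] <- s
  d <- dim(a)
  out <- array(0, d)
  src <- dst <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  if (s >= 0) {
    src[[axis]] <- seq_len(d[axis] - s); dst[[axis]] <- src[[axis]] + s
  } else {
    src[[axis]] <- seq(1 - s, d[axis]); dst[[axis]] <- src[[axis]] + s
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Extract a triangulated surface from a bone mask
#'
#' Runs marching tetrahedra on the (optionally box-smoothed) binary mask at
#' the given iso level, in physical mm coordinates. The mask is zero-padded
#' before contouring so surfaces touching the array boundary stay closed.
#'
#' @param mask a [bone_mask()] or 3D logical array.
#' @param spacing voxel spacing in mm (taken from `volume` conventions);
#'   scalar or length 3.
#' @param iso iso level on the smoothed occupancy field (default 0.5, the
#'   half-occupancy surface).
#' @param origin physical position of voxel `[1,1,1]` (default `c(0,0,0)`).
#' @param smoothing apply one separable 3-voxel box-filter pass before
#'   contouring (default `TRUE`). Smoothing places vertices at sub-voxel
#'   positions and is accurate for smooth, bone-like surfaces; on sharp
#'   polyhedral solids it chamfers edges over about one voxel, so contour
#'   such shapes with `smoothing = FALSE` (the raw midpoint staircase, which
#'   is exact for axis-aligned faces). Structures thinner than the smoothing
#'   support automatically fall back to raw contouring.
#' @param check_watertight verify that every mesh edge is shared by exactly
#'   two triangles (default `TRUE`); skipping the check sets the flag to `NA`
#'   and is useful in tight loops, the construction being closed by design.
#' @return An object of class `surface_mesh` with `vertices` (n x 3 mm),
#'   `faces` (m x 3 vertex indices, outward orientation) and `watertight`.
#' @export
extract_surface <- function(mask, spacing = c(1, 1, 1), iso = 0.5,
                            origin = c(0, 0, 0), smoothing = TRUE,
                            check_watertight = TRUE) {
  m <- as_mask_array(mask)
  if (!any(m))
    stop_osteo("mask is empty", "osteo_segmentation_empty")
  spacing <- rep_len(as.numeric(spacing), 3L)
  pad <- 2L
  binary <- pad3(array(as.numeric(m), dim(m)), pad, fill = 0)
  field <- if (smoothing) box_smooth3(binary) else binary
  ## origin of the padded grid's first voxel center
  org <- origin - pad * spacing
  tri <- marching_tets(field, spacing, org, iso)
  if (nrow(tri) == 0L && smoothing) {
    ## structures thinner than the smoothing support (about one voxel) are
    ## averaged below the iso level; contour the raw occupancy instead
    tri <- marching_tets(binary, spacing, org, iso)
  }
  if (nrow(tri) == 0L)
    stop_osteo("iso level produced no surface", "osteo_segmentation_empty")
  mesh <- compact_mesh(tri)
  wt <- if (check_watertight) is_watertight(mesh) else NA
  structure(list(vertices = mesh$vertices, faces = mesh$faces, watertight = wt),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d faces, watertight: %s\n",
              nrow(x$vertices), nrow(x$faces), format(x$watertight)))
  invisible(x)
}

## returns an n x 9 matrix: (x1,y1,z1, x2,y2,z2, x3,y3,z3) per triangle
marching_tets <- function(field, spacing, origin, iso) {
  d <- dim(field)
  nc <- d - 1L
  ## corner value arrays for every cube, in CUBE_OFFSETS order
  corner <- function(o) {
    field[(1 + o[1]):(nc[1] + o[1]),
          (1 + o[2]):(nc[2] + o[2]),
          (1 + o[3]):(nc[3] + o[3])]
  }
  vals <- lapply(seq_len(8L), function(i) corner(CUBE_OFFSETS[i, ]))
  cmin <- Reduce(pmin, vals)
  cmax <- Reduce(pmax, vals)
  active <- which(cmin <= iso & cmax > iso)
  if (length(active) == 0L)
    return(matrix(numeric(0), ncol = 9L))
  V <- vapply(vals, function(a) a[active], numeric(length(active)))
  if (!is.matrix(V)) V <- matrix(V, ncol = 8L)
  base <- arrayInd(active, nc) - 1L  # 0-based cube corner index
  tris <- vector("list", 6L * 8L)
  ti <- 0L
  for (t in seq_len(6L)) {
    ids <- CUBE_TETS[t, ]
    tv <- V[, ids, drop = FALSE]
    inside <- tv > iso
    code <- inside[, 1] + 2L * inside[, 2] + 4L * inside[, 3] + 8L * inside[, 4]
    for (piece in tet_cases()) {
      sel <- which(code == piece$code)
      if (length(sel) == 0L) next
      ti <- ti + 1L
      tris[[ti]] <- emit_tet_triangles(tv[sel, , drop = FALSE],
                                       base[sel, , drop = FALSE],
                                       ids, piece, spacing, origin, iso)
    }
  }
  tris <- tris[seq_len(ti)]
  if (length(tris) == 0L) return(matrix(numeric(0), ncol = 9L))
  do.call(rbind, tris)
}

## The 14 non-trivial inside/outside patterns of a tetrahedron. `inn`/`out`
## are local vertex ids (1..4); one inside or one outside vertex yields one
## triangle, two-and-two yields a quad split into two triangles.
tet_cases <- function() {
  if (!is.null(.tet_case_cache$cases)) return(.tet_case_cache$cases)
  cases <- list()
  for (code in 1:14) {
    inside <- as.logical(bitwAnd(code, c(1L, 2L, 4L, 8L)))
    inn <- which(inside)
    out <- which(!inside)
    cases[[length(cases) + 1L]] <- list(code = code, inn = inn, out = out)
  }
  .tet_case_cache$cases <- cases
  cases
}
.tet_case_cache <- new.env(parent = emptyenv())

emit_tet_triangles <- function(tv, base, ids, piece, spacing, origin, iso) {
  n <- nrow(tv)
  ## physical coordinates of the 4 tet vertices for each selected tet
  P <- lapply(seq_len(4L), function(k) {
    off <- CUBE_OFFSETS[ids[k], ]
    cbind(origin[1] + (base[, 1] + off[1]) * spacing[1],
          origin[2] + (base[, 2] + off[2]) * spacing[2],
          origin[3] + (base[, 3] + off[3]) * spacing[3])
  })
  interp <- function(a, b) {
    tt <- (iso - tv[, a]) / (tv[, b] - tv[, a])
    P[[a]] + tt * (P[[b]] - P[[a]])
  }
  inn <- piece$inn
  out <- piece$out
  if (length(inn) == 1L) {
    tri <- list(cbind(interp(inn, out[1]), interp(inn, out[2]),
                      interp(inn, out[3])))
    inward <- P[[inn]] - (P[[out[1]]] + P[[out[2]]] + P[[out[3]]]) / 3
  } else if (length(inn) == 3L) {
    q <- out[1]
    tri <- list(cbind(interp(inn[1], q), interp(inn[2], q), interp(inn[3], q)))
    inward <- (P[[inn[1]]] + P[[inn[2]]] + P[[inn[3]]]) / 3 - P[[q]]
  } else {
    a <- inn[1]; b <- inn[2]; c <- out[1]; dd <- out[2]
    q1 <- interp(a, c); q2 <- interp(a, dd); q3 <- interp(b, dd); q4 <- interp(b, c)
    tri <- list(cbind(q1, q2, q3), cbind(q1, q3, q4))
    inward <- (P[[a]] + P[[b]]) / 2 - (P[[c]] + P[[dd]]) / 2
  }
  out_tri <- lapply(tri, orient_outward, inward = inward)
  do.call(rbind, out_tri)
}

## flip triangles whose normal points toward the inside of the body
orient_outward <- function(tri9, inward) {
  e1 <- tri9[, 4:6, drop = FALSE] - tri9[, 1:3, drop = FALSE]
  e2 <- tri9[, 7:9, drop = FALSE] - tri9[, 1:3, drop = FALSE]
  nx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  ny <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  nz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  flip <- nx * inward[, 1] + ny * inward[, 2] + nz * inward[, 3] > 0
  if (any(flip)) {
    tmp <- tri9[flip, 4:6, drop = FALSE]
    tri9[flip, 4:6] <- tri9[flip, 7:9, drop = FALSE]
    tri9[flip, 7:9] <- tmp
  }
  tri9
}

compact_mesh <- function(tri9) {
  pts <- rbind(tri9[, 1:3, drop = FALSE], tri9[, 4:6, drop = FALSE],
               tri9[, 7:9, drop = FALSE])
  key <- paste(round(pts[, 1], 7), round(pts[, 2], 7), round(pts[, 3], 7))
  uid <- match(key, key)
  keep <- !duplicated(uid)
  idx <- match(uid, which(keep))
  n <- nrow(tri9)
  faces <- cbind(idx[seq_len(n)], idx[n + seq_len(n)], idx[2L * n + seq_len(n)])
  degen <- faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
    faces[, 1] == faces[, 3]
  list(vertices = pts[keep, , drop = FALSE], faces = faces[!degen, , drop = FALSE])
}

is_watertight <- function(mesh) {
  f <- mesh$faces
  e <- rbind(cbind(f[, 1], f[, 2]), cbind(f[, 2], f[, 3]), cbind(f[, 3], f[, 1]))
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(e[, 1] * (max(f) + 1) + e[, 2])
  all(cnt == 2L)
}

#' Surface area and enclosed volume of a triangle mesh
#'
#' Area is the sum of triangle areas; volume comes from the divergence
#' theorem and is reported positive regardless of the global orientation.
#'
#' @param mesh a [surface_mesh()] (or list with `vertices` and `faces`).
#' @return Named numeric vector `c(S = ..., V = ...)` in mm^2 and mm^3.
#' @export
surface_and_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  e1 <- b - a
  e2 <- cc - a
  nx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  ny <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  nz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  S <- sum(sqrt(nx^2 + ny^2 + nz^2)) / 2
  wt <- mesh$watertight %||% NA
  if (isFALSE(wt))
    stop_osteo("mesh is not watertight; enclosed volume is undefined (area is available via triangle sums)",
               "osteo_volume_error")
  V <- abs(sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
               a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
               a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1]))) / 6
  c(S = S, V = V)
}

#' Write a surface mesh as ASCII STL
#'
#' @param mesh a [surface_mesh()].
#' @param path output path.
#' @param name solid name embedded in the file.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, name = "bone") {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- cc - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n <- n / len
  fmt <- function(p) sprintf("%.9g %.9g %.9g", p[, 1], p[, 2], p[, 3])
  lines <- c(sprintf("solid %s", name),
             paste0("facet normal ", fmt(n), "\n outer loop\n  vertex ",
                    fmt(a), "\n  vertex ", fmt(b), "\n  vertex ", fmt(cc),
                    "\n endloop\nendfacet"),
             sprintf("endsolid %s", name))
  writeLines(lines, path)
  invisible(path)
}
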