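## Density-weighted mass properties and the body coordinate system: origin at
## the center of mass, axes along the principal axes of inertia. The long
## (head-to-base) axis carries the smallest principal moment and is labeled z;
## the remaining axes are labeled x (plantar-dorsal) and y (medial-lateral)
## either from caller-supplied anatomical reference directions or, as a
## documented fallback, by eigenvalue order.

voxel_centers <- function(volume, idx) {
  d <- dim(volume$grid)
  ijk <- arrayInd(idx, d) - 1L
  xyz <- sweep(ijk, 2L, volume$spacing, `*`)
  if (!identical(volume$orientation, diag(3)))
    xyz <- xyz %*% t(volume$orientation)
  sweep(xyz, 2L, volume$origin, `+`)
}

#' Density-weighted mass properties of a segmented bone
#'
#' Each masked voxel is treated as a point mass at its center; under the
#' default gray weighting the voxel mass is its gray value divided by the
#' water gray value (1024), so mass is dimensionless and the inertia tensor
#' has units mass x mm^2. The tensor is taken about the center of mass.
#'
#' @param volume a [density_volume()].
#' @param mask a [bone_mask()] (or 3D logical array) congruent with `volume`.
#' @param weighting `"gray"` (default) for density weighting, `"uniform"` for
#'   unit voxel masses.
#' @param self_moment add the analytic inertia of each voxel cuboid about its
#'   own center (a `spacing^2/12` correction); off by default, where voxels
#'   are pure point masses.
#' @return An object of class `mass_properties` with `total_mass`, `com`,
#'   `inertia_tensor`, `principal_moments` (ascending) and `principal_axes`
#'   (orthonormal columns, det +1).
#' @export
mass_properties <- function(volume, mask, weighting = c("gray", "uniform"),
                            self_moment = FALSE) {
  stopifnot(inherits(volume, "density_volume"))
  weighting <- match.arg(weighting)
  m <- as_mask_array(mask)
  if (!identical(dim(m), dim(volume$grid)))
    stop_osteo("mask and volume dimensions differ", "osteo_format_error")
  idx <- which(m)
  if (length(idx) == 0L)
    stop_osteo("mask is empty", "osteo_segmentation_empty")
  w <- if (weighting == "gray") volume$grid[idx] / GRAY_WATER else
    rep(1, length(idx))
  total <- sum(w)
  if (total <= 0)
    stop_osteo("all masked voxels have zero mass under gray weighting",
               "osteo_format_error")
  pts <- voxel_centers(volume, idx)
  com <- colSums(pts * w) / total
  p <- sweep(pts, 2L, com, `-`)
  wx2 <- sum(w * p[, 1]^2); wy2 <- sum(w * p[, 2]^2); wz2 <- sum(w * p[, 3]^2)
  Ixx <- wy2 + wz2; Iyy <- wx2 + wz2; Izz <- wx2 + wy2
  Ixy <- -sum(w * p[, 1] * p[, 2])
  Ixz <- -sum(w * p[, 1] * p[, 3])
  Iyz <- -sum(w * p[, 2] * p[, 3])
  I <- matrix(c(Ixx, Ixy, Ixz, Ixy, Iyy, Iyz, Ixz, Iyz, Izz), 3, 3)
  if (self_moment) {
    h2 <- (volume$orientation %*% diag(volume$spacing^2 / 12)) %*%
      t(volume$orientation)
    I <- I + total * (sum(diag(h2)) * diag(3) - h2)
  }
  ev <- eigen(I, symmetric = TRUE)
  ord <- order(ev$values)
  vals <- ev$values[ord]
  vecs <- ev$vectors[, ord, drop = FALSE]
  if (det(vecs) < 0) vecs[, 3] <- -vecs[, 3]
  structure(list(total_mass = total, com = com, inertia_tensor = I,
                 principal_moments = pmax(vals, 0), principal_axes = vecs,
                 weighting = weighting),
            class = "mass_properties")
}

#' @export
print.mass_properties <- function(x, ...) {
  cat(sprintf("<mass_properties> mass %.4g, COM (%s) mm\n", x$total_mass,
              paste(signif(x$com, 5), collapse = ", ")))
  cat("  principal moments (ascending):",
      paste(signif(x$principal_moments, 6), collapse = ", "), "\n")
  invisible(x)
}

#' Body coordinate frame from principal axes of inertia
#'
#' Defines the bone's body frame: origin at the center of mass and axes along
#' the principal axes. The z axis (head-to-base, the long axis) is always the
#' eigenvector of the *smallest* principal moment. The remaining two axes are
#' labeled x (plantar-dorsal) and y (medial-lateral) by maximal absolute
#' cosine with `anatomical_refs` when supplied; without references the
#' fallback labels x as the intermediate-moment axis and y as the
#' largest-moment axis (recorded in `labeling`). Axis signs follow the
#' reference directions, or — without references — the z axis is oriented so
#' the third central moment of mass along z is non-negative, and the frame is
#' completed right-handed.
#'
#' @param props a [mass_properties()].
#' @param anatomical_refs optional 3x3 matrix whose rows are approximate
#'   scanner-frame directions of the body x, y, z axes.
#' @param degeneracy_gap minimum relative eigenvalue separation, as a
#'   fraction of the largest moment, below which the decomposition is
#'   considered degenerate (default 1e-6).
#' @param skewness optional numeric: precomputed third central moment of the
#'   mass distribution along the candidate z axis, used internally by
#'   [measure_bone()] to fix the z sign without references.
#' @return An object of class `body_frame`: `origin`, `rotation` (rows are
#'   the body x, y, z axes in scanner coordinates), `axis_moments` (named
#'   PMIx, PMIy, PMIz) and `labeling` (`"reference"` or `"eigenvalue_order"`).
#' @export
principal_frame <- function(props, anatomical_refs = NULL,
                            degeneracy_gap = 1e-6, skewness = NULL) {
  stopifnot(inherits(props, "mass_properties"))
  lam <- props$principal_moments
  gap <- diff(lam) / max(lam[3], .Machine$double.eps)
  if (any(gap < degeneracy_gap) && is.null(anatomical_refs))
    stop_osteo(paste("principal moments are degenerate; supply `anatomical_refs`",
                     "to disambiguate the axis labeling"),
               "osteo_degeneracy_error")
  vz <- props$principal_axes[, 1]
  v2 <- props$principal_axes[, 2]  # intermediate moment
  v3 <- props$principal_axes[, 3]  # largest moment
  if (!is.null(anatomical_refs)) {
    refs <- as.matrix(anatomical_refs)
    if (!all(dim(refs) == c(3L, 3L)))
      stop_osteo("`anatomical_refs` must be a 3x3 matrix (rows: x, y, z refs)",
                 "osteo_format_error")
    refs <- refs / sqrt(rowSums(refs^2))
    ## x gets whichever remaining eigenvector lies closest to the x reference
    if (abs(sum(v2 * refs[1, ])) >= abs(sum(v3 * refs[1, ]))) {
      vx <- v2; vy <- v3; mx <- lam[2]; my <- lam[3]
    } else {
      vx <- v3; vy <- v2; mx <- lam[3]; my <- lam[2]
    }
    if (sum(vz * refs[3, ]) < 0) vz <- -vz
    if (sum(vx * refs[1, ]) < 0) vx <- -vx
    vy <- cross3(vz, vx)  # right-handed completion (parallel to the eigenvector)
    labeling <- "reference"
  } else {
    vx <- v2; vy <- v3; mx <- lam[2]; my <- lam[3]
    if (!is.null(skewness) && skewness < 0) vz <- -vz
    vy <- cross3(vz, vx)
    labeling <- "eigenvalue_order"
  }
  R <- rbind(x = vx, y = vy, z = vz)
  if (det(R) < 0) R["x", ] <- -R["x", ]  # keep det +1; extents are sign-invariant
  structure(list(origin = props$com, rotation = R,
                 axis_moments = c(pmi_x = unname(mx), pmi_y = unname(my),
                                  pmi_z = lam[1]),
                 labeling = labeling),
            class = "body_frame")
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @export
print.body_frame <- function(x, ...) {
  cat(sprintf("<body_frame> origin (%s) mm, labeling: %s\n",
              paste(signif(x$origin, 5), collapse = ", "), x$labeling))
  cat("  axis moments:", paste(names(x$axis_moments),
                               signif(x$axis_moments, 5), sep = " = ",
                               collapse = ", "), "\n")
  invisible(x)
}

#' Express scanner-frame points in the body frame
#'
#' Applies `p' = R (p - origin)`: after transforming the bone's own mass
#' distribution its center of mass maps to the origin and its inertia tensor
#' becomes diagonal.
#'
#' @param points numeric matrix (n x 3) or length-3 vector, mm, scanner frame.
#' @param frame a [body_frame()].
#' @return Matrix of the same shape in body coordinates.
#' @export
to_body_frame <- function(points, frame) {
  stopifnot(inherits(frame, "body_frame"))
  p <- if (is.matrix(points)) points else matrix(points, ncol = 3L)
  sweep(p, 2L, frame$origin, `-`) %*% t(frame$rotation)
}

#' @rdname to_body_frame
#' @export
from_body_frame <- function(points, frame) {
  stopifnot(inherits(frame, "body_frame"))
  p <- if (is.matrix(points)) points else matrix(points, ncol = 3L)
  sweep(p %*% frame$rotation, 2L, frame$origin, `+`)
}
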