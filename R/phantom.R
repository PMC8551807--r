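## Voxel phantoms with closed-form mass properties. Primitives (sphere,
## ellipsoid, cuboid, elliptical cylinder) are voxelized by center inclusion
## and composed analytically by the parallel-axis theorem, giving an exact
## oracle for the voxel mass-property estimators. Analytic masses use a
## continuous convention (volumetric density = gray/1024 per mm^3 times the
## primitive volume); voxel sums carry one mass unit per water-equivalent
## voxel, so oracle comparisons are made on specific (mass-normalized)
## quantities, which are convention-free.

#' Phantom primitive
#'
#' @param shape `"sphere"`, `"ellipsoid"`, `"cuboid"` or `"cylinder"` (solid
#'   elliptical cylinder along its local z).
#' @param center position in mm.
#' @param size shape parameters in mm: radius for a sphere; semi-axes
#'   (a, b, c) for an ellipsoid; half-extents for a cuboid; `(a, b, h)` for a
#'   cylinder (cross-section semi-axes and half-length).
#' @param orientation local-to-world rotation (3x3, det +1).
#' @param density_gray gray value of the solid (water = 1024).
#' @return A `phantom_primitive` list.
#' @export
phantom_primitive <- function(shape = c("sphere", "ellipsoid", "cuboid", "cylinder"),
                              center = c(0, 0, 0), size,
                              orientation = diag(3), density_gray = 1638.4) {
  shape <- match.arg(shape)
  size <- as.numeric(size)
  need <- if (shape == "sphere") 1L else 3L
  if (length(size) != need || any(size <= 0))
    stop_osteo(sprintf("`size` for a %s needs %d positive value(s)", shape, need),
               "osteo_format_error")
  structure(list(shape = shape, center = as.numeric(center), size = size,
                 orientation = as.matrix(orientation),
                 density_gray = density_gray),
            class = "phantom_primitive")
}

primitive_volume <- function(p) {
  s <- p$size
  switch(p$shape,
         sphere = 4 / 3 * pi * s[1]^3,
         ellipsoid = 4 / 3 * pi * prod(s),
         cuboid = 8 * prod(s),
         cylinder = 2 * pi * s[1] * s[2] * s[3])
}

## inertia tensor about the primitive's own COM, local frame, unit mass
primitive_specific_inertia <- function(p) {
  s <- p$size
  switch(p$shape,
    sphere = diag(rep(2 / 5 * s[1]^2, 3)),
    ellipsoid = diag(c(s[2]^2 + s[3]^2, s[1]^2 + s[3]^2, s[1]^2 + s[2]^2) / 5),
    cuboid = diag(c(s[2]^2 + s[3]^2, s[1]^2 + s[3]^2, s[1]^2 + s[2]^2) / 3),
    cylinder = diag(c(s[2]^2 / 4 + s[3]^2 / 3,
                      s[1]^2 / 4 + s[3]^2 / 3,
                      (s[1]^2 + s[2]^2) / 4)))
}

## conservative world-frame half-extents of a primitive
primitive_half_extent <- function(p) {
  s <- if (p$shape == "sphere") rep(p$size[1], 3) else p$size
  as.numeric(abs(p$orientation) %*% s)
}

primitive_contains <- function(p, pts) {
  q <- sweep(pts, 2L, p$center) %*% p$orientation  # world -> local
  s <- p$size
  switch(p$shape,
         sphere = rowSums(q^2) <= s[1]^2,
         ellipsoid = (q[, 1] / s[1])^2 + (q[, 2] / s[2])^2 +
           (q[, 3] / s[3])^2 <= 1,
         cuboid = abs(q[, 1]) <= s[1] & abs(q[, 2]) <= s[2] &
           abs(q[, 3]) <= s[3],
         cylinder = (q[, 1] / s[1])^2 + (q[, 2] / s[2])^2 <= 1 &
           abs(q[, 3]) <= s[3])
}

#' Phantom specification
#'
#' A list of primitives plus the voxel size at which [make_phantom()] will
#' rasterize them. Closed-form mass properties of the composite are exposed
#' by [analytic_mass_properties()]. Primitives are assumed non-overlapping
#' (tangency is allowed); overlap would double-count analytic mass.
#'
#' @param primitives list of [phantom_primitive()] objects (a single
#'   primitive may be passed bare).
#' @param voxel_size isotropic voxel size in mm.
#' @param margin empty border around the bounding box, in voxels.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(primitives, voxel_size = 0.5, margin = 2L) {
  if (inherits(primitives, "phantom_primitive")) primitives <- list(primitives)
  stopifnot(length(primitives) >= 1L,
            all(vapply(primitives, inherits, logical(1), "phantom_primitive")))
  if (voxel_size <= 0)
    stop_osteo("`voxel_size` must be positive", "osteo_format_error")
  structure(list(primitives = primitives, voxel_size = voxel_size,
                 margin = as.integer(margin)),
            class = "phantom_spec")
}

#' Closed-form mass properties of a phantom
#'
#' Per-primitive closed forms composed by the parallel-axis theorem about
#' the composite center of mass. Mass is volumetric: density (gray/1024)
#' times volume in mm^3.
#'
#' @param spec a [phantom_spec()].
#' @return A `mass_properties` object (see [mass_properties()]).
#' @export
analytic_mass_properties <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  ms <- vapply(spec$primitives, function(p)
    p$density_gray / GRAY_WATER * primitive_volume(p), numeric(1))
  centers <- t(vapply(spec$primitives, `[[`, numeric(3), "center"))
  M <- sum(ms)
  com <- colSums(centers * ms) / M
  I <- matrix(0, 3, 3)
  for (i in seq_along(spec$primitives)) {
    p <- spec$primitives[[i]]
    Il <- ms[i] * primitive_specific_inertia(p)
    Iw <- p$orientation %*% Il %*% t(p$orientation)
    d <- p$center - com
    I <- I + Iw + ms[i] * (sum(d^2) * diag(3) - outer(d, d))
  }
  ev <- eigen(I, symmetric = TRUE)
  ord <- order(ev$values)
  vecs <- ev$vectors[, ord, drop = FALSE]
  if (det(vecs) < 0) vecs[, 3] <- -vecs[, 3]
  structure(list(total_mass = M, com = com, inertia_tensor = I,
                 principal_moments = ev$values[ord], principal_axes = vecs,
                 weighting = "analytic"),
            class = "mass_properties")
}

#' Rasterize a phantom into a density volume
#'
#' Voxelization by center inclusion on a grid centered on the composite
#' bounding box (so symmetric bodies rasterize symmetrically and their voxel
#' center of mass is exact to rounding).
#'
#' @param spec a [phantom_spec()].
#' @return List with `volume` (a [density_volume()]), `mask` (a
#'   [bone_mask()]) and `analytic` (the closed-form [mass_properties()]).
#' @examples
#' ph <- make_phantom(phantom_spec(
#'   phantom_primitive("sphere", size = 10), voxel_size = 1))
#' ph$mask$voxel_count
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$voxel_size
  ext <- t(vapply(spec$primitives, primitive_half_extent, numeric(3)))
  centers <- t(vapply(spec$primitives, `[[`, numeric(3), "center"))
  lo <- apply(centers - ext, 2L, min)
  hi <- apply(centers + ext, 2L, max)
  cen <- (lo + hi) / 2
  n <- pmax(1L, as.integer(ceiling((hi - lo) / h))) + 2L * spec$margin
  origin <- cen - (n - 1) / 2 * h
  grid <- array(0, n)
  mask <- array(FALSE, n)
  ax <- lapply(1:3, function(k) origin[k] + (seq_len(n[k]) - 1) * h)
  for (p in spec$primitives) {
    he <- primitive_half_extent(p)
    rng <- lapply(1:3, function(k) {
      which(ax[[k]] >= p$center[k] - he[k] - h &
            ax[[k]] <= p$center[k] + he[k] + h)
    })
    if (any(lengths(rng) == 0L)) next
    pts <- as.matrix(expand.grid(ax[[1]][rng[[1]]], ax[[2]][rng[[2]]],
                                 ax[[3]][rng[[3]]]))
    inside <- primitive_contains(p, pts)
    if (!any(inside)) next
    sub <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))[inside, ,
                                                               drop = FALSE]
    grid[sub] <- p$density_gray
    mask[sub] <- TRUE
  }
  if (!any(mask))
    stop_osteo("voxel size too coarse: no voxel center falls inside any primitive",
               "osteo_format_error")
  list(volume = density_volume(grid, spacing = rep(h, 3), origin = origin),
       mask = bone_mask(mask),
       analytic = analytic_mass_properties(spec))
}

#' Stylized metatarsal phantom
#'
#' A tangent composition of an elliptical-cylinder shaft and two ellipsoidal
#' ends of different size (base larger than head), giving an elongated body
#' with three distinct principal moments, a nonzero mass skewness along the
#' long axis, and closed-form mass properties. Not an anatomical model: it
#' emulates the gross proportions that drive the positioning and
#' normalization pipeline.
#'
#' @param voxel_size voxel size in mm (default 0.4).
#' @param density_gray gray value of the solid; the default 1638.4
#'   corresponds to a relative bone density of 1.6.
#' @return A [phantom_spec()].
#' @export
metatarsal_phantom <- function(voxel_size = 0.4, density_gray = 1638.4) {
  phantom_spec(list(
    phantom_primitive("cylinder", center = c(0, 0, 0), size = c(4.5, 3.5, 20),
                      density_gray = density_gray),
    phantom_primitive("ellipsoid", center = c(0, 0, -27), size = c(8, 7, 7),
                      density_gray = density_gray),
    phantom_primitive("ellipsoid", center = c(0, 0, 26), size = c(6.5, 5.5, 6),
                      density_gray = density_gray)
  ), voxel_size = voxel_size)
}

#' Rigidly transform a phantom
#'
#' Rotates every primitive about `pivot` and translates it; the transformed
#' spec re-rasterizes at the same voxel size, which is how rigid-motion
#' equivariance of the measurement chain is exercised.
#'
#' @param spec a [phantom_spec()].
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 translation, mm.
#' @param pivot rotation pivot (default the analytic center of mass).
#' @return The transformed [phantom_spec()].
#' @export
transform_phantom <- function(spec, rotation = diag(3),
                              translation = c(0, 0, 0), pivot = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  pivot <- pivot %||% analytic_mass_properties(spec)$com
  prims <- lapply(spec$primitives, function(p) {
    p$center <- as.numeric(rotation %*% (p$center - pivot)) + pivot + translation
    p$orientation <- rotation %*% p$orientation
    p
  })
  phantom_spec(prims, spec$voxel_size, spec$margin)
}

#' Seeded random rigid motion of a phantom
#'
#' Draws a uniform random rotation (normalized quaternion) and a small
#' random translation (component-wise uniform in +/- 2 mm, exercising
#' sub-voxel phase), applies [transform_phantom()], and returns the applied
#' ground-truth transform.
#'
#' @param spec a [phantom_spec()].
#' @param seed optional integer seed for reproducibility.
#' @return List with `spec` (transformed), `rotation`, `translation`.
#' @export
random_rigid_transform <- function(spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  R <- quaternion_to_rotation(q)
  tr <- runif(3, -2, 2)
  list(spec = transform_phantom(spec, R, tr), rotation = R, translation = tr)
}

quaternion_to_rotation <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}
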