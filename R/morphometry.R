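## The eight per-bone variables: normalized length/width/height (fractions of
## the positioned extents), surface-area-to-volume ratio, bone density (mean
## gray / 1024) and the three normalized principal moments of inertia. Both
## normalized triplets are fractions summing to one; a percent display is a
## formatting choice, not a different quantity.

#' Extents of a positioned bone
#'
#' Max minus min of body-frame coordinates: length along z (the long axis),
#' width along y, height along x. Computed from surface-mesh vertices rather
#' than voxel centers to avoid half-voxel shrinkage.
#'
#' @param points n x 3 matrix of body-frame coordinates (mm), typically the
#'   surface vertices mapped through [to_body_frame()].
#' @return Named vector `c(Lp, Wp, Hp)` in mm.
#' @export
extents <- function(points) {
  p <- if (is.matrix(points)) points else matrix(points, ncol = 3L)
  if (nrow(p) < 4L || qr(sweep(p, 2L, colMeans(p)))$rank < 3L)
    stop_osteo("need at least 4 non-coplanar points to measure extents",
               "osteo_degenerate_error")
  r <- apply(p, 2L, range)
  ext <- unname(r[2, ] - r[1, ])
  c(Lp = ext[3], Wp = ext[2], Hp = ext[1])
}

#' Normalize a positive triplet to fractions
#'
#' Divides each component by the triplet sum, so the result sums to one. The
#' same operation normalizes the linear extents (Lp, Wp, Hp) and the three
#' principal moments; it makes the variables scale-free, removing the effect
#' of overall body size from both the linear and the inertial descriptors.
#'
#' @param a,b,c strictly positive quantities, or `a` a length-3 vector.
#' @param percent multiply by 100 for display (default `FALSE`; the internal
#'   representation is always the fraction form).
#' @return Numeric length-3 vector of fractions (or percent) summing to 1
#'   (or 100).
#' @examples
#' normalize_triplet(2, 1, 1)
#' @export
normalize_triplet <- function(a, b = NULL, c = NULL, percent = FALSE) {
  v <- if (is.null(b)) as.numeric(a) else c(a, b, c)
  if (length(v) != 3L || any(!is.finite(v)) || any(v <= 0))
    stop_osteo("triplet components must be three strictly positive numbers",
               "osteo_format_error")
  out <- v / sum(v)
  if (percent) out * 100 else out
}

#' Surface-area-to-volume ratio
#'
#' @param S surface area, mm^2.
#' @param V enclosed volume, mm^3 (> 0).
#' @return S / V in 1/mm.
#' @export
sa_to_v <- function(S, V) {
  if (!is.finite(V) || V <= 0)
    stop_osteo("volume must be strictly positive", "osteo_format_error")
  if (!is.finite(S) || S <= 0)
    stop_osteo("surface area must be strictly positive", "osteo_format_error")
  S / V
}

#' Mean bone density of a segmented volume
#'
#' The density of each voxel is its gray value over the water gray value
#' (1024); the bone density is the mean over the N masked voxels. It is a
#' dimensionless HU-derived ratio (water = 1), not a calibrated mineral
#' density.
#'
#' @inheritParams mass_properties
#' @return Mean relative density (numeric scalar).
#' @export
bone_density <- function(volume, mask) {
  stopifnot(inherits(volume, "density_volume"))
  m <- as_mask_array(mask)
  idx <- which(m)
  if (length(idx) == 0L)
    stop_osteo("mask is empty", "osteo_segmentation_empty")
  mean(volume$grid[idx]) / GRAY_WATER
}

#' Measure the eight bone variables of a segmented bone
#'
#' Full measurement chain: density-weighted mass properties, body frame from
#' the principal axes, surface extraction, positioned extents, and the
#' normalized linear and inertial triplets plus SA:V and bone density.
#'
#' @inheritParams mass_properties
#' @param anatomical_refs optional 3x3 matrix of approximate x, y, z body
#'   directions in the scanner frame (see [principal_frame()]).
#' @param subject_id,sex,side,metatarsal metadata carried into the record.
#' @param volume_from `"mesh"` (default) uses the mesh-enclosed volume for
#'   SA:V; `"voxels"` uses `N * voxel volume`.
#' @param smoothing passed to [extract_surface()].
#' @return A one-row `data.frame` of class `bone_record` with columns
#'   `subject_id, sex, side, metatarsal, Ln, Wn, Hn, sa_v, density,
#'   pmi_x, pmi_y, pmi_z` plus the raw `Lp, Wp, Hp, S, V` in mm units.
#' @export
measure_bone <- function(volume, mask, anatomical_refs = NULL,
                         weighting = c("gray", "uniform"),
                         subject_id = NA_character_,
                         sex = c("unknown", "male", "female"),
                         side = c("left", "right"), metatarsal = NA_integer_,
                         volume_from = c("mesh", "voxels"), smoothing = TRUE) {
  weighting <- match.arg(weighting)
  sex <- match.arg(sex)
  side <- match.arg(side)
  volume_from <- match.arg(volume_from)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_osteo(sprintf("[%s] %s", name, conditionMessage(e)),
                 "osteo_stage_error")
    })
  }
  props <- stage("mass_properties", mass_properties(volume, mask, weighting))
  frame <- stage("principal_frame", {
    ## without references, fix the z sign from the mass skewness along the
    ## candidate long axis (head/base asymmetry); a stand-in convention
    sk <- if (is.null(anatomical_refs)) {
      idx <- which(as_mask_array(mask))
      w <- if (weighting == "gray") volume$grid[idx] / GRAY_WATER else 1
      pts <- voxel_centers(volume, idx)
      zc <- sweep(pts, 2L, props$com) %*% props$principal_axes[, 1]
      sum(w * zc^3)
    } else NULL
    principal_frame(props, anatomical_refs, skewness = sk)
  })
  mesh <- stage("extract_surface", extract_surface(
    mask, spacing = volume$spacing, origin = volume$origin,
    smoothing = smoothing, check_watertight = FALSE))
  if (!identical(volume$orientation, diag(3)))
    mesh$vertices <- sweep(mesh$vertices %*% t(volume$orientation), 2L,
                           volume$origin - volume$orientation %*% volume$origin,
                           `+`)
  sv <- stage("surface_and_volume", surface_and_volume(mesh))
  body_pts <- stage("to_body_frame", to_body_frame(mesh$vertices, frame))
  ext <- stage("extents", extents(body_pts))
  lin <- normalize_triplet(ext[["Lp"]], ext[["Wp"]], ext[["Hp"]])
  pmi <- normalize_triplet(frame$axis_moments[["pmi_x"]],
                           frame$axis_moments[["pmi_y"]],
                           frame$axis_moments[["pmi_z"]])
  V_use <- if (volume_from == "mesh") sv[["V"]] else
    sum(as_mask_array(mask)) * prod(volume$spacing)
  rec <- data.frame(subject_id = subject_id, sex = sex, side = side,
                    metatarsal = metatarsal,
                    Ln = lin[1], Wn = lin[2], Hn = lin[3],
                    sa_v = sa_to_v(sv[["S"]], V_use),
                    density = bone_density(volume, mask),
                    pmi_x = pmi[1], pmi_y = pmi[2], pmi_z = pmi[3],
                    Lp = ext[["Lp"]], Wp = ext[["Wp"]], Hp = ext[["Hp"]],
                    S = sv[["S"]], V = V_use,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(rec) <- c("bone_record", class(rec))
  rec
}

#' @export
print.bone_record <- function(x, ...) {
  cat(sprintf("<bone_record> %s MT%s (%s)\n", x$side, format(x$metatarsal),
              x$sex))
  v <- unlist(x[c("Ln", "Wn", "Hn", "sa_v", "density",
                  "pmi_x", "pmi_y", "pmi_z")])
  print(round(v, 4))
  invisible(x)
}

BONE_VARIABLES <- c("Ln", "Wn", "Hn", "sa_v", "density",
                    "pmi_x", "pmi_y", "pmi_z")

#' Names of the eight bone variables
#'
#' @return Character vector: `Ln, Wn, Hn, sa_v, density, pmi_x, pmi_y, pmi_z`.
#' @export
bone_variables <- function() BONE_VARIABLES
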