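## Density volumes: gridded gray values plus the geometry needed to place
## voxel centers in the scanner frame. Physical coordinates of voxel (i,j,k)
## (1-based array index) are origin + orientation %*% ((index - 1) * spacing),
## i.e. `origin` is the physical position of the first voxel center.

#' Construct a density volume
#'
#' A density volume is a 3D grid of gray values together with voxel spacing,
#' origin and an orientation (direction cosine) matrix. Gray values use the
#' calibration in which air maps to 0 and water to 1024; see [hu_to_gray()].
#'
#' @param grid 3D numeric array of gray values.
#' @param spacing numeric length-3, voxel size along each axis in mm
#'   (strictly positive).
#' @param origin numeric length-3, physical position (mm) of the center of
#'   voxel `[1,1,1]`.
#' @param orientation 3x3 direction cosine matrix (orthonormal, det +1);
#'   columns are the physical directions of the array axes.
#' @return An object of class `density_volume`.
#' @examples
#' v <- density_volume(array(0, c(4, 4, 4)), spacing = c(1, 1, 1))
#' dim(v$grid)
#' @export
density_volume <- function(grid, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                           orientation = diag(3)) {
  if (!is.array(grid) || length(dim(grid)) != 3L)
    stop_osteo("`grid` must be a 3D array", "osteo_format_error")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop_osteo("`spacing` must be three strictly positive voxel sizes (mm)",
               "osteo_format_error")
  origin <- as.numeric(origin)
  if (length(origin) != 3L)
    stop_osteo("`origin` must be a length-3 position (mm)", "osteo_format_error")
  orientation <- as.matrix(orientation)
  if (!all(dim(orientation) == c(3L, 3L)) ||
      max(abs(crossprod(orientation) - diag(3))) > 1e-6 ||
      det(orientation) < 0)
    stop_osteo("`orientation` must be orthonormal with determinant +1",
               "osteo_format_error")
  structure(list(grid = grid, spacing = spacing, origin = origin,
                 orientation = orientation),
            class = "density_volume")
}

#' @export
print.density_volume <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("<density_volume> %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x ")))
  cat(sprintf("  gray range [%.1f, %.1f], origin (%s) mm\n",
              min(x$grid), max(x$grid),
              paste(signif(x$origin, 4), collapse = ", ")))
  invisible(x)
}

#' Convert between Hounsfield units and gray values
#'
#' The gray scale is anchored by two calibration points: air (-1024 HU) maps
#' to gray 0 and water (0 HU) maps to gray 1024, so `gray = hu + 1024`.
#' The calibrated range is -1024 to 4145 HU (gray 0 to 5169).
#'
#' @param hu numeric vector of Hounsfield units in `[-1024, 4145]`.
#' @param gray numeric vector of gray values in `[0, 5169]`.
#' @return The converted numeric vector.
#' @examples
#' hu_to_gray(c(-1024, 0, 120))  # 0, 1024, 1144
#' gray_to_hu(1024)              # 0
#' @export
hu_to_gray <- function(hu) {
  hu <- as.numeric(hu)
  if (any(!is.finite(hu)) || any(hu < HU_MIN) || any(hu > HU_MAX))
    stop_osteo(sprintf("HU values must lie in the calibrated range [%d, %d]",
                       HU_MIN, HU_MAX), "osteo_range_error")
  hu + GRAY_WATER
}

#' @rdname hu_to_gray
#' @export
gray_to_hu <- function(gray) {
  gray <- as.numeric(gray)
  if (any(!is.finite(gray)) || any(gray < 0) || any(gray > HU_MAX + GRAY_WATER))
    stop_osteo(sprintf("gray values must lie in [0, %d]", HU_MAX + GRAY_WATER),
               "osteo_range_error")
  gray - GRAY_WATER
}

#' Read a density volume from disk
#'
#' Supports NIfTI (.nii / .nii.gz) and MetaImage (.mha, or .mhd with a raw
#' data file). Values already stored on the gray scale are kept as-is; pass
#' `values = "hu"` for files storing Hounsfield units, which are converted
#' with [hu_to_gray()]. DICOM series are not supported by this build.
#'
#' @param path file path.
#' @param format one of `"nifti"`, `"metaimage"`, `"dicom_dir"`; the default
#'   guesses from the file extension.
#' @param values `"gray"` (default) or `"hu"`.
#' @return A [density_volume()].
#' @export
load_volume <- function(path, format = c("auto", "nifti", "metaimage", "dicom_dir"),
                        values = c("gray", "hu")) {
  format <- match.arg(format)
  values <- match.arg(values)
  if (format == "auto") {
    format <- if (grepl("\\.(mha|mhd)$", path, ignore.case = TRUE))
      "metaimage" else if (dir.exists(path)) "dicom_dir" else "nifti"
  }
  if (format == "dicom_dir")
    stop_osteo("DICOM series input is not supported; convert the series to NIfTI or MetaImage first",
               "osteo_format_error")
  if (!file.exists(path))
    stop_osteo(sprintf("file not found: %s", path), "osteo_io_error")
  vol <- switch(format,
    nifti = read_nifti_volume(path),
    metaimage = read_metaimage_volume(path)
  )
  if (values == "hu") vol$grid[] <- hu_to_gray(vol$grid)
  vol
}

read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L)
    stop_osteo(sprintf("expected a 3D image, got %d dimensions (field `dim`)",
                       length(dim(arr))), "osteo_format_error")
  pd <- attr(img, "pixdim") %||% RNifti::pixdim(img)
  if (is.null(pd) || length(pd) < 3L)
    stop_osteo("NIfTI header lacks voxel spacing (field `pixdim`)",
               "osteo_format_error")
  density_volume(arr, spacing = pd[1:3])
}

#' Write a density volume to disk
#'
#' @param volume a [density_volume()].
#' @param path output path; extension selects NIfTI (.nii/.nii.gz) or
#'   MetaImage (.mha/.mhd).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "density_volume"))
  if (grepl("\\.(mha|mhd)$", path, ignore.case = TRUE)) {
    write_metaimage_volume(volume, path)
  } else {
    img <- RNifti::asNifti(volume$grid)
    RNifti::pixdim(img) <- volume$spacing
    RNifti::writeNifti(img, path)
  }
  invisible(path)
}

## Minimal MetaImage IO: plain-text header followed by (or pointing to) a
## little-endian raw block. Covers the uncompressed scalar types we emit.
META_TYPES <- list(MET_UCHAR = list(what = "integer", size = 1L, signed = FALSE),
                   MET_SHORT = list(what = "integer", size = 2L, signed = TRUE),
                   MET_FLOAT = list(what = "numeric", size = 4L, signed = TRUE),
                   MET_DOUBLE = list(what = "numeric", size = 8L, signed = TRUE))

read_metaimage_volume <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L)
      stop_osteo("MetaImage header ended before ElementDataFile", "osteo_format_error")
    kv <- regmatches(line, regexec("^\\s*([A-Za-z0-9]+)\\s*=\\s*(.*)$", line))[[1]]
    if (length(kv) != 3L) next
    hdr[[kv[2]]] <- trimws(kv[3])
    if (kv[2] == "ElementDataFile") break
  }
  ndims <- as.integer(hdr$NDims %||% NA)
  if (is.na(ndims) || ndims != 3L)
    stop_osteo(sprintf("expected NDims = 3, got %s (field `NDims`)",
                       hdr$NDims %||% "<missing>"), "osteo_format_error")
  dims <- as.integer(strsplit(hdr$DimSize %||% "", "\\s+")[[1]])
  if (length(dims) != 3L || any(is.na(dims)))
    stop_osteo("missing or malformed field `DimSize`", "osteo_format_error")
  spacing <- as.numeric(strsplit(hdr$ElementSpacing %||% hdr$ElementSize %||% "",
                                 "\\s+")[[1]])
  if (length(spacing) != 3L || any(is.na(spacing)))
    stop_osteo("missing field `ElementSpacing`", "osteo_format_error")
  origin <- as.numeric(strsplit(hdr$Offset %||% "0 0 0", "\\s+")[[1]])
  tm <- as.numeric(strsplit(hdr$TransformMatrix %||% "1 0 0 0 1 0 0 0 1",
                            "\\s+")[[1]])
  typ <- META_TYPES[[hdr$ElementType %||% ""]]
  if (is.null(typ))
    stop_osteo(sprintf("unsupported ElementType `%s`", hdr$ElementType %||% "<missing>"),
               "osteo_format_error")
  if (!identical(tolower(hdr[["CompressedData"]] %||% "false"), "false"))
    stop_osteo("compressed MetaImage data is not supported", "osteo_format_error")
  n <- prod(dims)
  if (identical(hdr$ElementDataFile, "LOCAL")) {
    vals <- readBin(con, typ$what, n = n, size = typ$size, signed = typ$signed,
                    endian = "little")
  } else {
    raw_path <- file.path(dirname(path), hdr$ElementDataFile)
    if (!file.exists(raw_path))
      stop_osteo(sprintf("raw data file not found: %s", raw_path), "osteo_io_error")
    rcon <- file(raw_path, "rb")
    on.exit(close(rcon), add = TRUE)
    vals <- readBin(rcon, typ$what, n = n, size = typ$size, signed = typ$signed,
                    endian = "little")
  }
  if (length(vals) != n)
    stop_osteo("MetaImage data block shorter than DimSize implies", "osteo_format_error")
  density_volume(array(as.numeric(vals), dims), spacing = spacing,
                 origin = origin, orientation = matrix(tm, 3, 3, byrow = TRUE))
}

write_metaimage_volume <- function(volume, path) {
  d <- dim(volume$grid)
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           "CompressedData = False",
           sprintf("TransformMatrix = %s",
                   paste(format(t(volume$orientation), trim = TRUE), collapse = " ")),
           sprintf("Offset = %s", paste(format(volume$origin, trim = TRUE), collapse = " ")),
           sprintf("ElementSpacing = %s",
                   paste(format(volume$spacing, trim = TRUE), collapse = " ")),
           sprintf("DimSize = %d %d %d", d[1], d[2], d[3]),
           "ElementType = MET_DOUBLE")
  if (grepl("\\.mha$", path, ignore.case = TRUE)) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(c(hdr, "ElementDataFile = LOCAL"), con)
    writeBin(as.numeric(volume$grid), con, size = 8L, endian = "little")
  } else {
    raw_name <- sub("\\.mhd$", ".raw", basename(path), ignore.case = TRUE)
    writeLines(c(hdr, sprintf("ElementDataFile = %s", raw_name)), path)
    con <- file(file.path(dirname(path), raw_name), "wb")
    on.exit(close(con))
    writeBin(as.numeric(volume$grid), con, size = 8L, endian = "little")
  }
  invisible(path)
}

#' Construct a bone mask
#'
#' @param mask 3D logical array, congruent with its density volume.
#' @return An object of class `bone_mask` with elements `mask` and
#'   `voxel_count`.
#' @export
bone_mask <- function(mask) {
  if (!is.array(mask) || length(dim(mask)) != 3L || !is.logical(mask))
    stop_osteo("`mask` must be a 3D logical array", "osteo_format_error")
  structure(list(mask = mask, voxel_count = sum(mask)), class = "bone_mask")
}

#' @export
print.bone_mask <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf("<bone_mask> %d x %d x %d, %d voxels set\n",
              d[1], d[2], d[3], x$voxel_count))
  invisible(x)
}

as_mask_array <- function(mask) {
  if (inherits(mask, "bone_mask")) mask$mask else mask
}

## -- 3D binary morphology -----------------------------------------------

shift3 <- function(a, s, fill = FALSE) {
  d <- dim(a)
  out <- array(fill, d)
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    if (s[ax] >= 0) {
      src[[ax]] <- seq_len(d[ax] - s[ax])
      dst[[ax]] <- src[[ax]] + s[ax]
    } else {
      src[[ax]] <- seq(1 - s[ax], d[ax])
      dst[[ax]] <- src[[ax]] + s[ax]
    }
    if (length(src[[ax]]) == 0L) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

ball_offsets <- function(radius) {
  r <- as.integer(radius)
  g <- expand.grid(x = -r:r, y = -r:r, z = -r:r)
  g <- g[g$x^2 + g$y^2 + g$z^2 <= radius^2 + 1e-9, , drop = FALSE]
  as.matrix(g)
}

dilate3 <- function(mask, offsets) {
  out <- array(FALSE, dim(mask))
  for (i in seq_len(nrow(offsets)))
    out <- out | shift3(mask, offsets[i, ], fill = FALSE)
  out
}

erode3 <- function(mask, offsets, pad_value = FALSE) {
  out <- array(TRUE, dim(mask))
  for (i in seq_len(nrow(offsets)))
    out <- out & shift3(mask, offsets[i, ], fill = pad_value)
  out
}

pad3 <- function(a, n, fill = FALSE) {
  d <- dim(a)
  out <- array(fill, d + 2L * n)
  out[(n + 1):(n + d[1]), (n + 1):(n + d[2]), (n + 1):(n + d[3])] <- a
  out
}

unpad3 <- function(a, n, d) {
  a[(n + 1):(n + d[1]), (n + 1):(n + d[2]), (n + 1):(n + d[3])]
}

close3 <- function(mask, radius) {
  if (radius <= 0) return(mask)
  off <- ball_offsets(radius)
  d <- dim(mask)
  m <- pad3(mask, as.integer(ceiling(radius)))
  m <- erode3(dilate3(m, off), off, pad_value = FALSE)
  unpad3(m, as.integer(ceiling(radius)), d)
}

fill_holes3 <- function(mask) {
  ## background flood fill from the border; anything not reached is a hole
  outside <- array(FALSE, dim(mask) + 2L)
  bg <- pad3(!mask, 1L, fill = TRUE)
  outside[1, , ] <- TRUE; outside[dim(outside)[1], , ] <- TRUE
  outside[, 1, ] <- TRUE; outside[, dim(outside)[2], ] <- TRUE
  outside[, , 1] <- TRUE; outside[, , dim(outside)[3]] <- TRUE
  outside <- outside & bg
  off <- ball_offsets(1)
  repeat {
    grown <- dilate3(outside, off) & bg
    if (sum(grown) == sum(outside)) break
    outside <- grown
  }
  !unpad3(outside, 1L, dim(mask))
}

largest_component3 <- function(mask) {
  off <- ball_offsets(1)  # 6-connectivity
  off <- off[rowSums(abs(off)) <= 1, , drop = FALSE]
  remaining <- mask
  best <- NULL
  best_n <- 0L
  while (any(remaining)) {
    seed <- array(FALSE, dim(mask))
    seed[which(remaining)[1]] <- TRUE
    repeat {
      grown <- dilate3(seed, off) & remaining
      if (sum(grown) == sum(seed)) break
      seed <- grown
    }
    n <- sum(seed)
    if (n > best_n) { best <- seed; best_n <- n }
    remaining <- remaining & !seed
  }
  best %||% mask
}

#' Segment a bone by thresholding and morphological closing
#'
#' Thresholds the gray-value grid at `lower <= grid <= upper`, then applies a
#' binary morphological "close" with a discrete ball structuring element.
#' Matching the reconstruction protocol this emulates, hole filling and
#' largest-component filtering are *off* by default and available as
#' explicit opt-ins.
#'
#' @param volume a [density_volume()].
#' @param lower,upper gray-value thresholds (`lower < upper`). There is no
#'   default: the bone threshold is scanner- and protocol-specific.
#' @param close_radius radius (voxels) of the ball used for closing; 0
#'   disables closing.
#' @param fill_holes fill fully enclosed cavities (off by default).
#' @param keep_largest keep only the largest 6-connected component (off by
#'   default).
#' @return A [bone_mask()].
#' @examples
#' v <- density_volume(array(2000, c(5, 5, 5)))
#' m <- segment_bone(v, lower = 1300, upper = 5169, close_radius = 0)
#' m$voxel_count
#' @export
segment_bone <- function(volume, lower, upper, close_radius = 1,
                         fill_holes = FALSE, keep_largest = FALSE) {
  stopifnot(inherits(volume, "density_volume"))
  if (missing(lower) || missing(upper))
    stop_osteo("both `lower` and `upper` gray thresholds are required",
               "osteo_format_error")
  if (!(lower < upper))
    stop_osteo("`lower` must be strictly below `upper`", "osteo_format_error")
  if (close_radius < 0)
    stop_osteo("`close_radius` must be >= 0", "osteo_format_error")
  m <- volume$grid >= lower & volume$grid <= upper
  if (!any(m))
    stop_osteo("thresholding produced an empty mask", "osteo_segmentation_empty")
  m <- close3(m, close_radius)
  if (fill_holes) m <- fill_holes3(m)
  if (keep_largest) m <- largest_component3(m)
  bone_mask(m)
}
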