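#' Lung window specification
#'
#' CT display windowing with the lung-window defaults used throughout the
#' pipeline: width 1200 HU, level -600 HU, so that -1200 HU maps to 0 and
#' 0 HU maps to 1.
#'
#' @param width_hu window width in HU (> 0).
#' @param level_hu window level (center) in HU.
#' @return object of class `window_spec`.
#' @export
window_spec <- function(width_hu = 1200, level_hu = -600) {
  assert_that(width_hu > 0, "window width must be positive")
  structure(list(width_hu = width_hu, level_hu = level_hu), class = "window_spec")
}

#' Normalize a volume to [0, 1] with a display window
#'
#' `v' = clip((v - (level - width/2)) / width, 0, 1)`. A total function:
#' values outside the window clip to 0 or 1.
#'
#' @param volume a [ct_volume()] or bare numeric array.
#' @param spec a [window_spec()].
#' @return same container type with values in \[0, 1\].
#' @export
apply_window <- function(volume, spec = window_spec()) {
  arr <- if (inherits(volume, "ct_volume")) volume$data else volume
  assert_that(all(is.finite(arr)), "volume must be finite")
  lo <- spec$level_hu - spec$width_hu / 2
  out <- pmin(pmax((arr - lo) / spec$width_hu, 0), 1)
  if (inherits(volume, "ct_volume")) {
    volume$data <- array(out, dim = dim(arr))
    volume
  } else {
    array(out, dim = dim(arr))
  }
}

# Cubic-spline interpolation of a 3D array along one axis onto new
# fractional voxel-center coordinates (in units of input voxels).
interp_axis <- function(a, axis, new_coords, method = c("spline", "nearest")) {
  method <- match.arg(method)
  d <- dim(a)
  n <- d[axis]
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  ap <- aperm(a, perm)
  m <- matrix(ap, nrow = n)
  if (method == "nearest") {
    idx <- pmin(pmax(round(new_coords), 1), n)
    out <- m[idx, , drop = FALSE]
  } else if (n < 4) {
    out <- apply(m, 2, function(col) {
      stats::approx(seq_len(n), col, xout = pmin(pmax(new_coords, 1), n), rule = 2)$y
    })
    out <- matrix(out, nrow = length(new_coords))
  } else {
    xs <- pmin(pmax(new_coords, 1), n)
    out <- apply(m, 2, function(col) stats::splinefun(seq_len(n), col, method = "natural")(xs))
    out <- matrix(out, nrow = length(new_coords))
  }
  dn <- d[perm]
  dn[1] <- length(new_coords)
  res <- array(out, dim = dn)
  aperm(res, order(perm))
}

#' Resample a volume (and optionally its mask) to isotropic spacing
#'
#' Images are interpolated with a cubic spline applied per axis; masks use
#' nearest-neighbor interpolation and remain binary. Output shape is
#' `round(input_shape * input_spacing / target_spacing)`.
#'
#' @param volume a [ct_volume()] (its `spacing_mm` must be set).
#' @param mask optional congruent [roi_mask()].
#' @param target_spacing_mm target spacing, default 1 mm isotropic.
#' @return list with resampled `volume` and (if given) `mask`.
#' @export
resample_isotropic <- function(volume, mask = NULL, target_spacing_mm = c(1, 1, 1)) {
  assert_that(inherits(volume, "ct_volume"), "volume must be a ct_volume")
  sp <- volume$spacing_mm
  assert_that(length(sp) == 3 && all(is.finite(sp)) && all(sp > 0),
              "volume is missing valid spacing metadata")
  d <- dim(volume$data)
  new_shape <- pmax(1L, as.integer(round(d * sp / target_spacing_mm)))
  if (all(new_shape == d) && all(abs(sp - target_spacing_mm) < 1e-12)) {
    out <- list(volume = volume)
    if (!is.null(mask)) out$mask <- mask
    return(out)
  }
  coords <- lapply(1:3, function(ax) {
    # voxel-center alignment: world position of output center j is
    # (j - 0.5) * target; input index = position / sp + 0.5
    ((seq_len(new_shape[ax]) - 0.5) * target_spacing_mm[ax]) / sp[ax] + 0.5
  })
  arr <- volume$data
  for (ax in 1:3) arr <- interp_axis(arr, ax, coords[[ax]], "spline")
  res <- list(volume = ct_volume(arr, target_spacing_mm))
  if (!is.null(mask)) {
    mar <- mask$data * 1
    for (ax in 1:3) mar <- interp_axis(mar, ax, coords[[ax]], "nearest")
    res$mask <- roi_mask(mar > 0.5, target_spacing_mm, mask$rater_id)
  }
  res
}

#' Network input patch specification
#'
#' @param mode one of "2D", "2.5D", "3D".
#' @param side_voxels output side length: resize target for 2D/2.5D
#'   (default 224), cube side for 3D (default 64).
#' @param margin_voxels margin kept around the ROI bounding box for
#'   2D/2.5D crops (default 10).
#' @return object of class `patch_spec`.
#' @export
patch_spec <- function(mode = c("2.5D", "2D", "3D"), side_voxels = NULL,
                       margin_voxels = 10L) {
  mode <- match.arg(mode)
  if (is.null(side_voxels)) side_voxels <- if (mode == "3D") 64L else 224L
  assert_that(side_voxels >= 16, "side must be >= 16")
  structure(list(mode = mode, side_voxels = as.integer(side_voxels),
                 margin_voxels = as.integer(margin_voxels)),
            class = "patch_spec")
}

# Bilinear resize of a 2D matrix to side x side.
resize_bilinear <- function(m, side) {
  d <- dim(m)
  xi <- (seq_len(side) - 0.5) * d[1] / side + 0.5
  yi <- (seq_len(side) - 0.5) * d[2] / side + 0.5
  x0 <- pmin(pmax(floor(xi), 1), d[1]); x1 <- pmin(x0 + 1, d[1]); fx <- pmin(pmax(xi - x0, 0), 1)
  y0 <- pmin(pmax(floor(yi), 1), d[2]); y1 <- pmin(y0 + 1, d[2]); fy <- pmin(pmax(yi - y0, 0), 1)
  a <- m[x0, y0, drop = FALSE]; b <- m[x1, y0, drop = FALSE]
  c_ <- m[x0, y1, drop = FALSE]; e <- m[x1, y1, drop = FALSE]
  top <- a * (1 - fx) + b * fx
  bot <- c_ * (1 - fx) + e * fx
  top * rep(1 - fy, each = side) + bot * rep(fy, each = side)
}

# Crop arr[z, y, x] with zero padding for out-of-bounds indices.
crop_padded <- function(arr, zr, yr, xr) {
  d <- dim(arr)
  out <- array(0, dim = c(length(zr), length(yr), length(xr)))
  okz <- zr >= 1 & zr <= d[1]; oky <- yr >= 1 & yr <= d[2]; okx <- xr >= 1 & xr <= d[3]
  out[okz, oky, okx] <- arr[zr[okz], yr[oky], xr[okx]]
  out
}

#' Extract a network input patch around the ROI
#'
#' 2D: the axial slice maximizing ROI area, cropped around the ROI bounding
#' box with margin and bilinearly resized. 2.5D: that slice plus its
#' superior and inferior neighbors stacked as 3 channels. 3D: a cube of
#' `side_voxels` centered on the ROI centroid. Out-of-bounds regions are
#' zero padded.
#'
#' @param volume windowed, resampled [ct_volume()] (or bare array).
#' @param mask congruent [roi_mask()] (or logical array).
#' @param spec a [patch_spec()].
#' @return for 2D/2.5D an array (side, side, channels); for 3D an array
#'   (side, side, side, 1).
#' @export
extract_patch <- function(volume, mask, spec = patch_spec()) {
  arr <- if (inherits(volume, "ct_volume")) volume$data else volume
  m <- if (inherits(mask, "roi_mask")) mask$data else mask
  assert_that(sum(m) > 0, "empty mask")
  if (spec$mode == "3D") {
    cen <- round(colMeans(mask_coords(m)))
    half <- spec$side_voxels %/% 2
    zr <- (cen[1] - half):(cen[1] + half - 1 + spec$side_voxels %% 2)
    yr <- (cen[2] - half):(cen[2] + half - 1 + spec$side_voxels %% 2)
    xr <- (cen[3] - half):(cen[3] + half - 1 + spec$side_voxels %% 2)
    cube <- crop_padded(arr, zr, yr, xr)
    return(array(cube, dim = c(dim(cube), 1)))
  }
  areas <- apply(m, 1, sum)
  zi <- which.max(areas)
  idx <- which(m[zi, , ], arr.ind = TRUE)
  mg <- spec$margin_voxels
  yr <- (min(idx[, 1]) - mg):(max(idx[, 1]) + mg)
  xr <- (min(idx[, 2]) - mg):(max(idx[, 2]) + mg)
  slices <- if (spec$mode == "2D") zi else c(zi - 1, zi, zi + 1)
  chans <- lapply(slices, function(z) {
    sl <- crop_padded(arr, z, yr, xr)[1, , ]
    resize_bilinear(matrix(sl, nrow = length(yr)), spec$side_voxels)
  })
  out <- array(0, dim = c(spec$side_voxels, spec$side_voxels, length(chans)))
  for (i in seq_along(chans)) out[, , i] <- chans[[i]]
  if (spec$mode == "2D") out <- out[, , c(1, 1, 1), drop = FALSE] # replicate to 3 channels
  out
}
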