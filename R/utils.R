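# Internal helpers shared across modules. Arrays are 3D, indexed [z, y, x],
# 0-based voxel coordinates in the user-facing records, world spacing in mm.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so library code never disturbs user randomness.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream seed from a master seed and a small index, keeping the
# result inside the 32-bit integer range.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 7919 + as.double(index) * 104729) %% 2147483647)
}

# Shift a 3D array by (dz, dy, dx), filling exposed planes with `fill`.
shift3d <- function(a, dz, dy, dx, fill = NA_real_) {
  d <- dim(a)
  out <- array(fill, dim = d)
  src_z <- seq_len(d[1]) - dz; src_y <- seq_len(d[2]) - dy; src_x <- seq_len(d[3]) - dx
  ok_z <- src_z >= 1 & src_z <= d[1]
  ok_y <- src_y >= 1 & src_y <= d[2]
  ok_x <- src_x >= 1 & src_x <= d[3]
  out[ok_z, ok_y, ok_x] <- a[src_z[ok_z], src_y[ok_y], src_x[ok_x]]
  out
}

# Integer offsets of a discrete ball of radius r (in voxels, possibly
# anisotropic spacing); includes the origin.
ball_offsets <- function(radius_mm, spacing = c(1, 1, 1)) {
  r_vox <- ceiling(radius_mm / spacing)
  g <- expand.grid(dz = -r_vox[1]:r_vox[1], dy = -r_vox[2]:r_vox[2], dx = -r_vox[3]:r_vox[3])
  d2 <- (g$dz * spacing[1])^2 + (g$dy * spacing[2])^2 + (g$dx * spacing[3])^2
  g[d2 <= radius_mm^2 + 1e-9, , drop = FALSE]
}

# Binary dilation/erosion with a euclidean ball.
dilate3d <- function(mask, radius_mm, spacing = c(1, 1, 1)) {
  if (radius_mm <= 0) return(mask)
  offs <- ball_offsets(radius_mm, spacing)
  acc <- array(FALSE, dim = dim(mask))
  for (i in seq_len(nrow(offs))) {
    acc <- acc | shift3d(mask, offs$dz[i], offs$dy[i], offs$dx[i], fill = FALSE)
  }
  acc
}

erode3d <- function(mask, radius_mm, spacing = c(1, 1, 1)) {
  if (radius_mm <= 0) return(mask)
  !dilate3d(!mask, radius_mm, spacing)
}

# Voxel coordinates (z, y, x; 1-based matrix indices) of TRUE entries,
# in column-major scan order so row order is reproducible.
mask_coords <- function(mask) {
  which(mask, arr.ind = TRUE)
}

dice_coefficient <- function(a, b) {
  2 * sum(a & b) / (sum(a) + sum(b))
}

# Boundary voxels: in-mask voxels with at least one 6-neighbor outside.
mask_boundary <- function(mask) {
  inner <- mask
  for (d in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))) {
    inner <- inner & shift3d(mask, d[1], d[2], d[3], fill = FALSE)
  }
  mask & !inner
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stopf(fmt, ...)
  invisible(TRUE)
}

# Light-weight deterministic checksum of an R object (training manifests,
# frozen transforms) without external digest dependencies. Two weighted
# byte sums plus the length: ample for bookkeeping equality checks.
object_checksum <- function(x) {
  raw <- as.integer(serialize(x, connection = NULL, version = 2))
  n <- length(raw)
  w <- rep_len(as.double(1:127), n)
  s1 <- sum(as.double(raw) * w) %% 2147483647
  s2 <- sum(as.double(raw) * rev(w)) %% 2147483647
  sprintf("%d-%.0f-%.0f", n, s1, s2)
}
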