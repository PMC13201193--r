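# Image filters feeding the radiomics extractor. All operate on a cropped
# HU sub-volume; intensity rescaling follows the usual extractor
# conventions (outputs of the nonlinear transforms are rescaled back into
# the input's dynamic range).

filter_image <- function(arr, name, spacing) {
  switch(name,
    original = arr,
    log_sigma_1_0_mm_3D = laplacian3d(gauss_smooth(arr, 1, spacing), spacing),
    log_sigma_2_0_mm_3D = laplacian3d(gauss_smooth(arr, 2, spacing), spacing),
    log_sigma_3_0_mm_3D = laplacian3d(gauss_smooth(arr, 3, spacing), spacing),
    gradient = gradient_magnitude3d(arr, spacing),
    exponential = {
      mx <- max(abs(arr))
      if (mx == 0) arr else exp(log(mx) / mx * arr)
    },
    square = {
      mx <- max(abs(arr))
      if (mx == 0) arr else arr^2 / mx
    },
    squareroot = {
      mx <- max(abs(arr))
      if (mx == 0) arr else sign(arr) * sqrt(abs(arr) * mx)
    },
    logarithm = {
      mx <- max(abs(arr))
      if (mx == 0) arr else sign(arr) * log(abs(arr) + 1) * mx / log(mx + 1)
    },
    {
      if (grepl("^wavelet_", name)) haar_subband(arr, sub("wavelet_", "", name))
      else stopf("unknown filter '%s'", name)
    }
  )
}

# Undecimated single-level 3D Haar decomposition. `bands` is a 3-letter
# code (applied along z, y, x): L = smoothing pair, H = detail pair.
haar_subband <- function(arr, bands) {
  stopifnot(nchar(bands) == 3)
  out <- arr
  for (ax in 1:3) {
    b <- substr(bands, ax, ax)
    d <- c(0, 0, 0); d[ax] <- 1
    sh <- shift3d(out, d[1], d[2], d[3], fill = NA_real_)
    sh[is.na(sh)] <- out[is.na(sh)] # edge replication
    out <- if (b == "L") (out + sh) / sqrt(2) else (out - sh) / sqrt(2)
  }
  out
}

wavelet_band_names <- function() {
  paste0("wavelet_", apply(expand.grid(c("L", "H"), c("L", "H"), c("L", "H")),
                           1, paste, collapse = ""))
}

# Discretize masked voxel values to integer gray levels. Intensity-scale
# images use a fixed bin width; nonlinear filter responses use a fixed bin
# number (the usual recommendation for filter-response images).
discretize_levels <- function(values, bin_width = NULL, bin_count = NULL) {
  if (!is.null(bin_width)) {
    lev <- floor((values - min(values)) / bin_width) + 1L
  } else {
    rng <- max(values) - min(values)
    if (rng == 0) return(rep(1L, length(values)))
    lev <- pmin(ceiling((values - min(values)) / rng * bin_count), bin_count)
    lev[lev < 1L] <- 1L
  }
  as.integer(lev)
}

# The 13 unique 3D directions (up to sign) on the 26-neighborhood.
directions13 <- function() {
  g <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  g <- g[rowSums(abs(g)) > 0, ]
  keep <- apply(g, 1, function(d) {
    nz <- d[d != 0]
    nz[1] > 0 # canonical sign: first nonzero positive
  })
  unname(g[keep, , drop = FALSE])
}
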