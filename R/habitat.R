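# Habitat generation: per-voxel local feature stack, K-means clustering,
# Calinski-Harabasz selection of k over 2..9, and habitat mask export.

# Gaussian smoothing, separable per axis, edge-renormalized.
gauss_smooth <- function(a, sigma_mm, spacing = c(1, 1, 1)) {
  out <- a
  for (ax in 1:3) {
    sig_vox <- sigma_mm / spacing[ax]
    r <- max(1L, ceiling(3 * sig_vox))
    w <- stats::dnorm(-r:r, sd = sig_vox)
    num <- array(0, dim = dim(out))
    den <- array(0, dim = dim(out))
    ones <- array(1, dim = dim(out))
    for (i in seq_along(w)) {
      k <- (-r:r)[i]
      sh <- switch(ax, `1` = c(k, 0, 0), `2` = c(0, k, 0), `3` = c(0, 0, k))
      num <- num + w[i] * shift3d(out, sh[1], sh[2], sh[3], fill = 0)
      den <- den + w[i] * shift3d(ones, sh[1], sh[2], sh[3], fill = 0)
    }
    out <- num / den
  }
  out
}

# Discrete 6-neighbor Laplacian; edge neighbors are replicated (zero
# contribution across the volume boundary).
laplacian3d <- function(a, spacing = c(1, 1, 1)) {
  out <- array(0, dim = dim(a))
  dirs <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  sp2 <- c(spacing[1]^2, spacing[1]^2, spacing[2]^2, spacing[2]^2, spacing[3]^2, spacing[3]^2)
  for (i in seq_along(dirs)) {
    d <- dirs[[i]]
    sh <- shift3d(a, d[1], d[2], d[3], fill = NA_real_)
    sh[is.na(sh)] <- a[is.na(sh)]
    out <- out + (sh - a) / sp2[i]
  }
  out
}

# Central-difference gradient magnitude; one-sided at volume edges.
gradient_magnitude3d <- function(a, spacing = c(1, 1, 1)) {
  g2 <- array(0, dim = dim(a))
  for (ax in 1:3) {
    d <- c(0, 0, 0); d[ax] <- 1
    p <- shift3d(a, -d[1], -d[2], -d[3], fill = NA_real_)
    m <- shift3d(a, d[1], d[2], d[3], fill = NA_real_)
    p[is.na(p)] <- a[is.na(p)]
    m[is.na(m)] <- a[is.na(m)]
    g2 <- g2 + ((p - m) / (2 * spacing[ax]))^2
  }
  sqrt(g2)
}

# City-block distance of each mask voxel to the nearest background voxel,
# via iterative 6-connected erosion (layer peeling).
boundary_distance <- function(mask) {
  d <- array(0, dim = dim(mask))
  cur <- mask
  layer <- 0
  while (any(cur)) {
    layer <- layer + 1
    d[cur] <- layer
    cur <- erode3d(cur, 1, c(1, 1, 1))
    if (layer > max(dim(mask))) break
  }
  d
}

# Gather the values of all offsets in `offs` around each ROI voxel as an
# n_roi x n_offsets matrix (NA outside the volume).
gather_neighborhood <- function(arr, roi_idx, offs) {
  n <- length(roi_idx)
  out <- matrix(NA_real_, nrow = n, ncol = nrow(offs))
  for (i in seq_len(nrow(offs))) {
    sh <- shift3d(arr, offs$dz[i], offs$dy[i], offs$dx[i], fill = NA_real_)
    out[, i] <- sh[roi_idx]
  }
  out
}

row_entropy <- function(nb, nbins = 32L, lo = 0, hi = 1) {
  # Shannon entropy of the neighborhood histogram over equal-width bins of
  # the windowed range [lo, hi]
  apply(nb, 1, function(v) {
    v <- v[!is.na(v)]
    b <- pmin(pmax(floor((v - lo) / (hi - lo) * nbins) + 1L, 1L), nbins)
    p <- tabulate(b, nbins) / length(b)
    p <- p[p > 0]
    -sum(p * log2(p))
  })
}

row_uniformity <- function(nb, nbins = 32L, lo = 0, hi = 1) {
  apply(nb, 1, function(v) {
    v <- v[!is.na(v)]
    b <- pmin(pmax(floor((v - lo) / (hi - lo) * nbins) + 1L, 1L), nbins)
    p <- tabulate(b, nbins) / length(b)
    sum(p^2)
  })
}

#' Voxel-local feature stack for habitat clustering
#'
#' Computes the 19 per-voxel local features used for habitat generation
#' from a windowed (\[0, 1\]) and isotropically resampled volume: raw
#' intensity; 3x3x3-neighborhood mean, SD, skewness, kurtosis, energy,
#' entropy, range, median and uniformity; 5x5x5-neighborhood mean, SD and
#' entropy; gradient magnitude; Laplacian; Laplacian-of-Gaussian responses
#' at sigma = 1, 2, 3 mm; and normalized distance to the ROI boundary.
#' Neighborhoods are clipped at volume edges; entropy/uniformity use 32
#' equal-width bins over the windowed range. Row order follows the
#' column-major mask scan, so it is reproducible.
#'
#' @param volume windowed, resampled [ct_volume()] (or bare array with
#'   values in \[0, 1\]).
#' @param mask congruent [roi_mask()] (or logical array), >= 27 voxels.
#' @return object of class `voxel_features`: list with `features`
#'   (n x 19 named matrix), `coords` (n x 3, 1-based z/y/x indices) and
#'   `spacing_mm`.
#' @export
voxel_local_features <- function(volume, mask) {
  arr <- if (inherits(volume, "ct_volume")) volume$data else volume
  sp <- if (inherits(volume, "ct_volume")) volume$spacing_mm else c(1, 1, 1)
  m <- if (inherits(mask, "roi_mask")) mask$data else mask
  assert_that(sum(m) >= 27, "mask below 27 voxels")
  roi_idx <- which(m)
  coords <- which(m, arr.ind = TRUE)

  off3 <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  off5 <- expand.grid(dz = -2:2, dy = -2:2, dx = -2:2)
  nb3 <- gather_neighborhood(arr, roi_idx, off3)
  nb5 <- gather_neighborhood(arr, roi_idx, off5)

  mean3 <- rowMeans(nb3, na.rm = TRUE)
  sd3 <- apply(nb3, 1, stats::sd, na.rm = TRUE)
  cen3 <- nb3 - mean3
  n3 <- rowSums(!is.na(nb3))
  m2 <- rowSums(cen3^2, na.rm = TRUE) / n3
  m3 <- rowSums(cen3^3, na.rm = TRUE) / n3
  m4 <- rowSums(cen3^4, na.rm = TRUE) / n3
  skew3 <- ifelse(m2 > 1e-12, m3 / m2^1.5, 0)
  kurt3 <- ifelse(m2 > 1e-12, m4 / m2^2 - 3, 0)
  energy3 <- rowMeans(nb3^2, na.rm = TRUE)
  range3 <- apply(nb3, 1, function(v) diff(range(v, na.rm = TRUE)))
  med3 <- apply(nb3, 1, stats::median, na.rm = TRUE)

  grad <- gradient_magnitude3d(arr, sp)
  lap <- laplacian3d(arr, sp)
  log1 <- laplacian3d(gauss_smooth(arr, 1, sp), sp)
  log2 <- laplacian3d(gauss_smooth(arr, 2, sp), sp)
  log3 <- laplacian3d(gauss_smooth(arr, 3, sp), sp)
  bd <- boundary_distance(m)
  bd_norm <- bd / max(bd)

  feats <- cbind(
    intensity = arr[roi_idx],
    n3_mean = mean3, n3_sd = sd3, n3_skewness = skew3, n3_kurtosis = kurt3,
    n3_energy = energy3, n3_entropy = row_entropy(nb3), n3_range = range3,
    n3_median = med3, n3_uniformity = row_uniformity(nb3),
    n5_mean = rowMeans(nb5, na.rm = TRUE),
    n5_sd = apply(nb5, 1, stats::sd, na.rm = TRUE),
    n5_entropy = row_entropy(nb5),
    gradient_magnitude = grad[roi_idx],
    laplacian = lap[roi_idx],
    log_sigma_1 = log1[roi_idx],
    log_sigma_2 = log2[roi_idx],
    log_sigma_3 = log3[roi_idx],
    distance_to_boundary = bd_norm[roi_idx]
  )
  structure(list(features = feats, coords = coords, spacing_mm = sp,
                 dim = dim(arr)),
            class = "voxel_features")
}

#' Calinski-Harabasz index
#'
#' `CH = (B / (k - 1)) / (W / (n - k))` where B is the between-cluster
#' dispersion (cluster sizes times squared centroid distances to the grand
#' mean) and W the within-cluster sum of squared distances to centroids.
#' Degenerate cases: zero within-cluster scatter returns `Inf` (maximal);
#' all points identical returns 0.
#'
#' @param features numeric matrix (n x p).
#' @param labels integer cluster labels, each cluster non-empty.
#' @return the CH score.
#' @export
calinski_harabasz <- function(features, labels) {
  features <- as.matrix(features)
  labs <- as.integer(factor(labels))
  k <- max(labs)
  n <- nrow(features)
  assert_that(k >= 2, "need >= 2 clusters")
  assert_that(all(tabulate(labs, k) > 0), "a cluster is empty")
  grand <- colMeans(features)
  B <- 0; W <- 0
  for (c in seq_len(k)) {
    rows <- features[labs == c, , drop = FALSE]
    cen <- colMeans(rows)
    B <- B + nrow(rows) * sum((cen - grand)^2)
    W <- W + sum(sweep(rows, 2, cen)^2)
  }
  if (W < 1e-300) {
    if (B < 1e-300) return(0)
    return(Inf)
  }
  (B / (k - 1)) / (W / (n - k))
}

#' Fit habitat subregions by K-means with CH model selection
#'
#' Z-scores the feature columns, runs seeded multi-restart K-means for each
#' k in `k_range`, scores each solution with the Calinski-Harabasz index,
#' and picks the argmax (ties broken toward smaller k). Cluster labels are
#' re-indexed so that mean raw intensity is ascending (h1 darkest). The
#' fitted object freezes the standardization statistics and centroids so
#' that other nodules (all cohorts) can be labeled consistently via
#' [label_habitats()].
#'
#' @param features a [voxel_local_features()] result, or the pooled output
#'   of [pool_voxel_features()].
#' @param k_range candidate cluster counts (default 2:9).
#' @param seed integer seed.
#' @param nstart K-means restarts per k (default 10).
#' @return object of class `habitat_fit`: `ch_curve` (data.frame k/score),
#'   `k_star`, `centers` (standardized space, relabeled), `scale_center`,
#'   `scale_sd`, and `map` (a `habitat_map` for the fitted voxels).
#' @export
fit_habitats <- function(features, k_range = 2:9, seed = 1L, nstart = 10L) {
  vf <- features
  X <- vf$features
  n <- nrow(X)
  assert_that(min(k_range) >= 2 && max(k_range) <= n - 1,
              "k_range outside [2, n-1]")
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, `/`)

  scores <- numeric(length(k_range))
  fits <- vector("list", length(k_range))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    km <- with_seed(derive_seed(seed, k), {
      stats::kmeans(Xs, centers = k, nstart = nstart, iter.max = 100)
    })
    fits[[i]] <- km
    scores[i] <- calinski_harabasz(Xs, km$cluster)
  }
  best <- which.max(scores) # first max: ties break toward smaller k
  k_star <- k_range[best]
  km <- fits[[best]]

  mean_int <- tapply(X[, "intensity"], km$cluster, mean)
  relabel <- match(seq_len(k_star), order(mean_int)) # old -> new labels
  labels <- relabel[km$cluster]
  centers <- km$centers[order(mean_int), , drop = FALSE]
  rownames(centers) <- paste0("h", seq_len(k_star))

  structure(list(
    ch_curve = data.frame(k = k_range, score = scores),
    k_star = k_star,
    centers = centers,
    scale_center = mu, scale_sd = sdv,
    map = new_habitat_map(labels, vf, k_star)
  ), class = "habitat_fit")
}

new_habitat_map <- function(labels, vf, k) {
  mean_int <- tapply(vf$features[, "intensity"], factor(labels, levels = seq_len(k)), mean)
  structure(list(labels = labels, coords = vf$coords, dim = vf$dim,
                 spacing_mm = vf$spacing_mm, k = k,
                 counts = as.integer(tabulate(labels, k)),
                 mean_intensity = as.numeric(mean_int)),
            class = "habitat_map")
}

#' Label a nodule's voxels with frozen habitat centroids
#'
#' Applies the standardization and centroids frozen in a [fit_habitats()]
#' result (typically fitted on the pooled training voxels) to a new
#' nodule's voxel features, assigning each voxel to its nearest centroid.
#'
#' @param fit a `habitat_fit`.
#' @param features a [voxel_local_features()] result for the nodule.
#' @return a `habitat_map` for the nodule.
#' @export
label_habitats <- function(fit, features) {
  X <- sweep(sweep(features$features, 2, fit$scale_center), 2, fit$scale_sd, `/`)
  cen <- fit$centers
  d2 <- sapply(seq_len(nrow(cen)), function(j) {
    rowSums(sweep(X, 2, cen[j, ])^2)
  })
  labels <- max.col(-d2)
  new_habitat_map(labels, features, nrow(cen))
}

#' Pool voxel features of many nodules for cohort-level habitat fitting
#'
#' Concatenates the per-nodule voxel feature matrices (optionally capping
#' each nodule at `cap` voxels by seeded uniform subsampling) so that one
#' set of habitat centroids can be fitted on the training cohort and frozen.
#'
#' @param vf_list list of [voxel_local_features()] results.
#' @param cap per-nodule voxel cap (default 5000).
#' @param seed integer seed for the subsampling.
#' @return a pooled `voxel_features`-like object with a `nodule` index.
#' @export
pool_voxel_features <- function(vf_list, cap = 5000L, seed = 1L) {
  picked <- with_seed(seed, {
    lapply(vf_list, function(vf) {
      n <- nrow(vf$features)
      if (n > cap) sort(sample.int(n, cap)) else seq_len(n)
    })
  })
  feats <- do.call(rbind, Map(function(vf, id) vf$features[id, , drop = FALSE],
                              vf_list, picked))
  coords <- do.call(rbind, Map(function(vf, id) vf$coords[id, , drop = FALSE],
                               vf_list, picked))
  nod <- rep(seq_along(vf_list), vapply(picked, length, 1L))
  structure(list(features = feats, coords = coords, nodule = nod,
                 spacing_mm = vf_list[[1]]$spacing_mm, dim = vf_list[[1]]$dim),
            class = "voxel_features")
}

#' Reconstruct the habitat label field as a 3D array
#'
#' @param map a `habitat_map`.
#' @return integer array of the original volume shape; 0 outside the ROI.
#' @export
habitat_label_array <- function(map) {
  arr <- array(0L, dim = map$dim)
  arr[map$coords] <- map$labels
  arr
}

#' Export habitat subregions as binary masks
#'
#' The k binary masks partition the ROI exactly: their union is the ROI and
#' pairwise intersections are empty. If `dir` is given, each subregion is
#' also written as a NIfTI mask (`habitat_1.nii.gz`, ...).
#'
#' @param map a `habitat_map`.
#' @param dir optional output directory for NIfTI export.
#' @param prefix filename prefix (default "habitat").
#' @return named list of k logical arrays (h1..hk).
#' @export
export_habitat_masks <- function(map, dir = NULL, prefix = "habitat") {
  lab <- habitat_label_array(map)
  masks <- lapply(seq_len(map$k), function(h) lab == h)
  names(masks) <- paste0("h", seq_len(map$k))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (h in seq_len(map$k)) {
      write_nifti_volume(masks[[h]] * 1, map$spacing_mm,
                         file.path(dir, sprintf("%s_%d.nii.gz", prefix, h)))
    }
  }
  masks
}
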