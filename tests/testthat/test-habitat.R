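# Voxel-local features, Calinski-Harabasz scoring, habitat fitting.

test_that("voxel feature matrix has 19 columns with degenerate constants zeroed", {
  vol <- array(0.4, dim = c(14, 14, 14))
  msk <- array(FALSE, dim = c(14, 14, 14))
  msk[4:11, 4:11, 4:11] <- TRUE
  vf <- voxel_local_features(vol, msk)
  expect_equal(ncol(vf$features), 19L)
  zero_cols <- c("n3_sd", "n3_range", "n5_sd", "gradient_magnitude",
                 "laplacian", "log_sigma_1", "log_sigma_2", "log_sigma_3",
                 "n3_entropy", "n5_entropy")
  for (cn in zero_cols) {
    expect_lt(max(abs(vf$features[, cn])), 1e-9)
  }
  expect_true(all(abs(vf$features[, "n3_uniformity"] - 1) < 1e-12))
  expect_error(voxel_local_features(vol, array(FALSE, dim = dim(vol))), "27")
})

test_that("3x3x3 neighborhood mean matches a direct loop oracle", {
  withr::with_seed(11, {
    vol <- array(runif(12^3), dim = c(12, 12, 12))
  })
  msk <- array(FALSE, dim = c(12, 12, 12))
  msk[4:9, 4:9, 4:9] <- TRUE
  vf <- voxel_local_features(vol, msk)
  # pick an interior voxel; row order is column-major mask scan
  target <- c(6, 7, 5)
  row <- which(vf$coords[, 1] == target[1] & vf$coords[, 2] == target[2] &
                 vf$coords[, 3] == target[3])
  acc <- c()
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    acc <- c(acc, vol[target[1] + dz, target[2] + dy, target[3] + dx])
  }
  expect_equal(unname(vf$features[row, "n3_mean"]), mean(acc), tolerance = 1e-12)
})

test_that("Calinski-Harabasz matches an independent textbook oracle", {
  ch_oracle <- function(X, lab) {
    # coded straight from the definition, independent structure
    X <- as.matrix(X); lab <- as.integer(factor(lab))
    n <- nrow(X); k <- max(lab)
    gm <- colMeans(X)
    b <- 0; w <- 0
    for (g in 1:k) {
      xg <- X[lab == g, , drop = FALSE]
      cg <- colMeans(xg)
      b <- b + nrow(xg) * sum((cg - gm)^2)
      for (r in seq_len(nrow(xg))) w <- w + sum((xg[r, ] - cg)^2)
    }
    (b / (k - 1)) / (w / (n - k))
  }
  withr::with_seed(7, {
    X <- rbind(matrix(rnorm(200, 0, 0.3), 100, 2),
               matrix(rnorm(200, 4, 0.3), 100, 2),
               matrix(rnorm(200, c(0, 8), 0.3), 100, 2))
    lab <- rep(1:3, each = 100)
    expect_equal(calinski_harabasz(X, lab), ch_oracle(X, lab), tolerance = 1e-9)
    km <- kmeans(X, 3, nstart = 5)
    expect_equal(calinski_harabasz(X, km$cluster), ch_oracle(X, km$cluster),
                 tolerance = 1e-9)
  })
  # degenerate cases
  expect_identical(calinski_harabasz(matrix(c(0, 5), 2, 1), c(1, 2)), Inf)
  expect_identical(calinski_harabasz(matrix(1, 6, 2), rep(1:2, 3)), 0)
  expect_error(calinski_harabasz(matrix(rnorm(10), 5, 2), rep(1, 5)), "2 clusters")
})

test_that("habitat fitting recovers the planted three-zone structure", {
  nd <- fixture_zone_nodule()
  vf <- voxel_local_features(apply_window(nd$volume), nd$mask)
  fit <- fit_habitats(vf, seed = 3)
  expect_equal(fit$k_star, 3L)
  expect_equal(fit$ch_curve$k, 2:9)
  expect_equal(fit$ch_curve$score[fit$ch_curve$k == fit$k_star],
               max(fit$ch_curve$score))
  # labels ascend in mean intensity
  expect_true(all(diff(fit$map$mean_intensity) > 0))
  # same seed -> identical map
  fit2 <- fit_habitats(vf, seed = 3)
  expect_identical(fit$map$labels, fit2$map$labels)

  # per-voxel accuracy vs the planted zones after optimal label matching
  zones <- nd$zones[nd$mask$data]
  acc <- max(apply(gtools_permutations3(), 1, function(pm) {
    mean(pm[fit$map$labels] == zones)
  }))
  # voxel-level agreement is bounded by boundary blending: the rim is only
  # 1-2 voxels thick, so neighborhood features mix zones there
  expect_gte(acc, 0.65)

  # label stability across seeds: < 5% of voxels change
  fit3 <- fit_habitats(vf, seed = 99)
  expect_lt(mean(fit3$map$labels != fit$map$labels), 0.05)
})

test_that("k-means at k=2 separates two well-separated blobs exactly", {
  withr::with_seed(5, {
    X <- rbind(matrix(rnorm(120, 0, 0.2), 60, 2),
               matrix(rnorm(120, 6, 0.2), 60, 2))
  })
  colnames(X) <- c("intensity", "n3_mean")
  vf <- structure(list(features = X, coords = cbind(seq_len(120), 1L, 1L),
                       dim = c(120L, 1L, 1L), spacing_mm = c(1, 1, 1)),
                  class = "voxel_features")
  fit <- fit_habitats(vf, k_range = 2:2, seed = 1)
  truth <- rep(1:2, each = 60)
  agree <- max(mean(fit$map$labels == truth), mean(fit$map$labels == 3 - truth))
  expect_equal(agree, 1)
})

test_that("frozen centroids label new nodules and masks partition the ROI", {
  nd <- fixture_zone_nodule()
  vf <- voxel_local_features(apply_window(nd$volume), nd$mask)
  fit <- fit_habitats(vf, seed = 3)

  nd2 <- generate_nodule(fixed_zone_config(), 1, seed = 1234)
  vf2 <- voxel_local_features(apply_window(nd2$volume), nd2$mask)
  map2 <- label_habitats(fit, vf2)
  expect_equal(map2$k, 3L)
  expect_equal(sum(map2$counts), sum(nd2$mask$data))

  dir <- withr::local_tempdir()
  masks <- export_habitat_masks(map2, dir = dir)
  expect_equal(length(masks), 3L)
  uni <- Reduce(`|`, masks)
  expect_identical(uni, nd2$mask$data)
  expect_false(any(masks$h1 & masks$h2))
  expect_false(any(masks$h1 & masks$h3))
  expect_false(any(masks$h2 & masks$h3))
  expect_equal(sum(sapply(masks, sum)), sum(nd2$mask$data))
  # mean intensity ordering h1 < h3
  expect_lt(map2$mean_intensity[1], map2$mean_intensity[3])
  # NIfTI round trip reproduces the label field
  rt <- read_nifti_volume(file.path(dir, "habitat_2.nii.gz"))
  expect_identical(rt$data > 0.5, masks$h2)
})

test_that("pooled fitting caps per-nodule voxels reproducibly", {
  nd <- fixture_zone_nodule()
  vf <- voxel_local_features(apply_window(nd$volume), nd$mask)
  pooled <- pool_voxel_features(list(vf, vf), cap = 100L, seed = 4)
  expect_equal(nrow(pooled$features), 200L)
  pooled2 <- pool_voxel_features(list(vf, vf), cap = 100L, seed = 4)
  expect_identical(pooled$features, pooled2$features)
})
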