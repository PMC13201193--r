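# IBSI-style feature extraction, ICC and the stability filter.

test_that("constant-intensity ROI gives the expected degenerate features", {
  vol <- ct_volume(array(-400, dim = c(14, 14, 14)))
  msk <- roi_mask(array(TRUE, dim = c(14, 14, 14)))
  cfg <- feature_config(filters = c("original", "log_sigma_3_0_mm_3D"),
                        families = c("firstorder", "glszm"))
  fv <- extract_features(vol, msk, cfg)
  expect_equal(fv[["original_firstorder_Minimum"]], -400)
  expect_equal(fv[["original_firstorder_Maximum"]], -400)
  expect_equal(fv[["original_firstorder_Mean"]], -400)
  expect_equal(fv[["original_glszm_ZoneEntropy"]], 0)
  # linear filter of a constant image responds zero
  expect_equal(fv[["log_sigma_3_0_mm_3D_firstorder_Minimum"]], 0,
               tolerance = 1e-9)
})

test_that("first-order and GLCM features match a brute-force oracle on a toy array", {
  toy <- array(c(1, 2, 5, 2, 4, 1,
                 3, 5, 1, 3, 2, 2,
                 1, 3, 5, 5, 1, 4,
                 3, 1, 1, 1, 5, 3,
                 2, 4, 3, 2, 1, 5,
                 5, 1, 2, 4, 4, 1) * 30, dim = c(1, 6, 6)) # single axial slice
  msk <- array(TRUE, dim = c(1, 6, 6))
  cfg <- feature_config(filters = "original", families = c("firstorder", "glcm"),
                        bin_width_hu = 25)
  fv <- extract_features(ct_volume(toy), roi_mask(msk), cfg)

  vals <- as.vector(toy)
  expect_equal(fv[["original_firstorder_Energy"]], sum(vals^2))
  lev <- floor((vals - min(vals)) / 25) + 1
  p <- table(lev) / length(lev)
  expect_equal(fv[["original_firstorder_Entropy"]], -sum(p * log2(p)))
  expect_equal(fv[["original_firstorder_Mean"]], mean(vals))

  # brute-force symmetric co-occurrence over the in-plane directions;
  # out-of-plane directions contribute no pairs in a single-slice array
  ng <- max(lev)
  L <- matrix(lev, 6, 6) # (y, x) plane of the single slice
  contrasts <- c()
  for (d in list(c(1, 0), c(0, 1), c(1, 1), c(1, -1))) {
    P <- matrix(0, ng, ng)
    for (i in 1:6) for (j in 1:6) {
      i2 <- i + d[1]; j2 <- j + d[2]
      if (i2 >= 1 && i2 <= 6 && j2 >= 1 && j2 <= 6) {
        P[L[i, j], L[i2, j2]] <- P[L[i, j], L[i2, j2]] + 1
      }
    }
    P <- P + t(P)
    P <- P / sum(P)
    iv <- matrix(seq_len(ng), ng, ng)
    contrasts <- c(contrasts, sum((iv - t(iv))^2 * P))
  }
  expect_equal(fv[["original_glcm_Contrast"]], mean(contrasts), tolerance = 1e-12)
})

test_that("feature vectors are deterministic and direction aggregation is rotation-sane", {
  nd <- fixture_nodule(0, 3)
  cfg <- feature_config(filters = "original",
                        families = c("firstorder", "glcm", "glrlm"))
  a <- extract_features(nd$volume, nd$mask, cfg)
  b <- extract_features(nd$volume, nd$mask, cfg)
  expect_identical(a, b)

  # 90-degree axial rotation permutes the 13 directions among themselves
  rot <- function(arr) aperm(arr[, , dim(arr)[3]:1, drop = FALSE], c(1, 3, 2))
  vr <- ct_volume(rot(nd$volume$data))
  mr <- roi_mask(rot(nd$mask$data))
  r <- extract_features(vr, mr, cfg)
  glcm_cols <- grep("glcm", names(a), value = TRUE)
  expect_lt(max(abs(a[glcm_cols] - r[glcm_cols])), 1e-6)
})

test_that("habitat stream concatenation follows the partition arithmetic", {
  nd <- fixture_zone_nodule()
  vf <- voxel_local_features(apply_window(nd$volume), nd$mask)
  fit <- fit_habitats(vf, seed = 3)
  masks <- export_habitat_masks(fit$map)
  cfg <- feature_config(filters = "original", families = c("firstorder", "shape"))
  st <- extract_all_streams(nd$volume, nd$mask, masks, cfg)

  n_nonshape <- sum(!grepl("shape", feature_names(cfg)))
  expect_equal(length(st$habitat), 3L * n_nonshape)
  expect_equal(length(st$radiomics), length(feature_names(cfg)))

  # tumor mean equals the voxel-count-weighted mean of subregion means
  counts <- vapply(masks, sum, 0)
  sub_means <- vapply(1:3, function(h) st$habitat[[sprintf("h%d_original_firstorder_Mean", h)]], 0)
  expect_equal(st$radiomics[["original_firstorder_Mean"]],
               sum(counts * sub_means) / sum(counts), tolerance = 1e-9)

  # a sub-27-voxel region propagates explicit missing values
  tiny <- masks
  idx <- which(tiny$h1)
  keep <- idx[seq_len(min(10, length(idx)))]
  tiny$h1[] <- FALSE; tiny$h1[keep] <- TRUE
  # re-partition: dump removed voxels into h2 to keep the union intact
  tiny$h2 <- tiny$h2 | (masks$h1 & !tiny$h1)
  st2 <- extract_all_streams(nd$volume, nd$mask, tiny, cfg)
  expect_true(all(is.na(st2$habitat[grep("^h1_", names(st2$habitat))])))
  expect_false(anyNA(st2$habitat[grep("^h2_", names(st2$habitat))]))
})

test_that("ICC(2,1) matches hand mean-squares arithmetic and simulation bounds", {
  # classic 6 x 2 ratings table, worked by hand through the ANOVA sums
  x <- cbind(c(9, 6, 8, 7, 10, 6), c(2, 1, 4, 1, 5, 2))
  n <- 6; k <- 2
  grand <- mean(x)
  msr <- k * sum((rowMeans(x) - grand)^2) / (n - 1)
  msc <- n * sum((colMeans(x) - grand)^2) / (k - 1)
  sse <- sum((x - outer(rowMeans(x), rep(1, k)) -
                outer(rep(1, n), colMeans(x)) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  by_hand <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  expect_equal(icc(x), by_hand, tolerance = 1e-12)

  expect_equal(icc(cbind(1:10, 1:10)), 1.0)
  expect_identical(icc(matrix(5, 6, 2)), NA_real_)

  withr::with_seed(21, {
    noise <- cbind(rnorm(200), rnorm(200))
    expect_lt(abs(icc(noise)), 0.2)
  })
})

test_that("stability filter keeps only features stable across raters, strictly", {
  withr::with_seed(4, {
    n <- 30
    stable <- rnorm(n, sd = 3)
    f1 <- cbind(stable = stable, junk = rnorm(n))
    f2 <- cbind(stable = stable + rnorm(n, sd = 0.1), junk = rnorm(n))
    f1b <- cbind(stable = stable + rnorm(n, sd = 0.1), junk = f1[, "junk"] + rnorm(n, sd = 0.05))
  })
  rep_ <- stability_filter(f1, f2, f1b)
  expect_true("stable" %in% rep_$retained)
  expect_false("junk" %in% rep_$retained) # inter-rater ICC ~ 0

  # unperturbed masks everywhere -> ICC 1, everything retained
  rep2 <- stability_filter(f1, f1, f1)
  expect_true(all(abs(rep2$inter_icc - 1) < 1e-12))
  expect_setequal(rep2$retained, colnames(f1))

  # a feature whose ICC equals the threshold exactly is excluded
  v <- icc(cbind(f1[, 1], f2[, 1]))
  rep3 <- stability_filter(f1[, 1, drop = FALSE], f2[, 1, drop = FALSE],
                           f1[, 1, drop = FALSE], threshold = v)
  expect_length(rep3$retained, 0)

  colnames(f2) <- c("stable", "other")
  expect_error(stability_filter(f1, f2, f1b), "mismatch")
})

test_that("missing-value handling drops sparse features and imputes the rest", {
  X <- matrix(rnorm(100), 20, 5, dimnames = list(NULL, paste0("f", 1:5)))
  X[1:5, 1] <- NA   # 50% missing in the 10 training rows -> drop
  X[1, 2] <- NA     # 10% missing -> impute
  out <- handle_missing_features(X, train_idx = 1:10)
  expect_identical(out$dropped, "f1")
  expect_false(anyNA(out$table))
  expect_equal(unname(out$table[1, "f2"]), median(X[2:10, 2]))
})
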