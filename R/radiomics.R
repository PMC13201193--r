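#' Radiomics extraction configuration
#'
#' Controls discretization, the image filter bank and the feature families.
#' Defaults: bin width 25 HU for intensity-scale images (original, LoG,
#' gradient) and a fixed 32-level binning for nonlinear filter responses;
#' filters original, LoG (sigma 1/2/3 mm), exponential, square, squareroot,
#' logarithm, gradient and the 8 single-level Haar wavelet sub-bands;
#' families first order (18), 3D shape (14, original geometry only), GLCM
#' (24), GLRLM (16), GLSZM (16), GLDM (14) and NGTDM (5). Feature names
#' encode `filter_family_feature`, e.g.
#' `log_sigma_3_0_mm_3D_firstorder_Minimum` or
#' `exponential_glszm_ZoneEntropy`.
#'
#' @param bin_width_hu fixed bin width for intensity-scale images.
#' @param bin_count fixed bin number for nonlinear filter responses.
#' @param filters character vector of filter names.
#' @param families character vector of feature families.
#' @return object of class `feature_config`.
#' @export
feature_config <- function(bin_width_hu = 25,
                           bin_count = 32L,
                           filters = c("original",
                                       "log_sigma_1_0_mm_3D",
                                       "log_sigma_2_0_mm_3D",
                                       "log_sigma_3_0_mm_3D",
                                       "exponential", "square", "squareroot",
                                       "logarithm", "gradient",
                                       wavelet_band_names()),
                           families = c("firstorder", "shape", "glcm",
                                        "glrlm", "glszm", "gldm", "ngtdm")) {
  structure(list(bin_width_hu = bin_width_hu, bin_count = as.integer(bin_count),
                 filters = filters, families = families),
            class = "feature_config")
}

# Filters whose output keeps the HU intensity scale (fixed-bin-width
# discretization); everything else gets fixed-bin-number.
is_intensity_scale <- function(filter) {
  filter == "original" | grepl("^log_sigma", filter) | filter == "gradient"
}

family_feature_names <- list(
  firstorder = c("Energy", "TotalEnergy", "Entropy", "Minimum", "10Percentile",
                 "90Percentile", "Maximum", "Mean", "Median",
                 "InterquartileRange", "Range", "MeanAbsoluteDeviation",
                 "RobustMeanAbsoluteDeviation", "RootMeanSquared", "Skewness",
                 "Kurtosis", "Variance", "Uniformity"),
  shape = c("MeshVolume", "VoxelVolume", "SurfaceArea", "SurfaceVolumeRatio",
            "Sphericity", "Maximum3DDiameter", "Maximum2DDiameterSlice",
            "Maximum2DDiameterColumn", "Maximum2DDiameterRow",
            "MajorAxisLength", "MinorAxisLength", "LeastAxisLength",
            "Elongation", "Flatness"),
  glcm = c("Autocorrelation", "ClusterProminence", "ClusterShade",
           "ClusterTendency", "Contrast", "Correlation", "DifferenceAverage",
           "DifferenceEntropy", "DifferenceVariance", "Id", "Idm", "Idmn",
           "Idn", "Imc1", "Imc2", "InverseVariance", "JointAverage",
           "JointEnergy", "JointEntropy", "MCC", "MaximumProbability",
           "SumAverage", "SumEntropy", "SumSquares"),
  glrlm = c("ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
            "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
            "RunLengthNonUniformityNormalized", "RunPercentage",
            "GrayLevelVariance", "RunVariance", "RunEntropy",
            "LowGrayLevelRunEmphasis", "HighGrayLevelRunEmphasis",
            "ShortRunLowGrayLevelEmphasis", "ShortRunHighGrayLevelEmphasis",
            "LongRunLowGrayLevelEmphasis", "LongRunHighGrayLevelEmphasis"),
  glszm = c("SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
            "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
            "SizeZoneNonUniformityNormalized", "ZonePercentage",
            "GrayLevelVariance", "ZoneVariance", "ZoneEntropy",
            "LowGrayLevelZoneEmphasis", "HighGrayLevelZoneEmphasis",
            "SmallAreaLowGrayLevelEmphasis", "SmallAreaHighGrayLevelEmphasis",
            "LargeAreaLowGrayLevelEmphasis", "LargeAreaHighGrayLevelEmphasis"),
  gldm = c("SmallDependenceEmphasis", "LargeDependenceEmphasis",
           "GrayLevelNonUniformity", "DependenceNonUniformity",
           "DependenceNonUniformityNormalized", "GrayLevelVariance",
           "DependenceVariance", "DependenceEntropy", "LowGrayLevelEmphasis",
           "HighGrayLevelEmphasis", "SmallDependenceLowGrayLevelEmphasis",
           "SmallDependenceHighGrayLevelEmphasis",
           "LargeDependenceLowGrayLevelEmphasis",
           "LargeDependenceHighGrayLevelEmphasis"),
  ngtdm = c("Coarseness", "Contrast", "Busyness", "Complexity", "Strength")
)

#' Names of all features emitted under a configuration
#'
#' @param config a [feature_config()].
#' @return character vector of `filter_family_feature` names (shape on the
#'   original geometry only).
#' @export
feature_names <- function(config = feature_config()) {
  out <- character(0)
  if ("shape" %in% config$families) {
    out <- c(out, paste("original_shape", family_feature_names$shape, sep = "_"))
  }
  for (f in config$filters) {
    for (fam in setdiff(config$families, "shape")) {
      out <- c(out, paste(f, fam, family_feature_names[[fam]], sep = "_"))
    }
  }
  out
}

#' Extract an IBSI-style radiomics feature vector
#'
#' Features are computed on HU values (not windowed) of an isotropically
#' resampled volume. The volume is cropped to the ROI bounding box plus a
#' filter-support margin, each configured filter image is computed, masked
#' voxels are discretized (fixed bin width for intensity-scale images,
#' fixed bin number otherwise) and each configured family is evaluated.
#' GLCM/GLRLM statistics aggregate over the 13 unique 3D directions at
#' distance 1; zone/dependence statistics use 26-connectivity. Shape
#' features are computed on the original geometry only.
#'
#' Regions below 27 voxels yield a vector of `NA` (explicit missing values,
#' to be imputed or dropped downstream).
#'
#' @param volume a [ct_volume()] in HU.
#' @param mask congruent [roi_mask()].
#' @param config a [feature_config()].
#' @return named numeric vector.
#' @export
extract_features <- function(volume, mask, config = feature_config()) {
  nms <- feature_names(config)
  m <- if (inherits(mask, "roi_mask")) mask$data else mask
  if (sum(m) < 27) {
    out <- rep(NA_real_, length(nms))
    names(out) <- nms
    return(out)
  }
  arr <- if (inherits(volume, "ct_volume")) volume$data else volume
  sp <- if (inherits(volume, "ct_volume")) volume$spacing_mm else c(1, 1, 1)

  # crop with margin 10 for filter support
  idx <- which(m, arr.ind = TRUE)
  mg <- 10L
  d <- dim(arr)
  zr <- max(1, min(idx[, 1]) - mg):min(d[1], max(idx[, 1]) + mg)
  yr <- max(1, min(idx[, 2]) - mg):min(d[2], max(idx[, 2]) + mg)
  xr <- max(1, min(idx[, 3]) - mg):min(d[3], max(idx[, 3]) + mg)
  sub <- arr[zr, yr, xr, drop = FALSE]
  msub <- m[zr, yr, xr, drop = FALSE]
  np <- sum(msub)
  coords <- which(msub, arr.ind = TRUE)

  out <- numeric(0)
  if ("shape" %in% config$families) {
    sf <- shape_features(msub, sp)
    names(sf) <- paste("original_shape", names(sf), sep = "_")
    out <- c(out, sf)
  }
  fams <- setdiff(config$families, "shape")
  for (f in config$filters) {
    img <- filter_image(sub, f, sp)
    vals <- img[msub]
    levels <- if (is_intensity_scale(f)) {
      discretize_levels(vals, bin_width = config$bin_width_hu)
    } else {
      discretize_levels(vals, bin_count = config$bin_count)
    }
    ng <- max(levels)
    larr <- array(NA_integer_, dim = dim(sub))
    larr[msub] <- levels
    for (fam in fams) {
      fv <- switch(fam,
        firstorder = firstorder_features(vals, levels, prod(sp)),
        glcm = glcm_features(larr, ng),
        glrlm = glrlm_features(larr, coords, levels, ng, np),
        glszm = glszm_features(larr, ng, np),
        gldm = gldm_features(larr, ng, np),
        ngtdm = ngtdm_features(larr, ng, np))
      names(fv) <- paste(f, fam, names(fv), sep = "_")
      out <- c(out, fv)
    }
  }
  out[nms]
}

#' Extract tumor-ROI and habitat feature streams for one patient
#'
#' The radiomics stream is the feature vector of the whole tumor ROI; the
#' habitat stream concatenates per-subregion vectors (prefixed `h1_`,
#' `h2_`, ...) computed without shape features. Subregions below 27 voxels
#' propagate explicit missing values.
#'
#' @param volume a [ct_volume()] in HU.
#' @param roi tumor [roi_mask()].
#' @param habitat_masks named list of subregion masks (from
#'   [export_habitat_masks()]); must partition the ROI.
#' @param config a [feature_config()].
#' @return list with `radiomics` and `habitat` named vectors.
#' @export
extract_all_streams <- function(volume, roi, habitat_masks, config = feature_config()) {
  m <- if (inherits(roi, "roi_mask")) roi$data else roi
  uni <- Reduce(`|`, habitat_masks)
  assert_that(identical(which(uni), which(m)), "habitat masks must partition the ROI")
  sizes <- vapply(habitat_masks, sum, 0)
  for (i in seq_along(habitat_masks)) {
    for (j in seq_along(habitat_masks)) {
      if (i < j) assert_that(!any(habitat_masks[[i]] & habitat_masks[[j]]),
                             "habitat masks overlap")
    }
  }
  sub_cfg <- config
  sub_cfg$families <- setdiff(config$families, "shape")
  sp <- if (inherits(volume, "ct_volume")) volume$spacing_mm else c(1, 1, 1)
  hab <- lapply(seq_along(habitat_masks), function(h) {
    v <- extract_features(volume, roi_mask(habitat_masks[[h]], sp), sub_cfg)
    names(v) <- paste0("h", h, "_", names(v))
    v
  })
  list(radiomics = extract_features(volume, roi, config),
       habitat = unlist(hab))
}

#' Intraclass correlation coefficient ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single measurement, from
#' the standard mean-squares decomposition of an n x k ratings matrix.
#'
#' @param x numeric matrix, rows = subjects, columns = raters (k >= 2).
#' @return the ICC estimate, or `NA` (sentinel) when the total variance is
#'   zero and the coefficient is undefined.
#' @export
icc <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); k <- ncol(x)
  assert_that(n >= 3, "need >= 3 subject pairs")
  if (stats::var(as.vector(x)) < 1e-24) return(NA_real_)
  grand <- mean(x)
  rm_ <- rowMeans(x); cm <- colMeans(x)
  msr <- k * sum((rm_ - grand)^2) / (n - 1)
  msc <- n * sum((cm - grand)^2) / (k - 1)
  sse <- sum((x - outer(rm_, rep(1, k)) - outer(rep(1, n), cm) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

#' ICC-based feature stability filter
#'
#' Inter-rater ICC compares features from rater-1 and rater-2 masks;
#' intra-rater ICC compares rater-1 with a repeat perturbation draw. A
#' feature is retained only when both ICCs exceed the threshold (strict
#' inequality). Features whose ICC is undefined (zero variance) are not
#' retained.
#'
#' @param features_rater1,features_rater2,features_rater1_repeat congruent
#'   numeric matrices (patients x features) with identical column names.
#' @param threshold ICC retention threshold (default 0.75).
#' @return list with `inter_icc`, `intra_icc` (named vectors) and
#'   `retained` (character vector of feature names).
#' @export
stability_filter <- function(features_rater1, features_rater2,
                             features_rater1_repeat, threshold = 0.75) {
  f1 <- as.matrix(features_rater1)
  f2 <- as.matrix(features_rater2)
  f1b <- as.matrix(features_rater1_repeat)
  assert_that(identical(colnames(f1), colnames(f2)) &&
                identical(colnames(f1), colnames(f1b)),
              "feature names mismatch across rater tables")
  inter <- vapply(seq_len(ncol(f1)), function(j) {
    ok <- stats::complete.cases(cbind(f1[, j], f2[, j]))
    if (sum(ok) < 3) return(NA_real_)
    icc(cbind(f1[ok, j], f2[ok, j]))
  }, 0)
  intra <- vapply(seq_len(ncol(f1)), function(j) {
    ok <- stats::complete.cases(cbind(f1[, j], f1b[, j]))
    if (sum(ok) < 3) return(NA_real_)
    icc(cbind(f1[ok, j], f1b[ok, j]))
  }, 0)
  names(inter) <- names(intra) <- colnames(f1)
  keep <- !is.na(inter) & !is.na(intra) & inter > threshold & intra > threshold
  list(inter_icc = inter, intra_icc = intra, retained = colnames(f1)[keep])
}

#' Resolve missing feature values against training statistics
#'
#' Features missing in more than `max_missing_frac` of training rows are
#' dropped cohort-wide; the rest are median-imputed from training rows.
#'
#' @param table numeric matrix (samples x features).
#' @param train_idx integer indices of training rows.
#' @param max_missing_frac drop threshold (default 0.1).
#' @return list with the imputed `table`, `dropped` names and `medians`.
#' @export
handle_missing_features <- function(table, train_idx, max_missing_frac = 0.1) {
  tb <- as.matrix(table)
  frac <- colMeans(is.na(tb[train_idx, , drop = FALSE]))
  drop <- colnames(tb)[frac > max_missing_frac]
  keep <- setdiff(colnames(tb), drop)
  tb <- tb[, keep, drop = FALSE]
  med <- apply(tb[train_idx, , drop = FALSE], 2, stats::median, na.rm = TRUE)
  for (j in seq_len(ncol(tb))) {
    nas <- is.na(tb[, j])
    if (any(nas)) tb[nas, j] <- med[j]
  }
  list(table = tb, dropped = drop, medians = med)
}
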