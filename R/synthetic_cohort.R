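#' Phantom generator configuration
#'
#' Defines the geometry, attenuation, noise and center-effect model for the
#' synthetic ground-glass nodule (GGN) cohort. The two classes (0 = AIS/MIA,
#' 1 = IAC) differ in long/short axial diameter, mean attenuation, surface
#' lobulation, and share a three-zone concentric internal density structure
#' (dense core, intermediate transition, faint rim) that gives habitat
#' clustering a recoverable k = 3 ground truth.
#'
#' Default class distributions follow the published two-center GGN cohort
#' marginals: long diameter 9.25 +/- 3.63 mm (AIS/MIA) vs 15.66 +/- 5.46 mm
#' (IAC); mean CT attenuation -486.53 +/- 180.75 HU vs -338.35 +/- 184.68 HU.
#'
#' @param volume_shape integer vector (z, y, x) of voxel counts.
#' @param spacing_mm numeric vector (z, y, x) of voxel spacing in mm.
#' @param background_hu background lung attenuation in HU.
#' @param noise_sd_hu additive Gaussian noise standard deviation in HU.
#' @param zone_contrast_hu attenuation step between adjacent concentric
#'   zones, in HU. Zone separation relative to `noise_sd_hu` controls how
#'   recoverable the habitat structure is (default 80/15 > 5 SD).
#' @param class_params list of two lists (`ais_mia`, `iac`) with elements
#'   `long_diameter_mm`, `short_diameter_mm`, `ct_value_hu` (each
#'   `c(mean, sd)`), `n_bumps` (Poisson mean of lobulation bumps) and
#'   `bump_amplitude_mm`.
#' @param center_effects list of per-center lists with `shift_hu` (additive
#'   scanner offset) and `noise_mult` (noise multiplier), indexed "1", "2".
#' @param seed integer master seed.
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(volume_shape = c(48L, 48L, 48L),
                           spacing_mm = c(1, 1, 1),
                           background_hu = -800,
                           noise_sd_hu = 15,
                           zone_contrast_hu = 80,
                           class_params = NULL,
                           center_effects = NULL,
                           seed = 1L) {
  assert_that(length(volume_shape) == 3 && all(volume_shape > 0),
              "volume_shape must be 3 positive integers")
  assert_that(all(spacing_mm > 0), "spacing must be positive")
  if (is.null(class_params)) {
    class_params <- list(
      ais_mia = list(long_diameter_mm = c(9.25, 3.63),
                     short_diameter_mm = c(7.43, 2.45),
                     ct_value_hu = c(-486.53, 180.75),
                     n_bumps = 1, bump_amplitude_mm = 1.0),
      iac = list(long_diameter_mm = c(15.66, 5.46),
                 short_diameter_mm = c(11.15, 4.22),
                 ct_value_hu = c(-338.35, 184.68),
                 n_bumps = 4, bump_amplitude_mm = 1.8)
    )
  }
  assert_that(length(class_params) == 2, "class_params must define exactly 2 classes")
  if (is.null(center_effects)) {
    center_effects <- list(`1` = list(shift_hu = 0, noise_mult = 1),
                           `2` = list(shift_hu = 25, noise_mult = 1.2))
  }
  structure(list(volume_shape = as.integer(volume_shape),
                 spacing_mm = as.numeric(spacing_mm),
                 background_hu = background_hu,
                 noise_sd_hu = noise_sd_hu,
                 zone_contrast_hu = zone_contrast_hu,
                 class_params = class_params,
                 center_effects = center_effects,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

#' CT volume container
#'
#' @param data 3D numeric array of HU values, axis order (z, y, x).
#' @param spacing_mm per-axis voxel spacing in mm.
#' @return object of class `ct_volume`.
#' @export
ct_volume <- function(data, spacing_mm = c(1, 1, 1)) {
  assert_that(all(is.finite(data)), "CT volume must be finite")
  structure(list(data = data, spacing_mm = as.numeric(spacing_mm)),
            class = "ct_volume")
}

#' ROI mask container
#'
#' @param data 3D logical array congruent with its volume, axis order (z, y, x).
#' @param spacing_mm per-axis voxel spacing in mm.
#' @param rater_id character rater label.
#' @return object of class `roi_mask`.
#' @export
roi_mask <- function(data, spacing_mm = c(1, 1, 1), rater_id = "rater1") {
  structure(list(data = as.array(data) > 0, spacing_mm = as.numeric(spacing_mm),
                 rater_id = rater_id),
            class = "roi_mask")
}

# Render the concentric-zone ellipsoid + surface bumps in continuous mm
# coordinates. Returns the binary support and the per-voxel elliptical
# radius (for zone assignment).
render_shape <- function(shape, spacing, center_mm, semi_mm, bump_dirs, bump_amp) {
  zc <- (seq_len(shape[1]) - 0.5) * spacing[1]
  yc <- (seq_len(shape[2]) - 0.5) * spacing[2]
  xc <- (seq_len(shape[3]) - 0.5) * spacing[3]
  A <- ((zc - center_mm[1]) / semi_mm[1])^2
  B <- ((yc - center_mm[2]) / semi_mm[2])^2
  C <- ((xc - center_mm[3]) / semi_mm[3])^2
  rho2 <- outer(outer(A, B, `+`), C, `+`)
  support <- rho2 <= 1
  if (length(bump_amp) > 0) {
    for (j in seq_along(bump_amp)) {
      u <- bump_dirs[j, ]
      # surface point along direction u
      t <- 1 / sqrt(sum((u / semi_mm)^2))
      cj <- center_mm + u * t
      D <- outer(outer((zc - cj[1])^2, (yc - cj[2])^2, `+`), (xc - cj[3])^2, `+`)
      support <- support | (D <= bump_amp[j]^2)
    }
  }
  list(support = support, rho = sqrt(rho2))
}

# Caliper measurement on the maximum-area axial slice: long diameter is the
# largest pairwise boundary distance plus one voxel (edge-to-edge), short is
# the perpendicular width.
measure_diameters <- function(mask, spacing) {
  areas <- apply(mask, 1, sum)
  zi <- which.max(areas)
  sl <- mask[zi, , ]
  idx <- which(sl, arr.ind = TRUE) # (y, x)
  pts <- cbind(idx[, 1] * spacing[2], idx[, 2] * spacing[3])
  if (nrow(pts) == 1) return(c(long = spacing[3], short = spacing[2]))
  dmat <- as.matrix(stats::dist(pts))
  mx <- which(dmat == max(dmat), arr.ind = TRUE)[1, ]
  long <- dmat[mx[1], mx[2]] + mean(spacing[2:3])
  dir <- pts[mx[2], ] - pts[mx[1], ]
  dir <- dir / sqrt(sum(dir^2))
  perp <- c(-dir[2], dir[1])
  proj <- pts %*% perp
  short <- max(proj) - min(proj) + mean(spacing[2:3])
  c(long = long, short = unname(short))
}

# Draw from N(mean, sd) with the standardized deviate clamped symmetrically
# at +/- 2 (keeps the mean unbiased while bounding extreme geometry).
rnorm_clamped <- function(n, mean, sd, clamp = 2) {
  z <- pmin(pmax(stats::rnorm(n), -clamp), clamp)
  mean + sd * z
}

#' Generate one synthetic GGN phantom
#'
#' Renders a three-zone concentric ellipsoid (dense core, transition zone,
#' faint rim) with class-dependent surface lobulation bumps, embedded in
#' uniform background lung with additive Gaussian noise and the center's
#' scanner HU shift. The mask is the noise-free geometric support. The
#' clinical record combines covariates drawn from class-conditional
#' cohort-table distributions with quantities measured from the rendered
#' phantom itself (axial long/short diameter, mean attenuation inside the
#' mask). The in-plane semi-axes are calibrated by one re-render so that the
#' measured long/short diameters match the drawn values.
#'
#' @param config a [phantom_config()].
#' @param label class label: 0 (AIS/MIA) or 1 (IAC).
#' @param center acquisition center, 1 or 2.
#' @param seed integer seed for this nodule's random stream.
#' @param patient_id identifier stored in the clinical record.
#' @return list with `volume` (ct_volume), `mask` (roi_mask), `record`
#'   (one-row data.frame with all cohort-table covariates) and `zones`
#'   (integer array of planted zone labels: 0 background, 1 rim,
#'   2 transition, 3 core — the habitat ground truth).
#' @export
generate_nodule <- function(config, label, center = 1, seed = config$seed,
                            patient_id = "P0001") {
  assert_that(inherits(config, "phantom_config"), "config must be a phantom_config")
  assert_that(label %in% c(0, 1), "label must be 0 or 1")
  cp <- config$class_params[[label + 1L]]
  shape <- config$volume_shape
  spacing <- config$spacing_mm
  ce <- config$center_effects[[as.character(center)]]
  with_seed(seed, {
    L <- max(5, rnorm_clamped(1, cp$long_diameter_mm[1], cp$long_diameter_mm[2]))
    S <- max(4, min(L, rnorm_clamped(1, cp$short_diameter_mm[1], cp$short_diameter_mm[2])))
    m_hu <- rnorm_clamped(1, cp$ct_value_hu[1], cp$ct_value_hu[2])
    m_hu <- min(max(m_hu, -700), -150)
    n_bumps <- stats::rpois(1, cp$n_bumps)
    bump_amp <- rep(cp$bump_amplitude_mm, n_bumps) * stats::runif(n_bumps, 0.6, 1)
    bump_dirs <- matrix(stats::rnorm(3 * n_bumps), ncol = 3)
    if (n_bumps > 0) {
      bump_dirs <- bump_dirs / sqrt(rowSums(bump_dirs^2))
    }
    center_mm <- (shape * spacing) / 2 + stats::runif(3, -1, 1)

    semi <- c(S / 2, S / 2, L / 2) # (z, y, x): long axis along x
    max_amp <- if (n_bumps > 0) max(bump_amp) else 0
    if (any(semi + max_amp + 2 > shape * spacing / 2)) {
      stopf("nodule (semi-axes %.1f/%.1f/%.1f mm + bumps) does not fit volume",
            semi[1], semi[2], semi[3])
    }

    sh <- render_shape(shape, spacing, center_mm, semi, bump_dirs, bump_amp)
    meas <- measure_diameters(sh$support, spacing)
    # two calibration re-renders so measured caliper diameters hit the draws
    for (it in 1:2) {
      semi <- semi * c(S / meas["short"], S / meas["short"], L / meas["long"])
      sh <- render_shape(shape, spacing, center_mm, semi, bump_dirs, bump_amp)
      meas <- measure_diameters(sh$support, spacing)
    }

    support <- sh$support
    assert_that(sum(support) >= 27, "rendered nodule below 27 voxels")

    delta <- config$zone_contrast_hu
    mid_hu <- m_hu + 0.3969 * delta # volume-weighted mean equals m_hu
    zone_hu <- c(mid_hu - delta, mid_hu, mid_hu + delta) # rim, transition, core
    vol <- array(config$background_hu, dim = shape)
    rim <- support & (sh$rho > 0.8)
    mid <- support & (sh$rho <= 0.8) & (sh$rho > 0.45)
    core <- support & (sh$rho <= 0.45)
    vol[rim] <- zone_hu[1]
    vol[mid] <- zone_hu[2]
    vol[core] <- zone_hu[3]
    zones <- array(0L, dim = shape)
    zones[support] <- 1L # bump voxels outside the ellipsoid share the rim value
    zones[rim] <- 1L; zones[mid] <- 2L; zones[core] <- 3L
    vol <- vol + ce$shift_hu +
      array(stats::rnorm(prod(shape), 0, config$noise_sd_hu * ce$noise_mult), dim = shape)

    ct_meas <- mean(vol[support])

    cls0 <- label == 0
    record <- data.frame(
      patient_id = patient_id,
      center = as.integer(center),
      label = as.integer(label),
      gender = sample(c("Male", "Female"), 1,
                      prob = if (cls0) c(61, 124) else c(50, 105)),
      smoking = sample(c("No", "Yes"), 1,
                       prob = if (cls0) c(166, 19) else c(131, 24)),
      location = sample(c("RUL", "RML", "RLL", "LUL", "LLL"), 1,
                        prob = if (cls0) c(57, 11, 27, 57, 33) else c(49, 9, 30, 40, 27)),
      lobulation = sample(c("No", "Yes"), 1,
                          prob = if (cls0) c(72, 113) else c(5, 150)),
      spiculation = sample(c("No", "Yes"), 1,
                           prob = if (cls0) c(148, 37) else c(70, 85)),
      margin = sample(c("Clear", "Unclear"), 1,
                      prob = if (cls0) c(134, 51) else c(83, 72)),
      vessel_changes = sample(c("No", "Yes"), 1,
                              prob = if (cls0) c(99, 86) else c(16, 139)),
      bubble_lucency = sample(c("No", "Yes"), 1,
                              prob = if (cls0) c(139, 46) else c(97, 58)),
      pleural_retraction = sample(c("No", "Yes"), 1,
                                  prob = if (cls0) c(142, 43) else c(68, 87)),
      shape = sample(c("Round", "Irregular"), 1,
                     prob = if (cls0) c(115, 70) else c(27, 128)),
      long_diameter_mm = unname(meas["long"]),
      short_diameter_mm = unname(meas["short"]),
      age_years = if (cls0) rnorm_clamped(1, 51.03, 12.24) else rnorm_clamped(1, 60.35, 8.85),
      nse_ng_ml = exp(if (cls0) rnorm_clamped(1, log(14.53) - 0.5 * log(1 + (5.31 / 14.53)^2),
                                              sqrt(log(1 + (5.31 / 14.53)^2)))
                      else rnorm_clamped(1, log(15.74) - 0.5 * log(1 + (4.81 / 15.74)^2),
                                         sqrt(log(1 + (4.81 / 15.74)^2)))),
      cea_ng_ml = exp(if (cls0) rnorm_clamped(1, log(1.77) - 0.5 * log(1 + (1.17 / 1.77)^2),
                                              sqrt(log(1 + (1.17 / 1.77)^2)))
                      else rnorm_clamped(1, log(2.11) - 0.5 * log(1 + (1.31 / 2.11)^2),
                                         sqrt(log(1 + (1.31 / 2.11)^2)))),
      ct_value_hu = ct_meas,
      stringsAsFactors = FALSE
    )
    list(volume = ct_volume(vol, spacing),
         mask = roi_mask(support, spacing, "rater1"),
         record = record,
         zones = zones)
  })
}

#' Perturb an ROI mask to emulate a second rater
#'
#' Applies a random morphological dilation or erosion with structuring
#' radius drawn uniformly up to `magnitude_mm`, followed by independent
#' flips of boundary voxels. At the default magnitude of 1 mm the Dice
#' overlap with the original mask stays at or above 0.80 for analyzable
#' nodules.
#'
#' @param mask an [roi_mask()].
#' @param magnitude_mm maximum structuring-element radius (>= 0).
#' @param seed integer seed.
#' @param rater_id label for the perturbed mask.
#' @return perturbed [roi_mask()].
#' @export
perturb_mask <- function(mask, magnitude_mm = 1, seed = 1L, rater_id = "rater2") {
  assert_that(inherits(mask, "roi_mask"), "mask must be an roi_mask")
  assert_that(magnitude_mm >= 0, "magnitude must be >= 0")
  if (magnitude_mm == 0) {
    out <- mask
    out$rater_id <- rater_id
    return(out)
  }
  # refuse when the worst-case erosion would empty the mask
  worst <- erode3d(mask$data, magnitude_mm, mask$spacing_mm)
  if (sum(worst) == 0) {
    stopf("perturbation magnitude %.1f mm could empty a %d-voxel mask",
          magnitude_mm, sum(mask$data))
  }
  with_seed(seed, {
    r <- stats::runif(1, 0, magnitude_mm)
    sign <- sample(c(-1, 1), 1)
    m <- if (sign > 0) dilate3d(mask$data, r, mask$spacing_mm)
         else erode3d(mask$data, r, mask$spacing_mm)
    if (sum(m) == 0) m <- mask$data
    bnd <- which(mask_boundary(m))
    flip <- bnd[stats::runif(length(bnd)) < 0.05 * magnitude_mm]
    m[flip] <- !m[flip]
    # boundary flips may orphan voxels but never empty the mask
    if (sum(m) == 0) m <- mask$data
    roi_mask(m, mask$spacing_mm, rater_id)
  })
}

#' Stratified 7:3 train/validation split
#'
#' Splits center-1 samples into training and internal validation cohorts.
#' The validation size is `ceiling(0.3 * N)` (so 487 patients split into
#' 340 training and 147 validation), allocated across classes by largest
#' remainder so that per-split class fractions stay within one sample of
#' the global fraction.
#'
#' @param labels integer vector of class labels (0/1) for center-1 samples.
#' @param val_frac validation fraction (default 0.3).
#' @param seed integer seed for the within-class shuffles.
#' @return list with integer index vectors `train` and `validation`.
#' @export
train_val_split <- function(labels, val_frac = 0.3, seed = 1L) {
  n <- length(labels)
  n_val <- as.integer(ceiling(val_frac * n))
  classes <- sort(unique(labels))
  quota <- n_val * (table(factor(labels, levels = classes)) / n)
  base <- floor(quota)
  rem <- quota - base
  extra <- n_val - sum(base)
  if (extra > 0) {
    ord <- order(rem, decreasing = TRUE)
    base[ord[seq_len(extra)]] <- base[ord[seq_len(extra)]] + 1
  }
  with_seed(seed, {
    val_idx <- integer(0)
    for (i in seq_along(classes)) {
      idx <- which(labels == classes[i])
      val_idx <- c(val_idx, sample(idx, base[i]))
    }
    val_idx <- sort(val_idx)
    list(train = setdiff(seq_len(n), val_idx), validation = val_idx)
  })
}

#' Generate a full synthetic two-center cohort on disk
#'
#' Renders every patient's CT volume, true (rater-1) mask, a rater-2
#' perturbed mask and a rater-1 repeat perturbation (for inter- and
#' intra-rater stability analysis), writes NIfTI volumes/masks, a clinical
#' CSV and a JSON split manifest. Center-1 patients are stratified 7:3 into
#' training/validation; all center-2 patients form the external test cohort.
#'
#' @param out_dir output directory (created if missing).
#' @param config a [phantom_config()].
#' @param n_center1,n_center2 patients per center (each >= 20).
#' @param class_balance fraction of IAC (class 1) patients.
#' @param seed master seed; the full bundle is byte-reproducible from
#'   (config, seed).
#' @param rater2_magnitude_mm,repeat_magnitude_mm perturbation magnitudes
#'   for the second rater and the intra-rater repeat.
#' @param write if `FALSE`, skip NIfTI/CSV output and return everything in
#'   memory (used for desk-scale analysis without I/O).
#' @return invisibly, a list with `clinical` (data.frame), `manifest`
#'   (split assignment) and `nodules` (list of per-patient volume/mask
#'   bundles).
#' @export
generate_cohort <- function(out_dir = NULL, config = phantom_config(),
                            n_center1 = 40L, n_center2 = 20L,
                            class_balance = 0.45, seed = config$seed,
                            rater2_magnitude_mm = 1, repeat_magnitude_mm = 0.6,
                            write = !is.null(out_dir)) {
  assert_that(n_center1 >= 20 && n_center2 >= 20, "need >= 20 patients per center")
  n_tot <- n_center1 + n_center2
  centers <- rep(c(1L, 2L), c(n_center1, n_center2))
  labels <- integer(n_tot)
  with_seed(derive_seed(seed, 0L), {
    for (cen in 1:2) {
      idx <- which(centers == cen)
      n1 <- round(class_balance * length(idx))
      lab <- c(rep(1L, n1), rep(0L, length(idx) - n1))
      labels[idx] <- sample(lab)
    }
  })
  split1 <- train_val_split(labels[centers == 1], 0.3, derive_seed(seed, 1L))
  cohort <- character(n_tot)
  idx1 <- which(centers == 1)
  cohort[idx1[split1$train]] <- "train"
  cohort[idx1[split1$validation]] <- "validation"
  cohort[centers == 2] <- "test"
  counts <- table(cohort, labels)
  if (any(counts < 5)) {
    stopf("a class has fewer than 5 samples in some split; increase n or rebalance")
  }

  nodules <- vector("list", n_tot)
  records <- vector("list", n_tot)
  for (i in seq_len(n_tot)) {
    pid <- sprintf("P%04d", i)
    nd <- generate_nodule(config, labels[i], centers[i],
                          seed = derive_seed(seed, 100L + i), patient_id = pid)
    nd$mask_rater2 <- perturb_mask(nd$mask, rater2_magnitude_mm,
                                   seed = derive_seed(seed, 200000L + i), "rater2")
    nd$mask_rater1b <- perturb_mask(nd$mask, repeat_magnitude_mm,
                                    seed = derive_seed(seed, 400000L + i), "rater1b")
    nodules[[i]] <- nd
    records[[i]] <- nd$record
  }
  clinical <- do.call(rbind, records)
  clinical$cohort <- cohort
  manifest <- list(seed = seed,
                   n_center1 = n_center1, n_center2 = n_center2,
                   patient_id = clinical$patient_id,
                   center = centers, label = labels, cohort = cohort)

  if (write) {
    dir.create(file.path(out_dir, "volumes"), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(out_dir, "masks"), recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n_tot)) {
      pid <- clinical$patient_id[i]
      write_nifti_volume(nodules[[i]]$volume$data, config$spacing_mm,
                         file.path(out_dir, "volumes", paste0(pid, ".nii.gz")))
      write_nifti_volume(nodules[[i]]$mask$data * 1, config$spacing_mm,
                         file.path(out_dir, "masks", paste0(pid, "_rater1.nii.gz")))
      write_nifti_volume(nodules[[i]]$mask_rater2$data * 1, config$spacing_mm,
                         file.path(out_dir, "masks", paste0(pid, "_rater2.nii.gz")))
      write_nifti_volume(nodules[[i]]$mask_rater1b$data * 1, config$spacing_mm,
                         file.path(out_dir, "masks", paste0(pid, "_rater1b.nii.gz")))
    }
    utils::write.csv(clinical, file.path(out_dir, "clinical.csv"), row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(list(clinical = clinical, manifest = manifest, nodules = nodules))
}

#' Write a 3D array as NIfTI
#'
#' Arrays are stored in (z, y, x) axis order with the given spacing in mm.
#'
#' @param data 3D numeric array.
#' @param spacing_mm per-axis spacing.
#' @param path output path (`.nii` or `.nii.gz`).
#' @export
write_nifti_volume <- function(data, spacing_mm, path) {
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- spacing_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume written by this package
#'
#' @param path NIfTI file path.
#' @return list with `data` (3D array) and `spacing_mm`.
#' @export
read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  list(data = array(as.numeric(img), dim = dim(img)),
       spacing_mm = as.numeric(RNifti::pixdim(img)))
}
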