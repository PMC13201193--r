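# Phantom generator: geometry, attenuation, determinism, splits.

test_that("noise-free bump-free support equals the brute-force discrete ellipsoid", {
  shape <- c(32L, 32L, 32L)
  semi <- c(4, 4, 5) # (z, y, x) semi-axes in mm
  center <- c(16.2, 16.4, 16.1)
  sh <- habfuse:::render_shape(shape, c(1, 1, 1), center, semi,
                               matrix(0, 0, 3), numeric(0))
  # independent oracle: direct triple loop over voxel centers
  cnt <- 0L
  for (z in 1:32) for (y in 1:32) for (x in 1:32) {
    r2 <- ((z - 0.5 - center[1]) / semi[1])^2 +
      ((y - 0.5 - center[2]) / semi[2])^2 +
      ((x - 0.5 - center[3]) / semi[3])^2
    if (r2 <= 1) cnt <- cnt + 1L
  }
  expect_identical(sum(sh$support), cnt)
})

test_that("same seed gives bit-identical volume, mask and record", {
  cfg <- phantom_config()
  a <- generate_nodule(cfg, 1, seed = 9)
  b <- generate_nodule(cfg, 1, seed = 9)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$mask$data, b$mask$data)
  expect_identical(a$record, b$record)
  c <- generate_nodule(cfg, 1, seed = 10)
  expect_false(identical(a$volume$data, c$volume$data))
})

test_that("IAC long diameters match the configured class mean within 2 SEM", {
  cfg <- phantom_config()
  L <- vapply(1:200, function(i) {
    generate_nodule(cfg, 1, seed = 5000 + i)$record$long_diameter_mm
  }, 0)
  sem <- sd(L) / sqrt(length(L))
  expect_lt(abs(mean(L) - 15.66), 2 * sem)
})

test_that("phantom mean HU inside the mask matches the clinical record", {
  nd <- fixture_nodule(1, 42)
  expect_equal(mean(nd$volume$data[nd$mask$data]), nd$record$ct_value_hu)
  # every mask voxel lies inside the volume (congruent shapes)
  expect_identical(dim(nd$mask$data), dim(nd$volume$data))
})

test_that("center effect shifts background HU by the configured amount", {
  cfg <- phantom_config()
  shift <- cfg$center_effects[["2"]]$shift_hu
  bg <- function(center, seed) {
    nd <- generate_nodule(cfg, 0, center = center, seed = seed)
    out <- nd$volume$data[!habfuse:::dilate3d(nd$mask$data, 3)]
    c(mean(out), length(out))
  }
  m1 <- vapply(1:6, function(i) bg(1, 300 + i)[1], 0)
  m2 <- vapply(1:6, function(i) bg(2, 400 + i)[1], 0)
  # SEM of a background mean is tiny (1e5 voxels); use the noise model bound
  sem <- cfg$noise_sd_hu / sqrt(40000)
  expect_lt(abs((mean(m2) - mean(m1)) - shift), 2 * sem * 10)
})

test_that("mask perturbation respects magnitude, Dice floor and refusal guard", {
  nd <- fixture_zone_nodule()
  p0 <- perturb_mask(nd$mask, 0, seed = 1)
  expect_identical(p0$data, nd$mask$data)

  p1 <- perturb_mask(nd$mask, 1, seed = 3)
  d <- dice_between_masks(nd$mask$data, p1$data)
  expect_gte(d, 0.80)
  expect_lt(d, 1.0)

  tiny <- array(FALSE, dim = c(12, 12, 12))
  tiny[5:7, 5:7, 5:7] <- TRUE # 27 voxels
  expect_error(perturb_mask(roi_mask(tiny), 5, seed = 1), "empty")
})

test_that("center-1 split reproduces the 7:3 ceiling rule and stratification", {
  labels487 <- rep(c(0L, 1L), c(263L, 224L))
  sp <- train_val_split(labels487, 0.3, seed = 2)
  expect_equal(length(sp$validation), 147L)
  expect_equal(length(sp$train), 340L)

  sp10 <- train_val_split(rep(c(0L, 1L), 5), 0.3, seed = 2)
  expect_equal(length(sp10$validation), 3L)
  expect_equal(length(sp10$train), 7L)

  # per-split class fraction within 1 sample of the global fraction
  glob <- mean(labels487)
  for (part in sp) {
    expect_lte(abs(sum(labels487[part]) - glob * length(part)), 1)
  }
})

test_that("cohort bundle writes NIfTI, CSV and manifest and round-trips", {
  dir <- withr::local_tempdir()
  cfg <- phantom_config(volume_shape = c(40L, 40L, 40L))
  res <- suppressMessages(generate_cohort(dir, cfg, n_center1 = 34L,
                                          n_center2 = 20L, seed = 77))
  expect_equal(nrow(res$clinical), 54L)
  expect_setequal(unique(res$clinical$cohort), c("train", "validation", "test"))
  expect_true(all(res$clinical$cohort[res$clinical$center == 2] == "test"))

  csv <- read.csv(file.path(dir, "clinical.csv"))
  expect_equal(nrow(csv), 54L)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  expect_equal(man$cohort, res$clinical$cohort)

  rt <- read_nifti_volume(file.path(dir, "volumes", "P0001.nii.gz"))
  expect_equal(rt$data, res$nodules[[1]]$volume$data, tolerance = 1e-6)
  mk <- read_nifti_volume(file.path(dir, "masks", "P0001_rater1.nii.gz"))
  expect_identical(mk$data > 0.5, res$nodules[[1]]$mask$data)
})

test_that("undersized cohorts and unsplittable classes are refused", {
  expect_error(generate_cohort(NULL, phantom_config(), n_center1 = 10L,
                               n_center2 = 20L, write = FALSE), ">= 20")
  expect_error(suppressMessages(
    generate_cohort(NULL, phantom_config(), n_center1 = 20L, n_center2 = 20L,
                    class_balance = 0.1, seed = 3, write = FALSE)),
    "fewer than 5")
})
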