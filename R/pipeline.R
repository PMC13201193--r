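# End-to-end desk-scale study: synthetic cohort -> preprocessing ->
# habitats -> feature streams -> base models -> early/late fusion ->
# evaluation. One seeded call reproduces the whole analysis.

#' Run the full multi-stream GGN study on a synthetic cohort
#'
#' Generates a two-center cohort, preprocesses every volume (lung window +
#' isotropic resampling), fits pooled habitat centroids on training
#' nodules, extracts radiomics/habitat/deep/clinic feature streams, applies
#' ICC stability filtering to the radiomics stream, trains the four base
#' models plus early and late fusion, and evaluates everything on the
#' train/validation/test cohorts.
#'
#' Desk-scale defaults keep runtimes small: modest cohort sizes, a reduced
#' radiomics filter bank, and a shallow 2D embedding network. Every source
#' of randomness derives from `seed`, making the entire study reproducible.
#'
#' @param n_center1,n_center2 patients per center.
#' @param config a [phantom_config()].
#' @param seed master seed.
#' @param radiomics_config a [feature_config()]; default reduced bank
#'   (original, LoG sigma 3, exponential; first order + GLCM + GLSZM).
#' @param dl_spec a [net_spec()]; default depth-18 2D at side 32.
#' @param stability logical: run the two-rater ICC stability filter on the
#'   radiomics stream (doubles extraction work).
#' @param mrmr_k selection chain width.
#' @return list with `cohort`, `habitat_fit`, `streams` (feature tables),
#'   `models`, `predictions`, `labels`, `metrics` (model x cohort table)
#'   and `stability` (when enabled).
#' @export
run_ggn_study <- function(n_center1 = 40L, n_center2 = 20L,
                          config = phantom_config(), seed = 1L,
                          radiomics_config = feature_config(
                            filters = c("original", "log_sigma_3_0_mm_3D",
                                        "exponential"),
                            families = c("firstorder", "shape", "glcm", "glszm")),
                          dl_spec = net_spec(18, "2D", input_side = 32),
                          stability = FALSE, mrmr_k = 15) {
  cohort <- generate_cohort(out_dir = NULL, config = config,
                            n_center1 = n_center1, n_center2 = n_center2,
                            seed = seed, write = FALSE)
  clin <- cohort$clinical
  n <- nrow(clin)
  labels <- clin$label
  cohorts <- clin$cohort
  train_idx <- which(cohorts == "train")
  wspec <- window_spec()

  pre <- lapply(cohort$nodules, function(nd) {
    rs <- resample_isotropic(nd$volume, nd$mask)
    list(volume = rs$volume, windowed = apply_window(rs$volume, wspec),
         mask = rs$mask, nodule = nd)
  })

  vf <- lapply(pre, function(p) voxel_local_features(p$windowed, p$mask))
  pooled <- pool_voxel_features(vf[train_idx], cap = 2000L,
                                seed = derive_seed(seed, 3L))
  hab_fit <- fit_habitats(pooled, k_range = 2:9, seed = derive_seed(seed, 5L))
  hab_masks <- lapply(seq_len(n), function(i) {
    export_habitat_masks(label_habitats(hab_fit, vf[[i]]))
  })

  feats <- lapply(seq_len(n), function(i) {
    extract_all_streams(pre[[i]]$volume, pre[[i]]$mask, hab_masks[[i]],
                        radiomics_config)
  })
  rad_tab <- do.call(rbind, lapply(feats, `[[`, "radiomics"))
  hab_tab <- do.call(rbind, lapply(feats, `[[`, "habitat"))
  colnames(rad_tab) <- paste0("rad_", colnames(rad_tab))
  colnames(hab_tab) <- paste0("hab_", colnames(hab_tab))

  stab <- NULL
  if (stability) {
    sub_cfg <- radiomics_config
    f2 <- do.call(rbind, lapply(seq_len(n), function(i) {
      rs <- resample_isotropic(cohort$nodules[[i]]$volume,
                               cohort$nodules[[i]]$mask_rater2)
      extract_features(rs$volume, rs$mask, sub_cfg)
    }))
    f1b <- do.call(rbind, lapply(seq_len(n), function(i) {
      rs <- resample_isotropic(cohort$nodules[[i]]$volume,
                               cohort$nodules[[i]]$mask_rater1b)
      extract_features(rs$volume, rs$mask, sub_cfg)
    }))
    f1 <- do.call(rbind, lapply(feats, `[[`, "radiomics"))
    stab <- stability_filter(f1[train_idx, , drop = FALSE],
                             f2[train_idx, , drop = FALSE],
                             f1b[train_idx, , drop = FALSE])
    keep <- paste0("rad_", stab$retained)
    rad_tab <- rad_tab[, intersect(colnames(rad_tab), keep), drop = FALSE]
  }

  net <- build_network(dl_spec, seed = derive_seed(seed, 7L))
  pspec <- patch_spec(dl_spec$mode, side_voxels = dl_spec$input_side)
  patches <- lapply(pre, function(p) extract_patch(p$windowed, p$mask, pspec))
  dl_tab <- extract_embeddings(net, patches)

  clinic_tab <- clinic_design_matrix(clin)
  batch <- clin$center

  streams <- list(clinic = clinic_tab, radiomics = rad_tab,
                  habitat = hab_tab, DL = dl_tab)

  models <- list()
  models$clinic <- fit_clinic_model(clinic_tab, labels, train_idx,
                                    seed = derive_seed(seed, 11L))
  models$radiomics <- fit_stream_model(rad_tab, labels, train_idx, "radiomics",
                                       batch_labels = batch,
                                       combat_fit_on = seq_len(n),
                                       seed = derive_seed(seed, 13L),
                                       mrmr_k = mrmr_k)
  # habitat occupancy varies per patient (small subregions go missing), so
  # the habitat stream uses a laxer drop threshold with median imputation
  models$habitat <- fit_stream_model(hab_tab, labels, train_idx, "habitat",
                                     batch_labels = batch,
                                     combat_fit_on = seq_len(n),
                                     seed = derive_seed(seed, 15L),
                                     mrmr_k = mrmr_k, max_missing_frac = 0.5)
  models$DL <- fit_stream_model(dl_tab, labels, train_idx, "DL",
                                seed = derive_seed(seed, 17L),
                                mrmr_k = mrmr_k)

  early_tables <- list(clinic = clinic_tab, radiomics = rad_tab,
                       habitat = hab_tab, DL = dl_tab)
  models$early <- early_fusion(early_tables, labels, train_idx,
                               seed = derive_seed(seed, 19L), mrmr_k = mrmr_k,
                               max_missing_frac = 0.5)
  models$late <- late_fusion(streams, labels, train_idx,
                             batch_streams = c("radiomics", "habitat"),
                             batch_labels = batch,
                             clinic_streams = "clinic",
                             seed = derive_seed(seed, 21L), mrmr_k = mrmr_k,
                             max_missing_frac = 0.5)

  cohort_names <- c("train", "validation", "test")
  lab_list <- lapply(cohort_names, function(co) labels[cohorts == co])
  names(lab_list) <- cohort_names
  preds <- list()
  for (mn in names(models)) {
    pv <- if (mn == "late") {
      predict(models$late, streams, batch_labels = batch)
    } else if (mn == "clinic") {
      predict_stream(models$clinic, clinic_tab)
    } else if (mn == "early") {
      predict_stream(models$early, do.call(cbind, unname(early_tables)))
    } else {
      bl <- if (mn %in% c("radiomics", "habitat")) batch else NULL
      predict_stream(models[[mn]], streams[[mn]], bl)
    }
    preds[[mn]] <- lapply(cohort_names, function(co) pv[cohorts == co])
    names(preds[[mn]]) <- cohort_names
  }

  list(cohort = cohort, habitat_fit = hab_fit, streams = streams,
       models = models, predictions = preds, labels = lab_list,
       metrics = metrics_table(preds, lab_list), stability = stab,
       train_idx = train_idx, batch = batch)
}
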