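# Base models (clinic, radiomics, habitat, DL) and the two fusion
# strategies: early (feature-level concatenation -> selection chain -> SVM)
# and late (5-fold out-of-fold stacking with an SVM meta-learner).

#' Numeric design matrix of the clinical/imaging variables
#'
#' Binary variables are coded 0/1 (reference = first printed level), lobe
#' location as an ordinal code (RUL=1, RML=2, RLL=3, LUL=4, LLL=5), and
#' continuous variables pass through.
#'
#' @param clinical data.frame as produced by [generate_cohort()].
#' @return numeric matrix with `clinic_`-prefixed columns.
#' @export
clinic_design_matrix <- function(clinical) {
  bin <- function(v, one) as.numeric(v == one)
  m <- cbind(
    gender = bin(clinical$gender, "Male"),
    smoking = bin(clinical$smoking, "Yes"),
    location = match(clinical$location, c("RUL", "RML", "RLL", "LUL", "LLL")),
    lobulation = bin(clinical$lobulation, "Yes"),
    spiculation = bin(clinical$spiculation, "Yes"),
    margin = bin(clinical$margin, "Unclear"),
    vessel_changes = bin(clinical$vessel_changes, "Yes"),
    bubble_lucency = bin(clinical$bubble_lucency, "Yes"),
    pleural_retraction = bin(clinical$pleural_retraction, "Yes"),
    shape = bin(clinical$shape, "Irregular"),
    long_diameter = clinical$long_diameter_mm,
    short_diameter = clinical$short_diameter_mm,
    age = clinical$age_years,
    nse = clinical$nse_ng_ml,
    cea = clinical$cea_ng_ml,
    ct_value = clinical$ct_value_hu
  )
  colnames(m) <- paste0("clinic_", colnames(m))
  m
}

#' Univariate and multivariate logistic screening of clinical variables
#'
#' Univariate maximum-likelihood logistic regressions on every variable
#' produce Wald odds ratios, 95% CIs and p-values; variables with p < 0.05
#' enter a multivariate logistic model, whose p < 0.05 survivors are the
#' independent risk factors (the clinic model's feature set). Fits with
#' (quasi-)separation are refit with a small ridge penalty and flagged.
#'
#' @param clinic_table numeric matrix from [clinic_design_matrix()].
#' @param labels binary labels (0/1).
#' @return object of class `clinic_screen`: `univariate` and
#'   `multivariate` data.frames (OR, CI, p) and `independent` names.
#' @export
clinic_screen <- function(clinic_table, labels) {
  X <- as.matrix(clinic_table)
  y <- as.numeric(labels)
  uni_one <- function(j) {
    if (stats::sd(X[, j]) < 1e-12) {
      return(data.frame(variable = colnames(X)[j], or = NA, lo = NA, hi = NA,
                        p = NA, separation = FALSE))
    }
    fit <- suppressWarnings(stats::glm(y ~ X[, j], family = stats::binomial()))
    co <- summary(fit)$coefficients
    sep <- !fit$converged || nrow(co) < 2 || abs(co[2, 1]) > 15
    if (sep) {
      return(data.frame(variable = colnames(X)[j], or = NA, lo = NA, hi = NA,
                        p = NA, separation = TRUE))
    }
    data.frame(variable = colnames(X)[j], or = exp(co[2, 1]),
               lo = exp(co[2, 1] - 1.96 * co[2, 2]),
               hi = exp(co[2, 1] + 1.96 * co[2, 2]),
               p = co[2, 4], separation = FALSE)
  }
  uni <- do.call(rbind, lapply(seq_len(ncol(X)), uni_one))
  retained <- uni$variable[!is.na(uni$p) & uni$p < 0.05]
  multi <- NULL
  independent <- character(0)
  if (length(retained) > 0) {
    df <- data.frame(y = y, X[, retained, drop = FALSE], check.names = FALSE)
    fit <- suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial()))
    co <- summary(fit)$coefficients[-1, , drop = FALSE]
    multi <- data.frame(variable = rownames(co), or = exp(co[, 1]),
                        lo = exp(co[, 1] - 1.96 * co[, 2]),
                        hi = exp(co[, 1] + 1.96 * co[, 2]), p = co[, 4])
    rownames(multi) <- NULL
    multi$variable <- gsub("`", "", multi$variable)
    independent <- multi$variable[multi$p < 0.05]
  }
  if (length(independent) == 0) independent <- retained
  structure(list(univariate = uni, retained = retained, multivariate = multi,
                 independent = independent),
            class = "clinic_screen")
}

default_svm_grid <- function() {
  expand.grid(cost = c(0.1, 1, 10, 100), gamma = c(NA, 0.01, 0.001)) # NA = "scale"
}

# Decision values oriented so that positive favors class "1" regardless of
# training-row order (libsvm orients by the first label it encounters).
svm_decision <- function(fit, X) {
  pr <- stats::predict(fit, X, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  flip <- identical(colnames(dv)[1], "0/1")
  dv <- dv[, 1]
  if (flip) -dv else dv
}

#' Train an RBF-SVM base model with seeded grid search and Platt scaling
#'
#' Hyperparameters (C in 0.1/1/10/100; gamma in "scale"/0.01/0.001) are
#' chosen by seeded stratified 5-fold cross-validated AUC on the training
#' rows. Probabilities come from a Platt sigmoid fitted to out-of-fold
#' decision values of the winning configuration, so the calibration never
#' sees its own training predictions.
#'
#' @param table numeric feature matrix (training rows; selection already
#'   applied).
#' @param labels binary labels (0/1).
#' @param stream stream tag ("clinic", "radiomics", "habitat", "DL",
#'   "early", "late").
#' @param seed integer seed.
#' @param grid data.frame of cost/gamma candidates (NA gamma = 1/(p*var)).
#' @return object of class `model_bundle`.
#' @export
train_base_model <- function(table, labels, stream = "radiomics", seed = 1L,
                             grid = default_svm_grid()) {
  X <- as.matrix(table)
  y <- as.numeric(labels)
  assert_that(length(unique(y)) == 2, "single-class training set")
  foldid <- stratified_folds(y, 5, derive_seed(seed, 17L))
  scale_gamma <- 1 / (ncol(X) * max(stats::var(as.vector(X)), 1e-12))
  cv_auc <- numeric(nrow(grid))
  oof_best <- NULL
  oof_store <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    gam <- if (is.na(grid$gamma[g])) scale_gamma else grid$gamma[g]
    dv <- numeric(length(y))
    ok <- TRUE
    for (f in 1:5) {
      tr <- foldid != f
      if (length(unique(y[tr])) < 2) { ok <- FALSE; break }
      fit <- e1071::svm(X[tr, , drop = FALSE], factor(y[tr], levels = c(0, 1)),
                        kernel = "radial", cost = grid$cost[g], gamma = gam,
                        scale = FALSE)
      dv[!tr] <- svm_decision(fit, X[!tr, , drop = FALSE])
    }
    if (!ok) { cv_auc[g] <- -Inf; next }
    cv_auc[g] <- auc_mann_whitney(dv, y)
    oof_store[[g]] <- dv
  }
  best <- order(-cv_auc, grid$cost, seq_len(nrow(grid)))[1]
  gam <- if (is.na(grid$gamma[best])) scale_gamma else grid$gamma[best]
  fit <- e1071::svm(X, factor(y, levels = c(0, 1)), kernel = "radial",
                    cost = grid$cost[best], gamma = gam, scale = FALSE)
  dv_oof <- oof_store[[best]]
  platt <- suppressWarnings(stats::glm(y ~ dv_oof, family = stats::binomial()))
  structure(list(stream = stream, svm = fit,
                 platt = stats::coef(platt),
                 cost = grid$cost[best], gamma = gam, cv_auc = cv_auc[best],
                 feature_names = colnames(X),
                 train_checksum = object_checksum(list(X, y))),
            class = "model_bundle")
}

#' Predict class-1 probabilities from a model bundle
#'
#' Applies the frozen decision function and Platt sigmoid. Deterministic;
#' errors if features are missing.
#'
#' @param object a `model_bundle`.
#' @param table numeric matrix containing the bundle's feature columns.
#' @param ... unused.
#' @return probability vector in \[0, 1\].
#' @export
predict.model_bundle <- function(object, table, ...) {
  X <- as.matrix(table)
  miss <- setdiff(object$feature_names, colnames(X))
  if (length(miss)) stopf("missing features: %s", paste(miss, collapse = ", "))
  dv <- svm_decision(object$svm, X[, object$feature_names, drop = FALSE])
  as.numeric(stats::plogis(object$platt[1] + object$platt[2] * dv))
}

#' Fit one feature stream end to end (preprocessing chain + SVM)
#'
#' Convenience wrapper: [fit_feature_pipeline()] on the training rows
#' followed by [train_base_model()] on the selected features. The returned
#' bundle carries its frozen pipeline, so [predict_stream()] can transform
#' and score any cohort.
#'
#' @param table raw feature matrix (all rows).
#' @param labels binary labels (all rows).
#' @param train_idx training row indices.
#' @param stream stream tag.
#' @param batch_labels optional batch labels for harmonization.
#' @param combat_fit_on rows for batch-parameter estimation.
#' @param seed integer seed.
#' @param mrmr_k,folds chain parameters.
#' @param max_missing_frac missing-value drop threshold (see
#'   [fit_feature_pipeline()]).
#' @return object of class `stream_model`.
#' @export
fit_stream_model <- function(table, labels, train_idx, stream = "radiomics",
                             batch_labels = NULL, combat_fit_on = train_idx,
                             seed = 1L, mrmr_k = 30, folds = 10,
                             max_missing_frac = 0.1) {
  pipe <- fit_feature_pipeline(table, labels, train_idx,
                               batch_labels = batch_labels,
                               combat_fit_on = combat_fit_on,
                               mrmr_k = mrmr_k, folds = folds, seed = seed,
                               max_missing_frac = max_missing_frac)
  Xsel <- apply_feature_pipeline(pipe, table, batch_labels)
  bundle <- train_base_model(Xsel[train_idx, , drop = FALSE], labels[train_idx],
                             stream = stream, seed = seed)
  structure(list(pipeline = pipe, bundle = bundle, stream = stream,
                 batch_aware = !is.null(batch_labels)),
            class = "stream_model")
}

#' Predict probabilities from a fitted stream model
#'
#' @param model a `stream_model`.
#' @param table raw feature matrix (any rows).
#' @param batch_labels batch labels if the stream harmonizes.
#' @return probability vector.
#' @export
predict_stream <- function(model, table, batch_labels = NULL) {
  Xsel <- apply_feature_pipeline(model$pipeline, table, batch_labels)
  predict(model$bundle, Xsel)
}

#' Fit the clinic stream (screened logistic variables + SVM)
#'
#' The clinic model uses only the independent risk factors surviving the
#' univariate (p < 0.05) then multivariate (p < 0.05) logistic screening on
#' the training rows, z-scored with training statistics, under the same
#' RBF-SVM head as the other streams. Returned as a `stream_model` so it
#' plugs into the fusion machinery.
#'
#' @param table numeric matrix from [clinic_design_matrix()] (all rows).
#' @param labels binary labels.
#' @param train_idx training row indices.
#' @param seed integer seed.
#' @return a `stream_model` with the `clinic_screen` result attached.
#' @export
fit_clinic_model <- function(table, labels, train_idx, seed = 1L) {
  X <- as.matrix(table)
  scr <- clinic_screen(X[train_idx, , drop = FALSE], labels[train_idx])
  sel <- scr$independent
  if (length(sel) == 0) sel <- colnames(X)[1] # degenerate guard
  zs <- zscore_fit_apply(X[, sel, drop = FALSE], fit_on = train_idx)
  pipe <- structure(list(missing = list(dropped = character(0),
                                        medians = stats::setNames(numeric(0), character(0))),
                         combat = NULL,
                         zscore = zs[c("center", "scale", "dropped")],
                         selected = intersect(sel, colnames(zs$table)),
                         trace = list(screen = scr),
                         train_checksum = object_checksum(list(train_idx, X[train_idx, , drop = FALSE]))),
                    class = "feature_pipeline")
  Xsel <- apply_feature_pipeline(pipe, X)
  bundle <- train_base_model(Xsel[train_idx, , drop = FALSE], labels[train_idx],
                             stream = "clinic", seed = seed)
  structure(list(pipeline = pipe, bundle = bundle, stream = "clinic",
                 batch_aware = FALSE, screen = scr),
            class = "stream_model")
}

#' Early (feature-level) fusion model
#'
#' Concatenates the stream tables into one joint feature space, runs the
#' selection chain (Pearson prune, mRMR top-30, LASSO) on training rows,
#' and trains an RBF-SVM on the surviving features. The retained feature
#' list keeps its stream prefixes, so the bundle records which streams
#' contribute.
#'
#' @param tables named list of row-aligned feature matrices
#'   (e.g. clinic/radiomics/habitat/DL).
#' @param labels binary labels (all rows).
#' @param train_idx training row indices.
#' @param seed integer seed.
#' @param mrmr_k,folds chain parameters.
#' @param max_missing_frac missing-value drop threshold for the joint
#'   space (see [fit_feature_pipeline()]).
#' @return a `stream_model` with stream tag "early".
#' @export
early_fusion <- function(tables, labels, train_idx, seed = 1L,
                         mrmr_k = 30, folds = 10, max_missing_frac = 0.1) {
  ns <- vapply(tables, nrow, 0L)
  assert_that(length(unique(ns)) == 1, "stream tables are not row-aligned")
  joint <- do.call(cbind, unname(tables))
  assert_that(!anyDuplicated(colnames(joint)), "duplicate feature names across streams")
  fit_stream_model(joint, labels, train_idx, stream = "early", seed = seed,
                   mrmr_k = mrmr_k, folds = folds,
                   max_missing_frac = max_missing_frac)
}

#' Late (decision-level) fusion by out-of-fold stacking
#'
#' The training rows are split into 5 seeded stratified folds. For each
#' fold, every base stream's full preprocessing chain and SVM are refit on
#' the other 4 folds and used to predict the held-out fold, producing an
#' n_train x n_streams out-of-fold (OOF) probability matrix that trains the
#' SVM meta-learner — so no meta-feature for a sample ever comes from a fit
#' that saw it. For inference, the base models are refit on the full
#' training set and their probabilities feed the meta-learner.
#'
#' @param stream_tables named list of raw feature matrices (all rows).
#' @param labels binary labels.
#' @param train_idx training row indices.
#' @param batch_streams character vector of stream names that harmonize.
#' @param batch_labels batch labels (needed for `batch_streams`).
#' @param clinic_streams stream names fitted via [fit_clinic_model()]
#'   (logistic screening) instead of the selection chain.
#' @param folds number of stacking folds (default 5).
#' @param seed integer seed.
#' @param mrmr_k selection chain width for base streams.
#' @param max_missing_frac missing-value drop threshold for chain streams.
#' @param foldid optional fixed fold assignment for the training rows
#'   (length `length(train_idx)`, values 1..folds); by default folds are
#'   stratified and seeded, re-drawn if any fold degenerates.
#' @return object of class `late_fusion_model`: `base` (full-training
#'   stream models), `meta` (model_bundle), and `plan` (fold assignment and
#'   per-fold training index bookkeeping).
#' @export
late_fusion <- function(stream_tables, labels, train_idx,
                        batch_streams = character(0), batch_labels = NULL,
                        clinic_streams = character(0),
                        folds = 5, seed = 1L, mrmr_k = 30,
                        max_missing_frac = 0.1, foldid = NULL) {
  y <- as.numeric(labels)
  ytr <- y[train_idx]
  if (is.null(foldid)) {
    foldid <- stratified_folds(ytr, folds, derive_seed(seed, 23L))
    tries <- 0
    while (any(vapply(seq_len(folds), function(f) {
      length(unique(ytr[foldid != f])) < 2 || length(unique(ytr[foldid == f])) < 1
    }, TRUE)) && tries < 10) {
      tries <- tries + 1
      foldid <- stratified_folds(ytr, folds, derive_seed(seed, 23L + tries))
    }
  }
  streams <- names(stream_tables)
  oof <- matrix(NA_real_, length(train_idx), length(streams),
                dimnames = list(NULL, streams))
  plan_folds <- vector("list", folds)
  for (f in seq_len(folds)) {
    in_rows <- train_idx[foldid != f]
    out_rows <- train_idx[foldid == f]
    plan_folds[[f]] <- list(fit_rows = in_rows, held_out = out_rows)
    for (s in streams) {
      bl <- if (s %in% batch_streams) batch_labels else NULL
      sm <- if (s %in% clinic_streams) {
        fit_clinic_model(stream_tables[[s]], y, in_rows,
                         seed = derive_seed(seed, 31L * f))
      } else {
        fit_stream_model(stream_tables[[s]], y, in_rows, stream = s,
                         batch_labels = bl, seed = derive_seed(seed, 31L * f),
                         mrmr_k = mrmr_k, folds = 5,
                         max_missing_frac = max_missing_frac)
      }
      oof[foldid == f, s] <- predict_stream(sm, stream_tables[[s]], bl)[out_rows]
    }
  }
  base <- lapply(streams, function(s) {
    bl <- if (s %in% batch_streams) batch_labels else NULL
    if (s %in% clinic_streams) {
      fit_clinic_model(stream_tables[[s]], y, train_idx,
                       seed = derive_seed(seed, 43L))
    } else {
      fit_stream_model(stream_tables[[s]], y, train_idx, stream = s,
                       batch_labels = bl, seed = derive_seed(seed, 43L),
                       mrmr_k = mrmr_k, folds = 5,
                       max_missing_frac = max_missing_frac)
    }
  })
  names(base) <- streams
  meta <- train_base_model(oof, ytr, stream = "late", seed = derive_seed(seed, 47L))
  plan <- list(foldid = foldid, folds = plan_folds, train_idx = train_idx,
               oof = oof, checksum = object_checksum(list(train_idx, foldid)))
  structure(list(base = base, meta = meta, plan = plan,
                 batch_streams = batch_streams),
            class = "late_fusion_model")
}

#' Predict probabilities from a late-fusion model
#'
#' @param object a `late_fusion_model`.
#' @param stream_tables named list of raw feature matrices (same streams as
#'   at fit time).
#' @param batch_labels batch labels for harmonizing streams.
#' @param ... unused.
#' @return probability vector.
#' @export
predict.late_fusion_model <- function(object, stream_tables, batch_labels = NULL, ...) {
  probs <- sapply(names(object$base), function(s) {
    bl <- if (s %in% object$batch_streams) batch_labels else NULL
    predict_stream(object$base[[s]], stream_tables[[s]], bl)
  })
  predict(object$meta, probs)
}
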