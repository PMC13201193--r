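# Batch harmonization, standardization, and the three-stage feature
# selection chain (Pearson prune -> mRMR top-30 -> LASSO with 10-fold CV).

#' Empirical-Bayes batch harmonization with frozen parameters
#'
#' Parametric location/scale (ComBat-style) adjustment. Per-feature grand
#' mean and pooled variance plus per-batch empirical-Bayes location
#' (gamma*) and scale (delta*) posteriors are estimated on `fit_on` rows
#' only, then applied to every row, so validation/test data never influence
#' the transform. Zero-variance features pass through untouched with a
#' warning; with a single batch among the fit rows the transform is the
#' identity (warning).
#'
#' @param table numeric matrix (samples x features).
#' @param batch_labels batch (center/scanner) label per row.
#' @param fit_on row indices used for estimation (default all rows).
#' @return list with `table` (harmonized matrix) and `model` (class
#'   `combat_model`) for re-application via [combat_apply()].
#' @export
combat_fit_apply <- function(table, batch_labels, fit_on = seq_len(nrow(table))) {
  X <- as.matrix(table)
  batch <- factor(batch_labels)
  fit_batch <- droplevels(batch[fit_on])
  if (nlevels(fit_batch) < 2) {
    warning("single batch among fit rows; harmonization is the identity")
    model <- structure(list(identity = TRUE, batches = levels(batch)),
                       class = "combat_model")
    return(list(table = X, model = model))
  }
  tb <- table(fit_batch)
  assert_that(all(tb >= 3), "need >= 3 samples per batch among fit rows")

  Xf <- X[fit_on, , drop = FALSE]
  sdv <- apply(Xf, 2, stats::sd)
  const <- sdv < 1e-12
  if (any(const)) warning(sprintf("%d zero-variance features passed through", sum(const)))
  act <- which(!const)

  bl <- levels(fit_batch)
  nb <- as.numeric(tb[bl])
  N <- nrow(Xf)
  bm <- sapply(act, function(j) tapply(Xf[, j], fit_batch, mean)) # batches x feat
  bm <- matrix(bm, nrow = length(bl))
  alpha <- as.numeric((nb / N) %*% bm)
  resid <- Xf[, act, drop = FALSE] -
    bm[as.integer(fit_batch), , drop = FALSE]
  var_pooled <- colSums(resid^2) / N
  var_pooled[var_pooled < 1e-12] <- 1e-12

  Z <- sweep(sweep(Xf[, act, drop = FALSE], 2, alpha), 2, sqrt(var_pooled), `/`)
  gamma_hat <- sapply(seq_along(act), function(j) tapply(Z[, j], fit_batch, mean))
  gamma_hat <- matrix(gamma_hat, nrow = length(bl))
  delta_hat <- sapply(seq_along(act), function(j) tapply(Z[, j], fit_batch, stats::var))
  delta_hat <- matrix(delta_hat, nrow = length(bl))
  delta_hat[is.na(delta_hat) | delta_hat < 1e-12] <- 1e-12

  gamma_star <- gamma_hat
  delta_star <- delta_hat
  for (b in seq_along(bl)) {
    g <- gamma_hat[b, ]; d <- delta_hat[b, ]
    g_bar <- mean(g); t2 <- stats::var(g)
    m <- mean(d); s2 <- stats::var(d)
    if (!is.finite(t2) || t2 < 1e-12) t2 <- 1e-12
    if (!is.finite(s2) || s2 < 1e-12) s2 <- 1e-12
    a_prior <- (2 * s2 + m^2) / s2
    b_prior <- (m * s2 + m^3) / s2
    n_b <- nb[b]
    rows_b <- which(as.integer(fit_batch) == b)
    g_new <- g; d_new <- d
    for (it in 1:50) {
      g_old <- g_new; d_old <- d_new
      g_new <- (n_b * t2 * g + d_new * g_bar) / (n_b * t2 + d_new)
      ss <- colSums((Z[rows_b, , drop = FALSE] -
                       matrix(g_new, n_b, length(g), byrow = TRUE))^2)
      d_new <- (b_prior + 0.5 * ss) / (n_b / 2 + a_prior - 1)
      if (max(abs(g_new - g_old), abs(d_new - d_old)) < 1e-8) break
    }
    gamma_star[b, ] <- g_new
    delta_star[b, ] <- d_new
  }

  model <- structure(list(identity = FALSE, batches = bl, active = act,
                          alpha = alpha, var_pooled = var_pooled,
                          gamma_star = gamma_star, delta_star = delta_star,
                          feature_names = colnames(X)),
                     class = "combat_model")
  list(table = combat_apply(model, X, batch), model = model)
}

#' Apply a frozen harmonization model to new rows
#'
#' @param model a `combat_model` from [combat_fit_apply()].
#' @param table numeric matrix with the same feature columns.
#' @param batch_labels batch label per row; must be among the batches seen
#'   at fit time.
#' @return harmonized matrix.
#' @export
combat_apply <- function(model, table, batch_labels) {
  X <- as.matrix(table)
  if (model$identity) return(X)
  batch <- as.character(batch_labels)
  assert_that(all(batch %in% model$batches), "unseen batch label")
  bi <- match(batch, model$batches)
  act <- model$active
  Z <- sweep(sweep(X[, act, drop = FALSE], 2, model$alpha), 2,
             sqrt(model$var_pooled), `/`)
  adj <- (Z - model$gamma_star[bi, , drop = FALSE]) /
    sqrt(model$delta_star[bi, , drop = FALSE])
  X[, act] <- sweep(sweep(adj, 2, sqrt(model$var_pooled), `*`), 2,
                    model$alpha, `+`)
  X
}

#' Z-score standardization with training statistics
#'
#' Columns are centered and scaled with the mean and population SD of the
#' training rows only; validation/test rows are transformed with the same
#' statistics (no refitting). Zero-SD features are dropped with a message.
#'
#' @param table numeric matrix (samples x features).
#' @param fit_on training row indices.
#' @return list with `table`, `center`, `scale`, `dropped`.
#' @export
zscore_fit_apply <- function(table, fit_on = seq_len(nrow(table))) {
  X <- as.matrix(table)
  tr <- X[fit_on, , drop = FALSE]
  mu <- colMeans(tr)
  n <- nrow(tr)
  sdv <- sqrt(colSums(sweep(tr, 2, mu)^2) / n) # population SD convention
  drop <- colnames(X)[sdv < 1e-12]
  if (length(drop)) message(sprintf("dropping %d zero-SD features", length(drop)))
  keep <- sdv >= 1e-12
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2, mu[keep]), 2, sdv[keep], `/`)
  list(table = Xs, center = mu[keep], scale = sdv[keep], dropped = drop)
}

#' Greedy Pearson-correlation redundancy pruning
#'
#' Among every feature pair with `|r| >= threshold`, the member with the
#' smaller absolute point-biserial correlation to the label is dropped.
#' Pairs are processed in descending `|r|`, with a deterministic feature
#' name tie-break.
#'
#' @param table standardized numeric matrix.
#' @param labels binary labels (0/1).
#' @param threshold absolute correlation threshold (default 0.9).
#' @return list with `retained` (names), and `pairs` (data.frame trace of
#'   kept/dropped decisions with `|r|`).
#' @export
pearson_prune <- function(table, labels, threshold = 0.9) {
  X <- as.matrix(table)
  y <- as.numeric(labels)
  nms <- colnames(X)
  cm <- abs(stats::cor(X))
  rel <- abs(as.numeric(stats::cor(X, y)))
  ut <- which(upper.tri(cm) & cm >= threshold, arr.ind = TRUE)
  if (nrow(ut) == 0) {
    return(list(retained = nms, pairs = data.frame(kept = character(0),
                                                   dropped = character(0),
                                                   abs_r = numeric(0))))
  }
  r_vals <- cm[ut]
  ord <- order(-r_vals, nms[ut[, 1]], nms[ut[, 2]])
  ut <- ut[ord, , drop = FALSE]
  r_vals <- r_vals[ord]
  alive <- rep(TRUE, ncol(X))
  kept <- dropped <- character(0); rr <- numeric(0)
  for (p in seq_len(nrow(ut))) {
    i <- ut[p, 1]; j <- ut[p, 2]
    if (!alive[i] || !alive[j]) next
    # keep the more label-relevant member; ties keep the earlier name
    if (rel[i] > rel[j] || (rel[i] == rel[j] && nms[i] < nms[j])) {
      alive[j] <- FALSE; kept <- c(kept, nms[i]); dropped <- c(dropped, nms[j])
    } else {
      alive[i] <- FALSE; kept <- c(kept, nms[j]); dropped <- c(dropped, nms[i])
    }
    rr <- c(rr, r_vals[p])
  }
  list(retained = nms[alive],
       pairs = data.frame(kept = kept, dropped = dropped, abs_r = rr))
}

# One-way ANOVA F statistic of each feature against a binary label.
f_statistic <- function(X, y) {
  y <- as.integer(factor(y))
  n <- nrow(X)
  k <- max(y)
  grand <- colMeans(X)
  ssb <- 0; ssw <- 0
  for (g in seq_len(k)) {
    rows <- X[y == g, , drop = FALSE]
    m <- colMeans(rows)
    ssb <- ssb + nrow(rows) * (m - grand)^2
    ssw <- ssw + colSums(sweep(rows, 2, m)^2)
  }
  (ssb / (k - 1)) / (ssw / (n - k))
}

#' Minimum-redundancy maximum-relevance feature ranking
#'
#' Greedy forward selection under the MID (difference) scheme: relevance is
#' the one-way ANOVA F statistic of the feature against the binary label;
#' redundancy is the mean absolute Pearson correlation with the already
#' selected set. The first pick is the most relevant feature.
#'
#' @param table numeric matrix (samples x features).
#' @param labels binary labels.
#' @param k number of features to rank (default 30). With `k >=` the number
#'   of features, all are returned in relevance-aware greedy order.
#' @return list with `selected` (ordered names) and `scores` (greedy
#'   objective at each pick).
#' @export
mrmr_select <- function(table, labels, k = 30) {
  assert_that(k > 0, "k must be positive")
  X <- as.matrix(table)
  nms <- colnames(X)
  p <- ncol(X)
  k <- min(k, p)
  rel <- f_statistic(X, labels)
  rel[!is.finite(rel)] <- max(rel[is.finite(rel)], 1) * 10 # perfect separation
  cm <- abs(stats::cor(X))
  sel <- integer(0)
  scores <- numeric(0)
  for (step in seq_len(k)) {
    cand <- setdiff(seq_len(p), sel)
    obj <- if (length(sel) == 0) rel[cand] else {
      rel[cand] - colMeans(cm[sel, cand, drop = FALSE])
    }
    # deterministic tie-break on name
    best <- cand[order(-obj, nms[cand])][1]
    sel <- c(sel, best)
    scores <- c(scores, obj[match(best, cand)])
  }
  list(selected = nms[sel], scores = scores)
}

#' LASSO logistic feature selection with cross-validated penalty
#'
#' L1-penalized logistic regression over a logarithmic lambda grid; the
#' penalty is chosen at minimum mean cross-validated binomial deviance on
#' stratified, seeded folds. The selected set is the features with nonzero
#' coefficients at the chosen lambda; if that set is empty, the smallest
#' lambda with at least one nonzero coefficient is used instead (logged in
#' the trace). A final unpenalized logistic refit on the selected features
#' supplies coefficients.
#'
#' @param table standardized numeric matrix.
#' @param labels binary labels (0/1).
#' @param folds number of CV folds (default 10).
#' @param seed integer seed for fold assignment.
#' @return list with `selected`, `coefficients` (refit), `lambda`,
#'   `lambda_grid`, `cv_deviance`, `fallback` flag.
#' @export
lasso_select <- function(table, labels, folds = 10, seed = 1L) {
  X <- as.matrix(table)
  y <- as.numeric(labels)
  foldid <- stratified_folds(y, folds, seed)
  cvfit <- glmnet::cv.glmnet(X, y, family = "binomial", foldid = foldid,
                             type.measure = "deviance", standardize = FALSE)
  lam <- cvfit$lambda.min
  co <- as.matrix(stats::coef(cvfit, s = lam))[-1, 1]
  fallback <- FALSE
  if (all(co == 0)) {
    nz <- cvfit$glmnet.fit$df > 0
    if (any(nz)) {
      lam <- min(cvfit$glmnet.fit$lambda[nz])
      co <- as.matrix(stats::coef(cvfit$glmnet.fit, s = lam))[-1, 1]
      fallback <- TRUE
    }
  }
  sel <- names(co)[co != 0]
  refit <- if (length(sel)) {
    df <- data.frame(y = y, X[, sel, drop = FALSE], check.names = FALSE)
    suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial()))
  } else NULL
  list(selected = sel,
       coefficients = if (!is.null(refit)) stats::coef(refit) else NULL,
       lambda = lam, lambda_grid = cvfit$lambda, cv_deviance = cvfit$cvm,
       fallback = fallback)
}

# Stratified fold assignment, seeded and deterministic.
stratified_folds <- function(y, folds, seed) {
  foldid <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      foldid[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  foldid
}

#' Fit the full harmonize-and-select chain on training rows
#'
#' Runs, in order: missing-value resolution, optional batch harmonization,
#' z-score standardization, Pearson redundancy pruning, mRMR top-k ranking
#' and LASSO selection — every statistic estimated on training rows only —
#' and freezes all parameters so the identical transform can be applied to
#' any cohort with [apply_feature_pipeline()]. The `trace` element is the
#' ordered record of what every stage saw and decided.
#'
#' @param table numeric matrix (all samples x features).
#' @param labels binary labels for all rows (only training rows are used).
#' @param train_idx training row indices.
#' @param batch_labels optional batch labels (enables harmonization);
#'   harmonization parameters are estimated on `combat_fit_on` rows
#'   (default: the training rows).
#' @param combat_fit_on rows for batch-parameter estimation.
#' @param prune_threshold,mrmr_k,folds,seed chain parameters.
#' @param max_missing_frac features missing in more than this fraction of
#'   training rows are dropped (default 0.1); subregion streams whose
#'   occupancy varies per patient may need a laxer value.
#' @return object of class `feature_pipeline` with frozen parameters, the
#'   selection `trace`, and the transformed training table.
#' @export
fit_feature_pipeline <- function(table, labels, train_idx,
                                 batch_labels = NULL,
                                 combat_fit_on = train_idx,
                                 prune_threshold = 0.9, mrmr_k = 30,
                                 folds = 10, seed = 1L,
                                 max_missing_frac = 0.1) {
  X <- as.matrix(table)
  trace <- list(features_in = colnames(X))
  miss <- handle_missing_features(X, train_idx, max_missing_frac)
  X <- miss$table
  trace$missing_dropped <- miss$dropped
  assert_that(ncol(X) > 0, "no features left after missing-value filtering")

  combat_model <- NULL
  if (!is.null(batch_labels) && length(unique(batch_labels[combat_fit_on])) > 1) {
    cb <- combat_fit_apply(X, batch_labels, fit_on = combat_fit_on)
    X <- cb$table
    combat_model <- cb$model
  }
  zs <- zscore_fit_apply(X, fit_on = train_idx)
  Xs <- zs$table
  ytr <- labels[train_idx]
  Xtr <- Xs[train_idx, , drop = FALSE]

  pr <- pearson_prune(Xtr, ytr, prune_threshold)
  trace$pearson <- pr$pairs
  Xtr2 <- Xtr[, pr$retained, drop = FALSE]

  mr <- mrmr_select(Xtr2, ytr, mrmr_k)
  trace$mrmr <- mr
  Xtr3 <- Xtr2[, mr$selected, drop = FALSE]

  la <- lasso_select(Xtr3, ytr, folds = folds, seed = seed)
  trace$lasso <- la
  final <- if (length(la$selected)) la$selected else mr$selected[1]
  trace$final <- final

  pipe <- structure(list(missing = miss[c("dropped", "medians")],
                         combat = combat_model,
                         zscore = zs[c("center", "scale", "dropped")],
                         selected = final,
                         trace = trace,
                         train_checksum = object_checksum(list(train_idx, table[train_idx, , drop = FALSE]))),
                    class = "feature_pipeline")
  pipe
}

#' Apply a frozen feature pipeline to a cohort table
#'
#' @param pipe a `feature_pipeline`.
#' @param table numeric matrix with the original feature columns.
#' @param batch_labels batch labels (required if the pipeline harmonizes).
#' @return numeric matrix restricted to the selected, standardized features.
#' @export
apply_feature_pipeline <- function(pipe, table, batch_labels = NULL) {
  X <- as.matrix(table)
  keep <- setdiff(colnames(X), pipe$missing$dropped)
  X <- X[, keep, drop = FALSE]
  for (j in names(pipe$missing$medians)) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- pipe$missing$medians[j]
  }
  if (!is.null(pipe$combat)) {
    assert_that(!is.null(batch_labels), "pipeline harmonizes: batch labels required")
    X <- combat_apply(pipe$combat, X, batch_labels)
  }
  nm <- names(pipe$zscore$center)
  Xs <- sweep(sweep(X[, nm, drop = FALSE], 2, pipe$zscore$center), 2,
              pipe$zscore$scale, `/`)
  Xs[, pipe$selected, drop = FALSE]
}
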