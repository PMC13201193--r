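# Evaluation suite: ROC/AUC with DeLong machinery, threshold metrics,
# Hosmer-Lemeshow calibration, decision-curve analysis, and cohort
# statistics following the usual radiology-table conventions.

#' AUC by the midrank (Mann-Whitney) statistic
#'
#' Ties count one half, so the value equals exhaustive pair counting over
#' all positive x negative pairs.
#'
#' @param scores numeric scores or probabilities.
#' @param labels binary labels (0/1).
#' @return AUC in \[0, 1\].
#' @export
auc_mann_whitney <- function(scores, labels) {
  y <- as.numeric(labels)
  assert_that(length(unique(y)) == 2, "both classes must be present")
  r <- rank(scores, ties.method = "average")
  m <- sum(y == 1); n <- sum(y == 0)
  (sum(r[y == 1]) - m * (m + 1) / 2) / (m * n)
}

# DeLong structural components: V10 (per positive) and V01 (per negative).
delong_components <- function(scores, labels) {
  y <- as.numeric(labels)
  x <- scores[y == 1]; z <- scores[y == 0]
  m <- length(x); n <- length(z)
  all <- c(x, z)
  r_all <- rank(all, ties.method = "average")
  r_x <- rank(x, ties.method = "average")
  r_z <- rank(z, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_x) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_z) / m
  list(v10 = v10, v01 = v01, auc = (sum(r_all[seq_len(m)]) - m * (m + 1) / 2) / (m * n))
}

confusion_metrics <- function(probs, labels, threshold) {
  y <- as.numeric(labels)
  pred <- as.numeric(probs >= threshold)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  tn <- sum(pred == 0 & y == 0); fn <- sum(pred == 0 & y == 1)
  c(accuracy = (tp + tn) / length(y),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA,
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA)
}

#' ROC analysis with DeLong variance and threshold metrics
#'
#' AUC by midranks, DeLong structural-component variance, Wald 95% CI
#' truncated to \[0, 1\], and confusion metrics at a threshold. By default
#' the threshold maximizes the Youden index on this cohort; pass a frozen
#' `threshold` (e.g. determined on the training cohort) to evaluate
#' validation/test cohorts without re-optimizing.
#'
#' @param probs predicted probabilities (or scores).
#' @param labels binary labels (0/1), both classes present.
#' @param threshold optional frozen classification threshold.
#' @return object of class `roc_result`: auc, var, ci, roc points,
#'   threshold, metrics.
#' @export
roc_with_delong <- function(probs, labels, threshold = NULL) {
  y <- as.numeric(labels)
  assert_that(length(unique(y)) == 2, "both classes must be present")
  dc <- delong_components(probs, y)
  m <- length(dc$v10); n <- length(dc$v01)
  v <- stats::var(dc$v10) / m + stats::var(dc$v01) / n
  ci <- pmin(pmax(dc$auc + c(-1, 1) * 1.96 * sqrt(v), 0), 1)
  thr_grid <- sort(unique(probs))
  cand <- c(-Inf, (thr_grid[-1] + thr_grid[-length(thr_grid)]) / 2, Inf)
  youden <- vapply(cand, function(t) {
    cm <- confusion_metrics(probs, y, t)
    cm["sensitivity"] + cm["specificity"] - 1
  }, 0)
  youden_thr <- cand[which.max(youden)]
  thr <- threshold %||% youden_thr
  pts <- t(vapply(cand, function(t) {
    cm <- confusion_metrics(probs, y, t)
    c(threshold = t, sensitivity = cm[["sensitivity"]],
      specificity = cm[["specificity"]])
  }, numeric(3)))
  structure(list(auc = dc$auc, var = v, ci = ci,
                 roc = as.data.frame(pts),
                 threshold = thr, youden_threshold = youden_thr,
                 metrics = confusion_metrics(probs, y, thr)),
            class = "roc_result")
}

#' Paired DeLong test for two correlated AUCs
#'
#' Compares two models' scores on the same samples via the covariance of
#' their DeLong structural components; two-sided normal p-value. A
#' degenerate zero-variance difference returns p = 1 with a warning.
#'
#' @param probs_a,probs_b score vectors of the two models (same samples).
#' @param labels binary labels (0/1).
#' @return list with `auc_a`, `auc_b`, `z`, `p`.
#' @export
delong_paired_test <- function(probs_a, probs_b, labels) {
  assert_that(length(probs_a) == length(probs_b), "paired test needs same samples")
  y <- as.numeric(labels)
  a <- delong_components(probs_a, y)
  b <- delong_components(probs_b, y)
  m <- length(a$v10); n <- length(a$v01)
  s10 <- stats::cov(cbind(a$v10, b$v10))
  s01 <- stats::cov(cbind(a$v01, b$v01))
  vd <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  if (vd <= 1e-24) {
    warning("zero variance of AUC difference; returning p = 1")
    return(list(auc_a = a$auc, auc_b = b$auc, z = 0, p = 1))
  }
  z <- (a$auc - b$auc) / sqrt(vd)
  list(auc_a = a$auc, auc_b = b$auc, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Decile-of-risk bins (empty bins merged with their neighbor, logged via
#' message); `chi2 = sum (O - E)^2 / (E (1 - E / n_bin))`, df = bins - 2.
#'
#' @param probs predicted probabilities.
#' @param labels binary outcomes (0/1).
#' @param bins number of risk bins (default 10); requires `n >= 5 * bins`.
#' @return object of class `hl_result`: chi2, df, p, bin table.
#' @export
hosmer_lemeshow <- function(probs, labels, bins = 10) {
  y <- as.numeric(labels)
  n <- length(y)
  assert_that(n >= 5 * bins, "need >= 5 samples per bin")
  qs <- unique(stats::quantile(probs, seq(0, 1, length.out = bins + 1), type = 7))
  if (length(qs) < bins + 1) message("merging empty risk bins")
  bin <- cut(probs, qs, include.lowest = TRUE)
  obs <- tapply(y, bin, sum)
  expct <- tapply(probs, bin, sum)
  nb <- tapply(y, bin, length)
  keep <- !is.na(nb)
  obs <- obs[keep]; expct <- expct[keep]; nb <- nb[keep]
  chi2 <- sum((obs - expct)^2 / (expct * (1 - expct / nb)))
  df <- length(obs) - 2
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE),
       table = data.frame(bin = names(obs), n = as.numeric(nb),
                          observed = as.numeric(obs), expected = as.numeric(expct)))
}

#' Decision curve analysis
#'
#' Net benefit `NB(pt) = TP/n - FP/n * pt/(1-pt)` with classification at
#' probability >= pt, against treat-all (`pi - (1-pi) pt/(1-pt)`) and
#' treat-none (identically 0).
#'
#' @param probs predicted probabilities.
#' @param labels binary outcomes.
#' @param thresholds threshold probability grid (pt = 1 excluded).
#' @return data.frame with threshold, net_benefit, treat_all, treat_none.
#' @export
decision_curve <- function(probs, labels, thresholds = seq(0.01, 0.99, by = 0.01)) {
  y <- as.numeric(labels)
  n <- length(y)
  prev <- mean(y)
  thresholds <- thresholds[thresholds < 1]
  nb <- vapply(thresholds, function(pt) {
    pred <- probs >= pt
    tp <- sum(pred & y == 1); fp <- sum(pred & y == 0)
    tp / n - fp / n * pt / (1 - pt)
  }, 0)
  ta <- prev - (1 - prev) * thresholds / (1 - thresholds)
  data.frame(threshold = thresholds, net_benefit = nb,
             treat_all = ta, treat_none = 0)
}

#' Model-by-cohort performance table
#'
#' One row per model per cohort with AUC (95% CI), accuracy, sensitivity,
#' specificity, PPV and NPV. The classification threshold for each model
#' is the Youden maximizer on its training cohort, frozen for the other
#' cohorts; a cohort missing from a model's predictions is skipped with a
#' message.
#'
#' @param predictions nested list: `predictions[[model]][[cohort]]` =
#'   probability vector.
#' @param labels list: `labels[[cohort]]` = binary labels.
#' @param train_cohort name of the threshold-defining cohort.
#' @return data.frame report.
#' @export
metrics_table <- function(predictions, labels, train_cohort = "train") {
  rows <- list()
  for (mod in names(predictions)) {
    thr <- NULL
    if (train_cohort %in% names(predictions[[mod]])) {
      thr <- roc_with_delong(predictions[[mod]][[train_cohort]],
                             labels[[train_cohort]])$youden_threshold
    }
    for (coh in names(labels)) {
      pr <- predictions[[mod]][[coh]]
      if (is.null(pr)) { message(sprintf("skipping %s/%s", mod, coh)); next }
      rr <- roc_with_delong(pr, labels[[coh]], threshold = thr)
      rows[[length(rows) + 1]] <- data.frame(
        model = mod, cohort = coh, auc = rr$auc,
        auc_lo = rr$ci[1], auc_hi = rr$ci[2],
        accuracy = rr$metrics[["accuracy"]],
        sensitivity = rr$metrics[["sensitivity"]],
        specificity = rr$metrics[["specificity"]],
        ppv = rr$metrics[["ppv"]], npv = rr$metrics[["npv"]])
    }
  }
  do.call(rbind, rows)
}

#' Pooled-variance two-sample t test from summary statistics
#'
#' @param m1,s1,n1,m2,s2,n2 group means, SDs and sizes.
#' @return list with `t`, `df`, `p`.
#' @export
pooled_t_summary <- function(m1, s1, n1, m2, s2, n2) {
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
  t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Chi-square / Fisher test on a contingency table of counts
#'
#' 2x2 tables use the Yates continuity correction (truncated at zero, so a
#' table with `ad = bc` gives p = 1); any expected cell below 5 switches to
#' Fisher's exact test; r x 2 tables use the plain Pearson chi-square.
#'
#' @param counts integer matrix (levels x groups).
#' @return list with `test` ("chisq-yates", "chisq", "fisher") and `p`.
#' @export
categorical_test <- function(counts) {
  counts <- as.matrix(counts)
  expct <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (any(expct < 5)) {
    return(list(test = "fisher", p = stats::fisher.test(counts)$p.value))
  }
  if (nrow(counts) == 2 && ncol(counts) == 2) {
    list(test = "chisq-yates",
         p = stats::chisq.test(counts, correct = TRUE)$p.value)
  } else {
    list(test = "chisq",
         p = stats::chisq.test(counts, correct = FALSE)$p.value)
  }
}

#' Cohort comparison statistics (baseline table engine)
#'
#' For continuous variables: Shapiro-Wilk normality per group; if both
#' groups are consistent with normality (p > 0.05), a pooled-variance
#' two-sample t test on `mean +/- SD`; otherwise a Wilcoxon rank-sum test
#' (reported as such). Categorical variables: [categorical_test()] on the
#' level x group count table. p-values are rounded to 3 decimals;
#' percentages to 2.
#'
#' @param clinical data.frame of covariates.
#' @param group binary grouping vector (0/1).
#' @param continuous,categorical variable name vectors; defaults cover the
#'   standard GGN baseline table.
#' @return data.frame with variable, per-group summaries, test and p.
#' @export
cohort_stats <- function(clinical, group,
                         continuous = c("long_diameter_mm", "short_diameter_mm",
                                        "age_years", "nse_ng_ml", "cea_ng_ml",
                                        "ct_value_hu"),
                         categorical = c("gender", "smoking", "location",
                                         "lobulation", "spiculation", "margin",
                                         "vessel_changes", "bubble_lucency",
                                         "pleural_retraction", "shape")) {
  g <- as.numeric(group)
  rows <- list()
  for (v in intersect(categorical, names(clinical))) {
    tab <- table(clinical[[v]], factor(g, levels = c(0, 1)))
    if (any(colSums(tab) < 3)) next
    ct <- categorical_test(tab)
    pc <- function(col) paste(sprintf("%d (%.2f)", tab[, col],
                                      100 * tab[, col] / sum(tab[, col])),
                              collapse = "; ")
    rows[[length(rows) + 1]] <- data.frame(
      variable = v, group0 = pc(1), group1 = pc(2),
      test = ct$test, p = round(ct$p, 3))
  }
  for (v in intersect(continuous, names(clinical))) {
    x0 <- clinical[[v]][g == 0]; x1 <- clinical[[v]][g == 1]
    if (length(x0) < 3 || length(x1) < 3) next
    norm <- stats::shapiro.test(x0)$p.value > 0.05 &&
      stats::shapiro.test(x1)$p.value > 0.05
    if (norm) {
      res <- pooled_t_summary(mean(x0), stats::sd(x0), length(x0),
                              mean(x1), stats::sd(x1), length(x1))
      test <- "pooled-t"; p <- res$p
    } else {
      test <- "wilcoxon"
      p <- stats::wilcox.test(x0, x1, exact = FALSE)$p.value
    }
    rows[[length(rows) + 1]] <- data.frame(
      variable = v,
      group0 = sprintf("%.2f ± %.2f", mean(x0), stats::sd(x0)),
      group1 = sprintf("%.2f ± %.2f", mean(x1), stats::sd(x1)),
      test = test, p = round(p, 3))
  }
  do.call(rbind, rows)
}
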