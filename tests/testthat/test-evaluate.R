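# ROC/DeLong machinery, calibration, decision curves, cohort statistics,
# Shapley attributions.

auc_pair_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

test_that("AUC equals exhaustive pair counting with half-weight ties", {
  withr::with_seed(1, {
    for (i in 1:5) {
      n <- sample(20:100, 1)
      y <- rbinom(n, 1, 0.4)
      if (length(unique(y)) < 2) y[1:2] <- 0:1
      s <- sample(round(runif(n), 2)) # ties likely
      expect_equal(auc_mann_whitney(s, y), auc_pair_oracle(s, y))
    }
  })
})

test_that("ROC analysis covers separation, chance and threshold metrics", {
  sep <- c(rep(0.1, 30), rep(0.9, 30))
  y <- rep(0:1, each = 30)
  rr <- roc_with_delong(sep, y)
  expect_equal(rr$auc, 1.0)
  expect_equal(rr$ci[2], 1.0)
  expect_equal(unname(rr$metrics["sensitivity"]), 1.0)

  withr::with_seed(4, {
    yr <- rbinom(500, 1, 0.5)
    sr <- runif(500)
  })
  rr2 <- roc_with_delong(sr, yr)
  expect_lt(abs(rr2$auc - 0.5), 3 * sqrt(rr2$var))
  expect_gte(rr2$var, 0)
  expect_error(roc_with_delong(runif(10), rep(1, 10)), "both classes")

  # frozen threshold is honored
  rr3 <- roc_with_delong(sr, yr, threshold = 0.7)
  expect_equal(rr3$threshold, 0.7)
})

test_that("paired DeLong test is symmetric, calibrated and bootstrap-consistent", {
  withr::with_seed(6, {
    y <- rbinom(300, 1, 0.5)
    a <- y + rnorm(300, sd = 1.2)
    b <- rnorm(300)
  })
  expect_warning(same <- delong_paired_test(a, a, y), "zero variance")
  expect_equal(same$p, 1)

  strong <- delong_paired_test(y + rnorm(300, sd = 0.1), b, y)
  expect_lt(strong$p, 0.001)

  ab <- delong_paired_test(a, b, y)
  ba <- delong_paired_test(b, a, y)
  expect_equal(ab$p, ba$p)
  expect_equal(ab$z, -ba$z)
})

test_that("calibration test hits exact and anti-calibrated extremes", {
  # probabilities equal to within-bin event rates -> chi2 = 0, p = 1
  p <- rep(seq(0.1, 0.9, by = 0.2), each = 10)
  y <- unlist(lapply(seq(0.1, 0.9, by = 0.2), function(q) {
    c(rep(1, round(q * 10)), rep(0, 10 - round(q * 10)))
  }))
  hl <- hosmer_lemeshow(p, y, bins = 5)
  expect_equal(hl$chi2, 0, tolerance = 1e-12)
  expect_equal(hl$p, 1)

  withr::with_seed(8, {
    pr <- runif(600, 0.05, 0.95)
    yy <- rbinom(600, 1, pr)
  })
  hl_anti <- hosmer_lemeshow(1 - pr, yy)
  expect_lt(hl_anti$p, 0.001)
  expect_equal(hl_anti$df, 8) # ten risk deciles, df = bins - 2
})

test_that("net benefit matches the closed forms", {
  y <- rep(0:1, c(60, 40)) # prevalence 0.4
  perfect <- as.numeric(y)
  dc <- decision_curve(perfect, y)
  expect_true(all(abs(dc$net_benefit[dc$threshold < 1] - 0.4) < 1e-12))
  expect_true(all(dc$treat_none == 0))
  # treat-all crosses zero at the prevalence
  at_prev <- decision_curve(perfect, y, thresholds = 0.4)
  expect_equal(at_prev$treat_all, 0)
  # model NB never exceeds prevalence
  withr::with_seed(3, pr <- runif(100))
  dcr <- decision_curve(pr, y)
  expect_true(all(dcr$net_benefit <= 0.4 + 1e-12))
})

test_that("the metrics table reproduces confusion arithmetic per model and cohort", {
  # construct a cohort with exactly TP=90 FN=10 TN=80 FP=20 at threshold 0.5
  y <- c(rep(1, 100), rep(0, 100))
  p <- c(rep(0.9, 90), rep(0.1, 10), rep(0.1, 80), rep(0.9, 20))
  preds <- list(m1 = list(train = p, test = p))
  labs <- list(train = y, test = y)
  tb <- metrics_table(preds, labs)
  expect_equal(nrow(tb), 2L)
  row <- tb[tb$cohort == "test", ]
  expect_equal(row$sensitivity, 0.900)
  expect_equal(row$specificity, 0.800)
  expect_equal(row$ppv, 0.818, tolerance = 1e-3)
  expect_equal(row$npv, 0.889, tolerance = 1e-3)
  expect_equal(row$accuracy, 0.850)
  expect_message(metrics_table(list(m1 = list(train = p)), labs), "skipping")
})

test_that("baseline-table engine picks tests by the decision rules", {
  res <- pooled_t_summary(53.38, 11.45, 81, 59.38, 9.32, 53)
  expect_equal(round(res$p, 3), 0.002)

  # identical groups: t = 0, p = 1
  same <- pooled_t_summary(5, 1, 30, 5, 1, 30)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  # Yates truncation: ad = bc gives p = 1
  expect_equal(categorical_test(matrix(c(20, 10, 40, 20), 2))$p, 1)
  # low expected counts switch to the exact test
  small <- matrix(c(2, 8, 9, 1), 2)
  expect_identical(categorical_test(small)$test, "fisher")
  # r x 2 uses plain chi-square
  rx2 <- matrix(c(20, 30, 25, 18, 28, 22), 3)
  expect_identical(categorical_test(rx2)$test, "chisq")
  expect_equal(categorical_test(rx2)$p,
               chisq.test(rx2, correct = FALSE)$p.value)

  withr::with_seed(5, {
    clin <- data.frame(
      gender = sample(c("Male", "Female"), 80, replace = TRUE),
      age_years = c(rnorm(40, 50, 10), rnorm(40, 60, 10)),
      cea_ng_ml = exp(rnorm(80)) # clearly skewed -> rank-sum
    )
  })
  g <- rep(0:1, each = 40)
  st <- cohort_stats(clin, g)
  expect_identical(st$test[st$variable == "age_years"], "pooled-t")
  expect_identical(st$test[st$variable == "cea_ng_ml"], "wilcoxon")
  expect_true(all(st$p >= 0 & st$p <= 1))
})

test_that("sampling Shapley matches closed forms, exact enumeration and null players", {
  withr::with_seed(9, {
    B <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("x1", "x2", "x3")))
    E <- matrix(rnorm(6), 2, 3, dimnames = list(NULL, colnames(B)))
  })
  beta <- c(1.5, -2, 0) # x3 is a null player
  f_lin <- function(M) as.numeric(M %*% beta)
  rep_ <- shap_explain(f_lin, B, E, nperm = 60, seed = 2)
  # additive model with independent features: phi_j = beta_j (x_j - mean bg)
  closed <- sweep(E, 2, colMeans(B)) %*% diag(beta)
  expect_equal(unname(rep_$values), unname(closed), tolerance = 0.01)
  expect_lt(max(abs(rep_$values[, "x3"])), 1e-12)
  # additivity: base + sum(attributions) = prediction
  expect_lt(max(abs(rep_$base_value + rowSums(rep_$values) - rep_$prediction)), 1e-3)

  # nonlinear model vs exact coalition enumeration
  f_nl <- function(M) as.numeric(plogis(M[, 1] * M[, 2] + 0.5 * M[, 3]))
  rep_nl <- shap_explain(f_nl, B, E, nperm = 400, seed = 3)
  exact <- shap_exact(f_nl, B, E[1, ])
  expect_equal(unname(rep_nl$values[1, ]), unname(exact), tolerance = 0.01)

  wf <- shap_waterfall(rep_nl, 1)
  expect_equal(wf$cumulative[nrow(wf)], rep_nl$prediction[1], tolerance = 1e-3)
  expect_true(all(diff(abs(wf$attribution)) <= 1e-12)) # ordered by magnitude

  # symmetry: two identically-behaving features receive equal credit
  f_sym <- function(M) as.numeric(M[, 1] + M[, 2])
  Bs <- B; Es <- E
  Bs[, 2] <- Bs[, 1]; Es[, 2] <- Es[, 1]
  rep_s <- shap_explain(f_sym, Bs, Es, nperm = 200, seed = 4)
  expect_equal(rep_s$values[, 1], rep_s$values[, 2], tolerance = 0.02)
  expect_error(shap_explain(f_lin, B[0, ], E), "empty")
})
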