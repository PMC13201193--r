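# Batch harmonization, standardization and the selection chain.

test_that("harmonization removes a planted batch shift on fresh rows", {
  withr::with_seed(3, {
    X <- matrix(rnorm(200 * 10), 200, 10,
                dimnames = list(NULL, paste0("f", 1:10)))
    batch <- rep(1:2, each = 100)
    X[batch == 2, ] <- X[batch == 2, ] + 5
  })
  out <- combat_fit_apply(X, batch)
  gaps <- colMeans(out$table[batch == 2, ]) - colMeans(out$table[batch == 1, ])
  # empirical-Bayes shrinkage leaves per-feature sampling noise (the
  # reference implementation leaves the identical residual), so the batch
  # difference is judged in aggregate
  expect_lt(mean(abs(gaps)), 0.1)
  # frozen parameters give identical re-application
  expect_equal(combat_apply(out$model, X, batch), out$table)
  expect_error(combat_apply(out$model, X, rep(3, 200)), "unseen batch")
})

test_that("single batch passes through untouched with a warning", {
  X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  expect_warning(out <- combat_fit_apply(X, rep(1, 20)), "single batch")
  expect_identical(out$table, X)
})

test_that("harmonization preserves a planted class effect", {
  withr::with_seed(9, {
    n <- 200
    y <- rep(0:1, each = n / 2)
    batch <- rep(rep(1:2, each = n / 4), 2)
    X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
    X[, 1] <- X[, 1] + 1.2 * y       # class effect
    X <- X + 4 * (batch == 2)        # batch shift on everything
  })
  eff <- function(M) (mean(M[y == 1, 1]) - mean(M[y == 0, 1])) /
    stats::sd(M[, 1] - 1.2 * y)
  out <- combat_fit_apply(X, batch)
  expect_gt(eff(out$table) / eff(X - 4 * (batch == 2)), 0.8)
})

test_that("harmonization agrees with the reference empirical-Bayes implementation", {
  skip_if_not_installed("sva")
  withr::with_seed(12, {
    X <- matrix(rnorm(80 * 6), 80, 6, dimnames = list(NULL, paste0("f", 1:6)))
    batch <- rep(1:2, each = 40)
    X[batch == 2, ] <- X[batch == 2, ] * 1.4 + 2
  })
  ours <- combat_fit_apply(X, batch)$table
  ref <- t(sva::ComBat(dat = t(X), batch = batch))
  expect_equal(unname(ours), unname(ref), tolerance = 1e-4)
})

test_that("z-score standardization uses training statistics only", {
  X <- matrix(c(1, 2, 3, 10, 2), 5, 1, dimnames = list(NULL, "f1"))
  zs <- zscore_fit_apply(X, fit_on = 1:3)
  expect_equal(as.numeric(zs$table[1:3, 1]), c(-1.224745, 0, 1.224745),
               tolerance = 1e-6)
  expect_equal(unname(zs$table[5, 1]), 0) # equals the training mean
  # validation rows transformed with training stats do not recentre
  expect_false(abs(mean(zs$table[4:5, 1])) < 1e-9)
  # zero-SD feature dropped
  X2 <- cbind(X, const = rep(7, 5))
  expect_message(zs2 <- zscore_fit_apply(X2, fit_on = 1:3), "zero-SD")
  expect_identical(colnames(zs2$table), "f1")
})

test_that("correlation pruning keeps the more label-relevant duplicate", {
  withr::with_seed(5, {
    base <- rnorm(100)
    y <- as.numeric(base + rnorm(100, sd = 0.5) > 0)
    X <- cbind(a_informative = base,
               b_copy = base,
               c_copy = base,
               d_free = rnorm(100))
  })
  # make a_informative slightly more label-correlated by construction
  X[, "b_copy"] <- X[, "b_copy"] + rnorm(100, sd = 0.01)
  X[, "c_copy"] <- X[, "c_copy"] + rnorm(100, sd = 0.01)
  pr <- pearson_prune(X, y)
  copies <- c("a_informative", "b_copy", "c_copy")
  expect_equal(sum(copies %in% pr$retained), 1L)
  rel <- abs(cor(X[, copies], y))
  expect_true(copies[which.max(rel)] %in% pr$retained)
  expect_true("d_free" %in% pr$retained)
  # independent features: everything survives
  withr::with_seed(6, Z <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, letters[1:3])))
  expect_setequal(pearson_prune(Z, y)$retained, letters[1:3])
})

test_that("mRMR matches an exhaustive greedy oracle and honors contracts", {
  mrmr_oracle <- function(X, y, k) {
    # independent re-statement of greedy MID selection
    fs <- function(x) {
      summary(stats::aov(x ~ factor(y)))[[1]][["F value"]][1]
    }
    rel <- apply(X, 2, fs)
    sel <- character(0)
    for (i in seq_len(k)) {
      cand <- setdiff(colnames(X), sel)
      score <- sapply(cand, function(f) {
        red <- if (length(sel) == 0) 0 else mean(abs(cor(X[, f], X[, sel])))
        rel[f] - red
      })
      top <- max(score)
      sel <- c(sel, sort(cand[score == top])[1])
    }
    sel
  }
  withr::with_seed(8, {
    X <- matrix(rnorm(600), 60, 10, dimnames = list(NULL, paste0("v", 1:10)))
    y <- rbinom(60, 1, plogis(2 * X[, 4]))
    X[, 5] <- X[, 4] + rnorm(60, sd = 0.2) # redundant with the good one
  })
  for (k in c(3, 5)) {
    expect_identical(mrmr_select(X, y, k)$selected, mrmr_oracle(X, y, k))
  }
  # most relevant feature picked first
  expect_identical(mrmr_select(X, y, 3)$selected[1],
                   names(which.max(apply(X, 2, function(v) {
                     summary(stats::aov(v ~ factor(y)))[[1]][["F value"]][1]
                   }))))
  # k >= p returns everything
  expect_setequal(mrmr_select(X, y, 50)$selected, colnames(X))
  expect_error(mrmr_select(X, y, 0), "positive")
})

test_that("LASSO selection finds planted signal and a separable feature", {
  tab <- fixture_tabular(300, 20, 2)
  la <- lasso_select(tab$X, tab$y, folds = 10, seed = 4)
  expect_true(all(c("f001", "f002") %in% la$selected))
  expect_false(la$fallback)
  expect_true(la$lambda %in% la$lambda_grid ||
                la$lambda >= min(la$lambda_grid))

  withr::with_seed(10, {
    x1 <- c(rnorm(50, -3), rnorm(50, 3))
    ysep <- rep(0:1, each = 50)
    Xs <- cbind(sep = x1, noise = rnorm(100))
  })
  la2 <- lasso_select(Xs, ysep, folds = 5, seed = 1)
  expect_true("sep" %in% la2$selected)
})

test_that("the chain is idempotent and blind to non-training rows", {
  tab <- fixture_tabular(200, 30, 1)
  tr <- 1:140
  p1 <- fit_feature_pipeline(tab$X, tab$y, tr, seed = 6)
  p2 <- fit_feature_pipeline(tab$X, tab$y, tr, seed = 6)
  expect_identical(p1$trace, p2$trace)
  expect_identical(p1$selected, p2$selected)

  # corrupt validation rows: every fitted statistic must be unchanged
  Xc <- tab$X
  Xc[141:200, ] <- Xc[141:200, ] * 100 + 7
  p3 <- fit_feature_pipeline(Xc, tab$y, tr, seed = 6)
  expect_identical(p1$selected, p3$selected)
  expect_identical(p1$zscore, p3$zscore)
  expect_identical(p1$trace$mrmr, p3$trace$mrmr)
  # final stage sets are nested
  expect_true(all(p1$selected %in% p1$trace$mrmr$selected))
  expect_true(all(p1$trace$mrmr$selected %in% p1$trace$features_in))
})
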