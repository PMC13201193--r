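# Clinic screening, SVM base models, early and late fusion.

test_that("logistic screening flags a planted factor and matches the 2x2 OR identity", {
  withr::with_seed(2, {
    n <- 340
    strong <- rnorm(n)
    y <- rbinom(n, 1, plogis(1.5 * strong))
    noisevar <- rnorm(n)
    binv <- rbinom(n, 1, 0.4)
  })
  X <- cbind(clinic_strong = strong, clinic_noise = noisevar, clinic_bin = binv)
  scr <- clinic_screen(X, y)
  row <- scr$univariate[scr$univariate$variable == "clinic_strong", ]
  expect_lt(row$p, 0.05)
  expect_gt(row$or, 1)
  expect_true("clinic_strong" %in% scr$independent)

  # odds ratio of a binary variable equals the cross-product from its 2x2 table
  tab <- table(binv, y)
  or_tab <- (tab[2, 2] * tab[1, 1]) / (tab[2, 1] * tab[1, 2])
  row_b <- scr$univariate[scr$univariate$variable == "clinic_bin", ]
  expect_equal(row_b$or, unname(or_tab), tolerance = 1e-6)
})

test_that("a label-independent variable is usually screened out", {
  hits <- vapply(1:10, function(i) {
    withr::with_seed(100 + i, {
      y <- rbinom(340, 1, 0.45)
      X <- cbind(clinic_null = rnorm(340))
    })
    scr <- clinic_screen(X, y)
    is.na(scr$univariate$p[1]) || scr$univariate$p[1] >= 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("SVM base models are deterministic, calibrated and honest under nulls", {
  withr::with_seed(3, {
    X <- rbind(matrix(rnorm(100, -2), 50, 2), matrix(rnorm(100, 2), 50, 2))
    colnames(X) <- c("u", "v")
    y <- rep(0:1, each = 50)
  })
  b1 <- train_base_model(X, y, "radiomics", seed = 5)
  b2 <- train_base_model(X, y, "radiomics", seed = 5)
  expect_identical(c(b1$cost, b1$gamma), c(b2$cost, b2$gamma))
  pr <- predict(b1, X)
  expect_true(all(pr >= 0 & pr <= 1))
  expect_equal(mean((pr >= 0.5) == y), 1.0) # separable toy set

  # unused extra column leaves predictions unchanged
  X2 <- cbind(X, w = rnorm(100) + 100)
  expect_identical(predict(b1, X2), pr)
  expect_error(predict(b1, X[, 1, drop = FALSE]), "missing features")
  expect_error(train_base_model(X[y == 1, ], y[y == 1]), "single-class")

  # permuted labels: held-out AUC hovers at chance
  withr::with_seed(11, {
    Xn <- matrix(rnorm(300 * 4), 300, 4, dimnames = list(NULL, letters[1:4]))
    yn <- sample(rep(0:1, 150))
  })
  bn <- train_base_model(Xn[1:200, ], yn[1:200], seed = 2)
  expect_lt(abs(auc_mann_whitney(predict(bn, Xn[201:300, ]), yn[201:300]) - 0.5), 0.15)
})

test_that("early fusion prunes duplicated streams and tracks stream tags", {
  tab <- fixture_tabular(150, 10, 3)
  t1 <- tab$X
  colnames(t1) <- paste0("s1_", colnames(t1))
  t2 <- tab$X # exact duplicate stream under different names
  colnames(t2) <- paste0("s2_", colnames(t2))
  em <- suppressWarnings(early_fusion(list(a = t1, b = t2), tab$y, 1:100, seed = 4))
  sel <- em$pipeline$selected
  expect_gt(length(sel), 0)
  # the duplicate of any selected feature must have been pruned
  stems <- sub("^s[12]_", "", sel)
  expect_false(any(duplicated(stems)))
  pr <- predict_stream(em, cbind(t1, t2))
  expect_true(all(pr >= 0 & pr <= 1))
  expect_error(early_fusion(list(a = t1, b = t2[1:10, ]), tab$y, 1:100), "row-aligned")
})

test_that("stacking is leak-free by construction and uses out-of-fold predictions", {
  tab <- fixture_tabular(120, 8, 7)
  s1 <- tab$X[, 1:4]; colnames(s1) <- paste0("p_", 1:4)
  s2 <- tab$X[, 5:8]; colnames(s2) <- paste0("q_", 1:4)
  tr <- 1:90
  fold_fixed <- rep_len(1:5, 90)
  lf <- suppressWarnings(late_fusion(list(one = s1, two = s2), tab$y, tr,
                                     folds = 5, seed = 9, mrmr_k = 4,
                                     foldid = fold_fixed))
  plan <- lf$plan
  # bookkeeping: each OOF entry comes from a fit that excluded its sample
  for (f in seq_along(plan$folds)) {
    expect_length(intersect(plan$folds[[f]]$fit_rows, plan$folds[[f]]$held_out), 0)
    expect_setequal(c(plan$folds[[f]]$fit_rows, plan$folds[[f]]$held_out), tr)
  }
  expect_false(anyNA(plan$oof))

  # flipping one sample's label (folds held fixed) leaves its own OOF entry
  # unchanged: its prediction comes from a fit that excluded it
  y2 <- tab$y
  flip <- tr[5]
  y2[flip] <- 1 - y2[flip]
  lf2 <- suppressWarnings(late_fusion(list(one = s1, two = s2), y2, tr,
                                      folds = 5, seed = 9, mrmr_k = 4,
                                      foldid = fold_fixed))
  pos <- match(flip, tr)
  expect_equal(lf2$plan$oof[pos, ], plan$oof[pos, ])

  pr <- predict(lf, list(one = s1, two = s2))
  expect_true(all(pr >= 0 & pr <= 1))
})

test_that("an oracle base stream drives the meta-learner to near-perfect AUC", {
  tab <- fixture_tabular(150, 6, 13)
  withr::with_seed(13, {
    oracle <- cbind(o1 = tab$y + rnorm(150, sd = 0.01),
                    o2 = rnorm(150))
    noise <- matrix(rnorm(150 * 3), 150, 3, dimnames = list(NULL, paste0("n", 1:3)))
  })
  tr <- 1:100
  lf <- suppressWarnings(late_fusion(list(oracle = oracle, noise = noise),
                                     tab$y, tr, folds = 5, seed = 3, mrmr_k = 3))
  pr <- predict(lf, list(oracle = oracle, noise = noise))
  expect_gte(auc_mann_whitney(pr[tr], tab$y[tr]), 0.99)

  # no-information base streams leave the meta-learner near chance
  withr::with_seed(14, {
    j1 <- matrix(rnorm(150 * 2), 150, 2, dimnames = list(NULL, c("a1", "a2")))
    j2 <- matrix(rnorm(150 * 2), 150, 2, dimnames = list(NULL, c("b1", "b2")))
  })
  lf0 <- suppressWarnings(late_fusion(list(x = j1, z = j2), tab$y, tr,
                                      folds = 5, seed = 3, mrmr_k = 2))
  pr0 <- predict(lf0, list(x = j1, z = j2))
  expect_lt(abs(auc_mann_whitney(pr0[101:150], tab$y[101:150]) - 0.5), 0.2)
})
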