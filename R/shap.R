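# Shapley-value interpretation: model-agnostic sampling estimator on the
# post-selection feature space, with background medoids and exact
# additivity by construction (each permutation chain telescopes from a
# background row to the explained row).

#' Background medoids of the training rows
#'
#' @param table numeric training matrix (post-selection feature space).
#' @param k number of medoids (default 20, capped at n).
#' @param seed integer seed.
#' @return numeric matrix of medoid rows.
#' @export
shap_background <- function(table, k = 20, seed = 1L) {
  X <- as.matrix(table)
  k <- min(k, nrow(X))
  if (k == nrow(X)) return(X)
  with_seed(seed, {
    pm <- cluster::pam(X, k, pamonce = 5)
    X[pm$id.med, , drop = FALSE]
  })
}

#' Shapley additive explanations by permutation sampling
#'
#' Estimates per-feature attributions of `predict_fun` for each explained
#' row with the permutation-sampling Shapley algorithm: for every sampled
#' feature permutation and every background row, a chain of hybrid inputs
#' walks from the background row to the explained row, and each feature is
#' credited with the prediction change it causes. Attributions therefore
#' satisfy additivity exactly: `base + sum(attributions) = prediction`
#' (base value = mean prediction over the background rows).
#'
#' @param predict_fun function(matrix) -> numeric predictions.
#' @param background background matrix (e.g. [shap_background()]); must be
#'   non-empty.
#' @param explain matrix of rows to explain.
#' @param nperm number of sampled permutations per row (default 100).
#' @param seed integer seed.
#' @return object of class `shap_report`: `values` (rows x features),
#'   `base_value`, `prediction`, `importance` (mean absolute attribution).
#' @export
shap_explain <- function(predict_fun, background, explain, nperm = 100, seed = 1L) {
  B <- as.matrix(background)
  assert_that(nrow(B) > 0, "background is empty")
  E <- as.matrix(explain)
  p <- ncol(E)
  base_value <- mean(predict_fun(B))
  values <- matrix(0, nrow(E), p, dimnames = list(rownames(E), colnames(E)))
  preds <- predict_fun(E)
  nB <- nrow(B)
  with_seed(seed, {
    perms <- replicate(nperm, sample.int(p), simplify = FALSE)
    for (r in seq_len(nrow(E))) {
      x <- E[r, ]
      # all permutation chains x all background rows, one predict call
      blocks <- vector("list", nperm * nB)
      bi_idx <- 1L
      for (pi in perms) {
        for (bi in seq_len(nB)) {
          chain <- matrix(B[bi, ], p + 1, p, byrow = TRUE)
          for (step in seq_len(p)) {
            chain[(step + 1):(p + 1), pi[step]] <- x[pi[step]]
          }
          blocks[[bi_idx]] <- chain
          bi_idx <- bi_idx + 1L
        }
      }
      big <- do.call(rbind, blocks)
      colnames(big) <- colnames(E)
      f <- predict_fun(big)
      phi <- numeric(p)
      off <- 0L
      for (pi in perms) {
        for (bi in seq_len(nB)) {
          phi[pi] <- phi[pi] + diff(f[off + seq_len(p + 1)])
          off <- off + p + 1L
        }
      }
      values[r, ] <- phi / (nperm * nB)
    }
  })
  structure(list(values = values, base_value = base_value,
                 prediction = preds,
                 importance = colMeans(abs(values))),
            class = "shap_report")
}

#' Waterfall decomposition of a single explained row
#'
#' Orders the attributions by magnitude and accumulates from the base
#' value to the model output.
#'
#' @param report a `shap_report`.
#' @param row row index to decompose.
#' @return data.frame with feature, attribution, cumulative value.
#' @export
shap_waterfall <- function(report, row = 1) {
  v <- report$values[row, ]
  ord <- order(-abs(v))
  data.frame(feature = names(v)[ord],
             attribution = v[ord],
             cumulative = report$base_value + cumsum(v[ord]),
             row.names = NULL)
}

#' Exact Shapley values by coalition enumeration
#'
#' Reference implementation for small feature spaces (p <= 12): enumerates
#' all 2^p coalitions, valuing a coalition as the mean prediction with
#' coalition features from the explained row and the rest from each
#' background row, and combines them with exact Shapley weights. Used as
#' the independent check of the sampling estimator.
#'
#' @param predict_fun function(matrix) -> numeric predictions.
#' @param background background matrix.
#' @param x single explained row (numeric vector).
#' @return numeric vector of exact attributions.
#' @export
shap_exact <- function(predict_fun, background, x) {
  B <- as.matrix(background)
  p <- length(x)
  assert_that(p <= 12, "exact enumeration limited to p <= 12")
  nS <- 2^p
  vals <- numeric(nS)
  for (s in 0:(nS - 1)) {
    inS <- as.logical(bitwAnd(s, 2^(0:(p - 1))))
    M <- B
    M[, inS] <- matrix(x[inS], nrow(B), sum(inS), byrow = TRUE)
    colnames(M) <- names(x)
    vals[s + 1] <- mean(predict_fun(M))
  }
  phi <- numeric(p)
  fact <- factorial(0:p)
  for (j in seq_len(p)) {
    for (s in 0:(nS - 1)) {
      if (bitwAnd(s, 2^(j - 1)) > 0) next
      size <- sum(as.logical(bitwAnd(s, 2^(0:(p - 1)))))
      w <- fact[size + 1] * fact[p - size] / fact[p + 1]
      phi[j] <- phi[j] + w * (vals[s + 2^(j - 1) + 1] - vals[s + 1])
    }
  }
  names(phi) <- names(x)
  phi
}
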