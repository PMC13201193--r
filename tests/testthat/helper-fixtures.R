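# Shared fixtures, computed once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Fixed-geometry three-zone phantom (bump-free, 16 x 12 mm) whose zone
# attenuations are separated by >5 within-zone noise SDs.
fixed_zone_config <- function(noise_sd = 15) {
  cp <- list(
    ais_mia = list(long_diameter_mm = c(10, 0), short_diameter_mm = c(8, 0),
                   ct_value_hu = c(-487, 0), n_bumps = 0, bump_amplitude_mm = 0),
    iac = list(long_diameter_mm = c(16, 0), short_diameter_mm = c(12, 0),
               ct_value_hu = c(-338, 0), n_bumps = 0, bump_amplitude_mm = 0)
  )
  phantom_config(class_params = cp, noise_sd_hu = noise_sd)
}

fixture_nodule <- function(label = 1, seed = 42) {
  cached(sprintf("nodule_%d_%d", label, seed),
         generate_nodule(phantom_config(), label = label, seed = seed))
}

fixture_zone_nodule <- function(seed = 42) {
  cached(sprintf("zone_nodule_%d", seed),
         generate_nodule(fixed_zone_config(), label = 1, seed = seed))
}

# Small tabular classification problem with a planted signal.
fixture_tabular <- function(n = 200, p = 30, seed = 1) {
  cached(sprintf("tab_%d_%d_%d", n, p, seed), {
    withr::with_seed(seed, {
      X <- matrix(rnorm(n * p), n, p,
                  dimnames = list(NULL, sprintf("f%03d", seq_len(p))))
      y <- rbinom(n, 1, plogis(1.5 * X[, 1] - 1.2 * X[, 2] + X[, 3]))
      list(X = X, y = y)
    })
  })
}

# Reduced-size end-to-end study shared by pipeline tests.
fixture_study <- function(seed = 5) {
  cached(sprintf("study_%d", seed), small_study(seed))
}

small_study <- function(seed) {
  suppressMessages(suppressWarnings(run_ggn_study(
    n_center1 = 34L, n_center2 = 20L, seed = seed,
    radiomics_config = feature_config(filters = "original",
                                      families = c("firstorder", "glcm")),
    dl_spec = net_spec(18, "2D", input_side = 16),
    mrmr_k = 10
  )))
}

dice_between_masks <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# all permutations of 1:3, one per row (for optimal label matching)
gtools_permutations3 <- function() {
  rbind(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
}
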