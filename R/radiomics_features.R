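# Feature family computations. Conventions follow the common IBSI-style
# extractor defaults: symmetric distance-1 GLCM aggregated over the 13
# unique 3D directions (feature values averaged over directions), run and
# zone statistics on 26-connectivity, population moments for first order.

firstorder_features <- function(values, levels, voxel_volume) {
  n <- length(values)
  p <- tabulate(levels) / n
  p <- p[p > 0]
  mu <- mean(values)
  m2 <- mean((values - mu)^2)
  m3 <- mean((values - mu)^3)
  m4 <- mean((values - mu)^4)
  q <- stats::quantile(values, c(0.1, 0.25, 0.75, 0.9), names = FALSE, type = 7)
  sub <- values[values >= q[1] & values <= q[4]]
  c(Energy = sum(values^2),
    TotalEnergy = voxel_volume * sum(values^2),
    Entropy = -sum(p * log2(p)),
    Minimum = min(values),
    `10Percentile` = q[1],
    `90Percentile` = q[4],
    Maximum = max(values),
    Mean = mu,
    Median = stats::median(values),
    InterquartileRange = q[3] - q[2],
    Range = max(values) - min(values),
    MeanAbsoluteDeviation = mean(abs(values - mu)),
    RobustMeanAbsoluteDeviation = if (length(sub)) mean(abs(sub - mean(sub))) else 0,
    RootMeanSquared = sqrt(mean(values^2)),
    Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    Variance = m2,
    Uniformity = sum(p^2))
}

shape_features <- function(mask, spacing) {
  coords <- which(mask, arr.ind = TRUE)
  n <- nrow(coords)
  vv <- prod(spacing)
  vol <- n * vv
  # surface area by exposed-face counting
  area <- 0
  face_areas <- c(spacing[2] * spacing[3], spacing[2] * spacing[3],
                  spacing[1] * spacing[3], spacing[1] * spacing[3],
                  spacing[1] * spacing[2], spacing[1] * spacing[2])
  dirs <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (i in seq_along(dirs)) {
    d <- dirs[[i]]
    nb <- shift3d(mask, d[1], d[2], d[3], fill = FALSE)
    area <- area + sum(mask & !nb) * face_areas[i]
  }
  pts <- sweep(coords, 2, spacing, `*`)
  # caliper diameters from boundary voxels (cheaper, same extremes)
  bnd <- which(mask_boundary(mask), arr.ind = TRUE)
  bp <- sweep(bnd, 2, spacing, `*`)
  maxd <- function(m) if (nrow(m) < 2) 0 else max(stats::dist(m))
  d3 <- maxd(bp)
  d_slice <- maxd(bp[, 2:3, drop = FALSE])  # within axial plane (y, x)
  d_col <- maxd(bp[, c(1, 3), drop = FALSE]) # (z, x)
  d_row <- maxd(bp[, 1:2, drop = FALSE])     # (z, y)
  ev <- if (n > 3) {
    cv <- stats::cov(pts)
    sort(pmax(eigen(cv, symmetric = TRUE, only.values = TRUE)$values, 0),
         decreasing = TRUE)
  } else c(0, 0, 0)
  major <- 4 * sqrt(ev[1]); minor <- 4 * sqrt(ev[2]); least <- 4 * sqrt(ev[3])
  sph <- (pi^(1 / 3) * (6 * vol)^(2 / 3)) / area
  c(MeshVolume = vol, VoxelVolume = vol, SurfaceArea = area,
    SurfaceVolumeRatio = area / vol, Sphericity = sph,
    Maximum3DDiameter = d3, Maximum2DDiameterSlice = d_slice,
    Maximum2DDiameterColumn = d_col, Maximum2DDiameterRow = d_row,
    MajorAxisLength = major, MinorAxisLength = minor, LeastAxisLength = least,
    Elongation = if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 0,
    Flatness = if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 0)
}

glcm_from_direction <- function(larr, d, ng) {
  sh <- shift3d(larr, d[1], d[2], d[3], fill = NA_integer_)
  ok <- !is.na(larr) & !is.na(sh)
  if (!any(ok)) return(NULL)
  i <- larr[ok]; j <- sh[ok]
  m <- matrix(0, ng, ng)
  tb <- table(factor(i, levels = 1:ng), factor(j, levels = 1:ng))
  m <- m + as.matrix(tb)
  m <- m + t(m) # symmetric
  m / sum(m)
}

glcm_features_single <- function(p) {
  ng <- nrow(p)
  iv <- seq_len(ng)
  I <- matrix(iv, ng, ng)
  J <- t(I)
  px <- rowSums(p); py <- colSums(p)
  mux <- sum(iv * px); muy <- sum(iv * py)
  sx <- sqrt(sum((iv - mux)^2 * px)); sy <- sqrt(sum((iv - muy)^2 * py))
  # sum and difference distributions
  ks <- 2:(2 * ng)
  psum <- vapply(ks, function(k) sum(p[I + J == k]), 0)
  kd <- 0:(ng - 1)
  pdiff <- vapply(kd, function(k) sum(p[abs(I - J) == k]), 0)
  ent <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
  hxy <- ent(p)
  pxy <- outer(px, py)
  hxy1 <- -sum(p[pxy > 0] * log2(pxy[pxy > 0]))
  hxy2 <- ent(pxy)
  hx <- ent(px); hy <- ent(py)
  da <- sum(kd * pdiff)
  corr <- if (sx * sy > 0) (sum(I * J * p) - mux * muy) / (sx * sy) else 1
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(pmax(1 - exp(-2 * (hxy2 - hxy)), 0))
  mcc <- if (ng > 1) {
    # Q(i,j) = sum_k p(i,k) p(j,k) / (px(i) py(k))
    A <- sweep(p, 1, ifelse(px > 0, px, 1), `/`)
    B <- sweep(p, 2, ifelse(py > 0, py, 1), `/`)
    Q <- A %*% t(B)
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(max(ev[2], 0))
  } else 1
  c(Autocorrelation = sum(I * J * p),
    ClusterProminence = sum((I + J - mux - muy)^4 * p),
    ClusterShade = sum((I + J - mux - muy)^3 * p),
    ClusterTendency = sum((I + J - mux - muy)^2 * p),
    Contrast = sum((I - J)^2 * p),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = ent(pdiff),
    DifferenceVariance = sum((kd - da)^2 * pdiff),
    Id = sum(p / (1 + abs(I - J))),
    Idm = sum(p / (1 + (I - J)^2)),
    Idmn = sum(p / (1 + ((I - J) / ng)^2)),
    Idn = sum(p / (1 + abs(I - J) / ng)),
    Imc1 = imc1,
    Imc2 = imc2,
    InverseVariance = sum(p[I != J] / (I - J)[I != J]^2),
    JointAverage = mux,
    JointEnergy = sum(p^2),
    JointEntropy = hxy,
    MCC = mcc,
    MaximumProbability = max(p),
    SumAverage = sum(ks * psum),
    SumEntropy = ent(psum),
    SumSquares = sum((I - mux)^2 * p))
}

glcm_features <- function(larr, ng) {
  dirs <- directions13()
  acc <- NULL; nd <- 0
  for (r in seq_len(nrow(dirs))) {
    p <- glcm_from_direction(larr, dirs[r, ], ng)
    if (is.null(p)) next
    f <- glcm_features_single(p)
    acc <- if (is.null(acc)) f else acc + f
    nd <- nd + 1
  }
  if (nd == 0) {
    f <- glcm_features_single(matrix(1, 1, 1))
    nd <- 1; acc <- f
  }
  acc / nd
}

# Run-length matrix along one direction: counts R[level, run_length].
glrlm_from_direction <- function(coords, levels, d, ng) {
  # group voxels into lines: base = coord - t*d with t the coordinate along
  # the first nonzero axis of d
  ax <- which(d != 0)[1] # canonical directions have d[ax] = +1
  t <- coords[, ax]
  base <- coords - t %o% d
  key <- paste(base[, 1], base[, 2], base[, 3], sep = ",")
  ord <- order(key, t)
  k <- key[ord]; tt <- t[ord]; lv <- levels[ord]
  new_line <- c(TRUE, k[-1] != k[-length(k)])
  gap <- c(TRUE, diff(tt) != 1)
  chg <- c(TRUE, lv[-1] != lv[-length(lv)])
  run_start <- new_line | gap | chg
  run_id <- cumsum(run_start)
  rl <- tabulate(run_id)
  run_lv <- lv[run_start]
  maxl <- max(rl)
  m <- matrix(0, ng, maxl)
  for (i in seq_along(rl)) m[run_lv[i], rl[i]] <- m[run_lv[i], rl[i]] + 1
  m
}

rl_features <- function(R, np, prefix = c("run", "zone")) {
  prefix <- match.arg(prefix)
  nr <- sum(R)
  ng <- nrow(R); nl <- ncol(R)
  iv <- seq_len(ng); lv <- seq_len(nl)
  ri <- rowSums(R); rj <- colSums(R)
  p <- R / nr
  mu_i <- sum(iv * rowSums(p)); mu_j <- sum(lv * colSums(p))
  ent <- { q <- p[p > 0]; -sum(q * log2(q)) }
  gl_lo <- sum(ri / iv^2) / nr
  gl_hi <- sum(ri * iv^2) / nr
  IL2 <- outer(iv^2, lv^2)
  vals <- c(
    sum(rj / lv^2) / nr,                    # short emphasis
    sum(rj * lv^2) / nr,                    # long emphasis
    sum(ri^2) / nr,                         # gray level non-uniformity
    sum(ri^2) / nr^2,                       # ... normalized
    sum(rj^2) / nr,                         # length non-uniformity
    sum(rj^2) / nr^2,                       # ... normalized
    nr / np,                                # percentage
    sum(rowSums(p) * (iv - mu_i)^2),        # gray level variance
    sum(colSums(p) * (lv - mu_j)^2),        # length variance
    ent,                                    # entropy
    gl_lo,                                  # low gray level emphasis
    gl_hi,                                  # high gray level emphasis
    sum(R / IL2) / nr,                      # short + low
    sum(R * outer(iv^2, 1 / lv^2)) / nr,    # short + high
    sum(R * outer(1 / iv^2, lv^2)) / nr,    # long + low
    sum(R * IL2) / nr                       # long + high
  )
  names(vals) <- if (prefix == "run") {
    c("ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
      "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
      "RunLengthNonUniformityNormalized", "RunPercentage",
      "GrayLevelVariance", "RunVariance", "RunEntropy",
      "LowGrayLevelRunEmphasis", "HighGrayLevelRunEmphasis",
      "ShortRunLowGrayLevelEmphasis", "ShortRunHighGrayLevelEmphasis",
      "LongRunLowGrayLevelEmphasis", "LongRunHighGrayLevelEmphasis")
  } else {
    c("SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
      "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
      "SizeZoneNonUniformityNormalized", "ZonePercentage",
      "GrayLevelVariance", "ZoneVariance", "ZoneEntropy",
      "LowGrayLevelZoneEmphasis", "HighGrayLevelZoneEmphasis",
      "SmallAreaLowGrayLevelEmphasis", "SmallAreaHighGrayLevelEmphasis",
      "LargeAreaLowGrayLevelEmphasis", "LargeAreaHighGrayLevelEmphasis")
  }
  vals
}

glrlm_features <- function(larr, coords, levels, ng, np) {
  dirs <- directions13()
  acc <- NULL; nd <- 0
  for (r in seq_len(nrow(dirs))) {
    R <- glrlm_from_direction(coords, levels, dirs[r, ], ng)
    f <- rl_features(R, np, "run")
    acc <- if (is.null(acc)) f else acc + f
    nd <- nd + 1
  }
  acc / nd
}

# Connected components of constant gray level (26-connectivity) by
# iterative minimum-label propagation.
gray_zones <- function(larr) {
  d <- dim(larr)
  lab <- array(seq_len(prod(d)), dim = d)
  lab[is.na(larr)] <- NA_integer_
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  repeat {
    nxt <- lab
    for (r in seq_len(nrow(offs))) {
      shl <- shift3d(lab, offs[r, 1], offs[r, 2], offs[r, 3], fill = NA_integer_)
      shv <- shift3d(larr, offs[r, 1], offs[r, 2], offs[r, 3], fill = NA_integer_)
      ok <- !is.na(shl) & !is.na(larr) & shv == larr & shl < nxt
      nxt[ok] <- shl[ok]
    }
    if (identical(nxt, lab)) break
    lab <- nxt
  }
  inm <- !is.na(lab)
  zid <- match(lab[inm], unique(lab[inm]))
  data.frame(level = larr[inm], zone = zid)
}

glszm_features <- function(larr, ng, np) {
  z <- gray_zones(larr)
  sizes <- tapply(z$zone, z$zone, length)
  lvls <- tapply(z$level, z$zone, function(v) v[1])
  m <- matrix(0, ng, max(sizes))
  for (i in seq_along(sizes)) m[lvls[i], sizes[i]] <- m[lvls[i], sizes[i]] + 1
  rl_features(m, np, "zone")
}

# Neighbor level gathering for GLDM / NGTDM: list of 26 shifted level arrays.
neighbor_levels <- function(larr) {
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  lapply(seq_len(nrow(offs)), function(r) {
    shift3d(larr, offs[r, 1], offs[r, 2], offs[r, 3], fill = NA_integer_)
  })
}

gldm_features <- function(larr, ng, np, alpha = 0) {
  nbs <- neighbor_levels(larr)
  inm <- !is.na(larr)
  dep <- array(0L, dim = dim(larr))
  for (nb in nbs) {
    ok <- inm & !is.na(nb) & abs(nb - larr) <= alpha
    dep[ok] <- dep[ok] + 1L
  }
  i <- larr[inm]; j <- dep[inm] + 1L
  nd <- max(j)
  D <- unclass(table(factor(i, levels = 1:ng), factor(j, levels = 1:nd)))
  nz <- sum(D)
  p <- D / nz
  iv <- seq_len(ng); jv <- seq_len(nd)
  pi_ <- rowSums(p); pj <- colSums(p)
  mu_i <- sum(iv * pi_); mu_j <- sum(jv * pj)
  ent <- { q <- p[p > 0]; -sum(q * log2(q)) }
  c(SmallDependenceEmphasis = sum(sweep(p, 2, jv^2, `/`)),
    LargeDependenceEmphasis = sum(sweep(p, 2, jv^2, `*`)),
    GrayLevelNonUniformity = sum(rowSums(D)^2) / nz,
    DependenceNonUniformity = sum(colSums(D)^2) / nz,
    DependenceNonUniformityNormalized = sum(colSums(D)^2) / nz^2,
    GrayLevelVariance = sum(pi_ * (iv - mu_i)^2),
    DependenceVariance = sum(pj * (jv - mu_j)^2),
    DependenceEntropy = ent,
    LowGrayLevelEmphasis = sum(pi_ / iv^2),
    HighGrayLevelEmphasis = sum(pi_ * iv^2),
    SmallDependenceLowGrayLevelEmphasis = sum(p / outer(iv^2, jv^2)),
    SmallDependenceHighGrayLevelEmphasis = sum(p * outer(iv^2, 1 / jv^2)),
    LargeDependenceLowGrayLevelEmphasis = sum(p * outer(1 / iv^2, jv^2)),
    LargeDependenceHighGrayLevelEmphasis = sum(p * outer(iv^2, jv^2)))
}

ngtdm_features <- function(larr, ng, np) {
  nbs <- neighbor_levels(larr)
  inm <- !is.na(larr)
  ssum <- array(0, dim = dim(larr))
  scnt <- array(0L, dim = dim(larr))
  for (nb in nbs) {
    ok <- inm & !is.na(nb)
    ssum[ok] <- ssum[ok] + nb[ok]
    scnt[ok] <- scnt[ok] + 1L
  }
  has_nb <- inm & scnt > 0
  A <- ssum[has_nb] / scnt[has_nb]
  lv <- larr[has_nb]
  s <- vapply(1:ng, function(i) sum(abs(i - A)[lv == i]), 0)
  n_i <- tabulate(lv, ng)
  nvp <- sum(n_i)
  p <- n_i / nvp
  act <- which(p > 0)
  ngp <- length(act)
  coarse_den <- sum(p * s)
  contrast <- if (ngp > 1) {
    (sum(outer(p[act], p[act]) * outer(act, act, function(a, b) (a - b)^2)) /
       (ngp * (ngp - 1))) * (sum(s) / nvp)
  } else 0
  busy_den <- sum(abs(outer(act * p[act], act * p[act], `-`)))
  busy <- if (busy_den > 0) coarse_den / busy_den else 0
  cplx <- if (nvp > 0) {
    tot <- 0
    for (a in act) for (b in act) {
      tot <- tot + abs(a - b) * (p[a] * s[a] + p[b] * s[b]) / (p[a] + p[b])
    }
    tot / nvp
  } else 0
  strength <- if (sum(s) > 0) {
    tot <- 0
    for (a in act) for (b in act) tot <- tot + (p[a] + p[b]) * (a - b)^2
    tot / sum(s)
  } else 0
  c(Coarseness = if (coarse_den > 0) 1 / coarse_den else 1e6,
    Contrast = contrast,
    Busyness = busy,
    Complexity = cplx,
    Strength = strength)
}
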