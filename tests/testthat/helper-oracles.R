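# Brute-force oracles for the texture families, written as naive
# enumerations independent of the package's counting kernels and
# vectorised formula layer. Used on small volumes only.

oracle_offsets <- function() {
  list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
       c(1, 1, 0), c(1, -1, 0),
       c(1, 0, 1), c(1, 0, -1),
       c(0, 1, 1), c(0, 1, -1),
       c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))
}

# coordinates (n x 3) and levels of all in-mask voxels
oracle_voxels <- function(levels) {
  ix <- which(levels > 0, arr.ind = TRUE)
  list(coord = ix, lev = levels[ix])
}

# symmetric co-occurrence probability matrix for one offset, by O(n^2)
# pair enumeration over both +d and -d
oracle_glcm_matrix <- function(levels, ng, d) {
  vx <- oracle_voxels(levels)
  n <- nrow(vx$coord)
  P <- matrix(0, ng, ng)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    dd <- vx$coord[b, ] - vx$coord[a, ]
    if (all(dd == d) || all(dd == -d))
      P[vx$lev[a], vx$lev[b]] <- P[vx$lev[a], vx$lev[b]] + 1
  }
  if (sum(P) == 0) return(NULL)
  P / sum(P)
}

# GLCM features by plain scalar loops over the matrix
oracle_glcm_features <- function(P) {
  ng <- nrow(P)
  px <- numeric(ng); py <- numeric(ng)
  for (i in 1:ng) for (j in 1:ng) {
    px[i] <- px[i] + P[i, j]; py[j] <- py[j] + P[i, j]
  }
  mu_x <- sum((1:ng) * px); mu_y <- sum((1:ng) * py)
  sx <- sqrt(sum(((1:ng) - mu_x)^2 * px))
  f <- c(Autocorrelation = 0, ClusterProminence = 0, ClusterShade = 0,
         ClusterTendency = 0, Contrast = 0, Correlation = 0,
         DifferenceAverage = 0, DifferenceEntropy = 0,
         DifferenceVariance = 0, Id = 0, Idm = 0, Idmn = 0, Idn = 0,
         Imc1 = 0, Imc2 = 0, InverseVariance = 0, JointAverage = mu_x,
         JointEnergy = 0, JointEntropy = 0, MaximumProbability = max(P),
         MCC = 0, SumAverage = 0, SumEntropy = 0, SumSquares = 0)
  pd <- numeric(ng); psum <- numeric(2 * ng - 1)
  hxy <- 0; hxy1 <- 0
  for (i in 1:ng) for (j in 1:ng) {
    p <- P[i, j]
    f["Autocorrelation"] <- f["Autocorrelation"] + i * j * p
    f["ClusterProminence"] <- f["ClusterProminence"] +
      (i + j - mu_x - mu_y)^4 * p
    f["ClusterShade"] <- f["ClusterShade"] + (i + j - mu_x - mu_y)^3 * p
    f["ClusterTendency"] <- f["ClusterTendency"] +
      (i + j - mu_x - mu_y)^2 * p
    f["Contrast"] <- f["Contrast"] + (i - j)^2 * p
    f["Id"] <- f["Id"] + p / (1 + abs(i - j))
    f["Idm"] <- f["Idm"] + p / (1 + (i - j)^2)
    f["Idmn"] <- f["Idmn"] + p / (1 + (i - j)^2 / ng^2)
    f["Idn"] <- f["Idn"] + p / (1 + abs(i - j) / ng)
    if (i != j) f["InverseVariance"] <- f["InverseVariance"] +
        p / (i - j)^2
    f["JointEnergy"] <- f["JointEnergy"] + p^2
    f["SumSquares"] <- f["SumSquares"] + (i - mu_x)^2 * p
    pd[abs(i - j) + 1] <- pd[abs(i - j) + 1] + p
    psum[i + j - 1] <- psum[i + j - 1] + p
    if (p > 0) {
      hxy <- hxy - p * log2(p)
      if (px[i] * py[j] > 0) hxy1 <- hxy1 - p * log2(px[i] * py[j])
    }
  }
  hx <- -sum(px[px > 0] * log2(px[px > 0]))
  hxy2 <- 0
  for (i in 1:ng) for (j in 1:ng)
    if (px[i] * py[j] > 0)
      hxy2 <- hxy2 - px[i] * py[j] * log2(px[i] * py[j])
  da <- sum((0:(ng - 1)) * pd)
  f["DifferenceAverage"] <- da
  f["DifferenceEntropy"] <- -sum(pd[pd > 0] * log2(pd[pd > 0]))
  f["DifferenceVariance"] <- sum(((0:(ng - 1)) - da)^2 * pd)
  f["SumAverage"] <- sum((2:(2 * ng)) * psum)
  f["SumEntropy"] <- -sum(psum[psum > 0] * log2(psum[psum > 0]))
  f["JointEntropy"] <- hxy
  f["Correlation"] <- if (sx > 0)
    (f[["Autocorrelation"]] - mu_x * mu_y) / sx^2 else 1
  f["Imc1"] <- if (hx > 0) (hxy - hxy1) / hx else 0
  f["Imc2"] <- sqrt(max(1 - exp(-2 * (hxy2 - hxy)), 0))
  # MCC via explicit Q construction and a general eigensolver
  keep <- which(px > 0)
  f["MCC"] <- if (length(keep) < 2) 1 else {
    Q <- matrix(0, length(keep), length(keep))
    for (a in seq_along(keep)) for (b in seq_along(keep)) {
      for (kk in seq_along(keep)) {
        Q[a, b] <- Q[a, b] +
          P[keep[a], keep[kk]] * P[keep[b], keep[kk]] /
          (px[keep[a]] * py[keep[kk]])
      }
    }
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(max(ev[2], 0))
  }
  f
}

oracle_glcm <- function(levels, ng) {
  per_dir <- lapply(oracle_offsets(), function(d) {
    P <- oracle_glcm_matrix(levels, ng, d)
    if (is.null(P)) return(NULL)
    oracle_glcm_features(P)
  })
  per_dir <- per_dir[!vapply(per_dir, is.null, logical(1))]
  out <- rowMeans(do.call(cbind, per_dir))
  names(out) <- paste0("glcm_", names(out))
  out
}

# runs by walking complete grid lines and applying rle()
oracle_glrlm_matrix <- function(levels, ng, d) {
  dims <- dim(levels)
  maxlen <- max(dims)
  P <- matrix(0, ng, maxlen)
  starts <- which(array(TRUE, dims), arr.ind = TRUE)
  is_start <- apply(starts, 1, function(v) {
    p <- v - d
    any(p < 1) || p[1] > dims[1] || p[2] > dims[2] || p[3] > dims[3]
  })
  for (r in which(is_start)) {
    v <- starts[r, ]
    line <- integer(0)
    while (all(v >= 1) && v[1] <= dims[1] && v[2] <= dims[2] &&
           v[3] <= dims[3]) {
      line <- c(line, levels[v[1], v[2], v[3]])
      v <- v + d
    }
    rl <- rle(line)
    for (k in seq_along(rl$values))
      if (rl$values[k] > 0)
        P[rl$values[k], rl$lengths[k]] <- P[rl$values[k], rl$lengths[k]] + 1
  }
  P
}

oracle_rl_family_features <- function(P, np, kind = c("run", "zone",
                                                      "dependence")) {
  kind <- match.arg(kind)
  nr <- sum(P)
  nlev <- nrow(P); nlen <- ncol(P)
  sgl <- se <- le <- lgl <- hgl <- slgl <- shgl <- llgl <- lhgl <- 0
  for (i in 1:nlev) for (j in 1:nlen) {
    p <- P[i, j]
    se <- se + p / j^2; le <- le + p * j^2
    lgl <- lgl + p / i^2; hgl <- hgl + p * i^2
    slgl <- slgl + p / (i^2 * j^2); shgl <- shgl + p * i^2 / j^2
    llgl <- llgl + p * j^2 / i^2; lhgl <- lhgl + p * i^2 * j^2
  }
  gln <- sum(rowSums(P)^2); rln <- sum(colSums(P)^2)
  pg <- rowSums(P) / nr; pr <- colSums(P) / nr
  mug <- sum((1:nlev) * pg); mur <- sum((1:nlen) * pr)
  pp <- P / nr
  ent <- -sum(pp[pp > 0] * log2(pp[pp > 0]))
  list(SE = se / nr, LE = le / nr, LGL = lgl / nr, HGL = hgl / nr,
       SLGL = slgl / nr, SHGL = shgl / nr, LLGL = llgl / nr,
       LHGL = lhgl / nr, GLN = gln / nr, GLNN = gln / nr^2,
       RLN = rln / nr, RLNN = rln / nr^2, PCT = nr / np,
       GLV = sum((((1:nlev)) - mug)^2 * pg),
       RV = sum((((1:nlen)) - mur)^2 * pr), ENT = ent)
}

oracle_glrlm <- function(levels, ng, np) {
  per_dir <- lapply(oracle_offsets(), function(d) {
    o <- oracle_rl_family_features(oracle_glrlm_matrix(levels, ng, d), np)
    c(GrayLevelNonUniformity = o$GLN,
      GrayLevelNonUniformityNormalized = o$GLNN,
      GrayLevelVariance = o$GLV, HighGrayLevelRunEmphasis = o$HGL,
      LongRunEmphasis = o$LE, LongRunHighGrayLevelEmphasis = o$LHGL,
      LongRunLowGrayLevelEmphasis = o$LLGL,
      LowGrayLevelRunEmphasis = o$LGL, RunEntropy = o$ENT,
      RunLengthNonUniformity = o$RLN,
      RunLengthNonUniformityNormalized = o$RLNN, RunPercentage = o$PCT,
      RunVariance = o$RV, ShortRunEmphasis = o$SE,
      ShortRunHighGrayLevelEmphasis = o$SHGL,
      ShortRunLowGrayLevelEmphasis = o$SLGL)
  })
  out <- rowMeans(do.call(cbind, per_dir))
  names(out) <- paste0("glrlm_", names(out))
  out
}

# zones by breadth-first flood fill over 26-neighbourhoods
oracle_glszm_zones <- function(levels) {
  dims <- dim(levels)
  seen <- array(FALSE, dims)
  zones <- list()
  idx <- which(levels > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    v0 <- idx[r, ]
    if (seen[v0[1], v0[2], v0[3]]) next
    lv <- levels[v0[1], v0[2], v0[3]]
    queue <- list(v0)
    seen[v0[1], v0[2], v0[3]] <- TRUE
    size <- 0
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      size <- size + 1
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        if (dx == 0 && dy == 0 && dz == 0) next
        w <- v + c(dx, dy, dz)
        if (any(w < 1) || w[1] > dims[1] || w[2] > dims[2] ||
            w[3] > dims[3]) next
        if (!seen[w[1], w[2], w[3]] && levels[w[1], w[2], w[3]] == lv) {
          seen[w[1], w[2], w[3]] <- TRUE
          queue[[length(queue) + 1]] <- w
        }
      }
    }
    zones[[length(zones) + 1]] <- c(lv, size)
  }
  do.call(rbind, zones)
}

oracle_glszm <- function(levels, np) {
  z <- oracle_glszm_zones(levels)
  maxs <- max(z[, 2])
  P <- matrix(0, max(z[, 1]), maxs)
  for (r in seq_len(nrow(z))) P[z[r, 1], z[r, 2]] <- P[z[r, 1], z[r, 2]] + 1
  o <- oracle_rl_family_features(P, np)
  out <- c(GrayLevelNonUniformity = o$GLN,
           GrayLevelNonUniformityNormalized = o$GLNN,
           GrayLevelVariance = o$GLV, HighGrayLevelZoneEmphasis = o$HGL,
           LargeAreaEmphasis = o$LE,
           LargeAreaHighGrayLevelEmphasis = o$LHGL,
           LargeAreaLowGrayLevelEmphasis = o$LLGL,
           LowGrayLevelZoneEmphasis = o$LGL,
           SizeZoneNonUniformity = o$RLN,
           SizeZoneNonUniformityNormalized = o$RLNN,
           SmallAreaEmphasis = o$SE,
           SmallAreaHighGrayLevelEmphasis = o$SHGL,
           SmallAreaLowGrayLevelEmphasis = o$SLGL,
           ZoneEntropy = o$ENT, ZonePercentage = o$PCT,
           ZoneVariance = o$RV)
  names(out) <- paste0("glszm_", names(out))
  out
}

# dependence counts by scanning every other voxel for Chebyshev distance 1
oracle_gldm <- function(levels, ng, alpha = 0) {
  vx <- oracle_voxels(levels)
  n <- nrow(vx$coord)
  P <- matrix(0, ng, 27)
  for (a in seq_len(n)) {
    dep <- 0
    for (b in seq_len(n)) {
      if (a == b) next
      dd <- abs(vx$coord[b, ] - vx$coord[a, ])
      if (max(dd) == 1 && abs(vx$lev[b] - vx$lev[a]) <= alpha)
        dep <- dep + 1
    }
    P[vx$lev[a], dep + 1] <- P[vx$lev[a], dep + 1] + 1
  }
  o <- oracle_rl_family_features(P, n)
  out <- c(DependenceEntropy = o$ENT, DependenceNonUniformity = o$RLN,
           DependenceNonUniformityNormalized = o$RLNN,
           DependenceVariance = o$RV, GrayLevelNonUniformity = o$GLN,
           GrayLevelVariance = o$GLV, HighGrayLevelEmphasis = o$HGL,
           LargeDependenceEmphasis = o$LE,
           LargeDependenceHighGrayLevelEmphasis = o$LHGL,
           LargeDependenceLowGrayLevelEmphasis = o$LLGL,
           LowGrayLevelEmphasis = o$LGL, SmallDependenceEmphasis = o$SE,
           SmallDependenceHighGrayLevelEmphasis = o$SHGL,
           SmallDependenceLowGrayLevelEmphasis = o$SLGL)
  names(out) <- paste0("gldm_", names(out))
  out
}

# per-voxel neighbour means by scanning all other voxels
oracle_ngtdm <- function(levels, ng) {
  vx <- oracle_voxels(levels)
  n <- nrow(vx$coord)
  nv <- integer(ng); sv <- numeric(ng)
  for (a in seq_len(n)) {
    nb <- numeric(0)
    for (b in seq_len(n)) {
      if (a == b) next
      dd <- abs(vx$coord[b, ] - vx$coord[a, ])
      if (max(dd) == 1) nb <- c(nb, vx$lev[b])
    }
    if (!length(nb)) next
    i <- vx$lev[a]
    nv[i] <- nv[i] + 1L
    sv[i] <- sv[i] + abs(i - mean(nb))
  }
  nvp <- sum(nv)
  p <- nv / nvp
  act <- which(p > 0)
  ngp <- length(act)
  psum <- 0; busy_den <- 0; comp <- 0; strength_num <- 0; con1 <- 0
  for (i in act) psum <- psum + p[i] * sv[i]
  for (i in act) for (j in act) {
    con1 <- con1 + p[i] * p[j] * (i - j)^2
    busy_den <- busy_den + abs(i * p[i] - j * p[j])
    comp <- comp + abs(i - j) * (p[i] * sv[i] + p[j] * sv[j]) /
      (p[i] + p[j])
    strength_num <- strength_num + (p[i] + p[j]) * (i - j)^2
  }
  out <- c(
    Busyness = if (busy_den > 0) psum / busy_den else 0,
    Coarseness = if (psum > 0) min(1 / psum, 1e6) else 1e6,
    Complexity = comp / nvp,
    Contrast = if (ngp > 1)
      con1 / (ngp * (ngp - 1)) * sum(sv) / nvp else 0,
    Strength = if (sum(sv) > 0) strength_num / sum(sv) else 0)
  names(out) <- paste0("ngtdm_", names(out))
  out
}

# first-order statistics by explicit formulas on sorted data
oracle_first_order <- function(x, ng, vox_vol = 1) {
  n <- length(x)
  pct <- function(p) {
    s <- sort(x)
    h <- (n - 1) * p + 1
    lo <- floor(h)
    s[lo] + (h - lo) * (s[min(lo + 1, n)] - s[lo])
  }
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  lv <- if (max(x) > min(x))
    pmin(floor(ng * (x - min(x)) / (max(x) - min(x))) + 1, ng)
  else rep(1, n)
  p <- as.numeric(table(factor(lv, levels = 1:ng))) / n
  p10 <- pct(0.1); p90 <- pct(0.9)
  core <- x[x >= p10 & x <= p90]
  out <- c(Energy = sum(x^2), TotalEnergy = sum(x^2) * vox_vol,
           Entropy = -sum(p[p > 0] * log2(p[p > 0])),
           Minimum = min(x), `10Percentile` = p10, `90Percentile` = p90,
           Maximum = max(x), Mean = mu, Median = pct(0.5),
           InterquartileRange = pct(0.75) - pct(0.25),
           Range = max(x) - min(x),
           MeanAbsoluteDeviation = sum(abs(x - mu)) / n,
           RobustMeanAbsoluteDeviation =
             sum(abs(core - mean(core))) / length(core),
           RootMeanSquared = sqrt(sum(x^2) / n),
           Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
           Kurtosis = if (m2 > 0) m4 / m2^2 else 0,
           Variance = m2, Uniformity = sum(p^2))
  names(out) <- paste0("firstorder_", names(out))
  out
}

# full 93-feature oracle vector in registry order
oracle_all_features <- function(volume, mask, ng) {
  q <- quantise_voi(volume, mask, ng)
  x <- voi_values(volume, mask)
  np <- q$n_voxels
  c(oracle_first_order(x, ng, prod(volume$spacing_mm)),
    oracle_glcm(q$levels, ng),
    oracle_gldm(q$levels, ng),
    oracle_glrlm(q$levels, ng, np),
    oracle_glszm(q$levels, np),
    oracle_ngtdm(q$levels, ng))
}

# random small test volume with an irregular (possibly tight) mask
random_small_voi <- function(dims = c(5, 5, 3), p_mask = 0.85,
                             discrete = FALSE) {
  vals <- array(if (discrete) sample(0:9, prod(dims), TRUE)
                else runif(prod(dims)), dims)
  m <- array(as.integer(runif(prod(dims)) < p_mask), dims)
  if (sum(m) < 2) m[1:2] <- 1L
  list(volume = image_volume(vals), mask = voi_mask(m, check_connected = FALSE))
}
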