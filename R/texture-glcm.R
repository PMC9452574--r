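#' Grey-level co-occurrence matrix features
#'
#' Co-occurrences are counted for the 13 unique 3D unit offsets
#' (Chebyshev distance 1 in voxel index space), restricted to voxel pairs
#' inside the VOI, symmetrised by adding the transpose and normalised to
#' probabilities. The 24 registry features are computed per direction and
#' averaged at the feature level (matrices are not merged). On a
#' single-level VOI the entropy/contrast-type features take their 0
#' limits, `MaximumProbability` is 1, and `Correlation`/`MCC` return 1
#' with the degeneracy flag set.
#'
#' @param q A `quantised_voi` from [quantise_voi()].
#' @return `glcm_features()`: named numeric vector of 24 `glcm_*`
#'   features with a `degenerate` attribute. `glcm_matrices()`: list of
#'   13 normalised symmetric Ng x Ng probability matrices (one per
#'   direction); directions with no valid pair are dropped.
#' @export
glcm_features <- function(q) {
  mats <- glcm_matrices(q)
  aux <- glcm_aux(q$ng)
  per_dir <- vapply(mats, glcm_features_from_matrix, numeric(24),
                    aux = aux)
  out <- rowMeans(per_dir)
  names(out) <- paste0("glcm_", rownames(per_dir))
  attr(out, "degenerate") <- voi_n_levels(q) < 2L
  out
}

#' @rdname glcm_features
#' @export
glcm_matrices <- function(q) {
  counts <- cpp_glcm_counts(as.integer(q$levels), dim(q$levels), q$ng)
  mats <- lapply(counts, function(m) {
    s <- m + t(m)
    tot <- sum(s)
    if (tot == 0) return(NULL)
    s / tot
  })
  mats[!vapply(mats, is.null, logical(1))]
}

# index matrices and diagonal groupings reused across the 13 directions
glcm_aux <- function(ng) {
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  list(ng = ng, i = i, j = j,
       g_diff = as.vector(abs(i - j)) + 1L,   # 1 .. ng
       g_sum = as.vector(i + j) - 1L,         # 1 .. 2*ng - 1
       w_id = 1 / (1 + abs(i - j)),
       w_idm = 1 / (1 + (i - j)^2),
       w_idmn = 1 / (1 + (i - j)^2 / ng^2),
       w_idn = 1 / (1 + abs(i - j) / ng),
       w_iv = ifelse(i == j, 0, 1 / (i - j + (i == j))^2))
}

#' @rdname glcm_features
#' @param P A normalised symmetric co-occurrence probability matrix.
#' @param aux Precomputed index helper (internal; rebuilt when `NULL`).
#' @export
glcm_features_from_matrix <- function(P, aux = NULL) {
  ng <- nrow(P)
  if (is.null(aux) || aux$ng != ng) aux <- glcm_aux(ng)
  i <- aux$i; j <- aux$j
  px <- rowSums(P)           # == py by symmetry
  lev <- seq_len(ng)
  mu_x <- sum(lev * px)
  sig2_x <- sum((lev - mu_x)^2 * px)

  # diagonal / cross-diagonal marginals (|i - j| and i + j)
  k_diff <- 0:(ng - 1)
  p_diff <- as.vector(rowsum(as.vector(P), aux$g_diff, reorder = TRUE))
  if (length(p_diff) < ng) p_diff <- c(p_diff, rep(0, ng - length(p_diff)))
  # rowsum only returns occurring groups; groups 1..ng all occur for ng >= 1
  k_sum <- 2:(2 * ng)
  p_sum <- numeric(2 * ng - 1)
  ps <- rowsum(as.vector(P), aux$g_sum, reorder = TRUE)
  p_sum[as.integer(rownames(ps))] <- ps

  ent <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  hxy <- ent(P)
  hx <- ent(px)
  # with identical symmetric marginals, HXY1 = HXY2 = HX + HY = 2 * HX
  hxy1 <- 2 * hx
  hxy2 <- 2 * hx

  diff_avg <- sum(k_diff * p_diff)
  autocorr <- sum(i * j * P)
  correlation <- if (sig2_x > 0) (autocorr - mu_x^2) / sig2_x else 1
  imc1 <- if (hx > 0) (hxy - hxy1) / hx else 0
  imc2 <- sqrt(pmax(1 - exp(-2 * (hxy2 - hxy)), 0))

  # MCC: for symmetric P, Q = Dx^-1 P Dy^-1 P^T equals T^2 with
  # T = D^-1/2 P D^-1/2 symmetric, so the second-largest eigenvalue of Q
  # is the squared second-largest |eigenvalue| of T.
  mcc <- {
    keep <- px > 0
    if (sum(keep) < 2L) 1 else {
      d <- 1 / sqrt(px[keep])
      Tm <- P[keep, keep, drop = FALSE] * outer(d, d)
      ev <- sort(abs(eigen(Tm, symmetric = TRUE,
                           only.values = TRUE)$values),
                 decreasing = TRUE)
      ev[2]
    }
  }

  s1 <- i + j - 2 * mu_x
  s2 <- s1 * s1
  c(
    Autocorrelation = autocorr,
    ClusterProminence = sum(s2 * s2 * P),
    ClusterShade = sum(s2 * s1 * P),
    ClusterTendency = sum(s2 * P),
    Contrast = sum((i - j)^2 * P),
    Correlation = correlation,
    DifferenceAverage = diff_avg,
    DifferenceEntropy = ent(p_diff),
    DifferenceVariance = sum((k_diff - diff_avg)^2 * p_diff),
    Id = sum(P * aux$w_id),
    Idm = sum(P * aux$w_idm),
    Idmn = sum(P * aux$w_idmn),
    Idn = sum(P * aux$w_idn),
    Imc1 = imc1,
    Imc2 = imc2,
    InverseVariance = sum(P * aux$w_iv),
    JointAverage = mu_x,
    JointEnergy = sum(P^2),
    JointEntropy = hxy,
    MaximumProbability = max(P),
    MCC = mcc,
    SumAverage = sum(k_sum * p_sum),
    SumEntropy = ent(p_sum),
    SumSquares = sig2_x
  )
}
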