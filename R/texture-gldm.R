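#' Grey-level dependence matrix features
#'
#' For each in-VOI voxel the dependence is the number of its in-VOI
#' 26-neighbours whose grey level differs by at most `alpha` (0 by
#' default, i.e. equal level). The matrix is indexed by (level,
#' dependence + 1); every voxel contributes one count, so the total is
#' the VOI voxel count.
#'
#' @param q A `quantised_voi`.
#' @param alpha Non-negative integer level-difference tolerance.
#' @return Named numeric vector of 14 `gldm_*` features.
#' @export
gldm_features <- function(q, alpha = 0L) {
  P <- cpp_gldm_counts(as.integer(q$levels), dim(q$levels), q$ng,
                       as.integer(alpha))
  out <- gldm_features_from_matrix(P)
  names(out) <- paste0("gldm_", names(out))
  attr(out, "degenerate") <- voi_n_levels(q) < 2L
  out
}

#' @rdname gldm_features
#' @param P Dependence-count matrix, rows grey levels, column `d + 1`
#'   holding dependence `d`.
#' @export
gldm_features_from_matrix <- function(P) {
  nz <- sum(P)
  i <- matrix(seq_len(nrow(P)), nrow(P), ncol(P))
  j <- t(matrix(seq_len(ncol(P)), ncol(P), nrow(P)))
  p <- P / nz
  pg <- rowSums(p)
  pd <- colSums(p)
  mu_g <- sum(seq_along(pg) * pg)
  mu_d <- sum(seq_along(pd) * pd)
  p_pos <- p[p > 0]
  c(
    DependenceEntropy = -sum(p_pos * log2(p_pos)),
    DependenceNonUniformity = sum(colSums(P)^2) / nz,
    DependenceNonUniformityNormalized = sum(colSums(P)^2) / nz^2,
    DependenceVariance = sum((seq_along(pd) - mu_d)^2 * pd),
    GrayLevelNonUniformity = sum(rowSums(P)^2) / nz,
    GrayLevelVariance = sum((seq_along(pg) - mu_g)^2 * pg),
    HighGrayLevelEmphasis = sum(P * i^2) / nz,
    LargeDependenceEmphasis = sum(P * j^2) / nz,
    LargeDependenceHighGrayLevelEmphasis = sum(P * i^2 * j^2) / nz,
    LargeDependenceLowGrayLevelEmphasis = sum(P * j^2 / i^2) / nz,
    LowGrayLevelEmphasis = sum(P / i^2) / nz,
    SmallDependenceEmphasis = sum(P / j^2) / nz,
    SmallDependenceHighGrayLevelEmphasis = sum(P * i^2 / j^2) / nz,
    SmallDependenceLowGrayLevelEmphasis = sum(P / (i^2 * j^2)) / nz
  )
}
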