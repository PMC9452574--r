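#' Grey-level run-length matrix features
#'
#' Runs of equal grey level are counted along each of the 13 unique 3D
#' directions, broken at the VOI boundary; the 16 registry features are
#' computed per direction and averaged. Normalisations use the total run
#' count of that direction, and `RunPercentage` divides by the VOI voxel
#' count.
#'
#' @param q A `quantised_voi`.
#' @return `glrlm_features()`: named numeric vector of 16 `glrlm_*`
#'   features. `glrlm_matrices()`: list of 13 run-count matrices
#'   (Ng x max run length).
#' @export
glrlm_features <- function(q) {
  mats <- glrlm_matrices(q)
  np <- q$n_voxels
  per_dir <- vapply(mats, glrlm_features_from_matrix, numeric(16), np = np)
  out <- rowMeans(per_dir)
  names(out) <- paste0("glrlm_", rownames(per_dir))
  attr(out, "degenerate") <- voi_n_levels(q) < 2L
  out
}

#' @rdname glrlm_features
#' @export
glrlm_matrices <- function(q) {
  cpp_glrlm_counts(as.integer(q$levels), dim(q$levels), q$ng)
}

#' @rdname glrlm_features
#' @param P A run-count matrix (rows grey levels, columns run lengths).
#' @param np VOI voxel count (for `RunPercentage`).
#' @export
glrlm_features_from_matrix <- function(P, np) {
  nr <- sum(P)
  i <- matrix(seq_len(nrow(P)), nrow(P), ncol(P))
  j <- t(matrix(seq_len(ncol(P)), ncol(P), nrow(P)))
  p <- P / nr
  pg <- rowSums(p)
  pr <- colSums(p)
  mu_g <- sum(seq_along(pg) * pg)
  mu_r <- sum(seq_along(pr) * pr)
  p_pos <- p[p > 0]
  c(
    GrayLevelNonUniformity = sum(rowSums(P)^2) / nr,
    GrayLevelNonUniformityNormalized = sum(rowSums(P)^2) / nr^2,
    GrayLevelVariance = sum((seq_along(pg) - mu_g)^2 * pg),
    HighGrayLevelRunEmphasis = sum(P * i^2) / nr,
    LongRunEmphasis = sum(P * j^2) / nr,
    LongRunHighGrayLevelEmphasis = sum(P * i^2 * j^2) / nr,
    LongRunLowGrayLevelEmphasis = sum(P * j^2 / i^2) / nr,
    LowGrayLevelRunEmphasis = sum(P / i^2) / nr,
    RunEntropy = -sum(p_pos * log2(p_pos)),
    RunLengthNonUniformity = sum(colSums(P)^2) / nr,
    RunLengthNonUniformityNormalized = sum(colSums(P)^2) / nr^2,
    RunPercentage = nr / np,
    RunVariance = sum((seq_along(pr) - mu_r)^2 * pr),
    ShortRunEmphasis = sum(P / j^2) / nr,
    ShortRunHighGrayLevelEmphasis = sum(P * i^2 / j^2) / nr,
    ShortRunLowGrayLevelEmphasis = sum(P / (i^2 * j^2)) / nr
  )
}
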