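#' Grey-level size-zone matrix features
#'
#' Zones are 26-connected components of equal grey level within the VOI;
#' there is a single matrix (no directions). Feature definitions mirror
#' the run-length family with zone size in place of run length;
#' `ZonePercentage` is the zone count over the VOI voxel count.
#'
#' @param q A `quantised_voi`.
#' @return Named numeric vector of 16 `glszm_*` features.
#' @export
glszm_features <- function(q) {
  zones <- cpp_glszm_zones(as.integer(q$levels), dim(q$levels))
  out <- glszm_features_from_zones(zones[, 1], zones[, 2], q$n_voxels)
  names(out) <- paste0("glszm_", names(out))
  attr(out, "degenerate") <- voi_n_levels(q) < 2L
  out
}

#' @rdname glszm_features
#' @param level,size Integer vectors, one entry per zone.
#' @param np VOI voxel count.
#' @export
glszm_features_from_zones <- function(level, size, np) {
  nz <- length(level)
  i <- as.numeric(level)
  s <- as.numeric(size)
  p <- rep(1 / nz, nz)                       # each zone is one matrix count
  # grey-level and size marginals over distinct values
  gl_tab <- tapply(p, i, sum)
  sz_tab <- tapply(p, s, sum)
  gl_val <- as.numeric(names(gl_tab))
  sz_val <- as.numeric(names(sz_tab))
  mu_g <- sum(gl_val * gl_tab)
  mu_s <- sum(sz_val * sz_tab)
  cnt_g <- tapply(rep(1, nz), i, sum)
  cnt_s <- tapply(rep(1, nz), s, sum)
  cell <- tapply(rep(1 / nz, nz), paste(i, s), sum)  # P(i, s) / Nz
  c(
    GrayLevelNonUniformity = sum(cnt_g^2) / nz,
    GrayLevelNonUniformityNormalized = sum(cnt_g^2) / nz^2,
    GrayLevelVariance = sum((gl_val - mu_g)^2 * gl_tab),
    HighGrayLevelZoneEmphasis = sum(i^2) / nz,
    LargeAreaEmphasis = sum(s^2) / nz,
    LargeAreaHighGrayLevelEmphasis = sum(i^2 * s^2) / nz,
    LargeAreaLowGrayLevelEmphasis = sum(s^2 / i^2) / nz,
    LowGrayLevelZoneEmphasis = sum(1 / i^2) / nz,
    SizeZoneNonUniformity = sum(cnt_s^2) / nz,
    SizeZoneNonUniformityNormalized = sum(cnt_s^2) / nz^2,
    SmallAreaEmphasis = sum(1 / s^2) / nz,
    SmallAreaHighGrayLevelEmphasis = sum(i^2 / s^2) / nz,
    SmallAreaLowGrayLevelEmphasis = sum(1 / (i^2 * s^2)) / nz,
    ZoneEntropy = -sum(cell * log2(cell)),
    ZonePercentage = nz / np,
    ZoneVariance = sum((sz_val - mu_s)^2 * sz_tab)
  )
}
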