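#' Fixed-bin-count grey-level quantisation of a VOI
#'
#' Maps VOI intensities onto `ng` discrete grey levels by equal-width
#' binning of the VOI intensity range (min-max relative), the
#' "number of grey levels" semantics of the factorial design. With
#' `m = min`, `M = max` over VOI voxels, a voxel of intensity `x` gets
#' level `floor(ng * (x - m) / (M - m)) + 1`, with `x = M` mapped to
#' `ng`. A constant VOI maps every voxel to level 1 and sets the
#' degeneracy flag.
#'
#' @param volume An [image_volume()].
#' @param mask An aligned [voi_mask()].
#' @param ng Integer number of grey levels, at least 2.
#' @return A `quantised_voi`: list with `levels` (integer array, 0 outside
#'   the VOI), `mask`, `ng`, `n_voxels`, `voxel_volume_mm3` and
#'   `degenerate`.
#' @examples
#' v <- image_volume(array(seq(0, 3), c(4, 1, 1)))
#' m <- voi_mask(array(1, c(4, 1, 1)))
#' quantise_voi(v, m, 2)$levels[, 1, 1]  # 1 1 2 2
#' @export
quantise_voi <- function(volume, mask, ng) {
  check_aligned(volume, mask)
  ng <- as.integer(ng)
  if (is.na(ng) || ng < 2L) stop("`ng` must be an integer >= 2")
  inside <- mask$mask == 1L
  if (!any(inside)) stop("empty VOI")
  x <- volume$values[inside]
  m <- min(x); M <- max(x)
  degenerate <- (M == m)
  lv <- array(0L, dim = dim(mask$mask))
  if (degenerate) {
    lv[inside] <- 1L
  } else {
    lv[inside] <- pmin(as.integer(floor(ng * (x - m) / (M - m))) + 1L, ng)
  }
  structure(list(
    levels = lv,
    mask = mask$mask,
    ng = ng,
    n_levels = length(unique(lv[inside])),
    n_voxels = sum(inside),
    voxel_volume_mm3 = prod(volume$spacing_mm),
    degenerate = degenerate
  ), class = "quantised_voi")
}

# distinct grey levels present in the VOI (cached by quantise_voi)
voi_n_levels <- function(q) {
  if (!is.null(q$n_levels)) q$n_levels
  else length(unique(q$levels[q$mask == 1L]))
}
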