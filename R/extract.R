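#' Extract the full 93-feature radiomic vector from a VOI
#'
#' Quantises the VOI to `ng` grey levels (fixed bin count over the VOI
#' min-max) and computes all registry features: 18 first-order statistics
#' on the raw intensities plus the five texture families on the
#' quantised levels. No resampling and no image filtering are applied;
#' texture neighbourhoods are unit steps in voxel index space. The result
#' is deterministic.
#'
#' @param volume An [image_volume()].
#' @param mask An aligned [voi_mask()].
#' @param ng Grey-level count. Values outside the study set
#'   `c(8, 16, 32, 64, 128, 256)` are accepted with a warning.
#' @return Named numeric vector of exactly the 93 registry feature names
#'   (in registry order) with a logical `degenerate` attribute set for
#'   constant-intensity VOIs.
#' @examples
#' set.seed(1)
#' v <- image_volume(array(runif(60), c(5, 4, 3)))
#' m <- voi_mask(array(1, c(5, 4, 3)))
#' length(extract_features(v, m, 8))  # 93
#' @export
extract_features <- function(volume, mask, ng) {
  if (!ng %in% study_grey_levels())
    warning("grey-level count ", ng, " is outside the study set")
  q <- quantise_voi(volume, mask, ng)
  x <- voi_values(volume, mask)
  out <- c(
    first_order_features(x, ng = q$ng, voxel_volume_mm3 = q$voxel_volume_mm3),
    glcm_features(q),
    gldm_features(q),
    glrlm_features(q),
    glszm_features(q),
    ngtdm_features(q)
  )
  stopifnot(identical(names(out), feature_names()))
  attr(out, "degenerate") <- q$degenerate
  out
}

#' Factor levels of the factorial study design
#'
#' The analysed wavelength set (nm), grey-level quantisations and
#' reconstruction surrogates of the condition table.
#' @return Integer or character vector of levels.
#' @export
study_wavelengths <- function() c(700L, 730L, 750L, 760L, 770L, 800L, 820L,
                                  840L, 850L)

#' @rdname study_wavelengths
#' @export
study_grey_levels <- function() c(8L, 16L, 32L, 64L, 128L, 256L)

#' @rdname study_wavelengths
#' @export
study_reconstructions <- function() c("backprojection", "model_based")
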