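#' Image volumes and VOI masks
#'
#' Minimal containers for a 3D scalar photoacoustic image and its aligned
#' binary volume-of-interest mask. Values are stored as plain 3D arrays;
#' `spacing_mm` records the anisotropic voxel size (in-plane 75 um, 1 mm
#' between slices by default, matching the reconstruction grid the
#' analysis assumes).
#'
#' @param values 3D numeric array.
#' @param spacing_mm Positive numeric triple, voxel edge lengths in mm.
#' @return An object of class `image_volume` (list with `values`,
#'   `spacing_mm`).
#' @export
image_volume <- function(values, spacing_mm = c(0.075, 0.075, 1.0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0))
    stop("`spacing_mm` must be three strictly positive numbers")
  structure(list(values = values, spacing_mm = spacing_mm),
            class = "image_volume")
}

#' @param mask 3D array coercible to 0/1.
#' @param check_connected If `TRUE`, require the foreground to be a single
#'   26-connected component.
#' @rdname image_volume
#' @export
voi_mask <- function(mask, check_connected = TRUE) {
  mask <- as.array(mask)
  if (length(dim(mask)) != 3L) stop("`mask` must be a 3D array")
  u <- unique(as.vector(mask))
  if (!all(u %in% c(0, 1)))
    stop("mask must be binary; offending values: ",
         paste(utils::head(setdiff(u, c(0, 1)), 5), collapse = ", "))
  mask <- array(as.integer(mask), dim = dim(mask))
  if (sum(mask) < 1L) stop("mask has no foreground voxel")
  if (check_connected) {
    zones <- cpp_glszm_zones(as.integer(mask), dim(mask))
    if (nrow(zones) != 1L)
      stop("mask foreground must be a single 26-connected component (found ",
           nrow(zones), ")")
  }
  structure(list(mask = mask), class = "voi_mask")
}

check_aligned <- function(volume, mask) {
  if (!identical(dim(volume$values), dim(mask$mask)))
    stop("volume and mask grids are misaligned: ",
         paste(dim(volume$values), collapse = "x"), " vs ",
         paste(dim(mask$mask), collapse = "x"))
  invisible(TRUE)
}

#' @rdname image_volume
#' @param volume An `image_volume`.
#' @export
voi_values <- function(volume, mask) {
  check_aligned(volume, mask)
  as.numeric(volume$values[mask$mask == 1L])
}
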