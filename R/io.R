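#' Read and write NIfTI volumes and VOI masks
#'
#' Volumes are stored as float32 NIfTI (`.nii.gz`) with the anisotropic
#' voxel spacing in `pixdim`; masks as unsigned 8-bit 0/1 on the same
#' grid. Reading validates alignment and mask binarity.
#'
#' @param volume An [image_volume()].
#' @param path File path (`.nii` or `.nii.gz`).
#' @export
write_volume <- function(volume, path) {
  img <- RNifti::asNifti(volume$values)
  RNifti::pixdim(img) <- volume$spacing_mm
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' @rdname write_volume
#' @param mask A [voi_mask()].
#' @param reference The `image_volume` the mask belongs to (grid and
#'   spacing are taken from it).
#' @export
write_mask <- function(mask, reference, path) {
  check_aligned(reference, mask)
  img <- RNifti::asNifti(mask$mask)
  RNifti::pixdim(img) <- reference$spacing_mm
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such volume file: ", path)
  img <- RNifti::readNifti(path)
  image_volume(array(as.numeric(img), dim = dim(img)),
               RNifti::pixdim(img)[seq_len(3)])
}

#' @rdname write_volume
#' @param volume_path,mask_path Paths of an aligned volume/mask pair.
#' @return `read_volume_and_mask()`: list with `volume` and `mask`;
#'   errors if grids mismatch or the mask is not binary.
#' @export
read_volume_and_mask <- function(volume_path, mask_path) {
  vol <- read_volume(volume_path)
  if (!file.exists(mask_path)) stop("no such mask file: ", mask_path)
  mimg <- RNifti::readNifti(mask_path)
  mask <- voi_mask(array(as.numeric(mimg), dim = dim(mimg)),
                   check_connected = FALSE)
  check_aligned(vol, mask)
  list(volume = vol, mask = mask)
}

#' Extract features for every row of a condition table
#'
#' Runs [extract_features()] per design row, reusing each volume across
#' its grey-level settings (quantisation happens at extraction). Input
#' is either an in-memory cohort from [generate_cohort()] or a design
#' table with `volume_path`/`mask_path` columns.
#'
#' @param design Condition table (data frame).
#' @param cohort Optional in-memory cohort; when `NULL`, volumes are read
#'   from the paths in `design`.
#' @return Wide data frame: the condition columns, `voi_voxels`,
#'   `degenerate`, then the 93 feature columns.
#' @export
extract_cohort_features <- function(design, cohort = NULL) {
  keys <- cohort_key(design$specimen_id, design$wavelength_nm,
                     design$reconstruction)
  ukeys <- unique(keys)
  feats <- matrix(NA_real_, nrow(design), 93,
                  dimnames = list(NULL, feature_names()))
  voxels <- integer(nrow(design))
  degen <- logical(nrow(design))
  for (key in ukeys) {
    rows <- which(keys == key)
    r1 <- rows[1]
    if (!is.null(cohort)) {
      vol <- cohort$volumes[[key]]
      msk <- cohort$masks[[design$specimen_id[r1]]]
      if (is.null(vol) || is.null(msk))
        stop("cohort is missing volume or mask for ", key)
    } else {
      pair <- read_volume_and_mask(design$volume_path[r1],
                                   design$mask_path[r1])
      vol <- pair$volume
      msk <- pair$mask
    }
    nvox <- sum(msk$mask)
    for (r in rows) {
      fv <- extract_features(vol, msk, design$grey_levels[r])
      feats[r, ] <- fv
      voxels[r] <- nvox
      degen[r] <- isTRUE(attr(fv, "degenerate"))
    }
  }
  cbind(design[, c("specimen_id", "tumour_model", "wavelength_nm",
                   "grey_levels", "reconstruction")],
        voi_voxels = voxels, degenerate = degen,
        as.data.frame(feats, check.names = FALSE))
}

#' Reshape a wide feature table to long format
#'
#' @param wide Output of [extract_cohort_features()].
#' @return Long data frame with the condition columns plus `feature` and
#'   `value`.
#' @export
features_long <- function(wide) {
  keys <- c("specimen_id", "tumour_model", "wavelength_nm", "grey_levels",
            "reconstruction", "voi_voxels", "degenerate")
  keys <- intersect(keys, names(wide))
  fn <- setdiff(names(wide), keys)
  out <- data.frame(
    wide[rep(seq_len(nrow(wide)), length(fn)), keys, drop = FALSE],
    feature = rep(fn, each = nrow(wide)),
    value = unlist(wide[, fn], use.names = FALSE),
    row.names = NULL, stringsAsFactors = FALSE
  )
  out
}
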