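#' Phantom cohort configuration
#'
#' Parameters of the synthetic photoacoustic cohort. The phantom emulates
#' the statistical structure the downstream analysis relies on: basal
#' VOI intensities are gamma-distributed (right-tailed, positive
#' skewness), luminal intensities are zero-truncated Gaussian (near
#' symmetric); basal tumours are larger with a wider volume spread;
#' wavelength-dependent contrast follows a smooth synthetic
#' two-chromophore mixing curve whose model-specific factors coincide at
#' the 800 nm isobestic point; and two reconstruction surrogates shift
#' first-order statistics (seeded high-frequency noise for
#' backprojection, light in-plane smoothing plus an affine intensity
#' rescale for the model-based algorithm) while approximately preserving
#' skewness.
#'
#' @param grid_shape Integer triple, volume grid dimensions.
#' @param spacing_mm Voxel size in mm.
#' @param basal_shape,basal_scale Gamma shape/scale of basal VOI
#'   intensities (shape 2 gives population skewness `2/sqrt(2) = 1.41`).
#' @param luminal_mean,luminal_sd Gaussian parameters of luminal VOI
#'   intensities, truncated at zero.
#' @param background_mean,background_sd Background intensity parameters
#'   (Gaussian truncated at zero, distinctly below the VOI level).
#' @param amp_jitter_sdlog Log-normal sd of a per-specimen global
#'   amplitude factor (specimen-to-specimen signal variation).
#' @param basal_meanlog,basal_sdlog,luminal_meanlog,luminal_sdlog
#'   Log-normal parameters of the target VOI voxel counts per model;
#'   basal mean and spread exceed luminal under the defaults.
#' @param volume_range Allowed range of target VOI voxel counts.
#' @param oxygenation Named fractions of the oxygenated chromophore per
#'   tumour model; any pair of fractions gives equal scale factors at
#'   800 nm by construction.
#' @param curve_oxy,curve_deoxy Linear and quadratic coefficients of the
#'   synthetic chromophore extinction curves in `u = (lambda - 800)/100`.
#' @param wavelength_domain Wavelength range (nm) the contrast curve is
#'   defined on.
#' @param bp_noise_sd Additive noise sd of the backprojection surrogate.
#' @param mb_smooth Cross-neighbour weight of the model-based in-plane
#'   smoothing kernel (centre weight `1 - 4 * mb_smooth`).
#' @param mb_gain,mb_offset Affine intensity rescale of the model-based
#'   surrogate.
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(48L, 48L, 10L),
                           spacing_mm = c(0.075, 0.075, 1.0),
                           basal_shape = 2, basal_scale = 1.5,
                           luminal_mean = 3, luminal_sd = 0.8,
                           background_mean = 0.3, background_sd = 0.12,
                           amp_jitter_sdlog = 0.15,
                           basal_meanlog = log(2600), basal_sdlog = 0.45,
                           luminal_meanlog = log(1400), luminal_sdlog = 0.22,
                           volume_range = c(300L, 4500L),
                           oxygenation = c(basal = 0.35, luminal = 0.65),
                           curve_oxy = c(0.35, 0.10),
                           curve_deoxy = c(-0.30, 0.15),
                           wavelength_domain = c(700, 880),
                           bp_noise_sd = 0.35,
                           mb_smooth = 0.06,
                           mb_gain = 0.75, mb_offset = 0.8) {
  cfg <- list(grid_shape = as.integer(grid_shape), spacing_mm = spacing_mm,
              basal_shape = basal_shape, basal_scale = basal_scale,
              luminal_mean = luminal_mean, luminal_sd = luminal_sd,
              background_mean = background_mean, background_sd = background_sd,
              amp_jitter_sdlog = amp_jitter_sdlog,
              basal_meanlog = basal_meanlog, basal_sdlog = basal_sdlog,
              luminal_meanlog = luminal_meanlog, luminal_sdlog = luminal_sdlog,
              volume_range = volume_range,
              oxygenation = oxygenation,
              curve_oxy = curve_oxy, curve_deoxy = curve_deoxy,
              wavelength_domain = wavelength_domain,
              bp_noise_sd = bp_noise_sd, mb_smooth = mb_smooth,
              mb_gain = mb_gain, mb_offset = mb_offset)
  scales <- c(cfg$basal_shape, cfg$basal_scale, cfg$luminal_sd,
              cfg$background_sd)
  if (any(scales <= 0)) stop("all scale parameters must be positive")
  if (exp(basal_meanlog) <= exp(luminal_meanlog))
    stop("basal mean target volume must exceed luminal")
  structure(cfg, class = "phantom_config")
}

#' Specimen specifications for a cohort
#'
#' Draws per-specimen target VOI voxel counts from the model-specific
#' log-normal volume distributions (basal larger and more spread).
#'
#' @param n_basal,n_luminal Specimen counts per tumour model.
#' @param config A [phantom_config()].
#' @param seed Integer cohort seed.
#' @return Data frame with `specimen_id`, `tumour_model`,
#'   `target_voi_voxels`.
#' @export
make_specimens <- function(n_basal = 10L, n_luminal = 11L,
                           config = phantom_config(), seed = 1L) {
  draw <- function(n, meanlog, sdlog, tag) {
    with_seed(derive_seed(seed, "specimen-volumes", tag), {
      v <- round(rlnorm(n, meanlog, sdlog))
      pmin(pmax(v, config$volume_range[1]), config$volume_range[2])
    })
  }
  vb <- draw(n_basal, config$basal_meanlog, config$basal_sdlog, "basal")
  vl <- draw(n_luminal, config$luminal_meanlog, config$luminal_sdlog,
             "luminal")
  data.frame(
    specimen_id = c(sprintf("basal_%02d", seq_len(n_basal)),
                    sprintf("luminal_%02d", seq_len(n_luminal))),
    tumour_model = rep(c("basal", "luminal"), c(n_basal, n_luminal)),
    target_voi_voxels = as.integer(c(vb, vl)),
    stringsAsFactors = FALSE
  )
}

#' Build the full-factorial condition table
#'
#' Cartesian product of specimens x wavelengths x grey levels x
#' reconstructions. With `balance = TRUE`, specimen counts per tumour
#' model are equalised first by removing a seeded-random surplus
#' specimen from the larger group, which makes the subsequent analysis
#' of variance fully balanced (10 + 11 specimens under the study factor
#' levels give 2160 rows after balancing).
#'
#' @param specimens Data frame with `specimen_id` and `tumour_model`.
#' @param wavelengths,grey_levels,reconstructions Factor level vectors.
#' @param balance Equalise specimen counts per model.
#' @param seed Seed for the balancing removal.
#' @return Data frame with one row per condition; attribute `removed`
#'   lists specimens dropped by balancing.
#' @export
build_design_table <- function(specimens,
                               wavelengths = study_wavelengths(),
                               grey_levels = study_grey_levels(),
                               reconstructions = study_reconstructions(),
                               balance = TRUE, seed = 1L) {
  if (length(wavelengths) == 0 || length(grey_levels) == 0 ||
      length(reconstructions) == 0 || nrow(specimens) == 0)
    stop("all factor level lists must be non-empty")
  removed <- character(0)
  if (balance) {
    counts <- table(specimens$tumour_model)
    if (all(counts == 0)) stop("balance requested with empty groups")
    while (length(unique(counts)) > 1L) {
      big <- names(counts)[which.max(counts)]
      pool <- specimens$specimen_id[specimens$tumour_model == big]
      drop <- with_seed(derive_seed(seed, "balance", big,
                                    length(removed)),
                        sample(pool, 1L))
      removed <- c(removed, drop)
      specimens <- specimens[specimens$specimen_id != drop, , drop = FALSE]
      counts <- table(specimens$tumour_model)
    }
  }
  grid <- expand.grid(
    grey_levels = as.integer(grey_levels),
    reconstruction = as.character(reconstructions),
    wavelength_nm = as.integer(wavelengths),
    specimen_id = specimens$specimen_id,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  grid$tumour_model <- specimens$tumour_model[
    match(grid$specimen_id, specimens$specimen_id)]
  out <- grid[, c("specimen_id", "tumour_model", "wavelength_nm",
                  "grey_levels", "reconstruction")]
  rownames(out) <- NULL
  attr(out, "removed") <- removed
  out
}

#' Simulate one specimen volume and VOI mask
#'
#' Places an ellipsoidal VOI of approximately `target_voi_voxels`
#' foreground voxels at the grid centre; VOI intensities are drawn from
#' the model-specific distribution (gamma for basal, truncated Gaussian
#' for luminal) scaled by a per-specimen amplitude factor, and the
#' background from a distinct low-intensity distribution. Deterministic
#' given `(spec, config, seed)`.
#'
#' @param spec One-row data frame (or list) with `specimen_id`,
#'   `tumour_model`, `target_voi_voxels`.
#' @param config A [phantom_config()].
#' @param seed Integer seed (per-specimen seeds are derived from it and
#'   the specimen id).
#' @return List with `volume` ([image_volume()]) and `mask`
#'   ([voi_mask()]).
#' @export
simulate_specimen <- function(spec, config = phantom_config(), seed = 1L) {
  dims <- config$grid_shape
  target <- spec$target_voi_voxels
  if (target < 27) stop("target_voi_voxels must be at least 27")
  # ellipsoid semi-axes: fixed axial extent, in-plane radius from target
  cz <- (dims[3] - 4) / 2
  a <- sqrt(3 * target / (4 * pi * cz))
  if (2 * a + 2 > min(dims[1], dims[2]) || cz < 1)
    stop("target volume exceeds grid capacity for specimen ",
         spec$specimen_id)
  ctr <- (dims + 1) / 2
  gx <- ((seq_len(dims[1]) - ctr[1]) / a)^2
  gy <- ((seq_len(dims[2]) - ctr[2]) / a)^2
  gz <- ((seq_len(dims[3]) - ctr[3]) / cz)^2
  d2 <- outer(outer(gx, gy, "+"), gz, "+")
  mask <- array(as.integer(d2 <= 1), dim = dims)
  n_in <- sum(mask)

  vals <- with_seed(derive_seed(seed, "specimen", spec$specimen_id), {
    amp <- rlnorm(1, 0, config$amp_jitter_sdlog)
    bg <- pmax(rnorm(prod(dims), config$background_mean,
                     config$background_sd), 0)
    voi <- if (spec$tumour_model == "basal") {
      rgamma(n_in, shape = config$basal_shape, scale = config$basal_scale)
    } else {
      pmax(rnorm(n_in, config$luminal_mean, config$luminal_sd), 0)
    }
    v <- array(bg, dim = dims)
    v[mask == 1L] <- amp * voi
    v
  })
  list(volume = image_volume(vals, config$spacing_mm),
       mask = voi_mask(mask, check_connected = FALSE))
}

#' Wavelength scale factor of the synthetic contrast curve
#'
#' Mixes two smooth synthetic chromophore curves with the model-specific
#' oxygenation fraction. The curves are anchored to the value 1 at
#' 800 nm, so the factors of the two models coincide there (isobestic
#' construction); away from it the models diverge, emulating the
#' differential absorption of oxy- and deoxy-haemoglobin.
#'
#' @param wavelength_nm Wavelength in nm within the configured domain.
#' @param tumour_model `"basal"` or `"luminal"`.
#' @param config A [phantom_config()].
#' @return Positive scalar factor.
#' @export
wavelength_factor <- function(wavelength_nm, tumour_model,
                              config = phantom_config()) {
  dom <- config$wavelength_domain
  if (wavelength_nm < dom[1] || wavelength_nm > dom[2])
    stop("wavelength ", wavelength_nm, " nm outside curve domain [",
         dom[1], ", ", dom[2], "]")
  u <- (wavelength_nm - 800) / 100
  eps_oxy <- 1 + config$curve_oxy[1] * u + config$curve_oxy[2] * u^2
  eps_deoxy <- 1 + config$curve_deoxy[1] * u + config$curve_deoxy[2] * u^2
  f <- config$oxygenation[[tumour_model]]
  f * eps_oxy + (1 - f) * eps_deoxy
}

#' Apply wavelength-dependent contrast to a VOI
#'
#' Rescales VOI intensities by the model- and wavelength-specific
#' [wavelength_factor()]. The map is multiplicative and therefore
#' monotone (rank-preserving within the VOI) and leaves skewness
#' unchanged.
#'
#' @inheritParams wavelength_factor
#' @param volume An [image_volume()].
#' @param mask An aligned [voi_mask()].
#' @return A new `image_volume`.
#' @export
apply_wavelength_contrast <- function(volume, mask, wavelength_nm,
                                      tumour_model,
                                      config = phantom_config()) {
  check_aligned(volume, mask)
  f <- wavelength_factor(wavelength_nm, tumour_model, config)
  v <- volume$values
  v[mask$mask == 1L] <- v[mask$mask == 1L] * f
  image_volume(v, volume$spacing_mm)
}

#' Reconstruction surrogate transforms
#'
#' Desk-scale stand-ins for the two image-formation algorithms of the
#' acquisition software. `backprojection` adds seeded high-frequency
#' (voxel-wise independent) noise; `model_based` applies a light
#' in-plane smoothing followed by an affine intensity rescale. Both are
#' deterministic given the seed; first-order statistics (mean, RMS,
#' percentiles) differ between the two while skewness is approximately
#' preserved (exactly so under the affine part).
#'
#' @param volume An [image_volume()].
#' @param reconstruction `"backprojection"` or `"model_based"`.
#' @param config A [phantom_config()].
#' @param seed Integer seed for the noise draw.
#' @return A new `image_volume`.
#' @export
apply_reconstruction_surrogate <- function(volume, reconstruction,
                                           config = phantom_config(),
                                           seed = 1L) {
  v <- volume$values
  if (reconstruction == "backprojection") {
    if (config$bp_noise_sd > 0)
      v <- v + with_seed(derive_seed(seed, "bp-noise"),
                         array(rnorm(length(v), 0, config$bp_noise_sd),
                               dim = dim(v)))
  } else if (reconstruction == "model_based") {
    if (config$mb_smooth > 0) v <- smooth_inplane(v, config$mb_smooth)
    v <- config$mb_gain * v + config$mb_offset
  } else {
    stop("unknown reconstruction label: ", reconstruction)
  }
  image_volume(v, volume$spacing_mm)
}

# 3x3 in-plane cross kernel with replicated edges; centre weight
# 1 - 4 * w keeps the kernel normalised.
smooth_inplane <- function(v, w) {
  dims <- dim(v)
  out <- v * (1 - 4 * w)
  shift <- function(m, dx, dy) {
    ix <- pmin(pmax(seq_len(dims[1]) + dx, 1), dims[1])
    iy <- pmin(pmax(seq_len(dims[2]) + dy, 1), dims[2])
    m[ix, iy, , drop = FALSE]
  }
  out + w * (shift(v, 1, 0) + shift(v, -1, 0) +
             shift(v, 0, 1) + shift(v, 0, -1))
}

#' Generate a full synthetic cohort
#'
#' Simulates every specimen, applies the wavelength contrast and both
#' reconstruction surrogates, and (optionally) persists one NIfTI
#' volume/mask pair per (specimen, wavelength, reconstruction) together
#' with the design table and a seed manifest. Grey levels enter only at
#' feature extraction, so they need no separate images.
#'
#' @param specimens Data frame from [make_specimens()].
#' @param config A [phantom_config()].
#' @param seed Integer cohort seed.
#' @param output_dir Directory for persisted artifacts (created if
#'   needed); required when `write = TRUE`.
#' @param write Persist volumes, masks, design table and manifest to
#'   `output_dir`; otherwise the cohort is returned in memory only.
#' @param balance,wavelengths,grey_levels,reconstructions Passed to
#'   [build_design_table()].
#' @return List with `design` (condition table, including paths when
#'   written), `volumes` (named list of `image_volume`), `masks` (named
#'   list per specimen) and `manifest`.
#' @export
generate_cohort <- function(specimens = make_specimens(),
                            config = phantom_config(), seed = 1L,
                            output_dir = NULL, write = !is.null(output_dir),
                            balance = TRUE,
                            wavelengths = study_wavelengths(),
                            grey_levels = study_grey_levels(),
                            reconstructions = study_reconstructions()) {
  design <- build_design_table(specimens, wavelengths = wavelengths,
                               grey_levels = grey_levels,
                               reconstructions = reconstructions,
                               balance = balance, seed = seed)
  kept <- unique(design$specimen_id)
  specimens <- specimens[specimens$specimen_id %in% kept, , drop = FALSE]

  if (write) {
    if (is.null(output_dir)) stop("`output_dir` required when write = TRUE")
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(output_dir))
      stop("cannot create output directory: ", output_dir)
  }

  volumes <- list()
  masks <- list()
  for (si in seq_len(nrow(specimens))) {
    spec <- specimens[si, ]
    base <- simulate_specimen(spec, config, seed)
    masks[[spec$specimen_id]] <- base$mask
    for (wl in unique(design$wavelength_nm)) {
      contrasted <- apply_wavelength_contrast(base$volume, base$mask, wl,
                                              spec$tumour_model, config)
      for (rec in unique(design$reconstruction)) {
        key <- cohort_key(spec$specimen_id, wl, rec)
        volumes[[key]] <- apply_reconstruction_surrogate(
          contrasted, rec, config,
          seed = derive_seed(seed, spec$specimen_id, wl, rec))
      }
    }
  }

  if (write) {
    design$volume_path <- file.path(
      output_dir, paste0(cohort_key(design$specimen_id, design$wavelength_nm,
                                    design$reconstruction), ".nii.gz"))
    design$mask_path <- file.path(output_dir,
                                  paste0("mask_", design$specimen_id,
                                         ".nii.gz"))
    for (key in names(volumes))
      write_volume(volumes[[key]], file.path(output_dir,
                                             paste0(key, ".nii.gz")))
    for (sid in names(masks))
      write_mask(masks[[sid]], volumes[[cohort_key(
        sid, design$wavelength_nm[1], design$reconstruction[1])]],
        file.path(output_dir, paste0("mask_", sid, ".nii.gz")))
    write.csv(design, file.path(output_dir, "design.csv"),
              row.names = FALSE)
  }

  manifest <- list(
    seed = seed,
    n_specimens = nrow(specimens),
    removed_for_balance = attr(design, "removed"),
    n_volumes = length(volumes),
    n_design_rows = nrow(design),
    specimen_seeds = setNames(
      lapply(specimens$specimen_id,
             function(s) derive_seed(seed, "specimen", s)),
      specimens$specimen_id)
  )
  if (write)
    jsonlite::write_json(manifest,
                         file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)

  list(design = design, volumes = volumes, masks = masks,
       specimens = specimens, manifest = manifest)
}

cohort_key <- function(specimen_id, wavelength_nm, reconstruction) {
  paste(specimen_id, wavelength_nm, reconstruction, sep = "_")
}
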