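# Study-sized phantom cohort, built once and shared across test files.
# Seed 42 is the fixed study seed of the test conditions.
.cohort_cache <- new.env(parent = emptyenv())

phantom_study <- function() {
  if (!exists("study", envir = .cohort_cache)) {
    cohort <- generate_cohort(make_specimens(seed = 42),
                              phantom_config(), seed = 42)
    wide <- extract_cohort_features(cohort$design, cohort)
    assign("study",
           list(cohort = cohort, wide = wide, long = features_long(wide)),
           envir = .cohort_cache)
  }
  get("study", envir = .cohort_cache)
}

study_factors <- c("tumour_model", "wavelength_nm", "grey_levels",
                   "reconstruction")

# balanced synthetic long-format feature table with planted factor effects;
# effect sds are per-factor contributions on top of unit-free noise
synthetic_feature_table <- function(n_per_model = 10, wavelengths = 1:3,
                                    recons = c("bp", "mb"),
                                    greys = c(8, 16),
                                    model_sd = 1, recon_sd = 0, noise_sd = 0.1,
                                    feature = "f1", seed = 1) {
  set.seed(seed)
  specs <- data.frame(
    specimen_id = sprintf("s%02d", seq_len(2 * n_per_model)),
    tumour_model = rep(c("basal", "luminal"), each = n_per_model))
  g <- expand.grid(specimen_id = specs$specimen_id,
                   wavelength_nm = wavelengths, grey_levels = greys,
                   reconstruction = recons, stringsAsFactors = FALSE)
  g$tumour_model <- specs$tumour_model[match(g$specimen_id,
                                             specs$specimen_id)]
  g$feature <- feature
  model_eff <- ifelse(g$tumour_model == "basal", model_sd, -model_sd)
  recon_eff <- ifelse(g$reconstruction == recons[1], recon_sd, -recon_sd)
  g$value <- model_eff + recon_eff + rnorm(nrow(g), 0, noise_sd)
  g
}
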