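#' End-to-end run configuration
#'
#' Bundles the phantom configuration, factor levels and analysis
#' switches behind one object consumed by [run_pipeline()].
#'
#' @param specimens Specimen table (default: study-sized cohort of 10
#'   basal + 11 luminal drawn from the volume distributions).
#' @param phantom A [phantom_config()].
#' @param wavelengths,grey_levels,reconstructions Factor levels.
#' @param standardise Named list of standardisation sweeps to run, e.g.
#'   `list(grey_levels = 8L, reconstruction = "backprojection")`.
#' @param folds Folds of the CoV robustness stage.
#' @param removal_rule Specimens removed per model per fold.
#' @param q Benjamini-Hochberg FDR level.
#' @param corr_threshold Correlation-pruning threshold.
#' @param eta_threshold Robust-feature share threshold.
#' @param seed Master seed; every stage derives its own seed from it.
#' @param output_dir Output directory (tables, volumes, manifest).
#' @param write_volumes Persist NIfTI volumes (tables and manifest are
#'   always written).
#' @param score_max_rows,shap_eval_n Runtime caps of the scoring and
#'   Shapley stages.
#' @return List of class `run_config`.
#' @export
run_config <- function(specimens = NULL, phantom = phantom_config(),
                       wavelengths = study_wavelengths(),
                       grey_levels = study_grey_levels(),
                       reconstructions = study_reconstructions(),
                       standardise = list(grey_levels = 8L,
                                          reconstruction = "backprojection"),
                       folds = 5L,
                       removal_rule = c(basal = 2L, luminal = 2L),
                       q = 0.25, corr_threshold = 0.9,
                       eta_threshold = 0.8, seed = 1L,
                       output_dir = tempfile("paradiomics_run_"),
                       write_volumes = FALSE,
                       score_max_rows = 800L, shap_eval_n = 150L) {
  if (is.null(specimens))
    specimens <- make_specimens(config = phantom, seed = seed)
  structure(list(specimens = specimens, phantom = phantom,
                 wavelengths = wavelengths, grey_levels = grey_levels,
                 reconstructions = reconstructions,
                 standardise = standardise, folds = folds,
                 removal_rule = removal_rule, q = q,
                 corr_threshold = corr_threshold,
                 eta_threshold = eta_threshold, seed = seed,
                 output_dir = output_dir, write_volumes = write_volumes,
                 score_max_rows = score_max_rows,
                 shap_eval_n = shap_eval_n),
            class = "run_config")
}

#' Build a run configuration from a YAML file
#'
#' Reads a YAML mapping whose keys mirror the arguments of
#' [run_config()] (with `phantom:` holding [phantom_config()] arguments
#' and `specimens:` optional `n_basal`/`n_luminal` counts) and returns
#' the corresponding configuration.
#'
#' @param path YAML file path.
#' @param seed Master seed; overrides a `seed` key in the file when
#'   given.
#' @return A [run_config()].
#' @export
run_config_from_yaml <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  phantom <- do.call(phantom_config, as.list(y$phantom))
  y$phantom <- NULL
  if (!is.null(y$specimens)) {
    sp <- y$specimens
    y$specimens <- make_specimens(sp$n_basal %||% 10L,
                                  sp$n_luminal %||% 11L, phantom,
                                  seed = seed %||% y$seed %||% 1L)
  }
  if (!is.null(y$removal_rule)) y$removal_rule <- unlist(y$removal_rule)
  if (!is.null(seed)) y$seed <- seed
  do.call(run_config, c(y, list(phantom = phantom)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Phantom cohort generation, 93-feature extraction, main-effects
#' eta-squared decomposition with standardisation sweeps and k-fold CoV,
#' then the discrimination stage: volume correction, Kruskal-Wallis
#' with Benjamini-Hochberg control, repeated-measures correlation
#' pruning with single-feature classifier scores and a Shapley-ranked
#' random forest. Every intermediate table is persisted to
#' `config$output_dir`; the returned manifest records seeds and the
#' feature counts surviving each reduction step. Idempotent under an
#' identical configuration and seed.
#'
#' @param config A [run_config()].
#' @return The run manifest (list), invisibly also written as JSON.
#' @export
run_pipeline <- function(config = run_config()) {
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, code) {
    t0 <- Sys.time()
    res <- tryCatch(force(code), error = function(e)
      stop("stage [", name, "] failed: ", conditionMessage(e),
           call. = FALSE))
    message(sprintf("[%s] done in %.1fs", name,
                    as.numeric(Sys.time() - t0, units = "secs")))
    res
  }
  factors <- c("tumour_model", "wavelength_nm", "grey_levels",
               "reconstruction")

  cohort <- stage("phantom", generate_cohort(
    config$specimens, config$phantom, seed = config$seed,
    output_dir = if (config$write_volumes) out else NULL,
    write = config$write_volumes,
    wavelengths = config$wavelengths,
    grey_levels = config$grey_levels,
    reconstructions = config$reconstructions))
  if (!config$write_volumes)
    write.csv(cohort$design, file.path(out, "design.csv"),
              row.names = FALSE)

  wide <- stage("features", extract_cohort_features(cohort$design, cohort))
  write.csv(wide, file.path(out, "features_wide.csv"), row.names = FALSE)
  long <- features_long(wide)
  write.csv(long, file.path(out, "features_long.csv"), row.names = FALSE)

  decomp <- stage("sensitivity", eta_squared_main_effects(long, factors))
  write.csv(decomp, file.path(out, "eta2.csv"), row.names = FALSE)
  robust <- classify_robust_features(decomp, "tumour_model",
                                     config$eta_threshold)

  std <- list()
  for (f in names(config$standardise)) {
    lev <- config$standardise[[f]]
    std[[f]] <- stage(paste0("standardise-", f),
                      standardise_and_decompose(long, factors, f, lev))
    write.csv(std[[f]], file.path(out, paste0("eta2_std_", f, "_", lev,
                                              ".csv")), row.names = FALSE)
  }

  cov_tab <- stage("kfold-cov", kfold_cov(
    long, factors, k = config$folds, removal_rule = config$removal_rule,
    seed = derive_seed(config$seed, "folds")))
  write.csv(cov_tab[, c("feature", "factor", "mean_eta2", "sd_eta2",
                        "cov", "cov_defined")],
            file.path(out, "eta2_fold_cov.csv"), row.names = FALSE)

  # ---- discrimination -------------------------------------------------
  corr <- stage("volume-correction", correct_volume_dependency(wide))
  cw <- corr$corrected
  write.csv(corr$report, file.path(out, "volume_correction.csv"),
            row.names = FALSE)

  kw <- stage("kruskal-wallis", do.call(rbind, lapply(
    feature_names(), function(f) {
      r <- if (sd(cw[[f]]) == 0)
        list(H = NA_real_, df = 1L, p = NA_real_, degenerate = TRUE)
      else kruskal_wallis_h(cw[[f]], cw$tumour_model)
      data.frame(feature = f, H = r$H, df = r$df, p = r$p,
                 degenerate = r$degenerate, stringsAsFactors = FALSE)
    })))
  tested <- kw[!kw$degenerate, ]
  bh <- benjamini_hochberg(tested$p, q = config$q, names = tested$feature)
  kw$reject <- kw$feature %in% bh$name[bh$reject]
  write.csv(merge(kw, bh[, c("name", "rank", "critical")],
                  by.x = "feature", by.y = "name", all.x = TRUE,
                  sort = FALSE),
            file.path(out, "kw_bh.csv"), row.names = FALSE)
  survivors <- kw$feature[kw$reject]

  R <- stage("rmcorr", rmcorr_matrix(cw, survivors))
  write.csv(as.data.frame(R), file.path(out, "rmcorr.csv"))

  scores <- stage("scores", single_feature_scores(
    cw, survivors, seed = derive_seed(config$seed, "scores"),
    max_rows = config$score_max_rows))
  sel <- stage("pruning", prune_correlated(survivors, R, scores,
                                           config$corr_threshold))
  report <- list(discarded_by_bh = setdiff(kw$feature, survivors),
                 pruned_pairs = sel$pruned,
                 selected = sel$selected,
                 threshold = sel$threshold)
  jsonlite::write_json(report, file.path(out, "selection.json"),
                       auto_unbox = TRUE, pretty = TRUE,
                       dataframe = "rows")

  shap <- stage("shapley", fit_forest_and_shapley(
    cw, sel$selected, seed = derive_seed(config$seed, "shapley"),
    eval_n = config$shap_eval_n))
  write.csv(shap$ranking, file.path(out, "shapley_ranking.csv"),
            row.names = FALSE)

  cfg_path <- file.path(out, "run_config.json")
  jsonlite::write_json(config[setdiff(names(config), "specimens")],
                       cfg_path, auto_unbox = TRUE, pretty = TRUE,
                       force = TRUE)

  manifest <- list(
    tool_version = as.character(utils::packageVersion("paradiomics")),
    seed = config$seed,
    config_hash = unname(tools::md5sum(cfg_path)),
    n_design_rows = nrow(cohort$design),
    n_specimens = nrow(cohort$specimens),
    n_volumes = length(cohort$volumes),
    n_features_extracted = sum(feature_names() %in% names(wide)),
    n_robust_model_features = length(robust),
    robust_model_features = robust,
    n_folds = config$folds,
    fold_specimens_per_model = nrow(cohort$specimens) / 2 -
      unname(config$removal_rule[1]),
    n_bh_survivors = length(survivors),
    n_selected = length(sel$selected),
    selected = sel$selected,
    top_features = utils::head(shap$ranking$feature, 9),
    shap_base_value = shap$base_value
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest
}
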