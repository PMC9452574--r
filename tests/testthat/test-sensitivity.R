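test_that("hand-computed 2x2 decomposition is recovered exactly", {
  t <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2"),
                   stringsAsFactors = FALSE)
  t$feature <- "f"
  t$value <- c(0, 4, 2, 6)     # A adds 4, B adds 2: SS 16 + 4 of 20
  d <- eta_squared_main_effects(t, c("A", "B"))
  expect_equal(d$A, 0.8)
  expect_equal(d$B, 0.2)
  expect_equal(d$error, 0)
})

test_that("a factor explaining everything takes share one", {
  t <- data.frame(A = rep(c("x", "y"), each = 4),
                  feature = "f", value = rep(c(1, 5), each = 4))
  d <- eta_squared_main_effects(t, "A")
  expect_equal(d$A, 1)
  expect_equal(d$error, 0)
})

test_that("main-effect sums of squares agree with the linear-model oracle", {
  set.seed(21)
  for (rep in 1:5) {
    t <- synthetic_feature_table(n_per_model = 4, model_sd = runif(1, 0, 2),
                                 recon_sd = runif(1, 0, 1),
                                 noise_sd = 0.5, seed = rep)
    d <- eta_squared_main_effects(t, study_factors)
    av <- stats::anova(lm(value ~ factor(tumour_model) +
                            factor(wavelength_nm) + factor(grey_levels) +
                            factor(reconstruction), data = t))
    ss <- av$`Sum Sq`
    expect_equal(unname(unlist(d[1, study_factors])),
                 unname(ss[1:4] / sum(ss)), tolerance = 1e-10)
  }
})

test_that("shares always close to one and ignore affine feature rescaling", {
  set.seed(33)
  for (rep in 1:8) {
    t <- synthetic_feature_table(model_sd = runif(1), recon_sd = runif(1),
                                 noise_sd = runif(1, 0.1, 1), seed = 100 + rep)
    d <- eta_squared_main_effects(t, study_factors)
    expect_equal(sum(d[1, c(study_factors, "error")]), 1,
                 tolerance = 1e-12)
    t2 <- t; t2$value <- -3.7 * t2$value + 11
    d2 <- eta_squared_main_effects(t2, study_factors)
    expect_equal(unlist(d[1, study_factors]), unlist(d2[1, study_factors]),
                 tolerance = 1e-10)
  }
})

test_that("unbalanced designs are rejected with cell context", {
  t <- synthetic_feature_table(seed = 2)
  expect_error(eta_squared_main_effects(t[-1, ], study_factors),
               "not balanced")
})

test_that("constant feature columns are flagged, not propagated as NaN", {
  t <- synthetic_feature_table(seed = 3)
  t$value <- 5
  d <- eta_squared_main_effects(t, study_factors)
  expect_true(d$degenerate[1])
  expect_equal(unname(unlist(d[1, c(study_factors, "error")])),
               rep(0, 5))
})

test_that("label permutation drives the model share to its null decay", {
  set.seed(55)
  null_share <- vapply(c(8, 16, 32), function(n) {
    mean(vapply(1:20, function(r) {
      t <- synthetic_feature_table(n_per_model = n / 2, wavelengths = 1,
                                   greys = 8, model_sd = 0, noise_sd = 1,
                                   seed = 1000 * n + r)
      specs <- unique(t$specimen_id)
      perm <- setNames(sample(rep(c("basal", "luminal"),
                                  each = length(specs) / 2)), specs)
      t$tumour_model <- unname(perm[t$specimen_id])
      eta_squared_main_effects(t, c("tumour_model",
                                    "reconstruction"))$tumour_model
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(null_share) < 0))
})

test_that("standardising a factor removes its contribution", {
  t <- synthetic_feature_table(model_sd = 1, recon_sd = 0.5,
                               noise_sd = 0.2, seed = 4)
  d <- standardise_and_decompose(t, study_factors, "reconstruction", "bp")
  expect_false("reconstruction" %in% names(d))
  expect_equal(sum(d[1, c(setdiff(study_factors, "reconstruction"),
                          "error")]), 1, tolerance = 1e-12)
  # with the reconstruction effect gone, the model share can only grow
  d0 <- eta_squared_main_effects(t, study_factors)
  expect_gt(d$tumour_model[1], d0$tumour_model[1])
  expect_error(standardise_and_decompose(t, study_factors,
                                         "reconstruction", "nope"),
               "not present")
})

test_that("fixing a no-effect factor leaves other shares unchanged", {
  # noiseless table: value depends on model and wavelength only
  t <- synthetic_feature_table(model_sd = 1, recon_sd = 0, noise_sd = 0,
                               seed = 5)
  t$value <- t$value + as.numeric(t$wavelength_nm == 2) * 0.4
  d0 <- eta_squared_main_effects(t, study_factors)
  d1 <- standardise_and_decompose(t, study_factors, "grey_levels", 8)
  for (f in c("tumour_model", "wavelength_nm"))
    expect_equal(d1[[f]][1], d0[[f]][1], tolerance = 1e-10)
})

test_that("fold CoV reports stable shares with zero CoV and N/a flags", {
  t <- synthetic_feature_table(n_per_model = 10, model_sd = 1,
                               recon_sd = 0, noise_sd = 0, seed = 6)
  cv <- kfold_cov(t, study_factors, k = 3,
                  removal_rule = c(basal = 2L, luminal = 2L), seed = 9)
  row <- cv[cv$feature == "f1" & cv$factor == "tumour_model", ]
  expect_equal(row$mean_eta2, 1, tolerance = 1e-12)
  expect_equal(row$cov, 0, tolerance = 1e-12)
  # zero-share factor is flagged not-applicable
  gl <- cv[cv$feature == "f1" & cv$factor == "grey_levels", ]
  expect_false(gl$cov_defined)
  expect_true(is.na(gl$cov))
  # every fold retained 8 specimens per model
  for (cnt in attr(cv, "fold_specimen_counts"))
    expect_equal(as.integer(cnt), c(8L, 8L))
  expect_error(kfold_cov(t, study_factors, k = 2,
                         removal_rule = c(basal = 50L, luminal = 50L)),
               "exceeds")
})

test_that("robust-feature classification thresholds the model share", {
  d <- data.frame(feature = c("a", "b", "c"),
                  tumour_model = c(0.86, 0.5, 0.95),
                  error = c(0.14, 0.5, 0.05),
                  degenerate = FALSE)
  expect_equal(classify_robust_features(d), c("c", "a"))
  d$tumour_model <- 0
  expect_length(classify_robust_features(d), 0)
})
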