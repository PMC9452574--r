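fake_wide <- function(n_spec = 8, reps = 6, seed = 1) {
  set.seed(seed)
  specs <- sprintf("s%02d", seq_len(n_spec))
  model <- rep(c("basal", "luminal"), length.out = n_spec)
  w <- data.frame(
    specimen_id = rep(specs, each = reps),
    tumour_model = rep(model, each = reps),
    voi_voxels = rep(sample(500:3000, n_spec), each = reps))
  w
}

test_that("exact power-law volume dependency is removed completely", {
  w <- fake_wide(10, 6, seed = 2)
  w$f_dep <- 2.5 * w$voi_voxels^0.7
  w$f_free <- rep(rnorm(10), each = 6)[seq_len(nrow(w))]
  res <- correct_volume_dependency(w, c("f_dep", "f_free"))
  expect_lt(max(res$corrected$f_dep) - min(res$corrected$f_dep), 1e-8)
  rep_dep <- res$report[res$report$feature == "f_dep", ]
  expect_true(rep_dep$corrected)
  expect_equal(rep_dep$b, 0.7, tolerance = 1e-6)
})

test_that("volume-independent features pass through unchanged", {
  w <- fake_wide(10, 6, seed = 3)
  set.seed(4)
  w$f_free <- rnorm(nrow(w))
  res <- correct_volume_dependency(w, "f_free")
  expect_identical(res$corrected$f_free, w$f_free)
  expect_false(res$report$corrected)
  # shift invariance of the pass-through
  w2 <- w; w2$f_free <- w$f_free + 5
  res2 <- correct_volume_dependency(w2, "f_free")
  expect_equal(res2$corrected$f_free, res$corrected$f_free + 5)
})

test_that("Kruskal-Wallis H matches the hand formula and stats oracle", {
  r <- kruskal_wallis_h(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(r$H, 27 / 7, tolerance = 1e-12)
  expect_equal(r$df, 1L)

  # identical rank distributions -> H = 0
  r0 <- kruskal_wallis_h(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(r0$H, 0, tolerance = 1e-12)

  set.seed(10)
  for (rep in 1:8) {
    x <- sample(1:6, 30, replace = TRUE)     # heavy ties
    g <- sample(c("a", "b", "c"), 30, replace = TRUE)
    if (length(unique(g)) < 2 || length(unique(x)) < 2) next
    got <- kruskal_wallis_h(x, g)
    want <- kruskal.test(x, factor(g))
    expect_equal(got$H, unname(want$statistic), tolerance = 1e-10)
    expect_equal(got$p, want$p.value, tolerance = 1e-10)
  }

  expect_equal(kruskal_wallis_h(rep(2, 6),
                                rep(c("a", "b"), 3))$degenerate, TRUE)
})

test_that("Benjamini-Hochberg step-up matches hand example and p.adjust", {
  d <- benjamini_hochberg(c(0.01, 0.02, 0.2, 0.8), q = 0.25)
  expect_equal(d$critical, c(0.0625, 0.125, 0.1875, 0.25))
  expect_equal(d$reject, c(TRUE, TRUE, FALSE, FALSE))

  expect_false(any(benjamini_hochberg(rep(1, 5), 0.25)$reject))
  expect_equal(nrow(benjamini_hochberg(numeric(0))), 0)

  set.seed(12)
  for (rep in 1:10) {
    p <- runif(40)^2
    d <- benjamini_hochberg(p, q = 0.25, names = paste0("f", seq_along(p)))
    padj <- p.adjust(p, "BH")
    expect_setequal(d$name[d$reject],
                    paste0("f", which(padj <= 0.25)))
    # rejections form a prefix of the sorted list
    expect_true(all(diff(d$reject) <= 0))
  }
})

test_that("repeated-measures correlation recovers within-subject structure", {
  subj <- rep(letters[1:4], each = 5)
  x <- rep(seq(-2, 2), 4)
  off <- rep(c(0, 10, -4, 7), each = 5)
  r1 <- repeated_measures_correlation(x, 2 * x + off, subj)
  expect_equal(r1$r, 1, tolerance = 1e-12)
  r2 <- repeated_measures_correlation(x, -x + off, subj)
  expect_equal(r2$r, -1, tolerance = 1e-12)

  set.seed(14)
  x <- rnorm(24); y <- rnorm(24)
  subj <- rep(letters[1:6], each = 4)
  got <- repeated_measures_correlation(x, y, subj)
  # brute-force centred-covariance oracle
  cx <- unlist(lapply(split(x, subj), function(v) v - mean(v)))
  cy <- unlist(lapply(split(y, subj), function(v) v - mean(v)))
  expect_equal(got$r, sum(cx * cy) / sqrt(sum(cx^2) * sum(cy^2)),
               tolerance = 1e-12)
  expect_equal(got$df, 24 - 6 - 1)

  rz <- repeated_measures_correlation(rep(1, 24), y, subj)
  expect_true(rz$degenerate)
})

test_that("rmcorr matrix is symmetric with unit diagonal", {
  w <- fake_wide(6, 4, seed = 15)
  set.seed(15)
  w$a <- rnorm(nrow(w)); w$b <- w$a + rnorm(nrow(w), 0, 0.1)
  w$c <- rnorm(nrow(w))
  R <- rmcorr_matrix(w, c("a", "b", "c"))
  expect_equal(R, t(R))
  expect_equal(unname(diag(R)), rep(1, 3))
  expect_true(all(abs(R) <= 1 + 1e-12))
  expect_gt(R["a", "b"], 0.9)
  r_ref <- repeated_measures_correlation(w$a, w$c, w$specimen_id)$r
  expect_equal(R["a", "c"], r_ref, tolerance = 1e-12)
})

test_that("single-feature scores reward separation and are deterministic", {
  w <- fake_wide(10, 10, seed = 16)
  set.seed(16)
  w$sep <- ifelse(w$tumour_model == "basal", 1, 0) + rnorm(nrow(w), 0, 0.05)
  w$dup <- w$sep
  w$noise <- rnorm(nrow(w))
  s1 <- single_feature_scores(w, c("sep", "dup", "noise"), seed = 3)
  expect_equal(unname(s1["sep"]), 1.0)
  expect_identical(s1[["sep"]], s1[["dup"]])
  s2 <- single_feature_scores(w, c("sep", "dup", "noise"), seed = 3)
  expect_identical(s1, s2)
  w1 <- w; w1$tumour_model <- "basal"
  expect_error(single_feature_scores(w1, "sep"), "two classes")
})

test_that("correlation pruning keeps the best of each correlated clique", {
  feats <- c("firstorder_Mean", "firstorder_Median", "glcm_Contrast")
  R <- matrix(0.95, 3, 3, dimnames = list(feats, feats))
  diag(R) <- 1
  scores <- c(firstorder_Mean = 0.9, firstorder_Median = 0.8,
              glcm_Contrast = 0.7)
  sel <- prune_correlated(feats, R, scores)
  expect_equal(sel$selected, "firstorder_Mean")  # chain resolves to best

  # tie broken by registry order
  scores2 <- c(firstorder_Mean = 0.8, firstorder_Median = 0.8,
               glcm_Contrast = 0.8)
  R2 <- diag(3); dimnames(R2) <- list(feats, feats)
  R2["firstorder_Mean", "firstorder_Median"] <-
    R2["firstorder_Median", "firstorder_Mean"] <- 0.99
  sel2 <- prune_correlated(feats, R2, scores2)
  expect_setequal(sel2$selected, c("firstorder_Mean", "glcm_Contrast"))

  # nothing above threshold: selection unchanged
  R3 <- diag(3); dimnames(R3) <- list(feats, feats)
  sel3 <- prune_correlated(feats, R3, scores)
  expect_equal(sel3$selected, feats)
  expect_equal(nrow(sel3$pruned), 0)

  # no surviving pair exceeds the threshold
  expect_true(all(abs(R[sel$selected, sel$selected]
                      [upper.tri(diag(length(sel$selected)))]) <= 0.9))
})
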