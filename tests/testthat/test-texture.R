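make_q <- function(vals, dims, ng, mask = NULL) {
  v <- image_volume(array(vals, dims))
  m <- voi_mask(if (is.null(mask)) array(1, dims) else mask,
                check_connected = FALSE)
  quantise_voi(v, m, ng)
}

test_that("GLCM limits on a constant-level VOI", {
  q <- make_q(5, c(3, 3, 3), 8)
  f <- glcm_features(q)
  expect_equal(unname(f["glcm_Contrast"]), 0)
  expect_equal(unname(f["glcm_MaximumProbability"]), 1)
  expect_equal(unname(f["glcm_JointEntropy"]), 0)
  expect_true(attr(f, "degenerate"))
})

test_that("in-plane checkerboard gives unit contrast along axial offsets", {
  dims <- c(4, 4, 3)
  idx <- expand.grid(x = 1:4, y = 1:4, z = 1:3)
  vals <- (idx$x + idx$y) %% 2           # 2-level checkerboard per slice
  q <- make_q(vals, dims, 2)
  mats <- glcm_matrices(q)
  # offsets 1 and 2 are (1,0,0) and (0,1,0): all co-occurrences cross-level
  for (d in 1:2) {
    f <- glcm_features_from_matrix(mats[[d]])
    expect_equal(unname(f["Contrast"]), 1)
    expect_equal(unname(f["MaximumProbability"]), 0.5)
  }
})

test_that("GLRLM single-line run and run-percentage limits", {
  q <- make_q(2, c(1, 1, 6), 4)
  mats <- glrlm_matrices(q)
  d_axial <- mats[[3]]                   # direction (0, 0, 1)
  expect_equal(sum(d_axial), 1)          # one run ...
  expect_equal(d_axial[1, 6], 1L)        # ... of length 6 at level 1
  f <- glrlm_features_from_matrix(d_axial, np = 6)
  expect_equal(unname(f["LongRunEmphasis"]), 36)

  # all-distinct levels: every voxel is its own run in every direction
  q2 <- make_q(0:7, c(2, 2, 2), 8)
  f2 <- glrlm_features(q2)
  expect_equal(unname(f2["glrlm_RunPercentage"]), 1)
})

test_that("GLSZM zone limits", {
  q <- make_q(3, c(3, 3, 2), 4)          # constant VOI: one zone of 18
  f <- glszm_features(q)
  expect_equal(unname(f["glszm_ZonePercentage"]), 1 / 18)
  expect_equal(unname(f["glszm_LargeAreaEmphasis"]), 18^2)

  q2 <- make_q(0:7, c(2, 2, 2), 8)       # all isolated levels
  f2 <- glszm_features(q2)
  expect_equal(unname(f2["glszm_ZonePercentage"]), 1)
})

test_that("GLDM dependence counting matches neighbour geometry", {
  q <- make_q(1, c(3, 3, 3), 4)
  P <- paradiomics:::cpp_gldm_counts(as.integer(q$levels), dim(q$levels), q$ng, 0L)
  # 3x3x3 constant block: centre has 26 equal neighbours, corners 7
  expect_equal(P[1, 27], 1L)             # one voxel with dependence 26
  expect_equal(P[1, 8], 8L)              # eight corners with dependence 7

  # single-voxel VOI: dependence 0
  m <- array(0L, c(3, 3, 3)); m[2, 2, 2] <- 1L
  q1 <- make_q(1, c(3, 3, 3), 4, mask = m)
  P1 <- paradiomics:::cpp_gldm_counts(as.integer(q1$levels), dim(q1$levels), q1$ng, 0L)
  expect_equal(sum(P1), 1L)
  expect_equal(P1[1, 1], 1L)
})

test_that("NGTDM of a flat VOI is zero-difference", {
  q <- make_q(2, c(3, 3, 2), 4)
  acc <- paradiomics:::cpp_ngtdm_counts(as.integer(q$levels), dim(q$levels), q$ng)
  expect_equal(sum(acc$s), 0)
  f <- ngtdm_features(q)
  expect_equal(unname(f["ngtdm_Contrast"]), 0)
  expect_equal(unname(f["ngtdm_Coarseness"]), 1e6)
})

test_that("all texture families match brute-force oracles on random VOIs", {
  set.seed(31)
  for (rep in 1:6) {
    fix <- random_small_voi(dims = c(sample(3:5, 1), sample(3:5, 1),
                                     sample(2:3, 1)))
    for (ng in c(2, 4, 8)) {
      q <- quantise_voi(fix$volume, fix$mask, ng)
      cmp <- function(got, want)
        expect_equal(got[names(want)], want, tolerance = 1e-10)
      cmp(glcm_features(q), oracle_glcm(q$levels, ng))
      cmp(glrlm_features(q), oracle_glrlm(q$levels, ng, q$n_voxels))
      cmp(glszm_features(q), oracle_glszm(q$levels, q$n_voxels))
      cmp(gldm_features(q), oracle_gldm(q$levels, ng))
      cmp(ngtdm_features(q), oracle_ngtdm(q$levels, ng))
    }
  }
})

test_that("normalised co-occurrence matrices are probability tables", {
  set.seed(5)
  fix <- random_small_voi(c(5, 4, 3))
  q <- quantise_voi(fix$volume, fix$mask, 4)
  for (P in glcm_matrices(q)) {
    expect_equal(sum(P), 1, tolerance = 1e-12)
    expect_equal(P, t(P))
    expect_true(all(P >= 0))
  }
})

test_that("texture features are invariant to a global intensity shift", {
  set.seed(9)
  fix <- random_small_voi(c(5, 5, 3))
  f1 <- extract_features(fix$volume, fix$mask, 8)
  shifted <- image_volume(fix$volume$values + 17.3,
                          fix$volume$spacing_mm)
  f2 <- extract_features(shifted, fix$mask, 8)
  texture <- grep("^(glcm|gldm|glrlm|glszm|ngtdm)_", names(f1), value = TRUE)
  expect_equal(f1[texture], f2[texture], tolerance = 1e-10)
})
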