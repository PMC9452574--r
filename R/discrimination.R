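#' Correct intrinsic volume dependency of radiomic features
#'
#' Some radiomic features carry an intrinsic dependency on the VOI
#' volume. Per feature, the dependency is tested by Spearman correlation
#' with the VOI voxel count; when significant (`p < p_gate`), a power
#' law `value = a * V^b` is fitted by least squares on log-transformed
#' (positive-shifted where needed) values and the values are replaced by
#' the fit residuals recentred at the grand mean, mapped back to the
#' original scale. Non-dependent features pass through unchanged.
#'
#' @param wide Wide feature table from [extract_cohort_features()]
#'   (needs a `voi_voxels` column).
#' @param features Feature columns to consider (default: all registry
#'   features present).
#' @param p_gate Significance gate of the Spearman test.
#' @return List with `corrected` (the wide table with corrected columns)
#'   and `report` (per feature: `rho`, `p`, `corrected` flag, power-law
#'   `a`, `b`).
#' @export
correct_volume_dependency <- function(wide, features = NULL,
                                      p_gate = 0.05) {
  if (is.null(features))
    features <- intersect(feature_names(), names(wide))
  V <- wide$voi_voxels
  if (any(V <= 0)) stop("non-positive VOI volumes")
  rep_rows <- lapply(features, function(f) {
    y <- wide[[f]]
    if (sd(y) == 0 || !all(is.finite(y)))
      return(data.frame(feature = f, rho = 0, p = 1, corrected = FALSE,
                        a = NA_real_, b = NA_real_))
    ct <- suppressWarnings(cor.test(y, V, method = "spearman",
                                    exact = FALSE))
    if (is.na(ct$p.value) || ct$p.value >= p_gate)
      return(data.frame(feature = f, rho = unname(ct$estimate),
                        p = ct$p.value, corrected = FALSE,
                        a = NA_real_, b = NA_real_))
    shift <- if (min(y) <= 0) -min(y) + 1e-6 * max(abs(y), 1) else 0
    ly <- log(y + shift)
    fit <- lm(ly ~ log(V))
    resid_centred <- stats::residuals(fit) + mean(ly)
    wide[[f]] <<- exp(resid_centred) - shift
    data.frame(feature = f, rho = unname(ct$estimate), p = ct$p.value,
               corrected = TRUE,
               a = exp(unname(stats::coef(fit)[1])),
               b = unname(stats::coef(fit)[2]))
  })
  list(corrected = wide, report = do.call(rbind, rep_rows))
}

#' Tie-corrected Kruskal-Wallis H test
#'
#' Rank-based test of whether a feature's values come from the same
#' distribution in every group. Mid-ranks with the tie correction
#' `H_c = H / (1 - sum(t^3 - t) / (N^3 - N))`; p-value from the
#' chi-square distribution with `groups - 1` degrees of freedom.
#' All-identical values make H undefined: the result is flagged
#' degenerate and non-significant (`p = 1`).
#'
#' @param values Numeric vector.
#' @param groups Group labels (at least two non-empty groups).
#' @return List with `H`, `df`, `p`, `degenerate`.
#' @examples
#' kruskal_wallis_h(c(1, 2, 3, 4, 5, 6),
#'                  rep(c("a", "b"), each = 3))$H  # 27/7
#' @export
kruskal_wallis_h <- function(values, groups) {
  groups <- as.character(groups)
  ug <- unique(groups)
  if (length(ug) < 2L) stop("need at least two groups")
  n <- length(values)
  if (length(unique(values)) == 1L)
    return(list(H = NA_real_, df = length(ug) - 1L, p = 1,
                degenerate = TRUE))
  r <- rank(values)
  h <- 12 / (n * (n + 1)) *
    sum(vapply(ug, function(g) sum(r[groups == g])^2 / sum(groups == g),
               numeric(1))) - 3 * (n + 1)
  ties <- base::table(values)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  h <- h / corr
  df <- length(ug) - 1L
  list(H = h, df = df, p = pchisq(h, df, lower.tail = FALSE),
       degenerate = FALSE)
}

#' Benjamini-Hochberg step-up decision at FDR level q
#'
#' Sorts the p-values ascending (stable tie handling by feature name),
#' computes the per-rank critical values `k * q / m` and rejects the
#' hypotheses up to the largest rank whose p-value sits below its
#' critical value. Controls the expected false discovery rate at `q`.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param q Allowed false discovery rate (default 0.25).
#' @param names Optional hypothesis names.
#' @return Data frame with `name`, `p`, `rank`, `critical`, `reject`,
#'   in ascending-p order.
#' @export
benjamini_hochberg <- function(p, q = 0.25, names = NULL) {
  if (length(p) == 0)
    return(data.frame(name = character(0), p = numeric(0),
                      rank = integer(0), critical = numeric(0),
                      reject = logical(0)))
  stopifnot(all(p >= 0 & p <= 1), q > 0, q < 1)
  if (is.null(names)) names <- paste0("h", seq_along(p))
  ord <- order(p, names)
  m <- length(p)
  ps <- p[ord]
  crit <- seq_len(m) * q / m
  below <- which(ps <= crit)
  kstar <- if (length(below)) max(below) else 0L
  data.frame(name = names[ord], p = ps, rank = seq_len(m),
             critical = crit, reject = seq_len(m) <= kstar,
             stringsAsFactors = FALSE)
}

#' Repeated-measures correlation
#'
#' The within-subject association between two variables measured
#' repeatedly on the same subjects: subject means are removed from both
#' variables and the correlation of the centred values is computed, with
#' `df = N - k - 1` (N observations, k subjects) and the p-value from
#' the t transform. Appropriate here because all conditions of one
#' tumour are measurements of the same specimen, so ordinary correlation
#' across the pooled rows would conflate between- and within-subject
#' association.
#'
#' @param x,y Numeric vectors.
#' @param subjects Subject identifiers (the specimen).
#' @return List with `r`, `df`, `p`, `degenerate` (zero within-subject
#'   variance in either variable).
#' @export
repeated_measures_correlation <- function(x, y, subjects) {
  subjects <- as.character(subjects)
  if (length(unique(subjects)) < 2L) stop("need at least two subjects")
  cx <- x - stats::ave(x, subjects)
  cy <- y - stats::ave(y, subjects)
  sxx <- sum(cx^2); syy <- sum(cy^2)
  if (sxx == 0 || syy == 0)
    return(list(r = NA_real_, df = NA_integer_, p = NA_real_,
                degenerate = TRUE))
  r <- sum(cx * cy) / sqrt(sxx * syy)
  df <- length(x) - length(unique(subjects)) - 1L
  tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  list(r = r, df = df, p = 2 * pt(-abs(tstat), df), degenerate = FALSE)
}

#' Repeated-measures correlation matrix over features
#'
#' @param wide Wide feature table with `specimen_id`.
#' @param features Feature columns to correlate.
#' @return Symmetric correlation matrix (diagonal 1; `NA` where a
#'   feature has no within-subject variance).
#' @export
rmcorr_matrix <- function(wide, features) {
  centred <- vapply(features, function(f)
    wide[[f]] - stats::ave(wide[[f]], wide$specimen_id),
    numeric(nrow(wide)))
  ss <- sqrt(colSums(centred^2))
  R <- crossprod(centred) / outer(ss, ss)
  R[, ss == 0] <- NA_real_
  R[ss == 0, ] <- NA_real_
  diag(R) <- 1
  dimnames(R) <- list(features, features)
  R
}

#' Single-feature classification scores
#'
#' Specimen-grouped k-fold cross-validated classification accuracy of
#' each feature on its own, for three classifiers with fixed
#' hyperparameters: a random forest (100 trees), gradient-boosted trees
#' (depth 3, 100 estimators, learning rate 1.0) and an RBF-kernel SVM
#' (`gamma = 0.05`, `C = 1.0`, tolerance 0.001). Folds split whole
#' specimens so the many conditions of one tumour never straddle the
#' train/test boundary. The reported score per feature is the maximum
#' over the classifiers. Rows can be capped by a seeded stratified
#' subsample to bound runtime; scores are comparative (they feed
#' tie-breaking in the correlation pruning), not performance claims.
#'
#' @param wide Wide feature table with `specimen_id` and `tumour_model`.
#' @param features Feature columns to score.
#' @param k Number of grouped folds.
#' @param seed Integer seed.
#' @param max_rows Cap on rows used for scoring (`Inf` to use all).
#' @param classifiers Subset of `c("rf", "gbt", "svm")`.
#' @return Named numeric vector of scores in `[0, 1]`.
#' @export
single_feature_scores <- function(wide, features, k = 5L, seed = 1L,
                                  max_rows = 800L,
                                  classifiers = c("rf", "gbt", "svm")) {
  labels <- factor(wide$tumour_model)
  if (nlevels(labels) < 2L) stop("labels must contain two classes")
  if (nrow(wide) > max_rows) {
    keep <- with_seed(derive_seed(seed, "score-subsample"), {
      unlist(lapply(split(seq_len(nrow(wide)), labels), function(ix)
        sample(ix, round(length(ix) * max_rows / nrow(wide)))))
    })
    wide <- wide[keep, , drop = FALSE]
    labels <- factor(wide$tumour_model)
  }
  specs <- unique(wide$specimen_id)
  if (length(specs) < k) stop("fewer specimens than folds")
  fold_of <- with_seed(derive_seed(seed, "score-folds"),
                       setNames(sample(rep(seq_len(k),
                                           length.out = length(specs))),
                                specs))
  folds <- fold_of[wide$specimen_id]
  pos <- levels(labels)[2]
  vapply(features, function(f) {
    x <- wide[[f]]
    acc <- matrix(NA_real_, k, length(classifiers),
                  dimnames = list(NULL, classifiers))
    for (fd in seq_len(k)) {
      tr <- folds != fd
      if (length(unique(labels[tr])) < 2L) next
      xtr <- matrix(x[tr], ncol = 1); xte <- matrix(x[!tr], ncol = 1)
      ytr <- droplevels(labels[tr]); yte <- labels[!tr]
      if ("rf" %in% classifiers) {
        m <- with_seed(derive_seed(seed, "rf", f, fd),
                       randomForest::randomForest(xtr, ytr, ntree = 100))
        acc[fd, "rf"] <- mean(predict(m, xte) == yte)
      }
      if ("gbt" %in% classifiers) {
        m <- xgboost::xgboost(
          x = xtr, y = factor(ytr == pos), nrounds = 100,
          max_depth = 3, learning_rate = 1.0,
          objective = "binary:logistic", nthreads = 1, verbosity = 0)
        pr <- predict(m, xte, type = "response")
        acc[fd, "gbt"] <- mean((pr > 0.5) == (yte == pos))
      }
      if ("svm" %in% classifiers) {
        m <- e1071::svm(xtr, ytr, kernel = "radial", gamma = 0.05,
                        cost = 1.0, tolerance = 0.001)
        acc[fd, "svm"] <- mean(predict(m, xte) == yte)
      }
    }
    max(colMeans(acc, na.rm = TRUE))
  }, numeric(1))
}

#' Prune highly correlated features, keeping the better discriminator
#'
#' Greedy resolution of feature pairs whose absolute repeated-measures
#' correlation exceeds `threshold`, in descending `|r|` order: of each
#' still-surviving pair the lower-scoring member is dropped; score ties
#' are broken by registry order. No surviving pair exceeds the
#' threshold afterwards.
#'
#' @param features Candidate feature names (registry order defines tie
#'   precedence).
#' @param rmcorr Correlation matrix over (at least) these features.
#' @param scores Named vector of single-feature scores.
#' @param threshold Absolute-correlation threshold (default 0.9).
#' @return List of class `selection_report`: `selected`, `pruned`
#'   (data frame of kept/dropped/r/scores), `threshold`.
#' @export
prune_correlated <- function(features, rmcorr, scores, threshold = 0.9) {
  stopifnot(all(features %in% rownames(rmcorr)),
            all(features %in% names(scores)))
  reg_rank <- setNames(seq_along(feature_names()), feature_names())
  pairs <- which(upper.tri(rmcorr[features, features, drop = FALSE]) &
                   abs(rmcorr[features, features, drop = FALSE]) > threshold,
                 arr.ind = TRUE)
  keep <- setNames(rep(TRUE, length(features)), features)
  pruned <- list()
  if (nrow(pairs)) {
    rvals <- abs(rmcorr[features, features])[pairs]
    ord <- order(rvals, decreasing = TRUE)
    for (pi in ord) {
      f1 <- features[pairs[pi, 1]]
      f2 <- features[pairs[pi, 2]]
      if (!keep[f1] || !keep[f2]) next
      s1 <- scores[[f1]]; s2 <- scores[[f2]]
      drop <- if (s1 > s2) f2
      else if (s2 > s1) f1
      else if (reg_rank[[f1]] <= reg_rank[[f2]]) f2 else f1
      kept <- setdiff(c(f1, f2), drop)
      keep[drop] <- FALSE
      pruned[[length(pruned) + 1L]] <- data.frame(
        kept = kept, dropped = drop,
        r = rmcorr[f1, f2], score_kept = scores[[kept]],
        score_dropped = scores[[drop]], stringsAsFactors = FALSE)
    }
  }
  structure(list(
    selected = features[keep[features]],
    pruned = if (length(pruned)) do.call(rbind, pruned)
             else data.frame(kept = character(0), dropped = character(0),
                             r = numeric(0), score_kept = numeric(0),
                             score_dropped = numeric(0)),
    threshold = threshold
  ), class = "selection_report")
}
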