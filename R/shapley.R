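#' Random-forest fit with Shapley-value feature ranking
#'
#' Fits a seeded random forest on the selected features and attributes
#' its predicted probability of the positive (luminal) class to the
#' features by Shapley values under the marginal-expectation value
#' function: the worth of a coalition S for a sample x is the mean model
#' output over background rows with the features in S replaced by x's
#' values. Attributions are exact (full coalition enumeration) up to
#' `exact_max` features and estimated by a seeded permutation-sampling
#' scheme above it; both satisfy local accuracy exactly -- for every
#' sample, base value plus the attribution sum equals the model output.
#' The global ranking orders features by mean absolute attribution.
#'
#' @param wide Data frame holding the feature columns and
#'   `tumour_model`.
#' @param features Selected feature names (at least 2).
#' @param seed Integer seed (forest, permutations, subsampling).
#' @param positive Label treated as the signal class.
#' @param exact_max Feature count up to which coalitions are enumerated
#'   exactly.
#' @param n_perm Permutations per sample for the estimator.
#' @param background_n Background rows used by the value function.
#' @param eval_n Rows attributions are computed for (seeded subsample;
#'   `Inf` for all rows).
#' @param ntree Trees in the forest.
#' @return List of class `shapley_ranking`: `ranking` (data frame,
#'   decreasing mean |attribution|), `attributions` (sample x feature
#'   matrix), `base_value`, `predictions`, `eval_rows`, `model`.
#' @export
fit_forest_and_shapley <- function(wide, features, seed = 1L,
                                   positive = "luminal",
                                   exact_max = 10L, n_perm = 16L,
                                   background_n = 32L, eval_n = 150L,
                                   ntree = 100L) {
  if (length(features) < 2L) stop("need at least two selected features")
  labels <- factor(wide$tumour_model)
  if (nlevels(labels) != 2L) stop("labels must be binary")
  X <- as.matrix(wide[, features, drop = FALSE])
  model <- with_seed(derive_seed(seed, "forest"),
                    randomForest::randomForest(X, labels, ntree = ntree))
  predfun <- function(M) {
    colnames(M) <- features
    as.numeric(predict(model, M, type = "prob")[, positive])
  }

  bg_idx <- if (nrow(X) > background_n)
    with_seed(derive_seed(seed, "shap-bg"), sample(nrow(X), background_n))
  else seq_len(nrow(X))
  background <- X[bg_idx, , drop = FALSE]

  eval_rows <- if (nrow(X) > eval_n)
    with_seed(derive_seed(seed, "shap-eval"), sort(sample(nrow(X), eval_n)))
  else seq_len(nrow(X))

  preds <- predfun(X[eval_rows, , drop = FALSE])
  base_value <- mean(predfun(background))

  k <- length(features)
  phi <- if (k <= exact_max) {
    shapley_exact(X[eval_rows, , drop = FALSE], predfun, background)
  } else {
    shapley_permutation(X[eval_rows, , drop = FALSE], predfun, background,
                        n_perm = n_perm,
                        seed = derive_seed(seed, "shap-perm"))
  }
  colnames(phi) <- features
  if (sd(preds) == 0 && all(abs(phi) < 1e-12)) {
    flag <- TRUE
  } else flag <- FALSE

  ranking <- data.frame(feature = features,
                        mean_abs_shap = colMeans(abs(phi)),
                        stringsAsFactors = FALSE)
  ranking <- ranking[order(ranking$mean_abs_shap, decreasing = TRUE), ]
  rownames(ranking) <- NULL
  structure(list(ranking = ranking, attributions = phi,
                 base_value = base_value, predictions = preds,
                 eval_rows = eval_rows, degenerate = flag,
                 model = model),
            class = "shapley_ranking")
}

# Exact Shapley by subset enumeration. v(S) for sample x is the mean of
# predfun over the background with columns in S overwritten by x.
shapley_exact <- function(Xe, predfun, background) {
  k <- ncol(Xe)
  nb <- nrow(background)
  subsets <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), k)))
  sizes <- rowSums(subsets)
  # weight |S|! (k - |S| - 1)! / k!; the full set never occurs as an S
  w <- ifelse(sizes >= k, 0,
              factorial(sizes) * factorial(pmax(k - sizes - 1, 0)) /
                factorial(k))

  phi <- matrix(0, nrow(Xe), k)
  for (s in seq_len(nrow(Xe))) {
    x <- Xe[s, ]
    # v for every subset in one batched prediction
    hyb <- background[rep(seq_len(nb), nrow(subsets)), , drop = FALSE]
    for (jj in seq_len(k)) {
      on <- rep(subsets[, jj], each = nb)
      hyb[on, jj] <- x[jj]
    }
    v <- colMeans(matrix(predfun(hyb), nrow = nb))
    for (jj in seq_len(k)) {
      without <- !subsets[, jj]
      # index of S u {jj}: flipping bit jj adds 2^(jj-1) in expand.grid order
      with_j <- which(without) + 2^(jj - 1)
      phi[s, jj] <- sum(w[without] * (v[with_j] - v[which(without)]))
    }
  }
  phi
}

# Permutation-sampling Shapley estimator. Marginal contributions along a
# permutation telescope to v(full) - v(empty), so local accuracy holds
# exactly for the averaged estimate as well.
shapley_permutation <- function(Xe, predfun, background, n_perm, seed) {
  k <- ncol(Xe)
  nb <- nrow(background)
  perms <- with_seed(seed, replicate(n_perm, sample.int(k),
                                     simplify = FALSE))
  phi <- matrix(0, nrow(Xe), k)
  for (p in perms) {
    # build all k+1 nested coalitions for all samples in one batch
    for (s in seq_len(nrow(Xe))) {
      x <- Xe[s, ]
      hyb <- background[rep(seq_len(nb), k + 1), , drop = FALSE]
      for (step in seq_len(k)) {
        cols <- p[seq_len(step)]
        rows <- (step * nb + 1):((step + 1) * nb)
        hyb[rows, cols] <- matrix(x[cols], nb, step, byrow = TRUE)
      }
      v <- colMeans(matrix(predfun(hyb), nrow = nb))
      phi[s, p] <- phi[s, p] + diff(v)
    }
  }
  phi / n_perm
}
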