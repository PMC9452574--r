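#' Main-effects eta-squared variance decomposition
#'
#' For each feature of a balanced full-factorial table, apportions the
#' total sum of squares into main-effect shares: `SS_f = sum over levels
#' of n_level * (level mean - grand mean)^2`, `eta2_f = SS_f / SS_total`.
#' The remainder `1 - sum(eta2_f)` lumps factor interactions and
#' residual variation into a single `error` term, so the shares of every
#' feature sum to one and contributions to feature variance can be
#' apportioned directly. Balance across the listed factors is a
#' precondition: with a fully balanced design all classical ANOVA
#' sum-of-squares types coincide and the main-effect shares are
#' unambiguous.
#'
#' @param table Long feature table with columns `feature`, `value` and
#'   the factor columns.
#' @param factors Character vector of factor column names.
#' @return Data frame of class `eta_decomposition`: one row per feature,
#'   one column per factor plus `error` and `degenerate` (constant
#'   feature column; its shares are all zero).
#' @examples
#' t <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2"))
#' t$feature <- "f"; t$value <- c(0, 4, 2, 6)
#' eta_squared_main_effects(t, c("A", "B"))  # A 0.8, B 0.2, error 0
#' @export
eta_squared_main_effects <- function(table, factors) {
  stopifnot(all(c("feature", "value") %in% names(table)),
            all(factors %in% names(table)))
  check_balanced(table, factors)
  feats <- unique(table$feature)
  out <- matrix(0, length(feats), length(factors) + 1,
                dimnames = list(feats, c(factors, "error")))
  degen <- logical(length(feats))
  idx <- split(seq_len(nrow(table)), table$feature)
  for (k in seq_along(feats)) {
    rows <- idx[[feats[k]]]
    y <- table$value[rows]
    ss_tot <- sum((y - mean(y))^2)
    if (ss_tot == 0 || !all(is.finite(y))) {
      degen[k] <- TRUE
      next
    }
    shares <- vapply(factors, function(f) {
      g <- table[[f]][rows]
      means <- tapply(y, g, mean)
      n_lev <- tapply(y, g, length)
      sum(n_lev * (means - mean(y))^2) / ss_tot
    }, numeric(1))
    out[k, factors] <- shares
    out[k, "error"] <- 1 - sum(shares)
  }
  res <- data.frame(feature = feats, out, row.names = NULL,
                    check.names = FALSE, stringsAsFactors = FALSE)
  res$degenerate <- degen
  class(res) <- c("eta_decomposition", "data.frame")
  res
}

check_balanced <- function(table, factors) {
  if (length(factors) < 1L) stop("need at least one factor")
  f1 <- unique(table$feature)[1]
  sub <- table[table$feature == f1, , drop = FALSE]
  cells <- base::table(do.call(interaction, c(sub[factors], drop = FALSE)))
  cells <- cells[cells > 0]
  full <- prod(vapply(sub[factors],
                      function(x) length(unique(x)), numeric(1)))
  if (length(cells) != full || length(unique(as.integer(cells))) != 1L) {
    bad <- names(cells)[cells != cells[1]]
    stop("design is not balanced over ", paste(factors, collapse = ", "),
         if (length(bad)) paste0("; offending cells: ",
                                 paste(utils::head(bad, 5),
                                       collapse = ", ")))
  }
  invisible(TRUE)
}

#' Decompose after standardising one factor to a fixed level
#'
#' Subsets the table to a single level of `fixed_factor` and reruns the
#' main-effects decomposition over the remaining factors; the fixed
#' factor contributes zero variance by construction. Used to ask what
#' dominates once, say, the grey-level setting or the reconstruction is
#' held fixed.
#'
#' @inheritParams eta_squared_main_effects
#' @param fixed_factor Factor column name to hold fixed.
#' @param level The level to keep.
#' @return An `eta_decomposition` over the remaining factors.
#' @export
standardise_and_decompose <- function(table, factors, fixed_factor, level) {
  if (!fixed_factor %in% names(table))
    stop("unknown factor: ", fixed_factor)
  sub <- table[table[[fixed_factor]] == level, , drop = FALSE]
  if (nrow(sub) == 0) stop("level ", level, " not present in ", fixed_factor)
  eta_squared_main_effects(sub, setdiff(factors, fixed_factor))
}

#' K-fold robustness of the eta-squared shares
#'
#' Re-runs the decomposition on `k` seeded random specimen subsets, each
#' balanced by removing `removal_rule[model]` specimens per tumour
#' model, and reports per feature x factor the mean share, the sample
#' (n-1) standard deviation and the coefficient of variation
#' `CoV = sd / mean`. The CoV is flagged not-applicable when the mean
#' share is below `1e-6` (a factor with practically no effect).
#'
#' @inheritParams eta_squared_main_effects
#' @param k Number of folds.
#' @param removal_rule Named integer vector: specimens to remove per
#'   tumour model in every fold.
#' @param seed Master seed; per-fold removals draw derived seeds.
#' @return Data frame with `feature`, `factor`, `mean_eta2`, `sd_eta2`,
#'   `cov`, `cov_defined`, plus attributes `k` and `fold_decompositions`.
#' @export
kfold_cov <- function(table, factors, k = 5L,
                      removal_rule = c(basal = 2L, luminal = 2L),
                      seed = 1L) {
  spec_model <- unique(table[, c("specimen_id", "tumour_model")])
  folds <- vector("list", k)
  fold_specs <- vector("list", k)
  for (fd in seq_len(k)) {
    drop <- unlist(lapply(names(removal_rule), function(m) {
      pool <- spec_model$specimen_id[spec_model$tumour_model == m]
      if (length(pool) < removal_rule[[m]])
        stop("removal rule exceeds available ", m, " specimens")
      with_seed(derive_seed(seed, "fold", fd, m),
                sample(pool, removal_rule[[m]]))
    }))
    sub <- table[!table$specimen_id %in% drop, , drop = FALSE]
    counts <- base::table(unique(sub[, c("specimen_id",
                                         "tumour_model")])$tumour_model)
    if (length(unique(as.integer(counts))) != 1L)
      stop("removal rule yields an unbalanced fold")
    fold_specs[[fd]] <- counts
    folds[[fd]] <- eta_squared_main_effects(sub, factors)
  }
  feats <- folds[[1]]$feature
  cols <- setdiff(names(folds[[1]]), c("feature", "degenerate"))
  rows <- expand.grid(feature = feats, factor = cols,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  stats <- t(apply(rows, 1, function(r) {
    v <- vapply(folds, function(d)
      d[[r[["factor"]]]][d$feature == r[["feature"]]], numeric(1))
    c(mean(v), sd(v))
  }))
  out <- data.frame(rows, mean_eta2 = stats[, 1], sd_eta2 = stats[, 2],
                    stringsAsFactors = FALSE)
  out$cov_defined <- out$mean_eta2 >= 1e-6
  out$cov <- ifelse(out$cov_defined, out$sd_eta2 / out$mean_eta2, NA_real_)
  attr(out, "k") <- k
  attr(out, "fold_decompositions") <- folds
  attr(out, "fold_specimen_counts") <- fold_specs
  out
}

#' Features robustly sensitive to the tumour model
#'
#' Returns the features whose eta-squared share for the tumour-model
#' factor exceeds `threshold`, i.e. features dominated by true
#' between-model variation rather than by acquisition or reconstruction
#' confounders, sorted by decreasing share.
#'
#' @param decomp An `eta_decomposition`.
#' @param factor Name of the tumour-model factor column.
#' @param threshold Minimum share (default 0.8).
#' @return Character vector of feature names.
#' @export
classify_robust_features <- function(decomp, factor = "tumour_model",
                                     threshold = 0.8) {
  sel <- decomp[[factor]] > threshold & !decomp$degenerate
  decomp$feature[sel][order(decomp[[factor]][sel], decreasing = TRUE)]
}
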