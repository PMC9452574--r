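#' Neighbouring grey-tone difference matrix features
#'
#' For grey level `i`, `s_i` accumulates, over the `n_i` in-VOI voxels of
#' that level (with at least one in-VOI 26-neighbour), the absolute
#' difference between `i` and the mean level of the voxel's in-VOI
#' neighbours; `p_i = n_i / Nvp`. `Coarseness` is capped at 1e6 when its
#' denominator vanishes (fully flat VOI); `Busyness` and `Strength`
#' return 0 when their denominators vanish.
#'
#' @param q A `quantised_voi`.
#' @return Named numeric vector of the 5 `ngtdm_*` features.
#' @export
ngtdm_features <- function(q) {
  acc <- cpp_ngtdm_counts(as.integer(q$levels), dim(q$levels), q$ng)
  out <- ngtdm_features_from_counts(acc$n, acc$s)
  names(out) <- paste0("ngtdm_", names(out))
  attr(out, "degenerate") <- voi_n_levels(q) < 2L
  out
}

#' @rdname ngtdm_features
#' @param n Integer vector of per-level voxel counts.
#' @param s Numeric vector of per-level summed grey-tone differences.
#' @export
ngtdm_features_from_counts <- function(n, s) {
  nvp <- sum(n)
  p <- n / nvp
  lev <- seq_along(n)
  act <- p > 0
  ngp <- sum(act)
  i <- lev[act]; pi <- p[act]; si <- s[act]

  coarse_den <- sum(pi * si)
  coarseness <- if (coarse_den > 0) min(1 / coarse_den, 1e6) else 1e6

  contrast <- if (ngp > 1) {
    sum(outer(pi, pi) * outer(i, i, "-")^2) / (ngp * (ngp - 1)) *
      sum(si) / nvp
  } else 0

  # double sum over ordered level pairs; diagonal terms are zero
  busy_den <- sum(abs(outer(i * pi, i * pi, "-")))
  busyness <- if (busy_den > 0) sum(pi * si) / busy_den else 0

  complexity <- {
    num <- outer(pi * si, pi * si, "+") * abs(outer(i, i, "-")) /
      outer(pi, pi, "+")
    sum(num) / nvp
  }

  strength_den <- sum(si)
  strength <- if (strength_den > 0)
    sum(outer(pi, pi, "+") * outer(i, i, "-")^2) / strength_den else 0

  c(Busyness = busyness, Coarseness = coarseness, Complexity = complexity,
    Contrast = contrast, Strength = strength)
}
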