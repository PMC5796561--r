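# Group-wise differential phageome statistics and richness estimation:
# Mann-Whitney rank-sum tests with BH FDR, core/prevalence selection,
# incidence-based Chao2 richness, and rarefaction.

#' Mann-Whitney rank-sum test
#'
#' U is computed from midrank-tied pooled ranks.  For small samples
#' (`length(x) + length(y) <= 12`) the two-sided p-value is obtained by
#' exact enumeration of all group assignments of the observed pooled values
#' (ties included); for larger samples the normal approximation with tie
#' correction and continuity correction is used.  When every value is
#' identical across both groups, p = 1.
#'
#' @param x,y numeric vectors (each non-empty).
#' @return list: `U` (statistic for the first group) and `p` (two-sided).
#' @export
mann_whitney <- function(x, y) {
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  n <- length(x); m <- length(y)
  pool <- c(x, y)
  if (length(unique(pool)) == 1L)
    return(list(U = n * m / 2, p = 1))
  rk <- rank(pool)
  U <- sum(rk[seq_len(n)]) - n * (n + 1) / 2
  if (n + m <= 12L) {
    dev <- abs(U - n * m / 2)
    combs <- utils::combn(n + m, n)
    Us <- apply(combs, 2L, function(ix)
      sum(rk[ix]) - n * (n + 1) / 2)
    p <- mean(abs(Us - n * m / 2) >= dev - 1e-12)
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
    if (is.na(p)) p <- 1
  }
  list(U = U, p = p)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment, mapped back to input order.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of q-values.
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Select core or highly prevalent features
#'
#' Detection counts (value > 0 per sample) must strictly exceed the
#' threshold.  By default the threshold is `floor(frac * N)` with
#' `frac = 2/3` for the core mode and `frac = 0.7` for the prevalent mode
#' (for a 145-sample cohort the core mode gives n > 96).  Studies sometimes
#' state a literal sample count instead; pass it via `min_count`.
#'
#' @param mat samples x features matrix.
#' @param mode `"core_2of3"` or `"prevalent_70pct"`.
#' @param min_count optional explicit strict threshold overriding the
#'   mode-derived one.
#' @return character vector of feature (column) names kept.
#' @export
core_selection <- function(mat, mode = c("core_2of3", "prevalent_70pct"),
                           min_count = NULL) {
  mode <- match.arg(mode)
  N <- nrow(mat)
  thr <- min_count %||%
    floor(N * if (mode == "core_2of3") 2 / 3 else 0.7)
  det <- colSums(mat > 0, na.rm = TRUE)
  colnames(mat)[det > thr]
}

#' Differential phageome analysis between two groups
#'
#' Per-feature Mann-Whitney rank-sum tests on relative numbers with
#' Benjamini-Hochberg correction (within the supplied feature level);
#' features are flagged significant at p < `p_threshold` and
#' q < `q_threshold`.  Direction is determined from the case-vs-control
#' median difference (mean difference when medians tie).
#'
#' @param abundance samples x features matrix.
#' @param groups named character vector: sample -> `"control"`/`"case"`.
#' @param level label recorded for the tested features (e.g. `"pOTU"`,
#'   `"family"`).
#' @param p_threshold,q_threshold significance cutoffs (defaults 0.05 and
#'   0.25).
#' @return data.frame of class `diff_result`: feature_id, level, p, q,
#'   direction, prevalence, significant.
#' @export
differential_phageome <- function(abundance, groups, level = "pOTU",
                                  p_threshold = 0.05, q_threshold = 0.25) {
  samples <- rownames(abundance)
  stopifnot(!is.null(samples), all(samples %in% names(groups)))
  grp <- groups[samples]
  if (!all(c("control", "case") %in% grp))
    stopf("both groups must be present")
  res <- lapply(colnames(abundance), function(f) {
    v <- abundance[, f]
    ok <- !is.na(v)
    xc <- v[ok & grp == "case"]; x0 <- v[ok & grp == "control"]
    mw <- mann_whitney(xc, x0)
    dmed <- stats::median(xc) - stats::median(x0)
    if (dmed == 0) dmed <- mean(xc) - mean(x0)
    data.frame(feature_id = f, level = level, p = mw$p,
               direction = if (dmed >= 0) "up_in_case" else "up_in_control",
               prevalence = sum(v > 0, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- bh_fdr(out$p)
  out$significant <- out$p < p_threshold & out$q < q_threshold
  out <- out[c("feature_id", "level", "p", "q", "direction", "prevalence",
               "significant")]
  class(out) <- c("diff_result", class(out))
  out
}

#' Per-sample phage-load test
#'
#' Tests the per-sample normalized phage read fraction (all reads on
#' identified phage scaffolds over all sample reads) between the two groups.
#'
#' @param load named vector of per-sample phage loads.
#' @param groups named character vector: sample -> group.
#' @return list: `U`, `p`, `direction`.
#' @export
phage_load_test <- function(load, groups) {
  grp <- groups[names(load)]
  xc <- load[grp == "case"]; x0 <- load[grp == "control"]
  mw <- mann_whitney(xc, x0)
  c(mw, list(direction = if (stats::median(xc) >= stats::median(x0))
    "up_in_case" else "up_in_control"))
}

#' Chao2 incidence-based richness estimate
#'
#' `S = S_obs + ((m-1)/m) * Q1^2 / (2 Q2)` with Q1 and Q2 the numbers of
#' features observed in exactly one and exactly two samples and m the number
#' of samples; when Q2 = 0 the bias-corrected form
#' `S_obs + ((m-1)/m) * Q1 (Q1 - 1) / 2` is used.
#'
#' @param incidence samples x features matrix (presence = value > 0).
#' @return list: `estimate`, `S_obs`, `Q1`, `Q2`, `m`.
#' @export
chao2 <- function(incidence) {
  pres <- incidence > 0
  m <- nrow(pres)
  det <- colSums(pres)
  S_obs <- sum(det > 0)
  Q1 <- sum(det == 1L); Q2 <- sum(det == 2L)
  est <- if (Q2 > 0) S_obs + ((m - 1) / m) * Q1^2 / (2 * Q2)
         else S_obs + ((m - 1) / m) * Q1 * (Q1 - 1) / 2
  list(estimate = est, S_obs = S_obs, Q1 = Q1, Q2 = Q2, m = m)
}

#' Sample-based rarefaction curve
#'
#' Expected number of distinct features in a random k-sample subset, for
#' k = 1..m.  `method = "exact"` evaluates the hypergeometric closed form
#' (the exact mean over all subsets); `method = "permute"` averages over
#' `n_permutations` random sample orderings.
#'
#' @param incidence samples x features matrix (presence = value > 0).
#' @param method `"exact"` (default) or `"permute"`.
#' @param n_permutations permutations for the permutation method.
#' @param seed RNG seed for the permutation method.
#' @return data.frame: k, richness (monotone non-decreasing in k).
#' @export
rarefaction <- function(incidence, method = c("exact", "permute"),
                        n_permutations = 100L, seed = NULL) {
  method <- match.arg(method)
  pres <- incidence > 0
  m <- nrow(pres)
  det <- colSums(pres)
  det <- det[det > 0]
  if (method == "exact") {
    rich <- vapply(seq_len(m), function(k)
      sum(1 - exp(lchoose(m - det, k) - lchoose(m, k))), 0)
  } else {
    stopifnot(n_permutations >= 1L)
    rich <- with_seed(seed, {
      acc <- numeric(m)
      for (b in seq_len(n_permutations)) {
        ord <- sample.int(m)
        seen <- apply(pres[ord, , drop = FALSE], 2L, cummax)
        acc <- acc + rowSums(seen > 0)
      }
      acc / n_permutations
    })
  }
  data.frame(k = seq_len(m), richness = rich)
}
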