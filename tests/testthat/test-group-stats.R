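# Rank-sum testing, BH correction, core/prevalence selection, Chao2, and
# rarefaction -- each against an independent oracle or closed form.

# Independent enumeration oracle: own midranks, full C(n+m, n) enumeration.
mw_oracle <- function(x, y) {
  pool <- c(x, y)
  n <- length(x); m <- length(y)
  midrank <- function(v) {
    o <- order(v); r <- numeric(length(v))
    i <- 1L
    while (i <= length(v)) {
      j <- i
      while (j < length(v) && v[o[j + 1L]] == v[o[i]]) j <- j + 1L
      r[o[i:j]] <- mean(i:j)
      i <- j + 1L
    }
    r
  }
  rk <- midrank(pool)
  U_obs <- sum(rk[seq_len(n)]) - n * (n + 1) / 2
  dev <- abs(U_obs - n * m / 2)
  combs <- utils::combn(n + m, n)
  Us <- apply(combs, 2L, function(ix) sum(rk[ix]) - n * (n + 1) / 2)
  list(U = U_obs, p = mean(abs(Us - n * m / 2) >= dev - 1e-12))
}

test_that("rank-sum test reproduces the fully separated worked example", {
  got <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(got$U, 0)
  expect_equal(got$p, 0.1)     # 2 of the 20 arrangements are as extreme
})

test_that("identical samples give p = 1 and swapping is symmetric", {
  expect_equal(mann_whitney(c(1, 2, 2), c(2, 1, 2))$p, 1)
  expect_equal(mann_whitney(c(3, 3, 3), c(3, 3))$p, 1)
  set.seed(61)
  x <- rnorm(5); y <- rnorm(4)
  expect_equal(mann_whitney(x, y)$p, mann_whitney(y, x)$p)
  expect_equal(mann_whitney(x, y)$U, length(x) * length(y) -
                 mann_whitney(y, x)$U)
})

test_that("exact p equals full enumeration for all group sizes <= 6", {
  set.seed(62)
  for (n in 1:6) for (m in n:6) {
    for (rep in 1:3) {
      x <- sample(0:4, n, replace = TRUE)   # discrete values force ties
      y <- sample(0:4, m, replace = TRUE)
      got <- mann_whitney(x, y)
      want <- mw_oracle(x, y)
      expect_equal(got$U, want$U, tolerance = 1e-12)
      expect_equal(got$p, want$p, tolerance = 1e-12)
    }
  }
  # and agrees with the distribution-based exact test when there are no ties
  x <- c(1.2, 3.4, 0.7, 5.1); y <- c(2.2, 6.3, 4.4)
  expect_equal(mann_whitney(x, y)$p,
               stats::wilcox.test(x, y, exact = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("BH q-values match the hand example and the step-up oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  bh_oracle <- function(p) {
    mlen <- length(p)
    o <- order(p)
    q_sorted <- rev(cummin(rev(mlen * p[o] / seq_len(mlen))))
    q <- numeric(mlen); q[o] <- pmin(q_sorted, 1); q
  }
  set.seed(63)
  for (rep in 1:500) {
    p <- runif(sample(1:40, 1))
    q <- bh_fdr(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-12))
    expect_equal(order(q[order(p)]), seq_along(p)) # order-preserving
  }
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("core and prevalence selection use strict detection thresholds", {
  mk <- function(counts, N = 145L) {
    m <- matrix(0, N, length(counts),
                dimnames = list(NULL, sprintf("f%d", seq_along(counts))))
    for (j in seq_along(counts)) m[seq_len(counts[j]), j] <- 1
    m
  }
  m <- mk(c(97, 96, 145, 121, 120, 102, 101))
  core <- core_selection(m, "core_2of3")            # > 96 of 145
  expect_true(all(c("f1", "f3", "f4") %in% core))
  expect_false("f2" %in% core)
  prev_lit <- core_selection(m, "prevalent_70pct", min_count = 120L)
  expect_true(all(c("f3", "f4") %in% prev_lit))     # literal "> 120"
  expect_false("f5" %in% prev_lit)
  prev <- core_selection(m, "prevalent_70pct")      # > floor(0.7 * 145) = 101
  expect_true(all(c("f6", "f3") %in% prev))
  expect_false("f7" %in% prev)
  # a feature present everywhere is kept under every mode
  expect_true(all(vapply(list(core, prev, prev_lit),
                         function(s) "f3" %in% s, TRUE)))
})

test_that("differential testing flags direction and rejects empty groups", {
  set.seed(64)
  ab <- cbind(up = c(rnorm(10, 10), rnorm(10, 2)),
              null = rnorm(20, 5))
  rownames(ab) <- sprintf("s%d", 1:20)
  groups <- stats::setNames(rep(c("case", "control"), each = 10),
                            rownames(ab))
  res <- differential_phageome(ab, groups)
  expect_s3_class(res, "diff_result")
  expect_equal(res$direction[res$feature_id == "up"], "up_in_case")
  expect_true(res$significant[res$feature_id == "up"])
  expect_true(all(res$q >= res$p - 1e-12))
  expect_error(differential_phageome(ab, stats::setNames(rep("case", 20),
                                                         rownames(ab))),
               "both groups")
})

test_that("null data yields a calibrated 5% rejection rate", {
  set.seed(65)
  p <- vapply(1:1000, function(i)
    mann_whitney(rnorm(20), rnorm(20))$p, 0)
  frac <- mean(p < 0.05)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
})

test_that("Chao2 follows the closed form, including the Q2 = 0 branch", {
  # S_obs 50, Q1 10, Q2 5, m 30 -> 50 + (29/30) * 100 / 10
  mk_inc <- function(det, m) {
    mat <- matrix(0, m, length(det))
    for (j in seq_along(det)) mat[seq_len(det[j]), j] <- 1
    mat
  }
  det <- c(rep(1, 10), rep(2, 5), rep(3, 35))
  got <- chao2(mk_inc(det, 30))
  expect_equal(got$S_obs, 50L)
  expect_equal(got$estimate, 50 + (29 / 30) * 100 / 10, tolerance = 1e-12)
  # Q1 = 0 -> S = S_obs
  got2 <- chao2(mk_inc(rep(3, 20), 10))
  expect_equal(got2$estimate, 20)
  # Q2 = 0 -> bias-corrected form
  got3 <- chao2(mk_inc(c(rep(1, 4), rep(5, 6)), 10))
  expect_equal(got3$estimate, 10 + (9 / 10) * 4 * 3 / 2, tolerance = 1e-12)
  # never below the observed richness
  set.seed(66)
  for (i in 1:20) {
    inc <- matrix(rbinom(200, 1, 0.2), 10, 20)
    ch <- chao2(inc)
    expect_gte(ch$estimate, ch$S_obs)
  }
})

test_that("Chao2 agrees with vegan's incidence estimator when Q2 > 0", {
  skip_if_not_installed("vegan")
  set.seed(67)
  inc <- matrix(rbinom(40 * 60, 1, 0.12), 40, 60)
  got <- chao2(inc)
  skip_if(got$Q2 == 0L)
  sp <- vegan::specpool(inc)
  expect_equal(got$estimate, sp$chao, tolerance = 1e-9)
})

test_that("rarefaction matches exhaustive subset enumeration at m = 5", {
  set.seed(68)
  inc <- matrix(rbinom(5 * 12, 1, 0.4), 5, 12)
  got <- rarefaction(inc)      # exact hypergeometric form
  for (k in 1:5) {
    subsets <- utils::combn(5, k)
    rich <- apply(subsets, 2L, function(s)
      sum(colSums(inc[s, , drop = FALSE]) > 0))
    expect_equal(got$richness[k], mean(rich), tolerance = 1e-12)
  }
  expect_equal(got$richness[5], sum(colSums(inc) > 0))
  expect_true(all(diff(got$richness) >= -1e-12))
  # single ubiquitous feature: curve constant at 1
  one <- matrix(1, 4, 1)
  expect_equal(rarefaction(one)$richness, rep(1, 4))
  # permutation method approximates the exact curve
  perm <- rarefaction(inc, method = "permute", n_permutations = 2000,
                      seed = 3)
  expect_equal(perm$richness, got$richness, tolerance = 0.05)
})
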