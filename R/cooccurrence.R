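# Compositional co-occurrence/exclusion network between bacterial genera and
# pOTUs: log-ratio-variance basis correlations (SparCC-style) with
# permutation p-values and the published edge filters.

#' Prevalence filter for co-occurrence analysis
#'
#' Keeps the columns (taxa) detected (value > 0) in strictly more than
#' `min_samples` samples.
#'
#' @param mat samples x taxa matrix of non-negative counts/abundances.
#' @param min_samples strict detection threshold (default 72, i.e. half of a
#'   145-sample cohort).
#' @return the reduced matrix (possibly zero columns, with a warning).
#' @export
prevalence_filter <- function(mat, min_samples = 72L) {
  det <- colSums(mat > 0, na.rm = TRUE)
  keep <- det > min_samples
  if (!any(keep))
    warning("prevalence filter removed every column", call. = FALSE)
  mat[, keep, drop = FALSE]
}

# Direct basis-variance solve of the log-ratio variance system.
# T[i,j] = var(log x_i/x_j); row sums satisfy
# sum_j T[i,j] = (D-2) w_i + sum_j w_j when basis covariances average out,
# i.e. M w = t with M = (D-2) I + 1 1'.
solve_basis <- function(Tmat, excl = NULL) {
  D <- ncol(Tmat)
  M <- matrix(1, D, D) + diag(D - 2, D)
  tvec <- rowSums(Tmat)
  if (!is.null(excl) && nrow(excl)) {
    for (r in seq_len(nrow(excl))) {
      i <- excl[r, 1]; j <- excl[r, 2]
      tvec[i] <- tvec[i] - Tmat[i, j]
      tvec[j] <- tvec[j] - Tmat[i, j]
      M[i, i] <- M[i, i] - 1
      M[j, j] <- M[j, j] - 1
      M[i, j] <- M[i, j] - 1
      M[j, i] <- M[j, i] - 1
    }
  }
  w <- solve(M, tvec)
  pmax(w, .Machine$double.eps)
}

basis_correlation <- function(Tmat, w) {
  D <- ncol(Tmat)
  r <- (outer(w, w, "+") - Tmat) / (2 * sqrt(outer(w, w)))
  r[r > 1] <- 1; r[r < -1] <- -1
  diag(r) <- 1
  r
}

sparcc_once <- function(frac, n_exclusion_rounds, exclusion_threshold) {
  lf <- log(frac)
  D <- ncol(lf)
  C <- stats::cov(lf)
  v <- diag(C)
  Tmat <- outer(v, v, "+") - 2 * C   # var(log xi - log xj)
  excl <- matrix(integer(0), 0, 2)
  w <- solve_basis(Tmat, excl)
  r <- basis_correlation(Tmat, w)
  rounds <- 0L
  while (rounds < n_exclusion_rounds) {
    cand <- abs(r)
    diag(cand) <- 0
    if (nrow(excl)) {
      cand[excl] <- 0
      cand[excl[, 2:1, drop = FALSE]] <- 0
    }
    mx <- which(cand == max(cand), arr.ind = TRUE)[1, , drop = TRUE]
    if (cand[mx[1], mx[2]] <= exclusion_threshold) break
    excl_new <- rbind(excl, sort(c(mx[1], mx[2])))
    # a component excluded from too many pairs leaves the system singular;
    # keep the last solvable estimate in that case
    new_w <- tryCatch(solve_basis(Tmat, excl_new), error = function(e) NULL)
    if (is.null(new_w) ||
        max(tabulate(as.vector(excl_new), nbins = D)) > D - 3L) break
    excl <- excl_new
    w <- new_w
    r <- basis_correlation(Tmat, w)
    rounds <- rounds + 1L
  }
  r
}

#' SparCC-style basis correlations for compositional count data
#'
#' Infers correlations between underlying (basis) abundances from pairwise
#' log-ratio variances, with iterative exclusion of the most strongly
#' correlated pairs from the basis-variance system.  Counts are converted to
#' fractions after adding `pseudocount` to zeros; with `n_resamples > 1`
#' fractions are drawn from a posterior Dirichlet per sample and the
#' correlation estimate is averaged over the resamplings.  With
#' `n_resamples = 1` the estimate is the deterministic point solve.
#'
#' A Spearman rank correlation on the raw values is available as a fallback
#' engine behind the same interface.
#'
#' @param counts samples x taxa matrix (>= 4 taxa for the basis system).
#' @param pseudocount added to zero counts (default 0.5).
#' @param n_resamples Dirichlet resamplings to average over (default 20).
#' @param n_exclusion_rounds maximum strongly-correlated pair exclusions
#'   (default 10).
#' @param exclusion_threshold correlation magnitude above which a pair is
#'   excluded from the basis solve (default 0.1).
#' @param seed RNG seed for the resampling.
#' @param engine `"sparcc"` (default) or `"spearman"`.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
sparcc_corr <- function(counts, pseudocount = 0.5, n_resamples = 20L,
                        n_exclusion_rounds = 10L, exclusion_threshold = 0.1,
                        seed = NULL, engine = c("sparcc", "spearman")) {
  engine <- match.arg(engine)
  counts <- as.matrix(counts)
  if (engine == "spearman") {
    r <- stats::cor(counts, method = "spearman")
    diag(r) <- 1
    return(r)
  }
  D <- ncol(counts)
  if (D < 4L)
    stopf("SparCC-style estimation needs >= 4 taxa; use engine = \"spearman\" for smaller sets")
  x <- counts
  x[x == 0] <- pseudocount
  if (n_resamples <= 1L) {
    frac <- x / rowSums(x)
    return(sparcc_once(frac, n_exclusion_rounds, exclusion_threshold))
  }
  with_seed(seed, {
    acc <- matrix(0, D, D)
    for (b in seq_len(n_resamples)) {
      g <- matrix(stats::rgamma(length(x), shape = x, rate = 1), nrow(x))
      frac <- g / rowSums(g)
      acc <- acc + sparcc_once(frac, n_exclusion_rounds, exclusion_threshold)
    }
    r <- acc / n_resamples
    dimnames(r) <- list(colnames(counts), colnames(counts))
    diag(r) <- 1
    r
  })
}

#' Permutation p-values for pairwise correlations
#'
#' Columns are permuted independently in each round and the correlation is
#' recomputed with the same engine (point solve, no resampling, for speed);
#' the two-sided p-value for a pair is
#' `(1 + #(|r_perm| >= |r_obs|)) / (1 + n_perm)`.
#'
#' @param counts samples x taxa matrix.
#' @param r_obs observed correlation matrix ([sparcc_corr()]).
#' @param n_perm number of permutations (>= 100).
#' @param seed RNG seed.
#' @param engine,pseudocount,n_exclusion_rounds,exclusion_threshold
#'   engine parameters, as in [sparcc_corr()].
#' @return matrix of p-values (diagonal NA).
#' @export
permutation_p <- function(counts, r_obs, n_perm = 100L, seed = NULL,
                          engine = c("sparcc", "spearman"),
                          pseudocount = 0.5, n_exclusion_rounds = 10L,
                          exclusion_threshold = 0.1) {
  engine <- match.arg(engine)
  if (n_perm < 100L) stopf("n_perm must be >= 100")
  counts <- as.matrix(counts)
  D <- ncol(counts)
  with_seed(seed, {
    exceed <- matrix(0L, D, D)
    for (b in seq_len(n_perm)) {
      perm <- apply(counts, 2L, sample)
      rp <- sparcc_corr(perm, pseudocount = pseudocount, n_resamples = 1L,
                        n_exclusion_rounds = n_exclusion_rounds,
                        exclusion_threshold = exclusion_threshold,
                        engine = engine)
      exceed <- exceed + (abs(rp) >= abs(r_obs))
    }
    p <- (1 + exceed) / (1 + n_perm)
    diag(p) <- NA_real_
    dimnames(p) <- dimnames(r_obs)
    p
  })
}

#' Build the co-occurrence/exclusion network from correlation and p matrices
#'
#' Keeps edges with `|r| > r_threshold` (strict) and `p < p_threshold`
#' (strict); unconnected nodes are dropped from the node list.  Positive
#' correlations are co-occurrence edges, negative ones exclusion edges.
#'
#' @param corr correlation matrix.
#' @param p p-value matrix.
#' @param r_threshold strict correlation-magnitude threshold (default 0.3).
#' @param p_threshold strict p-value threshold (default 0.01).
#' @param node_types optional named character vector (`"bacterium"` /
#'   `"pOTU"`).
#' @return list of class `coocc_network`: `edges` (node_a, node_b, r, p,
#'   sign) and `nodes` (id, type).
#' @export
build_coocc_network <- function(corr, p, r_threshold = 0.3,
                                p_threshold = 0.01, node_types = NULL) {
  stopifnot(identical(dim(corr), dim(p)))
  ids <- colnames(corr) %||% sprintf("t%d", seq_len(ncol(corr)))
  edges <- list()
  D <- ncol(corr)
  for (i in seq_len(D - 1L)) for (j in (i + 1L):D) {
    if (is.na(p[i, j])) next
    if (abs(corr[i, j]) > r_threshold && p[i, j] < p_threshold)
      edges[[length(edges) + 1L]] <- data.frame(
        node_a = ids[i], node_b = ids[j], r = corr[i, j], p = p[i, j],
        sign = if (corr[i, j] > 0) "co-occurrence" else "exclusion",
        stringsAsFactors = FALSE)
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(node_a = character(0), node_b = character(0), r = numeric(0),
               p = numeric(0), sign = character(0))
  used <- unique(c(edges$node_a, edges$node_b))
  nodes <- data.frame(id = used,
                      type = if (is.null(node_types))
                               rep(NA_character_, length(used))
                             else unname(node_types[used]),
                      stringsAsFactors = FALSE)
  structure(list(edges = edges, nodes = nodes), class = "coocc_network")
}

#' @export
print.coocc_network <- function(x, ...) {
  cat(sprintf("Co-occurrence network: %d nodes, %d edges (%d co-occurrence, %d exclusion)\n",
              nrow(x$nodes), nrow(x$edges),
              sum(x$edges$sign == "co-occurrence"),
              sum(x$edges$sign == "exclusion")))
  invisible(x)
}
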