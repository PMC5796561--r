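# CRISPR array detection (repeat-seed heuristic), spacer extraction, and
# spacer-to-protospacer matching against candidate phage scaffolds.

#' Detect CRISPR arrays on a scaffold
#'
#' Seeds with exact k-mers that recur at regular spacing, merges co-anchored
#' seeds into repeat intervals, and validates repeat length, spacer length,
#' minimum repeat count and pairwise repeat identity.  Spacers are the
#' inter-repeat intervals.  Arrays whose repeats contain N are discarded.
#' Detection is a text-level heuristic and therefore finds arrays
#' irrespective of strand (a reverse-complemented scaffold yields the same
#' arrays with mirrored coordinates).
#'
#' @param scaffold single DNA sequence (character, optionally named).
#' @param scaffold_id id recorded in the output.
#' @param repeat_len_range allowed repeat lengths, bp (default 21--48).
#' @param spacer_len_range allowed spacer lengths, bp (default 18--50).
#' @param min_repeats minimum repeats per array (default 3).
#' @param min_repeat_identity minimum pairwise repeat identity (default 0.9).
#' @param k seed k-mer length (default 13).
#' @return list with data.frames `arrays` (array_id, scaffold_id, start, end,
#'   n_repeats, repeat_consensus), `repeats` (array_id, start, end) and
#'   `spacers` (array_id, spacer_id, spacer_index, start, end, seq);
#'   coordinates 0-based half-open.
#' @export
detect_arrays <- function(scaffold, scaffold_id = NULL,
                          repeat_len_range = c(21L, 48L),
                          spacer_len_range = c(18L, 50L),
                          min_repeats = 3L, min_repeat_identity = 0.9,
                          k = 13L) {
  scaffold_id <- scaffold_id %||% names(scaffold) %||% "scaffold"
  seq <- toupper(unname(scaffold))
  L <- nchar(seq)
  empty <- list(
    arrays = data.frame(array_id = character(0), scaffold_id = character(0),
                        start = integer(0), end = integer(0),
                        n_repeats = integer(0),
                        repeat_consensus = character(0)),
    repeats = data.frame(array_id = character(0), start = integer(0),
                         end = integer(0)),
    spacers = data.frame(array_id = character(0), scaffold_id = character(0),
                         spacer_id = character(0),
                         spacer_index = integer(0), start = integer(0),
                         end = integer(0), seq = character(0)))
  if (L < 2L * repeat_len_range[1] + spacer_len_range[1]) return(empty)

  period_min <- repeat_len_range[1] + spacer_len_range[1]
  period_max <- repeat_len_range[2] + spacer_len_range[2]

  n_k <- L - k + 1L
  kmers <- substring(seq, 1:n_k, (1:n_k) + k - 1L)
  dup <- table(kmers)
  dup <- names(dup[dup >= min_repeats])
  if (!length(dup)) return(empty)
  pos_by_kmer <- split(seq_len(n_k) - 1L, kmers)[dup]   # 0-based positions

  # maximal runs with inter-occurrence gaps inside the array period
  runs <- list()
  for (km in names(pos_by_kmer)) {
    ps <- sort(pos_by_kmer[[km]])
    gap_ok <- diff(ps) >= period_min & diff(ps) <= period_max
    r <- rle(gap_ok)
    idx_end <- cumsum(r$lengths)
    idx_start <- idx_end - r$lengths + 1L
    for (j in which(r$values & r$lengths >= min_repeats - 1L))
      runs[[length(runs) + 1L]] <- ps[idx_start[j]:(idx_end[j] + 1L)]
  }
  if (!length(runs)) return(empty)

  # cluster runs that anchor the same array: identical gap structure and
  # first positions within one repeat length
  ord <- order(vapply(runs, `[[`, 1L, 1L))
  runs <- runs[ord]
  clusters <- list()
  for (run in runs) {
    placed <- FALSE
    for (ci in seq_along(clusters)) {
      ref <- clusters[[ci]][[1]]
      if (length(run) == length(ref) &&
          abs(run[1] - ref[1]) <= repeat_len_range[2] - k &&
          all(diff(run) == diff(ref))) {
        clusters[[ci]] <- c(clusters[[ci]], list(run))
        placed <- TRUE
        break
      }
    }
    if (!placed) clusters[[length(clusters) + 1L]] <- list(run)
  }

  cand <- list()
  for (cl in clusters) {
    mat <- do.call(rbind, cl)           # runs x instances, 0-based starts
    rep_start <- apply(mat, 2L, min)
    rep_end <- apply(mat, 2L, max) + k
    rl <- rep_end - rep_start
    if (length(unique(rl)) != 1L) next
    if (rl[1] < repeat_len_range[1] || rl[1] > repeat_len_range[2]) next
    sp_len <- rep_start[-1L] - rep_end[-length(rep_end)]
    if (any(sp_len < spacer_len_range[1] | sp_len > spacer_len_range[2])) next
    reps <- substring(seq, rep_start + 1L, rep_end)
    if (any(grepl("N", reps, fixed = TRUE))) next
    pid <- utils::combn(length(reps), 2L, function(ij)
      1 - str_mismatches(reps[ij[1]], reps[ij[2]]) / rl[1])
    if (min(pid) < min_repeat_identity) next
    cand[[length(cand) + 1L]] <- list(rep_start = rep_start,
                                      rep_end = rep_end, reps = reps)
  }
  if (!length(cand)) return(empty)

  # maximal non-overlapping arrays, preferring more repeats then longer span
  ord <- order(-vapply(cand, function(x) length(x$rep_start), 1L),
               -vapply(cand, function(x) max(x$rep_end) - min(x$rep_start), 1L))
  cand <- cand[ord]
  kept <- list()
  for (x in cand) {
    span <- c(min(x$rep_start), max(x$rep_end))
    clash <- any(vapply(kept, function(y)
      span[1] < max(y$rep_end) && min(y$rep_start) < span[2], TRUE))
    if (!clash) kept[[length(kept) + 1L]] <- x
  }
  kept <- kept[order(vapply(kept, function(x) min(x$rep_start), 1L))]

  arrays <- list(); repeats <- list(); spacers <- list()
  for (ai in seq_along(kept)) {
    x <- kept[[ai]]
    aid <- sprintf("%s_arr%d", scaffold_id, ai)
    consensus <- names(sort(table(x$reps), decreasing = TRUE))[1]
    arrays[[ai]] <- data.frame(
      array_id = aid, scaffold_id = scaffold_id,
      start = min(x$rep_start), end = max(x$rep_end),
      n_repeats = length(x$rep_start), repeat_consensus = consensus,
      stringsAsFactors = FALSE)
    repeats[[ai]] <- data.frame(array_id = aid, start = x$rep_start,
                                end = x$rep_end, stringsAsFactors = FALSE)
    ns <- length(x$rep_start) - 1L
    sp_start <- x$rep_end[-length(x$rep_end)]
    sp_end <- x$rep_start[-1L]
    spacers[[ai]] <- data.frame(
      array_id = aid, scaffold_id = scaffold_id,
      spacer_id = sprintf("%s_s%d", aid, seq_len(ns) - 1L),
      spacer_index = seq_len(ns) - 1L, start = sp_start, end = sp_end,
      seq = substring(seq, sp_start + 1L, sp_end), stringsAsFactors = FALSE)
  }
  list(arrays = do.call(rbind, arrays), repeats = do.call(rbind, repeats),
       spacers = do.call(rbind, spacers))
}

#' Detect CRISPR arrays on a scaffold set
#' @param scaffolds named character vector.
#' @param ... passed to [detect_arrays()].
#' @return combined list of `arrays`, `repeats`, `spacers` data.frames.
#' @export
detect_arrays_set <- function(scaffolds, ...) {
  res <- lapply(names(scaffolds), function(id)
    detect_arrays(scaffolds[[id]], scaffold_id = id, ...))
  list(arrays = do.call(rbind, lapply(res, `[[`, "arrays")),
       repeats = do.call(rbind, lapply(res, `[[`, "repeats")),
       spacers = do.call(rbind, lapply(res, `[[`, "spacers")))
}

#' Match CRISPR spacers against candidate (pro)phage scaffolds
#'
#' Finds every occurrence of each spacer on either strand of the target
#' scaffolds with at most `max_mismatch` substitutions.  The `same_sample`
#' flag compares the sample set of the spacer's source scaffold with the
#' target's (via `sample_membership`); it is `NA` when no membership map is
#' supplied.
#'
#' @param spacers data.frame with columns spacer_id, seq and optionally
#'   scaffold_id (the array's scaffold).
#' @param targets named character vector of target scaffolds.
#' @param max_mismatch maximum substitutions (default 1).
#' @param min_spacer_len spacers shorter than this are skipped (default 18).
#' @param sample_membership optional named list: scaffold_id -> character
#'   vector of sample ids containing it.
#' @return data.frame: spacer_id, source_scaffold_id, target_id, position
#'   (0-based), strand, mismatches, same_sample.
#' @export
match_spacers <- function(spacers, targets, max_mismatch = 1L,
                          min_spacer_len = 18L, sample_membership = NULL) {
  empty <- data.frame(spacer_id = character(0),
                      source_scaffold_id = character(0),
                      target_id = character(0), position = integer(0),
                      strand = character(0), mismatches = integer(0),
                      same_sample = logical(0))
  if (!nrow(spacers) || !length(targets)) return(empty)
  tgt <- Biostrings::DNAStringSet(targets)
  out <- list()
  for (i in seq_len(nrow(spacers))) {
    sp <- spacers$seq[i]
    if (nchar(sp) < min_spacer_len) next
    src <- if ("scaffold_id" %in% names(spacers)) spacers$scaffold_id[i]
           else NA_character_
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") sp else revcomp(sp)
      m <- Biostrings::vmatchPattern(pat, tgt, max.mismatch = max_mismatch,
                                     fixed = TRUE)
      st <- Biostrings::startIndex(m)
      for (t in which(lengths(st) > 0L)) {
        ps <- st[[t]]
        ps <- ps[ps >= 1L & ps + nchar(sp) - 1L <= nchar(targets[[t]])]
        if (!length(ps)) next
        nm <- Biostrings::neditStartingAt(Biostrings::DNAString(pat), tgt[[t]],
                                          starting.at = ps,
                                          with.indels = FALSE)
        keep <- nm <= max_mismatch
        if (!any(keep)) next
        out[[length(out) + 1L]] <- data.frame(
          spacer_id = spacers$spacer_id[i], source_scaffold_id = src,
          target_id = names(targets)[t], position = ps[keep] - 1L,
          strand = strand, mismatches = nm[keep], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res$same_sample <- NA
  if (!is.null(sample_membership)) {
    res$same_sample <- mapply(function(a, b) {
      sa <- sample_membership[[a]]; sb <- sample_membership[[b]]
      if (is.null(sa) || is.null(sb)) NA else length(intersect(sa, sb)) > 0L
    }, res$source_scaffold_id, res$target_id)
  }
  rownames(res) <- NULL
  res
}
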