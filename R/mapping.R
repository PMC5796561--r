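# Exact-seed read mapping, SAM ingestion, and breadth/depth of coverage --
# the screening statistics used throughout the pipeline.

#' Map reads to references with an exact-seed, ungapped extension mapper
#'
#' A read aligns to a reference when an exact seed (the read's first
#' `seed_len` bases, on either strand) extends to an ungapped full-length
#' placement with identity >= `min_identity`.  The best placement (fewest
#' mismatches) is reported; ties are broken by (ref_id, position)
#' lexicographic order.  With `report = "all_best"` all equally-best
#' placements are returned (used by callers that discard ambiguous reads).
#'
#' @param reads named character vector of reads.
#' @param refs named character vector of reference sequences.
#' @param seed_len exact seed length (default 21); must not exceed the
#'   shortest read.
#' @param min_identity minimum full-read identity (default 0.95).
#' @param report `"best"` (default) or `"all_best"`.
#' @return data.frame: read_id, ref_id, ref_start, ref_end (0-based,
#'   half-open), strand, mismatches, n_best (number of equally-best
#'   placements for the read).
#' @export
map_reads <- function(reads, refs, seed_len = 21L, min_identity = 0.95,
                      report = c("best", "all_best")) {
  report <- match.arg(report)
  if (!length(refs)) stopf("empty reference set")
  empty <- data.frame(read_id = character(0), ref_id = character(0),
                      ref_start = integer(0), ref_end = integer(0),
                      strand = character(0), mismatches = integer(0),
                      n_best = integer(0))
  if (!length(reads)) return(empty)
  if (is.null(names(reads))) names(reads) <- sprintf("read%d", seq_along(reads))
  rl <- nchar(reads)
  if (any(rl < seed_len))
    stopf("seed_len (%d) exceeds the shortest read (%d bp)", seed_len, min(rl))

  reads_dna <- Biostrings::DNAStringSet(reads)
  rc_dna <- Biostrings::reverseComplement(reads_dna)
  rc_chr <- as.character(rc_dna)
  pd_f <- Biostrings::PDict(Biostrings::subseq(reads_dna, 1L, seed_len))
  pd_r <- Biostrings::PDict(Biostrings::subseq(rc_dna, 1L, seed_len))
  refs_dna <- Biostrings::DNAStringSet(refs)
  ref_len <- nchar(refs)

  rows <- list()
  for (r in seq_along(refs)) {
    subj <- refs_dna[[r]]
    for (strand in c("+", "-")) {
      pd <- if (strand == "+") pd_f else pd_r
      starts <- Biostrings::startIndex(Biostrings::matchPDict(pd, subj))
      n_per <- lengths(starts)
      if (!sum(n_per)) next
      ridx <- rep.int(seq_along(starts), n_per)
      ps <- unlist(starts, use.names = FALSE)
      keep <- ps + rl[ridx] - 1L <= ref_len[r]    # full read must fit
      ridx <- ridx[keep]; ps <- ps[keep]
      if (!length(ps)) next
      qseq <- (if (strand == "+") unname(reads) else rc_chr)[ridx]
      rsub <- substring(refs[[r]], ps, ps + rl[ridx] - 1L)
      nm <- integer(length(ps))
      for (ii in which(qseq != rsub))
        nm[ii] <- sum(utf8ToInt(qseq[ii]) != utf8ToInt(rsub[ii]))
      ok <- nm <= floor((1 - min_identity) * rl[ridx])
      if (!any(ok)) next
      rows[[length(rows) + 1L]] <- data.frame(
        read_id = names(reads)[ridx[ok]], ref_id = names(refs)[r],
        ref_start = ps[ok] - 1L, ref_end = ps[ok] - 1L + rl[ridx[ok]],
        strand = strand, mismatches = nm[ok], stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  aln <- do.call(rbind, rows)
  # per read: keep minimal-mismatch placements, dedupe identical placements
  aln <- aln[order(aln$read_id, aln$mismatches, aln$ref_id, aln$ref_start,
                   aln$strand), , drop = FALSE]
  aln <- aln[!duplicated(aln[c("read_id", "ref_id", "ref_start", "strand")]), ,
             drop = FALSE]
  best_nm <- tapply(aln$mismatches, aln$read_id, min)
  aln <- aln[aln$mismatches == best_nm[aln$read_id], , drop = FALSE]
  nb <- table(aln$read_id)
  aln$n_best <- as.integer(nb[aln$read_id])
  if (report == "best")
    aln <- aln[!duplicated(aln$read_id), , drop = FALSE]
  rownames(aln) <- NULL
  aln
}

#' Ingest alignments from a SAM file
#'
#' Only primary, mapped records are used (FLAG bits 0x4, 0x100, 0x800
#' excluded).  The reference span is computed from the CIGAR string
#' (M/D/N/=/X operations).
#'
#' @param path SAM file path.
#' @return Alignment data.frame in the same layout as [map_reads()].
#' @export
read_sam <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  empty <- data.frame(read_id = character(0), ref_id = character(0),
                      ref_start = integer(0), ref_end = integer(0),
                      strand = character(0), mismatches = integer(0),
                      n_best = integer(0))
  if (!length(lines)) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 11L)
  if (length(bad)) stopf("malformed SAM record at line %d", bad[1])
  flag <- as.integer(vapply(fields, `[[`, "", 2L))
  keep <- bitwAnd(flag, 0x4L) == 0L & bitwAnd(flag, 0x100L) == 0L &
    bitwAnd(flag, 0x800L) == 0L
  fields <- fields[keep]; flag <- flag[keep]
  if (!length(fields)) return(empty)
  cigar <- vapply(fields, `[[`, "", 6L)
  ref_width <- vapply(cigar, function(cg) {
    if (cg == "*") return(NA_integer_)
    ops <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    n <- as.integer(sub("[A-Z=]", "", ops))
    op <- sub("\\d+", "", ops)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, 1L, USE.NAMES = FALSE)
  pos <- as.integer(vapply(fields, `[[`, "", 4L))
  data.frame(
    read_id = vapply(fields, `[[`, "", 1L),
    ref_id = vapply(fields, `[[`, "", 3L),
    ref_start = pos - 1L,
    ref_end = pos - 1L + ref_width,
    strand = ifelse(bitwAnd(flag, 0x10L) > 0L, "-", "+"),
    mismatches = NA_integer_, n_best = 1L, stringsAsFactors = FALSE)
}

#' Breadth and depth of coverage per reference
#'
#' Breadth is the fraction of reference positions covered by at least one
#' alignment; depth is total aligned bases divided by reference length.
#'
#' @param alignments data.frame from [map_reads()] or [read_sam()].
#' @param ref_lengths named integer vector of reference lengths.
#' @return data.frame: ref_id, n_reads, breadth, depth (one row per
#'   reference, including uncovered ones).
#' @export
coverage_stats <- function(alignments, ref_lengths) {
  if (is.null(names(ref_lengths))) stopf("ref_lengths must be named")
  unknown <- setdiff(unique(alignments$ref_id), names(ref_lengths))
  if (length(unknown))
    stopf("alignments reference unknown ref(s): %s",
          paste(unknown, collapse = ", "))
  if (nrow(alignments)) {
    oob <- alignments$ref_start < 0L |
      alignments$ref_end > ref_lengths[alignments$ref_id]
    if (any(oob)) stopf("alignment out of reference bounds (%s)",
                        alignments$read_id[which(oob)[1]])
  }
  out <- lapply(names(ref_lengths), function(r) {
    a <- alignments[alignments$ref_id == r, , drop = FALSE]
    L <- ref_lengths[[r]]
    if (!nrow(a))
      return(data.frame(ref_id = r, n_reads = 0L, breadth = 0, depth = 0,
                        stringsAsFactors = FALSE))
    ir <- IRanges::IRanges(a$ref_start + 1L, a$ref_end)
    data.frame(ref_id = r, n_reads = nrow(a),
               breadth = sum(IRanges::width(IRanges::reduce(ir))) / L,
               depth = sum(IRanges::width(ir)) / L, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Select references passing a breadth-of-coverage screen
#'
#' The comparator is explicit because the screening thresholds differ in
#' strictness: the known-genome screen keeps breadth strictly > 0.30 while
#' the VLP evidence strategy keeps breadth >= 0.40.
#'
#' @param coverage data.frame from [coverage_stats()].
#' @param min_breadth threshold in `[0, 1]`.
#' @param comparator `">"` (strict, default) or `">="`.
#' @return character vector of ref ids.
#' @export
select_covered <- function(coverage, min_breadth, comparator = c(">", ">=")) {
  comparator <- match.arg(comparator)
  stopifnot(min_breadth >= 0, min_breadth <= 1)
  if (!nrow(coverage)) return(character(0))
  keep <- if (comparator == ">") coverage$breadth > min_breadth
          else coverage$breadth >= min_breadth
  coverage$ref_id[keep]
}

#' Per-sample normalized scaffold abundance and phage load
#'
#' Normalizes per-scaffold mapped-read counts by the total read number of
#' each sample, and sums them into the per-sample phage load (all reads on
#' identified phage scaffolds over all reads of the sample).
#'
#' @param counts data.frame: sample_id, scaffold_id, n_reads.
#' @param total_reads named vector: total reads per sample (> 0).
#' @return list with `abundance` (data.frame sample_id, scaffold_id, value)
#'   and `load` (named vector per sample).
#' @export
scaffold_relative_abundance <- function(counts, total_reads) {
  if (any(total_reads <= 0)) stopf("total_reads must be positive")
  missing <- setdiff(unique(counts$sample_id), names(total_reads))
  if (length(missing))
    stopf("no total read count for sample(s): %s",
          paste(missing, collapse = ", "))
  ab <- data.frame(sample_id = counts$sample_id,
                   scaffold_id = counts$scaffold_id,
                   value = counts$n_reads / total_reads[counts$sample_id],
                   stringsAsFactors = FALSE)
  load <- vapply(names(total_reads), function(s)
    sum(ab$value[ab$sample_id == s]), 0)
  list(abundance = ab, load = load)
}
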