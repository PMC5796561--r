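# Readers/writers for FASTA/FASTQ and BLAST-style hit tables, a six-frame
# ORF caller, and a k-mer protein search used at fixture scale.

#' Read a FASTA file
#'
#' Sequences are upper-cased on read; wrapping width is irrelevant.
#'
#' @param path file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) && !startsWith(trimws(lines[nonempty[1]]), ">"))
    stopf("malformed FASTA record at line %d: expected '>' header", nonempty[1])
  x <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to FASTA
#' @param records named character vector.
#' @param path output path.
#' @param width line wrap width.
#' @export
write_fasta <- function(records, path, width = 70L) {
  x <- Biostrings::BStringSet(records)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read / write FASTQ
#' @rdname read_fasta
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' @rdname write_fasta
#' @export
write_fastq <- function(records, path) {
  x <- Biostrings::DNAStringSet(records)
  Biostrings::writeXStringSet(x, path, format = "fastq")
  invisible(path)
}

#' Call open reading frames on all six frames
#'
#' Maximal ATG-to-stop ORFs (standard genetic code, ATG-only starts) with at
#' least `min_aa` encoded amino acids, non-nested within a frame.  Reported
#' intervals are 0-based half-open on the input scaffold and include the stop
#' codon; the protein is the translation without the stop.  Ambiguity bases
#' (N) translate to X.
#'
#' @param scaffold a single DNA sequence (character) or named length-1 vector.
#' @param min_aa minimum protein length in amino acids (default 33).
#' @param scaffold_id id recorded in the output (defaults to the name).
#' @return data.frame: gene_id, scaffold_id, start, end, strand, protein.
#' @export
call_orfs <- function(scaffold, min_aa = 33L, scaffold_id = NULL) {
  stopifnot(length(scaffold) == 1L, min_aa >= 1L)
  scaffold_id <- scaffold_id %||% names(scaffold) %||% "scaffold"
  seq <- toupper(unname(scaffold))
  L <- nchar(seq)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp(seq)
    for (f in 0:2) {
      n_cod <- (L - f) %/% 3L
      if (n_cod < 2L) next
      sub <- substr(s, f + 1L, f + 3L * n_cod)
      prot <- translate_dna(sub)
      # Split at stops; within each stop-terminated segment take the first M.
      stops <- gregexpr("*", prot, fixed = TRUE)[[1]]
      if (stops[1] == -1L) next
      seg_start <- c(1L, stops[-length(stops)] + 1L)  # aa index of segment start
      for (k in seq_along(stops)) {
        seg <- substr(prot, seg_start[k], stops[k] - 1L)
        m <- regexpr("M", seg, fixed = TRUE)
        if (m == -1L) next
        aa0 <- seg_start[k] + as.integer(m) - 1L      # first codon (1-based)
        n_aa <- stops[k] - aa0                        # protein length
        if (n_aa < min_aa) next
        nt_start <- f + 3L * (aa0 - 1L)               # 0-based, on strand s
        nt_end <- f + 3L * stops[k]                   # incl. stop codon
        if (strand == "+") {
          st <- nt_start; en <- nt_end
        } else {
          st <- L - nt_end; en <- L - nt_start
        }
        out[[length(out) + 1L]] <- data.frame(
          scaffold_id = scaffold_id, start = st, end = en, strand = strand,
          protein = substr(seg, as.integer(m), nchar(seg)),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(gene_id = character(0), scaffold_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), protein = character(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$end, res$strand), , drop = FALSE]
  res <- cbind(gene_id = sprintf("%s_orf%04d", scaffold_id, seq_len(nrow(res))),
               res, stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Call ORFs on a set of scaffolds
#' @param scaffolds named character vector.
#' @inheritParams call_orfs
#' @return combined data.frame of genes.
#' @export
call_orfs_set <- function(scaffolds, min_aa = 33L) {
  res <- lapply(names(scaffolds), function(id)
    call_orfs(scaffolds[[id]], min_aa = min_aa, scaffold_id = id))
  do.call(rbind, res)
}

#' Read a 12-column BLAST-style tabular hit file
#'
#' Dialect: query, subject, identity (percent), length, mismatches, gapopens,
#' qstart, qend, sstart, send, evalue, bitscore.  Records above `max_evalue`
#' are dropped and only the best (lowest e-value) record per (query, subject)
#' pair is kept.
#'
#' @param path file path.
#' @param max_evalue e-value cutoff (default `Inf` keeps everything).
#' @return data.frame: query_id, subject_id, identity (fraction), evalue,
#'   bitscore.
#' @export
read_hits <- function(path, max_evalue = Inf) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = "character", quote = "")
  if (!nrow(raw))
    return(data.frame(query_id = character(0), subject_id = character(0),
                      identity = numeric(0), evalue = numeric(0),
                      bitscore = numeric(0)))
  if (ncol(raw) < 12L) stopf("hit table must have 12 columns, found %d", ncol(raw))
  ev <- suppressWarnings(as.numeric(raw[[11]]))
  if (anyNA(ev))
    stopf("non-numeric e-value at line %d", which(is.na(ev))[1])
  bs <- suppressWarnings(as.numeric(raw[[12]]))
  idf <- suppressWarnings(as.numeric(raw[[3]]))
  hits <- data.frame(query_id = raw[[1]], subject_id = raw[[2]],
                     identity = idf / 100, evalue = ev, bitscore = bs,
                     stringsAsFactors = FALSE)
  filter_hits(hits, max_evalue)
}

# Drop hits above the cutoff and keep the best e-value per (query, subject).
filter_hits <- function(hits, max_evalue = Inf) {
  hits <- hits[hits$evalue <= max_evalue, , drop = FALSE]
  if (!nrow(hits)) return(hits)
  hits <- hits[order(hits$query_id, hits$subject_id, hits$evalue,
                     -hits$bitscore), , drop = FALSE]
  keep <- !duplicated(hits[c("query_id", "subject_id")])
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write hits in the 12-column tabular dialect
#' @param hits data.frame as returned by [read_hits()].
#' @param path output path.
#' @export
write_hits <- function(hits, path) {
  out <- data.frame(hits$query_id, hits$subject_id,
                    sprintf("%.2f", hits$identity * 100), 0L, 0L, 0L,
                    0L, 0L, 0L, 0L,
                    format(hits$evalue, digits = 3),
                    format(hits$bitscore, digits = 6))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Shared k-mer protein search
#'
#' Fixture-scale homology search: each query is scored against each database
#' entry by the number of shared distinct amino-acid k-mers; the score is
#' converted to a pseudo e-value `|db| * 2^-score`, monotone decreasing in
#' the score.  A query that is an exact substring of an entry receives a
#' +0.5 score bonus so exact matches always outrank non-exact ones.
#' Ambiguity residues (X) never participate in matching k-mers.
#'
#' @param queries named character vector of protein sequences.
#' @param db named character vector of protein sequences.
#' @param k k-mer size (default 4).
#' @param max_evalue drop hits above this pseudo e-value.
#' @param min_score minimum shared k-mer count to report (default 1).
#' @return data.frame: query_id, subject_id, identity (shared fraction of the
#'   query's k-mers), evalue, bitscore.
#' @export
naive_protein_search <- function(queries, db, k = 4L, max_evalue = Inf,
                                 min_score = 1) {
  if (!length(db)) stopf("empty protein database")
  if (!length(queries))
    return(data.frame(query_id = character(0), subject_id = character(0),
                      identity = numeric(0), evalue = numeric(0),
                      bitscore = numeric(0)))
  if (min(nchar(c(queries, db))) < k)
    stopf("k = %d exceeds the shortest sequence length", k)
  if (is.null(names(queries))) names(queries) <- sprintf("q%d", seq_along(queries))
  if (is.null(names(db))) names(db) <- sprintf("s%d", seq_along(db))

  kmerize <- function(seqs) {
    lapply(seqs, function(s) {
      n <- nchar(s)
      km <- substring(s, 1:(n - k + 1L), k:n)
      unique(km[!grepl("X", km, fixed = TRUE)])
    })
  }
  qk <- kmerize(queries)
  dk <- kmerize(db)
  universe <- unique(unlist(dk, use.names = FALSE))
  dij <- data.frame(
    i = rep.int(seq_along(dk), lengths(dk)),
    j = match(unlist(dk, use.names = FALSE), universe))
  qmatch <- lapply(qk, function(x) {
    m <- match(x, universe); m[!is.na(m)]
  })
  qij <- data.frame(
    i = rep.int(seq_along(qmatch), lengths(qmatch)),
    j = unlist(qmatch, use.names = FALSE))
  if (!nrow(qij))
    return(data.frame(query_id = character(0), subject_id = character(0),
                      identity = numeric(0), evalue = numeric(0),
                      bitscore = numeric(0)))
  nk <- length(universe)
  Mq <- Matrix::sparseMatrix(i = qij$i, j = qij$j, x = 1,
                             dims = c(length(queries), nk))
  Md <- Matrix::sparseMatrix(i = dij$i, j = dij$j, x = 1,
                             dims = c(length(db), nk))
  S <- Matrix::summary(Mq %*% Matrix::t(Md))
  S <- S[S$x >= min_score, , drop = FALSE]
  if (!nrow(S))
    return(data.frame(query_id = character(0), subject_id = character(0),
                      identity = numeric(0), evalue = numeric(0),
                      bitscore = numeric(0)))
  score <- S$x
  # exact-substring bonus for full-score pairs
  full <- which(score >= lengths(qk)[S$i])
  if (length(full)) {
    is_sub <- vapply(full, function(r)
      grepl(queries[[S$i[r]]], db[[S$j[r]]], fixed = TRUE), TRUE)
    score[full[is_sub]] <- score[full[is_sub]] + 0.5
  }
  hits <- data.frame(
    query_id = names(queries)[S$i],
    subject_id = names(db)[S$j],
    identity = pmin(1, S$x / pmax(lengths(qk)[S$i], 1L)),
    evalue = length(db) * 2^(-score),
    bitscore = score, stringsAsFactors = FALSE)
  hits <- hits[hits$evalue <= max_evalue, , drop = FALSE]
  hits <- hits[order(hits$query_id, hits$evalue, -hits$bitscore,
                     hits$subject_id), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}
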