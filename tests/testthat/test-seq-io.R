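# FASTA/FASTQ round trips, hit-table filtering, the six-frame ORF caller
# (against a brute-force oracle), and the k-mer protein search.

test_that("FASTA round trip preserves ids and sequences", {
  recs <- c(a = "ACGTACGT", b = "GGGGCCCCAAAA", c = "AT")
  f <- tempfile(fileext = ".fasta")
  write_fasta(recs, f, width = 5L)
  expect_identical(read_fasta(f), recs)
})

test_that("FASTA reading normalizes case and handles empty files", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">x", "acgTn"), f)
  expect_identical(read_fasta(f), c(x = "ACGTN"))
  f2 <- tempfile(); file.create(f2)
  expect_length(read_fasta(f2), 0L)
})

test_that("malformed FASTA reports the offending line", {
  f <- tempfile()
  writeLines(c("ACGT", ">x", "ACGT"), f)
  expect_error(read_fasta(f), "line 1")
})

test_that("FASTQ round trip preserves content", {
  recs <- c(r1 = "ACGTACGTAA", r2 = "TTTTGGGGCC")
  f <- tempfile(fileext = ".fastq")
  write_fastq(recs, f)
  expect_identical(read_fastq(f), recs)
})

test_that("call_orfs recovers a hand-translated minimal gene", {
  g <- call_orfs("ATGAAATAA", min_aa = 2)
  expect_equal(nrow(g), 1L)
  expect_equal(g$protein, "MK")
  expect_equal(g$start, 0L)
  expect_equal(g$end, 9L)
  expect_equal((g$end - g$start) %% 3L, 0L)
})

test_that("short or stop-free sequences yield no ORFs", {
  expect_equal(nrow(call_orfs("ATGAAA", min_aa = 2)), 0L)      # no stop
  expect_equal(nrow(call_orfs("ATGTAA", min_aa = 2)), 0L)      # too short
  expect_equal(nrow(call_orfs(strrep("C", 90), min_aa = 2)), 0L)
})

# Independent oracle: explicit codon scan per frame and strand.
orf_oracle <- function(seq, min_aa) {
  code <- Biostrings::GENETIC_CODE
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  L <- nchar(seq)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else rc
    for (f in 0:2) {
      n_cod <- (L - f) %/% 3L
      if (n_cod < 1L) next
      codons <- substring(s, f + 1L + 3L * (0:(n_cod - 1L)),
                          f + 3L * (1:n_cod))
      aa <- unname(code[codons])
      aa[is.na(aa)] <- "X"
      start_cod <- NA
      for (i in seq_along(aa)) {
        if (is.na(start_cod) && codons[i] == "ATG") start_cod <- i
        if (aa[i] == "*") {
          if (!is.na(start_cod) && (i - start_cod) >= min_aa) {
            nt0 <- f + 3L * (start_cod - 1L); nt1 <- f + 3L * i
            iv <- if (strand == "+") c(nt0, nt1) else c(L - nt1, L - nt0)
            out[[length(out) + 1L]] <- data.frame(
              start = iv[1], end = iv[2], strand = strand,
              protein = paste(aa[start_cod:(i - 1L)], collapse = ""))
          }
          start_cod <- NA
        }
      }
    }
  }
  if (!length(out)) return(data.frame(start = integer(0), end = integer(0),
                                      strand = character(0),
                                      protein = character(0)))
  res <- do.call(rbind, out)
  res[order(res$start, res$end, res$strand), , drop = FALSE]
}

test_that("ORF caller matches the brute-force six-frame oracle", {
  set.seed(11)
  for (i in 1:100) {
    seq <- random_dna_str(2000)
    got <- call_orfs(seq, min_aa = 20)
    want <- orf_oracle(seq, min_aa = 20)
    expect_equal(got[c("start", "end", "strand", "protein")], want,
                 ignore_attr = TRUE)
  }
})

test_that("planted marker ORFs are recovered exactly", {
  w <- tiny_world()
  genes <- call_orfs_set(w$com$scaffolds)
  pg <- w$com$truth$planted_genes
  found <- mapply(function(sc, st, en, pr)
    any(genes$scaffold_id == sc & genes$start == st & genes$end == en &
          genes$protein == pr),
    pg$scaffold_id, pg$start, pg$end, pg$protein)
  expect_true(all(found))
})

test_that("hit tables filter by e-value and dedupe (query, subject) pairs", {
  f <- tempfile()
  rows <- c("g1\tp1\t90\t100\t1\t0\t1\t100\t1\t100\t1e-20\t200",
            "g1\tp1\t88\t100\t2\t0\t1\t100\t1\t100\t1e-10\t150",
            "g1\tp2\t80\t100\t5\t0\t1\t100\t1\t100\t1e-03\t80",
            "g2\tp1\t70\t100\t9\t0\t1\t100\t1\t100\t0.5\t40",
            "g3\tp3\t95\t100\t1\t0\t1\t100\t1\t100\t1e-08\t120")
  writeLines(rows, f)
  h <- read_hits(f, max_evalue = 1e-05)
  expect_equal(nrow(h), 2L)                    # g1/p1 (deduped) and g3/p3
  expect_equal(h$evalue[h$query_id == "g1"], 1e-20)
  expect_equal(nrow(read_hits(f, max_evalue = Inf)), 4L)  # 5 rows, 1 dup
  writeLines(c("g1\tp1\t90\t100\t1\t0\t1\t100\t1\t100\tnot_a_number\t200"), f)
  expect_error(read_hits(f), "non-numeric e-value")
})

test_that("filtering hit tables is idempotent", {
  f <- tempfile()
  writeLines(c("g1\tp1\t90\t100\t1\t0\t1\t100\t1\t100\t1e-20\t200",
               "g2\tp2\t90\t100\t1\t0\t1\t100\t1\t100\t1e-07\t100"), f)
  h1 <- read_hits(f, max_evalue = 1e-05)
  expect_identical(phageome:::filter_hits(h1, 1e-05), h1)
})

test_that("protein search ranks exact matches first and finds no spurious hits", {
  set.seed(5)
  db <- vapply(1:8, function(i)
    paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 120,
                 replace = TRUE), collapse = ""), "")
  names(db) <- sprintf("p%d", 1:8)
  q <- c(exact = db[["p3"]])
  hits <- naive_protein_search(q, db)
  expect_equal(hits$subject_id[1], "p3")
  expect_equal(hits$bitscore[hits$subject_id == "p3"],
               max(hits$bitscore))
  # query sharing no k-mer: a poly-W sequence vs W-free db entries
  q2 <- c(nohit = strrep("W", 60))
  db2 <- c(x = strrep("A", 120))
  expect_equal(nrow(naive_protein_search(q2, db2)), 0L)
  expect_error(naive_protein_search(c(q = "ACD"), db, k = 10),
               "shortest sequence")
})

test_that("protein search scores agree with brute-force k-mer counting", {
  set.seed(6)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  db <- vapply(1:6, function(i)
    paste(sample(aa, 80, replace = TRUE), collapse = ""), "")
  names(db) <- sprintf("d%d", 1:6)
  queries <- vapply(1:50, function(i) {
    base <- db[[sample.int(6, 1)]]
    n <- sample(20:60, 1)
    at <- sample.int(nchar(base) - n, 1)
    mut <- substr(base, at, at + n - 1L)
    p <- sample.int(n, 3)
    for (j in p) substr(mut, j, j) <- sample(aa, 1)
    mut
  }, "")
  names(queries) <- sprintf("q%d", 1:50)
  hits <- naive_protein_search(queries, db, k = 4)
  kmers <- function(s, k = 4) unique(substring(s, 1:(nchar(s) - k + 1L),
                                               k:nchar(s)))
  for (qi in names(queries)) for (di in names(db)) {
    shared <- length(intersect(kmers(queries[[qi]]), kmers(db[[di]])))
    got <- hits$bitscore[hits$query_id == qi & hits$subject_id == di]
    if (shared == 0) expect_length(got, 0L)
    else expect_equal(floor(got), shared)   # +0.5 bonus only for exact
  }
})
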