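# pOTU definition, marker-based read counting (tie rule), 16S counting, and
# 16S-normalized abundance arithmetic.

mk_tax <- function(n, family = "Siphoviridae", genus = NULL, host = "Bacteroides") {
  data.frame(phage_id = sprintf("ph%d", seq_len(n)), group = "dsDNA",
             order = "Caudovirales", family = family,
             subfamily = "unclassified_subfamily",
             genus = genus %||% sprintf("g%d", seq_len(n)),
             host_genus = host, stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("pOTUs partition genomes by taxonomy and host genus", {
  # identical five levels + host -> one pOTU with two members
  t1 <- mk_tax(2, genus = c("gX", "gX"))
  p1 <- define_potus(t1)
  expect_equal(nrow(p1), 1L)
  expect_equal(p1$n_members, 2L)
  # same five levels, different host genus -> two pOTUs
  t2 <- mk_tax(2, genus = c("gX", "gX"), host = c("Bacteroides", "Prevotella"))
  expect_equal(nrow(define_potus(t2)), 2L)
  # all distinct -> n pOTUs
  t3 <- mk_tax(5)
  expect_equal(nrow(define_potus(t3)), 5L)
  # deterministic ids
  expect_identical(define_potus(t3), define_potus(t3))
  # missing taxonomy is a data error
  t4 <- t3; t4$family[2] <- NA
  expect_error(define_potus(t4), "missing values")
  expect_error(define_potus(t3[-1]), "phage_id")
})

test_that("genome counts match the read-origin truth", {
  w <- tiny_world()
  counts <- count_genome_reads(w$reads$wcms, w$refs$marker_genes)
  org <- w$reads$origins
  truth <- table(factor(org$sample_id, levels = rownames(counts)),
                 factor(org$marker_phage, levels = colnames(counts)))
  expect_equal(unclass(counts), unclass(truth), ignore_attr = TRUE)
  # bacterial-origin reads contribute nothing
  expect_true(sum(counts) <= sum(!is.na(org$marker_phage)))
})

test_that("reads matching two genomes equally are discarded", {
  mk <- data.frame(gene_id = c("gA", "gB"), phage_id = c("A", "B"),
                   cds = rep(paste0("ATG", strrep("GATTACAGCA", 30), "TAA"),
                             2),
                   stringsAsFactors = FALSE)
  reads <- list(s1 = c(r1 = substr(mk$cds[1], 10, 109)))
  counts <- count_genome_reads(reads, mk)
  expect_equal(sum(counts), 0L)
  # unique marker: counted for its genome
  mk2 <- mk
  mk2$cds[2] <- paste0("ATG", strrep("CTGAGGTCAT", 30), "TAA")
  counts2 <- count_genome_reads(reads, mk2)
  expect_equal(counts2["s1", "A"], 1L)
  expect_equal(counts2["s1", "B"], 0L)
})

test_that("16S counting matches truth and scales linearly", {
  w <- tiny_world()
  n16 <- count_16s(w$reads$wcms, w$refs$ribosomal_db)
  want <- stats::setNames(w$reads$per_sample_totals$n_16s_true,
                          w$reads$per_sample_totals$sample_id)
  expect_equal(n16, want[names(n16)])
  # doubling the reads doubles the count
  dbl <- list(s = c(w$reads$wcms[[1]],
                    stats::setNames(w$reads$wcms[[1]],
                                    paste0(names(w$reads$wcms[[1]]), "_b"))))
  expect_equal(unname(count_16s(dbl, w$refs$ribosomal_db)["s"]),
               2L * unname(n16[1]))
  expect_error(count_16s(w$reads$wcms, character(0)), "empty 16S")
})

test_that("pOTU abundance is summed member counts over n16S", {
  tax <- mk_tax(3, genus = c("gX", "gX", "gY"))
  potus <- define_potus(tax)         # ph1+ph2 together, ph3 alone
  counts <- matrix(c(30L, 20L, 5L, 0L, 0L, 0L), nrow = 2, byrow = TRUE,
                   dimnames = list(c("s1", "s2"), c("ph1", "ph2", "ph3")))
  ab <- potu_abundance(counts, potus, c(s1 = 50L, s2 = 10L))
  two <- potus$potu_id[potus$n_members == 2L]
  one <- potus$potu_id[potus$n_members == 1L]
  expect_equal(unname(ab$abundance["s1", two]), 1.0)
  expect_equal(unname(ab$abundance["s1", one]), 0.1)
  expect_equal(unname(ab$abundance["s2", ]), c(0, 0), ignore_attr = TRUE)
  # family rollup equals the sum of its pOTUs in every sample
  expect_equal(ab$family[, "Siphoviridae"], rowSums(ab$abundance))
  # a pOTU with no counted member genome stays zero
  counts2 <- cbind(counts, phX = c(0L, 0L))
  expect_equal(unname(ab$abundance["s2", one]), 0)
})

test_that("zero-16S samples become missing", {
  tax <- mk_tax(2)
  potus <- define_potus(tax)
  counts <- matrix(c(5L, 5L, 3L, 3L), nrow = 2, byrow = TRUE,
                   dimnames = list(c("s1", "s2"), c("ph1", "ph2")))
  ab <- potu_abundance(counts, potus, c(s1 = 10L, s2 = 0L))
  expect_true(all(is.na(ab$abundance["s2", ])))
  expect_false(anyNA(ab$abundance["s1", ]))
})

test_that("planted fold changes are recovered from the abundance matrix", {
  run <- default_run()
  eff <- run$community$truth$planted_effects
  groups <- stats::setNames(run$community$truth$sample_groups$group,
                            run$community$truth$sample_groups$sample_id)
  ab <- run$profile$abundance
  for (i in seq_len(nrow(eff))) {
    v <- ab[, eff$potu_id[i]]
    ratio <- mean(v[groups[rownames(ab)] == "case"], na.rm = TRUE) /
      mean(v[groups[rownames(ab)] == "control"], na.rm = TRUE)
    expect_gte(ratio, 2)
    expect_lte(ratio, 4)
  }
})

test_that("abundance is stable under 50% read down-sampling", {
  w <- tiny_world()
  set.seed(7)
  half <- lapply(w$reads$wcms, function(r)
    r[sort(sample.int(length(r), length(r) %/% 2L))])
  potus <- define_potus(w$refs$taxonomy)
  full_counts <- count_genome_reads(w$reads$wcms, w$refs$marker_genes)
  half_counts <- count_genome_reads(half, w$refs$marker_genes)
  n16_full <- count_16s(w$reads$wcms, w$refs$ribosomal_db)
  n16_half <- count_16s(half, w$refs$ribosomal_db)
  ab_full <- potu_abundance(full_counts, potus, n16_full)$abundance
  ab_half <- potu_abundance(half_counts, potus, n16_half)$abundance
  # compare pooled means (per-sample counts are tiny): within 10%
  expect_equal(mean(ab_half, na.rm = TRUE), mean(ab_full, na.rm = TRUE),
               tolerance = 0.1)
})
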