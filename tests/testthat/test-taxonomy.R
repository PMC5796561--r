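# Weighted-vote taxonomy (PFR/BGR): worked examples, threshold strictness,
# equivalence with a brute-force oracle, and LST motif calls.

mk_hits <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(query_id = r[[1]], subject_id = r[[2]],
               identity = 1, evalue = as.numeric(r[[3]]),
               bitscore = as.numeric(r[[4]]), stringsAsFactors = FALSE)))
}

test_that("a single hit gives PFR 1 and the hit's family", {
  hits <- mk_hits(list("g1", "p1", 1e-20, 100))
  got <- assign_phage_family(hits, c(p1 = "Siphoviridae"), "s")
  expect_equal(got$label, "Siphoviridae")
  expect_equal(got$ratio, 1)
  expect_equal(got$gene_votes, 1L)
})

test_that("weighted votes accumulate 1.0/0.5 over the top two hits", {
  # gene1: top Sipho (1.0), second Myo (0.5); gene2: top+second Myo (1.5)
  hits <- mk_hits(list("g1", "pS", 1e-30, 200), list("g1", "pM1", 1e-20, 150),
                  list("g2", "pM1", 1e-25, 180), list("g2", "pM2", 1e-10, 90))
  fam <- c(pS = "Siphoviridae", pM1 = "Myoviridae", pM2 = "Myoviridae")
  got <- assign_phage_family(hits, fam, "s")
  expect_equal(got$label, "Myoviridae")
  expect_equal(got$ratio, 2 / 3)
  expect_equal(got$gene_votes, 2L)
})

test_that("a PFR of exactly 0.5 is unclassified (strict >)", {
  # two genes, single hit each, different families: 1.0 vs 1.0
  hits <- mk_hits(list("g1", "pS", 1e-20, 100), list("g2", "pM", 1e-20, 100),
                  list("g1", "pS2", 1e-10, 50), list("g2", "pM2", 1e-10, 50))
  fam <- c(pS = "Siphoviridae", pS2 = "Siphoviridae",
           pM = "Myoviridae", pM2 = "Myoviridae")
  got <- assign_phage_family(hits, fam, "s")
  expect_equal(got$ratio, 0.5)
  expect_equal(got$label, "unclassified")
})

test_that("a BGR of exactly 0.70 is assigned (inclusive >=)", {
  # scores: A = 2 x 1.0 + 3 x 0.5 = 3.5 of total 5.0 -> 0.70
  hits <- mk_hits(
    list("g1", "a1", 1e-30, 100), list("g1", "b1", 1e-20, 80),
    list("g2", "a2", 1e-30, 100), list("g2", "b1", 1e-20, 80),
    list("g3", "b2", 1e-30, 100), list("g3", "a3", 1e-20, 80),
    list("g4", "b3", 1e-30, 100), list("g4", "a4", 1e-20, 80),
    list("g5", "b4", 1e-30, 100), list("g5", "a5", 1e-20, 80))
  gen <- c(a1 = "A", a2 = "A", a3 = "A", a4 = "A", a5 = "A",
           b1 = "B", b2 = "B", b3 = "B", b4 = "B")
  got <- assign_bacterial_genus(hits, gen, "s")
  expect_equal(got$ratio, 4 / 7.5)
  expect_equal(got$label, "unclassified")   # 0.533 < 0.70
  # exactly 0.70: two single-hit genes on A, plus A/B and B/A top-second
  # pairs -> A = 1 + 1 + 1 + 0.5 = 3.5 of 5.0
  hits2 <- mk_hits(
    list("g1", "a1", 1e-30, 100),
    list("g2", "a2", 1e-30, 100),
    list("g3", "a3", 1e-30, 100), list("g3", "b1", 1e-20, 80),
    list("g4", "b2", 1e-30, 100), list("g4", "a4", 1e-20, 80))
  got2 <- assign_bacterial_genus(hits2, gen, "s")
  expect_equal(got2$ratio, 0.7)             # 3.5 / 5.0
  expect_equal(got2$label, "A")
  # just below the threshold stays unclassified
  hits3 <- mk_hits(list("g1", "a1", 1e-30, 100), list("g1", "b1", 1e-20, 80),
                   list("g2", "a1", 1e-30, 100))
  got3 <- assign_bacterial_genus(hits3, c(a1 = "A", b1 = "B"), "s")
  expect_equal(got3$ratio, 2 / 2.5)         # 0.80 assigned
  expect_equal(got3$label, "A")
  got4 <- assign_bacterial_genus(
    mk_hits(list("g1", "a1", 1e-30, 100), list("g1", "b1", 1e-20, 80)),
    c(a1 = "A", b1 = "B"), "s")
  expect_equal(got4$ratio, 1 / 1.5)
  expect_equal(got4$label, "unclassified")  # 0.667 < 0.70
})

test_that("no voting genes yields unclassified with ratio 0", {
  got <- assign_phage_family(mk_hits(list("g", "p", 1e-9, 1))[0, ],
                             c(p = "Siphoviridae"), "s")
  expect_equal(got$label, "unclassified")
  expect_equal(got$ratio, 0)
})

# Independent oracle: explicit enumeration of every gene's ranked votes.
vote_oracle <- function(hits, labels, threshold, strict) {
  scores <- list()
  for (g in unique(hits$query_id)) {
    h <- hits[hits$query_id == g, ]
    h <- h[order(h$evalue, -h$bitscore, h$subject_id), ]
    seen <- character(0); w <- c(1, 0.5); wi <- 1L
    for (r in seq_len(nrow(h))) {
      if (h$subject_id[r] %in% seen) next
      seen <- c(seen, h$subject_id[r])
      lab <- labels[[h$subject_id[r]]]
      scores[[lab]] <- (scores[[lab]] %||% 0) + w[wi]
      wi <- wi + 1L
      if (wi > 2L) break
    }
  }
  sc <- unlist(scores)
  if (is.null(sc)) return(list(label = "unclassified", ratio = 0))
  ratio <- max(sc) / sum(sc)
  top <- sort(names(sc)[sc == max(sc)])[1]
  ok <- if (strict) ratio > threshold else ratio >= threshold
  list(label = if (ok) top else "unclassified", ratio = ratio)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("weighted vote matches the brute-force oracle on random tables", {
  set.seed(41)
  labels_pool <- c("Siphoviridae", "Myoviridae", "Podoviridae",
                   "unclassified_family")
  subjects <- sprintf("p%02d", 1:12)
  labels <- stats::setNames(sample(labels_pool, 12, replace = TRUE), subjects)
  for (rep in 1:200) {
    n_genes <- sample(1:6, 1)
    n_hits <- sample(1:5, n_genes, replace = TRUE)
    hits <- do.call(rbind, lapply(seq_len(n_genes), function(g) {
      data.frame(query_id = sprintf("g%d", g),
                 subject_id = sample(subjects, n_hits[g]),
                 identity = 1,
                 # discrete e-values force frequent ranking ties
                 evalue = sample(c(1e-30, 1e-20, 1e-10, 1e-6), n_hits[g],
                                 replace = TRUE),
                 bitscore = sample(c(50, 100, 150), n_hits[g],
                                   replace = TRUE),
                 stringsAsFactors = FALSE)
    }))
    got <- assign_phage_family(hits, labels, "s")
    want <- vote_oracle(hits, labels, 0.5, strict = TRUE)
    expect_identical(got$label, want$label)
    expect_equal(got$ratio, want$ratio)
    gotg <- assign_bacterial_genus(hits, labels, "s")
    wantg <- vote_oracle(hits, labels, 0.7, strict = FALSE)
    expect_identical(gotg$label, wantg$label)
  }
})

test_that("assignments are invariant to hit row order", {
  set.seed(42)
  hits <- mk_hits(list("g1", "pS", 1e-30, 200), list("g1", "pM1", 1e-20, 150),
                  list("g2", "pM1", 1e-25, 180), list("g2", "pM2", 1e-10, 90))
  fam <- c(pS = "Siphoviridae", pM1 = "Myoviridae", pM2 = "Myoviridae")
  base <- assign_phage_family(hits, fam, "s")
  for (i in 1:10) {
    got <- assign_phage_family(hits[sample.int(nrow(hits)), ], fam, "s")
    expect_identical(got, base)
  }
})

test_that("synthetic bacterial scaffolds recover their genus at 100%", {
  run <- tiny_run()
  w <- tiny_world()
  tb <- run$taxonomy_bacterial
  tb <- tb[tb$label != "unclassified", ]
  truth <- w$com$scaffold_info$genus[match(tb$scaffold_id,
                                           w$com$scaffold_info$scaffold_id)]
  expect_gt(nrow(tb), 0L)
  expect_true(all(tb$label == truth))
  # and phage scaffolds recover their planted family
  tp <- run$taxonomy_phage
  pid <- w$com$scaffold_info$phage_id[match(tp$scaffold_id,
                                            w$com$scaffold_info$scaffold_id)]
  fam <- w$refs$taxonomy$family[match(pid, w$refs$taxonomy$phage_id)]
  expect_true(all(tp$label == fam))
})

test_that("LST motif calls report the best domain with name-order ties", {
  motifs <- c(Terminase_1 = "WWHARDYKKW", Terminase_3 = "MMCCDDEEFF")
  prots <- c(
    hit1 = paste0("MAAA", motifs[["Terminase_3"]], "KKKK"),
    none = "MKLVNNNNPQRSTVVV",
    both = paste0("M", motifs[["Terminase_1"]], "AAA",
                  motifs[["Terminase_3"]]))
  got <- identify_lst(prots, motifs)
  expect_setequal(got$gene_id, c("hit1", "both"))
  expect_equal(got$domain[got$gene_id == "hit1"], "Terminase_3")
  # equal scores: first domain in name order wins
  expect_equal(got$domain[got$gene_id == "both"], "Terminase_1")
})

test_that("planted terminase motifs are recovered on synthetic proteins", {
  w <- tiny_world()
  mk <- w$refs$marker_genes
  prots <- stats::setNames(mk$protein, mk$gene_id)
  got <- identify_lst(prots, w$refs$lst_motifs)
  want <- mk[!is.na(mk$domain), ]
  expect_setequal(got$gene_id, want$gene_id)
  expect_equal(got$domain[match(want$gene_id, got$gene_id)], want$domain)
})
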