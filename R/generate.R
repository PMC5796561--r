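# Synthetic community generator: reference databases, scaffold catalog with
# planted prophages / CRISPR arrays / 16S copies, and read simulation with
# full ground-truth tables.  Coordinates are 0-based, half-open throughout.

GUT_GENERA <- c("Bacteroides", "Eubacterium", "Megamonas", "Clostridium",
                "Prevotella", "Ruminococcus", "Faecalibacterium", "Roseburia",
                "Escherichia", "Lactobacillus")

PHAGE_FAMILIES <- c("Siphoviridae", "Myoviridae", "Podoviridae",
                    "unclassified_family")

TERMINASE_DOMAINS <- c("Terminase_1", "Terminase_3", "Terminase_6",
                       "Terminase_GpA")

#' Generate synthetic reference databases
#'
#' Builds the reference side of the synthetic world: phage genomes with a
#' five-level taxonomy (group|order|family|subfamily|genus) plus a bacterial
#' host genus, a phage marker-gene database (each genome carries at least
#' three marker genes planted as exact ORFs), a mixed bacterial+phage protein
#' database with source labels (used by the ambiguity screen), genus-specific
#' bacterial genes, 16S-like ribosomal references, and the four large-subunit
#' terminase domain motifs.
#'
#' Deterministic given `config$rng_seed`.
#'
#' @param config a [world_config()].
#' @return A list of class `phage_refs` with elements `taxonomy`, `genomes`,
#'   `marker_genes`, `bacterial_genes`, `protein_db`, `ribosomal_db`,
#'   `lst_motifs` and `genera`.
#' @export
generate_references <- function(config) {
  validate_world_config(config)
  with_seed(config$rng_seed, {
    ng <- config$n_bacterial_genera
    genera <- if (ng <= length(GUT_GENERA)) GUT_GENERA[seq_len(ng)] else
      c(GUT_GENERA, sprintf("Genus_%02d", seq_len(ng - length(GUT_GENERA))))

    np <- config$n_phage_genomes
    phage_ids <- sprintf("phage_%02d", seq_len(np))
    taxonomy <- data.frame(
      phage_id = phage_ids,
      group = "dsDNA",
      order = "Caudovirales",
      family = sample(PHAGE_FAMILIES, np, replace = TRUE,
                      prob = c(0.45, 0.25, 0.15, 0.15)),
      subfamily = ifelse(runif(np) < 0.3, "unclassified_subfamily",
                         sprintf("Subfamily_%02d", sample.int(8, np, TRUE))),
      genus = sprintf("Phagegenus_%02d", seq_len(np)),
      host_genus = genera[((seq_len(np) - 1L) %% ng) + 1L],
      stringsAsFactors = FALSE
    )

    # Four terminase domain motifs, planted into the first marker gene of
    # each genome (round-robin over domains).
    lst_motifs <- stats::setNames(
      vapply(TERMINASE_DOMAINS, function(d) random_protein(15L), ""),
      TERMINASE_DOMAINS)

    nm <- config$n_marker_genes_per_phage
    genomes <- character(np)
    marker_rows <- vector("list", np)
    for (i in seq_len(np)) {
      glen <- sample(config$phage_genome_len_range[1]:
                     config$phage_genome_len_range[2], 1L)
      seq <- random_dna(glen)
      # One marker per equal-size block; each insert is "TAA" + CDS so the
      # ORF caller recovers exactly the planted gene.
      rows <- vector("list", nm)
      block <- glen %/% nm
      for (j in seq_len(nm)) {
        aa_len <- sample(config$marker_len_aa_range[1]:
                         config$marker_len_aa_range[2], 1L)
        prot <- paste0("M", random_protein(aa_len - 1L))
        domain <- NA_character_
        if (j == 1L) {
          domain <- TERMINASE_DOMAINS[((i - 1L) %% 4L) + 1L]
          motif <- lst_motifs[[domain]]
          at <- sample(10:(aa_len - nchar(motif) - 5L), 1L)
          substr(prot, at, at + nchar(motif) - 1L) <- motif
        }
        cds <- paste0(back_translate(prot), "TAA")
        ins <- paste0("TAA", cds)
        wid <- nchar(ins)
        lo <- (j - 1L) * block
        at0 <- lo + sample.int(block - wid - 1L, 1L)  # 0-based insert start
        if (at0 + wid > glen) stopf("phage genome too short for marker genes")
        substr(seq, at0 + 1L, at0 + wid) <- ins
        rows[[j]] <- data.frame(
          gene_id = sprintf("%s_g%d", phage_ids[i], j),
          phage_id = phage_ids[i],
          start = at0 + 3L, end = at0 + wid,   # CDS incl. stop, excl. guard
          protein = prot, cds = cds, domain = domain,
          stringsAsFactors = FALSE)
      }
      genomes[i] <- seq
      marker_rows[[i]] <- do.call(rbind, rows)
    }
    names(genomes) <- phage_ids
    marker_genes <- do.call(rbind, marker_rows)
    rownames(marker_genes) <- NULL

    bacterial_genes <- do.call(rbind, lapply(genera, function(g) {
      n <- 4L
      prot <- vapply(seq_len(n), function(j)
        paste0("M", random_protein(sample(config$marker_len_aa_range[1]:
                                          config$marker_len_aa_range[2], 1L) - 1L)), "")
      data.frame(protein_id = sprintf("%s_p%d", g, seq_len(n)),
                 genus = g, protein = prot,
                 cds = paste0(vapply(prot, back_translate, ""), "TAA"),
                 stringsAsFactors = FALSE)
    }))
    rownames(bacterial_genes) <- NULL

    protein_db <- rbind(
      data.frame(protein_id = marker_genes$gene_id, source = "phage",
                 label = taxonomy$family[match(marker_genes$phage_id,
                                               taxonomy$phage_id)],
                 protein = marker_genes$protein, stringsAsFactors = FALSE),
      data.frame(protein_id = bacterial_genes$protein_id, source = "bacterial",
                 label = bacterial_genes$genus,
                 protein = bacterial_genes$protein, stringsAsFactors = FALSE))

    ribosomal_db <- stats::setNames(
      vapply(genera, function(g) random_dna(1500L), ""),
      paste0("16S_", genera))

    structure(list(taxonomy = taxonomy, genomes = genomes,
                   marker_genes = marker_genes,
                   bacterial_genes = bacterial_genes,
                   protein_db = protein_db, ribosomal_db = ribosomal_db,
                   lst_motifs = lst_motifs, genera = genera),
              class = "phage_refs")
  })
}

# Place `widths` non-overlapping features uniformly, one per equal-size block.
# Returns 0-based starts.  Errors when the scaffold cannot host the inserts.
place_features <- function(scaffold_len, widths) {
  k <- length(widths)
  if (k == 0L) return(integer(0))
  block <- scaffold_len %/% k
  if (block <= max(widths) + 1L)
    stopf("generation error: scaffold (%d bp) too short to host %d inserts of up to %d bp",
          scaffold_len, k, max(widths))
  ord <- sample.int(k)  # shuffle which feature lands in which block
  starts <- integer(k)
  for (b in seq_len(k)) {
    j <- ord[b]
    starts[j] <- (b - 1L) * block + sample.int(block - widths[j] - 1L, 1L)
  }
  starts
}

mutate_bases <- function(seq, n_sub) {
  if (n_sub <= 0L) return(seq)
  pos <- sample.int(nchar(seq), n_sub)
  for (p in pos) {
    cur <- substr(seq, p, p)
    substr(seq, p, p) <- sample(setdiff(DNA_BASES, cur), 1L)
  }
  seq
}

#' Generate the synthetic scaffold catalog and truth tables
#'
#' Builds a cohort-level catalog of assembled scaffolds: purely bacterial
#' scaffolds (with genus-specific genes, 16S copies and, on a configured
#' fraction, one CRISPR array) and prophage-bearing scaffolds in which a
#' complete phage genome is inserted verbatim between bacterial flanks.
#' CRISPR arrays are repeat--spacer--repeat structures with
#' `n_repeats_per_array` repeats and one fewer spacers; each spacer is copied
#' from a phage genome whose host genus matches the scaffold's genus.
#'
#' All planted features are recorded in `truth` with 0-based, half-open
#' coordinates, so every downstream stage can be checked against ground truth.
#'
#' @param config a [world_config()].
#' @param refs output of [generate_references()].
#' @return A list of class `phage_community`: `scaffolds` (named character),
#'   `scaffold_info`, and `truth` (prophage intervals, CRISPR arrays, spacer
#'   origins, planted genes, 16S copies, sample groups, planted effects,
#'   phage taxonomy).
#' @export
generate_community <- function(config, refs) {
  validate_world_config(config)
  stopifnot(inherits(refs, "phage_refs"))
  with_seed(config$rng_seed + 1L, {
    np <- if (config$prophage_rate > 0) config$n_phage_genomes else 0L
    nb <- if (config$prophage_rate > 0)
      max(0L, as.integer(round(np / config$prophage_rate)) - np)
    else config$n_phage_genomes

    scaffolds <- character(0)
    info <- list(); genes <- list(); sixteen <- list()
    arrays <- list(); spacers <- list(); prophages <- list()

    pick_genus_genes <- function(genus, n) {
      pool <- refs$bacterial_genes[refs$bacterial_genes$genus == genus, ]
      pool[sample.int(nrow(pool), n), ]
    }

    # --- purely bacterial scaffolds -----------------------------------
    has_array <- rep(FALSE, nb)
    if (nb > 0L && config$crispr_rate > 0)
      has_array[sample.int(nb, round(config$crispr_rate * nb))] <- TRUE
    for (i in seq_len(nb)) {
      id <- sprintf("scf_b%03d", i)
      genus <- refs$genera[((i - 1L) %% length(refs$genera)) + 1L]
      len <- sample(config$bacterial_scaffold_len_range[1]:
                    config$bacterial_scaffold_len_range[2], 1L)
      seq <- random_dna(len)

      g <- pick_genus_genes(genus, 2L)
      n16 <- sample(config$n_16s_copies_range[1]:config$n_16s_copies_range[2], 1L)
      rib <- refs$ribosomal_db[[paste0("16S_", genus)]]

      feat_seqs <- c(paste0("TAA", g$cds),
                     rep(rib, n16))
      feat_kind <- c(rep("gene", 2L), rep("16s", n16))
      if (has_array[i]) {
        arr <- build_crispr_array(config, refs, genus, id,
                                  sprintf("array_%03d", length(arrays) + 1L))
        feat_seqs <- c(feat_seqs, arr$seq)
        feat_kind <- c(feat_kind, "array")
      }
      starts <- place_features(len, nchar(feat_seqs))
      for (f in seq_along(feat_seqs))
        substr(seq, starts[f] + 1L, starts[f] + nchar(feat_seqs[f])) <-
          feat_seqs[f]

      gi <- which(feat_kind == "gene")
      genes[[length(genes) + 1L]] <- data.frame(
        scaffold_id = id, start = starts[gi] + 3L,
        end = starts[gi] + nchar(feat_seqs[gi]),
        protein = g$protein, source = "bacterial", label = genus,
        stringsAsFactors = FALSE)
      si <- which(feat_kind == "16s")
      if (length(si))
        sixteen[[length(sixteen) + 1L]] <- data.frame(
          scaffold_id = id, start = starts[si],
          end = starts[si] + nchar(feat_seqs[si]), genus = genus,
          stringsAsFactors = FALSE)
      ai <- which(feat_kind == "array")
      if (length(ai)) {
        arr$truth$start <- arr$truth$start + starts[ai]
        arr$truth$end <- arr$truth$end + starts[ai]
        arr$spacers$start <- arr$spacers$start + starts[ai]
        arr$spacers$end <- arr$spacers$end + starts[ai]
        arrays[[length(arrays) + 1L]] <- arr$truth
        spacers[[length(spacers) + 1L]] <- arr$spacers
      }
      scaffolds[id] <- seq
      info[[length(info) + 1L]] <- data.frame(
        scaffold_id = id, length = len, type = "bacterial", genus = genus,
        phage_id = NA_character_, stringsAsFactors = FALSE)
    }

    # --- prophage-bearing scaffolds -----------------------------------
    for (i in seq_len(np)) {
      id <- sprintf("scf_p%03d", i)
      pid <- refs$taxonomy$phage_id[i]
      genus <- refs$taxonomy$host_genus[i]
      genome <- refs$genomes[[pid]]
      fl <- sample(config$prophage_flank_len_range[1]:
                   config$prophage_flank_len_range[2], 2L, replace = TRUE)
      g <- pick_genus_genes(genus, 1L)
      ins <- paste0("TAA", g$cds)
      if (fl[1] < nchar(ins) + 2L)
        stopf("generation error: prophage flank (%d bp) too short to host a %d bp gene",
              fl[1], nchar(ins))
      left <- random_dna(fl[1]); right <- random_dna(fl[2])
      gs <- sample.int(fl[1] - nchar(ins) - 1L, 1L)  # 0-based within left flank
      substr(left, gs + 1L, gs + nchar(ins)) <- ins
      seq <- paste0(left, genome, right)
      scaffolds[id] <- seq
      prophages[[length(prophages) + 1L]] <- data.frame(
        scaffold_id = id, start = fl[1], end = fl[1] + nchar(genome),
        phage_id = pid, stringsAsFactors = FALSE)
      genes[[length(genes) + 1L]] <- rbind(
        data.frame(scaffold_id = id, start = gs + 3L, end = gs + nchar(ins),
                   protein = g$protein, source = "bacterial", label = genus,
                   stringsAsFactors = FALSE),
        {
          mk <- refs$marker_genes[refs$marker_genes$phage_id == pid, ]
          data.frame(scaffold_id = id, start = mk$start + fl[1],
                     end = mk$end + fl[1], protein = mk$protein,
                     source = "phage",
                     label = refs$taxonomy$family[i], stringsAsFactors = FALSE)
        })
      info[[length(info) + 1L]] <- data.frame(
        scaffold_id = id, length = nchar(seq), type = "prophage",
        genus = genus, phage_id = pid, stringsAsFactors = FALSE)
    }

    scaffold_info <- do.call(rbind, info)
    n <- config$n_samples_per_group
    sample_groups <- data.frame(
      sample_id = c(sprintf("ctrl_%02d", seq_len(n)),
                    sprintf("case_%02d", seq_len(n))),
      group = rep(c("control", "case"), each = n), stringsAsFactors = FALSE)

    potus <- define_potus(refs$taxonomy)
    planted_effects <- data.frame(phage_id = character(0),
                                  potu_id = character(0),
                                  fold_change = numeric(0))
    if (length(config$effect_potus)) {
      eff_ids <- names(config$effect_potus)
      miss <- setdiff(eff_ids, refs$taxonomy$phage_id)
      if (length(miss))
        stopf("invalid world_config: unknown effect phage id(s): %s",
              paste(miss, collapse = ", "))
      planted_effects <- data.frame(
        phage_id = eff_ids,
        potu_id = potus$potu_id[vapply(eff_ids, function(p)
          which(vapply(potus$members, function(m) p %in% m, TRUE))[1], 1L)],
        fold_change = unname(config$effect_potus), stringsAsFactors = FALSE)
    }

    truth <- list(
      prophage_intervals = rbind_or_empty(prophages,
        c("scaffold_id", "start", "end", "phage_id")),
      crispr_arrays = rbind_or_empty(arrays,
        c("array_id", "scaffold_id", "start", "end", "repeat_consensus")),
      spacer_origins = rbind_or_empty(spacers,
        c("array_id", "scaffold_id", "spacer_index", "spacer_id", "start",
          "end", "seq", "source_phage_id", "source_pos")),
      planted_genes = do.call(rbind, genes),
      sixteen_s = rbind_or_empty(sixteen,
        c("scaffold_id", "start", "end", "genus")),
      phage_taxonomy = refs$taxonomy,
      sample_groups = sample_groups,
      planted_effects = planted_effects)

    structure(list(scaffolds = scaffolds, scaffold_info = scaffold_info,
                   truth = truth),
              class = "phage_community")
  })
}

rbind_or_empty <- function(lst, cols) {
  if (length(lst)) {
    out <- do.call(rbind, lst); rownames(out) <- NULL; out
  } else {
    out <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)),
                                         cols))
    out
  }
}

# Build one CRISPR array for a scaffold of `genus`; coordinates relative to
# the array start (shifted by the caller once placed).
build_crispr_array <- function(config, refs, genus, scaffold_id, array_id) {
  nr <- config$n_repeats_per_array
  rl <- config$repeat_len
  sl <- config$spacer_len
  rep_seq <- random_dna(rl)
  cand <- refs$taxonomy$phage_id[refs$taxonomy$host_genus == genus]
  if (!length(cand)) cand <- refs$taxonomy$phage_id
  src <- sample(cand, nr - 1L, replace = TRUE)
  sp_seq <- character(nr - 1L); sp_pos <- integer(nr - 1L)
  for (j in seq_len(nr - 1L)) {
    genome <- refs$genomes[[src[j]]]
    p0 <- sample.int(nchar(genome) - sl + 1L, 1L) - 1L
    sp_pos[j] <- p0
    sp_seq[j] <- mutate_bases(substr(genome, p0 + 1L, p0 + sl),
                              config$spacer_mutations)
  }
  seq <- paste0(rep_seq, paste0(sp_seq, rep_seq, collapse = ""))
  period <- rl + sl
  rep_starts <- (seq_len(nr) - 1L) * period
  sp_starts <- rep_starts[-nr] + rl
  list(
    seq = seq,
    truth = data.frame(array_id = array_id, scaffold_id = scaffold_id,
                       start = 0L, end = nchar(seq),
                       repeat_consensus = rep_seq, stringsAsFactors = FALSE),
    spacers = data.frame(array_id = array_id, scaffold_id = scaffold_id,
                         spacer_index = seq_len(nr - 1L) - 1L,
                         spacer_id = sprintf("%s_s%d", array_id,
                                             seq_len(nr - 1L) - 1L),
                         start = sp_starts, end = sp_starts + sl,
                         seq = sp_seq, source_phage_id = src,
                         source_pos = sp_pos, stringsAsFactors = FALSE))
}

#' Simulate WCMS and VLP reads with recorded origins
#'
#' Whole-community (WCMS) reads are drawn from the scaffold catalog with
#' per-sample lognormal abundance weights; scaffolds whose prophage belongs
#' to an effect pOTU have their weight multiplied by the planted fold change
#' in case samples.  VLP reads are drawn from the phage genomes only
#' (phage-enriched sequencing).  Reads are error-free unless
#' `config$read_error_rate > 0`.  Every read's origin (scaffold/genome,
#' interval, strand) is recorded, together with per-sample totals including
#' the true number of 16S-derived reads, and a per-sample bacterial genus
#' profile derived from non-prophage read origins.
#'
#' @param config a [world_config()].
#' @param community output of [generate_community()].
#' @param refs output of [generate_references()].
#' @return A list of class `phage_reads`: `wcms` and `vlp` (named lists of
#'   named character vectors per sample), `origins`, `vlp_origins`,
#'   `genus_profile` (samples x genera matrix) and `per_sample_totals`.
#' @export
simulate_reads <- function(config, community, refs) {
  validate_world_config(config)
  stopifnot(inherits(community, "phage_community"))
  with_seed(config$rng_seed + 2L, {
    rl <- config$read_len
    sg <- community$truth$sample_groups
    si <- community$scaffold_info
    eff <- community$truth$planted_effects
    scf <- community$scaffolds
    eligible <- si$length >= rl

    pro <- community$truth$prophage_intervals
    s16 <- community$truth$sixteen_s
    mk <- refs$marker_genes

    wcms <- list(); vlp <- list()
    origins <- list(); vlp_origins <- list(); totals <- list()
    genus_profile <- matrix(0, nrow(sg), length(refs$genera),
                            dimnames = list(sg$sample_id, refs$genera))
    genus_counts <- matrix(0L, nrow(sg), length(refs$genera),
                           dimnames = list(sg$sample_id, refs$genera))

    for (s in seq_len(nrow(sg))) {
      sid <- sg$sample_id[s]
      case <- sg$group[s] == "case"
      w <- stats::rlnorm(nrow(si), 0, config$abundance_sdlog)
      if (case && nrow(eff))
        w <- w * ifelse(!is.na(si$phage_id) & si$phage_id %in% eff$phage_id,
                        eff$fold_change[match(si$phage_id, eff$phage_id)], 1)
      w[is.na(w)] <- 0

      # WCMS reads
      n <- config$reads_per_sample
      if (n > 0L && any(eligible)) {
        p <- w * pmax(si$length - rl + 1L, 0L) * eligible
        cnt <- as.vector(stats::rmultinom(1L, n, p))
        idx <- rep.int(seq_len(nrow(si)), cnt)
        starts <- vapply(seq_along(idx), function(k)
          sample.int(si$length[idx[k]] - rl + 1L, 1L) - 1L, 1L)
        strand <- sample(c("+", "-"), length(idx), replace = TRUE)
        seqs <- substring(scf[si$scaffold_id[idx]], starts + 1L, starts + rl)
        if (any(strand == "-"))
          seqs[strand == "-"] <- revcomp(seqs[strand == "-"])
        if (config$read_error_rate > 0)
          seqs <- vapply(seqs, function(x)
            mutate_bases(x, stats::rbinom(1L, rl, config$read_error_rate)), "",
            USE.NAMES = FALSE)
        ids <- sprintf("%s_r%05d", sid, seq_along(idx))
        names(seqs) <- ids
        wcms[[sid]] <- seqs
        org <- data.frame(sample_id = sid, read_id = ids,
                          scaffold_id = si$scaffold_id[idx],
                          start = starts, end = starts + rl, strand = strand,
                          stringsAsFactors = FALSE)
        org$is_16s <- interval_within(org, s16)
        org$from_prophage <- interval_overlaps(org, pro)
        org$marker_phage <- marker_phage_of(org, mk, pro)
        origins[[sid]] <- org
        bac <- org[!org$from_prophage, , drop = FALSE]
        if (nrow(bac)) {
          tab <- table(si$genus[match(bac$scaffold_id, si$scaffold_id)])
          genus_counts[sid, names(tab)] <- as.integer(tab)
          genus_profile[sid, names(tab)] <- as.numeric(tab) / nrow(org)
        }
      } else {
        wcms[[sid]] <- character(0)
      }

      # VLP reads (phage genomes only)
      nv <- config$vlp_reads_per_sample
      glen <- nchar(refs$genomes)
      if (nv > 0L && length(glen)) {
        wv <- stats::rlnorm(length(glen), 0, config$abundance_sdlog)
        if (case && nrow(eff)) {
          m <- match(names(refs$genomes), eff$phage_id)
          wv <- wv * ifelse(is.na(m), 1, eff$fold_change[m])
        }
        pv <- wv * pmax(glen - rl + 1L, 0L)
        cntv <- as.vector(stats::rmultinom(1L, nv, pv))
        idxv <- rep.int(seq_along(glen), cntv)
        startsv <- vapply(seq_along(idxv), function(k)
          sample.int(glen[idxv[k]] - rl + 1L, 1L) - 1L, 1L)
        strandv <- sample(c("+", "-"), length(idxv), replace = TRUE)
        seqsv <- substring(refs$genomes[idxv], startsv + 1L, startsv + rl)
        if (any(strandv == "-"))
          seqsv[strandv == "-"] <- revcomp(seqsv[strandv == "-"])
        idsv <- sprintf("%s_v%05d", sid, seq_along(idxv))
        names(seqsv) <- idsv
        vlp[[sid]] <- seqsv
        vlp_origins[[sid]] <- data.frame(
          sample_id = sid, read_id = idsv,
          phage_id = names(refs$genomes)[idxv],
          start = startsv, end = startsv + rl, strand = strandv,
          stringsAsFactors = FALSE)
      } else {
        vlp[[sid]] <- character(0)
      }

      totals[[sid]] <- data.frame(
        sample_id = sid, group = sg$group[s],
        n_wcms = length(wcms[[sid]]), n_vlp = length(vlp[[sid]]),
        n_16s_true = if (!is.null(origins[[sid]])) sum(origins[[sid]]$is_16s)
                     else 0L,
        stringsAsFactors = FALSE)
    }

    structure(list(
      wcms = wcms, vlp = vlp,
      origins = if (length(origins)) do.call(rbind, origins) else NULL,
      vlp_origins = if (length(vlp_origins)) do.call(rbind, vlp_origins)
                    else NULL,
      genus_profile = genus_profile,
      genus_counts = genus_counts,
      per_sample_totals = do.call(rbind, c(totals,
                                           list(make.row.names = FALSE)))),
      class = "phage_reads")
  })
}

# TRUE when the query interval on its scaffold lies fully inside a feature
# interval of `feats` on the same scaffold.
interval_within <- function(q, feats) {
  if (!nrow(feats)) return(rep(FALSE, nrow(q)))
  out <- rep(FALSE, nrow(q))
  for (sc in unique(q$scaffold_id)) {
    f <- feats[feats$scaffold_id == sc, , drop = FALSE]
    if (!nrow(f)) next
    qi <- which(q$scaffold_id == sc)
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(q$start[qi] + 1L, q$end[qi]),
      IRanges::IRanges(f$start + 1L, f$end), type = "within")
    out[qi[unique(S4Vectors::queryHits(ov))]] <- TRUE
  }
  out
}

interval_overlaps <- function(q, feats) {
  if (!nrow(feats)) return(rep(FALSE, nrow(q)))
  out <- rep(FALSE, nrow(q))
  for (sc in unique(q$scaffold_id)) {
    f <- feats[feats$scaffold_id == sc, , drop = FALSE]
    if (!nrow(f)) next
    qi <- which(q$scaffold_id == sc)
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(q$start[qi] + 1L, q$end[qi]),
      IRanges::IRanges(f$start + 1L, f$end))
    out[qi[unique(S4Vectors::queryHits(ov))]] <- TRUE
  }
  out
}

# For reads on prophage scaffolds, the phage id of the marker CDS the read
# falls fully inside (NA otherwise); used only for truth checks.
marker_phage_of <- function(org, markers, prophages) {
  out <- rep(NA_character_, nrow(org))
  if (!nrow(prophages)) return(out)
  for (k in seq_len(nrow(prophages))) {
    pr <- prophages[k, ]
    mk <- markers[markers$phage_id == pr$phage_id, , drop = FALSE]
    if (!nrow(mk)) next
    qi <- which(org$scaffold_id == pr$scaffold_id)
    if (!length(qi)) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(org$start[qi] + 1L, org$end[qi]),
      IRanges::IRanges(mk$start + pr$start + 1L, mk$end + pr$start),
      type = "within")
    out[qi[S4Vectors::queryHits(ov)]] <- pr$phage_id
  }
  out
}
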