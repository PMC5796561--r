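# End-to-end orchestration of the phageome pipeline on a synthetic world
# (or on pre-built inputs), with a run manifest and report writers.

#' Default pipeline parameters
#'
#' Every screening threshold of the pipeline with its standard value: the
#' 10 kb large-scaffold cutoff, the 0.40 VLP and 0.30 known-genome breadth
#' thresholds, the 1e-05 homology e-value cutoff (1e-10 for conserved-domain
#' style searches), the >0.5 PFR and >=0.7 BGR voting thresholds, the strict
#' prevalence/core detection counts, and the r > 0.3 / p < 0.01 network and
#' p < 0.05 / FDR < 0.25 significance filters.
#'
#' @param ... overrides of the defaults.
#' @return named list of parameters.
#' @export
pipeline_params <- function(...) {
  defaults <- list(
    min_scaffold_len = 10000L,
    vlp_breadth = 0.40,          # inclusive (>=)
    enadb_breadth = 0.30,        # strict (>)
    evalue_max = 1e-05,
    evalue_domain = 1e-10,
    pfr_threshold = 0.5,         # strict (>)
    bgr_threshold = 0.7,         # inclusive (>=)
    min_phage_genes = 1L,
    ambiguity_factor = 2,
    min_aa = 33L,
    kmer_protein = 4L,
    seed_len = 21L,
    min_identity = 0.95,
    spacer_max_mismatch = 1L,
    coocc_r_threshold = 0.3,     # strict (>)
    coocc_p_threshold = 0.01,    # strict (<)
    coocc_n_perm = 200L,
    p_threshold = 0.05,
    q_threshold = 0.25,
    include_vlp = TRUE
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stopf("unknown pipeline parameter(s): %s", paste(unknown, collapse = ", "))
  utils::modifyList(defaults, over)
}

#' Run the whole phageome pipeline on a synthetic world
#'
#' Executes the stages in dependency order: reference/community/read
#' generation, gene calling, homology search, CRISPR detection and spacer
#' matching, three-strategy phage discovery with the ambiguity screen,
#' PFR/BGR taxonomic assignment, LST identification, pOTU profiling
#' normalized by 16S reads, phage-host network construction, phage load,
#' group-wise differential tests, richness/rarefaction, and the
#' co-occurrence network.  Deterministic stages reproduce byte-identical
#' outputs for the same config.
#'
#' @param config a [world_config()].
#' @param params a [pipeline_params()] list.
#' @param run_cooccurrence set `FALSE` to skip the (permutation-heavy)
#'   co-occurrence stage.
#' @return object of class `phageome_run`.
#' @export
run_phageome <- function(config = world_config(),
                         params = pipeline_params(),
                         run_cooccurrence = TRUE) {
  log_stage <- function(fmt, ...) message(sprintf(paste0("[phageome] ", fmt), ...))

  log_stage("generating references (%d phage genomes, %d genera)",
            config$n_phage_genomes, config$n_bacterial_genera)
  refs <- generate_references(config)
  community <- generate_community(config, refs)
  reads <- simulate_reads(config, community, refs)
  scaffolds <- community$scaffolds
  info <- community$scaffold_info
  log_stage("community: %d scaffolds (%d prophage-bearing), %d+%d samples",
            nrow(info), sum(info$type == "prophage"),
            config$n_samples_per_group, config$n_samples_per_group)

  large <- large_scaffolds(info, params$min_scaffold_len)

  # gene calling + homology over the mixed protein database
  genes <- call_orfs_set(scaffolds, min_aa = params$min_aa)
  prot_db <- stats::setNames(refs$protein_db$protein,
                             refs$protein_db$protein_id)
  hits <- naive_protein_search(stats::setNames(genes$protein, genes$gene_id),
                               prot_db, k = params$kmer_protein,
                               max_evalue = params$evalue_max)
  src <- stats::setNames(refs$protein_db$source, refs$protein_db$protein_id)
  phage_hits <- hits[src[hits$subject_id] == "phage", , drop = FALSE]
  bact_hits <- hits[src[hits$subject_id] == "bacterial", , drop = FALSE]
  log_stage("genes: %d called, %d with hits at e <= %.0e",
            nrow(genes), length(unique(hits$query_id)), params$evalue_max)

  # CRISPR arrays and spacer matching against large scaffolds
  arrays <- detect_arrays_set(scaffolds)
  membership <- stats::setNames(
    rep(list(community$truth$sample_groups$sample_id), nrow(info)),
    info$scaffold_id)
  matches <- if (!is.null(arrays$spacers) && nrow(arrays$spacers))
    match_spacers(arrays$spacers, scaffolds[large],
                  max_mismatch = params$spacer_max_mismatch,
                  sample_membership = membership)
  else
    match_spacers(data.frame(spacer_id = character(0), seq = character(0)),
                  scaffolds[large])
  log_stage("CRISPR: %d arrays, %d spacers, %d spacer matches",
            if (is.null(arrays$arrays)) 0L else nrow(arrays$arrays),
            if (is.null(arrays$spacers)) 0L else nrow(arrays$spacers),
            nrow(matches))

  # VLP coverage of large scaffolds (reads pooled over samples)
  vlp_cov <- NULL
  set_ii <- character(0)
  if (params$include_vlp) {
    vlp_all <- unlist(unname(reads$vlp))
    vlp_aln <- if (length(vlp_all))
      map_reads(vlp_all, scaffolds[large], seed_len = params$seed_len,
                min_identity = params$min_identity)
    else NULL
    vlp_cov <- coverage_stats(
      vlp_aln %||% data.frame(read_id = character(0), ref_id = character(0),
                              ref_start = integer(0), ref_end = integer(0)),
      stats::setNames(info$length, info$scaffold_id)[large])
    set_ii <- strategy_vlp(large, vlp_cov, params$vlp_breadth)
  }

  sets <- list(I = strategy_spacer(large, matches),
               II = set_ii,
               III = strategy_homology(large, genes, phage_hits,
                                       params$min_phage_genes))
  calls <- merge_and_screen(sets, genes, hits, src, info,
                            params$ambiguity_factor)
  accepted <- accepted_scaffolds(calls)
  log_stage("discovery: I=%d II=%d III=%d -> %d candidates, %d accepted",
            length(sets$I), length(sets$II), length(sets$III),
            nrow(calls$calls), length(accepted))

  # taxonomy: PFR for accepted phage scaffolds, BGR for the other large
  # scaffolds (the putative bacterial ones)
  fam_labels <- stats::setNames(refs$protein_db$label,
                                refs$protein_db$protein_id)[src == "phage"]
  gen_labels <- stats::setNames(refs$protein_db$label,
                                refs$protein_db$protein_id)[src == "bacterial"]
  tax_phage <- assign_taxonomy_set(genes, phage_hits, fam_labels,
                                   level = "family", scaffold_ids = accepted)
  bacterial_ids <- setdiff(large, accepted)
  tax_bact <- assign_taxonomy_set(genes, bact_hits, gen_labels,
                                  level = "genus",
                                  scaffold_ids = bacterial_ids)

  lst <- identify_lst(
    stats::setNames(genes$protein, genes$gene_id)[
      genes$scaffold_id %in% accepted],
    refs$lst_motifs)

  # pOTU profiling
  potus <- define_potus(refs$taxonomy)
  genome_counts <- count_genome_reads(reads$wcms, refs$marker_genes,
                                      seed_len = params$seed_len,
                                      min_identity = params$min_identity)
  n16s <- count_16s(reads$wcms, refs$ribosomal_db,
                    seed_len = params$seed_len,
                    min_identity = params$min_identity)
  profile <- potu_abundance(genome_counts, potus, n16s)
  log_stage("pOTUs: %d defined, median n16S = %s", nrow(potus),
            format(stats::median(n16s)))

  # phage-host network
  genus_map <- stats::setNames(tax_bact$label, tax_bact$scaffold_id)
  family_map <- stats::setNames(tax_phage$label, tax_phage$scaffold_id)
  net_matches <- matches[matches$target_id %in% accepted, , drop = FALSE]
  network <- build_network(net_matches, genus_map, family_map)
  specificity <- specificity_stats(network, net_matches, membership)

  # per-sample phage load from reads mapped to accepted scaffolds
  all_wcms <- unlist(unname(reads$wcms))
  totals <- stats::setNames(reads$per_sample_totals$n_wcms,
                            reads$per_sample_totals$sample_id)
  load <- list(abundance = NULL,
               load = stats::setNames(rep(0, length(totals)), names(totals)))
  if (length(all_wcms) && length(accepted) && all(totals > 0)) {
    sample_of <- rep(names(reads$wcms), lengths(reads$wcms))
    aln <- map_reads(all_wcms, scaffolds[accepted],
                     seed_len = params$seed_len,
                     min_identity = params$min_identity)
    if (nrow(aln)) {
      s_of <- sample_of[match(aln$read_id, names(all_wcms))]
      tab <- as.data.frame(table(s_of, aln$ref_id),
                           stringsAsFactors = FALSE)
      tab <- tab[tab$Freq > 0, , drop = FALSE]
      names(tab) <- c("sample_id", "scaffold_id", "n_reads")
      load <- scaffold_relative_abundance(tab, totals)
      miss <- setdiff(names(totals), names(load$load))
      if (length(miss)) load$load[miss] <- 0
      load$load <- load$load[names(totals)]
      load$load[is.na(load$load)] <- 0
    }
  }

  # group statistics
  groups <- stats::setNames(community$truth$sample_groups$group,
                            community$truth$sample_groups$sample_id)
  diff_potu <- differential_phageome(profile$abundance, groups,
                                     level = "pOTU",
                                     p_threshold = params$p_threshold,
                                     q_threshold = params$q_threshold)
  diff_family <- differential_phageome(profile$family, groups,
                                       level = "family",
                                       p_threshold = params$p_threshold,
                                       q_threshold = params$q_threshold)
  load_test <- phage_load_test(load$load, groups)
  richness <- chao2(profile$abundance)
  rare <- lapply(split(rownames(profile$abundance), groups[rownames(profile$abundance)]),
                 function(s) rarefaction(profile$abundance[s, , drop = FALSE]))
  log_stage("stats: %d/%d pOTUs significant, load p = %.3g",
            sum(diff_potu$significant), nrow(diff_potu), load_test$p)

  # co-occurrence network between bacterial genera and pOTUs
  coocc <- NULL
  if (run_cooccurrence) {
    comb <- cbind(reads$genus_counts, genome_counts)
    colnames(comb) <- c(colnames(reads$genus_counts), colnames(genome_counts))
    half <- floor(nrow(comb) / 2)
    filt <- prevalence_filter(comb, min_samples = half)
    if (ncol(filt) >= 4L) {
      rmat <- sparcc_corr(filt, seed = config$rng_seed + 10L)
      pmat <- permutation_p(filt, rmat, n_perm = params$coocc_n_perm,
                            seed = config$rng_seed + 11L)
      ntypes <- stats::setNames(
        ifelse(colnames(filt) %in% colnames(reads$genus_counts),
               "bacterium", "pOTU"), colnames(filt))
      coocc <- build_coocc_network(rmat, pmat,
                                   r_threshold = params$coocc_r_threshold,
                                   p_threshold = params$coocc_p_threshold,
                                   node_types = ntypes)
      log_stage("co-occurrence: %d nodes, %d edges",
                nrow(coocc$nodes), nrow(coocc$edges))
    } else {
      log_stage("co-occurrence skipped: fewer than 4 prevalent taxa")
    }
  }

  run <- structure(list(
    config = config, params = params, refs = refs, community = community,
    reads = reads, genes = genes, hits = hits, arrays = arrays,
    spacer_matches = matches, vlp_coverage = vlp_cov, strategy_sets = sets,
    calls = calls, taxonomy_phage = tax_phage, taxonomy_bacterial = tax_bact,
    lst = lst, potus = potus, genome_counts = genome_counts, n16s = n16s,
    profile = profile, network = network, specificity = specificity,
    load = load, diff_potu = diff_potu, diff_family = diff_family,
    load_test = load_test, richness = richness, rarefaction = rare,
    cooccurrence = coocc), class = "phageome_run")
  run$manifest <- run_manifest(run)
  run
}

# Stage counts + parameter fingerprints; checksums over key result tables.
run_manifest <- function(run) {
  checksum <- function(x) {
    f <- tempfile()
    on.exit(unlink(f))
    saveRDS(x, f, compress = FALSE)
    unname(tools::md5sum(f))
  }
  list(
    seed = run$config$rng_seed,
    params = run$params,
    n_samples = nrow(run$community$truth$sample_groups),
    n_scaffolds = nrow(run$community$scaffold_info),
    n_large_scaffolds = length(large_scaffolds(run$community$scaffold_info,
                                               run$params$min_scaffold_len)),
    n_genes = nrow(run$genes),
    n_arrays = if (is.null(run$arrays$arrays)) 0L else nrow(run$arrays$arrays),
    n_spacer_matches = nrow(run$spacer_matches),
    strategy_counts = lengths(run$strategy_sets),
    venn = run$calls$venn,
    n_accepted = length(accepted_scaffolds(run$calls)),
    n_potus = nrow(run$potus),
    vlp_enabled = run$params$include_vlp,
    checksums = c(calls = checksum(run$calls$calls),
                  abundance = checksum(run$profile$abundance),
                  taxonomy = checksum(run$taxonomy_phage)))
}

#' @export
print.phageome_run <- function(x, ...) {
  m <- x$manifest
  cat("phageome pipeline run\n")
  cat(sprintf("  %d samples, %d scaffolds (%d large), seed %d\n",
              m$n_samples, m$n_scaffolds, m$n_large_scaffolds, m$seed))
  cat(sprintf("  strategies I/II/III: %d/%d/%d; accepted phage scaffolds: %d\n",
              m$strategy_counts[["I"]], m$strategy_counts[["II"]],
              m$strategy_counts[["III"]], m$n_accepted))
  cat(sprintf("  pOTUs: %d; significant: %d; Chao2 richness: %.1f\n",
              m$n_potus, sum(x$diff_potu$significant),
              x$richness$estimate))
  if (!is.null(x$cooccurrence))
    cat(sprintf("  co-occurrence edges: %d\n", nrow(x$cooccurrence$edges)))
  invisible(x)
}

#' Write the pipeline's report files
#'
#' Emits the declared external interfaces: scaffold FASTA, call table,
#' coverage report, array/spacer-match tables, taxonomy and LST tables, the
#' abundance matrix with an n16S column, differential results, edge lists
#' (TSV + GraphML), and the JSON manifest/Venn summary.
#'
#' @param run a `phageome_run`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_run_reports <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  write_fasta(run$community$scaffolds, file.path(dir, "scaffolds.fasta"))
  tsv(run$calls$calls, "phage_calls.tsv")
  if (!is.null(run$vlp_coverage)) tsv(run$vlp_coverage, "vlp_coverage.tsv")
  if (!is.null(run$arrays$arrays)) tsv(run$arrays$arrays, "crispr_arrays.tsv")
  tsv(run$spacer_matches, "spacer_matches.tsv")
  tsv(rbind(run$taxonomy_phage, run$taxonomy_bacterial), "taxonomy.tsv")
  tsv(run$lst, "lst_calls.tsv")
  ab <- cbind(data.frame(sample_id = rownames(run$profile$abundance),
                         n16S = run$profile$n16s),
              as.data.frame(run$profile$abundance))
  tsv(ab, "potu_abundance.tsv")
  tsv(as.data.frame(run$diff_potu), "differential_potu.tsv")
  tsv(run$network$edges, "host_edges.tsv")
  if (nrow(run$network$edges))
    write_graphml(run$network$edges, file.path(dir, "host_network.graphml"))
  if (!is.null(run$cooccurrence)) {
    tsv(run$cooccurrence$edges, "coocc_edges.tsv")
    if (nrow(run$cooccurrence$edges))
      write_graphml(run$cooccurrence$edges,
                    file.path(dir, "coocc_network.graphml"),
                    node_types = stats::setNames(run$cooccurrence$nodes$type,
                                                 run$cooccurrence$nodes$id))
  }
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
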