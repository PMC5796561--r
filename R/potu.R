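# pOTU definition and 16S-normalized abundance profiling.

#' Define phage operational taxonomic units (pOTUs)
#'
#' A pOTU is the collection of all phages sharing identical taxonomy at all
#' five levels (group|order|family|subfamily|genus) and the same bacterial
#' host genus.  Missing levels must carry explicit `"unclassified_<level>"`
#' tokens.  Ids are deterministic: pOTU keys are sorted and numbered.
#'
#' @param taxonomy data.frame with columns phage_id, group, order, family,
#'   subfamily, genus, host_genus (complete, no NA).
#' @return data.frame: potu_id, potu_key
#'   (`group|order|family|subfamily|genus|host_genus`), family, host_genus,
#'   n_members, and a `members` list-column of phage ids.
#' @export
define_potus <- function(taxonomy) {
  need <- c("phage_id", "group", "order", "family", "subfamily", "genus",
            "host_genus")
  miss <- setdiff(need, names(taxonomy))
  if (length(miss))
    stopf("taxonomy table lacks column(s): %s", paste(miss, collapse = ", "))
  if (anyNA(taxonomy[need]))
    stopf("taxonomy table contains missing values; use explicit 'unclassified_<level>' tokens")
  key <- paste(taxonomy$group, taxonomy$order, taxonomy$family,
               taxonomy$subfamily, taxonomy$genus, taxonomy$host_genus,
               sep = "|")
  keys <- sort(unique(key))
  members <- lapply(keys, function(k) taxonomy$phage_id[key == k])
  out <- data.frame(
    potu_id = sprintf("V%03d", seq_along(keys)),
    potu_key = keys,
    family = vapply(strsplit(keys, "|", fixed = TRUE), `[[`, "", 3L),
    host_genus = vapply(strsplit(keys, "|", fixed = TRUE), `[[`, "", 6L),
    n_members = lengths(members), stringsAsFactors = FALSE)
  out$members <- members
  out
}

#' Count reads per (sample, phage genome) via marker genes
#'
#' Each read is assigned to at most one genome by its best nucleotide match
#' to a marker-gene CDS; reads whose equally-best hits span more than one
#' genome are discarded (tie rule).
#'
#' @param reads named list (per sample) of named read vectors.
#' @param marker_genes data.frame with gene_id, phage_id, cds.
#' @param seed_len,min_identity mapper parameters (see [map_reads()]).
#' @return integer matrix samples x genomes.
#' @export
count_genome_reads <- function(reads, marker_genes, seed_len = 21L,
                               min_identity = 0.95) {
  genomes <- unique(marker_genes$phage_id)
  counts <- matrix(0L, length(reads), length(genomes),
                   dimnames = list(names(reads), genomes))
  refs <- stats::setNames(marker_genes$cds, marker_genes$gene_id)
  all_reads <- unlist(unname(reads))
  if (!length(all_reads)) return(counts)
  sample_of <- stats::setNames(rep(names(reads), lengths(reads)),
                               names(all_reads))
  aln <- map_reads(all_reads, refs, seed_len = seed_len,
                   min_identity = min_identity, report = "all_best")
  if (!nrow(aln)) return(counts)
  aln$phage_id <- marker_genes$phage_id[match(aln$ref_id,
                                              marker_genes$gene_id)]
  per_read <- tapply(aln$phage_id, aln$read_id,
                     function(x) if (length(unique(x)) == 1L) x[1]
                                 else NA_character_)
  per_read <- per_read[!is.na(per_read)]
  tab <- table(sample_of[names(per_read)], unname(per_read))
  counts[rownames(tab), colnames(tab)] <- tab
  counts
}

#' Count 16S rRNA gene reads per sample
#'
#' Reads mapping to any 16S reference are counted once.  Samples with zero
#' 16S reads are flagged with a warning; their pOTU values become missing in
#' [potu_abundance()].
#'
#' @param reads named list (per sample) of named read vectors.
#' @param ribosomal_db named character vector of 16S-like references.
#' @param seed_len,min_identity mapper parameters.
#' @return named integer vector per sample.
#' @export
count_16s <- function(reads, ribosomal_db, seed_len = 21L,
                      min_identity = 0.95) {
  if (!length(ribosomal_db)) stopf("empty 16S reference set")
  out <- stats::setNames(integer(length(reads)), names(reads))
  all_reads <- unlist(unname(reads))
  if (length(all_reads)) {
    sample_of <- stats::setNames(rep(names(reads), lengths(reads)),
                                 names(all_reads))
    aln <- map_reads(all_reads, ribosomal_db, seed_len = seed_len,
                     min_identity = min_identity, report = "best")
    if (nrow(aln)) {
      tab <- table(sample_of[unique(aln$read_id)])
      out[names(tab)] <- as.integer(tab)
    }
  }
  if (any(out == 0L))
    warning(sprintf("sample(s) with zero 16S reads: %s",
                    paste(names(out)[out == 0L], collapse = ", ")),
            call. = FALSE)
  out
}

#' 16S-normalized pOTU abundance matrix
#'
#' The relative number of a pOTU in a sample is the sum of read counts of
#' all member genomes divided by the sample's 16S read count.  Values are
#' deliberately not renormalized across pOTUs.  A family-level rollup sums
#' the pOTUs sharing a family label.
#'
#' @param genome_counts matrix samples x genomes ([count_genome_reads()]).
#' @param potus data.frame from [define_potus()].
#' @param n16s named vector of per-sample 16S read counts.
#' @return list with `abundance` (samples x pOTUs matrix; rows with
#'   `n16s == 0` are NA), `family` (samples x families rollup) and `n16s`.
#' @export
potu_abundance <- function(genome_counts, potus, n16s) {
  samples <- rownames(genome_counts)
  stopifnot(!is.null(samples), all(samples %in% names(n16s)))
  ab <- matrix(0, length(samples), nrow(potus),
               dimnames = list(samples, potus$potu_id))
  for (i in seq_len(nrow(potus))) {
    mem <- intersect(potus$members[[i]], colnames(genome_counts))
    if (length(mem))
      ab[, i] <- rowSums(genome_counts[, mem, drop = FALSE])
  }
  ab <- sweep(ab, 1L, n16s[samples], "/")
  ab[n16s[samples] == 0L, ] <- NA_real_
  fams <- sort(unique(potus$family))
  fam <- vapply(fams, function(f)
    rowSums(ab[, potus$potu_id[potus$family == f], drop = FALSE]),
    numeric(length(samples)))
  if (is.null(dim(fam))) fam <- matrix(fam, nrow = length(samples),
                                       dimnames = list(samples, fams))
  list(abundance = ab, family = fam, n16s = n16s[samples])
}
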