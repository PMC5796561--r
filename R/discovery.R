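# Large-phage-scaffold discovery: three evidence strategies over scaffolds
# >= 10 kb, a codified ambiguity screen, and per-strategy Venn counts.

#' Scaffolds eligible for phage discovery
#' @param scaffold_info data.frame with scaffold_id and length.
#' @param min_length large-scaffold cutoff, bp (default 10000).
#' @return character vector of scaffold ids with length >= `min_length`.
#' @export
large_scaffolds <- function(scaffold_info, min_length = 10000L) {
  scaffold_info$scaffold_id[scaffold_info$length >= min_length]
}

#' Strategy I: scaffolds probed by CRISPR spacers
#'
#' A scaffold qualifies when at least one spacer from a *different*
#' scaffold's array matches it (self-targeting matches are ignored).
#'
#' @param candidates character vector of eligible scaffold ids (>= 10 kb).
#' @param spacer_matches data.frame from [match_spacers()].
#' @return character vector of scaffold ids.
#' @export
strategy_spacer <- function(candidates, spacer_matches) {
  if (!nrow(spacer_matches)) return(character(0))
  m <- spacer_matches[is.na(spacer_matches$source_scaffold_id) |
                        spacer_matches$source_scaffold_id !=
                        spacer_matches$target_id, , drop = FALSE]
  intersect(candidates, unique(m$target_id))
}

#' Strategy II: scaffolds with high VLP breadth of coverage
#'
#' Scaffolds mapped by virus-like-particle metagenomic reads with a breadth
#' of coverage >= `min_breadth` (inclusive threshold, default 0.40).
#'
#' @param candidates character vector of eligible scaffold ids.
#' @param vlp_coverage data.frame from [coverage_stats()] on VLP reads.
#' @param min_breadth inclusive breadth threshold (default 0.40).
#' @return character vector of scaffold ids.
#' @export
strategy_vlp <- function(candidates, vlp_coverage, min_breadth = 0.40) {
  intersect(candidates,
            select_covered(vlp_coverage, min_breadth, comparator = ">="))
}

#' Strategy III: scaffolds encoding genes homologous to known phage genes
#'
#' @param candidates character vector of eligible scaffold ids.
#' @param genes gene table ([call_orfs_set()]) mapping gene_id to scaffold_id.
#' @param phage_hits hit table of genes vs a phage protein set, already
#'   filtered to the working e-value cutoff (1e-05).
#' @param min_phage_genes minimum phage-gene hits per scaffold (default 1).
#' @return character vector of scaffold ids.
#' @export
strategy_homology <- function(candidates, genes, phage_hits,
                              min_phage_genes = 1L) {
  if (!nrow(phage_hits)) return(character(0))
  g <- unique(phage_hits$query_id)
  scf <- genes$scaffold_id[match(g, genes$gene_id)]
  tab <- table(scf)
  intersect(candidates, names(tab[tab >= min_phage_genes]))
}

#' Merge strategy candidates and apply the ambiguity screen
#'
#' Takes the union of the three strategy sets and discards candidates whose
#' genes look predominantly bacterial: a candidate is
#' `discarded_ambiguous` when the summed bit-score of its genes against
#' bacterial-source proteins exceeds the summed bit-score against
#' phage-source proteins by more than `ambiguity_factor` (a codified,
#' deterministic stand-in for the study's manual check).  Venn counts over
#' the three strategies are emitted alongside the calls.
#'
#' @param sets named list of character vectors: `I`, `II`, `III`.
#' @param genes gene table mapping gene_id to scaffold_id.
#' @param mixed_hits hit table of genes vs the mixed bacterial+phage protein
#'   database (already e-value filtered).
#' @param protein_sources named character vector: protein_id -> source
#'   (`"phage"` or `"bacterial"`).
#' @param scaffold_info data.frame with scaffold_id and length.
#' @param ambiguity_factor bacterial/phage bit-score ratio above which a
#'   candidate is discarded (default 2).
#' @return list of class `phage_calls`: `calls` (scaffold_id, length,
#'   strategies, status, n_spacer_hits, vlp_breadth, n_phage_gene_hits,
#'   bacterial_score, phage_score) and `venn` (named counts over the 7
#'   strategy combinations).
#' @export
merge_and_screen <- function(sets, genes, mixed_hits, protein_sources,
                             scaffold_info, ambiguity_factor = 2) {
  stopifnot(all(c("I", "II", "III") %in% names(sets)))
  union_ids <- sort(unique(unlist(sets)))
  strategies <- vapply(union_ids, function(id)
    paste(c("I", "II", "III")[c(id %in% sets$I, id %in% sets$II,
                                id %in% sets$III)], collapse = "+"), "")

  # bacterial vs phage summed bit-scores per candidate scaffold
  bsc <- psc <- stats::setNames(numeric(length(union_ids)), union_ids)
  if (nrow(mixed_hits)) {
    src <- protein_sources[mixed_hits$subject_id]
    scf <- genes$scaffold_id[match(mixed_hits$query_id, genes$gene_id)]
    keep <- scf %in% union_ids & !is.na(src)
    if (any(keep)) {
      agg <- tapply(mixed_hits$bitscore[keep],
                    list(scf[keep], src[keep]), sum)
      if ("bacterial" %in% colnames(agg)) {
        v <- agg[, "bacterial"]; v[is.na(v)] <- 0
        bsc[rownames(agg)] <- v
      }
      if ("phage" %in% colnames(agg)) {
        v <- agg[, "phage"]; v[is.na(v)] <- 0
        psc[rownames(agg)] <- v
      }
    }
  }
  status <- ifelse(bsc > ambiguity_factor * psc,
                   "discarded_ambiguous", "accepted")

  calls <- data.frame(
    scaffold_id = union_ids,
    length = scaffold_info$length[match(union_ids,
                                        scaffold_info$scaffold_id)],
    strategies = strategies, status = status,
    bacterial_score = unname(bsc), phage_score = unname(psc),
    stringsAsFactors = FALSE)
  rownames(calls) <- NULL

  combos <- c("I", "II", "III", "I+II", "I+III", "II+III", "I+II+III")
  venn <- stats::setNames(integer(length(combos)), combos)
  tab <- table(strategies)
  venn[names(tab)] <- as.integer(tab)

  structure(list(calls = calls, venn = venn), class = "phage_calls")
}

#' @export
print.phage_calls <- function(x, ...) {
  cat(sprintf("Phage scaffold calls: %d candidates, %d accepted, %d discarded as ambiguous\n",
              nrow(x$calls), sum(x$calls$status == "accepted"),
              sum(x$calls$status == "discarded_ambiguous")))
  cat("Strategy Venn counts:\n")
  print(x$venn)
  invisible(x)
}

#' Accepted phage scaffold ids
#' @param calls a `phage_calls` object.
#' @return character vector.
#' @export
accepted_scaffolds <- function(calls) {
  calls$calls$scaffold_id[calls$calls$status == "accepted"]
}
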