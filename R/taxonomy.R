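# Weighted-vote taxonomic assignment: phage family ratio (PFR) and bacterial
# genus ratio (BGR), plus large-subunit terminase (LST) identification.

# Core weighted vote shared by PFR and BGR.  Per gene, hits are ranked by
# ascending e-value (ties: descending bitscore, then subject id); the
# top-ranked distinct subject contributes 1.0 and the second 0.5 to its
# label's score.  The ratio is the winning label's share of all scores.
weighted_vote <- function(hits, subject_labels, threshold, strict) {
  if (!nrow(hits))
    return(list(label = "unclassified", ratio = 0, gene_votes = 0L,
                scores = numeric(0)))
  hits <- hits[order(hits$query_id, hits$evalue, -hits$bitscore,
                     hits$subject_id), , drop = FALSE]
  scores <- numeric(0)
  genes <- unique(hits$query_id)
  for (g in genes) {
    h <- hits[hits$query_id == g, , drop = FALSE]
    h <- h[!duplicated(h$subject_id), , drop = FALSE]
    w <- c(1, 0.5)[seq_len(min(2L, nrow(h)))]
    lab <- subject_labels[h$subject_id[seq_along(w)]]
    for (j in seq_along(w)) {
      if (is.na(lab[j])) next
      scores[lab[j]] <- (if (lab[j] %in% names(scores)) scores[[lab[j]]] else 0) + w[j]
    }
  }
  if (!length(scores) || sum(scores) == 0)
    return(list(label = "unclassified", ratio = 0, gene_votes = length(genes),
                scores = scores))
  ratio <- max(scores) / sum(scores)
  # deterministic argmax: alphabetical first among tied maxima
  top <- sort(names(scores)[scores == max(scores)])[1]
  pass <- if (strict) ratio > threshold else ratio >= threshold
  list(label = if (pass) top else "unclassified", ratio = ratio,
       gene_votes = length(genes), scores = scores)
}

#' Assign a phage family to a scaffold by the phage family ratio (PFR)
#'
#' Only genes with at least one hit vote.  Each voting gene contributes 1.0
#' for its top hit's family and 0.5 for its second hit's family (top two
#' distinct subject proteins, ranked by ascending e-value with bitscore then
#' subject-id tiebreaks).  The PFR of a family is its summed score divided by
#' the scaffold's total score; the scaffold is assigned to the maximal family
#' if its PFR is strictly greater than 0.5 and is `"unclassified"` otherwise.
#'
#' @param hits hit table (gene vs taxon-labeled phage proteins) for one
#'   scaffold, already filtered to e-value <= 1e-05.
#' @param subject_families named character vector: protein id -> family.
#' @param scaffold_id id recorded in the output.
#' @param threshold PFR threshold (default 0.5, strict).
#' @return one-row data.frame: scaffold_id, level, label, ratio, gene_votes.
#' @export
assign_phage_family <- function(hits, subject_families, scaffold_id = NA,
                                threshold = 0.5) {
  v <- weighted_vote(hits, subject_families, threshold, strict = TRUE)
  data.frame(scaffold_id = scaffold_id, level = "family", label = v$label,
             ratio = v$ratio, gene_votes = v$gene_votes,
             stringsAsFactors = FALSE)
}

#' Assign a bacterial genus to a scaffold by the bacterial genus ratio (BGR)
#'
#' Same weighted vote as [assign_phage_family()] over genus labels; the
#' genus is assigned when the BGR is at least 0.70 (inclusive threshold).
#'
#' @param hits hit table (gene vs genus-labeled proteins) for one scaffold.
#' @param subject_genera named character vector: protein id -> genus.
#' @param scaffold_id id recorded in the output.
#' @param threshold BGR threshold (default 0.7, inclusive).
#' @return one-row data.frame: scaffold_id, level, label, ratio, gene_votes.
#' @export
assign_bacterial_genus <- function(hits, subject_genera, scaffold_id = NA,
                                   threshold = 0.7) {
  v <- weighted_vote(hits, subject_genera, threshold, strict = FALSE)
  data.frame(scaffold_id = scaffold_id, level = "genus", label = v$label,
             ratio = v$ratio, gene_votes = v$gene_votes,
             stringsAsFactors = FALSE)
}

#' Assign taxonomy for many scaffolds at once
#'
#' @param genes gene table mapping gene_id to scaffold_id.
#' @param hits hit table across all genes (e-value filtered).
#' @param subject_labels named character vector: protein id -> label.
#' @param level `"family"` (PFR, strict > 0.5) or `"genus"`
#'   (BGR, >= 0.7).
#' @param scaffold_ids scaffolds to assign (default: all in `genes`).
#' @return data.frame, one row per scaffold.
#' @export
assign_taxonomy_set <- function(genes, hits, subject_labels,
                                level = c("family", "genus"),
                                scaffold_ids = NULL) {
  level <- match.arg(level)
  scaffold_ids <- scaffold_ids %||% unique(genes$scaffold_id)
  hits$scaffold_id <- genes$scaffold_id[match(hits$query_id, genes$gene_id)]
  fun <- if (level == "family") assign_phage_family else assign_bacterial_genus
  out <- lapply(scaffold_ids, function(sc)
    fun(hits[!is.na(hits$scaffold_id) & hits$scaffold_id == sc, ,
             drop = FALSE],
        subject_labels, scaffold_id = sc))
  do.call(rbind, out)
}

#' Identify large-subunit terminases by domain motifs
#'
#' Scores each protein against the four terminase domain motifs
#' (Terminase_1, Terminase_3, Terminase_6, Terminase_GpA); proteins matching
#' at least one motif at or below `max_mismatch` substitutions are reported
#' with their best domain (score = motif length minus mismatches; ties are
#' broken by domain name order).
#'
#' @param proteins named character vector of protein sequences.
#' @param domain_motifs named character vector of the four domain motifs.
#' @param max_mismatch allowed substitutions within the motif (default 0).
#' @return data.frame: gene_id, domain, score.
#' @export
identify_lst <- function(proteins, domain_motifs, max_mismatch = 0L) {
  stopifnot(length(domain_motifs) >= 1L, !is.null(names(domain_motifs)))
  if (!length(proteins))
    return(data.frame(gene_id = character(0), domain = character(0),
                      score = numeric(0)))
  aaset <- Biostrings::AAStringSet(proteins)
  doms <- sort(names(domain_motifs))
  best_dom <- rep(NA_character_, length(proteins))
  best_score <- rep(-Inf, length(proteins))
  for (d in doms) {
    motif <- domain_motifs[[d]]
    m <- Biostrings::vmatchPattern(motif, aaset, max.mismatch = max_mismatch,
                                   fixed = TRUE)
    st <- Biostrings::startIndex(m)
    for (i in which(lengths(st) > 0L)) {
      nm <- min(Biostrings::neditStartingAt(
        Biostrings::AAString(motif), aaset[[i]],
        starting.at = st[[i]], with.indels = FALSE))
      score <- nchar(motif) - nm
      if (score > best_score[i]) { best_score[i] <- score; best_dom[i] <- d }
    }
  }
  hit <- which(!is.na(best_dom))
  res <- data.frame(gene_id = names(proteins)[hit], domain = best_dom[hit],
                    score = best_score[hit], stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Neighbor-joining tree of LST proteins (convenience output)
#'
#' Builds a neighbor-joining tree from pairwise p-distances of globally
#' aligned LST protein sequences.  Provided for visual inspection only.
#'
#' @param proteins named character vector (>= 3 sequences).
#' @return an `ape::phylo` tree, or `NULL` when ape is unavailable.
#' @export
lst_tree <- function(proteins) {
  if (!requireNamespace("ape", quietly = TRUE)) return(NULL)
  n <- length(proteins)
  stopifnot(n >= 3L)
  d <- matrix(0, n, n, dimnames = list(names(proteins), names(proteins)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(proteins[[i]]), Biostrings::AAString(proteins[[j]]),
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5)
    d[i, j] <- d[j, i] <- 1 - Biostrings::pid(pa) / 100
  }
  ape::nj(stats::as.dist(d))
}
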