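# CRISPR-spacer-based phage-host bipartite network and specificity summary.

#' Build the phage-host bipartite network from spacer matches
#'
#' One edge per (phage scaffold, bacterial scaffold) pair, with spacer
#' multiplicity; the spacer records the bacterium's infection history, so
#' edges are directed bacterium -> phage.  Self-links (a spacer matching its
#' own scaffold) are excluded.  The network keeps only bacterial scaffolds
#' with a taxonomic (genus) assignment; the unfiltered edge list is returned
#' alongside.
#'
#' @param spacer_matches data.frame from [match_spacers()]; targets must be
#'   identified phage scaffolds.
#' @param bacterial_genus named character vector: bacterial scaffold id ->
#'   genus label (may be `"unclassified"`).
#' @param phage_family named character vector: phage scaffold id -> family
#'   label (optional; `"unclassified"` when absent).
#' @return list of class `host_network`: `edges` (genus-assigned bacterial
#'   scaffolds only) and `all_edges`; columns phage_scaffold_id,
#'   bacterial_scaffold_id, n_spacers, phage_family, host_genus.
#' @export
build_network <- function(spacer_matches, bacterial_genus,
                          phage_family = NULL) {
  m <- spacer_matches[!is.na(spacer_matches$source_scaffold_id) &
                        spacer_matches$source_scaffold_id !=
                        spacer_matches$target_id, , drop = FALSE]
  if (!nrow(m)) {
    e <- data.frame(phage_scaffold_id = character(0),
                    bacterial_scaffold_id = character(0),
                    n_spacers = integer(0), phage_family = character(0),
                    host_genus = character(0))
    return(structure(list(edges = e, all_edges = e), class = "host_network"))
  }
  # spacer multiplicity: distinct spacers of the bacterial scaffold matching
  # the phage scaffold
  key <- paste(m$target_id, m$source_scaffold_id, sep = "\r")
  n_sp <- tapply(m$spacer_id, key, function(x) length(unique(x)))
  parts <- strsplit(names(n_sp), "\r", fixed = TRUE)
  edges <- data.frame(
    phage_scaffold_id = vapply(parts, `[[`, "", 1L),
    bacterial_scaffold_id = vapply(parts, `[[`, "", 2L),
    n_spacers = as.integer(n_sp), stringsAsFactors = FALSE)
  edges$phage_family <- if (is.null(phage_family)) "unclassified" else
    ifelse(is.na(phage_family[edges$phage_scaffold_id]), "unclassified",
           phage_family[edges$phage_scaffold_id])
  edges$host_genus <- ifelse(
    is.na(bacterial_genus[edges$bacterial_scaffold_id]), "unclassified",
    bacterial_genus[edges$bacterial_scaffold_id])
  rownames(edges) <- NULL
  keep <- edges$host_genus != "unclassified"
  structure(list(edges = edges[keep, , drop = FALSE], all_edges = edges),
            class = "host_network")
}

#' Host-specificity and co-existence summary of the phage-host network
#'
#' Reports, per phage scaffold, the number of distinct host genera; the
#' fraction of phage scaffolds paired to exactly one host genus; the list of
#' multi-genus phages; and (when `spacer_matches` and `sample_membership`
#' are given) the fraction of spacer-phage pairs whose source bacterial
#' scaffold and target phage scaffold co-exist in at least one sample.
#'
#' @param network a `host_network` from [build_network()].
#' @param spacer_matches optional match table for the co-existence fraction.
#' @param sample_membership optional named list: scaffold_id -> sample ids.
#' @return list: `per_phage` (data.frame phage_scaffold_id, n_host_genera),
#'   `specificity_fraction`, `multi_genus_phages`, `coexistence_fraction`
#'   (NA without sample information), `n_phage`, `n_bacterial`, `n_edges`.
#' @export
specificity_stats <- function(network, spacer_matches = NULL,
                              sample_membership = NULL) {
  e <- network$edges
  if (!nrow(e))
    return(list(per_phage = data.frame(phage_scaffold_id = character(0),
                                       n_host_genera = integer(0)),
                specificity_fraction = NA_real_,
                multi_genus_phages = character(0),
                coexistence_fraction = NA_real_,
                n_phage = 0L, n_bacterial = 0L, n_edges = 0L))
  ng <- tapply(e$host_genus, e$phage_scaffold_id,
               function(x) length(unique(x)))
  per_phage <- data.frame(phage_scaffold_id = names(ng),
                          n_host_genera = as.integer(ng),
                          stringsAsFactors = FALSE)
  coex <- NA_real_
  if (!is.null(spacer_matches) && !is.null(sample_membership) &&
      nrow(spacer_matches)) {
    m <- spacer_matches[!is.na(spacer_matches$source_scaffold_id) &
                          spacer_matches$source_scaffold_id !=
                          spacer_matches$target_id, , drop = FALSE]
    if (nrow(m)) {
      co <- mapply(function(a, b) {
        sa <- sample_membership[[a]]; sb <- sample_membership[[b]]
        !is.null(sa) && !is.null(sb) && length(intersect(sa, sb)) > 0L
      }, m$source_scaffold_id, m$target_id)
      coex <- mean(co)
    }
  }
  list(per_phage = per_phage,
       specificity_fraction = mean(per_phage$n_host_genera == 1L),
       multi_genus_phages =
         per_phage$phage_scaffold_id[per_phage$n_host_genera > 1L],
       coexistence_fraction = coex,
       n_phage = length(unique(e$phage_scaffold_id)),
       n_bacterial = length(unique(e$bacterial_scaffold_id)),
       n_edges = nrow(e))
}

#' Export a host network (or co-occurrence network) to GraphML
#'
#' @param edges data.frame with the first two columns naming the endpoint
#'   nodes; remaining columns become edge attributes.
#' @param path output path.
#' @param node_types optional named character vector of node type attributes.
#' @export
write_graphml <- function(edges, path, node_types = NULL) {
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  if (!is.null(node_types))
    igraph::V(g)$type_label <-
      unname(node_types[igraph::V(g)$name])
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
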