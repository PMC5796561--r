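#' Configuration for the synthetic gut-metagenome world
#'
#' Defines every knob of the synthetic multi-sample community: a two-group
#' (control vs case) design, a catalog of bacterial scaffolds carrying planted
#' prophages (>= 10 kb inserts), CRISPR arrays whose spacers are verbatim
#' copies of phage subsequences, 16S rRNA gene copies, and whole-community
#' (WCMS) plus virus-like-particle (VLP) read sets.  Planted fold changes on a
#' subset of pOTUs give the case group a known differential signal.
#'
#' Defaults describe the study conditions exercised by the test-suite: a
#' 20 + 20 sample design with 37 phage genomes (each forming its own pOTU,
#' 7 of them with a fold-3 case effect) and a read depth of 1000 WCMS reads
#' per sample.
#'
#' @param n_samples_per_group samples per group (control and case each).
#' @param n_bacterial_genera number of bacterial genera in the community.
#' @param n_phage_genomes number of reference phage genomes.
#' @param phage_genome_len_range genome length range, bp.
#' @param bacterial_scaffold_len_range length range for purely bacterial
#'   scaffolds, bp.
#' @param prophage_flank_len_range bacterial flank length range on either side
#'   of a planted prophage, bp.
#' @param prophage_rate fraction of bacterial scaffolds carrying one prophage.
#' @param crispr_rate fraction of purely bacterial scaffolds carrying one
#'   CRISPR array.
#' @param spacer_len,repeat_len,n_repeats_per_array CRISPR array geometry, bp.
#' @param reads_per_sample,read_len WCMS read count per sample and read
#'   length, bp.
#' @param vlp_reads_per_sample VLP (phage-enriched) reads per sample.
#' @param n_16s_copies_range 16S gene copies planted per purely bacterial
#'   scaffold (uniform integer range).
#' @param n_marker_genes_per_phage phage marker genes planted per genome
#'   (must be >= 3).
#' @param marker_len_aa_range marker protein length range, amino acids.
#' @param effect_potus named numeric vector: names are phage genome ids
#'   (e.g. `"phage_01"`), values are fold changes (> 1) applied to the case
#'   group; the generator translates genome ids to the pOTU ids they define.
#' @param abundance_sdlog sd (log scale) of the per-sample, per-scaffold
#'   lognormal abundance weights.
#' @param read_error_rate per-base substitution rate of simulated reads
#'   (0 = error-free, the default).
#' @param spacer_mutations substitutions applied to each planted spacer
#'   relative to its phage source (0 = exact copies, the default).
#' @param rng_seed integer seed controlling all randomness downstream.
#'
#' @return An object of class `world_config` (a validated list).
#' @export
world_config <- function(n_samples_per_group = 20,
                         n_bacterial_genera = 6,
                         n_phage_genomes = 37,
                         phage_genome_len_range = c(12000L, 16000L),
                         bacterial_scaffold_len_range = c(8000L, 14000L),
                         prophage_flank_len_range = c(1500L, 3000L),
                         prophage_rate = 0.5,
                         crispr_rate = 0.3,
                         spacer_len = 32L,
                         repeat_len = 29L,
                         n_repeats_per_array = 6L,
                         reads_per_sample = 1000L,
                         read_len = 100L,
                         vlp_reads_per_sample = 500L,
                         n_16s_copies_range = c(1L, 2L),
                         n_marker_genes_per_phage = 4L,
                         marker_len_aa_range = c(200L, 280L),
                         effect_potus = stats::setNames(
                           rep(3, 7), sprintf("phage_%02d", 1:7)),
                         abundance_sdlog = 0.5,
                         read_error_rate = 0,
                         spacer_mutations = 0L,
                         rng_seed = 1L) {
  cfg <- list(
    n_samples_per_group = as.integer(n_samples_per_group),
    n_bacterial_genera = as.integer(n_bacterial_genera),
    n_phage_genomes = as.integer(n_phage_genomes),
    phage_genome_len_range = as.integer(phage_genome_len_range),
    bacterial_scaffold_len_range = as.integer(bacterial_scaffold_len_range),
    prophage_flank_len_range = as.integer(prophage_flank_len_range),
    prophage_rate = prophage_rate,
    crispr_rate = crispr_rate,
    spacer_len = as.integer(spacer_len),
    repeat_len = as.integer(repeat_len),
    n_repeats_per_array = as.integer(n_repeats_per_array),
    reads_per_sample = as.integer(reads_per_sample),
    read_len = as.integer(read_len),
    vlp_reads_per_sample = as.integer(vlp_reads_per_sample),
    n_16s_copies_range = as.integer(n_16s_copies_range),
    n_marker_genes_per_phage = as.integer(n_marker_genes_per_phage),
    marker_len_aa_range = as.integer(marker_len_aa_range),
    effect_potus = effect_potus,
    abundance_sdlog = abundance_sdlog,
    read_error_rate = read_error_rate,
    spacer_mutations = as.integer(spacer_mutations),
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "world_config"
  validate_world_config(cfg)
  cfg
}

validate_world_config <- function(cfg) {
  chk_pos <- function(field) {
    if (any(!is.finite(cfg[[field]])) || any(cfg[[field]] <= 0))
      stopf("invalid world_config: '%s' must be positive", field)
  }
  chk_range <- function(field) {
    chk_pos(field)
    if (length(cfg[[field]]) != 2L || cfg[[field]][1] > cfg[[field]][2])
      stopf("invalid world_config: '%s' must be an increasing (min,max) pair",
            field)
  }
  chk_rate <- function(field) {
    if (!is.finite(cfg[[field]]) || cfg[[field]] < 0 || cfg[[field]] > 1)
      stopf("invalid world_config: '%s' must lie in [0, 1]", field)
  }
  for (f in c("n_samples_per_group", "n_bacterial_genera", "n_phage_genomes",
              "spacer_len", "repeat_len", "n_repeats_per_array", "read_len",
              "n_marker_genes_per_phage"))
    chk_pos(f)
  for (f in c("phage_genome_len_range", "bacterial_scaffold_len_range",
              "prophage_flank_len_range", "n_16s_copies_range",
              "marker_len_aa_range"))
    chk_range(f)
  for (f in c("prophage_rate", "crispr_rate", "read_error_rate"))
    chk_rate(f)
  if (cfg$reads_per_sample < 0 || cfg$vlp_reads_per_sample < 0)
    stopf("invalid world_config: read counts must be non-negative")
  if (cfg$n_marker_genes_per_phage < 3L)
    stopf("invalid world_config: 'n_marker_genes_per_phage' must be >= 3")
  if (length(cfg$effect_potus) &&
      (is.null(names(cfg$effect_potus)) || any(cfg$effect_potus <= 1)))
    stopf("invalid world_config: 'effect_potus' must be a named vector of fold changes > 1")
  # Planted prophages must clear the large-scaffold screen (>= 10 kb).
  if (cfg$prophage_rate > 0 && cfg$phage_genome_len_range[1] < 10000L)
    stopf("invalid world_config: 'phage_genome_len_range' minimum below 10 kb; planted prophages must be large-scaffold sized")
  invisible(cfg)
}

#' @export
print.world_config <- function(x, ...) {
  cat("Synthetic world configuration\n")
  cat(sprintf("  samples: %d control + %d case\n",
              x$n_samples_per_group, x$n_samples_per_group))
  cat(sprintf("  phage genomes: %d (%d-%d bp), bacterial genera: %d\n",
              x$n_phage_genomes, x$phage_genome_len_range[1],
              x$phage_genome_len_range[2], x$n_bacterial_genera))
  cat(sprintf("  reads/sample: %d WCMS + %d VLP (%d bp)\n",
              x$reads_per_sample, x$vlp_reads_per_sample, x$read_len))
  if (length(x$effect_potus))
    cat(sprintf("  planted effects: %d pOTUs, fold %s\n",
                length(x$effect_potus),
                paste(unique(x$effect_potus), collapse = "/")))
  cat(sprintf("  seed: %d\n", x$rng_seed))
  invisible(x)
}
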