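# Shared synthetic worlds, generated once per test run.

.world_cache <- new.env(parent = emptyenv())

tiny_config <- function(...) {
  base <- list(n_samples_per_group = 3, n_phage_genomes = 6,
               n_bacterial_genera = 3, reads_per_sample = 400,
               vlp_reads_per_sample = 300,
               effect_potus = stats::setNames(rep(3, 2),
                                              sprintf("phage_%02d", 1:2)),
               rng_seed = 42)
  do.call(world_config, utils::modifyList(base, list(...)))
}

# A 3+3-sample, 6-phage world for fast unit tests.
tiny_world <- function() {
  if (is.null(.world_cache$tiny)) {
    cfg <- tiny_config()
    refs <- generate_references(cfg)
    com <- generate_community(cfg, refs)
    reads <- simulate_reads(cfg, com, refs)
    .world_cache$tiny <- list(cfg = cfg, refs = refs, com = com,
                              reads = reads)
  }
  .world_cache$tiny
}

# Full pipeline over the tiny world (no co-occurrence), cached.
tiny_run <- function() {
  if (is.null(.world_cache$tiny_run)) {
    .world_cache$tiny_run <- suppressMessages(suppressWarnings(
      run_phageome(tiny_config(), run_cooccurrence = FALSE)))
  }
  .world_cache$tiny_run
}

# The full 20+20-sample study-condition world, pipeline included; used by
# the acceptance checks and the parameter-recovery tests.
default_run <- function() {
  if (is.null(.world_cache$default)) {
    .world_cache$default <- suppressMessages(suppressWarnings(
      run_phageome(world_config(rng_seed = 2024),
                   run_cooccurrence = FALSE)))
  }
  .world_cache$default
}

random_dna_str <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
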