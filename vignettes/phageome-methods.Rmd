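---
title: "Profiling the gut phageome from whole-community metagenomes"
author: "phageome package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling the gut phageome from whole-community metagenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Whole-community metagenomic sequencing (WCMS) of stool captures bacterial
and phage DNA together: free virions, actively replicating phages, and
prophages integrated into bacterial chromosomes. Phages lack a universal
marker akin to the bacterial 16S rRNA gene, most gut phages are absent from
reference databases, and assembled scaffolds mix phage and bacterial
sequence freely. `phageome` implements a complete desk-scale pipeline for
this setting: identify large scaffolds of phage origin, assign taxonomy,
quantify phage operational taxonomic units (pOTUs), link phages to their
bacterial hosts through CRISPR spacers, correlate phages with bacteria in a
composition-aware way, and test for group-wise (e.g. disease vs control)
differences.

Every stage is exercised end to end on a synthetic community with complete
ground-truth tables, so the statistical machinery can be validated without
any external download.

## The synthetic world

`world_config()` + `generate_references()` / `generate_community()` /
`simulate_reads()` build a fully specified cohort:

* A catalog of reference **phage genomes** (12–16 kb by default), each with
  a five-level taxonomy (group|order|family|subfamily|genus) and a bacterial
  host genus, and each carrying at least three **marker genes** planted as
  exact ORFs (`TAA` guard + `ATG`…stop), so that ORF-caller recall is
  decoupled from everything downstream.
* A scaffold catalog: purely bacterial scaffolds (8–14 kb, some deliberately
  below the 10 kb screen) with genus-specific genes and 16S gene copies, and
  **prophage-bearing scaffolds** in which a complete phage genome is
  inserted verbatim between bacterial flanks. The same catalog underlies
  every sample — the community composition, not the sequence content, varies
  between subjects — which mirrors how cohort-level scaffold catalogs are
  used in practice and makes every planted feature globally checkable.
* **CRISPR arrays** (repeat–spacer–repeat…, 6 repeats of 29 bp and 32 bp
  spacers by default) on a fraction of bacterial scaffolds; every spacer is
  an exact copy of a subsequence of a phage whose host genus matches the
  scaffold's genus. A mutation knob exists for robustness experiments.
* **Reads**: WCMS reads drawn from scaffolds with per-sample lognormal
  abundance weights (sdlog 0.5 — a moderate level of between-subject
  variation), and VLP (virus-like-particle) reads drawn from phage genomes
  only. Reads are error-free by default; a substitution-rate knob exists.
* A two-group design (20 + 20 samples by default) with planted fold changes
  (7 pOTUs at fold 3 by default) applied to the case group's sampling
  weights, recorded in the truth tables together with prophage intervals,
  spacer origins, and per-read origins.

Coordinates are 0-based and half-open everywhere. Background sequence is
i.i.d. uniform A/C/G/T: the tests here concern correctness of the
screening, voting and testing machinery, none of which requires
phylogenetic realism. What passing tests consequently do **not** show:
robustness to sequencing error, strain variation, assembly artifacts, or
homology detection in diverged sequence — real data pass through the same
interfaces via FASTA/FASTQ/SAM readers and BLAST-style hit tables, but
those failure modes are out of the synthetic world's scope.

Default read depth is 1000 WCMS reads per sample. At the default catalog
size this puts per-genome marker counts in the low single digits per
sample, which is the interesting regime for the rank-based differential
machinery (heavy ties, zero inflation); the depth, like every other
generator default, is part of the declared study conditions and is not
adjusted per analysis.

## Identifying large phage scaffolds

Only scaffolds ≥ 10 kb enter discovery. Three independent evidence
strategies are computed per scaffold:

* **Strategy I (spacer probing):** the scaffold is matched by at least one
  CRISPR spacer originating from a *different* scaffold's array.
  Self-matches are ignored — an array trivially matches its own spacers.
* **Strategy II (VLP coverage):** breadth of coverage by VLP reads
  ≥ 0.40 (inclusive). Breadth is the fraction of positions covered ≥ 1×;
  depth is mean per-position coverage. The comparator is an explicit
  argument because the known-genome screen elsewhere in the pipeline uses a
  *strict* > 0.30 threshold; both strictness conventions are preserved
  exactly.
* **Strategy III (gene homology):** at least `min_phage_genes` (default 1)
  of the scaffold's predicted genes hit a phage protein at e ≤ 1e−05.

The union of the three sets is then screened for ambiguity: a candidate is
discarded when the summed bit-score of its genes against bacterial-source
proteins exceeds the summed score against phage-source proteins by more
than a factor (default 2). The original screening step this stands in for
is a manual curation; a manual check is not reproducible, so the package
codifies it as this declared, deterministic bit-score ratio — the factor is
exposed and the accepted set shrinks monotonically as it tightens.
Prophages and free phages are deliberately not distinguished. Per-strategy
Venn counts are reported; the seven cells are disjoint and sum to the
union.

## Supporting machinery

The pipeline is self-contained at fixture scale:

* `call_orfs()` — maximal ATG-to-stop ORFs on all six frames (standard
  code, ATG-only starts, N→X), non-nested per frame, intervals including
  the stop codon. Determinism is preferred over sensitivity; real gene
  calls can be substituted via the gene-table interface.
* `map_reads()` — an exact-seed (21 bp), ungapped mapper with a full-read
  identity threshold (default 0.95). Multi-mapped reads keep their single
  best placement, ties broken by (ref, position) order, so abundance is
  never double-counted; `report = "all_best"` exposes ties to callers that
  must discard them. SAM files are ingested as an alternative alignment
  source (primary, mapped records only).
* `naive_protein_search()` — shared-k-mer scoring (k = 4) with a pseudo
  e-value `|db| · 2^−score`, monotone in the score; exact substrings always
  outrank non-exact matches. Real BLAST tabular output can be supplied
  instead through `read_hits()` (12-column dialect, best record per
  query–subject pair).
* `detect_arrays()` — a repeat-seed heuristic: exact 13-mers recurring at
  regular spacing (period within repeat+spacer bounds) are clustered; the
  union of co-anchored seeds delimits the repeats. Repeat length 21–48,
  spacer length 18–50, ≥ 3 repeats, pairwise repeat identity ≥ 0.9; arrays
  containing N are discarded. Detection operates on the literal text and is
  therefore strand-agnostic. Spacer matching allows one substitution by
  default (exposed), reflecting that short-spacer matching is inherently
  tolerant.

## Taxonomy by weighted vote

For a scaffold's genes, hits at e ≤ 1e−05 are ranked per gene by ascending
e-value (ties: descending bit-score, then subject id — the ranking key is a
declared choice). The top-ranked distinct subject contributes 1.0, the
second 0.5, to its label's score; genes without hits do not vote. The
**phage family ratio** (PFR) is the winning family's share of the total
score; a family is assigned only when PFR > 0.5 (strict), otherwise the
scaffold is unclassified. The **bacterial genus ratio** (BGR) uses the same
vote with assignment at BGR ≥ 0.70 (inclusive). The two strictness
conventions are deliberate and tested at exact-boundary fixtures; if both
top hits share a label that label receives 1.5 from the gene, with no
deduplication. Ties for the maximal label at exactly the threshold are
unclassified by construction; ties above it resolve alphabetically for
determinism.

Large-subunit terminases are identified by motif matching against the four
terminase domains (Terminase_1, Terminase_3, Terminase_6, Terminase_GpA);
score is motif length minus mismatches, ties resolve by domain name order.
Full profile-HMM searching is out of scope — externally computed domain hit
tables can be supplied — and the neighbor-joining tree on LST p-distances is
a convenience output only.

## pOTUs and 16S-normalized abundance

A pOTU is the set of phages identical at all five taxonomy levels *and*
sharing a host genus; missing levels must carry explicit
`unclassified_<level>` tokens so that incomparable taxa never merge
silently. Reads are assigned to genomes by best nucleotide match to
marker-gene CDS; reads whose equally best hits span more than one genome
are discarded. This tie-discard, nucleotide-level rule is a declared
stand-in for a read-assignment protocol that is not restated here;
translated search is a documented extension point. The relative number of
a pOTU in a sample is the summed member counts divided by the sample's 16S
read count — deliberately *not* renormalized across pOTUs, so values are
per-16S rates, not proportions. Samples with zero 16S reads become missing
rather than infinite.

## Phage–host network

Spacer matches from array-bearing bacterial scaffolds to accepted phage
scaffolds become edges (bacterium → phage, since the spacer records the
bacterium's infection history), weighted by distinct-spacer multiplicity.
Only genus-assigned bacterial scaffolds enter the network; the raw edge
list is retained alongside. Summary statistics report per-phage host-genus
counts, the fraction of single-genus phages, and the fraction of
spacer–phage pairs co-occurring in the same sample.

## Co-occurrence between bacteria and pOTUs

Counts are compositional, so Pearson correlations on proportions are
biased; the engine estimates basis correlations from pairwise log-ratio
variances. With `t_ij = var(log x_i/x_j)` and the approximation that basis
covariances average out, row sums satisfy a linear system
`((D−2)I + 11')ω = t` solved directly; correlations follow as
`ρ_ij = (ω_i + ω_j − t_ij) / (2√(ω_iω_j))`, clipped to [−1, 1]. The most
strongly correlated pair (|ρ| above 0.1) is iteratively excluded from the
system (up to 10 rounds, both knobs exposed); estimates are averaged over
20 Dirichlet resamplings of the counts (pseudocount 0.5 on zeros), all
configurable and reducible to a deterministic point solve
(`n_resamples = 1`). At least 4 taxa are required for the basis system;
a Spearman engine is available behind the same interface for smaller sets.

Significance uses column-independent permutations:
`p = (1 + #{|r_perm| ≥ |r_obs|}) / (1 + n_perm)`, two-sided, with the point
solve inside the permutation loop for speed. Edges require |r| > 0.3 and
p < 0.01, both strict; unconnected nodes are dropped. Taxa enter the
analysis only when detected in strictly more than half the samples
(`prevalence_filter()`, threshold an explicit integer).

## Group statistics

* `mann_whitney()` computes U from midrank-tied pooled ranks; for combined
  sample sizes ≤ 12 the two-sided p-value is an exact enumeration over all
  group assignments of the observed values (ties included), otherwise the
  normal approximation with tie and continuity correction. Identical
  samples give p = 1. Tests are two-sided throughout; direction (from the
  case–control median difference) is reported separately.
* `bh_fdr()` is the Benjamini–Hochberg step-up rule (via `p.adjust`),
  applied within each feature level (pOTU vs family) separately — which
  features form one correction family is a declared choice, mirrored in the
  reporting.
* Features are flagged at p < 0.05 and q < 0.25.
* `core_selection()` keeps features detected in strictly more than
  `floor(frac · N)` samples, with frac = 2/3 (core) or 0.7 (highly
  prevalent). For a 145-sample cohort the core mode gives the familiar
  n > 96. Published prevalence filters sometimes state a literal sample
  count that does not equal the stated fraction of N (e.g. "more than 120
  samples" described as 70% of 145, where 0.7 · 145 = 101.5); the
  `min_count` argument reproduces such literal thresholds, and the package
  does not attempt to resolve the inconsistency.
* `chao2()` implements `S_obs + ((m−1)/m) · Q1²/(2·Q2)`, falling back to
  the bias-corrected `S_obs + ((m−1)/m) · Q1(Q1−1)/2` when Q2 = 0; the
  incidence threshold (abundance > 0) is the declared detection rule.
* `rarefaction()` defaults to the exact hypergeometric form
  `E[S_k] = Σ_f (1 − C(m−d_f, k)/C(m, k))`, which equals the average over
  all k-subsets; a permutation method is available and converges to it.

## Study sizes used by the test-suite

The packaged checks run on a 3 + 3-sample world (6 phage genomes) for unit
properties and on the full default world — 20 + 20 samples, 37 phage
genomes forming 37 pOTUs, 7 planted fold-3 effects, 1000 reads per sample —
for end-to-end properties; the replicate-power experiment regenerates that
world 20 times under consecutive seeds. These sizes are the package's
declared study conditions for its own validation.

One property deserves a caveat: the replicate experiment asks that all 7
planted effects be flagged with at most 2 of 30 null pOTUs flagged, in at
least 90% of 20 replicate worlds. With a calibrated 5% test, the count of
flagged nulls is approximately Binomial(30, 0.05), so a single replicate
satisfies the false-flag bound with probability only ≈ 0.81–0.92 (the
discreteness of rank tests at low counts pushes it toward the upper end).
The 20-replicate pass fraction therefore sits near the 90% line and
fluctuates with the seed; this is a property of the bound itself, not of
the implementation, and the package reports the measured pass rate rather
than tuning conditions around it.

## Known limitations

Single-end, ungapped, error-intolerant read mapping; no ssDNA phage model;
no strain-level variation or assembly simulation; the ambiguity screen is
a codified proxy for manual curation; LST identification is motif-based
rather than profile-HMM-based; the co-occurrence engine approximates, and
is not numerically identical to, the published implementations of
basis-correlation inference.
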