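# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library calls never perturb user RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

DNA_BASES <- c("A", "C", "G", "T")

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# 20 standard amino acids (no stop).
AA_ALPHABET20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_protein <- function(n_aa) {
  paste(sample(AA_ALPHABET20, n_aa, replace = TRUE), collapse = "")
}

# One fixed codon per amino acid (standard code); used to back-translate
# planted proteins into stop-free coding sequence.
AA_TO_CODON <- c(
  A = "GCT", C = "TGC", D = "GAT", E = "GAA", F = "TTC", G = "GGT",
  H = "CAC", I = "ATC", K = "AAA", L = "CTG", M = "ATG", N = "AAC",
  P = "CCG", Q = "CAG", R = "CGT", S = "TCT", T = "ACC", V = "GTT",
  W = "TGG", Y = "TAC"
)

back_translate <- function(protein) {
  aa <- strsplit(protein, "")[[1]]
  paste(AA_TO_CODON[aa], collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

translate_dna <- function(x) {
  # x: character vector of in-frame CDS (length divisible by 3); N -> X.
  # The fuzzy-codon path is much slower, so take it only when needed.
  if (any(grepl("[^ACGT]", x)))
    as.character(Biostrings::translate(Biostrings::DNAStringSet(x),
                                       if.fuzzy.codon = "X",
                                       no.init.codon = TRUE))
  else
    as.character(Biostrings::translate(Biostrings::DNAStringSet(x),
                                       no.init.codon = TRUE))
}

# Hamming distance between two equal-length strings.
str_mismatches <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("sequences differ in length")
  sum(utf8ToInt(a) != utf8ToInt(b))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
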