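# Low-level sequence helpers shared across the package. All matching is done
# in the DNA alphabet; RNA input (U) is normalized to T at ingest.

#' Normalize a nucleotide sequence to the DNA alphabet
#'
#' Upper-cases and converts U to T. All internal matching, reverse
#' complementation and site classification operate on {A,C,G,T}.
#'
#' @param x character vector of sequences.
#' @return character vector over the DNA alphabet.
#' @export
normalize_dna <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

#' Reverse complement (DNA alphabet)
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(normalize_dna(x))))
}

# Hamming distance between two equal-length strings; Inf if lengths differ.
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) return(Inf)
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Positions at which two equal-length strings differ.
mismatch_positions <- function(a, b) {
  which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Random DNA of given lengths under a fixed composition.
random_dna <- function(n, len, prob = rep(0.25, 4)) {
  vapply(rep(len, length.out = n), function(l) {
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE, prob = prob),
          collapse = "")
  }, character(1))
}

# Does the (mirna_base, target_base) pair form a Watson-Crick or G:U pair
# in the RNA duplex? Sequences are stored as DNA, so U == T here.
can_pair <- function(m, t) {
  (m == "A" & t == "T") | (m == "T" & t == "A") |
    (m == "G" & t == "C") | (m == "C" & t == "G") |
    (m == "G" & t == "T") | (m == "T" & t == "G")
}

# Pair score used by the duplex DP: GC=3, AU=2, GU=1, else 0.
pair_score <- function(m, t) {
  ifelse((m == "G" & t == "C") | (m == "C" & t == "G"), 3L,
  ifelse((m == "A" & t == "T") | (m == "T" & t == "A"), 2L,
  ifelse((m == "G" & t == "T") | (m == "T" & t == "G"), 1L, 0L)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
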