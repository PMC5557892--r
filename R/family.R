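# miRNA catalog handling and seed-family nomenclature.

#' Seed-derived miRNA family key
#'
#' Two mature miRNAs belong to the same family when they share the seed that
#' defines the 8mer site class on targets. The target-side 8mer consists of
#' Watson-Crick matches to miRNA positions 2-8 plus an adenosine opposite
#' position 1; the A is target-encoded, so the miRNA-side invariant -- and
#' the family key -- is the 7-nt subsequence at positions 2-8 (5' to 3').
#'
#' @param sequence character vector of mature miRNA sequences (RNA or DNA
#'   alphabet; at least 9 nt).
#' @return character vector of 7-nt family keys.
#' @examples
#' family_key("CAAAGTGCTTACAGTGCAGGTAGT")  # miR-17-5p family: "AAAGTGC"
#' @export
family_key <- function(sequence) {
  sequence <- normalize_dna(sequence)
  if (any(nchar(sequence) < 9)) {
    stop("miRNA sequences must be at least 9 nt to carry a seed family key")
  }
  substr(sequence, 2L, 8L)
}

#' Build a miRNA catalog
#'
#' @param name miRNA names (e.g. "bta-miR-17-5p").
#' @param sequence mature sequences (RNA or DNA alphabet, 17-26 nt typical).
#' @param precursor optional data.frame with columns chrom, start, end,
#'   strand, name giving hairpin loci (0-based half-open) to attach.
#' @return data.frame with columns name, sequence, family_key, one row per
#'   mature miRNA, ordered by name.
#' @export
mirna_catalog <- function(name, sequence, precursor = NULL) {
  sequence <- normalize_dna(sequence)
  stopifnot(length(name) == length(sequence), !anyDuplicated(name))
  cat <- data.frame(name = as.character(name), sequence = sequence,
                    family_key = family_key(sequence),
                    stringsAsFactors = FALSE)
  cat <- cat[order(tolower(cat$name), method = "radix"), , drop = FALSE]
  rownames(cat) <- NULL
  attr(cat, "precursors") <- precursor
  class(cat) <- c("mirna_catalog", "data.frame")
  cat
}

#' Read a miRNA catalog from a FASTA file
#'
#' @param path FASTA of mature miRNA sequences; record names become miRNA
#'   names (first whitespace-delimited token).
#' @return a [mirna_catalog()] data.frame.
#' @export
read_mirna_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  mirna_catalog(nm, as.character(ss))
}

#' Write a miRNA catalog to FASTA
#' @param catalog a [mirna_catalog()].
#' @param path output path.
#' @export
write_mirna_fasta <- function(catalog, path) {
  ss <- Biostrings::DNAStringSet(catalog$sequence)
  names(ss) <- catalog$name
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
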