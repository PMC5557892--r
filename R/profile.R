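# AGO-loaded miRNA profiling and detection of non-annotated hairpin arms.

#' Profile AGO-loaded miRNAs
#'
#' A read counts toward a mature miRNA if and only if the entire read is a
#' contiguous, zero-mismatch substring of the mature sequence. Reads
#' matching several catalog entries count toward the first in
#' case-insensitive alphanumeric order.
#'
#' @param reads read data.frame (barcode-stripped sequences) with 17-26 nt
#'   reads; longer/shorter reads never match.
#' @param catalog a [mirna_catalog()].
#' @param min_len,max_len read length bounds considered (defaults 17, 26).
#' @return list with `counts` (data.frame name, count, including zero rows)
#'   and `unmatched` (character vector of the read sequences that matched no
#'   catalog entry).
#' @export
profile_ago_mirnas <- function(reads, catalog, min_len = 17L, max_len = 26L) {
  # dictionary of every catalog substring in the length range; catalog is
  # stored in alphanumeric order so the first writer of a key wins
  dict <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(catalog))) {
    s <- catalog$sequence[i]; L <- nchar(s)
    for (w in seq(min_len, min(max_len, L))) {
      for (o in seq_len(L - w + 1L)) {
        sub <- substr(s, o, o + w - 1L)
        if (is.null(dict[[sub]])) dict[[sub]] <- catalog$name[i]
      }
    }
  }
  hit <- vapply(reads$sequence, function(s) dict[[s]] %||% NA_character_,
                character(1), USE.NAMES = FALSE)
  counts <- table(factor(hit, levels = catalog$name))
  list(counts = data.frame(name = catalog$name,
                           count = as.integer(counts),
                           stringsAsFactors = FALSE),
       unmatched = reads$sequence[is.na(hit)])
}

#' Detect candidate non-annotated miRNA hairpin arms
#'
#' Abundant sequencing reads that fail to match any annotated mature miRNA
#' but map inside a known hairpin on the arm opposite an annotated mature
#' species suggest a missing 5p/3p annotation.
#'
#' @param unmatched character vector of read sequences rejected by
#'   [profile_ago_mirnas()] (with multiplicity).
#' @param genome named character vector of chromosome sequences.
#' @param precursors data.frame of hairpin loci: chrom, start, end, strand,
#'   name, annotated_arm ("5p" or "3p").
#' @param min_count minimum collapsed read count (default 100).
#' @param min_len,max_len sequence length bounds (defaults 17, 25).
#' @return data.frame: sequence, count, hairpin, proposed_arm,
#'   proposed_name; empty when nothing qualifies.
#' @export
detect_novel_arm_candidates <- function(unmatched, genome, precursors,
                                        min_count = 100L,
                                        min_len = 17L, max_len = 25L) {
  empty <- data.frame(sequence = character(0), count = integer(0),
                      hairpin = character(0), proposed_arm = character(0),
                      proposed_name = character(0))
  len <- nchar(unmatched)
  unmatched <- unmatched[len >= min_len & len <= max_len]
  if (!length(unmatched)) return(empty)
  tab <- table(unmatched)
  tab <- tab[tab >= min_count]
  if (!length(tab)) return(empty)
  mapped <- map_segments(names(tab), genome, max_mismatch = 0L)
  if (!nrow(mapped)) return(empty)
  pg <- df_to_granges(precursors)
  mg <- df_to_granges(mapped)
  hits <- GenomicRanges::findOverlaps(mg, pg, type = "within")
  res <- list()
  for (j in seq_along(hits)) {
    qi <- S4Vectors::queryHits(hits)[j]
    pi <- S4Vectors::subjectHits(hits)[j]
    p <- precursors[pi, ]
    mid <- (mapped$start[qi] + mapped$end[qi]) / 2
    frac <- (mid - p$start) / (p$end - p$start)
    arm <- if (p$strand == "+") {
      if (frac < 0.5) "5p" else "3p"
    } else {
      if (frac < 0.5) "3p" else "5p"
    }
    if (identical(arm, p$annotated_arm)) next
    res[[length(res) + 1L]] <- data.frame(
      sequence = mapped$sequence[qi],
      count = as.integer(tab[[mapped$sequence[qi]]]),
      hairpin = p$name,
      proposed_arm = arm,
      proposed_name = paste0(p$name, "-", arm),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res) %||% empty
  out[order(-out$count), , drop = FALSE]
}
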