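# Seed-site taxonomy. Site classes are defined on the target sequence
# (5'->3') by complementarity to the miRNA 5' end:
#   8mer     : Watson-Crick match to miRNA positions 2-8 plus an A opposite
#              position 1 (the A is target-encoded)
#   7mer-m8  : match to positions 2-8
#   7mer-A1  : match to positions 2-7 plus the A
#   6mer     : match to positions 2-7
#   5mer     : match to positions 2-6
#   mismatch : a single non-Watson-Crick (or G:U) position inside an
#              8/7/6mer span
#   bulged   : a single extra unpaired target nucleotide inside an 8/7mer
#              span
# Canonical classes use exact string matches, so a G:U inside the seed
# falls into the mismatch class by construction. Priority: canonical before
# variant, longer before shorter, leftmost site on ties.

seed_patterns <- function(mirna) {
  mirna <- normalize_dna(mirna)
  r28 <- reverse_complement(substr(mirna, 2, 8))
  r27 <- reverse_complement(substr(mirna, 2, 7))
  r26 <- reverse_complement(substr(mirna, 2, 6))
  list(`8mer` = paste0(r28, "A"), `7mer-m8` = r28,
       `7mer-A1` = paste0(r27, "A"), `6mer` = r27, `5mer` = r26)
}

# All single-substitution variants of a pattern (exactly one differing
# position), with the defect position attached.
substitution_variants <- function(pat) {
  ch <- strsplit(pat, "")[[1]]
  out <- list()
  for (pos in seq_along(ch)) {
    for (b in setdiff(c("A", "C", "G", "T"), ch[pos])) {
      v <- ch; v[pos] <- b
      out[[length(out) + 1L]] <- c(paste(v, collapse = ""), pos)
    }
  }
  out
}

# All single-insertion variants (one extra nucleotide strictly inside the
# span), with the insertion position attached.
insertion_variants <- function(pat) {
  ch <- strsplit(pat, "")[[1]]
  out <- list()
  for (pos in seq_len(length(ch) - 1L)) {  # insert after position pos
    for (b in c("A", "C", "G", "T")) {
      v <- append(ch, b, after = pos)
      out[[length(out) + 1L]] <- c(paste(v, collapse = ""), pos + 1L)
    }
  }
  out
}

# Leftmost occurrence of any variant string in target; returns c(site, pos)
# start (1-based) and defect annotation, or NULL.
leftmost_variant_hit <- function(target, variants) {
  best <- NULL
  for (v in variants) {
    p <- regexpr(v[1], target, fixed = TRUE)[[1]]
    if (p > 0 && (is.null(best) || p < best[1])) best <- c(p, as.integer(v[2]))
  }
  best
}

#' Classify the seed-site type of a target window
#'
#' Scans the target 5'->3' for sites complementary to the miRNA 5' end and
#' returns the single highest-priority site class (see the taxonomy above),
#' with the leftmost site winning within a class.
#'
#' @param mirna mature miRNA sequence (at least 9 nt).
#' @param target target sequence (at least 8 nt), 5'->3'.
#' @return list with `category` (e.g. "8mer", "mismatch-7mer",
#'   "bulged-8mer", "none"), `site_start` (0-based offset of the site in the
#'   target, NA for "none") and `detail` (defect position within the site,
#'   1-based; NA for canonical sites).
#' @export
classify_seed <- function(mirna, target) {
  target <- normalize_dna(target)
  stopifnot(nchar(target) >= 8)
  pats <- seed_patterns(mirna)
  for (cls in names(pats)) {
    p <- regexpr(pats[[cls]], target, fixed = TRUE)[[1]]
    if (p > 0) {
      return(list(category = cls, site_start = p - 1L, detail = NA_integer_))
    }
  }
  for (cls in c("8mer", "7mer-m8", "6mer")) {
    hit <- leftmost_variant_hit(target, substitution_variants(pats[[cls]]))
    if (!is.null(hit)) {
      lab <- paste0("mismatch-", sub("-m8", "", cls))
      return(list(category = lab, site_start = hit[1] - 1L,
                  detail = hit[2]))
    }
  }
  for (cls in c("8mer", "7mer-m8")) {
    hit <- leftmost_variant_hit(target, insertion_variants(pats[[cls]]))
    if (!is.null(hit)) {
      lab <- paste0("bulged-", sub("-m8", "", cls))
      return(list(category = lab, site_start = hit[1] - 1L,
                  detail = hit[2]))
    }
  }
  list(category = "none", site_start = NA_integer_, detail = NA_integer_)
}

#' Collapse seed categories to report-level classes
#'
#' Both 7mer subtypes report as "7mer"; single-defect variants report as
#' "mismatch"/"bulged"; everything else as "noncanonical".
#'
#' @param category character vector of [classify_seed()] categories.
#' @return character vector over {8mer, 7mer, 6mer, 5mer, mismatch, bulged,
#'   noncanonical}.
#' @export
seed_report_class <- function(category) {
  ifelse(category == "8mer", "8mer",
  ifelse(category %in% c("7mer-m8", "7mer-A1"), "7mer",
  ifelse(category == "6mer", "6mer",
  ifelse(category == "5mer", "5mer",
  ifelse(startsWith(category, "mismatch"), "mismatch",
  ifelse(startsWith(category, "bulged"), "bulged", "noncanonical"))))))
}

#' Prepare the fixed-width target window for duplex prediction
#'
#' Interaction clusters are normalized to 75-nt windows: spans at most 75 nt
#' are extended symmetrically from the genome, spans of 76-100 nt are
#' trimmed symmetrically, and spans above 100 nt are omitted (structure
#' prediction over long intervals is unreliable).
#'
#' @param cluster one-row data.frame (chrom, start, end, strand).
#' @param genome named character vector of chromosome sequences.
#' @param width window width (default 75).
#' @param max_span longest usable cluster span (default 100).
#' @return list with `sequence` (strand-correct window, or NULL when
#'   omitted), `start`, `end` (possibly clipped window coordinates) and
#'   `clipped` flag; NULL when the cluster is omitted.
#' @export
prepare_target_window <- function(cluster, genome, width = 75L,
                                  max_span = 100L) {
  span <- cluster$end - cluster$start
  if (span > max_span) return(NULL)
  if (span >= width) {
    trim <- span - width
    s <- cluster$start + trim %/% 2L
    e <- s + width
  } else {
    pad <- width - span
    s <- cluster$start - pad %/% 2L
    e <- s + width
  }
  clen <- nchar(genome[[cluster$chrom]])
  clipped <- FALSE
  if (s < 0L) { s <- 0L; e <- min(width, clen); clipped <- TRUE }
  if (e > clen) { e <- clen; s <- max(0L, e - width); clipped <- TRUE }
  list(sequence = genome_subseq(genome, cluster$chrom, s, e,
                                cluster$strand),
       start = s, end = e, clipped = clipped)
}
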