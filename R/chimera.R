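# Chimera identification: tolerant reverse-matching of mature miRNAs inside
# reads, target segment extraction, genome mapping, PCR-duplicate
# collapsing, and interaction clustering.

#' Find mature miRNAs inside CLIP reads
#'
#' Reverse-matches every catalog miRNA (and its 1-nt 5'- or 3'-truncated
#' variants) against the read sequences. A hit tolerates at most 1 mismatch
#' within the first 18 nt of the matched miRNA and at most 2 mismatches in
#' total. When two or more miRNAs match at offsets within 4 nt of each
#' other, only the first in case-insensitive alphanumeric name order is
#' kept, so each ligation junction is represented once; hits more than 4 nt
#' apart (e.g. miRNA-miRNA chimeras) may coexist.
#'
#' @param reads data.frame from [read_fastq_reads()] (read_id, sequence,
#'   barcode, replicate_id).
#' @param catalog a [mirna_catalog()].
#' @param max_mismatch_first18 mismatches tolerated in the first 18 nt of
#'   the matched miRNA (default 1).
#' @param max_mismatch_total total mismatches tolerated (default 2).
#' @return data.frame of hits: read_idx, mirna_name, offset (0-based within
#'   the barcode-stripped read), matched_length, mismatches, truncation
#'   ("none", "5p1" or "3p1").
#' @export
find_mirna_in_reads <- function(reads, catalog,
                                max_mismatch_first18 = 1L,
                                max_mismatch_total = 2L) {
  stopifnot(nrow(catalog) > 0)
  subject <- Biostrings::DNAStringSet(reads$sequence)
  variants <- list(none = function(s) s,
                   `5p1` = function(s) substr(s, 2L, nchar(s)),
                   `3p1` = function(s) substr(s, 1L, nchar(s) - 1L))
  hits <- list()
  for (vi in names(variants)) {
    pats <- variants[[vi]](catalog$sequence)
    for (i in seq_len(nrow(catalog))) {
      m <- Biostrings::vmatchPattern(pats[i], subject,
                                     max.mismatch = max_mismatch_total)
      nh <- S4Vectors::elementNROWS(m)
      if (!sum(nh)) next
      um <- unlist(m)
      ridx <- rep(seq_along(nh), nh)
      # drop matches hanging off the read ends (end truncation is modeled
      # by the explicit variants, not by out-of-bounds mismatches)
      inb <- IRanges::start(um) >= 1L &
        IRanges::end(um) <= nchar(reads$sequence)[ridx]
      if (!any(inb)) next
      um <- um[inb]; ridx <- ridx[inb]
      hits[[length(hits) + 1L]] <- data.frame(
        read_idx = ridx,
        mirna_name = catalog$name[i],
        offset = IRanges::start(um) - 1L,
        matched_length = IRanges::width(um),
        pattern = pats[i],
        truncation = vi,
        stringsAsFactors = FALSE)
    }
  }
  empty <- data.frame(read_idx = integer(0), mirna_name = character(0),
                      offset = integer(0), matched_length = integer(0),
                      mismatches = integer(0), truncation = character(0))
  if (!length(hits)) return(empty)
  h <- do.call(rbind, hits)

  # mismatch accounting + first-18 rule
  obs <- substr(reads$sequence[h$read_idx], h$offset + 1L,
                h$offset + h$matched_length)
  keep <- logical(nrow(h))
  mms <- integer(nrow(h))
  for (j in seq_len(nrow(h))) {
    mp <- mismatch_positions(obs[j], h$pattern[j])
    mms[j] <- length(mp)
    keep[j] <- length(mp) <= max_mismatch_total &&
      sum(mp <= 18L) <= max_mismatch_first18
  }
  h$mismatches <- mms
  h <- h[keep, , drop = FALSE]
  if (!nrow(h)) return(empty)

  # per (read, miRNA, locus): keep the best variant
  # (fewest mismatches, then longest match, then leftmost)
  h <- h[order(h$read_idx, h$mirna_name, h$offset, h$mismatches,
               -h$matched_length, method = "radix"), , drop = FALSE]
  h <- resolve_read_loci(h)
  h$pattern <- NULL
  rownames(h) <- NULL
  h
}

# Group hits within each read into loci (offsets within 4 nt linked), pick
# one hit per locus: first alphanumeric miRNA name (case-insensitive), then
# fewest mismatches, longest match, smallest offset.
resolve_read_loci <- function(h) {
  ord <- order(h$read_idx, h$offset, method = "radix")
  h <- h[ord, , drop = FALSE]
  new_locus <- c(TRUE, diff(h$read_idx) != 0L | diff(h$offset) > 4L)
  locus <- cumsum(new_locus)
  pick <- order(locus, tolower(h$mirna_name), h$mismatches,
                -h$matched_length, h$offset, method = "radix")
  h <- h[pick, , drop = FALSE]
  h <- h[!duplicated(locus[pick]), , drop = FALSE]
  h[order(h$read_idx, h$offset, method = "radix"), , drop = FALSE]
}

#' Extract candidate target segments flanking a miRNA hit
#'
#' The read sequence downstream of the miRNA becomes a miRfirst candidate
#' and the sequence upstream a miRlast candidate; both can arise from one
#' read. Segments shorter than `min_len` (default 19 nt) are dropped.
#'
#' @param reads read table as in [find_mirna_in_reads()].
#' @param hits hit table from [find_mirna_in_reads()].
#' @param min_len minimum target length in nt.
#' @return data.frame: read_idx, mirna_name, chimera_type
#'   ("miRfirst"/"miRlast"), target_sequence, barcode, replicate_id.
#' @export
extract_target_segments <- function(reads, hits, min_len = 19L) {
  res <- list()
  seqs <- reads$sequence[hits$read_idx]
  up <- substr(seqs, 1L, hits$offset)
  down <- substr(seqs, hits$offset + hits$matched_length + 1L, nchar(seqs))
  for (side in c("down", "up")) {
    seg <- if (side == "down") down else up
    ok <- nchar(seg) >= min_len
    if (!any(ok)) next
    res[[side]] <- data.frame(
      read_idx = hits$read_idx[ok],
      mirna_name = hits$mirna_name[ok],
      chimera_type = if (side == "down") "miRfirst" else "miRlast",
      target_sequence = seg[ok],
      barcode = reads$barcode[hits$read_idx[ok]],
      replicate_id = reads$replicate_id[hits$read_idx[ok]],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res) %||%
    data.frame(read_idx = integer(0), mirna_name = character(0),
               chimera_type = character(0), target_sequence = character(0),
               barcode = character(0), replicate_id = character(0))
  rownames(out) <- NULL
  out
}

# Map segment sequences to the genome with the built-in tolerant matcher.
# Returns one row per uniquely-best-mapped sequence index; multi-mappers and
# unmapped sequences are absent.
map_segments <- function(sequences, genome, max_mismatch = 2L) {
  chroms <- names(genome)
  subj_chr <- c(genome, vapply(genome, reverse_complement, character(1)))
  subj <- Biostrings::DNAStringSet(subj_chr)
  strands <- rep(c("+", "-"), each = length(chroms))
  chrom_of <- rep(chroms, 2L)
  chrom_len <- nchar(genome)[chrom_of]
  uniq <- unique(sequences)
  maps <- vector("list", length(uniq))
  names(maps) <- uniq
  for (s in uniq) {
    m <- Biostrings::vmatchPattern(s, subj, max.mismatch = max_mismatch)
    nh <- S4Vectors::elementNROWS(m)
    if (!sum(nh)) next
    um <- unlist(m)
    si <- rep(seq_along(nh), nh)
    inb <- IRanges::start(um) >= 1L & IRanges::end(um) <= nchar(subj_chr)[si]
    if (!any(inb)) next
    um <- um[inb]; si <- si[inb]
    cand <- data.frame(chrom = chrom_of[si], strand = strands[si],
                       s1 = IRanges::start(um), e1 = IRanges::end(um),
                       len = chrom_len[si], stringsAsFactors = FALSE)
    patv <- strsplit(s, "")[[1]]
    cand$mm <- vapply(seq_len(nrow(cand)), function(j) {
      obs <- substr(subj_chr[[si[j]]], cand$s1[j], cand$e1[j])
      sum(strsplit(obs, "")[[1]] != patv)
    }, numeric(1))
    best <- cand[cand$mm == min(cand$mm), , drop = FALSE]
    if (nrow(best) != 1L) next  # multi-mapper at the best stratum
    # convert minus-strand (match on reverse-complemented chromosome) back
    # to forward coordinates, 0-based half-open
    if (best$strand == "-") {
      st <- best$len - best$e1
      en <- best$len - best$s1 + 1L
    } else {
      st <- best$s1 - 1L
      en <- best$e1
    }
    maps[[s]] <- data.frame(chrom = best$chrom, start = st, end = en,
                            strand = best$strand, mismatches = best$mm,
                            stringsAsFactors = FALSE)
  }
  found <- !vapply(maps, is.null, logical(1))
  if (!any(found)) {
    return(data.frame(sequence = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), mismatches = integer(0)))
  }
  out <- do.call(rbind, maps[found])
  out$sequence <- uniq[found]
  rownames(out) <- NULL
  out[, c("sequence", "chrom", "start", "end", "strand", "mismatches")]
}

#' Map target segments and collapse PCR duplicates
#'
#' Segments are mapped with the built-in tolerant matcher (unique best hit
#' with at most `max_mismatch` mismatches required; multi-mappers dropped).
#' Events identical in (target coordinates, strand, miRNA, barcode) collapse
#' to a single chimera; chimeras whose target falls within an annotated
#' miRNA precursor locus are removed.
#'
#' @param segments data.frame from [extract_target_segments()].
#' @param genome named character vector of chromosome sequences.
#' @param precursors optional data.frame of precursor loci (chrom, start,
#'   end, strand).
#' @param catalog optional [mirna_catalog()] used to attach family keys.
#' @param max_mismatch mapping tolerance (default 2).
#' @return data.frame of deduplicated chimeras: mirna_name, family_key,
#'   chimera_type, chrom, start, end, strand, target_sequence, replicate_id,
#'   barcode, n_reads (reads collapsed into the event). Attribute
#'   `counters` records dropped segment tallies.
#' @export
map_and_dedup <- function(segments, genome, precursors = NULL,
                          catalog = NULL, max_mismatch = 2L) {
  mapped <- map_segments(segments$target_sequence, genome,
                         max_mismatch = max_mismatch)
  idx <- match(segments$target_sequence, mapped$sequence)
  ok <- !is.na(idx)
  n_unmapped <- sum(!ok)
  ch <- cbind(segments[ok, , drop = FALSE],
              mapped[idx[ok], c("chrom", "start", "end", "strand"),
                     drop = FALSE])
  # PCR duplicates: same coordinates, strand, miRNA and barcode
  key <- paste(ch$chrom, ch$start, ch$end, ch$strand, ch$mirna_name,
               ch$barcode, sep = "\r")
  ord <- order(key, ch$replicate_id, method = "radix")
  ch <- ch[ord, , drop = FALSE]; key <- key[ord]
  n_reads <- as.integer(table(factor(key, levels = unique(key))))
  ch <- ch[!duplicated(key), , drop = FALSE]
  ch$n_reads <- n_reads
  n_dups <- sum(n_reads) - nrow(ch)

  n_precursor <- 0L
  if (!is.null(precursors) && nrow(ch)) {
    hit <- IRanges::overlapsAny(
      df_to_granges(ch), df_to_granges(precursors), ignore.strand = TRUE)
    n_precursor <- sum(hit)
    ch <- ch[!hit, , drop = FALSE]
  }
  if (!is.null(catalog)) {
    ch$family_key <- catalog$family_key[match(ch$mirna_name, catalog$name)]
  } else {
    ch$family_key <- rep(NA_character_, nrow(ch))
  }
  ch$read_idx <- NULL
  rownames(ch) <- NULL
  cols <- c("mirna_name", "family_key", "chimera_type", "chrom", "start",
            "end", "strand", "target_sequence", "replicate_id", "barcode",
            "n_reads")
  ch <- ch[, cols]
  attr(ch, "counters") <- c(unmapped_or_multi = n_unmapped,
                            pcr_duplicates = n_dups,
                            precursor_hits = n_precursor)
  ch
}

#' Call miRNA-target chimeras from read libraries
#'
#' Convenience wrapper running [find_mirna_in_reads()],
#' [extract_target_segments()] and [map_and_dedup()] over one or more
#' replicate read tables.
#'
#' @param reads a read data.frame or list of them (one per replicate).
#' @param catalog a [mirna_catalog()].
#' @param genome named character vector of chromosome sequences.
#' @param precursors optional precursor loci to filter against.
#' @param models optional `gene_models`; when given, chimeras gain region
#'   and gene_id columns via [annotate_intervals()].
#' @param min_target_len minimum target segment length (default 19).
#' @return deduplicated chimera data.frame (see [map_and_dedup()]).
#' @export
call_chimeras <- function(reads, catalog, genome, precursors = NULL,
                          models = NULL, min_target_len = 19L) {
  if (is.data.frame(reads)) reads <- list(reads)
  segs <- lapply(reads, function(r) {
    h <- find_mirna_in_reads(r, catalog)
    extract_target_segments(r, h, min_len = min_target_len)
  })
  segs <- do.call(rbind, segs)
  ch <- map_and_dedup(segs, genome, precursors = precursors,
                      catalog = catalog)
  if (!is.null(models) && nrow(ch)) {
    ann <- annotate_intervals(ch, models)
    ch$region <- ann$region
    ch$gene_id <- ann$gene_id
  }
  ch
}

#' Cluster chimeras into miRNA-target interactions
#'
#' Single-linkage clustering of chimera target intervals keyed by miRNA (or
#' seed family). Each cluster carries its unique-chimera count and its
#' biological complexity (BC): the number of distinct replicates
#' contributing members.
#'
#' @param chimeras deduplicated chimera data.frame.
#' @param level "mirna" or "family" clustering key.
#' @param models optional `gene_models` for region annotation of spans.
#' @param max_gap maximum merge gap in nt (default 0: overlap only).
#' @return list with `chimeras` (input plus cluster_id) and `clusters`
#'   (cluster_id, key, chrom, start, end, strand, chimera_count, BC and,
#'   when models given, region/gene_id).
#' @export
build_interaction_clusters <- function(chimeras, level = c("mirna", "family"),
                                       models = NULL, max_gap = 0L) {
  level <- match.arg(level)
  chimeras$key <- if (level == "mirna") chimeras$mirna_name else
    chimeras$family_key
  cl <- cluster_intervals(chimeras, key_col = "key", max_gap = max_gap)
  bc <- tapply(cl$records$replicate_id, cl$records$cluster_id,
               function(x) length(unique(x)))
  clusters <- cl$clusters
  clusters$chimera_count <- clusters$n_members
  clusters$n_members <- NULL
  clusters$BC <- as.integer(bc[as.character(clusters$cluster_id)])
  if (!is.null(models) && nrow(clusters)) {
    ann <- annotate_intervals(clusters, models)
    clusters$region <- ann$region
    clusters$gene_id <- ann$gene_id
  }
  list(chimeras = cl$records, clusters = clusters)
}
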