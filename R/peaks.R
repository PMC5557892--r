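# Exact read mapping for coverage and the simple peak caller used as a
# stand-in for an external peak-calling engine: peaks are contiguous
# regions of read-start-extended coverage above a height threshold, with
# nearby summits merged.

#' Map reads to the genome by exact unique matching
#'
#' Exact, zero-mismatch placement of full-length reads; reads with no hit
#' or with multiple genomic hits are dropped.
#'
#' @param sequences character vector of read sequences.
#' @param genome named character vector of chromosome sequences.
#' @return data.frame: seq_idx (index into `sequences`), chrom, start, end
#'   (0-based half-open), strand.
#' @export
map_reads_exact <- function(sequences, genome) {
  chroms <- names(genome)
  subj_chr <- c(genome, vapply(genome, reverse_complement, character(1)))
  subj <- Biostrings::DNAStringSet(subj_chr)
  strands <- rep(c("+", "-"), each = length(chroms))
  chrom_of <- rep(chroms, 2L)
  chrom_len <- nchar(genome)[chrom_of]
  res <- list()
  for (w in unique(nchar(sequences))) {
    idx <- which(nchar(sequences) == w)
    pats <- Biostrings::DNAStringSet(sequences[idx])
    pd <- Biostrings::PDict(pats)
    per <- list()
    for (sj in seq_along(subj)) {
      m <- Biostrings::matchPDict(pd, subj[[sj]])
      nh <- S4Vectors::elementNROWS(m)
      if (!sum(nh)) next
      um <- unlist(m)
      per[[length(per) + 1L]] <- data.frame(
        i = idx[rep(seq_along(nh), nh)], sj = sj,
        s1 = IRanges::start(um), e1 = IRanges::end(um))
    }
    if (length(per)) res[[length(res) + 1L]] <- do.call(rbind, per)
  }
  if (!length(res)) {
    return(data.frame(seq_idx = integer(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0)))
  }
  all <- do.call(rbind, res)
  nhit <- table(all$i)
  uniq <- as.integer(names(nhit)[nhit == 1L])
  all <- all[all$i %in% uniq, , drop = FALSE]
  st <- ifelse(all$sj > length(chroms),
               chrom_len[all$sj] - all$e1, all$s1 - 1L)
  en <- ifelse(all$sj > length(chroms),
               chrom_len[all$sj] - all$s1 + 1L, all$e1)
  out <- data.frame(seq_idx = all$i, chrom = chrom_of[all$sj],
                    start = as.integer(st), end = as.integer(en),
                    strand = strands[all$sj], stringsAsFactors = FALSE)
  out[order(out$seq_idx), , drop = FALSE]
}

#' Call peaks from read-start coverage
#'
#' Each mapped read contributes a fragment of `fragment_length` nt extending
#' from its 5' end in the strand direction. Peaks are maximal regions with
#' coverage at least `min_height`; regions whose summits lie closer than
#' `min_distance` nt are merged into one peak whose height is the maximum
#' coverage attained.
#'
#' @param mapped data.frame of mapped reads: chrom, start, end, strand
#'   (0-based half-open; deduplicated).
#' @param chrom_sizes named vector of chromosome lengths.
#' @param fragment_length fragment extension in nt (default 53).
#' @param min_distance minimum inter-summit distance in nt (default 75).
#' @param min_height coverage threshold; `NULL` (default) uses
#'   max(2, 99.9% Poisson tail of the per-strand background rate). This is a
#'   height threshold, not a significance model.
#' @param total_reads library size used for height normalization (default
#'   `nrow(mapped)`).
#' @return data.frame of peaks: chrom, start, end, strand, height,
#'   normalized_height (height per million library reads).
#' @export
call_peaks_simple <- function(mapped, chrom_sizes, fragment_length = 53L,
                              min_distance = 75L, min_height = NULL,
                              total_reads = nrow(mapped)) {
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      height = integer(0), normalized_height = numeric(0))
  if (!nrow(mapped)) return(empty)
  frag_start <- ifelse(mapped$strand == "+", mapped$start,
                       pmax(0L, mapped$end - fragment_length))
  frag_end <- ifelse(mapped$strand == "+",
                     pmin(chrom_sizes[mapped$chrom],
                          mapped$start + fragment_length),
                     mapped$end)
  peaks <- list()
  for (str in unique(mapped$strand)) {
    sel <- mapped$strand == str
    if (is.null(min_height)) {
      lambda <- sum(frag_end[sel] - frag_start[sel]) / sum(chrom_sizes)
      mh <- max(2L, stats::qpois(0.999, lambda))
    } else mh <- min_height
    for (chr in unique(mapped$chrom[sel])) {
      cs <- sel & mapped$chrom == chr
      if (!any(cs)) next
      cov <- IRanges::coverage(
        IRanges::IRanges(frag_start[cs] + 1L, frag_end[cs]),
        width = chrom_sizes[[chr]])
      sl <- IRanges::slice(cov, lower = mh)
      if (!length(sl)) next
      rs <- IRanges::start(sl); re <- IRanges::end(sl)
      hmax <- IRanges::viewMaxs(sl)
      summit <- IRanges::viewWhichMaxs(sl)
      # merge regions with summits closer than min_distance
      grp <- cumsum(c(1L, diff(summit) >= min_distance))
      peaks[[length(peaks) + 1L]] <- data.frame(
        chrom = chr,
        start = as.integer(tapply(rs, grp, min)) - 1L,
        end = as.integer(tapply(re, grp, max)),
        strand = str,
        height = as.integer(tapply(hmax, grp, max)),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, peaks) %||% empty
  rownames(out) <- NULL
  out$normalized_height <- out$height / total_reads * 1e6
  out[order(out$chrom, out$start), , drop = FALSE]
}
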