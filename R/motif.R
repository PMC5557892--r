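# Enumerative de novo 7mer motif discovery on chimera target windows.
# Every 7mer is scored by a hypergeometric presence/absence enrichment of
# foreground over background windows; candidate motifs are then screened by
# their match to the cognate miRNA (s), the information content of their
# occurrence profile, and a combined confidence statistic
#   c = (-log10(p) - 10)/10 + (s - 0.35) * 6.7.

all_kmers <- function(k = 7L) {
  do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), k),
                              stringsAsFactors = FALSE)[, k:1])
}

#' Assemble motif foreground and background sequence sets for one miRNA
#'
#' A miRNA is eligible when it has at least `min_chimeras` chimeras spread
#' over at least `min_clusters` interaction clusters. The background is 5x
#' the foreground size, sampled uniformly without replacement from the
#' windows of other miRNAs, excluding any miRNA sharing the same seed
#' family (identical canonical sites would contaminate the null). Three
#' replicate backgrounds with distinct seeds support triplicate runs.
#'
#' @param windows data.frame with columns mirna_name, family_key,
#'   cluster_id, window (75-nt target window sequence).
#' @param mirna miRNA to build sets for.
#' @param min_chimeras,min_clusters eligibility thresholds (defaults 50
#'   and 40).
#' @param bg_ratio background multiple of the foreground (default 5).
#' @param n_replicates number of background replicates (default 3).
#' @param seed base RNG seed; replicate r uses seed + r - 1.
#' @return NULL when ineligible; else list with `foreground` (character),
#'   `backgrounds` (list of character vectors) and `with_replacement` flag
#'   (TRUE when the background pool was too small, flagged).
#' @export
build_motif_sets <- function(windows, mirna, min_chimeras = 50L,
                             min_clusters = 40L, bg_ratio = 5L,
                             n_replicates = 3L, seed = 1L) {
  fg <- windows[windows$mirna_name == mirna, , drop = FALSE]
  if (nrow(fg) < min_chimeras ||
      length(unique(fg$cluster_id)) < min_clusters) return(NULL)
  fam <- fg$family_key[1]
  pool <- windows$window[windows$family_key != fam]
  need <- bg_ratio * nrow(fg)
  replace <- length(pool) < need
  backgrounds <- lapply(seq_len(n_replicates), function(r) {
    set.seed(seed + r - 1L)
    sample(pool, need, replace = replace)
  })
  list(foreground = fg$window, backgrounds = backgrounds,
       with_replacement = replace)
}

# Presence/absence of each 7mer per sequence -> named presence counts.
kmer_presence_counts <- function(seqs, k = 7L) {
  ss <- Biostrings::DNAStringSet(seqs)
  cnt <- Biostrings::oligonucleotideFrequency(ss, width = k)
  colSums(cnt > 0L)
}

#' Hypergeometric 7mer enrichment of foreground over background
#'
#' For each of the 4^7 7mers, sequences are scored present/absent and the
#' enrichment p-value is the hypergeometric upper tail of the foreground
#' presence count given the pooled presence count.
#'
#' @param foreground,background character vectors of window sequences.
#' @param k motif length (default 7).
#' @return data.frame (one row per 7mer with at least one foreground
#'   occurrence): motif, fg_present, bg_present, p_value; sorted by
#'   ascending p.
#' @export
motif_enrichment <- function(foreground, background, k = 7L) {
  stopifnot(length(foreground) > 0, length(background) > 0)
  fgc <- kmer_presence_counts(foreground, k)
  bgc <- kmer_presence_counts(background, k)
  nf <- length(foreground); nb <- length(background)
  keep <- fgc > 0L
  kv <- fgc[keep]; Kv <- kv + bgc[keep]
  p <- stats::phyper(kv - 1L, Kv, nf + nb - Kv, nf, lower.tail = FALSE)
  out <- data.frame(motif = names(kv), fg_present = as.integer(kv),
                    bg_present = as.integer(bgc[keep]), p_value = p,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$motif, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Match score of a motif against its cognate miRNA
#'
#' Slides the motif along the reverse complement of the mature miRNA at
#' every ungapped full-overlap offset; s is the best fraction of identical
#' positions. The reported miRNA position is the one opposite the motif's
#' 3' end at the best offset (ties resolved toward the miRNA 5' end), i.e.
#' a seed-complementary motif reports position 2.
#'
#' @param motif 7-nt motif string.
#' @param mirna mature miRNA sequence.
#' @return list with `s` (in 0..1) and `mirna_position`.
#' @export
match_score <- function(motif, mirna) {
  motif <- strsplit(normalize_dna(motif), "")[[1]]
  k <- length(motif)
  rc <- strsplit(reverse_complement(mirna), "")[[1]]
  L <- length(rc)
  stopifnot(L >= k)
  best_s <- -1; best_pos <- NA_integer_
  for (o in seq_len(L - k + 1L)) {
    s <- sum(rc[o:(o + k - 1L)] == motif) / k
    pos <- L - (o + k - 1L) + 1L  # miRNA position opposite the motif 3' end
    if (s > best_s || (s == best_s && pos < best_pos)) {
      best_s <- s; best_pos <- pos
    }
  }
  list(s = best_s, mirna_position = best_pos)
}

#' Combined motif confidence
#'
#' c = (-log10(p) - 10)/10 + (s - 0.35) * 6.7. Zero p-values are replaced
#' by the smallest representable positive double (flagged by attribute).
#'
#' @param p enrichment p-value(s) in (0, 1].
#' @param s match score(s) in [0, 1].
#' @return numeric confidence value(s).
#' @export
motif_confidence <- function(p, s) {
  flagged <- p == 0
  p[flagged] <- .Machine$double.xmin
  out <- (-log10(p) - 10) / 10 + (s - 0.35) * 6.7
  attr(out, "zero_p_replaced") <- any(flagged)
  out
}

# Information content per bp (bits) of a PWM with uniform background:
# mean over columns of 2 - H_j.
pwm_ic_per_bp <- function(pwm) {
  h <- apply(pwm, 2, function(col) {
    col <- col[col > 0]
    -sum(col * log2(col))
  })
  mean(2 - h)
}

# PWM from all occurrences of `motif` in `seqs` allowing <= 1 mismatch.
motif_pwm <- function(motif, seqs, max_mismatch = 1L) {
  pat <- Biostrings::DNAString(motif)
  ss <- Biostrings::DNAStringSet(seqs)
  m <- Biostrings::vmatchPattern(pat, ss, max.mismatch = max_mismatch)
  nh <- S4Vectors::elementNROWS(m)
  if (!sum(nh)) return(NULL)
  um <- unlist(m)
  occ <- substr(rep(seqs, nh), IRanges::start(um), IRanges::end(um))
  mat <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(occ),
                                     baseOnly = TRUE)[1:4, , drop = FALSE]
  sweep(mat, 2, colSums(mat), "/")
}

#' Score, filter and report motifs for one miRNA
#'
#' Runs [motif_enrichment()] on each background replicate, attaches the
#' match score, PWM information content and combined confidence, and
#' applies the screening thresholds s >= 0.35, IC/bp >= 1.75 and c >= 1.
#'
#' @param sets output of [build_motif_sets()].
#' @param mirna_seq mature sequence of the cognate miRNA.
#' @param top number of top-ranked motifs evaluated per replicate
#'   (default 30; the hypergeometric ranking is computed for all 7mers).
#' @param s_min,ic_min,c_min screening thresholds (defaults 0.35, 1.75, 1).
#' @return data.frame of evaluated motifs with columns motif, replicate,
#'   p_value, s, mirna_position, ic_per_bp, confidence, pass.
#' @export
score_motifs <- function(sets, mirna_seq, top = 30L,
                         s_min = 0.35, ic_min = 1.75, c_min = 1) {
  res <- list()
  for (r in seq_along(sets$backgrounds)) {
    enr <- motif_enrichment(sets$foreground, sets$backgrounds[[r]])
    enr <- utils::head(enr, top)
    for (i in seq_len(nrow(enr))) {
      ms <- match_score(enr$motif[i], mirna_seq)
      pwm <- motif_pwm(enr$motif[i], sets$foreground)
      ic <- if (is.null(pwm)) 0 else pwm_ic_per_bp(pwm)
      cc <- as.numeric(motif_confidence(enr$p_value[i], ms$s))
      res[[length(res) + 1L]] <- data.frame(
        motif = enr$motif[i], replicate = r, p_value = enr$p_value[i],
        s = ms$s, mirna_position = ms$mirna_position, ic_per_bp = ic,
        confidence = cc,
        pass = ms$s >= s_min && ic >= ic_min && cc >= c_min,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Positional motif-presence heatmap across miRNAs
#'
#' For each miRNA, the percentage of its foreground windows containing a
#' passing motif mapped to each miRNA position. Rows are ordered by
#' hierarchical clustering (average linkage, Euclidean distance).
#'
#' @param motif_tables named list (by miRNA) of [score_motifs()] outputs.
#' @param windows_by_mirna named list of foreground window sets.
#' @param max_position number of miRNA positions (columns; default 24).
#' @return numeric matrix miRNA x position of percent presence (zero rows
#'   for miRNAs with no passing motif), row-ordered by clustering.
#' @export
positional_heatmap <- function(motif_tables, windows_by_mirna,
                               max_position = 24L) {
  mirnas <- names(motif_tables)
  mat <- matrix(0, length(mirnas), max_position,
                dimnames = list(mirnas, seq_len(max_position)))
  for (mi in mirnas) {
    tab <- motif_tables[[mi]]
    tab <- tab[tab$pass, , drop = FALSE]
    if (!nrow(tab)) next
    fg <- windows_by_mirna[[mi]]
    for (pos in unique(tab$mirna_position)) {
      if (pos > max_position) next
      motifs <- unique(tab$motif[tab$mirna_position == pos])
      present <- Reduce(`|`, lapply(motifs, function(m)
        grepl(m, fg, fixed = TRUE)))
      mat[mi, pos] <- 100 * mean(present)
    }
  }
  if (nrow(mat) > 2L) {
    ord <- stats::hclust(stats::dist(mat), method = "average")$order
    mat <- mat[ord, , drop = FALSE]
  }
  mat
}
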