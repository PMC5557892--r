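# Expression normalization, the AGO sequestration coefficient (ASC),
# GO gene-set selection, cooperativity consensus clustering and ceRNA
# region detection.

#' Compute expression abundance measures
#'
#' @param counts data.frame with gene_id plus one or more integer count
#'   columns (samples of one condition).
#' @param gene_lengths named vector of mature transcript lengths in nt.
#' @param min_tags expression threshold: a gene is `expressed` when its
#'   summed raw count reaches this value (default 100).
#' @return data.frame: gene_id, count (summed), cpm, rpkm, expressed.
#' @export
compute_abundance <- function(counts, gene_lengths, min_tags = 100L) {
  cnt <- rowSums(counts[, -1, drop = FALSE])
  lib <- sum(cnt)
  if (lib == 0) stop("zero library size")
  len <- gene_lengths[counts$gene_id]
  if (any(is.na(len) | len <= 0)) stop("missing or non-positive gene length")
  cpm <- cnt / lib * 1e6
  data.frame(gene_id = counts$gene_id, count = as.numeric(cnt),
             cpm = cpm, rpkm = cpm / (len / 1000),
             expressed = cnt >= min_tags,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' AGO sequestration coefficients per (gene, miRNA family)
#'
#' For each family with at least `min_family_chimeras` chimeras on 3'UTRs
#' (the 3'UTR label includes the downstream extension), the ASC of gene r is
#' log2( (chimeras_f(r) / chimeras_f(total)) / RPKM(r) ): the gene's share
#' of the family's chimera pool normalized by its expression. High ASC
#' marks disproportionately targeted transcripts. The lower level of
#' quantification (lloq) is the ASC implied by a single chimera at the
#' gene's RPKM.
#'
#' @param chimeras annotated chimera data.frame (family_key, gene_id,
#'   region columns).
#' @param abundance output of [compute_abundance()].
#' @param min_family_chimeras family eligibility threshold (default 500).
#' @param region region label whose chimeras are counted (default "3'UTR").
#' @return data.frame: family_key, gene_id, n_chimeras, total_chimeras,
#'   rpkm, asc (NA, flagged, when rpkm is 0), lloq. Genes with zero family
#'   chimeras (non-targeted) are absent.
#' @export
compute_asc <- function(chimeras, abundance, min_family_chimeras = 500L,
                        region = "3'UTR") {
  ch <- chimeras[!is.na(chimeras$gene_id) & chimeras$region == region, ,
                 drop = FALSE]
  fam_tot <- table(ch$family_key)
  fams <- names(fam_tot)[fam_tot >= min_family_chimeras]
  if (!length(fams)) {
    return(data.frame(family_key = character(0), gene_id = character(0),
                      n_chimeras = integer(0), total_chimeras = integer(0),
                      rpkm = numeric(0), asc = numeric(0),
                      lloq = numeric(0)))
  }
  ch <- ch[ch$family_key %in% fams, , drop = FALSE]
  agg <- as.data.frame(table(family_key = ch$family_key,
                             gene_id = ch$gene_id),
                       stringsAsFactors = FALSE)
  agg <- agg[agg$Freq > 0L, , drop = FALSE]
  agg$total_chimeras <- as.integer(fam_tot[agg$family_key])
  agg$rpkm <- abundance$rpkm[match(agg$gene_id, abundance$gene_id)]
  agg$asc <- ifelse(agg$rpkm > 0,
                    log2((agg$Freq / agg$total_chimeras) / agg$rpkm),
                    NA_real_)
  agg$lloq <- ifelse(agg$rpkm > 0,
                     log2((1 / agg$total_chimeras) / agg$rpkm), NA_real_)
  names(agg)[names(agg) == "Freq"] <- "n_chimeras"
  rownames(agg) <- NULL
  agg[, c("family_key", "gene_id", "n_chimeras", "total_chimeras", "rpkm",
          "asc", "lloq")]
}

#' Select the high-ASC gene set of a family for GO export
#'
#' Genes whose ASC exceeds the family mean (computed over targeted genes
#' with a defined ASC only; strict inequality) are selected; the background
#' is every gene in the expression table.
#'
#' @param asc_records output of [compute_asc()].
#' @param family family key to select for.
#' @return list with `genes` (character vector, possibly empty),
#'   `background` (all gene_ids in the records) and `mean_asc`.
#' @export
select_go_geneset <- function(asc_records, family) {
  rec <- asc_records[asc_records$family_key == family &
                       !is.na(asc_records$asc), , drop = FALSE]
  if (!nrow(rec)) {
    return(list(genes = character(0),
                background = unique(asc_records$gene_id),
                mean_asc = NA_real_))
  }
  m <- mean(rec$asc)
  list(genes = sort(rec$gene_id[rec$asc > m]),
       background = unique(asc_records$gene_id), mean_asc = m)
}

#' Gene x family ASC matrix
#'
#' @param asc_records output of [compute_asc()].
#' @param genes optional gene universe for rows (default: genes appearing
#'   in the records).
#' @return numeric matrix (genes x families); NA marks non-targeted cells.
#' @export
asc_matrix <- function(asc_records, genes = NULL) {
  fams <- sort(unique(asc_records$family_key))
  genes <- genes %||% sort(unique(asc_records$gene_id))
  mat <- matrix(NA_real_, length(genes), length(fams),
                dimnames = list(genes, fams))
  idx <- cbind(match(asc_records$gene_id, genes),
               match(asc_records$family_key, fams))
  ok <- !is.na(idx[, 1])
  mat[idx[ok, , drop = FALSE]] <- asc_records$asc[ok]
  mat
}

#' Consensus k-means cooperativity of miRNA families
#'
#' Genes are clustered by their family-specific ASC profiles in several
#' independent k-means iterations. A cluster's signature is the set of
#' families whose within-cluster mean ASC exceeds their global mean by at
#' least `margin` standard deviations of that family's ASC column (a
#' scale-free enrichment rule: random independent columns then produce no
#' recurrent signatures); signatures recurring in at least `min_support`
#' iterations define cooperative family combinations. Non-targeted cells
#' are imputed to one unit below the smallest defined ASC.
#'
#' @param mat gene x family ASC matrix ([asc_matrix()]), NAs allowed.
#' @param k clusters per iteration (default 45).
#' @param n_starts k-means random restarts per iteration (default 1000;
#'   the analysis scales up to 100000).
#' @param iterations independent clustering iterations (default 3).
#' @param min_support iterations a signature must recur in (default 3;
#'   2 admits borderline combinations).
#' @param margin enrichment margin in column-sd units (default 1.0).
#' @param seed RNG seed; iteration i uses seed + i - 1.
#' @return object of class `cooperativity`: list with `signatures`
#'   (data.frame signature, size, support), `pairwise` (family x family
#'   matrix of support counts, symmetric) and `iterations` (per-iteration
#'   signature lists).
#' @export
cooperativity_consensus <- function(mat, k = 45L, n_starts = 1000L,
                                    iterations = 3L, min_support = 3L,
                                    margin = 1.0, seed = 1L) {
  if (k > nrow(mat)) stop("more clusters than genes")
  floor_val <- min(mat, na.rm = TRUE) - 1
  mat[is.na(mat)] <- floor_val
  gmean <- colMeans(mat)
  gsd <- apply(mat, 2, stats::sd)
  gsd[gsd == 0] <- 1
  fams <- colnames(mat)
  per_iter <- vector("list", iterations)
  for (it in seq_len(iterations)) {
    set.seed(seed + it - 1L)
    km <- stats::kmeans(mat, centers = k, nstart = n_starts,
                        iter.max = 50L)
    sigs <- character(0)
    for (cl in seq_len(k)) {
      rows <- km$cluster == cl
      if (!any(rows)) next
      cm <- colMeans(mat[rows, , drop = FALSE])
      sig <- fams[cm >= gmean + margin * gsd]
      if (length(sig)) sigs <- c(sigs, paste(sort(sig), collapse = "+"))
    }
    per_iter[[it]] <- unique(sigs)
  }
  all_sigs <- unique(unlist(per_iter))
  support <- vapply(all_sigs, function(s)
    sum(vapply(per_iter, function(x) s %in% x, logical(1))), integer(1))
  keep <- support >= min_support
  signatures <- data.frame(
    signature = all_sigs[keep],
    size = lengths(strsplit(all_sigs[keep], "+", fixed = TRUE)),
    support = support[keep], row.names = NULL, stringsAsFactors = FALSE)
  pairwise <- matrix(0L, length(fams), length(fams),
                     dimnames = list(fams, fams))
  for (i in seq_len(nrow(signatures))) {
    mem <- strsplit(signatures$signature[i], "+", fixed = TRUE)[[1]]
    if (length(mem) < 2L) next
    for (a in mem) for (b in mem) if (a != b) {
      pairwise[a, b] <- max(pairwise[a, b], signatures$support[i])
    }
  }
  structure(list(signatures = signatures, pairwise = pairwise,
                 iterations = per_iter),
            class = "cooperativity")
}

#' @export
print.cooperativity <- function(x, ...) {
  cat("cooperativity:", nrow(x$signatures), "recurrent signatures over",
      length(x$iterations), "iterations\n")
  if (nrow(x$signatures)) print(x$signatures)
  invisible(x)
}

#' Detect candidate ceRNA regions
#'
#' Reports every maximal genomic window of at most `window` bp (per
#' chromosome and strand) containing at least `min_clusters` interaction
#' clusters that each hold at least `min_chimeras` unique chimeras.
#'
#' @param clusters interaction cluster data.frame (chrom, start, end,
#'   strand, chimera_count).
#' @param window window span cap in bp (default 3000).
#' @param min_clusters minimum qualifying clusters per window (default 3).
#' @param min_chimeras minimum unique chimeras per cluster (default 5).
#' @param models optional `gene_models` for region annotation.
#' @return data.frame of regions: chrom, start, end, strand, n_clusters
#'   (plus region/gene_id when models given).
#' @export
detect_cerna_regions <- function(clusters, window = 3000L,
                                 min_clusters = 3L, min_chimeras = 5L,
                                 models = NULL) {
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      n_clusters = integer(0))
  q <- clusters[clusters$chimera_count >= min_chimeras, , drop = FALSE]
  if (nrow(q) < min_clusters) return(empty)
  out <- list()
  for (grp in split(q, paste(q$chrom, q$strand))) {
    grp <- grp[order(grp$start, grp$end), , drop = FALSE]
    n <- nrow(grp)
    for (i in seq_len(n)) {
      inside <- which(grp$start >= grp$start[i] &
                        grp$end <= grp$start[i] + window)
      if (length(inside) < min_clusters) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = grp$chrom[1], start = grp$start[i],
        end = max(grp$end[inside]), strand = grp$strand[1],
        n_clusters = length(inside), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out) %||% empty
  if (!nrow(res)) return(empty)
  # keep maximal regions only (drop windows contained in another)
  keep <- rep(TRUE, nrow(res))
  for (i in seq_len(nrow(res))) {
    contained <- res$chrom == res$chrom[i] & res$strand == res$strand[i] &
      res$start <= res$start[i] & res$end >= res$end[i] &
      seq_len(nrow(res)) != i &
      !(res$start == res$start[i] & res$end == res$end[i] &
          seq_len(nrow(res)) < i)
    if (any(contained & keep)) keep[i] <- FALSE
  }
  res <- res[keep, , drop = FALSE]
  res <- res[!duplicated(res[, c("chrom", "start", "end", "strand")]), ,
             drop = FALSE]
  rownames(res) <- NULL
  if (!is.null(models) && nrow(res)) {
    ann <- annotate_intervals(res, models)
    res$region <- ann$region
    res$gene_id <- ann$gene_id
  }
  res
}
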