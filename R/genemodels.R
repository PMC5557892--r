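# Gene models, region annotation and interval clustering.
#
# Internal coordinate convention: 0-based half-open [start, end) plus strand,
# carried in plain data.frames with columns chrom, start, end, strand.
# GTF is read as 1-based inclusive and converted; BED is written 0-based
# half-open. GRanges (1-based) are used internally for overlap arithmetic.

# data.frame (0-based half-open) -> GRanges (1-based closed)
df_to_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = df$strand
  )
}

granges_to_df <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
}

#' Read gene models from a GTF file
#'
#' Builds per-gene labeled regions (5'UTR, CDS, 3'UTR, introns) from GTF
#' features. Because 3'-end annotation of draft genomes is frequently
#' incomplete, every 3'UTR is extended by a derived downstream region
#' (default 10 kb) that inherits the 3'UTR label during annotation.
#'
#' @param path GTF file; feature types `five_prime_utr` (or `5UTR`), `CDS`,
#'   `three_prime_utr` (or `3UTR`) and optionally `exon` are used. Intronic
#'   intervals are derived as within-gene gaps between labeled regions.
#' @param downstream extension length in nt appended past each 3'UTR end on
#'   the transcript strand (default 10000).
#' @param chrom_sizes optional named vector of chromosome lengths used to
#'   clip derived regions.
#' @return an object of class `gene_models`: list with `regions` (data.frame
#'   chrom/start/end/strand/type/gene_id, 0-based half-open), `genes`
#'   (gene_id, mature_length = total exonic nt) and `downstream`.
#' @export
read_gene_models <- function(path, downstream = 10000L, chrom_sizes = NULL) {
  gtf <- rtracklayer::import(path, format = "gtf")
  df <- granges_to_df(gtf)
  df$type <- as.character(gtf$type)
  df$gene_id <- as.character(gtf$gene_id)
  gene_models_from_regions(df, downstream = downstream,
                           chrom_sizes = chrom_sizes)
}

#' Construct gene models from a region table
#'
#' @param regions data.frame with chrom, start, end (0-based half-open),
#'   strand, type, gene_id. Types `five_prime_utr`/`5UTR`/`utr5`,
#'   `CDS`/`cds`, `three_prime_utr`/`3UTR`/`utr3` are recognized; others
#'   (e.g. `exon`, `transcript`) are ignored for labeling but contribute to
#'   the gene span used to derive introns.
#' @inheritParams read_gene_models
#' @return a `gene_models` object.
#' @export
gene_models_from_regions <- function(regions, downstream = 10000L,
                                     chrom_sizes = NULL) {
  type_map <- c(five_prime_utr = "utr5", `5UTR` = "utr5", utr5 = "utr5",
                CDS = "cds", cds = "cds",
                three_prime_utr = "utr3", `3UTR` = "utr3", utr3 = "utr3",
                intron = "intron")
  regions$label <- unname(type_map[regions$type])
  lab <- regions[!is.na(regions$label),
                 c("chrom", "start", "end", "strand", "label", "gene_id")]
  names(lab)[names(lab) == "label"] <- "type"

  # derive introns as within-gene gaps not covered by any labeled region
  out <- lapply(split(lab, lab$gene_id), function(g) {
    g <- g[order(g$start), , drop = FALSE]
    span_start <- min(g$start); span_end <- max(g$end)
    cov <- IRanges::reduce(IRanges::IRanges(g$start + 1L, g$end))
    gaps <- IRanges::setdiff(IRanges::IRanges(span_start + 1L, span_end), cov)
    if (length(gaps) && !any(g$type == "intron")) {
      g <- rbind(g, data.frame(
        chrom = g$chrom[1], start = IRanges::start(gaps) - 1L,
        end = IRanges::end(gaps), strand = g$strand[1],
        type = "intron", gene_id = g$gene_id[1]))
    }
    # downstream extension abutting the 3'UTR end on the transcript strand
    u3 <- g[g$type == "utr3", , drop = FALSE]
    if (nrow(u3) && downstream > 0) {
      if (g$strand[1] == "+") {
        ds <- max(u3$end)
        dse <- ds + downstream
        if (!is.null(chrom_sizes) && g$chrom[1] %in% names(chrom_sizes))
          dse <- min(dse, chrom_sizes[[g$chrom[1]]])
        if (dse > ds)
          g <- rbind(g, data.frame(chrom = g$chrom[1], start = ds, end = dse,
                                   strand = "+", type = "downstream10k",
                                   gene_id = g$gene_id[1]))
      } else {
        ds <- min(u3$start)
        dss <- max(0L, ds - downstream)
        if (dss < ds)
          g <- rbind(g, data.frame(chrom = g$chrom[1], start = dss, end = ds,
                                   strand = "-", type = "downstream10k",
                                   gene_id = g$gene_id[1]))
      }
    }
    g
  })
  reg <- do.call(rbind, out)
  rownames(reg) <- NULL

  exonic <- reg[reg$type %in% c("utr5", "cds", "utr3"), , drop = FALSE]
  glen <- tapply(exonic$end - exonic$start, exonic$gene_id, sum)
  genes <- data.frame(gene_id = names(glen),
                      mature_length = as.integer(glen),
                      stringsAsFactors = FALSE)
  rownames(genes) <- NULL

  structure(list(regions = reg, genes = genes,
                 downstream = as.integer(downstream),
                 chrom_sizes = chrom_sizes),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", nrow(x$genes), "genes,", nrow(x$regions),
      "labeled regions (3'UTRs extended by", x$downstream, "nt)\n")
  invisible(x)
}

#' Annotate genomic intervals with genic region labels
#'
#' Labels each interval with one of 3'UTR, CDS, 5'UTR, intron or intergenic
#' plus the supporting gene. An interval overlapping an annotated 3'UTR *or
#' its downstream extension* is labeled 3'UTR. Precedence is
#' 3'UTR > CDS > 5'UTR > intron > intergenic; within the winning label, ties
#' are broken by larger overlap and then lexicographic gene_id. Annotation is
#' strand-aware.
#'
#' @param intervals data.frame with chrom, start, end, strand
#'   (0-based half-open).
#' @param models a `gene_models` object.
#' @return data.frame with columns `region` (factor-free character:
#'   "3'UTR", "CDS", "5'UTR", "intron", "intergenic") and `gene_id`
#'   (NA for intergenic), one row per input interval, in input order.
#' @export
annotate_intervals <- function(intervals, models) {
  stopifnot(inherits(models, "gene_models"))
  n <- nrow(intervals)
  region <- rep("intergenic", n)
  gene <- rep(NA_character_, n)
  if (n == 0L) return(data.frame(region = character(0),
                                 gene_id = character(0)))

  known <- unique(models$regions$chrom)
  if (any(!intervals$chrom %in% known)) {
    warning("intervals on chromosomes absent from the annotation were ",
            "labeled intergenic")
  }

  q <- df_to_granges(intervals)
  prio <- list(`3'UTR` = c("utr3", "downstream10k"),
               CDS = "cds", `5'UTR` = "utr5", intron = "intron")
  unassigned <- rep(TRUE, n)
  for (lab in names(prio)) {
    sub <- models$regions[models$regions$type %in% prio[[lab]], , drop = FALSE]
    if (!nrow(sub)) next
    s <- df_to_granges(sub)
    # seqlevel mismatches already warned about above
    hits <- suppressWarnings(GenomicRanges::findOverlaps(q, s))
    hits <- hits[unassigned[S4Vectors::queryHits(hits)]]
    if (!length(hits)) next
    ov <- GenomicRanges::width(suppressWarnings(GenomicRanges::pintersect(
      q[S4Vectors::queryHits(hits)], s[S4Vectors::subjectHits(hits)])))
    hd <- data.frame(qi = S4Vectors::queryHits(hits),
                     gene = sub$gene_id[S4Vectors::subjectHits(hits)],
                     ov = ov)
    # largest overlap wins; ties by lexicographic gene_id
    hd <- hd[order(hd$qi, -hd$ov, hd$gene, method = "radix"), , drop = FALSE]
    hd <- hd[!duplicated(hd$qi), , drop = FALSE]
    region[hd$qi] <- lab
    gene[hd$qi] <- hd$gene
    unassigned[hd$qi] <- FALSE
  }
  data.frame(region = region, gene_id = gene, stringsAsFactors = FALSE)
}

#' Single-linkage clustering of keyed genomic intervals
#'
#' Merges intervals that share a key (e.g. miRNA or family) and strand and
#' that overlap, or whose gap is at most `max_gap` nt. The cluster span is
#' the union of member spans. With `max_gap = 0` only genuinely overlapping
#' intervals merge (half-open adjacency is not overlap).
#'
#' @param records data.frame with chrom, start, end, strand plus a key
#'   column.
#' @param key_col name of the key column (default "key").
#' @param max_gap maximum tolerated gap in nt between merged intervals.
#' @return list with `records` (input plus `cluster_id`) and `clusters`
#'   (cluster_id, key, chrom, start, end, strand, n_members).
#' @export
cluster_intervals <- function(records, key_col = "key", max_gap = 0L) {
  n <- nrow(records)
  if (n == 0L) {
    return(list(records = cbind(records, cluster_id = integer(0)),
                clusters = data.frame(cluster_id = integer(0),
                                      key = character(0), chrom = character(0),
                                      start = integer(0), end = integer(0),
                                      strand = character(0),
                                      n_members = integer(0))))
  }
  key <- as.character(records[[key_col]])
  ord <- order(key, records$chrom, records$strand, records$start,
               records$end, method = "radix")
  k <- key[ord]; ch <- records$chrom[ord]; st <- records$strand[ord]
  s <- records$start[ord]; e <- records$end[ord]
  cid <- integer(n)
  cur <- 0L; cur_end <- -Inf
  for (i in seq_len(n)) {
    new_group <- i == 1L || k[i] != k[i - 1L] || ch[i] != ch[i - 1L] ||
      st[i] != st[i - 1L]
    if (new_group || s[i] - cur_end > max_gap ||
        (max_gap == 0L && s[i] >= cur_end)) {
      cur <- cur + 1L
      cur_end <- e[i]
    } else {
      cur_end <- max(cur_end, e[i])
    }
    cid[i] <- cur
  }
  cluster_id <- integer(n)
  cluster_id[ord] <- cid
  first <- ord[!duplicated(cid)]
  clusters <- data.frame(
    cluster_id = seq_len(max(cid)),
    key = key[first],
    chrom = records$chrom[first],
    start = as.integer(tapply(s, cid, min)),
    end = as.integer(tapply(e, cid, max)),
    strand = records$strand[first],
    n_members = as.integer(tabulate(cid)),
    stringsAsFactors = FALSE
  )
  out <- records
  out$cluster_id <- cluster_id
  list(records = out, clusters = clusters)
}
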