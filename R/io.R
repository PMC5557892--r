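# File-format helpers. Sequence formats go through Biostrings; interval
# formats through rtracklayer.

#' Read a CLIP read library from FASTQ
#'
#' The degenerate barcode carried in the 5' RNA linker occupies the first
#' `barcode_len` bases of every read; it is split off into its own column so
#' PCR-duplicate collapsing can key on it.
#'
#' @param path FASTQ file (uncompressed or gzipped).
#' @param barcode_len length of the 5' degenerate barcode (default 5).
#' @param replicate_id replicate label attached to every read (default the
#'   file name).
#' @return data.frame with read_id, sequence (barcode removed, DNA
#'   alphabet), barcode, replicate_id.
#' @export
read_fastq_reads <- function(path, barcode_len = 5L,
                             replicate_id = basename(path)) {
  ss <- Biostrings::readBStringSet(path, format = "fastq")
  seqs <- normalize_dna(as.character(ss))
  data.frame(
    read_id = sub("\\s.*$", "", names(ss)),
    sequence = substr(seqs, barcode_len + 1L, nchar(seqs)),
    barcode = substr(seqs, 1L, barcode_len),
    replicate_id = replicate_id,
    stringsAsFactors = FALSE
  )
}

#' Read a genome from FASTA
#' @param path FASTA file.
#' @return named character vector of chromosome sequences (DNA alphabet).
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  g <- as.character(ss)
  names(g) <- sub("\\s.*$", "", names(ss))
  g
}

#' Extract the strand-correct sequence of one genomic interval
#'
#' @param genome named character vector of chromosome sequences.
#' @param chrom chromosome name.
#' @param start,end 0-based half-open interval.
#' @param strand "+" or "-" (minus returns the reverse complement).
#' @return the interval sequence, 5'->3' on the requested strand.
#' @export
genome_subseq <- function(genome, chrom, start, end, strand = "+") {
  s <- substr(genome[[chrom]], start + 1L, end)
  if (strand == "-") s <- reverse_complement(s) else s
}

#' Write intervals as BED6
#'
#' @param df data.frame with chrom, start, end (0-based half-open), strand;
#'   optional name and score columns.
#' @param path output path.
#' @export
write_bed <- function(df, path) {
  bed <- data.frame(chrom = df$chrom, start = df$start, end = df$end,
                    name = df$name %||% ".",
                    score = df$score %||% 0,
                    strand = df$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file of intervals
#' @param path BED3+ file.
#' @return data.frame chrom, start, end, name, score, strand (missing BED
#'   columns filled with defaults).
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  df <- granges_to_df(gr)
  df$name <- if (!is.null(gr$name)) as.character(gr$name) else "."
  df$score <- if (!is.null(gr$score)) as.numeric(gr$score) else 0
  df[, c("chrom", "start", "end", "name", "score", "strand")]
}

#' Read a gene expression count table
#'
#' @param path TSV with a gene_id column followed by one column per sample.
#' @return data.frame; first column gene_id, remaining columns integer
#'   counts.
#' @export
read_counts_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a data.frame as TSV
#' @param df data.frame. @param path output path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
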