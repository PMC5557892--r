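# Micro-fixtures for the read-level chimera caller: tolerant miRNA
# matching, target extraction, mapping, PCR-duplicate collapsing and
# interaction clustering.

mk_reads <- function(seqs, barcode = "ACGTA", replicate = "rep1") {
  data.frame(read_id = sprintf("r%03d", seq_along(seqs)),
             sequence = seqs,
             barcode = rep_len(barcode, length(seqs)),
             replicate_id = rep_len(replicate, length(seqs)),
             stringsAsFactors = FALSE)
}

mutate_at <- function(s, pos, to = NULL) {
  ch <- strsplit(s, "")[[1]]
  ch[pos] <- if (is.null(to))
    setdiff(c("A", "C", "G", "T"), ch[pos])[1] else to
  paste(ch, collapse = "")
}

test_that("miRNA detection tolerates 1 mismatch in the first 18 nt", {
  cat <- toy_catalog()
  m224 <- "CAAAATGGTACCCTAGTGACT"
  set.seed(2)
  tail25 <- rand_seq(1, 25)
  reads <- mk_reads(c(
    paste0(m224, tail25),                      # exact
    paste0(mutate_at(m224, 10), tail25),       # 1 mismatch at position 10
    paste0(mutate_at(mutate_at(m224, 5), 9), tail25),  # mismatches 5 + 9
    rand_seq(1, 46)))                          # no miRNA at all
  h <- find_mirna_in_reads(reads, cat)
  expect_setequal(h$read_idx, c(1L, 2L))
  expect_true(all(h$mirna_name == "bta-miR-224-3p"))
  expect_equal(h$mismatches[h$read_idx == 2L], 1L)
})

test_that("two mismatches are tolerated only outside the first 18 nt", {
  cat <- toy_catalog()
  m17 <- "CAAAGTGCTTACAGTGCAGGTAGT"  # 24 nt
  set.seed(3)
  tail <- rand_seq(1, 24)
  reads <- mk_reads(c(
    paste0(mutate_at(mutate_at(m17, 5), 21), tail),  # mm at 5 and 21: ok
    paste0(mutate_at(mutate_at(m17, 5), 9), tail)))  # both in first 18
  h <- find_mirna_in_reads(reads, cat)
  expect_identical(h$read_idx, 1L)
  expect_equal(h$mismatches, 2L)
})

test_that("1-nt truncated miRNA variants are detected", {
  cat <- toy_catalog()
  m224 <- "CAAAATGGTACCCTAGTGACT"
  set.seed(4)
  # tail must not begin with the truncated base, or the full-length
  # pattern would match exactly
  tail <- paste0("G", rand_seq(1, 21))
  reads <- mk_reads(c(paste0(substr(m224, 2, 21), tail),
                      paste0(substr(m224, 1, 20), tail)))
  h <- find_mirna_in_reads(reads, cat)
  expect_setequal(h$truncation[order(h$read_idx)], c("5p1", "3p1"))
})

test_that("co-located hits resolve to the first alphanumeric miRNA", {
  seqA <- "TAGCAGCACGTAAATATTGGCG"   # identical except last 2 nt
  seqB <- paste0(substr(seqA, 1, 20), "AA")
  cat <- mirna_catalog(c("bta-miR-15b", "bta-miR-15a"), c(seqB, seqA))
  set.seed(5)
  reads <- mk_reads(paste0(seqA, rand_seq(1, 25)))
  h <- find_mirna_in_reads(reads, cat)
  expect_identical(h$mirna_name, "bta-miR-15a")
  # distinct loci > 4 nt apart coexist
  reads2 <- mk_reads(paste0(seqA, rand_seq(1, 10), seqA))
  h2 <- find_mirna_in_reads(reads2, cat)
  expect_equal(nrow(h2), 2L)
})

test_that("target segments follow the >=19 nt and both-sides rules", {
  hits <- data.frame(read_idx = 1:3, mirna_name = "m",
                     offset = c(0L, 0L, 20L),
                     matched_length = c(21L, 21L, 21L),
                     mismatches = 0L, truncation = "none")
  reads <- mk_reads(c(
    paste0(strrep("A", 21), rand_seq(1, 25)),   # 25-nt downstream
    paste0(strrep("A", 21), rand_seq(1, 18)),   # 18-nt downstream: drop
    paste0(rand_seq(1, 20), strrep("A", 21), rand_seq(1, 30))))
  segs <- extract_target_segments(reads, hits)
  expect_equal(nrow(segs[segs$read_idx == 1, ]), 1L)
  expect_identical(segs$chimera_type[segs$read_idx == 1], "miRfirst")
  expect_equal(nchar(segs$target_sequence[segs$read_idx == 1]), 25L)
  expect_equal(nrow(segs[segs$read_idx == 2, ]), 0L)
  s3 <- segs[segs$read_idx == 3, ]
  expect_setequal(s3$chimera_type, c("miRfirst", "miRlast"))
})

test_that("mapping collapses PCR duplicates and filters precursors", {
  set.seed(6)
  genome <- c(chr1 = rand_seq(1, 5000))
  target <- substr(genome[["chr1"]], 1001, 1030)
  prec_target <- substr(genome[["chr1"]], 3001, 3030)
  precursors <- data.frame(chrom = "chr1", start = 2990L, end = 3070L,
                           strand = "+", name = "hp1",
                           annotated_arm = "5p")
  seg <- function(ts, bc, rep_ = "rep1") {
    data.frame(read_idx = NA_integer_, mirna_name = "miR-x",
               chimera_type = "miRfirst", target_sequence = ts,
               barcode = bc, replicate_id = rep_,
               stringsAsFactors = FALSE)
  }
  segs <- rbind(seg(target, "AAAAA"), seg(target, "AAAAA"),
                seg(target, "CCCCC"), seg(prec_target, "GGGGG"))
  cat <- mirna_catalog("miR-x", "TGAGGTAGTAGGTTGTATAGTT")
  ch <- map_and_dedup(segs, genome, precursors = precursors,
                      catalog = cat)
  # 2 identical (coords, barcode) -> 1; different barcode -> extra event;
  # precursor target removed
  expect_equal(nrow(ch), 2L)
  expect_setequal(ch$barcode, c("AAAAA", "CCCCC"))
  expect_equal(ch$n_reads[ch$barcode == "AAAAA"], 2L)
  cnt <- attr(ch, "counters")
  expect_equal(unname(cnt["precursor_hits"]), 1L)
})

test_that("dedup is idempotent and multi-mappers are dropped", {
  set.seed(7)
  core <- rand_seq(1, 3000)
  dupseg <- rand_seq(1, 25)
  genome <- c(chr1 = paste0(core, dupseg, rand_seq(1, 200), dupseg))
  uniqseg <- substr(core, 101, 130)
  segs <- data.frame(read_idx = NA_integer_, mirna_name = "miR-x",
                     chimera_type = "miRfirst",
                     target_sequence = c(uniqseg, dupseg),
                     barcode = c("AAAAA", "CCCCC"),
                     replicate_id = "rep1", stringsAsFactors = FALSE)
  ch <- map_and_dedup(segs, genome)
  expect_equal(nrow(ch), 1L)  # multi-mapper dropped
  expect_equal(ch$start, 100L)
  # idempotence: re-running dedup on the called events changes nothing
  segs2 <- data.frame(read_idx = NA_integer_, mirna_name = ch$mirna_name,
                      chimera_type = ch$chimera_type,
                      target_sequence = ch$target_sequence,
                      barcode = ch$barcode, replicate_id = ch$replicate_id,
                      stringsAsFactors = FALSE)
  ch2 <- map_and_dedup(segs2, genome)
  expect_equal(ch2[, c("mirna_name", "chrom", "start", "end", "strand",
                       "barcode")],
               ch[, c("mirna_name", "chrom", "start", "end", "strand",
                      "barcode")])
})

test_that("interaction clusters carry chimera counts and BC", {
  ch <- data.frame(
    mirna_name = c("miR-29a", "miR-29a", "miR-29a", "miR-29b"),
    family_key = "CTGGTTT",
    chimera_type = "miRfirst",
    chrom = "chr1",
    start = c(100L, 120L, 140L, 130L),
    end = c(130L, 150L, 170L, 160L),
    strand = "+",
    target_sequence = "N", replicate_id = c("r1", "r1", "r2", "r3"),
    barcode = c("A", "B", "C", "D"), n_reads = 1L,
    stringsAsFactors = FALSE)
  cl <- build_interaction_clusters(ch, level = "mirna")
  a <- cl$clusters[cl$clusters$key == "miR-29a", ]
  expect_equal(a$chimera_count, 3L)
  expect_equal(a$BC, 2L)
  expect_equal(nrow(cl$clusters), 2L)
  # family level merges the two members over one region
  clf <- build_interaction_clusters(ch, level = "family")
  expect_equal(nrow(clf$clusters), 1L)
  expect_equal(clf$clusters$chimera_count, 4L)
  expect_equal(clf$clusters$BC, 3L)
  # partition: cluster counts sum to the number of chimeras
  expect_equal(sum(cl$clusters$chimera_count), nrow(ch))
})

test_that("AGO profiling counts only exact full-read substrings", {
  cat <- toy_catalog()
  m17 <- "CAAAGTGCTTACAGTGCAGGTAGT"
  reads <- mk_reads(c(
    m17,                      # identical
    mutate_at(m17, 12),       # 1 mismatch: rejected
    substr(m17, 1, 19),       # positions 1-19 of the mature: counted
    rand_seq(1, 21)))
  pr <- profile_ago_mirnas(reads, cat)
  expect_equal(pr$counts$count[pr$counts$name == "bta-miR-17-5p"], 2L)
  expect_equal(length(pr$unmatched), 2L)
  # independent check of the substring rule for every read
  for (i in seq_len(nrow(reads))) {
    manual <- any(vapply(cat$sequence, function(s)
      grepl(reads$sequence[i], s, fixed = TRUE), logical(1)))
    expect_identical(!reads$sequence[i] %in% pr$unmatched, manual)
  }
})

test_that("ambiguous profile reads count toward the first alphanumeric", {
  shared <- "TAGCAGCACGTAAATATTGGCG"
  cat <- mirna_catalog(c("mir-B", "mir-A"),
                       c(paste0(shared, "GT"), paste0(shared, "AC")))
  pr <- profile_ago_mirnas(mk_reads(shared), cat)
  expect_equal(pr$counts$count[pr$counts$name == "mir-A"], 1L)
  expect_equal(pr$counts$count[pr$counts$name == "mir-B"], 0L)
})

test_that("novel arm candidates require length, count and opposite arm", {
  set.seed(8)
  arm5 <- rand_seq(1, 20); arm3 <- rand_seq(1, 20)
  elsewhere <- rand_seq(1, 20)
  genome <- c(chr1 = paste0(rand_seq(1, 500), arm5, "GTGTATGTTG", arm3,
                            rand_seq(1, 500), elsewhere, rand_seq(1, 100)))
  precursors <- data.frame(chrom = "chr1", start = 500L,
                           end = 500L + 50L, strand = "+", name = "hp9",
                           annotated_arm = "3p")
  unmatched <- c(rep(arm5, 120),          # opposite arm, abundant
                 rep(arm3, 150),          # annotated arm: rejected
                 rep(elsewhere, 200),     # outside any hairpin
                 rep(substr(arm5, 1, 16), 300))  # 16 nt: too short
  out <- detect_novel_arm_candidates(unmatched, genome, precursors,
                                     min_count = 100L)
  expect_equal(nrow(out), 1L)
  expect_identical(out$sequence, arm5)
  expect_identical(out$proposed_name, "hp9-5p")
  # below min_count: nothing
  out2 <- detect_novel_arm_candidates(rep(arm5, 99), genome, precursors)
  expect_equal(nrow(out2), 0L)
})

test_that("peak calling merges close summits and spans fragment length", {
  sizes <- c(chr1 = 10000L)
  # no coverage
  expect_equal(nrow(call_peaks_simple(
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               strand = character(0)), sizes)), 0L)
  # two summits 50 nt apart merge into one peak
  mk <- function(starts) data.frame(chrom = "chr1", start = starts,
                                    end = starts + 40L, strand = "+")
  mapped <- mk(c(rep(1000L, 5), rep(1050L, 5)))
  pk <- call_peaks_simple(mapped, sizes, min_height = 3L,
                          total_reads = 10L)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$height, 10L)
  # summits 200 nt apart stay separate
  pk2 <- call_peaks_simple(mk(c(rep(1000L, 5), rep(1200L, 5))), sizes,
                           min_height = 3L, total_reads = 10L)
  expect_equal(nrow(pk2), 2L)
  # a single read start yields a fragment_length-wide candidate region
  pk3 <- call_peaks_simple(mk(2000L), sizes, min_height = 1L,
                           total_reads = 1L)
  expect_equal(pk3$end - pk3$start, 53L)
  expect_equal(pk3$normalized_height, 1e6)
})
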