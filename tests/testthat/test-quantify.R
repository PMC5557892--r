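# Abundance normalization, ASC, GO gene sets, cooperativity consensus and
# ceRNA region detection.

mk_chim <- function(family, gene, n, region = "3'UTR") {
  data.frame(family_key = rep(family, n), gene_id = rep(gene, n),
             region = region, stringsAsFactors = FALSE)
}

test_that("abundance follows CPM/RPKM arithmetic and the 100-tag rule", {
  counts <- data.frame(gene_id = c("g1", "g2", "g3"),
                       s1 = c(10L, 0L, 49L), s2 = c(0L, 0L, 50L))
  # scale so the library is 1e6 for easy arithmetic
  counts$s1 <- counts$s1 * 1L
  lens <- c(g1 = 1000, g2 = 500, g3 = 2000)
  ab <- compute_abundance(counts, lens)
  lib <- sum(counts$s1 + counts$s2)
  expect_equal(ab$cpm[1], 10 / lib * 1e6)
  expect_equal(ab$rpkm[1], ab$cpm[1])          # 1 kb gene
  expect_equal(ab$cpm[2], 0)
  expect_equal(ab$rpkm[2], 0)
  expect_identical(ab$expressed, c(FALSE, FALSE, FALSE))
  counts$s1[3] <- 50L
  expect_true(compute_abundance(counts, lens)$expressed[3])
  expect_error(compute_abundance(
    data.frame(gene_id = "g1", s1 = 0L), lens), "zero library")
})

test_that("ASC follows its closed form and the 500-chimera rule", {
  ab <- data.frame(gene_id = c("g1", "g2"), count = c(1000, 1000),
                   cpm = c(1, 2), rpkm = c(1, 2), expressed = TRUE)
  ch <- rbind(mk_chim("FAMAAAA", "g1", 8), mk_chim("FAMAAAA", "g2", 56))
  asc <- compute_asc(ch, ab, min_family_chimeras = 10L)
  r1 <- asc[asc$gene_id == "g1", ]
  expect_equal(r1$asc, log2((8 / 64) / 1))  # = -3
  expect_equal(r1$asc, -3)
  expect_equal(r1$lloq, log2((1 / 64) / 1))
  # doubling RPKM lowers asc by exactly 1
  ab2 <- ab; ab2$rpkm <- ab2$rpkm * 2
  asc2 <- compute_asc(ch, ab2, min_family_chimeras = 10L)
  expect_equal(asc2$asc, asc$asc - 1)
  # family below the chimera threshold is skipped entirely
  expect_equal(nrow(compute_asc(ch[1:63, ], ab,
                                min_family_chimeras = 64L)), 0L)
  expect_equal(nrow(compute_asc(ch, ab, min_family_chimeras = 64L)), 2L)
  # zero RPKM with chimeras present: asc undefined
  ab3 <- ab; ab3$rpkm[1] <- 0
  asc3 <- compute_asc(ch, ab3, min_family_chimeras = 10L)
  expect_true(is.na(asc3$asc[asc3$gene_id == "g1"]))
})

test_that("ASC is equivariant in RPKM scale and chimera-count scale", {
  set.seed(51)
  ab <- data.frame(gene_id = paste0("g", 1:20),
                   rpkm = runif(20, 0.5, 50))
  ch <- do.call(rbind, lapply(1:20, function(i)
    mk_chim("FAMAAAA", paste0("g", i), sample(1:30, 1))))
  base <- compute_asc(ch, ab, min_family_chimeras = 1L)
  scaled <- ab; scaled$rpkm <- scaled$rpkm * 8
  shifted <- compute_asc(ch, scaled, min_family_chimeras = 1L)
  expect_equal(shifted$asc, base$asc - log2(8), tolerance = 1e-12)
  # replicating every chimera beta times cancels in the ratio
  beta <- 3L
  ch3 <- ch[rep(seq_len(nrow(ch)), beta), ]
  tripled <- compute_asc(ch3, ab, min_family_chimeras = 1L)
  expect_equal(tripled$asc, base$asc, tolerance = 1e-12)
})

test_that("GO gene sets take genes strictly above the family mean", {
  asc <- data.frame(family_key = "FAM", gene_id = c("a", "b", "c"),
                    n_chimeras = 1L, total_chimeras = 3L, rpkm = 1,
                    asc = c(-1, -2, -3), lloq = -5)
  sel <- select_go_geneset(asc, "FAM")
  expect_equal(sel$mean_asc, -2)
  expect_identical(sel$genes, "a")
  # all equal: strict inequality selects nothing
  asc$asc <- -2
  expect_length(select_go_geneset(asc, "FAM")$genes, 0L)
  # undefined asc values never enter the mean
  asc2 <- rbind(asc, data.frame(family_key = "FAM", gene_id = "d",
                                n_chimeras = 1L, total_chimeras = 3L,
                                rpkm = 0, asc = NA_real_, lloq = NA_real_))
  expect_equal(select_go_geneset(asc2, "FAM")$mean_asc, -2)
  # invariance to gene order
  asc$asc <- c(-1, -2, -3)
  perm <- asc[c(3, 1, 2), ]
  expect_identical(select_go_geneset(perm, "FAM")$genes,
                   select_go_geneset(asc, "FAM")$genes)
})

test_that("identical-ASC families co-cluster in every iteration", {
  set.seed(52)
  n_genes <- 60
  shared <- rnorm(n_genes, -6, 2)
  mat <- cbind(f_29a = shared, f_29b = shared,
               f_x = rnorm(n_genes, -6, 2), f_y = rnorm(n_genes, -6, 2))
  rownames(mat) <- paste0("g", 1:n_genes)
  coop <- cooperativity_consensus(mat, k = 6, n_starts = 50,
                                  iterations = 3, min_support = 3,
                                  seed = 99)
  expect_gte(coop$pairwise["f_29a", "f_29b"], 3L)
  expect_identical(coop$pairwise, t(coop$pairwise))
})

test_that("null ASC columns yield no recurrent multi-family signature", {
  set.seed(53)
  hits <- vapply(1:20, function(i) {
    mat <- matrix(rnorm(240 * 4, -6, 2), 240, 4,
                  dimnames = list(NULL, paste0("f", 1:4)))
    coop <- cooperativity_consensus(mat, k = 6, n_starts = 25,
                                    iterations = 3, min_support = 3,
                                    seed = i * 7)
    any(coop$signatures$size >= 2)
  }, logical(1))
  expect_gte(mean(!hits), 0.95)
})

test_that("min_support = 2 retains two-of-three signatures", {
  set.seed(54)
  mat <- matrix(rnorm(40 * 3, -6, 2), 40, 3,
                dimnames = list(NULL, paste0("f", 1:3)))
  mat[1:8, 1] <- mat[1:8, 1] + 6
  c3 <- cooperativity_consensus(mat, k = 5, n_starts = 30,
                                iterations = 3, min_support = 3, seed = 1)
  c2 <- cooperativity_consensus(mat, k = 5, n_starts = 30,
                                iterations = 3, min_support = 2, seed = 1)
  expect_gte(nrow(c2$signatures), nrow(c3$signatures))
  expect_true(all(c2$signatures$support >= 2))
})

test_that("consensus clustering is reproducible under identical seeds", {
  set.seed(55)
  mat <- matrix(rnorm(50 * 4, -6, 2), 50, 4,
                dimnames = list(NULL, paste0("f", 1:4)))
  a <- cooperativity_consensus(mat, k = 5, n_starts = 20, seed = 3,
                               min_support = 1)
  b <- cooperativity_consensus(mat, k = 5, n_starts = 20, seed = 3,
                               min_support = 1)
  expect_identical(a$signatures, b$signatures)
  expect_error(cooperativity_consensus(mat, k = 100, seed = 1),
               "more clusters")
})

test_that("ceRNA regions obey the 3-cluster/5-chimera/3000-bp rule", {
  mk_cl <- function(starts, counts, strand = "+") {
    data.frame(chrom = "chr1", start = starts, end = starts + 60L,
               strand = strand, chimera_count = counts,
               stringsAsFactors = FALSE)
  }
  # 5,5,6 chimeras within 2900 bp: one region
  r <- detect_cerna_regions(mk_cl(c(0L, 1400L, 2840L), c(5L, 5L, 6L)))
  expect_equal(nrow(r), 1L)
  expect_equal(r$n_clusters, 3L)
  # one cluster too small
  expect_equal(nrow(detect_cerna_regions(
    mk_cl(c(0L, 1400L, 2840L), c(5L, 5L, 4L)))), 0L)
  # span 3050 bp: too wide
  expect_equal(nrow(detect_cerna_regions(
    mk_cl(c(0L, 1400L, 2990L), c(5L, 5L, 6L)))), 0L)
  # strands are never mixed
  mixed <- rbind(mk_cl(c(0L, 1400L), c(5L, 5L)),
                 mk_cl(2000L, 9L, strand = "-"))
  expect_equal(nrow(detect_cerna_regions(mixed)), 0L)
})

test_that("ceRNA detection equals a brute-force all-offsets scan", {
  brute <- function(cl, window = 3000L, min_clusters = 3L,
                    min_chimeras = 5L) {
    q <- cl[cl$chimera_count >= min_chimeras, , drop = FALSE]
    found <- list()
    for (grp in split(q, paste(q$chrom, q$strand))) {
      lo <- min(grp$start); hi <- max(grp$end)
      for (s in lo:(max(lo, hi - 1L))) {
        inside <- grp$start >= s & grp$end <= s + window
        if (sum(inside) >= min_clusters) {
          found[[length(found) + 1L]] <- data.frame(
            chrom = grp$chrom[1],
            start = min(grp$start[inside]),
            end = max(grp$end[inside]), strand = grp$strand[1])
        }
      }
    }
    if (!length(found)) return(NULL)
    u <- unique(do.call(rbind, found))
    keep <- vapply(seq_len(nrow(u)), function(i) {
      !any(u$start <= u$start[i] & u$end >= u$end[i] &
             seq_len(nrow(u)) != i &
             !(u$start == u$start[i] & u$end == u$end[i] &
                 seq_len(nrow(u)) > i))
    }, logical(1))
    u <- u[keep, ]
    u[order(u$start), ]
  }
  set.seed(56)
  for (trial in 1:10) {
    n <- sample(8:25, 1)
    cl <- data.frame(chrom = "chr1",
                     start = sort(sample(0:8000, n)), strand = "+",
                     chimera_count = sample(3:8, n, replace = TRUE))
    cl$end <- cl$start + sample(40:80, n, replace = TRUE)
    got <- detect_cerna_regions(cl)
    want <- brute(cl)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(got[, c("start", "end")], want[, c("start", "end")],
                   ignore_attr = TRUE)
    }
  }
})
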