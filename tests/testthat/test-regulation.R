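# Fold-change contrasts, grouped KS comparisons, targetome overlap,
# chimera-peak support with the sigmoid fit, and prediction intersection.

test_that("log2 fold changes follow the pseudocount CPM ratio", {
  t <- data.frame(gene_id = c("g1", "g2", "g3"),
                  r1 = c(200L, 400L, 0L), r2 = c(200L, 400L, 0L))
  c_ <- data.frame(gene_id = c("g1", "g2", "g3"),
                   r1 = c(200L, 200L, 0L), r2 = c(200L, 200L, 0L))
  fc <- compute_log2fc(t, c_, min_tags = 0L)
  expect_equal(fc$log2fc[fc$gene_id == "g1"],
               log2((fc$cpm_treated[1] + 0.5) / (fc$cpm_control[1] + 0.5)))
  # doubled counts give roughly +1 (library-size normalization shifts it)
  expect_gt(fc$log2fc[fc$gene_id == "g2"],
            fc$log2fc[fc$gene_id == "g1"])
  expect_equal(fc$log2fc[fc$gene_id == "g3"], 0)  # 0/0 via pseudocount
  # expression filter removes low-count genes
  fc2 <- compute_log2fc(t, c_, min_tags = 100L)
  expect_false("g3" %in% fc2$gene_id)
  expect_error(compute_log2fc(t, data.frame(gene_id = "zz", r1 = 1L)),
               "no overlapping genes")
})

test_that("grouped KS comparison reports medians and asymptotic p", {
  set.seed(61)
  fc <- data.frame(gene_id = paste0("g", 1:400),
                   log2fc = rnorm(400, 0, 0.3))
  grouping <- rep(c("none", "site"), each = 200)
  # identical distributions: p not small
  out <- cdf_ks_compare(fc, grouping, reference = "none")
  expect_equal(out$ks_p[out$group == "none"], 1)
  expect_gt(out$ks_p[out$group == "site"], 0.01)
  # a group equal to the reference values exactly gives D = 0, p = 1
  fc2 <- rbind(fc[1:50, ], fc[1:50, ])
  g2 <- rep(c("none", "dup"), each = 50)
  out2 <- cdf_ks_compare(fc2, g2, reference = "none")
  expect_equal(out2$ks_D[out2$group == "dup"], 0)
  expect_equal(out2$ks_p[out2$group == "dup"], 1)
  # single-member group: p undefined
  g3 <- c(rep("none", 399), "tiny")
  out3 <- cdf_ks_compare(fc, g3, reference = "none")
  expect_true(is.na(out3$ks_p[out3$group == "tiny"]))
})

test_that("a planted shift at the study's effect scale is detected", {
  set.seed(62)
  # noise at the scale of the observed fold-change CDFs, which separate
  # clearly at a 0.11 shift
  detected <- vapply(1:20, function(i) {
    lfc <- c(rnorm(500, 0.11, 0.3), rnorm(500, 0, 0.3))
    fc <- data.frame(gene_id = paste0("g", 1:1000), log2fc = lfc)
    grouping <- rep(c("target", "none"), each = 500)
    out <- cdf_ks_compare(fc, grouping, reference = "none")
    out$ks_p[out$group == "target"] < 0.01
  }, logical(1))
  expect_gte(mean(detected), 0.95)
})

test_that("null KS p-values show no excess below 0.05", {
  set.seed(63)
  p <- vapply(1:1000, function(i) {
    x <- rnorm(60); y <- rnorm(120)
    suppressWarnings(stats::ks.test(x, y, exact = FALSE)$p.value)
  }, numeric(1))
  expect_lte(mean(p < 0.05), 0.07)
})

test_that("targetome overlap matches the exact hypergeometric bound", {
  mk <- function(mirna, genes) data.frame(mirna_name = mirna,
                                          gene_id = genes,
                                          stringsAsFactors = FALSE)
  genes <- paste0("g", 1:100)
  a <- rbind(mk("miR-1", genes[1:30]), mk("bg", genes))
  b <- rbind(mk("miR-1", genes[1:30]), mk("bg", genes))
  out <- targetome_overlap(a, b, min_fraction = 0.01)
  row <- out[out$mirna == "miR-1", ]
  # complete overlap: K = n = k = 30 in N = 100
  expect_equal(row$p_value, 1 / choose(100, 30), tolerance = 1e-12)
  # a miRNA below 1% abundance in one dataset is not tested
  a2 <- rbind(a, mk("miR-rare", genes[1]))
  b2 <- rbind(b, do.call(rbind, replicate(30, mk("bg", genes),
                                          simplify = FALSE)))
  out2 <- targetome_overlap(a2, b2)
  expect_false("miR-rare" %in% out2$mirna)
  expect_error(targetome_overlap(mk("m", "gX"), mk("m", "gY")),
               "empty gene universe")
})

test_that("overlap p equals brute-force enumeration on small universes", {
  set.seed(64)
  for (i in 1:10) {
    N <- sample(10:40, 1)
    K <- sample(3:(N - 2), 1)
    n <- sample(3:(N - 2), 1)
    k <- sample(max(0, K + n - N):min(K, n), 1)
    expect_equal(
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
      oracle_hyper_upper(k, K, N, n), tolerance = 1e-10)
  }
})

test_that("the sigmoid support fit recovers a planted asymptote", {
  set.seed(65)
  x <- seq(0.5, 10, length.out = 10)
  A_hat <- vapply(1:25, function(i) {
    y_true <- 0.88 / (1 + exp(-(x - 3) / 1.2))
    y <- vapply(y_true, function(p) stats::rbinom(1, 200, p) / 200,
                numeric(1))
    fit <- chimeramap:::fit_sigmoid(x, y)
    unname(fit$fit["A"])
  }, numeric(1))
  expect_lt(abs(mean(A_hat) - 0.88), 0.02)
  # invariance to bin order
  ord <- sample(10)
  y <- 0.88 / (1 + exp(-(x - 3) / 1.2))
  f1 <- chimeramap:::fit_sigmoid(x, y)
  f2 <- chimeramap:::fit_sigmoid(x[ord], y[ord])
  expect_equal(f1$fit, f2$fit, tolerance = 1e-6)
})

test_that("peak support bins are fractions and saturate when planted", {
  set.seed(66)
  n <- 400
  peaks <- data.frame(chrom = "chr1",
                      start = seq(0L, by = 1000L, length.out = n))
  peaks$end <- peaks$start + 60L
  peaks$strand <- "+"
  peaks$normalized_height <- stats::rlnorm(n, 2, 1)
  # support probability rises with height toward 1
  psup <- 1 / (1 + exp(-(log(peaks$normalized_height) - 1.5)))
  sup <- stats::runif(n) < psup
  chim <- data.frame(chrom = "chr1", start = peaks$start[sup] + 10L,
                     end = peaks$start[sup] + 40L, strand = "+")
  sc <- chimera_peak_support(peaks, chim)
  expect_true(all(sc$bins$support >= 0 & sc$bins$support <= 1))
  expect_true(sc$converged)
  # fully supported peaks at all heights: flat curve with A near 1
  chim_all <- data.frame(chrom = "chr1", start = peaks$start + 10L,
                         end = peaks$start + 40L, strand = "+")
  sc2 <- chimera_peak_support(peaks, chim_all)
  expect_true(all(sc2$bins$support == 1))
  if (sc2$converged) expect_gt(unname(sc2$fit["A"]), 0.97)
})

test_that("support by BC is a fraction per complexity level", {
  clusters <- data.frame(chrom = "chr1",
                         start = c(0L, 1000L, 2000L, 3000L),
                         end = c(60L, 1060L, 2060L, 3060L),
                         strand = "+", BC = c(1L, 1L, 2L, 2L))
  peaks <- data.frame(chrom = "chr1", start = c(10L, 2010L),
                      end = c(50L, 2050L), strand = "+")
  out <- support_by_bc(clusters, peaks)
  expect_equal(out$support[out$BC == 1], 0.5)
  expect_equal(out$support[out$BC == 2], 0.5)
})

test_that("prediction intersection respects family labels and expression", {
  clusters <- data.frame(
    chrom = "chr1", start = c(100L, 500L, 900L), end = c(160L, 560L, 960L),
    strand = "+", key = c("FAM1", "FAM1", "FAM2"),
    gene_id = c("g1", "g2", "g3"),
    seed_class = c("8mer", "6mer", "8mer"), stringsAsFactors = FALSE)
  predictions <- data.frame(
    chrom = "chr1", start = c(110L, 905L), end = c(150L, 955L),
    strand = "+", family = c("FAM1", "FAM1"), stringsAsFactors = FALSE)
  abundance <- data.frame(gene_id = c("g1", "g2", "g3"),
                          expressed = c(TRUE, TRUE, FALSE))
  out <- intersect_predictions(clusters, predictions, abundance)
  # g3 fails expression (80-tag style) and FAM2 has no predictions;
  # FAM1: cluster 1 overlaps a same-family prediction, cluster 2 does not
  expect_equal(out$by_family$overlap_fraction[out$by_family$family ==
                                                "FAM1"], 0.5)
  bc <- out$by_seed_class
  expect_equal(bc$overlap_fraction[bc$seed_class == "8mer"], 1)
  expect_equal(bc$overlap_fraction[bc$seed_class == "6mer"], 0)
})

test_that("planted prediction truth makes 8mer overlap exceed 6mer", {
  set.seed(67)
  n <- 60
  cl <- data.frame(chrom = "chr1",
                   start = seq(0L, by = 500L, length.out = n))
  cl$end <- cl$start + 60L
  cl$strand <- "+"
  cl$key <- "FAM1"
  cl$gene_id <- paste0("g", seq_len(n))
  cl$seed_class <- rep(c("8mer", "6mer"), each = n / 2)
  # predictions exist only for 8mer sites
  idx <- which(cl$seed_class == "8mer")
  predictions <- data.frame(chrom = "chr1", start = cl$start[idx] + 5L,
                            end = cl$end[idx] - 5L, strand = "+",
                            family = "FAM1")
  out <- intersect_predictions(cl, predictions)
  bc <- out$by_seed_class
  expect_gt(bc$overlap_fraction[bc$seed_class == "8mer"],
            bc$overlap_fraction[bc$seed_class == "6mer"])
  expect_equal(out$prediction_support, 1)
})
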