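# Functional validation analyses: fold-change tables, grouped CDF/KS
# comparisons, targetome overlap, chimera support of CLIP peaks with a
# sigmoidal saturation fit, and intersection with external prediction
# intervals.

#' Per-gene log2 fold changes between two conditions
#'
#' A deliberately simple, ordering-faithful contrast: CPMs are averaged
#' over replicates per condition and the fold change is
#' log2((CPM_t + 0.5) / (CPM_c + 0.5)). Genes below the expression
#' threshold in the pooled data are excluded.
#'
#' @param counts_treated,counts_control data.frames: gene_id plus replicate
#'   count columns; the same gene universe.
#' @param min_tags pooled-count expression filter (default 100).
#' @param pseudocount added to both CPMs (default 0.5).
#' @return data.frame: gene_id, cpm_treated, cpm_control, log2fc.
#' @export
compute_log2fc <- function(counts_treated, counts_control,
                           min_tags = 100L, pseudocount = 0.5) {
  common <- intersect(counts_treated$gene_id, counts_control$gene_id)
  if (!length(common)) stop("no overlapping genes between conditions")
  t <- counts_treated[match(common, counts_treated$gene_id), , drop = FALSE]
  c_ <- counts_control[match(common, counts_control$gene_id), , drop = FALSE]
  cpm_one <- function(df) {
    m <- as.matrix(df[, -1, drop = FALSE])
    rowMeans(sweep(m, 2, colSums(m), "/") * 1e6)
  }
  cpm_t <- cpm_one(t); cpm_c <- cpm_one(c_)
  tot <- rowSums(as.matrix(t[, -1, drop = FALSE])) +
    rowSums(as.matrix(c_[, -1, drop = FALSE]))
  keep <- tot >= min_tags
  data.frame(gene_id = common[keep],
             cpm_treated = cpm_t[keep], cpm_control = cpm_c[keep],
             log2fc = log2((cpm_t[keep] + pseudocount) /
                             (cpm_c[keep] + pseudocount)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Grouped CDF comparison of fold changes by two-sided KS tests
#'
#' Compares the log2 fold-change distribution of each group against the
#' reference group (typically genes without a site or chimera), reporting
#' group size, median and the asymptotic two-sided Kolmogorov-Smirnov
#' p-value.
#'
#' @param fc_table output of [compute_log2fc()].
#' @param grouping character vector (parallel to `fc_table` rows) of group
#'   labels; every gene belongs to exactly one group.
#' @param reference label of the reference group.
#' @return data.frame: group, n, median_log2fc, ks_D, ks_p (NA when
#'   n < 2).
#' @export
cdf_ks_compare <- function(fc_table, grouping, reference = "none") {
  stopifnot(length(grouping) == nrow(fc_table))
  ref <- fc_table$log2fc[grouping == reference]
  groups <- unique(grouping)
  res <- lapply(groups, function(g) {
    x <- fc_table$log2fc[grouping == g]
    if (g == reference) {
      ks <- c(0, 1)
    } else if (length(x) < 2L || length(ref) < 2L) {
      ks <- c(NA_real_, NA_real_)
    } else {
      t <- suppressWarnings(stats::ks.test(x, ref, exact = FALSE))
      ks <- c(unname(t$statistic), t$p.value)
    }
    data.frame(group = g, n = length(x), median_log2fc = stats::median(x),
               ks_D = ks[1], ks_p = ks[2], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Hypergeometric targetome overlap between two chimera datasets
#'
#' The gene universe is every gene carrying at least one chimera (any
#' region) in both datasets. miRNAs present in at least `min_fraction` of
#' chimeras in both datasets are tested: the overlap p-value is the
#' hypergeometric upper tail of the shared-target count.
#'
#' @param chimeras_a,chimeras_b chimera data.frames with mirna_name and
#'   gene_id columns.
#' @param min_fraction abundance threshold for tested miRNAs
#'   (default 0.01).
#' @return data.frame: mirna, n_a, n_b (targeted genes in each dataset
#'   within the universe), shared, universe, p_value.
#' @export
targetome_overlap <- function(chimeras_a, chimeras_b,
                              min_fraction = 0.01) {
  a <- chimeras_a[!is.na(chimeras_a$gene_id), , drop = FALSE]
  b <- chimeras_b[!is.na(chimeras_b$gene_id), , drop = FALSE]
  universe <- intersect(unique(a$gene_id), unique(b$gene_id))
  if (!length(universe)) stop("empty gene universe")
  fa <- table(a$mirna_name) / nrow(a)
  fb <- table(b$mirna_name) / nrow(b)
  tested <- intersect(names(fa)[fa >= min_fraction],
                      names(fb)[fb >= min_fraction])
  res <- lapply(tested, function(mi) {
    ta <- intersect(unique(a$gene_id[a$mirna_name == mi]), universe)
    tb <- intersect(unique(b$gene_id[b$mirna_name == mi]), universe)
    shared <- length(intersect(ta, tb))
    N <- length(universe)
    p <- stats::phyper(shared - 1L, length(ta), N - length(ta),
                       length(tb), lower.tail = FALSE)
    data.frame(mirna = mi, n_a = length(ta), n_b = length(tb),
               shared = shared, universe = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res) %||%
    data.frame(mirna = character(0), n_a = integer(0), n_b = integer(0),
               shared = integer(0), universe = integer(0),
               p_value = numeric(0))
  rownames(out) <- NULL
  out
}

#' Chimera support of CLIP peaks as a function of peak height
#'
#' Bins peaks by normalized height (deciles by default), computes the
#' fraction of peaks in each bin overlapping at least one chimera, and fits
#' the three-parameter logistic y = A / (1 + exp(-(x - x0)/w)) by least
#' squares. The asymptote A estimates the maximum attainable fraction of
#' chimera-supported peaks.
#'
#' @param peaks peak data.frame (chrom, start, end, strand,
#'   normalized_height).
#' @param chimeras chimera data.frame (chrom, start, end, strand).
#' @param n_bins number of height bins (default 10).
#' @return object of class `support_curve`: list with `bins` (data.frame
#'   height, support, n), `fit` (named vector A, x0, w or NULL), `A_ci`
#'   (95% CI for A) and `converged`.
#' @export
chimera_peak_support <- function(peaks, chimeras, n_bins = 10L) {
  supported <- IRanges::overlapsAny(df_to_granges(peaks),
                                          df_to_granges(chimeras))
  br <- stats::quantile(peaks$normalized_height,
                        probs = seq(0, 1, length.out = n_bins + 1L))
  br[1] <- -Inf; br[length(br)] <- Inf
  bin <- cut(peaks$normalized_height, breaks = unique(br),
             include.lowest = TRUE)
  bins <- data.frame(
    height = as.numeric(tapply(peaks$normalized_height, bin, mean)),
    support = as.numeric(tapply(supported, bin, mean)),
    n = as.integer(table(bin)))
  bins <- bins[bins$n > 0 & !is.na(bins$height), , drop = FALSE]
  rownames(bins) <- NULL
  fit <- fit_sigmoid(bins$height, bins$support)
  structure(c(list(bins = bins), fit,
              list(supported_overall = mean(supported))),
            class = "support_curve")
}

# Least-squares 3-parameter logistic fit; returns fit params + 95% CI on A.
# Several starting points are tried (a too-flat start makes the model
# locally unidentifiable); the converged fit with the smallest RSS wins.
fit_sigmoid <- function(x, y) {
  rng <- diff(range(x))
  if (rng == 0) rng <- 1
  starts <- expand.grid(
    x0 = stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE),
    w = rng * c(0.05, 0.15, 0.5))
  fit <- NULL
  for (i in seq_len(nrow(starts))) {
    f <- tryCatch(
      minpack.lm::nlsLM(y ~ A / (1 + exp(-(x - x0) / w)),
                        start = list(A = max(y), x0 = starts$x0[i],
                                     w = starts$w[i]),
                        lower = c(A = 0, x0 = -Inf, w = 1e-6),
                        upper = c(A = 1.5, x0 = Inf, w = Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(f) &&
        (is.null(fit) || stats::deviance(f) < stats::deviance(fit))) {
      fit <- f
    }
  }
  if (is.null(fit)) {
    return(list(fit = NULL, A_ci = c(NA_real_, NA_real_),
                converged = FALSE))
  }
  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients["A", "Std. Error"],
                 error = function(e) NA_real_)
  list(fit = est, A_ci = unname(est["A"] + c(-1.96, 1.96) * se),
       converged = TRUE)
}

#' @export
print.support_curve <- function(x, ...) {
  cat("support_curve over", nrow(x$bins), "height bins; overall support",
      sprintf("%.3f", x$supported_overall), "\n")
  if (x$converged) {
    cat(sprintf(" sigmoid fit: A = %.3f [%.3f, %.3f], x0 = %.3g, w = %.3g\n",
                x$fit["A"], x$A_ci[1], x$A_ci[2], x$fit["x0"], x$fit["w"]))
  } else cat(" sigmoid fit did not converge; empirical curve only\n")
  invisible(x)
}

#' Chimera support of peaks stratified by biological complexity
#'
#' @param clusters interaction clusters with BC column.
#' @param peaks peak data.frame.
#' @return data.frame: BC, n, support (fraction of clusters at that BC
#'   overlapping a peak).
#' @export
support_by_bc <- function(clusters, peaks) {
  hit <- IRanges::overlapsAny(df_to_granges(clusters),
                                    df_to_granges(peaks))
  res <- lapply(sort(unique(clusters$BC)), function(b) {
    sel <- clusters$BC == b
    data.frame(BC = b, n = sum(sel), support = mean(hit[sel]))
  })
  do.call(rbind, res)
}

#' Overlap of chimera clusters with external prediction intervals
#'
#' @param clusters interaction clusters (chrom, start, end, strand, key =
#'   family, gene_id, plus a seed class column named `seed_class`).
#' @param predictions data.frame of prediction intervals with chrom, start,
#'   end, strand and `family` columns.
#' @param abundance optional [compute_abundance()] table; clusters on genes
#'   failing the expressed flag are excluded.
#' @return list with `by_seed_class` (seed_class, n, overlap_fraction),
#'   `by_family` (family, n, overlap_fraction) and
#'   `prediction_support` (fraction of predictions overlapped by a
#'   matching-family cluster).
#' @export
intersect_predictions <- function(clusters, predictions,
                                  abundance = NULL) {
  if (!is.null(abundance)) {
    expressed <- abundance$gene_id[abundance$expressed]
    clusters <- clusters[!is.na(clusters$gene_id) &
                           clusters$gene_id %in% expressed, , drop = FALSE]
  }
  fams <- intersect(unique(clusters$key), unique(predictions$family))
  if (!length(fams) || !nrow(clusters)) {
    return(list(by_seed_class = data.frame(), by_family = data.frame(),
                prediction_support = NA_real_))
  }
  clusters <- clusters[clusters$key %in% fams, , drop = FALSE]
  predictions <- predictions[predictions$family %in% fams, , drop = FALSE]
  cg <- df_to_granges(clusters)
  pg <- df_to_granges(predictions)
  hits <- GenomicRanges::findOverlaps(cg, pg)
  match_fam <- clusters$key[S4Vectors::queryHits(hits)] ==
    predictions$family[S4Vectors::subjectHits(hits)]
  cl_hit <- rep(FALSE, nrow(clusters))
  cl_hit[unique(S4Vectors::queryHits(hits)[match_fam])] <- TRUE
  pr_hit <- rep(FALSE, nrow(predictions))
  pr_hit[unique(S4Vectors::subjectHits(hits)[match_fam])] <- TRUE

  by_class <- do.call(rbind, lapply(unique(clusters$seed_class),
    function(sc) {
      sel <- clusters$seed_class == sc
      data.frame(seed_class = sc, n = sum(sel),
                 overlap_fraction = mean(cl_hit[sel]),
                 stringsAsFactors = FALSE)
    }))
  by_family <- do.call(rbind, lapply(fams, function(f) {
    sel <- clusters$key == f
    data.frame(family = f, n = sum(sel),
               overlap_fraction = mean(cl_hit[sel]),
               stringsAsFactors = FALSE)
  }))
  list(by_seed_class = by_class, by_family = by_family,
       prediction_support = mean(pr_hit))
}
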