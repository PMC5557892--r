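# Binary pairing-vector clustering into structure groups and per-miRNA
# group enrichment.

#' Stack duplex structures into a pairing matrix
#'
#' @param structures list of `duplex_structure` objects.
#' @return 0/1 matrix, one row per structure, columns right-padded with 0
#'   to the longest miRNA.
#' @export
pairing_matrix <- function(structures) {
  maxlen <- max(vapply(structures, function(s) length(s$pairing_vector),
                       integer(1)))
  t(vapply(structures, function(s) {
    v <- s$pairing_vector
    c(v, integer(maxlen - length(v)))
  }, integer(maxlen)))
}

#' Cluster duplex structures by k-means
#'
#' Partitions binary pairing vectors into k structure groups (binding
#' modes). Also returns the within-cluster sum of squares over a range of k
#' for elbow-style model selection.
#'
#' @param mat 0/1 matrix from [pairing_matrix()].
#' @param k number of structure groups (default 8).
#' @param n_starts random restarts (default 50).
#' @param seed RNG seed for reproducible clustering (default 1234).
#' @param elbow_k k values for the elbow curve (default 3:12, clipped to
#'   the number of rows).
#' @return list with `cluster` (assignment 1..k per row), `centers`
#'   (k x positions centroid matrix) and `elbow` (data.frame k, wcss).
#' @export
cluster_structures <- function(mat, k = 8L, n_starts = 50L, seed = 1234L,
                               elbow_k = 3:12) {
  if (nrow(mat) < k) stop("fewer structures than clusters requested")
  run_km <- function(kk) {
    set.seed(seed)
    if (nrow(unique(mat)) <= kk) {
      # degenerate: at most kk distinct rows; assign by identity
      u <- unique(mat)
      cl <- match(apply(mat, 1, paste, collapse = ""),
                  apply(u, 1, paste, collapse = ""))
      return(list(cluster = cl, centers = u, tot.withinss = 0))
    }
    stats::kmeans(mat, centers = kk, nstart = n_starts, iter.max = 50L)
  }
  km <- run_km(k)
  elbow_k <- sort(elbow_k[elbow_k <= nrow(mat)])
  # elbow curve; warm starts from the previous solution keep it monotone
  wcss <- numeric(length(elbow_k))
  prev <- NULL
  for (ei in seq_along(elbow_k)) {
    kk <- elbow_k[ei]
    sol <- run_km(kk)
    if (!is.null(prev) && !is.null(prev$centers) &&
        nrow(prev$centers) < kk && nrow(unique(mat)) > kk) {
      d2 <- rowSums((mat - prev$centers[prev$cluster, , drop = FALSE])^2)
      init <- rbind(prev$centers,
                    mat[order(-d2)[seq_len(kk - nrow(prev$centers))], ,
                        drop = FALSE])
      warm <- tryCatch(stats::kmeans(mat, centers = init, iter.max = 50L),
                       error = function(e) NULL)
      if (!is.null(warm) && warm$tot.withinss < sol$tot.withinss) sol <- warm
    }
    wcss[ei] <- sol$tot.withinss
    prev <- sol
  }
  list(cluster = km$cluster, centers = km$centers,
       elbow = data.frame(k = elbow_k, wcss = wcss))
}

#' Per-miRNA enrichment in structure groups
#'
#' For each (miRNA, group) pair, a two-sided Fisher exact test compares the
#' miRNA's distribution over the group against that of all interactions:
#' the 2x2 table is (miRNA in group, miRNA elsewhere; others in group,
#' others elsewhere).
#'
#' @param assignments integer vector of structure-group ids.
#' @param mirna_labels character vector (same length) of miRNA names.
#' @return data.frame: mirna, group, n_in_group, n_total, odds_ratio,
#'   p_value (p = 1 for empty groups).
#' @export
group_enrichment <- function(assignments, mirna_labels) {
  stopifnot(length(assignments) == length(mirna_labels))
  groups <- sort(unique(assignments))
  mirnas <- sort(unique(mirna_labels))
  res <- list()
  for (mi in mirnas) {
    is_mi <- mirna_labels == mi
    for (g in groups) {
      in_g <- assignments == g
      tab <- matrix(c(sum(is_mi & in_g), sum(is_mi & !in_g),
                      sum(!is_mi & in_g), sum(!is_mi & !in_g)), 2L)
      p <- if (sum(in_g) == 0L) 1 else stats::fisher.test(tab)$p.value
      or <- if (all(tab > 0)) (tab[1, 1] * tab[2, 2]) /
        (tab[1, 2] * tab[2, 1]) else NA_real_
      res[[length(res) + 1L]] <- data.frame(
        mirna = mi, group = g, n_in_group = tab[1, 1],
        n_total = sum(is_mi), odds_ratio = or, p_value = p,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
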