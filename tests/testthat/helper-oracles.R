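# Independent oracles and tiny fixture builders shared by the suite.
# The oracles deliberately use different algorithmic routes than the
# package implementations (window scanning vs variant enumeration for seed
# sites; exhaustive chain enumeration vs dynamic programming for duplexes;
# direct tail summation vs phyper).

rand_seq <- function(n, len) {
  vapply(rep(len, length.out = n), function(l)
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = ""),
    character(1))
}

# --- seed classification oracle: sliding-window mismatch counting --------

oracle_classify_seed <- function(mirna, target) {
  rc1 <- function(s) chimeramap::reverse_complement(s)
  tch <- strsplit(target, "")[[1]]
  pats <- list(`8mer` = paste0(rc1(substr(mirna, 2, 8)), "A"),
               `7mer-m8` = rc1(substr(mirna, 2, 8)),
               `7mer-A1` = paste0(rc1(substr(mirna, 2, 7)), "A"),
               `6mer` = rc1(substr(mirna, 2, 7)),
               `5mer` = rc1(substr(mirna, 2, 6)))
  ham_at <- function(pat, off) {
    pch <- strsplit(pat, "")[[1]]
    sum(tch[off:(off + length(pch) - 1L)] != pch)
  }
  scan <- function(pat, want_mm) {
    L <- nchar(pat)
    if (length(tch) < L) return(NA_integer_)
    for (off in seq_len(length(tch) - L + 1L)) {
      if (ham_at(pat, off) == want_mm) return(off)
    }
    NA_integer_
  }
  for (cls in names(pats)) {
    off <- scan(pats[[cls]], 0L)
    if (!is.na(off)) return(list(category = cls, site_start = off - 1L))
  }
  for (cls in c("8mer", "7mer-m8", "6mer")) {
    off <- scan(pats[[cls]], 1L)
    if (!is.na(off)) {
      return(list(category = paste0("mismatch-", sub("-m8", "", cls)),
                  site_start = off - 1L))
    }
  }
  # bulge: 1 extra target nt strictly inside the span
  bulge_scan <- function(pat) {
    pch <- strsplit(pat, "")[[1]]
    L <- length(pch) + 1L
    if (length(tch) < L) return(NA_integer_)
    for (off in seq_len(length(tch) - L + 1L)) {
      w <- tch[off:(off + L - 1L)]
      for (d in 2:(L - 1L)) {
        if (identical(w[-d], pch)) return(off)
      }
    }
    NA_integer_
  }
  for (cls in c("8mer", "7mer-m8")) {
    off <- bulge_scan(pats[[cls]])
    if (!is.na(off)) {
      return(list(category = paste0("bulged-", sub("-m8", "", cls)),
                  site_start = off - 1L))
    }
  }
  list(category = "none", site_start = NA_integer_)
}

# --- duplex oracle: exhaustive chain enumeration -------------------------

oracle_duplex <- function(mirna, target, forced = integer(0),
                          loop_max = 15, bulge_max = 5) {
  m <- strsplit(mirna, "")[[1]]; t <- strsplit(target, "")[[1]]
  pv <- outer(m, t, chimeramap:::pair_score)
  M <- length(m); T <- length(t)
  best <- list(val = -Inf, chain = NULL)
  legal_next <- function(i, j, ip, jp) {
    gm <- ip - i - 1; gt <- j - 1 - jp
    if (gm < 0 || gt < 0) return(FALSE)
    if (gm == 0 && gt == 0) return(TRUE)
    if (gm == 0) return(gt <= bulge_max)
    if (gt == 0) return(gm <= bulge_max)
    gm <= loop_max && gt <= loop_max
  }
  lex_less <- function(a, b) {
    for (k in seq_len(min(length(a), length(b)))) {
      if (a[[k]][1] != b[[k]][1]) return(a[[k]][1] < b[[k]][1])
      if (a[[k]][2] != b[[k]][2]) return(a[[k]][2] < b[[k]][2])
    }
    length(a) < length(b)
  }
  rec <- function(chain) {
    last <- chain[[length(chain)]]
    covered <- vapply(chain, `[`, 0, 1)
    if (all(forced %in% covered)) {
      sc <- sum(vapply(chain, function(p) pv[p[1], p[2]], 0))
      val <- sc * 64 + length(chain)
      if (val > best$val ||
          (val == best$val && lex_less(chain, best$chain))) {
        best <<- list(val = val, chain = chain)
      }
    }
    if (last[1] >= M || last[2] <= 1) return()
    for (ip in (last[1] + 1):M) for (jp in seq_len(last[2] - 1)) {
      if (pv[ip, jp] > 0 && legal_next(last[1], last[2], ip, jp)) {
        if (length(forced[forced > last[1] & forced < ip])) next
        rec(c(chain, list(c(ip, jp))))
      }
    }
  }
  for (i in seq_len(M)) for (j in seq_len(T)) {
    if (pv[i, j] > 0 && !(length(forced) && i > min(forced))) {
      rec(list(c(i, j)))
    }
  }
  if (!is.finite(best$val)) return(NULL)
  vec <- integer(M)
  for (p in best$chain) vec[p[1]] <- 1L
  list(score = (best$val - length(best$chain)) / 64, pairing_vector = vec,
       pairs = matrix(as.integer(unlist(best$chain)), ncol = 2,
                      byrow = TRUE))
}

# --- hypergeometric upper tail by direct summation -----------------------

oracle_hyper_upper <- function(k, K, N, n) {
  # P(X >= k) for X ~ Hypergeometric(N, K, n)
  kk <- max(k, max(0, n - (N - K))):min(n, K)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# --- adjusted Rand index -------------------------------------------------

adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  exp_ <- sum_a * sum_b / choose(n, 2)
  max_ <- (sum_a + sum_b) / 2
  (sum_ij - exp_) / (max_ - exp_)
}

# --- tiny fixtures -------------------------------------------------------

# Two-gene annotation (one per strand) on a short toy chromosome.
toy_models <- function(downstream = 10000L, chrom_len = 60000L) {
  regions <- data.frame(
    chrom = "chrT",
    start = c(1000L, 1200L, 1800L, 30000L, 30400L, 31000L),
    end = c(1200L, 1800L, 2200L, 30400L, 31000L, 31200L),
    strand = c("+", "+", "+", "-", "-", "-"),
    type = c("five_prime_utr", "CDS", "three_prime_utr",
             "three_prime_utr", "CDS", "five_prime_utr"),
    gene_id = c("geneA", "geneA", "geneA", "geneB", "geneB", "geneB"),
    stringsAsFactors = FALSE)
  chimeramap::gene_models_from_regions(
    regions, downstream = downstream,
    chrom_sizes = c(chrT = chrom_len))
}

toy_catalog <- function() {
  chimeramap::mirna_catalog(
    name = c("bta-miR-17-5p", "bta-miR-224-3p", "syn-miR-900"),
    sequence = c("CAAAGTGCTTACAGTGCAGGTAGT",
                 "CAAAATGGTACCCTAGTGACT",
                 "TGAGGTAGTAGGTTGTATAGTT"))
}
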