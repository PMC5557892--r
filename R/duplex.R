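# Constrained miRNA:target duplex prediction.
#
# The structure model is a maximum-score intermolecular co-fold: an
# antiparallel chain of base pairs (i on the miRNA, j on the target; i
# increasing, j decreasing) scored GC=3, AU=2, GU=1, with no intramolecular
# pairs. Between consecutive pairs, the number of unpaired nucleotides is
# capped at 5 per side for bulges (one side unpaired) and 15 per side for
# internal loops (both sides unpaired). Selected miRNA positions can be
# forced to pair (seed constraints). Optimal structures are tie-broken by
# more pairs, then by the lexicographically smallest pair chain.

# Value encoding: each pair contributes pair_score*64 + 1, so comparing
# encoded values ranks by total score first and number of pairs second
# (npairs <= 26 < 64).

# Dynamic program over chain suffixes. Returns the value matrix
# Fw[i, j] = best encoded value of a legal chain whose first (leftmost on
# the miRNA) pair is (i, j), honoring forced positions from i onward.
# -Inf marks unusable states.
duplex_forward_table <- function(pv, forced, loop_max = 15L,
                                 bulge_max = 5L) {
  M <- nrow(pv); T <- ncol(pv)
  cf <- cumsum(seq_len(M) %in% forced)     # forced positions <= i
  nforced <- if (length(forced)) max(forced) else 0L
  contrib <- ifelse(pv > 0, pv * 64 + 1, -Inf)
  Fw <- matrix(-Inf, M, T)
  # sliding-window maxima of already-computed rows, built lazily
  win_max <- function(row, lo, hi) {
    # w[j] = max(row[j - hi .. j - lo]) (successor j' < j)
    w <- rep(-Inf, T)
    for (d in lo:hi) {
      idx <- seq_len(T) - d
      ok <- idx >= 1L
      w[ok] <- pmax(w[ok], row[idx[ok]])
    }
    w
  }
  W1 <- vector("list", M)   # window j-1 .. j-(bulge_max+1) (gm = 0)
  W2 <- vector("list", M)   # window j-1 .. j-(loop_max+1)  (gm in 1..bulge)
  W3 <- vector("list", M)   # window j-2 .. j-(loop_max+1)  (gm > bulge)
  for (i in M:1) {
    # termination allowed at (i, .) iff no forced position beyond i
    base <- if (nforced <= i) 0 else -Inf
    best_succ <- rep(base, T)
    for (gm in 0:min(loop_max, M - i - 1L)) {
      ip <- i + 1L + gm
      if (ip > M) break
      # no forced position may be skipped strictly between i and ip
      if ((cf[ip - 1L] - cf[i]) > 0L) break
      w <- if (gm == 0L) W1[[ip]] else if (gm <= bulge_max) W2[[ip]] else
        W3[[ip]]
      if (!is.null(w)) best_succ <- pmax(best_succ, w)
    }
    Fw[i, ] <- ifelse(is.finite(contrib[i, ]),
                      contrib[i, ] + best_succ, -Inf)
    Fw[i, ][!is.finite(Fw[i, ])] <- -Inf
    W1[[i]] <- win_max(Fw[i, ], 1L, bulge_max + 1L)
    W2[[i]] <- win_max(Fw[i, ], 1L, loop_max + 1L)
    W3[[i]] <- win_max(Fw[i, ], 2L, loop_max + 1L)
  }
  Fw
}

# Reconstruct the optimal chain (list of c(i, j)) from the forward table:
# lexicographically smallest among value-optimal chains.
duplex_traceback <- function(Fw, pv, forced, loop_max = 15L,
                             bulge_max = 5L) {
  M <- nrow(Fw); T <- ncol(Fw)
  cf <- cumsum(seq_len(M) %in% forced)
  # a chain may start at i only if no forced position lies before i
  start_ok <- if (length(forced)) seq_len(M) <= min(forced) else
    rep(TRUE, M)
  total <- -Inf; si <- NA; sj <- NA
  for (i in which(start_ok)) for (j in seq_len(T)) {
    if (Fw[i, j] > total) { total <- Fw[i, j]; si <- i; sj <- j }
  }
  if (!is.finite(total)) return(NULL)
  chain <- list(c(si, sj))
  i <- si; j <- sj
  repeat {
    r <- Fw[i, j] - (pv[i, j] * 64 + 1)
    if (r == 0) break
    found <- FALSE
    for (ip in (i + 1L):min(M, i + 1L + loop_max)) {
      gm <- ip - i - 1L
      if ((cf[ip - 1L] - cf[i]) > 0L) break
      gt_lo <- if (gm == 0L) 0L else if (gm <= bulge_max) 0L else 1L
      gt_hi <- if (gm == 0L) bulge_max else loop_max
      # prefer the smallest target position (largest gap) on ties
      for (gt in gt_hi:gt_lo) {
        jp <- j - 1L - gt
        if (jp < 1L) next
        if (is.finite(Fw[ip, jp]) && Fw[ip, jp] == r) {
          chain[[length(chain) + 1L]] <- c(ip, jp)
          i <- ip; j <- jp; found <- TRUE
          break
        }
      }
      if (found) break
    }
    if (!found) stop("duplex traceback failed (internal error)")
  }
  chain
}

# Core solver: best chain under forced miRNA positions.
# Returns NULL when no legal chain satisfies the constraints.
duplex_solve <- function(mirna, target, forced = integer(0),
                         loop_max = 15L, bulge_max = 5L) {
  m <- strsplit(normalize_dna(mirna), "")[[1]]
  t <- strsplit(normalize_dna(target), "")[[1]]
  pv <- outer(m, t, pair_score)
  Fw <- duplex_forward_table(pv, forced, loop_max, bulge_max)
  chain <- duplex_traceback(Fw, pv, forced, loop_max, bulge_max)
  if (is.null(chain)) return(NULL)
  vec <- integer(length(m))
  score <- 0L
  for (p in chain) {
    vec[p[1]] <- 1L
    score <- score + pv[p[1], p[2]]
  }
  list(pairing_vector = vec, score = as.integer(score),
       pairs = do.call(rbind, chain))
}

# Forced miRNA positions implied by a seed class (the Watson-Crick-matched
# span; the target-encoded A of 8mer/7mer-A1 sites is recognized by the
# protein, not paired).
seed_forced_positions <- function(category) {
  switch(category,
         `8mer` = 2:8, `7mer-m8` = 2:8,
         `7mer-A1` = 2:7, `6mer` = 2:7,
         `5mer` = 2:6,
         integer(0))
}

#' Predict the miRNA:target duplex structure
#'
#' Runs the pair-scoring dynamic program with seed-dependent constraints:
#' perfect seed sites force pairing over the matched seed span; mismatch or
#' bulged seeds trigger two runs forcing positions {3,4} and {5,6}, keeping
#' the structure with more pairs in positions 2-8 (ties: more total pairs,
#' then the {3,4} run); targets without a seed site fold unconstrained.
#' Infeasible constraints fall back to the unconstrained fold, flagged.
#'
#' @param mirna mature miRNA sequence.
#' @param target target window sequence (at most 100 nt).
#' @param seed a [classify_seed()] result for this pair; computed when
#'   missing.
#' @param loop_max,bulge_max per-side caps on internal loops and bulges
#'   (defaults 15 and 5).
#' @return object of class `duplex_structure`: list with `pairing_vector`
#'   (0/1 per miRNA position, Watson-Crick or G:U = 1), `score`,
#'   `constraints_used` (forced miRNA positions), `seed_category` and
#'   `fallback` flag.
#' @export
predict_duplex <- function(mirna, target, seed = NULL,
                           loop_max = 15L, bulge_max = 5L) {
  mirna <- normalize_dna(mirna); target <- normalize_dna(target)
  stopifnot(nchar(target) <= 100)
  if (is.null(seed)) seed <- classify_seed(mirna, target)
  cat <- seed$category
  fallback <- FALSE
  if (cat %in% c("8mer", "7mer-m8", "7mer-A1", "6mer", "5mer")) {
    forced <- seed_forced_positions(cat)
    sol <- duplex_solve(mirna, target, forced, loop_max, bulge_max)
    if (is.null(sol)) {
      fallback <- TRUE
      forced <- integer(0)
      sol <- duplex_solve(mirna, target, forced, loop_max, bulge_max)
    }
  } else if (startsWith(cat, "mismatch") || startsWith(cat, "bulged")) {
    s34 <- duplex_solve(mirna, target, 3:4, loop_max, bulge_max)
    s56 <- duplex_solve(mirna, target, 5:6, loop_max, bulge_max)
    if (is.null(s34) && is.null(s56)) {
      fallback <- TRUE
      forced <- integer(0)
      sol <- duplex_solve(mirna, target, forced, loop_max, bulge_max)
    } else if (is.null(s56)) {
      sol <- s34; forced <- 3:4
    } else if (is.null(s34)) {
      sol <- s56; forced <- 5:6
    } else {
      seed_pairs <- function(s) sum(s$pairing_vector[2:8])
      pick34 <- seed_pairs(s34) > seed_pairs(s56) ||
        (seed_pairs(s34) == seed_pairs(s56) &&
           sum(s34$pairing_vector) >= sum(s56$pairing_vector))
      if (pick34) { sol <- s34; forced <- 3:4 } else { sol <- s56
        forced <- 5:6 }
    }
  } else {
    forced <- integer(0)
    sol <- duplex_solve(mirna, target, forced, loop_max, bulge_max)
  }
  if (is.null(sol)) {
    sol <- list(pairing_vector = integer(nchar(mirna)), score = 0L,
                pairs = NULL)
  }
  structure(list(pairing_vector = sol$pairing_vector,
                 score = sol$score,
                 pairs = sol$pairs,
                 constraints_used = forced,
                 seed_category = cat,
                 fallback = fallback),
            class = "duplex_structure")
}

#' @export
print.duplex_structure <- function(x, ...) {
  cat("duplex_structure: score", x$score, "seed", x$seed_category, "\n")
  cat(" pairing:", paste(x$pairing_vector, collapse = ""), "\n")
  if (length(x$constraints_used))
    cat(" forced :", paste(x$constraints_used, collapse = ","),
        if (x$fallback) "(fallback: constraints infeasible)" else "", "\n")
  invisible(x)
}
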