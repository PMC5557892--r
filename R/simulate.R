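# Synthetic data generator: toy genome + annotation, miRNome with seed
# families and hairpin loci, planted miRNA-target interactions, CLIP read
# libraries with chimeras / PCR duplicates / background peaks, and
# expression tables with a planted de-repression of targeted genes.
# Ground truth travels alongside every output so recovery can be scored.

#' Simulation configuration
#'
#' Defaults describe the desk-scale study conditions used throughout the
#' test-suite: 50 genes, 20 miRNAs in 16 seed families, 3 replicates,
#' 1e5 reads with 2% chimeras (within the 0.5-5% range seen in real
#' libraries), a 30% PCR duplicate rate, a 5-nt degenerate barcode and a
#' planted de-repression of log2FC 0.11 for chimera-targeted genes.
#'
#' @param rng_seed master seed; all stages derive their streams from it.
#' @param n_genes,n_mirnas,n_families reference dimensions.
#' @param n_hairpins hairpin loci carrying one annotated and one novel arm.
#' @param replicates CLIP replicate libraries.
#' @param n_interactions planted miRNA-target interactions.
#' @param seed_type_mix named fractions over site classes (must sum to 1).
#' @param mirfirst_fraction fraction of chimeric reads with the miRNA 5' of
#'   the target.
#' @param chimera_fraction chimeric fraction of total reads.
#' @param mirna_read_fraction fraction of reads that are pure AGO-loaded
#'   miRNA sequences.
#' @param duplicate_rate fraction of reads that are PCR re-emissions.
#' @param read_depth total reads across replicates.
#' @param mismatch_rate,truncation_rate per-chimera probability of a 1-nt
#'   substitution / 1-nt end truncation in the miRNA portion.
#' @param barcode_length degenerate barcode length.
#' @param planted_log2fc de-repression effect for targeted genes.
#' @param dispersion gamma-Poisson expression dispersion.
#' @param expression_reps replicates per expression condition.
#' @param novel_arm_reads copies emitted per non-annotated hairpin arm.
#' @param cds_site_fraction,downstream_site_fraction minority site
#'   placement outside 3'UTRs.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(rng_seed = 1L,
                       n_genes = 50L, n_mirnas = 20L, n_families = 16L,
                       n_hairpins = 4L, replicates = 3L,
                       n_interactions = 150L,
                       seed_type_mix = c(`8mer` = 0.40, `7mer` = 0.25,
                                         `6mer` = 0.15, mismatch = 0.10,
                                         bulged = 0.05,
                                         noncanonical = 0.05),
                       mirfirst_fraction = 0.8,
                       chimera_fraction = 0.02,
                       mirna_read_fraction = 0.05,
                       duplicate_rate = 0.3,
                       read_depth = 1e5,
                       mismatch_rate = 0.05, truncation_rate = 0.05,
                       barcode_length = 5L,
                       planted_log2fc = 0.11,
                       dispersion = 0.1,
                       expression_reps = 3L,
                       novel_arm_reads = 150L,
                       cds_site_fraction = 0.10,
                       downstream_site_fraction = 0.05) {
  stopifnot(abs(sum(seed_type_mix) - 1) < 1e-8,
            n_families <= n_mirnas, n_hairpins <= n_mirnas)
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

# Gene geometry (nt) used by the reference builder.
.gene_geom <- list(utr5 = 200L, cds1 = 300L, intron = 150L, cds2 = 300L,
                   utr3 = 400L, spacer = 12000L, genes_per_chrom = 10L)

#' Simulate the toy reference: genome, gene models, hairpin slots
#'
#' Genes carry 5'UTR / split CDS with one intron / 3'UTR and alternate
#' strands; intergenic spacing exceeds 10 kb so the downstream-of-3'UTR
#' annotation rule is exercised. Hairpin loci are reserved in intergenic
#' space and filled by [simulate_mirnome()].
#'
#' @param config a [sim_config()].
#' @return list: `genome` (named character vector), `models`
#'   (`gene_models`), `gene_table`, `hairpin_slots` (data.frame of loci),
#'   `chrom_sizes`.
#' @export
simulate_reference <- function(config) {
  set.seed(config$rng_seed)
  g <- .gene_geom
  gene_len <- g$utr5 + g$cds1 + g$intron + g$cds2 + g$utr3
  n_chrom <- ceiling(config$n_genes / g$genes_per_chrom)
  chrom_len <- g$genes_per_chrom * (gene_len + g$spacer) + g$spacer
  genome <- stats::setNames(random_dna(n_chrom, chrom_len),
                            paste0("chr", seq_len(n_chrom)))
  regions <- list()
  gene_table <- list()
  gi <- 0L
  for (ci in seq_len(n_chrom)) {
    for (s in seq_len(g$genes_per_chrom)) {
      gi <- gi + 1L
      if (gi > config$n_genes) break
      gstart <- g$spacer + (s - 1L) * (gene_len + g$spacer)
      strand <- if (gi %% 2L == 0L) "-" else "+"
      gene_id <- sprintf("gene%03d", gi)
      # genomic-order block lengths; on '-' the transcript reads right->left
      blocks <- if (strand == "+") {
        c(utr5 = g$utr5, cds = g$cds1, intron = g$intron, cds2 = g$cds2,
          utr3 = g$utr3)
      } else {
        c(utr3 = g$utr3, cds = g$cds2, intron = g$intron, cds2 = g$cds1,
          utr5 = g$utr5)
      }
      off <- gstart
      for (b in seq_along(blocks)) {
        ty <- sub("2$", "", names(blocks)[b])
        regions[[length(regions) + 1L]] <- data.frame(
          chrom = names(genome)[ci], start = off, end = off + blocks[b],
          strand = strand,
          type = c(utr5 = "five_prime_utr", cds = "CDS",
                   intron = "intron", utr3 = "three_prime_utr")[[ty]],
          gene_id = gene_id, stringsAsFactors = FALSE)
        off <- off + blocks[b]
      }
      gene_table[[length(gene_table) + 1L]] <- data.frame(
        chrom = names(genome)[ci], start = gstart, end = gstart + gene_len,
        strand = strand, gene_id = gene_id, stringsAsFactors = FALSE)
    }
  }
  regions <- do.call(rbind, regions)
  gene_table <- do.call(rbind, gene_table)
  chrom_sizes <- stats::setNames(rep(chrom_len, n_chrom), names(genome))
  models <- gene_models_from_regions(regions, chrom_sizes = chrom_sizes)

  # hairpin slots midway through intergenic gaps on chr1
  slots <- data.frame(
    chrom = "chr1",
    start = g$spacer %/% 2L +
      seq_len(config$n_hairpins) * (gene_len + g$spacer),
    strand = "+", stringsAsFactors = FALSE)
  slots$end <- slots$start  # filled by simulate_mirnome

  list(genome = genome, models = models, gene_table = gene_table,
       hairpin_slots = slots, chrom_sizes = chrom_sizes)
}

#' Simulate the miRNome and fill hairpin loci
#'
#' Generates `n_mirnas` mature sequences over `n_families` distinct seeds
#' (the first families carry two members each when miRNAs outnumber
#' families, giving shared-seed fixtures). The first `n_hairpins` miRNAs
#' become the annotated arms of genomic hairpins whose opposite arm is an
#' unannotated (novel) mature sequence written into the genome.
#'
#' @param config a [sim_config()].
#' @param reference output of [simulate_reference()]; its genome is
#'   modified in the returned copy.
#' @return list: `catalog` ([mirna_catalog()]), `genome` (with hairpins
#'   written in), `precursors` (chrom, start, end, strand, name,
#'   annotated_arm), `novel_arms` (data.frame name, sequence, hairpin,
#'   arm).
#' @export
simulate_mirnome <- function(config, reference) {
  set.seed(config$rng_seed + 1L)
  n <- config$n_mirnas
  seeds <- character(0)
  while (length(unique(seeds)) < config$n_families)
    seeds <- unique(c(seeds, random_dna(config$n_families, 7L)))
  seeds <- seeds[seq_len(config$n_families)]
  extra <- n - config$n_families
  fam_of <- c(seq_len(config$n_families),
              rep(seq_len(max(1L, extra)), length.out = max(0L, extra)))
  seqs <- vapply(fam_of, function(f) {
    len <- sample(21:22, 1L)
    paste0(random_dna(1L, 1L), seeds[f], random_dna(1L, len - 8L))
  }, character(1))
  while (anyDuplicated(seqs)) {
    d <- which(duplicated(seqs))
    seqs[d] <- vapply(fam_of[d], function(f)
      paste0(random_dna(1L, 1L), seeds[f], random_dna(1L, 13L)),
      character(1))
  }
  names_ <- sprintf("syn-miR-%03d", seq_len(n))

  genome <- reference$genome
  slots <- reference$hairpin_slots
  loop <- "GTGTATGTTG"
  precursors <- list(); novel <- list()
  for (h in seq_len(config$n_hairpins)) {
    annotated_arm <- if (h %% 2L == 1L) "5p" else "3p"
    mature <- seqs[h]
    # opposite arm: near-reverse-complement of the mature (3 substitutions
    # keep its genomic placement unique)
    opp <- strsplit(reverse_complement(mature), "")[[1]]
    mut <- sample(seq_along(opp), 3L)
    for (p in mut) opp[p] <- sample(setdiff(c("A", "C", "G", "T"), opp[p]),
                                    1L)
    opp <- paste(opp, collapse = "")
    hp_seq <- if (annotated_arm == "5p") paste0(mature, loop, opp) else
      paste0(opp, loop, mature)
    st <- slots$start[h]
    substr(genome[[slots$chrom[h]]], st + 1L, st + nchar(hp_seq)) <- hp_seq
    hp_name <- sprintf("syn-hairpin-%03d", h)
    precursors[[h]] <- data.frame(
      chrom = slots$chrom[h], start = st, end = st + nchar(hp_seq),
      strand = "+", name = hp_name, annotated_arm = annotated_arm,
      stringsAsFactors = FALSE)
    novel[[h]] <- data.frame(
      name = paste0(hp_name, "-", if (annotated_arm == "5p") "3p" else
        "5p"),
      sequence = opp, hairpin = hp_name,
      arm = if (annotated_arm == "5p") "3p" else "5p",
      stringsAsFactors = FALSE)
  }
  precursors <- do.call(rbind, precursors)
  list(catalog = mirna_catalog(names_, seqs, precursor = precursors),
       genome = genome, precursors = precursors,
       novel_arms = do.call(rbind, novel))
}

# Site sequence for a seed class (target 5'->3'), plus the classify_seed
# category it should produce.
.plant_site <- function(mirna, type) {
  pats <- seed_patterns(mirna)
  if (type == "8mer") return(pats$`8mer`)
  # trailing non-A guards keep a 7mer from being promoted to an 8mer (and
  # a 6mer to a 7mer-A1) by a chance adenosine in the flank
  if (type == "7mer")
    return(paste0(pats$`7mer-m8`, sample(c("C", "G", "T"), 1L)))
  if (type == "6mer")
    return(paste0(pats$`6mer`, sample(c("C", "G", "T"), 1L)))
  if (type == "mismatch") {
    # defect at positions 3-6 of the 7mer span so no canonical 6/5mer
    # sub-site survives intact
    ch <- strsplit(pats$`7mer-m8`, "")[[1]]
    p <- sample(3:6, 1L)
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
    return(paste(ch, collapse = ""))
  }
  if (type == "bulged") {
    # insertion inside positions 3-6 interrupts every canonical sub-site
    ch <- strsplit(pats$`8mer`, "")[[1]]
    p <- sample(3:6, 1L)
    ins <- sample(setdiff(c("A", "C", "G", "T"), ch[p + 1L]), 1L)
    return(paste(append(ch, ins, after = p), collapse = ""))
  }
  # noncanonical: random, rejected while it contains even a 5mer site
  repeat {
    s <- random_dna(1L, 8L)
    if (!grepl(pats$`5mer`, s, fixed = TRUE)) return(s)
  }
}

#' Plant ground-truth interactions into the reference
#'
#' Sites of the configured seed-type mix are written into gene 3'UTRs
#' (with configurable minorities in CDS and the 10-kb downstream region),
#' spaced at least 80 nt apart so interaction clusters stay distinct. Each
#' interaction carries a structure archetype and an expected chimera
#' weight. Interaction counts per miRNA follow a fixed allocation giving
#' the first miRNAs deep coverage (motif-eligible) and the rest sparse
#' coverage.
#'
#' @param config a [sim_config()].
#' @param reference output of [simulate_reference()].
#' @param mirnome output of [simulate_mirnome()].
#' @return list: `truth` (one row per interaction: interaction_id, gene_id,
#'   mirna_name, family_key, chrom, site_start, site_end, strand, region,
#'   seed_type, archetype, weight), `genome` (with sites planted).
#' @export
simulate_truth <- function(config, reference, mirnome) {
  set.seed(config$rng_seed + 2L)
  genome <- mirnome$genome
  catalog <- mirnome$catalog
  g <- .gene_geom
  n <- config$n_interactions
  # per-miRNA allocation: deep for the first three, uniform for the rest
  deep <- pmin(c(45L, 25L, 15L), n)
  while (sum(deep) > n) deep[which.max(deep)] <- deep[which.max(deep)] - 1L
  alloc <- c(deep, rep(0L, nrow(catalog) - length(deep)))
  rest <- n - sum(deep)
  if (rest > 0L && nrow(catalog) > length(deep)) {
    others <- (length(deep) + 1L):nrow(catalog)
    add <- table(factor(sample(others, rest, replace = TRUE),
                        levels = others))
    alloc[others] <- as.integer(add)
  }
  # free site slots per gene, 80 nt apart
  slots <- list()
  for (r in seq_len(nrow(reference$gene_table))) {
    gene <- reference$gene_table[r, ]
    reg <- reference$models$regions
    u3 <- reg[reg$gene_id == gene$gene_id & reg$type == "utr3", ][1, ]
    cds <- reg[reg$gene_id == gene$gene_id & reg$type == "cds", ][1, ]
    ds <- reg[reg$gene_id == gene$gene_id & reg$type == "downstream10k", ][1, ]
    mk <- function(row, lab, nslot) {
      if (is.na(row$start)) return(NULL)
      pos <- seq(row$start + 20L, row$end - 30L, by = 80L)
      if (length(pos) > nslot) pos <- pos[seq_len(nslot)]
      data.frame(gene_id = gene$gene_id, chrom = row$chrom, pos = pos,
                 strand = row$strand, region = lab,
                 stringsAsFactors = FALSE)
    }
    slots[[length(slots) + 1L]] <- rbind(mk(u3, "utr3", 4L),
                                         mk(cds, "cds", 2L),
                                         mk(ds, "downstream10k", 2L))
  }
  slots <- do.call(rbind, slots)
  slots <- slots[sample(nrow(slots)), , drop = FALSE]

  mix <- config$seed_type_mix
  types <- sample(names(mix), n, replace = TRUE, prob = mix)
  region_pick <- function() {
    u <- stats::runif(1)
    if (u < config$cds_site_fraction) "cds"
    else if (u < config$cds_site_fraction +
             config$downstream_site_fraction) "downstream10k"
    else "utr3"
  }
  truth <- list()
  used <- rep(FALSE, nrow(slots))
  ii <- 0L
  for (mi in seq_along(alloc)) {
    for (rep_i in seq_len(alloc[mi])) {
      want <- region_pick()
      free <- which(!used & slots$region == want)
      if (!length(free)) free <- which(!used)
      if (!length(free)) next
      sl <- free[1L]; used[sl] <- TRUE
      ii <- ii + 1L
      type <- types[ii]
      site <- .plant_site(catalog$sequence[mi], type)
      # write the site in transcript orientation
      s <- slots$pos[sl]
      gseq <- if (slots$strand[sl] == "+") site else
        reverse_complement(site)
      substr(genome[[slots$chrom[sl]]], s + 1L, s + nchar(site)) <- gseq
      truth[[ii]] <- data.frame(
        interaction_id = sprintf("int%04d", ii),
        gene_id = slots$gene_id[sl], mirna_name = catalog$name[mi],
        family_key = catalog$family_key[mi],
        chrom = slots$chrom[sl], site_start = s,
        site_end = s + nchar(site), strand = slots$strand[sl],
        region = slots$region[sl], seed_type = type,
        archetype = sample(8L, 1L),
        weight = 1L + stats::rpois(1L, 2L),
        stringsAsFactors = FALSE)
    }
  }
  list(truth = do.call(rbind, truth), genome = genome)
}

#' Simulate CLIP read libraries
#'
#' Emits, per replicate: background reads (half concentrated at planted
#' sites, forming peaks, half uniform over gene bodies), pure AGO-loaded
#' miRNA reads (plus abundant copies of the novel hairpin arms), and
#' chimeric reads (barcode + miRNA + target for miRfirst; barcode + target
#' + miRNA for miRlast) with configurable miRNA substitution/truncation
#' rates. PCR duplicates re-emit existing reads with the same barcode.
#'
#' @param config a [sim_config()].
#' @param reference output of [simulate_reference()].
#' @param mirnome output of [simulate_mirnome()].
#' @param truth output of [simulate_truth()] (its genome carries the
#'   planted sites).
#' @return list: `reads` (list of per-replicate data.frames: read_id,
#'   sequence, barcode, replicate_id), `provenance` (data.frame read_id,
#'   class, interaction_id, exact), `genome`.
#' @export
simulate_clip_reads <- function(config, reference, mirnome, truth) {
  set.seed(config$rng_seed + 3L)
  genome <- truth$genome
  tr <- truth$truth
  catalog <- mirnome$catalog
  depth <- config$read_depth
  n_unique <- round(depth * (1 - config$duplicate_rate))
  n_chim_u <- round(n_unique * config$chimera_fraction)
  n_mir_u <- round(n_unique * config$mirna_read_fraction)
  n_novel <- if (nrow(mirnome$novel_arms %||% data.frame()) > 0)
    nrow(mirnome$novel_arms) * config$novel_arm_reads else 0L
  n_bg_u <- n_unique - n_chim_u - n_mir_u - n_novel
  bc <- function(k) vapply(seq_len(k), function(i)
    paste(sample(c("A", "C", "G", "T"), config$barcode_length, TRUE),
          collapse = ""), character(1))

  # --- chimeric reads (vectorized)
  ints <- sample(nrow(tr), n_chim_u, replace = TRUE, prob = tr$weight)
  t_ <- tr[ints, , drop = FALSE]
  mseq <- catalog$sequence[match(t_$mirna_name, catalog$name)]
  exact <- rep(TRUE, n_chim_u)
  trunc <- stats::runif(n_chim_u) < config$truncation_rate
  t5 <- trunc & stats::runif(n_chim_u) < 0.5
  mseq[t5] <- substr(mseq[t5], 2L, nchar(mseq[t5]))
  mseq[trunc & !t5] <- substr(mseq[trunc & !t5], 1L,
                              nchar(mseq[trunc & !t5]) - 1L)
  mism <- stats::runif(n_chim_u) < config$mismatch_rate
  for (i in which(mism)) {
    p <- sample(nchar(mseq[i]), 1L)
    ch <- strsplit(mseq[i], "")[[1]]
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
    mseq[i] <- paste(ch, collapse = "")
  }
  exact[trunc | mism] <- FALSE
  flen <- sample(25:35, n_chim_u, replace = TRUE)
  off <- sample(0:8, n_chim_u, replace = TRUE)
  plus <- t_$strand == "+"
  fs <- ifelse(plus, pmax(0L, t_$site_start - off),
               pmax(0L, t_$site_end + off - flen))
  frag <- substring(genome[t_$chrom], fs + 1L, fs + flen)
  frag[!plus] <- reverse_complement(frag[!plus])
  mirfirst <- stats::runif(n_chim_u) < config$mirfirst_fraction
  chim <- if (n_chim_u == 0L) NULL else data.frame(
    read_id = sprintf("chim|%s|%06d", t_$interaction_id,
                      seq_len(n_chim_u)),
    sequence = ifelse(mirfirst, paste0(mseq, frag), paste0(frag, mseq)),
    class = "chimera", interaction_id = t_$interaction_id, exact = exact,
    stringsAsFactors = FALSE)

  # --- pure miRNA reads
  wts <- (nrow(catalog):1)^2
  mi <- sample(nrow(catalog), n_mir_u, replace = TRUE, prob = wts)
  mir_seq <- vapply(mi, function(j) {
    s <- catalog$sequence[j]
    if (stats::runif(1) < 0.8) s else {
      w <- sample(17:min(26, nchar(s)), 1L)
      o <- sample(nchar(s) - w + 1L, 1L)
      substr(s, o, o + w - 1L)
    }
  }, character(1))
  mir <- if (n_mir_u == 0L) NULL else
    data.frame(read_id = sprintf("mirna|%06d", seq_len(n_mir_u)),
                    sequence = mir_seq, class = "mirna",
                    interaction_id = NA_character_, exact = TRUE,
                    stringsAsFactors = FALSE)

  # --- novel-arm reads
  nov <- NULL
  if (n_novel > 0L) {
    nov <- data.frame(
      read_id = sprintf("novel|%06d", seq_len(n_novel)),
      sequence = rep(mirnome$novel_arms$sequence,
                     each = config$novel_arm_reads),
      class = "novel_arm", interaction_id = NA_character_, exact = TRUE,
      stringsAsFactors = FALSE)
  }

  # --- background reads (exact 50-nt genomic copies, vectorized)
  rl <- 50L
  n_peak <- round(n_bg_u * 0.5)
  pk <- tr[sample(nrow(tr), n_peak, replace = TRUE, prob = tr$weight), ,
           drop = FALSE]
  jit <- sample(0:30, n_peak, replace = TRUE)
  pk_fs <- ifelse(pk$strand == "+", pmax(0L, pk$site_start - jit),
                  pmax(0L, pk$site_end + jit - rl))
  gidx <- sample(nrow(reference$gene_table), n_bg_u - n_peak,
                 replace = TRUE)
  gn <- reference$gene_table[gidx, , drop = FALSE]
  un_fs <- gn$start + floor(stats::runif(nrow(gn)) *
                              (gn$end - gn$start - rl))
  chrom <- c(pk$chrom, gn$chrom)
  strand <- c(pk$strand, gn$strand)
  fs <- c(pk_fs, un_fs)
  bseq <- substring(genome[chrom], fs + 1L, fs + rl)
  bseq[strand == "-"] <- reverse_complement(bseq[strand == "-"])
  bg <- data.frame(read_id = sprintf("bg|%06d", seq_len(n_bg_u)),
                   sequence = bseq, class = "background",
                   interaction_id = NA_character_, exact = TRUE,
                   stringsAsFactors = FALSE)

  pool <- rbind(chim, mir, nov, bg)
  pool$barcode <- bc(nrow(pool))
  pool$replicate_id <- paste0("rep", sample(config$replicates,
                                            nrow(pool), replace = TRUE))
  # --- PCR duplicates: re-emit existing reads, same barcode & replicate
  n_dup <- depth - nrow(pool)
  if (n_dup > 0L) {
    src <- pool[sample(nrow(pool), n_dup, replace = TRUE), , drop = FALSE]
    src$read_id <- sprintf("dup|%06d|%s", seq_len(n_dup), src$read_id)
    src$class <- "duplicate"
    pool <- rbind(pool, src)
  }
  pool <- pool[sample(nrow(pool)), , drop = FALSE]
  rownames(pool) <- NULL
  reads <- lapply(split(pool, pool$replicate_id), function(p)
    p[, c("read_id", "sequence", "barcode", "replicate_id")])
  provenance <- pool[, c("read_id", "class", "interaction_id", "exact",
                         "replicate_id", "barcode")]
  list(reads = reads, provenance = provenance, genome = genome)
}

#' Simulate expression count tables with a planted de-repression
#'
#' Gamma-Poisson (negative binomial) counts for two conditions; targeted
#' genes receive a multiplicative `2^effect` increase in the treated
#' condition.
#'
#' @param gene_ids character vector of genes.
#' @param targeted logical or character subset receiving the effect.
#' @param effect planted log2 fold change (default 0.11).
#' @param dispersion gamma-Poisson dispersion (default 0.1).
#' @param n_reps replicates per condition (default 3).
#' @param mean_count expected baseline count (default 300).
#' @param seed optional RNG seed.
#' @return list: `treated`, `control` (data.frames gene_id + rep columns),
#'   `truth` (gene_id, targeted, mu).
#' @export
simulate_expression <- function(gene_ids, targeted, effect = 0.11,
                                dispersion = 0.1, n_reps = 3L,
                                mean_count = 300, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.logical(targeted)) targeted <- gene_ids %in% targeted
  n <- length(gene_ids)
  mu <- stats::rlnorm(n, log(mean_count), 0.6)
  draw <- function(mu_vec) {
    as.data.frame(vapply(seq_len(n_reps), function(r)
      stats::rnbinom(n, mu = mu_vec, size = 1 / dispersion), numeric(n)))
  }
  ctrl <- draw(mu)
  trt <- draw(mu * ifelse(targeted, 2^effect, 1))
  names(ctrl) <- paste0("control_", seq_len(n_reps))
  names(trt) <- paste0("treated_", seq_len(n_reps))
  list(treated = cbind(data.frame(gene_id = gene_ids), trt),
       control = cbind(data.frame(gene_id = gene_ids), ctrl),
       truth = data.frame(gene_id = gene_ids, targeted = targeted,
                          mu = mu, stringsAsFactors = FALSE))
}

#' The eight structure archetypes used by the generator
#'
#' Binary pairing templates over 22 miRNA positions reflecting the binding
#' modes recurrently seen in chimera data: seed-only, seed plus central or
#' 3' auxiliary pairing (two variants), seedless 3' pairing, bipartite and
#' tripartite patterns, and near-full pairing.
#'
#' @return 8 x 22 0/1 matrix.
#' @export
structure_archetypes <- function() {
  a <- rbind(
    c(1,1,1,1,1,1,1,1, 0,0,0,0,0,0,0,0,0,0,0,0,0,0),  # seed only
    c(1,1,1,1,1,1,1,1, 0,0,1,1,1,1,0,0,0,0,0,0,0,0),  # seed + central
    c(1,1,1,1,1,1,1,1, 0,0,0,0,0,1,1,1,1,1,1,1,0,0),  # seed + 3' aux
    c(0,0,0,0,0,0,0,0, 0,0,0,1,1,1,1,1,1,1,1,1,1,0),  # 3' only (no seed)
    c(1,1,1,1,1,1,1,1, 0,0,1,1,1,0,0,0,1,1,1,1,0,0),  # bipartite aux
    c(1,1,1,1,1,1,0,0, 0,1,1,1,0,0,1,1,1,0,0,1,1,0),  # tripartite
    c(1,1,1,1,1,1,1,1, 1,1,1,1,1,1,1,1,1,1,1,1,1,1),  # near-full
    c(1,1,1,1,1,0,0,0, 0,0,0,0,0,0,1,1,1,1,1,1,1,1))  # 5' partial + 3'
  storage.mode(a) <- "integer"
  a
}

#' Simulate noisy pairing vectors from the structure archetypes
#'
#' @param n_per structures per archetype.
#' @param flip_rate per-position bit-flip probability (default 0.05).
#' @param seed optional RNG seed.
#' @return list: `mat` (0/1 matrix), `labels` (archetype id per row).
#' @export
simulate_pairing_vectors <- function(n_per = 100L, flip_rate = 0.05,
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  arch <- structure_archetypes()
  mat <- arch[rep(seq_len(nrow(arch)), each = n_per), , drop = FALSE]
  flips <- matrix(stats::runif(length(mat)) < flip_rate, nrow(mat))
  mat[flips] <- 1L - mat[flips]
  list(mat = mat, labels = rep(seq_len(nrow(arch)), each = n_per))
}

#' Run the full generator
#'
#' @param config a [sim_config()].
#' @return list with all simulation products: reference, mirnome, truth,
#'   reads (+ provenance), expression.
#' @export
simulate_dataset <- function(config = sim_config()) {
  ref <- simulate_reference(config)
  mir <- simulate_mirnome(config, ref)
  tru <- simulate_truth(config, ref, mir)
  rd <- simulate_clip_reads(config, ref, mir, tru)
  targeted <- unique(tru$truth$gene_id)
  expr <- simulate_expression(ref$gene_table$gene_id, targeted,
                              effect = config$planted_log2fc,
                              dispersion = config$dispersion,
                              n_reps = config$expression_reps,
                              seed = config$rng_seed + 4L)
  list(config = config, reference = ref, mirnome = mir,
       truth = tru$truth, genome = rd$genome, reads = rd$reads,
       provenance = rd$provenance, expression = expr)
}

#' Write a simulated dataset to disk
#'
#' Writes genome.fa, genes.gtf, mirnas.fa, reads_<rep>.fq, counts
#' (treated/control TSV), precursors.tsv and truth.tsv under `outdir`.
#'
#' @param sim output of [simulate_dataset()].
#' @param outdir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_dataset <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- list()
  p$genome <- file.path(outdir, "genome.fa")
  ss <- Biostrings::DNAStringSet(sim$genome)
  Biostrings::writeXStringSet(ss, p$genome)
  p$gtf <- file.path(outdir, "genes.gtf")
  write_gtf(sim$reference$models$regions, p$gtf)
  p$mirnas <- file.path(outdir, "mirnas.fa")
  write_mirna_fasta(sim$mirnome$catalog, p$mirnas)
  for (rep_ in names(sim$reads)) {
    fp <- file.path(outdir, paste0("reads_", rep_, ".fq"))
    write_fastq(sim$reads[[rep_]], fp)
    p[[paste0("reads_", rep_)]] <- fp
  }
  p$counts_treated <- file.path(outdir, "counts_treated.tsv")
  write_tsv(sim$expression$treated, p$counts_treated)
  p$counts_control <- file.path(outdir, "counts_control.tsv")
  write_tsv(sim$expression$control, p$counts_control)
  p$precursors <- file.path(outdir, "precursors.tsv")
  write_tsv(sim$mirnome$precursors, p$precursors)
  p$truth <- file.path(outdir, "truth.tsv")
  write_tsv(sim$truth, p$truth)
  invisible(p)
}

#' Write reads as FASTQ (barcode re-attached as the first bases)
#' @param reads read data.frame (read_id, sequence, barcode).
#' @param path output path.
#' @export
write_fastq <- function(reads, path) {
  seq_ <- paste0(reads$barcode, reads$sequence)
  out <- character(4L * nrow(reads))
  out[c(TRUE, FALSE, FALSE, FALSE)] <- paste0("@", reads$read_id)
  out[c(FALSE, TRUE, FALSE, FALSE)] <- seq_
  out[c(FALSE, FALSE, TRUE, FALSE)] <- "+"
  out[c(FALSE, FALSE, FALSE, TRUE)] <-
    vapply(nchar(seq_), function(n) strrep("I", n), character(1))
  writeLines(out, path)
  invisible(path)
}

# Minimal GTF writer for the simulator's gene models (1-based inclusive).
write_gtf <- function(regions, path) {
  reg <- regions[regions$type %in% c("five_prime_utr", "CDS",
                                     "three_prime_utr", "utr5", "cds",
                                     "utr3", "intron"), , drop = FALSE]
  back <- c(utr5 = "five_prime_utr", cds = "CDS", utr3 = "three_prime_utr",
            five_prime_utr = "five_prime_utr", CDS = "CDS",
            three_prime_utr = "three_prime_utr", intron = "intron")
  lines <- sprintf(
    '%s\tsim\t%s\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s.t1";',
    reg$chrom, back[reg$type], reg$start + 1L, reg$end, reg$strand,
    reg$gene_id, reg$gene_id)
  writeLines(lines, path)
  invisible(path)
}
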