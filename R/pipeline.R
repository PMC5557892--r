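# End-to-end convenience wrapper and ground-truth scoring.

#' Score called chimeras against simulation ground truth
#'
#' Recall: the fraction of planted exact-sequence unique chimeric reads for
#' which a called event with the same miRNA, barcode and replicate overlaps
#' the planted site (within `slack` nt). FDR: the fraction of called events
#' not attributable to any planted interaction of the same miRNA.
#'
#' @param chimeras called chimera data.frame ([map_and_dedup()]).
#' @param truth truth table from [simulate_truth()].
#' @param provenance provenance table from [simulate_clip_reads()].
#' @param slack coordinate slack in nt (default 60).
#' @return list with `recall`, `fdr`, `n_planted`, `n_called`,
#'   `n_recovered`.
#' @export
score_chimera_recovery <- function(chimeras, truth, provenance,
                                   slack = 60L) {
  planted <- provenance[provenance$class == "chimera" & provenance$exact, ,
                        drop = FALSE]
  tidx <- match(planted$interaction_id, truth$interaction_id)
  planted$mirna_name <- truth$mirna_name[tidx]
  planted$chrom <- truth$chrom[tidx]
  planted$site_start <- truth$site_start[tidx]
  planted$site_end <- truth$site_end[tidx]

  ckey <- paste(chimeras$mirna_name, chimeras$barcode,
                chimeras$replicate_id)
  pkey <- paste(planted$mirna_name, planted$barcode, planted$replicate_id)
  recovered <- logical(nrow(planted))
  called_by_key <- split(seq_len(nrow(chimeras)), ckey)
  for (i in seq_len(nrow(planted))) {
    idx <- called_by_key[[pkey[i]]]
    if (is.null(idx)) next
    recovered[i] <- any(
      chimeras$chrom[idx] == planted$chrom[i] &
        chimeras$start[idx] < planted$site_end[i] + slack &
        chimeras$end[idx] > planted$site_start[i] - slack)
  }

  # FDR: called events with no same-miRNA planted site nearby
  matched <- logical(nrow(chimeras))
  truth_by_mirna <- split(truth, truth$mirna_name)
  for (i in seq_len(nrow(chimeras))) {
    tt <- truth_by_mirna[[chimeras$mirna_name[i]]]
    if (is.null(tt)) next
    matched[i] <- any(tt$chrom == chimeras$chrom[i] &
                        tt$site_start - slack < chimeras$end[i] &
                        tt$site_end + slack > chimeras$start[i])
  }
  list(recall = if (nrow(planted)) mean(recovered) else NA_real_,
       fdr = if (nrow(chimeras)) mean(!matched) else NA_real_,
       n_planted = nrow(planted), n_called = nrow(chimeras),
       n_recovered = sum(recovered))
}

#' Run the chimera-calling pipeline on a simulated dataset
#'
#' Calls chimeras across all replicates, clusters them at the miRNA and
#' family level, profiles AGO-loaded miRNAs, detects novel hairpin arms,
#' maps background reads and calls peaks.
#'
#' @param sim output of [simulate_dataset()].
#' @param min_peak_height optional override for the peak caller.
#' @return list: chimeras, clusters (miRNA level), family_clusters,
#'   profile, novel_arms, peaks, recovery (ground-truth scoring).
#' @export
run_chimera_pipeline <- function(sim, min_peak_height = NULL) {
  models <- sim$reference$models
  chim <- call_chimeras(sim$reads, sim$mirnome$catalog, sim$genome,
                        precursors = sim$mirnome$precursors,
                        models = models)
  cl <- build_interaction_clusters(chim[chim$chimera_type == "miRfirst", ,
                                        drop = FALSE],
                                   level = "mirna", models = models)
  fcl <- build_interaction_clusters(chim[chim$chimera_type == "miRfirst", ,
                                         drop = FALSE],
                                    level = "family", models = models)
  all_reads <- do.call(rbind, sim$reads)
  prof <- profile_ago_mirnas(all_reads, sim$mirnome$catalog)
  novel <- detect_novel_arm_candidates(prof$unmatched, sim$genome,
                                       sim$mirnome$precursors)
  # peak track from non-chimeric reads (deduplicated exact placements)
  bg <- all_reads[!duplicated(paste(all_reads$sequence,
                                    all_reads$barcode)), , drop = FALSE]
  mapped <- map_reads_exact(bg$sequence, sim$genome)
  peaks <- call_peaks_simple(mapped, sim$reference$chrom_sizes,
                             min_height = min_peak_height)
  recovery <- score_chimera_recovery(chim, sim$truth, sim$provenance)
  list(chimeras = chim, clusters = cl, family_clusters = fcl,
       profile = prof, novel_arms = novel, peaks = peaks, mapped = mapped,
       recovery = recovery)
}
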