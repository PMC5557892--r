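# chimeramap

Mapping miRNA–target interactions from AGO-CLIP chimeric reads.

CLEAR-CLIP and related protocols ligate a miRNA to the target fragment it
occupies on the Argonaute (AGO) protein, so one sequencing read carries
the miRNA fused to its target — an unambiguous record of a regulatory
interaction. `chimeramap` is an R package for the full analysis of such
libraries:

- **Chimera calling** — tolerant reverse-matching of mature miRNAs inside
  reads (≤1 mismatch in the first 18 nt, ≤2 total, ±1-nt truncation),
  extraction of ≥19-nt miRfirst/miRlast target fragments, unique-best
  genome mapping, PCR-duplicate collapsing on degenerate 5'-linker
  barcodes, and removal of precursor-mapping artifacts.
- **Interaction clustering** — single-linkage clustering of target
  intervals per miRNA or seed family, each cluster carrying its unique
  chimera count and biological complexity (BC = replicates supporting it),
  with genic annotation that extends every 3'UTR by 10 kb downstream.
- **Seed and duplex characterization** — a strict seed-site taxonomy
  (8mer, 7mer-m8, 7mer-A1, 6mer, 5mer, single-mismatch, single-bulge) and
  a constrained maximum-score duplex dynamic program (GC=3 / AU=2 / GU=1,
  loop ≤15 nt, bulge ≤5 nt per side, seed-dependent forced pairing)
  producing binary pairing vectors, clustered into k = 8 binding modes.
- **Motif discovery** — enumerative 7mer enrichment (hypergeometric,
  5× same-seed-excluding background, triplicate) with the combined
  confidence statistic c = (−log10 p − 10)/10 + (s − 0.35)·6.7 and the
  s ≥ 0.35 / IC ≥ 1.75 bits / c ≥ 1 screen.
- **Gene targeting profiles** — the AGO sequestration coefficient
  ASC = log2((chimeras_f(r)/chimeras_f(t)) / RPKM(r)) for families with
  ≥500 3'UTR chimeras, above-mean GO gene-set export, consensus k-means
  cooperativity across miRNA families, and ceRNA candidate regions
  (≥3 clusters × ≥5 chimeras within 3000 bp).
- **Regulation analyses** — grouped CDF/KS fold-change comparisons,
  hypergeometric targetome overlap (≥1% abundance rule), chimera support
  of CLIP peaks with a sigmoidal saturation fit, and intersection with
  external target-prediction intervals.
- **A synthetic-data generator** — toy genome/annotation/miRNome, planted
  interactions with a configurable seed-type mix, CLIP read libraries
  with background peaks, PCR duplicates and miRNA sequence variants, and
  expression tables with a planted de-repression — every stage's ground
  truth retained for recovery scoring.

## Worked example

Simulate a small study (20,000 reads, 80 planted interactions) and run
the chimera pipeline end to end:

```r
library(chimeramap)

cfg <- sim_config(rng_seed = 42, read_depth = 2e4, n_interactions = 80)
sim <- simulate_dataset(cfg)
res <- run_chimera_pipeline(sim)

nrow(res$chimeras)
#> [1] 280
head(res$chimeras[, c("mirna_name", "chimera_type", "chrom", "start",
                      "end", "strand", "region", "n_reads")], 4)
#>    mirna_name chimera_type chrom  start    end strand region n_reads
#> 1 syn-miR-001      miRlast  chr1 105525 105559      -  3'UTR       3
#> 2 syn-miR-001     miRfirst  chr1 105528 105563      -  3'UTR       2
#> 3 syn-miR-001     miRfirst  chr1 105531 105560      -  3'UTR       2
#> 4 syn-miR-001     miRfirst  chr1 105533 105565      -  3'UTR       2
```

280 deduplicated ligation events were called; `n_reads` counts the PCR
copies collapsed into each event, and the planted sites sit in 3'UTRs as
configured. Recovery against the generator's truth is perfect here:

```r
res$recovery[c("recall", "fdr")]
#> $recall
#> [1] 1
#> $fdr
#> [1] 0

head(res$clusters$clusters[order(-res$clusters$clusters$chimera_count),
     c("key", "chrom", "start", "end", "chimera_count", "BC", "region")], 2)
#>            key chrom start   end chimera_count BC region
#> 6  syn-miR-001  chr1 79144 79184             9  3  3'UTR
#> 17 syn-miR-001  chr2 78984 79026             9  3  3'UTR
```

The deepest interaction clusters hold 9 unique chimeras seen in all
3 replicates (BC = 3). The generator also plants hairpins with one
unannotated arm; abundant reads from the opposite arm surface as novel
miRNA candidates:

```r
res$novel_arms[, c("sequence", "count", "proposed_name")]
#>                 sequence count      proposed_name
#> 3  CTCAAGCCCGGGGCAGCTCAT   217 syn-hairpin-002-5p
#> 1  ATGGAGCCTAGTAATCAGGCC   211 syn-hairpin-001-3p
#> 2 CACGTAGTAATCTATGGGGACT   211 syn-hairpin-003-3p
#> 4  TTTCTTCTGGCTTATGCGATC   207 syn-hairpin-004-5p
```

A duplex prediction for an 8mer site forces seed pairing (positions 2–8)
and reports the binary pairing vector used for structure clustering:

```r
m <- sim$mirnome$catalog$sequence[1]
target <- paste0(strrep("T", 20),
                 paste0(reverse_complement(substr(m, 2, 8)), "A"),
                 strrep("T", 20))
predict_duplex(m, target)
#> duplex_structure: score 27 seed 8mer
#>  pairing: 111111110100111000110
#>  forced : 2,3,4,5,6,7,8
```

The motif confidence statistic evaluates exactly on its closed form,
e.g. `motif_confidence(1e-20, 0.35)` returns `1`.

## Documentation

The methods vignette (`vignettes/chimeramap-methods.Rmd`) describes the
models, the parameter defaults and their rationale, what the synthetic
generator does and does not emulate, and the package's numerical and
design choices.
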