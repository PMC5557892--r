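---
title: "Mapping miRNA-target interactions from AGO-CLIP chimeras: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping miRNA-target interactions from AGO-CLIP chimeras: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chimeramap)
```

## The problem

CLEAR-CLIP and related protocols ligate the miRNA to its bound target
fragment while both sit on the Argonaute protein, so a single sequencing
read can contain a mature miRNA fused to the transcript fragment it was
regulating. `chimeramap` turns such small-RNA libraries into a catalog of
miRNA-target interactions and carries them through the downstream analyses
that interactions support: seed-site and duplex-structure
characterization, de novo motif discovery, gene-level targeting profiles
(ASC), family cooperativity, ceRNA candidates, and validation against
expression perturbations and external target predictions.

This vignette explains the models and the parameter choices; the README
shows the worked end-to-end example.

## Chimera identification

A read is searched for every catalog miRNA and its 1-nt 5'- or
3'-truncated variants, tolerating at most one mismatch within the first
18 nt of the matched miRNA and two mismatches in total. This codifies the
tolerance of a short-read aligner run with a 18-nt seed, one seed
mismatch and modest total error, without requiring quality strings. When
several miRNAs match within 4 nt of the same read position, only the
first in case-insensitive alphanumeric order is kept, so each ligation
junction is counted once; matches farther apart (miRNA-miRNA chimeras)
may coexist.

Read sequence downstream of the miRNA becomes a *miRfirst* target
candidate, upstream a *miRlast* candidate; fragments shorter than 19 nt
are discarded as unmappable. The built-in mapper places fragments on the
toy genome allowing up to two mismatches and requires a unique best hit;
multi-mappers are dropped (a policy choice: the alternative of random
assignment would contaminate interaction clusters). PCR duplicates are
collapsed on (target coordinates, strand, miRNA, degenerate barcode);
two ligation events that collide in all four are indistinguishable and
count once — with a 5-nt barcode the collision probability per
coordinate-sharing pair is 4^-5 ≈ 0.1%. Fragments mapping inside
annotated miRNA precursors are removed, since a miRNA ligated to its own
hairpin is a processing artifact, not a target interaction.

Deduplicated chimeras are single-linkage clustered per miRNA (or per
seed family) into interaction clusters; a cluster's *biological
complexity* (BC) is the number of distinct replicates contributing to it.
With the default `max_gap = 0`, only genuinely overlapping target
intervals merge — half-open adjacency is not overlap.

## Annotation conventions

Coordinates are 0-based half-open internally; GTF is 1-based inclusive on
input, BED 0-based half-open on output. Because 3'-end annotation of
draft genomes is chronically incomplete, the 10 kb downstream of each
annotated 3'UTR inherits the 3'UTR label. Label precedence is
3'UTR > CDS > 5'UTR > intron > intergenic, with ties broken by larger
overlap and then lexicographic gene id, which makes annotation
order-independent and deterministic.

The seed-derived family key is the miRNA subsequence at positions 2-8.
The 8mer site class is defined target-side as Watson-Crick
complementarity to positions 2-8 plus an adenosine opposite position 1;
that adenosine is recognized by the protein and is target-encoded, so the
miRNA-side invariant that defines a family is positions 2-8, not 1-8.

## Seed taxonomy and duplex model

Site classes are searched in priority order: 8mer, 7mer-m8, 7mer-A1,
6mer, 5mer, then single-defect variants (one mismatching position inside
an 8/7/6mer span; one extra target nucleotide strictly inside an 8/7mer
span), leftmost site winning within a class. Canonical classes use exact
string matches, so a G:U wobble inside the seed deliberately lands in the
mismatch class: canonical sites are defined by Watson-Crick pairing.

Duplex structures are predicted by a maximum-score intermolecular
co-folding dynamic program rather than a thermodynamic folder: each
Watson-Crick or G:U pair scores 3 (GC), 2 (AU) or 1 (GU), internal loops
are capped at 15 nt per side and bulges at 5 nt per side, and
intramolecular pairs are not modeled. The analyses consume structures
only as binary per-position pairing vectors, so the pair-scoring program
is sufficient and exactly testable: on small instances it is verified
against exhaustive enumeration of every legal structure, including
tie-breaks (more pairs, then the lexicographically smallest pair chain).
When a perfect seed site is present, the full matched seed span is forced
paired (positions 2-8, 2-7 or 2-6 depending on the class; the A1 position
is protein-recognized and never forced). Mismatch or bulged seeds trigger
two constrained runs forcing positions {3,4} and {5,6}; the structure
with more pairs in positions 2-8 wins (ties: more total pairs, then the
{3,4} run). Infeasible constraints fall back to the unconstrained fold
and are flagged.

Interaction clusters longer than 100 nt are omitted from structure
prediction (one structure over a long interval is not meaningful);
spans of 76-100 nt are trimmed and shorter spans extended symmetrically
to a 75-nt window.

Pairing vectors are partitioned into k = 8 structure groups by k-means
(fixed seed 1234, 50 restarts by default); the within-cluster
sum-of-squares over k = 3..12 is reported for elbow inspection, computed
with warm starts so the curve is provably non-increasing. Per-miRNA
enrichment in a group uses a two-sided Fisher exact test of the miRNA's
group membership against all interactions.

## Motif discovery

For each miRNA with at least 50 chimeras spanning at least 40 clusters,
all 4^7 7mers are scored by presence/absence in the 75-nt foreground
windows against a background of 5x as many windows drawn (without
replacement when possible, flagged otherwise) from other miRNAs'
chimeras, excluding any miRNA with the same family key. The enrichment
p-value is the hypergeometric upper tail of foreground presence given
pooled presence; backgrounds are drawn in triplicate with seeds
(seed, seed+1, seed+2).

A motif's match score *s* is the best fraction of identical positions
when sliding it ungapped along the reverse complement of the mature
miRNA; the miRNA position opposite the motif's 3' end at the best offset
localizes the motif on the miRNA (seed-complementary motifs map to
position 2). The combined confidence is

c = (−log10 p − 10)/10 + (s − 0.35) × 6.7,

and motifs pass with s ≥ 0.35 (at least 5 of 7 positions matching),
information content ≥ 1.75 bits per position (computed from the
≤1-mismatch occurrence profile against a uniform background), and c ≥ 1.
The two constants in c calibrate an external motif tool's
match-score scale; our s shares its range but not necessarily its exact
distribution, so the thresholds are kept at their standard values and the screen
should be read as a confidence filter, not a calibrated probability.

## ASC, cooperativity, ceRNA

For each family with at least 500 chimeras on 3'UTRs (downstream rule
included), the AGO sequestration coefficient of gene r is

ASC = log2( (chimeras_f(r) / chimeras_f(total)) / RPKM(r) ),

the gene's share of the family's chimera pool normalized by its
expression; doubling RPKM lowers ASC by exactly one unit and a uniform
rescaling of chimera counts cancels. The lower level of quantification is
the ASC a single chimera would imply at the gene's RPKM. GO gene sets
take genes strictly above the family mean, computed over targeted genes
with defined ASC only.

Cooperativity is read from consensus k-means over the gene x family ASC
matrix (non-targeted cells imputed to one unit below the observed
minimum): three iterations, 45 clusters and up to 100,000 random starts
at full scale (1,000 by default at desk scale), with a cluster signature
defined as the families whose within-cluster mean exceeds their global
mean by at least one standard deviation of that family's ASC column.
The margin is expressed in column-sd units rather than absolute ASC
units: the absolute variant makes the null behavior depend on the
incidental spread of the ASC columns (wide columns generate recurrent
chance signatures in nearly every run), whereas the scale-free rule
leaves independent random columns signature-free while identical-seed
families still co-cluster in every iteration. Signatures recurring in
all three iterations (two may be admitted explicitly) populate the
pairwise and multi-family cooperativity matrices.

Candidate ceRNA regions are maximal windows of at most 3000 bp per
strand containing at least three clusters of at least five unique
chimeras each; the implementation is checked against a brute-force
all-offsets scan.

## Regulation analyses

Fold changes are pseudocount CPM ratios, log2((CPM_t + 0.5)/(CPM_c +
0.5)) with CPMs averaged over replicates — a deliberately simple,
ordering-faithful contrast in place of a count-model fit, because the
grouped comparisons only need a consistent per-gene ordering. Groups
(seed-in-peak class, chimera BC, canonical/non-canonical, prediction
score bins) are compared against the no-site reference by two-sided
asymptotic Kolmogorov-Smirnov tests.

Targetome overlap between two chimera datasets tests, for each miRNA
present in at least 1% of chimeras in both, the hypergeometric upper tail
of shared target genes within the universe of genes carrying at least one
chimera in both datasets.

Chimera support of CLIP peaks is summarized per normalized-height decile
(the original binning is unstated; deciles keep bin counts equal) and
fitted with a three-parameter logistic A / (1 + exp(−(x − x0)/w)) by
Levenberg-Marquardt least squares from a small grid of starting values
(a single too-flat start is locally unidentifiable). The asymptote A
estimates the maximum attainable fraction of chimera-supported peaks.

The simple peak caller extends deduplicated read starts by 53 nt,
thresholds coverage at max(2, the 99.9% Poisson tail of the per-strand
background rate) and merges summits closer than 75 nt. It is a height
threshold, not a significance model, and is labeled as such.

## The synthetic-data generator

All tests run on generated data with known truth. The generator emulates
the features the analyses assume: a toy genome of 50 genes (5'UTR, split
CDS with one intron, 3'UTR; intergenic spacing > 10 kb so the downstream
rule is exercised), 20 miRNAs over 16 seed families (the first families
carry two members, giving shared-seed fixtures), four hairpin loci with
one annotated and one unannotated arm, 150 planted interactions with a
configurable seed-type mix (40% 8mer, 25% 7mer, 15% 6mer, 10% mismatch,
5% bulged, 5% noncanonical — the canonical-heavy spectrum reported for
3'UTR interactions), 10^5 reads of which 2% are chimeric (within the
observed 0.5-5% range), 80% miRfirst, a 30% PCR duplicate rate, a 5-nt
degenerate barcode (the real linker design is unstated; 5 nt gives a
0.1% per-pair collision rate), 5% miRNA substitution and truncation
rates, and gamma-Poisson expression with dispersion 0.1 and a planted
log2FC of 0.11 on chimera-targeted genes.

What the generator does *not* emulate: sequencing error beyond uniform
substitution, adapter read-through, crosslink-induced deletions,
transcript isoform structure, repeat-derived multi-mapping, and the
covariance structure of real expression noise. Passing tests therefore
demonstrate that the algorithms implement their stated rules and recover
planted truth under idealized noise — not that real libraries of this
depth would yield the same recall.

## Numerical choices and problem sizes

Deterministic behavior is part of the contract: the generator derives
every stage's stream from one master seed and regenerating a dataset is
byte-identical; consensus clustering with identical seeds is
bit-reproducible. Monte-Carlo checks in the test-suite use fixed seeds
and statistically robust aggregates (e.g. the mean recovered sigmoid
asymptote over 100 simulated curves, the mean recovered median log2FC
and the median KS p over 25 expression simulations) rather than
single-draw assertions. Problem sizes were chosen so the whole suite
exercises full-depth libraries (10^5 reads) once and desk-scale ones
(2-3 x 10^4) elsewhere; duplex oracle equivalence is verified on
instances up to 9 x 12 nt where exhaustive enumeration is exact.

Known limitations: the duplex program optimizes pair score, not free
energy, so its structures are comparable to thermodynamic predictions
only at the binary pairing-vector level; the motif match-score scale is
not identical to the original tool's despite sharing its range and
thresholds; the built-in mapper is for toy genomes (real data should be
aligned externally and ingested); and the pseudocount CPM contrast is not
a replacement for a dispersion-modeling differential-expression fit when
absolute effect sizes matter.
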