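---
title: "Methods and design notes for mitochar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for mitochar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitochar)
```

`mitochar` characterizes annotated vertebrate mitochondrial genomes: gene
architecture, composition and strand skews, codon usage, pairwise
evolutionary rates and distances, diversity profiles, control-region
features, and distance-based trees. This vignette records the statistical
conventions the package commits to, the parameters that matter, and the
design decisions taken where the field's tools disagree.

## Coordinates and the architecture ledger

All coordinates are 1-based inclusive, the convention of published
mitogenome gene tables; converters to 0-based half-open intervals exist only
at format boundaries. Features are ordered by start, ties broken by end then
by name. For consecutive features the signed intergenic count is
`IN = start₂ − end₁ − 1`: positive values are spacers, negative overlaps,
zero abutting genes. The ledger is linear (n − 1 junctions); the pair that
wraps across the origin of the circular molecule is reported in an
attribute, not as a row, mirroring how printed tables leave the control
region's entry blank. When the first feature starts at 1 and the last ends
at the genome length, `sum(sizes) + sum(IN)` equals the genome length — a
conservation identity the tests exercise on both the bundled gene table and
every synthetic genome.

Two bookkeeping discrepancies in the reference gene table are surfaced, not
reconciled: the table contains 12 positive intergenic entries though the
accompanying text counts 11 spacers, and the rRNA sizes (953 + 1,681 =
2,634 bp) disagree with a separately printed rRNA partition total of
2,587 bp. The package always reports what the coordinates imply.

## Stop codons

Start codons are the first three nucleotides of the strand-oriented gene;
stop codons are whatever trails the last complete internal codon: a full
3-mer when the gene length is divisible by 3, otherwise a 1–2 nt remnant
printed `T--` or `TA-` (completed to TAA by post-transcriptional
polyadenylation in vivo). Completeness is judged against the vertebrate
mitochondrial stop set {TAA, TAG, AGA, AGG}. Annotated codons read from a
feature table are kept verbatim and reported *alongside* recomputed calls:
published tables occasionally annotate stops (e.g. a two-letter `TT-` on a
gene whose length mod 3 is 1) that sequence arithmetic cannot reproduce, and
silently preferring either value would hide the conflict.

## Composition and skews

Counts cover unambiguous residues only; N and gaps are excluded
(`n_excluded` reports how many). Skews are `(A − T)/(A + T)` and
`(G − C)/(G + C)`; zero denominators give `NA` rather than an error so that
report generation never aborts on a degenerate partition. Partition
composition is computed on heavy-strand coordinates **without**
reverse-complementing light-strand genes. Published per-partition skews are
only consistent with their whole-genome rows under this convention —
reverse-complementing the L-strand genes flips their skew contribution — so
it is the default, with `strand_oriented = TRUE` available as a sensitivity
check (the tests verify the two modes actually differ on the tRNA
partition, 8 of 22 genes being L-strand). Overlapping bases belong to every
feature containing them, so partition totals are sums of feature sizes.

## Codon usage and RSCU

Codons are read in frame from strand-oriented coding sequences; 1–2 nt
terminal remnants are sub-codon and dropped; stop codons are excluded from
totals by default. Translation uses NCBI table 2 throughout (AGA/AGG stops,
ATA Met, TGA Trp). RSCU is the observed count relative to its synonymous
family mean. Family definition is genuinely ambiguous in practice: codon
usage figures conventionally print RSCU = 1 for Met-AUG and Trp-UGG, which
is only possible if ATG and TGG are singleton families, even though table 2
places {ATA, ATG} in one Met family and {TGA, TGG} in one Trp family. The
default `family_mode = "report"` therefore detaches ATG and TGG as
singletons (reproducing the conventional figure values exactly), and
`family_mode = "code"` gives the strict amino-acid grouping. Amino-acid
profiles merge the two Leu and two Ser families. Multi-genome "average
RSCU" is provided in both readings — pooled counts and per-genome means —
since published averages rarely state which was used.

## Distances, saturation, diversity

Gap handling is complete pairwise deletion everywhere (the common
MEGA/DnaSP default): a site is compared for a pair only when both rows hold
an unambiguous base. Transitions are purine↔purine or
pyrimidine↔pyrimidine mismatches. K2P is
`−½ ln((1 − 2P − Q)√(1 − 2Q))`; F84 uses the standard closed form with base
frequencies estimated from the pooled pair. Both are validated in the test
suite against `ape::dist.dna` to 1e−12 on simulated pairs, and both return
`NA` with a diagnostic on saturated pairs (non-positive log arguments)
rather than failing; matrix summaries then average the defined entries and
report how many there were. Percent distances are conventionally
100 × d.

Nucleotide diversity profiles use 200 bp windows stepped by 25 bp (the
usual DnaSP profile settings); per window π is the mean over sequence pairs
of pairwise differences over pairwise compared sites. The estimator omits
the n/(n − 1) sample correction by default — the convention DnaSP-derived
reports rarely state — with `corrected = TRUE` applying it exactly. Each
window also carries pooled difference/site counts so the window partition
of a gapless alignment reconstructs the whole-alignment π to 1e−12, a
conservation identity the acceptance tests assert. A window longer than
the alignment yields a single truncated, flagged window.

## Nei–Gojobori Ka/Ks

Site counting follows the 1986 method under table 2: at each codon
position the synonymous fraction is computed over one-step changes,
with mutations to stop codons disregarded — removed from numerator *and*
denominator, so a position whose only non-stop alternative is synonymous
counts as a full synonymous site. Observed differences in multi-hit codons
are averaged with equal weight over shortest mutational paths; paths
passing through stop codons are excluded, falling back to all paths when
none survive. Proportions get the Jukes–Cantor correction
`−¾ ln(1 − 4p/3)`; p ≥ 3/4 yields `NA` with a warning, and the Ka/Ks ratio
is `NA` whenever Ks is 0 or undefined. The procedure is symmetric in its
arguments (asserted by test). The modified-NG variant (transition/
transversion-weighted site counting) is deliberately not implemented;
`pairwise_kaks` runs the plain method per gene per genome pair and skips
length-mismatched gene pairs rather than aligning them (no aligner is
bundled; indels are out of the simulator's scope, see below).

## Control-region features

CSB consensus building is majority rule per alignment column over a seed
window (ties broken alphabetically); scanning slides each consensus
ungapped along a control region and reports the best Hamming match, with an
explicit absence record when the best match exceeds `max_mismatch`
(default 4). Seed motifs for simulation and examples are synthetic
sequences at the canonical block lengths (18/21/18/20 bp for
CSB-D/1/2/3) — configuration data, not claims about any species' true
consensus, which should always be derived from an alignment.

The tandem-repeat detector is a deterministic seed-and-verify scan, not a
reimplementation of the Tandem Repeats Finder probabilistic model: for each
candidate period p it scores the lag-p self-match profile (match +2,
mismatch −7, the TRF weights; indels are not modelled) and keeps
maximal-scoring segments with score ≥ 30 and ≥ 1.5 copies, merging
overlapping reports in favour of the higher score. Copy number is span /
period to 1 decimal place. The defaults keep i.i.d. 900 bp sequences quiet
(≤ 5% of seeds produce any period ≥ 10 call at ≥ 1.9 copies, asserted by a
100-seed null test) while recovering an implanted 17 bp × 2.2-copy repeat
exactly.

## Neighbor joining

The Q-criterion agglomeration with Studier–Keppler reduction; branch
lengths from the three-point equations, negatives clamped to zero with the
clamped deficit recorded on the tree. On additive matrices the output
reproduces the input path lengths to 1e−9 and matches `ape::nj` topologies
(tests). Newick output is deterministic: children are ordered by smallest
descendant label and lengths printed at 6 decimals. NJ on K2P distances is
the package's tree method by design — likelihood and Bayesian inference are
out of scope, being better served by dedicated software — and a
seed-controlled site-resampling bootstrap reports split support for the
distance tree. Outgroup rooting is display-only.

## The synthetic-data generator

`make_ancestor()` emulates the statistical structure of a cyprinid
mitogenome, and its defaults are the package's study conditions: the
standard vertebrate gene order and strand layout at the bundled template's
exact coordinates (16,571 bp; 37 genes + CR; ATP8/ATP6 and ND4L/ND4 each
overlapping 7 bp, ND5/ND6 by 4 bp), per-partition base-frequency targets
set to a typical AT-rich, negatively GC-skewed composition (~57.7% A+T
genome-wide, ~68.7% in the CR), kappa = 4 (a realistic fish mitochondrial
transition/transversion rate ratio) and omega = 0.05 (mid-range purifying
selection for mitochondrial PCGs; published per-gene estimates run roughly
0.01–0.07).

PCGs are built codon-wise from a distribution over non-stop codons whose
induced base composition is fixed-point-adjusted to the partition target,
so whole-genome composition lands within about a percentage point of the
target despite the exclusion of stop codons. The three PCG/PCG overlaps
are resolved by pinning the shared junction bases before generation: in the
7 bp in-frame overlaps the downstream ATG sits inside the upstream gene and
the upstream stop (pinned to TAG) inside the downstream one, a geometry in
which neither reading frame can acquire a stop (the flanking codons take
the forms xTA, TGx, Gxx, and yyA with stops excluded by conditional
sampling); the 4 bp head-to-tail ND5/ND6 junction pins one extra base so
the L-strand gene's terminal TAG falls out of the reverse complement of the
H-strand gene's TAA. Generation is strictly left-to-right and never
overwrites a written residue, so overlapping tRNAs simply share bases.
Custom templates with other overlap geometries are rejected with an error
rather than silently mis-generated.

`evolve_genomes()` is a proposal/acceptance simulator: proposals arrive at
`branch_length` per site (Poisson), transitions kappa-fold favoured;
within PCGs, stop-creating proposals are rejected, nonsynonymous proposals
accepted with probability omega (multiplied across genes when a site lies
in two overlapping PCGs), terminal stops must remain stops; everything else
is neutral. Branch lengths are therefore *proposal* rates; realized counts
are returned as truth. Indels are not simulated — the analyses the package
implements are substitution-centric — so simulated sets are positionally
aligned by construction. What passing tests on synthetic data do **not**
show: robustness to real-data features such as indels and alignment error,
heterogeneous rates along the genome, saturated deep divergences, or
annotation errors. `simulate_k80_pair()` complements the event simulator
with an exact closed-form pair generator (per-site difference categories at
the K80 probabilities for a given distance), which is what the
parameter-recovery checks use.

Everything stochastic flows from a single integer seed; the same
configuration reproduces output byte-for-byte.

## Problem sizes and tolerances

Test and acceptance runs use desk-scale sizes chosen to make sampling error
negligible relative to the assertions: 4–10 kb simulated pairs for distance
recovery (10–20 replicates, agreement within three standard errors), 500
codons × 20 replicates for ω recovery (estimates asserted within
[0.02, 0.12] around the true 0.05 — the plain NG estimator is mildly
conservative under multiple hits), 10,000 codons for the uniform-usage RSCU
check, 100 seeds for the tandem-repeat null. Closed-form cross-checks
(K2P/F84 vs an independent implementation, NJ on additive matrices) use
1e−9–1e−12 tolerances; conservation identities (ledger sum, π partition)
are exact to floating point.

## Known limitations

- Features spanning the circular origin are not represented (the standard
  vertebrate gene order does not need them); GenBank `join(...)` locations
  are rejected.
- The GenBank reader is minimal by design: LOCUS/ACCESSION, the feature
  keys CDS/tRNA/rRNA/D-loop with `a..b` and `complement(a..b)` locations,
  and `/gene`, `/product`, `/note` qualifiers.
- `pairwise_kaks` assumes equal-length (positionally aligned) gene pairs.
- The tandem-repeat detector does not model indel-containing repeats and
  does not reproduce TRF scores, only period / copy number / motif.
- Distance-based NJ stands in for model-based phylogenetics; no model
  selection, no posterior support.
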