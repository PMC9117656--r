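---
title: "Methods: comparative plastome analysis with plastcomp"
author: "plastcomp authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative plastome analysis with plastcomp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`plastcomp` re-implements, as tested library code, the comparative analyses
that plastid-genome studies typically run with a patchwork of GUI tools and
ad-hoc scripts: quadripartite structure determination, microsatellite (SSR)
and dispersed-repeat scanning, alignment-based SNP/indel statistics
stratified by annotation class, SNP-density hotspot discovery, and a light
distance-based phylogeny. This vignette records the models, the parameters
that matter, the numerical conventions, and what the synthetic-data
generator does and does not emulate.

## Coordinates and containers

All coordinates are 1-based closed intervals, the GenBank convention, both
internally (IRanges-backed interval arithmetic) and in every report file.
Features that wrap the circular origin are stored as ordered part lists
sharing a `feature_id`; lengths are sums over parts. A genome is an
`AnnotatedGenome` (uppercase A/C/G/T/N sequence plus a feature table), an
alignment a `PlastomeAlignment` (equal-length gapped rows with a designated
reference row). Derived feature kinds — introns (the gaps inside `join()`
locations) and intergenic spacers (IGS, named `geneA-geneB` after the
flanking genes in genome order) — are recomputed on read rather than
serialised, so GenBank read→write→read is the identity on the complete
feature set.

## Quadripartite structure

The inverted repeats are defined as the longest pair of disjoint intervals
whose sequences are exact reverse complements, each at least `minIrLen`
(default 1000 bp). Detection seeds on exact 25-mers shared between the
sequence and its reverse complement, groups seeds by diagonal, and extends
each candidate with circular (mod-length) indexing, so the result is
invariant under rotation of the circular sequence; ties break toward the
longer repeat, then the smaller start. The exact-match definition is
appropriate for genera whose IR copies are near-identical; a genome without
a qualifying repeat is reported as single-copy via an error. The two arcs
between the arms are labelled LSC (longer) and SSC (shorter); validity
enforces `lsc + ssc + 2*ir = total`.

GC content is `100 * (G + C) / (A + C + G + T)`, N excluded from both sides,
rounded half away from zero to one decimal — the convention of printed
summary tables. The subgenus SSC summary uses the population
(divide-by-`n`) standard deviation: on the published 22-genome table the
printed `17,941.00 ± 3.37` for subgenus *Amaranthus* is reproduced by the
population SD, while the sample SD gives 3.69, so the population convention
is the one the source tables use. Off-diagonal cells pool the samples of
the two subgenera before computing mean and SD.

## SSR scanning

Only perfect tandem repeats are called (no interruptions, no compound-run
merging), with unit-count thresholds 10, 5, 4, 3, 3, 3 for periods 1–6.
Scanning marks positions where `S[i] == S[i+p]`, takes maximal runs, trims
to whole units, and reports each run once: a motif that is itself a tandem
of a shorter motif is suppressed (the run is already called at the shorter
period), and calls whose interval is contained in another call's interval
are dropped. Circular genomes are scanned on a doubled sequence with
wrapped calls deduplicated by start position. Marker-matrix keys use the
canonical motif — the lexicographic minimum over rotations and
reverse-complement rotations — while records keep the observed motif and
coordinates. The discriminating-combination search enumerates column
subsets of increasing cardinality (lexicographic order within a
cardinality) and reports the first subset on which a species pair differs;
pairs with identical rows are reported inseparable. An absent locus (NA)
counts as a distinguishing state against a number.

## Dispersed repeats

Repeat pairs come in the four standard senses: forward (direct copy),
palindromic (reverse-complement copy), reverse (reversed copy) and
complement (base-complemented copy). The contract is `length >= 30` bp and
`identity >= 0.90` under the sense's transform, with a Hamming (gap-free)
mismatch model, so every reported pair re-validates by direct base
comparison (`repeatIdentity()`). Detection seeds on exact 12-mers between
the sequence and its transformed copy, and extends each seed to its
maximal-scoring window (match +1, mismatch −θ/(1−θ), X-drop) — an extension
is score-positive exactly while local identity stays at the threshold, and
score ties extend (prefer the longer window). Both window ends are matches;
records whose arms are both contained in another record's arms are dropped,
as is each pair's mirror image. A consequence of local thresholded
extension is that a qualifying repeat is only detectable if its mismatches
are spread out (at least one exact 12-mer to seed on, and roughly nine
matches per mismatch to bridge); the simulator plants mismatches
accordingly. With a quadripartite structure supplied, the one "repeat" that
is really the IR pair itself (a palindromic hit with both arms inside
IRa+IRb at near-IR length) is suppressed — it is reported separately as the
quadripartite structure.

Loci across samples are formed by projecting each record's first arm
through the alignment onto the reference and single-linkage clustering with
a 2 kb gap; a locus is `common` when every sample contributes and
`variable_length` when member lengths differ. The symmetry report maps arm
midpoints to angles on the circle; the antipodality score is
`|180° − angular separation|`, so exactly opposite arms score 0.

## Alignment variation

The consensus takes each column's most frequent non-gap base, ties broken
alphabetically (A < C < G < T); all-gap columns are dropped. A SNP site is
a column with at least two distinct non-gap, non-N bases among the ingroup
rows (multi-allelic columns count once); an indel site is a column where at
least one ingroup row has a gap and at least one a base. Columns are
assigned one class by projecting the reference features with precedence
CDS > tRNA > rRNA > intron > IGS; insertion columns that fall between
projected feature spans are IGS (non-coding insertions relative to the
reference). The Gene tally is CDS + tRNA + rRNA + intron, class lengths are
measured on the consensus, and class lengths tile it exactly, so counts are
conserved across the stratification. Frequencies are true percentages
(100 · count / class length).

Two counting units coexist deliberately: class tallies count indel-bearing
*columns* (the unit behind genome-wide percentages), while pairwise reports
count maximal-run *events* (the unit behind statements like "144 indels
between two species"). Both are exposed, clearly labelled. Outgroups are
excluded from genus-level tallies via the `ingroup` argument. The package
validates alignments but does not align; the alignment is produced
externally (or emitted as truth by the simulator).

## Hotspots

`scanWindows()` is the exhaustive search: every start position on the
consensus (step 1; a larger step is only a speed knob), window 1000 bp,
qualifying when it holds at least 11 SNP sites — the strict reading of
"more than 10 per 1000 bp". Wrap-around windows are included on circular
consensi. Overlapping or adjacent qualifying windows are unioned into
maximal regions and the SNP count recomputed on the merged interval, so a
merged region's frequency can fall below the window threshold — expected
behaviour of the union, not a defect. Concordance screening builds a
neighbor-joining tree from each region's sub-alignment and reports, over
`b = 100` site-resampling replicates, the fraction in which every labelled
clade is monophyletic; regions with no variable column are non-concordant
by definition, and regions under 100 bp are skipped with a warning. The
resampling uses the session RNG; the pipeline seeds it and records the seed
in the run manifest.

## Distance phylogeny

p-distances exclude gap/N-bearing columns pairwise (not listwise); a pair
with no comparable column is an error. Trees are standard Saitou–Nei
neighbor joining with negative branch lengths clamped to zero, and
monophyly is tested after rooting at a named outgroup. NJ deliberately
stands in for the maximum-likelihood/Bayesian machinery of a full study:
the testable surface of a published tree is which labelled clades are
monophyletic, and NJ on whole-plastome distances answers that; bootstrap
and posterior support values are out of scope.

## The synthetic plastome generator

The generator's defaults are the study conditions the package targets:
LSC/SSC/IR of 84,000 / 18,000 / 24,300 bp, GC 36.6% (sequence drawn with
exact base composition so the target is met at any size), a gene layout
with named plastid genes (rbcL, ycf2, rpoC2, ndhF, ycf1, the four rRNAs in
the IR, atpF and clpP always intron-bearing, tRNAs, CDS filler, named IGS
gaps), a 6 + 6 + 10 three-clade taxon sample plus one outgroup on a preset
subgenus topology, per-class substitution rates equal to the published
class-wise SNP frequencies (CDS 0.0129, tRNA 0.0032, rRNA 0.0007, intron
0.0168, IGS 0.0326) with the ingroup tree normalised to total length 1 so
those rates are also the expected site frequencies in the output, and
per-class indel column rates from the published indel frequencies
(geometric lengths, mean 2 bp, half deletions, half insertions). Thirty
SSRs (55.6% A/T-only, 77.8% LSC, 71.9% IGS), four dispersed repeats
(including an antipodal LSC/SSC pair, the circular-symmetry motif), two
clade-stem deletions (387 bp in `ycf2`, 384 bp in the `psbM-trnD` spacer)
and two rate-boosted hotspot segments are planted with recorded
coordinates.

Modelling choices worth knowing:

* **Branch lengths are per-site substitution probabilities** (times the
  class rate), not rates under a reversible model — this keeps recovery
  arithmetic closed-form. A per-branch probability above 0.5 is rejected as
  saturated.
* **Concerted IR evolution**: substitutions drawn on IRa are mirrored into
  IRb and indels are suppressed inside the IRs, so leaves keep exact
  inverted repeats, as real plastomes (through copy correction) and the
  partition module both expect. Because the configured indel rates are
  observed whole-class column frequencies, the per-eligible-site event rate
  is scaled by class-total/class-eligible so the emitted alignment
  reproduces the configured class frequencies.
* **The true homology alignment is emitted directly** (insertions become
  gap columns for non-carriers), so no external aligner enters the test
  loop; an option writes unaligned FASTA for end-to-end runs with a real
  aligner.
* **Inserted material is never mutated further down the tree**, and
  mutations apply only to ancestral columns — a simplification that keeps
  every leaf exactly reproducible from the per-edge ground-truth records
  (`replayLeaf()` re-applies them and must match byte-for-byte).
* **Determinism**: one integer seed makes the whole simulation
  byte-reproducible; the ancestor and the evolution consume separate seeded
  streams so each is individually reproducible.

What passing tests on simulated data do *not* show: the generator draws
sites independently (no codon structure, no selection, no mutational
spectra), indel lengths are geometric plus planted long events rather than
the heavy-tailed empirical distribution, IR boundaries never expand or
contract, and the emitted alignment is the true one — real studies add
aligner error on top. Planted repeats are constructed to be detectable
(mismatches spaced for seeding); heavily clustered mismatches would defeat
any local-extension scanner and REPuter-style tools alike.

## Problem sizes and test design

The test suite validates each scanner against an independent oracle:
a direct-loop SSR enumerator, an exhaustive per-diagonal match-vector scan
for repeats, a per-window recount for hotspots, cophenetic distances of
random trees for NJ, and the generator's ground truth for everything
planted. Property tests run at reduced problem sizes chosen for adequate
signal rather than realism — 200 × 400 bp sequences for the SSR oracle,
50 × 5 kb for repeat recall, 37–48 kb ten-taxon genomes for variant-,
hotspot- and tree-level checks, 50 replicates for class-frequency recovery
and 100 for clade-monophyly recovery — while the acceptance script runs one
full-scale (150.6 kb, 23 taxa) simulation. Frequency-recovery comparisons
use closed-form expectations (SNPs: the probability of at least one
substitution on the spanning tree, corrected for insertion-column inflation
of class lengths; indels: exact per-replicate expectations from the
ground-truth event records), with a tolerance of 3 standard errors plus a
floor of one indel-event width per class for the column-reclassification
edge effect described above.

## Known limitations

GenBank parsing covers the subset of the format annotated plastomes use
(single-record files; `join`/`complement` locations; `/gene` and `/product`
qualifiers); exotic location operators are not supported. The repeat
scanner's Hamming model differs from REPuter's edit-distance default — a
deliberate trade for oracle-testable semantics — so indel-containing
repeats are found as two shorter pairs rather than one gapped pair. The
hotspot count on real data depends on manual curation decisions (which
neighbouring regions to fuse, which to discard) that the package does not
attempt to reproduce; its hotspot output is the deterministic
scan-and-merge result. Species assignment, annotation transfer and
alignment construction are upstream of the package.
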