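---
title: "From targeted capture read counts to a RIL genetic map: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From targeted capture read counts to a RIL genetic map}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capmapr)
```

## The problem

Genotyping-by-capture designs short synthetic baits against polymorphisms
previously discovered between the two parents of a mapping population,
hybridises them to genomic DNA of each line, sequences the captured
fragments and calls genotypes from per-allele read counts.  For a
recombinant inbred line (RIL) population of an allotetraploid such as
durum wheat, the end product is a dense genetic map in which linkage
groups correspond to the 14 chromosomes of the A and B subgenomes.

`capmapr` implements that analysis chain — bait design, count-based
genotype calling, a quality-filter cascade, de novo linkage mapping and
map validation — together with a synthetic-data module that simulates the
whole experiment, so every stage can be exercised and property-tested on
data with a known truth.

## Bait design

Baits are 120-mers drawn from a single exon (a bait spanning an intron
would not hybridise to genomic DNA), one SNP per contig to spread markers
over as many loci as possible.  Targets are laid out in three types:

* **Type 1** (exons with at least 120 bp on both sides of the SNP): four
  baits — two SNP-centred allele baits, one per parental allele, plus two
  allele-invariant baits placed immediately 5' and 3' of the SNP, so
  coverage extends at least 100 bp on each side (about 200 bp around the
  SNP).  The exact flanking geometry is not fully specified by the
  published figure this layout follows; placing the flanks adjacent to
  the SNP is this package's choice, and it keeps the SNP out of the
  flanking baits so exactly two baits per target carry an allele.
* **Type 2** (long exons, remainder of the design budget): two shifted
  allele baits, the SNP at 1/3 and 2/3 of the bait (`type2_offsets`).
* **Type 3** (exons of 120–199 bp): two baits at identical coordinates
  differing only at the SNP.

The split of long-exon targets between types 1 and 2 is a configurable
fraction (`type1_fraction`, default 3625/4133 — the mix of the design
this package re-implements, which fixed the counts historically without a
published rule).  When several SNPs on one contig are eligible the one in
the longest exon wins, ties broken by smallest position — deterministic
and reproducible.

Every bait is screened for tandem microsatellites: a dinucleotide motif
repeated ≥ 7 times or a trinucleotide motif repeated ≥ 5 times.
"Repeated n times" is read as n tandem copies of the unit (the stricter
of the two possible readings); homopolymer runs qualify through the
dinucleotide rule (14 identical bases are seven copies of a
dinucleotide).  The screen is implemented as a backreference regular
expression and is checked in the test suite against a brute-force
enumeration of tandem runs over all phases.

## Genotype calling

The published experiment called genotypes with a probabilistic
read-mapping model; `capmapr` substitutes a transparent threshold caller,
on the grounds that the downstream filters dominate the result and a
closed-form rule is auditable and fast:

* missing when total depth < `min_depth` (2 for targeted loci — the
  design guarantees the polymorphism exists — and 4 for untargeted
  "bonus" positions);
* heterozygous when the minor allele has ≥ 2 reads **and** ≥ 20% of the
  depth;
* otherwise homozygous for the majority allele; equal counts failing the
  heterozygote rule are uncallable and returned as missing.

Each targeted locus is then classified: `not_captured` (no calls),
`monomorphic` (one homozygote class only — typical of targets drawn from
an external polymorphism panel that are not actually polymorphic between
the two parents), `het_only`, or `ER` ("expected recovered", usable).
Bonus SNPs are discovered on untargeted positions (homeologous or
paralogous contigs pulled down by the baits) at the stricter depth and
kept only when both parental classes are observed.

## The filter cascade

Loci surviving classification are filtered by the conjunction of three
criteria (order-independent, applied jointly):

* **Fis > 0.8** — a selfed F6 population should be ~98.4% homozygous;
  an excess of heterozygous calls indicates a paralog collapse or
  systematic miscall.  Fis = 1 − Ho/He.
* **≥ 100 of 135 lines genotyped** — completeness.
* **Nei's He ≥ 0.34** — with He = 2pq this keeps allele frequencies in
  roughly [0.22, 0.78], screening out segregation distortion.  The
  source describes the threshold once as "minimum of 0.34" and once as
  "> 0.34"; `capmapr` implements ≥ and both boundaries are configurable
  (`filter_thresholds()`).

Heterozygotes contribute half an allele to each class; no small-sample
correction is applied to He.  Bonus SNPs on targeted contigs are
discarded (redundant through near-complete linkage disequilibrium with
the targeted SNP), then one bonus SNP is kept per remaining contig (most
genotyped, then highest He, then smallest position).  `snp_accounting()`
assembles the full bookkeeping with its identities enforced, and
reproduces the published recovery table exactly when fed its primary
counts.

## Linkage mapping

Mapping operates on A/B calls only (heterozygotes are set to missing:
the lines are ~98.5% homozygous and two-point statistics for selfed RILs
treat lines as binary).

1. **Redundancy merging.** Markers are co-binned when their calls agree
   at every co-genotyped line and they share at least 30 such lines
   (`min_shared`); bins are the transitive closure of that relation and
   are carried to a single map position.
2. **Two-point statistics.** For each pair, the recombinant-line
   fraction `R` among shared informative lines; LOD =
   k·log10(R) + (n−k)·log10(1−R) + n·log10 2 at the maximum-likelihood
   R (0 when R ≥ 0.5); the meiotic recombination fraction through the
   Haldane–Waddington correction r = R/(2(1−R)); Haldane distance
   d = −50·ln(1−2r).
3. **Grouping.** Single-linkage closure over pairs with LOD ≥ 7 *and*
   R ≤ 0.14.  The distance threshold is interpreted on the
   recombinant-line-fraction scale (exposed as `rf_max`).  Groups of
   fewer than 3 markers and unlinked singletons are reported but kept
   out of the map.
4. **Chromosome assignment.** Each group takes the modal putative
   chromosome of its markers (from an external assignment table, e.g.
   BLAST hits against a reference wheat assembly); ties leave the group
   unassigned.  Groups assigned to the same chromosome are pooled
   before ordering.
5. **Ordering.** Orders minimise the sum of adjacent two-point
   distances (the SARF criterion) — a deliberate, desk-scale proxy for
   the multipoint EM likelihood used by full mapping software; for
   dense RIL data the two objectives give near-identical orders, and
   this is the package's main simplification relative to that software.
   Groups of ≤ 8 markers are solved exhaustively; larger groups use
   greedy insertion, simulated annealing on segment reversals
   (geometric cooling from `t0` = 5 over `n_iter` = 30,000 moves, O(1)
   delta evaluation) and exhaustive sliding-window reversals (window
   ≤ 5) until no improvement.  Ordering is deterministic under a fixed
   seed.  Orientation of a chromosome is intrinsically arbitrary; when
   putative coordinates are available the order is flipped to correlate
   positively with them.

Positions are cumulative adjacent Haldane distances.  Because the
population is F6 rather than F∞, the expected recombinant-line fraction
between close markers is ~5–9% below the Haldane–Waddington limit, so
estimated map lengths run correspondingly short; recovery tests bound
the total-length error at 15%, which comfortably absorbs this known
bias, and it is documented here rather than "corrected" because the
F∞ correction is the field's standard practice for F6 RIL maps.

## Map validation

* Per-chromosome Spearman rank correlation between map positions and
  putative physical (and genetic) positions, average ranks for ties.
* A cubic least-squares regression of genetic on physical position per
  chromosome; markers outside the pointwise 95% **prediction** band are
  tagged as outliers.  A prediction band (not the mean-response band) is
  the deliberate default: tagging individual markers requires the
  band to include residual spread; `band = "confidence"` switches
  behaviour.  The regressor is centred and scaled internally (raw cubic
  terms of bp-scale coordinates are numerically catastrophic), and an
  essentially interpolating fit tags nothing rather than flagging
  numerical noise.
* Translocation-like blocks: maximal runs of ≥ 3 consecutive assigned
  markers (adjacent gaps ≤ 10 cM) whose putative chromosome is identical
  and **non-homeologous** to the mapped chromosome (homeologs share the
  numeral: 1A↔1B).  Three is the smallest defensible run length — the
  blocks this is designed to find have 4–11 markers; both knobs are
  arguments.  Markers without an assignment are skipped, markers
  assigned to the mapped chromosome break a run.
* Segment recombination rates in cM/Mb as genetic span over physical
  span of the markers inside a physical interval.

## The synthetic-data module

`generate_reference()`, `make_map_spec()`, `simulate_ril_population()`
and `simulate_capture_readcounts()` emulate the statistical structure the
pipeline assumes, with defaults set once to the conditions of the
experiment the package re-implements:

* 135 F6 lines; selfing is simulated generation by generation from the
  F1 by single-seed descent, crossovers a Poisson process on the cM
  scale (Haldane, no interference — no interference model is published
  for this material).  Six selfing rounds are the default so residual
  heterozygosity matches the stated 1.5% expectation ((1/2)^6 =
  1.5625%); the material is labelled F6, and the two statements are
  reconciled by making `generations` configurable.
* Per-locus coverage: median 11.4 reads per targeted 2-bait contig per
  line; 4-bait loci get twice the mean (stoichiometry); a lognormal
  per-locus capture-efficiency factor (sd 0.6 on the log scale — the
  published account reports only a median and heavy skew, so the
  distribution form is this package's modelling decision, not a
  published fact) and negative-binomial line-level noise (size 3);
  6% of loci fail capture outright; 20 microsatellite "sink" contigs
  absorb 42% of the total read budget (returned with exact budget
  accounting); 1% allele cross-talk.
* 41% of external-panel (EPO) targets are truly monomorphic between the
  parents (768 of 1,888 in the re-implemented design); residual
  heterozygotes are retained in the truth so the Fis filter has signal
  to act on.
* A configurable fraction of contigs receives a homeologous near-copy
  (3% divergence) carrying one segregating bonus site, and a fraction
  receives an embedded tandem microsatellite.

What the simulation does **not** model: read-level artefacts (base
qualities, PCR duplicates, mapping ambiguity), segregation distortion,
residual heterozygosity hotspots, and realistic linkage disequilibrium
between a homeolog's bonus site and distant loci.  Passing recovery
tests therefore demonstrates the correctness of the statistics and
algorithms under the stated model, not robustness to every artefact of
real capture data.

## Problem sizes and determinism

Recovery experiments in the test-suite and the acceptance script run at
the study scale where it matters — 135 lines, 14 chromosomes of 150 cM,
~1,400 markers for grouping/ordering recovery — and at reduced scale
(tens to hundreds of loci) for unit-level properties; these sizes were
chosen as the smallest at which the quantities being checked are
statistically stable.  Every stochastic function takes an explicit seed,
restores the caller's RNG state, and re-running any stage with the same
configuration reproduces its output byte for byte; pipeline CSVs carry a
provenance header (package version, seed, configuration hash).

## Known limitations

* Two-point SARF ordering can locally permute markers separated by less
  than one detectable recombination (~0.7 cM at n = 135); bins make most
  such ties explicit, but order within a gap-free run of near-zero
  distances is not identifiable from the data.
* The caller has no genotype likelihoods; at depth 2 a true heterozygote
  is usually seen as a homozygote.  This mirrors the downstream filters'
  assumption that residual heterozygosity is noise to be filtered, not
  signal to be recovered.
* Markers genotyped in 50–99 lines are excluded rather than placed by a
  secondary method; the map output format reserves a `DL_mapped` type
  for them but no placement algorithm is provided.
* `snp_accounting()` percentages are integer-rounded to match the
  published table's presentation.
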