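---
title: "Methods: miRNA discovery, degradome validation and module integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA discovery, degradome validation and module integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirbloom)
```

This vignette documents the models and procedures behind `mirbloom`, the
assumptions they make, the parameters that matter, and what the
synthetic-data tests do and do not demonstrate about real sequencing
data.

## Study design

The package models a flowering time-course: three genotypes with
contrasting bloom phenology (`FD` early, `MU` an earlier-flowering
mutant of FD, `LH` late) sampled at four petal stages (`BS` blooming,
`IF` initial flowering, `FB` full blooming, `DE` decay), three
biological replicates per cell — 36 small-RNA and 36 mRNA libraries.
Degradome libraries are one per genotype, with the four stages pooled
before library construction; all degradome inference is therefore
per-genotype, never per-stage. Contrasts come in two families:
*developmental* (two stages within one genotype, the later stage as
numerator, e.g. `FD:DEvsBS`) and *varietal* (two genotypes within one
stage, e.g. `BS:LHvsFD`).

## Five-group miRNA classification

Each collapsed 18–26 nt tag is reduced to three evidence bits: a hit in
the mature reference (ungapped, forward strand, ≤ 2 substitutions by
default — a conservative, configurable tolerance, since vendor pipelines
do not publish theirs), exact genome mappability of the reference
precursor matched by that hit, and exact genome mappability of the tag
itself (both strands, all loci kept). Genome matching is exact (0
mismatches) by default: with 18–26 nt queries, substitution tolerance
mainly manufactures spurious loci. Matching is ungapped throughout;
indel-tolerant alignment adds nothing at these lengths. The decision
tree is evaluated in a fixed order — gp1 (mature hit, precursor maps),
gp2a (mature hit, precursor absent, tag maps, hairpin at some locus),
gp2b (as gp2a, hairpin at no locus), gp3 (mature hit, tag does not map),
gp4 (no mature hit, tag maps, hairpin at some locus) — and anything else
is `UNCLASSIFIED`, a normal outcome rather than an error. Multi-locus
tags use existential semantics: one hairpin-positive locus suffices.

## The fold-back hairpin criterion

Whether a genomic locus can host a miRNA precursor is decided by a
duplex heuristic rather than thermodynamic folding: the candidate mature
arm is slid (ungapped, anti-parallel) along each flank — 120 nt per
side by default, the scale of plant pre-miRNA arms — and the best window
is scored by Watson–Crick plus G:U wobble pairing. A locus is accepted
when at least 16 mature positions are paired, the largest internal
bulge in the mature stem is ≤ 3 nt, and a loop of ≥ 3 nt separates the
arms (windows overlapping the mature are never considered, so the mature
cannot span the loop). The thresholds follow community miRNA-annotation
practice for plant precursors and are all configurable via
`hairpin_params()`. The heuristic trades thermodynamic accuracy for
exactness and testability: it is deterministic, symmetric under reverse
complement (verified by property test), and its accept/reject decisions
can be planted by construction in the simulator. It will disagree with a
free-energy folder on marginal loci — e.g. long asymmetric bulges that a
folder would tolerate — which is acceptable here because both the
generator and the classifier use the same declared criterion.

Ties between candidate windows are broken by more paired positions,
then smaller loop, then smaller bulge; between the two arm orientations
by paired count. Loci extending past a contig end are truncated rather
than rejected.

## Differential expression

Counts are normalised to counts-per-million (CPM); the minimal,
reproducible choice when library composition is not being modelled.
DEM calling is a per-feature one-way ANOVA F-test on log2(CPM + 1),
across stages within a genotype or across genotypes within a stage,
with significance tiers 0.01/0.05/0.1 and the inclusive boundary
*P* ≤ α. Pairwise miRNA contrasts use the same machinery on two groups
(equivalent to the equal-variance t-test); the directions of those
pairwise calls are what module integration consumes. DEG calling uses a
Welch t-test on log2(CPM + 1) jointly with a fold-change rule on the
CPM means (pseudocount 1 for stability): a gene is called only when
fold change > 2 or < 0.5 **and** *P* < 0.05 — the strict boundary,
deliberately different from the DEM rule, both literal. The F and t
statistics are computed by vectorised row-wise arithmetic (the
standard approach when testing thousands of features); tests verify
bit-level agreement with `aov()` and `t.test()` per feature. Features
with zero variance everywhere get *P* = 1 by convention rather than
NaN. No multiple-testing correction is applied, matching the stated
raw-P criteria; `p.adjust`-style correction would be a one-line
extension but is off by default, so reported rejection rates are
per-test error rates, not FDR.

Under the null, the ANOVA on log2-transformed negative-binomial counts
is only asymptotically F-distributed; at μ = 100 and dispersion 0.05
the measured type-I rate at α = 0.05 sits inside the exact binomial
95% interval around 0.05 (the acceptance suite checks this on 2,000
null features).

## Target prediction and degradome validation

Binding sites are scored by position-weighted complementarity
penalties: mismatch 1.0, G:U wobble 0.5, both doubled at miRNA
positions 2–13 (the functionally critical 5′ region), cutoff 2.5 —
the parameterisation style of plant target predictors, declared
explicitly in `target_params()` and fully configurable. Every
transcript window of miRNA length is scanned; the expected cleavage
coordinate is the transcript nucleotide opposite miRNA position 10,
where slicer cuts the duplex. Degradome tags are accumulated into
per-position 5′-end densities per genotype; a predicted site is
validated when a count peak exists within ±1 nt of the expected
position (ties resolved towards the expected position, then leftwards).
Validated sites are graded by the t-plot convention: category 0 — the
peak is the transcript's unique maximum; 1 — a tied maximum; 2 — above
the transcript mean but below the maximum; 3 — more than one read but
at most the mean; 4 — a single raw read. "Transcript mean" is the mean
over positions with signal, the scale on which t-plots are read. A pair
is degradome-validated when supported in any genotype's library;
per-genotype flags are retained so differential degradation between
genotypes stays inspectable.

## Module integration

Genes called in any developmental contrast form the developmental
union; genes called in any varietal contrast form the varietal union. A
module is emitted for a (miRNA, target) pair exactly when the pair has
a validated cleavage site, the miRNA is a DEM and the target is in the
corresponding union, and in at least one shared contrast their
significant directions are opposite — miRNA up/target down or the
reverse. The evidence class records which contrast family supplied the
antagonism (`developmental`, `varietal`, or `dual` for both). Targets
carrying a transcription-factor annotation extend the pair to a
miRNA–mRNA–TF module; the exported edge list (`silences` and
`encodes_tf` edges) is importable by standard network tools.

## qPCR relative quantification

`relative_quantity()` implements 2^−ΔΔCt: technical replicates are
averaged on the Ct scale (the standard order of operations), ΔCt is
target minus reference gene, ΔΔCt is relative to a calibrator sample,
and RQ = 2^−ΔΔCt. The default calibrator in the pipeline is each
genotype's blooming-stage sample, a choice the method leaves open; RQ
levels therefore depend on it, but stage *profiles* do not, which is
why validation correlates profiles (Pearson on log2) rather than
comparing absolute RQ.

## The synthetic-data generator

The generator plants everything the pipeline is supposed to find.
Hairpin-positive loci (gp1/gp2a/gp4) are inverted-repeat cassettes —
mature, a random 8–20 nt loop, the mature's reverse complement —
verified during generation by the same `fold_back()` oracle the
discovery stage uses; gp2b matures are embedded bare and their flanks
reshuffled (rejection sampling, bounded at 1,000 attempts) until the
hairpin test fails; gp3 matures are verified genome-absent. Reference
precursors are the exact genomic cassette for gp1 (so they map back)
and synthetic, genome-absent stem-loops for gp2a/gp2b/gp3; gp4 matures
appear in neither reference. Counts are negative-binomial — the
standard count-noise model, which makes type-I and power statements
meaningful — with mean μ·2^effect in a planted genotype × stage cell
and μ elsewhere (defaults μ = 100, dispersion 0.05, |log2FC| = 2,
sequencing depth per library is a knob, not a claim). Each planted
module pairs a miRNA up-effect with the opposite-signed effect on its
target in the same cell, plants the reverse complement of the miRNA in
the target transcript, and plants a degradome peak holding 90% of that
transcript's tags at the expected cleavage position; transcripts
without planted sites get a sparse single-count background. All
randomness flows from one seed through per-component sub-streams, so
every emitted file is byte-deterministic and regenerating one component
never perturbs another. A null configuration (`effect_log2fc = 0`)
plants no differential truth and hence no modules, since antagonism is
undefined without effects.

What the generator does **not** emulate: read-level errors, adapter
contamination (tags arrive pre-trimmed and collapsed), rRNA/tRNA
contaminant classes, isomiR variation, library-composition effects
beyond what planted effects induce, multi-exon gene structure, or a
genome large enough to create repeat-driven multi-mapping. Passing
recovery tests therefore demonstrates the correctness of the decision
logic and statistics under the declared noise model — not performance
on real libraries, where contaminant filtering and reference
completeness dominate.

## Problem sizes and numerical choices

Default simulations use 3 × 20 kb contigs, 28 planted miRNAs across
the five groups, 80 transcripts (0.6–1.5 kb), 50 decoy tags, and the
full 36-library design — sizes chosen so a complete run takes seconds
while every code path (all five groups, both contrast families, TF and
non-TF targets, background-only transcripts) is exercised; the
acceptance checks scale the catalog to 200+ tags and the null
calibration to 2,000 features. Penalty comparisons use a 1e-9 slack on
the cutoff to absorb float summation; CPM column sums are exact by
construction; degenerate statistics (all-constant features, empty
profiles, empty module sets) return defined values (*P* = 1, no
record, empty tibble) rather than NaN or errors.

## Known limitations

* The hairpin heuristic is not a thermodynamic folder; borderline
  precursors may be judged differently than by free-energy methods.
* The mature-reference tolerance (≤ 2 substitutions) stands in for
  unpublished vendor behaviour; real catalogs may need tuning.
* "Pre-miRNA" vs "unique miRNA" counts in the group census are
  reported as distinct-precursor-locus and distinct-mature-sequence
  counts respectively; with unique planted sequences the two coincide.
* Degradome categories carry no statistical significance; they grade
  signal dominance only.
* Counts of targets with "differential degradation" between genotypes
  are exposed as per-genotype presence/absence flags; no numeric
  criterion is imposed.
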