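---
title: "Quantifying the TMEJ deletion footprint in mutation-accumulation lines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the TMEJ deletion footprint in mutation-accumulation lines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmejsig)
```

## The problem

When a replication fork in the germ line meets a template lesion that the
translesion synthesis (TLS) polymerases cannot bypass, the stalled fork can
collapse into a double-strand break whose repair by polymerase
theta-mediated end joining (TMEJ) leaves a characteristic scar: a deletion of
roughly 50–500 bp whose junction shows short micro-homology and, in a subset
of events, a small insert copied from DNA near the breakpoints. Counting and
characterising these scars in clonally propagated mutation-accumulation (MA)
lines therefore measures, indirectly, how often replication encounters
blocking lesions and which repair chemistry resolves them.

`tmejsig` implements the downstream analysis of such an experiment: it takes
variant calls (from any caller) plus a reference genome, and produces
per-generation mutation rates by variant class, junction micro-homology
statistics against a shuffled null, insertion-origin categories, and
breakpoint base-composition profiles. A paired generator simulates MA lines
with known ground truth so every statistic can be validated end to end.

## Allele normalisation: maximal 5' conservation

A deletion inside a repeat admits many equivalent annotations. All junction
statistics here assume the *maximal 5' conservation* convention: while the
first deleted base equals the first base retained after the deletion, the
deleted interval shifts one base toward the 3' end, so shared bases are
absorbed into the retained 5' flank. This is the opposite of VCF
left-alignment (`left_align_deletions()` converts back for export).

```{r normalise}
ref <- c(chr1 = "ACCCA")
tab <- data.frame(chrom = "chr1", start = 2, end = 3, ref_allele = "CC",
                  alt_allele = "", genotype = "wt", subpop = "L1",
                  generations = 40)
normalize_deletions(tab, ref)[, c("start", "end", "ref_allele", "shifted_by")]
```

Two consequences matter for interpretation. First, after normalisation the
base at position −1 on the 5' side can never equal the base at +1 on the 3'
side, so the (−1, +1) heatmap cell is *structurally* zero — a property of the
annotation rule, not of repair. Second, the homologous bases that the rule
moves into the 5' flank elevate the (+1, −1) cell. Both effects are
deliberately reproduced in the shuffled null (below) so that observed and
null heatmaps carry the same methodological skew. Deletions that arrive with
an inserted sequence are never shifted — the rule speaks only of reference
bases, and sliding a junction past an insert would change its meaning — and
are flagged `shift_blocked` instead.

## Junction windows and micro-homology

`build_junction_context()` cuts four windows of width `w` (default 10 bp)
around a deletion: retained and lost sequence at each breakpoint, indexed by
the convention that +k is the k-th retained base counting away from the
junction and −k the k-th lost base counting into the deletion. Windows are
N-padded past contig ends, and N never scores as a match.

`mh_length()` is the largest k such that retained 5' positions +1..+k equal
lost 3' positions −1..−k, i.e. the longest suffix the retained 5' flank
shares with the deleted sequence. The value is capped at
`min(w, deletion_size)`: a deletion cannot carry more micro-homology than its
own length, and for deletions shorter than `w` the lost windows deliberately
overlap retained sequence (they are plain reference substrings), so the cap
keeps the statistic meaningful there.

`mh_heatmap()` generalises this to all position pairs: for every event, each
5' position is compared with each 3' position; a cell holds the fraction of
events whose bases match, with N-carrying events dropped from that cell's
denominator. The micro-homology signal concentrates on the (+k, −k)
diagonal.

## The shuffled null

Chance matches make heatmap cells nonzero even without any repair-driven
micro-homology, at a level set by local base composition. The null model
(`shuffled_null()`) therefore shuffles each of the four windows of each
event independently — exactly preserving composition — and then *re-applies*
the maximal-5'-conservation rule to the shuffled windows before scoring.
Re-annotation is done in window space: each shift slides all four windows
one base junction-ward, and a base that would have to slide in from beyond a
window is unknown and becomes N (contexts carry only their windows, not the
whole locus). Those N positions are excluded from cell denominators, so the
approximation costs coverage at far positions after multiple shifts but
introduces no bias. Ten replicates are pooled by summing match counts and
denominators; the replicate count and seed are recorded.

`compare_cell()` then tests one cell with a 2×2 Pearson chi-square (no
continuity correction) on identity yes/no × observed/shuffled counts,
starring p < 0.001 and reporting a zero-margin table as inapplicable rather
than NaN.

## Insertion origins

Deletions subdivide into `simple` (no insert), `templated` (insert of at
least 5 bp whose full sequence, on either strand, occurs within 40 bp of
either breakpoint), and `misc` (inserts below 5 bp or of unknown origin).
"Within 40 bp of a breakpoint" is implemented as 40 bases on each side of
each breakpoint, *including* the deleted sequence adjacent to it; matching is
exact and full-length by default, with a mismatch-tolerance hook
(`max_mismatch`) for exploratory use. Exactness was chosen for determinism:
an insert either is or is not mappable to a recorded origin.

## Breakpoint composition

If one junction of a damage-induced deletion is defined by the nascent
strand stalled at the lesion, the blocking base should appear at a fixed
junction position — most visibly as an enrichment at −1, the first lost
base. `composition_profile()` tallies base frequencies at positions +100..−100
around every junction (each event contributes its 5' and 3' junction) and
normalises each base's per-position frequency by that base's mean over all
200 positions, i.e. by the local AT/CG content. Outliers are flagged beyond
`k = 3` per-base standard deviations, where the SD is a per-base scalar
computed across positions — flat dashed bands, not per-position binomial
errors (a per-position standard-error mode would be a straightforward
extension, but the scalar SD matches how such profiles are usually drawn and
read). Positions covered by fewer than 90% of junctions (contig-end N
padding) are reported but excluded from the mean/SD estimation.

Because it is not obvious on which strand the 3' junction should be read,
both readings are first-class: the default `mirrored` mode reads the 3'
junction on the reverse-complement strand so both junctions run
retained-to-lost in their own nascent-strand frame (the natural frame for a
junction-symmetric lesion model), while `top_strand` reads both junctions
literally off the reference. Results are labelled with the mode used.

## Rates and the lesion-frequency arithmetic

Variants accepted as de novo (private to one subpopulation, seen on both
strands, depth ≥ 5 — consumed as caller flags, never recomputed; absent
flags pass vacuously by default) are stratified by genotype × class, and
each stratum's rate is its count divided by the summed generations of that
genotype's lines. Counts are small, so intervals are exact Poisson
(Garwood) rather than Wald; rate ratios use the conditional-binomial
construction, which is exact for Poisson counts. `estimate_rates()` returns
a fitted-model-style object with `coef`, `confint`, `predict` and
`simulate` methods (the latter a parametric bootstrap of the count table).

Variant classes partition every record: SNVs; microsatellite indels (an
indel inside a supplied repeat tract, or — absent tracts — whose sequence is
a whole multiple of a ≤4 bp unit present in ≥3 tandem copies across allele
plus adjacent reference; the unit/copy thresholds are configurable since
"microsatellite" has no single field-wide definition); deletions of
50–500 bp (the TMEJ size class, with or without insert); structural records
(tagged inversions, tandem duplications, gross rearrangements); and
insertion / other-deletion catch-alls.

`mann_whitney_exact()` supports size-distribution comparisons: p-values are
permutation-exact by complete enumeration of midrank assignments up to a
pooled n of 12 (ties handled exactly), and tie-corrected normal with
continuity correction beyond. Two-sided exact p-values use the permutation
distribution of |U − n_x n_y / 2|.

`lesion_frequency()` encodes the closing arithmetic: with d deletions per
generation, m germline divisions per generation and a genome of g bases,
one unbypassable lesion occurs per m·g/d bases replicated.

```{r lesion}
lesion_frequency(0.1, 10, 1e8)
lesion_frequency(1, 10, 1e8)
```

## What the generator emulates — and what it does not

`simulate_ma_lines()` draws, per line, Poisson event counts at configurable
per-generation class rates (defaults 0.23 SNVs, 0.04 microsatellite indels,
0.04 deletions — wild-type-like values), over 40–60 generations per line
(uniform draw; fixable). Deletion sizes are log-uniform on [50, 500] bp;
micro-homology lengths geometric (p = 0.5, capped at 8); a configurable
fraction of deletions carries an insert, templated ones copied from a
recorded origin within 40 bp of a breakpoint on either strand. The
`minus1_c_bias` parameter is the probability that the first deleted base of
the anchored junction is forced to cytosine; with the default uniform-GC
reference, 0.25 is exactly neutral. Anchoring defaults to the 5' junction of
the top strand, with a switch to randomise the anchored side — mirroring the
same strand ambiguity the two composition modes address.

Construction is inverse to the analysis: all constraints (the homology
suffix, the forced mismatch one base deeper, the anchored −1 base, and the
stability of the right-shifted annotation) are written into the *reference*,
so emitted records are already normalised and ground-truth labels
(`true_mh_length`, insert origin and strand, anchored base) are exact by
construction. Events are placed uniformly with rejection so they never
overlap.

Deliberate simplifications: no read-level errors or coverage variation
(flags are emitted as passing; a `shared_fraction` knob creates
cross-line duplicates to exercise the de novo filter); no clustered or
nested events; independent lines with a single-bottleneck pedigree; i.i.d.
base composition rather than real isochore or repeat structure. Passing the
recovery suite therefore demonstrates the statistical machinery is correct,
not that caller artefacts in real data are handled — the de novo filter
consumes, but cannot audit, upstream evidence.

## Numerical and design choices

* Coordinates are 1-based inclusive everywhere at the interface; pure
  insertions use `end == start − 1` (the insert sits before `start`).
  BED/VCF writers convert conventions explicitly.
* The G-quadruplex scanner uses the standard G3+ N1–7 pattern
  (`(G{3,}[ACGTN]{1,7}){3}G{3,}`) with all parameters exposed; matches are
  maximal and non-overlapping per strand, with minus-strand hits found on
  the reverse complement and mapped back. No thermodynamic scoring is
  attempted.
* The VCF reader is a deliberately minimal subset: single-allelic records,
  anchor-base stripping, and `<DEL>` with `END=`/`INSSEQ=` INFO keys; the
  TSV dialect is the canonical interchange format.
* Degenerate inputs are reported, not crashed on: zero-margin chi-square
  tables are "inapplicable", a zero deletion rate yields an explicit
  undefined `bases_per_event`, zero-SD bases produce no composition flags
  (with a warning), and zero-count rate strata get one-sided intervals.
* Statistical unit tests use Monte-Carlo bounds of 3 standard errors for
  single comparisons, with a small family-wise allowance when hundreds of
  cells are checked at once (at 3σ, roughly 1 in 370 honest cells is
  expected outside the band).

## Problem sizes used by the validation suite

The test suite validates oracle equivalence on 10^4 random micro-homology
instances, 10^3 insertion classifications against exhaustive search, and
every Mann–Whitney sample-size split with pooled n ≤ 8 against full
enumeration. Whole-pipeline recovery runs 200 simulated lines of 40
generations (~2,500 events on a 5 Mb reference) and checks class rates
within 3 SE, the planted templated fraction within 3 binomial SE, the
heatmap diagonal against the planted geometric law, and the −1 cytosine
flag at bias 0.7 (with no flag at the neutral 0.25). These sizes resolve
all planted signals comfortably; larger runs change nothing but precision.

## Limitations

Known limits worth restating: micro-homology is measured exactly (no
mismatch-tolerant or probabilistic homology model); insert origins are exact
full-length matches; structural variants are carried as tagged records, not
resolved into breakpoint graphs; and the composition profile's two
orientation modes bracket, but cannot decide, the strand on which a real
lesion sat. Where the underlying convention was ambiguous, both readings
are implemented and labelled rather than silently chosen.
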