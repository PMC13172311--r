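---
title: "Detecting and quantifying recursive splice sites from junction and coverage evidence"
author: "recsplice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and quantifying recursive splice sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Long introns are often removed in several consecutive steps rather than
in a single donor–acceptor reaction. At each intermediate step the
spliceosome joins an exon's 5' splice site to a cryptic acceptor deep
inside the intron; the sequence immediately after that acceptor
regenerates a donor-like dinucleotide that seeds the next step. The
acceptor context is a pyrimidine–A–G trinucleotide followed by the two
regenerated-donor bases — the YAG|NN motif. In RNA-seq data these
recursive splice sites (RSSs) leave two signatures: *hybrid* junction
reads joining an annotated exon 3' end to an intron-internal position,
and a *sawtooth* coverage profile in which intronic signal decays along
the direction of transcription and drops sharply at each used RS point.

`recsplice` implements this analysis end-to-end for bulk RNA-seq:
candidate detection from junction tables, a three-criterion filter,
per-sample usage quantification, differential usage between genotypes,
and the downstream annotation statistics (RS-exon association,
cryptic-exon coverage enrichment, donor-class enrichment, conservation
strata and profiles, RSS-per-million, intron-length correlation, and
AS-overlap enrichment). A ground-truthed synthetic generator emits every
input format the pipeline reads, so the whole method is testable without
external data.

## Coordinates and orientation

All internal coordinates are 0-based half-open; conversion to and from
the 1-based inclusive GFF3 and STAR junction conventions happens only at
file boundaries. "Upstream", "downstream" and "exon 3' end" always refer
to transcription orientation: on the minus strand all motif logic runs
on the reverse complement, and an RS point is stored as the boundary
coordinate between the acceptor G and the first regenerated-donor base.

## Detection

A junction is a candidate when (i) its donor side coincides *exactly*
with an annotated exon 3' end (RS donors are exon-terminal 5' splice
sites; no tolerance), (ii) its acceptor lies strictly inside the intron
that follows that exon, at least `min_margin` (default 20) nt from
either intron end, and (iii) the acceptor is not an ordinary alternative
acceptor. For (iii) we exclude acceptors that coincide with the 5'
start of an annotated exon of the host gene **unless that exon lies
entirely within the host intron**: an intron-contained exon starting at
the acceptor is, by definition, a putative RS-exon, and discarding those
would remove precisely the sites the method is after. The host-gene
restriction (rather than a genome-wide exon scan) keeps the rule local
and configurable. Junctions whose donor matches exon ends of more than
one gene are skipped and counted. Introns are deduplicated per gene by
(interval, donor boundary), and when alternative downstream exons create
nested same-donor introns the shortest intron containing the acceptor is
used. Only uniquely mapped junction reads are counted; the strand column
of the junction table is authoritative and never inferred from motifs.

Candidates failing the `[CT]AG` acceptor check (including any window
containing N, flagged `ambiguous_base`) are retained in the catalog for
auditing but can never pass filtering.

## The three filter criteria

1. **Conservation** — the arithmetic mean of per-base PhastCons values
   over the 5 motif bases (YAG + NN) must *strictly* exceed 0.5. The
   window is the motif itself; the later conserved/non-conserved
   stratification at 0.45 uses the same 5-nt mean, with the exact-0.45
   point mass deterministically assigned to "low" and counted.
2. **Junction support** — the junction's maximum overhang must strictly
   exceed 5 nt (i.e. at least 6).
3. **Sawtooth** — mean coverage in the 500-nt window upstream of the RS
   point (transcription orientation, truncated to the intron, minimum
   50 nt after truncation) is compared with the downstream window
   through the pseudo-counted fold `(up + 0.5) / (down + 0.5)`, which
   must strictly exceed 2. Consistency is assessed by a breakpoint
   permutation test: 1000 breakpoints are redrawn uniformly from the
   intron interior, the same statistic computed at each, and the
   add-one estimator `p = (1 + #{S_null >= S_obs}) / (n_perm + 1)` must
   fall below 0.01. Breakpoint randomization (rather than label
   shuffling) preserves the positional autocorrelation of coverage; the
   add-one estimator never returns 0 and attains its floor
   `1/(n_perm+1)` when the observed statistic beats every draw.

Window means exclude positions covered by annotated exons of the host
gene lying inside the host intron. The criterion measures *intronic*
signal density; an included cryptic RS-exon sits immediately downstream
of its RS point and would otherwise contaminate the downstream window
and mask a genuine step. The same masking applies to every permutation
draw, so observed and null statistics remain exchangeable.

Candidates whose intron cannot host the minimum windows are flagged
`untestable` — a distinct failure reason, not a silent pass. Finally,
any candidate whose (gene, RS point) was detected with at least one read
in any poly(A)-enriched library is subtracted: splicing intermediates
visible in mature poly(A)+ RNA are treated as artifacts.

The sawtooth RNG is seeded per candidate from the run seed and the
candidate's genomic position, so P-values are reproducible and
independent of catalog order. All per-stage survivor counts are recorded
and are monotone along the chain motif → conservation → overhang →
sawtooth → poly(A).

## Usage and differential testing

RS usage in a sample is the RS junction's unique reads divided by, in
the default `upstream_exon` mode, the unique reads of **all** junctions
sharing the RSS's upstream-exon donor (which bounds usage in [0, 1]);
the alternative `flanking_exons` mode divides by the canonical junction
joining the exons flanking the host intron instead. The two definitions
answer slightly different questions — the first measures the donor's
partitioning, the second the RS flux relative to complete intron
removal — and they differ numerically (5 RS reads against 15 canonical
reads give 0.25 vs 0.33), so both are implemented and the mode is
explicit.

Differential usage between two conditions uses a two-tailed
pooled-variance Student's t-test at P < 0.05, with no multiple-testing
correction — gained and lost are both reported, hence two-tailed. An RSS
absent from a replicate counts as usage 0 there only when its donor has
at least `min_donor_reads` (default 10) junction reads, distinguishing
absence of splicing from absence of power; otherwise the replicate is
unusable, and RSSs with fewer than two usable replicates per condition
are `untestable`. Zero pooled variance is handled deterministically
(equal means → p = 1; unequal → p = 0).

## Annotation statistics

* **RS-exon association**: an annotated exon of the host gene (any
  isoform) starting exactly at the RS point (tolerance configurable,
  default 0 — the RS acceptor AG is by definition the RS-exon's 3'
  splice site) and contained in the host intron. Unassociated sites
  behave as "zero-length" exons.
* **Cryptic exons**: an associated RS-exon is cryptic when its mean
  coverage exceeds twice the mean over equal-width intronic flanking
  windows (pseudo-count 0.5 on both).
* **Donor classes**: gained/lost vs unchanged RSSs are cross-tabulated
  against donor dinucleotide patterns (default the mutually exclusive
  partition GT/GV/AT/AV/CN/TN plus the composites GN and AN; IUPAC-like
  letters N = any, V = A/C/G) with two-tailed Fisher exact tests, one
  pattern and direction at a time.
* **AS overlap**: one-tailed (over-representation) hypergeometric test
  of RS-gene overlap with each alternative-splicing event type within a
  caller-provided gene universe.
* **Profiles and logos**: per-offset conservation means and
  column-stochastic position probability matrices around aligned
  boundaries (position 0 = first regenerated-donor base), with random
  intronic sites drawn from the same introns as controls; Ns are
  excluded from PPM denominators.

## The synthetic generator

The generator emits exactly the formats the pipeline reads (FASTA, GFF3,
bedGraph, STAR-style junction TSV, manifest) plus a truth table, from
one seeded RNG with per-sample substreams derived by stable hashing, so
every file is byte-reproducible.

Its defaults define the study conditions: 20 genes (4 exons each) on
alternating strands; 40 true RSSs — 20 "lost" (usage 0.25 in the
reference condition, 0.05 in the knockout), 20 unchanged at 0.25 — and
20 decoys, 4 per failing criterion (non-YAG context, low conservation,
overhang ≤ 5 nt, no coverage step, poly(A) leakage); replicate usage
noise sd 0.03; 3 replicates per condition plus one poly(A) library;
donor classes mixed so that roughly 55% of donors are non-GN, with GT
the single largest class; 90% of true sites carry an annotated RS-exon
isoform (60–120 nt), 20% of those cryptic.

Intron lengths default to 8–15 kb with one planted site per intron.
Recursive splicing is a long-intron phenomenon — RSS counts scale with
median intron length — and the permutation null also needs an intron
interior that is large relative to the 500-nt windows: breakpoints
within a few tens of nt of a genuine step reproduce near-observed folds,
so in a multi-kilobase intron that neighborhood must be well under 1% of
the interior for a real step to clear the 0.01 cutoff. Both
`intron_length` and `n_rss_per_intron` are configurable.

Coverage is modeled as exonic plateaus plus intronic exponential decay
(rate 1e-4/nt from the intron's transcription start) with a
multiplicative drop of `step_fold^(usage/0.25)` at each used RS point
(default full fold 4), cryptic RS-exons boosted 6-fold, and per-base
Poisson noise — the minimal generative model consistent with the filter
statistic. Junction counts are Binomial(donor total, usage + noise) with
the remainder on the canonical junction; donor totals are
Poisson(200). Conservation is clipped-normal around 0.85 (or 0.15 for
conservation decoys) over planted motifs, with conserved windows at
canonical acceptors and sparse low background elsewhere.

What the generator does **not** emulate: mapping artifacts and
multimapping junctions, library-preparation biases (GC, fragment
length), transcription-rate variation along genes, overlapping genes,
partial intron retention, or read-level data (no FASTQ/BAM). Passing
tests therefore demonstrate correctness of the statistical machinery
under the stated generative model, not robustness to alignment noise in
real libraries.

## Numerical choices and degenerate inputs

* ε = 0.5 pseudo-count in both the sawtooth fold and the cryptic-exon
  fold: avoids division by zero on sparse introns.
* Strict inequalities at every published threshold (0.5, 5 nt, 2-fold,
  0.01, 0.05, 0.45): boundary values fail, and the 0.45 boundary case is
  additionally counted.
* Fisher tests with an empty pattern margin return P = 1 and are
  flagged rather than erroring.
* Zero-variance t-tests, zero-denominator usage, empty catalogs, introns
  too short for the sawtooth windows, and all-N PPM columns each have
  explicit, deterministic behavior (see the function documentation).
* Catalogs are ordered by (chromosome, RS point); reruns with the same
  seed are byte-identical.

## Problem sizes used by the test suite

The suite exercises the full pipeline on the default 20-gene experiment
(about half a megabase of genome, seven samples), the permutation
calibration on 500 null introns of 3 kb at 1000 permutations each, and
differential power/size on 50 planted lost plus 50 null sites with 3
replicates per condition — sizes chosen so each property is measured
with usable statistical resolution while the whole suite stays
interactive.

## Known limitations

* The sawtooth test assumes a single dominant step within each window
  pair; closely spaced RS points (≪ window width apart) shade each
  other's statistics. Model-based piecewise fitting of
  co-transcriptional decay is out of scope.
* No FDR control across candidates for either the sawtooth or the
  differential test; both apply the published per-site cutoffs.
* The poly(A) subtraction is binary (any read in any poly(A) sample);
  no abundance model for intermediates in mature RNA.
* Minor-spliceosome (AT–AC) introns, branch-point prediction and de
  novo junction discovery from raw reads are out of scope; junction
  tables are the input contract.
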