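---
title: "Designing focused CRISPR screen libraries with guidescreen"
author: "guidescreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing focused CRISPR screen libraries with guidescreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model

A focused CRISPR knockout screen targets a curated list of genes — up to
1000 per request here, with 1 to 30 guides per gene — instead of the whole
genome. The design problem is to pick, for each gene, the guides most
likely to knock the gene out cleanly: active at their intended site,
inactive elsewhere, robust to genetic variation in the assayed cells, and
positioned where cutting disables as much of the gene as possible.

`guidescreen` casts this as candidate discovery followed by multi-criteria
selection. Discovery is exhaustive: every occurrence of
`[N x 19-or-20]NGG` on either strand whose protospacer overlaps the gene's
reduced exon union is a candidate (`scanPamSites()`,
`collectGeneCandidates()`). Only the canonical SpCas9 NGG PAM is used; NAG
and other non-canonical PAMs are ignored, and exons are the only targeted
space (no promoter or intron tiling). The blunt SpCas9 cut site is placed
3 bp 5' of the PAM, between positions 17 and 18 of a 20-mer protospacer;
it anchors both the isoform-commonality criterion and (by default, plus
the PAM) the variant footprint.

## The four ranking criteria

**Efficiency.** Predicted cleavage activity is a positional-linear
function of the sequence context — 10 nt of 5' flank, the spacer, 10 nt of
3' flank covering the PAM: `score = intercept + sum weight(position,
base)`. This is the functional form of LASSO-trained sequence models; the
coefficients are read from a TSV so any such model can be plugged in. The
shipped file is a synthetic example (GC-favouring, intercept 0.2, weights
±0.02 over the spacer positions) chosen so that scores span zero and the
below-zero filter is exercised; it is **not** trained on cleavage data, and
real designs should substitute published coefficients. Candidates whose
context is truncated by a chromosome end cannot be scored and are treated
as failing the efficiency filter.

**Specificity.** All genomic loci within 3 mismatches of the spacer and
followed by NGG are enumerated exhaustively on both strands
(`enumerateOfftargets()`; brute force via Biostrings pattern matching,
appropriate at the package's desk scale — an index could be added without
any interface change). Each non-on-target hit contributes a Hsu-style
penalty combining the experimentally derived per-position mismatch weights
(shipped 20-value table), the mean pairwise distance between mismatch
positions and the squared mismatch count; the aggregate
`100 / (1 + sum s_h)` is 100 exactly when there are no off-target hits and
50 for a single perfect-match off-target. Two conventions the formula
itself leaves open are fixed as follows: for hits with fewer than two
mismatches the mean pairwise distance is taken as 19, making the distance
factor exactly 1 (the convention of the original scoring tools); and for
19-nt spacers the PAM-distal entry of the 20-value penalty table is
dropped, so the PAM-proximal weights — the ones that matter — keep their
positions. Perfect-match hits *inside the queried gene's span* are tagged
`ON_TARGET` and excluded: a guide may legitimately match several isoform
copies of its own locus.

**Conservation.** The mean per-base score over the protospacer from a
user-supplied bedGraph track in \[0, 1\]; positions not covered by the track
count 0, so sparse tracks remain averageable. The track is consumed, never
computed — no alignments are run.

**Isoform commonality.** The fraction of the gene's transcripts having an
exon that contains the cut site. When the cut site falls in no exon but
the protospacer still overlaps one (a guide hanging off an exon edge), the
maximum per-base transcript-usage fraction over the overlapped bases is
used instead, so the score is always in (0, 1] and equals 1 for
single-isoform genes.

## Filters

A candidate is removed when any of these holds, and every violated rule is
recorded:

* overlap between the candidate footprint (spacer + PAM by default;
  spacer-only is available because a PAM-disrupting variant also abolishes
  cutting, while some users prefer the narrower definition) and a SNP with
  minor allele frequency **strictly greater than 0.05**, or — only when
  somatic avoidance is requested — a somatic mutation locus;
* **strictly more than 40%** guanines in the spacer (9/20 fails, 8/20
  passes), a composition associated with elevated off-target activity;
* efficiency **strictly below 0** (0.0 passes), or unscorable;
* at least one perfect-match off-target.

Candidates whose *only* defect is the perfect-match off-target form the
rescue pool; variant-overlapping or G-rich candidates are never rescued.
The rule order is immaterial — the rules are independent predicates.

## CRITIC weighting and the summary score

The four criteria are on incommensurate scales and their informativeness
varies gene by gene (for many genes every candidate has specificity 100,
say). Rather than fixed weights, the package uses CRITIC: min-max
normalize each criterion column over the gene's candidates, then give
criterion *j* the weight

> `w_j = C_j / sum(C)`, with `C_j = sigma_j * sum_k (1 - r_jk)`

where `sigma_j` is the sample standard deviation of the normalized column
(contrast intensity) and `r_jk` the Pearson correlation between normalized
columns (so `1 - r` measures conflict: a criterion duplicating another
transmits less independent information). A constant column normalizes to
all zeros and gets zero weight; any correlation undefined because of a
zero-variance column is set to 0. With fewer than 3 candidates correlation
is meaningless and the weights fall back to uniform (0.25 each), as they
do when every `C_j` is 0. The conflict aggregation is the sum form of the
original CRITIC formulation by default; a multiplicative variant
`prod(1 - r)` is selectable via `conflict = "product"` since both readings
of "aggregation of one minus correlation" exist in the literature.
Normalizing before computing `sigma` makes the weights invariant under
affine rescaling of any raw criterion — a property the test suite checks.

Candidates are ranked by `S_i = sum_j w_j * normalized_ij` (normalized
values, so the weighted sum is scale-free), descending, with ties broken
by ascending (chromosome, start, strand) for full determinism.

## Rescue

When fewer candidates pass than requested, the rescue pool is drawn down
in increasing order of off-target severity: first candidates whose perfect
hits are all non-exonic, then those hitting exons of non-coding genes,
last those hitting coding exons (a gene with both coding and non-coding
transcripts counts as coding — the conservative reading). Within a
category, fewer perfect hits win; ties go to the higher summary score,
then to genomic coordinate. When a rescue is needed, one pooled criteria
matrix over passed + rescuable candidates supplies the weights and scores
for *both* phases, so every reported score for that gene is on a single
scale. Only the rescued candidates strictly need pooled weights for their
ordering; extending the same matrix to the passed candidates keeps the
output table coherent.

# The synthetic study system

`generateFixture()` builds the conditions the whole test suite and the
acceptance script run under, as a pure function of one seed: three
chromosomes (14 kb, 14 kb, 6 kb) of uniform random sequence; five queried
coding genes with 2–4 isoforms assembled from four 90-bp exon slots
(60-bp introns) whose per-exon usage fractions span 1/4 to 1; a
single-transcript non-coding gene and a non-queried coding decoy on chr2
as off-target landing sites. Into this it plants, deterministically:
three exact protospacer+PAM copies of otherwise-clean candidates — one
into intergenic chr3, one into the non-coding gene's exon, one into the
decoy's coding exon — giving one ground-truth rescue candidate of each
category; SNPs at allele frequencies 0.2 (above the 0.05 floor, inside
one candidate's spacer) and 0.01 (below it, inside another's); a somatic
locus inside a third; and a piecewise-constant conservation track (500-bp
blocks cycling 0, 0.25, 0.5, 0.75, 1). A truth table records each planted
event and its expected pipeline outcome.

What the fixture does **not** emulate: real genomes' repeat structure and
base composition (uniform random 20-mers are essentially always unique, so
near-miss off-targets at 1–3 mismatches are rare rather than pervasive),
real exon length and isoform diversity distributions, genome-scale N runs,
and trained efficiency coefficients. Passing tests therefore demonstrate
the correctness of the rules, scores and orderings — not the biological
quality of designs on a real genome, which depends on the user's inputs
(genome, annotation, variant and conservation tracks, trained model).

The default problem sizes — ~34 kb of genome, 50–60 candidates per gene,
a 3-mismatch exhaustive search, 100 random 5-kb sequences for the scanner
oracle and 200 random 5×4 matrices for the weighting oracle — were chosen
as the smallest scale at which every code path (both strands, every filter
reason, every rescue category, degenerate weight fall-backs) is exercised.

# Numerical and interface choices

* Internal coordinates are 1-based closed `GRanges`/`IRanges` throughout,
  the Bioconductor convention; GFF3/VCF (1-based) and BED/bedGraph
  (0-based half-open) are converted once, at the parse boundary, by
  rtracklayer and VariantAnnotation.
* Candidates whose spacer contains N (assembly gaps) are dropped silently;
  N in a *potential off-target window* counts as a mismatch.
* Exon overlap for candidate collection is defined on the protospacer
  interval — the PAM may hang outside the exon.
* The VCF allele-frequency INFO key defaults to `AF` and is configurable,
  since dbSNP-derived files vary; records lacking the key are skipped with
  a warning rather than failing the batch.
* BED12 carries no gene grouping, so `name` fields of the form
  `GENE:TX` are split into gene and transcript identifiers; otherwise the
  name serves as both. A transcript is coding when `thickStart <
  thickEnd` (BED12) or when it has CDS features (GFF3).
* Gene identifiers resolve case-insensitively, by gene symbol first and
  transcript identifier second; unresolvable identifiers warn and are
  skipped so one typo cannot fail a 1000-gene batch.
* Every weight vector, score and file output is deterministic given the
  inputs; the library TSV is written with fixed 4-decimal formatting and
  LF endings so repeated runs are byte-identical.

# Known limitations

* Off-target search is exhaustive and scales linearly with genome size;
  it is meant for the focused-screen setting with desk-scale genomes or
  pre-restricted regions, not for whole-mammalian-genome scans in bulk.
* No RNA/DNA bulge off-target models, no chromatin-accessibility
  weighting, and no training of efficiency models — the efficiency scorer
  evaluates whatever positional-linear coefficients it is given.
* The shipped control-guide lists are synthetic placeholders; the shipped
  U6 promoter and SpCas9 scaffold are the standard public sequences, and
  all three are meant to be replaced from the user's validated stocks.
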