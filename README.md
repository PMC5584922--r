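# guidescreen

Batch sgRNA library design for **focused CRISPR knockout screens**: screens
that target a curated gene set (up to 1000 genes, up to 30 guides per gene)
rather than the whole genome. Given a reference genome (FASTA), gene models
with isoforms (GFF3 or BED12) and a gene list, the package discovers every
candidate protospacer with a canonical SpCas9 NGG PAM over the genes' exons,
annotates each candidate with five classes of evidence, and selects and
ranks guides per gene by a filter-and-rescue procedure, emitting a
synthesis-ready oligo table with negative and positive control guides.

It is aimed at screen designers who want the whole batch pipeline —
candidate discovery, scoring, variant avoidance, multi-criteria ranking and
oligo assembly — as composable R functions over Bioconductor data
structures (`GRanges`, `DNAStringSet`), plus a command-line wrapper.

## The method

Each candidate guide is scored on four criteria:

* **Efficiency** — predicted on-target cleavage activity from a
  positional-linear model over the spacer and its flanking context
  (the functional form of LASSO-derived sequence models; coefficients are
  pluggable from a TSV, and a synthetic example model ships with the
  package). Candidates scoring below zero are filtered.
* **Specificity** — a 0–100 Hsu-style aggregate over putative off-target
  loci (up to 3 mismatches, NGG-gated, both strands). Each off-target hit
  `h` with mismatch position set `p` (n = |p|, mean pairwise distance
  `dbar`, per-position penalty `W`) contributes
  `s_h = prod(1 - W[p]) / ((((19 - dbar)/19) * 4 + 1) * n^2)`,
  and the score is `100 / (1 + sum_h s_h)` — 100 means no off-targets, a
  single perfect-match off-target gives 50.
* **Conservation** — mean per-base phastCons-style score over the
  protospacer, from a user bedGraph track (uncovered bases count 0).
* **Isoform commonality** — the fraction of the gene's transcripts whose
  exons contain the guide's cut site (3 bp 5' of the PAM), so guides in
  exons shared by all isoforms are preferred.

**Filter and rescue.** Hard filters remove candidates that overlap a common
SNP (minor allele frequency strictly above 0.05) or, optionally, a somatic
mutation locus; contain strictly more than 40% guanines; score below zero
efficiency; or have a perfect-match off-target. Survivors are ranked by a
summary score `S_i = sum_j w_j * normalized_ij`, where the weights come from
the **CRITIC** method (Criteria Importance Through Intercriteria
Correlation): each criterion's weight is proportional to
`C_j = sigma_j * sum_k (1 - r_jk)` — its contrast intensity (standard
deviation of the min-max-normalized column) times its conflict with the
other criteria — normalized to sum to 1. If too few candidates survive,
guides whose only defect is a perfect-match off-target are *rescued*,
drawing first from candidates whose off-targets are non-exonic, then those
hitting non-coding exons, last coding exons; within a category fewer hits
win, then higher summary score.

## Worked example

No downloads are needed: the package generates a complete synthetic study
system (three chromosomes, five queried multi-isoform coding genes, a
non-coding gene and a decoy coding gene as off-target landing sites,
planted SNPs straddling the 0.05 frequency cutoff, a somatic locus and a
blockwise conservation track).

```r
library(guidescreen)

fx  <- generateFixture(syntheticSpec(seed = 1), "fixture")
req <- validateRequest(c("GENE1", "GENE2"), n_per_gene = 3,
                       genome = fx$genome, annotation = fx$annotation,
                       snps = fx$snps, somatic = fx$somatic,
                       conservation = fx$conservation, use_somatic = TRUE)
res <- runDesign(req, "library.tsv")
res$rows[, c("gene_id", "rank", "spacer", "efficiency", "specificity",
             "conservation", "commonality", "summary_score", "status")]
```

The per-gene log lines and the returned table look like this:

```
[GENE1] candidates=53 passed=51 filtered=1 rescuable=1 selected=3
[GENE2] candidates=57 passed=52 filtered=4 rescuable=1 selected=3
 gene_id rank               spacer efficiency specificity conservation commonality summary_score status
   GENE1    1 TTCCAAGTAGGCCGCTCCGC      0.335         100       0.7000           1     0.9024410 PASSED
   GENE1    2 AGTGACGGAACGAGTCTTGA      0.265         100       0.7500           1     0.8929986 PASSED
   GENE1    3 GTGACGGAACGAGTCTTGAA      0.265         100       0.7500           1     0.8929986 PASSED
   GENE2    1 CAGGGACCGCTCCGGGTAGC      0.405         100       0.7375           1     0.8876528 PASSED
   GENE2    2 TCAGGGACCGCTCCGGGTAG      0.370         100       0.7500           1     0.8576686 PASSED
   GENE2    3 CGCTAGCCCGCTACCCGGAG      0.405         100       0.6250           1     0.8395040 PASSED
```

Each row is one selected guide: its genomic protospacer, the four raw
criterion values, the CRITIC-weighted summary score it was ranked by, and
its provenance (`PASSED` through every filter, or `RESCUED_<category>`).
For GENE1 the CRITIC weights were 0.2497 / 0 / 0.3095 / 0.4409 for
efficiency / specificity / conservation / commonality — specificity got no
weight because every surviving candidate scored a constant 100, so that
criterion transmitted no information for this gene. `library.tsv` holds the
same table (floats at 4 decimals, byte-stable across runs), with control
rows appended when `add_controls` is set and an `oligo` column
(U6 promoter + spacer + scaffold) when `append_construct` is set.

A command-line wrapper over the same functions ships at
`system.file("scripts", "sgdesign.R", package = "guidescreen")` with
`design` and `makefixture` subcommands.

### Coefficient and penalty files

* Efficiency model TSV: a header line `#intercept<TAB>value`, then
  `position` (1 = first context base; the spacer starts at position 11),
  `nucleotide`, `weight`. See
  `inst/extdata/efficiency_model_synthetic.tsv` (synthetic example
  coefficients, not trained on cleavage data).
* Specificity penalty TSV: `position` (1 = PAM-distal), `weight` in
  \[0, 1\]; the shipped `inst/extdata/hsu2013_mismatch_penalties.tsv` is the
  published Hsu et al. 2013 matrix.
* Control lists: `name<TAB>spacer`; shipped negative/positive sets are
  synthetic placeholders (`controls_*_synthetic.tsv`) meant to be replaced
  with lab-validated safe-harbor and essential-gene guides.

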