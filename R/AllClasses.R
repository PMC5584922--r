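#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<- Rle
#'   split queryHits subjectHits
#' @importFrom BiocGenerics start end width strand sort unlist
#'   start<- end<- strand<-
#' @importFrom GenomicRanges GRanges seqnames findOverlaps countOverlaps
#'   reduce granges GRangesList coverage
#' @importFrom IRanges IRanges overlapsAny subsetByOverlaps IntegerList
#'   restrict pintersect
#' @importFrom GenomeInfoDb seqlevels seqlengths seqinfo Seqinfo
#' @importFrom SummarizedExperiment rowRanges
#' @importFrom Biostrings DNAString DNAStringSet readBStringSet
#'   writeXStringSet reverseComplement matchPattern mismatch subseq
#'   letterFrequency
#' @importFrom stats setNames sd cor dist
#' @importFrom utils read.table write.table head
NULL

## ---------------------------------------------------------------------------
## ReferenceAssembly
## ---------------------------------------------------------------------------

#' Reference genome assembly
#'
#' Holds the genome as a named [Biostrings::DNAStringSet] restricted to the
#' alphabet A, C, G, T, N (uppercased on load). All annotation readers
#' validate their chromosome names against this object.
#'
#' @slot sequences A named `DNAStringSet`, one entry per chromosome.
#'
#' @seealso [readGenome()], [refLengths()], [getRefSeq()]
#' @export
setClass("ReferenceAssembly", representation(sequences = "DNAStringSet"))

setValidity("ReferenceAssembly", function(object) {
    seqs <- object@sequences
    if (length(seqs) == 0L) return("assembly holds no sequences")
    if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
        return("chromosome names must be present and unique")
    bad <- Biostrings::alphabetFrequency(seqs, baseOnly = TRUE)[, "other"]
    nN <- Biostrings::letterFrequency(seqs, "N")
    if (any(bad - nN > 0))
        return("sequences contain letters outside {A,C,G,T,N}")
    TRUE
})

#' @describeIn ReferenceAssembly Named integer vector of chromosome lengths.
#' @param asm A `ReferenceAssembly`.
#' @export
refLengths <- function(asm) {
    stats::setNames(Biostrings::width(asm@sequences), names(asm@sequences))
}

#' @describeIn ReferenceAssembly The genome as a `DNAStringSet`.
#' @export
refSequences <- function(asm) asm@sequences

setMethod("show", "ReferenceAssembly", function(object) {
    len <- refLengths(object)
    cat("ReferenceAssembly with", length(len), "sequence(s),",
        sum(as.numeric(len)), "bp total\n")
    show(utils::head(len, 10))
})

## ---------------------------------------------------------------------------
## GeneModels
## ---------------------------------------------------------------------------

#' Gene models with isoform structure
#'
#' Container for exon structures of multi-isoform genes, keyed by gene
#' identifier and by transcript identifier.
#'
#' @slot exons A `GRanges` of exons with metadata columns `transcript_id`
#'   and `gene_id`; 1-based closed coordinates on the assembly.
#' @slot txInfo A `DataFrame` with one row per transcript: `transcript_id`,
#'   `gene_id`, `chrom`, `strand`, `coding` (logical; TRUE when the
#'   transcript carries CDS).
#'
#' @seealso [readGeneModels()], [geneIds()], [exonUnion()], [geneSpan()]
#' @export
setClass("GeneModels",
         representation(exons = "GRanges", txInfo = "DataFrame"))

setValidity("GeneModels", function(object) {
    need <- c("transcript_id", "gene_id")
    if (!all(need %in% colnames(mcols(object@exons))))
        return("exons must carry transcript_id and gene_id")
    ti <- object@txInfo
    need <- c("transcript_id", "gene_id", "chrom", "strand", "coding")
    if (!all(need %in% colnames(ti)))
        return("txInfo missing required columns")
    if (!all(object@exons$transcript_id %in% ti$transcript_id))
        return("exon transcript_id absent from txInfo")
    if (!all(ti$transcript_id %in% object@exons$transcript_id))
        return("transcript without exons")
    TRUE
})

#' @describeIn GeneModels Gene identifiers, in file order.
#' @param models A `GeneModels` object.
#' @export
geneIds <- function(models) unique(models@txInfo$gene_id)

#' @describeIn GeneModels Transcript table (`DataFrame`) for one gene, or all
#'   genes when `gene_id` is missing.
#' @param gene_id A single gene identifier.
#' @export
transcriptInfo <- function(models, gene_id) {
    if (missing(gene_id)) return(models@txInfo)
    models@txInfo[models@txInfo$gene_id == gene_id, , drop = FALSE]
}

#' @describeIn GeneModels All exons (`GRanges`) of the set, or of one gene.
#' @export
geneExons <- function(models, gene_id) {
    if (missing(gene_id)) return(models@exons)
    models@exons[models@exons$gene_id == gene_id]
}

#' @describeIn GeneModels Reduced union of all exons of a gene (`GRanges`,
#'   unstranded).
#' @export
exonUnion <- function(models, gene_id) {
    ex <- geneExons(models, gene_id)
    if (length(ex) == 0L) return(GRanges())
    reduce(granges(ex), ignore.strand = TRUE)
}

#' @describeIn GeneModels Single covering interval of a gene (`GRanges`).
#' @export
geneSpan <- function(models, gene_id) {
    u <- exonUnion(models, gene_id)
    if (length(u) == 0L) return(GRanges())
    GRanges(seqnames(u)[1], IRanges(min(start(u)), max(end(u))))
}

#' @describeIn GeneModels TRUE when at least one transcript of the gene
#'   carries CDS.
#' @export
isCodingGene <- function(models, gene_id) {
    any(transcriptInfo(models, gene_id)$coding)
}

#' @describeIn GeneModels Per-transcript exon `GRangesList` (reduced) for one
#'   gene.
#' @export
transcriptExons <- function(models, gene_id) {
    ex <- geneExons(models, gene_id)
    lst <- split(granges(ex), ex$transcript_id)
    GRangesList(lapply(lst, reduce))
}

setMethod("show", "GeneModels", function(object) {
    cat("GeneModels:", length(geneIds(object)), "gene(s),",
        nrow(object@txInfo), "transcript(s),",
        length(object@exons), "exon record(s)\n")
})

## ---------------------------------------------------------------------------
## GuideSet
## ---------------------------------------------------------------------------

#' A set of sgRNA candidates
#'
#' A `GRanges` subclass in which each range is the genomic protospacer
#' interval of one candidate (1-based closed, reference-strand coordinates;
#' the `strand` is the protospacer strand). Metadata columns hold the spacer
#' and PAM sequences, the predicted cut site, the sequence context used by
#' efficiency models, the four ranking criteria, variant and off-target
#' annotations, and the selection status.
#'
#' Criterion columns start as `NA` and are populated by [scoreEfficiency()],
#' [annotateOfftargets()], [annotateConservation()] and [annotateVariants()];
#' `commonality` is attached by [collectGeneCandidates()].
#'
#' @seealso [scanPamSites()], [collectGeneCandidates()]
#' @export
setClass("GuideSet", contains = "GRanges")

.guide_mcols <- c("gene_id", "spacer", "pam", "cut_site", "context",
                  "efficiency", "specificity", "conservation", "commonality",
                  "guanine_fraction", "n_snp_hits", "n_somatic_hits",
                  "n_perfect_offtargets", "offtarget_category", "status")

setValidity("GuideSet", function(object) {
    mc <- mcols(object)
    if (!all(.guide_mcols %in% colnames(mc)))
        return(paste("missing metadata column(s):",
                     paste(setdiff(.guide_mcols, colnames(mc)),
                           collapse = ", ")))
    if (length(object) == 0L) return(TRUE)
    if (any(substr(mc$pam, 2L, 3L) != "GG"))
        return("all PAMs must match NGG on the protospacer strand")
    if (any(mc$cut_site < start(object) | mc$cut_site > end(object)))
        return("cut_site must lie inside the protospacer interval")
    if (any(nchar(mc$spacer) != width(object)))
        return("spacer length must equal protospacer width")
    TRUE
})

newGuideSet <- function(gr = GRanges(), gene_id = character(length(gr)),
                        spacer = character(length(gr)),
                        pam = character(length(gr)),
                        cut_site = integer(length(gr)),
                        context = rep(NA_character_, length(gr))) {
    n <- length(gr)
    mcols(gr) <- DataFrame(
        gene_id = gene_id, spacer = spacer, pam = pam,
        cut_site = as.integer(cut_site), context = context,
        efficiency = rep(NA_real_, n), specificity = rep(NA_real_, n),
        conservation = rep(NA_real_, n), commonality = rep(NA_real_, n),
        guanine_fraction = if (n) .g_fraction(spacer) else numeric(0),
        n_snp_hits = rep(NA_integer_, n),
        n_somatic_hits = rep(NA_integer_, n),
        n_perfect_offtargets = rep(NA_integer_, n),
        offtarget_category = rep(NA_character_, n),
        status = rep("CANDIDATE", n))
    methods::new("GuideSet", gr)
}

.g_fraction <- function(spacer) {
    vapply(strsplit(spacer, ""), function(x) mean(x == "G"), numeric(1))
}

setMethod("show", "GuideSet", function(object) {
    cat("GuideSet with", length(object), "candidate(s)\n")
    methods::callNextMethod()
})

## ---------------------------------------------------------------------------
## EfficiencyModel
## ---------------------------------------------------------------------------

#' Positional-linear cleavage-efficiency model
#'
#' A pluggable scorer of the LASSO family: the score of a candidate is the
#' intercept plus the sum of per-(position, nucleotide) weights over its
#' sequence context (5' flank + spacer + 3' flank, the 3' flank covering the
#' PAM). Coefficients are loaded from a TSV file; any coefficient set of this
#' functional form can be used.
#'
#' @slot spacer_len Spacer length the model was built for (19 or 20).
#' @slot flank5,flank3 Number of context bases on each side of the spacer.
#' @slot intercept Model intercept.
#' @slot weights Numeric matrix `window x 4` with columns A, C, G, T; row
#'   `i` is context position `i` (1 = first context base). Absent
#'   coefficients are 0.
#'
#' @seealso [readEfficiencyModel()], [scoreEfficiency()]
#' @export
setClass("EfficiencyModel",
         representation(spacer_len = "integer", flank5 = "integer",
                        flank3 = "integer", intercept = "numeric",
                        weights = "matrix"))

setValidity("EfficiencyModel", function(object) {
    win <- object@flank5 + object@spacer_len + object@flank3
    if (!identical(dim(object@weights), c(as.integer(win), 4L)))
        return("weights must be (flank5 + spacer_len + flank3) x 4")
    if (!identical(colnames(object@weights), c("A", "C", "G", "T")))
        return("weight columns must be A, C, G, T")
    if (!(object@spacer_len %in% c(19L, 20L)))
        return("spacer_len must be 19 or 20")
    TRUE
})

setMethod("show", "EfficiencyModel", function(object) {
    cat(sprintf(
        "EfficiencyModel: %d-nt spacer, flanks %d/%d, intercept %.4g, %d non-zero weight(s)\n",
        object@spacer_len, object@flank5, object@flank3, object@intercept,
        sum(object@weights != 0)))
})

## ---------------------------------------------------------------------------
## SpecificityPenalty
## ---------------------------------------------------------------------------

#' Per-position mismatch penalty table for specificity scoring
#'
#' Hsu-style experimentally derived mismatch weights, one per spacer
#' position ordered PAM-distal to PAM-proximal. Shipped as an editable TSV
#' so alternative penalty tables can be swapped in.
#'
#' @slot weights Numeric vector of length equal to the spacer length, each
#'   in \[0, 1\].
#'
#' @seealso [readSpecificityPenalty()], [specificityScore()]
#' @export
setClass("SpecificityPenalty", representation(weights = "numeric"))

setValidity("SpecificityPenalty", function(object) {
    w <- object@weights
    if (length(w) < 1L) return("empty weight vector")
    if (any(w < 0 | w > 1)) return("weights must lie in [0, 1]")
    TRUE
})

setMethod("show", "SpecificityPenalty", function(object) {
    cat("SpecificityPenalty over", length(object@weights), "positions\n")
})

## ---------------------------------------------------------------------------
## CriteriaMatrix
## ---------------------------------------------------------------------------

#' Per-gene criteria matrix with CRITIC weights
#'
#' Candidates x 4 criteria (efficiency, specificity, conservation,
#' commonality) together with every intermediate of the CRITIC weighting:
#' min-max normalized columns, their standard deviations (contrast
#' intensity), the Pearson correlation matrix (conflict), the information
#' amounts `C_j` and the final weight vector.
#'
#' @slot gene_id Gene the matrix belongs to.
#' @slot candidate_ids Candidate identifiers (row names of `raw`).
#' @slot raw,normalized Numeric matrices, candidates x 4.
#' @slot sigma,infoC,weights Numeric 4-vectors.
#' @slot corr Numeric 4 x 4 matrix.
#' @slot conflict `"sum"` or `"product"` aggregation of `(1 - r)`.
#'
#' @seealso [buildCriteriaMatrix()], [criticWeights()], [summaryScores()]
#' @export
setClass("CriteriaMatrix",
         representation(gene_id = "character", candidate_ids = "character",
                        raw = "matrix", normalized = "matrix",
                        sigma = "numeric", corr = "matrix", infoC = "numeric",
                        weights = "numeric", conflict = "character"))

setValidity("CriteriaMatrix", function(object) {
    if (ncol(object@raw) != 4L) return("raw must have 4 criterion columns")
    if (!identical(dim(object@raw), dim(object@normalized)))
        return("raw and normalized differ in shape")
    if (nrow(object@raw) != length(object@candidate_ids))
        return("candidate_ids length != rows of raw")
    w <- object@weights
    if (length(w) == 4L &&
        (any(w < -1e-9) || abs(sum(w) - 1) > 1e-9))
        return("weights must be non-negative and sum to 1")
    TRUE
})

#' @describeIn CriteriaMatrix The CRITIC weight 4-vector
#'   (efficiency, specificity, conservation, commonality).
#' @param x A `CriteriaMatrix`.
#' @export
criteriaWeights <- function(x) x@weights

setMethod("show", "CriteriaMatrix", function(object) {
    cat(sprintf("CriteriaMatrix for %s: %d candidate(s); weights = %s\n",
                object@gene_id, nrow(object@raw),
                paste(sprintf("%.3f", object@weights), collapse = " ")))
})

## ---------------------------------------------------------------------------
## FilterReport
## ---------------------------------------------------------------------------

#' Outcome of the hard-filter step for one gene
#'
#' Partitions the scored candidates of a gene into those passing every
#' filter, those removed outright, and the rescue pool (candidates whose
#' only defect is a perfect-match off-target, partitioned by the worst
#' category among their perfect hits). Every input candidate appears in
#' exactly one partition.
#'
#' @slot gene_id Gene identifier.
#' @slot passed,filtered,rescuePool `GuideSet`s; `filtered` carries a
#'   `reasons` metadata column, `rescuePool` a `rescue_category` column.
#' @slot n_input Number of candidates before filtering.
#'
#' @seealso [filterCandidates()], [rescueGuides()]
#' @export
setClass("FilterReport",
         representation(gene_id = "character", passed = "GuideSet",
                        filtered = "GuideSet", rescuePool = "GuideSet",
                        n_input = "integer"))

setValidity("FilterReport", function(object) {
    n <- length(object@passed) + length(object@filtered) +
        length(object@rescuePool)
    if (n != object@n_input)
        return("partitions do not cover the input exactly")
    TRUE
})

#' @describeIn FilterReport Candidates passing every filter (`GuideSet`).
#' @param report A `FilterReport`.
#' @export
passedGuides <- function(report) report@passed

#' @describeIn FilterReport Candidates removed outright, with a `reasons`
#'   metadata column.
#' @export
filteredGuides <- function(report) report@filtered

#' @describeIn FilterReport Rescue pool with `rescue_category` metadata.
#' @export
rescuePool <- function(report) report@rescuePool

setMethod("show", "FilterReport", function(object) {
    cat(sprintf(
        "FilterReport for %s: %d in -> %d passed, %d filtered, %d rescuable\n",
        object@gene_id, object@n_input, length(object@passed),
        length(object@filtered), length(object@rescuePool)))
})

## Off-target category severity ordering, least to most severe.
.OT_LEVELS <- c("NON_EXON", "EXON_NONCODING", "CODING")
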