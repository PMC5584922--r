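## Discovery of spacer+PAM occurrences and the isoform-commonality
## criterion.

#' Scan a region for canonical PAM sites
#'
#' Finds every occurrence of `[N x spacer_len]NGG` on either strand whose
#' protospacer interval overlaps the query region. The SpCas9 blunt cut site
#' is placed 3 bp 5' of the PAM (between bases 17 and 18 of a 20-mer
#' protospacer). Spacers containing N are dropped; sequence context (spacer
#' plus `flank` bases on each side, the 3' side covering the PAM) is
#' recorded for efficiency models and set to `NA` when truncated at a
#' chromosome end. Candidates are deduplicated on
#' (chromosome, strand, interval).
#'
#' @param asm A [ReferenceAssembly-class].
#' @param region `GRanges` of regions to scan (strand ignored); must lie
#'   within the assembly.
#' @param spacer_len Spacer length, 19 or 20.
#' @param flank Context flank on each side of the spacer (default 10).
#' @return A [GuideSet-class] (criterion columns unset), sorted by
#'   (chromosome, start, strand).
#' @export
scanPamSites <- function(asm, region, spacer_len = 20L, flank = 10L) {
    spacer_len <- as.integer(spacer_len)
    if (!spacer_len %in% c(19L, 20L)) stop("spacer_len must be 19 or 20")
    len <- refLengths(asm)
    chr <- as.character(seqnames(region))
    if (!all(chr %in% names(len)))
        stop("region on unknown chromosome(s): ",
             paste(setdiff(unique(chr), names(len)), collapse = ", "))
    if (any(start(region) < 1L | end(region) > len[chr]))
        stop("region outside chromosome bounds")

    parts <- lapply(unique(chr), function(cn) {
        sub <- region[chr == cn]
        .scan_chrom(asm, cn, sub, spacer_len, flank)
    })
    gs <- do.call(rbind, parts)
    if (is.null(gs) || nrow(gs) == 0L) return(newGuideSet())
    gs <- gs[!duplicated(gs[c("chrom", "strand", "start")]), , drop = FALSE]
    ord <- order(gs$chrom, gs$start, gs$strand)
    gs <- gs[ord, , drop = FALSE]
    gr <- GRanges(gs$chrom, IRanges(gs$start, gs$end), strand = gs$strand,
                  seqlengths = len)
    newGuideSet(gr, gene_id = rep(NA_character_, nrow(gs)),
                spacer = gs$spacer, pam = gs$pam, cut_site = gs$cut,
                context = gs$context)
}

## One chromosome: locate GG (plus) / CC (minus) dinucleotides and derive
## protospacer windows. Returns a plain data.frame for cheap rbind.
.scan_chrom <- function(asm, chrom, region, spacer_len, flank) {
    seqlen <- refLengths(asm)[[chrom]]
    chs <- asm@sequences[[chrom]]
    rows <- list()

    gg <- start(matchPattern("GG", chs))            # plus strand: PAM = N|GG
    if (length(gg)) {
        pam_start <- gg - 1L
        sp_start <- pam_start - spacer_len
        keep <- sp_start >= 1L & pam_start >= 1L
        sp_start <- sp_start[keep]; pam_start <- pam_start[keep]
        if (length(sp_start)) {
            iv <- IRanges(sp_start, width = spacer_len)
            hit <- overlapsAny(iv, IRanges::ranges(region))
            sp_start <- sp_start[hit]; pam_start <- pam_start[hit]
            if (length(sp_start))
                rows[["+"]] <- .mk_rows(chs, chrom, seqlen, sp_start,
                                        pam_start, "+", spacer_len, flank)
        }
    }
    cc <- start(matchPattern("CC", chs))            # minus strand: CC|N
    if (length(cc)) {
        pam_start <- cc                              # genomic CCN
        sp_start <- cc + 3L
        keep <- sp_start + spacer_len - 1L <= seqlen
        sp_start <- sp_start[keep]; pam_start <- pam_start[keep]
        if (length(sp_start)) {
            iv <- IRanges(sp_start, width = spacer_len)
            hit <- overlapsAny(iv, IRanges::ranges(region))
            sp_start <- sp_start[hit]; pam_start <- pam_start[hit]
            if (length(sp_start))
                rows[["-"]] <- .mk_rows(chs, chrom, seqlen, sp_start,
                                        pam_start, "-", spacer_len, flank)
        }
    }
    if (length(rows)) do.call(rbind, rows) else NULL
}

.mk_rows <- function(chs, chrom, seqlen, sp_start, pam_start, strand,
                     spacer_len, flank) {
    sp_end <- sp_start + spacer_len - 1L
    sp_seq <- as.character(Biostrings::extractAt(
        chs, IRanges(sp_start, sp_end)))
    pam_seq <- as.character(Biostrings::extractAt(
        chs, IRanges(pam_start, pam_start + 2L)))
    if (strand == "-") {
        sp_seq <- as.character(reverseComplement(DNAStringSet(sp_seq)))
        pam_seq <- as.character(reverseComplement(DNAStringSet(pam_seq)))
        cut <- sp_start + 2L
    } else {
        cut <- sp_end - 2L
    }
    keep <- !grepl("N", sp_seq, fixed = TRUE)
    if (!any(keep)) return(NULL)
    sp_start <- sp_start[keep]; sp_end <- sp_end[keep]
    sp_seq <- sp_seq[keep]; pam_seq <- pam_seq[keep]; cut <- cut[keep]

    cx_start <- sp_start - flank
    cx_end <- sp_end + flank
    ok <- cx_start >= 1L & cx_end <= seqlen
    context <- rep(NA_character_, length(sp_start))
    if (any(ok)) {
        cx <- as.character(Biostrings::extractAt(
            chs, IRanges(cx_start[ok], cx_end[ok])))
        if (strand == "-")
            cx <- as.character(reverseComplement(DNAStringSet(cx)))
        cx[grepl("N", cx, fixed = TRUE)] <- NA_character_
        context[ok] <- cx
    }
    data.frame(chrom = chrom, start = sp_start, end = sp_end,
               strand = strand, spacer = sp_seq, pam = pam_seq,
               cut = cut, context = context, stringsAsFactors = FALSE)
}

#' Collect all sgRNA candidates of a gene
#'
#' Scans the reduced exon union of the gene for PAM sites (candidate overlap
#' is defined on the protospacer interval; the PAM may lie outside the
#' exon), deduplicates, tags candidates with the gene identifier and
#' attaches the isoform-commonality criterion.
#'
#' @inheritParams scanPamSites
#' @param gene_id Gene identifier present in `models`.
#' @param models A [GeneModels-class].
#' @return A [GuideSet-class] with `gene_id` and `commonality` populated.
#'   Empty, with a warning, when the gene has no exons in the assembly.
#' @export
collectGeneCandidates <- function(gene_id, models, asm, spacer_len = 20L,
                                  flank = 10L) {
    u <- exonUnion(models, gene_id)
    if (length(u) == 0L) {
        warning("gene '", gene_id, "' has no exons; no candidates")
        return(newGuideSet())
    }
    guides <- scanPamSites(asm, u, spacer_len = spacer_len, flank = flank)
    if (length(guides) == 0L) return(guides)
    guides$gene_id <- gene_id
    guides$commonality <- isoformCommonality(models, gene_id, guides)
    guides
}

#' Isoform commonality of candidates
#'
#' Fraction of a gene's transcripts whose exons contain the candidate's cut
#' site. When the cut site lies in no exon but the protospacer overlaps one,
#' the maximum per-base transcript-usage fraction over the overlapped bases
#' is used instead, so the score is always in (0, 1] for candidates
#' overlapping the gene.
#'
#' @param models A [GeneModels-class].
#' @param gene_id Gene identifier.
#' @param guides A [GuideSet-class]; every candidate must overlap the gene's
#'   exon union.
#' @return Numeric vector in (0, 1].
#' @export
isoformCommonality <- function(models, gene_id, guides) {
    tx <- transcriptExons(models, gene_id)
    n_tx <- length(tx)
    if (n_tx == 0L) stop("gene '", gene_id, "' has no transcripts")
    u <- exonUnion(models, gene_id)
    if (!all(overlapsAny(granges(guides), u, ignore.strand = TRUE)))
        stop("candidate does not overlap gene '", gene_id, "'")
    cuts <- GRanges(seqnames(guides), IRanges(guides$cut_site,
                                              guides$cut_site))
    hit <- vapply(seq_len(n_tx), function(t)
        overlapsAny(cuts, tx[[t]], ignore.strand = TRUE), logical(length(guides)))
    hit <- matrix(hit, nrow = length(guides))
    score <- rowMeans(hit)

    miss <- score == 0
    if (any(miss)) {
        # per-base transcript usage over the protospacer, maximum taken
        score[miss] <- vapply(which(miss), function(i) {
            pos <- GRanges(seqnames(guides)[i],
                           IRanges(start(guides)[i]:end(guides)[i],
                                   width = 1L))
            cnt <- Reduce(`+`, lapply(seq_len(n_tx), function(t)
                as.integer(overlapsAny(pos, tx[[t]],
                                       ignore.strand = TRUE))))
            max(cnt) / n_tx
        }, numeric(1))
    }
    score
}
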