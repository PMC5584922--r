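## The four ranking criteria and the variant / off-target annotations.

## ---------------------------------------------------------------------------
## Efficiency
## ---------------------------------------------------------------------------

#' Read a positional-linear efficiency model from TSV
#'
#' File format: a header line `#intercept<TAB>value`, then three columns
#' `position` (integer, 1 = first context base), `nucleotide` (A/C/G/T) and
#' `weight`. Any (position, nucleotide) pair not listed has weight 0. The
#' context window is `flank5 + spacer_len + flank3` bases; listed positions
#' must lie inside it.
#'
#' The package ships a synthetic example model in
#' `system.file("extdata", "efficiency_model_synthetic.tsv",
#' package = "guidescreen")`.
#'
#' @param path Coefficient TSV.
#' @param spacer_len Spacer length the model applies to (19 or 20).
#' @param flank5,flank3 Context flank lengths (default 10/10, matching
#'   [scanPamSites()]).
#' @return An [EfficiencyModel-class].
#' @export
readEfficiencyModel <- function(path, spacer_len = 20L, flank5 = 10L,
                                flank3 = 10L) {
    lines <- readLines(path)
    ihdr <- grep("^#intercept\t", lines)
    if (length(ihdr) != 1L)
        stop("efficiency model lacks a '#intercept<TAB>value' header: ", path)
    intercept <- as.numeric(sub("^#intercept\t", "", lines[ihdr]))
    body <- lines[!startsWith(lines, "#")]
    body <- body[nzchar(body)]
    win <- as.integer(flank5 + spacer_len + flank3)
    w <- matrix(0, nrow = win, ncol = 4,
                dimnames = list(NULL, c("A", "C", "G", "T")))
    if (length(body)) {
        tab <- utils::read.table(text = body, sep = "\t",
                                 col.names = c("position", "nucleotide",
                                               "weight"))
        if (any(tab$position < 1L | tab$position > win))
            stop("coefficient position outside the context window")
        if (!all(tab$nucleotide %in% c("A", "C", "G", "T")))
            stop("coefficient nucleotide outside {A,C,G,T}")
        w[cbind(tab$position, match(tab$nucleotide, colnames(w)))] <-
            tab$weight
    }
    methods::new("EfficiencyModel", spacer_len = as.integer(spacer_len),
                 flank5 = as.integer(flank5), flank3 = as.integer(flank3),
                 intercept = intercept, weights = w)
}

#' Score predicted cleavage efficiency
#'
#' `score = intercept + sum over context positions of weight(position,
#' base)`. Candidates whose context is missing (truncated at a chromosome
#' end) or does not match the model window are unscorable and get `NA`;
#' the filter step removes them.
#'
#' @param guides A [GuideSet-class] with `context` populated.
#' @param model An [EfficiencyModel-class].
#' @return The `GuideSet` with the `efficiency` column filled.
#' @export
scoreEfficiency <- function(guides, model) {
    if (length(guides) == 0L) return(guides)
    win <- nrow(model@weights)
    ctx <- guides$context
    ok <- !is.na(ctx) & nchar(ctx) == win
    eff <- rep(NA_real_, length(guides))
    if (any(ok)) {
        mat <- do.call(rbind, strsplit(ctx[ok], ""))
        contrib <- matrix(0, nrow = nrow(mat), ncol = win)
        for (nt in colnames(model@weights)) {
            hitmat <- mat == nt
            contrib <- contrib + sweep(hitmat, 2, model@weights[, nt], `*`)
        }
        eff[ok] <- model@intercept + rowSums(contrib)
    }
    guides$efficiency <- eff
    guides
}

## ---------------------------------------------------------------------------
## Off-targets and specificity
## ---------------------------------------------------------------------------

#' Read a per-position mismatch penalty table
#'
#' TSV with columns `position` (1 = PAM-distal end) and `weight` in
#' \[0, 1\]. The shipped table
#' (`system.file("extdata", "hsu2013_mismatch_penalties.tsv",
#' package = "guidescreen")`) is the published 20-position Hsu et al. 2013
#' matrix; for a 19-nt spacer the PAM-distal entries are dropped so the
#' PAM-proximal positions keep their weights.
#'
#' @param path Penalty TSV.
#' @param spacer_len Spacer length in use.
#' @return A [SpecificityPenalty-class].
#' @export
readSpecificityPenalty <- function(path, spacer_len = 20L) {
    tab <- utils::read.table(path, header = TRUE, sep = "\t")
    if (!all(c("position", "weight") %in% colnames(tab)))
        stop("penalty file needs 'position' and 'weight' columns: ", path)
    w <- tab$weight[order(tab$position)]
    if (length(w) < spacer_len)
        stop("penalty table shorter than the spacer length")
    w <- w[(length(w) - spacer_len + 1L):length(w)]
    methods::new("SpecificityPenalty", weights = w)
}

#' Enumerate putative off-target loci of one candidate
#'
#' Exhaustively scans every chromosome on both strands for
#' `spacer_len`-mers followed by an NGG PAM that differ from the spacer at
#' `max_mismatch` or fewer positions. Hits within the queried gene's span
#' are tagged `ON_TARGET`; all others are categorized by exon overlap
#' (`CODING` > `EXON_NONCODING` > `NON_EXON`).
#'
#' @param spacer Spacer sequence (character, 5' to 3').
#' @param asm A [ReferenceAssembly-class].
#' @param max_mismatch Maximum mismatches (default 3).
#' @param index Optional exon region index from [buildRegionIndex()]; when
#'   `NULL` every non-on-target hit is categorized `NON_EXON`.
#' @param gene_span Optional `GRanges` giving the queried gene's span. When
#'   `NULL`, only an exact coordinate match with `self` marks `ON_TARGET`.
#' @param self Optional `GRanges` of the candidate's own protospacer, used
#'   when `gene_span` is absent.
#' @return A `GRanges` of protospacer hits with metadata columns
#'   `n_mismatch`, `mismatch_positions` (an `IntegerList` of spacer indices,
#'   PAM-distal = 0) and `category`.
#' @export
enumerateOfftargets <- function(spacer, asm, max_mismatch = 3L,
                                index = NULL, gene_span = NULL,
                                self = NULL) {
    if (max_mismatch < 0L) stop("max_mismatch must be >= 0")
    L <- nchar(spacer)
    pat_fwd <- DNAString(spacer)
    pat_rev <- reverseComplement(pat_fwd)
    len <- refLengths(asm)
    hits <- list()
    for (chrom in names(len)) {
        chs <- asm@sequences[[chrom]]
        m <- matchPattern(pat_fwd, chs, max.mismatch = max_mismatch)
        if (length(m)) {
            mm <- mismatch(pat_fwd, m)
            pam_ok <- end(m) + 3L <= len[[chrom]] &
                vapply(seq_along(m), function(i) {
                    p <- end(m)[i]
                    as.character(subseq(chs, p + 2L, p + 3L)) == "GG"
                }, logical(1))
            if (any(pam_ok)) {
                g <- GRanges(chrom, IRanges(start(m)[pam_ok],
                                            end(m)[pam_ok]), strand = "+",
                             seqlengths = len)
                g$n_mismatch <- lengths(mm)[pam_ok]
                g$mismatch_positions <- IntegerList(
                    lapply(mm[pam_ok], function(p) sort(p - 1L)))
                hits[[length(hits) + 1L]] <- g
            }
        }
        m <- matchPattern(pat_rev, chs, max.mismatch = max_mismatch)
        if (length(m)) {
            mm <- mismatch(pat_rev, m)
            pam_ok <- start(m) - 3L >= 1L &
                vapply(seq_along(m), function(i) {
                    p <- start(m)[i]
                    as.character(subseq(chs, p - 3L, p - 2L)) == "CC"
                }, logical(1))
            if (any(pam_ok)) {
                g <- GRanges(chrom, IRanges(start(m)[pam_ok],
                                            end(m)[pam_ok]), strand = "-",
                             seqlengths = len)
                g$n_mismatch <- lengths(mm)[pam_ok]
                # positions were relative to the reverse complement
                g$mismatch_positions <- IntegerList(
                    lapply(mm[pam_ok], function(p) sort(L - p)))
                hits[[length(hits) + 1L]] <- g
            }
        }
    }
    if (length(hits) == 0L) {
        out <- GRanges()
        out$n_mismatch <- integer(0)
        out$mismatch_positions <- IntegerList()
        out$category <- character(0)
        return(out)
    }
    out <- suppressWarnings(do.call(c, unname(hits)))
    cat_ <- if (is.null(index)) rep("NON_EXON", length(out))
            else classifyInterval(index, out)
    on <- if (!is.null(gene_span)) {
        overlapsAny(out, gene_span, ignore.strand = TRUE)
    } else if (!is.null(self)) {
        as.character(seqnames(out)) == as.character(seqnames(self)) &
            start(out) == start(self) &
            as.character(strand(out)) == as.character(strand(self))
    } else rep(FALSE, length(out))
    cat_[on] <- "ON_TARGET"
    out$category <- cat_
    sort(out)
}

#' Aggregate off-target hits into a specificity score
#'
#' Hsu-style aggregation. Each non-on-target hit `h` with mismatch
#' positions `p` (n = |p|) contributes
#' `s_h = prod(1 - W[p]) * 1 / (((19 - dbar)/19) * 4 + 1) * 1 / n^2`
#' where `dbar` is the mean pairwise distance between mismatch positions
#' (taken as 19 when n < 2, making the distance factor 1) and `W` the
#' per-position penalty; a perfect-match hit contributes 1. The aggregate
#' score is `100 / (1 + sum(s_h))`, so 100 means no off-targets at all and
#' a single perfect-match off-target gives 50.
#'
#' @param hits `GRanges` from [enumerateOfftargets()]; must contain at least
#'   the on-target hit.
#' @param penalty A [SpecificityPenalty-class].
#' @return A number in \[0, 100\].
#' @export
specificityScore <- function(hits, penalty) {
    if (length(hits) == 0L)
        stop("no hits supplied; the on-target locus must be present")
    off <- hits[hits$category != "ON_TARGET"]
    if (length(off) == 0L) return(100)
    W <- penalty@weights
    s <- vapply(seq_along(off), function(i) {
        p <- off$mismatch_positions[[i]]
        n <- length(p)
        if (n == 0L) return(1)
        prodW <- prod(1 - W[p + 1L])
        dbar <- if (n < 2L) 19 else mean(stats::dist(p))
        prodW * (1 / (((19 - dbar) / 19) * 4 + 1)) * (1 / n^2)
    }, numeric(1))
    100 / (1 + sum(s))
}

#' Annotate candidates with off-target information
#'
#' Runs [enumerateOfftargets()] for every candidate of a gene and fills
#' `specificity`, `n_perfect_offtargets` and `offtarget_category` (the
#' worst category among perfect-match hits outside the gene span; `NA` when
#' there is none).
#'
#' @param guides A [GuideSet-class] (one gene).
#' @param asm A [ReferenceAssembly-class].
#' @param index Region index from [buildRegionIndex()].
#' @param gene_span `GRanges` span of the queried gene.
#' @param penalty A [SpecificityPenalty-class].
#' @param max_mismatch Maximum mismatches for the search (default 3).
#' @return The `GuideSet` with off-target columns filled.
#' @export
annotateOfftargets <- function(guides, asm, index, gene_span, penalty,
                               max_mismatch = 3L) {
    if (length(guides) == 0L) return(guides)
    for (i in seq_along(guides)) {
        hits <- enumerateOfftargets(guides$spacer[i], asm,
                                    max_mismatch = max_mismatch,
                                    index = index, gene_span = gene_span)
        guides$specificity[i] <- specificityScore(hits, penalty)
        perf <- hits[hits$n_mismatch == 0L & hits$category != "ON_TARGET"]
        guides$n_perfect_offtargets[i] <- length(perf)
        guides$offtarget_category[i] <- if (length(perf) == 0L)
            NA_character_
        else .OT_LEVELS[max(match(perf$category, .OT_LEVELS))]
    }
    guides
}

#' Annotate candidates with conservation
#'
#' Mean per-base conservation over the protospacer interval, uncovered
#' bases counting 0 (see [meanConservation()]).
#'
#' @param guides A [GuideSet-class].
#' @param track Conservation `GRanges`, or `NULL` for an all-zero track.
#' @return The `GuideSet` with `conservation` filled.
#' @export
annotateConservation <- function(guides, track = NULL) {
    if (length(guides) == 0L) return(guides)
    guides$conservation <- if (is.null(track)) 0
                           else meanConservation(track, granges(guides))
    guides
}

## ---------------------------------------------------------------------------
## Variants
## ---------------------------------------------------------------------------

#' Annotate candidates with overlapping variants
#'
#' Counts SNP and somatic loci falling inside the candidate footprint. The
#' default footprint is the protospacer plus the PAM (a PAM-disrupting
#' variant abolishes cutting); `"SPACER"` restricts it to the protospacer.
#'
#' @param guides A [GuideSet-class].
#' @param variants Variant `GRanges` from [readVariants()] (SNPs already
#'   MAF-filtered), or `NULL`.
#' @param footprint `"SPACER_PLUS_PAM"` (default) or `"SPACER"`.
#' @return The `GuideSet` with `n_snp_hits` and `n_somatic_hits` filled.
#' @export
annotateVariants <- function(guides, variants = NULL,
                             footprint = c("SPACER_PLUS_PAM", "SPACER")) {
    footprint <- match.arg(footprint)
    if (length(guides) == 0L) return(guides)
    fp <- granges(guides)
    if (footprint == "SPACER_PLUS_PAM") {
        plus <- as.character(strand(fp)) == "+"
        end(fp)[plus] <- end(fp)[plus] + 3L
        start(fp)[!plus] <- start(fp)[!plus] - 3L
    }
    if (is.null(variants) || length(variants) == 0L) {
        guides$n_snp_hits <- 0L
        guides$n_somatic_hits <- 0L
        return(guides)
    }
    guides$n_snp_hits <- countOverlaps(
        fp, variants[variants$kind == "SNP"], ignore.strand = TRUE)
    guides$n_somatic_hits <- countOverlaps(
        fp, variants[variants$kind == "SOMATIC"], ignore.strand = TRUE)
    guides
}
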