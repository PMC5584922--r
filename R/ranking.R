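## Filter step, CRITIC criterion weighting, summary scores and the rescue
## step that fills the requested guide count per gene.

## Filter reason codes, in reporting order.
.FILTER_REASONS <- c("VARIANT_OVERLAP", "HIGH_G", "PERFECT_OFFTARGET",
                     "LOW_EFFICIENCY")

#' Apply the hard filters to a gene's candidates
#'
#' A candidate is removed when any of these holds: it overlaps a SNP (or a
#' somatic locus when `use_somatic`), its spacer contains strictly more
#' than 40% guanines, its efficiency score is strictly below zero (or
#' unscorable, `NA`), or it has a perfect-match off-target. Candidates
#' whose only defect is the perfect-match off-target form the rescue pool,
#' partitioned by the worst category among their perfect hits; all violated
#' reasons are recorded for every removed candidate.
#'
#' @param guides A fully scored and annotated [GuideSet-class] (one gene).
#' @param use_somatic Count somatic-locus overlaps as variant overlaps.
#' @param g_max Maximum tolerated guanine fraction (default 0.40, strict).
#' @param efficiency_floor Minimum tolerated efficiency (default 0, strict:
#'   scores below it are removed, a score equal to it is kept).
#' @return A [FilterReport-class].
#' @export
filterCandidates <- function(guides, use_somatic = FALSE, g_max = 0.40,
                             efficiency_floor = 0) {
    n <- length(guides)
    gene <- if (n) guides$gene_id[1] else NA_character_
    variant <- if (n) {
        guides$n_snp_hits > 0L |
            (use_somatic & guides$n_somatic_hits > 0L)
    } else logical(0)
    high_g <- guides$guanine_fraction > g_max
    low_eff <- is.na(guides$efficiency) |
        guides$efficiency < efficiency_floor
    perfect <- !is.na(guides$n_perfect_offtargets) &
        guides$n_perfect_offtargets > 0L

    reasons <- lapply(seq_len(n), function(i)
        .FILTER_REASONS[c(variant[i], high_g[i], perfect[i], low_eff[i])])
    n_reasons <- lengths(reasons)

    pass_idx <- n_reasons == 0L
    rescue_idx <- n_reasons == 1L & perfect
    filt_idx <- !pass_idx & !rescue_idx

    passed <- guides[pass_idx]
    if (length(passed)) passed$status <- "PASSED"

    filtered <- guides[filt_idx]
    if (length(filtered)) {
        rs <- vapply(reasons[filt_idx], paste, character(1), collapse = "+")
        filtered$status <- paste0("FILTERED_", rs)
        mcols(filtered)$reasons <- rs
    } else {
        mcols(filtered)$reasons <- character(0)
    }

    pool <- guides[rescue_idx]
    mcols(pool)$rescue_category <- if (length(pool))
        pool$offtarget_category else character(0)

    methods::new("FilterReport", gene_id = gene,
                 passed = methods::new("GuideSet", passed),
                 filtered = methods::new("GuideSet", filtered),
                 rescuePool = methods::new("GuideSet", pool),
                 n_input = as.integer(n))
}

#' Build the per-gene criteria matrix
#'
#' Assembles the candidates x 4 matrix of raw criterion values
#' (efficiency, specificity, conservation, commonality), min-max normalizes
#' each column, and computes the CRITIC weight vector (see
#' [criticWeights()]).
#'
#' @param guides A scored [GuideSet-class]; at least one candidate.
#' @param conflict `"sum"` (default) aggregates conflict as
#'   `sum(1 - r)`, `"product"` as `prod(1 - r)` over the other criteria.
#' @return A [CriteriaMatrix-class].
#' @export
buildCriteriaMatrix <- function(guides, conflict = c("sum", "product")) {
    conflict <- match.arg(conflict)
    if (length(guides) == 0L) stop("cannot build a criteria matrix from 0 candidates")
    raw <- cbind(efficiency = guides$efficiency,
                 specificity = guides$specificity,
                 conservation = guides$conservation,
                 commonality = guides$commonality)
    rownames(raw) <- guideKeys(guides)
    cm <- methods::new("CriteriaMatrix",
                       gene_id = guides$gene_id[1],
                       candidate_ids = rownames(raw),
                       raw = raw, normalized = raw * NA_real_,
                       sigma = numeric(4), corr = diag(4),
                       infoC = numeric(4), weights = numeric(0),
                       conflict = conflict)
    criticWeights(cm)
}

#' Canonical candidate keys (chrom:start:strand)
#'
#' @param guides A [GuideSet-class].
#' @return Character vector of unique keys.
#' @export
guideKeys <- function(guides) {
    paste(as.character(seqnames(guides)), start(guides),
          as.character(strand(guides)), sep = ":")
}

#' CRITIC criterion weighting
#'
#' Criteria Importance Through Intercriteria Correlation: each criterion's
#' weight scales with its contrast intensity (standard deviation of the
#' min-max normalized column) and its conflict with the other criteria
#' (aggregated `1 - r` Pearson terms). `C_j = sigma_j * conflict_j` and
#' `w_j = C_j / sum(C)`. Constant columns normalize to all-zero and any
#' undefined correlation is set to 0. With fewer than 3 candidates, or when
#' every `C_j` is zero, the weights fall back to uniform (0.25 each).
#'
#' @param cm A [CriteriaMatrix-class] with `raw` populated.
#' @return The `CriteriaMatrix` with `normalized`, `sigma`, `corr`, `infoC` and
#'   `weights` filled.
#' @export
criticWeights <- function(cm) {
    raw <- cm@raw
    if (nrow(raw) == 0L) stop("empty criteria matrix")
    norm <- apply(raw, 2, function(x) {
        rng <- range(x)
        if (diff(rng) == 0) rep(0, length(x))
        else (x - rng[1]) / diff(rng)
    })
    norm <- matrix(norm, nrow = nrow(raw), dimnames = dimnames(raw))
    sigma <- if (nrow(norm) > 1L) apply(norm, 2, stats::sd) else rep(0, 4)
    corr <- suppressWarnings(stats::cor(norm))
    corr[!is.finite(corr)] <- 0
    conflict_term <- vapply(seq_len(4), function(j) {
        others <- (1 - corr[j, ])[-j]
        if (cm@conflict == "sum") sum(others) else prod(others)
    }, numeric(1))
    C <- sigma * conflict_term
    weights <- if (nrow(norm) < 3L || sum(C) == 0) rep(0.25, 4)
               else C / sum(C)
    names(weights) <- names(C) <- colnames(raw)
    methods::initialize(cm, normalized = norm, sigma = sigma, corr = corr,
                        infoC = C, weights = weights)
}

#' Weighted summary scores
#'
#' `S_i = sum_j w_j * normalized_ij` over the four criteria; guides are
#' ranked by descending `S` with ties broken by ascending
#' (chromosome, start, strand).
#'
#' @param cm A [CriteriaMatrix-class] with weights computed.
#' @return Named numeric vector of summary scores, one per candidate.
#' @export
summaryScores <- function(cm) {
    if (length(cm@weights) != 4L) stop("weights not computed")
    drop(cm@normalized %*% cm@weights)
}

#' Rescue off-target-bearing candidates
#'
#' Fills the shortfall when fewer candidates pass the filters than
#' requested. Rescue draws first from candidates whose perfect off-target
#' hits are all non-exonic, then from those hitting non-coding exons, last
#' from those hitting coding exons; within a category candidates with fewer
#' perfect hits come first, ties broken by descending summary score
#' (computed on the pooled passed + rescue-pool criteria matrix, so the two
#' phases are comparable), then ascending genomic coordinate.
#'
#' @param report A [FilterReport-class].
#' @param needed Number of candidates to rescue.
#' @param conflict CRITIC conflict aggregation, see [buildCriteriaMatrix()].
#' @return A [GuideSet-class] of at most `needed` rescued candidates,
#'   statuses `RESCUED_<category>`, in rescue order.
#' @export
rescueGuides <- function(report, needed, conflict = "sum") {
    pool <- rescuePool(report)
    if (needed <= 0L || length(pool) == 0L) return(newGuideSet())
    all_g <- methods::new("GuideSet", suppressWarnings(
        c(as(passedGuides(report), "GRanges"),
          .drop_extra_mcols(pool))))
    cm <- buildCriteriaMatrix(all_g, conflict = conflict)
    scores <- summaryScores(cm)
    pool_scores <- scores[seq(length(passedGuides(report)) + 1L,
                              length(all_g))]
    cat_rank <- match(pool$rescue_category, .OT_LEVELS)
    ord <- order(cat_rank, pool$n_perfect_offtargets, -pool_scores,
                 as.character(seqnames(pool)), start(pool),
                 as.character(strand(pool)))
    take <- ord[seq_len(min(needed, length(pool)))]
    out <- pool[take]
    out$status <- paste0("RESCUED_", out$rescue_category)
    mcols(out)$summary_score <- pool_scores[take]
    out
}

.drop_extra_mcols <- function(gs) {
    gr <- as(gs, "GRanges")
    mcols(gr) <- mcols(gr)[, .guide_mcols]
    gr
}

#' Select and rank guides for one gene
#'
#' The full per-gene pipeline: collect candidates over the exon union,
#' score all four criteria and the variant/off-target annotations, apply
#' the hard filters, rank the survivors by CRITIC-weighted summary score,
#' rescue off-target-bearing candidates if the request is short, and return
#' the top `n`. When a rescue is needed, one pooled criteria matrix
#' (passed + rescue pool) supplies the weights and summary scores for both
#' phases so all reported scores share a scale.
#'
#' @param gene_id Gene identifier resolvable in `models`.
#' @param models A [GeneModels-class].
#' @param asm A [ReferenceAssembly-class].
#' @param n Number of guides requested, 1--30.
#' @param eff_model An [EfficiencyModel-class].
#' @param penalty A [SpecificityPenalty-class].
#' @param index Region index from [buildRegionIndex()]; built from `models`
#'   when `NULL`.
#' @param variants Variant `GRanges` from [readVariants()], or `NULL`.
#' @param cons_track Conservation `GRanges`, or `NULL`.
#' @param spacer_len Spacer length, 19 or 20.
#' @param use_somatic Count somatic loci in the variant filter.
#' @param max_mismatch Off-target mismatch cap (default 3).
#' @param conflict CRITIC conflict aggregation (`"sum"` or `"product"`).
#' @param footprint Variant footprint, see [annotateVariants()].
#' @return A list with elements `rows` (a `data.frame` of ranked guides:
#'   passed first by descending summary score, then rescued in rescue
#'   order, rank contiguous from 1), `report` (the [FilterReport-class])
#'   and `weights` (the CRITIC 4-vector used). Genes with no candidates
#'   yield zero rows and a warning.
#' @export
selectGuides <- function(gene_id, models, asm, n, eff_model, penalty,
                         index = NULL, variants = NULL, cons_track = NULL,
                         spacer_len = 20L, use_somatic = FALSE,
                         max_mismatch = 3L, conflict = "sum",
                         footprint = "SPACER_PLUS_PAM") {
    if (n < 1L || n > 30L) stop("n must be between 1 and 30")
    if (is.null(index)) index <- buildRegionIndex(models)

    guides <- collectGeneCandidates(gene_id, models, asm,
                                    spacer_len = spacer_len)
    if (length(guides) == 0L) {
        warning("gene '", gene_id, "': no candidates found")
        return(list(rows = .empty_rows(), report = NULL,
                    weights = rep(NA_real_, 4)))
    }
    guides <- scoreEfficiency(guides, eff_model)
    guides <- annotateOfftargets(guides, asm, index,
                                 geneSpan(models, gene_id), penalty,
                                 max_mismatch = max_mismatch)
    guides <- annotateConservation(guides, cons_track)
    guides <- annotateVariants(guides, variants, footprint = footprint)

    report <- filterCandidates(guides, use_somatic = use_somatic)
    passed <- passedGuides(report)
    need_rescue <- length(passed) < n && length(rescuePool(report)) > 0L

    rescued <- newGuideSet()
    if (length(passed) == 0L && !need_rescue) {
        warning("gene '", gene_id, "': no candidates pass the filters")
        return(list(rows = .empty_rows(), report = report,
                    weights = rep(NA_real_, 4)))
    }

    if (need_rescue) {
        pool_all <- methods::new("GuideSet", suppressWarnings(
            c(as(passed, "GRanges"), .drop_extra_mcols(rescuePool(report)))))
        cm <- buildCriteriaMatrix(pool_all, conflict = conflict)
        scores_all <- summaryScores(cm)
        pass_scores <- if (length(passed))
            scores_all[seq_len(length(passed))] else numeric(0)
        rescued <- rescueGuides(report, n - length(passed),
                                conflict = conflict)
    } else {
        cm <- buildCriteriaMatrix(passed, conflict = conflict)
        pass_scores <- summaryScores(cm)
    }

    ord <- order(-pass_scores, as.character(seqnames(passed)),
                 start(passed), as.character(strand(passed)))
    keep <- ord[seq_len(min(n, length(passed)))]
    passed <- passed[keep]
    pass_scores <- pass_scores[keep]

    rows <- rbind(.rows_from_guides(passed, pass_scores, cm@weights),
                  .rows_from_guides(rescued,
                                    if (length(rescued))
                                        rescued$summary_score else numeric(0),
                                    cm@weights))
    if (nrow(rows)) rows$rank <- seq_len(nrow(rows))
    if (nrow(rows) < n)
        warning("gene '", gene_id, "': only ", nrow(rows), " of ", n,
                " requested guides designable")
    list(rows = rows, report = report, weights = cm@weights)
}

.empty_rows <- function() {
    data.frame(gene_id = character(0), rank = integer(0),
               chrom = character(0), start = integer(0), end = integer(0),
               strand = character(0), spacer = character(0),
               pam = character(0), efficiency = numeric(0),
               specificity = numeric(0), conservation = numeric(0),
               commonality = numeric(0), summary_score = numeric(0),
               w_efficiency = numeric(0), w_specificity = numeric(0),
               w_conservation = numeric(0), w_commonality = numeric(0),
               n_variant_hits = integer(0),
               n_perfect_offtargets = integer(0),
               offtarget_category = character(0), status = character(0),
               stringsAsFactors = FALSE)
}

.rows_from_guides <- function(guides, scores, weights) {
    if (length(guides) == 0L) return(.empty_rows())
    weights <- unname(weights)
    data.frame(gene_id = guides$gene_id, rank = NA_integer_,
               chrom = as.character(seqnames(guides)),
               start = start(guides), end = end(guides),
               strand = as.character(strand(guides)),
               spacer = guides$spacer, pam = guides$pam,
               efficiency = guides$efficiency,
               specificity = guides$specificity,
               conservation = guides$conservation,
               commonality = guides$commonality,
               summary_score = as.numeric(scores),
               w_efficiency = weights[1], w_specificity = weights[2],
               w_conservation = weights[3], w_commonality = weights[4],
               n_variant_hits = guides$n_snp_hits + guides$n_somatic_hits,
               n_perfect_offtargets = guides$n_perfect_offtargets,
               offtarget_category = guides$offtarget_category,
               status = guides$status, stringsAsFactors = FALSE)
}
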