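## Request validation against the portal limits and the end-to-end batch
## driver.

#' Construct and validate a design request
#'
#' Enforces the batch limits before any file is opened: at most 1000 genes
#' per request, 1--30 guides per gene, spacer length 19 or 20. Gene
#' identifiers are deduplicated preserving order; identifiers that later
#' fail to resolve against the annotation are reported per gene, not
#' fatally.
#'
#' @param gene_ids Character vector of gene symbols or transcript IDs.
#' @param n_per_gene Guides requested per gene (1--30).
#' @param spacer_len Spacer length, 19 or 20.
#' @param genome,annotation Mandatory input paths (checked by [runDesign()],
#'   not here).
#' @param snps,somatic,conservation,efficiency_model,specificity_penalty,
#'   controls_neg,controls_pos,construct_config Optional input paths.
#' @param use_somatic Count somatic loci in the variant filter.
#' @param add_controls Append control guides to the output.
#' @param append_construct Emit assembled oligos.
#' @param force_5prime_g Prepend G to non-G-initial spacers in oligos.
#' @param conflict CRITIC conflict aggregation, `"sum"` or `"product"`.
#' @param max_mismatch Off-target mismatch cap.
#' @param footprint Variant footprint (see [annotateVariants()]).
#' @return The validated request as a list.
#' @export
validateRequest <- function(gene_ids, n_per_gene, spacer_len = 20L,
                            genome = NULL, annotation = NULL, snps = NULL,
                            somatic = NULL, conservation = NULL,
                            efficiency_model = NULL,
                            specificity_penalty = NULL,
                            controls_neg = NULL, controls_pos = NULL,
                            construct_config = NULL,
                            use_somatic = FALSE, add_controls = FALSE,
                            append_construct = FALSE,
                            force_5prime_g = FALSE, conflict = "sum",
                            max_mismatch = 3L,
                            footprint = "SPACER_PLUS_PAM") {
    gene_ids <- unique(as.character(gene_ids))
    if (length(gene_ids) < 1L)
        stop("validation error: no gene identifiers supplied")
    if (length(gene_ids) > 1000L)
        stop("validation error: ", length(gene_ids),
             " genes requested; the limit is 1000")
    if (length(n_per_gene) != 1L || is.na(n_per_gene) ||
        n_per_gene < 1L || n_per_gene > 30L)
        stop("validation error: n_per_gene must be between 1 and 30")
    if (!spacer_len %in% c(19L, 20L))
        stop("validation error: spacer_len must be 19 or 20")
    if (!conflict %in% c("sum", "product"))
        stop("validation error: conflict must be 'sum' or 'product'")
    if (max_mismatch < 0L)
        stop("validation error: max_mismatch must be >= 0")
    list(gene_ids = gene_ids, n_per_gene = as.integer(n_per_gene),
         spacer_len = as.integer(spacer_len), genome = genome,
         annotation = annotation, snps = snps, somatic = somatic,
         conservation = conservation, efficiency_model = efficiency_model,
         specificity_penalty = specificity_penalty,
         controls_neg = controls_neg, controls_pos = controls_pos,
         construct_config = construct_config, use_somatic = use_somatic,
         add_controls = add_controls, append_construct = append_construct,
         force_5prime_g = force_5prime_g, conflict = conflict,
         max_mismatch = as.integer(max_mismatch), footprint = footprint)
}

#' Resolve a gene identifier against the annotation
#'
#' Exact match on gene symbol first, then on transcript identifier, both
#' case-insensitive.
#'
#' @param models A [GeneModels-class].
#' @param id Query identifier.
#' @return The resolved gene_id, or `NA_character_`.
#' @export
resolveGeneId <- function(models, id) {
    ids <- geneIds(models)
    hit <- which(tolower(ids) == tolower(id))
    if (length(hit)) return(ids[hit[1]])
    ti <- models@txInfo
    hit <- which(tolower(ti$transcript_id) == tolower(id))
    if (length(hit)) return(ti$gene_id[hit[1]])
    NA_character_
}

#' Run a batch library design
#'
#' Executes the whole pipeline for a validated request: read inputs, then
#' per gene collect, score, filter, CRITIC-rank and (if short) rescue, then
#' append controls and write the library TSV. Per-gene candidate / filtered
#' / passed / rescued counts are logged with `message()`. Genes that fail
#' to resolve or yield no guides produce warnings, not errors.
#'
#' @param req A request from [validateRequest()]; `genome` and `annotation`
#'   are mandatory here.
#' @param out Output TSV path.
#' @return Invisibly, a list: `rows` (the library `data.frame`), `path`,
#'   `reports` (per-gene [FilterReport-class]s), `weights` (per-gene CRITIC
#'   vectors).
#' @export
runDesign <- function(req, out) {
    if (is.null(req$genome) || is.null(req$annotation))
        stop("usage error: genome and annotation are mandatory")
    asm <- readGenome(req$genome)
    models <- readGeneModels(req$annotation, asm)
    index <- buildRegionIndex(models)
    variants <- if (!is.null(req$snps) || !is.null(req$somatic))
        readVariants(req$snps, req$somatic) else NULL
    cons <- if (!is.null(req$conservation))
        readConservation(req$conservation) else NULL
    eff_path <- req$efficiency_model %||%
        system.file("extdata", "efficiency_model_synthetic.tsv",
                    package = "guidescreen")
    eff <- readEfficiencyModel(eff_path, spacer_len = req$spacer_len)
    pen_path <- req$specificity_penalty %||%
        system.file("extdata", "hsu2013_mismatch_penalties.tsv",
                    package = "guidescreen")
    pen <- readSpecificityPenalty(pen_path, spacer_len = req$spacer_len)

    all_rows <- list()
    reports <- list()
    weights <- list()
    for (id in req$gene_ids) {
        gid <- resolveGeneId(models, id)
        if (is.na(gid)) {
            warning("gene '", id, "' not found in the annotation; skipped")
            next
        }
        res <- withCallingHandlers(
            selectGuides(gid, models, asm, n = req$n_per_gene,
                         eff_model = eff, penalty = pen, index = index,
                         variants = variants, cons_track = cons,
                         spacer_len = req$spacer_len,
                         use_somatic = req$use_somatic,
                         max_mismatch = req$max_mismatch,
                         conflict = req$conflict,
                         footprint = req$footprint),
            warning = function(w) {
                message("[", gid, "] ", conditionMessage(w))
                invokeRestart("muffleWarning")
            })
        reports[[gid]] <- res$report
        weights[[gid]] <- res$weights
        all_rows[[gid]] <- res$rows
        rep_ <- res$report
        message(sprintf(
            "[%s] candidates=%d passed=%d filtered=%d rescuable=%d selected=%d",
            gid, if (is.null(rep_)) 0L else rep_@n_input,
            if (is.null(rep_)) 0L else length(passedGuides(rep_)),
            if (is.null(rep_)) 0L else length(filteredGuides(rep_)),
            if (is.null(rep_)) 0L else length(rescuePool(rep_)),
            nrow(res$rows)))
    }
    rows <- do.call(rbind, c(list(.empty_rows()), unname(all_rows)))

    if (isTRUE(req$add_controls)) {
        neg <- if (!is.null(req$controls_neg))
            readControls(req$controls_neg, req$spacer_len) else NULL
        pos <- if (!is.null(req$controls_pos))
            readControls(req$controls_pos, req$spacer_len) else NULL
        rows <- attachControls(rows, neg, pos)
    }
    construct <- if (!is.null(req$construct_config))
        readConstructConfig(req$construct_config)
    else list(promoter = "", scaffold = "")
    writeLibrary(rows, out, include_oligo = isTRUE(req$append_construct),
                 construct = construct,
                 force_5prime_g = isTRUE(req$force_5prime_g))
    invisible(list(rows = rows, path = out, reports = reports,
                   weights = weights))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
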