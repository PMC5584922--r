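## Seeded synthetic-fixture generator. Produces a small genome with planted
## structure -- multi-isoform genes, exact protospacer duplications in
## intergenic / non-coding-exon / coding-exon space, SNPs straddling the MAF
## cutoff, a somatic locus, piecewise-constant conservation -- plus a truth
## table recording what the pipeline must recover. Generation is a pure
## function of its specification object: the same seed yields identical files.

#' Specification for a synthetic fixture
#'
#' Defaults define the study conditions used throughout the test suite and
#' the acceptance script: five queried coding genes with 2--4 isoforms, one
#' non-coding gene and one non-queried coding decoy as off-target landing
#' sites, three planted exact protospacer duplications (one per off-target
#' category), planted SNPs at minor allele frequencies 0.2 (above the 0.05
#' floor) and 0.01 (below it), one somatic locus, and 500-bp conservation
#' blocks cycling 0, 0.25, 0.5, 0.75, 1.
#'
#' @param seed Integer seed; the fixture is a pure function of it.
#' @param chrom_len Named integer vector of chromosome lengths.
#' @param exon_size,intron_size Exon/intron sizes (bp) of queried genes.
#' @param planted_mafs Two SNP allele frequencies, one above and one below
#'   the 0.05 floor.
#' @param cons_block,cons_scores Conservation block length and the cycled
#'   block scores.
#' @param spacer_len Spacer length used when picking plant candidates.
#' @return A list of class `SyntheticSpec`.
#' @export
syntheticSpec <- function(seed = 1L,
                          chrom_len = c(chr1 = 14000L, chr2 = 14000L,
                                        chr3 = 6000L),
                          exon_size = 90L, intron_size = 60L,
                          planted_mafs = c(0.2, 0.01),
                          cons_block = 500L,
                          cons_scores = c(0, 0.25, 0.5, 0.75, 1),
                          spacer_len = 20L) {
    spec <- list(seed = as.integer(seed), chrom_len = chrom_len,
                 exon_size = as.integer(exon_size),
                 intron_size = as.integer(intron_size),
                 planted_mafs = planted_mafs,
                 cons_block = as.integer(cons_block),
                 cons_scores = cons_scores,
                 spacer_len = as.integer(spacer_len))
    class(spec) <- "SyntheticSpec"
    spec
}

## Isoform exon-usage patterns per queried gene: list of per-isoform exon
## index sets over the gene's four exon slots. Chosen so exon commonality
## fractions span 1/4 .. 1.
.GENE_PLANS <- list(
    GENE1 = list(chrom = "chr1", start = 1000L,
                 iso = list(1:4, c(1L, 3L, 4L))),
    GENE2 = list(chrom = "chr1", start = 4000L,
                 iso = list(1:4, c(1L, 3L, 4L), c(1L, 4L))),
    GENE3 = list(chrom = "chr1", start = 7000L,
                 iso = list(1:4, c(1L, 2L, 4L), c(1L, 4L), c(1L, 3L, 4L))),
    GENE4 = list(chrom = "chr2", start = 1000L,
                 iso = list(1:4, c(1L, 3L, 4L))),
    GENE5 = list(chrom = "chr2", start = 4000L,
                 iso = list(1:4, c(1L, 3L, 4L), c(1L, 4L))))

#' Generate a synthetic fixture
#'
#' Writes `genome.fa`, `genes.gff3`, `snps.vcf`, `somatic.tsv`,
#' `conservation.bedGraph` and `truth.tsv` into `outdir`. The truth table
#' records, per planted event, the candidate key (`chrom:start:strand`),
#' its spacer and the expected pipeline outcome: rescue category for the
#' three planted duplications, variant-filter outcome for the planted SNPs
#' and somatic locus, and the exact isoform-commonality fraction of every
#' queried exon.
#'
#' @param spec A [syntheticSpec()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a named list of the six file paths plus the truth
#'   `data.frame`.
#' @export
generateFixture <- function(spec = syntheticSpec(), outdir) {
    stopifnot(inherits(spec, "SyntheticSpec"))
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    set.seed(spec$seed)

    ## --- random genome ----------------------------------------------------
    seqs <- lapply(spec$chrom_len, function(n)
        paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
              collapse = ""))

    ## --- gene models ------------------------------------------------------
    exw <- spec$exon_size; inw <- spec$intron_size
    slot_start <- function(g0, k) g0 + (k - 1L) * (exw + inw)
    gene_end <- function(g0) slot_start(g0, 4L) + exw - 1L
    for (gn in names(.GENE_PLANS)) {
        pl <- .GENE_PLANS[[gn]]
        if (gene_end(pl$start) > spec$chrom_len[[pl$chrom]])
            stop("infeasible spec: exons of ", gn, " exceed ", pl$chrom)
    }
    extra <- list(
        NCGENE1 = list(chrom = "chr2", start = 8000L, exons = cbind(
            c(8000L, 8250L), c(8149L, 8399L)), coding = FALSE),
        DECOY1 = list(chrom = "chr2", start = 10000L, exons = cbind(
            c(10000L, 10250L), c(10149L, 10399L)), coding = TRUE))
    for (gn in names(extra))
        if (max(extra[[gn]]$exons[, 2]) > spec$chrom_len[[extra[[gn]]$chrom]])
            stop("infeasible spec: exons of ", gn, " exceed chromosome")

    gff <- c("##gff-version 3")
    truth <- list()
    for (gn in names(.GENE_PLANS)) {
        pl <- .GENE_PLANS[[gn]]
        g0 <- pl$start
        slots <- cbind(start = vapply(1:4, slot_start, integer(1), g0 = g0),
                       end = vapply(1:4, function(k)
                           slot_start(g0, k) + exw - 1L, integer(1)))
        gff <- c(gff, sprintf(
            "%s\t.\tgene\t%d\t%d\t.\t+\t.\tID=%s;Name=%s",
            pl$chrom, g0, gene_end(g0), gn, gn))
        n_iso <- length(pl$iso)
        for (t in seq_len(n_iso)) {
            tid <- sprintf("%s.t%d", gn, t)
            use <- pl$iso[[t]]
            gff <- c(gff, sprintf(
                "%s\t.\tmRNA\t%d\t%d\t.\t+\t.\tID=%s;Parent=%s",
                pl$chrom, slots[min(use), 1], slots[max(use), 2], tid, gn))
            for (k in use) {
                gff <- c(gff, sprintf(
                    "%s\t.\texon\t%d\t%d\t.\t+\t.\tID=%s.e%d;Parent=%s",
                    pl$chrom, slots[k, 1], slots[k, 2], tid, k, tid))
                gff <- c(gff, sprintf(
                    "%s\t.\tCDS\t%d\t%d\t.\t+\t0\tID=%s.c%d;Parent=%s",
                    pl$chrom, slots[k, 1], slots[k, 2], tid, k, tid))
            }
        }
        usage <- vapply(1:4, function(k)
            mean(vapply(pl$iso, function(u) k %in% u, logical(1))),
            numeric(1))
        for (k in 1:4)
            truth[[length(truth) + 1L]] <- data.frame(
                record = "COMMONALITY", gene_id = gn,
                key = sprintf("%s:%d-%d", pl$chrom, slots[k, 1],
                              slots[k, 2]),
                spacer = "", expected = format(usage[k], digits = 15),
                stringsAsFactors = FALSE)
    }
    for (gn in names(extra)) {
        pl <- extra[[gn]]
        gff <- c(gff, sprintf(
            "%s\t.\tgene\t%d\t%d\t.\t+\t.\tID=%s;Name=%s",
            pl$chrom, min(pl$exons[, 1]), max(pl$exons[, 2]), gn, gn))
        tid <- paste0(gn, ".t1")
        ttype <- if (pl$coding) "mRNA" else "ncRNA"
        gff <- c(gff, sprintf(
            "%s\t.\t%s\t%d\t%d\t.\t+\t.\tID=%s;Parent=%s",
            pl$chrom, ttype, min(pl$exons[, 1]), max(pl$exons[, 2]), tid, gn))
        for (k in seq_len(nrow(pl$exons))) {
            gff <- c(gff, sprintf(
                "%s\t.\texon\t%d\t%d\t.\t+\t.\tID=%s.e%d;Parent=%s",
                pl$chrom, pl$exons[k, 1], pl$exons[k, 2], tid, k, tid))
            if (pl$coding)
                gff <- c(gff, sprintf(
                    "%s\t.\tCDS\t%d\t%d\t.\t+\t0\tID=%s.c%d;Parent=%s",
                    pl$chrom, pl$exons[k, 1], pl$exons[k, 2], tid, k, tid))
        }
    }

    ## --- pick plantable candidates on the pre-plant genome ----------------
    asm0 <- methods::new("ReferenceAssembly",
                         sequences = DNAStringSet(unlist(seqs)))
    gff_tmp <- tempfile(fileext = ".gff3")
    writeLines(gff, gff_tmp)
    models <- readGeneModels(gff_tmp, asm0)
    unlink(gff_tmp)
    eff <- readEfficiencyModel(
        system.file("extdata", "efficiency_model_synthetic.tsv",
                    package = "guidescreen"),
        spacer_len = spec$spacer_len)

    pick <- function(gene, not_near = integer(0), margin = 40L) {
        g <- collectGeneCandidates(gene, models, asm0,
                                   spacer_len = spec$spacer_len)
        g <- scoreEfficiency(g, eff)
        ok <- !is.na(g$efficiency) & g$efficiency >= 0 &
            g$guanine_fraction <= 0.40 & !is.na(g$context)
        if (length(not_near))
            ok <- ok & vapply(seq_along(g), function(i)
                all(abs(g$cut_site[i] - not_near) > margin), logical(1))
        if (!any(ok)) stop("infeasible spec: no plantable candidate in ",
                           gene, " (seed ", spec$seed, ")")
        g[which(ok)[1]]
    }
    plant_seq <- function(cand) {
        ## protospacer + PAM in reference-plus orientation
        chrom <- as.character(seqnames(cand))
        if (as.character(strand(cand)) == "+")
            substr(seqs[[chrom]], start(cand), end(cand) + 3L)
        else substr(seqs[[chrom]], start(cand) - 3L, end(cand))
    }
    do_plant <- function(chrom, at, payload) {
        substr(seqs[[chrom]], at, at + nchar(payload) - 1L) <<- payload
    }
    cand_key <- function(cand) guideKeys(cand)

    ot_plan <- list(
        list(gene = "GENE1", target_chrom = "chr3", at = 2000L,
             category = "NON_EXON"),
        list(gene = "GENE2", target_chrom = "chr2", at = 8020L,
             category = "EXON_NONCODING"),      # inside NCGENE1 exon 1
        list(gene = "GENE3", target_chrom = "chr2", at = 10020L,
             category = "CODING"))               # inside DECOY1 exon 1
    for (p in ot_plan) {
        cand <- pick(p$gene)
        do_plant(p$target_chrom, p$at, plant_seq(cand))
        truth[[length(truth) + 1L]] <- data.frame(
            record = "OFFTARGET", gene_id = p$gene, key = cand_key(cand),
            spacer = cand$spacer, expected = p$category,
            stringsAsFactors = FALSE)
    }

    ## --- variants ---------------------------------------------------------
    other_base <- function(chrom, pos) {
        b <- substr(seqs[[chrom]], pos, pos)
        c(A = "C", C = "A", G = "T", T = "G")[[b]]
    }
    c_hi <- pick("GENE4")
    c_lo <- pick("GENE4", not_near = c_hi$cut_site)
    c_som <- pick("GENE5")
    vcf_rec <- function(chrom, pos, af) sprintf(
        "%s\t%d\t.\t%s\t%s\t100\tPASS\tAF=%s", chrom, pos,
        substr(seqs[[chrom]], pos, pos), other_base(chrom, pos),
        format(af, digits = 15))
    vcf <- c("##fileformat=VCFv4.2",
             "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele Frequency\">",
             sprintf("##contig=<ID=%s,length=%d>", names(spec$chrom_len),
                     spec$chrom_len),
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
             vcf_rec("chr2", c_hi$cut_site, spec$planted_mafs[1]),
             vcf_rec("chr2", c_lo$cut_site, spec$planted_mafs[2]),
             ## intergenic SNP above the floor, outside every footprint
             vcf_rec("chr1", 13500L, 0.30))
    truth[[length(truth) + 1L]] <- data.frame(
        record = "SNP_FILTERED", gene_id = "GENE4", key = cand_key(c_hi),
        spacer = c_hi$spacer, expected = "VARIANT_OVERLAP",
        stringsAsFactors = FALSE)
    truth[[length(truth) + 1L]] <- data.frame(
        record = "SNP_RETAINED", gene_id = "GENE4", key = cand_key(c_lo),
        spacer = c_lo$spacer, expected = "NOT_VARIANT_FILTERED",
        stringsAsFactors = FALSE)
    somatic <- sprintf("chr2\t%d\t%s", c_som$cut_site,
                       other_base("chr2", c_som$cut_site))
    truth[[length(truth) + 1L]] <- data.frame(
        record = "SOMATIC", gene_id = "GENE5", key = cand_key(c_som),
        spacer = c_som$spacer, expected = "VARIANT_OVERLAP_IF_SOMATIC",
        stringsAsFactors = FALSE)

    ## --- conservation: piecewise-constant blocks --------------------------
    bg <- character(0)
    for (chrom in names(spec$chrom_len)) {
        n <- spec$chrom_len[[chrom]]
        starts <- seq(0L, n - 1L, by = spec$cons_block)   # bedGraph 0-based
        ends <- pmin(starts + spec$cons_block, n)
        sc <- spec$cons_scores[(seq_along(starts) - 1L) %%
                                   length(spec$cons_scores) + 1L]
        bg <- c(bg, sprintf("%s\t%d\t%d\t%s", chrom, starts, ends,
                            format(sc, digits = 15)))
    }

    ## --- write everything -------------------------------------------------
    paths <- list(
        genome = file.path(outdir, "genome.fa"),
        annotation = file.path(outdir, "genes.gff3"),
        snps = file.path(outdir, "snps.vcf"),
        somatic = file.path(outdir, "somatic.tsv"),
        conservation = file.path(outdir, "conservation.bedGraph"),
        truth = file.path(outdir, "truth.tsv"))
    writeXStringSet(DNAStringSet(unlist(seqs)), paths$genome, width = 80L)
    writeLines(gff, paths$annotation)
    writeLines(vcf, paths$snps)
    writeLines(somatic, paths$somatic)
    writeLines(bg, paths$conservation)
    truth_df <- do.call(rbind, truth)
    utils::write.table(truth_df, paths$truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(c(paths, list(truth_table = truth_df)))
}

#' Queried gene identifiers of the default fixture
#'
#' @return Character vector of the five queried coding genes.
#' @export
fixtureGenes <- function() names(.GENE_PLANS)
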