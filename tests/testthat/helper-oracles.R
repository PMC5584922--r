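# Independent oracles and tiny in-code fixture builders. The oracles use
# base-R string handling only, so they share no code path with the package.

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(Biostrings)
})

revcomp_chr <- function(x) {
    vapply(x, function(s) {
        paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]),
              collapse = "")
    }, character(1), USE.NAMES = FALSE)
}

# Brute-force regex PAM scan of one sequence, both strands.
oracle_pam_scan <- function(seq, L = 20L) {
    n <- nchar(seq)
    rows <- list()
    gg <- as.integer(gregexpr("(?=GG)", seq, perl = TRUE)[[1]])
    gg <- gg[gg > 0]
    for (g in gg) {                       # plus: spacer | N GG
        sp_start <- g - 1L - L
        if (sp_start < 1L) next
        spacer <- substr(seq, sp_start, sp_start + L - 1L)
        if (grepl("N", spacer, fixed = TRUE)) next
        rows[[length(rows) + 1L]] <- data.frame(
            start = sp_start, end = sp_start + L - 1L, strand = "+",
            spacer = spacer, pam = substr(seq, g - 1L, g + 1L))
    }
    cc <- as.integer(gregexpr("(?=CC)", seq, perl = TRUE)[[1]])
    cc <- cc[cc > 0]
    for (cpos in cc) {                    # minus: CC N | revcomp spacer
        sp_start <- cpos + 3L
        sp_end <- sp_start + L - 1L
        if (sp_end > n) next
        spacer <- revcomp_chr(substr(seq, sp_start, sp_end))
        if (grepl("N", spacer, fixed = TRUE)) next
        rows[[length(rows) + 1L]] <- data.frame(
            start = sp_start, end = sp_end, strand = "-", spacer = spacer,
            pam = revcomp_chr(substr(seq, cpos, cpos + 2L)))
    }
    if (length(rows) == 0L)
        return(data.frame(start = integer(0), end = integer(0),
                          strand = character(0), spacer = character(0),
                          pam = character(0)))
    out <- do.call(rbind, rows)
    out <- out[!duplicated(out[c("start", "strand")]), ]
    out[order(out$start, out$strand), ]
}

# Sliding-window Hamming off-target scan over a named character genome.
oracle_offtargets <- function(seqs, spacer, max_mismatch = 3L) {
    L <- nchar(spacer)
    sp <- strsplit(spacer, "")[[1]]
    sp_rc <- strsplit(revcomp_chr(spacer), "")[[1]]
    rows <- list()
    for (chrom in names(seqs)) {
        chars <- strsplit(seqs[[chrom]], "")[[1]]
        n <- length(chars)
        nw <- n - L + 1L
        if (nw < 1L) next
        mm_f <- mm_r <- integer(nw)
        for (j in seq_len(L)) {
            win <- chars[seq(j, j + nw - 1L)]
            mm_f <- mm_f + (win != sp[j])
            mm_r <- mm_r + (win != sp_rc[j])
        }
        p <- which(mm_f <= max_mismatch)
        p <- p[p + L + 2L <= n & chars[p + L + 1L] == "G" &
                   chars[p + L + 2L] == "G"]
        for (q in p)
            rows[[length(rows) + 1L]] <- data.frame(
                chrom = chrom, start = q, strand = "+",
                n_mismatch = mm_f[q])
        p <- which(mm_r <= max_mismatch)
        p <- p[p >= 4L & chars[p - 3L] == "C" & chars[p - 2L] == "C"]
        for (q in p)
            rows[[length(rows) + 1L]] <- data.frame(
                chrom = chrom, start = q, strand = "-",
                n_mismatch = mm_r[q])
    }
    if (length(rows) == 0L)
        return(data.frame(chrom = character(0), start = integer(0),
                          strand = character(0), n_mismatch = integer(0)))
    out <- do.call(rbind, rows)
    out[order(out$chrom, out$start, out$strand), ]
}

# Step-by-step CRITIC weighting with explicit loops (no apply/cor).
oracle_critic <- function(raw, conflict = "sum") {
    nr <- nrow(raw); nc <- ncol(raw)
    norm <- matrix(0, nr, nc)
    for (j in seq_len(nc)) {
        lo <- min(raw[, j]); hi <- max(raw[, j])
        if (hi > lo) norm[, j] <- (raw[, j] - lo) / (hi - lo)
    }
    sigma <- numeric(nc)
    if (nr > 1L) for (j in seq_len(nc)) {
        m <- sum(norm[, j]) / nr
        sigma[j] <- sqrt(sum((norm[, j] - m)^2) / (nr - 1L))
    }
    r <- matrix(0, nc, nc)
    for (j in seq_len(nc)) for (k in seq_len(nc)) {
        x <- norm[, j]; y <- norm[, k]
        sx <- sqrt(sum((x - mean(x))^2)); sy <- sqrt(sum((y - mean(y))^2))
        r[j, k] <- if (sx == 0 || sy == 0) 0
                   else sum((x - mean(x)) * (y - mean(y))) / (sx * sy)
    }
    C <- numeric(nc)
    for (j in seq_len(nc)) {
        term <- if (conflict == "sum") 0 else 1
        for (k in seq_len(nc)) if (k != j) {
            term <- if (conflict == "sum") term + (1 - r[j, k])
                    else term * (1 - r[j, k])
        }
        C[j] <- sigma[j] * term
    }
    if (nr < 3L || sum(C) == 0) rep(1 / nc, nc) else C / sum(C)
}

# Random DNA string.
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# Assembly from named character sequences, via the FASTA reader.
make_asm <- function(seqs) {
    fa <- tempfile(fileext = ".fa")
    writeLines(unlist(lapply(names(seqs), function(n)
        c(paste0(">", n), seqs[[n]]))), fa)
    on.exit(unlink(fa))
    readGenome(fa)
}

# GeneModels from a compact transcript table:
# list(list(gene=, tx=, chrom=, strand=, coding=, exons=matrix 2 cols)).
make_models <- function(txs, asm) {
    gff <- "##gff-version 3"
    genes <- unique(vapply(txs, `[[`, character(1), "gene"))
    for (g in genes) {
        sub <- Filter(function(t) t$gene == g, txs)
        allx <- do.call(rbind, lapply(sub, `[[`, "exons"))
        gff <- c(gff, sprintf("%s\t.\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
                              sub[[1]]$chrom, min(allx[, 1]), max(allx[, 2]),
                              sub[[1]]$strand, g, g))
        for (t in sub) {
            ttype <- if (isTRUE(t$coding)) "mRNA" else "ncRNA"
            gff <- c(gff, sprintf("%s\t.\t%s\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                                  t$chrom, ttype, min(t$exons[, 1]),
                                  max(t$exons[, 2]), t$strand, t$tx, g))
            for (k in seq_len(nrow(t$exons))) {
                gff <- c(gff, sprintf(
                    "%s\t.\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
                    t$chrom, t$exons[k, 1], t$exons[k, 2], t$strand,
                    t$tx, k, t$tx))
                if (isTRUE(t$coding))
                    gff <- c(gff, sprintf(
                        "%s\t.\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.c%d;Parent=%s",
                        t$chrom, t$exons[k, 1], t$exons[k, 2], t$strand,
                        t$tx, k, t$tx))
            }
        }
    }
    path <- tempfile(fileext = ".gff3")
    writeLines(gff, path)
    on.exit(unlink(path))
    readGeneModels(path, asm)
}

# Fabricate a scored GuideSet for ranking/assembly tests. `spec` is a
# data.frame with columns: start, strand, spacer and optionally efficiency,
# specificity, conservation, commonality, n_snp, n_somatic, n_perfect,
# category.
make_guides <- function(spec, gene = "G1", chrom = "chr1") {
    L <- nchar(spec$spacer[1])
    gr <- GRanges(chrom, IRanges(spec$start, width = L),
                  strand = spec$strand)
    cut <- ifelse(spec$strand == "+", spec$start + L - 3L, spec$start + 2L)
    gs <- guidescreen:::newGuideSet(
        gr, gene_id = rep(gene, nrow(spec)), spacer = spec$spacer,
        pam = rep("AGG", nrow(spec)), cut_site = cut)
    grab <- function(col, dflt) if (col %in% names(spec)) spec[[col]]
                                else rep(dflt, nrow(spec))
    gs$efficiency <- grab("efficiency", 0.5)
    gs$specificity <- grab("specificity", 100)
    gs$conservation <- grab("conservation", 0.5)
    gs$commonality <- grab("commonality", 1)
    gs$n_snp_hits <- as.integer(grab("n_snp", 0L))
    gs$n_somatic_hits <- as.integer(grab("n_somatic", 0L))
    gs$n_perfect_offtargets <- as.integer(grab("n_perfect", 0L))
    gs$offtarget_category <- grab("category", NA_character_)
    gs
}

# Random spacer with a guanine fraction below the filter bound.
rand_spacer <- function(L = 20L) {
    paste(sample(c("A", "C", "T"), L, TRUE), collapse = "")
}

fixture_dir_cache <- new.env(parent = emptyenv())

# Default synthetic fixture, generated once per test run.
default_fixture <- function(seed = 1L) {
    key <- paste0("s", seed)
    if (is.null(fixture_dir_cache[[key]])) {
        dir <- file.path(tempdir(), paste0("guidescreen_fx_", seed))
        fixture_dir_cache[[key]] <- generateFixture(
            syntheticSpec(seed = seed), dir)
    }
    fixture_dir_cache[[key]]
}

# Temp-file efficiency model with given intercept and coefficient rows.
eff_model_file <- function(intercept, rows = NULL) {
    path <- tempfile(fileext = ".tsv")
    lines <- sprintf("#intercept\t%s", format(intercept, digits = 15))
    if (!is.null(rows))
        lines <- c(lines, sprintf("%d\t%s\t%s", rows$position,
                                  rows$nucleotide,
                                  format(rows$weight, digits = 15)))
    writeLines(lines, path)
    path
}

hsu_penalty <- function(spacer_len = 20L) {
    readSpecificityPenalty(
        system.file("extdata", "hsu2013_mismatch_penalties.tsv",
                    package = "guidescreen"), spacer_len)
}
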