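## Readers for the genome, gene models, variant tracks and conservation
## track. All coordinates are converted at these boundaries to the internal
## 1-based closed GRanges convention.

#' Read a reference genome from FASTA
#'
#' Sequences are uppercased on load and the alphabet is restricted to
#' A, C, G, T, N; any other letter is an error naming the record and
#' position. Gzipped input is accepted. The record name is the first
#' whitespace-delimited word of the header.
#'
#' @param path Path to a FASTA file (optionally gzipped).
#' @return A [ReferenceAssembly-class].
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "acgtACGTNNacgt"), fa)
#' refLengths(readGenome(fa))
#' @export
readGenome <- function(path) {
    if (!file.exists(path)) stop("genome FASTA not found: ", path)
    seqs <- tryCatch(readBStringSet(path),
                     error = function(e) stop("malformed FASTA '", path,
                                              "': ", conditionMessage(e)))
    if (length(seqs) == 0L) stop("empty FASTA: ", path)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    chars <- toupper(as.character(seqs))
    bad <- regexpr("[^ACGTN]", chars)
    if (any(bad > 0L)) {
        i <- which(bad > 0L)[1L]
        stop(sprintf(
            "invalid character '%s' in record '%s' at position %d (alphabet is A,C,G,T,N)",
            substr(chars[i], bad[i], bad[i]), names(seqs)[i], bad[i]))
    }
    methods::new("ReferenceAssembly",
                 sequences = DNAStringSet(stats::setNames(chars, names(seqs))))
}

#' Extract genomic subsequences
#'
#' Returns the sequence of each range in `gr`, reverse-complemented for
#' minus-strand ranges, as a character vector. Ranges must lie within the
#' assembly.
#'
#' @param asm A [ReferenceAssembly-class].
#' @param gr A `GRanges`.
#' @return Character vector of sequences, one per range.
#' @export
getRefSeq <- function(asm, gr) {
    len <- refLengths(asm)
    chr <- as.character(seqnames(gr))
    if (!all(chr %in% names(len)))
        stop("unknown chromosome(s): ",
             paste(unique(setdiff(chr, names(len))), collapse = ", "))
    if (any(start(gr) < 1L | end(gr) > len[chr]))
        stop("range outside chromosome bounds")
    out <- vapply(seq_along(gr), function(i) {
        as.character(subseq(asm@sequences[[chr[i]]], start(gr)[i], end(gr)[i]))
    }, character(1))
    neg <- as.character(strand(gr)) == "-"
    if (any(neg))
        out[neg] <- as.character(reverseComplement(DNAStringSet(out[neg])))
    out
}

#' Read gene models from GFF3 or BED12
#'
#' GFF3 transcripts are grouped under their parent gene (the gene's `Name`
#' attribute, falling back to `ID`, is the gene symbol); a transcript is
#' coding when it has CDS features. BED12 has no gene grouping: a `name`
#' field of the form `GENE:TX` is split into gene and transcript
#' identifiers, otherwise the name serves as both; a transcript is coding
#' when `thickStart < thickEnd`. Both formats are converted to 1-based
#' closed coordinates (GFF3 natively; BED12 blocks from 0-based half-open).
#'
#' @param path GFF3 (`.gff`, `.gff3`) or BED12 (`.bed`) file, optionally
#'   gzipped.
#' @param asm A [ReferenceAssembly-class]; all annotation chromosomes must
#'   exist in it and exons must lie within chromosome bounds.
#' @return A [GeneModels-class].
#' @export
readGeneModels <- function(path, asm) {
    if (!file.exists(path)) stop("annotation file not found: ", path)
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    models <- if (ext %in% c("gff", "gff3")) {
        .models_from_gff3(path)
    } else if (ext == "bed") {
        .models_from_bed12(path)
    } else stop("unrecognised annotation format (need .gff3/.gff or .bed): ",
                path)
    .validate_models(models, asm)
    models
}

.models_from_gff3 <- function(path) {
    gr <- rtracklayer::import(path, format = "gff3")
    type <- as.character(gr$type)
    first_chr <- function(x) vapply(x, function(v)
        if (length(v)) v[[1]] else NA_character_, character(1))
    genes <- gr[type == "gene"]
    gene_name <- stats::setNames(
        ifelse(!is.null(genes$Name) & !is.na(genes$Name),
               genes$Name, genes$ID), genes$ID)
    is_tx <- type %in% c("mRNA", "transcript", "ncRNA", "lnc_RNA",
                         "primary_transcript")
    txs <- gr[is_tx]
    if (length(txs) == 0L) stop("no transcript features in GFF3: ", path)
    tx_gene <- first_chr(txs$Parent)
    tx_gene <- ifelse(tx_gene %in% names(gene_name),
                      gene_name[tx_gene], tx_gene)
    tx_ids <- txs$ID
    exons <- gr[type == "exon"]
    if (length(exons) == 0L) stop("no exon features in GFF3: ", path)
    ex_tx <- first_chr(exons$Parent)
    if (!all(ex_tx %in% tx_ids))
        stop("exon with unknown Parent transcript in ", path)
    cds_tx <- unique(first_chr(gr[type == "CDS"]$Parent))
    ex <- granges(exons)
    mcols(ex) <- DataFrame(
        transcript_id = ex_tx,
        gene_id = stats::setNames(tx_gene, tx_ids)[ex_tx])
    ti <- DataFrame(
        transcript_id = tx_ids, gene_id = tx_gene,
        chrom = as.character(seqnames(txs)),
        strand = as.character(strand(txs)),
        coding = tx_ids %in% cds_tx)
    methods::new("GeneModels", exons = sort(ex), txInfo = ti)
}

.models_from_bed12 <- function(path) {
    gr <- rtracklayer::import(path, format = "bed")
    if (is.null(gr$blocks))
        stop("BED file lacks block (BED12) columns: ", path)
    nm <- gr$name
    has_sep <- grepl(":", nm, fixed = TRUE)
    gene_id <- ifelse(has_sep, sub(":.*$", "", nm), nm)
    tx_id <- ifelse(has_sep, sub("^[^:]*:", "", nm), nm)
    ex_list <- lapply(seq_along(gr), function(i) {
        bl <- gr$blocks[[i]]
        if (length(bl) == 0L)
            stop("transcript with zero exons in BED12: ", nm[i])
        GRanges(seqnames(gr)[i],
                IRanges::shift(bl, start(gr)[i] - 1L),
                strand = strand(gr)[i])
    })
    ex <- unlist(GRangesList(ex_list))
    mcols(ex) <- DataFrame(
        transcript_id = rep(tx_id, lengths(ex_list)),
        gene_id = rep(gene_id, lengths(ex_list)))
    ti <- DataFrame(
        transcript_id = tx_id, gene_id = gene_id,
        chrom = as.character(seqnames(gr)),
        strand = as.character(strand(gr)),
        coding = width(gr$thick) > 0L)
    methods::new("GeneModels", exons = sort(ex), txInfo = ti)
}

.validate_models <- function(models, asm) {
    len <- refLengths(asm)
    ex <- models@exons
    chr <- as.character(seqnames(ex))
    if (!all(chr %in% names(len)))
        stop("annotation references unknown chromosome(s): ",
             paste(unique(setdiff(chr, names(len))), collapse = ", "))
    if (any(start(ex) < 1L | end(ex) > len[chr]))
        stop("exon outside chromosome bounds")
    invisible(TRUE)
}

#' Write gene models as BED12
#'
#' One BED12 line per transcript, `name` = `gene_id:transcript_id`,
#' thick region spanning the whole transcript for coding transcripts and
#' zero-width for non-coding ones. Re-reading the file with
#' [readGeneModels()] reproduces the exon intervals exactly.
#'
#' @param models A [GeneModels-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeGeneModelsBed <- function(models, path) {
    ti <- models@txInfo
    lines <- vapply(seq_len(nrow(ti)), function(i) {
        ex <- models@exons[models@exons$transcript_id == ti$transcript_id[i]]
        ex <- sort(granges(ex))
        cs <- min(start(ex)) - 1L            # 0-based chromStart
        ce <- max(end(ex))
        thick <- if (ti$coding[i]) c(cs, ce) else c(cs, cs)
        paste(ti$chrom[i], cs, ce,
              paste0(ti$gene_id[i], ":", ti$transcript_id[i]), 0L,
              ti$strand[i], thick[1], thick[2], "0", length(ex),
              paste0(paste(width(ex), collapse = ","), ","),
              paste0(paste(start(ex) - 1L - cs, collapse = ","), ","),
              sep = "\t")
    }, character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Read SNP and somatic-mutation loci
#'
#' SNPs are read from a VCF; only records whose allele frequency (INFO key
#' `af_key`, default `AF`) is strictly greater than `maf_floor` are
#' retained. Records lacking the key are skipped with a warning. Somatic
#' loci are read from a 3-column TSV `chrom`, `pos` (1-based), `alt` and are
#' all retained regardless of frequency.
#'
#' @param vcf_path VCF file with SNPs, or `NULL`.
#' @param somatic_path TSV file with somatic loci, or `NULL`.
#' @param maf_floor Minor-allele-frequency floor; strictly-greater records
#'   kept. Default 0.05.
#' @param af_key INFO key holding the allele frequency. Default `"AF"`.
#' @return A `GRanges` of width-1 loci with metadata columns `ref`, `alt`,
#'   `maf` (`NA` for somatic records) and `kind` (`"SNP"` or `"SOMATIC"`).
#' @export
readVariants <- function(vcf_path = NULL, somatic_path = NULL,
                         maf_floor = 0.05, af_key = "AF") {
    out <- GRanges()
    if (!is.null(vcf_path)) {
        vcf <- VariantAnnotation::readVcf(vcf_path, genome = "user")
        rr <- SummarizedExperiment::rowRanges(vcf)
        if (length(rr)) {
            inf <- VariantAnnotation::info(vcf)
            if (!af_key %in% colnames(inf))
                stop("VCF INFO lacks frequency key '", af_key, "'")
            af <- inf[[af_key]]
            maf <- if (is(af, "List"))
                vapply(af, function(x)
                    if (length(x)) as.numeric(x[[1]]) else NA_real_,
                    numeric(1))
            else as.numeric(af)
            miss <- is.na(maf)
            if (any(miss))
                warning(sum(miss), " VCF record(s) without INFO/", af_key,
                        " skipped")
            keep <- !miss & maf > maf_floor
            if (any(keep)) {
                g <- granges(rr)[keep]
                mcols(g) <- DataFrame(
                    ref = as.character(rr$REF)[keep],
                    alt = vapply(rr$ALT[keep], function(a)
                        as.character(a[[1]]), character(1)),
                    maf = maf[keep], kind = "SNP")
                out <- g
            }
        }
    }
    if (!is.null(somatic_path)) {
        tab <- utils::read.table(somatic_path, header = FALSE, sep = "\t",
                                 col.names = c("chrom", "pos", "alt"),
                                 colClasses = c("character", "integer",
                                                "character"))
        if (nrow(tab)) {
            g <- GRanges(tab$chrom, IRanges(tab$pos, tab$pos))
            mcols(g) <- DataFrame(ref = NA_character_, alt = tab$alt,
                                  maf = NA_real_, kind = "SOMATIC")
            out <- if (length(out)) suppressWarnings(c(out, g)) else g
        }
    }
    out
}

#' Read a conservation track from bedGraph
#'
#' @param path bedGraph file (0-based half-open, converted on import);
#'   scores must lie in \[0, 1\]. Intervals must not overlap within a
#'   chromosome.
#' @return A `GRanges` with a `score` metadata column. Positions not covered
#'   by any interval implicitly score 0.
#' @export
readConservation <- function(path) {
    gr <- rtracklayer::import(path, format = "bedGraph")
    if (any(gr$score < 0 | gr$score > 1))
        stop("conservation scores must lie in [0, 1]")
    if (any(countOverlaps(gr, gr) > 1L))
        stop("conservation intervals overlap within a chromosome")
    gr
}

#' Mean conservation over intervals
#'
#' Arithmetic mean of per-base conservation over each query interval, with
#' bases not covered by the track counting 0.
#'
#' @param track Conservation `GRanges` from [readConservation()] (or any
#'   non-overlapping scored `GRanges`).
#' @param gr Query `GRanges`; empty (zero-width) intervals are an error.
#' @return Numeric vector in \[0, 1\], one value per query.
#' @examples
#' track <- GenomicRanges::GRanges("chr1",
#'     IRanges::IRanges(c(1, 11), c(10, 20)), score = c(0.2, 0.6))
#' meanConservation(track, GenomicRanges::GRanges("chr1",
#'     IRanges::IRanges(6, 15)))   # 0.4
#' @export
meanConservation <- function(track, gr) {
    if (any(width(gr) < 1L)) stop("empty interval in conservation query")
    hits <- findOverlaps(gr, track, ignore.strand = TRUE)
    covered <- numeric(length(gr))
    if (length(hits)) {
        ov <- pintersect(granges(gr)[S4Vectors::queryHits(hits)],
                         granges(track)[S4Vectors::subjectHits(hits)],
                         ignore.strand = TRUE)
        contrib <- width(ov) * track$score[S4Vectors::subjectHits(hits)]
        agg <- tapply(contrib, S4Vectors::queryHits(hits), sum)
        covered[as.integer(names(agg))] <- agg
    }
    covered / width(gr)
}

#' Build an exon region index for off-target classification
#'
#' Indexes every exon of every gene (coding and non-coding). A gene with at
#' least one CDS-bearing transcript is a coding gene; all its exons are
#' tagged coding.
#'
#' @param models A [GeneModels-class].
#' @return A `GRanges` with metadata columns `gene_id` and `coding`.
#' @export
buildRegionIndex <- function(models) {
    ex <- models@exons
    coding_genes <- unique(models@txInfo$gene_id[models@txInfo$coding])
    idx <- granges(ex)
    mcols(idx) <- DataFrame(gene_id = ex$gene_id,
                            coding = ex$gene_id %in% coding_genes)
    idx
}

#' Classify intervals by exon overlap
#'
#' Returns, for each query interval, `"CODING"` when it overlaps any exon of
#' a coding gene, otherwise `"EXON_NONCODING"` when it overlaps any exon of
#' a non-coding gene, otherwise `"NON_EXON"`. Strand is ignored.
#'
#' @param index Region index from [buildRegionIndex()].
#' @param gr Query `GRanges`.
#' @return Character vector over `{"CODING", "EXON_NONCODING", "NON_EXON"}`.
#' @export
classifyInterval <- function(index, gr) {
    out <- rep("NON_EXON", length(gr))
    out[overlapsAny(gr, index[!index$coding], ignore.strand = TRUE)] <-
        "EXON_NONCODING"
    out[overlapsAny(gr, index[index$coding], ignore.strand = TRUE)] <-
        "CODING"
    out
}
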