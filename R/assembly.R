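## Synthesis-ready oligo assembly, control-guide injection and the final
## library table.

#' Read a construct configuration
#'
#' Key--value TSV with at least the keys `promoter` (5' element, e.g. a U6
#' promoter) and `scaffold` (3' element, e.g. the SpCas9 scaffold). Either
#' value may be empty. The package ships standard public sequences in
#' `system.file("extdata", "construct_u6_scaffold.tsv",
#' package = "guidescreen")`; both are user-replaceable.
#'
#' @param path Construct config TSV.
#' @return A list with elements `promoter` and `scaffold`.
#' @export
readConstructConfig <- function(path) {
    tab <- utils::read.table(path, header = FALSE, sep = "\t",
                             col.names = c("key", "value"),
                             colClasses = "character", fill = TRUE,
                             quote = "")
    kv <- stats::setNames(tab$value, tab$key)
    for (k in c("promoter", "scaffold"))
        if (!k %in% names(kv)) stop("construct config lacks key '", k, "'")
    list(promoter = toupper(kv[["promoter"]]),
         scaffold = toupper(kv[["scaffold"]]))
}

#' Assemble a synthesis oligo
#'
#' Concatenates `promoter + spacer + scaffold`. With `force_5prime_g`, a G
#' is prepended to the spacer segment when it does not already start with
#' one (required for efficient transcription from U6-family promoters).
#'
#' @param spacer Spacer sequence (non-empty).
#' @param construct List with `promoter` and `scaffold` elements (either may
#'   be the empty string), e.g. from [readConstructConfig()].
#' @param force_5prime_g Prepend G to non-G-initial spacers.
#' @return The oligo sequence (character scalar).
#' @examples
#' buildOligo("ACGTACGTACGTACGTACGT",
#'            list(promoter = "AAA", scaffold = "TTT"))
#' @export
buildOligo <- function(spacer,
                       construct = list(promoter = "", scaffold = ""),
                       force_5prime_g = FALSE) {
    if (length(spacer) != 1L || is.na(spacer) || !nzchar(spacer))
        stop("empty spacer")
    seg <- spacer
    if (force_5prime_g && substr(seg, 1L, 1L) != "G")
        seg <- paste0("G", seg)
    paste0(construct$promoter, seg, construct$scaffold)
}

#' Read a control-guide list
#'
#' TSV with two columns, `name` and `spacer` (a header line is allowed and
#' detected). Spacer lengths must equal the library spacer length; a
#' mismatch is an error naming the offending entry.
#'
#' @param path Control TSV.
#' @param spacer_len Required spacer length.
#' @return A `data.frame` with columns `name` and `spacer`.
#' @export
readControls <- function(path, spacer_len = 20L) {
    tab <- utils::read.table(path, header = FALSE, sep = "\t",
                             col.names = c("name", "spacer"),
                             colClasses = "character", quote = "")
    if (nrow(tab) && tolower(tab$name[1]) == "name")
        tab <- tab[-1L, , drop = FALSE]
    bad <- nchar(tab$spacer) != spacer_len
    if (any(bad))
        stop("control spacer length mismatch (need ", spacer_len, " nt): ",
             paste(tab$name[bad], collapse = ", "))
    rownames(tab) <- NULL
    tab
}

#' Append control guides to a library
#'
#' Negative controls get gene_id `CTRL_NEG`, positive controls `CTRL_POS`;
#' scores are blank and the status is `CONTROL`. Requesting more controls
#' than a set provides takes the whole set.
#'
#' @param rows Library `data.frame` from [selectGuides()]/`runDesign()`.
#' @param negatives,positives Control `data.frame`s from [readControls()],
#'   or `NULL`.
#' @param n_neg,n_pos Number of controls to append from each set (default:
#'   all).
#' @return The library `data.frame` with control rows appended.
#' @export
attachControls <- function(rows, negatives = NULL, positives = NULL,
                           n_neg = Inf, n_pos = Inf) {
    add <- function(set, label, k) {
        if (is.null(set) || nrow(set) == 0L || k <= 0) return(NULL)
        set <- set[seq_len(min(k, nrow(set))), , drop = FALSE]
        out <- data.frame(gene_id = label, rank = seq_len(nrow(set)),
                          chrom = NA_character_, start = NA_integer_,
                          end = NA_integer_, strand = NA_character_,
                          spacer = set$spacer, pam = NA_character_,
                          efficiency = NA_real_, specificity = NA_real_,
                          conservation = NA_real_, commonality = NA_real_,
                          summary_score = NA_real_,
                          w_efficiency = NA_real_, w_specificity = NA_real_,
                          w_conservation = NA_real_,
                          w_commonality = NA_real_,
                          n_variant_hits = NA_integer_,
                          n_perfect_offtargets = NA_integer_,
                          offtarget_category = NA_character_,
                          status = "CONTROL", stringsAsFactors = FALSE)
        out
    }
    rbind(rows, add(negatives, "CTRL_NEG", n_neg),
          add(positives, "CTRL_POS", n_pos))
}

#' Write the library table
#'
#' Tab-separated, one header line, fixed column order; floats printed at 4
#' decimals, missing values as empty fields. Output is byte-identical
#' across runs on identical input. Optionally adds an `oligo` column
#' assembled with [buildOligo()].
#'
#' @param rows Library `data.frame`.
#' @param path Output path.
#' @param include_oligo Add the assembled-oligo column.
#' @param construct Construct list for [buildOligo()] (used only when
#'   `include_oligo`).
#' @param force_5prime_g Passed to [buildOligo()].
#' @return `path`, invisibly.
#' @export
writeLibrary <- function(rows, path, include_oligo = FALSE,
                         construct = list(promoter = "", scaffold = ""),
                         force_5prime_g = FALSE) {
    num4 <- c("efficiency", "specificity", "conservation", "commonality",
              "summary_score", "w_efficiency", "w_specificity",
              "w_conservation", "w_commonality")
    out <- rows
    for (cl in num4)
        out[[cl]] <- ifelse(is.na(rows[[cl]]), "",
                            sprintf("%.4f", rows[[cl]]))
    if (include_oligo)
        out$oligo <- vapply(rows$spacer, buildOligo, character(1),
                            construct = construct,
                            force_5prime_g = force_5prime_g,
                            USE.NAMES = FALSE)
    for (cl in colnames(out))
        if (!is.character(out[[cl]]))
            out[[cl]] <- ifelse(is.na(out[[cl]]), "",
                                as.character(out[[cl]]))
        else out[[cl]][is.na(out[[cl]])] <- ""
    con <- file(path, open = "wb")          # LF endings on every platform
    on.exit(close(con))
    writeLines(paste(colnames(out), collapse = "\t"), con)
    if (nrow(out))
        writeLines(do.call(paste, c(unname(as.list(out)), sep = "\t")), con)
    invisible(path)
}

#' Re-validate library rows against the genome
#'
#' Checks that every non-control row's spacer, re-extracted from the
#' assembly at (chrom, start, end, strand), equals the stored spacer.
#'
#' @param rows Library `data.frame`.
#' @param asm A [ReferenceAssembly-class].
#' @return `TRUE`, invisibly; mismatches are an error.
#' @export
validateLibrary <- function(rows, asm) {
    g <- rows[rows$status != "CONTROL", , drop = FALSE]
    if (nrow(g) == 0L) return(invisible(TRUE))
    gr <- GRanges(g$chrom, IRanges(g$start, g$end), strand = g$strand)
    got <- getRefSeq(asm, gr)
    bad <- got != g$spacer
    if (any(bad))
        stop("library row(s) do not re-validate against the genome: ",
             paste(utils::head(which(bad)), collapse = ", "))
    invisible(TRUE)
}
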