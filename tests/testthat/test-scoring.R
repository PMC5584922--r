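test_that("efficiency scoring is the intercept plus positional weights", {
    set.seed(31)
    asm <- make_asm(list(c1 = rand_dna(2000)))
    g <- scanPamSites(asm, GRanges("c1", IRanges(1, 2000)))
    g <- g[!is.na(g$context)]

    m0 <- readEfficiencyModel(eff_model_file(0.37))
    expect_true(all(scoreEfficiency(g, m0)$efficiency == 0.37))

    # +1 for G at context position 1: scores differ by exactly 1
    m1 <- readEfficiencyModel(eff_model_file(
        0, data.frame(position = 1L, nucleotide = "G", weight = 1)))
    s1 <- scoreEfficiency(g, m1)$efficiency
    first <- substr(g$context, 1, 1)
    expect_true(all(s1[first == "G"] == 1))
    expect_true(all(s1[first != "G"] == 0))

    # toy 4-position model, hand-summed on one candidate
    rows <- data.frame(position = c(1L, 2L, 11L, 30L),
                       nucleotide = c("A", "C", "G", "T"),
                       weight = c(0.1, -0.2, 0.3, 0.05))
    mt <- readEfficiencyModel(eff_model_file(0.5, rows))
    ctx <- strsplit(g$context[1], "")[[1]]
    hand <- 0.5 +
        0.1 * (ctx[1] == "A") - 0.2 * (ctx[2] == "C") +
        0.3 * (ctx[11] == "G") + 0.05 * (ctx[30] == "T")
    expect_equal(scoreEfficiency(g[1], mt)$efficiency, hand)
})

test_that("efficiency scoring is linear in the coefficient table", {
    set.seed(32)
    asm <- make_asm(list(c1 = rand_dna(1500)))
    g <- scanPamSites(asm, GRanges("c1", IRanges(1, 1500)))
    g <- g[!is.na(g$context)][1:10]
    rowsA <- data.frame(position = c(3L, 12L, 25L),
                        nucleotide = c("A", "G", "T"),
                        weight = c(0.2, 0.4, -0.1))
    rowsB <- data.frame(position = c(4L, 18L),
                        nucleotide = c("A", "C"),
                        weight = c(-0.05, 0.33))
    mA <- readEfficiencyModel(eff_model_file(0.1, rowsA))
    mB <- readEfficiencyModel(eff_model_file(0.25, rowsB))
    mAB <- readEfficiencyModel(eff_model_file(
        0.35, rbind(rowsA, rowsB)))
    sA <- scoreEfficiency(g, mA)$efficiency
    sB <- scoreEfficiency(g, mB)$efficiency
    sAB <- scoreEfficiency(g, mAB)$efficiency
    expect_equal(sAB, sA + sB, tolerance = 1e-12)
})

test_that("candidates with truncated context are unscorable", {
    # protospacer close to the chromosome start: no 5' flank
    s <- paste0(rand_dna(22), "AGG", rand_dna(50))
    asm <- make_asm(list(c1 = s))
    g <- scanPamSites(asm, GRanges("c1", IRanges(1, nchar(s))))
    near_start <- g[start(g) <= 10 & strand(g) == "+"]
    if (length(near_start)) {
        m <- readEfficiencyModel(eff_model_file(1))
        expect_true(all(is.na(scoreEfficiency(near_start, m)$efficiency)))
    }
    expect_true(any(is.na(g$context)) || length(near_start) == 0L)
})

test_that("off-target enumeration matches the sliding-window Hamming oracle", {
    set.seed(41)
    # planted structure: an exact copy and near-matches at 1-3 mismatches
    spacer <- NULL
    base <- rand_dna(8000)
    asm0 <- make_asm(list(c1 = base))
    g <- scanPamSites(asm0, GRanges("c1", IRanges(1, 2000)))
    g <- g[strand(g) == "+"]
    spacer <- g$spacer[1]
    mutate_at <- function(s, pos) {
        for (p in pos) {
            old <- substr(s, p, p)
            substr(s, p, p) <- setdiff(c("A", "C", "G", "T"), old)[1]
        }
        s
    }
    copies <- paste0(
        spacer, "TGG", rand_dna(20),
        mutate_at(spacer, 5L), "AGG", rand_dna(20),
        mutate_at(spacer, c(3L, 17L)), "CGG", rand_dna(20),
        mutate_at(spacer, c(2L, 9L, 15L)), "GGG", rand_dna(20),
        mutate_at(spacer, c(1L, 6L, 11L, 16L)), "AGG", rand_dna(20),  # 4 mm
        mutate_at(spacer, 8L), "ATT", rand_dna(20))                   # bad PAM
    seqs <- list(c1 = base, c2 = paste0(rand_dna(500), copies,
                                        rand_dna(500)))
    asm <- make_asm(seqs)
    hits <- enumerateOfftargets(spacer, asm, max_mismatch = 3L)
    o <- oracle_offtargets(vapply(seqs, identity, character(1)), spacer, 3L)
    expect_identical(length(hits), nrow(o))
    expect_setequal(
        paste(seqnames(hits), start(hits), strand(hits), hits$n_mismatch),
        paste(o$chrom, o$start, o$strand, o$n_mismatch))
    # mismatch positions are PAM-distal-0 indices of actual mismatches
    for (i in seq_along(hits)) {
        got <- getRefSeq(asm, granges(hits[i]))
        mmpos <- which(strsplit(got, "")[[1]] !=
                       strsplit(spacer, "")[[1]]) - 1L
        expect_identical(hits$mismatch_positions[[i]], mmpos)
    }
    # planted exact copy on c2 is a perfect hit; the 4-mismatch and bad-PAM
    # copies are absent
    perf <- hits[hits$n_mismatch == 0L]
    expect_setequal(as.character(seqnames(perf)), c("c1", "c2"))
})

test_that("a unique spacer yields only its own locus", {
    set.seed(43)
    asm <- make_asm(list(c1 = rand_dna(4000)))
    g <- scanPamSites(asm, GRanges("c1", IRanges(1, 4000)))
    hits <- enumerateOfftargets(g$spacer[1], asm, max_mismatch = 0L,
                                self = granges(g[1]))
    expect_identical(length(hits), 1L)
    expect_identical(hits$category, "ON_TARGET")
})

test_that("specificity aggregates Hsu penalties over off-target hits", {
    pen <- hsu_penalty()
    mk_hits <- function(mm_list, categories) {
        gr <- GRanges("c9", IRanges(seq(1, by = 50,
                                        length.out = length(mm_list)),
                                    width = 20), strand = "+")
        gr$n_mismatch <- lengths(mm_list)
        gr$mismatch_positions <- IRanges::IntegerList(mm_list)
        gr$category <- categories
        gr
    }
    on <- mk_hits(list(integer(0)), "ON_TARGET")
    expect_equal(specificityScore(on, pen), 100)
    one_perfect <- mk_hits(list(integer(0), integer(0)),
                           c("ON_TARGET", "NON_EXON"))
    expect_equal(specificityScore(one_perfect, pen), 50)

    # hand-evaluated single hit with mismatches at indices 5 and 10
    h <- mk_hits(list(integer(0), c(5L, 10L)), c("ON_TARGET", "CODING"))
    W <- c(0.000, 0.000, 0.014, 0.000, 0.000, 0.395, 0.317, 0.000, 0.389,
           0.079, 0.445, 0.508, 0.613, 0.851, 0.732, 0.828, 0.615, 0.804,
           0.685, 0.583)
    s_h <- (1 - W[6]) * (1 - W[11]) *
        (1 / (((19 - 5) / 19) * 4 + 1)) * (1 / 4)
    expect_equal(specificityScore(h, pen), 100 / (1 + s_h))

    # monotonicity: every added off-target lowers the score
    prev <- 100
    mm <- list(integer(0))
    cats <- "ON_TARGET"
    set.seed(5)
    for (k in 1:6) {
        mm <- c(mm, list(sort(sample(0:19, sample(0:3, 1)))))
        cats <- c(cats, "NON_EXON")
        cur <- specificityScore(mk_hits(mm, cats), pen)
        expect_lt(cur, prev)
        prev <- cur
    }
    expect_error(specificityScore(GRanges(), pen), "on-target")
})

test_that("variant annotation respects the footprint choice", {
    g <- make_guides(data.frame(start = 101L, strand = "+",
                                spacer = rand_spacer()))
    # spacer occupies 101..120, PAM 121..123 on the plus strand
    at <- function(pos) GRanges("chr1", IRanges(pos, pos), ref = "A",
                                alt = "T", maf = 0.2, kind = "SNP")
    expect_identical(
        annotateVariants(g, at(105L))$n_snp_hits, 1L)          # inside spacer
    expect_identical(
        annotateVariants(g, at(124L))$n_snp_hits, 0L)          # past the PAM
    expect_identical(
        annotateVariants(g, at(122L))$n_snp_hits, 1L)          # in the PAM
    expect_identical(
        annotateVariants(g, at(122L), footprint = "SPACER")$n_snp_hits, 0L)

    # minus-strand PAM lies 5' of the protospacer interval
    gm <- make_guides(data.frame(start = 201L, strand = "-",
                                 spacer = rand_spacer()))
    expect_identical(
        annotateVariants(gm, at(199L))$n_snp_hits, 1L)
    expect_identical(
        annotateVariants(gm, at(199L), footprint = "SPACER")$n_snp_hits, 0L)
})
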