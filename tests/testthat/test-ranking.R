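test_that("hard filters apply strict boundaries and record all reasons", {
    sp9 <- paste0(strrep("G", 9), strrep("A", 11))    # 45% G
    sp8 <- paste0(strrep("G", 8), strrep("A", 12))    # 40% G
    g <- make_guides(data.frame(
        start = c(101L, 201L, 301L, 401L, 501L, 601L, 701L),
        strand = "+",
        spacer = c(sp9, sp8, rand_spacer(), rand_spacer(), rand_spacer(),
                   rand_spacer(), sp9),
        efficiency = c(0.5, 0.5, -0.01, 0, 0.5, 0.5, -1),
        n_snp = c(0L, 0L, 0L, 0L, 1L, 0L, 1L),
        n_perfect = c(0L, 0L, 0L, 0L, 0L, 1L, 0L),
        category = c(NA, NA, NA, NA, NA, "NON_EXON", NA)))
    rep <- filterCandidates(g)
    passed <- passedGuides(rep)
    filtered <- filteredGuides(rep)
    pool <- rescuePool(rep)

    # strict > 40% G: 9/20 removed, 8/20 kept
    expect_true(101 %in% start(filtered) &&
                grepl("HIGH_G", filtered$reasons[start(filtered) == 101]))
    expect_true(201 %in% start(passed))
    # strict < 0 efficiency: -0.01 removed, 0.0 kept
    expect_true(301 %in% start(filtered) &&
                grepl("LOW_EFFICIENCY",
                      filtered$reasons[start(filtered) == 301]))
    expect_true(401 %in% start(passed))
    # variant overlap removed
    expect_true(501 %in% start(filtered))
    # perfect off-target only -> rescue pool with its category
    expect_identical(start(pool), 601L)
    expect_identical(pool$rescue_category, "NON_EXON")
    # multiple violations recorded together
    r7 <- filtered$reasons[start(filtered) == 701]
    expect_true(grepl("VARIANT_OVERLAP", r7) && grepl("HIGH_G", r7) &&
                grepl("LOW_EFFICIENCY", r7))

    # somatic hits only count when requested
    gs <- make_guides(data.frame(start = 101L, strand = "+",
                                 spacer = rand_spacer(), n_somatic = 1L))
    expect_identical(length(passedGuides(filterCandidates(gs))), 1L)
    expect_identical(
        length(passedGuides(filterCandidates(gs, use_somatic = TRUE))), 0L)
})

test_that("filtering partitions the input exactly", {
    set.seed(53)
    for (rep_i in 1:10) {
        n <- sample(1:40, 1)
        g <- make_guides(data.frame(
            start = seq(101L, by = 50L, length.out = n), strand = "+",
            spacer = vapply(seq_len(n), function(i) rand_spacer(),
                            character(1)),
            efficiency = runif(n, -0.5, 1),
            n_snp = rbinom(n, 1, 0.2),
            n_perfect = rbinom(n, 2, 0.2),
            category = sample(c("NON_EXON", "CODING"), n, TRUE)))
        g$offtarget_category[g$n_perfect_offtargets == 0L] <- NA_character_
        r <- filterCandidates(g)
        expect_identical(length(passedGuides(r)) +
                         length(filteredGuides(r)) +
                         length(rescuePool(r)), length(g))
        keys <- c(guideKeys(passedGuides(r)), guideKeys(filteredGuides(r)),
                  guideKeys(rescuePool(r)))
        expect_setequal(keys, guideKeys(g))
    }
})

cm_from_raw <- function(raw, conflict = "sum") {
    g <- make_guides(data.frame(
        start = seq(101L, by = 50L, length.out = nrow(raw)), strand = "+",
        spacer = vapply(seq_len(nrow(raw)), function(i) rand_spacer(),
                        character(1)),
        efficiency = raw[, 1], specificity = raw[, 2],
        conservation = raw[, 3], commonality = raw[, 4]))
    buildCriteriaMatrix(g, conflict = conflict)
}

test_that("CRITIC puts all weight on the only informative criterion", {
    raw <- cbind(c(0.1, 0.5, 0.9), rep(50, 3), rep(0.5, 3), rep(1, 3))
    cm <- cm_from_raw(raw)
    expect_equal(unname(criteriaWeights(cm)), c(1, 0, 0, 0))
})

test_that("perfectly correlated criteria share reduced weight", {
    x <- c(0.1, 0.4, 0.9, 0.2)
    raw_pair <- cbind(x, 100 * x, rep(0.5, 4), rep(1, 4))
    w_pair <- criteriaWeights(cm_from_raw(raw_pair))
    raw_solo <- cbind(x, rep(50, 4), rep(0.5, 4), rep(1, 4))
    w_solo <- criteriaWeights(cm_from_raw(raw_solo))
    # both normalize to the same column: equal split between the pair
    expect_equal(w_pair[[1]], w_pair[[2]], tolerance = 1e-12)
    expect_equal(w_pair[[1]] + w_pair[[2]], 1, tolerance = 1e-12)
    expect_lt(w_pair[[1]], w_solo[[1]])
    # hand evaluation: sigma equal, r = 1 within the pair, r = 0 to the
    # constant columns -> C_j = sigma * (0 + 1 + 1) for each of the pair
    expect_equal(unname(w_pair), c(0.5, 0.5, 0, 0), tolerance = 1e-12)
})

test_that("CRITIC weights match an independent step-by-step oracle", {
    set.seed(61)
    for (rep_i in 1:60) {
        raw <- matrix(runif(20), 5, 4)
        conflict <- sample(c("sum", "product"), 1)
        cm <- cm_from_raw(raw, conflict)
        expect_equal(unname(criteriaWeights(cm)),
                     oracle_critic(raw, conflict), tolerance = 1e-9)
        expect_equal(sum(criteriaWeights(cm)), 1, tolerance = 1e-9)
        expect_true(all(criteriaWeights(cm) >= 0))
    }
})

test_that("degenerate criteria matrices fall back to uniform weights", {
    # all-constant matrix
    cm <- cm_from_raw(matrix(rep(c(0.3, 50, 0.5, 1), each = 4), 4, 4))
    expect_equal(unname(criteriaWeights(cm)), rep(0.25, 4))
    # fewer than 3 candidates
    cm2 <- cm_from_raw(matrix(runif(8), 2, 4))
    expect_equal(unname(criteriaWeights(cm2)), rep(0.25, 4))
    expect_error(buildCriteriaMatrix(guidescreen:::newGuideSet()),
                 "0 candidates")
})

test_that("weights are invariant under affine rescaling of a raw column", {
    set.seed(67)
    raw <- matrix(runif(24), 6, 4)
    w1 <- criteriaWeights(cm_from_raw(raw))
    raw2 <- raw
    raw2[, 2] <- raw2[, 2] * 37 + 5
    w2 <- criteriaWeights(cm_from_raw(raw2))
    expect_equal(w1, w2, tolerance = 1e-12)
})

test_that("summary scores are the weighted normalized criteria", {
    set.seed(71)
    raw <- matrix(runif(20), 5, 4)
    cm <- cm_from_raw(raw)
    s <- summaryScores(cm)
    # dot-product oracle
    norm <- apply(raw, 2, function(x) (x - min(x)) / (max(x) - min(x)))
    expect_equal(unname(s), unname(drop(norm %*% criteriaWeights(cm))),
                 tolerance = 1e-12)

    # a candidate dominating every criterion ranks first
    raw_dom <- rbind(c(1, 100, 1, 1), matrix(runif(12, 0, 0.5), 3, 4))
    cm_dom <- cm_from_raw(raw_dom)
    expect_identical(unname(which.max(summaryScores(cm_dom))), 1L)

    # with a single informative criterion the ranking follows it
    raw_eff <- cbind(runif(5), rep(50, 5), rep(0.5, 5), rep(1, 5))
    cm_eff <- cm_from_raw(raw_eff)
    expect_identical(order(-summaryScores(cm_eff)), order(-raw_eff[, 1]))
})

rescue_report <- function(spec) {
    g <- make_guides(spec)
    filterCandidates(g)
}

test_that("rescue prefers benign categories, then fewer hits, then score", {
    # category precedence
    r <- rescue_report(data.frame(
        start = c(101L, 201L), strand = "+",
        spacer = c(rand_spacer(), rand_spacer()),
        n_perfect = 1L, category = c("NON_EXON", "CODING")))
    out <- rescueGuides(r, 1L)
    expect_identical(start(out), 101L)
    expect_identical(out$status, "RESCUED_NON_EXON")

    # fewer hits first within a category
    r <- rescue_report(data.frame(
        start = c(101L, 201L), strand = "+",
        spacer = c(rand_spacer(), rand_spacer()),
        n_perfect = c(2L, 1L), category = "NON_EXON"))
    expect_identical(start(rescueGuides(r, 1L)), 201L)

    # equal category and count: higher summary score wins
    r <- rescue_report(data.frame(
        start = c(101L, 201L, 301L, 401L), strand = "+",
        spacer = vapply(1:4, function(i) rand_spacer(), character(1)),
        efficiency = c(0.9, 0.9, 0.1, 0.9),
        conservation = c(0.9, 0.2, 0.8, 0.1),
        n_perfect = c(0L, 1L, 1L, 0L),
        category = c(NA, "EXON_NONCODING", "EXON_NONCODING", NA)))
    out <- rescueGuides(r, 2L)
    expect_identical(start(out), c(201L, 301L))  # 201 scores higher
})

test_that("rescue ordering satisfies category over count over score", {
    set.seed(73)
    for (rep_i in 1:25) {
        n <- sample(4:15, 1)
        spec <- data.frame(
            start = seq(101L, by = 50L, length.out = n), strand = "+",
            spacer = vapply(seq_len(n), function(i) rand_spacer(),
                            character(1)),
            efficiency = runif(n), conservation = runif(n),
            n_perfect = sample(1:3, n, TRUE),
            category = sample(c("NON_EXON", "EXON_NONCODING", "CODING"),
                              n, TRUE))
        r <- rescue_report(spec)
        out <- rescueGuides(r, n)
        expect_identical(length(out), length(rescuePool(r)))
        lev <- match(out$rescue_category,
                     c("NON_EXON", "EXON_NONCODING", "CODING"))
        expect_true(all(diff(lev) >= 0))
        within_cat <- split(seq_along(out), lev)
        for (idx in within_cat)
            expect_true(all(diff(out$n_perfect_offtargets[idx]) >= 0))
        # score-descending within equal (category, count) blocks
        key <- paste(lev, out$n_perfect_offtargets)
        for (blk in split(seq_along(out), key))
            expect_true(all(diff(out$summary_score[blk]) <= 1e-12))
        # no CODING rescue while a NON_EXON candidate remains unrescued
        short <- rescueGuides(r, 1L)
        if (any(out$rescue_category == "NON_EXON"))
            expect_identical(short$rescue_category, "NON_EXON")
    }
})

test_that("selectGuides composes collection, scoring, filtering and ranking", {
    set.seed(79)
    asm <- make_asm(list(chr1 = rand_dna(3000)))
    models <- make_models(list(
        list(gene = "G", tx = "t1", chrom = "chr1", strand = "+",
             coding = TRUE, exons = rbind(c(501L, 800L)))), asm)
    eff <- readEfficiencyModel(eff_model_file(1))   # everything passes
    pen <- readSpecificityPenalty(
        system.file("extdata", "hsu2013_mismatch_penalties.tsv",
                    package = "guidescreen"))
    res <- selectGuides("G", models, asm, n = 5, eff_model = eff,
                        penalty = pen)
    expect_identical(nrow(res$rows), 5L)
    expect_true(all(res$rows$status == "PASSED"))
    expect_identical(res$rows$rank, 1:5)
    expect_true(all(diff(res$rows$summary_score) <= 1e-12))
    expect_equal(sum(res$weights), 1, tolerance = 1e-9)

    # identical call is deterministic
    res2 <- selectGuides("G", models, asm, n = 5, eff_model = eff,
                         penalty = pen)
    expect_identical(res$rows, res2$rows)

    # n outside 1..30 is rejected; missing gene warns and yields no rows
    expect_error(selectGuides("G", models, asm, n = 31, eff_model = eff,
                              penalty = pen), "between 1 and 30")
    expect_warning(
        r0 <- selectGuides("NOPE", models, asm, n = 3, eff_model = eff,
                           penalty = pen), "no exons|no candidates")
    expect_identical(nrow(r0$rows), 0L)
})
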