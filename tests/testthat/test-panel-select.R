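test_that("spacing pruning removes the lower-scoring conflicting locus", {
    cand <- data.frame(locus_id = c("La", "Lb"), chrom = "chr1",
                       pos = c(1e6, 1.5e6), score = c(0.9, 0.8))
    res <- pruneBySpacing(cand, 1e6)
    expect_equal(res$survivors$locus_id, "La")
    expect_equal(res$removals$removed, "Lb")
    expect_equal(res$removals$conflicting, "La")
})

test_that("loci on different chromosomes never conflict", {
    cand <- data.frame(locus_id = paste0("L", 1:4),
                       chrom = c("chr1", "chr2", "chr3", "chr4"),
                       pos = rep(100L, 4), score = runif(4))
    res <- pruneBySpacing(cand, 1e6)
    expect_equal(nrow(res$survivors), 4L)
    expect_equal(nrow(res$removals), 0L)
})

test_that("random instances satisfy the post-hoc spacing oracle", {
    set.seed(77)
    for (k in 1:5) {
        cand <- data.frame(
            locus_id = sprintf("L%03d", 1:100),
            chrom = sample(paste0("chr", 1:4), 100, replace = TRUE),
            pos = sample.int(3e7, 100),
            score = round(runif(100), 3))
        res <- pruneBySpacing(cand, 1e6)
        expect_true(spacingOracleOK(cand, res, 1e6))
        ## every removal names a retained, at-least-as-good conflict
        for (i in seq_len(nrow(res$removals))) {
            rem <- res$removals$removed[i]
            con <- res$removals$conflicting[i]
            expect_true(con %in% res$survivors$locus_id)
            expect_gte(cand$score[cand$locus_id == con],
                       cand$score[cand$locus_id == rem])
        }
    }
})

test_that("pruning is invariant to input row order", {
    set.seed(42)
    cand <- data.frame(locus_id = sprintf("L%03d", 1:60),
                       chrom = sample(paste0("chr", 1:2), 60,
                                      replace = TRUE),
                       pos = sample.int(2e7, 60),
                       score = round(runif(60), 3))
    a <- pruneBySpacing(cand, 1e6)
    b <- pruneBySpacing(cand[sample(60), ], 1e6)
    expect_setequal(a$survivors$locus_id, b$survivors$locus_id)
})

test_that("top-K selection honours quotas and score ordering", {
    brown <- data.frame(locus_id = c("L1", "L2"), chrom = c("c1", "c2"),
                        pos = c(1e6, 1e6), score = c(0.7, 0.3))
    black <- data.frame(locus_id = "L3", chrom = "c3", pos = 1e6,
                        score = 0.5)
    between <- data.frame(locus_id = "L4", theta = 1)
    p <- selectPanel(brown, black, between,
                     selectConfig(top_k_per_species = 1, n_diagnostic = 0))
    expect_equal(panelLoci(p, "brown_informative"), "L1")
    expect_equal(nrow(panelEntries(p)), 2L)
})

test_that("small instances match brute-force greedy enumeration", {
    set.seed(55)
    for (k in 1:4) {
        cand <- data.frame(locus_id = sprintf("L%02d", 1:20),
                           chrom = sample(c("c1", "c2"), 20,
                                          replace = TRUE),
                           pos = sample.int(8e6, 20),
                           score = round(runif(20), 3))
        ## brute force: walk loci in descending score, keep if compatible
        ord <- order(-cand$score, cand$locus_id)
        kept <- integer()
        for (i in ord) {
            ok <- !any(cand$chrom[kept] == cand$chrom[i] &
                       abs(cand$pos[kept] - cand$pos[i]) < 1e6)
            if (ok) kept <- c(kept, i)
        }
        expected_top <- cand$locus_id[kept][
            order(-cand$score[kept], cand$locus_id[kept])][1:5]
        surv <- pruneBySpacing(cand, 1e6)$survivors
        top <- surv[order(-surv$score, surv$locus_id), ][1:5, "locus_id"]
        expect_equal(top, expected_top)
    }
})

test_that("panel selection respects quotas, spacing and role exclusivity", {
    cfg <- simConfig(seed = 202, n_loci = 800L, n_per_pop = 15L)
    ge <- simulateGenotypes(cfg)
    des <- designPanel(ge, selectCfg = selectConfig(
        top_k_per_species = 50, n_diagnostic = 4))
    e <- panelEntries(des$panel)
    for (role in c("brown_informative", "black_informative")) {
        sel <- e$score[e$role == role]
        expect_equal(length(sel), 50L)
    }
    ## spacing invariant within each informative role
    li <- as.data.frame(locusInfo(ge))
    for (role in c("brown_informative", "black_informative")) {
        ids <- e$locus_id[e$role == role]
        pos <- li$pos[match(ids, li$locus_id)]
        chr <- li$chrom[match(ids, li$locus_id)]
        for (ch in unique(chr)) {
            p <- sort(pos[chr == ch])
            if (length(p) > 1) expect_gte(min(diff(p)), 1e6)
        }
    }
    ## roles are exclusive: no locus appears twice
    expect_equal(anyDuplicated(e$locus_id), 0L)
})

test_that("diagnostic loci prefer fixed species differences", {
    cfg <- simConfig(seed = 301, n_loci = 600L, n_per_pop = 15L,
                     n_diagnostic_fixed = 60L)
    ge <- simulateGenotypes(cfg)
    des <- designPanel(ge, selectCfg = selectConfig(
        top_k_per_species = 30, n_diagnostic = 8))
    e <- panelEntries(des$panel)
    diag <- e[e$role == "species_diagnostic", ]
    expect_equal(nrow(diag), 8L)
    truth <- S4Vectors::metadata(ge)$diagnostic_loci
    ## fixed differences carry theta 1 and should dominate the picks
    expect_gte(sum(diag$locus_id %in% truth), 6L)
    expect_gte(min(diag$score), 0.9)
})

test_that("panel JSON round-trips", {
    brown <- data.frame(locus_id = c("L1", "L2"), chrom = "c1",
                        pos = c(1e6, 5e6), score = c(0.7, 0.3))
    black <- data.frame(locus_id = "L3", chrom = "c3", pos = 1e6,
                        score = 0.5)
    between <- data.frame(locus_id = "L4", theta = 1)
    p <- suppressWarnings(selectPanel(  # black supply short of top_k = 2
        brown, black, between,
        selectConfig(top_k_per_species = 2, n_diagnostic = 1)))
    json <- withr::local_tempfile(fileext = ".json")
    tsv <- withr::local_tempfile(fileext = ".tsv")
    expect_warning(writePanel(p, json, tsv), NA)
    back <- readPanel(json)
    expect_equal(panelEntries(back), panelEntries(p))
})
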