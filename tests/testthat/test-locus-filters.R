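test_that("locusStats matches hand counts and flags all-missing loci", {
    g <- rbind(c(0L, 1L, 2L, NA), c(NA, NA, NA, NA))
    ge <- makeGE(g)
    st <- locusStats(ge)
    expect_equal(st$call_rate, c(0.75, 0))
    expect_equal(st$p[1], 0.5)
    expect_equal(st$maf[1], 0.5)
    expect_equal(st$ho[1], 1 / 3)
    expect_true(all(is.na(st[2, c("p", "maf", "ho")])))
})

test_that("locusStats equals a brute-force per-cell tally", {
    cfg <- simConfig(seed = 5, n_loci = 60L, n_pops = 2L, n_per_pop = 50L,
                     replicate_fraction = 0)
    ge <- simulateGenotypes(cfg)   # 200 samples
    st <- locusStats(ge, "brown")
    g <- genotypes(ge)[, sampleMeta(ge)$species == "brown", drop = FALSE]
    d <- depths(ge)[, sampleMeta(ge)$species == "brown", drop = FALSE]
    for (i in c(1, 17, 42, 60)) {
        row <- g[i, ]
        called <- sum(!is.na(row))
        expect_equal(st$call_rate[i], called / length(row))
        expect_equal(st$p[i],
                     (2 * sum(row == 2, na.rm = TRUE) +
                      sum(row == 1, na.rm = TRUE)) / (2 * called))
        expect_equal(st$ho[i], sum(row == 1, na.rm = TRUE) / called)
        expect_equal(st$mean_depth[i], mean(d[i, !is.na(row)]))
    }
})

test_that("overall call-rate threshold is a strict greater-than", {
    ## 0.89 < 0.90 and 0.90 itself both fail; 0.91 passes
    g <- matrix(rep(c(0L, 1L, 2L, 0L, 1L), 20), nrow = 1)  # 100 samples
    g <- rbind(g, g, g)
    g[1, 1:11] <- NA   # call rate 0.89
    g[2, 1:10] <- NA   # call rate 0.90 exactly
    g[3, 1:9] <- NA    # call rate 0.91
    ge <- makeGE(g, populations = rep(c("i1", "i2"), each = 50),
                 species = rep(c("brown", "black"), each = 50))
    res <- suppressWarnings(applyFilterCascade(
        ge, filterConfig(min_call_rate_species = 0.8,
                         min_mean_depth_species = 0)))
    expect_setequal(res$report$removed$call_rate_all, c("L001", "L002"))
    expect_true("L003" %in% res$report$surviving)
})

test_that("a clean locus survives every stage", {
    fix <- makeCascadeFixture()
    res <- applyFilterCascade(fix$ge)
    expect_true(all(fix$survivors %in% res$report$surviving))
})

test_that("12-locus fixture loses one designed casualty per stage", {
    fix <- makeCascadeFixture()
    res <- applyFilterCascade(fix$ge)
    expect_equal(sort(res$report$surviving), fix$survivors)
    for (locus in names(fix$expected)) {
        stage <- fix$expected[[locus]]
        expect_true(locus %in% res$report$removed[[stage]],
                    label = paste(locus, "removed at", stage))
    }
    expect_equal(sum(lengths(res$report$removed)), 8L)
})

test_that("one-SNP-per-tag keeps the argmax under the stated ordering", {
    set.seed(31)
    n_tags <- 50L
    per_tag <- sample(1:4, n_tags, replace = TRUE)
    loci <- data.frame(
        locus_id = sprintf("L%03d", seq_len(sum(per_tag))),
        radtag_id = rep(sprintf("T%03d", seq_len(n_tags)), per_tag),
        tag_offset = sample(1:90, sum(per_tag), replace = TRUE))
    stats <- data.frame(
        locus_id = loci$locus_id,
        call_rate = round(runif(nrow(loci), 0.8, 1), 2),
        maf = round(runif(nrow(loci), 0, 0.5), 2))
    kept <- selectOneSnpPerTag(loci, stats)
    expect_equal(length(kept), n_tags)
    ## brute-force argmax per tag
    for (tag in unique(loci$radtag_id)) {
        ids <- loci$locus_id[loci$radtag_id == tag]
        s <- stats[match(ids, stats$locus_id), ]
        o <- order(-s$call_rate, -s$maf,
                   loci$tag_offset[match(ids, loci$locus_id)], ids)
        expect_true(ids[o][1] %in% kept, label = paste("tag", tag))
        expect_equal(sum(ids %in% kept), 1L)
    }
})

test_that("single-SNP tags and stated call-rate rule are honoured", {
    loci <- data.frame(locus_id = c("La", "Lb", "Lc"),
                       radtag_id = c("T1", "T2", "T2"),
                       tag_offset = c(50L, 50L, 45L))
    stats <- data.frame(locus_id = c("La", "Lb", "Lc"),
                        call_rate = c(0.93, 0.99, 0.95),
                        maf = c(0.1, 0.2, 0.3))
    expect_setequal(selectOneSnpPerTag(loci, stats), c("La", "Lb"))
})

test_that("cascade is idempotent and conserves locus counts", {
    cfg <- simConfig(seed = 13, n_loci = 400L, n_per_pop = 15L)
    ge <- simulateGenotypes(cfg)
    res <- applyFilterCascade(ge)
    st <- res$report$stages
    ## conservation at every stage and across the whole cascade
    expect_equal(st$n_in[-1], st$n_out[-nrow(st)])
    expect_equal(st$n_in[1] - sum(lengths(res$report$removed)),
                 st$n_out[nrow(st)])
    ## removed sets disjoint across stages
    all_removed <- unlist(res$report$removed)
    expect_equal(anyDuplicated(all_removed), 0L)
    ## idempotence
    res2 <- applyFilterCascade(res$ge)
    expect_equal(sum(lengths(res2$report$removed)), 0L)
    expect_identical(res2$report$surviving, res$report$surviving)
})

test_that("relaxing any single threshold never shrinks the survivors", {
    cfg <- simConfig(seed = 21, n_loci = 300L, n_per_pop = 12L)
    ge <- simulateGenotypes(cfg)
    base <- applyFilterCascade(ge)$report$surviving
    relaxed <- list(
        filterConfig(min_call_rate_all = 0.80),
        filterConfig(min_maf = 0.01),
        filterConfig(max_ho = 0.70),
        filterConfig(min_call_rate_species = 0.80),
        filterConfig(min_mean_depth_species = 1),
        filterConfig(tag_window = c(20L, 80L)))
    for (cfgR in relaxed) {
        surv <- applyFilterCascade(ge, cfgR)$report$surviving
        expect_true(all(base %in% surv))
    }
})

test_that("final surviving set is invariant to input locus order", {
    cfg <- simConfig(seed = 23, n_loci = 200L, n_per_pop = 10L)
    ge <- simulateGenotypes(cfg)
    perm <- sample(nrow(ge))
    a <- applyFilterCascade(ge)$report$surviving
    b <- applyFilterCascade(ge[perm, ])$report$surviving
    expect_setequal(a, b)
})
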