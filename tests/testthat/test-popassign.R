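test_that("reference counts equal a brute-force tally and merges pool", {
    set.seed(4)
    g <- matrix(sample(c(0:2, NA), 20 * 12, replace = TRUE), 20, 12)
    pops <- rep(c("Faraday", "Murchison", "Tanu"), each = 4)
    ge <- makeGE(g, populations = pops)
    ref <- buildReference(ge)
    for (p in unique(pops)) {
        sub <- g[, pops == p, drop = FALSE]
        expect_equal(unname(ref$n_alt[p, ]),
                     unname(rowSums(sub, na.rm = TRUE)))
        expect_equal(unname(ref$m[p, ]),
                     unname(2 * rowSums(!is.na(sub))))
    }
    merged <- buildReference(ge, list(c("Faraday", "Murchison")))
    expect_true("Faraday/Murchison" %in% merged$populations)
    expect_equal(unname(merged$n_alt["Faraday/Murchison", ]),
                 unname(ref$n_alt["Faraday", ] + ref$n_alt["Murchison", ]))
    expect_error(buildReference(ge, list(c("Atlantis"))), "Atlantis")
})

test_that("genotype likelihood matches Beta-posterior integration", {
    ## single locus, n_alt = 9 of m = 10 copies, K = 2:
    ## P(hom-alt) = integral p^2 dBeta(p; 9.5, 1.5)
    orc <- integrate(function(p) p^2 * dbeta(p, 9 + 0.5, 1 + 0.5), 0, 1)
    expect_equal(orc$value, (9.5 * 10.5) / (11 * 12), tolerance = 1e-9)

    ge <- makeGE(matrix(2L, 1, 1))
    ref <- list(n_alt = matrix(9, 1, 1, dimnames = list("p1", "L001")),
                m = matrix(10, 1, 1, dimnames = list("p1", "L001")),
                loci = "L001", populations = "p1",
                sample_pop = character(), genotype = NULL)
    class(ref) <- "AlleleCountTable"
    res <- assignPopulations(ge, ref, loo = FALSE)
    expect_equal(res$loglik[1, 1], log((9.5 * 10.5) / (11 * 12)))

    ## heterozygote probability against the same integral
    orc_het <- integrate(function(p) 2 * p * (1 - p) *
                         dbeta(p, 9.5, 1.5), 0, 1)
    ge2 <- makeGE(matrix(1L, 1, 1))
    res2 <- assignPopulations(ge2, ref, loo = FALSE)
    expect_equal(exp(res2$loglik[1, 1]), orc_het$value, tolerance = 1e-6)
})

test_that("identical reference populations give a 50/50 posterior", {
    set.seed(9)
    g <- matrix(sample(0:2, 30 * 8, replace = TRUE), 30, 8)
    ge <- makeGE(cbind(g[, 1:4], g[, 1:4]),
                 populations = rep(c("pA", "pB"), each = 4))
    ref <- buildReference(ge)
    q <- makeGE(matrix(sample(0:2, 30, replace = TRUE), 30, 1))
    res <- assignPopulations(q, ref, loo = FALSE)
    expect_equal(unname(res$posterior[1, ]), c(0.5, 0.5))
})

test_that("posteriors normalize and ignore uninformative loci", {
    cfg <- simConfig(seed = 71, n_loci = 120L, n_pops = 3L,
                     n_per_pop = 12L, replicate_fraction = 0)
    ge <- simulateGenotypes(cfg)
    brown <- ge[, sampleMeta(ge)$species == "brown"]
    ref <- buildReference(brown)
    res <- assignPopulations(brown, ref)
    expect_equal(unname(rowSums(res$posterior)),
                 rep(1, nrow(res$posterior)), tolerance = 1e-9)
    expect_true(all(is.finite(res$loglik)))
    ## appending a locus with identical counts in every population must
    ## not change the posterior ordering
    ref2 <- ref
    ref2$n_alt <- cbind(ref2$n_alt, EXTRA = 5)
    ref2$m <- cbind(ref2$m, EXTRA = 20)
    ref2$loci <- c(ref2$loci, "EXTRA")
    g2 <- rbind(genotypes(brown), EXTRA = 1L)
    ge2 <- GenotypeExperiment(
        g2, sampleData = as.data.frame(sampleMeta(brown)),
        locusData = rbind(as.data.frame(locusInfo(brown)),
                          data.frame(locus_id = "EXTRA", chrom = "chrX",
                                     pos = 1L, radtag_id = "TX",
                                     tag_offset = 50L, ref_allele = "A",
                                     alt_allele = "C")))
    ref2$genotype <- genotypes(ge2)
    res2 <- assignPopulations(ge2, ref2)
    expect_identical(apply(res$posterior, 1, which.max),
                     apply(res2$posterior, 1, which.max))
})

test_that("leave-one-out removes exactly the individual's own copies", {
    g <- matrix(c(0L, 1L, 2L, 2L, 1L, 0L), 3, 2)
    ge <- makeGE(g, populations = c("pA", "pA"))
    ## add a second population so assignment has a contrast
    g2 <- cbind(g, matrix(2L, 3, 2))
    ge2 <- makeGE(g2, populations = rep(c("pA", "pB"), each = 2))
    ref <- buildReference(ge2)
    res_loo <- assignPopulations(ge2[, 1], ref, loo = TRUE)
    ## manual: subtract s001's genotypes from pA counts, then score
    n_alt <- ref$n_alt["pA", ] - g[, 1]
    m <- ref$m["pA", ] - 2
    manual <- sum(vapply(1:3, function(l) {
        na <- n_alt[l]; nr <- m[l] - na; geno <- g[l, 1]
        if (geno == 0) log((nr + .5) * (nr + 1.5)) - log((m[l] + 1) * (m[l] + 2))
        else if (geno == 1) log(2 * (nr + .5) * (na + .5)) -
            log((m[l] + 1) * (m[l] + 2))
        else log((na + .5) * (na + 1.5)) - log((m[l] + 1) * (m[l] + 2))
    }, numeric(1)))
    expect_equal(res_loo$loglik[1, "pA"], manual)
    expect_true(res_loo$loo[["s001"]])
    ## without LOO the likelihood must differ (own copies included)
    res_no <- assignPopulations(ge2[, 1], ref, loo = FALSE)
    expect_false(isTRUE(all.equal(res_no$loglik[1, "pA"],
                                  res_loo$loglik[1, "pA"])))
})

test_that("simulated individuals assign to their true island", {
    cfg <- simConfig(seed = 303, n_loci = 300L, n_pops = 3L,
                     n_per_pop = 25L, target_fst = 0.1,
                     replicate_fraction = 0, n_diagnostic_fixed = 0L)
    ge <- simulateGenotypes(cfg)
    brown <- ge[, sampleMeta(ge)$species == "brown"]
    ref <- buildReference(brown)
    res <- assignPopulations(brown, ref, loo = TRUE)
    truth <- sampleMeta(brown)$population
    expect_gte(mean(res$top == truth), 0.95)
})

test_that("assignment accuracy does not decrease with differentiation", {
    acc <- vapply(c(0.05, 0.1, 0.2), function(fst) {
        cfg <- simConfig(seed = 404, n_loci = 40L, n_pops = 2L,
                         n_per_pop = 15L, target_fst = fst,
                         replicate_fraction = 0, n_diagnostic_fixed = 0L)
        ge <- simulateGenotypes(cfg)
        brown <- ge[, sampleMeta(ge)$species == "brown"]
        ref <- buildReference(brown)
        res <- assignPopulations(brown, ref, loo = TRUE)
        mean(res$top == sampleMeta(brown)$population)
    }, numeric(1))
    expect_true(all(diff(acc) >= 0))
})

test_that("PCA projection of complete reference data is exact", {
    cfg <- simConfig(seed = 88, n_loci = 150L, n_pops = 2L,
                     n_per_pop = 15L, missing_rate = 0,
                     replicate_fraction = 0)
    ge <- simulateGenotypes(cfg)
    brown <- ge[, sampleMeta(ge)$species == "brown"]
    model <- fitReferencePCA(brown, 5)
    expect_equal(crossprod(model$V), diag(5), tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_false(is.unsorted(rev(model$eigenvalues)))
    expect_true(all(model$eigenvalues >= 0))
    proj <- projectSamples(model, brown)
    expect_equal(proj, model$scores, tolerance = 1e-9,
                 ignore_attr = TRUE)
})

test_that("masked projection recovers the full-data score", {
    cfg <- simConfig(seed = 89, n_loci = 400L, n_pops = 3L,
                     n_per_pop = 20L, missing_rate = 0,
                     replicate_fraction = 0)
    ge <- simulateGenotypes(cfg)
    brown <- ge[, sampleMeta(ge)$species == "brown"]
    model <- fitReferencePCA(brown, 4)
    full <- projectSamples(model, brown[, 1])
    set.seed(1)
    g <- genotypes(brown)
    mask <- sample(nrow(g), floor(0.3 * nrow(g)))
    g[mask, 1] <- NA
    masked_ge <- GenotypeExperiment(
        g[, 1, drop = FALSE],
        sampleData = as.data.frame(sampleMeta(brown))[1, ],
        locusData = as.data.frame(locusInfo(brown)))
    got <- projectSamples(model, masked_ge)
    ## least-squares oracle on the unmasked rows
    keep <- intersect(model$loci, rownames(g)[-mask])
    mi <- match(keep, model$loci)
    z <- (g[keep, 1] - model$mu[mi]) / model$s[mi]
    beta <- qr.solve(model$V[mi, , drop = FALSE], z)
    expect_equal(unname(got[1, ]), unname(beta), tolerance = 1e-8)
    ## and the masked score stays close to the full-data score
    expect_lt(max(abs(got - full)), 0.2 * max(abs(full)))
})

test_that("DAPC separates species and admits symmetric uncertainty", {
    ## two classes separated by several fixed loci
    cfg <- simConfig(seed = 99, n_loci = 100L, n_pops = 2L,
                     n_per_pop = 15L, n_diagnostic_fixed = 10L,
                     missing_rate = 0, replicate_fraction = 0)
    ge <- simulateGenotypes(cfg)
    res <- dapcClassify(ge, ge)
    truth <- sampleMeta(ge)$species
    expect_true(all(res$class == truth))
    expect_true(all(res$posterior[cbind(sampleMeta(ge)$sample_id,
                                        truth)] >= 0.999))
    expect_equal(unname(rowSums(res$posterior)),
                 rep(1, length(truth)), tolerance = 1e-9)
})
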