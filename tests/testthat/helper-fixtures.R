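## Shared fixture builders and independent oracles.

## Minimal GenotypeExperiment from a loci x samples matrix.
makeGE <- function(g, populations = NULL, species = NULL, depth = NULL,
                   chrom = NULL, pos = NULL, radtag = NULL, offset = NULL,
                   replicate_group = NULL, method = "ddRAD") {
    n <- ncol(g); L <- nrow(g)
    if (is.null(populations)) populations <- rep("popA", n)
    if (is.null(species)) species <- rep("brown", n)
    if (is.null(chrom)) chrom <- rep("chr1", L)
    if (is.null(pos)) pos <- as.integer(seq_len(L) * 2e6)
    if (is.null(radtag)) radtag <- sprintf("T%03d", seq_len(L))
    if (is.null(offset)) offset <- rep(50L, L)
    if (is.null(replicate_group)) replicate_group <- rep(NA_character_, n)
    GenotypeExperiment(
        g,
        sampleData = data.frame(
            sample_id = sprintf("s%03d", seq_len(n)), species = species,
            population = populations, method = method,
            replicate_group = replicate_group, stringsAsFactors = FALSE),
        locusData = data.frame(
            locus_id = sprintf("L%03d", seq_len(L)), chrom = chrom,
            pos = pos, radtag_id = radtag, tag_offset = offset,
            ref_allele = "A", alt_allele = "C", stringsAsFactors = FALSE),
        depth = depth)
}

## Independent transcription of the two-population Weir-Cockerham
## variance components, written as explicit sums over populations
## (general-r form specialized by r = 2), kept separate from the package
## implementation.
wcOracle <- function(g1, g2) {
    g1 <- g1[!is.na(g1)]; g2 <- g2[!is.na(g2)]
    n <- c(length(g1), length(g2))
    p <- c(sum(g1) / (2 * n[1]), sum(g2) / (2 * n[2]))
    h <- c(mean(g1 == 1), mean(g2 == 1))
    r <- 2
    nbar <- mean(n)
    CV2 <- sum((n - nbar)^2) / (r * nbar^2)  # squared CV of sample sizes
    nc <- nbar * (1 - CV2 / (r - 1))
    pbar <- sum(n * p) / sum(n)
    s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n * h) / sum(n)
    a <- (nbar / nc) * (s2 - 1 / (nbar - 1) *
        (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
    b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
        (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    list(a = a, b = b, c = cc, theta = a / (a + b + cc))
}

## 12-locus cascade fixture: 20 samples (10 brown / 10 black, one
## population each), one designed casualty per stage, four survivors.
## Returns the GenotypeExperiment and the expected stage attribution.
makeCascadeFixture <- function() {
    good <- rep(c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L, 2L, 2L), 2)  # maf .4, ho .4
    G <- matrix(rep(good, 12), nrow = 12, byrow = TRUE)
    D <- matrix(20, 12, 20)
    ## L1: overall call rate 17/20 = 0.85 (stage 1)
    G[1, c(1, 2, 11)] <- NA
    ## L2: one het only -> overall maf 0.025 (stage 2)
    G[2, ] <- 0L; G[2, 1] <- 1L
    ## L3: all het -> ho = 1 (stage 3)
    G[3, ] <- 1L
    ## L4: same RADtag as L9, lower call rate (stage 4)
    G[4, 1] <- NA
    ## L5: fixed difference, monomorphic within each species (stage 5)
    G[5, 1:10] <- 0L; G[5, 11:20] <- 2L
    ## L6: brown call rate exactly 0.9, not > 0.9 (stage 6)
    G[6, 1] <- NA
    ## L7: mean depth 4 in brown (stage 7)
    D[7, 1:10] <- 4
    ## L8: tag offset 30, outside [40, 60] (stage 8)
    offset <- rep(50L, 12); offset[8] <- 30L
    radtag <- sprintf("T%03d", 1:12); radtag[4] <- radtag[9]
    ge <- makeGE(G, populations = rep(c("isl_brown", "isl_black"),
                                      each = 10),
                 species = rep(c("brown", "black"), each = 10),
                 depth = D, radtag = radtag, offset = offset)
    expected <- c(L001 = "call_rate_all", L002 = "maf_all",
                  L003 = "ho_all", L004 = "one_snp_per_tag",
                  L005 = "variable_in_a_species",
                  L006 = "call_rate_species",
                  L007 = "mean_depth_species", L008 = "tag_offset_window")
    list(ge = ge, expected = expected,
         survivors = sprintf("L%03d", 9:12))
}

## Independent post-hoc validity check for spacing pruning.
spacingOracleOK <- function(candidates, result, min_spacing) {
    surv <- result$survivors
    ok <- TRUE
    for (ch in unique(surv$chrom)) {
        p <- sort(surv$pos[surv$chrom == ch])
        if (length(p) > 1 && any(diff(p) < min_spacing)) ok <- FALSE
    }
    removed <- setdiff(candidates$locus_id, surv$locus_id)
    for (id in removed) {
        row <- candidates[candidates$locus_id == id, ]
        nb <- surv[surv$chrom == row$chrom &
                   abs(surv$pos - row$pos) < min_spacing, ]
        if (!nrow(nb) || max(nb$score) < row$score) ok <- FALSE
    }
    ok
}

## Small deterministic amplicon fixture used by QC tests.
tinyCounts <- function() {
    loci <- sprintf("A%02d", 1:10)
    cc <- expand.grid(sample_id = c("s1", "s2"), locus_id = loci,
                      stringsAsFactors = FALSE)
    cc$allele1_count <- 50L; cc$allele2_count <- 50L; cc$other_count <- 0L
    primer <- setNames(rep(200, 10), loci)
    primer["A01"] <- 3000           # ~62% of the library: culled
    artifact <- setNames(numeric(10), loci)
    artifact["A02"] <- 10           # 5% of the locus's 200 reads
    dimers <- data.frame(locus1 = "A03", locus2 = "A04",
                         stringsAsFactors = FALSE)
    primer["A03"] <- 250            # greater primer share: dimer victim
    AmpliconCounts(cc, primerReads = primer, artifactReads = artifact,
                   dimerPairs = dimers)
}
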