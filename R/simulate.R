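#' Simulation configuration for the two-species archipelago generator
#'
#' Defaults emulate a ddRAD survey of two rat species across a handful of
#' island populations: a Balding-Nichols island model per species (direct
#' control of the target differentiation), uniform ancestral allele
#' frequencies, RADtag geometry compatible with 100 bp reads, and a small
#' set of loci fixed between the species.
#'
#' @param seed integer seed, mandatory for reproducibility
#' @param n_pops island populations per species (default 3)
#' @param n_per_pop diploid samples per population (default 20)
#' @param n_loci total simulated SNP loci (default 2000)
#' @param target_fst target differentiation among each species' islands
#'   (default 0.1; length-2 vector for brown/black)
#' @param n_diagnostic_fixed loci fixed hom-ref in brown and hom-alt in
#'   black (default 10)
#' @param missing_rate per-cell missing-genotype probability
#'   (default 0.03)
#' @param depth_mean mean Poisson read depth per called cell
#'   (default 100)
#' @param allele_error_rate per-read probability of reporting the wrong
#'   allele in amplicon counts (default 0.005)
#' @param n_chromosomes,chrom_length genome layout for locus positions
#'   (default 20 chromosomes of 150 Mb)
#' @param replicate_fraction fraction of samples duplicated as technical
#'   replicates (default 0.04)
#' @param flip_rate per-genotype flip probability applied to replicate
#'   copies, to exercise nonzero replicate-error reporting (default 0)
#' @param n_overrep_loci,n_artifact_loci,n_dimer_pairs loci designated as
#'   over-represented, artifact-heavy, or hetero-dimer pairs when
#'   simulating amplicon counts (defaults 2, 2, 1)
#' @return list of class \code{SimConfig}
#' @export
simConfig <- function(seed, n_pops = 3L, n_per_pop = 20L, n_loci = 2000L,
                      target_fst = 0.1, n_diagnostic_fixed = 10L,
                      missing_rate = 0.03, depth_mean = 100,
                      allele_error_rate = 0.005, n_chromosomes = 20L,
                      chrom_length = 150e6, replicate_fraction = 0.04,
                      flip_rate = 0, n_overrep_loci = 2L,
                      n_artifact_loci = 2L, n_dimer_pairs = 1L) {
    if (missing(seed)) stop("seed is mandatory")
    if (length(target_fst) == 1L) target_fst <- rep(target_fst, 2L)
    rates <- c(missing_rate, allele_error_rate, replicate_fraction,
               flip_rate, target_fst)
    if (any(rates < 0 | rates > 1)) stop("rates must be in [0,1]")
    if (n_diagnostic_fixed > n_loci)
        stop("more diagnostic loci than loci")
    if (any(c(n_pops, n_per_pop, n_loci, n_chromosomes,
              chrom_length) < 1))
        stop("counts must be positive")
    structure(list(seed = as.integer(seed), n_pops = as.integer(n_pops),
                   n_per_pop = as.integer(n_per_pop),
                   n_loci = as.integer(n_loci),
                   target_fst = setNames(target_fst, c("brown", "black")),
                   n_diagnostic_fixed = as.integer(n_diagnostic_fixed),
                   missing_rate = missing_rate, depth_mean = depth_mean,
                   allele_error_rate = allele_error_rate,
                   n_chromosomes = as.integer(n_chromosomes),
                   chrom_length = chrom_length,
                   replicate_fraction = replicate_fraction,
                   flip_rate = flip_rate,
                   n_overrep_loci = as.integer(n_overrep_loci),
                   n_artifact_loci = as.integer(n_artifact_loci),
                   n_dimer_pairs = as.integer(n_dimer_pairs)),
              class = "SimConfig")
}

.bnFreq <- function(p, fst) {
    if (fst <= 0) return(p)
    rbeta(length(p), p * (1 - fst) / fst, (1 - p) * (1 - fst) / fst)
}

#' Simulate a two-species, multi-island genotype matrix
#'
#' Per species, each locus draws an ancestral alternate-allele frequency
#' from Uniform(0.05, 0.95); each island population draws its frequency
#' from the Balding-Nichols Beta distribution at the species' target
#' differentiation, and genotypes are Binomial(2, p).  A designated set
#' of diagnostic loci is fixed hom-ref in brown and hom-alt in black.
#' Locus positions are uniform over the configured chromosomes, each
#' locus on its own RADtag with a tag offset uniform over 1-90 bp.
#' Missingness is Bernoulli per cell; technical replicates are exact
#' genotype copies (before independent missingness and the optional flip
#' rate).  Deterministic under the config seed.
#'
#' @param cfg a \code{\link{simConfig}}
#' @return a \linkS4class{GenotypeExperiment} with genotype and depth
#'   assays; the diagnostic locus ids are in
#'   \code{metadata(ge)$diagnostic_loci}
#' @export
simulateGenotypes <- function(cfg) {
    stopifnot(inherits(cfg, "SimConfig"))
    set.seed(cfg$seed)
    L <- cfg$n_loci
    species <- c("brown", "black")
    pops <- unlist(lapply(species, function(s)
        paste0(s, "_isl", seq_len(cfg$n_pops))))
    pop_species <- rep(species, each = cfg$n_pops)
    n_samp <- length(pops) * cfg$n_per_pop
    sample_pop <- rep(pops, each = cfg$n_per_pop)
    sample_species <- rep(pop_species, each = cfg$n_per_pop)
    sample_id <- paste0(sample_pop, "_s",
                        sprintf("%02d", sequence(rep(cfg$n_per_pop,
                                                     length(pops)))))
    diag_idx <- if (cfg$n_diagnostic_fixed > 0)
        sort(sample.int(L, cfg$n_diagnostic_fixed)) else integer()

    g <- matrix(NA_integer_, L, n_samp)
    for (s in species) {
        anc <- runif(L, 0.05, 0.95)
        fst <- cfg$target_fst[[s]]
        for (p in pops[pop_species == s]) {
            pf <- .bnFreq(anc, fst)
            cols <- which(sample_pop == p)
            g[, cols] <- rbinom(L * length(cols), 2L, pf)
        }
    }
    if (length(diag_idx)) {
        g[diag_idx, sample_species == "brown"] <- 0L
        g[diag_idx, sample_species == "black"] <- 2L
    }

    ## technical replicates: exact copies of the pre-missingness genotypes
    n_rep <- floor(cfg$replicate_fraction * n_samp)
    rep_src <- if (n_rep > 0) sort(sample.int(n_samp, n_rep)) else integer()
    if (length(rep_src)) {
        g <- cbind(g, g[, rep_src, drop = FALSE])
        if (cfg$flip_rate > 0) {
            block <- g[, n_samp + seq_along(rep_src), drop = FALSE]
            flip <- matrix(runif(length(block)) < cfg$flip_rate,
                           nrow(block))
            block[flip] <- (block[flip] + 1L) %% 3L
            g[, n_samp + seq_along(rep_src)] <- block
        }
        sample_id <- c(sample_id, paste0(sample_id[rep_src], "_rep"))
        sample_pop <- c(sample_pop, sample_pop[rep_src])
        sample_species <- c(sample_species, sample_species[rep_src])
    }
    rep_group <- rep(NA_character_, length(sample_id))
    if (length(rep_src)) {
        rep_group[rep_src] <- sample_id[rep_src]
        rep_group[n_samp + seq_along(rep_src)] <- sample_id[rep_src]
    }

    if (cfg$missing_rate > 0)
        g[matrix(runif(length(g)) < cfg$missing_rate, nrow(g))] <-
            NA_integer_
    depth <- matrix(rpois(length(g), cfg$depth_mean), nrow(g))

    alleles <- c("A", "C", "G", "T")
    ra <- t(vapply(seq_len(L), function(i) sample(alleles, 2L),
                   character(2)))
    locusData <- data.frame(
        locus_id = sprintf("L%05d", seq_len(L)),
        chrom = paste0("chr", sample.int(cfg$n_chromosomes, L,
                                         replace = TRUE)),
        pos = as.integer(ceiling(runif(L) * cfg$chrom_length)),
        radtag_id = sprintf("T%05d", seq_len(L)),
        tag_offset = sample.int(90L, L, replace = TRUE),
        ref_allele = ra[, 1], alt_allele = ra[, 2],
        stringsAsFactors = FALSE)
    sampleData <- data.frame(
        sample_id = sample_id, species = sample_species,
        population = sample_pop, method = "ddRAD",
        replicate_group = rep_group, stringsAsFactors = FALSE)
    ge <- GenotypeExperiment(g, sampleData, locusData, depth = depth)
    S4Vectors::metadata(ge)$diagnostic_loci <-
        locusData$locus_id[diag_idx]
    ge
}

#' Simulate amplicon read counts from known genotypes
#'
#' Per (sample, locus) cell: read depth is Poisson with the configured
#' mean (zero for missing genotypes, emulating dropout); allele-1 reads
#' are Binomial with expected fraction 1, 0.5 or 0 for hom-ref, het and
#' hom-alt genotypes, perturbed by the allele error rate.  The configured
#' numbers of loci are designated over-represented (forward-primer reads
#' inflated to 5\% of the library total), artifact-heavy (artifact reads
#' set to 5\% of the locus total) and hetero-dimer pairs.  Deterministic
#' under the given seed.
#'
#' @param ge a \linkS4class{GenotypeExperiment} (e.g. panel loci only)
#' @param cfg a \code{\link{simConfig}}
#' @param seed seed for the count draws (default \code{cfg$seed + 1})
#' @return an \linkS4class{AmpliconCounts}
#' @export
simulateAmpliconCounts <- function(ge, cfg, seed = cfg$seed + 1L) {
    stopifnot(inherits(cfg, "SimConfig"))
    set.seed(seed)
    g <- genotypes(ge)
    loci <- locusInfo(ge)$locus_id
    samples <- sampleMeta(ge)$sample_id
    long <- expand.grid(locus = seq_along(loci),
                        sample = seq_along(samples))
    geno <- g[cbind(long$locus, long$sample)]
    depth <- rpois(nrow(long), cfg$depth_mean)
    depth[is.na(geno)] <- 0L
    e <- cfg$allele_error_rate
    f1 <- ifelse(is.na(geno), 0,
                 c(1 - e, 0.5, e)[geno + 1L])
    a1 <- rbinom(nrow(long), depth, f1)
    counts <- data.frame(sample_id = samples[long$sample],
                         locus_id = loci[long$locus],
                         allele1_count = a1,
                         allele2_count = depth - a1,
                         other_count = 0L, stringsAsFactors = FALSE)
    on_target <- tapply(depth, loci[long$locus], sum)[loci]
    primer <- as.numeric(on_target)
    names(primer) <- loci
    artifact <- setNames(numeric(length(loci)), loci)

    pool <- sample(loci)
    take <- function(n) {
        n <- min(n, length(pool))
        out <- pool[seq_len(n)]
        pool <<- pool[-seq_len(n)]
        out
    }
    over <- take(cfg$n_overrep_loci)
    art <- take(cfg$n_artifact_loci)
    dim1 <- take(cfg$n_dimer_pairs)
    dim2 <- take(cfg$n_dimer_pairs)
    if (length(over))
        primer[over] <- 0.05 * sum(primer)
    if (length(art))
        artifact[art] <- 0.05 * primer[art]
    dimers <- data.frame(locus1 = dim1, locus2 = dim2,
                         stringsAsFactors = FALSE)
    AmpliconCounts(counts, primerReads = primer, artifactReads = artifact,
                   dimerPairs = dimers)
}

#' Write a simulated dataset in the pipeline's input formats
#'
#' Emits the VCF, popmap TSV and locus-table TSV that
#' \code{\link{readGenotypeVcf}}, \code{\link{readPopmap}} and
#' \code{\link{readLocusTable}} consume.
#'
#' @param ge a \linkS4class{GenotypeExperiment}
#' @param dir output directory (created if needed)
#' @return named character vector of the written paths
#' @export
writeSimulatedInputs <- function(ge, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    vcf <- file.path(dir, "genotypes.vcf.gz")
    writeGenotypeVcf(ge, vcf)
    pm <- file.path(dir, "popmap.tsv")
    sm <- as.data.frame(sampleMeta(ge))
    sm$replicate_group[is.na(sm$replicate_group)] <- ""
    utils::write.table(
        sm[, c("sample_id", "species", "population", "method",
               "replicate_group")],
        pm, sep = "\t", quote = FALSE, row.names = FALSE)
    lt <- file.path(dir, "loci.tsv")
    li <- as.data.frame(locusInfo(ge))
    utils::write.table(
        data.frame(locus_id = li$locus_id, chrom = li$chrom, pos = li$pos,
                   radtag_id = li$radtag_id, tag_offset = li$tag_offset,
                   ref = li$ref_allele, alt = li$alt_allele),
        lt, sep = "\t", quote = FALSE, row.names = FALSE)
    c(vcf = vcf, popmap = pm, loci = lt)
}
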