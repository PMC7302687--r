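#' Amplicon QC and genotype-calling configuration
#'
#' @param max_primer_fraction cull loci whose forward-primer reads exceed
#'   this fraction of the library's total forward-primer reads
#'   (default 0.01, strict >)
#' @param max_artifact_fraction cull loci whose PCR-artifact reads exceed
#'   this fraction (default 0.01, strict >); the denominator is the
#'   locus's own total reads by default, or the library-wide artifact
#'   total with \code{artifact_denominator = "library"}
#' @param artifact_denominator \code{"locus"} (default) or
#'   \code{"library"}
#' @param max_sample_missing drop samples whose missing fraction exceeds
#'   this (default 0.50, strict >)
#' @param hom_ratio minor-allele read fraction below which a homozygote
#'   is called (default 0.10)
#' @param het_band inclusive minor-fraction interval for heterozygote
#'   calls (default c(0.20, 0.80)); fractions between \code{hom_ratio}
#'   and the band are ambiguous and yield a missing call
#' @param min_depth minimum on-target reads to call a genotype
#'   (default 10)
#' @return list of class \code{QCConfig}
#' @export
qcConfig <- function(max_primer_fraction = 0.01,
                     max_artifact_fraction = 0.01,
                     artifact_denominator = c("locus", "library"),
                     max_sample_missing = 0.50, hom_ratio = 0.10,
                     het_band = c(0.20, 0.80), min_depth = 10L) {
    artifact_denominator <- match.arg(artifact_denominator)
    fr <- c(max_primer_fraction, max_artifact_fraction, max_sample_missing,
            hom_ratio, het_band)
    if (any(fr < 0 | fr > 1)) stop("fractions must be in [0,1]")
    if (het_band[1] <= hom_ratio)
        stop("het_band must start above hom_ratio (ambiguity gap)")
    structure(list(max_primer_fraction = max_primer_fraction,
                   max_artifact_fraction = max_artifact_fraction,
                   artifact_denominator = artifact_denominator,
                   max_sample_missing = max_sample_missing,
                   hom_ratio = hom_ratio, het_band = het_band,
                   min_depth = as.integer(min_depth)),
              class = "QCConfig")
}

#' Cull problem loci from an amplicon library
#'
#' Removes, in a fixed attribution order so each locus is removed once:
#' (1) over-represented loci, whose forward-primer reads exceed
#' \code{max_primer_fraction} of the library's total forward-primer
#' reads; (2) artifact-heavy loci, whose artifact reads exceed
#' \code{max_artifact_fraction} of the chosen denominator; (3) one locus
#' per hetero-dimer pair — the member with the greater forward-primer
#' read share (the greedier primer being the likelier artifact driver),
#' ties broken by removing the lexicographically later locus_id.  A dimer
#' pair whose members are both already removed is a logged no-op.
#'
#' @param ac an \linkS4class{AmpliconCounts}
#' @param cfg a \code{\link{qcConfig}}
#' @return list with \code{retained} (locus_ids) and \code{removals}
#'   (data.frame \code{locus_id}, \code{reason})
#' @export
cullLoci <- function(ac, cfg = qcConfig()) {
    stopifnot(is(ac, "AmpliconCounts"), inherits(cfg, "QCConfig"))
    pr <- primerReads(ac)
    loci <- names(pr)
    total_primer <- sum(pr)
    removals <- data.frame(locus_id = character(), reason = character(),
                           stringsAsFactors = FALSE)
    drop <- function(ids, reason) {
        ids <- setdiff(ids, removals$locus_id)
        if (length(ids))
            removals <<- rbind(removals,
                data.frame(locus_id = ids, reason = reason,
                           stringsAsFactors = FALSE))
    }
    over <- loci[pr > cfg$max_primer_fraction * total_primer]
    drop(over, "over_represented_primer")

    ar <- artifactReads(ac)[loci]
    ar[is.na(ar)] <- 0
    denom <- if (cfg$artifact_denominator == "library")
        rep(sum(ar), length(loci))
    else {
        cc <- countsTable(ac)
        tot <- tapply(cc$allele1_count + cc$allele2_count + cc$other_count,
                      cc$locus_id, sum)
        as.numeric(tot[loci])
    }
    art <- loci[denom > 0 & ar > cfg$max_artifact_fraction * denom]
    drop(art, "pcr_artifact")

    dp <- dimerPairs(ac)
    for (k in seq_len(nrow(dp))) {
        pair <- c(dp$locus1[k], dp$locus2[k])
        if (all(pair %in% removals$locus_id)) {
            message("dimer pair already removed: ",
                    paste(pair, collapse = " / "))
            next
        }
        alive <- setdiff(pair, removals$locus_id)
        if (length(alive) == 1L) next  # one member already gone
        victim <- if (pr[pair[1]] > pr[pair[2]]) pair[1]
                  else if (pr[pair[2]] > pr[pair[1]]) pair[2]
                  else sort(pair)[2]
        drop(victim, "hetero_dimer")
    }
    list(retained = setdiff(loci, removals$locus_id), removals = removals)
}

#' Call genotypes from allele read counts
#'
#' Allele-ratio caller: on-target depth is allele1 + allele2 reads; below
#' \code{min_depth} the cell is missing.  With minor-allele read fraction
#' \code{m}: \code{m < hom_ratio} calls a homozygote for the majority
#' allele, \code{m} inside \code{het_band} calls a heterozygote, and the
#' ambiguity gap between them yields a missing call.  Calls are invariant
#' to scaling both allele counts above \code{min_depth}.
#'
#' @param ac an \linkS4class{AmpliconCounts}
#' @param panelLoci character vector of loci to call (e.g. the retained
#'   list from \code{\link{cullLoci}}); allele1 is the reference allele
#' @param sampleData data.frame of sample metadata (as in
#'   \code{\link{GenotypeExperiment}}); defaults to GTseq samples with
#'   unknown species/population
#' @param locusData optional locus metadata data.frame aligned by
#'   locus_id
#' @param cfg a \code{\link{qcConfig}}
#' @return a \linkS4class{GenotypeExperiment} with genotype and depth
#'   assays
#' @export
callGenotypes <- function(ac, panelLoci = NULL, sampleData = NULL,
                          locusData = NULL, cfg = qcConfig()) {
    stopifnot(is(ac, "AmpliconCounts"), inherits(cfg, "QCConfig"))
    cc <- countsTable(ac)
    if (is.null(panelLoci)) panelLoci <- unique(cc$locus_id)
    cc <- cc[cc$locus_id %in% panelLoci, , drop = FALSE]
    samples <- unique(cc$sample_id)
    depth <- cc$allele1_count + cc$allele2_count
    minor <- pmin(cc$allele1_count, cc$allele2_count)
    m <- ifelse(depth > 0, minor / depth, NA_real_)
    call <- rep(NA_integer_, nrow(cc))
    ok <- depth >= cfg$min_depth
    hom <- ok & m < cfg$hom_ratio
    call[hom] <- ifelse(cc$allele1_count[hom] >= cc$allele2_count[hom],
                        0L, 2L)
    het <- ok & m >= cfg$het_band[1] & m <= cfg$het_band[2]
    call[het] <- 1L
    gmat <- matrix(NA_integer_, length(panelLoci), length(samples),
                   dimnames = list(panelLoci, samples))
    dmat <- matrix(0, length(panelLoci), length(samples),
                   dimnames = list(panelLoci, samples))
    idx <- cbind(match(cc$locus_id, panelLoci),
                 match(cc$sample_id, samples))
    gmat[idx] <- call
    dmat[idx] <- depth
    if (is.null(sampleData))
        sampleData <- data.frame(sample_id = samples, species = "unknown",
                                 population = "unknown", method = "GTseq",
                                 replicate_group = NA_character_,
                                 stringsAsFactors = FALSE)
    else
        sampleData <- sampleData[match(samples, sampleData$sample_id), ,
                                 drop = FALSE]
    if (is.null(locusData))
        locusData <- data.frame(locus_id = panelLoci, chrom = NA_character_,
                                pos = NA_integer_, stringsAsFactors = FALSE)
    else
        locusData <- locusData[match(panelLoci, locusData$locus_id), ,
                               drop = FALSE]
    GenotypeExperiment(gmat, sampleData, locusData, depth = dmat)
}

#' Drop failed loci, then failed samples
#'
#' Removes loci with zero called genotypes first, then samples whose
#' missing fraction across the remaining loci strictly exceeds
#' \code{max_sample_missing} (a sample at exactly the threshold is
#' retained).  Dropping dead loci first can rescue borderline samples.
#'
#' @param ge a \linkS4class{GenotypeExperiment}
#' @param cfg a \code{\link{qcConfig}}
#' @return list with \code{ge} (the pruned object) and \code{report}
#'   (list of \code{dropped_loci}, \code{dropped_samples}, and each
#'   dropped sample's missing fraction)
#' @export
dropFailedSamplesAndLoci <- function(ge, cfg = qcConfig()) {
    g <- genotypes(ge)
    dead <- rowSums(!is.na(g)) == 0L
    dropped_loci <- locusInfo(ge)$locus_id[dead]
    if (any(dead)) ge <- ge[!dead, ]
    g <- genotypes(ge)
    miss <- colMeans(is.na(g))
    bad <- miss > cfg$max_sample_missing
    dropped_samples <- sampleMeta(ge)$sample_id[bad]
    if (any(bad)) ge <- ge[, !bad]
    if (ncol(ge) == 0L || nrow(ge) == 0L)
        warning("QC removed all samples or all loci")
    list(ge = ge,
         report = list(dropped_loci = dropped_loci,
                       dropped_samples = dropped_samples,
                       sample_missing = miss[bad]))
}
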