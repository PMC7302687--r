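#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames rowData colData
NULL

.GT_CODES <- c(0L, 1L, 2L)
.SPECIES_LEVELS <- c("brown", "black", "unknown")
.METHOD_LEVELS <- c("ddRAD", "GTseq")
.PANEL_ROLES <- c("brown_informative", "black_informative", "species_diagnostic")

#' GenotypeExperiment: diploid SNP genotypes with sample and locus metadata
#'
#' The central container of the package: a
#' \linkS4class{SummarizedExperiment} whose rows are biallelic SNP loci and
#' whose columns are individuals.  The \code{"genotype"} assay holds codes
#' 0 (homozygous reference), 1 (heterozygous), 2 (homozygous alternate) and
#' \code{NA} (missing); an optional \code{"depth"} assay holds per-cell read
#' depth.  Column data carry \code{sample_id}, \code{species} (brown, black
#' or unknown), \code{population}, genotyping \code{method} (ddRAD or GTseq)
#' and an optional \code{replicate_group} shared by technical replicates.
#' Row data carry \code{locus_id}, \code{chrom}, \code{pos} (1-based bp),
#' \code{radtag_id}, \code{tag_offset} (1-based bp offset of the SNP from
#' the RADtag start) and the \code{ref_allele}/\code{alt_allele} pair.
#'
#' @aliases GenotypeExperiment-class
#' @exportClass GenotypeExperiment
setClass("GenotypeExperiment", contains = "SummarizedExperiment")

setValidity("GenotypeExperiment", function(object) {
    msg <- character()
    if (!"genotype" %in% assayNames(object))
        return("assay 'genotype' is required")
    g <- assay(object, "genotype")
    bad <- !is.na(g) & !(g %in% .GT_CODES)
    if (any(bad))
        msg <- c(msg, "genotype codes must be 0, 1, 2 or NA")
    if ("depth" %in% assayNames(object)) {
        d <- assay(object, "depth")
        if (!identical(dim(d), dim(g)))
            msg <- c(msg, "depth assay must match genotype dimensions")
        if (any(!is.na(d) & d < 0))
            msg <- c(msg, "depth must be non-negative")
    }
    need_col <- c("sample_id", "species", "population", "method")
    miss <- setdiff(need_col, colnames(colData(object)))
    if (length(miss))
        msg <- c(msg, paste0("colData lacks: ", paste(miss, collapse = ", ")))
    else {
        if (anyDuplicated(colData(object)$sample_id))
            msg <- c(msg, "sample_id must be unique")
        if (!all(colData(object)$species %in% .SPECIES_LEVELS))
            msg <- c(msg, "species must be one of brown/black/unknown")
        if (!all(colData(object)$method %in% .METHOD_LEVELS))
            msg <- c(msg, "method must be one of ddRAD/GTseq")
    }
    need_row <- c("locus_id", "chrom", "pos")
    miss <- setdiff(need_row, colnames(rowData(object)))
    if (length(miss))
        msg <- c(msg, paste0("rowData lacks: ", paste(miss, collapse = ", ")))
    else if (anyDuplicated(rowData(object)$locus_id))
        msg <- c(msg, "locus_id must be unique")
    if (length(msg)) msg else TRUE
})

#' Construct a GenotypeExperiment
#'
#' @param genotype integer matrix, loci in rows, samples in columns, codes
#'   0/1/2/NA.
#' @param sampleData data.frame (or DataFrame) with columns \code{sample_id},
#'   \code{species}, \code{population}, \code{method} and optionally
#'   \code{replicate_group} (NA when the sample has no technical replicate).
#' @param locusData data.frame with columns \code{locus_id}, \code{chrom},
#'   \code{pos} and optionally \code{radtag_id}, \code{tag_offset},
#'   \code{ref_allele}, \code{alt_allele}.
#' @param depth optional numeric matrix of per-cell read depth, same shape
#'   as \code{genotype}.
#' @return A \linkS4class{GenotypeExperiment}.
#' @export
#' @examples
#' g <- matrix(c(0L, 1L, 2L, NA), nrow = 2,
#'             dimnames = list(c("L1", "L2"), c("s1", "s2")))
#' ge <- GenotypeExperiment(g,
#'   sampleData = data.frame(sample_id = c("s1", "s2"), species = "brown",
#'                           population = "IslandA", method = "ddRAD"),
#'   locusData = data.frame(locus_id = c("L1", "L2"), chrom = "chr1",
#'                          pos = c(100L, 2e6L)))
#' genotypes(ge)
GenotypeExperiment <- function(genotype, sampleData, locusData, depth = NULL) {
    genotype <- as.matrix(genotype)
    storage.mode(genotype) <- "integer"
    sampleData <- DataFrame(sampleData)
    locusData <- DataFrame(locusData)
    if (is.null(sampleData$replicate_group))
        sampleData$replicate_group <- NA_character_
    sampleData$replicate_group[!is.na(sampleData$replicate_group) &
                               sampleData$replicate_group == ""] <- NA_character_
    if (nrow(sampleData) != ncol(genotype))
        stop("sampleData rows must match genotype columns")
    if (nrow(locusData) != nrow(genotype))
        stop("locusData rows must match genotype rows")
    rownames(genotype) <- locusData$locus_id
    colnames(genotype) <- sampleData$sample_id
    rownames(locusData) <- locusData$locus_id
    rownames(sampleData) <- sampleData$sample_id
    assays <- list(genotype = genotype)
    if (!is.null(depth)) {
        depth <- as.matrix(depth)
        dimnames(depth) <- dimnames(genotype)
        assays$depth <- depth
    }
    se <- SummarizedExperiment(assays = assays, rowData = locusData,
                               colData = sampleData)
    new("GenotypeExperiment", se)
}

#' SnpPanel: a selected amplicon panel with role tags and provenance
#'
#' Holds the outcome of panel selection: one row per retained locus with its
#' role (\code{brown_informative}, \code{black_informative} or
#' \code{species_diagnostic}) and ranking score, the list of loci removed by
#' genomic spacing pruning together with the retained locus each conflicted
#' with, and a snapshot of the selection configuration.
#'
#' @aliases SnpPanel-class
#' @exportClass SnpPanel
setClass("SnpPanel", representation(
    entries = "data.frame",
    spacingRemovals = "data.frame",
    config = "list"))

setValidity("SnpPanel", function(object) {
    msg <- character()
    e <- object@entries
    need <- c("locus_id", "role", "score")
    if (!all(need %in% names(e)))
        return("entries needs columns locus_id, role, score")
    if (anyDuplicated(e$locus_id))
        msg <- c(msg, "panel entries must be unique by locus_id")
    if (!all(e$role %in% .PANEL_ROLES))
        msg <- c(msg, "unknown panel role")
    r <- object@spacingRemovals
    if (nrow(r) && !all(c("removed", "conflicting") %in% names(r)))
        msg <- c(msg, "spacingRemovals needs columns removed, conflicting")
    if (length(msg)) msg else TRUE
})

#' AmpliconCounts: per-sample, per-locus amplicon read counts
#'
#' Long-format allele read counts from a multiplexed amplicon (GT-seq)
#' library, plus the per-locus library-wide diagnostics the optimization
#' step consumes: total forward-primer reads, reads attributed to PCR
#' artifacts, and locus pairs flagged as primer hetero-dimers.
#'
#' @aliases AmpliconCounts-class
#' @exportClass AmpliconCounts
setClass("AmpliconCounts", representation(
    counts = "data.frame",
    primerReads = "numeric",
    artifactReads = "numeric",
    dimerPairs = "data.frame"))

setValidity("AmpliconCounts", function(object) {
    msg <- character()
    cc <- object@counts
    need <- c("sample_id", "locus_id", "allele1_count", "allele2_count",
              "other_count")
    if (!all(need %in% names(cc)))
        return(paste0("counts needs columns: ", paste(need, collapse = ", ")))
    num <- c("allele1_count", "allele2_count", "other_count")
    if (any(vapply(cc[num], function(x) any(x < 0, na.rm = TRUE), logical(1))))
        msg <- c(msg, "read counts must be non-negative")
    loci <- unique(cc$locus_id)
    if (is.null(names(object@primerReads)) ||
        !all(loci %in% names(object@primerReads)))
        msg <- c(msg, "primerReads must be named for every locus in counts")
    if (any(object@primerReads < 0) || any(object@artifactReads < 0))
        msg <- c(msg, "primer/artifact totals must be non-negative")
    dp <- object@dimerPairs
    if (nrow(dp)) {
        if (!all(c("locus1", "locus2") %in% names(dp)))
            msg <- c(msg, "dimerPairs needs columns locus1, locus2")
        else if (!all(c(dp$locus1, dp$locus2) %in% loci))
            msg <- c(msg, "dimer pairs must reference known loci")
    }
    if (length(msg)) msg else TRUE
})

#' Construct an AmpliconCounts object
#'
#' @param counts data.frame with columns \code{sample_id}, \code{locus_id},
#'   \code{allele1_count}, \code{allele2_count}, \code{other_count}.
#' @param primerReads named numeric: library-wide forward-primer reads per
#'   locus.  Defaults to the per-locus sum of on-target reads.
#' @param artifactReads named numeric: reads attributed to PCR artifacts per
#'   locus (default 0).
#' @param dimerPairs data.frame with columns \code{locus1}, \code{locus2}
#'   listing unordered hetero-dimer pairs (default none).
#' @return An \linkS4class{AmpliconCounts}.
#' @export
AmpliconCounts <- function(counts, primerReads = NULL, artifactReads = NULL,
                           dimerPairs = NULL) {
    counts <- as.data.frame(counts)
    loci <- unique(counts$locus_id)
    on_target <- counts$allele1_count + counts$allele2_count +
        counts$other_count
    tot <- tapply(on_target, counts$locus_id, sum)
    if (is.null(primerReads))
        primerReads <- as.numeric(tot)[match(loci, names(tot))]
    if (is.null(names(primerReads)))
        names(primerReads) <- loci
    if (is.null(artifactReads))
        artifactReads <- setNames(numeric(length(loci)), loci)
    if (is.null(dimerPairs))
        dimerPairs <- data.frame(locus1 = character(), locus2 = character())
    new("AmpliconCounts", counts = counts, primerReads = primerReads,
        artifactReads = artifactReads, dimerPairs = as.data.frame(dimerPairs))
}
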