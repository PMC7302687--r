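#' @rdname GenotypeExperiment
#' @export
setMethod("genotypes", "GenotypeExperiment", function(x)
    assay(x, "genotype"))

#' @rdname GenotypeExperiment
#' @export
setMethod("depths", "GenotypeExperiment", function(x) {
    if ("depth" %in% assayNames(x)) assay(x, "depth") else NULL
})

#' @rdname GenotypeExperiment
#' @export
setMethod("sampleMeta", "GenotypeExperiment", function(x) colData(x))

#' @rdname GenotypeExperiment
#' @export
setMethod("locusInfo", "GenotypeExperiment", function(x) rowData(x))

setMethod("show", "GenotypeExperiment", function(object) {
    g <- genotypes(object)
    sm <- sampleMeta(object)
    cat("GenotypeExperiment:", nrow(object), "loci x", ncol(object),
        "samples\n")
    cat("  species:", paste(sprintf("%s=%d", names(table(sm$species)),
        table(sm$species)), collapse = ", "), "\n")
    cat("  populations:", length(unique(sm$population)), "| methods:",
        paste(unique(sm$method), collapse = ","), "\n")
    cat(sprintf("  missing genotypes: %.1f%%", 100 * mean(is.na(g))))
    if ("depth" %in% assayNames(object)) cat(" | depth assay present")
    cat("\n")
})

#' Subset samples of a GenotypeExperiment by sample id
#'
#' @param x a GenotypeExperiment
#' @param ids character vector of sample ids (order preserved)
#' @return the subsetted GenotypeExperiment
#' @export
selectSamples <- function(x, ids) {
    idx <- match(ids, sampleMeta(x)$sample_id)
    if (anyNA(idx))
        stop("unknown sample ids: ", paste(ids[is.na(idx)], collapse = ", "))
    x[, idx]
}

#' Subset loci of a GenotypeExperiment by locus id
#'
#' @param x a GenotypeExperiment
#' @param ids character vector of locus ids (order preserved)
#' @return the subsetted GenotypeExperiment
#' @export
selectLoci <- function(x, ids) {
    idx <- match(ids, locusInfo(x)$locus_id)
    if (anyNA(idx))
        stop("unknown locus ids: ", paste(ids[is.na(idx)], collapse = ", "))
    x[idx, ]
}

## ---- SnpPanel ----

#' @rdname SnpPanel
#' @param x a SnpPanel
#' @export
setMethod("panelEntries", "SnpPanel", function(x) x@entries)

#' @rdname SnpPanel
#' @param role optional role filter (one of brown_informative,
#'   black_informative, species_diagnostic)
#' @export
setMethod("panelLoci", "SnpPanel", function(x, role = NULL) {
    e <- x@entries
    if (!is.null(role)) e <- e[e$role %in% role, , drop = FALSE]
    e$locus_id
})

#' @rdname SnpPanel
#' @export
setMethod("spacingRemovals", "SnpPanel", function(x) x@spacingRemovals)

setMethod("show", "SnpPanel", function(object) {
    e <- object@entries
    cat("SnpPanel:", nrow(e), "loci\n")
    for (r in .PANEL_ROLES)
        cat(sprintf("  %-20s %d\n", r, sum(e$role == r)))
    cat("  spacing removals:", nrow(object@spacingRemovals), "\n")
})

## ---- AmpliconCounts ----

#' @rdname AmpliconCounts
#' @param x an AmpliconCounts
#' @export
setMethod("countsTable", "AmpliconCounts", function(x) x@counts)

#' @rdname AmpliconCounts
#' @export
setMethod("primerReads", "AmpliconCounts", function(x) x@primerReads)

#' @rdname AmpliconCounts
#' @export
setMethod("artifactReads", "AmpliconCounts", function(x) x@artifactReads)

#' @rdname AmpliconCounts
#' @export
setMethod("dimerPairs", "AmpliconCounts", function(x) x@dimerPairs)

setMethod("show", "AmpliconCounts", function(object) {
    cc <- object@counts
    cat("AmpliconCounts:", length(unique(cc$locus_id)), "loci x",
        length(unique(cc$sample_id)), "samples,",
        nrow(object@dimerPairs), "dimer pairs\n")
})
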