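#' @rdname GenotypeExperiment
#' @param object,x a \linkS4class{GenotypeExperiment}
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname GenotypeExperiment
#' @export
setGeneric("depths", function(x) standardGeneric("depths"))

#' @rdname GenotypeExperiment
#' @export
setGeneric("sampleMeta", function(x) standardGeneric("sampleMeta"))

#' @rdname GenotypeExperiment
#' @export
setGeneric("locusInfo", function(x) standardGeneric("locusInfo"))

#' @rdname SnpPanel
#' @export
setGeneric("panelEntries", function(x) standardGeneric("panelEntries"))

#' @rdname SnpPanel
#' @export
setGeneric("panelLoci", function(x, role = NULL) standardGeneric("panelLoci"))

#' @rdname SnpPanel
#' @export
setGeneric("spacingRemovals", function(x) standardGeneric("spacingRemovals"))

#' @rdname AmpliconCounts
#' @export
setGeneric("countsTable", function(x) standardGeneric("countsTable"))

#' @rdname AmpliconCounts
#' @export
setGeneric("primerReads", function(x) standardGeneric("primerReads"))

#' @rdname AmpliconCounts
#' @export
setGeneric("artifactReads", function(x) standardGeneric("artifactReads"))

#' @rdname AmpliconCounts
#' @export
setGeneric("dimerPairs", function(x) standardGeneric("dimerPairs"))
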