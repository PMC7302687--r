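#' @importFrom SummarizedExperiment rowData<- colData<-
#' @importFrom stats setNames rbinom rpois runif rbeta
NULL

.resolve_group <- function(ge, group) {
    sm <- sampleMeta(ge)
    if (identical(group, "all")) return(seq_len(ncol(ge)))
    if (group %in% sm$species) return(which(sm$species == group))
    if (group %in% sm$population) return(which(sm$population == group))
    stop("group '", group, "' matches no species or population")
}

#' Per-locus summary statistics over a sample group
#'
#' Computes, for every locus over the non-missing genotypes of a group of
#' samples: call rate, alternate-allele frequency \code{p}, minor-allele
#' frequency, observed heterozygosity and mean read depth.  The group is
#' \code{"all"}, a species label or a population label.  Loci with zero
#' called genotypes get call rate 0 and \code{NA} (flagged undefined)
#' frequency statistics.
#'
#' @param ge a \linkS4class{GenotypeExperiment}
#' @param group \code{"all"} (default), a species or a population label
#' @return data.frame with one row per locus: \code{locus_id},
#'   \code{group}, \code{n_called}, \code{call_rate}, \code{p}, \code{maf},
#'   \code{ho}, \code{mean_depth} (NA when no depth assay is present)
#' @export
locusStats <- function(ge, group = "all") {
    idx <- .resolve_group(ge, group)
    if (!length(idx)) stop("empty sample group: ", group)
    g <- genotypes(ge)[, idx, drop = FALSE]
    called <- !is.na(g)
    n_called <- rowSums(called)
    n_alt <- rowSums(g, na.rm = TRUE)
    p <- ifelse(n_called > 0, n_alt / (2 * n_called), NA_real_)
    maf <- pmin(p, 1 - p)
    ho <- ifelse(n_called > 0,
                 rowSums(g == 1L, na.rm = TRUE) / n_called, NA_real_)
    d <- depths(ge)
    mean_depth <- if (is.null(d)) rep(NA_real_, nrow(g)) else {
        dd <- d[, idx, drop = FALSE]
        dd[!called] <- NA
        ifelse(n_called > 0, rowMeans(dd, na.rm = TRUE), NA_real_)
    }
    data.frame(locus_id = locusInfo(ge)$locus_id, group = group,
               n_called = n_called, call_rate = n_called / length(idx),
               p = p, maf = maf, ho = ho, mean_depth = mean_depth,
               row.names = NULL, stringsAsFactors = FALSE)
}
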