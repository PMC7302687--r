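#' Build a reference allele-count table for population assignment
#'
#' Tallies reference and alternate allele copies per (population, locus)
#' from called genotypes only.  Population labels listed together in
#' \code{merges} are pooled under a combined label (names of the list
#' element, or the labels joined with "/").
#'
#' @param ge a \linkS4class{GenotypeExperiment} of reference samples
#'   (typically the ddRAD individuals)
#' @param merges list of character vectors of population labels to pool;
#'   element names become the merged labels
#' @return list of class \code{AlleleCountTable}: \code{n_alt} and
#'   \code{m} (populations x loci matrices of alternate-allele copies and
#'   total called copies), \code{loci}, \code{populations},
#'   \code{sample_pop} (named vector mapping reference sample_id to its
#'   reference population label) and \code{genotype} (the reference
#'   genotype matrix, kept for leave-one-out bookkeeping)
#' @export
buildReference <- function(ge, merges = list()) {
    sm <- sampleMeta(ge)
    pop <- sm$population
    for (k in seq_along(merges)) {
        labels <- merges[[k]]
        miss <- setdiff(labels, unique(sm$population))
        if (length(miss))
            stop("merge names unknown population(s): ",
                 paste(miss, collapse = ", "))
        merged <- names(merges)[k]
        if (is.null(merged) || !nzchar(merged))
            merged <- paste(labels, collapse = "/")
        pop[pop %in% labels] <- merged
    }
    g <- genotypes(ge)
    pops <- unique(pop)
    loci <- locusInfo(ge)$locus_id
    n_alt <- matrix(0, length(pops), length(loci),
                    dimnames = list(pops, loci))
    m <- n_alt
    for (p in pops) {
        sub <- g[, pop == p, drop = FALSE]
        n_alt[p, ] <- rowSums(sub, na.rm = TRUE)
        m[p, ] <- 2 * rowSums(!is.na(sub))
    }
    if (any(rowSums(m) == 0))
        stop("reference population with no called genotypes: ",
             paste(pops[rowSums(m) == 0], collapse = ", "))
    structure(list(n_alt = n_alt, m = m, loci = loci, populations = pops,
                   sample_pop = setNames(pop, sm$sample_id),
                   genotype = g),
              class = "AlleleCountTable")
}

## log P(genotype | population counts) for one population across loci,
## Dirichlet(1/K) prior with K = 2 alleles:
##   P(aa) = (n_a + 1/2)(n_a + 3/2) / ((m + 1)(m + 2))
##   P(ab) = 2 (n_a + 1/2)(n_b + 1/2) / ((m + 1)(m + 2))
.rmLogLik <- function(geno, n_alt, m) {
    n_ref <- m - n_alt
    denom <- log(m + 1) + log(m + 2)
    ll <- numeric(length(geno))
    hom_ref <- geno == 0L
    ll[hom_ref] <- log(n_ref[hom_ref] + 0.5) +
        log(n_ref[hom_ref] + 1.5) - denom[hom_ref]
    het <- geno == 1L
    ll[het] <- log(2) + log(n_ref[het] + 0.5) + log(n_alt[het] + 0.5) -
        denom[het]
    hom_alt <- geno == 2L
    ll[hom_alt] <- log(n_alt[hom_alt] + 0.5) +
        log(n_alt[hom_alt] + 1.5) - denom[hom_alt]
    sum(ll)
}

#' Bayesian assignment of individuals to reference populations
#'
#' Rannala-Mountain style assignment: for each individual, the
#' log-likelihood of its multilocus genotype under each reference
#' population's posterior-predictive allele frequencies (Dirichlet prior
#' with 1/K per allele, K = 2), summed over the individual's called loci
#' that overlap the reference.  Posterior probabilities use a uniform
#' prior over populations and are normalized with max-subtraction for
#' numerical safety.  With leave-one-out, an individual that belongs to a
#' reference population has its own two gene copies subtracted from that
#' population's counts before evaluation.
#'
#' @param ge a \linkS4class{GenotypeExperiment} of query individuals
#' @param ref an \code{AlleleCountTable} from \code{\link{buildReference}}
#' @param loo \code{"auto"} (leave-one-out for samples present in the
#'   reference; default), \code{TRUE} or \code{FALSE}
#' @return list of class \code{AssignmentResult}: \code{posterior} and
#'   \code{loglik} (samples x populations matrices), \code{top} (named
#'   character vector of highest-posterior population per sample) and
#'   \code{loo} (named logical: was leave-one-out applied)
#' @export
assignPopulations <- function(ge, ref, loo = "auto") {
    stopifnot(inherits(ref, "AlleleCountTable"))
    shared <- intersect(locusInfo(ge)$locus_id, ref$loci)
    if (!length(shared))
        stop("query shares no loci with the reference")
    g <- genotypes(ge)[shared, , drop = FALSE]
    n_alt <- ref$n_alt[, shared, drop = FALSE]
    m <- ref$m[, shared, drop = FALSE]
    samples <- sampleMeta(ge)$sample_id
    pops <- ref$populations
    ll <- matrix(NA_real_, length(samples), length(pops),
                 dimnames = list(samples, pops))
    loo_used <- setNames(logical(length(samples)), samples)
    for (s in samples) {
        geno <- g[, s]
        called <- !is.na(geno)
        if (!any(called))
            stop("sample ", s, " has no called locus overlapping the ",
                 "reference")
        use_loo <- if (identical(loo, "auto"))
            s %in% names(ref$sample_pop) else isTRUE(loo)
        for (p in pops) {
            na <- n_alt[p, called]; mm <- m[p, called]
            if (use_loo && s %in% names(ref$sample_pop) &&
                ref$sample_pop[[s]] == p) {
                own <- ref$genotype[shared, s][called]
                has <- !is.na(own)
                na[has] <- na[has] - own[has]
                mm[has] <- mm[has] - 2
                loo_used[s] <- TRUE
            }
            ll[s, p] <- .rmLogLik(geno[called], na, mm)
        }
    }
    post <- t(apply(ll, 1, function(x) {
        w <- exp(x - max(x)); w / sum(w)
    }))
    dimnames(post) <- dimnames(ll)
    top <- pops[apply(post, 1, which.max)]
    names(top) <- samples
    structure(list(posterior = post, loglik = ll, top = top,
                   loo = loo_used),
              class = "AssignmentResult")
}

#' Write assignment posteriors as a CSV of percentages
#'
#' Mirrors the field's reporting convention: one row per individual with
#' its sampled population and the posterior probability of assignment to
#' each reference population as a percentage rounded to two decimals.
#'
#' @param res an \code{AssignmentResult}
#' @param ge the query \linkS4class{GenotypeExperiment} (for sampled
#'   population labels)
#' @param path output CSV path
#' @return the written data.frame, invisibly
#' @export
writeAssignmentCsv <- function(res, ge, path) {
    sm <- sampleMeta(ge)
    pct <- round(100 * res$posterior, 2)
    out <- data.frame(sample_id = rownames(pct),
                      sampled_population =
                          sm$population[match(rownames(pct), sm$sample_id)],
                      pct, check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    invisible(out)
}
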