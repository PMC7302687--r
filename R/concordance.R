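.alignedPair <- function(gm_a, gm_b, samples, loci) {
    a <- gm_a[loci, samples, drop = FALSE]
    b <- gm_b[loci, samples, drop = FALSE]
    both <- !is.na(a) & !is.na(b)
    list(a = a, b = b, both = both)
}

#' Genotype discordance between two genotyping methods
#'
#' Aligns two genotype objects by sample and locus id and measures the
#' fraction of cells, called in both, whose genotype codes differ.  Cells
#' missing in either dataset are excluded from both numerator and
#' denominator.  Any mismatch (het vs hom, or opposite homozygotes)
#' counts as one discordant cell.
#'
#' @param geA,geB \linkS4class{GenotypeExperiment}s (e.g. ddRAD vs GTseq
#'   calls of the same individuals)
#' @return list of class \code{ConcordanceReport}: \code{n_comparable},
#'   \code{n_discordant}, \code{discordance}, plus \code{per_sample} and
#'   \code{per_locus} data.frames
#' @export
crossMethodDiscordance <- function(geA, geB) {
    samples <- intersect(sampleMeta(geA)$sample_id,
                         sampleMeta(geB)$sample_id)
    loci <- intersect(locusInfo(geA)$locus_id, locusInfo(geB)$locus_id)
    if (!length(samples) || !length(loci))
        stop("no shared samples or loci between the two datasets")
    al <- .alignedPair(genotypes(geA), genotypes(geB), samples, loci)
    dis <- al$both & (al$a != al$b)
    per_sample <- data.frame(
        sample_id = samples,
        n_comparable = colSums(al$both),
        n_discordant = colSums(dis),
        discordance = ifelse(colSums(al$both) > 0,
                             colSums(dis) / colSums(al$both), NA_real_),
        row.names = NULL, stringsAsFactors = FALSE)
    per_locus <- data.frame(
        locus_id = loci,
        n_comparable = rowSums(al$both),
        n_discordant = rowSums(dis),
        discordance = ifelse(rowSums(al$both) > 0,
                             rowSums(dis) / rowSums(al$both), NA_real_),
        row.names = NULL, stringsAsFactors = FALSE)
    structure(list(n_comparable = sum(al$both), n_discordant = sum(dis),
                   discordance = if (sum(al$both) > 0)
                       sum(dis) / sum(al$both) else NA_real_,
                   per_sample = per_sample, per_locus = per_locus),
              class = "ConcordanceReport")
}

#' Genotyping error rate between technical replicates
#'
#' For each replicate group (samples sharing a \code{replicate_group}
#' label), measures pairwise genotype discordance over loci called in
#' both members; groups larger than two use all pairs.  The overall rate
#' pools discordant and comparable counts across pairs (robust to
#' unequal denominators) rather than averaging per-pair rates.
#'
#' @param ge a \linkS4class{GenotypeExperiment} whose colData carries
#'   \code{replicate_group}
#' @return list with \code{overall} (pooled error rate),
#'   \code{n_comparable}, \code{n_discordant}, and \code{per_pair}
#'   data.frame (group, sample_a, sample_b, n_comparable, n_discordant,
#'   error)
#' @export
replicateError <- function(ge) {
    sm <- sampleMeta(ge)
    groups <- unique(sm$replicate_group[!is.na(sm$replicate_group)])
    groups <- groups[vapply(groups, function(gr)
        sum(sm$replicate_group %in% gr) >= 2L, logical(1))]
    if (!length(groups))
        stop("no replicate group with at least two members")
    g <- genotypes(ge)
    rows <- list()
    for (gr in groups) {
        ids <- sm$sample_id[sm$replicate_group %in% gr]
        pr <- utils::combn(ids, 2L)
        for (k in seq_len(ncol(pr))) {
            a <- g[, pr[1, k]]; b <- g[, pr[2, k]]
            both <- !is.na(a) & !is.na(b)
            rows[[length(rows) + 1L]] <- data.frame(
                group = gr, sample_a = pr[1, k], sample_b = pr[2, k],
                n_comparable = sum(both),
                n_discordant = sum(both & a != b),
                stringsAsFactors = FALSE)
        }
    }
    pp <- do.call(rbind, rows)
    pp$error <- ifelse(pp$n_comparable > 0,
                       pp$n_discordant / pp$n_comparable, NA_real_)
    n_comp <- sum(pp$n_comparable); n_dis <- sum(pp$n_discordant)
    list(overall = if (n_comp > 0) n_dis / n_comp else NA_real_,
         n_comparable = n_comp, n_discordant = n_dis, per_pair = pp)
}
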