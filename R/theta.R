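## Two-population variance components of the Weir-Cockerham theta
## estimator, vectorized over loci.  n: diploid individuals called;
## p: alternate-allele frequency; h: observed heterozygote proportion.
.wcComponents <- function(n1, p1, h1, n2, p2, h2) {
    r <- 2
    nbar <- (n1 + n2) / r
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- (nbar / nc) *
        (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
        (pbar * (1 - pbar) - (r - 1) / r * s2 -
             (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    list(a = a, b = b, c = cc)
}

#' Weir-Cockerham theta for one locus and two populations
#'
#' Computes the among-population (a), among-individual-within-population
#' (b) and within-individual (c) variance components of the unbiased
#' theta estimator for two populations at one biallelic locus, and
#' \code{theta = a / (a + b + c)}.  Theta is undefined (NA, flagged) when
#' the denominator is zero, which happens exactly when the locus is
#' monomorphic across the pair.  Each population needs at least two
#' individuals with called genotypes.
#'
#' @param g1,g2 integer genotype code vectors (0/1/2/NA) for the two
#'   populations at the locus
#' @return list with \code{a}, \code{b}, \code{c}, \code{theta},
#'   \code{defined} (logical) and \code{skipped} (reason string or NA)
#' @export
weirCockerhamTheta <- function(g1, g2) {
    g1 <- g1[!is.na(g1)]; g2 <- g2[!is.na(g2)]
    n1 <- length(g1); n2 <- length(g2)
    if (n1 < 2L || n2 < 2L)
        return(list(a = NA_real_, b = NA_real_, c = NA_real_,
                    theta = NA_real_, defined = FALSE,
                    skipped = "fewer than 2 called genotypes in a population"))
    p1 <- sum(g1) / (2 * n1); p2 <- sum(g2) / (2 * n2)
    h1 <- mean(g1 == 1L); h2 <- mean(g2 == 1L)
    comp <- .wcComponents(n1, p1, h1, n2, p2, h2)
    denom <- comp$a + comp$b + comp$c
    defined <- abs(denom) > 1e-12
    list(a = comp$a, b = comp$b, c = comp$c,
         theta = if (defined) comp$a / denom else NA_real_,
         defined = defined, skipped = NA_character_)
}

.groupFreqStats <- function(g, idx) {
    sub <- g[, idx, drop = FALSE]
    n <- rowSums(!is.na(sub))
    p <- ifelse(n > 0, rowSums(sub, na.rm = TRUE) / (2 * n), NA_real_)
    h <- ifelse(n > 0, rowSums(sub == 1L, na.rm = TRUE) / n, NA_real_)
    list(n = n, p = p, h = h)
}

.pairTheta <- function(s1, s2) {
    ok <- s1$n >= 2L & s2$n >= 2L
    a <- b <- cc <- theta <- rep(NA_real_, length(s1$n))
    defined <- rep(FALSE, length(s1$n))
    if (any(ok)) {
        comp <- .wcComponents(s1$n[ok], s1$p[ok], s1$h[ok],
                              s2$n[ok], s2$p[ok], s2$h[ok])
        denom <- comp$a + comp$b + comp$c
        def <- abs(denom) > 1e-12
        a[ok] <- comp$a; b[ok] <- comp$b; cc[ok] <- comp$c
        theta[ok][def] <- comp$a[def] / denom[def]
        defined[ok] <- def
    }
    list(a = a, b = b, c = cc, theta = theta, defined = defined,
         skipped = ifelse(ok, NA_character_,
                          "fewer than 2 called genotypes in a population"))
}

#' Per-locus theta for all population pairs
#'
#' Computes the two-population Weir-Cockerham theta for every unordered
#' pair of populations at every locus, and (optionally) one
#' species-vs-species contrast per locus that pools each species' samples
#' into a single population.  Loci monomorphic across a pair are flagged
#' undefined, never silently zero.
#'
#' @param ge a \linkS4class{GenotypeExperiment}
#' @param speciesContrast add a brown-vs-black contrast per locus
#'   (default TRUE when both species are present)
#' @return data.frame of class \code{ThetaTable} with columns
#'   \code{locus_id}, \code{pop_a}, \code{pop_b}, \code{a}, \code{b},
#'   \code{c}, \code{theta}, \code{defined}, \code{contrast}
#'   (\code{"population"} or \code{"species"})
#' @export
thetaAllPairs <- function(ge, speciesContrast = NA) {
    sm <- sampleMeta(ge)
    pops <- unique(sm$population)
    if (length(pops) < 2L && !isTRUE(speciesContrast))
        stop("at least two populations are required")
    g <- genotypes(ge)
    ids <- locusInfo(ge)$locus_id
    stats <- lapply(pops, function(p)
        .groupFreqStats(g, which(sm$population == p)))
    names(stats) <- pops
    out <- list()
    if (length(pops) >= 2L) {
        pr <- utils::combn(sort(pops), 2L)
        for (k in seq_len(ncol(pr))) {
            pa <- pr[1, k]; pb <- pr[2, k]
            th <- .pairTheta(stats[[pa]], stats[[pb]])
            out[[length(out) + 1L]] <- data.frame(
                locus_id = ids, pop_a = pa, pop_b = pb, a = th$a, b = th$b,
                c = th$c, theta = th$theta, defined = th$defined,
                contrast = "population", stringsAsFactors = FALSE)
        }
    }
    species <- intersect(c("brown", "black"), unique(sm$species))
    if (is.na(speciesContrast)) speciesContrast <- length(species) == 2L
    if (isTRUE(speciesContrast)) {
        if (length(species) != 2L)
            stop("species contrast requires both species present")
        s1 <- .groupFreqStats(g, which(sm$species == species[1]))
        s2 <- .groupFreqStats(g, which(sm$species == species[2]))
        th <- .pairTheta(s1, s2)
        out[[length(out) + 1L]] <- data.frame(
            locus_id = ids, pop_a = species[1], pop_b = species[2],
            a = th$a, b = th$b, c = th$c, theta = th$theta,
            defined = th$defined, contrast = "species",
            stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
    class(res) <- c("ThetaTable", "data.frame")
    res
}

#' Per-species ranking scores from a theta table
#'
#' Reduces the pairwise thetas among one species' populations to a single
#' discriminatory-power score per locus: the maximum (default) or mean
#' pairwise theta over that species' population pairs.  Loci with no
#' defined pairwise theta within the species get no score (excluded from
#' ranking rather than scored zero).
#'
#' @param thetaTable a \code{ThetaTable} from \code{\link{thetaAllPairs}}
#' @param ge the GenotypeExperiment the table came from (provides the
#'   population-to-species map)
#' @param species \code{"brown"} or \code{"black"}
#' @param method \code{"max"} (default) or \code{"mean"}
#' @return data.frame with \code{locus_id}, \code{score}, sorted by
#'   decreasing score
#' @export
thetaScores <- function(thetaTable, ge, species,
                        method = c("max", "mean")) {
    method <- match.arg(method)
    sm <- sampleMeta(ge)
    sp_pops <- unique(sm$population[sm$species == species])
    tt <- thetaTable[thetaTable$contrast == "population" &
                     thetaTable$pop_a %in% sp_pops &
                     thetaTable$pop_b %in% sp_pops &
                     thetaTable$defined, , drop = FALSE]
    if (!nrow(tt))
        return(data.frame(locus_id = character(), score = numeric()))
    agg <- tapply(tt$theta, tt$locus_id,
                  if (method == "max") max else mean)
    out <- data.frame(locus_id = names(agg), score = as.numeric(agg),
                      stringsAsFactors = FALSE)
    out[order(-out$score, out$locus_id), , drop = FALSE]
}

#' Multilocus theta by summing variance components
#'
#' Combines per-locus estimates the way the estimator's authors
#' recommend: summing the a, b and c components over loci (optionally
#' restricted to one population pair) and taking the ratio.  This
#' weights loci by their information content and avoids the small-sample
#' bias of averaging per-locus ratios.
#'
#' @param thetaTable a \code{ThetaTable} from \code{\link{thetaAllPairs}}
#' @param pair optional length-2 character vector restricting to one
#'   population pair
#' @return a single multilocus theta estimate
#' @export
thetaMultilocus <- function(thetaTable, pair = NULL) {
    tt <- thetaTable[thetaTable$defined, , drop = FALSE]
    if (!is.null(pair)) {
        pair <- sort(pair)
        tt <- tt[tt$pop_a == pair[1] & tt$pop_b == pair[2], ,
                 drop = FALSE]
    }
    if (!nrow(tt)) return(NA_real_)
    sum(tt$a) / sum(tt$a + tt$b + tt$c)
}

#' Write a theta table as TSV
#'
#' @param thetaTable a ThetaTable
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeThetaTable <- function(thetaTable, path) {
    utils::write.table(thetaTable, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
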