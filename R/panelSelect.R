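#' Panel-selection configuration
#'
#' @param top_k_per_species informative loci retained per species
#'   (default 350)
#' @param n_diagnostic additional species-diagnostic loci (default 8)
#' @param min_spacing minimum genomic distance in bp between retained
#'   same-chromosome loci (default 1e6, i.e. 1 Mb)
#' @param score_method per-species ranking reduction passed to
#'   \code{\link{thetaScores}} (\code{"max"} or \code{"mean"})
#' @return list of class \code{SelectConfig}
#' @export
selectConfig <- function(top_k_per_species = 350L, n_diagnostic = 8L,
                         min_spacing = 1e6, score_method = "max") {
    if (top_k_per_species < 1 || n_diagnostic < 0 || min_spacing <= 0)
        stop("selectConfig values must be positive")
    structure(list(top_k_per_species = as.integer(top_k_per_species),
                   n_diagnostic = as.integer(n_diagnostic),
                   min_spacing = min_spacing, score_method = score_method),
              class = "SelectConfig")
}

#' Prune candidate loci closer than a minimum genomic spacing
#'
#' Candidates are visited in descending score order (score ties broken by
#' lexicographic locus_id for determinism).  A candidate is kept unless it
#' lies closer than \code{min_spacing} to an already-kept locus on the
#' same chromosome; when a conflict arises the lower-scoring locus is the
#' one removed, and the removal records the nearest retained locus it
#' conflicted with (whose score is necessarily at least as high).  The
#' result is independent of input order: no retained same-chromosome pair
#' is closer than \code{min_spacing}, and every removed locus has a
#' retained conflicting neighbor with a score at least its own.
#'
#' @param candidates data.frame with \code{locus_id}, \code{chrom},
#'   \code{pos}, \code{score} (all scores defined)
#' @param min_spacing minimum distance in bp
#' @return list with \code{survivors} (the retained rows of
#'   \code{candidates}, input order preserved) and \code{removals}
#'   (data.frame \code{removed}, \code{conflicting}: each removed locus
#'   with the retained, at-least-as-high-scoring locus it conflicted with)
#' @export
pruneBySpacing <- function(candidates, min_spacing = 1e6) {
    stopifnot(all(c("locus_id", "chrom", "pos", "score") %in%
                  names(candidates)))
    if (any(is.na(candidates$score)))
        stop("every candidate needs a defined score")
    removed <- character(); conflicting <- character()
    for (ch in unique(candidates$chrom)) {
        sub <- candidates[candidates$chrom == ch, , drop = FALSE]
        sub <- sub[order(-sub$score, sub$locus_id), , drop = FALSE]
        kept_pos <- numeric(); kept_id <- character()
        for (i in seq_len(nrow(sub))) {
            if (length(kept_pos)) {
                d <- abs(kept_pos - sub$pos[i])
                hit <- which(d < min_spacing)
                if (length(hit)) {
                    near <- hit[which.min(d[hit])]
                    removed <- c(removed, sub$locus_id[i])
                    conflicting <- c(conflicting, kept_id[near])
                    next
                }
            }
            kept_pos <- c(kept_pos, sub$pos[i])
            kept_id <- c(kept_id, sub$locus_id[i])
        }
    }
    keep <- !(candidates$locus_id %in% removed)
    list(survivors = candidates[keep, , drop = FALSE],
         removals = data.frame(removed = removed,
                               conflicting = conflicting,
                               stringsAsFactors = FALSE))
}

.topK <- function(scored, k) {
    ord <- order(-scored$score, scored$locus_id)
    scored[ord, , drop = FALSE][seq_len(min(k, nrow(scored))), ,
                                drop = FALSE]
}

#' Select the putative amplicon panel
#'
#' Per species: applies \code{\link{pruneBySpacing}} to that species'
#' scored candidates, then retains the \code{top_k_per_species} loci with
#' the highest discriminatory score.  Selection is sequential with
#' exclusion, so a locus informative for both species is used once.
#' Finally the \code{n_diagnostic} not-yet-selected loci with the highest
#' between-species theta (fixed differences, theta = 1, rank first) are
#' added as species-diagnostic.  When supply falls short of a quota, all
#' available loci are taken with a warning.
#'
#' @param brownCandidates,blackCandidates data.frames with
#'   \code{locus_id}, \code{chrom}, \code{pos}, \code{score} — each
#'   species' filtered, theta-scored candidates
#' @param betweenSpecies data.frame with \code{locus_id}, \code{theta}:
#'   candidates for species-diagnostic loci with their between-species
#'   theta (typically quality-filtered without the within-species
#'   variability requirement)
#' @param cfg a \code{\link{selectConfig}}
#' @return a \linkS4class{SnpPanel}
#' @export
selectPanel <- function(brownCandidates, blackCandidates, betweenSpecies,
                        cfg = selectConfig()) {
    stopifnot(inherits(cfg, "SelectConfig"))
    if (!nrow(brownCandidates) || !nrow(blackCandidates))
        stop("empty candidate list for a species")
    pr_brown <- pruneBySpacing(brownCandidates, cfg$min_spacing)
    top_brown <- .topK(pr_brown$survivors, cfg$top_k_per_species)

    blackPool <- blackCandidates[
        !(blackCandidates$locus_id %in% top_brown$locus_id), , drop = FALSE]
    pr_black <- pruneBySpacing(blackPool, cfg$min_spacing)
    top_black <- .topK(pr_black$survivors, cfg$top_k_per_species)

    taken <- c(top_brown$locus_id, top_black$locus_id)
    diagPool <- betweenSpecies[!(betweenSpecies$locus_id %in% taken) &
                               !is.na(betweenSpecies$theta), , drop = FALSE]
    ordd <- order(-diagPool$theta, diagPool$locus_id)
    diag <- diagPool[ordd, , drop = FALSE][
        seq_len(min(cfg$n_diagnostic, nrow(diagPool))), , drop = FALSE]

    short <- c(brown = cfg$top_k_per_species - nrow(top_brown),
               black = cfg$top_k_per_species - nrow(top_black),
               diagnostic = cfg$n_diagnostic - nrow(diag))
    if (any(short > 0))
        warning("candidate supply short of quota: ",
                paste(sprintf("%s by %d", names(short)[short > 0],
                              short[short > 0]), collapse = ", "))

    roleDf <- function(ids, role, score)
        data.frame(locus_id = as.character(ids),
                   role = rep(role, length(ids)),
                   score = as.numeric(score), stringsAsFactors = FALSE)
    entries <- rbind(
        roleDf(top_brown$locus_id, "brown_informative", top_brown$score),
        roleDf(top_black$locus_id, "black_informative", top_black$score),
        roleDf(diag$locus_id, "species_diagnostic", diag$theta))
    removals <- rbind(pr_brown$removals, pr_black$removals)
    new("SnpPanel", entries = entries, spacingRemovals = removals,
        config = unclass(cfg))
}

#' Write a SnpPanel as JSON and per-locus TSV
#'
#' @param panel a \linkS4class{SnpPanel}
#' @param jsonPath,tsvPath output paths
#' @return invisibly, the entries data.frame
#' @export
writePanel <- function(panel, jsonPath, tsvPath) {
    jsonlite::write_json(list(entries = panelEntries(panel),
                              spacing_removals = spacingRemovals(panel),
                              config = panel@config),
                         jsonPath, auto_unbox = TRUE, digits = NA)
    utils::write.table(panelEntries(panel), tsvPath, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(panelEntries(panel))
}

#' Read a SnpPanel back from its JSON serialization
#'
#' @param jsonPath path written by \code{\link{writePanel}}
#' @return a \linkS4class{SnpPanel}
#' @export
readPanel <- function(jsonPath) {
    x <- jsonlite::read_json(jsonPath, simplifyVector = TRUE)
    rem <- as.data.frame(x$spacing_removals)
    if (!nrow(rem))
        rem <- data.frame(removed = character(), conflicting = character())
    new("SnpPanel", entries = as.data.frame(x$entries),
        spacingRemovals = rem, config = as.list(x$config))
}

#' Emit a FASTA of RADtag sequences for the selected panel loci
#'
#' A passthrough handoff for primer design: sequences are supplied by the
#' caller (e.g. from the RADtag catalog) and written for the panel's loci
#' in panel order.
#'
#' @param panel a \linkS4class{SnpPanel}
#' @param tagSeqs named character vector of RADtag sequences keyed by
#'   locus_id (must cover the panel)
#' @param path output FASTA path
#' @return \code{path}, invisibly
#' @export
panelFasta <- function(panel, tagSeqs, path) {
    ids <- panelLoci(panel)
    miss <- setdiff(ids, names(tagSeqs))
    if (length(miss))
        stop("no RADtag sequence for: ", paste(miss, collapse = ", "))
    if (requireNamespace("Biostrings", quietly = TRUE)) {
        Biostrings::writeXStringSet(
            Biostrings::DNAStringSet(tagSeqs[ids]), path)
    } else {
        writeLines(paste0(">", ids, "\n", tagSeqs[ids]), path)
    }
    invisible(path)
}

#' Design a panel end-to-end from a filtered-candidate genotype object
#'
#' Orchestrates the design stage: runs the filter cascade for
#' species-informative candidacy, a second quality-only pass (without the
#' variable-in-a-species requirement) for the species-diagnostic pool,
#' computes pairwise and between-species theta, scores each species'
#' candidates and calls \code{\link{selectPanel}}.
#'
#' @param ge a \linkS4class{GenotypeExperiment} with both species, ddRAD
#'   reference samples
#' @param filterCfg a \code{\link{filterConfig}}
#' @param selectCfg a \code{\link{selectConfig}}
#' @return list with \code{panel} (\linkS4class{SnpPanel}),
#'   \code{filterReport}, \code{thetaTable} and \code{candidates}
#'   (per-species candidate counts entering selection)
#' @export
designPanel <- function(ge, filterCfg = filterConfig(),
                        selectCfg = selectConfig()) {
    flt <- applyFilterCascade(ge, filterCfg)
    tt <- thetaAllPairs(flt$ge, speciesContrast = TRUE)
    li <- as.data.frame(locusInfo(flt$ge))
    cand <- function(species) {
        sc <- thetaScores(tt, flt$ge, species, selectCfg$score_method)
        m <- match(sc$locus_id, li$locus_id)
        data.frame(locus_id = sc$locus_id, chrom = li$chrom[m],
                   pos = li$pos[m], score = sc$score,
                   stringsAsFactors = FALSE)
    }
    brown <- cand("brown"); black <- cand("black")

    diagCfg <- filterCfg
    diagCfg$require_species_variable <- FALSE
    fltDiag <- applyFilterCascade(ge, diagCfg)
    ttDiag <- thetaAllPairs(fltDiag$ge, speciesContrast = TRUE)
    between <- ttDiag[ttDiag$contrast == "species" & ttDiag$defined,
                      c("locus_id", "theta"), drop = FALSE]

    panel <- selectPanel(brown, black, between, selectCfg)
    list(panel = panel, filterReport = flt$report, thetaTable = tt,
         candidates = c(brown = nrow(brown), black = nrow(black),
                        diagnostic = nrow(between)))
}
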