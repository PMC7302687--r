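#' Filter-cascade configuration
#'
#' Thresholds for the candidate-locus filter cascade.  Comparison
#' directions follow the stated rules exactly: overall and per-species
#' call rates are strict (call rate must exceed the threshold), MAF and
#' mean depth are inclusive minima, observed heterozygosity is an
#' inclusive maximum, and the RADtag offset window is inclusive at both
#' ends.
#'
#' @param min_call_rate_all loci must be genotyped in more than this
#'   fraction of all individuals (default 0.90, strict >)
#' @param min_maf minimum overall minor-allele frequency (default 0.05, >=)
#' @param max_ho maximum overall observed heterozygosity (default 0.50, <=)
#' @param min_call_rate_species per-species call-rate threshold
#'   (default 0.90, strict >)
#' @param min_mean_depth_species per-species minimum mean depth
#'   (default 6, >=)
#' @param tag_window inclusive bp window for the SNP offset from the
#'   RADtag start (default c(40, 60))
#' @param one_snp_per_tag keep a single SNP per RADtag (default TRUE)
#' @param require_species_variable require the locus to be variable
#'   (MAF > 0) in at least one species (default TRUE); disable to build
#'   the candidate pool for species-diagnostic loci, which are typically
#'   monomorphic within each species
#' @return a list of class \code{FilterConfig}
#' @export
filterConfig <- function(min_call_rate_all = 0.90, min_maf = 0.05,
                         max_ho = 0.50, min_call_rate_species = 0.90,
                         min_mean_depth_species = 6,
                         tag_window = c(40L, 60L), one_snp_per_tag = TRUE,
                         require_species_variable = TRUE) {
    fr <- c(min_call_rate_all, min_maf, max_ho, min_call_rate_species)
    if (any(fr < 0 | fr > 1)) stop("fractional thresholds must be in [0,1]")
    if (length(tag_window) != 2L || tag_window[1] > tag_window[2])
        stop("tag_window must be an ordered length-2 interval")
    structure(list(min_call_rate_all = min_call_rate_all, min_maf = min_maf,
                   max_ho = max_ho,
                   min_call_rate_species = min_call_rate_species,
                   min_mean_depth_species = min_mean_depth_species,
                   tag_window = tag_window, one_snp_per_tag = one_snp_per_tag,
                   require_species_variable = require_species_variable),
              class = "FilterConfig")
}

#' Pick one SNP per RADtag
#'
#' Within each RADtag, keeps the SNP with the highest overall call rate,
#' breaking ties by higher MAF and then by smallest tag offset (a
#' deterministic rule; linkage within a tag makes any single choice
#' equivalent for the panel).
#'
#' @param loci data.frame with locus_id, radtag_id, tag_offset
#' @param stats data.frame from \code{\link{locusStats}} covering every
#'   locus (group "all")
#' @return character vector of surviving locus_ids
#' @export
selectOneSnpPerTag <- function(loci, stats) {
    i <- match(loci$locus_id, stats$locus_id)
    if (anyNA(i)) stop("stats missing for some loci")
    ord <- order(loci$radtag_id,
                 -stats$call_rate[i],
                 -ifelse(is.na(stats$maf[i]), -1, stats$maf[i]),
                 loci$tag_offset,
                 loci$locus_id)
    first <- !duplicated(loci$radtag_id[ord])
    sort_back <- loci$locus_id[ord][first]
    loci$locus_id[loci$locus_id %in% sort_back]
}

#' Apply the candidate-locus filter cascade
#'
#' Stages, applied in a fixed order with every removal attributed:
#' \enumerate{
#'   \item overall call rate strictly above \code{min_call_rate_all};
#'   \item overall MAF at least \code{min_maf};
#'   \item overall observed heterozygosity at most \code{max_ho};
#'   \item one SNP per RADtag (\code{\link{selectOneSnpPerTag}});
#'   \item variable (MAF > 0) in at least one species;
#'   \item call rate strictly above \code{min_call_rate_species} in each
#'     species separately;
#'   \item mean depth at least \code{min_mean_depth_species} in each
#'     species separately (skipped with a warning when the object has no
#'     depth assay);
#'   \item tag offset inside the inclusive \code{tag_window}.
#' }
#'
#' @param ge a \linkS4class{GenotypeExperiment} containing both species
#' @param cfg a \code{\link{filterConfig}}
#' @return list with \code{ge} (the filtered object) and \code{report}, a
#'   list with \code{stages} (data.frame stage/n_in/n_out) and
#'   \code{removed} (named list of locus_ids removed per stage)
#' @export
applyFilterCascade <- function(ge, cfg = filterConfig()) {
    stopifnot(inherits(cfg, "FilterConfig"))
    species <- intersect(c("brown", "black"), unique(sampleMeta(ge)$species))
    stages <- character(); n_in <- integer(); n_out <- integer()
    removed <- list()
    keep_stage <- function(name, keep_ids) {
        ids <- locusInfo(ge)$locus_id
        drop <- setdiff(ids, keep_ids)
        stages <<- c(stages, name)
        n_in <<- c(n_in, length(ids))
        n_out <<- c(n_out, length(ids) - length(drop))
        removed[[name]] <<- drop
        if (length(drop)) ge <<- selectLoci(ge, setdiff(ids, drop))
        invisible(NULL)
    }

    st <- locusStats(ge, "all")
    keep_stage("call_rate_all",
               st$locus_id[st$call_rate > cfg$min_call_rate_all])
    st <- locusStats(ge, "all")
    keep_stage("maf_all",
               st$locus_id[!is.na(st$maf) & st$maf >= cfg$min_maf])
    st <- locusStats(ge, "all")
    keep_stage("ho_all", st$locus_id[!is.na(st$ho) & st$ho <= cfg$max_ho])

    if (isTRUE(cfg$one_snp_per_tag)) {
        li <- as.data.frame(locusInfo(ge))
        if (all(is.na(li$radtag_id))) {
            keep_stage("one_snp_per_tag", li$locus_id)
        } else {
            st <- locusStats(ge, "all")
            keep_stage("one_snp_per_tag", selectOneSnpPerTag(li, st))
        }
    }

    if (isTRUE(cfg$require_species_variable) && length(species)) {
        sp_stats <- lapply(species, function(s) locusStats(ge, s))
        variable <- Reduce(`|`, lapply(sp_stats, function(s)
            !is.na(s$maf) & s$maf > 0))
        keep_stage("variable_in_a_species",
                   locusInfo(ge)$locus_id[variable])
    }

    if (length(species)) {
        sp_stats <- lapply(species, function(s) locusStats(ge, s))
        ok <- Reduce(`&`, lapply(sp_stats, function(s)
            s$call_rate > cfg$min_call_rate_species))
        keep_stage("call_rate_species", locusInfo(ge)$locus_id[ok])

        if (is.null(depths(ge))) {
            warning("no depth assay: per-species mean-depth stage skipped")
            keep_stage("mean_depth_species", locusInfo(ge)$locus_id)
        } else {
            sp_stats <- lapply(species, function(s) locusStats(ge, s))
            ok <- Reduce(`&`, lapply(sp_stats, function(s)
                !is.na(s$mean_depth) &
                    s$mean_depth >= cfg$min_mean_depth_species))
            keep_stage("mean_depth_species", locusInfo(ge)$locus_id[ok])
        }
    }

    li <- as.data.frame(locusInfo(ge))
    if (all(is.na(li$tag_offset))) {
        keep_stage("tag_offset_window", li$locus_id)
    } else {
        ok <- !is.na(li$tag_offset) &
            li$tag_offset >= cfg$tag_window[1] &
            li$tag_offset <= cfg$tag_window[2]
        keep_stage("tag_offset_window", li$locus_id[ok])
    }

    if (nrow(ge) == 0L) warning("no loci survive the filter cascade")
    report <- list(
        stages = data.frame(stage = stages, n_in = n_in, n_out = n_out,
                            stringsAsFactors = FALSE),
        removed = removed,
        surviving = locusInfo(ge)$locus_id)
    list(ge = ge, report = report)
}

#' Write a filter report as TSV (stage, locus_id) plus a JSON summary
#'
#' @param report the \code{report} element of
#'   \code{\link{applyFilterCascade}}'s value
#' @param tsvPath,jsonPath output paths
#' @return invisibly, the removal data.frame
#' @export
writeFilterReport <- function(report, tsvPath, jsonPath) {
    rem <- do.call(rbind, lapply(names(report$removed), function(s) {
        ids <- report$removed[[s]]
        if (!length(ids)) return(NULL)
        data.frame(stage = s, locus_id = ids, stringsAsFactors = FALSE)
    }))
    if (is.null(rem))
        rem <- data.frame(stage = character(), locus_id = character())
    utils::write.table(rem, tsvPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    jsonlite::write_json(list(stages = report$stages,
                              n_surviving = length(report$surviving)),
                         jsonPath, auto_unbox = TRUE, digits = NA)
    invisible(rem)
}
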