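#' @importClassesFrom vcfR vcfR
NULL

#' Read a biallelic SNP VCF into a GenotypeExperiment
#'
#' Reads a VCF (v4.2, plain or bgzipped) via \pkg{vcfR}.  Each record
#' becomes one locus; GT fields \code{0/0}, \code{0/1} (or \code{1/0}),
#' \code{1/1} map to codes 0, 1, 2 and \code{./.} to \code{NA}; phased
#' separators are accepted and phase is discarded.  Per-cell DP populates
#' the depth assay when present.  Multi-allelic records are rejected.
#'
#' Sample metadata defaults to species/population/method "unknown" until a
#' popmap is attached with \code{popmap =} or \code{\link{attachPopmap}}.
#'
#' @param path path to the VCF file
#' @param popmap optional data.frame from \code{\link{readPopmap}}; must
#'   cover every VCF sample
#' @param locusTable optional data.frame from \code{\link{readLocusTable}};
#'   must cover every VCF locus
#' @return a \linkS4class{GenotypeExperiment}
#' @export
readGenotypeVcf <- function(path, popmap = NULL, locusTable = NULL) {
    if (!file.exists(path)) stop("no such file: ", path)
    vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                    error = function(e)
                        stop("malformed VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE))
    fix <- vcfR::getFIX(vcf)
    if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                         dimnames = list(NULL, names(fix)))
    alt <- fix[, "ALT"]
    multi <- grepl(",", alt)
    if (any(multi))
        stop("multi-allelic record(s) not supported: ",
             paste(paste0(fix[multi, "CHROM"], ":", fix[multi, "POS"]),
                   collapse = ", "))
    gt_raw <- vcfR::extract.gt(vcf, element = "GT")
    if (is.null(dim(gt_raw)))
        gt_raw <- matrix(gt_raw, nrow = nrow(fix))
    gt_clean <- gsub("\\|", "/", gt_raw)
    code <- matrix(NA_integer_, nrow(gt_clean), ncol(gt_clean))
    code[gt_clean %in% "0/0"] <- 0L
    code[gt_clean %in% c("0/1", "1/0")] <- 1L
    code[gt_clean %in% "1/1"] <- 2L
    unknown <- !is.na(gt_clean) & !(gt_clean %in%
        c("0/0", "0/1", "1/0", "1/1", "./.", "."))
    if (any(unknown))
        stop("unparseable GT value(s): ",
             paste(unique(gt_clean[unknown]), collapse = ", "))
    depth <- NULL
    fmt <- vcf@gt[, 1]
    if (all(grepl("DP", fmt))) {
        depth <- suppressWarnings(
            vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE))
        if (is.null(dim(depth))) depth <- matrix(depth, nrow = nrow(fix))
    }
    ids <- fix[, "ID"]
    blank <- is.na(ids) | ids == "."
    ids[blank] <- paste0(fix[blank, "CHROM"], "_", fix[blank, "POS"])
    locusData <- data.frame(
        locus_id = ids, chrom = fix[, "CHROM"],
        pos = as.integer(fix[, "POS"]),
        radtag_id = NA_character_, tag_offset = NA_integer_,
        ref_allele = fix[, "REF"], alt_allele = alt,
        stringsAsFactors = FALSE)
    samples <- colnames(vcf@gt)[-1]
    sampleData <- data.frame(
        sample_id = samples, species = "unknown", population = "unknown",
        method = "ddRAD", replicate_group = NA_character_,
        stringsAsFactors = FALSE)
    ge <- GenotypeExperiment(code, sampleData, locusData, depth = depth)
    if (!is.null(popmap)) ge <- attachPopmap(ge, popmap)
    if (!is.null(locusTable)) ge <- attachLocusTable(ge, locusTable)
    ge
}

#' Write a GenotypeExperiment as a (bgzipped) VCF
#'
#' Emits a minimal VCF v4.2 with GT (and DP when a depth assay is present)
#' through \code{vcfR::write.vcf}, which bgzips its output; pass a path
#' ending in \code{.vcf.gz}.  Round-trips genotype codes and coordinates
#' through \code{\link{readGenotypeVcf}} losslessly.
#'
#' @param ge a \linkS4class{GenotypeExperiment}
#' @param path output path (\code{.vcf.gz})
#' @return \code{path}, invisibly
#' @export
writeGenotypeVcf <- function(ge, path) {
    li <- as.data.frame(locusInfo(ge))
    g <- genotypes(ge)
    d <- depths(ge)
    gt_str <- matrix(c("0/0", "0/1", "1/1")[g + 1L], nrow(g), ncol(g))
    gt_str[is.na(g)] <- "./."
    fmt <- "GT"
    if (!is.null(d)) {
        dp <- ifelse(is.na(d), ".", as.character(d))
        gt_str <- matrix(paste(gt_str, dp, sep = ":"), nrow(g), ncol(g))
        fmt <- "GT:DP"
    }
    ref <- if ("ref_allele" %in% names(li)) li$ref_allele else "A"
    alt <- if ("alt_allele" %in% names(li)) li$alt_allele else "C"
    fix <- cbind(CHROM = as.character(li$chrom), POS = as.character(li$pos),
                 ID = li$locus_id, REF = ref, ALT = alt, QUAL = ".",
                 FILTER = "PASS", INFO = ".")
    gt <- cbind(FORMAT = fmt, gt_str)
    colnames(gt) <- c("FORMAT", sampleMeta(ge)$sample_id)
    vcf <- new("vcfR",
               meta = c("##fileformat=VCFv4.2",
                        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                        "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read Depth\">"),
               fix = fix, gt = gt)
    vcfR::write.vcf(vcf, file = path)
    invisible(path)
}

#' Read a population map (popmap) TSV
#'
#' Expects a header line and columns \code{sample_id}, \code{species},
#' \code{population}, \code{method}, \code{replicate_group} (the last may
#' be empty).  Species must be \code{brown}, \code{black} or
#' \code{unknown}; method \code{ddRAD} or \code{GTseq}.
#'
#' @param path path to the TSV
#' @return data.frame of sample metadata in file order
#' @export
readPopmap <- function(path) {
    pm <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character")
    need <- c("sample_id", "species", "population", "method",
              "replicate_group")
    miss <- setdiff(need, names(pm))
    if (length(miss))
        stop("popmap lacks column(s): ", paste(miss, collapse = ", "))
    dup <- pm$sample_id[duplicated(pm$sample_id)]
    if (length(dup))
        stop("duplicate sample_id in popmap: ",
             paste(unique(dup), collapse = ", "))
    bad <- setdiff(unique(pm$species), .SPECIES_LEVELS)
    if (length(bad))
        stop("unknown species token(s): ", paste(bad, collapse = ", "))
    bad <- setdiff(unique(pm$method), .METHOD_LEVELS)
    if (length(bad))
        stop("unknown method token(s): ", paste(bad, collapse = ", "))
    pm$replicate_group[pm$replicate_group == ""] <- NA_character_
    rg <- table(pm$replicate_group)
    if (any(rg < 2))
        stop("replicate_group with a single member: ",
             paste(names(rg)[rg < 2], collapse = ", "))
    pm[, need]
}

#' Attach popmap metadata to a GenotypeExperiment
#'
#' @param ge a GenotypeExperiment
#' @param popmap data.frame from \code{\link{readPopmap}}
#' @return the GenotypeExperiment with colData replaced from the popmap
#' @export
attachPopmap <- function(ge, popmap) {
    idx <- match(sampleMeta(ge)$sample_id, popmap$sample_id)
    if (anyNA(idx))
        stop("samples absent from popmap: ",
             paste(sampleMeta(ge)$sample_id[is.na(idx)], collapse = ", "))
    cd <- DataFrame(popmap[idx, , drop = FALSE])
    rownames(cd) <- cd$sample_id
    colData(ge) <- cd
    ge
}

#' Read a RADtag locus table TSV
#'
#' Expects a header and columns \code{locus_id}, \code{chrom}, \code{pos},
#' \code{radtag_id}, \code{tag_offset}, \code{ref}, \code{alt}.
#' Coordinates and tag offsets are 1-based and must be >= 1.
#'
#' @param path path to the TSV
#' @return data.frame of locus records
#' @export
readLocusTable <- function(path) {
    lt <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("locus_id", "chrom", "pos", "radtag_id", "tag_offset",
              "ref", "alt")
    miss <- setdiff(need, names(lt))
    if (length(miss))
        stop("locus table lacks column(s): ", paste(miss, collapse = ", "))
    if (any(lt$pos < 1))
        stop("pos must be >= 1 (1-based coordinates)")
    if (any(lt$tag_offset < 1))
        stop("tag_offset must be >= 1 (1-based from RADtag start)")
    ok <- c("A", "C", "G", "T")
    if (!all(lt$ref %in% ok) || !all(lt$alt %in% ok) ||
        any(lt$ref == lt$alt))
        stop("alleles must be distinct single nucleotides A/C/G/T")
    lt
}

#' Attach RADtag geometry from a locus table
#'
#' Aligns records to the object's loci by \code{locus_id}; any locus in the
#' object missing from the table is an error.
#'
#' @param ge a GenotypeExperiment
#' @param locusTable data.frame from \code{\link{readLocusTable}}
#' @return the GenotypeExperiment with rowData completed
#' @export
attachLocusTable <- function(ge, locusTable) {
    idx <- match(locusInfo(ge)$locus_id, locusTable$locus_id)
    if (anyNA(idx))
        stop("loci absent from locus table: ",
             paste(locusInfo(ge)$locus_id[is.na(idx)], collapse = ", "))
    lt <- locusTable[idx, , drop = FALSE]
    rd <- DataFrame(locus_id = lt$locus_id, chrom = lt$chrom,
                    pos = as.integer(lt$pos), radtag_id = lt$radtag_id,
                    tag_offset = as.integer(lt$tag_offset),
                    ref_allele = lt$ref, alt_allele = lt$alt)
    rownames(rd) <- rd$locus_id
    rowData(ge) <- rd
    ge
}

#' Read a long-format amplicon counts TSV
#'
#' Columns: \code{sample_id}, \code{locus_id}, \code{allele1_count},
#' \code{allele2_count}, \code{other_count}.  Optional companion tables
#' give per-locus forward-primer totals, artifact reads and dimer pairs.
#'
#' @param path counts TSV
#' @param primerPath optional TSV with columns locus_id, forward_primer_reads
#' @param artifactPath optional TSV with columns locus_id, artifact_reads
#' @param dimerPath optional TSV with columns locus1, locus2
#' @return an \linkS4class{AmpliconCounts}
#' @export
readAmpliconCounts <- function(path, primerPath = NULL, artifactPath = NULL,
                               dimerPath = NULL) {
    cc <- utils::read.delim(path, stringsAsFactors = FALSE)
    pr <- NULL
    if (!is.null(primerPath)) {
        p <- utils::read.delim(primerPath, stringsAsFactors = FALSE)
        pr <- setNames(p$forward_primer_reads, p$locus_id)
    }
    ar <- NULL
    if (!is.null(artifactPath)) {
        a <- utils::read.delim(artifactPath, stringsAsFactors = FALSE)
        ar <- setNames(a$artifact_reads, a$locus_id)
        loci <- unique(cc$locus_id)
        full <- setNames(numeric(length(loci)), loci)
        full[names(ar)] <- ar
        ar <- full
    }
    dm <- if (!is.null(dimerPath))
        utils::read.delim(dimerPath, stringsAsFactors = FALSE) else NULL
    AmpliconCounts(cc, primerReads = pr, artifactReads = ar,
                   dimerPairs = dm)
}
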