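#' Fit a reference PCA for projection of new samples
#'
#' Standardizes reference genotypes per locus — centering by the mean
#' genotype \eqn{\mu_l} and scaling by \eqn{\sqrt{p_l (1 - p_l)}} with
#' \eqn{p_l = \mu_l / 2} the reference alternate-allele frequency — with
#' missing cells mean-imputed (zero after centering), then
#' eigendecomposes via SVD.  Loci monomorphic in the reference are
#' dropped from the model.  New samples are mapped onto the fixed
#' eigenvectors with \code{\link{projectSamples}} rather than refitting.
#'
#' @param ge a \linkS4class{GenotypeExperiment} of reference samples
#' @param nComponents number of components to retain (default 10, capped
#'   at the available rank)
#' @return list of class \code{PCAModel}: \code{mu}, \code{s} (per-locus
#'   center/scale), \code{V} (loci x components eigenvector matrix with
#'   orthonormal columns), \code{eigenvalues} (non-increasing),
#'   \code{scores} (reference samples x components) and \code{loci}
#' @export
fitReferencePCA <- function(ge, nComponents = 10L) {
    g <- genotypes(ge)
    mu <- rowMeans(g, na.rm = TRUE)
    p <- mu / 2
    s <- sqrt(p * (1 - p))
    keep <- !is.na(s) & s > 0
    if (!any(keep)) stop("no polymorphic locus in the reference")
    g <- g[keep, , drop = FALSE]
    mu <- mu[keep]; s <- s[keep]
    z <- (g - mu) / s
    z[is.na(z)] <- 0
    zt <- t(z)  # samples x loci
    sv <- svd(zt)
    k <- min(nComponents, sum(sv$d > 1e-9))
    V <- sv$v[, seq_len(k), drop = FALSE]
    rownames(V) <- rownames(g)
    scores <- zt %*% V
    colnames(scores) <- paste0("PC", seq_len(k))
    colnames(V) <- colnames(scores)
    structure(list(mu = mu, s = s, V = V,
                   eigenvalues = sv$d[seq_len(k)]^2 / (nrow(zt) - 1),
                   scores = scores, loci = rownames(g)),
              class = "PCAModel")
}

#' Project samples onto a fitted reference PCA
#'
#' Each sample is standardized with the model's per-locus center and
#' scale, restricted to its called model loci, and projected by least
#' squares onto the retained eigenvectors.  A sample with no missing data
#' projects exactly to \eqn{V^\top z}; with missing data the projection
#' solves the normal equations over the observed loci.
#'
#' @param model a \code{PCAModel} from \code{\link{fitReferencePCA}}
#' @param ge a \linkS4class{GenotypeExperiment} sharing the model's loci
#' @return samples x components score matrix
#' @export
projectSamples <- function(model, ge) {
    stopifnot(inherits(model, "PCAModel"))
    shared <- intersect(model$loci, locusInfo(ge)$locus_id)
    if (!length(shared)) stop("no model locus present in the new samples")
    g <- genotypes(ge)[shared, , drop = FALSE]
    mi <- match(shared, model$loci)
    mu <- model$mu[mi]; s <- model$s[mi]
    V <- model$V[mi, , drop = FALSE]
    out <- matrix(NA_real_, ncol(g), ncol(V),
                  dimnames = list(colnames(g), colnames(V)))
    for (j in seq_len(ncol(g))) {
        z <- (g[, j] - mu) / s
        obs <- !is.na(z)
        if (!any(obs))
            stop("sample ", colnames(g)[j],
                 " has no called locus in the PCA model")
        Vo <- V[obs, , drop = FALSE]
        out[j, ] <- qr.solve(crossprod(Vo), crossprod(Vo, z[obs]))
    }
    out
}

#' DAPC-style species/class classification
#'
#' Discriminant analysis of principal components: a PCA is fitted on the
#' labelled reference samples, components are retained up to a cumulative
#' explained-variance target (capped at a third of the reference sample
#' count), linear discriminant analysis is fitted on the retained scores,
#' and new samples are projected into the same space and scored.  Class
#' posteriors sum to one per sample.
#'
#' @param refGe labelled reference \linkS4class{GenotypeExperiment}
#' @param classes character vector of class labels aligned to the
#'   reference samples (default the species column); at least two classes
#'   with at least two samples each
#' @param newGe samples to classify (may be the reference itself)
#' @param cumVar cumulative explained-variance target for retained
#'   components (default 0.9)
#' @return list with \code{posterior} (samples x classes), \code{class}
#'   (named vector of the highest-posterior class) and \code{nPC}
#' @export
dapcClassify <- function(refGe, newGe, classes = NULL, cumVar = 0.9) {
    if (is.null(classes)) classes <- sampleMeta(refGe)$species
    classes <- as.character(classes)
    tab <- table(classes)
    if (length(tab) < 2L) stop("at least two classes are required")
    if (any(tab < 2L))
        stop("class with a single sample: ",
             paste(names(tab)[tab < 2L], collapse = ", "))
    n <- ncol(refGe)
    model <- fitReferencePCA(refGe, nComponents = max(2L, floor(n / 3)))
    ev <- model$eigenvalues / sum(model$eigenvalues)
    k <- min(max(2L, which(cumsum(ev) >= cumVar)[1]),
             max(2L, floor(n / 3)), ncol(model$scores))
    tr <- as.data.frame(model$scores[, seq_len(k), drop = FALSE])
    fit <- MASS::lda(tr, grouping = factor(classes))
    proj <- projectSamples(model, newGe)[, seq_len(k), drop = FALSE]
    pred <- stats::predict(fit, as.data.frame(proj))
    post <- pred$posterior
    rownames(post) <- sampleMeta(newGe)$sample_id
    cls <- as.character(pred$class)
    names(cls) <- rownames(post)
    list(posterior = post, class = cls, nPC = k)
}
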