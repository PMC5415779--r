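## Tissue-level similarity: profile averaging, Euclidean hierarchical
## clustering, Pearson correlation and corrgram-style PCA ordering.

#' Average window profiles by group
#'
#' Arithmetic mean per group per analyzed window (ND windows are dropped),
#' e.g. the per-tissue average RPKM profiles used for the tissue dendrogram.
#'
#' @param we A \code{WindowExperiment}.
#' @param grouping Factor/character of length \code{ncol(we)} (e.g.
#'   \code{colData(we)$tissue}); use sample ids for per-sample profiles.
#' @param assayName Assay averaged (default "rpkm").
#' @return Numeric matrix, groups x analyzed windows.
#' @export
averageProfiles <- function(we, grouping, assayName = "rpkm") {
    stopifnot(length(grouping) == ncol(we))
    if (any(table(grouping) == 0L)) stop("empty group")
    m <- assay(we, assayName)[analyzedWindows(we), , drop = FALSE]
    groups <- unique(as.character(grouping))
    out <- t(vapply(groups, function(g)
        rowMeans(m[, grouping == g, drop = FALSE]), numeric(nrow(m))))
    rownames(out) <- groups
    out
}

#' Hierarchical clustering of profiles
#'
#' \code{hclust} on the Euclidean distance between profile rows
#' (complete linkage by default); deterministic given input order.
#'
#' @param profiles Matrix, profiles x windows.
#' @param metric Distance metric (default "euclidean").
#' @param linkage Agglomeration method (default "complete").
#' @return An \code{hclust} tree.
#' @export
clusterProfiles <- function(profiles, metric = "euclidean",
                            linkage = "complete") {
    if (nrow(profiles) < 2L) stop("need >= 2 profiles")
    if (any(!is.finite(profiles))) stop("non-finite values in profiles")
    hclust(dist(profiles, method = metric), method = linkage)
}

#' Pearson correlation matrix between profiles
#'
#' @param profiles Matrix, profiles x windows (>= 2 windows, nonzero
#'   variance per profile).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlationMatrix <- function(profiles) {
    if (ncol(profiles) < 2L) stop("need >= 2 windows per profile")
    v <- apply(profiles, 1L, sd)
    if (any(v == 0))
        stop("zero-variance profile(s): ",
             paste(rownames(profiles)[v == 0], collapse = ", "))
    cor(t(profiles))
}

#' Corrgram-style PCA ordering of a correlation matrix
#'
#' Samples are ordered by the angle \code{atan2(PC2, PC1)} of the first two
#' eigenvectors of the correlation matrix (the ordering used by corrgram's
#' "PCA" option).  Eigenvector signs are fixed by making the
#' largest-magnitude loading positive so the ordering is reproducible; ties
#' break by original index.
#'
#' @param cmat Square correlation matrix.
#' @return Integer permutation of \code{seq_len(nrow(cmat))}.
#' @export
pcaOrder <- function(cmat) {
    cmat <- as.matrix(cmat)
    if (nrow(cmat) != ncol(cmat)) stop("correlation matrix must be square")
    ev <- eigen(cmat, symmetric = TRUE)
    fix <- function(v) if (v[which.max(abs(v))] < 0) -v else v
    pc1 <- fix(ev$vectors[, 1])
    pc2 <- if (ncol(ev$vectors) >= 2) fix(ev$vectors[, 2]) else
        rep(0, nrow(cmat))
    ang <- atan2(pc2, pc1)
    order(ang, seq_len(nrow(cmat)))
}

#' Export a dendrogram in Newick format
#'
#' @param hc An \code{hclust} tree.
#' @param path Output file.
#' @export
exportNewick <- function(hc, path) {
    write.tree(as.phylo(hc), file = path)
    invisible(path)
}

#' Write a square matrix (distance or correlation) as TSV
#' @param m Matrix.
#' @param path Output file.
#' @export
writeMatrixTsv <- function(m, path) {
    write.table(as.matrix(m), path, sep = "\t", quote = FALSE,
                col.names = NA)
    invisible(path)
}
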