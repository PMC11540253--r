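#' Cluster genes by similarity of fitness profiles
#'
#' Hierarchical agglomerative clustering (Ward linkage, Euclidean distance
#' on the raw fitness scores — they already share a common log2 scale) with
#' the number of clusters chosen by maximum mean silhouette width over
#' `kRange`; ties break toward the smaller k.  Missing cells are imputed to
#' 0 (neutral — "not scored") before clustering, with a message giving the
#' imputed count.
#'
#' @param fitnessMatrix Numeric gene x condition matrix (e.g. the `fitness`
#'   assay of a [GeneFitness-class], typically restricted to significant
#'   genes), or a `GeneFitness` object.
#' @param kRange Candidate cluster numbers (default 2:12); truncated to
#'   `n - 1`.
#' @param linkage [stats::hclust()] method (default `"ward.D2"`).
#' @return A [ClusterResult-class].
#' @examples
#' m <- rbind(matrix(rnorm(20, -3, .1), 10), matrix(rnorm(20, 3, .1), 10))
#' rownames(m) <- paste0("g", 1:20)
#' clusterGenes(m, kRange = 2:5)
#' @export
clusterGenes <- function(fitnessMatrix, kRange = 2:12, linkage = "ward.D2") {
    if (is(fitnessMatrix, "GeneFitness"))
        fitnessMatrix <- SummarizedExperiment::assay(fitnessMatrix, "fitness")
    m <- as.matrix(fitnessMatrix)
    if (nrow(m) < 3L) stop("need at least 3 genes to cluster")
    nNA <- sum(is.na(m))
    if (nNA > 0L) {
        message("imputing ", nNA, " missing fitness cell(s) to 0 (neutral)")
        m[is.na(m)] <- 0
    }
    d <- stats::dist(m)
    if (all(d < .Machine$double.eps * 100))
        stop("degenerate input: all fitness profiles identical, ",
             "silhouette is undefined")
    kRange <- sort(unique(as.integer(kRange)))
    kRange <- kRange[kRange >= 2L & kRange <= nrow(m) - 1L]
    if (!length(kRange)) stop("kRange must intersect [2, n - 1]")
    hc <- stats::hclust(d, method = linkage)
    msw <- vapply(kRange, function(k) {
        sil <- cluster::silhouette(stats::cutree(hc, k), d)
        mean(sil[, "sil_width"])
    }, numeric(1))
    k <- kRange[which.max(msw)]   # which.max takes the first = smallest k
    new("ClusterResult",
        assignments = stats::cutree(hc, k),
        k = as.integer(k),
        silhouetteByK = data.frame(k = kRange, meanSilWidth = msw),
        linkage = linkage, tree = hc)
}

#' Pathway over-representation per cluster (hypergeometric test)
#'
#' For each cluster and each pathway annotated in the universe, tests
#' over-representation with the hypergeometric upper tail
#' `P(X >= overlap)` where X ~ Hypergeometric(universe, pathway, cluster).
#' Rows are sorted by p within cluster; p-values are reported raw (ranking
#' statistic) with a Benjamini-Hochberg-adjusted column alongside.
#'
#' @param clusters A [ClusterResult-class] or named vector gene -> cluster.
#' @param annotation Two-column table (`gene`, `pathway`) or named character
#'   vector gene -> pathway tag; genes without annotation contribute to the
#'   universe only.
#' @param universe Character vector of all genes considered; must contain
#'   every clustered gene (default: union of clustered and annotated genes).
#' @param topN Keep the `topN` smallest-p pathways per cluster (`Inf` = all).
#' @return `data.frame` with columns `cluster`, `pathway`, `overlap`,
#'   `clusterSize`, `pathwaySize`, `universeSize`, `p`, `padj`.
#' @export
enrichClusters <- function(clusters, annotation, universe = NULL,
                           topN = Inf) {
    asg <- if (is(clusters, "ClusterResult")) clusterAssignments(clusters)
           else clusters
    if (!is.null(dim(annotation)))
        annotation <- setNames(as.character(annotation$pathway),
                               annotation$gene)
    if (is.null(universe))
        universe <- union(names(asg), names(annotation))
    if (!all(names(asg) %in% universe))
        stop("universe must contain every clustered gene")
    universe <- unique(universe)
    N <- length(universe)
    ann <- annotation[intersect(names(annotation), universe)]
    rows <- list()
    for (cl in sort(unique(asg))) {
        clGenes <- names(asg)[asg == cl]
        n <- length(clGenes)
        for (pw in sort(unique(ann))) {
            pwGenes <- names(ann)[ann == pw]
            K <- length(pwGenes)
            ov <- length(intersect(clGenes, pwGenes))
            p <- stats::phyper(ov - 1L, K, N - K, n, lower.tail = FALSE)
            rows[[length(rows) + 1L]] <- data.frame(
                cluster = cl, pathway = pw, overlap = ov,
                clusterSize = n, pathwaySize = K, universeSize = N, p = p)
        }
    }
    out <- do.call(rbind, rows)
    if (is.null(out)) return(data.frame(
        cluster = integer(0), pathway = character(0), overlap = integer(0),
        clusterSize = integer(0), pathwaySize = integer(0),
        universeSize = integer(0), p = numeric(0), padj = numeric(0)))
    out$padj <- stats::p.adjust(out$p, method = "BH")
    out <- out[order(out$cluster, out$p, out$pathway), ]
    if (is.finite(topN))
        out <- do.call(rbind, lapply(split(out, out$cluster),
                                     utils::head, n = topN))
    rownames(out) <- NULL
    out
}
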