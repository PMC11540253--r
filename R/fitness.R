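#' Per-sample barcode frequencies
#'
#' Converts counts to pseudocounted frequencies:
#' `(count + pseudocount) / sum(count + pseudocount)` per sample.  The
#' pseudocount keeps log fold changes finite for barcodes washed out of the
#' pool, at the price of a conservative bias for very large |log2FC|.
#'
#' @param counts A [BarcodeCounts-class] or a count matrix.
#' @param pseudocount Positive pseudocount added to every cell (default 0.5).
#' @return Numeric matrix of frequencies; columns sum to 1.
#' @export
normalizeCounts <- function(counts, pseudocount = 0.5) {
    if (pseudocount <= 0) stop("pseudocount must be > 0")
    m <- if (is(counts, "BarcodeCounts"))
        SummarizedExperiment::assay(counts, "counts") else as.matrix(counts)
    zero <- colSums(m) == 0
    if (any(zero))
        stop("sample(s) with all-zero counts: ",
             paste(colnames(m)[zero], collapse = ", "))
    m <- m + pseudocount
    sweep(m, 2L, colSums(m), "/")
}

#' Barcode abundance trajectories (log2 fold change vs. T0)
#'
#' For every condition x replicate, computes per barcode
#' `delta(g) = log2 freq(g) - log2 freq(0)` against the matched T0 sample
#' (generation 0, same condition, regime and replicate).
#'
#' @param counts A [BarcodeCounts-class].
#' @param pseudocount Passed to [normalizeCounts()].
#' @return A `data.frame` in long form: `barcode`, `condition`, `regime`,
#'   `replicate`, `generation`, `delta`.  T0 rows are omitted (`delta` is 0
#'   there by construction).
#' @export
barcodeLog2FC <- function(counts, pseudocount = 0.5) {
    stopifnot(is(counts, "BarcodeCounts"))
    freq <- normalizeCounts(counts, pseudocount)
    cd <- SummarizedExperiment::colData(counts)
    key <- paste(cd$condition, cd$regime, cd$replicate, sep = "\r")
    out <- list()
    for (k in unique(key)) {
        cols <- which(key == k)
        t0 <- cols[cd$generation[cols] == 0]
        if (length(t0) == 0L)
            stop("missing T0 sample for condition/replicate: ",
                 gsub("\r", "/", k))
        t0 <- t0[1L]
        later <- cols[cd$generation[cols] > 0]
        for (j in later) {
            out[[length(out) + 1L]] <- data.frame(
                barcode = rownames(freq),
                condition = cd$condition[j],
                regime = cd$regime[j],
                replicate = cd$replicate[j],
                generation = cd$generation[j],
                delta = log2(freq[, j]) - log2(freq[, t0]),
                stringsAsFactors = FALSE)
        }
    }
    do.call(rbind, out)
}

#' Gene-level fitness scores
#'
#' Per condition, the gene fitness score f is the unweighted mean of barcode
#' log2 fold changes over the gene's assigned barcodes, averaged across
#' replicates, then centered by subtracting the per-condition median over
#' all scored genes (so a typical gene is neutral by construction).  Genes
#' with no assigned barcode get `NA`, never an imputed zero.
#'
#' @param trajectories Long-form trajectories from [barcodeLog2FC()].
#' @param barcodeGeneMap Either a named character vector barcode -> locus_tag
#'   or a table with `barcode` and `gene` columns (e.g. from
#'   [assignGenes()]); barcodes mapping to `NA` are ignored.
#' @param generation Generation at which genes are scored (default 8;
#'   scores at other sampled generations are computed by calling this again).
#' @param center Subtract the per-condition median (default `TRUE`).
#' @return A [GeneFitness-class] (genes x conditions) with assays `fitness`,
#'   `sd` (between-replicate SD) and `nBarcodes`;
#'   `metadata()$generation` records the scoring generation.
#' @export
geneFitness <- function(trajectories, barcodeGeneMap, generation = 8,
                        center = TRUE) {
    if (!is.null(dim(barcodeGeneMap))) {
        barcodeGeneMap <- setNames(as.character(barcodeGeneMap$gene),
                                   barcodeGeneMap$barcode)
    }
    barcodeGeneMap <- barcodeGeneMap[!is.na(barcodeGeneMap)]
    if (!length(barcodeGeneMap)) stop("empty barcode-to-gene mapping")
    tr <- trajectories[trajectories$generation == generation, , drop = FALSE]
    if (!nrow(tr))
        stop("no samples at generation ", generation)
    tr$gene <- unname(barcodeGeneMap[tr$barcode])
    tr <- tr[!is.na(tr$gene), , drop = FALSE]
    geneIds <- sort(unique(tr$gene))
    conds <- unique(tr$condition)
    f <- sdm <- nbm <- matrix(NA_real_, length(geneIds), length(conds),
                              dimnames = list(geneIds, conds))
    for (cc in conds) {
        sub <- tr[tr$condition == cc, , drop = FALSE]
        # per replicate: mean barcode delta per gene; then across replicates
        repMeans <- tapply(sub$delta, list(sub$gene, sub$replicate), mean)
        f[rownames(repMeans), cc] <- rowMeans(repMeans, na.rm = TRUE)
        sdm[rownames(repMeans), cc] <- apply(repMeans, 1L, stats::sd, na.rm = TRUE)
        nb <- tapply(sub$barcode, sub$gene,
                     function(b) length(unique(b)))
        nbm[names(nb), cc] <- nb
    }
    if (center)
        f <- sweep(f, 2L, apply(f, 2L, stats::median, na.rm = TRUE), "-")
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(fitness = f, sd = sdm, nBarcodes = nbm),
        colData = S4Vectors::DataFrame(condition = conds, row.names = conds))
    S4Vectors::metadata(se)$generation <- generation
    new("GeneFitness", se)
}

#' Select significant genes by fitness threshold
#'
#' A gene is significant overall iff |f| >= `threshold` in any condition,
#' scored at a generation of at least `minGenerations` (default: |f| >= 2
#' after at least eight generations).
#'
#' @param fitness A [GeneFitness-class].
#' @param threshold Absolute fitness-score cutoff (inclusive; default 2).
#' @param minGenerations Minimum scoring generation for the table to qualify
#'   (default 8).
#' @return A list with `perCondition` (named list of gene vectors) and
#'   `overall` (union over conditions).
#' @export
significantGenes <- function(fitness, threshold = 2, minGenerations = 8) {
    stopifnot(is(fitness, "GeneFitness"))
    if (threshold <= 0) stop("threshold must be > 0")
    g <- S4Vectors::metadata(fitness)$generation
    if (!is.null(g) && g < minGenerations)
        stop("fitness table scored at generation ", g,
             " < minGenerations = ", minGenerations)
    f <- SummarizedExperiment::assay(fitness, "fitness")
    perCond <- lapply(seq_len(ncol(f)), function(j) {
        rownames(f)[!is.na(f[, j]) & abs(f[, j]) >= threshold]
    })
    names(perCond) <- colnames(f)
    list(perCondition = perCond,
         overall = sort(unique(unlist(perCond, use.names = FALSE))))
}

#' Estimate mutant growth rate from abundance log2 fold change
#'
#' Inverts the rare-mutant competition model: with exponential growth
#' `x_i(t) = x_i(0) exp(mu_i t)` and population time to g doublings
#' `t = g ln(2) / mu_pop`, a rare mutant's frequency log2 fold change is
#' `delta = g (mu_i / mu_pop - 1)`, hence
#' \deqn{\mu = \mu_{pop} (1 + \Delta / g).}
#' `delta = 0` returns `mu_pop` exactly; `delta = -g` corresponds to a
#' non-growing mutant (mu = 0).  The neglected correction term (the pool's
#' own composition shift) is negligible while each mutant is a tiny fraction
#' of the pool.
#'
#' @param delta Log2 fold change(s) of mutant abundance vs. T0.
#' @param g Generations (population doublings) elapsed; > 0.
#' @param muPop Nominal population growth rate in 1/h; > 0.
#' @return `data.frame` with columns `delta`, `g`, `muPop`, `mu` (1/h).
#' @examples
#' estimateGrowthRate(delta = 1.6, g = 8, muPop = 0.1)
#' @export
estimateGrowthRate <- function(delta, g, muPop) {
    if (any(g <= 0)) stop("g must be > 0")
    if (any(muPop <= 0)) stop("muPop must be > 0")
    data.frame(delta = delta, g = g, muPop = muPop,
               mu = muPop * (1 + delta / g))
}
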