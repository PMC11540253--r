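#' Build a competition sample sheet
#'
#' Convenience constructor for the sample metadata used by
#' [simulateCompetition()]: one row per condition x regime x generation x
#' replicate, mirroring a pooled-library competition sampled at 0, 8 and 16
#' population doublings under continuous (growth-rate selective) or pulsed
#' (yield selective) feeding.
#'
#' @param conditions Character vector of condition labels.
#' @param regimes Feeding regime per condition set; `"continuous"`,
#'   `"pulsed"` or `"batch"`.
#' @param generations Numeric vector of sampled generations (must include 0).
#' @param replicates Number of biological replicates.
#' @return A `data.frame` with columns `sample_id`, `condition`, `regime`,
#'   `generation`, `replicate`.
#' @examples
#' makeSampleSheet("fructose", "continuous", c(0, 8), replicates = 2)
#' @export
makeSampleSheet <- function(conditions = "fructose",
                            regimes = "continuous",
                            generations = c(0, 8, 16),
                            replicates = 4L) {
    if (!any(generations == 0))
        stop("generations must include 0 (the T0 reference)")
    grid <- expand.grid(generation = generations,
                        replicate = seq_len(replicates),
                        regime = regimes,
                        condition = conditions,
                        stringsAsFactors = FALSE)
    grid <- grid[, c("condition", "regime", "generation", "replicate")]
    grid$sample_id <- sprintf("%s_%s_g%g_r%d", grid$condition,
                              substr(grid$regime, 1, 4),
                              grid$generation, grid$replicate)
    grid[, c("sample_id", "condition", "regime", "generation", "replicate")]
}

#' Simulate a pooled competition experiment
#'
#' Forward model that gene-fitness scoring inverts.  Mutant frequencies
#' follow selection on the planted relative fitness w:
#' \deqn{p_i(g) = p_i(0)\, 2^{g w_i} / \sum_j p_j(0)\, 2^{g w_j}}
#' so the expected log2 fold change of a rare mutant is `g * (w - 1)`.
#' Sequencing counts per sample are a single multinomial draw of size
#' `depth`.  Under the pulsed regime the population additionally passes a
#' dilution bottleneck at each pulse (one pulse per doubling): a multinomial
#' survival draw retaining `bottleneckFrac` of `popSize` cells, a source of
#' drift absent from the continuous regime.
#'
#' Initial barcode abundances are drawn once per library (log-normal,
#' `sdlog = p0Sdlog`) and shared by all samples, so replicate T0 columns are
#' resamplings of the same underlying pool.
#'
#' @param library A [MutantLibrary-class].
#' @param samples Sample sheet as from [makeSampleSheet()].
#' @param depth Sequencing depth per sample (multinomial total).
#' @param seed Integer seed; per-sample streams are derived from it.
#' @param fitnessMatrix Optional numeric matrix (barcode x condition) of
#'   relative fitness overriding the library's single planted `w` per
#'   barcode, for condition-dependent phenotypes.
#' @param popSize Simulated population size at each pulse (pulsed regime).
#' @param bottleneckFrac Fraction of the population retained per pulse
#'   (default 0.062, the 4 mL / 65 mL dilution geometry).
#' @param p0Sdlog Log-normal spread of initial barcode abundances (0 = even
#'   pool).
#' @return A [BarcodeCounts-class] (barcode x sample).
#' @examples
#' g <- makeGenome(nGenes = 5, nReplicons = 1, seed = 1)
#' lib <- makeLibrary(g, nMutants = 50, seed = 2)
#' sheet <- makeSampleSheet("fructose", "continuous", c(0, 8), 2)
#' bc <- simulateCompetition(lib, sheet, depth = 1e4, seed = 3)
#' bc
#' @export
simulateCompetition <- function(library, samples, depth = 2e6, seed = 1L,
                                fitnessMatrix = NULL, popSize = 1e7,
                                bottleneckFrac = 0.062, p0Sdlog = 0.5) {
    stopifnot(is(library, "MutantLibrary"))
    if (depth <= 0) stop("depth must be > 0")
    need <- c("sample_id", "condition", "regime", "generation", "replicate")
    if (!all(need %in% colnames(samples)))
        stop("samples must have columns: ", paste(need, collapse = ", "))
    if (any(samples$generation < 0)) stop("generations must be >= 0")
    e <- libraryEntries(library)
    nb <- nrow(e)
    if (nb == 0L) stop("sample with unknown barcode set: library is empty")
    if (!is.null(fitnessMatrix)) {
        if (is.null(rownames(fitnessMatrix)) ||
            !setequal(rownames(fitnessMatrix), e$barcode))
            stop("fitnessMatrix rownames must be exactly the library barcodes")
        fitnessMatrix <- fitnessMatrix[e$barcode, , drop = FALSE]
    }
    counts <- matrix(0L, nrow = nb, ncol = nrow(samples),
                     dimnames = list(e$barcode, samples$sample_id))
    p0 <- withr::with_seed(as.integer(seed), {
        a <- if (p0Sdlog > 0) stats::rlnorm(nb, 0, p0Sdlog) else rep(1, nb)
        a / sum(a)
    })
    for (i in seq_len(nrow(samples))) {
        g <- samples$generation[i]
        cond <- samples$condition[i]
        w <- if (!is.null(fitnessMatrix) && cond %in% colnames(fitnessMatrix))
            fitnessMatrix[, cond] else e$w
        counts[, i] <- withr::with_seed(.childSeed(seed, i), {
            p <- p0
            if (identical(samples$regime[i], "pulsed") && g > 0) {
                nPulses <- ceiling(g)
                dg <- g / nPulses
                for (k in seq_len(nPulses)) {
                    p <- p * 2^(dg * w)
                    p <- p / sum(p)
                    keep <- stats::rmultinom(1L, max(1L, round(popSize * bottleneckFrac)), p)[, 1L]
                    p <- keep / sum(keep)
                }
            } else {
                p <- p * 2^(g * w)
                p <- p / sum(p)
            }
            stats::rmultinom(1L, as.integer(depth), p)[, 1L]
        })
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts),
        colData = S4Vectors::DataFrame(samples[, need[-1]],
                                       row.names = samples$sample_id))
    new("BarcodeCounts", se)
}
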