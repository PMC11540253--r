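suppressPackageStartupMessages({
    library(SummarizedExperiment)
    library(Biostrings)
})

# amplicon structure used throughout the tests
demoFlanks <- function(maxMismatch = 0L)
    FlankSpec("GTCGACCTGCAGCGTACG", "AGAGACCTCGTGGACATC",
              maxMismatch = maxMismatch)

assayCounts <- function(x) SummarizedExperiment::assay(x, "counts")

# hand-built BarcodeCounts from a count matrix + minimal metadata
makeCounts <- function(m, condition = "fructose", regime = "continuous",
                       generation, replicate) {
    se <- SummarizedExperiment(
        assays = list(counts = m),
        colData = S4Vectors::DataFrame(
            condition = condition, regime = regime,
            generation = generation, replicate = replicate,
            row.names = colnames(m)))
    new("BarcodeCounts", se)
}

# small standard scenario shared by several tests
smallScenario <- function(nGenes = 40, nMutants = 250, depth = 5e4,
                          seed = 7, w = NULL) {
    g <- makeGenome(nGenes = nGenes, nReplicons = 2, seed = seed)
    lib <- makeLibrary(g, nMutants = nMutants, fitnessSpec = w,
                       seed = seed + 1)
    sheet <- makeSampleSheet("fructose", "continuous", c(0, 8), 2)
    bc <- simulateCompetition(lib, sheet, depth = depth, seed = seed + 2)
    list(genome = g, lib = lib, sheet = sheet, counts = bc)
}

# independent oracle for the polar-effect closure: breadth-first
# reachability on an explicit edge list (gene -> downstream gene in unit;
# regulator gene -> every gene of each dependent unit)
oracleReach <- function(knockout, om) {
    units <- operonUnits(om); regs <- regulatorTargets(om)
    edges <- list()
    for (u in units)
        for (i in seq_along(u))
            for (j in seq_along(u))
                if (j > i) edges[[length(edges) + 1]] <- c(u[i], u[j])
    for (rg in names(regs))
        for (p in regs[[rg]])
            for (tg in units[[p]])
                edges[[length(edges) + 1]] <- c(rg, tg)
    reach <- knockout
    repeat {
        new <- unlist(lapply(edges, function(e)
            if (e[1] %in% reach) e[2] else NULL))
        new <- setdiff(new, reach)
        if (!length(new)) break
        reach <- c(reach, new)
    }
    sort(unique(reach))
}

# adjusted Rand index from the contingency table (independent of any
# clustering package)
ari <- function(a, b) {
    tab <- table(a, b)
    n <- sum(tab)
    sumij <- sum(choose(tab, 2))
    sumi <- sum(choose(rowSums(tab), 2))
    sumj <- sum(choose(colSums(tab), 2))
    expected <- sumi * sumj / choose(n, 2)
    (sumij - expected) / ((sumi + sumj) / 2 - expected)
}
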