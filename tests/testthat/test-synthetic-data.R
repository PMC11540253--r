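test_that("makeGenome tiles non-overlapping genes with fixed gaps", {
    g <- makeGenome(nGenes = 10, nReplicons = 1, meanGeneLen = 900,
                    intergenicLen = 100, seed = 42)
    gr <- genes(g)
    expect_length(gr, 10)
    # independent interval arithmetic: the annotated span equals the sum of
    # the drawn gene lengths, and consecutive genes are 100 bp apart
    st <- start(gr); en <- end(gr)
    expect_true(all(en >= st))
    o <- order(st)
    expect_true(all(st[o][-1] - en[o][-10] - 1L == 100L))
    spanSum <- sum(vapply(seq_along(gr),
                          function(i) en[i] - st[i] + 1L, integer(1)))
    expect_identical(spanSum, sum(width(gr)))
    expect_true(max(en) <= length(replicons(g)[[1]]))
})

test_that("makeGenome handles the empty case and rejects bad arguments", {
    g <- makeGenome(nGenes = 0, nReplicons = 2, seed = 1)
    expect_length(genes(g), 0)
    expect_length(replicons(g), 2)
    expect_error(makeGenome(nGenes = -1), "nGenes")
    expect_error(makeGenome(nGenes = 5, meanGeneLen = 0), "meanGeneLen")
})

test_that("makeGenome default scale matches the organism it emulates", {
    g <- makeGenome(seed = 3)
    expect_length(genes(g), 6600)
    expect_length(replicons(g), 3)
    # determinism for a fixed seed
    g2 <- makeGenome(seed = 3)
    expect_identical(as.character(genes(g2)), as.character(genes(g)))
})

test_that("makeLibrary places insertions uniformly and excludes essentials", {
    g <- makeGenome(nGenes = 40, nReplicons = 1, meanGeneLen = 600,
                    intergenicLen = 100, seed = 5)
    expect_length(makeLibrary(g, nMutants = 0, seed = 1), 0)

    # total exclusion: every insertion is intergenic
    allEss <- genes(g)$locus_tag
    libEss <- makeLibrary(g, nMutants = 200, essentialGenes = allEss,
                          seed = 2)
    expect_true(all(is.na(libraryEntries(libEss)$gene)))

    # closed-form binomial expectation: per-gene insertion counts follow
    # Binomial(n, gene_len / genome_len)
    lib <- makeLibrary(g, nMutants = 50000, seed = 3)
    e <- libraryEntries(lib)
    expect_false(anyDuplicated(e$barcode) > 0)
    expect_true(all(nchar(e$barcode) == 20))
    gr <- genes(g)
    tot <- genomeLength(g)
    obs <- table(factor(e$gene, levels = gr$locus_tag))
    obs <- c(as.integer(obs), sum(is.na(e$gene)))
    expProb <- c(width(gr) / tot, 1 - sum(width(gr)) / tot)
    pval <- suppressWarnings(stats::chisq.test(obs, p = expProb)$p.value)
    expect_gt(pval, 0.01)
})

test_that("simulateCompetition conserves depth and neutral frequencies", {
    sc <- smallScenario(seed = 21)
    m <- assayCounts(sc$counts)
    expect_true(all(colSums(m) == 5e4))
    # all w = 1: observed g=8 frequencies lie within 4 SE of T0 frequencies
    f0 <- m[, "fructose_cont_g0_r1"] / 5e4
    f8 <- m[, "fructose_cont_g8_r1"] / 5e4
    se <- sqrt(pmax(f0 * (1 - f0), 1e-12) / 5e4) * sqrt(2)
    expect_gt(mean(abs(f8 - f0) <= 4 * se), 0.98)
})

test_that("rare-mutant log2FC matches the closed form g*(w-1)", {
    # even pool of 10,000 barcodes -> p0 = 1e-4 each; one mutant w = 1.5,
    # sampled at g = 4: expected log2 frequency change = 4 * 0.5 = 2
    g <- makeGenome(nGenes = 4, nReplicons = 1, seed = 31)
    lib <- makeLibrary(g, nMutants = 10000, seed = 32)
    e <- libraryEntries(lib)
    wvec <- setNames(rep(1, nrow(e)), e$barcode)
    wvec[1] <- 1.5
    fm <- matrix(wvec, ncol = 1, dimnames = list(names(wvec), "fructose"))
    nrep <- 150
    sheet <- makeSampleSheet("fructose", "continuous", c(0, 4), nrep)
    bc <- simulateCompetition(lib, sheet, depth = 2e5, seed = 33,
                              fitnessMatrix = fm, p0Sdlog = 0)
    tr <- barcodeLog2FC(bc)
    d <- tr$delta[tr$barcode == names(wvec)[1]]
    expect_length(d, nrep)
    se <- sd(d) / sqrt(nrep)
    expect_lt(abs(mean(d) - 2), 3 * se)
})

test_that("pulsed feeding adds bottleneck drift, continuous does not", {
    g <- makeGenome(nGenes = 4, nReplicons = 1, seed = 41)
    lib <- makeLibrary(g, nMutants = 500, seed = 42)
    sheet <- makeSampleSheet("fructose", c("continuous", "pulsed"),
                             c(0, 8), 4)
    bc <- simulateCompetition(lib, sheet, depth = 1e5, seed = 43,
                              popSize = 1e5)
    tr <- barcodeLog2FC(bc)
    v <- tapply(tr$delta, tr$regime, var)
    expect_gt(v[["pulsed"]], v[["continuous"]])
})

test_that("simulateReads emits the exact amplicon structure", {
    g <- makeGenome(nGenes = 6, nReplicons = 1, seed = 51)
    lib <- makeLibrary(g, nMutants = 30, seed = 52)
    fs <- demoFlanks()
    e <- libraryEntries(lib)
    cts <- setNames(rep(3L, 30), e$barcode)

    rds <- simulateReads(lib, cts, "barseq", fs, seed = 53)[[1]]
    expect_length(rds, sum(cts))
    expect_true(all(substr(rds, 1, 18) == fs@leftFlank))
    bcs <- substr(rds, 19, 38)
    expect_true(all(bcs %in% e$barcode))
    expect_true(all(substr(rds, 39, 56) == fs@rightFlank))
    # read count per barcode equals the count entry
    expect_equal(as.vector(table(factor(bcs, levels = e$barcode))),
                 unname(cts))

    # tnseq: the genomic tail is a verbatim copy of the reference at the
    # insertion locus (checked against an independent subseq lookup)
    trds <- simulateReads(lib, cts, "tnseq", fs, genome = g,
                          genomicTailLen = 30, seed = 54)[[1]]
    tails <- substr(trds, 57, nchar(trds))
    bcs <- substr(trds, 19, 38)
    i <- match(bcs, e$barcode)
    rep1 <- replicons(g)[[1]]
    L <- length(rep1)
    for (k in sample(length(trds), 20)) {
        pos <- e$position[i[k]]
        ref <- if (e$strand[i[k]] == "+")
            as.character(subseq(rep1, pos, min(L, pos + 29)))
        else
            as.character(reverseComplement(
                subseq(rep1, max(1, pos - 29), pos)))
        expect_identical(unname(tails[k]), ref)
    }
})

test_that("substitution errors arrive at the requested rate", {
    g <- makeGenome(nGenes = 4, nReplicons = 1, seed = 61)
    lib <- makeLibrary(g, nMutants = 10, seed = 62)
    fs <- demoFlanks()
    cts <- setNames(rep(1000L, 10), libraryEntries(lib)$barcode)
    clean <- simulateReads(lib, cts, "barseq", fs, readLength = 75,
                           errorRate = 0, seed = 63)[[1]]
    noisy <- simulateReads(lib, cts, "barseq", fs, readLength = 75,
                           errorRate = 0.01, seed = 63)[[1]]
    # same seed => same padding, so mismatches are exactly the injected errors
    nsub <- vapply(seq_along(clean), function(i)
        sum(strsplit(clean[i], "")[[1]] != strsplit(noisy[i], "")[[1]]),
        integer(1))
    expected <- 75 * 0.01
    se <- sqrt(75 * 0.01 * 0.99 / length(clean))
    expect_lt(abs(mean(nsub) - expected), 3 * se)
})

test_that("FASTQ output round-trips through the counting loader", {
    g <- makeGenome(nGenes = 4, nReplicons = 1, seed = 71)
    lib <- makeLibrary(g, nMutants = 20, seed = 72)
    fs <- demoFlanks()
    cts <- setNames(rep(2L, 20), libraryEntries(lib)$barcode)
    dir <- withr::local_tempdir()
    paths <- simulateReads(lib, cts, "barseq", fs, seed = 73, dir = dir)
    expect_true(file.exists(paths[[1]]))
    reads <- readDNAStringSet(paths[[1]], format = "fastq")
    expect_length(reads, 40)
    lines <- readLines(paths[[1]])
    expect_identical(length(lines), 160L)
    expect_true(all(startsWith(lines[seq(1, 160, 4)], "@")))
})
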