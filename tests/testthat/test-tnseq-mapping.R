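test_that("error-free junction reads map every barcode to its true site", {
    g <- makeGenome(nGenes = 60, nReplicons = 2, seed = 111)
    lib <- makeLibrary(g, nMutants = 400, seed = 112)
    fs <- demoFlanks()
    e <- libraryEntries(lib)
    cts <- setNames(rep(5L, nrow(e)), e$barcode)
    rds <- simulateReads(lib, cts, "tnseq", fs, genome = g,
                         genomicTailLen = 30, seed = 113)[[1]]
    im <- mapInsertions(rds, g, fs)
    expect_identical(nrow(im), nrow(e))
    # barcodes whose tail runs off a replicon end below 20 bp cannot map
    # and must surface as unmapped, not vanish
    truncBc <- unique(substr(rds[grepl(":trunc", names(rds))], 19, 38))
    mappable <- setdiff(e$barcode, truncBc)
    imM <- im[im$barcode %in% mappable, ]
    expect_true(all(imM$status == "unique"))
    expect_true(all(im$status[!im$barcode %in% mappable] %in%
                    c("unique", "unmapped")))
    mm <- merge(as.data.frame(imM), as.data.frame(e), by = "barcode")
    expect_true(all(mm$replicon.x == mm$replicon.y))
    expect_true(all(mm$position.x == mm$position.y))
    expect_true(all(mm$strand.x == mm$strand.y))
    expect_true(all(imM$supportReads == 5L))
})

test_that("mapping is invariant to read order", {
    g <- makeGenome(nGenes = 10, nReplicons = 1, seed = 121)
    lib <- makeLibrary(g, nMutants = 40, seed = 122)
    fs <- demoFlanks()
    cts <- setNames(rep(4L, 40), libraryEntries(lib)$barcode)
    rds <- simulateReads(lib, cts, "tnseq", fs, genome = g, seed = 123)[[1]]
    a <- mapInsertions(rds, g, fs)
    set.seed(1)
    b <- mapInsertions(rds[sample(length(rds))], g, fs)
    a <- a[order(a$barcode), ]; b <- b[order(b$barcode), ]
    expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("multi-locus tails are flagged ambiguous and excluded from genes", {
    # genome with a planted duplication: the same 40-bp block at two loci
    block <- strrep("ACGTTGCA", 5)
    seq1 <- paste0(strrep("A", 200), block, strrep("C", 200), block,
                   strrep("G", 200))
    reps <- DNAStringSet(c(chrA = seq1))
    gr <- GenomicRanges::GRanges("chrA", IRanges::IRanges(150, 550), "+")
    gr$locus_tag <- "gene_dup"; gr$pathway <- "PWY01"
    GenomeInfoDb::seqlengths(gr) <- nchar(seq1)
    g <- new("AnnotatedGenome", replicons = reps, genes = gr)
    fs <- demoFlanks()
    bcd <- strrep("AC", 10)
    read <- paste0(fs@leftFlank, bcd, fs@rightFlank, substr(block, 1, 30))
    im <- mapInsertions(rep(read, 3), g, fs)
    expect_identical(im$status, "ambiguous")
    ag <- assignGenes(im, g)
    expect_true(is.na(ag$gene))
})

test_that("majority vote resolves minor disagreement at >= 0.75", {
    g <- makeGenome(nGenes = 10, nReplicons = 1, seed = 131)
    lib <- makeLibrary(g, nMutants = 1, seed = 132)
    e <- libraryEntries(lib)
    fs <- demoFlanks()
    rep1 <- replicons(g)[[1]]
    mkread <- function(pos) paste0(fs@leftFlank, e$barcode, fs@rightFlank,
        as.character(subseq(rep1, pos, pos + 29)))
    pTrue <- 1000L; pOther <- 3000L
    # 4 of 5 reads at the true site: majority 0.8 >= 0.75 -> unique there
    im <- mapInsertions(c(rep(mkread(pTrue), 4), mkread(pOther)), g, fs)
    expect_identical(im$status, "unique")
    expect_identical(im$position, pTrue)
    expect_identical(im$supportReads, 5L)
    # 3 of 5: majority 0.6 < 0.75 -> ambiguous
    im2 <- mapInsertions(c(rep(mkread(pTrue), 3), rep(mkread(pOther), 2)),
                         g, fs)
    expect_identical(im2$status, "ambiguous")
})

test_that("mapInsertions rejects an empty genome", {
    g <- new("AnnotatedGenome", replicons = DNAStringSet(),
             genes = GenomicRanges::GRanges())
    expect_error(mapInsertions("ACGT", g, demoFlanks()), "empty genome")
})

test_that("assignGenes applies the strand-aware central window", {
    reps <- DNAStringSet(c(chr = strrep("ACGT", 500)))
    gr <- GenomicRanges::GRanges("chr", IRanges::IRanges(c(101, 1001),
                                                         c(200, 1100)),
                                 c("+", "-"))
    gr$locus_tag <- c("gPlus", "gMinus"); gr$pathway <- "PWY01"
    GenomeInfoDb::seqlengths(gr) <- 2000L
    g <- new("AnnotatedGenome", replicons = reps, genes = gr)
    im <- S4Vectors::DataFrame(
        barcode = c("b1", "b2", "b3", "b4"),
        replicon = "chr",
        position = c(150L, 105L, 1050L, 1095L),
        strand = "+", supportReads = 1L, status = "unique")
    ag <- assignGenes(im, g, centralWindow = c(0.1, 0.9))
    # b1: 50% into gPlus -> assigned; b2: 4% -> outside window
    expect_identical(ag$gene[ag$barcode == "b1"], "gPlus")
    expect_true(is.na(ag$gene[ag$barcode == "b2"]))
    # minus-strand gene (start codon at plus-coordinate 1100): 1050 is 50%
    # along the gene -> assigned; 1095 is 5% from the start -> outside
    expect_identical(ag$gene[ag$barcode == "b3"], "gMinus")
    expect_true(is.na(ag$gene[ag$barcode == "b4"]))
    expect_error(assignGenes(im, g, centralWindow = c(0.9, 0.1)),
                 "centralWindow")
})

test_that("assignGenes equals an independent interval-scan oracle", {
    g <- makeGenome(nGenes = 30, nReplicons = 2, seed = 141)
    lib <- makeLibrary(g, nMutants = 500, seed = 142)
    e <- libraryEntries(lib)
    im <- S4Vectors::DataFrame(
        barcode = e$barcode, replicon = e$replicon, position = e$position,
        strand = e$strand, supportReads = 1L, status = "unique")
    lo <- 0.1; hi <- 0.9
    ag <- assignGenes(im, g, centralWindow = c(lo, hi))
    gr <- as.data.frame(genes(g))
    oracle <- vapply(seq_len(nrow(e)), function(i) {
        hit <- which(gr$seqnames == e$replicon[i] &
                     gr$start <= e$position[i] & gr$end >= e$position[i])
        if (!length(hit)) return(NA_character_)
        hit <- hit[1]
        rel <- if (gr$strand[hit] == "-")
            (gr$end[hit] - e$position[i]) / gr$width[hit]
        else
            (e$position[i] - gr$start[hit]) / gr$width[hit]
        if (rel >= lo && rel < hi) gr$locus_tag[hit] else NA_character_
    }, character(1))
    expect_identical(ag$gene, oracle)
    # per-gene insertion counts never exceed the unique barcodes
    cnt <- S4Vectors::metadata(ag)$geneInsertions
    expect_true(sum(cnt) <= sum(im$status == "unique"))
    expect_identical(unname(sum(cnt)), sum(!is.na(oracle)))
})
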