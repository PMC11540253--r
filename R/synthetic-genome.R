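#' Simulate an annotated bacterial genome
#'
#' Generates a multi-replicon genome with non-overlapping genes tiled along
#' each replicon, separated by fixed intergenic gaps.  Defaults emulate a
#' *C. necator*-like genome: ~6,600 genes split over two chromosomes and a
#' small megaplasmid.  Gene lengths are gamma-distributed around
#' `meanGeneLen`; strands are random; each gene gets a pathway tag drawn from
#' `pathwayTags` (the substrate for enrichment testing downstream).
#'
#' @param nGenes Total number of genes (default 6600).
#' @param nReplicons Number of replicons (default 3).
#' @param meanGeneLen Mean gene length in bp (default 900).
#' @param intergenicLen Fixed intergenic gap in bp (default 100).
#' @param repliconWeights Fraction of genes per replicon; defaults to a
#'   two-chromosomes-plus-megaplasmid split, recycled/truncated to
#'   `nReplicons` and renormalized.
#' @param pathwayTags Label set for gene pathway annotation.
#' @param seed Integer seed; the result is deterministic for a fixed seed.
#' @return An [AnnotatedGenome-class].
#' @examples
#' g <- makeGenome(nGenes = 20, nReplicons = 2, seed = 1)
#' genes(g)
#' @export
makeGenome <- function(nGenes = 6600L, nReplicons = 3L,
                       meanGeneLen = 900L, intergenicLen = 100L,
                       repliconWeights = c(0.55, 0.37, 0.08),
                       pathwayTags = paste0("PWY", sprintf("%02d", 1:20)),
                       seed = 1L) {
    if (nGenes < 0L || nReplicons < 1L)
        stop("nGenes must be >= 0 and nReplicons >= 1")
    if (meanGeneLen <= 0L || intergenicLen <= 0L)
        stop("meanGeneLen and intergenicLen must be > 0")
    w <- rep_len(repliconWeights, nReplicons)
    w <- w / sum(w)
    withr::with_seed(as.integer(seed), {
        perRep <- diff(c(0L, round(cumsum(w) * nGenes)))
        repNames <- if (nReplicons == 3L) c("chr1", "chr2", "pHG1")
                    else paste0("replicon", seq_len(nReplicons))
        seqs <- character(nReplicons)
        granges <- list()
        for (r in seq_len(nReplicons)) {
            n <- perRep[r]
            if (n > 0L) {
                lens <- pmax(90L, as.integer(round(
                    stats::rgamma(n, shape = 10, scale = meanGeneLen / 10))))
                starts <- intergenicLen + cumsum(c(0L, head(lens, -1L) + intergenicLen)) + 1L
                ends <- starts + lens - 1L
                total <- max(ends) + intergenicLen
                granges[[r]] <- GRanges(
                    seqnames = repNames[r],
                    ranges = IRanges(start = starts, end = ends),
                    strand = sample(c("+", "-"), n, replace = TRUE))
            } else {
                total <- 10L * intergenicLen
                granges[[r]] <- GRanges()
            }
            seqs[r] <- .randomDNA(1L, total)
        }
        reps <- DNAStringSet(seqs)
        names(reps) <- repNames
        g <- suppressWarnings(do.call(c, granges))
        if (length(g)) {
            g$locus_tag <- sprintf("gene_%05d", seq_along(g))
            g$pathway <- sample(pathwayTags, length(g), replace = TRUE)
        } else {
            g <- GRanges()
            S4Vectors::mcols(g)$locus_tag <- character(0)
            S4Vectors::mcols(g)$pathway <- character(0)
        }
        GenomeInfoDb::seqlevels(g) <- repNames
        GenomeInfoDb::seqlengths(g) <- width(reps)
        new("AnnotatedGenome", replicons = reps, genes = g)
    })
}

#' Simulate a library with a fixed number of barcodes per gene
#'
#' Design-controlled variant of [makeLibrary()]: every non-essential gene
#' receives exactly `barcodesPerGene` insertions, placed uniformly within
#' its central region (so every gene is scoreable and no insertion sits in
#' the terminal fraction excluded by gene assignment), plus a fraction of
#' intergenic insertions.  Used to study scoring accuracy at a controlled
#' per-gene coverage.
#'
#' @param genome An [AnnotatedGenome-class].
#' @param barcodesPerGene Insertions per gene (default 5).
#' @param intergenicFrac Intergenic insertions as a fraction of the genic
#'   count (default 0.1).
#' @param essentialGenes Locus tags receiving no insertions.
#' @param fitnessSpec Named numeric vector, locus_tag -> w.
#' @param centralWindow Relative region of each gene insertions are placed
#'   in (default `c(0.15, 0.85)`).
#' @param seed Integer seed.
#' @return A [MutantLibrary-class].
#' @export
makeBalancedLibrary <- function(genome, barcodesPerGene = 5L,
                                intergenicFrac = 0.1,
                                essentialGenes = character(),
                                fitnessSpec = NULL,
                                centralWindow = c(0.15, 0.85),
                                seed = 1L) {
    stopifnot(is(genome, "AnnotatedGenome"))
    g <- genes(genome)
    g <- g[!(g$locus_tag %in% essentialGenes)]
    if (!length(g)) stop("no non-essential genes to cover")
    withr::with_seed(as.integer(seed), {
        nGenic <- length(g) * as.integer(barcodesPerGene)
        gi <- rep(seq_along(g), each = barcodesPerGene)
        rel <- stats::runif(nGenic, centralWindow[1], centralWindow[2])
        plus <- as.character(strand(g)[gi]) != "-"
        pos <- as.integer(ifelse(plus,
            start(g)[gi] + floor(rel * width(g)[gi]),
            end(g)[gi] - floor(rel * width(g)[gi])))
        repl <- as.character(seqnames(g))[gi]
        gene <- g$locus_tag[gi]
        # intergenic extras via rejection against all genes
        nInter <- as.integer(round(nGenic * intergenicFrac))
        if (nInter > 0L) {
            ie <- NULL
            draw <- 4L * nInter
            while (is.null(ie) || nrow(ie) < nInter) {
                inter <- makeLibrary(genome, nMutants = draw,
                                     seed = sample.int(1e6, 1))
                cand <- libraryEntries(inter)
                ie <- rbind(ie, as.data.frame(cand[is.na(cand$gene), ]))
                draw <- draw * 2L
            }
            ie <- ie[seq_len(nInter), ]
            repl <- c(repl, ie$replicon); pos <- c(pos, ie$position)
            gene <- c(gene, rep(NA_character_, nInter))
        }
        n <- length(pos)
        w <- rep(1, n)
        if (!is.null(fitnessSpec)) {
            m <- match(gene, names(fitnessSpec))
            w[!is.na(m)] <- unname(fitnessSpec[m[!is.na(m)]])
        }
        new("MutantLibrary", entries = DataFrame(
            barcode = .randomBarcodes(n),
            replicon = repl, position = pos,
            strand = sample(c("+", "-"), n, replace = TRUE),
            gene = gene, w = w))
    })
}

#' Simulate a barcoded transposon mutant library
#'
#' Draws insertion positions uniformly over the genome, excluding declared
#' essential genes (strictly essential genes yield no viable mutants, hence
#' no insertions and no downstream fitness score).  Each mutant receives a
#' unique random 20-nt barcode and a planted relative fitness `w`
#' (doublings per population doubling; neutral w = 1): genic insertions take
#' the gene's value from `fitnessSpec`, intergenic insertions are neutral.
#'
#' @param genome An [AnnotatedGenome-class].
#' @param nMutants Number of mutants to draw (default 60000).
#' @param essentialGenes Character vector of locus_tags excluded from
#'   insertion.
#' @param fitnessSpec Named numeric vector, locus_tag -> w.  Genes absent
#'   from it are neutral (w = 1).
#' @param seed Integer seed.
#' @return A [MutantLibrary-class].
#' @examples
#' g <- makeGenome(nGenes = 10, nReplicons = 1, seed = 1)
#' lib <- makeLibrary(g, nMutants = 100, seed = 2)
#' lib
#' @export
makeLibrary <- function(genome, nMutants = 60000L,
                        essentialGenes = character(),
                        fitnessSpec = NULL, seed = 1L) {
    stopifnot(is(genome, "AnnotatedGenome"))
    if (nMutants < 0L) stop("nMutants must be >= 0")
    nMutants <- as.integer(nMutants)
    reps <- replicons(genome)
    g <- genes(genome)
    ess <- g[g$locus_tag %in% essentialGenes]
    totalEss <- sum(width(ess))
    if (nMutants > 0L && totalEss >= genomeLength(genome))
        stop("no insertable positions: essential genes cover the genome")
    withr::with_seed(as.integer(seed), {
        repW <- width(reps)
        pos <- integer(0); repIdx <- integer(0)
        # vectorized rejection sampling against essential intervals
        while (length(pos) < nMutants) {
            need <- max(nMutants - length(pos), 1L) * 2L
            ri <- sample.int(length(reps), need, replace = TRUE,
                             prob = repW / sum(repW))
            pp <- as.integer(floor(stats::runif(need) * repW[ri])) + 1L
            if (length(ess)) {
                cand <- GRanges(names(reps)[ri], IRanges(pp, pp))
                GenomeInfoDb::seqlevels(cand) <- GenomeInfoDb::seqlevels(g)
                bad <- IRanges::overlapsAny(cand, ess, ignore.strand = TRUE)
                ri <- ri[!bad]; pp <- pp[!bad]
            }
            pos <- c(pos, pp); repIdx <- c(repIdx, ri)
        }
        pos <- pos[seq_len(nMutants)]
        repIdx <- repIdx[seq_len(nMutants)]
        strand <- sample(c("+", "-"), nMutants, replace = TRUE)
        barcodes <- .randomBarcodes(nMutants)
        gene <- rep(NA_character_, nMutants)
        if (nMutants > 0L && length(g)) {
            ins <- GRanges(names(reps)[repIdx], IRanges(pos, pos))
            GenomeInfoDb::seqlevels(ins) <- GenomeInfoDb::seqlevels(g)
            hit <- GenomicRanges::findOverlaps(ins, g, ignore.strand = TRUE,
                                               select = "first")
            gene[!is.na(hit)] <- g$locus_tag[hit[!is.na(hit)]]
        }
        w <- rep(1, nMutants)
        if (!is.null(fitnessSpec) && nMutants > 0L) {
            m <- match(gene, names(fitnessSpec))
            w[!is.na(m)] <- unname(fitnessSpec[m[!is.na(m)]])
        }
        new("MutantLibrary", entries = DataFrame(
            barcode = barcodes,
            replicon = if (nMutants) names(reps)[repIdx] else character(0),
            position = pos, strand = strand, gene = gene, w = w))
    })
}
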