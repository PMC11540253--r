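#' Map barcodes to genomic insertion sites from TnSeq junction reads
#'
#' Extracts the barcode and the genomic tail from each junction read, locates
#' the tail by exact substring search against both strands of every replicon,
#' and aggregates per barcode.  A barcode is `unique` when all its reads
#' agree on one locus (within a `jitter`-bp window), or when a majority of at
#' least `majority` of its mapped reads does; `ambiguous` when a tail matches
#' multiple genomic loci or reads disagree beyond the majority rule;
#' `unmapped` when no read places it.  The insertion position is the first
#' genome base after the transposon junction (1-based), i.e. the first base
#' of the tail on its strand.
#'
#' @param reads TnSeq reads: FASTQ path, `DNAStringSet` or character vector.
#' @param genome An [AnnotatedGenome-class].
#' @param flankSpec [FlankSpec-class] describing the barcode context; the
#'   genomic tail is everything after the full right flank.
#' @param minGenomicLen Minimum tail length to attempt mapping (default 20).
#' @param jitter Positions within this many bp count as the same locus.
#' @param majority Fraction of mapped reads required for a majority call.
#' @return A `DataFrame` (one row per barcode) with columns `barcode`,
#'   `replicon`, `position`, `strand`, `supportReads`, `status`.
#' @seealso [assignGenes()]
#' @export
mapInsertions <- function(reads, genome, flankSpec, minGenomicLen = 20L,
                          jitter = 3L, majority = 0.75) {
    stopifnot(is(genome, "AnnotatedGenome"), is(flankSpec, "FlankSpec"))
    reps <- replicons(genome)
    if (length(reps) == 0L || sum(width(reps)) == 0L)
        stop("empty genome")
    reads <- .loadReads(reads)
    chars <- as.character(reads)
    ext <- extractBarcode(reads, flankSpec, withPosition = TRUE)
    keep <- !is.na(ext$barcode)
    chars <- chars[keep]
    bc <- ext$barcode[keep]
    # tail = sequence after left + barcode + full right flank, located
    # relative to the (leftmost acceptable) barcode placement
    tailStart <- ext$start[keep] +
        flankSpec@barcodeLength + nchar(flankSpec@rightFlank)
    tails <- substr(chars, tailStart, nchar(chars))
    allBc <- unique(bc)   # short-tail barcodes stay, reported as unmapped
    long <- nchar(tails) >= minGenomicLen
    bc <- bc[long]; tails <- tails[long]
    loci <- .locateTails(tails, reps)   # list of data.frames per distinct tail
    res <- data.frame(barcode = allBc, replicon = NA_character_,
                      position = NA_integer_, strand = NA_character_,
                      supportReads = 0L, status = "unmapped",
                      stringsAsFactors = FALSE)
    tailIdx <- match(tails, names(loci))
    for (i in seq_along(allBc)) {
        sel <- which(bc == allBc[i])
        hits <- loci[tailIdx[sel]]
        nhit <- vapply(hits, nrow, integer(1))
        mapped <- nhit >= 1L
        if (!any(mapped)) next
        res$supportReads[i] <- sum(mapped)
        if (any(nhit > 1L)) { res$status[i] <- "ambiguous"; next }
        h <- do.call(rbind, hits[mapped])
        grp <- .jitterGroups(h, jitter)
        tab <- tabulate(grp)
        best <- which.max(tab)
        if (length(tab) == 1L || tab[best] / sum(tab) >= majority) {
            sel2 <- grp == best
            pos <- h$position[sel2]
            res$replicon[i] <- h$replicon[which(sel2)[1]]
            res$strand[i] <- h$strand[which(sel2)[1]]
            res$position[i] <- as.integer(stats::median(pos))
            res$status[i] <- "unique"
        } else {
            res$status[i] <- "ambiguous"
        }
    }
    DataFrame(res)
}

# Exact both-strand search of distinct tails against all replicons.
# Returns, per distinct tail, a data.frame of loci (replicon, position,
# strand) where position is the first tail base on the matching strand.
.locateTails <- function(tails, reps) {
    utails <- unique(tails)
    out <- replicate(length(utails),
                     data.frame(replicon = character(0),
                                position = integer(0),
                                strand = character(0),
                                stringsAsFactors = FALSE),
                     simplify = FALSE)
    names(out) <- utails
    if (!length(utails)) return(out)
    widths <- nchar(utails)
    for (wd in unique(widths)) {
        sel <- which(widths == wd)
        pd <- Biostrings::PDict(DNAStringSet(utails[sel]))
        for (r in seq_along(reps)) {
            fwd <- Biostrings::matchPDict(pd, reps[[r]])
            rc <- Biostrings::matchPDict(pd, Biostrings::reverseComplement(reps[[r]]))
            L <- length(reps[[r]])
            for (k in seq_along(sel)) {
                tname <- utails[sel[k]]
                f <- fwd[[k]]; b <- rc[[k]]
                if (length(f))
                    out[[tname]] <- rbind(out[[tname]], data.frame(
                        replicon = names(reps)[r],
                        position = IRanges::start(f),
                        strand = "+", stringsAsFactors = FALSE))
                if (length(b))
                    # match at [s,e] on the RC corresponds to plus-strand
                    # interval [L-e+1, L-s+1]; the first tail base sits at
                    # its right edge on the minus strand
                    out[[tname]] <- rbind(out[[tname]], data.frame(
                        replicon = names(reps)[r],
                        position = L - IRanges::start(b) + 1L,
                        strand = "-", stringsAsFactors = FALSE))
            }
        }
    }
    out
}

# Group loci that agree within the jitter window (same replicon + strand,
# position difference <= jitter, chained).
.jitterGroups <- function(h, jitter) {
    key <- paste(h$replicon, h$strand)
    grp <- integer(nrow(h))
    next_id <- 0L
    for (k in unique(key)) {
        sel <- which(key == k)
        o <- sel[order(h$position[sel])]
        brk <- c(0L, cumsum(diff(h$position[o]) > jitter))
        grp[o] <- next_id + brk + 1L
        next_id <- max(grp[o])
    }
    grp
}

#' Assign mapped insertions to genes
#'
#' An insertion is assigned to a gene iff its position lies inside the gene
#' interval and its relative position along the gene (strand-aware: 0 at the
#' gene start codon side) falls in `[lo, hi)`.  Insertions in the terminal
#' portions of a gene often leave function intact, so the default central
#' window is (0.1, 0.9).  Intergenic, edge and non-`unique` insertions are
#' unassigned (`NA`) but retained.
#'
#' @param insertionMap Output of [mapInsertions()] (or the library table in
#'   the same shape).
#' @param genome An [AnnotatedGenome-class].
#' @param centralWindow Numeric `(lo, hi)` with `0 <= lo < hi <= 1`.
#' @return A `DataFrame` with columns `barcode`, `gene` (locus_tag or `NA`),
#'   plus the input mapping columns; per-gene insertion counts in
#'   `metadata()$geneInsertions`.
#' @export
assignGenes <- function(insertionMap, genome, centralWindow = c(0.1, 0.9)) {
    stopifnot(is(genome, "AnnotatedGenome"))
    lo <- centralWindow[1]; hi <- centralWindow[2]
    if (!(lo >= 0 && lo < hi && hi <= 1))
        stop("centralWindow must satisfy 0 <= lo < hi <= 1")
    m <- as.data.frame(insertionMap)
    if (is.null(m$status)) m$status <- "unique"
    g <- genes(genome)
    gene <- rep(NA_character_, nrow(m))
    usable <- which(m$status == "unique" & !is.na(m$position))
    if (length(usable) && length(g)) {
        ins <- GRanges(m$replicon[usable], IRanges(m$position[usable],
                                                   m$position[usable]))
        GenomeInfoDb::seqlevels(ins) <- GenomeInfoDb::seqlevels(g)
        hit <- GenomicRanges::findOverlaps(ins, g, ignore.strand = TRUE,
                                           select = "first")
        hasHit <- which(!is.na(hit))
        if (length(hasHit)) {
            gi <- hit[hasHit]
            pos <- m$position[usable[hasHit]]
            plus <- as.character(strand(g)[gi]) != "-"
            rel <- ifelse(plus,
                          (pos - start(g)[gi]) / width(g)[gi],
                          (end(g)[gi] - pos) / width(g)[gi])
            inWin <- rel >= lo & rel < hi
            gene[usable[hasHit][inWin]] <- g$locus_tag[gi[inWin]]
        }
    }
    out <- DataFrame(barcode = m$barcode, gene = gene,
                     m[, setdiff(colnames(m), c("barcode", "gene")),
                       drop = FALSE])
    cnt <- table(gene[!is.na(gene)])
    S4Vectors::metadata(out)$geneInsertions <-
        setNames(as.integer(cnt), names(cnt))
    out
}
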