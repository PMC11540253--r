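#' Extract barcodes from amplicon reads by flanking-sequence recognition
#'
#' Locates the left flank allowing up to `maxMismatch` substitutions (no
#' indels), takes the next `barcodeLength` bases as the barcode and verifies
#' the first `anchorLength` bases of the right flank under the same mismatch
#' budget.  The leftmost acceptable match wins.  Reads where no acceptable
#' placement exists yield `NA` (tallied, not an error).
#'
#' @param reads A `DNAStringSet` or character vector of read sequences.
#' @param flankSpec A [FlankSpec-class].
#' @param withPosition If `TRUE`, return a `data.frame` with columns
#'   `barcode` and `start` (1-based barcode start in the read) instead of a
#'   bare character vector.
#' @return Character vector of barcodes (`NA` where extraction failed), or a
#'   `data.frame` when `withPosition = TRUE`.
#' @examples
#' fs <- FlankSpec("GTCGACCTGCAGCGTACG", "AGAGACCTCGTGGACATC")
#' extractBarcode(paste0("GTCGACCTGCAGCGTACG", strrep("A", 20),
#'                       "AGAGACCTCGTGGACATC"), fs)
#' @export
extractBarcode <- function(reads, flankSpec, withPosition = FALSE) {
    stopifnot(is(flankSpec, "FlankSpec"))
    if (is.character(reads)) reads <- DNAStringSet(reads)
    n <- length(reads)
    if (n == 0L) {
        if (withPosition)
            return(data.frame(barcode = character(0), start = integer(0)))
        return(character(0))
    }
    left <- flankSpec@leftFlank
    blen <- flankSpec@barcodeLength
    mm <- flankSpec@maxMismatch
    anchor <- substr(flankSpec@rightFlank, 1L, flankSpec@anchorLength)
    hits <- Biostrings::vmatchPattern(left, reads, max.mismatch = mm)
    starts <- Biostrings::startIndex(hits)
    chars <- as.character(reads)
    rw <- nchar(chars)
    out <- rep(NA_character_, n)
    pos <- rep(NA_integer_, n)
    nh <- lengths(starts)
    # fast path: single candidate (overwhelmingly common)
    one <- which(nh == 1L)
    if (length(one)) {
        s <- unlist(starts[one], use.names = FALSE)
        bs <- s + nchar(left)
        ok <- s >= 1L & bs + blen - 1L <= rw[one]
        bc <- substr(chars[one], bs, bs + blen - 1L)
        anc <- substr(chars[one], bs + blen, bs + blen + nchar(anchor) - 1L)
        pass <- ok & .hammingToConst(anc, anchor) <= mm
        out[one[pass]] <- bc[pass]
        pos[one[pass]] <- bs[pass]
    }
    multi <- which(nh > 1L)
    for (i in multi) {
        for (s in sort(starts[[i]])) {
            if (s < 1L) next
            bs <- s + nchar(left)
            if (bs + blen - 1L > rw[i]) next
            anc <- substr(chars[i], bs + blen, bs + blen + nchar(anchor) - 1L)
            if (.hammingToConst(anc, anchor) <= mm) {
                out[i] <- substr(chars[i], bs, bs + blen - 1L)
                pos[i] <- bs
                break
            }
        }
    }
    if (withPosition) return(data.frame(barcode = out, start = pos))
    out
}

#' Count barcodes per sample from FASTQ reads
#'
#' Extracts barcodes from each sample's reads and tallies them against the
#' pre-mapped library barcodes.  Barcodes not in `knownBarcodes` are dropped
#' by default; with `collapse = "hamming1"` an unknown barcode is collapsed
#' onto a known barcode at Hamming distance 1 when that neighbor is unique.
#' A run report (total reads, extracted, matched per sample) is stored in
#' `metadata()$report`.
#'
#' @param readsBySample Named list: sample_id -> FASTQ path (plain or gzip),
#'   `DNAStringSet`, or character vector of read sequences.
#' @param flankSpec A [FlankSpec-class].
#' @param knownBarcodes Character vector of library barcodes (rows of the
#'   result).
#' @param sampleMeta `data.frame` with `sample_id`, `condition`, `regime`,
#'   `generation`, `replicate` for the samples.
#' @param collapse `"none"` (exact match only) or `"hamming1"`.
#' @return A [BarcodeCounts-class].
#' @seealso [extractBarcode()], [filterCounts()]
#' @export
countBarcodes <- function(readsBySample, flankSpec, knownBarcodes,
                          sampleMeta, collapse = c("none", "hamming1")) {
    collapse <- match.arg(collapse)
    stopifnot(is(flankSpec, "FlankSpec"))
    if (is.null(names(readsBySample)))
        stop("readsBySample must be named by sample_id")
    need <- c("sample_id", "condition", "regime", "generation", "replicate")
    if (!all(need %in% colnames(sampleMeta)))
        stop("sampleMeta must have columns: ", paste(need, collapse = ", "))
    if (!all(names(readsBySample) %in% sampleMeta$sample_id))
        stop("every sample in readsBySample needs metadata")
    sampleMeta <- sampleMeta[match(names(readsBySample), sampleMeta$sample_id), ]
    nS <- length(readsBySample)
    counts <- matrix(0L, nrow = length(knownBarcodes), ncol = nS,
                     dimnames = list(knownBarcodes, names(readsBySample)))
    report <- data.frame(sample_id = names(readsBySample),
                         total = 0L, extracted = 0L, matched = 0L)
    for (j in seq_len(nS)) {
        reads <- .loadReads(readsBySample[[j]])
        bc <- extractBarcode(reads, flankSpec)
        report$total[j] <- length(bc)
        bc <- bc[!is.na(bc)]
        report$extracted[j] <- length(bc)
        if (collapse == "hamming1" && length(bc))
            bc <- .collapseHamming1(bc, knownBarcodes)
        tab <- table(factor(bc, levels = knownBarcodes))
        counts[, j] <- as.integer(tab)
        report$matched[j] <- sum(tab)
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts),
        colData = S4Vectors::DataFrame(sampleMeta[, need[-1]],
                                       row.names = sampleMeta$sample_id))
    S4Vectors::metadata(se)$report <- report
    new("BarcodeCounts", se)
}

.loadReads <- function(x) {
    if (is(x, "DNAStringSet")) return(x)
    if (is.character(x) && length(x) == 1L && file.exists(x))
        return(Biostrings::readDNAStringSet(x, format = "fastq"))
    if (is.character(x)) return(DNAStringSet(x))
    stop("cannot interpret reads input of class ", class(x)[1])
}

# Collapse extracted barcodes not in the known set onto a known barcode at
# Hamming distance exactly 1, when that neighbor is unique; ambiguous or
# distant barcodes are dropped.  Works on distinct strings, then maps back.
.collapseHamming1 <- function(bc, known) {
    inKnown <- bc %in% known
    unk <- unique(bc[!inKnown])
    if (!length(unk)) return(bc[inKnown])
    env <- new.env(hash = TRUE, size = length(known) * 2L)
    for (k in known) assign(k, TRUE, envir = env)
    mapTo <- vapply(unk, function(u) {
        hitsFound <- character(0)
        for (p in seq_len(nchar(u))) {
            orig <- substr(u, p, p)
            for (b in setdiff(DNA_BASES, orig)) {
                cand <- u
                substr(cand, p, p) <- b
                if (exists(cand, envir = env, inherits = FALSE)) {
                    hitsFound <- c(hitsFound, cand)
                    if (length(hitsFound) > 1L) return(NA_character_)
                }
            }
        }
        if (length(hitsFound) == 1L) hitsFound else NA_character_
    }, character(1))
    res <- bc
    m <- match(bc, unk)
    res[!is.na(m)] <- mapTo[m[!is.na(m)]]
    res[!is.na(res)]
}

#' Filter barcodes on mean T0 abundance
#'
#' Removes barcodes whose mean read count across all T0 columns
#' (`generation == 0`) is below `minT0Count`; low-count T0 barcodes make
#' log2 fold changes unstable.  Column metadata and the run report are
#' preserved.  Idempotent.
#'
#' @param counts A [BarcodeCounts-class].
#' @param minT0Count Minimum mean T0 count (default 10).
#' @return The filtered [BarcodeCounts-class].
#' @export
filterCounts <- function(counts, minT0Count = 10) {
    stopifnot(is(counts, "BarcodeCounts"))
    t0 <- which(counts$generation == 0)
    if (!length(t0))
        stop("no T0 (generation == 0) columns present")
    m <- SummarizedExperiment::assay(counts, "counts")[, t0, drop = FALSE]
    keep <- rowMeans(m) >= minT0Count
    counts[keep, ]
}
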