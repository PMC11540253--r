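#' Simulate BarSeq or TnSeq reads from a count matrix
#'
#' Produces, per sample, the raw amplicon reads the counting / mapping stages
#' consume.  BarSeq reads have the fixed structure
#' `leftFlank + barcode + rightFlank` (padded with random bases to
#' `readLength` if requested); TnSeq reads additionally carry
#' `genomicTailLen` bases of genome sequence downstream of the insertion
#' point on the insertion strand.  Substitution errors are injected i.i.d.
#' at `errorRate`; the number of reads per barcode equals the count matrix
#' entry exactly.  A tail truncated at a replicon end is flagged with
#' `:trunc` in the read name.
#'
#' @param library A [MutantLibrary-class].
#' @param counts A [BarcodeCounts-class] whose rownames are library barcodes,
#'   or a named integer vector (single sample).
#' @param mode `"barseq"` or `"tnseq"`.
#' @param flankSpec A [FlankSpec-class].
#' @param genome [AnnotatedGenome-class]; required for `mode = "tnseq"`.
#' @param genomicTailLen Genomic bases after the right flank (tnseq).
#' @param errorRate Per-base substitution probability.
#' @param readLength Pad barseq reads with random bases to this length
#'   (`NULL` = no padding).
#' @param seed Integer seed.
#' @param dir If non-`NULL`, write one FASTQ file per sample into this
#'   directory (plain text, Phred+33, constant quality `"I"`) and return the
#'   file paths; otherwise return a list of character vectors of read
#'   sequences (names = read ids).
#' @return Named list (per sample) of read vectors, or of FASTQ paths.
#' @examples
#' g <- makeGenome(nGenes = 5, nReplicons = 1, seed = 1)
#' lib <- makeLibrary(g, nMutants = 20, seed = 2)
#' fs <- FlankSpec("GTCGACCTGCAGCGTACG", "AGAGACCTCGTGGACATC")
#' cts <- setNames(rep(2L, 20), libraryEntries(lib)$barcode)
#' rds <- simulateReads(lib, cts, "barseq", fs, seed = 3)
#' @export
simulateReads <- function(library, counts, mode = c("barseq", "tnseq"),
                          flankSpec, genome = NULL, genomicTailLen = 30L,
                          errorRate = 0, readLength = NULL, seed = 1L,
                          dir = NULL) {
    mode <- match.arg(mode)
    stopifnot(is(library, "MutantLibrary"), is(flankSpec, "FlankSpec"))
    if (mode == "tnseq" && is.null(genome))
        stop("tnseq mode requires the genome")
    e <- libraryEntries(library)
    if (is(counts, "BarcodeCounts")) {
        mat <- SummarizedExperiment::assay(counts, "counts")
    } else {
        mat <- matrix(as.integer(counts), ncol = 1,
                      dimnames = list(names(counts), "sample1"))
    }
    if (!all(rownames(mat) %in% e$barcode))
        stop("count matrix contains barcodes not in the library")
    idx <- match(rownames(mat), e$barcode)
    tails <- NULL
    trunc <- rep(FALSE, nrow(mat))
    if (mode == "tnseq") {
        tt <- .genomicTails(e[idx, ], genome, genomicTailLen)
        tails <- tt$tail
        trunc <- tt$trunc
    }
    out <- vector("list", ncol(mat))
    names(out) <- colnames(mat)
    for (j in seq_len(ncol(mat))) {
        out[[j]] <- withr::with_seed(.childSeed(seed, j), {
            n <- mat[, j]
            rows <- rep.int(seq_along(n), n)
            core <- paste0(flankSpec@leftFlank, rownames(mat)[rows],
                           flankSpec@rightFlank)
            if (mode == "tnseq") core <- paste0(core, tails[rows])
            if (!is.null(readLength)) {
                pad <- readLength - nchar(core)
                for (k in unique(pad[pad > 0])) {
                    sel <- which(pad == k)
                    core[sel] <- paste0(core[sel], .randomDNA(length(sel), k))
                }
            }
            core <- .injectErrors(core, errorRate)
            names(core) <- sprintf("read_%s_%d%s", colnames(mat)[j],
                                   seq_along(core),
                                   ifelse(trunc[rows], ":trunc", ""))
            core
        })
    }
    if (!is.null(dir)) {
        if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
        paths <- file.path(dir, paste0(names(out), ".fastq"))
        for (j in seq_along(out)) writeFastq(out[[j]], paths[j])
        names(paths) <- names(out)
        return(paths)
    }
    out
}

# Reference substring downstream of each insertion point, strand-aware:
# '+' -> bases [pos, pos+L-1]; '-' -> reverse complement of [pos-L+1, pos].
# Truncated at replicon bounds and flagged.
.genomicTails <- function(entries, genome, tailLen) {
    reps <- replicons(genome)
    w <- width(reps)[match(entries$replicon, names(reps))]
    plus <- entries$strand == "+"
    start <- ifelse(plus, entries$position,
                    pmax(1L, entries$position - tailLen + 1L))
    end <- ifelse(plus, pmin(w, entries$position + tailLen - 1L),
                  entries$position)
    trunc <- (end - start + 1L) < tailLen
    seqs <- as.character(Biostrings::subseq(
        reps[match(entries$replicon, names(reps))], start = start, end = end))
    seqs[!plus] <- as.character(Biostrings::reverseComplement(
        DNAStringSet(seqs[!plus])))
    list(tail = unname(seqs), trunc = trunc)
}

#' Write reads as a plain-text FASTQ file
#'
#' Four-line records, Phred+33, constant quality.
#'
#' @param reads Named character vector (names become read ids).
#' @param path Output file.
#' @param quality Single quality character applied to every base.
#' @return `path`, invisibly.
#' @export
writeFastq <- function(reads, path, quality = "I") {
    ids <- names(reads)
    if (is.null(ids)) ids <- paste0("read_", seq_along(reads))
    rec <- paste0("@", ids, "\n", reads, "\n+\n", strrep(quality, nchar(reads)))
    writeLines(rec, path)
    invisible(path)
}
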