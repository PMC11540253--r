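#' Export a genome as FASTA and GFF3
#'
#' Replicon sequences go to FASTA; the gene model to GFF3 (1-based closed
#' coordinates, `type = "gene"`, `locus_tag` and `pathway` attributes)
#' via rtracklayer.
#'
#' @param genome An [AnnotatedGenome-class].
#' @param fastaFile,gffFile Output paths (either may be `NULL` to skip).
#' @return Invisibly, the written paths.
#' @export
exportGenome <- function(genome, fastaFile = NULL, gffFile = NULL) {
    stopifnot(is(genome, "AnnotatedGenome"))
    if (!is.null(fastaFile))
        Biostrings::writeXStringSet(replicons(genome), fastaFile)
    if (!is.null(gffFile)) {
        g <- genes(genome)
        g$type <- "gene"
        g$ID <- g$locus_tag
        rtracklayer::export(g, gffFile, format = "gff3")
    }
    invisible(c(fasta = fastaFile, gff = gffFile))
}

#' Import a genome from FASTA and GFF3
#'
#' Counterpart of [exportGenome()]; accepts any GFF3 whose records carry a
#' `locus_tag` (or `ID`) attribute.  Records without a `pathway` attribute
#' get `NA`.
#'
#' @param fastaFile Replicon FASTA.
#' @param gffFile Gene model GFF3.
#' @param feature GFF3 type to keep (default `"gene"`).
#' @return An [AnnotatedGenome-class].
#' @export
importGenome <- function(fastaFile, gffFile, feature = "gene") {
    reps <- Biostrings::readDNAStringSet(fastaFile)
    names(reps) <- sub("\\s.*$", "", names(reps))
    g <- rtracklayer::import(gffFile, format = "gff3")
    g <- g[g$type %in% feature]
    lt <- if (!is.null(g$locus_tag)) g$locus_tag else g$ID
    mc <- S4Vectors::DataFrame(locus_tag = lt,
        pathway = if (!is.null(g$pathway)) g$pathway
                  else rep(NA_character_, length(g)))
    S4Vectors::mcols(g) <- mc
    GenomeInfoDb::seqlevels(g) <- names(reps)
    GenomeInfoDb::seqlengths(g) <- width(reps)
    new("AnnotatedGenome", replicons = reps, genes = g)
}

#' Write a mutant library table as TSV
#'
#' Columns: `barcode`, `replicon`, `position`, `strand`, `gene`, `w`.
#'
#' @param library A [MutantLibrary-class].
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
writeLibrary <- function(library, file) {
    stopifnot(is(library, "MutantLibrary"))
    utils::write.table(as.data.frame(libraryEntries(library)), file,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(file)
}

#' Read a mutant library table from TSV
#'
#' @param file TSV as written by [writeLibrary()].
#' @return A [MutantLibrary-class].
#' @export
readLibrary <- function(file) {
    d <- utils::read.delim(file, stringsAsFactors = FALSE)
    if (is.null(d$w)) d$w <- 1
    if (is.null(d$gene)) d$gene <- NA_character_
    new("MutantLibrary", entries = DataFrame(d))
}

#' Write barcode counts (and sample sheet) as TSV
#'
#' @param counts A [BarcodeCounts-class].
#' @param countsFile Count matrix TSV (barcodes as rows, first column
#'   `barcode`).
#' @param samplesFile Optional sample sheet TSV.
#' @return Invisibly, the written paths.
#' @export
writeBarcodeCounts <- function(counts, countsFile, samplesFile = NULL) {
    stopifnot(is(counts, "BarcodeCounts"))
    m <- SummarizedExperiment::assay(counts, "counts")
    utils::write.table(
        data.frame(barcode = rownames(m), m, check.names = FALSE),
        countsFile, sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(samplesFile)) {
        cd <- as.data.frame(SummarizedExperiment::colData(counts))
        utils::write.table(
            data.frame(sample_id = rownames(cd), cd, check.names = FALSE),
            samplesFile, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    invisible(c(counts = countsFile, samples = samplesFile))
}

#' Read barcode counts from TSV
#'
#' @param countsFile Count matrix TSV as written by [writeBarcodeCounts()].
#' @param samplesFile Sample sheet TSV with `sample_id`, `condition`,
#'   `regime`, `generation`, `replicate`.
#' @return A [BarcodeCounts-class].
#' @export
readBarcodeCounts <- function(countsFile, samplesFile) {
    d <- utils::read.delim(countsFile, check.names = FALSE,
                           stringsAsFactors = FALSE)
    m <- as.matrix(d[, -1, drop = FALSE])
    rownames(m) <- d[[1]]
    storage.mode(m) <- "integer"
    s <- utils::read.delim(samplesFile, stringsAsFactors = FALSE)
    s <- s[match(colnames(m), s$sample_id), ]
    s$generation <- as.numeric(s$generation)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = m),
        colData = S4Vectors::DataFrame(
            s[, c("condition", "regime", "generation", "replicate")],
            row.names = s$sample_id))
    new("BarcodeCounts", se)
}

#' Write an insertion map as TSV
#'
#' @param map `DataFrame` from [mapInsertions()] or [assignGenes()].
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
writeInsertionMap <- function(map, file) {
    utils::write.table(as.data.frame(map), file, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(file)
}

#' Write a gene fitness table as long-form TSV
#'
#' Columns: `gene`, `condition`, `fitness`, `sd`, `n_barcodes`.
#'
#' @param fitness A [GeneFitness-class].
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
writeFitness <- function(fitness, file) {
    stopifnot(is(fitness, "GeneFitness"))
    f <- SummarizedExperiment::assay(fitness, "fitness")
    s <- SummarizedExperiment::assay(fitness, "sd")
    nb <- SummarizedExperiment::assay(fitness, "nBarcodes")
    long <- data.frame(
        gene = rep(rownames(f), times = ncol(f)),
        condition = rep(colnames(f), each = nrow(f)),
        fitness = as.vector(f), sd = as.vector(s),
        n_barcodes = as.vector(nb))
    utils::write.table(long, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(file)
}

#' Read an OD time series from TSV
#'
#' @param file TSV with columns `time_h` and `od`.
#' @return `data.frame` with `time_h`, `od`.
#' @export
readOdSeries <- function(file) {
    d <- utils::read.delim(file, stringsAsFactors = FALSE)
    if (!all(c("time_h", "od") %in% colnames(d)))
        stop("OD file needs columns time_h and od")
    d
}
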