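#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom GenomicRanges GRanges seqnames start end strand width
#' @importFrom IRanges IRanges
#' @importFrom Biostrings DNAStringSet
NULL

#' Annotated genome: replicon sequences plus gene model
#'
#' Holds the replicon sequences of a (real or simulated) bacterial genome as a
#' [Biostrings::DNAStringSet] together with a gene model as a
#' [GenomicRanges::GRanges] (1-based closed coordinates, one range per gene,
#' metadata columns `locus_tag` and `pathway`). The default simulated scale
#' mirrors a *Cupriavidus necator*-like genome: ~6,600 genes over two
#' chromosomes and one small megaplasmid.
#'
#' @slot replicons A `DNAStringSet`, one entry per replicon.
#' @slot genes A `GRanges` of gene intervals with metadata columns
#'   `locus_tag` (unique) and `pathway`.
#'
#' @seealso [makeGenome()], [replicons()], [genes()]
#' @export
setClass("AnnotatedGenome",
    slots = c(replicons = "DNAStringSet", genes = "GRanges"))

setValidity("AnnotatedGenome", function(object) {
    msg <- character()
    g <- object@genes
    rl <- object@replicons
    if (length(g) > 0) {
        if (is.null(g$locus_tag))
            msg <- c(msg, "genes must carry a 'locus_tag' metadata column")
        else if (anyDuplicated(g$locus_tag))
            msg <- c(msg, "locus_tags must be unique")
        sn <- as.character(seqnames(g))
        if (!all(sn %in% names(rl)))
            msg <- c(msg, "every gene must lie on a declared replicon")
        else {
            lens <- width(rl)[match(sn, names(rl))]
            if (any(start(g) < 1L) || any(end(g) > lens))
                msg <- c(msg, "gene intervals must lie within their replicon")
        }
        if (any(width(g) < 1L))
            msg <- c(msg, "gene intervals must be non-empty")
    }
    if (length(msg)) msg else TRUE
})

#' Barcoded transposon mutant library
#'
#' Maps each 20-nt random barcode to its transposon insertion locus.  In
#' synthetic mode each barcode additionally carries a planted relative fitness
#' `w` (doublings per population doubling; 1 = neutral), the ground truth that
#' downstream scoring is tested against.
#'
#' The insertion position is the first genome base after the transposon
#' junction (1-based).
#'
#' @slot entries A `DataFrame` with columns `barcode` (unique 20-nt strings),
#'   `replicon`, `position`, `strand`, `gene` (locus_tag or `NA` for
#'   intergenic insertions) and `w` (planted relative fitness).
#'
#' @seealso [makeLibrary()], [libraryEntries()], [plantedFitness()]
#' @export
setClass("MutantLibrary", slots = c(entries = "DataFrame"))

setValidity("MutantLibrary", function(object) {
    e <- object@entries
    msg <- character()
    need <- c("barcode", "replicon", "position", "strand", "gene", "w")
    if (!all(need %in% colnames(e)))
        return(paste("entries must have columns:", paste(need, collapse = ", ")))
    if (nrow(e) > 0) {
        if (anyDuplicated(e$barcode))
            msg <- c(msg, "barcodes must be unique")
        if (any(nchar(e$barcode) != 20L))
            msg <- c(msg, "barcodes must be exactly 20 nt")
        if (any(e$position < 1L))
            msg <- c(msg, "insertion positions must be >= 1")
        if (!all(e$strand %in% c("+", "-")))
            msg <- c(msg, "strand must be '+' or '-'")
    }
    if (length(msg)) msg else TRUE
})

#' Barcode count matrix with sample metadata
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding a barcode x sample
#' matrix of read counts (assay `"counts"`) with per-sample metadata in
#' `colData`: `condition` (growth condition label), `regime`
#' (`"continuous"`, `"pulsed"` or `"batch"` feeding), `generation`
#' (population doublings since T0) and `replicate`.
#'
#' @seealso [simulateCompetition()], [countBarcodes()], [filterCounts()]
#' @export
setClass("BarcodeCounts", contains = "SummarizedExperiment")

setValidity("BarcodeCounts", function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        return("must contain a 'counts' assay")
    cn <- colnames(SummarizedExperiment::colData(object))
    need <- c("condition", "regime", "generation", "replicate")
    if (!all(need %in% cn))
        msg <- c(msg, paste("colData must have columns:",
                            paste(need, collapse = ", ")))
    cts <- SummarizedExperiment::assay(object, "counts")
    if (any(cts < 0)) msg <- c(msg, "counts must be non-negative")
    if (all(need %in% cn) && any(object$generation < 0))
        msg <- c(msg, "generations must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Gene x condition fitness table
#'
#' A [SummarizedExperiment::SummarizedExperiment] of gene-level fitness
#' scores: assays `"fitness"` (median-centered mean barcode log2 fold change;
#' `NA` where a gene has no scored barcodes), `"sd"` (between-replicate SD)
#' and `"nBarcodes"`.  Columns are conditions; the scoring generation is in
#' `metadata()$generation`.
#'
#' @seealso [geneFitness()], [significantGenes()]
#' @export
setClass("GeneFitness", contains = "SummarizedExperiment")

setValidity("GeneFitness", function(object) {
    an <- SummarizedExperiment::assayNames(object)
    need <- c("fitness", "sd", "nBarcodes")
    if (!all(need %in% an))
        return(paste("must contain assays:", paste(need, collapse = ", ")))
    TRUE
})

#' Operon / regulator topology for the polar-effect cost model
#'
#' Transcription units are ordered gene vectors, each driven by one promoter;
#' regulator dependencies say which promoters require which (regulator) gene
#' product.  A transposon insertion is assumed fully polar: it silences the
#' inactivated gene and everything downstream in the same unit, and — through
#' the regulator dependencies — every unit whose promoter loses its activator,
#' iterated to closure.
#'
#' @slot units Named list of character vectors; each element is a
#'   transcription unit (genes in transcription order), named by its
#'   promoter id.
#' @slot regulators Named list; names are regulator genes, elements are
#'   character vectors of promoter ids the regulator activates.  The induced
#'   dependency graph must be acyclic.
#'
#' @seealso [OperonModel()], [affectedGenes()], [totalCost()]
#' @export
setClass("OperonModel", slots = c(units = "list", regulators = "list"))

setValidity("OperonModel", function(object) {
    msg <- character()
    u <- object@units
    if (length(u)) {
        if (is.null(names(u)) || anyDuplicated(names(u)))
            msg <- c(msg, "units must be uniquely named by promoter id")
        allg <- unlist(u, use.names = FALSE)
        if (anyDuplicated(allg))
            msg <- c(msg, "each gene may appear in at most one unit")
    }
    r <- object@regulators
    if (length(r)) {
        if (is.null(names(r)))
            msg <- c(msg, "regulators must be named by regulator gene")
        unknown <- setdiff(unlist(r, use.names = FALSE), names(u))
        if (length(unknown))
            msg <- c(msg, paste("regulator targets reference unknown promoters:",
                                paste(unknown, collapse = ", ")))
        if (.operonHasCycle(u, r))
            msg <- c(msg, "regulator dependency graph must be acyclic")
    }
    if (length(msg)) msg else TRUE
})

# Cycle check on the promoter-level graph: promoter A -> promoter B when a
# regulator of B is a gene transcribed from A. Depth-first search; the
# topologies this models (hox/hyp-scale) are tiny.
.operonHasCycle <- function(units, regulators) {
    geneUnit <- rep(names(units), lengths(units))
    names(geneUnit) <- unlist(units, use.names = FALSE)
    adj <- lapply(names(units), function(p) {
        regs <- names(regulators)[vapply(names(regulators), function(rg)
            identical(unname(geneUnit[rg]), p), logical(1))]
        unique(unlist(regulators[regs], use.names = FALSE))
    })
    names(adj) <- names(units)
    state <- setNames(rep(0L, length(units)), names(units)) # 0 new, 1 open, 2 done
    visit <- function(p) {
        if (state[[p]] == 1L) return(TRUE)
        if (state[[p]] == 2L) return(FALSE)
        state[[p]] <<- 1L
        for (q in adj[[p]]) if (visit(q)) return(TRUE)
        state[[p]] <<- 2L
        FALSE
    }
    for (p in names(units)) if (visit(p)) return(TRUE)
    FALSE
}

#' Result of silhouette-selected hierarchical clustering
#'
#' @slot assignments Named integer vector: gene -> cluster id in `1:k`.
#' @slot k Chosen number of clusters (maximum mean silhouette width over the
#'   scanned range; ties broken toward smaller k).
#' @slot silhouetteByK `data.frame` with columns `k` and `meanSilWidth`.
#' @slot linkage Agglomeration method tag passed to [stats::hclust()].
#' @slot tree The `hclust` object.
#'
#' @seealso [clusterGenes()]
#' @export
setClass("ClusterResult",
    slots = c(assignments = "integer", k = "integer",
              silhouetteByK = "data.frame", linkage = "character",
              tree = "ANY"))

setValidity("ClusterResult", function(object) {
    a <- object@assignments
    if (length(a) && (is.null(names(a)) || any(a < 1L) || any(a > object@k)))
        return("assignments must be named and lie in 1:k")
    TRUE
})

#' Flanking-sequence specification for barcode extraction
#'
#' Describes the fixed amplicon structure around the 20-nt random barcode:
#' the constant left flank (upstream priming site), the right flank, the
#' barcode length, the per-flank substitution budget, and how many bases of
#' the right flank are checked as an anchor.
#'
#' @slot leftFlank,rightFlank Constant DNA strings surrounding the barcode.
#' @slot barcodeLength Barcode length in nt (default 20).
#' @slot maxMismatch Maximum substitutions tolerated in the left flank and in
#'   the right anchor (no indels).
#' @slot anchorLength Number of leading right-flank bases verified after the
#'   barcode.
#'
#' @seealso [FlankSpec()], [extractBarcode()]
#' @export
setClass("FlankSpec",
    slots = c(leftFlank = "character", rightFlank = "character",
              barcodeLength = "integer", maxMismatch = "integer",
              anchorLength = "integer"))

setValidity("FlankSpec", function(object) {
    msg <- character()
    if (!nzchar(object@leftFlank) || !nzchar(object@rightFlank))
        msg <- c(msg, "flanks must be non-empty")
    if (object@barcodeLength < 1L)
        msg <- c(msg, "barcodeLength must be > 0")
    if (object@maxMismatch < 0L)
        msg <- c(msg, "maxMismatch must be >= 0")
    if (object@anchorLength < 1L ||
        object@anchorLength > nchar(object@rightFlank))
        msg <- c(msg, "anchorLength must be in [1, nchar(rightFlank)]")
    if (length(msg)) msg else TRUE
})
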