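#' @rdname AnnotatedGenome-class
#' @param object,x An `AnnotatedGenome`.
#' @export
setGeneric("replicons", function(x) standardGeneric("replicons"))

#' @rdname AnnotatedGenome-class
#' @export
setMethod("replicons", "AnnotatedGenome", function(x) x@replicons)

#' @rdname AnnotatedGenome-class
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))

#' @rdname AnnotatedGenome-class
#' @export
setMethod("genes", "AnnotatedGenome", function(x) x@genes)

#' Total genome length (sum of replicon widths)
#' @param x An `AnnotatedGenome`.
#' @return Integer, total number of bases over all replicons.
#' @export
genomeLength <- function(x) {
    stopifnot(is(x, "AnnotatedGenome"))
    sum(width(replicons(x)))
}

setMethod("show", "AnnotatedGenome", function(object) {
    cat("AnnotatedGenome:", length(object@replicons), "replicon(s),",
        length(object@genes), "gene(s),",
        sum(width(object@replicons)), "bp total\n")
    if (length(object@replicons)) {
        w <- width(object@replicons)
        for (i in seq_along(w))
            cat("  ", names(object@replicons)[i], ": ", w[i], " bp\n", sep = "")
    }
})

#' @rdname MutantLibrary-class
#' @param x A `MutantLibrary`.
#' @export
setGeneric("libraryEntries", function(x) standardGeneric("libraryEntries"))

#' @rdname MutantLibrary-class
#' @export
setMethod("libraryEntries", "MutantLibrary", function(x) x@entries)

#' @rdname MutantLibrary-class
#' @export
setGeneric("plantedFitness", function(x) standardGeneric("plantedFitness"))

#' @rdname MutantLibrary-class
#' @export
setMethod("plantedFitness", "MutantLibrary", function(x)
    setNames(x@entries$w, x@entries$barcode))

#' @rdname MutantLibrary-class
#' @export
setMethod("length", "MutantLibrary", function(x) nrow(x@entries))

setMethod("show", "MutantLibrary", function(object) {
    e <- object@entries
    cat("MutantLibrary:", nrow(e), "barcoded mutant(s)\n")
    if (nrow(e)) {
        cat("  genic:", sum(!is.na(e$gene)),
            " intergenic:", sum(is.na(e$gene)), "\n")
        cat("  planted fitness w: range",
            sprintf("[%.3g, %.3g]", min(e$w), max(e$w)), "\n")
    }
})

#' @rdname OperonModel-class
#' @param x An `OperonModel`.
#' @export
setGeneric("operonUnits", function(x) standardGeneric("operonUnits"))

#' @rdname OperonModel-class
#' @export
setMethod("operonUnits", "OperonModel", function(x) x@units)

#' @rdname OperonModel-class
#' @export
setGeneric("regulatorTargets", function(x) standardGeneric("regulatorTargets"))

#' @rdname OperonModel-class
#' @export
setMethod("regulatorTargets", "OperonModel", function(x) x@regulators)

setMethod("show", "OperonModel", function(object) {
    cat("OperonModel:", length(object@units), "transcription unit(s),",
        length(unlist(object@units)), "gene(s),",
        length(object@regulators), "regulator(s)\n")
})

#' @rdname ClusterResult-class
#' @param x A `ClusterResult`.
#' @export
setGeneric("clusterAssignments", function(x) standardGeneric("clusterAssignments"))

#' @rdname ClusterResult-class
#' @export
setMethod("clusterAssignments", "ClusterResult", function(x) x@assignments)

#' @rdname ClusterResult-class
#' @export
setGeneric("chosenK", function(x) standardGeneric("chosenK"))

#' @rdname ClusterResult-class
#' @export
setMethod("chosenK", "ClusterResult", function(x) x@k)

#' @rdname ClusterResult-class
#' @export
setGeneric("silhouetteByK", function(x) standardGeneric("silhouetteByK"))

#' @rdname ClusterResult-class
#' @export
setMethod("silhouetteByK", "ClusterResult", function(x) x@silhouetteByK)

setMethod("show", "ClusterResult", function(object) {
    cat("ClusterResult:", length(object@assignments), "gene(s) in",
        object@k, "cluster(s) [", object@linkage, "linkage ]\n")
    tab <- table(object@assignments)
    cat("  sizes:", paste(tab, collapse = ", "), "\n")
})

#' Construct a FlankSpec
#'
#' @param leftFlank,rightFlank Constant DNA sequences flanking the barcode.
#' @param barcodeLength Barcode length in nt.
#' @param maxMismatch Substitution budget per flank (no indels).
#' @param anchorLength Leading right-flank bases verified as anchor; defaults
#'   to `min(6, nchar(rightFlank))`.
#' @return A [FlankSpec-class] object.
#' @examples
#' FlankSpec("GTCGACCTGCAGCGTACG", "AGAGACCTCGTGGACATC")
#' @export
FlankSpec <- function(leftFlank, rightFlank, barcodeLength = 20L,
                      maxMismatch = 0L,
                      anchorLength = min(6L, nchar(rightFlank))) {
    new("FlankSpec",
        leftFlank = toupper(as.character(leftFlank)),
        rightFlank = toupper(as.character(rightFlank)),
        barcodeLength = as.integer(barcodeLength),
        maxMismatch = as.integer(maxMismatch),
        anchorLength = as.integer(anchorLength))
}

setMethod("show", "FlankSpec", function(object) {
    cat("FlankSpec: ", object@leftFlank, "-[N",
        object@barcodeLength, "]-", object@rightFlank,
        "  (<=", object@maxMismatch, " mismatch/flank, anchor ",
        object@anchorLength, " nt)\n", sep = "")
})

#' Construct an OperonModel
#'
#' @param units Named list of character vectors: transcription units in gene
#'   order, named by promoter id.
#' @param regulators Named list: regulator gene -> character vector of
#'   promoter ids it activates.  Must be acyclic.
#' @return An [OperonModel-class] object.
#' @examples
#' OperonModel(units = list(P1 = c("A", "B", "R"), P2 = c("X", "Y")),
#'             regulators = list(R = "P2"))
#' @export
OperonModel <- function(units = list(), regulators = list()) {
    units <- lapply(units, as.character)
    regulators <- lapply(regulators, as.character)
    new("OperonModel", units = units, regulators = regulators)
}
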