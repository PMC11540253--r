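#' @importFrom withr with_seed
NULL

DNA_BASES <- c("A", "C", "G", "T")

# Hamming distance between each element of a character vector and one
# constant string; elements shorter than the constant get the missing
# positions counted as mismatches.
.hammingToConst <- function(x, const) {
    k <- nchar(const)
    d <- integer(length(x))
    for (j in seq_len(k)) {
        cj <- substr(x, j, j)
        d <- d + (cj != substr(const, j, j) | cj == "")
    }
    d
}

# Random DNA strings of a fixed width.  Two regimes: many short strings
# (column-wise paste0) vs. few long ones (collapse per string).
.randomDNA <- function(n, width) {
    if (n == 0L) return(character(0))
    if (width > 200L || n == 1L)
        return(vapply(seq_len(n), function(i)
            paste(sample(DNA_BASES, width, replace = TRUE), collapse = ""),
            character(1)))
    cols <- lapply(seq_len(width), function(j)
        sample(DNA_BASES, n, replace = TRUE))
    do.call(paste0, cols)
}

# n unique random barcodes of the given width.
.randomBarcodes <- function(n, width = 20L, maxTries = 50L) {
    bc <- unique(.randomDNA(n, width))
    tries <- 0L
    while (length(bc) < n) {
        tries <- tries + 1L
        if (tries > maxTries)
            stop("barcode space exhausted: cannot draw ", n,
                 " unique barcodes of width ", width)
        bc <- unique(c(bc, .randomDNA(n - length(bc), width)))
    }
    bc[seq_len(n)]
}

# Inject i.i.d. substitution errors at the given per-base rate into a
# character vector of reads.  Substitutions are drawn uniformly from the
# three non-identical bases.
.injectErrors <- function(reads, errorRate) {
    if (errorRate <= 0 || length(reads) == 0L) return(reads)
    w <- nchar(reads)
    nerr <- stats::rbinom(length(reads), w, errorRate)
    hit <- which(nerr > 0L)
    for (i in hit) {
        pos <- sample.int(w[i], nerr[i])
        for (p in pos) {
            old <- substr(reads[i], p, p)
            substr(reads[i], p, p) <- sample(setdiff(DNA_BASES, old), 1L)
        }
    }
    reads
}

# Derive a bounded child seed from a base seed and an index (stays < 2^31).
.childSeed <- function(seed, index) {
    (as.integer(seed) %% 1000003L) * 2011L + as.integer(index) * 7L + 11L
}
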