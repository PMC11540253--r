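#' Individual protein cost of a gene
#'
#' The proteome mass fraction psi of the gene's product, in percent of total
#' protein mass.  A gene absent from the table costs 0, with a warning.
#'
#' @param gene Locus tag / gene name (vectorized).
#' @param massTable Named numeric vector gene -> psi (percent), or a table
#'   with `gene` and `psi_percent` columns (see [readMassTable()]).
#' @return Numeric vector of percent mass fractions.
#' @export
individualCost <- function(gene, massTable) {
    massTable <- .asMassVector(massTable)
    psi <- unname(massTable[gene])
    if (anyNA(psi)) {
        warning("gene(s) absent from mass table, cost 0: ",
                paste(gene[is.na(psi)], collapse = ", "))
        psi[is.na(psi)] <- 0
    }
    psi
}

.asMassVector <- function(massTable) {
    if (!is.null(dim(massTable)))
        massTable <- setNames(massTable$psi_percent, massTable$gene)
    if (any(massTable < 0)) stop("mass fractions must be >= 0")
    massTable
}

#' Genes whose expression is lost when one gene is knocked out
#'
#' A transposon insertion is fully polar: it silences the inactivated gene
#' and every gene downstream of it in the same transcription unit.  If a
#' silenced gene is a regulator, every unit whose promoter depends on it is
#' silenced too; the rule is iterated to a fixed point.  With
#' `mode = "inframe"` (a markerless in-frame deletion) only the gene itself
#' is affected, but its loss as a regulator still propagates.
#'
#' @param knockout The inactivated gene.  A gene unknown to the model
#'   affects only itself.
#' @param operonModel An [OperonModel-class].
#' @param mode `"polar"` (transposon; default) or `"inframe"`.
#' @return Character vector: the affected gene set (always contains
#'   `knockout`).
#' @examples
#' om <- OperonModel(units = list(P1 = c("A", "B", "C")))
#' affectedGenes("A", om)
#' @export
affectedGenes <- function(knockout, operonModel,
                          mode = c("polar", "inframe")) {
    mode <- match.arg(mode)
    stopifnot(is(operonModel, "OperonModel"))
    units <- operonUnits(operonModel)
    regs <- regulatorTargets(operonModel)
    downstream <- function(gene) {
        for (u in units) {
            i <- match(gene, u)
            if (!is.na(i))
                return(if (mode == "polar") u[i:length(u)] else gene)
        }
        gene
    }
    affected <- downstream(knockout)
    repeat {
        lostRegs <- intersect(affected, names(regs))
        lostProms <- unique(unlist(regs[lostRegs], use.names = FALSE))
        newGenes <- setdiff(unlist(units[lostProms], use.names = FALSE),
                            affected)
        if (!length(newGenes)) break
        # a silenced promoter silences its whole unit
        affected <- union(affected, newGenes)
    }
    sort(unique(affected))
}

#' Total (polar + regulatory) protein cost of a knockout
#'
#' Sum of proteome mass fractions over [affectedGenes()]: the cost actually
#' freed by the knockout once disruption of downstream and
#' regulator-dependent gene expression is taken into account.  Always >=
#' the individual cost.
#'
#' @inheritParams affectedGenes
#' @param massTable As in [individualCost()]; affected genes missing from
#'   the table contribute 0 (no warning — operon models commonly list genes
#'   below proteomic detection).
#' @return A one-row `data.frame`: `gene`, `individual`, `total`,
#'   `nAffected`.  Vectorize over knockouts with [costReport()].
#' @export
totalCost <- function(knockout, operonModel, massTable,
                      mode = c("polar", "inframe")) {
    mode <- match.arg(mode)
    massTable <- .asMassVector(massTable)
    aff <- affectedGenes(knockout, operonModel, mode)
    psi <- massTable[aff]
    psi[is.na(psi)] <- 0
    ind <- if (knockout %in% names(massTable))
        unname(massTable[knockout]) else 0
    data.frame(gene = knockout, individual = ind,
               total = sum(psi), nAffected = length(aff))
}

#' Cost report over a set of knockouts
#'
#' @param knockouts Character vector of genes to knock out (default: every
#'   gene in the operon model).
#' @inheritParams totalCost
#' @return `data.frame` with one row per knockout: `gene`, `individual`,
#'   `total`, `nAffected`.
#' @export
costReport <- function(knockouts = NULL, operonModel, massTable,
                       mode = c("polar", "inframe")) {
    mode <- match.arg(mode)
    if (is.null(knockouts))
        knockouts <- unlist(operonUnits(operonModel), use.names = FALSE)
    do.call(rbind, lapply(knockouts, totalCost, operonModel = operonModel,
                          massTable = massTable, mode = mode))
}

#' Correlate total protein cost with growth-rate gain
#'
#' Pearson correlation between the total protein cost freed by each knockout
#' and its estimated growth-rate gain (mu - mu_pop): under the protein-cost
#' hypothesis, removing a larger idle proteome burden buys a larger growth
#' advantage.
#'
#' @param totalCosts Numeric vector of total costs (percent), named by gene.
#' @param growthEstimates `data.frame` with `mu` and `muPop` columns as from
#'   [estimateGrowthRate()] (rows matching `totalCosts`), or a numeric
#'   vector of growth-rate gains.
#' @return A list: `r` (Pearson correlation; `NA` with a message when either
#'   vector has zero variance) and `n`.
#' @export
costRateCorrelation <- function(totalCosts, growthEstimates) {
    gain <- if (is.data.frame(growthEstimates))
        growthEstimates$mu - growthEstimates$muPop else growthEstimates
    if (length(totalCosts) != length(gain))
        stop("costs and growth estimates must be paired")
    if (length(gain) < 3L) stop("need at least 3 paired observations")
    if (stats::sd(totalCosts) == 0 || stats::sd(gain) == 0) {
        message("zero variance in costs or gains: correlation undefined")
        return(list(r = NA_real_, n = length(gain)))
    }
    list(r = stats::cor(totalCosts, gain, method = "pearson"),
         n = length(gain))
}

#' Read an operon model from TSV files
#'
#' @param unitsFile TSV with columns `unit` (promoter id), `position`
#'   (1-based index within the unit) and `gene`.
#' @param regulatorsFile Optional TSV with columns `regulator` (gene) and
#'   `promoter` (unit id it activates).
#' @return An [OperonModel-class].
#' @seealso The packaged hox/hyp example:
#'   `system.file("extdata", "hoxhyp_operons.tsv", package = "BarSeqFit")`
#' @export
readOperonModel <- function(unitsFile, regulatorsFile = NULL) {
    u <- utils::read.delim(unitsFile, stringsAsFactors = FALSE)
    units <- lapply(split(u, u$unit),
                    function(d) d$gene[order(d$position)])
    regulators <- list()
    if (!is.null(regulatorsFile)) {
        r <- utils::read.delim(regulatorsFile, stringsAsFactors = FALSE)
        regulators <- lapply(split(r$promoter, r$regulator), unique)
    }
    OperonModel(units = units, regulators = regulators)
}

#' Read a proteome mass-fraction table from TSV
#'
#' @param file TSV with columns `gene` and `psi_percent` (percent of total
#'   protein mass); an optional `condition` column is filtered with
#'   `condition`.
#' @param condition Condition to select when the table carries one.
#' @return Named numeric vector gene -> psi (percent).
#' @export
readMassTable <- function(file, condition = NULL) {
    d <- utils::read.delim(file, stringsAsFactors = FALSE)
    if (!is.null(condition) && "condition" %in% colnames(d))
        d <- d[d$condition == condition, , drop = FALSE]
    if (sum(d$psi_percent) > 100)
        stop("mass fractions sum to > 100%")
    setNames(d$psi_percent, d$gene)
}
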