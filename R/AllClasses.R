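#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#'   rowData colData<-
#' @importFrom stats median sd rnorm runif var complete.cases model.matrix
#'   pt pnorm p.adjust setNames wilcox.test fisher.test quantile digamma
#'   trigamma rchisq
#' @importFrom utils read.delim write.table count.fields modifyList
NULL

## ---------------------------------------------------------------------------
## CtExperiment: raw quantification-cycle (Ct) data
## ---------------------------------------------------------------------------

#' CtExperiment: a matrix of raw Ct values with sample annotation
#'
#' A thin [SummarizedExperiment::SummarizedExperiment-class] subclass holding
#' one assay named `"Ct"`: quantification cycles for miRNAs (rows) by samples
#' (columns). Undetected reactions (instrument "Undetermined") are stored as
#' `NA`; they are never encoded as a numeric sentinel such as 40, so no
#' arithmetic can accidentally include censored wells. Finite Ct values must
#' lie in the open interval (0, 45) - the physical cycle range of a qPCR run.
#'
#' Sample-level annotation (group, age, BMI, cohort phase, QC status) lives in
#' `colData`.
#'
#' @aliases CtExperiment-class
#' @seealso [DeltaCtExperiment-class] for normalized data
#' @export
setClass("CtExperiment", contains = "SummarizedExperiment")

setValidity("CtExperiment", function(object) {
    msg <- character()
    if (!"Ct" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'Ct' is required")
    else {
        ct <- assay(object, "Ct")
        if (!is.numeric(ct))
            msg <- c(msg, "'Ct' assay must be numeric")
        else {
            fin <- ct[!is.na(ct)]
            if (any(!is.finite(fin)))
                msg <- c(msg, "Ct values must be finite or NA (undetected)")
            else if (length(fin) && (any(fin <= 0) || any(fin >= 45)))
                msg <- c(msg, "finite Ct values must lie in (0, 45)")
        }
    }
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "unique, non-NULL miRNA identifiers (rownames) required")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "unique, non-NULL sample identifiers (colnames) required")
    if (length(msg)) msg else TRUE
})

#' Construct a CtExperiment
#'
#' @param ct numeric matrix of Ct values (miRNAs x samples), `NA` marking
#'   undetected wells; must carry unique dimnames.
#' @param colData optional `DataFrame`/`data.frame` of per-sample annotation,
#'   rows aligned with `colnames(ct)`. Conventional columns: `group`
#'   (factor/character, e.g. `"non-OSA"`/`"OSA"`), `age`, `bmi`, `phase`,
#'   `qc_pass`.
#' @return a [CtExperiment-class] object.
#' @examples
#' ct <- matrix(c(20, 25, 21, 26), 2, 2,
#'              dimnames = list(c("miR-a", "miR-b"), c("s1", "s2")))
#' CtExperiment(ct)
#' @export
CtExperiment <- function(ct, colData = NULL) {
    ct <- as.matrix(ct)
    if (is.null(colData))
        colData <- DataFrame(row.names = colnames(ct))
    se <- SummarizedExperiment(assays = list(Ct = ct), colData = colData)
    new("CtExperiment", se)
}

#' Extract the Ct matrix
#'
#' @param x a [CtExperiment-class].
#' @return numeric matrix with `NA` for undetected wells.
#' @export
ctValues <- function(x) {
    stopifnot(is(x, "CtExperiment"))
    assay(x, "Ct")
}

#' Logical detection mask
#'
#' @param x a [CtExperiment-class].
#' @return logical matrix, `TRUE` where the reaction was detected.
#' @export
isDetected <- function(x) !is.na(ctValues(x))

setMethod("show", "CtExperiment", function(object) {
    ct <- ctValues(object)
    cat(sprintf("CtExperiment: %d miRNAs x %d samples (%d undetected wells)\n",
                nrow(ct), ncol(ct), sum(is.na(ct))))
    callNextMethod()
})

## ---------------------------------------------------------------------------
## DeltaCtExperiment: normalized data
## ---------------------------------------------------------------------------

#' DeltaCtExperiment: delta-Ct values relative to a per-sample reference
#'
#' Holds one assay `"deltaCt"`: Ct minus a per-sample reference value, i.e.
#' a negative log2 expression ratio against the reference. The reference
#' scheme is recorded in the `referenceScheme` slot: `"globalMean"` (the
#' per-sample mean Ct of detected miRNAs, mean-centre normalization) or
#' `"ecSpike"` (mean of selected endogenous controls, optionally with the
#' exogenous spike-in).
#'
#' @slot referenceScheme single string naming the normalization reference.
#' @aliases DeltaCtExperiment-class referenceScheme
#' @export referenceScheme
#' @export
setClass("DeltaCtExperiment",
         contains = "SummarizedExperiment",
         representation(referenceScheme = "character"))

setValidity("DeltaCtExperiment", function(object) {
    msg <- character()
    if (!"deltaCt" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'deltaCt' is required")
    if (length(object@referenceScheme) != 1L ||
        !object@referenceScheme %in% c("globalMean", "ecSpike"))
        msg <- c(msg, "referenceScheme must be 'globalMean' or 'ecSpike'")
    if (length(msg)) msg else TRUE
})

#' @rdname DeltaCtExperiment-class
#' @param x a `DeltaCtExperiment`.
#' @return `referenceScheme(x)` returns the scheme string.
referenceScheme <- function(x) {
    stopifnot(is(x, "DeltaCtExperiment"))
    x@referenceScheme
}

#' Extract the delta-Ct matrix
#'
#' @param x a [DeltaCtExperiment-class].
#' @return numeric matrix of normalized values (`NA` = undetected).
#' @export
deltaCtValues <- function(x) {
    stopifnot(is(x, "DeltaCtExperiment"))
    assay(x, "deltaCt")
}

setMethod("show", "DeltaCtExperiment", function(object) {
    cat(sprintf("DeltaCtExperiment (reference: %s): %d miRNAs x %d samples\n",
                object@referenceScheme, nrow(object), ncol(object)))
    callNextMethod()
})

## ---------------------------------------------------------------------------
## QCReport
## ---------------------------------------------------------------------------

#' QCReport: result of spike-in sample quality control
#'
#' @slot excluded character, sample identifiers failing QC.
#' @slot deviation named numeric, per-sample deviation of the spike-in Ct
#'   from the cohort median (Ct units; `NA` when the spike-in was undetected).
#' @slot maxDev numeric(1), the exclusion threshold used (Ct units).
#' @slot center numeric(1), the median spike-in Ct the deviations refer to.
#' @aliases QCReport-class
#' @export
setClass("QCReport",
         representation(excluded = "character", deviation = "numeric",
                        maxDev = "numeric", center = "numeric"))

setValidity("QCReport", function(object) {
    if (!all(object@excluded %in% names(object@deviation)))
        "excluded samples must be a subset of the assayed samples"
    else TRUE
})

#' @describeIn QCReport-class sample ids excluded by the QC rule
#' @param x a `QCReport`.
#' @export
excludedSamples <- function(x) {
    stopifnot(is(x, "QCReport"))
    x@excluded
}

setMethod("show", "QCReport", function(object) {
    cat(sprintf("QCReport: %d/%d samples excluded (|Ct - median| > %.2f)\n",
                length(object@excluded), length(object@deviation),
                object@maxDev))
    if (length(object@excluded))
        cat("  excluded:", paste(object@excluded, collapse = ", "), "\n")
})

## ---------------------------------------------------------------------------
## CandidateSet
## ---------------------------------------------------------------------------

#' CandidateSet: miRNAs nominated as endogenous-control candidates
#'
#' One row per candidate with the selection method(s) that nominated it
#' (mean-centre + SD, concordance-correlation-restricted, or both), the rank
#' and score within each method.
#'
#' @slot table a `DataFrame` with columns `id`, `inMCSD`, `inCCR`,
#'   `mcsdRank`, `ccrRank`, `sdScore`, `cccScore`, `method`.
#' @aliases CandidateSet-class
#' @export
setClass("CandidateSet", representation(table = "DataFrame"))

setValidity("CandidateSet", function(object) {
    tab <- object@table
    need <- c("id", "inMCSD", "inCCR", "mcsdRank", "ccrRank",
              "sdScore", "cccScore", "method")
    msg <- character()
    if (!all(need %in% colnames(tab)))
        msg <- c(msg, paste("missing columns:",
                            paste(setdiff(need, colnames(tab)), collapse = ", ")))
    else {
        if (anyDuplicated(tab$id))
            msg <- c(msg, "candidate ids must be unique")
        if (nrow(tab) && !all(tab$inMCSD | tab$inCCR))
            msg <- c(msg, "every candidate needs at least one selection method")
    }
    if (length(msg)) msg else TRUE
})

#' @describeIn CandidateSet-class candidate identifiers
#' @param x a `CandidateSet`.
#' @export
candidateIds <- function(x) {
    stopifnot(is(x, "CandidateSet"))
    as.character(x@table$id)
}

#' @describeIn CandidateSet-class the full annotation table
#' @export
candidateTable <- function(x) {
    stopifnot(is(x, "CandidateSet"))
    x@table
}

setMethod("show", "CandidateSet", function(object) {
    tab <- object@table
    cat(sprintf("CandidateSet: %d candidates (%d MC+SD only, %d CCR only, %d both)\n",
                nrow(tab), sum(tab$inMCSD & !tab$inCCR),
                sum(tab$inCCR & !tab$inMCSD), sum(tab$inMCSD & tab$inCCR)))
})

## ---------------------------------------------------------------------------
## StabilityReport
## ---------------------------------------------------------------------------

#' StabilityReport: geNorm / NormFinder stability assessment of candidates
#'
#' @slot table `DataFrame`, one row per candidate: `id`, `genormM` (geNorm
#'   M-value from the full candidate set), `genormRank` (from iterative
#'   exclusion; the final pair is tied at 1.5), `exclusionOrder` (1 = first
#'   excluded, i.e. least stable), `normfinderStability`, `normfinderRank`,
#'   `combinedRank`.
#' @slot pairwiseVariation named numeric, geNorm V(n, n+1) series.
#' @slot concordance list with elements `tau` and `p`: Kendall rank
#'   concordance between the geNorm and NormFinder rankings.
#' @slot fusion single string, the rank-fusion rule used for `combinedRank`
#'   (`"mean"`, `"genorm"` or `"normfinder"`).
#' @aliases StabilityReport-class
#' @export
setClass("StabilityReport",
         representation(table = "DataFrame", pairwiseVariation = "numeric",
                        concordance = "list", fusion = "character"))

setValidity("StabilityReport", function(object) {
    tab <- object@table
    msg <- character()
    if (anyDuplicated(tab$id)) msg <- c(msg, "ids must be unique")
    if (any(tab$genormM < 0, na.rm = TRUE))
        msg <- c(msg, "geNorm M must be nonnegative")
    if (any(object@pairwiseVariation < 0, na.rm = TRUE))
        msg <- c(msg, "pairwise variation must be nonnegative")
    if (length(msg)) msg else TRUE
})

#' @describeIn StabilityReport-class the per-candidate stability table
#' @param x a `StabilityReport`.
#' @export
stabilityTable <- function(x) {
    stopifnot(is(x, "StabilityReport"))
    x@table
}

#' @describeIn StabilityReport-class the geNorm pairwise-variation series
#' @export
pairwiseVariation <- function(x) {
    stopifnot(is(x, "StabilityReport"))
    x@pairwiseVariation
}

#' @describeIn StabilityReport-class Kendall concordance between the rankings
#' @export
rankingConcordance <- function(x) {
    stopifnot(is(x, "StabilityReport"))
    x@concordance
}

setMethod("show", "StabilityReport", function(object) {
    tab <- object@table
    o <- order(tab$combinedRank)
    cat(sprintf("StabilityReport: %d candidates (rank fusion: %s)\n",
                nrow(tab), object@fusion))
    cat(sprintf("  geNorm/NormFinder rank concordance: tau = %.3f (p = %.3g)\n",
                object@concordance$tau, object@concordance$p))
    cat("  most stable:",
        paste(utils::head(as.character(tab$id[o]), 3), collapse = ", "), "\n")
})
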