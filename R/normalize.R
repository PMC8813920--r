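## Delta-Ct normalization schemes. All arithmetic stays on the Ct scale:
## a Ct difference is an exact (negative) log2 expression ratio, so the
## geNorm log-ratio identities hold without back-transformation.

#' Mean-centre (global-mean) normalization
#'
#' Subtracts from each sample its mean Ct over detected miRNAs. This removes
#' per-sample global offsets (RNA input, pipetting) exactly; within each
#' sample the detected normalized values have mean zero. Undetected wells
#' stay undetected.
#'
#' @param x a [CtExperiment-class].
#' @return a [DeltaCtExperiment-class] with `referenceScheme = "globalMean"`;
#'   `colData` is carried over and the per-sample reference is stored in
#'   `colData(x)$referenceCt`.
#' @examples
#' ct <- matrix(c(10, 20, 30, 12, 22, 32), 3, 2,
#'              dimnames = list(paste0("m", 1:3), c("s1", "s2")))
#' deltaCtValues(meanCentreNormalize(CtExperiment(ct)))
#' @export
meanCentreNormalize <- function(x) {
    stopifnot(is(x, "CtExperiment"))
    ct <- ctValues(x)
    nDet <- colSums(!is.na(ct))
    if (any(nDet < 2L))
        stop("fewer than 2 detected miRNAs in sample(s): ",
             paste(colnames(ct)[nDet < 2L], collapse = ", "))
    ref <- colMeans(ct, na.rm = TRUE)
    norm <- sweep(ct, 2L, ref, "-")
    cd <- colData(x)
    cd$referenceCt <- unname(ref)
    se <- SummarizedExperiment(assays = list(deltaCt = norm), colData = cd)
    new("DeltaCtExperiment", se, referenceScheme = "globalMean")
}

#' Endogenous-control plus spike-in delta-Ct normalization
#'
#' For each sample the reference is the arithmetic mean Ct of the selected
#' endogenous controls and (by default) the exogenous spike-in, i.e. the
#' geometric mean of their expression levels; each miRNA's normalized value
#' is its Ct minus that reference. With `spikeMode = "sequential"` the
#' spike-in is first subtracted from every Ct and the EC mean of the
#' spike-corrected values is then removed - algebraically this cancels the
#' spike-in, leaving a pure EC delta-Ct.
#'
#' @param x a [CtExperiment-class].
#' @param ecIds endogenous-control miRNA ids; each must be detected in every
#'   sample.
#' @param spike named numeric spike-in Ct vector covering all samples of `x`
#'   (ignored in `"sequential"` mode after the cancellation noted above;
#'   may be `NULL` when `spikeWeight` use is off).
#' @param dropECs drop the EC rows from the output (default `TRUE`).
#' @param spikeMode `"equal"` (default): the spike-in enters the reference
#'   mean as one more member; `"sequential"`: spike-in correction then EC
#'   delta-Ct.
#' @return a [DeltaCtExperiment-class] with `referenceScheme = "ecSpike"`.
#' @export
ecNormalize <- function(x, ecIds, spike = NULL, dropECs = TRUE,
                        spikeMode = c("equal", "sequential")) {
    stopifnot(is(x, "CtExperiment"))
    spikeMode <- match.arg(spikeMode)
    ct <- ctValues(x)
    miss <- setdiff(ecIds, rownames(ct))
    if (length(miss))
        stop("EC id(s) absent from matrix: ", paste(miss, collapse = ", "))
    ec <- ct[ecIds, , drop = FALSE]
    if (anyNA(ec)) {
        idx <- which(is.na(ec), arr.ind = TRUE)[1L, ]
        stop(sprintf("EC '%s' undetected in sample '%s'",
                     ecIds[idx[1L]], colnames(ec)[idx[2L]]))
    }
    if (spikeMode == "equal") {
        if (is.null(spike)) stop("spike-in vector required for 'equal' mode")
        spike <- spike[colnames(ct)]
        if (anyNA(spike))
            stop("spike-in missing or undetected for sample(s): ",
                 paste(colnames(ct)[is.na(spike)], collapse = ", "))
        ref <- colMeans(rbind(ec, spike = unname(spike)))
    } else {
        ref <- colMeans(ec)
    }
    norm <- sweep(ct, 2L, ref, "-")
    if (dropECs) norm <- norm[setdiff(rownames(norm), ecIds), , drop = FALSE]
    cd <- colData(x)
    cd$referenceCt <- unname(ref)
    se <- SummarizedExperiment(assays = list(deltaCt = norm), colData = cd)
    new("DeltaCtExperiment", se, referenceScheme = "ecSpike")
}
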