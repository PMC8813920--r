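## Sample- and miRNA-level quality control.

#' Spike-in based sample quality control
#'
#' The exogenous spike-in (e.g. cel-miR-39-3p) is added at a fixed amount
#' before RNA extraction, so its Ct should be near-constant across samples;
#' a deviant spike-in flags a technical failure of extraction or loading.
#' A sample is excluded when its spike-in Ct deviates from the cohort median
#' by more than `maxDev` cycles. Samples whose spike-in is undetected are
#' always excluded. The rule is invariant to adding a constant to all
#' spike-in values.
#'
#' @param spike named numeric vector, one spike-in Ct per sample (`NA` =
#'   undetected).
#' @param maxDev maximum tolerated absolute deviation from the median, in
#'   Ct units (default 1.5).
#' @return a [QCReport-class].
#' @examples
#' spikeInQC(c(s1 = 20.0, s2 = 20.1, s3 = 19.9, s4 = 24.0), maxDev = 1.5)
#' @export
spikeInQC <- function(spike, maxDev = 1.5) {
    if (is.null(names(spike)) || anyDuplicated(names(spike)))
        stop("spike-in vector must carry unique sample names")
    if (all(is.na(spike)))
        stop("spike-in undetected in every sample; cannot run QC")
    if (maxDev <= 0) stop("maxDev must be positive")
    center <- median(spike, na.rm = TRUE)
    dev <- spike - center
    excluded <- names(spike)[is.na(dev) | abs(dev) > maxDev]
    new("QCReport", excluded = excluded, deviation = dev,
        maxDev = maxDev, center = center)
}

#' Highly detected miRNAs
#'
#' Returns the miRNAs whose Ct is detected and strictly below `maxCt` in
#' every sample - the eligibility rule for endogenous-control candidates
#' ("highly detected in all samples"). Raising `maxCt` never shrinks the
#' returned set.
#'
#' @param x a [CtExperiment-class] (after any sample exclusions).
#' @param maxCt detection threshold in Ct units, in (0, 45); default 32.
#' @return character vector of miRNA ids (possibly empty).
#' @export
detectionFilter <- function(x, maxCt = 32) {
    stopifnot(is(x, "CtExperiment"))
    if (maxCt <= 0 || maxCt >= 45) stop("maxCt must be in (0, 45)")
    ct <- ctValues(x)
    keep <- apply(ct, 1L, function(v) all(!is.na(v) & v < maxCt))
    rownames(ct)[keep]
}

#' Fully detected miRNAs
#'
#' miRNAs with no undetected well in any sample; this set defines the
#' reference ("global mean of fully detected miRNAs") for
#' concordance-correlation-restricted candidate selection.
#'
#' @param x a [CtExperiment-class].
#' @return character vector of miRNA ids.
#' @export
fullyDetectedSet <- function(x) {
    stopifnot(is(x, "CtExperiment"))
    ct <- ctValues(x)
    rownames(ct)[rowSums(is.na(ct)) == 0L]
}

#' Two-group cohort characteristics table
#'
#' Summarizes baseline variables per group as median \[P25; P75\] for
#' continuous variables (compared with the exact two-sided Mann-Whitney U
#' test) and as n (%) for categorical variables (compared with Fisher's
#' exact test).
#'
#' @param meta `DataFrame`/`data.frame` of per-sample metadata.
#' @param continuous character, names of continuous columns.
#' @param categorical character, names of categorical columns.
#' @param group name of the two-level grouping column (default `"group"`).
#' @return a `data.frame` with one row per variable (one per level for
#'   categorical variables): formatted per-group summaries and the numeric
#'   p-value.
#' @export
cohortSummary <- function(meta, continuous = c("age", "bmi"),
                          categorical = character(), group = "group") {
    meta <- as.data.frame(meta)
    for (v in c(continuous, categorical, group))
        if (!v %in% colnames(meta)) stop("variable absent from metadata: ", v)
    g <- factor(meta[[group]])
    if (nlevels(g) != 2L) stop("exactly two groups are required")
    lv <- levels(g)

    fmtCont <- function(v, gi) {
        q <- quantile(v[g == gi], c(0.5, 0.25, 0.75), na.rm = TRUE, names = FALSE)
        sprintf("%.1f [%.1f;%.1f]", q[1], q[2], q[3])
    }
    rows <- list()
    for (v in continuous) {
        x <- meta[[v]]
        p <- suppressWarnings(
            wilcox.test(x[g == lv[1]], x[g == lv[2]],
                        alternative = "two.sided")$p.value)
        rows[[length(rows) + 1L]] <- data.frame(
            variable = v, level = NA_character_,
            group1 = fmtCont(x, lv[1]), group2 = fmtCont(x, lv[2]),
            test = "Mann-Whitney U", p = p, stringsAsFactors = FALSE)
    }
    for (v in categorical) {
        x <- factor(meta[[v]])
        tab <- table(x, g)
        p <- fisher.test(tab)$p.value
        for (l in levels(x)) {
            n1 <- tab[l, lv[1]]; n2 <- tab[l, lv[2]]
            rows[[length(rows) + 1L]] <- data.frame(
                variable = v, level = l,
                group1 = sprintf("%d (%.1f%%)", n1, 100 * n1 / sum(tab[, lv[1]])),
                group2 = sprintf("%d (%.1f%%)", n2, 100 * n2 / sum(tab[, lv[2]])),
                test = "Fisher exact", p = p, stringsAsFactors = FALSE)
        }
    }
    out <- do.call(rbind, rows)
    names(out)[names(out) == "group1"] <- lv[1]
    names(out)[names(out) == "group2"] <- lv[2]
    rownames(out) <- NULL
    out
}

#' Serialize a QCReport as delimited text
#'
#' @param qc a [QCReport-class].
#' @param path output path (`.csv` comma, else tab).
#' @return `path`, invisibly.
#' @export
writeQCReport <- function(qc, path) {
    stopifnot(is(qc, "QCReport"))
    df <- data.frame(sample_id = names(qc@deviation),
                     spike_deviation = unname(qc@deviation),
                     excluded = names(qc@deviation) %in% qc@excluded,
                     max_dev = qc@maxDev)
    write.table(df, path, sep = .sepFor(path, "auto"), quote = FALSE,
                row.names = FALSE)
    invisible(path)
}
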