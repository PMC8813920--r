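## End-to-end orchestration of the two-phase design: a discovery (array)
## screen that nominates endogenous controls and differential candidates,
## and an independent validation phase that re-checks EC stability,
## normalizes against the final ECs plus the spike-in, and re-tests the
## candidates with covariate adjustment. Stage outputs are materialized to
## disk when an output directory is given, so the pipeline is auditable and
## the two phases are separable.

#' Pipeline parameters
#'
#' All tunable thresholds of the two-phase pipeline, with the defaults the
#' package is designed around: detection at Ct < 32, ten candidates per
#' nomination method, eight ECs carried to validation, three final ECs,
#' differential expression at raw p < 0.025, spike-in exclusion at 1.5 Ct
#' from the median.
#'
#' @param detectionMaxCt detection threshold (Ct), default 32.
#' @param kMCSD,kCCR candidates per selection method, default 10 each.
#' @param topNValidation ECs carried to the validation phase, default 8.
#' @param topNFinal final ECs used for normalization, default 3.
#' @param deThreshold raw p-value threshold, default 0.025.
#' @param spikeMaxDev spike-in QC threshold (Ct), default 1.5.
#' @param moderated use moderated t (default `TRUE`).
#' @param fusion stability rank-fusion rule (default `"mean"`).
#' @param validationCovariates covariates adjusted for in the validation
#'   DE model, default `c("age", "bmi")` (the discovery cohort is
#'   age/BMI-matched and runs unadjusted).
#' @param spikeMode spike-in handling in [ecNormalize()], default
#'   `"equal"`.
#' @return a named list of validated parameters.
#' @export
pipelineParams <- function(detectionMaxCt = 32, kMCSD = 10, kCCR = 10,
                           topNValidation = 8, topNFinal = 3,
                           deThreshold = 0.025, spikeMaxDev = 1.5,
                           moderated = TRUE, fusion = "mean",
                           validationCovariates = c("age", "bmi"),
                           spikeMode = "equal") {
    p <- list(detectionMaxCt = detectionMaxCt, kMCSD = kMCSD, kCCR = kCCR,
              topNValidation = topNValidation, topNFinal = topNFinal,
              deThreshold = deThreshold, spikeMaxDev = spikeMaxDev,
              moderated = isTRUE(moderated), fusion = fusion,
              validationCovariates = validationCovariates,
              spikeMode = spikeMode)
    if (p$detectionMaxCt <= 0 || p$detectionMaxCt >= 45)
        stop("detectionMaxCt must be in (0, 45)")
    if (p$deThreshold <= 0 || p$deThreshold >= 1)
        stop("deThreshold must be in (0, 1)")
    if (p$topNFinal > p$topNValidation)
        stop("topNFinal cannot exceed topNValidation")
    if (any(c(p$kMCSD, p$kCCR, p$topNValidation, p$topNFinal,
              p$spikeMaxDev) <= 0))
        stop("counts and thresholds must be positive")
    p
}

#' Discovery-phase run
#'
#' Stage sequence: spike-in QC and sample exclusion, detection filter,
#' mean-centre normalization, candidate nomination by MC+SD and CCR,
#' candidate merging, geNorm + NormFinder stability ranking, selection of
#' the EC candidates for validation, and the differential-expression
#' screen on the detection-filtered panel.
#'
#' @param x discovery [CtExperiment-class] with a `group` column in
#'   `colData`.
#' @param spike named spike-in Ct vector covering the samples of `x`.
#' @param params list from [pipelineParams()].
#' @param outDir optional directory; when given, every stage table is
#'   written there.
#' @return a list: `qc`, `keptSamples`, `detectedIds`, `mcsd`, `ccr`,
#'   `candidates`, `stability`, `ecCandidates`, `de`, `deIds`.
#' @export
runDiscovery <- function(x, spike, params = pipelineParams(),
                         outDir = NULL) {
    stopifnot(is(x, "CtExperiment"))
    qc <- spikeInQC(spike[colnames(x)], maxDev = params$spikeMaxDev)
    kept <- setdiff(colnames(x), excludedSamples(qc))
    if (length(kept) < 4L)
        stop("discovery stage 'spike-in QC': fewer than 4 samples survive")
    xk <- x[, kept]

    detected <- detectionFilter(xk, maxCt = params$detectionMaxCt)
    if (length(detected) < 3L)
        stop("discovery stage 'detection filter': fewer than 3 miRNAs detected")

    nx <- meanCentreNormalize(xk)
    mcsd <- rankBySD(nx, eligible = detected, k = params$kMCSD)
    ccr <- ccrSelect(xk, k = params$kCCR)
    cand <- mergeCandidates(mcsd, ccr)

    stab <- stabilityReport(xk[candidateIds(cand), ], fusion = params$fusion)
    ecs <- selectTopStable(stab, min(params$topNValidation,
                                     length(candidateIds(cand))))

    de <- runDE(nx[detected, ], moderated = params$moderated,
                threshold = params$deThreshold)
    deIds <- selectDE(de, params$deThreshold)

    rep <- list(qc = qc, keptSamples = kept, detectedIds = detected,
                mcsd = mcsd, ccr = ccr, candidates = cand, stability = stab,
                ecCandidates = ecs, de = de, deIds = deIds)
    if (!is.null(outDir)) .writeDiscovery(rep, outDir)
    rep
}

.writeDiscovery <- function(rep, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeQCReport(rep$qc, file.path(dir, "discovery_qc.csv"))
    write.table(rep$mcsd, file.path(dir, "discovery_mcsd.csv"), sep = ",",
                quote = FALSE, row.names = FALSE)
    write.table(rep$ccr, file.path(dir, "discovery_ccr.csv"), sep = ",",
                quote = FALSE, row.names = FALSE)
    writeCandidateSet(rep$candidates, file.path(dir, "discovery_candidates.csv"))
    writeStabilityReport(rep$stability, file.path(dir, "discovery_stability.csv"))
    writeLines(rep$ecCandidates, file.path(dir, "discovery_ec_candidates.txt"))
    write.table(rep$de, file.path(dir, "discovery_de.csv"), sep = ",",
                quote = FALSE, row.names = FALSE)
    writeLines(rep$deIds, file.path(dir, "discovery_de_ids.txt"))
    invisible(dir)
}

#' Validation-phase run
#'
#' Re-checks the stability of the EC candidates on the validation data,
#' keeps the top final ECs, normalizes the panel against them together
#' with the spike-in, and re-tests the candidate differential miRNAs with
#' covariate adjustment.
#'
#' @param x validation [CtExperiment-class] (must contain every id in
#'   `ecIds` and `candidateDeIds`).
#' @param spike named spike-in Ct vector covering the samples of `x`.
#' @param ecIds EC candidates from the discovery phase.
#' @param candidateDeIds differential candidates from the discovery phase.
#' @inheritParams runDiscovery
#' @return a list: `stability`, `finalECs`, `de`, `validatedIds`.
#' @export
runValidation <- function(x, spike, ecIds, candidateDeIds,
                          params = pipelineParams(), outDir = NULL) {
    stopifnot(is(x, "CtExperiment"))
    miss <- setdiff(c(ecIds, candidateDeIds), rownames(x))
    if (length(miss))
        stop("id(s) absent from the validation matrix: ",
             paste(miss, collapse = ", "))

    stab <- stabilityReport(x[ecIds, ], fusion = params$fusion)
    finalECs <- selectTopStable(stab, min(params$topNFinal, length(ecIds)))

    nx <- ecNormalize(x, finalECs, spike = spike[colnames(x)],
                      dropECs = TRUE, spikeMode = params$spikeMode)
    testIds <- intersect(setdiff(candidateDeIds, finalECs), rownames(nx))
    de <- runDE(nx[testIds, ], covariates = params$validationCovariates,
                moderated = params$moderated, threshold = params$deThreshold)
    validated <- selectDE(de, params$deThreshold)

    rep <- list(stability = stab, finalECs = finalECs, de = de,
                validatedIds = validated)
    if (!is.null(outDir)) {
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        writeStabilityReport(stab, file.path(outDir, "validation_stability.csv"))
        writeLines(finalECs, file.path(outDir, "validation_final_ecs.txt"))
        write.table(de, file.path(outDir, "validation_de.csv"), sep = ",",
                    quote = FALSE, row.names = FALSE)
        writeLines(validated, file.path(outDir, "validation_de_ids.txt"))
    }
    rep
}

#' Full two-phase pipeline on a simulated cohort
#'
#' Runs [runDiscovery()] on the discovery phase, carries the selected EC
#' candidates and differential candidates into [runValidation()], and (for
#' synthetic data) scores the output against the planted ground truth.
#'
#' @param sim a [SimulatedCohort-class].
#' @param params list from [pipelineParams()].
#' @param outDir optional output directory for all stage tables.
#' @return a list: `discovery`, `validation`, `scorecard`.
#' @export
runPipeline <- function(sim, params = pipelineParams(), outDir = NULL) {
    stopifnot(is(sim, "SimulatedCohort"))
    disc <- runDiscovery(discoveryPhase(sim), spikeIn(sim), params, outDir)
    val <- runValidation(validationPhase(sim), spikeIn(sim),
                         ecIds = disc$ecCandidates,
                         candidateDeIds = intersect(disc$deIds,
                                                    rownames(validationPhase(sim))),
                         params = params, outDir = outDir)
    score <- scorePipeline(disc, val, groundTruth(sim))
    if (!is.null(outDir))
        write.table(score, file.path(outDir, "scorecard.csv"), sep = ",",
                    quote = FALSE, row.names = FALSE)
    list(discovery = disc, validation = val, scorecard = score)
}

#' Score pipeline output against planted ground truth
#'
#' @param disc discovery report from [runDiscovery()].
#' @param val validation report from [runValidation()] (or `NULL`).
#' @param truth a [GroundTruth-class].
#' @return `data.frame` with one row per metric (`metric`, `value`):
#'   spike-in QC hits, EC precision/recall among the selected candidates,
#'   discovery DE recall and false positives, validation DE recall.
#' @export
scorePipeline <- function(disc, val, truth) {
    stopifnot(is(truth, "GroundTruth"))
    ecs <- disc$ecCandidates
    deIds <- disc$deIds
    metrics <- list(
        qc_excluded_match = as.numeric(setequal(excludedSamples(disc$qc),
                                                truth@outlierSamples)),
        ec_precision = if (length(ecs))
            length(intersect(ecs, truth@stableIds)) / length(ecs) else NA_real_,
        ec_recall = if (length(truth@stableIds))
            length(intersect(ecs, truth@stableIds)) /
                length(truth@stableIds) else NA_real_,
        discovery_de_recall = if (length(truth@deIds))
            length(intersect(deIds, truth@deIds)) /
                length(truth@deIds) else NA_real_,
        discovery_de_false_positives =
            length(setdiff(deIds, truth@deIds)))
    if (!is.null(val)) {
        metrics$validation_de_recall <- if (length(truth@deIds))
            length(intersect(val$validatedIds, truth@deIds)) /
                length(truth@deIds) else NA_real_
        metrics$validation_de_count <- length(val$validatedIds)
    }
    data.frame(metric = names(metrics), value = unlist(metrics),
               row.names = NULL, stringsAsFactors = FALSE)
}
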