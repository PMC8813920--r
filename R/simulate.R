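## Synthetic two-phase cohort generator with known ground truth.
##
## The generative model for a Ct value is
##   Ct_ij = base_i + effect_i * 1[group_j = OSA] + shift_j + eps_ij
## with eps_ij ~ N(0, sd_i), sd_i = stableSD for planted endogenous controls
## and backgroundSD otherwise, and shift_j ~ N(0, sampleShiftSD) a per-sample
## global offset shared by all miRNAs of a sample (RNA input / pipetting).
## Ct is a log2-scale quantity, so additive Gaussian Ct noise corresponds to
## log-normal expression noise. Values above the limit of detection are
## censored to the undetected marker (NA).

#' SimulationConfig: parameters of the synthetic cohort generator
#'
#' Defaults emulate the study geometry the package is designed for: a
#' discovery (TLDA) cohort of 188 circulating miRNAs in 12 + 12 samples
#' (pre-QC) and an RT-qPCR validation cohort of 26 + 38 samples measuring
#' only the differential candidates and the planted endogenous controls.
#'
#' @slot nMirnas number of miRNAs on the discovery panel (default 188).
#' @slot nDiscovery integer(2), discovery samples per group
#'   (non-OSA, OSA; default 12, 12).
#' @slot nValidation integer(2), validation samples per group
#'   (non-OSA, OSA; default 26, 38).
#' @slot nStable number of planted stable (endogenous-control) miRNAs
#'   (default 8).
#' @slot nDE number of planted group-differential miRNAs (default 27).
#' @slot deEffect between-group Ct shift of differential miRNAs, in cycles
#'   (1 Ct = 2-fold expression; default 1.0). Sign is drawn per miRNA.
#' @slot stableSD within-group Ct SD of planted stable miRNAs (default 0.15).
#' @slot backgroundSD within-group Ct SD of all other miRNAs (default 0.8).
#' @slot sampleShiftSD SD of the per-sample global Ct offset (default 0.5).
#' @slot lodCt limit-of-detection Ct; larger values are censored (default 35).
#' @slot censorFraction fraction of background miRNAs whose baseline sits
#'   near the LOD, producing undetected wells (default 0.1).
#' @slot spikeOutlierSamples number of discovery samples given a deviant
#'   spike-in Ct (default 3).
#' @slot spikeOutlierShift Ct shift applied to outlier spike-ins (>= 3 Ct;
#'   default 4).
#' @slot spikeMeanCt,spikeSD mean and SD of the spike-in Ct (defaults 20, 0.1).
#' @slot ageMean,ageSD,bmiMean,bmiSD numeric(2) each (non-OSA, OSA): group
#'   means/SDs of the age (years) and BMI (kg/m^2) covariates.
#' @slot seed integer master seed; a fixed seed makes the output
#'   bit-identical across runs.
#' @aliases SimulationConfig-class
#' @export
setClass("SimulationConfig",
    representation(nMirnas = "integer", nDiscovery = "integer",
                   nValidation = "integer", nStable = "integer",
                   nDE = "integer", deEffect = "numeric", stableSD = "numeric",
                   backgroundSD = "numeric", sampleShiftSD = "numeric",
                   lodCt = "numeric", censorFraction = "numeric",
                   spikeOutlierSamples = "integer",
                   spikeOutlierShift = "numeric", spikeMeanCt = "numeric",
                   spikeSD = "numeric", ageMean = "numeric", ageSD = "numeric",
                   bmiMean = "numeric", bmiSD = "numeric", seed = "integer"),
    prototype(nMirnas = 188L, nDiscovery = c(12L, 12L),
              nValidation = c(26L, 38L), nStable = 8L, nDE = 27L,
              deEffect = 1.0, stableSD = 0.15, backgroundSD = 0.8,
              sampleShiftSD = 0.5, lodCt = 35, censorFraction = 0.1,
              spikeOutlierSamples = 3L, spikeOutlierShift = 4,
              spikeMeanCt = 20, spikeSD = 0.1,
              ageMean = c(47.5, 54.0), ageSD = c(9.3, 6.3),
              bmiMean = c(29.9, 32.0), bmiSD = c(7.0, 5.6), seed = 1L))

setValidity("SimulationConfig", function(object) {
    msg <- character()
    cnt <- c(nMirnas = object@nMirnas, object@nDiscovery, object@nValidation)
    if (any(cnt <= 0L)) msg <- c(msg, "sample and panel counts must be positive")
    if (length(object@nDiscovery) != 2L || length(object@nValidation) != 2L)
        msg <- c(msg, "nDiscovery and nValidation must give (non-OSA, OSA) counts")
    if (object@nStable < 0L || object@nDE < 0L)
        msg <- c(msg, "nStable and nDE must be nonnegative")
    if (object@nStable + object@nDE > object@nMirnas)
        msg <- c(msg, "nStable + nDE must not exceed nMirnas")
    sds <- c(object@stableSD, object@backgroundSD, object@sampleShiftSD,
             object@spikeSD, object@ageSD, object@bmiSD)
    if (any(sds <= 0)) msg <- c(msg, "all SDs must be strictly positive")
    if (object@censorFraction < 0 || object@censorFraction >= 1)
        msg <- c(msg, "censorFraction must be in [0, 1)")
    if (object@lodCt <= 0 || object@lodCt >= 45)
        msg <- c(msg, "lodCt must be in (0, 45)")
    if (object@spikeOutlierSamples < 0L ||
        object@spikeOutlierSamples > object@nDiscovery[2L])
        msg <- c(msg, "spikeOutlierSamples must fit in the discovery OSA group")
    if (object@spikeOutlierShift < 3)
        msg <- c(msg, "spikeOutlierShift must be at least 3 Ct")
    if (length(msg)) msg else TRUE
})

#' Construct a SimulationConfig
#'
#' @param ... named values overriding the defaults documented in
#'   [SimulationConfig-class]; integer-like slots are coerced.
#' @return a validated `SimulationConfig`.
#' @examples
#' SimulationConfig(seed = 7, deEffect = 0)
#' @export
SimulationConfig <- function(...) {
    args <- list(...)
    obj <- new("SimulationConfig")
    intSlots <- c("nMirnas", "nDiscovery", "nValidation", "nStable", "nDE",
                  "spikeOutlierSamples", "seed")
    for (nm in names(args)) {
        if (!nm %in% slotNames(obj))
            stop("unknown SimulationConfig parameter: ", nm)
        val <- args[[nm]]
        if (nm %in% intSlots) val <- as.integer(val)
        slot(obj, nm) <- val
    }
    validObject(obj)
    obj
}

setMethod("show", "SimulationConfig", function(object) {
    cat(sprintf(paste0("SimulationConfig: %d miRNAs; discovery %d+%d, ",
                       "validation %d+%d samples\n"),
                object@nMirnas, object@nDiscovery[1], object@nDiscovery[2],
                object@nValidation[1], object@nValidation[2]))
    cat(sprintf("  planted: %d stable (SD %.2f), %d differential (effect %.2f Ct)\n",
                object@nStable, object@stableSD, object@nDE, object@deEffect))
    cat(sprintf("  seed %d\n", object@seed))
})

#' GroundTruth: the planted structure of a synthetic cohort
#'
#' @slot stableIds ids of planted stable (endogenous-control) miRNAs.
#' @slot deIds ids of planted group-differential miRNAs.
#' @slot deEffects named numeric, signed Ct group effect (OSA minus non-OSA)
#'   for each differential miRNA.
#' @slot sampleShifts named numeric, per-sample global Ct offset.
#' @slot outlierSamples ids of samples given a deviant spike-in.
#' @aliases GroundTruth-class
#' @export
setClass("GroundTruth",
         representation(stableIds = "character", deIds = "character",
                        deEffects = "numeric", sampleShifts = "numeric",
                        outlierSamples = "character"))

setValidity("GroundTruth", function(object) {
    msg <- character()
    if (length(intersect(object@stableIds, object@deIds)))
        msg <- c(msg, "stable and differential id sets must be disjoint")
    if (!setequal(names(object@deEffects), object@deIds))
        msg <- c(msg, "deEffects must be named by deIds")
    if (length(msg)) msg else TRUE
})

setMethod("show", "GroundTruth", function(object) {
    cat(sprintf("GroundTruth: %d stable, %d differential miRNAs; %d spike-in outlier samples\n",
                length(object@stableIds), length(object@deIds),
                length(object@outlierSamples)))
})

#' SimulatedCohort: a two-phase synthetic study with ground truth
#'
#' @slot discovery [CtExperiment-class], full discovery panel.
#' @slot validation [CtExperiment-class], validation panel (planted
#'   differential miRNAs plus planted endogenous controls only).
#' @slot spikeIn named numeric, spike-in Ct for every sample of both phases.
#' @slot groundTruth a [GroundTruth-class].
#' @slot config the [SimulationConfig-class] used.
#' @aliases SimulatedCohort-class
#' @export
setClass("SimulatedCohort",
         representation(discovery = "CtExperiment", validation = "CtExperiment",
                        spikeIn = "numeric", groundTruth = "GroundTruth",
                        config = "SimulationConfig"))

#' @describeIn SimulatedCohort-class the discovery-phase CtExperiment
#' @param x a `SimulatedCohort`.
#' @export
discoveryPhase <- function(x) { stopifnot(is(x, "SimulatedCohort")); x@discovery }

#' @describeIn SimulatedCohort-class the validation-phase CtExperiment
#' @export
validationPhase <- function(x) { stopifnot(is(x, "SimulatedCohort")); x@validation }

#' @describeIn SimulatedCohort-class spike-in Ct vector over all samples
#' @export
spikeIn <- function(x) { stopifnot(is(x, "SimulatedCohort")); x@spikeIn }

#' @describeIn SimulatedCohort-class the planted ground truth
#' @export
groundTruth <- function(x) { stopifnot(is(x, "SimulatedCohort")); x@groundTruth }

setMethod("show", "SimulatedCohort", function(object) {
    cat("SimulatedCohort\n  discovery: ")
    show(object@discovery)
    cat("  validation: ")
    show(object@validation)
    show(object@groundTruth)
})

## run `expr` under the given seed, restoring the caller's RNG state
withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()))
    }
    set.seed(seed)
    force(expr)
}

#' Generate a synthetic two-phase cohort
#'
#' Draws a discovery and a validation Ct matrix, sample metadata (group,
#' age, BMI, phase), per-sample spike-in Ct values, and the ground truth of
#' what was planted. Ct values are generated as
#' `base + group effect + sample shift + noise`; values above the limit of
#' detection are censored to `NA`. A configurable number of discovery OSA
#' samples receive a deviant spike-in (technical failures for the QC stage
#' to catch). The validation matrix carries only the planted differential
#' miRNAs and the planted stable miRNAs, emulating a targeted RT-qPCR panel.
#'
#' @param config a [SimulationConfig-class].
#' @return a [SimulatedCohort-class].
#' @examples
#' sim <- simulateCohort(SimulationConfig(seed = 7))
#' dim(discoveryPhase(sim))
#' @export
simulateCohort <- function(config = SimulationConfig()) {
    validObject(config)
    withSeed(config@seed, .simulateCohort(config))
}

#' Generate a null synthetic cohort (no group effects)
#'
#' Identical to [simulateCohort()] except that all between-group effects are
#' zero and the ground-truth differential set is empty. The validation panel
#' keeps the same genes so every pipeline stage still has input. Intended as
#' a type-I-error harness.
#'
#' @inheritParams simulateCohort
#' @return a [SimulatedCohort-class] with `groundTruth(x)@deIds` empty.
#' @export
simulateNullCohort <- function(config = SimulationConfig()) {
    validObject(config)
    cfg <- config
    cfg@deEffect <- 0
    sim <- withSeed(cfg@seed, .simulateCohort(cfg, nullEffects = TRUE))
    sim
}

.simulateCohort <- function(config, nullEffects = FALSE) {
    nM <- config@nMirnas
    ids <- sprintf("miR-s%03d", seq_len(nM))

    ## role assignment (draw order is fixed; changing it changes the stream)
    roleIds <- sample(ids, config@nStable + config@nDE)
    stableIds <- sort(roleIds[seq_len(config@nStable)])
    deIds <- sort(roleIds[config@nStable + seq_len(config@nDE)])
    otherIds <- setdiff(ids, c(stableIds, deIds))

    ## baselines: stables well above detection, differentials away from the
    ## LOD (they must be measurable in validation), a censorFraction of the
    ## remaining background sits near the LOD
    base <- setNames(numeric(nM), ids)
    base[stableIds] <- runif(length(stableIds), 20, 26)
    base[deIds] <- runif(length(deIds), 18, 29)
    base[otherIds] <- runif(length(otherIds), 18, 30)
    nCensor <- floor(config@censorFraction * nM)
    censorIds <- sample(otherIds, min(nCensor, length(otherIds)))
    base[censorIds] <- runif(length(censorIds), config@lodCt - 1,
                             config@lodCt + 0.5)

    effects <- setNames(rep(0, nM), ids)
    if (length(deIds)) {
        sgn <- sample(c(-1, 1), length(deIds), replace = TRUE)
        effects[deIds] <- sgn * config@deEffect
    }

    sdVec <- setNames(rep(config@backgroundSD, nM), ids)
    sdVec[stableIds] <- config@stableSD

    drawPhase <- function(nGroup, sampleIds, panelIds) {
        group <- rep(c("non-OSA", "OSA"), nGroup)
        shifts <- setNames(rnorm(length(sampleIds), 0, config@sampleShiftSD),
                           sampleIds)
        grpEff <- outer(effects[panelIds], as.numeric(group == "OSA"))
        noise <- matrix(rnorm(length(panelIds) * length(sampleIds),
                              sd = sdVec[panelIds]),
                        nrow = length(panelIds))
        ct <- base[panelIds] + grpEff +
            rep(shifts, each = length(panelIds)) + noise
        dimnames(ct) <- list(panelIds, sampleIds)
        ct[ct > config@lodCt] <- NA_real_
        ct[ct <= 0] <- NA_real_   # physically impossible; treat as undetected
        age <- rnorm(length(sampleIds),
                     config@ageMean[(group == "OSA") + 1L],
                     config@ageSD[(group == "OSA") + 1L])
        bmi <- rnorm(length(sampleIds),
                     config@bmiMean[(group == "OSA") + 1L],
                     config@bmiSD[(group == "OSA") + 1L])
        list(ct = ct, group = group, shifts = shifts,
             age = round(age, 1), bmi = round(bmi, 1))
    }

    discSamples <- sprintf("D%02d", seq_len(sum(config@nDiscovery)))
    disc <- drawPhase(config@nDiscovery, discSamples, ids)

    panelIds <- c(deIds, stableIds)
    valSamples <- sprintf("V%02d", seq_len(sum(config@nValidation)))
    val <- drawPhase(config@nValidation, valSamples, panelIds)

    ## spike-in: near-constant, with planted outliers among discovery OSA
    allSamples <- c(discSamples, valSamples)
    spike <- setNames(rnorm(length(allSamples), config@spikeMeanCt,
                            config@spikeSD), allSamples)
    osaDisc <- discSamples[disc$group == "OSA"]
    outliers <- if (config@spikeOutlierSamples > 0L)
        sort(sample(osaDisc, config@spikeOutlierSamples)) else character()
    spike[outliers] <- spike[outliers] + config@spikeOutlierShift

    mkColData <- function(ph, phase) DataFrame(
        group = ph$group, age = ph$age, bmi = ph$bmi, phase = phase,
        row.names = colnames(ph$ct))

    truth <- new("GroundTruth",
                 stableIds = stableIds,
                 deIds = if (nullEffects) character() else deIds,
                 deEffects = if (nullEffects) setNames(numeric(), character())
                             else effects[deIds],
                 sampleShifts = c(disc$shifts, val$shifts),
                 outlierSamples = outliers)

    new("SimulatedCohort",
        discovery = CtExperiment(disc$ct, mkColData(disc, "discovery")),
        validation = CtExperiment(val$ct, mkColData(val, "validation")),
        spikeIn = spike, groundTruth = truth, config = config)
}

#' Sample metadata of a simulated cohort as one table
#'
#' @param x a [SimulatedCohort-class].
#' @return a `DataFrame` with columns `group`, `age`, `bmi`, `phase` for all
#'   discovery and validation samples.
#' @export
cohortMetadata <- function(x) {
    stopifnot(is(x, "SimulatedCohort"))
    rbind(colData(x@discovery), colData(x@validation))
}
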