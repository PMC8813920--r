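mkDelta <- function(m, cd = NULL) {
    if (is.null(cd))
        cd <- S4Vectors::DataFrame(row.names = colnames(m))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(deltaCt = m), colData = cd)
    new("DeltaCtExperiment", se, referenceScheme = "globalMean")
}

test_that("design matrix: OSA coding, covariate standardization, rank check", {
    meta <- data.frame(group = c("non-OSA", "OSA", "OSA", "non-OSA"),
                       age = c(40, 50, 60, 45), bmi = c(25, 30, 35, 28),
                       row.names = paste0("s", 1:4))
    X <- makeDesign(meta, covariates = c("age", "bmi"))
    expect_identical(colnames(X), c("(Intercept)", "group", "age", "bmi"))
    expect_identical(unname(X[, "group"]), c(0, 1, 1, 0))
    expect_equal(mean(X[, "age"]), 0)
    expect_equal(sd(X[, "age"]), 1)
    meta$dup <- meta$age
    expect_error(makeDesign(meta, covariates = c("age", "age")),
                 "rank deficient")
    expect_error(makeDesign(data.frame(group = rep("OSA", 3))), "two groups")
})

test_that("per-miRNA OLS: exact trivial fits and group-mean identity", {
    m <- rbind(clean = c(0, 0, 0, 1, 1, 1),
               noisy = c(0.1, -0.2, 0.1, 0.9, 1.3, 0.8))
    colnames(m) <- paste0("s", 1:6)
    meta <- data.frame(group = rep(c("non-OSA", "OSA"), each = 3),
                       row.names = colnames(m))
    fit <- fitLinearModels(m, makeDesign(meta))
    expect_equal(fit$coefficients["clean", "group"], 1)
    expect_equal(fit$sigma2[1], 0)
    ## group coefficient == difference of group means (no covariates)
    gm <- function(v) mean(v[4:6]) - mean(v[1:3])
    expect_equal(unname(fit$coefficients[, "group"]),
                 c(gm(m["clean", ]), gm(m["noisy", ])))
    expect_identical(unname(fit$df), c(4, 4))
})

test_that("OLS coefficients match the normal-equations oracle with covariates", {
    set.seed(150)
    meta <- data.frame(group = rep(c("non-OSA", "OSA"), each = 8),
                       age = rnorm(16, 50, 8), bmi = rnorm(16, 30, 4),
                       row.names = paste0("s", 1:16))
    X <- makeDesign(meta, covariates = c("age", "bmi"))
    Y <- matrix(rnorm(20 * 16), 20, 16,
                dimnames = list(paste0("g", 1:20), rownames(meta)))
    Y[3, 5] <- NA   # one miRNA with a missing well: df adjusts
    fit <- fitLinearModels(Y, X)
    for (i in seq_len(20)) {
        obs <- !is.na(Y[i, ])
        ora <- oracleOLS(Y[i, obs], X[obs, , drop = FALSE])
        expect_equal(unname(fit$coefficients[i, ]), unname(ora$coef),
                     tolerance = 1e-10)
        expect_equal(fit$sigma2[i], ora$sigma2, tolerance = 1e-10)
        expect_equal(unname(fit$stdevUnscaled[i, ]),
                     unname(ora$stdevUnscaled), tolerance = 1e-10)
        expect_equal(fit$df[i], ora$df)
    }
    expect_equal(fit$df[3], 11)
})

test_that("moderated t reduces to ordinary t at d0 = 0 and to a common-variance statistic at d0 = Inf", {
    set.seed(160)
    m <- matrix(rnorm(30 * 10), 30, 10,
                dimnames = list(paste0("g", 1:30), paste0("s", 1:10)))
    meta <- data.frame(group = rep(c("non-OSA", "OSA"), each = 5),
                       row.names = colnames(m))
    X <- makeDesign(meta)
    fit <- fitLinearModels(m, X)

    ord <- empiricalBayesModerate(fit, priorDf = 0, priorVar = 1)
    tOrd <- fit$coefficients[, "group"] /
        (sqrt(fit$sigma2) * fit$stdevUnscaled[, "group"])
    expect_equal(ord$t, unname(tOrd), tolerance = 1e-12)
    expect_equal(ord$df.total, rep(8, 30))
    expect_equal(ord$p, unname(2 * pt(-abs(tOrd), 8)), tolerance = 1e-12)

    s02 <- 0.7
    inf <- empiricalBayesModerate(fit, priorDf = Inf, priorVar = s02)
    expect_equal(inf$t, unname(fit$coefficients[, "group"] /
                               (sqrt(s02) * fit$stdevUnscaled[, "group"])),
                 tolerance = 1e-12)
    ## t -> z: normal-tail p-values with common variance
    expect_equal(inf$p, unname(2 * pnorm(-abs(inf$t))), tolerance = 1e-12)
    expect_error(empiricalBayesModerate(fit, priorDf = Inf, priorVar = 0),
                 "positive priorVar")
})

test_that("prior hyperparameters are recovered from scaled-F variances", {
    set.seed(170)
    d0 <- 4; s02 <- 0.25; d <- 10; nG <- 5000
    s2 <- s02 * (rchisq(nG, d) / d) / (rchisq(nG, d0) / d0)
    pr <- estimatePrior(s2, d)
    expect_lt(abs(pr$priorDf / d0 - 1), 0.1)
    expect_lt(abs(pr$priorVar / s02 - 1), 0.1)
})

test_that("moderated pipeline agrees with the established array linear-model toolkit", {
    skip_if_not_installed("limma")
    set.seed(180)
    m <- matrix(rnorm(60 * 12, sd = rep(runif(60, 0.3, 1.5), 12)), 60, 12,
                dimnames = list(paste0("g", 1:60), paste0("s", 1:12)))
    meta <- data.frame(group = rep(c("non-OSA", "OSA"), each = 6),
                       row.names = colnames(m))
    X <- makeDesign(meta)
    fit <- fitLinearModels(m, X)
    mine <- empiricalBayesModerate(fit)

    lf <- limma::lmFit(m, X)
    eb <- limma::eBayes(lf)
    expect_equal(unname(fit$coefficients[, "group"]),
                 unname(lf$coefficients[, "group"]), tolerance = 1e-10)
    expect_equal(unname(fit$sigma2), unname(lf$sigma^2), tolerance = 1e-10)
    expect_equal(attr(mine, "priorDf"), eb$df.prior, tolerance = 1e-6)
    expect_equal(attr(mine, "priorVar"), eb$s2.prior, tolerance = 1e-6)
    expect_equal(mine$t, unname(eb$t[, "group"]), tolerance = 1e-8)
    expect_equal(mine$p, unname(eb$p.value[, "group"]), tolerance = 1e-8)
})

test_that("group-label swap negates effects and preserves p-values", {
    set.seed(190)
    m <- matrix(rnorm(40 * 14), 40, 14,
                dimnames = list(paste0("g", 1:40), paste0("s", 1:14)))
    meta1 <- data.frame(group = rep(c("non-OSA", "OSA"), each = 7),
                        row.names = colnames(m))
    meta2 <- meta1
    meta2$group <- ifelse(meta1$group == "OSA", "non-OSA", "OSA")
    r1 <- runDE(mkDelta(m, S4Vectors::DataFrame(meta1)))
    r2 <- runDE(mkDelta(m, S4Vectors::DataFrame(meta2)))
    expect_equal(r1$logFC, -r2$logFC, tolerance = 1e-10)
    expect_equal(r1$t, -r2$t, tolerance = 1e-10)
    expect_equal(r1$p, r2$p, tolerance = 1e-10)

    ## per-sample constants on the raw Ct scale are removed by mean
    ## centring, so the downstream p-values are unchanged
    raw <- m + 25
    rawShift <- sweep(raw, 2, rnorm(14, 0, 2), "+")
    pA <- runDE(meanCentreNormalize(CtExperiment(
        raw, S4Vectors::DataFrame(meta1))))$p
    pB <- runDE(meanCentreNormalize(CtExperiment(
        rawShift, S4Vectors::DataFrame(meta1))))$p
    expect_equal(pA, pB, tolerance = 1e-10)

    ## covariates orthogonal to group leave the group coefficient unchanged
    m4 <- matrix(rnorm(20 * 16), 20, 16,
                 dimnames = list(paste0("h", 1:20), paste0("t", 1:16)))
    meta4 <- data.frame(group = rep(c("non-OSA", "OSA"), each = 8),
                        age = rep(c(-1, 1), 8),   # balanced within groups
                        row.names = colnames(m4))
    f0 <- fitLinearModels(m4, makeDesign(meta4))
    f1 <- fitLinearModels(m4, makeDesign(meta4, covariates = "age"))
    expect_equal(f0$coefficients[, "group"], f1$coefficients[, "group"],
                 tolerance = 1e-10)
})

test_that("selection at the threshold is strict and the volcano table is a faithful transform", {
    res <- data.frame(id = c("a", "b", "c"), logFC = c(1, -2, 0.5),
                      p = c(0.025, 0.024, 1))
    expect_identical(selectDE(res, 0.025), "b")
    expect_identical(selectDE(res[0, ], 0.025), character())
    expect_error(selectDE(res, 0), "in \\(0, 1\\)")

    v <- volcanoTable(res, threshold = 0.025)
    expect_identical(nrow(v), 3L)
    expect_equal(v$negLog10P[3], 0)
    expect_identical(v$significant, c(FALSE, TRUE, FALSE))
    expect_equal(v$log2FC, res$logFC)
})

test_that("power to detect planted effects grows with effect size", {
    recovery <- vapply(c(0.3, 1.0, 2.0), function(eff) {
        hits <- 0; total <- 0
        for (s in 1:3) {
            sim <- simulateCohort(SimulationConfig(seed = 300 + s,
                                                   deEffect = eff))
            disc <- discoveryPhase(sim)
            qc <- spikeInQC(spikeIn(sim)[colnames(disc)])
            disc <- disc[, setdiff(colnames(disc), excludedSamples(qc))]
            det <- detectionFilter(disc, 32)
            res <- runDE(meanCentreNormalize(disc)[det, ])
            gt <- groundTruth(sim)
            hits <- hits + length(intersect(selectDE(res), gt@deIds))
            total <- total + length(intersect(gt@deIds, det))
        }
        hits / total
    }, numeric(1))
    expect_true(recovery[1] < recovery[2])
    expect_true(recovery[2] <= recovery[3] + 0.05)
    expect_gt(recovery[3], 0.9)
})
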