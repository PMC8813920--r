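test_that("rankBySD orders by across-sample SD with deterministic ties", {
    m <- rbind(tight = c(0.1, -0.1, 0.05, -0.05),
               loose = c(1, -1, 0.5, -0.5),
               flatB = c(0.2, 0.2, 0.2, 0.2),
               flatA = c(0.3, 0.3, 0.3, 0.3))
    colnames(m) <- paste0("s", 1:4)
    nx <- new("DeltaCtExperiment",
              SummarizedExperiment::SummarizedExperiment(
                  assays = list(deltaCt = m)),
              referenceScheme = "globalMean")
    top1 <- rankBySD(nx, k = 1)
    expect_identical(top1$id, "flatA")      # SD 0 wins; tie broken by id
    expect_identical(top1$sd, 0)
    all4 <- rankBySD(nx, k = 4)
    expect_identical(all4$id, c("flatA", "flatB", "tight", "loose"))
    expect_error(rankBySD(nx, k = 0), "positive")
    expect_error(rankBySD(nx, k = 5), "exceeds")
})

test_that("Lin's concordance matches the defining formula and conventions", {
    expect_identical(concordanceCorrelation(c(1, 2, 3), c(1, 2, 3)), 1)
    ## anti-parallel with equal mean and variance: perfect disagreement
    expect_equal(concordanceCorrelation(c(1, 2, 3), c(3, 2, 1)), -1)
    expect_equal(concordanceCorrelation(c(1, 2, 3), c(3, 2, 1)),
                 oracleCCC(c(1, 2, 3), c(3, 2, 1)))
    ## hand-computed from the formula: cov = 2/3, var = 2/3 each, shift 1
    ## => 2*(2/3) / (2/3 + 2/3 + 1) = 4/7
    expect_equal(concordanceCorrelation(c(1, 2, 3), c(2, 3, 4)), 4 / 7)
    expect_equal(concordanceCorrelation(c(1, 2, 3), c(2, 3, 4)),
                 oracleCCC(c(1, 2, 3), c(2, 3, 4)))
    ## degenerate conventions
    expect_identical(concordanceCorrelation(c(2, 2, 2), c(2, 2, 2)), 1)
    expect_identical(concordanceCorrelation(c(2, 2, 2), c(3, 3, 3)), 0)
    expect_identical(concordanceCorrelation(c(2, 2, 2), c(1, 2, 3)), 0)
    expect_error(concordanceCorrelation(1:2, 1:2), "at least 3")
    expect_error(concordanceCorrelation(1:3, 1:4), "equal length")
    expect_error(concordanceCorrelation(c(1, NA, 3), c(1, 2, 3)), "finite")
})

test_that("|CCC| never exceeds |Pearson r| (1000 random pairs)", {
    set.seed(404)
    for (i in 1:1000) {
        n <- sample(3:20, 1)
        x <- rnorm(n, sample(-5:5, 1), runif(1, 0.5, 3))
        y <- rnorm(n, sample(-5:5, 1), runif(1, 0.5, 3))
        cc <- concordanceCorrelation(x, y)
        expect_lte(abs(cc), abs(cor(x, y)) + 1e-12)
        expect_lte(abs(cc), 1 + 1e-12)
    }
})

test_that("CCR selection scores fully detected miRNAs against the global mean", {
    ## construct b + c = 2a so that the global mean over {a,b,c} equals a
    sA <- c(20, 21, 22, 21.5)
    sB <- sA + c(1, -1, 2, 0.5)
    sC <- 2 * sA - sB
    ct <- rbind(a = sA, b = sB, c = sC)
    colnames(ct) <- paste0("s", 1:4)
    out <- ccrSelect(CtExperiment(ct), k = 3)
    expect_identical(out$id[1], "a")
    expect_equal(out$ccc[1], 1)
    expect_identical(nrow(out), 3L)      # k = |fully detected|: all returned

    expect_error(ccrSelect(CtExperiment(ct), k = 4), "exceeds")
    ## an undetected well removes the miRNA from the eligible pool entirely
    ctNA <- ct; ctNA["b", 1] <- NA
    out2 <- ccrSelect(CtExperiment(ctNA), k = 2)
    expect_identical(nrow(out2), 2L)
    expect_false("b" %in% out2$id)
})

test_that("selection invariances: sample shifts for MC+SD, gene offsets only for MC+SD", {
    set.seed(71)
    ct <- randomCtMatrix(12, 8, sd = 1.5)
    shifts <- rnorm(8, 0, 2)
    ctShift <- sweep(ct, 2, shifts, "+")

    ## MC+SD is exactly invariant to per-sample constant shifts (the mean
    ## centring removes them); scores, not just ids, are preserved
    n1 <- meanCentreNormalize(CtExperiment(ct))
    n2 <- meanCentreNormalize(CtExperiment(ctShift))
    expect_identical(rankBySD(n1, k = 12)$id, rankBySD(n2, k = 12)$id)
    expect_equal(rankBySD(n1, k = 12)$sd, rankBySD(n2, k = 12)$sd,
                 tolerance = 1e-10)
    ## CCR scores genes against a reference that shifts with the samples,
    ## and Lin's coefficient is a function of the joint moments, not of the
    ## differences alone - so its scores respond to sample shifts
    expect_false(isTRUE(all.equal(ccrSelect(CtExperiment(ct), k = 5)$ccc,
                                  ccrSelect(CtExperiment(ctShift), k = 5)$ccc)))

    ## per-gene offsets: MC+SD invariant, CCR not (location penalty)
    offs <- seq(-4, 4, length.out = 12)
    ctOff <- ct + offs
    n3 <- meanCentreNormalize(CtExperiment(ctOff))
    expect_identical(rankBySD(n1, k = 12)$id, rankBySD(n3, k = 12)$id)
    expect_false(identical(ccrSelect(CtExperiment(ct), k = 12)$id,
                           ccrSelect(CtExperiment(ctOff), k = 12)$id))
})

test_that("candidate merging unions the lists and keeps both method tags", {
    mk <- function(ids, col) data.frame(id = ids, rank = seq_along(ids),
        sd = seq_along(ids) / 10, ccc = 1 - seq_along(ids) / 10)
    m <- mk(c("A", "B"))[, c("id", "rank", "sd")]
    c1 <- mk(c("B", "C"))[, c("id", "rank", "ccc")]
    cs <- mergeCandidates(m, c1)
    tab <- candidateTable(cs)
    expect_setequal(candidateIds(cs), c("A", "B", "C"))
    expect_identical(tab$method[tab$id == "A"], "MC+SD")
    expect_identical(tab$method[tab$id == "B"], "CCR and MC+SD")
    expect_identical(tab$method[tab$id == "C"], "CCR")

    ## union cardinality: k1 + k2 - |intersection|
    ids <- sprintf("m%02d", 1:15)
    mcsd <- data.frame(id = ids[1:10], rank = 1:10, sd = (1:10) / 10)
    ccr5 <- data.frame(id = ids[6:15], rank = 1:10, ccc = (10:1) / 10)
    expect_length(candidateIds(mergeCandidates(mcsd, ccr5)), 15L)
    disjoint <- data.frame(id = sprintf("x%02d", 1:10), rank = 1:10,
                           ccc = (10:1) / 10)
    expect_length(candidateIds(mergeCandidates(mcsd, disjoint)), 20L)
})

test_that("synthetic cohort: MC+SD finds the planted stables, lists overlap", {
    sim <- simulateCohort(SimulationConfig(seed = 31))
    disc <- discoveryPhase(sim)
    gt <- groundTruth(sim)
    det <- detectionFilter(disc, 32)
    nx <- meanCentreNormalize(disc)
    mcsd <- rankBySD(nx, eligible = det, k = 10)
    expect_true(all(gt@stableIds %in% mcsd$id))
    ccr <- ccrSelect(disc, k = 10)
    merged <- mergeCandidates(mcsd, ccr)
    expect_lte(length(candidateIds(merged)), 20L)
    expect_gte(length(candidateIds(merged)), 10L)
})
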