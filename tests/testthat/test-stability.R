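test_that("geNorm M: parallel genes are maximally stable, identical rows give M = 0", {
    ct <- rbind(g1 = c(10, 11, 12), g2 = c(20, 21, 22),
                g3 = c(15, 19, 13))
    colnames(ct) <- paste0("s", 1:3)
    M <- geNormM(ct)
    ## V(g1, g2) = 0, so g1 and g2 share the minimal M
    expect_equal(M[["g1"]], M[["g2"]])
    expect_lt(M[["g1"]], M[["g3"]])

    same <- matrix(rep(c(20, 22, 21, 23), each = 4), 4, 4, byrow = FALSE,
                   dimnames = list(paste0("g", 1:4), paste0("s", 1:4)))
    expect_equal(unname(geNormM(same)), rep(0, 4))

    expect_error(geNormM(ct[1:2, ]), "at least 3")
    ctNA <- ct; ctNA[1, 1] <- NA
    expect_error(geNormM(ctNA), "undetected")
})

test_that("geNorm matches the brute-force pairwise-SD oracle on random instances", {
    set.seed(202)
    for (rep in 1:25) {
        k <- sample(3:8, 1); n <- sample(4:12, 1)
        ct <- randomCtMatrix(k, n, sd = runif(1, 0.3, 2))
        expect_equal(geNormM(ct), oracleGeNormM(ct), tolerance = 1e-12)
        gr <- geNormRank(ct)
        V <- geNormPairwiseVariation(ct, gr$stabilityOrder)
        expect_equal(unname(V), oracleGeNormV(ct, gr$stabilityOrder),
                     tolerance = 1e-12)
        expect_length(V, k - 2)
        expect_true(all(V >= 0))
    }
})

test_that("geNorm iterative exclusion removes the noisiest gene first", {
    set.seed(7)
    ct <- rbind(a = c(10, 11, 12, 11.5, 10.5),
                b = c(20, 21, 22, 21.5, 20.5),
                noisy = c(15, 25, 10, 30, 12))
    colnames(ct) <- paste0("s", 1:5)
    gr <- geNormRank(ct)
    expect_identical(gr$exclusionOrder[1], "noisy")
    expect_setequal(gr$finalPair, c("a", "b"))
    expect_equal(unname(gr$ranks[c("a", "b")]), c(1.5, 1.5))
    expect_equal(gr$ranks[["noisy"]], 3)
})

test_that("geNorm is invariant to per-sample shifts and per-gene offsets", {
    set.seed(55)
    ct <- randomCtMatrix(6, 10)
    shifted <- sweep(ct, 2, rnorm(10, 0, 3), "+") + seq(0, 5, length.out = 6)
    expect_equal(geNormM(ct), geNormM(shifted), tolerance = 1e-10)
    expect_identical(geNormRank(ct)$exclusionOrder,
                     geNormRank(shifted)$exclusionOrder)
})

test_that("pairwise variation flags redundancy when duplicating the most stable gene", {
    set.seed(77)
    ct <- randomCtMatrix(5, 10)
    gr <- geNormRank(ct)
    best <- gr$stabilityOrder[1]
    dup <- rbind(ct, dupbest = ct[best, ])
    rownames(dup)[6] <- "zz-dup"
    gr2 <- geNormRank(dup)
    ## the duplicate pair is perfectly stable: it becomes the final pair
    expect_setequal(gr2$finalPair, c(best, "zz-dup"))
    V2 <- geNormPairwiseVariation(dup, gr2$stabilityOrder)
    expect_equal(unname(V2), oracleGeNormV(dup, gr2$stabilityOrder),
                 tolerance = 1e-12)
})

test_that("NormFinder: a constant gene is the most stable; single-group mode ranks by residual SD", {
    set.seed(91)
    ct <- rbind(flat = rep(21, 12), randomCtMatrix(4, 12, sd = 1))
    rownames(ct)[1] <- "flat"
    groups <- rep(c("A", "B"), each = 6)
    nf <- normFinder(ct, groups)
    expect_identical(names(which.min(nf$stability)), "flat")

    ## single group, no sample effects: stability order == residual SD order
    sds <- c(0.5, 0.7, 1, 1.4, 2, 2.8)
    ctA <- 24 + matrix(rnorm(6 * 30, sd = rep(sds, 30)), 6, 30,
                       dimnames = list(paste0("g", 1:6), paste0("s", 1:30)))
    nf1 <- normFinder(ctA, groups = NULL)
    expect_true(all(nf1$intraVar > 0))
    ## residuals after removing gene and sample effects, as the model does
    z <- sweep(ctA - rowMeans(ctA), 2, colMeans(ctA - rowMeans(ctA)), "-")
    expect_identical(order(nf1$stability), order(rowSums(z^2)))
})

test_that("NormFinder stability is exchangeable under group-label permutations", {
    set.seed(101)
    ct <- randomCtMatrix(6, 20, sd = 0.8)
    groups <- rep(c("A", "B"), each = 10)
    base <- normFinder(ct, groups)$stability
    ## no true group effects: permuting labels must not shift stability
    ## systematically
    perms <- replicate(30, {
        g <- sample(groups)
        normFinder(ct, g)$stability
    })
    for (i in seq_len(nrow(ct))) {
        center <- median(perms[i, ])
        spread <- mad(perms[i, ]) + 1e-3
        expect_lt(abs(base[i] - center) / spread, 5)
    }
})

test_that("Kendall concordance: limits, exact enumeration, cor.test agreement", {
    r <- setNames(1:8, letters[1:8])
    expect_equal(rankConcordance(r, r)$tau, 1)
    expect_equal(rankConcordance(r, setNames(8:1, letters[1:8]))$tau, -1)

    ## n = 4: exact p equals brute-force enumeration over all 24 permutations
    set.seed(12)
    for (rep in 1:10) {
        a <- setNames(sample(4), letters[1:4])
        b <- setNames(sample(4), letters[1:4])
        got <- rankConcordance(a, b)
        ora <- oracleKendall(a[letters[1:4]], b[letters[1:4]])
        expect_identical(got$method, "exact")
        expect_equal(got$tau, ora$tau, tolerance = 1e-12)
        expect_equal(got$p, ora$p, tolerance = 1e-12)
    }

    ## antisymmetry under ranking reversal; bounds
    set.seed(13)
    for (rep in 1:20) {
        n <- sample(4:12, 1)
        a <- setNames(sample(n), paste0("i", 1:n))
        b <- setNames(sample(n), paste0("i", 1:n))
        t1 <- rankConcordance(a, b)$tau
        t2 <- rankConcordance(a, setNames((n + 1) - b, names(b)))$tau
        expect_equal(t1, -t2, tolerance = 1e-12)
        expect_lte(abs(t1), 1)
        ## tau agrees with stats::cor's tie-corrected tau
        expect_equal(t1, cor(a[names(b)], b, method = "kendall"),
                     tolerance = 1e-12)
    }

    ## ties (the geNorm final pair) are handled via tau-b
    a <- setNames(c(1.5, 1.5, 3, 4, 5), letters[1:5])
    b <- setNames(c(2, 1, 3, 5, 4), letters[1:5])
    got <- rankConcordance(a, b)
    expect_identical(got$method, "normal")
    expect_equal(got$tau, cor(a, b, method = "kendall"), tolerance = 1e-12)

    expect_error(rankConcordance(r, setNames(1:8, LETTERS[1:8])), "same id")
})

test_that("stability report fuses rankings and selects top ECs deterministically", {
    set.seed(121)
    ## graded stability: noise SDs from tight to loose
    sds <- c(0.05, 0.1, 0.2, 0.5, 0.9, 1.4)
    ct <- 24 + matrix(rnorm(6 * 16, sd = rep(sds, 16)), 6, 16,
                      dimnames = list(paste0("g", 1:6), paste0("s", 1:16)))
    shifts <- rnorm(16, 0, 1)
    ct <- sweep(ct, 2, shifts, "+")
    rep1 <- stabilityReport(ct, groups = rep(c("A", "B"), each = 8))
    tab <- stabilityTable(rep1)
    expect_setequal(as.character(tab$id), paste0("g", 1:6))
    expect_true(all(tab$genormM >= 0))
    expect_true(is.numeric(pairwiseVariation(rep1)))
    expect_length(pairwiseVariation(rep1), 4L)
    conc <- rankingConcordance(rep1)
    expect_true(abs(conc$tau) <= 1)

    top3 <- selectTopStable(rep1, 3)
    expect_length(top3, 3L)
    expect_true(all(top3 %in% paste0("g", 1:3)))  # clearly graded design
    expect_error(selectTopStable(rep1, 0), "positive")
    expect_error(selectTopStable(rep1, 7), "exceeds")

    ## both methods agreeing => combined rank = that ordering
    expect_identical(selectTopStable(rep1, 6)[1:2],
                     as.character(tab$id[order(tab$normfinderRank)])[1:2])
})
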