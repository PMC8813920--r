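## Reference-gene stability analysis.
##
## geNorm works on pairwise Ct differences: for genes j, k the vector
## Ct_k - Ct_j across samples is an exact log2 expression ratio, its SD
## (denominator n - 1) is the pairwise variation V_jk, and the M-value of
## gene j is the mean of V_jk over all partners k. The least stable gene
## (highest M) is excluded iteratively until two remain; geNorm cannot
## order the final pair, which is reported tied at rank 1.5.
##
## NormFinder fits a two-way model per group on the Ct (log) scale,
## y_igj = mu_i + beta_gj + eps_igj (gene i, group g, sample j), estimating
## a per-gene, per-group intragroup variance and a shrunken intergroup
## offset; the stability value combines both (lower = more stable).

.checkCandidateMatrix <- function(ct, minGenes = 3L) {
    ct <- as.matrix(ct)
    if (nrow(ct) < minGenes)
        stop("need at least ", minGenes, " candidate genes")
    if (anyNA(ct))
        stop("candidate matrix must have no undetected cells")
    if (is.null(rownames(ct)) || anyDuplicated(rownames(ct)))
        stop("candidate matrix needs unique rownames")
    ct
}

#' geNorm M-values
#'
#' For each candidate gene, the mean over all partner genes of the
#' standard deviation (across samples, denominator n - 1) of the pairwise
#' Ct difference. Lower M means more stable. Invariant to per-sample
#' constant Ct shifts and to per-gene constant offsets.
#'
#' @param ct numeric matrix, candidate genes x samples, no `NA`; or a
#'   [CtExperiment-class] restricted to the candidates.
#' @return named numeric vector of M-values.
#' @export
geNormM <- function(ct) {
    if (is(ct, "CtExperiment")) ct <- ctValues(ct)
    ct <- .checkCandidateMatrix(ct)
    k <- nrow(ct)
    M <- setNames(numeric(k), rownames(ct))
    for (j in seq_len(k)) {
        v <- vapply(seq_len(k)[-j],
                    function(l) sd(ct[l, ] - ct[j, ]), numeric(1))
        M[j] <- mean(v)
    }
    M
}

#' geNorm iterative ranking
#'
#' Repeatedly recomputes M on the surviving candidates and removes the gene
#' with the highest M until two remain. Ties in the maximum M are broken by
#' removing the lexicographically first of the tied ids. The final pair is
#' unordered and shares rank 1.5.
#'
#' @inheritParams geNormM
#' @return a list: `exclusionOrder` (ids, 1 = first excluded = least
#'   stable), `ranks` (named numeric stability ranks, final pair = 1.5),
#'   `stabilityOrder` (ids, most stable first; the tied final pair in
#'   lexicographic order), `finalPair`.
#' @export
geNormRank <- function(ct) {
    if (is(ct, "CtExperiment")) ct <- ctValues(ct)
    ct <- .checkCandidateMatrix(ct)
    surviving <- rownames(ct)
    excluded <- character()
    while (length(surviving) > 2L) {
        M <- geNormM(ct[surviving, , drop = FALSE])
        worst <- sort(names(M)[M == max(M)])[1L]
        excluded <- c(excluded, worst)
        surviving <- setdiff(surviving, worst)
    }
    finalPair <- sort(surviving)
    ranks <- setNames(numeric(nrow(ct)), rownames(ct))
    ranks[finalPair] <- 1.5
    nEx <- length(excluded)
    if (nEx) ranks[excluded] <- 2L + rev(seq_len(nEx))
    list(exclusionOrder = excluded,
         ranks = ranks,
         stabilityOrder = c(finalPair, rev(excluded)),
         finalPair = finalPair)
}

#' geNorm pairwise variation V(n, n+1)
#'
#' The normalization factor built from the n most stable genes is, per
#' sample, the arithmetic mean of their Ct values (the geometric mean of
#' expression on the log2 scale). `V(n, n+1)` is the SD across samples of
#' the difference between the n-gene and the (n+1)-gene factor; a small
#' value means adding the (n+1)-th gene barely changes the normalization.
#'
#' @inheritParams geNormM
#' @param stabilityOrder ids ordered most stable first, e.g.
#'   `geNormRank(ct)$stabilityOrder`; computed if `NULL`.
#' @return named numeric vector `V2.3, V3.4, ...` of length
#'   `nrow(ct) - 2`.
#' @export
geNormPairwiseVariation <- function(ct, stabilityOrder = NULL) {
    if (is(ct, "CtExperiment")) ct <- ctValues(ct)
    ct <- .checkCandidateMatrix(ct)
    if (is.null(stabilityOrder))
        stabilityOrder <- geNormRank(ct)$stabilityOrder
    if (!setequal(stabilityOrder, rownames(ct)))
        stop("stabilityOrder must be a permutation of the candidate ids")
    k <- length(stabilityOrder)
    V <- setNames(numeric(k - 2L),
                  sprintf("V%d.%d", 2:(k - 1L), 3:k))
    for (n in 2:(k - 1L)) {
        nfN <- colMeans(ct[stabilityOrder[seq_len(n)], , drop = FALSE])
        nfN1 <- colMeans(ct[stabilityOrder[seq_len(n + 1L)], , drop = FALSE])
        V[n - 1L] <- sd(nfN - nfN1)
    }
    V
}

#' NormFinder stability values
#'
#' Variance-decomposition stability model on the Ct (log2) scale. Within
#' each group the model `y_igj = mu_ig + beta_gj + eps_igj` is fitted by
#' double centering; the intragroup variance of gene i in group g is
#' estimated from the residual sums of squares with the k/(k - 2)
#' gene-count correction (k genes),
#' `sigma2_ig = (u_ig - sum(u_g)/(k (k - 1))) * k / (k - 2)`,
#' `u_ig = RSS_ig / (n_g - 1)`, truncated at zero. The intergroup offset is
#' `d_ig = ybar_ig. - ybar_i.. - (ybar_.g. - ybar_...)` (grand means
#' weighted by group size) and is shrunk toward zero by the empirical-Bayes
#' factor `gamma2 / (gamma2 + sigma2_ig / n_g)`, where `gamma2` is a
#' method-of-moments estimate of the variance of the true offsets. The
#' stability value of gene i is the mean over groups of
#' `|d_shrunk_ig| + sqrt(sigma2_ig / n_g)` - intergroup variation plus the
#' sampling uncertainty of the gene's intragroup level; lower = more
#' stable. With a single group the stability value is the intragroup SD
#' itself.
#'
#' @param ct numeric matrix (genes x samples, no `NA`, >= 3 genes) or a
#'   [CtExperiment-class]; if the latter and `groups` is `NULL`, the
#'   `colData` column `group` is used when present.
#' @param groups factor/character of length `ncol(ct)`, or `NULL` for
#'   single-group (group-blind) mode.
#' @return a list: `stability` (named numeric, lower = more stable),
#'   `intraVar` (genes x groups matrix of intragroup variance estimates),
#'   `dHat` and `dShrunk` (genes x groups intergroup offsets, raw and
#'   shrunken; all zero in single-group mode), `gamma2`.
#' @export
normFinder <- function(ct, groups = NULL) {
    if (is(ct, "CtExperiment")) {
        if (is.null(groups) && "group" %in% colnames(colData(ct)))
            groups <- colData(ct)$group
        ct <- ctValues(ct)
    }
    ct <- .checkCandidateMatrix(ct)
    k <- nrow(ct)
    if (is.null(groups)) groups <- rep("all", ncol(ct))
    groups <- factor(groups)
    if (length(groups) != ncol(ct))
        stop("groups must have one entry per sample")
    if (any(table(groups) < 2L))
        stop("need at least 2 samples per group")
    G <- nlevels(groups)
    ng <- as.vector(table(groups))

    intraVar <- matrix(NA_real_, k, G, dimnames = list(rownames(ct),
                                                       levels(groups)))
    groupMeans <- matrix(NA_real_, k, G)
    for (g in seq_len(G)) {
        y <- ct[, groups == levels(groups)[g], drop = FALSE]
        n <- ncol(y)
        z <- y - rowMeans(y)
        z <- sweep(z, 2L, colMeans(z), "-")     # double-centered residuals
        u <- rowSums(z^2) / (n - 1L)
        s2 <- (u - sum(u) / (k * (k - 1L))) * k / (k - 2L)
        intraVar[, g] <- pmax(s2, 0)
        groupMeans[, g] <- rowMeans(y)
    }

    if (G == 1L) {
        stab <- sqrt(intraVar[, 1L])
        zeros <- matrix(0, k, 1L, dimnames = dimnames(intraVar))
        return(list(stability = setNames(stab, rownames(ct)),
                    intraVar = intraVar, dHat = zeros, dShrunk = zeros,
                    gamma2 = 0))
    }

    w <- ng / sum(ng)
    geneGrand <- as.vector(groupMeans %*% w)        # ybar_i.. (weighted)
    groupGrand <- colMeans(groupMeans)              # ybar_.g.
    grand <- sum(groupGrand * w)                    # ybar_...
    dHat <- sweep(sweep(groupMeans, 1L, geneGrand, "-"),
                  2L, groupGrand - grand, "-")
    dimnames(dHat) <- dimnames(intraVar)

    varD <- sweep(intraVar, 2L, ng, "/")            # sampling var of dHat
    gamma2 <- max(sum(dHat^2) / ((k - 1L) * (G - 1L)) - mean(varD), 0)
    shrink <- gamma2 / (gamma2 + varD)
    shrink[varD == 0 & gamma2 == 0] <- 0
    dShrunk <- dHat * shrink
    stab <- rowMeans(abs(dShrunk) + sqrt(varD))

    list(stability = setNames(stab, rownames(ct)), intraVar = intraVar,
         dHat = dHat, dShrunk = dShrunk, gamma2 = gamma2)
}

## Kendall tau-b with exact small-sample p-value ------------------------------

.kendallExactP <- function(S, n) {
    ## distribution of S = concordant - discordant over the n! permutations,
    ## via the inversion-number convolution recurrence
    counts <- 1
    for (m in 2:n) {
        new <- numeric(length(counts) + m - 1L)
        for (i in seq_along(counts))
            new[i:(i + m - 1L)] <- new[i:(i + m - 1L)] + counts[i]
        counts <- new
    }
    ## counts[i] = #permutations with (i-1) inversions; S = n0 - 2*inv
    n0 <- n * (n - 1L) / 2L
    inv <- 0:(length(counts) - 1L)
    svals <- n0 - 2L * inv
    tot <- sum(counts)
    pGE <- sum(counts[svals >= S]) / tot
    pLE <- sum(counts[svals <= S]) / tot
    min(1, 2 * min(pGE, pLE))
}

#' Kendall rank concordance between two rankings
#'
#' Kendall's tau-b (tie-corrected) between two rankings of the same items,
#' with an exact two-sided p-value by enumeration of the inversion-number
#' distribution for n <= 10 without ties, and the tie-corrected normal
#' approximation otherwise.
#'
#' @param rankA,rankB named numeric rank vectors over the same id set
#'   (ties allowed, e.g. the geNorm final pair at 1.5).
#' @return a list: `tau`, `p`, `method` (`"exact"` or `"normal"`).
#' @export
rankConcordance <- function(rankA, rankB) {
    if (is.null(names(rankA)) || is.null(names(rankB)))
        stop("rank vectors must be named by item id")
    if (!setequal(names(rankA), names(rankB)))
        stop("the two rankings must cover the same id set")
    a <- rankA[sort(names(rankA))]
    b <- rankB[names(a)]
    n <- length(a)
    if (n < 2L) stop("need at least 2 items")

    C <- 0L; D <- 0L
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        s <- sign(a[j] - a[i]) * sign(b[j] - b[i])
        if (s > 0) C <- C + 1L else if (s < 0) D <- D + 1L
    }
    n0 <- n * (n - 1) / 2
    tiesOf <- function(v) { t <- table(v); t[t > 1L] }
    ta <- tiesOf(a); tb <- tiesOf(b)
    n1 <- sum(ta * (ta - 1) / 2); n2 <- sum(tb * (tb - 1) / 2)
    S <- C - D
    tau <- S / sqrt((n0 - n1) * (n0 - n2))

    if (n <= 10L && n1 == 0 && n2 == 0) {
        p <- .kendallExactP(S, n)
        method <- "exact"
    } else {
        v0 <- n * (n - 1) * (2 * n + 5)
        vt <- sum(ta * (ta - 1) * (2 * ta + 5))
        vu <- sum(tb * (tb - 1) * (2 * tb + 5))
        v1 <- sum(ta * (ta - 1)) * sum(tb * (tb - 1)) / (2 * n * (n - 1))
        v2 <- sum(ta * (ta - 1) * (ta - 2)) * sum(tb * (tb - 1) * (tb - 2)) /
            (9 * n * (n - 1) * (n - 2))
        varS <- (v0 - vt - vu) / 18 + v1 + v2
        z <- if (varS > 0) S / sqrt(varS) else 0
        p <- 2 * pnorm(-abs(z))
        method <- "normal"
    }
    list(tau = unname(tau), p = p, method = method)
}

## Report assembly ------------------------------------------------------------

#' Full stability assessment of a candidate set
#'
#' Runs geNorm (M-values, iterative exclusion ranking, pairwise variation)
#' and NormFinder on the candidate Ct matrix, fuses the two rankings into a
#' combined rank, and reports their Kendall concordance.
#'
#' @param ct candidate Ct matrix (genes x samples, no `NA`) or a
#'   [CtExperiment-class] restricted to the candidates.
#' @param groups group labels for NormFinder; `NULL` runs NormFinder
#'   group-blind. When `ct` is a `CtExperiment` with a `group` column the
#'   labels are taken from `colData` by default.
#' @param fusion rank-fusion rule for the combined rank: `"mean"`
#'   (arithmetic mean of the geNorm and NormFinder ranks, default),
#'   `"genorm"`, or `"normfinder"`.
#' @return a [StabilityReport-class].
#' @export
stabilityReport <- function(ct, groups = NULL,
                            fusion = c("mean", "genorm", "normfinder")) {
    fusion <- match.arg(fusion)
    if (is(ct, "CtExperiment")) {
        if (is.null(groups) && "group" %in% colnames(colData(ct)))
            groups <- colData(ct)$group
        ct <- ctValues(ct)
    }
    ct <- .checkCandidateMatrix(ct)
    M <- geNormM(ct)
    gr <- geNormRank(ct)
    V <- geNormPairwiseVariation(ct, gr$stabilityOrder)
    nf <- normFinder(ct, groups)
    nfRank <- rank(nf$stability, ties.method = "average")
    ids <- rownames(ct)
    combined <- switch(fusion,
        mean = (gr$ranks[ids] + nfRank[ids]) / 2,
        genorm = gr$ranks[ids],
        normfinder = nfRank[ids])
    conc <- rankConcordance(gr$ranks, nfRank)
    exclOrder <- setNames(rep(NA_real_, length(ids)), ids)
    exclOrder[gr$exclusionOrder] <- seq_along(gr$exclusionOrder)
    tab <- DataFrame(id = ids, genormM = unname(M[ids]),
                     genormRank = unname(gr$ranks[ids]),
                     exclusionOrder = unname(exclOrder[ids]),
                     normfinderStability = unname(nf$stability[ids]),
                     normfinderRank = unname(nfRank[ids]),
                     combinedRank = unname(combined))
    new("StabilityReport", table = tab, pairwiseVariation = V,
        concordance = conc[c("tau", "p")], fusion = fusion)
}

#' Select the most stable endogenous controls
#'
#' Orders candidates by combined rank (ascending); ties are broken by the
#' better NormFinder rank, then lexicographically by id.
#'
#' @param report a [StabilityReport-class].
#' @param n how many ECs to return (must be positive and at most the
#'   candidate count).
#' @return character vector of ids, most stable first.
#' @export
selectTopStable <- function(report, n) {
    stopifnot(is(report, "StabilityReport"))
    tab <- report@table
    if (n <= 0) stop("n must be positive")
    if (n > nrow(tab)) stop("n exceeds the number of candidates")
    o <- order(tab$combinedRank, tab$normfinderRank, tab$id)
    as.character(tab$id[o])[seq_len(n)]
}

#' Serialize a StabilityReport as delimited text
#'
#' @param x a [StabilityReport-class].
#' @param path output path (`.csv` comma, else tab).
#' @return `path`, invisibly.
#' @export
writeStabilityReport <- function(x, path) {
    stopifnot(is(x, "StabilityReport"))
    write.table(as.data.frame(x@table), path, sep = .sepFor(path, "auto"),
                quote = FALSE, row.names = FALSE)
    invisible(path)
}
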