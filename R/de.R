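## Two-group differential-expression screen on normalized delta-Ct values:
## per-miRNA ordinary least squares, then empirical-Bayes variance
## moderation (scaled-F / inverse-gamma prior on the residual variances,
## hyperparameters by moment matching on log s^2).
##
## Sign convention: on the delta-Ct scale a NEGATIVE group coefficient means
## higher expression in the OSA group, so log2 fold change is reported as
## minus the group coefficient (positive = up-regulated in OSA).

#' Build a design matrix from sample metadata
#'
#' Intercept plus a group indicator (OSA = 1, non-OSA reference), plus
#' optional covariates standardized to z-scores (for conditioning and
#' coefficient comparability).
#'
#' @param meta `DataFrame`/`data.frame` of per-sample metadata (rownames =
#'   sample ids).
#' @param group name of the two-level grouping column (default `"group"`);
#'   level `"OSA"` is coded 1 when present, otherwise the second factor
#'   level.
#' @param covariates character vector of numeric covariate columns to
#'   adjust for (e.g. `c("age", "bmi")`).
#' @return numeric design matrix with rownames = sample ids; full column
#'   rank is checked.
#' @export
makeDesign <- function(meta, group = "group", covariates = character()) {
    meta <- as.data.frame(meta)
    if (!group %in% colnames(meta)) stop("grouping column absent: ", group)
    g <- factor(meta[[group]])
    if (nlevels(g) != 2L) stop("exactly two groups are required")
    if ("OSA" %in% levels(g)) g <- stats::relevel(g, setdiff(levels(g), "OSA")[1L])
    X <- cbind("(Intercept)" = 1, group = as.numeric(g == levels(g)[2L]))
    for (v in covariates) {
        if (!v %in% colnames(meta)) stop("covariate absent: ", v)
        x <- meta[[v]]
        if (!is.numeric(x)) stop("covariate must be numeric: ", v)
        X <- cbind(X, scale(x)[, 1L])
        colnames(X)[ncol(X)] <- v
    }
    rownames(X) <- rownames(meta)
    if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
    X
}

#' Per-miRNA ordinary least squares
#'
#' Fits the same linear model to every miRNA row of a normalized matrix.
#' Undetected cells are dropped per miRNA, with the residual degrees of
#' freedom adjusted accordingly; miRNAs left with fewer than 1 residual df
#' (or with the design rank-deficient on their detected samples) are
#' flagged (`ok = FALSE`) and carry `NA` statistics.
#'
#' @param x a [DeltaCtExperiment-class] or numeric matrix (miRNAs x
#'   samples).
#' @param design design matrix from [makeDesign()], rows aligned with the
#'   samples of `x`.
#' @return a list: `coefficients` (miRNAs x coefficients), `stdevUnscaled`
#'   (sqrt of the diagonal of (X'X)^-1 per miRNA), `sigma2` (residual
#'   variances), `df` (residual df), `ok` (logical).
#' @export
fitLinearModels <- function(x, design) {
    Y <- if (is(x, "DeltaCtExperiment")) deltaCtValues(x) else as.matrix(x)
    if (ncol(Y) != nrow(design))
        stop("design rows must match the number of samples")
    if (!is.null(rownames(design)) && !is.null(colnames(Y)) &&
        !identical(colnames(Y), rownames(design)))
        stop("design rows are not aligned with the sample columns")
    if (qr(design)$rank < ncol(design)) stop("design matrix is rank deficient")
    p <- ncol(design)
    nG <- nrow(Y)
    coef <- matrix(NA_real_, nG, p, dimnames = list(rownames(Y),
                                                    colnames(design)))
    su <- coef
    sigma2 <- rep(NA_real_, nG)
    df <- rep(NA_real_, nG)
    ok <- rep(FALSE, nG)

    fitOne <- function(y, X) {
        obs <- !is.na(y)
        n <- sum(obs)
        if (n < p + 1L) return(NULL)
        Xo <- X[obs, , drop = FALSE]
        qrX <- qr(Xo)
        if (qrX$rank < p) return(NULL)
        b <- qr.coef(qrX, y[obs])
        res <- y[obs] - Xo %*% b
        dfr <- n - p
        XtXinv <- chol2inv(chol(crossprod(Xo)))
        list(b = b, su = sqrt(diag(XtXinv)), s2 = sum(res^2) / dfr, df = dfr)
    }

    complete <- rowSums(is.na(Y)) == 0L
    if (any(complete)) {
        qrX <- qr(design)
        B <- t(qr.coef(qrX, t(Y[complete, , drop = FALSE])))
        fitted <- B %*% t(design)
        res <- Y[complete, , drop = FALSE] - fitted
        dfr <- ncol(Y) - p
        XtXinv <- chol2inv(chol(crossprod(design)))
        coef[complete, ] <- B
        su[complete, ] <- matrix(sqrt(diag(XtXinv)), sum(complete), p,
                                 byrow = TRUE)
        sigma2[complete] <- rowSums(res^2) / dfr
        df[complete] <- dfr
        ok[complete] <- dfr >= 1L
    }
    for (i in which(!complete)) {
        f <- fitOne(Y[i, ], design)
        if (is.null(f)) next
        coef[i, ] <- f$b
        su[i, ] <- f$su
        sigma2[i] <- f$s2
        df[i] <- f$df
        ok[i] <- TRUE
    }
    list(coefficients = coef, stdevUnscaled = su, sigma2 = sigma2,
         df = df, ok = ok)
}

## solve trigamma(x) = y for x > 0 (Newton on 1/trigamma, which is nearly
## linear), used by the moment-matching hyperparameter estimator
trigammaInverse <- function(y) {
    vapply(y, function(yi) {
        if (!is.finite(yi) || yi <= 0) return(NA_real_)
        if (yi > 1e7) return(1 / sqrt(yi))
        if (yi < 1e-6) return(1 / yi)
        x <- 0.5 + 1 / yi
        for (it in 1:50) {
            tri <- trigamma(x)
            dif <- tri * (1 - tri / yi) / psigamma(x, 2L)
            x <- x + dif
            if (abs(dif) / x < 1e-10) break
        }
        x
    }, numeric(1))
}

#' Estimate the scaled-F prior on residual variances
#'
#' Moment matching on `log(s^2)` as in the empirical-Bayes moderated-t
#' model: with `s^2 ~ s0^2 * F(df, d0)`, `e = log(s^2) - digamma(df/2) +
#' log(df/2)` has mean `log(s0^2) + digamma(d0/2)... ` inverted via the
#' digamma/trigamma equations. Returns `d0 = Inf` (common variance) when
#' the observed spread of `log(s^2)` does not exceed its sampling
#' expectation.
#'
#' @param sigma2 positive residual variances (miRNAs with df >= 1).
#' @param df residual degrees of freedom (scalar or vector).
#' @return list with `priorDf` (`d0`, possibly `Inf`) and `priorVar`
#'   (`s0^2`).
#' @export
estimatePrior <- function(sigma2, df) {
    keep <- is.finite(sigma2) & sigma2 > 0 & is.finite(df) & df > 0
    if (sum(keep) < 5L)
        stop("need at least 5 positive residual variances")
    s2 <- sigma2[keep]
    d <- rep_len(df, length(sigma2))[keep]
    e <- log(s2) - digamma(d / 2) + log(d / 2)
    ebar <- mean(e)
    n <- length(e)
    evar <- mean((e - ebar)^2) * n / (n - 1) - mean(trigamma(d / 2))
    if (is.finite(evar) && evar > 0) {
        d0 <- 2 * trigammaInverse(evar)
        s02 <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
    } else {
        d0 <- Inf
        s02 <- exp(ebar)
    }
    list(priorDf = d0, priorVar = s02)
}

#' Empirical-Bayes moderated t-statistics
#'
#' Shrinks each miRNA's residual variance toward the prior,
#' `s2_tilde = (d0 * s0^2 + df * s^2) / (d0 + df)`, and tests the chosen
#' coefficient with `t = b / (sqrt(s2_tilde) * stdevUnscaled)` on
#' `df + d0` degrees of freedom. Limits: `priorDf = 0` reproduces the
#' ordinary t-test; `priorDf = Inf` gives a common-variance z-like
#' statistic with `s2_tilde = s0^2` for every miRNA.
#'
#' @param fit result of [fitLinearModels()].
#' @param coef name or index of the coefficient to test (default
#'   `"group"`).
#' @param priorDf,priorVar optional fixed hyperparameters; when `NULL`
#'   (default) both are estimated with [estimatePrior()]. `priorDf = Inf`
#'   requires a positive `priorVar` (supplied or estimated).
#' @return `data.frame`: `id`, `logFC` (minus the delta-Ct coefficient:
#'   positive = up in OSA), `coefficient`, `t`, `df.total`, `p`, `adj.p`
#'   (Benjamini-Hochberg, informational only), `sigma2`, `s2.post`.
#' @export
empiricalBayesModerate <- function(fit, coef = "group", priorDf = NULL,
                                   priorVar = NULL) {
    b <- fit$coefficients[, coef]
    su <- fit$stdevUnscaled[, coef]
    s2 <- fit$sigma2
    df <- fit$df
    usable <- fit$ok & is.finite(s2)
    if (!any(usable)) stop("no miRNA with an estimable model")
    if (all(s2[usable] == 0))
        stop("all residual variances are zero; moderation is degenerate")

    if (is.null(priorDf) || is.null(priorVar)) {
        pr <- estimatePrior(s2[usable], df[usable])
        if (is.null(priorDf)) priorDf <- pr$priorDf
        if (is.null(priorVar)) priorVar <- pr$priorVar
    }
    if (is.infinite(priorDf) && (!is.finite(priorVar) || priorVar <= 0))
        stop("priorDf = Inf requires a positive priorVar")

    s2post <- if (is.infinite(priorDf)) rep(priorVar, length(s2))
              else (priorDf * priorVar + df * s2) / (priorDf + df)
    tstat <- b / (sqrt(s2post) * su)
    dfTotal <- df + priorDf
    p <- 2 * pt(-abs(tstat), df = dfTotal)
    out <- data.frame(id = rownames(fit$coefficients),
                      logFC = -b, coefficient = b, t = tstat,
                      df.total = dfTotal, p = p,
                      adj.p = p.adjust(p, "BH"),
                      sigma2 = s2, s2.post = s2post,
                      stringsAsFactors = FALSE)
    out[!usable, c("logFC", "coefficient", "t", "df.total", "p", "adj.p",
                   "s2.post")] <- NA
    attr(out, "priorDf") <- priorDf
    attr(out, "priorVar") <- priorVar
    rownames(out) <- NULL
    out
}

#' Differential-expression screen on a normalized matrix
#'
#' Convenience wrapper: builds the design from `colData`, fits per-miRNA
#' models, applies (optionally) empirical-Bayes moderation, and flags
#' significance at the raw-p threshold (strict `p < threshold`, no
#' multiplicity gate - an adjusted-p column is reported for information
#' only).
#'
#' @param x a [DeltaCtExperiment-class] whose `colData` has a `group`
#'   column.
#' @param covariates covariate columns to adjust for (default none).
#' @param moderated use empirical-Bayes moderated t (default `TRUE`);
#'   `FALSE` gives the ordinary t-test (`priorDf = 0`).
#' @param threshold significance threshold on the raw p-value (default
#'   0.025).
#' @return the [empiricalBayesModerate()] table plus a logical
#'   `significant` column.
#' @export
runDE <- function(x, covariates = character(), moderated = TRUE,
                  threshold = 0.025) {
    stopifnot(is(x, "DeltaCtExperiment"))
    if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
    design <- makeDesign(colData(x), covariates = covariates)
    fit <- fitLinearModels(x, design)
    res <- if (moderated) empiricalBayesModerate(fit)
           else empiricalBayesModerate(fit, priorDf = 0, priorVar = 1)
    res$significant <- !is.na(res$p) & res$p < threshold
    attr(res, "threshold") <- threshold
    res
}

#' Significant miRNA ids at a raw-p threshold
#'
#' Strict inequality (`p == threshold` is not selected); no multiplicity
#' adjustment.
#'
#' @param res result table from [runDE()] / [empiricalBayesModerate()].
#' @param threshold p-value threshold in (0, 1) (default 0.025).
#' @return character vector of ids (possibly empty).
#' @export
selectDE <- function(res, threshold = 0.025) {
    if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
    if (nrow(res) == 0L) return(character())
    res$id[!is.na(res$p) & res$p < threshold]
}

#' Volcano-plot table
#'
#' @param res result table from [runDE()].
#' @param threshold significance threshold (default 0.025).
#' @return `data.frame` with `id`, `log2FC`, `negLog10P`, `significant`.
#' @export
volcanoTable <- function(res, threshold = 0.025) {
    data.frame(id = res$id, log2FC = res$logFC,
               negLog10P = -log10(res$p),
               significant = !is.na(res$p) & res$p < threshold,
               stringsAsFactors = FALSE)
}
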