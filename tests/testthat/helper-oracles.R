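## Independent brute-force oracles, written with scalar arithmetic only so
## they share no code path with the package implementations.

## sample SD, denominator n - 1, computed from first principles
oracleSD <- function(v) {
    n <- length(v)
    m <- sum(v) / n
    sqrt(sum((v - m)^2) / (n - 1))
}

## geNorm M by explicit double loop over gene pairs
oracleGeNormM <- function(ct) {
    k <- nrow(ct)
    M <- numeric(k)
    for (j in 1:k) {
        tot <- 0
        for (l in 1:k) {
            if (l == j) next
            r <- ct[l, ] - ct[j, ]
            tot <- tot + oracleSD(r)
        }
        M[j] <- tot / (k - 1)
    }
    names(M) <- rownames(ct)
    M
}

## geNorm pairwise variation by explicit recomputation
oracleGeNormV <- function(ct, ord) {
    k <- length(ord)
    V <- numeric(k - 2)
    for (n in 2:(k - 1)) {
        nfA <- apply(ct[ord[1:n], , drop = FALSE], 2, function(col) sum(col) / n)
        nfB <- apply(ct[ord[1:(n + 1)], , drop = FALSE], 2,
                     function(col) sum(col) / (n + 1))
        V[n - 1] <- oracleSD(nfA - nfB)
    }
    V
}

## Lin's CCC straight from the defining formula (1/n moments)
oracleCCC <- function(x, y) {
    n <- length(x)
    mx <- sum(x) / n; my <- sum(y) / n
    vx <- sum((x - mx)^2) / n
    vy <- sum((y - my)^2) / n
    cxy <- sum((x - mx) * (y - my)) / n
    2 * cxy / (vx + vy + (mx - my)^2)
}

## OLS by direct normal-equations solve
oracleOLS <- function(y, X) {
    b <- solve(t(X) %*% X, t(X) %*% y)
    res <- y - X %*% b
    df <- length(y) - ncol(X)
    list(coef = drop(b), sigma2 = sum(res^2) / df, df = df,
         stdevUnscaled = sqrt(diag(solve(t(X) %*% X))))
}

## Kendall tau and exact two-sided p by enumeration of all permutations
## (feasible for n <= 6)
oracleKendall <- function(a, b) {
    n <- length(a)
    Sof <- function(x, y) {
        s <- 0
        for (i in 1:(n - 1)) for (j in (i + 1):n)
            s <- s + sign(x[j] - x[i]) * sign(y[j] - y[i])
        s
    }
    S <- unname(Sof(a, b))
    perms <- function(v) {
        if (length(v) <= 1) return(list(v))
        out <- list()
        for (i in seq_along(v))
            for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
        out
    }
    allS <- vapply(perms(seq_len(n)), function(p) Sof(a[p], b), numeric(1))
    pGE <- mean(allS >= S); pLE <- mean(allS <= S)
    list(tau = S / (n * (n - 1) / 2), S = S,
         p = min(1, 2 * min(pGE, pLE)))
}

## Fisher exact two-sided p for a 2x2 table by hypergeometric enumeration
oracleFisher2x2 <- function(tab) {
    m <- sum(tab[1, ]); n <- sum(tab[2, ]); kk <- sum(tab[, 1])
    support <- max(0, kk - n):min(kk, m)
    dens <- vapply(support, function(x)
        choose(m, x) * choose(n, kk - x) / choose(m + n, kk), numeric(1))
    pObs <- dens[support == tab[1, 1]]
    sum(dens[dens <= pObs * (1 + 1e-7)])
}

## small random Ct matrix with dimnames
randomCtMatrix <- function(nGenes, nSamples, base = 25, sd = 1) {
    m <- matrix(rnorm(nGenes * nSamples, base, sd), nGenes, nSamples,
                dimnames = list(sprintf("g%02d", seq_len(nGenes)),
                                sprintf("s%02d", seq_len(nSamples))))
    m
}
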