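## Candidate endogenous-control nomination: mean-centre + SD ranking and
## concordance-correlation-restricted (CCR) selection, plus candidate
## merging. Tie-breaking in every ranking is deterministic: ties are broken
## lexicographically by miRNA id.

#' Rank miRNAs by across-sample standard deviation (mean-centre + SD)
#'
#' On mean-centre-normalized data, a good endogenous control tracks the
#' global mean, so its normalized values barely vary across samples. miRNAs
#' are ranked by the sample standard deviation (denominator n - 1) of their
#' normalized values, ascending; the `k` least variable are returned.
#'
#' @param x a [DeltaCtExperiment-class] (typically from
#'   [meanCentreNormalize()]).
#' @param eligible ids to rank; default: miRNAs detected in all samples.
#'   Every eligible id must be fully detected.
#' @param k number of candidates to return (default 10).
#' @return `data.frame` with columns `id`, `sd`, `rank` (rows ordered by
#'   rank).
#' @export
rankBySD <- function(x, eligible = NULL, k = 10) {
    stopifnot(is(x, "DeltaCtExperiment"))
    if (k <= 0) stop("k must be positive")
    m <- deltaCtValues(x)
    if (is.null(eligible))
        eligible <- rownames(m)[rowSums(is.na(m)) == 0L]
    miss <- setdiff(eligible, rownames(m))
    if (length(miss))
        stop("eligible id(s) absent: ", paste(miss, collapse = ", "))
    sub <- m[eligible, , drop = FALSE]
    if (anyNA(sub))
        stop("eligible miRNAs must be detected in all samples")
    if (k > length(eligible))
        stop("k exceeds the number of eligible miRNAs")
    s <- apply(sub, 1L, sd)
    o <- order(s, names(s))
    out <- data.frame(id = names(s)[o], sd = unname(s[o]),
                      rank = seq_along(s), stringsAsFactors = FALSE)
    out[seq_len(k), , drop = FALSE]
}

#' Lin's concordance correlation coefficient
#'
#' Agreement between two measurement vectors:
#' `rho_c = 2 cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2)`,
#' with population (1/n) moments as in Lin's original definition. Unlike
#' Pearson correlation it penalizes location and scale shifts, so
#' `|rho_c| <= |r|` always. Degenerate conventions: if both vectors are
#' constant and equal, `rho_c = 1`; if exactly one is constant, `rho_c = 0`.
#'
#' @param x,y numeric vectors of equal length >= 3, finite.
#' @return the coefficient, in \[-1, 1\].
#' @examples
#' concordanceCorrelation(c(1, 2, 3), c(1, 2, 3))   # 1
#' concordanceCorrelation(c(1, 2, 3), c(3, 2, 1))   # -0.5
#' @export
concordanceCorrelation <- function(x, y) {
    if (length(x) != length(y)) stop("x and y must have equal length")
    if (length(x) < 3L) stop("need at least 3 observations")
    if (!all(is.finite(x)) || !all(is.finite(y)))
        stop("x and y must be finite")
    n <- length(x)
    mx <- mean(x); my <- mean(y)
    vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
    cxy <- mean((x - mx) * (y - my))
    if (vx == 0 && vy == 0) return(if (mx == my) 1 else 0)
    if (vx == 0 || vy == 0) return(0)
    2 * cxy / (vx + vy + (mx - my)^2)
}

#' Concordance-correlation-restricted (CCR) candidate selection
#'
#' The reference profile is the per-sample mean Ct over the fully detected
#' miRNAs. Each fully detected miRNA is scored by Lin's concordance
#' correlation against that reference and the `k` most concordant are
#' returned. Because the coefficient penalizes location shift, candidates
#' must not only co-vary with but also sit near the global-mean level.
#'
#' @param x a [CtExperiment-class] (raw Ct values).
#' @param k number of candidates (default 10).
#' @param cccCutoff optional minimum coefficient; when given, candidates
#'   below the cutoff are dropped even inside the top `k`.
#' @return `data.frame` with columns `id`, `ccc`, `rank`.
#' @export
ccrSelect <- function(x, k = 10, cccCutoff = NULL) {
    stopifnot(is(x, "CtExperiment"))
    if (k <= 0) stop("k must be positive")
    fd <- fullyDetectedSet(x)
    if (length(fd) == 0L) stop("no fully detected miRNAs")
    if (k > length(fd))
        stop("k exceeds the number of fully detected miRNAs (", length(fd), ")")
    ct <- ctValues(x)[fd, , drop = FALSE]
    ref <- colMeans(ct)
    ccc <- apply(ct, 1L, concordanceCorrelation, y = ref)
    o <- order(-ccc, names(ccc))
    out <- data.frame(id = names(ccc)[o], ccc = unname(ccc[o]),
                      rank = seq_along(ccc), stringsAsFactors = FALSE)
    out <- out[seq_len(k), , drop = FALSE]
    if (!is.null(cccCutoff)) out <- out[out$ccc >= cccCutoff, , drop = FALSE]
    out
}

#' Merge candidate lists from the two selection methods
#'
#' Union of the mean-centre + SD and CCR candidate lists; a miRNA nominated
#' by both carries both method tags. The union size is
#' `k1 + k2 - |intersection|`.
#'
#' @param mcsd `data.frame` from [rankBySD()].
#' @param ccr `data.frame` from [ccrSelect()].
#' @return a [CandidateSet-class], rows ordered by id.
#' @export
mergeCandidates <- function(mcsd, ccr) {
    ids <- sort(union(mcsd$id, ccr$id))
    inM <- ids %in% mcsd$id
    inC <- ids %in% ccr$id
    idx <- function(tab, col) {
        v <- tab[[col]][match(ids, tab$id)]
        v
    }
    method <- ifelse(inM & inC, "CCR and MC+SD", ifelse(inM, "MC+SD", "CCR"))
    tab <- DataFrame(id = ids, inMCSD = inM, inCCR = inC,
                     mcsdRank = idx(mcsd, "rank"), ccrRank = idx(ccr, "rank"),
                     sdScore = idx(mcsd, "sd"), cccScore = idx(ccr, "ccc"),
                     method = method)
    new("CandidateSet", table = tab)
}

#' Serialize a CandidateSet as delimited text
#'
#' @param x a [CandidateSet-class].
#' @param path output path (`.csv` comma, else tab).
#' @return `path`, invisibly.
#' @export
writeCandidateSet <- function(x, path) {
    stopifnot(is(x, "CandidateSet"))
    write.table(as.data.frame(x@table), path, sep = .sepFor(path, "auto"),
                quote = FALSE, row.names = FALSE)
    invisible(path)
}
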