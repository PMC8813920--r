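## Delimited-text I/O for Ct matrices, sample metadata and spike-in vectors.
## Field separator is auto-detected from the file extension: ".csv" reads as
## comma-separated, anything else as tab-separated. Undetected wells are
## written as "Undetermined", matching instrument exports.

.sepFor <- function(path, dialect = c("auto", "csv", "tsv")) {
    dialect <- match.arg(dialect)
    if (dialect == "csv") return(",")
    if (dialect == "tsv") return("\t")
    if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

.undetectedTokens <- c("Undetermined", "NA", "")

#' Read a Ct matrix from delimited text
#'
#' Expects a header row of sample identifiers; the first column holds miRNA
#' identifiers and the remaining cells Ct values. The tokens `"Undetermined"`,
#' `"NA"` and the empty string mark undetected reactions and become `NA`.
#' Row and column order are preserved.
#'
#' @param path file path; `.csv` is read comma-separated, anything else
#'   tab-separated (override with `dialect`).
#' @param dialect `"auto"` (default), `"csv"` or `"tsv"`.
#' @return a [CtExperiment-class] (with empty `colData`).
#' @seealso [writeCtMatrix()]
#' @export
readCtMatrix <- function(path, dialect = c("auto", "csv", "tsv")) {
    sep <- .sepFor(path, dialect)
    nf <- count.fields(path, sep = sep, quote = "\"", blank.lines.skip = FALSE)
    nf <- nf[!is.na(nf)]
    if (length(unique(nf)) > 1L)
        stop("ragged rows in '", path, "': rows have ",
             paste(unique(nf), collapse = "/"), " fields")
    df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                     colClasses = "character", na.strings = NULL)
    if (ncol(df) < 2L)
        stop("expected an id column plus at least one sample column")
    ids <- df[[1L]]
    if (anyDuplicated(ids))
        stop("duplicated miRNA id(s): ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    cells <- as.matrix(df[, -1L, drop = FALSE])
    undet <- cells %in% .undetectedTokens
    vals <- suppressWarnings(as.numeric(cells))
    bad <- which(is.na(vals) & !undet)
    if (length(bad)) {
        rc <- arrayInd(bad[1L], dim(cells))
        stop(sprintf("non-numeric Ct '%s' at row '%s', column '%s'",
                     cells[bad[1L]], ids[rc[1L]], colnames(cells)[rc[2L]]))
    }
    vals[undet] <- NA_real_
    dim(vals) <- dim(cells)
    dimnames(vals) <- list(ids, colnames(cells))
    CtExperiment(vals)
}

#' Write a Ct matrix as delimited text
#'
#' Inverse of [readCtMatrix()]: undetected wells are written as
#' `"Undetermined"`; reading the file back reproduces the object's Ct matrix
#' and undetected pattern exactly.
#'
#' @param x a [CtExperiment-class] (or bare numeric matrix with dimnames).
#' @param path output path; `.csv` writes comma-separated, else tab.
#' @param dialect `"auto"` (default), `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
writeCtMatrix <- function(x, path, dialect = c("auto", "csv", "tsv")) {
    ct <- if (is(x, "CtExperiment")) ctValues(x) else as.matrix(x)
    if (any(!is.finite(ct) & !is.na(ct)))
        stop("non-finite Ct values cannot be serialized")
    sep <- .sepFor(path, dialect)
    header <- paste(c("mirna_id", colnames(ct)), collapse = sep)
    if (nrow(ct) == 0L) {
        writeLines(header, path)
        return(invisible(path))
    }
    out <- sprintf("%.17g", ct)          # full precision: read-back is exact
    out[is.na(ct)] <- "Undetermined"
    dim(out) <- dim(ct)
    body <- apply(cbind(rownames(ct), out), 1L, paste, collapse = sep)
    writeLines(c(header, body), path)
    invisible(path)
}

#' Read / write a sample-metadata table
#'
#' The table requires columns `sample_id`, `group`, `age`, `bmi`, `phase`;
#' an optional `qc_pass` column is kept. `group` must have at most the two
#' levels `"non-OSA"` and `"OSA"`.
#'
#' @param path delimited-text file (`.csv` comma, else tab).
#' @return `readSampleMetadata`: a `DataFrame` with `sample_id` as rownames.
#' @export
readSampleMetadata <- function(path) {
    sep <- .sepFor(path, "auto")
    df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                     stringsAsFactors = FALSE)
    need <- c("sample_id", "group", "age", "bmi", "phase")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop("metadata is missing column(s): ", paste(miss, collapse = ", "))
    if (anyDuplicated(df$sample_id))
        stop("duplicated sample_id in metadata")
    bad <- setdiff(unique(df$group), c("non-OSA", "OSA"))
    if (length(bad))
        stop("unknown group label(s): ", paste(bad, collapse = ", "))
    out <- DataFrame(df[setdiff(colnames(df), "sample_id")],
                     row.names = df$sample_id)
    out
}

#' @rdname readSampleMetadata
#' @param meta a `DataFrame`/`data.frame` with sample ids as rownames.
#' @return `writeSampleMetadata`: `path`, invisibly.
#' @export
writeSampleMetadata <- function(meta, path) {
    df <- as.data.frame(meta)
    df <- cbind(sample_id = rownames(df), df)
    write.table(df, path, sep = .sepFor(path, "auto"), quote = FALSE,
                row.names = FALSE)
    invisible(path)
}

#' Read / write a spike-in Ct vector
#'
#' Two-column table (`sample_id`, `ct`); `"Undetermined"` becomes `NA`.
#'
#' @param path delimited-text file (`.csv` comma, else tab).
#' @return `readSpikeIn`: a named numeric vector.
#' @export
readSpikeIn <- function(path) {
    sep <- .sepFor(path, "auto")
    df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                     colClasses = "character")
    if (!all(c("sample_id", "ct") %in% colnames(df)))
        stop("spike-in table needs columns 'sample_id' and 'ct'")
    undet <- df$ct %in% .undetectedTokens
    vals <- suppressWarnings(as.numeric(df$ct))
    if (any(is.na(vals) & !undet))
        stop("non-numeric spike-in Ct for sample ",
             df$sample_id[which(is.na(vals) & !undet)[1L]])
    vals[undet] <- NA_real_
    setNames(vals, df$sample_id)
}

#' @rdname readSpikeIn
#' @param spike named numeric vector of spike-in Ct values.
#' @return `writeSpikeIn`: `path`, invisibly.
#' @export
writeSpikeIn <- function(spike, path) {
    ct <- ifelse(is.na(spike), "Undetermined", sprintf("%.17g", spike))
    df <- data.frame(sample_id = names(spike), ct = ct)
    write.table(df, path, sep = .sepFor(path, "auto"), quote = FALSE,
                row.names = FALSE)
    invisible(path)
}

#' Write all input files of a simulated cohort
#'
#' Materializes the four pipeline inputs (discovery matrix, validation
#' matrix, metadata, spike-in) plus a ground-truth sidecar table so that
#' pipeline output can be scored externally.
#'
#' @param sim a [SimulatedCohort-class].
#' @param dir output directory (created if needed).
#' @param dialect `"csv"` (default) or `"tsv"`.
#' @return named character vector of the files written, invisibly.
#' @export
writeCohort <- function(sim, dir, dialect = c("csv", "tsv")) {
    stopifnot(is(sim, "SimulatedCohort"))
    dialect <- match.arg(dialect)
    ext <- dialect
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(stem) file.path(dir, paste0(stem, ".", ext))
    writeCtMatrix(sim@discovery, p("discovery_ct"))
    writeCtMatrix(sim@validation, p("validation_ct"))
    writeSampleMetadata(cohortMetadata(sim), p("sample_metadata"))
    writeSpikeIn(sim@spikeIn, p("spike_in"))
    gt <- sim@groundTruth
    truthDf <- data.frame(
        id = c(gt@stableIds, gt@deIds),
        role = c(rep("stable", length(gt@stableIds)),
                 rep("differential", length(gt@deIds))),
        effect = c(rep(0, length(gt@stableIds)),
                   unname(gt@deEffects[gt@deIds])))
    write.table(truthDf, p("ground_truth"), sep = .sepFor(p("x"), "auto"),
                quote = FALSE, row.names = FALSE)
    files <- c(discovery = p("discovery_ct"), validation = p("validation_ct"),
               metadata = p("sample_metadata"), spike = p("spike_in"),
               truth = p("ground_truth"))
    invisible(files)
}
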