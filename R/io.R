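#' @include study.R
NULL

# read non-comment lines of a UTF-8 text file
read_data_lines <- function(path, strip_comments = TRUE) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    if (strip_comments) lines <- lines[!startsWith(lines, "#")]
    lines[nzchar(lines)]
}

# parse a character matrix of cells into numeric, reporting coordinates
parse_numeric_cells <- function(cells, feature_ids, sample_ids) {
    suppressWarnings(vals <- as.numeric(cells))
    if (anyNA(vals)) {
        bad <- which(is.na(vals))[1L]
        n <- length(sample_ids)
        r <- ((bad - 1L) %/% n) + 1L
        c <- ((bad - 1L) %% n) + 1L
        stop("non-numeric expression cell at row ", r, " (feature '",
             feature_ids[r], "'), column ", c, " (sample '", sample_ids[c],
             "'): '", cells[bad], "'")
    }
    matrix(vals, nrow = length(feature_ids), byrow = TRUE,
           dimnames = list(feature_ids, sample_ids))
}

#' Read and write log2 expression matrices (TSV / GCT v1.2)
#'
#' The TSV dialect is: a header row of sample IDs whose first field names the
#' feature-ID column, then one row per feature; `#`-prefixed lines are
#' comments. GCT follows version 1.2 exactly (a `#1.2` line, a dimension
#' line, then `NAME`/`Description` columns); v1.3 files are rejected. Row and
#' column order are preserved, duplicate IDs and non-numeric cells are hard
#' errors, so a reader never silently drops rows.
#'
#' @param path File path.
#' @param format `"tsv"` or `"gct"`.
#' @return For the reader, a numeric matrix (features x samples) of log2
#'   intensities with ID dimnames.
#' @export
readExpressionMatrix <- function(path, format = c("tsv", "gct")) {
    format <- match.arg(format)
    if (format == "tsv") {
        lines <- read_data_lines(path)
        if (length(lines) < 2L) stop("expression TSV needs a header and data: ", path)
        header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
        sample_ids <- header[-1L]
        rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
        nf <- lengths(rows)
        if (any(nf != length(header)))
            stop("row ", which(nf != length(header))[1L],
                 " has ", nf[nf != length(header)][1L], " fields, expected ",
                 length(header))
        feature_ids <- vapply(rows, `[[`, character(1), 1L)
        cells <- unlist(lapply(rows, `[`, -1L), use.names = FALSE)
    } else {
        lines <- read_data_lines(path, strip_comments = FALSE)
        if (length(lines) < 3L) stop("truncated GCT file: ", path)
        if (identical(lines[1L], "#1.3"))
            stop("GCT v1.3 is not supported; only v1.2 is accepted")
        if (!identical(lines[1L], "#1.2"))
            stop("not a GCT v1.2 file (first line must be '#1.2'): ", path)
        dims <- suppressWarnings(
            as.integer(strsplit(lines[2L], "\t", fixed = TRUE)[[1L]]))
        if (length(dims) < 2L || anyNA(dims[1:2]))
            stop("malformed GCT dimension line: '", lines[2L], "'")
        header <- strsplit(lines[3L], "\t", fixed = TRUE)[[1L]]
        if (length(header) != dims[2L] + 2L)
            stop("GCT header has ", length(header) - 2L,
                 " sample columns but dimension line declares ", dims[2L])
        sample_ids <- header[-(1:2)]
        body <- lines[-(1:3)]
        if (length(body) != dims[1L])
            stop("GCT declares ", dims[1L], " rows but file has ",
                 length(body), " data rows")
        rows <- strsplit(body, "\t", fixed = TRUE)
        if (any(lengths(rows) != dims[2L] + 2L))
            stop("GCT data row ", which(lengths(rows) != dims[2L] + 2L)[1L],
                 " has the wrong number of fields")
        feature_ids <- vapply(rows, `[[`, character(1), 1L)
        cells <- unlist(lapply(rows, `[`, -(1:2)), use.names = FALSE)
    }
    m <- parse_numeric_cells(cells, feature_ids, sample_ids)
    validate_exprs(m)
    m
}

#' @rdname readExpressionMatrix
#' @param m Numeric matrix with feature/sample dimnames.
#' @param descriptions Optional per-feature descriptions for the GCT
#'   `Description` column (defaults to the feature IDs).
#' @export
writeExpressionMatrix <- function(m, path, format = c("tsv", "gct"),
                                  descriptions = NULL) {
    format <- match.arg(format)
    validate_exprs(m)
    fmt_row <- function(id, vals) paste(c(id, sprintf("%.17g", vals)),
                                        collapse = "\t")
    body <- vapply(seq_len(nrow(m)),
                   function(i) fmt_row(rownames(m)[i], m[i, ]), character(1))
    if (format == "tsv") {
        lines <- c(paste(c("feature_id", colnames(m)), collapse = "\t"), body)
    } else {
        if (is.null(descriptions)) descriptions <- rownames(m)
        body <- vapply(seq_len(nrow(m)), function(i)
            paste(c(rownames(m)[i], descriptions[i], sprintf("%.17g", m[i, ])),
                  collapse = "\t"), character(1))
        lines <- c("#1.2",
                   paste(nrow(m), ncol(m), sep = "\t"),
                   paste(c("NAME", "Description", colnames(m)), collapse = "\t"),
                   body)
    }
    writeLines(lines, path, useBytes = TRUE)
    invisible(path)
}

#' Read and write gene-set collections in GMT format
#'
#' One set per line: name, description, then genes, tab-separated (the MSigDB
#' convention used for hallmark/reactome collections and marker panels).
#' Duplicate genes within a line are de-duplicated preserving first
#' occurrence; a line whose gene list is empty, a line with fewer than three
#' fields, or a duplicated set name is a hard error.
#'
#' @param path File path.
#' @return `readGmt()`: a named list of unique character gene vectors with a
#'   `"description"` attribute (named character vector).
#' @export
readGmt <- function(path) {
    lines <- read_data_lines(path, strip_comments = FALSE)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf < 3L))
        stop("GMT line ", which(nf < 3L)[1L], " has fewer than 3 fields")
    nm <- vapply(parts, `[[`, character(1), 1L)
    dup <- nm[duplicated(nm)]
    if (length(dup))
        stop("duplicate gene-set name(s): ", paste(unique(dup), collapse = ", "))
    desc <- vapply(parts, `[[`, character(1), 2L)
    sets <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
    empty <- which(lengths(sets) == 0L)
    if (length(empty))
        stop("GMT line ", empty[1L], " ('", nm[empty[1L]],
             "') has an empty gene list")
    names(sets) <- nm
    attr(sets, "description") <- stats::setNames(desc, nm)
    sets
}

#' @rdname readGmt
#' @param sets Named list of character gene vectors; an optional
#'   `"description"` attribute supplies the second GMT column.
#' @export
writeGmt <- function(sets, path) {
    if (is.null(names(sets)) || anyDuplicated(names(sets)))
        stop("gene sets must have unique names")
    desc <- attr(sets, "description")
    if (is.null(desc)) desc <- stats::setNames(names(sets), names(sets))
    lines <- vapply(names(sets), function(nm)
        paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t"), character(1))
    writeLines(lines, path, useBytes = TRUE)
    invisible(path)
}

#' Read and write sample tables
#'
#' A sample table is a TSV with columns `sample_id`, `subject_id`,
#' `condition`; conditions are validated against [acneConditions()], sample
#' IDs must be unique, and a subject may contribute at most one sample per
#' condition.
#'
#' @param path File path.
#' @return `readSampleTable()`: a validated `data.frame`.
#' @export
readSampleTable <- function(path) {
    lines <- read_data_lines(path)
    tb <- utils::read.delim(text = paste(lines, collapse = "\n"),
                            colClasses = "character", check.names = FALSE)
    validate_sample_table(tb)
    tb
}

#' @rdname readSampleTable
#' @param samples A sample-table `data.frame`.
#' @export
writeSampleTable <- function(samples, path) {
    validate_sample_table(samples)
    lines <- c("sample_id\tsubject_id\tcondition",
               paste(samples$sample_id, samples$subject_id,
                     samples$condition, sep = "\t"))
    writeLines(lines, path, useBytes = TRUE)
    invisible(path)
}

#' Read a probe-to-gene map
#'
#' Two-column TSV (`probe_id`, `gene_symbol`); probe IDs must be unique, many
#' probes may map to one gene. Used by [collapseProbes()] to reduce
#' probe-level matrices to unique annotated genes.
#'
#' @param path File path.
#' @return `data.frame` with columns `probe_id`, `gene_symbol`.
#' @export
readProbeGeneMap <- function(path) {
    lines <- read_data_lines(path)
    tb <- utils::read.delim(text = paste(lines, collapse = "\n"),
                            colClasses = "character", check.names = FALSE)
    if (!all(c("probe_id", "gene_symbol") %in% names(tb)))
        stop("probe map must have columns probe_id, gene_symbol")
    dup <- tb$probe_id[duplicated(tb$probe_id)]
    if (length(dup))
        stop("duplicate probe_id(s): ", paste(unique(dup), collapse = ", "))
    tb
}
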