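#' Construct a score matrix
#'
#' @param scores numeric matrix of raw compatibility scores (higher =
#'   more compatible), with domain ids as rownames and template ids as
#'   colnames, or bare with \code{row_ids}/\code{col_ids} supplied.
#' @param row_ids,col_ids optional identifiers when \code{scores} lacks
#'   dimnames.
#' @return a \linkS4class{ScoreMatrix}.
#' @examples
#' ScoreMatrix(matrix(1:6, 2, 3), row_ids = c("d1", "d2"),
#'     col_ids = c("t1", "t2", "t3"))
#' @export
ScoreMatrix <- function(scores, row_ids = NULL, col_ids = NULL) {
    scores <- as.matrix(scores)
    storage.mode(scores) <- "double"
    if (!is.null(row_ids)) rownames(scores) <- as.character(row_ids)
    if (!is.null(col_ids)) colnames(scores) <- as.character(col_ids)
    methods::new("ScoreMatrix", scores = scores)
}

.newPess <- function(scores, provenance) {
    methods::new("PessMatrix", scores = scores, provenance = provenance)
}

#' Read a query-by-template score matrix from TSV
#'
#' Canonical interchange format so any threading engine can feed the
#' pipeline: one header row of template ids (first column \code{id}),
#' one row per domain, tab-separated, \code{"."} decimal regardless of
#' locale.
#'
#' @param path TSV file path.
#' @param expect_templates optional \linkS4class{TemplateLibrary}; when
#'   given, the file's columns must be exactly that template set and are
#'   reordered to the library order.
#' @return a \linkS4class{ScoreMatrix}.
#' @seealso \code{\link{writeScoreMatrix}}
#' @export
readScoreMatrix <- function(path, expect_templates = NULL) {
    if (!file.exists(path)) .stopf("score matrix file not found: %s", path)
    header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
    if (length(header) < 2L)
        .stopf("score matrix %s: header must name at least one template", path)
    tpl <- header[-1L]
    if (anyDuplicated(tpl))
        .stopf("score matrix %s: duplicated template columns: %s", path,
            paste(unique(tpl[duplicated(tpl)]), collapse = ", "))
    tab <- utils::read.table(path, header = TRUE, sep = "\t", dec = ".",
        row.names = NULL, check.names = FALSE, stringsAsFactors = FALSE,
        colClasses = c("character", rep("character", length(tpl))))
    ids <- tab[[1L]]
    if (anyDuplicated(ids))
        .stopf("score matrix %s: duplicated domain id(s): %s", path,
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
    m <- matrix(NA_real_, nrow(tab), length(tpl),
        dimnames = list(ids, tpl))
    for (j in seq_along(tpl)) {
        v <- suppressWarnings(as.numeric(tab[[j + 1L]]))
        bad <- which(is.na(v) & !is.na(tab[[j + 1L]]))
        if (length(bad))
            .stopf("score matrix %s: non-numeric cell at row '%s', column '%s' (value '%s')",
                path, ids[bad[1L]], tpl[j], tab[[j + 1L]][bad[1L]])
        if (anyNA(v))
            .stopf("score matrix %s: missing cell at row '%s', column '%s'",
                path, ids[which(is.na(v))[1L]], tpl[j])
        m[, j] <- v
    }
    sm <- ScoreMatrix(m)
    if (!is.null(expect_templates))
        sm <- reorderToLibrary(sm, expect_templates)
    sm
}

#' Write a score matrix to TSV
#'
#' @param x a \linkS4class{ScoreMatrix} (or \linkS4class{PessMatrix}).
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeScoreMatrix <- function(x, path) {
    stopifnot(methods::is(x, "ScoreMatrix"))
    m <- x@scores
    con <- file(path, "w", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(paste(c("id", colnames(m)), collapse = "\t"), con)
    # format() respects the "." decimal; avoid locale-dependent output
    body <- apply(m, 1L, function(r)
        paste(format(r, trim = TRUE, scientific = FALSE, digits = 15),
            collapse = "\t"))
    writeLines(paste(rownames(m), body, sep = "\t"), con)
    invisible(path)
}

#' Reorder score matrix columns to a template library's order
#'
#' @param x a \linkS4class{ScoreMatrix}.
#' @param templates a \linkS4class{TemplateLibrary} or character vector
#'   of template ids.
#' @return the matrix with columns in library order.
#' @export
reorderToLibrary <- function(x, templates) {
    want <- if (methods::is(templates, "TemplateLibrary"))
        templateIds(templates) else as.character(templates)
    have <- colnames(x@scores)
    missing <- setdiff(want, have)
    extra <- setdiff(have, want)
    if (length(missing) || length(extra))
        .stopf("score matrix columns do not match the template library (missing: %s; unexpected: %s)",
            if (length(missing)) paste(missing, collapse = ", ") else "none",
            if (length(extra)) paste(extra, collapse = ", ") else "none")
    out <- x
    out@scores <- x@scores[, want, drop = FALSE]
    out
}

#' Fold prediction from the single best template
#'
#' Baseline that skips the feature-space construction entirely: each
#' domain is assigned the fold of its highest-scoring template. Ties are
#' broken by the lowest column index. Raw scores are used as produced by
#' the scorer.
#'
#' @param raw a \linkS4class{ScoreMatrix} of raw scores.
#' @param templates a \linkS4class{TemplateLibrary} with fold annotations
#'   for every template.
#' @return named character vector: predicted fold per domain.
#' @export
topTemplateBaseline <- function(raw, templates) {
    stopifnot(methods::is(raw, "ScoreMatrix"),
        methods::is(templates, "TemplateLibrary"))
    folds <- templateFolds(templates)
    if (is.null(folds) || anyNA(folds))
        .stopf("topTemplateBaseline requires a fold annotation for every template")
    m <- reorderToLibrary(raw, templates)@scores
    best <- apply(m, 1L, which.max)   # first max = lowest column index
    stats::setNames(unname(folds[best]), rownames(m))
}
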