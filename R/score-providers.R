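#' Stand-in sequence-template compatibility score
#'
#' A desk-scale substitute for a structural threading engine: the
#' Smith-Waterman local-alignment similarity of the query against the
#' template sequence (BLOSUM62, affine gaps, open 11 / extend 1 by
#' default). This is a sequence-compatibility score, not a structural
#' threading score; it fills the same role in the pipeline (higher =
#' more compatible) so that the feature-space machinery can be exercised
#' and externally computed threading scores can be swapped in via
#' \code{\link{readScoreMatrix}}. Scores are floored at 0 (the empty
#' local alignment).
#'
#' @param query,template amino-acid strings (length >= 1; \code{X},
#'   \code{B}, \code{Z} tolerated).
#' @param substitutionMatrix scoring matrix name or matrix (default
#'   \code{"BLOSUM62"}).
#' @param gapOpening,gapExtension positive gap penalties; a gap of
#'   length L costs \code{gapOpening + L * gapExtension}.
#' @return a single numeric score, deterministic in its inputs.
#' @examples
#' standInScore("MKVLITAGPTREPLD", "MKVLITAGPTREPLD")
#' @export
standInScore <- function(query, template, substitutionMatrix = "BLOSUM62",
        gapOpening = 11, gapExtension = 1) {
    query <- .checkAASeq(query, "query")
    template <- .checkAASeq(template, "template")
    sm <- if (is.character(substitutionMatrix))
        .getSubMatrix(substitutionMatrix) else substitutionMatrix
    s <- Biostrings::pairwiseAlignment(query, template, type = "local",
        substitutionMatrix = sm, gapOpening = gapOpening,
        gapExtension = gapExtension, scoreOnly = TRUE)
    max(0, s)
}

.getSubMatrix <- local({
    cache <- list()
    function(name) {
        if (is.null(cache[[name]])) {
            e <- new.env()
            utils::data(list = name, package = "Biostrings", envir = e)
            cache[[name]] <<- get(name, envir = e)
        }
        cache[[name]]
    }
})

#' Score a set of domains against a template library
#'
#' Applies a pairwise scorer to every (domain, template) pair. Domains
#' shorter than \code{min_len} residues are rejected (short sequences are
#' not scoreable by threading engines and are removed upstream of any
#' real run). The result is bit-identical regardless of \code{workers}.
#'
#' @param domains a data.frame of domain records as returned by
#'   \code{\link{readAstralFasta}} (columns \code{sid}, \code{sequence}),
#'   or a named character vector of sequences.
#' @param templates a \linkS4class{TemplateLibrary} with sequences.
#' @param scorer a function \code{(query, template) -> numeric}; default
#'   \code{\link{standInScore}}.
#' @param workers positive integer; forked parallelism over domains via
#'   \pkg{parallel} when > 1 (unix only; falls back to serial).
#' @param min_len minimum domain length (default 25 residues).
#' @return a \linkS4class{ScoreMatrix} with rows in domain order and
#'   columns in library order.
#' @export
buildScoreMatrix <- function(domains, templates, scorer = standInScore,
        workers = 1L, min_len = 25L) {
    if (is.data.frame(domains)) {
        seqs <- stats::setNames(as.character(domains$sequence),
            as.character(domains$sid))
    } else {
        seqs <- as.character(domains)
        if (is.null(names(seqs)))
            names(seqs) <- sprintf("domain%03d", seq_along(seqs))
    }
    stopifnot(methods::is(templates, "TemplateLibrary"))
    tseqs <- templateSeqs(templates)
    if (is.null(tseqs))
        .stopf("template library carries no sequences; cannot score")
    tooShort <- nchar(seqs) < min_len
    if (any(tooShort))
        .stopf("domain(s) shorter than %d residues: %s", min_len,
            paste(names(seqs)[tooShort], collapse = ", "))
    tchar <- as.character(tseqs)
    scoreOne <- function(i) {
        vapply(seq_along(tchar), function(j) {
            s <- tryCatch(scorer(seqs[[i]], tchar[[j]]), error = function(e)
                .stopf("scorer failed on pair (%s, %s): %s",
                    names(seqs)[i], templateIds(templates)[j],
                    conditionMessage(e)))
            as.numeric(s)
        }, numeric(1))
    }
    workers <- max(1L, as.integer(workers))
    rows <- if (workers > 1L && .Platform$OS.type == "unix") {
        parallel::mclapply(seq_along(seqs), scoreOne, mc.cores = workers)
    } else {
        lapply(seq_along(seqs), scoreOne)
    }
    m <- do.call(rbind, rows)
    dimnames(m) <- list(names(seqs), templateIds(templates))
    ScoreMatrix(m)
}
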