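#' Construct a template library
#'
#' @param ids character vector of unique template identifiers; their
#'   order is fixed and defines the column order of every score matrix.
#' @param seqs optional amino-acid sequences, one per template: a named
#'   or unnamed character vector or an \code{AAStringSet}.
#' @param folds optional fold label per template (\code{"a.1"} style or a
#'   full sccs, which is truncated to its fold prefix). \code{NA} allowed.
#' @return a \linkS4class{TemplateLibrary}.
#' @examples
#' TemplateLibrary(c("t1", "t2"), folds = c("a.1", "b.2.1.1"))
#' @export
TemplateLibrary <- function(ids, seqs = NULL, folds = NULL) {
    ids <- as.character(ids)
    if (!is.null(seqs)) {
        if (is.character(seqs)) seqs <- Biostrings::AAStringSet(seqs)
        names(seqs) <- ids
    }
    if (!is.null(folds)) {
        folds <- as.character(folds)
        # accept either bare fold labels or full sccs strings
        full <- !is.na(folds) & grepl("^[a-z]\\.[0-9]+\\.", folds)
        folds[full] <- .foldFromSccs(folds[full])
    } else folds <- character(0)
    methods::new("TemplateLibrary", ids = ids, seqs = seqs, folds = folds)
}

#' Read a template library from TSV or FASTA
#'
#' The TSV dialect has a header and columns \code{id}, optionally
#' \code{fold} (an sccs prefix) and \code{sequence}. Alternatively a
#' FASTA file in the Astral header dialect (\code{>sid sccs ...})
#' provides ids, folds and sequences at once.
#'
#' @param path file path.
#' @param format \code{"tsv"} or \code{"fasta"}; guessed from the file
#'   extension by default.
#' @return a \linkS4class{TemplateLibrary}.
#' @export
readTemplateLibrary <- function(path, format = c("auto", "tsv", "fasta")) {
    format <- match.arg(format)
    if (format == "auto")
        format <- if (grepl("\\.(fa|fasta|fna|faa)$", path, ignore.case = TRUE))
            "fasta" else "tsv"
    if (format == "fasta") {
        rec <- readAstralFasta(path)
        return(TemplateLibrary(rec$sid, seqs = rec$sequence, folds = rec$fold))
    }
    tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    if (!"id" %in% names(tab))
        .stopf("template library TSV %s lacks an 'id' column", path)
    TemplateLibrary(tab$id,
        seqs = if ("sequence" %in% names(tab)) tab$sequence else NULL,
        folds = if ("fold" %in% names(tab)) tab$fold else NULL)
}
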