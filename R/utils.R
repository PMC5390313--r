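## Internal helpers shared across modules.

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

## All-pairs Euclidean distances between the rows of A (n x d) and the
## rows of B (m x d), returned as an n x m matrix. Cross-product form;
## small negatives from cancellation are clamped to zero.
.crossDist <- function(A, B) {
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
    d2[d2 < 0] <- 0
    sqrt(d2)
}

## argmin over each row with ties broken by the lowest column index
## (which.min's native behaviour, made explicit here).
.rowArgmin <- function(D) apply(D, 1L, which.min)

.assertColumnsMatch <- function(have, want, what = "matrix") {
    if (length(have) != length(want) || !all(have == want)) {
        missing <- setdiff(want, have)
        extra <- setdiff(have, want)
        if (length(missing) || length(extra))
            .stopf("%s columns do not match the expected template order (missing: %s; unexpected: %s)",
                what,
                if (length(missing)) paste(missing, collapse = ", ") else "none",
                if (length(extra)) paste(extra, collapse = ", ") else "none")
        .stopf("%s columns are a permutation of the expected template order; reorder first",
            what)
    }
    invisible(TRUE)
}

## Amino-acid alphabet check: the 20 standard residues plus the
## ambiguity codes tolerated by common substitution matrices.
.AA_OK <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X", "B", "Z", "U", "*")

.checkAASeq <- function(seq, id = "sequence") {
    if (!is.character(seq) || length(seq) != 1L || is.na(seq) || !nzchar(seq))
        .stopf("%s must be a non-empty amino-acid string", id)
    chars <- strsplit(toupper(seq), "")[[1]]
    bad <- setdiff(unique(chars), .AA_OK)
    if (length(bad))
        .stopf("%s contains characters outside the amino-acid alphabet: %s",
            id, paste(bad, collapse = ", "))
    invisible(toupper(seq))
}

## Derive the fold label (class.fold) from a full sccs string such as
## "a.1.1.2"; returns NA for strings that do not look like an sccs.
.foldFromSccs <- function(sccs) {
    out <- rep(NA_character_, length(sccs))
    ok <- !is.na(sccs) & grepl("^[a-z]\\.[0-9]+(\\.|$)", sccs)
    parts <- strsplit(sccs[ok], ".", fixed = TRUE)
    out[ok] <- vapply(parts, function(p) paste(p[1:2], collapse = "."), "")
    out
}

#' Extract the fold label from an sccs string
#'
#' SCOP concise classification strings (\code{class.fold.superfamily.family},
#' e.g. \code{"a.1.1.2"}) are truncated after the second field to give the
#' fold label (\code{"a.1"}). Strings that do not parse yield \code{NA}.
#'
#' @param sccs character vector of sccs strings.
#' @return character vector of fold labels.
#' @examples
#' foldFromSccs(c("a.1.1.2", "c.37.1.19", "not-an-sccs"))
#' @export
foldFromSccs <- function(sccs) .foldFromSccs(as.character(sccs))
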