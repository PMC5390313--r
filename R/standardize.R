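#' Fit per-template standardization parameters
#'
#' Learns a per-template mean and standard deviation from the training
#' rows only. The population sd (divide by n) is used; see the package
#' vignette for the rationale. Standard deviations are stored unfloored;
#' the zero-sd floor is applied at transform time.
#'
#' @param train a \linkS4class{ScoreMatrix} of raw training scores with
#'   at least two rows.
#' @return a \linkS4class{StandardizationParams}.
#' @seealso \code{\link{applyStandardization}}
#' @export
fitStandardization <- function(train) {
    stopifnot(methods::is(train, "ScoreMatrix"))
    m <- train@scores
    if (nrow(m) < 2L)
        .stopf("standardization needs at least 2 training rows (got %d): sd is undefined for the intended use",
            nrow(m))
    mu <- colMeans(m)
    sd <- sqrt(colMeans(sweep(m, 2L, mu)^2))   # population sd
    methods::new("StandardizationParams", template = colnames(m),
        mean = unname(mu), sd = unname(sd))
}

#' Apply standardization to a score matrix
#'
#' Transforms raw scores into standardized feature-space coordinates:
#' \code{(x - mean) / max(sd, floor)} per template column. Columns that
#' were constant in training (sd = 0) use divisor 1, so they map to
#' all-zero coordinates instead of NaN. Test-time transforms must use
#' parameters learned from training rows; the result's provenance flag
#' records which case this is.
#'
#' @param m a \linkS4class{ScoreMatrix} whose columns match the
#'   parameters' template order.
#' @param p a \linkS4class{StandardizationParams}.
#' @param trainedOn logical; set \code{TRUE} only when \code{m} is the
#'   very matrix \code{p} was fitted on.
#' @return a \linkS4class{PessMatrix}.
#' @export
applyStandardization <- function(m, p, trainedOn = FALSE) {
    stopifnot(methods::is(m, "ScoreMatrix"),
        methods::is(p, "StandardizationParams"))
    .assertColumnsMatch(colnames(m@scores), p@template, "score matrix")
    div <- ifelse(p@sd > 0, p@sd, 1)
    z <- sweep(sweep(m@scores, 2L, p@mean), 2L, div, "/")
    .newPess(z, if (trainedOn) "trained-on" else "transformed-with")
}

#' Fit on training rows and transform train and test together
#'
#' Convenience wrapper enforcing the no-leakage contract: parameters are
#' learned from \code{train} only and applied to both matrices.
#'
#' @param train,test \linkS4class{ScoreMatrix} objects with identical
#'   column order (\code{test} may be \code{NULL}).
#' @return list with elements \code{params}, \code{train}
#'   (provenance \code{"trained-on"}) and \code{test} (provenance
#'   \code{"transformed-with"}, or \code{NULL}).
#' @export
standardizeTrainTest <- function(train, test = NULL) {
    p <- fitStandardization(train)
    list(params = p,
        train = applyStandardization(train, p, trainedOn = TRUE),
        test = if (is.null(test)) NULL else applyStandardization(test, p))
}

#' Persist standardization parameters
#'
#' Writes a TSV (\code{template}, \code{mean}, \code{sd}) plus a JSON
#' sidecar (\code{<path>.json}) with provenance metadata.
#'
#' @param p a \linkS4class{StandardizationParams}.
#' @param path TSV output path.
#' @param metadata optional list merged into the sidecar.
#' @return \code{path}, invisibly.
#' @export
writeStandardizationParams <- function(p, path, metadata = list()) {
    stopifnot(methods::is(p, "StandardizationParams"))
    utils::write.table(
        data.frame(template = p@template, mean = p@mean, sd = p@sd),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    side <- c(list(format = "pessr-standardization-params",
        version = 1L, n_templates = length(p@template),
        sd_kind = "population", sd_zero_rule = "divisor 1 at transform time"),
        metadata)
    jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
    invisible(path)
}

#' Read persisted standardization parameters
#'
#' @param path TSV path written by \code{\link{writeStandardizationParams}}.
#' @return a \linkS4class{StandardizationParams}.
#' @export
readStandardizationParams <- function(path) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("template", "mean", "sd") %in% names(tab)))
        .stopf("%s is not a standardization parameter table", path)
    methods::new("StandardizationParams", template = tab$template,
        mean = tab$mean, sd = tab$sd)
}
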