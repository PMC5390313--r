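#' Leave-own-fold-out nearest-neighbour distance pairs
#'
#' For each labelled query, computes its nearest-neighbour distance to
#' the full training set (\code{d_with}) and again after removing every
#' training row of the query's own fold (\code{d_without}). The
#' \code{d_without} population emulates queries whose true fold is not
#' represented in training, which is what the rejection threshold must
#' catch. Both distances live in the standardized feature space;
#' \code{d_without >= d_with} always.
#'
#' @param model an \linkS4class{NNModel}; must contain at least two
#'   distinct folds.
#' @param queries a \linkS4class{PessMatrix} of labelled queries.
#' @param query_folds fold label per query; every fold must be present
#'   in the model.
#' @return data.frame with columns \code{domain_id}, \code{fold},
#'   \code{d_with}, \code{d_without}.
#' @seealso \code{\link{calibrateThreshold}}
#' @export
leaveFoldOutDistances <- function(model, queries, query_folds) {
    stopifnot(methods::is(model, "NNModel"),
        methods::is(queries, "PessMatrix"))
    query_folds <- as.character(query_folds)
    if (length(query_folds) != nrow(queries@scores))
        .stopf("query_folds must align with query rows")
    if (length(unique(model@labels)) < 2L)
        .stopf("model must contain at least two folds to leave one out")
    absent <- setdiff(unique(query_folds), unique(model@labels))
    if (length(absent))
        .stopf("query fold(s) absent from the model: %s",
            paste(absent, collapse = ", "))
    .assertColumnsMatch(colnames(queries@scores),
        colnames(model@features@scores), "query")
    D <- .crossDist(queries@scores, model@features@scores)
    dWith <- apply(D, 1L, min)
    dWithout <- vapply(seq_len(nrow(D)), function(i) {
        keep <- model@labels != query_folds[i]
        min(D[i, keep])
    }, numeric(1))
    data.frame(domain_id = rownames(queries@scores), fold = query_folds,
        d_with = dWith, d_without = dWithout,
        stringsAsFactors = FALSE, row.names = NULL)
}

#' Calibrate the rejection threshold from distance pairs
#'
#' Sweeps a grid of candidate thresholds t and computes, at each t,
#' FPR(t) — the fraction of fold-absent nearest-neighbour distances
#' (\code{d_without}) strictly below t, i.e. queries that would be
#' wrongly accepted — and FNR(t) — the fraction of fold-present
#' distances (\code{d_with}) at or above t, i.e. queries wrongly
#' rejected. The chosen threshold is the grid point minimising
#' |FPR - FNR| (the balance point), ties going to the smaller t.
#'
#' @param pairs a data.frame with columns \code{d_with} and
#'   \code{d_without} (as from \code{\link{leaveFoldOutDistances}}), or a
#'   list with numeric elements \code{d_with} and \code{d_without} of
#'   possibly different lengths (two independent populations).
#' @param grid ordered numeric candidate thresholds; default 0 to the
#'   maximum observed distance in steps of 0.5.
#' @return a \linkS4class{ThresholdCalibration}.
#' @export
calibrateThreshold <- function(pairs, grid = NULL) {
    dWith <- pairs$d_with
    dWithout <- pairs$d_without
    if (is.null(dWith) || is.null(dWithout) ||
        length(dWith) < 1L || length(dWithout) < 1L)
        .stopf("pairs must provide non-empty d_with and d_without distances")
    if (is.data.frame(pairs) && nrow(pairs) < 2L)
        .stopf("calibration needs at least 2 distance pairs")
    if (is.null(grid))
        grid <- seq(0, max(dWith, dWithout), by = 0.5)
    grid <- sort(unique(as.numeric(grid)))
    if (!length(grid)) .stopf("threshold grid must be non-empty")
    fpr <- vapply(grid, function(t) mean(dWithout < t), numeric(1))
    fnr <- vapply(grid, function(t) mean(dWith >= t), numeric(1))
    i <- which.min(abs(fpr - fnr))   # first minimum = smallest t
    methods::new("ThresholdCalibration",
        grid = data.frame(t = grid, fpr = fpr, fnr = fnr),
        threshold = grid[i], fpr = fpr[i], fnr = fnr[i],
        metadata = list(
            fpr_definition = "fraction of fold-absent NN distances (d_without) < t",
            fnr_definition = "fraction of fold-present NN distances (d_with) >= t",
            selection = "argmin |fpr - fnr|, ties to smaller t",
            n_with = length(dWith), n_without = length(dWithout)))
}

#' Write a calibration report
#'
#' Writes the rate curves as TSV (\code{t}, \code{fpr}, \code{fnr}) and a
#' JSON summary (chosen threshold, achieved rates, rate definitions) to
#' \code{<path>.json}.
#'
#' @param x a \linkS4class{ThresholdCalibration}.
#' @param path TSV output path.
#' @return \code{path}, invisibly.
#' @export
writeCalibrationReport <- function(x, path) {
    stopifnot(methods::is(x, "ThresholdCalibration"))
    utils::write.table(x@grid, path, sep = "\t", quote = FALSE,
        row.names = FALSE)
    jsonlite::write_json(c(list(threshold = x@threshold, fpr = x@fpr,
        fnr = x@fnr), x@metadata), paste0(path, ".json"),
        auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' Named threshold presets
#'
#' The distance thresholds used at the different stages of a
#' proteome-scale run: \code{classify} for confident fold assignment,
#' \code{explore} for a looser exploratory search, and \code{novelty}
#' for selecting far-from-training domains as novel-fold candidates.
#' The defaults are the constants used throughout the package's
#' reference workflow; recalibrate with
#' \code{\link{calibrateThreshold}} whenever the feature space or
#' training set changes.
#'
#' @return named numeric vector.
#' @export
thresholdPresets <- function() {
    c(classify = 17.5, explore = 20, novelty = 30)
}
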