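#' Save a fitted model to a versioned archive
#'
#' Serialises the model together with a format tag, a format version and
#' the training metadata, so archives written by older package versions
#' can be recognised and refused rather than misread.
#'
#' @param model an \linkS4class{NNModel}, \linkS4class{SVMModel}, a
#'   combined-model list, or a \linkS4class{ThresholdCalibration}.
#' @param path output file path (RDS).
#' @param extra optional list of metadata stored alongside.
#' @return \code{path}, invisibly.
#' @export
saveModel <- function(model, path, extra = list()) {
    archive <- list(format = "pessr-model-archive", version = 1L,
        class = class(model)[1L], created = format(Sys.time(), tz = "UTC"),
        package_version = as.character(utils::packageVersion("pessr")),
        metadata = extra, model = model)
    saveRDS(archive, path)
    invisible(path)
}

#' Load a model archive
#'
#' @param path path written by \code{\link{saveModel}}.
#' @return the stored model, with the archive metadata attached as the
#'   \code{"archive"} attribute.
#' @export
loadModel <- function(path) {
    if (!file.exists(path)) .stopf("model archive not found: %s", path)
    archive <- readRDS(path)
    if (!identical(archive$format, "pessr-model-archive"))
        .stopf("%s is not a model archive", path)
    if (archive$version > 1L)
        .stopf("model archive version %d is newer than this package understands",
            archive$version)
    model <- archive$model
    attr(model, "archive") <- archive[setdiff(names(archive), "model")]
    model
}

#' Write classification results to TSV
#'
#' Column layout \code{domain_id}, \code{predicted_fold},
#' \code{nn_distance}, \code{svm_confidence}, \code{phase}; the
#' rejection sentinel is spelled \code{NO_CLASSIFICATION} literally.
#'
#' @param results a classification result data.frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writePredictions <- function(results, path) {
    cols <- c("domain_id", "predicted_fold", "nn_distance",
        "svm_confidence", "phase")
    for (c in setdiff(cols, names(results))) results[[c]] <- NA
    utils::write.table(results[, cols], path, sep = "\t", quote = FALSE,
        row.names = FALSE)
    invisible(path)
}

#' Read classification results written by \code{\link{writePredictions}}
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
readPredictions <- function(path) {
    utils::read.delim(path, stringsAsFactors = FALSE)
}
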