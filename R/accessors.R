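#' @include AllClasses.R AllGenerics.R
NULL

#' @rdname ScoreMatrix-class
#' @param x a \linkS4class{ScoreMatrix}, \linkS4class{PessMatrix} or model
#'   object.
#' @export
setMethod("scores", "ScoreMatrix", function(x) x@scores)

#' @rdname ScoreMatrix-class
#' @export
setMethod("domainIds", "ScoreMatrix", function(x) rownames(x@scores))

#' @rdname TemplateLibrary-class
#' @param x a \linkS4class{TemplateLibrary} (or, for \code{templateIds},
#'   any object with template columns).
#' @export
setMethod("templateIds", "TemplateLibrary", function(x) x@ids)

#' @rdname TemplateLibrary-class
#' @export
setMethod("templateFolds", "TemplateLibrary", function(x) {
    if (length(x@folds)) stats::setNames(x@folds, x@ids) else NULL
})

#' @rdname TemplateLibrary-class
#' @export
setMethod("templateSeqs", "TemplateLibrary", function(x) x@seqs)

#' @rdname ScoreMatrix-class
#' @export
setMethod("templateIds", "ScoreMatrix", function(x) colnames(x@scores))

#' @rdname PessMatrix-class
#' @param x a \linkS4class{PessMatrix}.
#' @export
setMethod("provenance", "PessMatrix", function(x) x@provenance)

#' @rdname NNModel-class
#' @param x an \linkS4class{NNModel}.
#' @export
setMethod("foldLabels", "NNModel", function(x) x@labels)

#' @rdname NNModel-class
#' @export
setMethod("scores", "NNModel", function(x) x@features@scores)

#' @rdname NNModel-class
#' @export
setMethod("templateIds", "NNModel", function(x) colnames(x@features@scores))

#' @rdname SVMModel-class
#' @param x an \linkS4class{SVMModel}.
#' @export
setMethod("foldLabels", "SVMModel", function(x) rownames(x@weights))

#' @rdname SVMModel-class
#' @export
setMethod("templateIds", "SVMModel", function(x) x@templates)

#' @rdname ThresholdCalibration-class
#' @param x a \linkS4class{ThresholdCalibration}.
#' @export
setMethod("chosenThreshold", "ThresholdCalibration", function(x) x@threshold)

#' @rdname ThresholdCalibration-class
#' @export
setMethod("rateCurves", "ThresholdCalibration", function(x) x@grid)

setMethod("show", "TemplateLibrary", function(object) {
    cat(sprintf("TemplateLibrary with %d templates\n", length(object@ids)))
    cat(sprintf("  sequences: %s, folds: %s\n",
        if (is.null(object@seqs)) "absent" else "present",
        if (length(object@folds)) sprintf("%d annotated",
            sum(!is.na(object@folds))) else "absent"))
})

setMethod("show", "ScoreMatrix", function(object) {
    cat(sprintf("%s: %d domains x %d templates\n", class(object),
        nrow(object@scores), ncol(object@scores)))
    if (methods::is(object, "PessMatrix"))
        cat(sprintf("  standardized (%s)\n", object@provenance))
})

setMethod("show", "NNModel", function(object) {
    cat(sprintf("NNModel: %d training rows, %d folds, %d features\n",
        nrow(object@features@scores), length(unique(object@labels)),
        ncol(object@features@scores)))
})

setMethod("show", "SVMModel", function(object) {
    cat(sprintf(
        "SVMModel: one-vs-all linear SVM over %d large folds (%d features)\n",
        nrow(object@weights), ncol(object@weights)))
    cat(sprintf("  %d small folds excluded (min_examples = %s)\n",
        length(object@smallFolds),
        as.character(object@metadata$min_examples)))
})

setMethod("show", "ThresholdCalibration", function(object) {
    cat(sprintf(
        "ThresholdCalibration: threshold %.3g (FPR %.3f, FNR %.3f), grid of %d\n",
        object@threshold, object@fpr, object@fnr, nrow(object@grid)))
})

#' Dimensions of a score matrix
#'
#' @param x a \linkS4class{ScoreMatrix}.
#' @return \code{dim} of the underlying matrix.
#' @export
setMethod("dim", "ScoreMatrix", function(x) dim(x@scores))
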