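#' @include AllClasses.R
NULL

#' @rdname ScoreMatrix-class
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @rdname ScoreMatrix-class
#' @export
setGeneric("domainIds", function(x) standardGeneric("domainIds"))

#' @rdname TemplateLibrary-class
#' @export
setGeneric("templateIds", function(x) standardGeneric("templateIds"))

#' @rdname TemplateLibrary-class
#' @export
setGeneric("templateFolds", function(x) standardGeneric("templateFolds"))

#' @rdname TemplateLibrary-class
#' @export
setGeneric("templateSeqs", function(x) standardGeneric("templateSeqs"))

#' @rdname PessMatrix-class
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname NNModel-class
#' @export
setGeneric("foldLabels", function(x) standardGeneric("foldLabels"))

#' @rdname ThresholdCalibration-class
#' @export
setGeneric("chosenThreshold", function(x) standardGeneric("chosenThreshold"))

#' @rdname ThresholdCalibration-class
#' @export
setGeneric("rateCurves", function(x) standardGeneric("rateCurves"))
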