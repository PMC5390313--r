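#' Template library
#'
#' An ordered library of structure templates against which query domains
#' are scored. The library order is authoritative: it defines the column
#' order of every \linkS4class{ScoreMatrix} built against it. Sequences
#' and fold annotations are optional, but when present they align 1:1
#' with the template identifiers. Fold annotations are required by
#' \code{\link{topTemplateBaseline}}.
#'
#' @slot ids character vector of unique template identifiers.
#' @slot seqs \code{AAStringSet} of template amino-acid sequences, or an
#'   empty set when sequences are not available.
#' @slot folds character vector of fold labels (\code{"a.1"} style), or
#'   \code{character(0)} when not annotated. May contain \code{NA}.
#'
#' @seealso \code{\link{TemplateLibrary}}, \code{\link{readTemplateLibrary}}
#' @name TemplateLibrary-class
#' @aliases TemplateLibrary-class templateIds templateFolds templateSeqs
#' @exportClass TemplateLibrary
setClass("TemplateLibrary",
    representation(ids = "character", seqs = "ANY", folds = "character"),
    prototype(ids = character(0), seqs = NULL, folds = character(0)))

setValidity("TemplateLibrary", function(object) {
    msg <- character(0)
    if (anyDuplicated(object@ids))
        msg <- c(msg, sprintf("duplicated template ids: %s",
            paste(unique(object@ids[duplicated(object@ids)]), collapse = ", ")))
    if (any(is.na(object@ids)) || any(!nzchar(object@ids)))
        msg <- c(msg, "template ids must be non-empty and non-NA")
    if (!is.null(object@seqs)) {
        if (!methods::is(object@seqs, "AAStringSet"))
            msg <- c(msg, "seqs must be an AAStringSet or NULL")
        else if (length(object@seqs) != length(object@ids))
            msg <- c(msg, "seqs must align 1:1 with ids")
    }
    if (length(object@folds) && length(object@folds) != length(object@ids))
        msg <- c(msg, "folds must align 1:1 with ids")
    if (length(msg)) msg else TRUE
})

#' Raw query-by-template score matrix
#'
#' Dense matrix of raw compatibility scores, one row per query domain and
#' one column per template, in the template library's order. Higher
#' scores mean greater compatibility. These raw coordinates are the
#' pre-standardization positions of domains in the empirical structure
#' feature space; all classification happens after z-standardization
#' (see \code{\link{fitStandardization}}).
#'
#' @slot scores numeric matrix with unique, non-NA row names (domain
#'   identifiers) and column names (template identifiers); no missing
#'   cells.
#'
#' @seealso \code{\link{ScoreMatrix}}, \code{\link{readScoreMatrix}},
#'   \code{\link{buildScoreMatrix}}
#' @name ScoreMatrix-class
#' @aliases ScoreMatrix-class scores domainIds
#' @exportClass ScoreMatrix
setClass("ScoreMatrix", representation(scores = "matrix"))

.validScoreCore <- function(object) {
    msg <- character(0)
    m <- object@scores
    if (!is.numeric(m))
        msg <- c(msg, "scores must be numeric")
    if (is.null(rownames(m)) || is.null(colnames(m)))
        msg <- c(msg, "scores must carry row (domain) and column (template) names")
    else {
        if (anyDuplicated(rownames(m)))
            msg <- c(msg, sprintf("duplicated domain ids: %s",
                paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", ")))
        if (anyDuplicated(colnames(m)))
            msg <- c(msg, sprintf("duplicated template ids: %s",
                paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", ")))
    }
    if (anyNA(m))
        msg <- c(msg, "scores must not contain missing cells")
    msg
}

setValidity("ScoreMatrix", function(object) {
    msg <- .validScoreCore(object)
    if (length(msg)) msg else TRUE
})

#' Standardized feature matrix
#'
#' A \linkS4class{ScoreMatrix} after per-template z-standardization; the
#' coordinates on which all Euclidean distances (nearest-neighbour
#' distances, the rejection thresholds) are computed. The provenance flag
#' records whether the standardization parameters were fitted on these
#' very rows (\code{"trained-on"}) or learned elsewhere and applied here
#' (\code{"transformed-with"}); test-time transforms never recompute
#' moments from test rows.
#'
#' @slot provenance either \code{"trained-on"} or \code{"transformed-with"}.
#'
#' @seealso \code{\link{applyStandardization}}
#' @name PessMatrix-class
#' @aliases PessMatrix-class provenance
#' @exportClass PessMatrix
setClass("PessMatrix", contains = "ScoreMatrix",
    representation(provenance = "character"),
    prototype(provenance = "transformed-with"))

setValidity("PessMatrix", function(object) {
    if (length(object@provenance) != 1L ||
        !object@provenance %in% c("trained-on", "transformed-with"))
        return("provenance must be 'trained-on' or 'transformed-with'")
    TRUE
})

#' Per-template standardization parameters
#'
#' Column-wise mean and standard deviation learned from training rows
#' only. Standard deviations are stored as computed (population sd,
#' divide by n); a zero sd is replaced by a unit divisor at transform
#' time so constant templates map to all-zero coordinates rather than
#' NaN.
#'
#' @slot template character vector, template order (matches the library).
#' @slot mean numeric vector of per-template means.
#' @slot sd numeric vector of per-template population sds (>= 0),
#'   pre-flooring.
#'
#' @seealso \code{\link{fitStandardization}},
#'   \code{\link{applyStandardization}}
#' @name StandardizationParams-class
#' @exportClass StandardizationParams
setClass("StandardizationParams",
    representation(template = "character", mean = "numeric", sd = "numeric"))

setValidity("StandardizationParams", function(object) {
    msg <- character(0)
    n <- length(object@template)
    if (length(object@mean) != n || length(object@sd) != n)
        msg <- c(msg, "template, mean and sd must have equal length")
    if (anyDuplicated(object@template))
        msg <- c(msg, "duplicated template ids")
    if (any(object@sd < 0, na.rm = TRUE))
        msg <- c(msg, "sd values must be >= 0")
    if (length(msg)) msg else TRUE
})

#' First-nearest-neighbour fold model
#'
#' A lazy classifier: the standardized training coordinates and their
#' fold labels, stored verbatim. Adding a training example is a plain
#' append (\code{\link{appendTraining}}); no refit is needed.
#'
#' @slot features \linkS4class{PessMatrix} of training rows.
#' @slot labels character fold label per training row.
#' @slot params the \linkS4class{StandardizationParams} the features were
#'   standardized with, or \code{NULL}.
#'
#' @seealso \code{\link{trainNN}}, \code{\link{classifyNN}}
#' @name NNModel-class
#' @aliases NNModel-class foldLabels
#' @exportClass NNModel
setClass("NNModel",
    representation(features = "PessMatrix", labels = "character",
        params = "ANY"),
    prototype(params = NULL))

setValidity("NNModel", function(object) {
    msg <- character(0)
    if (length(object@labels) != nrow(object@features@scores))
        msg <- c(msg, "labels must align 1:1 with training rows")
    if (nrow(object@features@scores) == 0L)
        msg <- c(msg, "training set must not be empty")
    if (length(msg)) msg else TRUE
})

#' One-vs-all linear SVM fold model
#'
#' One binary linear decision function per "large" fold (a fold with at
#' least \code{min_examples} training rows), trained fold-vs-rest with
#' misclassification penalty C = 1/N where N is the fold's number of
#' positive examples. Decision functions are stored as explicit weight
#' vectors and offsets so that signed distances to each hyperplane are
#' computed by linear algebra, independent of the fitting backend.
#'
#' @slot weights numeric matrix, one row per large fold (rownames are
#'   fold labels), columns in template order.
#' @slot offsets numeric intercept per large fold.
#' @slot counts integer number of positive training examples per large fold.
#' @slot cost numeric penalty constant per large fold (1/N).
#' @slot smallFolds character labels of folds excluded for having fewer
#'   than \code{min_examples} training rows.
#' @slot templates character template (column) order.
#' @slot metadata list of training settings (solver, tolerance, seed,
#'   \code{min_examples}, confidence scaling).
#'
#' @seealso \code{\link{trainSVM}}, \code{\link{classifySVM}},
#'   \code{\link{classifyCombined}}
#' @name SVMModel-class
#' @exportClass SVMModel
setClass("SVMModel",
    representation(weights = "matrix", offsets = "numeric",
        counts = "integer", cost = "numeric", smallFolds = "character",
        templates = "character", metadata = "list"))

setValidity("SVMModel", function(object) {
    msg <- character(0)
    k <- nrow(object@weights)
    if (is.null(rownames(object@weights)))
        msg <- c(msg, "weights must carry fold labels as rownames")
    if (length(object@offsets) != k || length(object@counts) != k ||
        length(object@cost) != k)
        msg <- c(msg, "offsets, counts and cost must align with weights rows")
    if (ncol(object@weights) != length(object@templates))
        msg <- c(msg, "weights columns must align with templates")
    if (length(msg)) msg else TRUE
})

#' Rejection-threshold calibration
#'
#' The grid of candidate nearest-neighbour distance thresholds with the
#' false-positive-rate and false-negative-rate curves, and the selected
#' balance point. FPR(t) is the fraction of fold-absent nearest-neighbour
#' distances strictly below t (queries that would be wrongly accepted);
#' FNR(t) is the fraction of fold-present distances at or above t
#' (queries wrongly rejected). The chosen threshold minimises |FPR - FNR|
#' on the grid, ties going to the smaller threshold.
#'
#' @slot grid data.frame with columns \code{t}, \code{fpr}, \code{fnr}.
#' @slot threshold the selected threshold (always a grid value).
#' @slot fpr,fnr the rates achieved at the selected threshold.
#' @slot metadata list recording the rate definitions and input sizes.
#'
#' @seealso \code{\link{calibrateThreshold}},
#'   \code{\link{leaveFoldOutDistances}}
#' @name ThresholdCalibration-class
#' @aliases ThresholdCalibration-class chosenThreshold rateCurves
#' @exportClass ThresholdCalibration
setClass("ThresholdCalibration",
    representation(grid = "data.frame", threshold = "numeric",
        fpr = "numeric", fnr = "numeric", metadata = "list"))

setValidity("ThresholdCalibration", function(object) {
    msg <- character(0)
    if (!all(c("t", "fpr", "fnr") %in% names(object@grid)))
        msg <- c(msg, "grid must have columns t, fpr, fnr")
    else if (!object@threshold %in% object@grid$t)
        msg <- c(msg, "chosen threshold must be on the grid")
    if (length(msg)) msg else TRUE
})
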