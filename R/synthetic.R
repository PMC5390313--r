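#' Generate a synthetic score matrix with controlled fold structure
#'
#' Emulates the geometry that makes the empirical feature space work:
#' each fold occupies a compact region around a centroid, and members
#' scatter isotropically around it. Centroids are placed on orthonormal
#' directions (QR decomposition of a seeded Gaussian matrix) scaled so
#' that every pairwise centroid distance is exactly
#' \code{centroid_separation}. Noise is Gaussian and isotropic with
#' \code{noise_sd} measured on the distance scale — the RMS norm of a
#' member's displacement from its centroid is \code{noise_sd} regardless
#' of the number of templates — so the ratio
#' \code{centroid_separation / noise_sd} is a dimension-free separation
#' regime. Orphan folds (one member) are allowed.
#'
#' @param n_folds number of folds (>= 1; at most \code{n_templates},
#'   the orthonormal-frame capacity).
#' @param members_per_fold integer, or an integer vector of length
#'   \code{n_folds}.
#' @param n_templates feature-space dimension.
#' @param centroid_separation pairwise centroid distance Delta.
#' @param noise_sd within-fold dispersion sigma (>= 0), distance scale.
#' @param seed integer seed; same spec + seed is bit-reproducible.
#' @return list with \code{scores} (a \linkS4class{ScoreMatrix}),
#'   \code{labels} (fold per row) and \code{centroids} (fold-by-template
#'   matrix).
#' @export
generateSyntheticPess <- function(n_folds, members_per_fold, n_templates,
        centroid_separation, noise_sd, seed = 1L) {
    stopifnot(n_folds >= 1, n_templates >= 1, centroid_separation >= 0,
        noise_sd >= 0)
    if (n_folds > n_templates)
        .stopf("n_folds (%d) exceeds n_templates (%d): cannot place orthonormal centroids",
            n_folds, n_templates)
    members <- if (length(members_per_fold) == 1L)
        rep(as.integer(members_per_fold), n_folds)
        else as.integer(members_per_fold)
    if (length(members) != n_folds || any(members < 1L))
        .stopf("members_per_fold must be a positive count or one per fold")
    set.seed(seed)
    C <- .orthonormalCentroids(n_folds, n_templates, centroid_separation)
    foldNames <- .syntheticFoldNames(n_folds)
    dimnames(C) <- list(foldNames,
        sprintf("t%04d", seq_len(n_templates)))
    labels <- rep(foldNames, members)
    n <- length(labels)
    noise <- matrix(stats::rnorm(n * n_templates,
        sd = noise_sd / sqrt(n_templates)), n, n_templates)
    m <- C[labels, , drop = FALSE] + noise
    dimnames(m) <- list(sprintf("dom%05d", seq_len(n)),
        colnames(C))
    list(scores = ScoreMatrix(m), labels = labels, centroids = C)
}

## k orthonormal directions in d dimensions, scaled so that all pairwise
## centroid distances equal delta exactly.
.orthonormalCentroids <- function(k, d, delta) {
    Q <- qr.Q(qr(matrix(stats::rnorm(d * k), d, k)))
    t(Q) * delta / sqrt(2)
}

.syntheticFoldNames <- function(k) {
    sprintf("%s.%d", letters[(seq_len(k) - 1L) %% 7L + 1L], seq_len(k))
}

#' Generate a rejection-threshold testbed
#'
#' Builds a training set from \code{n_folds} fold centroids plus a query
#' set in which a stated fraction of queries belong to folds absent from
#' training. Absent-fold queries are drawn from additional held-out
#' centroids on the same orthonormal frame, so they sit at the same
#' centroid separation from every training fold — exactly the population
#' the rejection threshold must turn away.
#'
#' @inheritParams generateSyntheticPess
#' @param rejection_fraction fraction of queries that are fold-absent,
#'   in [0, 1].
#' @param n_queries total number of queries (default \code{n_folds}).
#' @return list with \code{train} (\linkS4class{ScoreMatrix}),
#'   \code{train_labels}, \code{queries} (\linkS4class{ScoreMatrix}),
#'   \code{query_folds} and \code{present} (logical: query fold present
#'   in training).
#' @export
generateThresholdTestbed <- function(n_folds, members_per_fold, n_templates,
        centroid_separation, noise_sd, rejection_fraction,
        n_queries = n_folds, seed = 1L) {
    stopifnot(rejection_fraction >= 0, rejection_fraction <= 1,
        n_queries >= 1)
    nAbsentQ <- round(rejection_fraction * n_queries)
    nPresentQ <- n_queries - nAbsentQ
    nAbsentFolds <- nAbsentQ   # one held-out centroid per absent query
    if (n_folds + nAbsentFolds > n_templates)
        .stopf("rejection_fraction %.2f needs %d held-out fold centroids, but only %d orthonormal directions remain beyond the %d training folds",
            rejection_fraction, nAbsentFolds, n_templates - n_folds, n_folds)
    set.seed(seed)
    k <- n_folds + nAbsentFolds
    C <- .orthonormalCentroids(k, n_templates, centroid_separation)
    foldNames <- .syntheticFoldNames(k)
    dimnames(C) <- list(foldNames, sprintf("t%04d", seq_len(n_templates)))
    presentFolds <- foldNames[seq_len(n_folds)]
    absentFolds <- setdiff(foldNames, presentFolds)

    members <- if (length(members_per_fold) == 1L)
        rep(as.integer(members_per_fold), n_folds)
        else as.integer(members_per_fold)
    trainLabels <- rep(presentFolds, members)
    sdc <- noise_sd / sqrt(n_templates)
    draw <- function(folds) {
        m <- C[folds, , drop = FALSE] +
            matrix(stats::rnorm(length(folds) * n_templates, sd = sdc),
                length(folds), n_templates)
        colnames(m) <- colnames(C)
        m
    }
    train <- draw(trainLabels)
    rownames(train) <- sprintf("train%05d", seq_along(trainLabels))
    queryFolds <- c(
        if (nPresentQ) rep_len(presentFolds, nPresentQ),
        absentFolds)
    queries <- draw(queryFolds)
    rownames(queries) <- sprintf("query%05d", seq_along(queryFolds))
    list(train = ScoreMatrix(train), train_labels = trainLabels,
        queries = ScoreMatrix(queries), query_folds = queryFolds,
        present = queryFolds %in% presentFolds)
}

#' Generate toy amino-acid sequences with scheduled pairwise identity
#'
#' For each of \code{n} random base sequences, emits mutated copies at
#' the identity levels in \code{identity_schedule}: a copy at level p
#' has \code{round((1 - p) * length)} positions substituted with a
#' different residue, so its exact identity to its base is close to p
#' (alignment-measured identity can differ slightly when the optimal
#' local alignment drops mutated ends). Useful for exercising
#' \code{\link{filterByIdentity}} with known ground truth.
#'
#' @param n number of base sequences.
#' @param length residue length (>= 25).
#' @param identity_schedule numeric identities in [0, 1]; may be empty
#'   for bases only.
#' @param seed integer seed.
#' @return data.frame with columns \code{sid}, \code{sequence},
#'   \code{length}, \code{base}, \code{target_identity} (NA for bases).
#' @export
generateToySequences <- function(n, length, identity_schedule = numeric(0),
        seed = 1L) {
    stopifnot(n >= 1, length >= 25)
    identity_schedule <- as.numeric(identity_schedule)
    if (any(is.na(identity_schedule)) || any(identity_schedule < 0) ||
        any(identity_schedule > 1))
        .stopf("identity_schedule values must lie in [0, 1]")
    set.seed(seed)
    aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    recs <- list()
    for (i in seq_len(n)) {
        base <- sample(aa, length, replace = TRUE)
        sid <- sprintf("base%02d", i)
        recs[[base::length(recs) + 1L]] <- data.frame(sid = sid,
            sequence = paste(base, collapse = ""), length = length,
            base = sid, target_identity = NA_real_,
            stringsAsFactors = FALSE)
        for (p in identity_schedule) {
            nMut <- round((1 - p) * length)
            mut <- base
            if (nMut > 0) {
                pos <- sample(length, nMut)
                for (j in pos)
                    mut[j] <- sample(setdiff(aa, mut[j]), 1L)
            }
            recs[[base::length(recs) + 1L]] <- data.frame(
                sid = sprintf("%s_id%02.0f", sid, 100 * p),
                sequence = paste(mut, collapse = ""), length = length,
                base = sid, target_identity = p, stringsAsFactors = FALSE)
        }
    }
    out <- do.call(rbind, recs)
    rownames(out) <- NULL
    out
}
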