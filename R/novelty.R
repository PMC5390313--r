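#' Select domains far from all training examples
#'
#' Candidate novel-fold domains are those whose nearest training
#' neighbour is at distance \code{min_distance} or more (inclusive
#' rule). These are the queries no known fold can plausibly claim, a
#' stricter condition than mere rejection at the classification
#' threshold.
#'
#' @param results a classification result data.frame carrying an
#'   \code{nn_distance} column (see \code{\link{classifyNN}}).
#' @param min_distance inclusive selection threshold (default 30, the
#'   \code{novelty} preset of \code{\link{thresholdPresets}}).
#' @return the selected rows (possibly none).
#' @export
selectUnclassified <- function(results, min_distance = 30) {
    stopifnot(is.data.frame(results))
    if (is.null(results$nn_distance))
        .stopf("results carry no nn_distance column")
    results[results$nn_distance >= min_distance, , drop = FALSE]
}

#' Embed feature-space rows in two dimensions with t-SNE
#'
#' Exact t-SNE on the standardized feature coordinates of the selected
#' domains, with the layout initialised from the first two principal
#' components. Same input and seed reproduce the same coordinates on a
#' given platform; cross-platform bit-equality is not promised, so
#' downstream checks should rely on the embedding's geometry, not raw
#' coordinates.
#'
#' @param features a \linkS4class{PessMatrix} (or plain matrix) of the
#'   selected rows; at least 3 rows, \code{perplexity < nrow}.
#' @param perplexity t-SNE perplexity (default 10).
#' @param init \code{"pca"} (default) or \code{"random"}.
#' @param seed integer seed (default 123).
#' @param ... further arguments to the optimiser (\code{max_iter},
#'   \code{eta}, \code{exaggeration}).
#' @return numeric matrix with one (x, y) row per domain.
#' @export
embed2D <- function(features, perplexity = 10, init = "pca", seed = 123L,
        ...) {
    X <- if (methods::is(features, "ScoreMatrix")) features@scores
        else as.matrix(features)
    .tsneExact(X, dims = 2L, perplexity = perplexity, init = init,
        seed = seed, ...)
}

#' Density-based clustering of embedded points
#'
#' DBSCAN over the 2-D embedding: a core point has at least
#' \code{min_samples} points (itself included) within radius \code{eps};
#' clusters are the connected components of density-reachability, and
#' points neither core nor reachable from one are labelled noise
#' (\code{-1}). Cluster ids are assigned in point order, so the labelling
#' is deterministic; it is invariant to point order up to a relabelling.
#'
#' @param coords numeric matrix of finite coordinates (rows = points).
#' @param eps neighbourhood radius (default 5).
#' @param min_samples minimum neighbourhood size for a core point,
#'   self included (default 5).
#' @return integer vector of cluster ids (1, 2, ...; noise = -1).
#' @export
clusterDensity <- function(coords, eps = 5, min_samples = 5L) {
    coords <- as.matrix(coords)
    if (!all(is.finite(coords))) .stopf("coordinates must be finite")
    n <- nrow(coords)
    if (n == 0L) return(integer(0))
    D <- as.matrix(stats::dist(coords))
    nb <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
    core <- lengths(nb) >= min_samples
    labels <- rep(-1L, n)
    cl <- 0L
    for (i in seq_len(n)) {
        if (!core[i] || labels[i] != -1L) next
        cl <- cl + 1L
        labels[i] <- cl
        queue <- i
        while (length(queue)) {
            j <- queue[[1L]]
            queue <- queue[-1L]
            for (kk in nb[[j]]) {
                if (labels[kk] == -1L) {
                    labels[kk] <- cl
                    if (core[kk]) queue <- c(queue, kk)
                }
            }
        }
    }
    labels
}

#' Summarise candidate novel-fold clusters
#'
#' Per-cluster size and mean residue length, with a flag for clusters
#' whose mean length exceeds \code{long_length} residues — far above a
#' typical domain, which suggests the members are unsplit multi-domain
#' segments (a segmentation error) rather than one novel fold.
#' Unclustered (noise) domains are listed separately, since isolated
#' points can be single examples of novel folds.
#'
#' @param clusters integer cluster ids (noise = -1), aligned with
#'   \code{ids} and \code{lengths}.
#' @param ids domain identifiers.
#' @param lengths residue length per domain.
#' @param long_length mean-length flag threshold (default 500).
#' @return list with \code{clusters} (data.frame: \code{cluster},
#'   \code{size}, \code{mean_length}, \code{length_outlier}),
#'   \code{n_clusters} and \code{noise_ids}.
#' @export
summarizeClusters <- function(clusters, ids, lengths, long_length = 500) {
    clusters <- as.integer(clusters)
    if (length(ids) != length(clusters) || length(lengths) != length(clusters))
        .stopf("clusters, ids and lengths must align")
    real <- sort(unique(clusters[clusters != -1L]))
    summ <- data.frame(cluster = real,
        size = vapply(real, function(cl) sum(clusters == cl), integer(1)),
        mean_length = vapply(real, function(cl)
            mean(lengths[clusters == cl]), numeric(1)))
    summ$length_outlier <- summ$mean_length > long_length
    list(clusters = summ, n_clusters = length(real),
        noise_ids = ids[clusters == -1L])
}

#' End-to-end novel-fold candidate report
#'
#' Selects far-from-training domains, embeds their feature-space rows in
#' two dimensions, clusters the embedding and summarises the clusters.
#'
#' @param results classification results with \code{nn_distance}.
#' @param features \linkS4class{PessMatrix} whose rows cover all result
#'   domains (standardized coordinates).
#' @param lengths named numeric vector: residue length per domain id.
#' @param min_distance selection threshold (default 30).
#' @param perplexity,seed embedding settings (see \code{\link{embed2D}});
#'   perplexity is reduced automatically when fewer points are selected
#'   than \code{perplexity + 1}.
#' @param eps,min_samples clustering settings (see
#'   \code{\link{clusterDensity}}).
#' @param long_length segmentation-error flag threshold.
#' @return list with \code{domains} (data.frame: \code{domain_id},
#'   \code{nn_distance}, \code{x}, \code{y}, \code{cluster},
#'   \code{length}), \code{summary} (see \code{\link{summarizeClusters}})
#'   and the settings used.
#' @export
noveltyReport <- function(results, features, lengths, min_distance = 30,
        perplexity = 10, seed = 123L, eps = 5, min_samples = 5L,
        long_length = 500) {
    sel <- selectUnclassified(results, min_distance)
    if (nrow(sel) < 3L)
        .stopf("only %d domain(s) selected at min_distance %g; need at least 3 to embed",
            nrow(sel), min_distance)
    feat <- if (methods::is(features, "ScoreMatrix")) features@scores
        else as.matrix(features)
    missing <- setdiff(sel$domain_id, rownames(feat))
    if (length(missing))
        .stopf("feature rows missing for selected domain(s): %s",
            paste(utils::head(missing, 5L), collapse = ", "))
    X <- feat[sel$domain_id, , drop = FALSE]
    perplexity <- min(perplexity, nrow(X) - 1)
    Y <- embed2D(X, perplexity = perplexity, seed = seed)
    cl <- clusterDensity(Y, eps = eps, min_samples = min_samples)
    len <- unname(lengths[sel$domain_id])
    domains <- data.frame(domain_id = sel$domain_id,
        nn_distance = sel$nn_distance, x = Y[, 1L], y = Y[, 2L],
        cluster = cl, length = len, stringsAsFactors = FALSE,
        row.names = NULL)
    list(domains = domains,
        summary = summarizeClusters(cl, sel$domain_id, len,
            long_length = long_length),
        settings = list(min_distance = min_distance,
            perplexity = perplexity, seed = seed, eps = eps,
            min_samples = min_samples, long_length = long_length))
}
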