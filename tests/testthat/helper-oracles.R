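# Independent oracles used across the suite. These deliberately share no
# code with the package: plain loops and textbook dynamic programming.

# Smith-Waterman with affine gaps (gap of length L costs open + L * ext),
# floored at zero. Three-state DP; returns the optimal local score.
swOracle <- function(a, b, sm, open = 11, ext = 1) {
    A <- strsplit(a, "")[[1]]
    B <- strsplit(b, "")[[1]]
    n <- length(A); m <- length(B)
    M <- matrix(0, n + 1, m + 1)
    Ix <- matrix(-Inf, n + 1, m + 1)   # gap in b (consumes a)
    Iy <- matrix(-Inf, n + 1, m + 1)   # gap in a (consumes b)
    best <- 0
    for (i in 2:(n + 1)) {
        for (j in 2:(m + 1)) {
            s <- sm[A[i - 1], B[j - 1]]
            M[i, j] <- max(0, s + max(M[i - 1, j - 1], Ix[i - 1, j - 1],
                Iy[i - 1, j - 1]))
            Ix[i, j] <- max(M[i - 1, j] - open - ext, Ix[i - 1, j] - ext)
            Iy[i, j] <- max(M[i, j - 1] - open - ext, Iy[i, j - 1] - ext)
            best <- max(best, M[i, j])
        }
    }
    best
}

# All-pairs nearest-neighbour oracle: plain double loop.
nnOracle <- function(trainX, labels, queryX) {
    idx <- integer(nrow(queryX))
    dst <- numeric(nrow(queryX))
    for (q in seq_len(nrow(queryX))) {
        dd <- numeric(nrow(trainX))
        for (t in seq_len(nrow(trainX)))
            dd[t] <- sqrt(sum((queryX[q, ] - trainX[t, ])^2))
        idx[q] <- which.min(dd)
        dst[q] <- dd[idx[q]]
    }
    list(label = labels[idx], distance = dst, index = idx)
}

# DBSCAN reachability oracle: connected components of the core-core
# eps-graph (igraph), plus the admissible cluster set for every border
# point (any neighbouring core's component). Noise is exact; border
# assignment is ambiguous by construction, so the test checks membership.
dbscanOracle <- function(coords, eps, min_samples) {
    D <- as.matrix(dist(coords))
    n <- nrow(D)
    nb <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
    core <- which(lengths(nb) >= min_samples)
    comp <- rep(NA_integer_, n)
    if (length(core)) {
        sub <- D[core, core, drop = FALSE] <= eps
        g <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected",
            diag = FALSE)
        comp[core] <- igraph::components(g)$membership
    }
    admissible <- lapply(seq_len(n), function(i) {
        if (i %in% core) return(comp[i])
        unique(comp[intersect(nb[[i]], core)])
    })
    list(core = core, coreComponent = comp,
        admissible = admissible,
        noise = which(lengths(admissible) == 0L |
            vapply(admissible, function(x) all(is.na(x)), TRUE)))
}

# Confusion-matrix evaluation oracle built from scratch.
evalOracle <- function(pred, truth) {
    folds <- sort(unique(c(truth, setdiff(pred, "NO_CLASSIFICATION"))))
    P <- R <- rep(NA_real_, length(folds))
    for (i in seq_along(folds)) {
        f <- folds[i]
        tp <- sum(pred == f & truth == f)
        fp <- sum(pred == f & truth != f)
        fn <- sum(pred != f & truth == f)
        if (tp + fp > 0) P[i] <- tp / (tp + fp)
        if (tp + fn > 0) R[i] <- tp / (tp + fn)
    }
    list(accuracy = mean(pred == truth),
        macroP = mean(P, na.rm = TRUE), macroR = mean(R, na.rm = TRUE))
}

# Standardized feature fixture: synthetic folds ready for classifiers.
makeStdFixture <- function(n_folds, members, d, delta, sigma, seed) {
    sim <- generateSyntheticPess(n_folds, members, d, delta, sigma,
        seed = seed)
    std <- standardizeTrainTest(sim$scores)
    list(sim = sim, feats = std$train, params = std$params,
        labels = sim$labels)
}

# Random PessMatrix wrapper for matrices built in tests.
asPess <- function(m, ids = NULL, cols = NULL) {
    if (is.null(rownames(m)) && is.null(ids))
        ids <- sprintf("q%03d", seq_len(nrow(m)))
    if (is.null(colnames(m)) && is.null(cols))
        cols <- sprintf("t%03d", seq_len(ncol(m)))
    sm <- ScoreMatrix(m, row_ids = ids, col_ids = cols)
    applyStandardization(sm,
        methods::new("StandardizationParams",
            template = colnames(pessr::scores(sm)),
            mean = rep(0, ncol(m)), sd = rep(1, ncol(m))))
}
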