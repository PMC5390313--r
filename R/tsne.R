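## Exact (non-Barnes-Hut) t-SNE, sufficient for the small domain subsets
## the novelty stage embeds. Conditional probabilities use the standard
## per-point precision binary search to the target perplexity; the layout
## is optimised by momentum gradient descent with adaptive gains and
## early exaggeration.

.tsneAffinities <- function(D2, perplexity, tol = 1e-5, maxTries = 50L) {
    n <- nrow(D2)
    logU <- log(perplexity)
    P <- matrix(0, n, n)
    for (i in seq_len(n)) {
        beta <- 1
        betaMin <- -Inf
        betaMax <- Inf
        di <- D2[i, -i]
        for (tries in seq_len(maxTries)) {
            ex <- exp(-di * beta)
            sumEx <- sum(ex)
            if (sumEx <= 0) { ex <- rep(1, length(di)); sumEx <- length(di) }
            H <- log(sumEx) + beta * sum(di * ex) / sumEx
            diff <- H - logU
            if (is.na(diff) || abs(diff) < tol) break
            if (diff > 0) {
                betaMin <- beta
                beta <- if (is.finite(betaMax)) (beta + betaMax) / 2 else beta * 2
            } else {
                betaMax <- beta
                beta <- if (is.finite(betaMin)) (beta + betaMin) / 2 else beta / 2
            }
        }
        P[i, -i] <- ex / sumEx
    }
    P
}

.tsneExact <- function(X, dims = 2L, perplexity = 10, init = c("pca", "random"),
        seed = 123L, max_iter = 800L, eta = NULL, exaggeration = 12,
        exag_iter = 100L) {
    init <- match.arg(init)
    X <- as.matrix(X)
    n <- nrow(X)
    if (n < 3L) .stopf("t-SNE needs at least 3 rows (got %d)", n)
    if (perplexity >= n)
        .stopf("perplexity (%g) must be smaller than the number of rows (%d)",
            perplexity, n)
    # auto learning rate scaled to the sample size; a fixed large rate
    # overshoots badly on the small subsets this stage embeds
    if (is.null(eta)) eta <- max(n / exaggeration / 4, 50)
    set.seed(seed)
    D2 <- as.matrix(stats::dist(X))^2
    P <- .tsneAffinities(D2, perplexity)
    P <- (P + t(P)) / (2 * n)
    P <- pmax(P, 1e-12)

    Y <- if (init == "pca") {
        pc <- stats::prcomp(X, rank. = dims)$x
        if (ncol(pc) < dims)
            pc <- cbind(pc, matrix(0, n, dims - ncol(pc)))
        s <- stats::sd(pc[, 1L])
        if (s > 0) pc * (1e-4 / s) else pc   # degenerate input: keep zeros
    } else {
        matrix(stats::rnorm(n * dims, sd = 1e-4), n, dims)
    }
    inc <- matrix(0, n, dims)
    gains <- matrix(1, n, dims)
    Pex <- P * exaggeration
    for (iter in seq_len(max_iter)) {
        Pt <- if (iter <= exag_iter) Pex else P
        sumY <- rowSums(Y^2)
        num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Y))
        diag(num) <- 0
        Q <- pmax(num / sum(num), 1e-12)
        L <- (Pt - Q) * num
        grad <- 4 * (diag(rowSums(L)) - L) %*% Y
        gains <- ifelse(sign(grad) != sign(inc), gains + 0.2, gains * 0.8)
        gains[gains < 0.01] <- 0.01
        mom <- if (iter <= 100L) 0.5 else 0.8
        inc <- mom * inc - eta * gains * grad
        Y <- Y + inc
        Y <- sweep(Y, 2L, colMeans(Y))
    }
    dimnames(Y) <- list(rownames(X), paste0("tsne", seq_len(dims)))
    Y
}
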