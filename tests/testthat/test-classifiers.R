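test_that("trainNN stores data verbatim and grows by appending", {
    set.seed(61)
    feats <- asPess(matrix(rnorm(15), 5, 3))
    model <- trainNN(feats, c("a.1", "a.1", "b.2", "c.3", "c.3"))
    expect_equal(nrow(scores(model)), 5L)
    expect_equal(foldLabels(model), c("a.1", "a.1", "b.2", "c.3", "c.3"))

    extra <- asPess(matrix(rnorm(3), 1, 3))
    bigger <- appendTraining(model, extra, "d.4")
    expect_equal(nrow(scores(bigger)), 6L)
    expect_equal(scores(bigger)[1:5, ], scores(model))

    expect_error(trainNN(feats, c("a.1", "b.2")), "align")
    expect_error(trainNN(asPess(matrix(numeric(0), 0, 3)), character(0)),
        "empty|names")
})

test_that("classifyNN recovers an exact training match at distance zero", {
    set.seed(62)
    X <- matrix(rnorm(60), 10, 6)
    model <- trainNN(asPess(X), rep(c("c.37", "d.58"), 5))
    q <- asPess(X[3, , drop = FALSE], ids = "q1")
    res <- classifyNN(model, q)
    expect_equal(res$predicted_fold, "c.37")
    expect_equal(res$nn_distance, 0)
    expect_equal(res$phase, "nn")
})

test_that("classifyNN equals the brute-force all-pairs oracle", {
    set.seed(63)
    for (rep in 1:8) {
        n <- sample(20:80, 1); d <- sample(5:40, 1); q <- sample(5:20, 1)
        X <- matrix(rnorm(n * d), n, d)
        labels <- sample(paste0("f.", 1:6), n, replace = TRUE)
        Q <- matrix(rnorm(q * d), q, d)
        res <- classifyNN(trainNN(asPess(X), labels), asPess(Q))
        orc <- nnOracle(X, labels, Q)
        expect_equal(res$predicted_fold, orc$label)
        expect_equal(res$nn_distance, orc$distance, tolerance = 1e-10)
    }
})

test_that("threshold rejection is strict and monotone", {
    set.seed(64)
    X <- matrix(rnorm(40), 8, 5)
    model <- trainNN(asPess(X), rep(c("a.1", "b.2"), 4))
    # a query exactly at the threshold distance is rejected
    u <- rep(0, 5); u[1] <- 1
    q <- asPess(X[1, , drop = FALSE] + 17.5 * matrix(u, 1, 5), ids = "q1")
    dist0 <- classifyNN(model, q)$nn_distance
    res <- classifyNN(model, q, distance_threshold = dist0)
    expect_equal(res$predicted_fold, "NO_CLASSIFICATION")
    expect_equal(res$phase, "rejected")

    Q <- asPess(matrix(rnorm(100), 20, 5))
    nClassified <- vapply(c(0.5, 1, 2, 4, 8), function(t)
        sum(classifyNN(model, Q, t)$predicted_fold != "NO_CLASSIFICATION"),
        numeric(1))
    expect_true(all(diff(nClassified) >= 0))
    # threshold absent classifies everything
    expect_true(all(classifyNN(model, Q)$phase == "nn"))
})

test_that("consistent feature permutation leaves predictions unchanged", {
    set.seed(65)
    X <- matrix(rnorm(120), 20, 6)
    colnames(X) <- paste0("t", 1:6)
    labels <- sample(paste0("f.", 1:4), 20, replace = TRUE)
    Q <- matrix(rnorm(30), 5, 6, dimnames = list(paste0("q", 1:5),
        colnames(X)))
    perm <- sample(6)
    res1 <- classifyNN(trainNN(asPess(X), labels), asPess(Q))
    res2 <- classifyNN(trainNN(asPess(X[, perm]), labels),
        asPess(Q[, perm]))
    expect_equal(res1$predicted_fold, res2$predicted_fold)
    expect_equal(res1$nn_distance, res2$nn_distance, tolerance = 1e-10)
})

test_that("trainSVM separates large folds and stores C = 1/N", {
    # two folds, 12 rows each, separable along the first coordinate by a
    # wide margin
    set.seed(66)
    X <- rbind(cbind(rnorm(12, -50, 1), matrix(rnorm(36), 12, 3)),
        cbind(rnorm(12, 50, 1), matrix(rnorm(36), 12, 3)))
    labels <- rep(c("a.1", "b.2"), each = 12)
    model <- trainSVM(asPess(X), labels, min_examples = 10)
    pred <- classifySVM(model, asPess(X))
    expect_equal(pred$predicted_fold, labels)
    expect_equal(unname(model@cost), 1 / unname(model@counts))

    # fold with N = 20 stores penalty constant 0.05
    X2 <- rbind(cbind(rnorm(20, -50, 1), matrix(rnorm(60), 20, 3)),
        cbind(rnorm(12, 50, 1), matrix(rnorm(36), 12, 3)))
    m2 <- trainSVM(asPess(X2), rep(c("a.1", "b.2"), c(20, 12)))
    expect_equal(unname(m2@cost[foldLabels(m2) == "a.1"]), 0.05)

    # large-fold filter: counts {12, 11, 4} with min_examples 10 -> 2 folds
    X3 <- matrix(rnorm(27 * 4), 27, 4)
    m3 <- trainSVM(asPess(X3), rep(c("a.1", "b.2", "c.3"), c(12, 11, 4)))
    expect_setequal(foldLabels(m3), c("a.1", "b.2"))
    expect_equal(m3@smallFolds, "c.3")

    expect_error(trainSVM(asPess(X3[1:9, ]), rep("a.1", 9)), "1NN")
})

test_that("classifySVM is the argmax of per-fold signed distances", {
    set.seed(67)
    fx <- makeStdFixture(4, 12, 30, 8, 0.5, seed = 68)
    model <- trainSVM(fx$feats, fx$labels)
    Q <- asPess(matrix(rnorm(10 * 30), 10, 30),
        cols = colnames(scores(fx$feats)))
    conf <- svmConfidences(model, Q)
    # loop oracle over folds: signed distance via stored hyperplanes
    for (f in foldLabels(model)) {
        w <- model@weights[f, ]
        expect_equal(unname(conf[, f]),
            drop(scores(Q) %*% w + model@offsets[foldLabels(model) == f]) /
                sqrt(sum(w^2)), tolerance = 1e-10, ignore_attr = TRUE)
    }
    res <- classifySVM(model, Q)
    for (i in 1:10)
        expect_equal(res$predicted_fold[i],
            colnames(conf)[which.max(conf[i, ])])

    # a query deep in one fold's half-space gets that fold, positively
    deep <- fx$sim$centroids["a.1", , drop = FALSE] * 2
    qd <- applyStandardization(ScoreMatrix(deep, row_ids = "deep"),
        fx$params)
    rd <- classifySVM(model, qd)
    expect_equal(rd$predicted_fold, "a.1")
    expect_gt(rd$svm_confidence, 0)

    # the origin of the standardized space lies between the (>= 3)
    # one-vs-all folds, on every hyperplane's negative side: the argmax
    # fold is still returned, with a negative confidence
    far <- matrix(0, 1, 30,
        dimnames = list("far", colnames(scores(fx$feats))))
    rf <- classifySVM(model, asPess(far))
    cf <- svmConfidences(model, asPess(far))
    expect_true(all(cf < 0))
    expect_equal(rf$predicted_fold, colnames(cf)[which.max(cf)])
})

test_that("stored hyperplanes agree with an independent linear SVM fit", {
    skip_if_not_installed("kernlab")
    set.seed(69)
    X <- rbind(matrix(rnorm(12 * 5, -4), 12, 5),
        matrix(rnorm(14 * 5, 4), 14, 5))
    y <- rep(c("a.1", "b.2"), c(12, 14))
    model <- trainSVM(asPess(X), y, min_examples = 10)
    k <- kernlab::ksvm(X, factor(y), kernel = "vanilladot",
        C = 1 / 12, scaled = FALSE, kpar = list())
    mine <- classifySVM(model, asPess(X))$predicted_fold
    theirs <- as.character(kernlab::predict(k, X))
    expect_gt(mean(mine == theirs), 0.95)
})

test_that("combined classification routes by the sign of the best confidence", {
    set.seed(70)
    sim <- generateSyntheticPess(6, c(15, 15, 15, 3, 2, 1), 40, 8, 0.5,
        seed = 71)
    std <- standardizeTrainTest(sim$scores)
    svm <- trainSVM(std$train, sim$labels)
    small <- sim$labels %in% svm@smallFolds
    feat <- std$train
    feat@scores <- scores(std$train)[small, , drop = FALSE]
    nnSmall <- trainNN(feat, sim$labels[small])

    res <- classifyCombined(svm, nnSmall, std$train)
    conf <- svmConfidences(svm, std$train)
    bestConf <- apply(conf, 1, max)
    expect_equal(res$phase == "svm", unname(bestConf > 0))
    expect_true(all(res$predicted_fold != "NO_CLASSIFICATION"))
    # fallback queries carry the small-fold 1NN label and a distance
    fb <- res$phase == "nn"
    if (any(fb)) {
        qs <- std$train
        qs@scores <- scores(std$train)[fb, , drop = FALSE]
        expect_equal(res$predicted_fold[fb],
            classifyNN(nnSmall, qs)$predicted_fold)
        expect_true(all(!is.na(res$nn_distance[fb])))
    }
    expect_true(all(is.na(res$nn_distance[!fb])))

    # overlap between SVM folds and the small-fold model is refused
    expect_error(classifyCombined(svm, trainNN(std$train, sim$labels),
        std$train), "configuration error")
})
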