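test_that("evaluateFolds reproduces the hand-worked five-item example", {
    truths <- c("A", "A", "B", "B", "C")
    preds <- c("A", "B", "B", "B", "C")
    rep <- evaluateFolds(preds, truths)
    expect_equal(rep$accuracy, 0.8)
    pf <- rep$per_fold
    expect_equal(pf$precision[pf$fold == "A"], 1)
    expect_equal(pf$recall[pf$fold == "A"], 0.5)
    expect_equal(pf$precision[pf$fold == "B"], 2 / 3)
    expect_equal(pf$recall[pf$fold == "B"], 1)
    expect_equal(pf$precision[pf$fold == "C"], 1)
    expect_equal(pf$recall[pf$fold == "C"], 1)
    expect_equal(rep$macro_precision, 8 / 9, tolerance = 1e-12)
    expect_equal(rep$macro_recall, 5 / 6, tolerance = 1e-12)

    # a fold that never occurs is excluded from both averages
    rep2 <- evaluateFolds(preds, truths, fold_universe = c("A", "B", "C", "D"))
    expect_equal(rep2$macro_precision, rep$macro_precision)
    expect_equal(rep2$macro_recall, rep$macro_recall)
    expect_equal(rep2$n_excluded_precision, 1L)
    expect_equal(rep2$n_excluded_recall, 1L)
    pfD <- rep2$per_fold[rep2$per_fold$fold == "D", ]
    expect_false(pfD$included_in_P_avg)
    expect_false(pfD$included_in_R_avg)

    perfect <- evaluateFolds(truths, truths)
    expect_equal(perfect$accuracy, 1)
    expect_true(all(perfect$per_fold$precision == 1))
    expect_true(all(perfect$per_fold$recall == 1))

    expect_error(evaluateFolds(c("A", "B"), c("A")), "align")
})

test_that("evaluateFolds agrees with a confusion-matrix oracle on random runs", {
    set.seed(101)
    for (rep in 1:6) {
        n <- sample(50:300, 1)
        k <- sample(3:20, 1)
        folds <- paste0("f.", seq_len(k))
        truth <- sample(folds, n, replace = TRUE)
        pred <- ifelse(runif(n) < 0.6, truth,
            sample(c(folds, "NO_CLASSIFICATION"), n, replace = TRUE))
        got <- evaluateFolds(pred, truth)
        orc <- evalOracle(pred, truth)
        expect_equal(got$accuracy, orc$accuracy)
        expect_equal(got$macro_precision, orc$macroP)
        expect_equal(got$macro_recall, orc$macroR)
    }
})

test_that("a rejected item is a false negative for its fold, never a true positive", {
    truths <- c("A", "A", "B")
    preds <- c("A", "NO_CLASSIFICATION", "B")
    rep <- evaluateFolds(preds, truths)
    expect_equal(rep$accuracy, 2 / 3)
    pf <- rep$per_fold
    expect_equal(pf$recall[pf$fold == "A"], 0.5)
    expect_equal(pf$precision[pf$fold == "A"], 1)   # the rejection is no FP
    expect_false("NO_CLASSIFICATION" %in% pf$fold)
})

test_that("orphanSubreport restricts metrics to single-example folds", {
    counts <- c(A = 5L, B = 1L, C = 1L, D = 1L, E = 2L)
    truths <- c("B", "B", "C", "D", "A", "E")
    preds <- c("B", "A", "C", "A", "A", "E")
    sub <- orphanSubreport(preds, truths, counts)
    expect_false(sub$empty)
    expect_setequal(sub$orphan_folds, c("B", "C", "D"))
    # 4 orphan-truth items (B, B, C, D), 2 correct
    expect_equal(sub$n, 4L)
    expect_equal(sub$accuracy, 0.5)

    single <- orphanSubreport("B", "B", c(A = 3L, B = 1L))
    expect_equal(single$accuracy, 1)

    none <- orphanSubreport(preds, truths, c(A = 5L, E = 2L))
    expect_true(none$empty)
})

test_that("cross-validation predicts every record exactly once, reproducibly", {
    sim <- generateSyntheticPess(4, 5, 15, 6, 1, seed = 102)
    cv1 <- crossValidate(sim$scores, sim$labels, k = 10, classifier = "nn",
        seed = 7)
    expect_equal(sort(cv1$predictions$domain_id),
        sort(domainIds(sim$scores)))
    expect_equal(nrow(cv1$predictions), length(sim$labels))
    cv2 <- crossValidate(sim$scores, sim$labels, k = 10, classifier = "nn",
        seed = 7)
    expect_identical(cv1$predictions, cv2$predictions)
    expect_identical(cv1$report$accuracy, cv2$report$accuracy)

    expect_error(crossValidate(sim$scores, sim$labels, k = 50), "exceeds")
    expect_error(crossValidate(sim$scores, sim$labels, k = 1), ">= 2")
})

test_that("cross-validation refits standardization inside every part (leakage canary)", {
    # an extreme outlier cohort makes a leaky global standardization
    # visibly different from the honest per-part refit
    set.seed(103)
    sim <- generateSyntheticPess(4, 6, 10, 6, 0.8, seed = 104)
    m <- scores(sim$scores)
    m[1:3, ] <- m[1:3, ] * 400    # outlier rows distort global moments
    raw <- ScoreMatrix(m)
    k <- 4L
    cv <- crossValidate(raw, sim$labels, k = k, classifier = "nn", seed = 9)

    # manual no-leak reference, same partition scheme
    set.seed(9)
    part <- sample(rep_len(seq_len(k), nrow(m)))
    manual <- character(nrow(m))
    for (i in seq_len(k)) {
        tr <- which(part != i); te <- which(part == i)
        mu <- colMeans(m[tr, ]); sdv <- sqrt(colMeans(sweep(m[tr, ], 2, mu)^2))
        sdv[sdv == 0] <- 1
        ztr <- sweep(sweep(m[tr, ], 2, mu), 2, sdv, "/")
        zte <- sweep(sweep(m[te, ], 2, mu), 2, sdv, "/")
        for (q in seq_along(te)) {
            dd <- sqrt(rowSums(sweep(ztr, 2, zte[q, ])^2))
            manual[te[q]] <- sim$labels[tr][which.min(dd)]
        }
    }
    idx <- match(cv$predictions$domain_id, rownames(m))
    expect_equal(cv$predictions$predicted_fold, manual[idx])

    # sanity of the canary itself: the outlier rows make global moments
    # very different from any part's training moments, so a leaky
    # transform would operate in a visibly different space
    muG <- colMeans(m)
    worst <- max(vapply(seq_len(k), function(i) {
        tr <- which(part != i)
        max(abs(muG - colMeans(m[tr, ])) /
            pmax(abs(colMeans(m[tr, ])), 1e-6))
    }, numeric(1)))
    expect_gt(worst, 0.5)
})

test_that("memorizing duplicates across partitions yields perfect accuracy", {
    sim <- generateSyntheticPess(3, 4, 8, 8, 0.5, seed = 105)
    m <- scores(sim$scores)
    dup <- rbind(m, m)
    rownames(dup) <- c(rownames(m), paste0(rownames(m), "_copy"))
    labels <- c(sim$labels, sim$labels)
    # k = 2 with a seeded shuffle: every record whose twin lands in the
    # other part is memorized exactly by 1NN (distance 0)
    cv <- crossValidate(ScoreMatrix(dup), labels, k = 2, classifier = "nn",
        seed = 11)
    straddling <- 0L
    set.seed(11)
    part <- sample(rep_len(1:2, nrow(dup)))
    n <- nrow(m)
    for (i in seq_len(n))
        if (part[i] != part[i + n]) straddling <- straddling + 2L
    correct <- cv$predictions$predicted_fold == cv$predictions$truth
    expect_gte(sum(correct), straddling)
})
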