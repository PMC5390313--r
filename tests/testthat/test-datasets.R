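writeFasta <- function(lines) {
    path <- withr::local_tempfile(fileext = ".fa",
        .local_envir = parent.frame())
    writeLines(lines, path)
    path
}

test_that("readAstralFasta parses the Astral header dialect tolerantly", {
    path <- writeFasta(c(
        ">d1abca_ a.1.1.2 (A:) Haemoglobin alpha",
        "MKVLITAGPTREPLDMKVLITAGPT",
        ">d2xyzb1 c.37.1.19 (B:1-120) P-loop NTPase",
        "ACDEFGHIKLMNPQRSTVWYACDEF",
        ">dweird__ no-sccs-here something",
        "ACDEFGHIKLMNPQRSTVWYAAAAA"))
    rec <- readAstralFasta(path)
    expect_equal(nrow(rec), 3L)
    expect_equal(rec$sid, c("d1abca_", "d2xyzb1", "dweird__"))
    expect_equal(rec$fold, c("a.1", "c.37", NA))
    expect_equal(rec$sccs[1], "a.1.1.2")
    expect_true(rec$flagged[3])
    expect_false(any(rec$flagged[1:2]))
    expect_equal(rec$length, nchar(rec$sequence))

    empty <- withr::local_tempfile(fileext = ".fa")
    writeLines(character(0), empty)
    expect_error(readAstralFasta(empty), "no records|read")
    expect_error(readAstralFasta("/nonexistent/x.fa"), "not found")
})

test_that("parseScopCla maps sid to sccs with last-wins duplicates", {
    path <- withr::local_tempfile(fileext = ".txt")
    writeLines(c(
        "# dir.cla-style comment",
        "d1abca_\t1abc\tA:\ta.1.1.2\t12345\tcl=46456",
        "d2defb_\t2def\tB:\tb.2.3.4\t23456\tcl=48724",
        "d3ghic_ 3ghi C: c.37.1.19 34567 cl=51349",
        "d4jkld_ 4jkl D: d.58.7.1 45678 cl=53931",
        "d5mnoe_ 5mno E: e.3.1.1 56789 cl=56572"), path)
    map <- parseScopCla(path)
    expect_length(map, 5L)
    expect_equal(unname(map["d1abca_"]), "a.1.1.2")
    expect_equal(unname(map["d3ghic_"]), "c.37.1.19")

    comments <- withr::local_tempfile(fileext = ".txt")
    writeLines(c("# only", "# comments", ""), comments)
    expect_length(parseScopCla(comments), 0L)

    dup <- withr::local_tempfile(fileext = ".txt")
    writeLines(c("dX 1xxx A: a.1.1.1 1 x", "dX 1xxx A: b.2.2.2 2 x"), dup)
    expect_warning(mp <- parseScopCla(dup), "dX")
    expect_equal(unname(mp["dX"]), "b.2.2.2")

    bad <- withr::local_tempfile(fileext = ".txt")
    writeLines(c("dY 1yyy A: a.1.1.1 1 x", "short line"), bad)
    expect_error(parseScopCla(bad), "line 2")
})

test_that("pairwiseIdentity reports alignment identity and query coverage", {
    set.seed(91)
    aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    s <- paste(sample(aa, 40, replace = TRUE), collapse = "")
    expect_equal(pairwiseIdentity(s, s), c(identity = 1, coverage = 1))

    # b is an exact 30-residue prefix of a: identity 1 over 75% of a
    b <- substr(s, 1, 30)
    ic <- pairwiseIdentity(s, b)
    expect_equal(unname(ic["identity"]), 1)
    expect_equal(unname(ic["coverage"]), 0.75)

    expect_equal(pairwiseIdentity("AAAAA", "WWWWW"),
        c(identity = 0, coverage = 0))
    expect_error(pairwiseIdentity("", s), "non-empty")
})

test_that("filterByIdentity removes exactly the high-identity high-coverage records", {
    toy <- generateToySequences(3, 60, c(1, 0.85, 0.2), seed = 92)
    bases <- toy$sequence[is.na(toy$target_identity)]
    copies <- toy[!is.na(toy$target_identity), ]
    fl <- filterByIdentity(copies, bases)

    # oracle: all-pairs check with the same measured identities
    shouldDrop <- vapply(seq_len(nrow(copies)), function(i)
        any(vapply(bases, function(r) {
            ic <- pairwiseIdentity(copies$sequence[i], r)
            ic["identity"] > 0.25 && ic["coverage"] >= 0.90
        }, TRUE)), TRUE)
    expect_setequal(fl$removed$sid, copies$sid[shouldDrop])
    expect_setequal(fl$kept$sid, copies$sid[!shouldDrop])
    # exact duplicates are always removed; ~20% copies always kept
    expect_true(all(copies$sid[copies$target_identity == 1] %in%
        fl$removed$sid))
    expect_true(all(copies$sid[copies$target_identity == 0.2] %in%
        fl$kept$sid))

    # idempotence on the kept set
    again <- filterByIdentity(fl$kept, bases)
    expect_equal(again$kept$sid, fl$kept$sid)
    expect_equal(nrow(again$removed), 0L)

    expect_error(filterByIdentity(copies, character(0)), "empty reference")
})

test_that("coverage gate keeps records whose match spans too little of them", {
    set.seed(93)
    aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    ref <- paste(sample(aa, 30, replace = TRUE), collapse = "")
    # record shares an exact 30-mer with the reference but is 100 long:
    # identity 1, coverage 0.3 -> kept under the 0.9 coverage gate
    rec <- data.frame(sid = "r1",
        sequence = paste0(ref, paste(sample(aa, 70, replace = TRUE),
            collapse = "")),
        stringsAsFactors = FALSE)
    fl <- filterByIdentity(rec, ref)
    expect_equal(fl$kept$sid, "r1")
})

test_that("makeSplit applies the anchored-subset protocol with reason codes", {
    pool <- data.frame(
        sid = sprintf("d%02d", 1:10),
        sequence = vapply(1:10, function(i)
            paste(rep("ACDEFGHIKLMNPQRSTVWY", 3), collapse = ""), ""),
        fold = c("a.1", "a.1", "b.2", "b.2", "c.3", "c.3", "c.3", "d.4",
            "d.4", "e.5"),
        stringsAsFactors = FALSE)
    pool$length <- nchar(pool$sequence)
    pool$length[7] <- 20
    pool$sequence[7] <- substr(pool$sequence[7], 1, 20)

    anchors <- c("d01", "d03", "d05", "d08")
    split <- makeSplit(pool, anchors)
    expect_setequal(split$train$sid, anchors)
    # d07 too short; d10 fold e.5 unrepresented in train
    expect_equal(sort(split$removed$sid), c("d07", "d10"))
    expect_equal(split$removed$reason[split$removed$sid == "d07"],
        "too_short")
    expect_equal(split$removed$reason[split$removed$sid == "d10"],
        "fold_unrepresented")
    expect_setequal(split$test$sid, c("d02", "d04", "d06", "d09"))
    # partition accounting
    expect_equal(nrow(split$train) + nrow(split$test) +
        nrow(split$removed), nrow(pool))
    # every test fold is represented in train
    expect_true(all(split$test$fold %in% split$train$fold))
    # orphan folds: exactly one training record each
    expect_setequal(split$orphan_folds, c("a.1", "b.2", "c.3", "d.4"))

    expect_warning(makeSplit(pool, c(anchors, "zz9")), "zz9")
    suppressWarnings(expect_error(makeSplit(pool, "none-such"),
        "empty training"))
})

test_that("template-similar records are removed in SCOP-25 mode", {
    toy <- generateToySequences(2, 60, c(1), seed = 94)
    bases <- toy[is.na(toy$target_identity), ]
    pool <- toy[!is.na(toy$target_identity), ]
    pool$fold <- c("a.1", "a.1")
    # add an unrelated record sharing the fold
    unrel <- generateToySequences(1, 60, seed = 95)
    unrel$fold <- "a.1"
    pool <- rbind(pool[, c("sid", "sequence", "length", "fold")],
        unrel[, c("sid", "sequence", "length", "fold")])
    lib <- TemplateLibrary(bases$sid, seqs = bases$sequence)
    split <- makeSplit(pool, anchor_ids = pool$sid[3], templates = lib,
        remove_template_similar = TRUE)
    expect_true(all(split$removed$reason == "template_similar"))
    expect_equal(sort(split$removed$sid), sort(toy$sid[!is.na(toy$target_identity)]))
})

test_that("split manifests record every record once with its partition", {
    pool <- data.frame(sid = c("a", "b", "c"),
        sequence = rep(strrep("ACDEF", 10), 3),
        fold = c("a.1", "a.1", "a.1"), length = rep(50, 3),
        stringsAsFactors = FALSE)
    split <- makeSplit(pool, "a")
    path <- withr::local_tempfile(fileext = ".tsv")
    writeSplitManifest(split, path)
    man <- utils::read.delim(path)
    expect_setequal(man$sid, pool$sid)
    expect_equal(sum(man$partition == "train"), 1L)
})
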