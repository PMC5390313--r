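#' Read domain records from an Astral-dialect FASTA file
#'
#' Astral headers look like \code{">d1abca_ a.1.1.2 (A:) Description"}:
#' the first token is the domain sid, the second the sccs classification
#' string. Records whose second token does not parse as an sccs are kept
#' with \code{fold = NA} and \code{flagged = TRUE} rather than dropped.
#'
#' @param path FASTA file path.
#' @return data.frame with columns \code{sid}, \code{sccs}, \code{fold},
#'   \code{sequence}, \code{length}, \code{flagged}.
#' @export
readAstralFasta <- function(path) {
    if (!file.exists(path)) .stopf("FASTA file not found: %s", path)
    set <- Biostrings::readAAStringSet(path)
    if (length(set) == 0L) .stopf("FASTA file %s contains no records", path)
    headers <- names(set)
    tok1 <- sub("\\s.*$", "", headers)
    rest <- sub("^\\S+\\s*", "", headers)
    tok2 <- sub("\\s.*$", "", rest)
    sccs <- ifelse(grepl("^[a-z]\\.[0-9]+(\\.[0-9]+)*$", tok2), tok2,
        NA_character_)
    fold <- .foldFromSccs(sccs)
    seqs <- toupper(as.character(set))
    data.frame(sid = tok1, sccs = sccs, fold = fold, sequence = unname(seqs),
        length = nchar(seqs), flagged = is.na(sccs),
        stringsAsFactors = FALSE, row.names = NULL)
}

#' Parse a SCOPe classification file (dir.cla dialect)
#'
#' Whitespace-delimited lines \code{sid pdb chain sccs sunid ...};
#' comment lines start with \code{#}. Duplicate sids keep the last
#' occurrence with a warning.
#'
#' @param path file path.
#' @return named character vector mapping sid to sccs.
#' @export
parseScopCla <- function(path) {
    if (!file.exists(path)) .stopf("classification file not found: %s", path)
    lines <- readLines(path, warn = FALSE)
    keep <- which(!grepl("^\\s*(#|$)", lines))
    if (!length(keep)) return(stats::setNames(character(0), character(0)))
    fields <- strsplit(trimws(lines[keep]), "\\s+")
    bad <- which(lengths(fields) < 4L)
    if (length(bad))
        .stopf("malformed classification line %d: '%s'", keep[bad[1L]],
            lines[keep[bad[1L]]])
    sid <- vapply(fields, `[`, "", 1L)
    sccs <- vapply(fields, `[`, "", 4L)
    if (anyDuplicated(sid)) {
        dups <- unique(sid[duplicated(sid)])
        .warnf("duplicate sid(s) in %s (last occurrence wins): %s", path,
            paste(dups, collapse = ", "))
    }
    out <- stats::setNames(sccs, sid)
    out[!duplicated(names(out), fromLast = TRUE)][unique(sid)]
}

#' Pairwise identity and coverage of two sequences
#'
#' Identity and query coverage from the optimal Smith-Waterman local
#' alignment (BLOSUM62, gap open 11 / extend 1 by default): identity is
#' exact matches divided by aligned columns (gap columns included);
#' coverage is the aligned span of \code{a} divided by the length of
#' \code{a}. Sequence pairs with no positive-scoring local alignment
#' return \code{(0, 0)}.
#'
#' @param a,b amino-acid strings; \code{a} is the query whose coverage
#'   is measured.
#' @param substitutionMatrix,gapOpening,gapExtension alignment scoring
#'   scheme, as in \code{\link{standInScore}}.
#' @return named numeric vector \code{c(identity =, coverage =)}, both
#'   in [0, 1].
#' @export
pairwiseIdentity <- function(a, b, substitutionMatrix = "BLOSUM62",
        gapOpening = 11, gapExtension = 1) {
    a <- .checkAASeq(a, "sequence a")
    b <- .checkAASeq(b, "sequence b")
    sm <- if (is.character(substitutionMatrix))
        .getSubMatrix(substitutionMatrix) else substitutionMatrix
    aln <- Biostrings::pairwiseAlignment(a, b, type = "local",
        substitutionMatrix = sm, gapOpening = gapOpening,
        gapExtension = gapExtension)
    if (Biostrings::score(aln) <= 0)
        return(c(identity = 0, coverage = 0))
    alnPat <- as.character(Biostrings::pattern(aln))   # includes gap chars
    ncols <- nchar(alnPat)                 # alignment columns
    ident <- Biostrings::nmatch(aln) / ncols
    # query residues consumed by the alignment = aligned span of a
    span <- nchar(gsub("-", "", alnPat, fixed = TRUE))
    c(identity = unname(ident), coverage = unname(span) / nchar(a))
}

#' Remove records similar to a reference set
#'
#' A record is removed when some reference sequence matches it with
#' identity above \code{max_identity} over at least \code{min_coverage}
#' of the record's length — the redundancy rule used to keep benchmark
#' sequences distinct from feature-space templates. The operation is
#' idempotent on its kept set.
#'
#' @param records data.frame of domain records (needs \code{sid},
#'   \code{sequence}).
#' @param reference_seqs character vector of reference sequences (e.g.
#'   template sequences), or an \code{AAStringSet}.
#' @param max_identity identity threshold in (0, 1]; strictly-greater
#'   rule (default 0.25).
#' @param min_coverage coverage threshold in (0, 1]; at-least rule
#'   (default 0.90).
#' @param ... scoring scheme passed to \code{\link{pairwiseIdentity}}.
#' @return list with data.frames \code{kept} and \code{removed};
#'   \code{removed} gains columns \code{hit_identity},
#'   \code{hit_coverage}.
#' @export
filterByIdentity <- function(records, reference_seqs, max_identity = 0.25,
        min_coverage = 0.90, ...) {
    stopifnot(is.data.frame(records),
        max_identity > 0, max_identity <= 1,
        min_coverage > 0, min_coverage <= 1)
    refs <- as.character(reference_seqs)
    if (!length(refs))
        .stopf("empty reference set; skip filtering instead of calling with no references")
    hitId <- rep(NA_real_, nrow(records))
    hitCov <- rep(NA_real_, nrow(records))
    drop <- logical(nrow(records))
    for (i in seq_len(nrow(records))) {
        for (r in refs) {
            ic <- pairwiseIdentity(records$sequence[i], r, ...)
            if (ic["identity"] > max_identity && ic["coverage"] >= min_coverage) {
                drop[i] <- TRUE
                hitId[i] <- ic["identity"]
                hitCov[i] <- ic["coverage"]
                break
            }
        }
    }
    removed <- records[drop, , drop = FALSE]
    if (nrow(removed)) {
        removed$hit_identity <- hitId[drop]
        removed$hit_coverage <- hitCov[drop]
    }
    list(kept = records[!drop, , drop = FALSE], removed = removed)
}

#' Build a train/test split by the anchored-subset protocol
#'
#' Reproduces the split protocol used for identity-filtered SCOP domain
#' sets: (1) optionally remove records redundant with the template
#' library (\code{\link{filterByIdentity}}); (2) remove records shorter
#' than \code{min_len} residues; (3) records whose sid belongs to
#' \code{anchor_ids} (a lower-identity subset used as a structural
#' coverage guide) go to training, the rest to test; (4) test records
#' whose fold has no training representative are removed. Every removed
#' record carries exactly one reason code: \code{template_similar},
#' \code{too_short} or \code{fold_unrepresented}.
#'
#' @param pool data.frame of domain records (\code{sid}, \code{sequence},
#'   \code{fold}, \code{length}).
#' @param anchor_ids character sids destined for training; sids outside
#'   the pool draw a warning.
#' @param templates optional \linkS4class{TemplateLibrary} with
#'   sequences, used when \code{remove_template_similar} is \code{TRUE}.
#' @param remove_template_similar logical (default \code{FALSE}).
#' @param min_len minimum record length (default 25).
#' @param max_identity,min_coverage thresholds for the template filter.
#' @return list with data.frames \code{train}, \code{test},
#'   \code{removed} (with column \code{reason}), plus
#'   \code{orphan_folds}: folds with exactly one training record.
#' @export
makeSplit <- function(pool, anchor_ids, templates = NULL,
        remove_template_similar = FALSE, min_len = 25L,
        max_identity = 0.25, min_coverage = 0.90) {
    stopifnot(is.data.frame(pool))
    anchor_ids <- as.character(anchor_ids)
    stray <- setdiff(anchor_ids, pool$sid)
    if (length(stray))
        .warnf("%d anchor id(s) not present in the pool: %s", length(stray),
            paste(utils::head(stray, 5L), collapse = ", "))
    removed <- pool[0, , drop = FALSE]
    removed$reason <- character(0)
    work <- pool

    if (remove_template_similar) {
        if (is.null(templates) || is.null(templateSeqs(templates)))
            .stopf("remove_template_similar requires a template library with sequences")
        fl <- filterByIdentity(work, as.character(templateSeqs(templates)),
            max_identity = max_identity, min_coverage = min_coverage)
        if (nrow(fl$removed)) {
            r <- fl$removed[, names(pool), drop = FALSE]
            r$reason <- "template_similar"
            removed <- rbind(removed, r)
        }
        work <- fl$kept
    }

    short <- work$length < min_len
    if (any(short)) {
        r <- work[short, , drop = FALSE]
        r$reason <- "too_short"
        removed <- rbind(removed, r)
        work <- work[!short, , drop = FALSE]
    }

    inTrain <- work$sid %in% anchor_ids
    train <- work[inTrain, , drop = FALSE]
    test <- work[!inTrain, , drop = FALSE]
    if (nrow(train) == 0L)
        .stopf("empty training set after filtering")

    unrep <- !(test$fold %in% train$fold)
    if (any(unrep)) {
        r <- test[unrep, , drop = FALSE]
        r$reason <- "fold_unrepresented"
        removed <- rbind(removed, r)
        test <- test[!unrep, , drop = FALSE]
    }
    counts <- table(train$fold)
    list(train = train, test = test, removed = removed,
        orphan_folds = names(counts)[counts == 1L])
}

#' Write a split manifest
#'
#' TSV with one line per pool record: \code{sid}, \code{partition}
#' (\code{train}/\code{test}/\code{removed}) and \code{reason} (empty
#' unless removed).
#'
#' @param split result of \code{\link{makeSplit}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeSplitManifest <- function(split, path) {
    man <- rbind(
        data.frame(sid = split$train$sid, partition = "train", reason = "",
            stringsAsFactors = FALSE),
        data.frame(sid = split$test$sid, partition = "test", reason = "",
            stringsAsFactors = FALSE),
        if (nrow(split$removed))
            data.frame(sid = split$removed$sid, partition = "removed",
                reason = split$removed$reason, stringsAsFactors = FALSE))
    utils::write.table(man, path, sep = "\t", quote = FALSE,
        row.names = FALSE)
    invisible(path)
}
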