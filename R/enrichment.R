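# Weighted Kolmogorov-Smirnov enrichment: running sum, enrichment score,
# leading edge, empirical significance and FDR control.

#' Weighted Kolmogorov-Smirnov running sum and enrichment score
#'
#' Walks down a ranked list and increases the running sum at in-class
#' ("hit") positions by `|w_i|^p / sum_hits |w_j|^p`, and decreases it at
#' out-of-class ("miss") positions by `1 / (N - N_hits)` — the increment
#' and decrement of the standard gene-set enrichment statistic.  The
#' enrichment score (ES) is the maximum deviation of the running sum from
#' zero, signed; with `exponent = 0` this is the classic K-S statistic.
#'
#' @param membership Logical vector along the ranked list: `TRUE` where
#'   the database residue belongs to the function class.
#' @param weights Ranked similarity scores, same length as `membership`.
#' @param exponent Weight exponent `p` (default 1; 0 gives the unweighted
#'   statistic).
#' @return List with `S` (running sum, one value per rank), `es` (the
#'   enrichment score in \[-1, 1\]) and `peak_index` (1-based position of
#'   the maximum |S|, earliest on ties).
#' @examples
#' runningSum(c(TRUE, FALSE, FALSE, TRUE), rep(1, 4), exponent = 0)
#' @export
runningSum <- function(membership, weights, exponent = 1) {
    membership <- as.logical(membership)
    n <- length(membership)
    if (length(weights) != n)
        stop("weights and membership must have equal length")
    n_hit <- sum(membership)
    if (n_hit == 0L || n_hit == n)
        stop("degenerate class: need at least one in-class and one ",
             "out-of-class element")
    w <- abs(weights)^exponent
    hit_total <- sum(w[membership])
    if (hit_total == 0)
        stop("sum of hit weights is zero; cannot normalise increments")
    # accumulate hits and misses separately so the extremes (every hit
    # before every miss) give an enrichment score of exactly +/-1 and the
    # final value telescopes to exactly zero
    hit_cum <- cumsum(ifelse(membership, w, 0)) / hit_total
    miss_cum <- cumsum(!membership) / (n - n_hit)
    S <- hit_cum - miss_cum
    peak <- which.max(abs(S))          # earliest index on exact ties
    list(S = S, es = S[peak], peak_index = peak)
}

#' Leading-edge subset of a running sum
#'
#' For a positive enrichment score, the in-class positions at or before
#' the running-sum peak — the database residues that drive the
#' enrichment and are mapped back onto the query as the residue-level
#' annotation.  Depletion (negative ES) yields no annotation.
#'
#' @param S Running sum from [runningSum()].
#' @param membership Logical in-class indicator along the ranked list.
#' @param peak_index Peak position from [runningSum()].
#' @param es Enrichment score (its sign selects the contract).
#' @param mode `"peak"` (default, the standard gene-set-enrichment
#'   convention: members at or before the running-sum peak) or
#'   `"score"` (members whose individual ranked score exceeds the score
#'   at the peak — an alternative reading of the same idea).
#' @param weights Ranked scores; required for `mode = "score"`.
#' @return Integer vector of ranked-list positions, in rank order; empty
#'   when `es <= 0`.
#' @export
leadingEdge <- function(S, membership, peak_index, es,
                        mode = c("peak", "score"), weights = NULL) {
    mode <- match.arg(mode)
    if (es <= 0) return(integer(0))
    if (mode == "peak") return(which(membership[seq_len(peak_index)]))
    if (is.null(weights))
        stop("mode = \"score\" needs the ranked weights")
    which(membership & weights >= weights[peak_index])
}

#' Empirical upper-tail p-value against a null score distribution
#'
#' `p = #\{d_i >= s\} / |D|`, or `(1 + #\{d_i >= s\}) / (1 + |D|)` with the
#' pseudocount (default), so that p is never exactly zero and downstream
#' FDR control is well behaved.
#'
#' @param s Observed enrichment score.
#' @param background Numeric vector of null scores for the same class.
#' @param pseudocount Add-one smoothing (default `TRUE`).
#' @return p-value in (0, 1\].
#' @export
empiricalPvalue <- function(s, background, pseudocount = TRUE) {
    if (!length(background)) stop("no background for class")
    k <- sum(background >= s)
    if (pseudocount) (1 + k) / (1 + length(background))
    else k / length(background)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up FDR-adjusted q-values in the input order (a validated wrapper
#' over [stats::p.adjust()]).
#'
#' @param pvalues Numeric p-values in \[0, 1\].
#' @return q-values, same order as the input.
#' @export
bhFdr <- function(pvalues) {
    if (!length(pvalues)) return(numeric(0))
    if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(pvalues, method = "BH")
}

# Per-class enrichment over one ranked list.  Returns a data.frame with
# one row per class in `classes` (default: all db classes), plus list
# columns of leading-edge positions.  `row_map` translates ranked rows
# back to original database flat rows when some rows were excluded.
.classEnrichment <- function(ranked, flat_class, exponent = 1,
                             row_map = NULL, classes = NULL,
                             le_mode = "peak") {
    ord <- ranked@order
    weights <- ranked@scores[ord]
    class_along <- flat_class[ord]
    if (is.null(classes)) classes <- unique(flat_class)
    if (is.null(row_map)) row_map <- seq_along(flat_class)
    out <- vector("list", length(classes))
    for (i in seq_along(classes)) {
        cl <- classes[i]
        membership <- class_along == cl
        n_hit <- sum(membership)
        if (n_hit == 0L || n_hit == length(membership)) {
            out[[i]] <- list(function_id = cl, es = NA_real_,
                             peak_index = NA_integer_, n_class = n_hit,
                             le_ranks = integer(0))
            next
        }
        rs <- runningSum(membership, weights, exponent)
        le <- leadingEdge(rs$S, membership, rs$peak_index, rs$es,
                          mode = le_mode, weights = weights)
        out[[i]] <- list(function_id = cl, es = rs$es,
                         peak_index = rs$peak_index, n_class = n_hit,
                         le_ranks = le)
    }
    res <- data.frame(
        function_id = vapply(out, `[[`, "", "function_id"),
        es = vapply(out, `[[`, 0, "es"),
        peak_index = vapply(out, `[[`, 0L, "peak_index"),
        n_class = vapply(out, `[[`, 0L, "n_class"),
        stringsAsFactors = FALSE)
    # leading edge as original database flat-row indices, in rank order
    res$leading_edge_db <- I(lapply(out, function(o)
        row_map[ord[o$le_ranks]]))
    res$le_ranks <- I(lapply(out, `[[`, "le_ranks"))
    res
}

#' Build function-specific empirical null distributions
#'
#' For every function class, the enrichment score of that class is
#' measured on each corpus protein \emph{not} annotated with the class;
#' the collected scores form the class's empirical null.  Classes ending
#' up with fewer than `min_size` null scores are excluded (with a
#' warning) rather than mis-scored.
#'
#' @param db A [ReferenceSiteDB-class].
#' @param corpus List of background proteins; each element a list with
#'   `table` (an [EmbeddingTable-class]), `function_ids` (character
#'   vector of classes truly annotated on that protein, possibly empty)
#'   and optionally `id`.
#' @param min_size Minimum null count per scored class (default 50).
#' @param exponent Weight exponent passed to [runningSum()].
#' @param plddt_threshold Confidence filter applied to each corpus
#'   protein before scoring (default 70).
#' @param statistic `"ks"` for the weighted K-S enrichment score, or
#'   `"mwu"` for the standardised Mann-Whitney U used by the rank-sum
#'   baseline.
#' @param exclude_self Drop database rows originating from the corpus
#'   protein's own structure before scoring (default `TRUE`).
#' @return A [BackgroundDistributions-class].
#' @export
buildBackground <- function(db, corpus, min_size = 50L, exponent = 1,
                            plddt_threshold = 70, statistic = c("ks", "mwu"),
                            exclude_self = TRUE) {
    statistic <- match.arg(statistic)
    classes <- names(db@classIndex)
    scores <- lapply(classes, function(cl) numeric(0))
    names(scores) <- classes
    provenance <- character(0)
    for (k in seq_along(corpus)) {
        prot <- corpus[[k]]
        id <- prot$id %||% paste0("background_", k)
        tab <- prot$table
        if (length(tab@plddt))
            tab <- suppressMessages(filterByPlddt(tab, plddt_threshold))
        if (!nResidues(tab)) next
        es <- .proteinClassScores(tab, db, exponent = exponent,
                                  statistic = statistic,
                                  exclude_self = exclude_self)
        keep <- setdiff(classes, prot$function_ids)
        for (cl in keep) {
            v <- es$es[match(cl, es$function_id)]
            if (is.finite(v)) scores[[cl]] <- c(scores[[cl]], v)
        }
        provenance <- c(provenance, id)
    }
    small <- names(scores)[lengths(scores) < min_size]
    if (length(small)) {
        warning("classes with fewer than ", min_size,
                " null scores excluded: ", paste(small, collapse = ", "))
        scores <- scores[lengths(scores) >= min_size]
    }
    new("BackgroundDistributions", dist = scores, provenance = provenance,
        minSize = as.integer(min_size), statistic = statistic)
}

# Rank the database against one query table and score every class.
# Returns the .classEnrichment data.frame plus the RankedList and row map
# as attributes.  statistic = "mwu" replaces the K-S enrichment score by
# the standardised one-sided Mann-Whitney U score (no leading edge).
.proteinClassScores <- function(table, db, exponent = 1,
                                statistic = c("ks", "mwu"),
                                exclude_self = TRUE, le_mode = "peak") {
    statistic <- match.arg(statistic)
    keep <- rep(TRUE, nrow(db@flatRefs))
    if (exclude_self) {
        qids <- unique(table@refs$structure_id)
        qids <- qids[nzchar(qids)]
        if (length(qids)) keep <- .selfExclusionMask(db, qids)
    }
    row_map <- which(keep)
    vectors <- db@flatVectors[keep, , drop = FALSE]
    flat_class <- db@flatClass[keep]
    if (!nrow(vectors)) stop("no database rows remain after self-exclusion")
    sim <- similarityMatrix(table, vectors)
    ranked <- rankDatabase(sim)
    res <- if (statistic == "ks") {
        .classEnrichment(ranked, flat_class, exponent = exponent,
                         row_map = row_map, classes = names(db@classIndex),
                         le_mode = le_mode)
    } else {
        .classMwuScores(ranked, flat_class, classes = names(db@classIndex),
                        row_map = row_map)
    }
    attr(res, "ranked") <- ranked
    attr(res, "row_map") <- row_map
    res
}

#' Annotate a query protein against the reference database
#'
#' The full annotation pipeline for one protein: pLDDT filtering, cosine
#' similarity to every database residue, max-similarity ranking, weighted
#' K-S enrichment per function class, leading-edge back-mapping onto the
#' query, function-specific empirical p-values, and Benjamini-Hochberg
#' FDR across the classes tested for this protein.  A class is called
#' significant when `q <= alpha` and its enrichment score is positive.
#'
#' @param query An [EmbeddingTable-class] of query residue embeddings.
#' @param db A [ReferenceSiteDB-class].
#' @param backgrounds A [BackgroundDistributions-class] covering the
#'   database classes; classes without a background are reported
#'   unscored (`p`, `q` = `NA`).
#' @param alpha FDR significance threshold (default 0.001, where
#'   validation performance plateaus).
#' @param exponent Weight exponent of the enrichment statistic.
#' @param plddt_threshold Minimum per-residue confidence (default 70).
#' @param exclude_self Drop database rows from the query's own structure.
#' @param pseudocount Add-one smoothing of empirical p-values.
#' @param leading_edge_mode Leading-edge convention (see [leadingEdge()]).
#' @param protein_id Identifier copied into the result table.
#' @return `data.frame`, one row per function class, sorted by q
#'   ascending then ES descending, with columns `protein_id`,
#'   `function_id`, `ec_number`, `es`, `peak_index`, `n_class`,
#'   `p_value`, `q_value`, `significant`, `leading_edge` (residue labels,
#'   comma-separated) and list columns `leading_edge_db` (database flat
#'   rows) and `leading_edge_query` (query row indices).
#' @export
annotateProtein <- function(query, db, backgrounds, alpha = 0.001,
                            exponent = 1, plddt_threshold = 70,
                            exclude_self = FALSE, pseudocount = TRUE,
                            leading_edge_mode = c("peak", "score"),
                            protein_id = NULL) {
    stopifnot(is(query, "EmbeddingTable"), is(db, "ReferenceSiteDB"),
              is(backgrounds, "BackgroundDistributions"))
    if (length(query@plddt))
        query <- suppressMessages(filterByPlddt(query, plddt_threshold))
    if (!nResidues(query))
        stop("no high-confidence residues in query after pLDDT filtering")
    if (is.null(protein_id)) {
        ids <- unique(query@refs$structure_id)
        protein_id <- if (length(ids) == 1L && nzchar(ids)) ids else "query"
    }
    statistic <- backgrounds@statistic
    leading_edge_mode <- match.arg(leading_edge_mode)
    res <- .proteinClassScores(query, db, exponent = exponent,
                               statistic = statistic,
                               exclude_self = exclude_self,
                               le_mode = leading_edge_mode)
    ranked <- attr(res, "ranked")
    row_map <- attr(res, "row_map")

    # map leading-edge database rows to their best-matching query rows
    best_q_by_dbrow <- integer(nrow(db@flatRefs))
    best_q_by_dbrow[row_map] <- ranked@bestQuery
    le_query <- lapply(res$leading_edge_db, function(dbrows) {
        if (!length(dbrows)) return(integer(0))
        unique(best_q_by_dbrow[dbrows])
    })

    p <- rep(NA_real_, nrow(res))
    for (i in seq_len(nrow(res))) {
        bg <- backgrounds@dist[[res$function_id[i]]]
        if (!is.null(bg) && is.finite(res$es[i]))
            p[i] <- empiricalPvalue(res$es[i], bg, pseudocount = pseudocount)
    }
    q <- rep(NA_real_, nrow(res))
    scored <- which(!is.na(p))
    q[scored] <- bhFdr(p[scored])

    ec <- ecMap(db)[res$function_id]
    out <- data.frame(
        protein_id = protein_id,
        function_id = res$function_id,
        ec_number = unname(ec),
        es = res$es,
        peak_index = res$peak_index,
        n_class = res$n_class,
        p_value = p,
        q_value = q,
        significant = !is.na(q) & q <= alpha & !is.na(res$es) & res$es > 0,
        stringsAsFactors = FALSE)
    out$leading_edge_db <- res$leading_edge_db
    out$leading_edge_query <- I(le_query)
    out$leading_edge <- vapply(le_query, function(idx)
        paste(.residueLabel(query@refs[idx, , drop = FALSE]),
              collapse = ","), "")
    ord <- order(ifelse(is.na(out$q_value), Inf, out$q_value), -out$es)
    out <- out[ord, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "ranked") <- ranked
    attr(out, "row_map") <- row_map
    attr(out, "query") <- query
    out
}

#' Save / load background distributions
#'
#' Versioned binary container keyed by function class.
#'
#' @param backgrounds A [BackgroundDistributions-class].
#' @param path Container path.
#' @return `saveBackgrounds` returns `path` invisibly; `loadBackgrounds`
#'   the object.
#' @export
saveBackgrounds <- function(backgrounds, path) {
    stopifnot(is(backgrounds, "BackgroundDistributions"))
    saveRDS(list(format = "sitenrich-backgrounds", version = 1L,
                 backgrounds = backgrounds), path)
    invisible(path)
}

#' @rdname saveBackgrounds
#' @export
loadBackgrounds <- function(path) {
    obj <- readRDS(path)
    if (!identical(obj$format, "sitenrich-backgrounds"))
        stop("not a backgrounds container: ", path)
    if (!identical(obj$version, 1L))
        stop("backgrounds container version mismatch: ", obj$version)
    validObject(obj$backgrounds)
    obj$backgrounds
}

#' Write prediction tables
#'
#' Tab-separated and/or JSON renderings of [annotateProtein()] output
#' (list columns are serialised as residue labels).  Output is
#' deterministic for identical inputs.
#'
#' @param predictions Prediction `data.frame` (possibly several proteins
#'   row-bound).
#' @param path Output path; format chosen by `format`.
#' @param format `"tsv"` or `"json"`.
#' @return Invisibly, `path`.
#' @export
writePredictions <- function(predictions, path, format = c("tsv", "json")) {
    format <- match.arg(format)
    cols <- c("protein_id", "function_id", "ec_number", "es", "p_value",
              "q_value", "significant", "leading_edge")
    cols <- intersect(cols, names(predictions))
    flat <- predictions[, cols, drop = FALSE]
    if (format == "tsv") {
        num <- vapply(flat, is.numeric, logical(1))
        flat[num] <- lapply(flat[num], .fmtNum)
        utils::write.table(flat, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    } else {
        jsonlite::write_json(flat, path, auto_unbox = FALSE, digits = NA,
                             pretty = TRUE)
    }
    invisible(path)
}
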