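# Structural confirmation of predictions: exact catalytic residue
# matching, Kabsch superposition, all-atom RMSD, and the proteome-scale
# coverage / RMSD filters.

#' Kabsch superposition of two corresponded point sets
#'
#' Finds the proper rotation and translation minimising the RMSD between
#' corresponded points (rows), via SVD of the cross-covariance matrix with
#' a determinant sign correction, and returns the minimised RMSD.
#' Degenerate (collinear or coincident) configurations still return a
#' minimising transform.
#'
#' @param X,Y Numeric matrices (k x 3), row i of `Y` corresponding to row
#'   i of `X`.  `Y` is rotated onto `X`.
#' @return List with `rotation` (3x3, determinant +1), `translation`
#'   (length 3; the fitted points are `Y %*% t(rotation) + translation`),
#'   and `rmsd` in the coordinate units (Angstrom).
#' @examples
#' X <- matrix(rnorm(30), 10, 3)
#' kabsch(X, X)$rmsd  # 0
#' @export
kabsch <- function(X, Y) {
    X <- as.matrix(X); Y <- as.matrix(Y)
    if (nrow(X) != nrow(Y) || ncol(X) != 3L || ncol(Y) != 3L)
        stop("X and Y must be corresponded k x 3 coordinate matrices")
    if (nrow(X) < 2L)
        stop("at least two corresponded points are required")
    cx <- colMeans(X); cy <- colMeans(Y)
    Xc <- sweep(X, 2L, cx); Yc <- sweep(Y, 2L, cy)
    H <- t(Yc) %*% Xc
    s <- svd(H)
    d <- sign(det(s$v %*% t(s$u)))
    if (d == 0) d <- 1   # rank-deficient: either sign minimises
    D <- diag(c(1, 1, d))
    R <- s$v %*% D %*% t(s$u)
    fitted <- Yc %*% t(R)
    rmsd <- sqrt(mean(rowSums((fitted - Xc)^2)))
    translation <- as.numeric(cx - cy %*% t(R))
    list(rotation = R, translation = translation, rmsd = rmsd)
}

#' Match predicted residues to reference catalytic residues
#'
#' Pairs each catalytic residue of a reference entry with the
#' leading-edge query residue that was its best match in the ranked list,
#' requiring an exact amino-acid type match.  Pairing is one-to-one on
#' both sides; when a query residue could serve several reference
#' residues, pairs are kept in decreasing order of embedding similarity.
#'
#' @param prediction One row of [annotateProtein()] output (a list or
#'   one-row `data.frame` with `function_id` and `leading_edge_db`).
#' @param entry The [ReferenceEntry-class] being matched against
#'   (`entry@functionId` must equal the prediction's class).
#' @param db The [ReferenceSiteDB-class] the prediction was made with.
#' @param ranked The [RankedList-class] from the annotation (available as
#'   `attr(predictions, "ranked")`).
#' @param query The (pLDDT-filtered) query [EmbeddingTable-class]
#'   (`attr(predictions, "query")`).
#' @param row_map Mapping from ranked rows to database flat rows when
#'   self-exclusion dropped rows (`attr(predictions, "row_map")`).
#' @return A [CatalyticMatch-class] with pairs and coverage; RMSD is left
#'   undefined until [catalyticRmsd()] is applied.
#' @export
matchCatalytic <- function(prediction, entry, db, ranked, query,
                           row_map = NULL) {
    if (is.data.frame(prediction)) prediction <- as.list(prediction[1L, ])
    if (!identical(prediction$function_id, entry@functionId))
        stop("prediction class ", prediction$function_id,
             " does not match entry class ", entry@functionId)
    le_db <- unlist(prediction$leading_edge_db)
    cat_refs <- entry@catalyticResidues
    n_ref <- nrow(cat_refs)
    if (is.null(row_map)) row_map <- seq_len(nrow(db@flatRefs))

    empty <- data.frame(
        ref_chain = character(0), ref_resno = integer(0),
        ref_icode = character(0), ref_aa = character(0),
        query_chain = character(0), query_resno = integer(0),
        query_icode = character(0), query_aa = character(0),
        similarity = numeric(0), stringsAsFactors = FALSE)
    if (!length(le_db))
        return(new("CatalyticMatch", pairs = empty, coverage = 0,
                   nReference = as.integer(n_ref), rmsd = NA_real_))

    # flat rows of this entry's catalytic residues
    flat <- db@flatRefs
    entry_idx <- which(vapply(db@entries, identical, logical(1), entry))
    if (!length(entry_idx)) stop("entry not found in database")
    cand <- which(flat$entry == entry_idx[1L] & flat$role == "catalytic")
    cand <- cand[cand %in% le_db]
    if (!length(cand))
        return(new("CatalyticMatch", pairs = empty, coverage = 0,
                   nReference = as.integer(n_ref), rmsd = NA_real_))

    ranked_pos <- match(cand, row_map)       # NA if row was excluded
    keep <- !is.na(ranked_pos)
    cand <- cand[keep]; ranked_pos <- ranked_pos[keep]
    qrow <- ranked@bestQuery[ranked_pos]
    sim <- ranked@scores[ranked_pos]
    same_aa <- flat$amino_acid[cand] == query@refs$amino_acid[qrow]
    cand <- cand[same_aa]; qrow <- qrow[same_aa]; sim <- sim[same_aa]

    # greedy one-to-one assignment by descending similarity
    ord <- order(-sim, cand)
    used_ref <- character(0); used_q <- integer(0)
    rows <- list()
    for (j in ord) {
        rkey <- .refKey(flat[cand[j], , drop = FALSE])
        if (rkey %in% used_ref || qrow[j] %in% used_q) next
        used_ref <- c(used_ref, rkey); used_q <- c(used_q, qrow[j])
        rows[[length(rows) + 1L]] <- data.frame(
            ref_chain = flat$chain_id[cand[j]],
            ref_resno = flat$residue_number[cand[j]],
            ref_icode = flat$insertion_code[cand[j]],
            ref_aa = flat$amino_acid[cand[j]],
            query_chain = query@refs$chain_id[qrow[j]],
            query_resno = query@refs$residue_number[qrow[j]],
            query_icode = query@refs$insertion_code[qrow[j]],
            query_aa = query@refs$amino_acid[qrow[j]],
            similarity = sim[j], stringsAsFactors = FALSE)
    }
    pairs <- if (length(rows)) do.call(rbind, rows) else empty
    new("CatalyticMatch", pairs = pairs,
        coverage = nrow(pairs) / max(n_ref, 1L),
        nReference = as.integer(n_ref), rmsd = NA_real_)
}

#' All-atom RMSD of matched catalytic residues
#'
#' Extracts all heavy atoms (backbone and side chain) of each matched
#' residue pair from the reference and query structures, corresponds them
#' by PDB atom name (atoms missing on either side are dropped pairwise),
#' superposes with [kabsch()] and records the RMSD on the match.
#'
#' @param match A [CatalyticMatch-class] from [matchCatalytic()].
#' @param ref_structure,query_structure Structures (see [atomTable()])
#'   containing the paired residues.
#' @param include_hydrogens Keep hydrogens in the correspondence
#'   (default `FALSE`).
#' @return The match with its `rmsd` slot filled in (left `NA` when
#'   fewer than two residue pairs yield atoms).
#' @export
catalyticRmsd <- function(match, ref_structure, query_structure,
                          include_hydrogens = FALSE) {
    stopifnot(is(match, "CatalyticMatch"))
    if (nrow(match@pairs) < 2L) return(match)
    rat <- atomTable(ref_structure)
    qat <- atomTable(query_structure)
    if (!include_hydrogens) {
        rat <- rat[rat$elesy != "H", , drop = FALSE]
        qat <- qat[qat$elesy != "H", , drop = FALSE]
    }
    ref_xyz <- list(); query_xyz <- list()
    kept_pairs <- 0L
    for (i in seq_len(nrow(match@pairs))) {
        p <- match@pairs[i, ]
        ra <- rat[rat$chain == p$ref_chain & rat$resno == p$ref_resno &
                  rat$insert == p$ref_icode, , drop = FALSE]
        qa <- qat[qat$chain == p$query_chain & qat$resno == p$query_resno &
                  qat$insert == p$query_icode, , drop = FALSE]
        common <- intersect(ra$elety, qa$elety)
        if (!length(common)) {
            warning("no common atoms for pair ", p$ref_aa, p$ref_resno,
                    "; pair dropped before RMSD")
            next
        }
        ra <- ra[match(common, ra$elety), , drop = FALSE]
        qa <- qa[match(common, qa$elety), , drop = FALSE]
        ref_xyz[[length(ref_xyz) + 1L]] <- as.matrix(ra[, c("x", "y", "z")])
        query_xyz[[length(query_xyz) + 1L]] <-
            as.matrix(qa[, c("x", "y", "z")])
        kept_pairs <- kept_pairs + 1L
    }
    if (kept_pairs < 2L) return(match)
    X <- do.call(rbind, ref_xyz)
    Y <- do.call(rbind, query_xyz)
    match@rmsd <- kabsch(X, Y)$rmsd
    validObject(match)
    match
}

#' Apply the proteome-scale structural filters
#'
#' A prediction passes when (1) at least `min_coverage` of the reference
#' catalytic residues were identified on the query (inclusive), (2) at
#' least `min_pairs` residues matched, and (3) the all-atom RMSD of the
#' matched catalytic residues is strictly below `max_rmsd`.
#'
#' @param match A [CatalyticMatch-class] with RMSD computed (see
#'   [catalyticRmsd()]).
#' @param min_coverage Minimum matched fraction (default 0.75, inclusive).
#' @param max_rmsd RMSD bound in Angstrom (default 5, strict `<`).
#' @param min_pairs Minimum matched residue count (default 2).
#' @return List with `pass` (logical) and `reasons` (character vector of
#'   failed conditions, empty on pass).
#' @export
applyFilters <- function(match, min_coverage = 0.75, max_rmsd = 5.0,
                         min_pairs = 2L) {
    stopifnot(is(match, "CatalyticMatch"))
    reasons <- character(0)
    if (match@coverage < min_coverage) reasons <- c(reasons, "coverage")
    if (nrow(match@pairs) < min_pairs) reasons <- c(reasons, "pairs")
    if (is.na(match@rmsd) || match@rmsd >= max_rmsd)
        reasons <- c(reasons, "rmsd")
    list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Structural filter report for a set of predictions
#'
#' Runs [matchCatalytic()], [catalyticRmsd()] and [applyFilters()] over
#' the significant predictions of one protein and returns the tabular
#' filter report.
#'
#' @param predictions Output of [annotateProtein()] (its `ranked`,
#'   `row_map` and `query` attributes are used).
#' @param db The [ReferenceSiteDB-class].
#' @param structures Named list of structures keyed by `structure_id`,
#'   covering the reference entries and the query.
#' @param query_structure_id Key of the query structure in `structures`.
#' @param significant_only Filter only significant predictions
#'   (default `TRUE`).
#' @inheritParams applyFilters
#' @return `data.frame` with columns `protein_id`, `function_id`,
#'   `coverage`, `n_pairs`, `rmsd`, `pass`, `reasons`.
#' @export
filterPredictions <- function(predictions, db, structures,
                              query_structure_id, significant_only = TRUE,
                              min_coverage = 0.75, max_rmsd = 5.0,
                              min_pairs = 2L) {
    ranked <- attr(predictions, "ranked")
    row_map <- attr(predictions, "row_map")
    query <- attr(predictions, "query")
    if (is.null(ranked) || is.null(query))
        stop("predictions must carry their ranking attributes ",
             "(pass annotateProtein() output directly)")
    rows <- if (significant_only) which(predictions$significant)
            else seq_len(nrow(predictions))
    out <- list()
    for (i in rows) {
        pred <- as.list(predictions[i, ])
        cls_entries <- Filter(function(e) e@functionId == pred$function_id,
                              db@entries)
        best <- NULL
        for (entry in cls_entries) {
            m <- matchCatalytic(pred, entry, db, ranked, query, row_map)
            if (nrow(m@pairs) >= 2L &&
                !is.null(structures[[entry@pdbId]]) &&
                !is.null(structures[[query_structure_id]]))
                m <- catalyticRmsd(m, structures[[entry@pdbId]],
                                   structures[[query_structure_id]])
            if (is.null(best) || m@coverage > best@coverage ||
                (m@coverage == best@coverage && !is.na(m@rmsd) &&
                 (is.na(best@rmsd) || m@rmsd < best@rmsd)))
                best <- m
        }
        if (is.null(best)) next
        verdict <- applyFilters(best, min_coverage, max_rmsd, min_pairs)
        out[[length(out) + 1L]] <- data.frame(
            protein_id = pred$protein_id, function_id = pred$function_id,
            coverage = best@coverage, n_pairs = nrow(best@pairs),
            rmsd = best@rmsd, pass = verdict$pass,
            reasons = paste(verdict$reasons, collapse = ";"),
            stringsAsFactors = FALSE)
    }
    if (!length(out))
        return(data.frame(protein_id = character(0),
                          function_id = character(0), coverage = numeric(0),
                          n_pairs = integer(0), rmsd = numeric(0),
                          pass = logical(0), reasons = character(0),
                          stringsAsFactors = FALSE))
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}
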