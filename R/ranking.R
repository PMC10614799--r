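# Query <-> database similarity and ranking.

#' Filter an embedding table by pLDDT confidence
#'
#' Retains rows with pLDDT at or above the threshold (inclusive), in the
#' original order.  Tables without a pLDDT column (e.g. experimental
#' structures) pass through unchanged with a notice.
#'
#' @param table An [EmbeddingTable-class].
#' @param threshold Confidence cutoff in \[0, 100\] (default 70, the
#'   usual high-confidence bound for predicted structures).
#' @return Filtered [EmbeddingTable-class].
#' @export
filterByPlddt <- function(table, threshold = 70) {
    stopifnot(is(table, "EmbeddingTable"))
    if (!is.numeric(threshold) || threshold < 0 || threshold > 100)
        stop("threshold must lie in [0, 100]")
    if (!length(table@plddt)) {
        message("no pLDDT values present; returning table unchanged")
        return(table)
    }
    .subsetTable(table, which(table@plddt >= threshold))
}

#' Pairwise cosine similarity between database and query embeddings
#'
#' @param query An [EmbeddingTable-class] (or numeric matrix) of query
#'   residue embeddings.
#' @param db_vectors Numeric matrix of database embeddings (N_db x D).
#' @return Matrix (N_db x n_query); entry (i, j) is the cosine similarity
#'   of database row i and query row j.
#' @export
similarityMatrix <- function(query, db_vectors) {
    qv <- if (is(query, "EmbeddingTable")) query@vectors else as.matrix(query)
    db_vectors <- as.matrix(db_vectors)
    if (ncol(qv) != ncol(db_vectors))
        stop("embedding dimensions differ: query ", ncol(qv),
             ", database ", ncol(db_vectors))
    qn <- sqrt(rowSums(qv^2))
    dn <- sqrt(rowSums(db_vectors^2))
    .nameZero <- function(norms, what, table) {
        bad <- which(norms == 0)
        if (!length(bad)) return()
        lab <- if (is(table, "EmbeddingTable"))
            .residueLabel(table@refs[bad, , drop = FALSE])
        else paste("row", bad)
        stop("zero-norm ", what, " embedding for residue(s): ",
             paste(lab, collapse = ", "))
    }
    .nameZero(qn, "query", query)
    .nameZero(dn, "database", db_vectors)
    sim <- (db_vectors %*% t(qv)) / outer(dn, qn)
    pmin(pmax(sim, -1), 1)
}

#' Rank database residues by maximum similarity to the query
#'
#' For each database residue the maximum similarity to any query residue
#' is found (ties broken by the lowest query index), and database rows
#' are sorted by this score, descending, with ties broken by ascending
#' database row so results are reproducible bit for bit.
#'
#' @param sim Similarity matrix from [similarityMatrix()] (N_db x n_query).
#' @return A [RankedList-class].
#' @export
rankDatabase <- function(sim) {
    sim <- as.matrix(sim)
    if (ncol(sim) == 0L || nrow(sim) == 0L)
        stop("no high-confidence residues to rank")
    if (!all(is.finite(sim))) stop("similarity matrix must be finite")
    best_query <- max.col(sim, ties.method = "first")
    scores <- sim[cbind(seq_len(nrow(sim)), best_query)]
    ord <- order(-scores, seq_along(scores))
    new("RankedList", order = as.integer(ord), scores = as.numeric(scores),
        bestQuery = as.integer(best_query), nQuery = ncol(sim))
}

# Drop database rows whose structure_id matches the query's own
# structure(s); used when a reference protein is annotated against the
# database that contains it (background construction).
.selfExclusionMask <- function(db, query_ids) {
    !(db@flatRefs$structure_id %in% query_ids)
}
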