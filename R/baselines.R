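# Simpler embedding-similarity baselines used as comparators for the
# enrichment workflow.

#' Max-similarity baseline
#'
#' Assigns the function class of the single database residue with the
#' highest similarity to any query residue (ties resolved to the lowest
#' database flat-row index by the ranking contract).
#'
#' @param ranked A [RankedList-class].
#' @param db The matching [ReferenceSiteDB-class].
#' @return Function class identifier (character).
#' @export
maxSimilarityBaseline <- function(ranked, db) {
    if (!length(ranked@order)) stop("empty ranked list")
    db@flatClass[ranked@order[1L]]
}

#' Top-k% mean similarity baseline
#'
#' For each function class, averages the scores of its top
#' `ceiling(k% * class size)` residues (rounding up, so every class
#' contributes at least one residue) and returns the class with the
#' highest average.
#'
#' @param ranked A [RankedList-class].
#' @param db The matching [ReferenceSiteDB-class].
#' @param k_percent Percentage in (0, 100\]; the comparison grid spans
#'   10-40.
#' @return List with `function_id` (argmax class; ties resolved to the
#'   first class in database order) and `means` (named per-class scores).
#' @export
topkMeanBaseline <- function(ranked, db, k_percent = 10) {
    if (!is.numeric(k_percent) || k_percent <= 0 || k_percent > 100)
        stop("k_percent must lie in (0, 100]")
    means <- vapply(db@classIndex, function(idx) {
        sc <- sort(ranked@scores[idx], decreasing = TRUE)
        k <- ceiling(k_percent / 100 * length(sc))
        mean(sc[seq_len(k)])
    }, 0)
    list(function_id = names(means)[which.max(means)], means = means)
}

#' One-sided Mann-Whitney U test on a ranked binary labelling
#'
#' Tests whether in-class similarity scores are stochastically larger
#' than out-of-class scores.  Ties take midranks.  The p-value is
#' computed by exhaustive enumeration over all in-class rank assignments
#' when the count is small (exact, including under ties), and by the
#' tie-corrected normal approximation with continuity correction
#' otherwise.
#'
#' @param scores Numeric similarity scores of all database residues.
#' @param in_class Logical; `TRUE` for residues of the tested class.
#' @param exact_limit Enumerate exhaustively while
#'   `choose(N, m) <= exact_limit` (default 2e5).
#' @return List with `u` (the U statistic of the in-class sample), `z`
#'   (standardised U, tie-corrected, without continuity correction) and
#'   `p` (one-sided upper-tail p-value).
#' @export
mwuTest <- function(scores, in_class, exact_limit = 2e5) {
    in_class <- as.logical(in_class)
    n_tot <- length(scores)
    m <- sum(in_class)
    n <- n_tot - m
    if (m == 0L || n == 0L)
        stop("need both in-class and out-of-class members")
    r <- rank(scores)                      # midranks
    u <- sum(r[in_class]) - m * (m + 1) / 2
    mu <- m * n / 2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n_tot * (n_tot - 1))
    sigma2 <- m * n / 12 * ((n_tot + 1) - tie_term)
    z <- if (sigma2 > 0) (u - mu) / sqrt(sigma2) else 0
    if (choose(n_tot, m) <= exact_limit) {
        combos <- utils::combn(n_tot, m)
        usum <- colSums(matrix(r[combos], nrow = m)) - m * (m + 1) / 2
        p <- mean(usum >= u)
    } else {
        p <- if (sigma2 > 0)
            stats::pnorm((u - 0.5 - mu) / sqrt(sigma2), lower.tail = FALSE)
        else 1
    }
    list(u = u, z = z, p = p)
}

#' Direct Mann-Whitney U baseline
#'
#' Binarises the ranked database residues per class and performs a
#' one-sided Mann-Whitney U test (in-class residues ranked nearer the
#' top); the class with the lowest p-value is returned.
#'
#' @param ranked A [RankedList-class].
#' @param db The matching [ReferenceSiteDB-class].
#' @return List with `function_id` (argmin-p class) and `p` (named
#'   per-class p-values).
#' @export
directMwuBaseline <- function(ranked, db) {
    classes <- names(db@classIndex)
    p <- vapply(classes, function(cl) {
        mwuTest(ranked@scores, db@flatClass == cl)$p
    }, 0)
    list(function_id = classes[which.min(p)], p = p)
}

# Per-class standardised MWU scores over one ranked list, shaped like
# .classEnrichment so the background/annotation machinery can consume it.
# The heuristic residue annotation is the set of in-class members ranked
# in the top half of the list (the U statistic has no running-sum peak).
.classMwuScores <- function(ranked, flat_class, classes = NULL,
                            row_map = NULL) {
    if (is.null(classes)) classes <- unique(flat_class)
    if (is.null(row_map)) row_map <- seq_along(flat_class)
    ord <- ranked@order
    class_along <- flat_class[ord]
    n_tot <- length(ord)
    half <- seq_len(floor(n_tot / 2))
    out <- lapply(classes, function(cl) {
        membership <- flat_class == cl
        n_hit <- sum(membership)
        if (n_hit == 0L || n_hit == n_tot)
            return(list(function_id = cl, es = NA_real_,
                        peak_index = NA_integer_, n_class = n_hit,
                        le_ranks = integer(0)))
        t <- mwuTest(ranked@scores, membership)
        le <- half[class_along[half] == cl]
        list(function_id = cl, es = t$z, peak_index = NA_integer_,
             n_class = n_hit, le_ranks = le)
    })
    res <- data.frame(
        function_id = vapply(out, `[[`, "", "function_id"),
        es = vapply(out, `[[`, 0, "es"),
        peak_index = vapply(out, `[[`, 0L, "peak_index"),
        n_class = vapply(out, `[[`, 0L, "n_class"),
        stringsAsFactors = FALSE)
    res$leading_edge_db <- I(lapply(out, function(o)
        row_map[ord[o$le_ranks]]))
    res$le_ranks <- I(lapply(out, `[[`, "le_ranks"))
    attr(res, "heuristic_residues") <- TRUE
    res
}

#' Rank-sum variant of the annotation workflow
#'
#' Replicates the full annotation pipeline with the per-class weighted
#' K-S enrichment score replaced by the standardised one-sided
#' Mann-Whitney U score.  Empirical backgrounds (built with
#' `statistic = "mwu"`) and BH FDR are applied identically.  The rank-sum
#' statistic has no running-sum peak, so the residue annotation falls
#' back to a heuristic — in-class residues ranked in the top half of the
#' list — and is flagged as such.
#'
#' @inheritParams annotateProtein
#' @return As [annotateProtein()]; the result carries
#'   `attr(, "heuristic_residues") = TRUE`.
#' @export
mwuWithBackgroundBaseline <- function(query, db, backgrounds, alpha = 0.001,
                                      plddt_threshold = 70,
                                      exclude_self = FALSE,
                                      pseudocount = TRUE,
                                      protein_id = NULL) {
    if (!identical(backgrounds@statistic, "mwu"))
        stop("backgrounds must be built with statistic = \"mwu\"")
    out <- annotateProtein(query, db, backgrounds, alpha = alpha,
                           plddt_threshold = plddt_threshold,
                           exclude_self = exclude_self,
                           pseudocount = pseudocount,
                           protein_id = protein_id)
    attr(out, "heuristic_residues") <- TRUE
    out
}
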