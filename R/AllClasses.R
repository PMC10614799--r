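# S4 classes for the annotation workflow.  Residue identity is kept in
# author (PDB) numbering with insertion codes throughout; residues are
# never renumbered.

.REF_COLS <- c("structure_id", "chain_id", "residue_number",
               "insertion_code", "amino_acid", "role")
.ROLES <- c("catalytic", "neighbor", "query")

# Validate a residue-reference data.frame; returns character(0) or messages.
.checkRefs <- function(refs, unique_key = TRUE) {
    msg <- character(0)
    missing_cols <- setdiff(.REF_COLS, names(refs))
    if (length(missing_cols))
        return(paste("missing residue columns:",
                     paste(missing_cols, collapse = ", ")))
    if (nrow(refs)) {
        if (!is.numeric(refs$residue_number) ||
            any(refs$residue_number != as.integer(refs$residue_number)))
            msg <- c(msg, "residue_number must be integer (author numbering)")
        if (any(nchar(refs$insertion_code) > 1L))
            msg <- c(msg, "insertion_code must be one character or empty")
        bad_aa <- !(refs$amino_acid %in% c(standardAminoAcids(), "UNK"))
        if (any(bad_aa))
            msg <- c(msg, paste("non-standard amino_acid codes:",
                                paste(unique(refs$amino_acid[bad_aa]),
                                      collapse = ", ")))
        if (!all(refs$role %in% .ROLES))
            msg <- c(msg, "role must be catalytic, neighbor or query")
        if (unique_key && anyDuplicated(.refKey(refs)))
            msg <- c(msg, paste("duplicate residue reference",
                                "(structure, chain, number, icode)"))
    }
    msg
}

#' EmbeddingTable: per-residue embedding vectors with residue identity
#'
#' Pairs an ordered set of residue references with a numeric embedding
#' matrix (one row per residue, fixed dimension), and optionally a
#' per-residue pLDDT confidence in \[0, 100\] (stored in the B-factor
#' column of AlphaFold-style models).
#'
#' @slot refs `data.frame` with columns `structure_id`, `chain_id`,
#'   `residue_number` (author numbering), `insertion_code`, `amino_acid`
#'   (3-letter code or `"UNK"`), `role` (`catalytic`/`neighbor`/`query`).
#' @slot vectors Numeric matrix, `nrow(refs)` rows, all values finite.
#' @slot plddt Numeric vector of length 0 (absent) or one value per residue.
#'
#' @aliases EmbeddingTable-class
#' @export EmbeddingTable
#' @exportClass EmbeddingTable
EmbeddingTable <- setClass("EmbeddingTable",
    representation(refs = "data.frame", vectors = "matrix",
                   plddt = "numeric"),
    prototype(refs = data.frame(), vectors = matrix(numeric(0), 0, 0),
              plddt = numeric(0)))

setValidity("EmbeddingTable", function(object) {
    msg <- .checkRefs(object@refs)
    if (nrow(object@refs) != nrow(object@vectors))
        msg <- c(msg, "number of refs must equal number of vector rows")
    if (length(object@vectors) && !all(is.finite(object@vectors)))
        msg <- c(msg, "all embedding values must be finite")
    if (length(object@plddt)) {
        if (length(object@plddt) != nrow(object@refs))
            msg <- c(msg, "plddt must have one value per residue")
        if (any(object@plddt < 0 | object@plddt > 100, na.rm = TRUE))
            msg <- c(msg, "plddt must lie in [0, 100]")
    }
    if (length(msg)) msg else TRUE
})

#' Construct an EmbeddingTable
#'
#' @param refs Residue-reference `data.frame` (see
#'   [EmbeddingTable-class]).  Amino-acid codes are normalised to the
#'   standard alphabet or `"UNK"`.
#' @param vectors Numeric matrix with one row per residue.
#' @param plddt Optional numeric vector of per-residue confidences.
#' @return An [EmbeddingTable-class] object.
#' @examples
#' refs <- data.frame(structure_id = "1abc", chain_id = "A",
#'                    residue_number = 1:2, insertion_code = "",
#'                    amino_acid = c("HIS", "GLU"), role = "query")
#' embeddingTable(refs, diag(2))
#' @export
embeddingTable <- function(refs, vectors, plddt = numeric(0)) {
    refs <- as.data.frame(refs, stringsAsFactors = FALSE)
    if (nrow(refs)) {
        refs$amino_acid <- .normalizeAA(refs$amino_acid)
        refs$residue_number <- as.integer(refs$residue_number)
        refs$insertion_code <- as.character(refs$insertion_code)
        refs$insertion_code[is.na(refs$insertion_code)] <- ""
    }
    rownames(refs) <- NULL
    vectors <- as.matrix(vectors)
    storage.mode(vectors) <- "double"
    dimnames(vectors) <- NULL
    new("EmbeddingTable", refs = refs, vectors = vectors,
        plddt = as.numeric(plddt))
}

#' @describeIn embeddingTable Number of residues in the table.
#' @param x,object An `EmbeddingTable`.
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))
#' @export
setMethod("nResidues", "EmbeddingTable", function(x) nrow(x@refs))

#' @describeIn embeddingTable Embedding dimension D.
#' @export
setGeneric("embeddingDim", function(x) standardGeneric("embeddingDim"))
#' @export
setMethod("embeddingDim", "EmbeddingTable", function(x) ncol(x@vectors))

#' @describeIn embeddingTable Residue-reference data.frame.
#' @export
setGeneric("residueRefs", function(x) standardGeneric("residueRefs"))
#' @export
setMethod("residueRefs", "EmbeddingTable", function(x) x@refs)

#' @describeIn embeddingTable Embedding matrix (n x D).
#' @export
setGeneric("embeddingVectors", function(x) standardGeneric("embeddingVectors"))
#' @export
setMethod("embeddingVectors", "EmbeddingTable", function(x) x@vectors)

#' @describeIn embeddingTable Per-residue pLDDT, or `numeric(0)` if absent.
#' @export
setGeneric("plddt", function(x) standardGeneric("plddt"))
#' @export
setMethod("plddt", "EmbeddingTable", function(x) x@plddt)

#' @export
setMethod("show", "EmbeddingTable", function(object) {
    cat(sprintf("EmbeddingTable: %d residues x %d dimensions%s\n",
                nResidues(object), embeddingDim(object),
                if (length(object@plddt)) " (with pLDDT)" else ""))
    if (nResidues(object))
        cat("  structures:",
            paste(unique(object@refs$structure_id), collapse = ", "), "\n")
})

# Subset rows of an EmbeddingTable.
.subsetTable <- function(table, idx) {
    embeddingTable(table@refs[idx, , drop = FALSE],
                   table@vectors[idx, , drop = FALSE],
                   if (length(table@plddt)) table@plddt[idx] else numeric(0))
}

#' ReferenceEntry: one functional site in the reference database
#'
#' A single reference enzyme: its function class (catalytic-mechanism
#' class, more specific than an EC number in some cases), EC number,
#' source structure and chain, the curated catalytic residues, the
#' expanded site (catalytic residues plus structural neighbours), and the
#' embeddings of every site residue.
#'
#' @slot functionId Function class identifier.
#' @slot ecNumber Dotted EC number (up to 4 levels).
#' @slot pdbId,chainId Source structure and chain.
#' @slot catalyticResidues,siteResidues Residue-reference data.frames;
#'   catalytic residues are a subset of site residues.
#' @slot embeddings [EmbeddingTable-class] over `siteResidues`.
#'
#' @aliases ReferenceEntry-class
#' @export ReferenceEntry
#' @exportClass ReferenceEntry
ReferenceEntry <- setClass("ReferenceEntry",
    representation(functionId = "character", ecNumber = "character",
                   pdbId = "character", chainId = "character",
                   catalyticResidues = "data.frame",
                   siteResidues = "data.frame",
                   embeddings = "EmbeddingTable"))

setValidity("ReferenceEntry", function(object) {
    msg <- character(0)
    if (!nrow(object@siteResidues))
        msg <- c(msg, "site_residues must be non-empty")
    if (!nrow(object@catalyticResidues))
        msg <- c(msg, "catalytic_residues must be non-empty")
    if (!all(.refKey(object@catalyticResidues) %in%
             .refKey(object@siteResidues)))
        msg <- c(msg, "catalytic residues must be a subset of site residues")
    if (nrow(object@siteResidues) != nResidues(object@embeddings))
        msg <- c(msg, "every site residue needs exactly one embedding row")
    if (length(msg)) msg else TRUE
})

#' ReferenceSiteDB: flattened database of embedded functional-site residues
#'
#' All site residues of all reference entries, concatenated into one flat
#' array with a function-class label per row, ready for similarity search.
#'
#' @slot entries List of [ReferenceEntry-class] objects.
#' @slot flatRefs Residue references of all site residues (one row per
#'   database residue), with an `entry` column giving the source entry.
#' @slot flatVectors Numeric matrix (N_total x D) of embeddings.
#' @slot flatClass Function-class label per flat row.
#' @slot classIndex Named list mapping function class to flat row indices.
#'
#' @aliases ReferenceSiteDB-class
#' @export ReferenceSiteDB
#' @exportClass ReferenceSiteDB
ReferenceSiteDB <- setClass("ReferenceSiteDB",
    representation(entries = "list", flatRefs = "data.frame",
                   flatVectors = "matrix", flatClass = "character",
                   classIndex = "list"))

setValidity("ReferenceSiteDB", function(object) {
    msg <- character(0)
    n_total <- sum(vapply(object@entries,
                          function(e) nrow(e@siteResidues), 0L))
    if (n_total != nrow(object@flatVectors) ||
        n_total != nrow(object@flatRefs) ||
        n_total != length(object@flatClass))
        msg <- c(msg, "flat arrays must cover every site residue exactly once")
    idx <- sort(unlist(object@classIndex, use.names = FALSE))
    if (length(idx) && !identical(idx, seq_len(n_total)))
        msg <- c(msg, "class_index must partition the flat rows")
    ec_by_fun <- vapply(object@entries, function(e) e@ecNumber, "")
    fun <- vapply(object@entries, function(e) e@functionId, "")
    if (any(vapply(split(ec_by_fun, fun),
                   function(x) length(unique(x)) > 1L, logical(1))))
        msg <- c(msg, "function class maps to more than one EC number")
    dims <- unique(vapply(object@entries,
                          function(e) embeddingDim(e@embeddings), 0L))
    if (length(dims) > 1L)
        msg <- c(msg, "embedding dimension must be uniform across entries")
    if (length(msg)) msg else TRUE
})

#' @describeIn ReferenceSiteDB-class List of reference entries.
#' @param x,object A `ReferenceSiteDB`.
#' @export
setGeneric("dbEntries", function(x) standardGeneric("dbEntries"))
#' @export
setMethod("dbEntries", "ReferenceSiteDB", function(x) x@entries)

#' @describeIn ReferenceSiteDB-class Flat residue references.
#' @export
setGeneric("flatRefs", function(x) standardGeneric("flatRefs"))
#' @export
setMethod("flatRefs", "ReferenceSiteDB", function(x) x@flatRefs)

#' @describeIn ReferenceSiteDB-class Flat embedding matrix.
#' @export
setGeneric("flatVectors", function(x) standardGeneric("flatVectors"))
#' @export
setMethod("flatVectors", "ReferenceSiteDB", function(x) x@flatVectors)

#' @describeIn ReferenceSiteDB-class Function class per flat row.
#' @export
setGeneric("flatClass", function(x) standardGeneric("flatClass"))
#' @export
setMethod("flatClass", "ReferenceSiteDB", function(x) x@flatClass)

#' @describeIn ReferenceSiteDB-class Function class to flat-row index map.
#' @export
setGeneric("classIndex", function(x) standardGeneric("classIndex"))
#' @export
setMethod("classIndex", "ReferenceSiteDB", function(x) x@classIndex)

#' @describeIn ReferenceSiteDB-class Function class to EC number map.
#' @export
setGeneric("ecMap", function(x) standardGeneric("ecMap"))
#' @export
setMethod("ecMap", "ReferenceSiteDB", function(x) {
    fun <- vapply(x@entries, function(e) e@functionId, "")
    ec <- vapply(x@entries, function(e) e@ecNumber, "")
    first <- !duplicated(fun)
    out <- ec[first][match(names(x@classIndex), fun[first])]
    names(out) <- names(x@classIndex)
    out
})

#' @export
setMethod("show", "ReferenceSiteDB", function(object) {
    cat(sprintf(
        "ReferenceSiteDB: %d residues, %d entries, %d function classes (D=%d)\n",
        nrow(object@flatRefs), length(object@entries),
        length(object@classIndex), ncol(object@flatVectors)))
})

#' RankedList: database residues ranked by similarity to a query
#'
#' For every database residue, the maximum cosine similarity to any query
#' residue and the query residue achieving it, plus the descending-score
#' ordering of database rows.
#'
#' @slot order Integer permutation of database flat rows, scores
#'   non-increasing (ties broken by ascending database row).
#' @slot scores Max similarity per database row (database-row order).
#' @slot bestQuery Query row index achieving the max, per database row
#'   (ties broken by lowest query index).
#' @slot nQuery Number of query residues compared.
#'
#' @aliases RankedList-class
#' @export RankedList
#' @exportClass RankedList
RankedList <- setClass("RankedList",
    representation(order = "integer", scores = "numeric",
                   bestQuery = "integer", nQuery = "integer"))

setValidity("RankedList", function(object) {
    msg <- character(0)
    n <- length(object@scores)
    if (length(object@order) != n || length(object@bestQuery) != n)
        msg <- c(msg, "order, scores and bestQuery must have equal length")
    if (n && !identical(sort(object@order), seq_len(n)))
        msg <- c(msg, "order must be a permutation of the database rows")
    if (n && is.unsorted(-object@scores[object@order]))
        msg <- c(msg, "scores must be non-increasing along order")
    if (n && (any(object@scores < -1 - 1e-9) || any(object@scores > 1 + 1e-9)))
        msg <- c(msg, "scores must lie in [-1, 1]")
    if (n && (any(object@bestQuery < 1L) ||
              any(object@bestQuery > object@nQuery)))
        msg <- c(msg, "bestQuery indices out of range")
    if (length(msg)) msg else TRUE
})

#' @describeIn RankedList-class Permutation of database rows by score.
#' @param x,object A `RankedList`.
#' @export
setGeneric("rankOrder", function(x) standardGeneric("rankOrder"))
#' @export
setMethod("rankOrder", "RankedList", function(x) x@order)

#' @describeIn RankedList-class Max similarity per database row.
#' @export
setGeneric("rankScores", function(x) standardGeneric("rankScores"))
#' @export
setMethod("rankScores", "RankedList", function(x) x@scores)

#' @describeIn RankedList-class Best-matching query row per database row.
#' @export
setGeneric("bestQuery", function(x) standardGeneric("bestQuery"))
#' @export
setMethod("bestQuery", "RankedList", function(x) x@bestQuery)

#' @export
setMethod("show", "RankedList", function(object) {
    cat(sprintf("RankedList: %d database residues vs %d query residues\n",
                length(object@scores), object@nQuery))
    if (length(object@scores))
        cat(sprintf("  top score %.4f (db row %d -> query row %d)\n",
                    object@scores[object@order[1L]], object@order[1L],
                    object@bestQuery[object@order[1L]]))
})

#' BackgroundDistributions: function-specific empirical null scores
#'
#' For each function class, the enrichment scores observed on background
#' proteins not annotated with that class.  Classes with fewer than
#' `minSize` null scores are excluded from significance calls.
#'
#' @slot dist Named list of numeric null-score vectors, one per class.
#' @slot provenance Protein identifiers contributing to the nulls.
#' @slot minSize Minimum null count required to score a class.
#' @slot statistic Score type the nulls were computed with
#'   (`"ks"` or `"mwu"`).
#'
#' @aliases BackgroundDistributions-class
#' @export BackgroundDistributions
#' @exportClass BackgroundDistributions
BackgroundDistributions <- setClass("BackgroundDistributions",
    representation(dist = "list", provenance = "character",
                   minSize = "integer", statistic = "character"),
    prototype(minSize = 50L, statistic = "ks"))

setValidity("BackgroundDistributions", function(object) {
    msg <- character(0)
    if (is.null(names(object@dist)) && length(object@dist))
        msg <- c(msg, "null distributions must be named by function class")
    finite <- vapply(object@dist, function(d) all(is.finite(d)), logical(1))
    if (length(finite) && !all(finite))
        msg <- c(msg, "all null scores must be finite")
    if (length(msg)) msg else TRUE
})

#' @describeIn BackgroundDistributions-class Null scores for one class.
#' @param x,object A `BackgroundDistributions`.
#' @param functionId Function class identifier.
#' @export
setGeneric("backgroundFor",
           function(x, functionId) standardGeneric("backgroundFor"))
#' @export
setMethod("backgroundFor", "BackgroundDistributions",
          function(x, functionId) x@dist[[functionId]])

#' @describeIn BackgroundDistributions-class Classes with a null
#'   distribution.
#' @export
setGeneric("backgroundClasses",
           function(x) standardGeneric("backgroundClasses"))
#' @export
setMethod("backgroundClasses", "BackgroundDistributions",
          function(x) names(x@dist))

#' @export
setMethod("show", "BackgroundDistributions", function(object) {
    sizes <- lengths(object@dist)
    cat(sprintf(
        "BackgroundDistributions (%s): %d classes, %s null scores each, min_size=%d\n",
        object@statistic, length(object@dist),
        if (length(sizes)) paste(range(sizes), collapse = "-") else "0",
        object@minSize))
})

#' CatalyticMatch: catalytic-residue correspondence for one prediction
#'
#' Exact amino-acid-type pairing between the catalytic residues of a
#' reference entry and the leading-edge residues annotated on the query,
#' with coverage and (once computed) the all-atom superposition RMSD.
#'
#' @slot pairs `data.frame` with reference and query residue identity
#'   columns (`ref_*`, `query_*`) and the embedding similarity of the pair.
#' @slot coverage Fraction of reference catalytic residues matched.
#' @slot nReference Number of reference catalytic residues.
#' @slot rmsd All-atom RMSD in Angstrom after Kabsch superposition, or
#'   `NA_real_` when fewer than two residues match.
#'
#' @aliases CatalyticMatch-class
#' @export CatalyticMatch
#' @exportClass CatalyticMatch
CatalyticMatch <- setClass("CatalyticMatch",
    representation(pairs = "data.frame", coverage = "numeric",
                   nReference = "integer", rmsd = "numeric"),
    prototype(rmsd = NA_real_))

setValidity("CatalyticMatch", function(object) {
    msg <- character(0)
    if (object@coverage < 0 || object@coverage > 1)
        msg <- c(msg, "coverage must lie in [0, 1]")
    if (nrow(object@pairs) > object@nReference)
        msg <- c(msg, "more pairs than reference catalytic residues")
    if (!is.na(object@rmsd) && nrow(object@pairs) < 2L)
        msg <- c(msg, "rmsd defined only when at least two residues match")
    if (length(msg)) msg else TRUE
})

#' @export
setMethod("show", "CatalyticMatch", function(object) {
    cat(sprintf(
        "CatalyticMatch: %d/%d catalytic residues matched (coverage %.2f), rmsd %s\n",
        nrow(object@pairs), object@nReference, object@coverage,
        if (is.na(object@rmsd)) "undefined"
        else sprintf("%.2f A", object@rmsd)))
})
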