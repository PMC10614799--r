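# Embedding table I/O and the pluggable embedding-backend contract.
#
# Two on-disk dialects: a human-readable tab-separated table (metadata
# columns then e0..e{D-1} float columns, >= 12 significant digits) and a
# binary container (serialized, bitwise round-trip) for scale.

.EMB_FORMAT_TAG <- "sitenrich-embeddings"
.EMB_FORMAT_VERSION <- 1L

#' Write an embedding table to disk
#'
#' @param table An [EmbeddingTable-class].
#' @param path Output path.
#' @param format `"tabular"` (TSV; round-trips vectors to at least 12
#'   significant digits) or `"binary"` (bitwise round-trip).
#' @return Invisibly, `path`.
#' @seealso [readEmbeddingTable()]
#' @export
writeEmbeddingTable <- function(table, path,
                                format = c("tabular", "binary")) {
    format <- match.arg(format)
    stopifnot(is(table, "EmbeddingTable"))
    validObject(table)
    if (format == "binary") {
        obj <- list(format = .EMB_FORMAT_TAG, version = .EMB_FORMAT_VERSION,
                    refs = table@refs, vectors = table@vectors,
                    plddt = table@plddt)
        saveRDS(obj, path)
        return(invisible(path))
    }
    d <- embeddingDim(table)
    header <- c("structure_id", "chain_id", "residue_number",
                "insertion_code", "amino_acid", "role",
                if (length(table@plddt)) "plddt",
                if (d > 0) paste0("e", seq_len(d) - 1L))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(header, collapse = "\t"), con)
    if (nResidues(table)) {
        meta <- cbind(table@refs$structure_id, table@refs$chain_id,
                      as.character(table@refs$residue_number),
                      table@refs$insertion_code, table@refs$amino_acid,
                      table@refs$role)
        if (length(table@plddt)) meta <- cbind(meta, .fmtNum(table@plddt))
        vec <- matrix(.fmtNum(table@vectors), nrow = nResidues(table))
        writeLines(apply(cbind(meta, vec), 1L, paste, collapse = "\t"), con)
    }
    invisible(path)
}

#' Read an embedding table from disk
#'
#' @param path File written by [writeEmbeddingTable()].
#' @param format `"tabular"` or `"binary"`.
#' @return An [EmbeddingTable-class]; row order is preserved from the
#'   file and all class invariants (finite vectors, uniform dimension,
#'   unique residue keys) are enforced.
#' @export
readEmbeddingTable <- function(path, format = c("tabular", "binary")) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("embedding file not found: ", path)
    if (format == "binary") {
        obj <- readRDS(path)
        if (!identical(obj$format, .EMB_FORMAT_TAG))
            stop("not an embedding container: ", path)
        if (!identical(obj$version, .EMB_FORMAT_VERSION))
            stop("embedding container version mismatch: ", obj$version)
        tab <- new("EmbeddingTable", refs = obj$refs, vectors = obj$vectors,
                   plddt = obj$plddt)
        validObject(tab)
        return(tab)
    }
    header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
    meta_cols <- c("structure_id", "chain_id", "residue_number",
                   "insertion_code", "amino_acid", "role")
    if (!identical(header[seq_along(meta_cols)], meta_cols))
        stop("malformed embedding table header in ", path)
    rest <- header[-seq_along(meta_cols)]
    has_plddt <- length(rest) > 0L && rest[1L] == "plddt"
    ecols <- if (has_plddt) rest[-1L] else rest
    if (length(ecols) && !identical(ecols, paste0("e", seq_along(ecols) - 1L)))
        stop("malformed embedding table header: expected e0..e",
             length(ecols) - 1L, " in ", path)
    df <- utils::read.delim(path, sep = "\t", header = TRUE,
                            colClasses = "character", check.names = FALSE,
                            na.strings = NULL, fill = FALSE,
                            quote = "", comment.char = "")
    n <- nrow(df)
    refs <- data.frame(
        structure_id   = df$structure_id %||% character(n),
        chain_id       = df$chain_id %||% character(n),
        residue_number = as.integer(df$residue_number),
        insertion_code = df$insertion_code %||% character(n),
        amino_acid     = df$amino_acid %||% character(n),
        role           = df$role %||% character(n),
        stringsAsFactors = FALSE)
    vectors <- matrix(numeric(0), n, length(ecols))
    if (length(ecols) && n)
        vectors <- vapply(df[ecols], as.numeric, numeric(n))
    if (is.null(dim(vectors))) vectors <- matrix(vectors, nrow = n)
    dimnames(vectors) <- NULL
    if (anyNA(vectors))
        stop("ragged or non-numeric embedding rows in ", path)
    tab <- embeddingTable(refs, vectors,
                          if (has_plddt) as.numeric(df$plddt)
                          else numeric(0))
    validObject(tab)
    tab
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' EmbeddingBackend: contract for per-residue embedding producers
#'
#' A backend maps (structure, chain, residues) to an
#' [EmbeddingTable-class] of fixed dimension, deterministically.  Real
#' backends (e.g. deep local-structure or protein-language models) are
#' external; the package ships a deterministic mock backend so the whole
#' workflow is testable without model weights.
#'
#' @slot name Backend name.
#' @slot dimension Embedding dimension produced.
#'
#' @aliases EmbeddingBackend-class MockEmbeddingBackend-class
#' @exportClass EmbeddingBackend
setClass("EmbeddingBackend", representation("VIRTUAL", name = "character",
                                            dimension = "integer"))

#' @rdname EmbeddingBackend-class
#' @exportClass MockEmbeddingBackend
setClass("MockEmbeddingBackend", contains = "EmbeddingBackend",
         representation(seed = "integer", plddtFromB = "logical"))

#' Deterministic mock embedding backend
#'
#' Each residue's vector is a pure function of (amino-acid type, the
#' multiset of atom-element counts within 10 Angstrom of the residue
#' centroid, backend seed), unit-normalised.  Identical local
#' environments therefore embed to identical vectors (cosine similarity
#' 1), which makes planted-site fixtures exact.
#'
#' @param dimension Embedding dimension.
#' @param seed Backend seed; part of the hashed identity of each vector.
#' @param plddtFromB If `TRUE`, carry per-residue mean B-factor values
#'   into the table's pLDDT column (AlphaFold-style models).
#' @return A `MockEmbeddingBackend`.
#' @examples
#' be <- mockEmbeddingBackend(dimension = 8)
#' @export
mockEmbeddingBackend <- function(dimension = 32L, seed = 1L,
                                 plddtFromB = FALSE) {
    new("MockEmbeddingBackend", name = "mock",
        dimension = as.integer(dimension), seed = as.integer(seed),
        plddtFromB = plddtFromB)
}

#' Embed residues with a backend
#'
#' @param backend An [EmbeddingBackend-class].
#' @param structure Structure (see [atomTable()]).
#' @param chain_id Chain holding the residues.
#' @param residues Residue-reference `data.frame`; every residue must be
#'   present in the structure.
#' @return An [EmbeddingTable-class], one row per requested residue.
#' @export
setGeneric("embedResidues", function(backend, structure, chain_id, residues)
    standardGeneric("embedResidues"))

#' @rdname embedResidues
#' @export
setMethod("embedResidues", "MockEmbeddingBackend",
    function(backend, structure, chain_id, residues) {
        mockEmbed(structure, chain_id, residues,
                  dimension = backend@dimension, seed = backend@seed,
                  plddtFromB = backend@plddtFromB)
    })

#' Deterministic mock embedding of residues
#'
#' Functional form of the mock backend: see [mockEmbeddingBackend()].
#'
#' @inheritParams embedResidues
#' @param dimension Embedding dimension.
#' @param seed Integer seed hashed into every vector.
#' @param radius Neighbourhood radius in Angstrom for the atom-element
#'   environment (default 10).
#' @param plddtFromB Carry per-residue mean B-factors as pLDDT.
#' @return An [EmbeddingTable-class].
#' @export
mockEmbed <- function(structure, chain_id, residues, dimension = 32L,
                      seed = 1L, radius = 10, plddtFromB = FALSE) {
    at <- atomTable(structure)
    chain_at <- at[at$chain == chain_id, , drop = FALSE]
    if (!nrow(chain_at)) stop("chain not found in structure: ", chain_id)
    residues <- as.data.frame(residues, stringsAsFactors = FALSE)
    own <- .atomsByResidue(chain_at, residues)
    coords <- as.matrix(at[, c("x", "y", "z")])
    n <- nrow(residues)
    vectors <- matrix(0, n, dimension)
    plddt_vals <- rep(NA_real_, n)
    for (i in seq_len(n)) {
        ai <- own[[i]]
        center <- colMeans(chain_at[ai, c("x", "y", "z"), drop = FALSE])
        d2 <- (coords[, 1] - center[1])^2 + (coords[, 2] - center[2])^2 +
              (coords[, 3] - center[3])^2
        env <- at$elesy[d2 <= radius^2]
        counts <- table(env)
        env_str <- paste(paste0(names(counts), ":", as.integer(counts)),
                         collapse = ",")
        aa <- .normalizeAA(residues$amino_acid[i])
        h <- .stringHash(paste(aa, env_str, seed, sep = "|"))
        v <- .withSeed(h, stats::rnorm(dimension))
        vectors[i, ] <- v / sqrt(sum(v^2))
        if (plddtFromB) plddt_vals[i] <- mean(chain_at$b[ai])
    }
    refs <- residues
    refs$amino_acid <- .normalizeAA(refs$amino_acid)
    embeddingTable(refs, vectors,
                   if (plddtFromB && !anyNA(plddt_vals)) plddt_vals
                   else numeric(0))
}

#' Validate an embedding backend against the backend contract
#'
#' Embeds a fixture twice and asserts determinism, constant dimension and
#' the [EmbeddingTable-class] invariants.
#'
#' @inheritParams embedResidues
#' @return `TRUE` invisibly; errors describe any contract violation.
#' @export
validateBackend <- function(backend, structure, chain_id, residues) {
    t1 <- embedResidues(backend, structure, chain_id, residues)
    t2 <- embedResidues(backend, structure, chain_id, residues)
    validObject(t1)
    if (embeddingDim(t1) != backend@dimension)
        stop("backend dimension mismatch: produced ", embeddingDim(t1),
             ", declared ", backend@dimension)
    if (!identical(t1@vectors, t2@vectors))
        stop("backend is not deterministic: repeated embedding differs")
    if (nResidues(t1) != nrow(residues))
        stop("backend must return one row per requested residue")
    invisible(TRUE)
}
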