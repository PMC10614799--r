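# Reference database construction: strip heteroatoms, expand each active
# site to its structural neighbourhood, embed all site residues, and
# flatten everything into one labelled residue array.

.DB_FORMAT_TAG <- "sitenrich-refdb"
.DB_FORMAT_VERSION <- 1L

#' Expand an active site to its structural neighbourhood
#'
#' Returns the catalytic residues plus every residue of the chain having
#' at least one atom within `cutoff` Angstrom (inclusive) of any atom of
#' any catalytic residue.  The average curated site has fewer than five
#' catalytic residues, too few for stable enrichment statistics; the 3.5 A
#' expansion captures every residue that may interact with a catalytic
#' residue (e.g. via hydrogen bonding).
#'
#' @param structure Structure with heteroatoms already stripped (see
#'   [stripHeteroatoms()]).
#' @param chain_id Chain identifier.
#' @param catalytic Residue-reference `data.frame` of catalytic residues,
#'   or a character vector / comma string of `"HIS:486"` tokens.
#' @param cutoff Distance cutoff in Angstrom (default 3.5, inclusive).
#' @param heavy_only If `TRUE`, hydrogens are ignored in the distance
#'   test; by default every atom present participates.
#' @param structure_id Identifier stamped on the returned refs.
#' @return Residue-reference `data.frame` in chain order, with `role`
#'   set to `"catalytic"` or `"neighbor"`.
#' @export
expandActiveSite <- function(structure, chain_id, catalytic, cutoff = 3.5,
                             heavy_only = FALSE, structure_id = "") {
    if (!is.numeric(cutoff) || cutoff <= 0)
        stop("cutoff must be a positive distance in Angstrom")
    at <- atomTable(structure)
    at <- at[at$chain == chain_id, , drop = FALSE]
    if (!nrow(at)) stop("chain not found in structure: ", chain_id)
    if (heavy_only) at <- at[at$elesy != "H", , drop = FALSE]
    if (is.character(catalytic))
        catalytic <- parseResidueTokens(catalytic, structure_id, chain_id)
    rownames(at) <- NULL
    cat_atoms <- .atomsByResidue(at, catalytic)   # errors if absent
    cat_idx <- sort(unique(unlist(cat_atoms)))
    coords <- as.matrix(at[, c("x", "y", "z")])
    cat_xyz <- coords[cat_idx, , drop = FALSE]
    # squared distance of every chain atom to its nearest catalytic atom
    cross <- coords %*% t(cat_xyz)
    d2 <- outer(rowSums(coords^2), rep(1, nrow(cat_xyz))) +
        outer(rep(1, nrow(coords)), rowSums(cat_xyz^2)) - 2 * cross
    near <- apply(d2, 1L, min) <= cutoff^2 + 1e-9
    residues <- .residuesOf(at, structure_id = structure_id,
                            role = "neighbor")
    res_key <- paste(residues$chain_id, residues$residue_number,
                     residues$insertion_code, sep = "\r")
    atom_key <- paste(at$chain, at$resno, at$insert, sep = "\r")
    hit <- res_key %in% unique(atom_key[near])
    cat_key <- paste(catalytic$chain_id, catalytic$residue_number,
                     catalytic$insertion_code, sep = "\r")
    is_cat <- res_key %in% cat_key
    out <- residues[hit | is_cat, , drop = FALSE]
    out$role <- ifelse(res_key[hit | is_cat] %in% cat_key,
                       "catalytic", "neighbor")
    # chain order (author numbering), independent of atom record order
    out <- out[order(out$residue_number, out$insertion_code), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Build the reference functional-site database
#'
#' For each entry: strip heteroatoms from the reference chain, expand the
#' active site around the curated catalytic residues, embed every site
#' residue with the backend, and assemble the flattened database used for
#' similarity search.
#'
#' @param entry_specs List of entry specifications; each a list with
#'   elements `function_id`, `ec_number`, `structure` (path or structure
#'   object), `chain`, `catalytic` (tokens or residue refs) and optional
#'   `structure_id`.  See [readEntryManifest()].
#' @param backend An [EmbeddingBackend-class].
#' @param cutoff Site-expansion cutoff in Angstrom (default 3.5).
#' @param fail_fast If `FALSE`, entries that fail are skipped and
#'   reported in the build report attribute instead of aborting.
#' @return A [ReferenceSiteDB-class].  Failed entries (when
#'   `fail_fast = FALSE`) are recorded in `attr(db, "build_report")`.
#' @export
buildReferenceDB <- function(entry_specs, backend, cutoff = 3.5,
                             fail_fast = TRUE) {
    entries <- list()
    report <- data.frame(function_id = character(0), status = character(0),
                         message = character(0), stringsAsFactors = FALSE)
    for (spec in entry_specs) {
        res <- tryCatch({
            structure <- spec$structure
            if (is.character(structure) && length(structure) == 1L)
                structure <- readStructure(structure)
            sid <- spec$structure_id %||% spec$pdb_id %||%
                (if (is.character(spec$structure)) basename(spec$structure)
                 else "structure")
            sid <- sub("\\.(pdb|ent|cif)$", "", sid)
            chain_at <- stripHeteroatoms(structure, spec$chain)
            catalytic <- spec$catalytic
            if (is.character(catalytic))
                catalytic <- parseResidueTokens(catalytic, sid, spec$chain)
            catalytic$structure_id <- sid
            # amino-acid types from coordinates, not from the manifest
            own <- .atomsByResidue(chain_at, catalytic)
            catalytic$amino_acid <- .normalizeAA(
                vapply(own, function(ai) chain_at$resid[ai[1L]], ""))
            site <- expandActiveSite(chain_at, spec$chain, catalytic,
                                     cutoff = cutoff, structure_id = sid)
            emb <- embedResidues(backend, chain_at, spec$chain, site)
            entry <- new("ReferenceEntry",
                         functionId = spec$function_id,
                         ecNumber = spec$ec_number, pdbId = sid,
                         chainId = spec$chain,
                         catalyticResidues = site[site$role == "catalytic", ,
                                                  drop = FALSE],
                         siteResidues = site, embeddings = emb)
            validObject(entry)
            entry
        }, error = function(e) e)
        if (inherits(res, "error")) {
            if (fail_fast)
                stop("entry ", spec$function_id, " failed: ",
                     conditionMessage(res))
            report <- rbind(report, data.frame(
                function_id = spec$function_id, status = "skipped",
                message = conditionMessage(res), stringsAsFactors = FALSE))
            warning("skipping entry ", spec$function_id, ": ",
                    conditionMessage(res))
        } else {
            entries <- c(entries, res)
            report <- rbind(report, data.frame(
                function_id = spec$function_id, status = "ok",
                message = "", stringsAsFactors = FALSE))
        }
    }
    db <- assembleReferenceDB(entries)
    attr(db, "build_report") <- report
    db
}

#' Assemble a ReferenceSiteDB from entries
#'
#' Flattens a list of [ReferenceEntry-class] objects into the search
#' arrays; used by [buildReferenceDB()] and the synthetic generators.
#'
#' @param entries List of `ReferenceEntry` objects.
#' @return A [ReferenceSiteDB-class].
#' @export
assembleReferenceDB <- function(entries) {
    if (!length(entries)) stop("reference database has no entries")
    refs_list <- lapply(seq_along(entries), function(i) {
        r <- entries[[i]]@siteResidues
        r$entry <- i
        r
    })
    flat_refs <- do.call(rbind, refs_list)
    rownames(flat_refs) <- NULL
    flat_vectors <- do.call(rbind, lapply(entries,
                                          function(e) e@embeddings@vectors))
    flat_class <- rep(vapply(entries, function(e) e@functionId, ""),
                      vapply(entries, function(e) nrow(e@siteResidues), 0L))
    class_index <- split(seq_along(flat_class), flat_class)
    class_index <- class_index[unique(flat_class)]  # stable class order
    db <- new("ReferenceSiteDB", entries = entries, flatRefs = flat_refs,
              flatVectors = flat_vectors, flatClass = flat_class,
              classIndex = class_index)
    validObject(db)
    db
}

#' Read a reference-entry manifest
#'
#' Tab-separated, one reference entry per line with columns
#' `function_id`, `ec_number`, `structure_path`, `chain`, `catalytic`
#' (comma-separated `"HIS:486"` tokens).  Relative structure paths are
#' resolved against the manifest's directory.
#'
#' @param path Manifest path.
#' @return List of entry specifications for [buildReferenceDB()].
#' @export
readEntryManifest <- function(path) {
    df <- utils::read.delim(path, sep = "\t", header = TRUE,
                            colClasses = "character", quote = "",
                            comment.char = "#")
    need <- c("function_id", "ec_number", "structure_path", "chain",
              "catalytic")
    if (!all(need %in% names(df)))
        stop("manifest must have columns: ", paste(need, collapse = ", "))
    base <- dirname(normalizePath(path))
    lapply(seq_len(nrow(df)), function(i) {
        sp <- df$structure_path[i]
        if (!file.exists(sp) && file.exists(file.path(base, sp)))
            sp <- file.path(base, sp)
        list(function_id = df$function_id[i], ec_number = df$ec_number[i],
             structure = sp, chain = df$chain[i],
             catalytic = df$catalytic[i])
    })
}

#' Save / load a reference database
#'
#' Versioned binary container; round-trips bitwise on vectors and
#' field-equal on metadata.
#'
#' @param db A [ReferenceSiteDB-class].
#' @param path Container path.
#' @return `saveReferenceDB` returns `path` invisibly; `loadReferenceDB`
#'   returns the database.
#' @export
saveReferenceDB <- function(db, path) {
    stopifnot(is(db, "ReferenceSiteDB"))
    attr(db, "build_report") <- NULL
    saveRDS(list(format = .DB_FORMAT_TAG, version = .DB_FORMAT_VERSION,
                 db = db), path)
    invisible(path)
}

#' @rdname saveReferenceDB
#' @export
loadReferenceDB <- function(path) {
    obj <- readRDS(path)
    if (!identical(obj$format, .DB_FORMAT_TAG))
        stop("not a reference database container: ", path)
    if (!identical(obj$version, .DB_FORMAT_VERSION))
        stop("reference database container version mismatch: ", obj$version)
    validObject(obj$db)
    obj$db
}
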