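# Structure handling.  Structures are parsed with bio3d (PDB and mmCIF)
# and normalised internally to a plain atom table: one row per atom with
# columns type, elety, elesy, resid, chain, resno, insert, alt, x, y, z, b.

.ATOM_COLS <- c("type", "elety", "elesy", "resid", "chain", "resno",
                "insert", "alt", "x", "y", "z", "b")

#' Read a protein structure file
#'
#' Parses a PDB or mmCIF file via \pkg{bio3d} and returns a normalised
#' atom table.  For AlphaFold-style models the B-factor column carries the
#' per-residue pLDDT confidence; it is preserved in column `b`.
#'
#' @param path Path to a `.pdb`/`.ent` or `.cif` file.
#' @return Atom `data.frame` (one row per atom) accepted by every
#'   structure operation in the package.
#' @seealso [stripHeteroatoms()], [expandActiveSite()]
#' @export
readStructure <- function(path) {
    if (!file.exists(path)) stop("structure file not found: ", path)
    ext <- tolower(tools::file_ext(path))
    pdb <- if (ext == "cif") bio3d::read.cif(path) else bio3d::read.pdb(path)
    atomTable(pdb)
}

#' Normalise a structure to an atom table
#'
#' Accepts a `bio3d` `pdb` object or an atom `data.frame` and returns the
#' canonical atom table used internally.  Missing element symbols are
#' derived from atom names; blank insertion codes and altlocs become `""`.
#'
#' @param structure `bio3d` `pdb` object or atom `data.frame` with at
#'   least columns `type`, `elety`, `resid`, `chain`, `resno`, `x`, `y`,
#'   `z`.
#' @return Atom `data.frame` with the canonical columns.
#' @export
atomTable <- function(structure) {
    at <- if (inherits(structure, "pdb")) structure$atom
          else as.data.frame(structure, stringsAsFactors = FALSE)
    need <- c("type", "elety", "resid", "chain", "resno", "x", "y", "z")
    missing_cols <- setdiff(need, names(at))
    if (length(missing_cols))
        stop("atom table lacks columns: ",
             paste(missing_cols, collapse = ", "))
    if (is.null(at$insert)) at$insert <- ""
    if (is.null(at$alt)) at$alt <- ""
    if (is.null(at$b)) at$b <- NA_real_
    if (is.null(at$elesy) || all(is.na(at$elesy)))
        at$elesy <- .elementFromName(at$elety)
    for (col in c("insert", "alt", "elesy"))
        at[[col]][is.na(at[[col]])] <- ""
    at$resno <- as.integer(at$resno)
    at[, .ATOM_COLS]
}

# Element symbol from a PDB atom name: strip digits/primes, take the
# leading alphabetic token ("CA" -> C is wrong for calcium hetatms, but
# retained rows are polymer atoms where the first letter is the element).
.elementFromName <- function(elety) {
    e <- gsub("[^A-Za-z]", "", as.character(elety))
    toupper(substr(e, 1L, 1L))
}

#' Remove ligands, waters and other heteroatoms from a chain
#'
#' Retains only standard polymer residues of the requested protein chain:
#' waters, ions, ligands and any other `HETATM` records are dropped, as
#' are alternate conformers other than altloc `"A"` or blank.  The
#' coordinates of retained atoms are unchanged.
#'
#' @param structure Structure (see [atomTable()]).
#' @param chain_id Chain identifier to retain.
#' @return Atom table containing only standard residues of the chain.
#' @export
stripHeteroatoms <- function(structure, chain_id) {
    at <- atomTable(structure)
    if (!chain_id %in% at$chain)
        stop("chain not found in structure: ", chain_id)
    at <- at[at$chain == chain_id, , drop = FALSE]
    keep <- at$type == "ATOM" &
        toupper(at$resid) %in% standardAminoAcids() &
        at$alt %in% c("", "A")
    at <- at[keep, , drop = FALSE]
    if (!nrow(at))
        stop("chain ", chain_id,
             " is empty after heteroatom removal (no standard residues)")
    rownames(at) <- NULL
    at
}

#' List the residues of a structure
#'
#' Residue references (author numbering, insertion codes preserved) for
#' every residue of a structure, in order of first appearance — the
#' residue set to embed when annotating a whole protein.
#'
#' @param structure Structure (see [atomTable()]).
#' @param structure_id Identifier stamped on the refs.
#' @param role Role assigned to every residue (default `"query"`).
#' @param chain_id Optional chain restriction.
#' @return Residue-reference `data.frame`.
#' @export
structureResidues <- function(structure, structure_id = "",
                              role = "query", chain_id = NULL) {
    at <- atomTable(structure)
    if (!is.null(chain_id)) {
        at <- at[at$chain == chain_id, , drop = FALSE]
        if (!nrow(at)) stop("chain not found in structure: ", chain_id)
    }
    .residuesOf(at, structure_id = structure_id, role = role)
}

# Residue references (author numbering) for every residue of an atom
# table, in order of first appearance in the file.
.residuesOf <- function(at, structure_id = "", role = "query") {
    key <- paste(at$chain, at$resno, at$insert, sep = "\r")
    first <- !duplicated(key)
    data.frame(
        structure_id   = structure_id,
        chain_id       = at$chain[first],
        residue_number = at$resno[first],
        insertion_code = at$insert[first],
        amino_acid     = .normalizeAA(at$resid[first]),
        role           = role,
        stringsAsFactors = FALSE)
}

# Row indices of the atoms belonging to each residue ref (list parallel
# to the rows of `refs`); errors on refs absent from the table.
.atomsByResidue <- function(at, refs) {
    akey <- paste(at$chain, at$resno, at$insert, sep = "\r")
    rkey <- paste(refs$chain_id, refs$residue_number, refs$insertion_code,
                  sep = "\r")
    idx <- split(seq_len(nrow(at)), factor(akey, levels = unique(rkey)))
    miss <- lengths(idx) == 0L
    if (any(miss))
        stop("residue(s) not found in structure: ",
             paste(.residueLabel(refs[match(names(idx)[miss],
                                            rkey), , drop = FALSE]),
                   collapse = ", "))
    idx[match(rkey, names(idx))]
}

#' Write an atom table to a PDB file
#'
#' Thin wrapper over [bio3d::write.pdb()] used by the synthetic fixture
#' generators and the command-line tool.
#'
#' @param structure Structure (see [atomTable()]).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
writeStructurePdb <- function(structure, path) {
    at <- atomTable(structure)
    n <- nrow(at)
    xyz <- as.numeric(t(as.matrix(at[, c("x", "y", "z")])))
    bio3d::write.pdb(file = path, xyz = xyz, type = at$type,
                     eleno = seq_len(n), resno = at$resno,
                     resid = at$resid, chain = at$chain,
                     insert = ifelse(nzchar(at$insert), at$insert, NA),
                     elety = at$elety, elesy = at$elesy,
                     b = ifelse(is.na(at$b), 0, at$b), o = rep(1, n))
    invisible(path)
}
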