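# Internal helpers shared across modules.

#' Standard amino acid three-letter codes
#'
#' The twenty standard residue codes recognised throughout the package;
#' anything else is mapped to `"UNK"`.
#'
#' @return Character vector of 20 three-letter codes.
#' @export
standardAminoAcids <- function() {
    c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
      "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
      "TYR", "VAL")
}

# Map arbitrary residue codes to the standard alphabet (else "UNK").
.normalizeAA <- function(aa) {
    aa <- toupper(as.character(aa))
    ifelse(aa %in% standardAminoAcids(), aa, "UNK")
}

# Deterministic 31-adic string hash into [1, 2^31 - 2]; used to derive
# RNG streams for the mock embedding backend.  Not cryptographic.
.stringHash <- function(s) {
    m <- 2147483647  # 2^31 - 1, prime
    h <- 0
    for (code in utf8ToInt(s)) h <- (h * 31 + code) %% m
    as.integer(h %% (m - 1) + 1)
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.
.withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
        on.exit(suppressWarnings(
            rm(".Random.seed", envir = globalenv())), add = TRUE)
    }
    set.seed(as.integer(seed))
    expr
}

# Residue key used for uniqueness checks: structure/chain/number/icode.
.refKey <- function(refs) {
    paste(refs$structure_id, refs$chain_id, refs$residue_number,
          refs$insertion_code, sep = "\r")
}

#' Parse catalytic residue tokens
#'
#' Tokens have the form `"HIS:486"` or `"HIS:486:A"` (residue type, author
#' residue number, optional insertion code), comma-separated in manifests.
#'
#' @param tokens Character vector of tokens, or a single comma-separated
#'   string.
#' @param structure_id,chain_id Identifiers attached to the parsed refs.
#' @return A residue-reference `data.frame` with `role = "catalytic"`.
#' @export
parseResidueTokens <- function(tokens, structure_id = "", chain_id = "") {
    if (length(tokens) == 1L && grepl(",", tokens))
        tokens <- strsplit(tokens, ",")[[1]]
    tokens <- trimws(tokens)
    tokens <- tokens[nzchar(tokens)]
    parts <- strsplit(tokens, ":", fixed = TRUE)
    bad <- vapply(parts, function(p) length(p) < 2L || length(p) > 3L,
                  logical(1))
    if (any(bad))
        stop("malformed residue token(s): ",
             paste(tokens[bad], collapse = ", "))
    data.frame(
        structure_id   = structure_id,
        chain_id       = chain_id,
        residue_number = as.integer(vapply(parts, `[`, "", 2L)),
        insertion_code = vapply(parts, function(p)
            if (length(p) == 3L) p[3L] else "", ""),
        amino_acid     = .normalizeAA(vapply(parts, `[`, "", 1L)),
        role           = "catalytic",
        stringsAsFactors = FALSE)
}

# Format residue refs as "CHAIN:RESNAME:RESNUM[:ICODE]" labels.
.residueLabel <- function(refs) {
    lab <- paste(refs$chain_id, refs$amino_acid, refs$residue_number,
                 sep = ":")
    has_icode <- nzchar(refs$insertion_code)
    lab[has_icode] <- paste(lab[has_icode],
                            refs$insertion_code[has_icode], sep = ":")
    lab
}

# Significant-digit text rendering used by the tabular writers; %.15g
# round-trips doubles well beyond the promised 12 significant digits.
.fmtNum <- function(x) sprintf("%.15g", x)
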