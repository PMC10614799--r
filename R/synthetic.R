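# Synthetic fixtures: embedding corpora with planted functional sites,
# null corpora for background calibration, and toy 3-D catalytic
# coordinate sets for the structural filters.  All generators are pure
# functions of (spec, seed).

#' Specification for the synthetic embedding generator
#'
#' Defines the statistical structure the annotation model assumes:
#' function classes as centroids on the unit embedding sphere with a
#' guaranteed pairwise angular separation, site residues as noisy copies
#' of their class centroid, and query proteins as uniform background
#' vectors with optional planted sites.  Noise is isotropic Gaussian of
#' expected norm `noise_sd` followed by renormalisation, so the angular
#' scatter of a class is approximately `noise_sd` radians and separation
#' relative to noise is controlled by one ratio.
#'
#' @param n_classes Number of function classes.
#' @param sites_per_class Reference entries per class.
#' @param residues_per_site Site residues per entry.
#' @param dimension Embedding dimension.
#' @param centroid_separation Minimum pairwise angular distance between
#'   class centroids, radians.  The default keeps separation at four
#'   times the noise scale, the regime in which planted sites are
#'   reliably recoverable.
#' @param noise_sd Noise scale (expected norm of the perturbation of a
#'   unit centroid).
#' @param query_length Number of residues per generated query protein.
#' @param planted `data.frame` with columns `class` and `position`
#'   (1-based query positions), or `NULL` for pure-noise queries.
#' @param plddt_low_fraction If non-`NULL`, queries carry a pLDDT column
#'   with this fraction of residues below the confidence threshold.
#' @param seed Base RNG seed.
#' @return A `sitenrich_spec` list, validated.
#' @export
syntheticSpec <- function(n_classes = 5L, sites_per_class = 1L,
                          residues_per_site = 6L, dimension = 32L,
                          centroid_separation = 0.8, noise_sd = 0.2,
                          query_length = 50L, planted = NULL,
                          plddt_low_fraction = NULL, seed = 1L) {
    spec <- list(n_classes = as.integer(n_classes),
                 sites_per_class = as.integer(sites_per_class),
                 residues_per_site = as.integer(residues_per_site),
                 dimension = as.integer(dimension),
                 centroid_separation = centroid_separation,
                 noise_sd = noise_sd,
                 query_length = as.integer(query_length),
                 planted = planted,
                 plddt_low_fraction = plddt_low_fraction,
                 seed = as.integer(seed))
    counts <- c(spec$n_classes, spec$sites_per_class,
                spec$residues_per_site, spec$dimension, spec$query_length)
    if (any(counts <= 0L)) stop("all counts must be positive")
    if (spec$noise_sd < 0) stop("noise_sd must be non-negative")
    if (!is.null(planted)) {
        if (!all(c("class", "position") %in% names(planted)))
            stop("planted must have columns class and position")
        if (any(planted$position < 1L |
                planted$position > spec$query_length))
            stop("planted positions must lie within query_length")
    }
    class(spec) <- "sitenrich_spec"
    spec
}

# Uniform random unit vectors (rows).
.runifSphere <- function(n, d) {
    m <- matrix(stats::rnorm(n * d), n, d)
    m / sqrt(rowSums(m^2))
}

# Noisy unit-sphere copy of a centroid: c + noise_sd * g, renormalised,
# with g standard Gaussian scaled to expected unit norm.
.noisyCopy <- function(centroid, noise_sd) {
    d <- length(centroid)
    v <- centroid + noise_sd * stats::rnorm(d) / sqrt(d)
    v / sqrt(sum(v^2))
}

#' Generate a synthetic reference database
#'
#' Draws class centroids on the unit sphere by rejection sampling until
#' every pair is at least `centroid_separation` radians apart, then
#' builds `sites_per_class` reference entries per class whose residue
#' embeddings are noisy copies of the class centroid.  Metadata
#' (synthetic structure ids, author residue numbers, catalytic roles) is
#' populated so the result is a fully valid [ReferenceSiteDB-class].
#'
#' @param spec A [syntheticSpec()].
#' @return List with `db` ([ReferenceSiteDB-class]) and `centroids`
#'   (n_classes x dimension matrix).
#' @export
generateReference <- function(spec) {
    stopifnot(inherits(spec, "sitenrich_spec"))
    .withSeed(spec$seed, {
        centroids <- matrix(0, spec$n_classes, spec$dimension)
        accepted <- 0L
        tries <- 0L
        while (accepted < spec$n_classes) {
            tries <- tries + 1L
            if (tries > 100000L)
                stop("cannot place ", spec$n_classes, " centroids with ",
                     "pairwise separation ", spec$centroid_separation)
            cand <- .runifSphere(1L, spec$dimension)[1L, ]
            ok <- TRUE
            if (accepted > 0L) {
                cosines <- centroids[seq_len(accepted), , drop = FALSE] %*%
                    cand
                ok <- all(acos(pmin(pmax(cosines, -1), 1)) >=
                          spec$centroid_separation)
            }
            if (ok) {
                accepted <- accepted + 1L
                centroids[accepted, ] <- cand
            }
        }
        n_cat <- max(1L, ceiling(spec$residues_per_site / 3))
        aas <- standardAminoAcids()
        entries <- list()
        for (k in seq_len(spec$n_classes)) {
            for (j in seq_len(spec$sites_per_class)) {
                n <- spec$residues_per_site
                vectors <- t(vapply(seq_len(n), function(i)
                    .noisyCopy(centroids[k, ], spec$noise_sd),
                    numeric(spec$dimension)))
                sid <- sprintf("SYN%02dS%02d", k, j)
                refs <- data.frame(
                    structure_id = sid, chain_id = "A",
                    residue_number = seq_len(n), insertion_code = "",
                    amino_acid = aas[sample.int(20L, n, replace = TRUE)],
                    role = c(rep("catalytic", n_cat),
                             rep("neighbor", n - n_cat)),
                    stringsAsFactors = FALSE)
                entries[[length(entries) + 1L]] <- new(
                    "ReferenceEntry",
                    functionId = sprintf("class_%d", k),
                    ecNumber = sprintf("1.1.1.%d", k),
                    pdbId = sid, chainId = "A",
                    catalyticResidues = refs[refs$role == "catalytic", ,
                                             drop = FALSE],
                    siteResidues = refs,
                    embeddings = embeddingTable(refs, vectors))
            }
        }
        list(db = assembleReferenceDB(entries), centroids = centroids)
    })
}

#' Generate a synthetic query protein
#'
#' Background residues are uniform random unit vectors; planted residues
#' are noisy copies of their class centroid.  Optionally a pLDDT column
#' is attached with a configurable fraction of low-confidence residues
#' (to exercise confidence filtering).
#'
#' @param spec A [syntheticSpec()].
#' @param centroids Centroid matrix from [generateReference()].
#' @param seed RNG seed for this query (default `spec$seed`).
#' @param planted Planted-site `data.frame` (`class`, `position`);
#'   defaults to `spec$planted`.
#' @param structure_id Identifier stamped on the query residues.
#' @return List with `table` (an [EmbeddingTable-class]) and `truth`
#'   (the planted `data.frame`, zero rows when nothing is planted).
#' @export
generateQuery <- function(spec, centroids, seed = spec$seed,
                          planted = spec$planted,
                          structure_id = "QUERY") {
    stopifnot(inherits(spec, "sitenrich_spec"))
    .withSeed(seed, {
        L <- spec$query_length
        vectors <- .runifSphere(L, spec$dimension)
        truth <- if (is.null(planted))
            data.frame(class = character(0), position = integer(0))
        else as.data.frame(planted, stringsAsFactors = FALSE)
        if (nrow(truth)) {
            k_of <- as.integer(sub("class_", "", truth$class))
            for (i in seq_len(nrow(truth)))
                vectors[truth$position[i], ] <-
                    .noisyCopy(centroids[k_of[i], ], spec$noise_sd)
        }
        aas <- standardAminoAcids()
        refs <- data.frame(
            structure_id = structure_id, chain_id = "A",
            residue_number = seq_len(L), insertion_code = "",
            amino_acid = aas[sample.int(20L, L, replace = TRUE)],
            role = "query", stringsAsFactors = FALSE)
        pl <- numeric(0)
        if (!is.null(spec$plddt_low_fraction)) {
            pl <- stats::runif(L, 75, 99)
            n_low <- round(spec$plddt_low_fraction * L)
            if (n_low > 0)
                pl[sample.int(L, n_low)] <- stats::runif(n_low, 30, 69.5)
        }
        list(table = embeddingTable(refs, vectors, pl), truth = truth)
    })
}

#' Generate a null corpus for background calibration
#'
#' Pure-background proteins (no planted sites, no class labels) in the
#' corpus format consumed by [buildBackground()].
#'
#' @param spec A [syntheticSpec()].
#' @param n_proteins Corpus size.
#' @param seed Base seed; protein i uses `seed + i`.
#' @return List of corpus elements (`table`, `function_ids`, `id`).
#' @export
generateNullCorpus <- function(spec, n_proteins, seed = spec$seed) {
    lapply(seq_len(n_proteins), function(i) {
        id <- sprintf("null_%04d", i)
        q <- generateQuery(spec, centroids = matrix(0, 0, spec$dimension),
                           seed = seed + i, planted = NULL,
                           structure_id = id)
        list(table = q$table, function_ids = character(0), id = id)
    })
}

#' Generate toy 3-D catalytic sites related by a rigid transform
#'
#' Builds a reference coordinate set of `k_residues` residues (each with
#' `atoms_per_residue` atoms) and a query copy obtained by a rigid
#' rotation + translation plus isotropic Gaussian coordinate noise, with
#' exact atom correspondence.  Residue amino-acid labels are assigned so
#' exact-match and mismatch code paths can both be exercised.
#'
#' @param k_residues Number of catalytic residues.
#' @param atoms_per_residue Atoms per residue (first atoms of the
#'   standard backbone/side-chain naming).
#' @param noise_sd Coordinate noise in Angstrom applied to the query.
#' @param seed RNG seed.
#' @param rotation Optional 3x3 proper rotation (random if `NULL`).
#' @param translation Optional length-3 translation (random if `NULL`).
#' @param labels Optional per-residue amino-acid labels (random if
#'   `NULL`).
#' @return List with `ref_coords`, `query_coords` (k*atoms x 3, row
#'   corresponded), `atom_names`, `residue_index` (per atom), `ref_labels`
#'   and `query_labels` (per-residue amino acids, identical by default),
#'   `rotation`, `translation`.
#' @export
generateToySites <- function(k_residues = 4L, atoms_per_residue = 4L,
                             noise_sd = 0, seed = 1L, rotation = NULL,
                             translation = NULL, labels = NULL) {
    atom_pool <- c("N", "CA", "C", "O", "CB", "CG", "CD", "CE", "NZ", "OG")
    if (atoms_per_residue > length(atom_pool))
        stop("atoms_per_residue must be <= ", length(atom_pool))
    .withSeed(seed, {
        # 7 A spacing with 0.4 A atom jitter keeps every atom well clear
        # of the 10 A environment boundary, so the mock embedding of a
        # rigidly copied site is stable under small coordinate noise
        centers <- cbind(7 * seq_len(k_residues), 0, 0)
        jitter <- matrix(stats::rnorm(k_residues * atoms_per_residue * 3,
                                      sd = 0.4),
                         ncol = 3)
        ref <- centers[rep(seq_len(k_residues), each = atoms_per_residue), ] +
            jitter
        if (is.null(rotation)) rotation <- .randomRotation()
        if (is.null(translation)) translation <- stats::runif(3, -5, 5)
        query <- ref %*% t(rotation) +
            matrix(translation, nrow(ref), 3, byrow = TRUE)
        if (noise_sd > 0)
            query <- query + matrix(stats::rnorm(length(query),
                                                 sd = noise_sd), ncol = 3)
        if (is.null(labels))
            labels <- standardAminoAcids()[sample.int(20L, k_residues,
                                                      replace = TRUE)]
        list(ref_coords = ref, query_coords = query,
             atom_names = rep(atom_pool[seq_len(atoms_per_residue)],
                              k_residues),
             residue_index = rep(seq_len(k_residues),
                                 each = atoms_per_residue),
             ref_labels = labels, query_labels = labels,
             rotation = rotation, translation = translation)
    })
}

# Uniform-ish random proper rotation via QR decomposition.
.randomRotation <- function() {
    qr_dec <- qr(matrix(stats::rnorm(9), 3, 3))
    R <- qr.Q(qr_dec)
    R <- R %*% diag(sign(diag(qr.R(qr_dec))))
    if (det(R) < 0) R[, 3] <- -R[, 3]
    R
}

# Atom table for a toy site: chain A, residues numbered from `first_resno`.
.toyAtomTable <- function(coords, atom_names, residue_index, labels,
                          first_resno = 1L, chain = "A", b = NA_real_) {
    element <- substr(atom_names, 1L, 1L)
    data.frame(
        type = "ATOM", elety = atom_names, elesy = element,
        resid = labels[residue_index], chain = chain,
        resno = as.integer(first_resno + residue_index - 1L),
        insert = "", alt = "",
        x = coords[, 1], y = coords[, 2], z = coords[, 3],
        b = b, stringsAsFactors = FALSE)
}

#' Generate a toy end-to-end structural fixture
#'
#' Composes [generateToySites()] into a complete miniature study: one toy
#' reference structure per function class, and a query structure that
#' embeds a rigid-transformed (optionally noised) copy of the first
#' class's site among isolated background residues, plus pure-background
#' null structures for calibrating empirical nulls.  Together with the
#' mock embedding backend this exercises the full build / background /
#' annotate / filter workflow on structures alone.
#'
#' @param n_classes Number of reference classes (toy structures).
#' @param residues_per_site Catalytic residues per reference site.
#' @param atoms_per_residue Atoms per residue.
#' @param n_background Background residues in the query structure.
#' @param n_null Number of null structures for background calibration.
#' @param noise_sd Coordinate noise (Angstrom) on the planted site copy.
#' @param seed RNG seed.
#' @return List with `entry_specs` (for [buildReferenceDB()]),
#'   `structures` (named list incl. the query), `query_structure_id`,
#'   `null_structures` (named list) and `planted_class`.
#' @export
generatePipelineFixture <- function(n_classes = 3L, residues_per_site = 4L,
                                    atoms_per_residue = 4L,
                                    n_background = 6L, n_null = 12L,
                                    noise_sd = 0.2, seed = 1L) {
    entry_specs <- list()
    structures <- list()
    planted_class <- "class_1"
    query_at <- NULL
    if (n_classes * residues_per_site > 20L)
        stop("toy fixture supports at most 20 site residues in total")
    # distinct labels across classes: the mock environments of these toy
    # sites are coarse, so sharing an amino acid at the same site
    # position would alias residues between classes
    all_labels <- .withSeed(seed, standardAminoAcids()[
        sample.int(20L, n_classes * residues_per_site)])
    for (k in seq_len(n_classes)) {
        site <- generateToySites(
            residues_per_site, atoms_per_residue, noise_sd = 0,
            seed = seed + 17L * k,
            labels = all_labels[(k - 1L) * residues_per_site +
                                seq_len(residues_per_site)])
        sid <- sprintf("SYNREF%02d", k)
        at <- .toyAtomTable(site$ref_coords, site$atom_names,
                            site$residue_index, site$ref_labels,
                            first_resno = 10L)
        structures[[sid]] <- at
        tokens <- paste(site$ref_labels, 10L + seq_len(residues_per_site) -
                        1L, sep = ":", collapse = ",")
        entry_specs[[k]] <- list(
            function_id = sprintf("class_%d", k),
            ec_number = sprintf("1.1.1.%d", k),
            structure = at, structure_id = sid, chain = "A",
            catalytic = tokens)
        if (k == 1L) {
            # rigid copy of this exact site (same residue labels), with
            # optional coordinate noise, planted into the query
            planted_coords <- .withSeed(seed + 9900L, {
                R <- .randomRotation()
                tr <- stats::runif(3, -5, 5)
                pc <- site$ref_coords %*% t(R) +
                    matrix(tr, nrow(site$ref_coords), 3, byrow = TRUE)
                if (noise_sd > 0)
                    pc <- pc + matrix(stats::rnorm(length(pc),
                                                   sd = noise_sd), ncol = 3)
                pc
            })
            query_at <- .toyAtomTable(planted_coords, site$atom_names,
                                      site$residue_index, site$ref_labels,
                                      first_resno = 101L)
        }
    }
    .makeBackgroundAtoms <- function(n, seed_i, first_resno) {
        bg <- list()
        aas <- standardAminoAcids()
        .withSeed(seed_i, {
            labels <- aas[sample.int(20L, n, replace = TRUE)]
            jitter <- matrix(stats::rnorm(n * atoms_per_residue * 3,
                                          sd = 0.8), ncol = 3)
            centers <- cbind(100 + 20 * seq_len(n), 100, 100)
            coords <- centers[rep(seq_len(n), each = atoms_per_residue), ] +
                jitter
            .toyAtomTable(coords,
                          rep(c("N", "CA", "C", "O", "CB", "CG", "CD",
                                "CE", "NZ", "OG")[seq_len(atoms_per_residue)],
                              n),
                          rep(seq_len(n), each = atoms_per_residue),
                          labels, first_resno = first_resno)
        })
    }
    query_at <- rbind(query_at,
                      .makeBackgroundAtoms(n_background, seed + 9901L, 201L))
    structures[["QUERY"]] <- query_at
    null_structures <- list()
    for (i in seq_len(n_null)) {
        nid <- sprintf("NULL%03d", i)
        null_structures[[nid]] <- .makeBackgroundAtoms(
            n_background + residues_per_site, seed + 7000L + i, 301L)
    }
    list(entry_specs = entry_specs, structures = structures,
         query_structure_id = "QUERY", null_structures = null_structures,
         planted_class = planted_class)
}
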