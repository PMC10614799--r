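# Reference database construction: heteroatom stripping, active-site
# expansion, assembly and serialisation.

test_that("stripHeteroatoms removes waters, ions and altlocs only", {
    at <- make_toy_protein(5, seed = 1, with_het = TRUE)
    clean <- stripHeteroatoms(at, "A")
    expect_equal(sum(clean$type == "HETATM"), 0L)
    expect_equal(length(unique(clean$resno)), 5L)
    expect_equal(nrow(clean), 20L)  # 5 residues x 4 atoms
    # coordinates untouched
    expect_identical(clean$x, at$x[at$type == "ATOM"])

    # no heteroatoms: identity
    plain <- make_toy_protein(4, seed = 2)
    expect_equal(nrow(stripHeteroatoms(plain, "A")), nrow(plain))

    # altloc B dropped, A retained
    alt <- plain
    alt$alt[1] <- "B"
    alt$alt[2] <- "A"
    expect_equal(nrow(stripHeteroatoms(alt, "A")), nrow(plain) - 1L)

    # only heteroatoms -> degenerate chain error
    het_only <- at[at$type == "HETATM", ]
    expect_error(stripHeteroatoms(het_only, "A"), "empty")
    expect_error(stripHeteroatoms(at, "Z"), "chain")
})

test_that("active-site expansion honours the inclusive 3.5 A boundary", {
    # catalytic atom at origin; neighbours at 3.4 (in) and 3.6 (out)
    at <- data.frame(
        type = "ATOM", elety = "CA", elesy = "C",
        resid = c("HIS", "GLY", "ALA"), chain = "A", resno = 1:3,
        insert = "", alt = "", x = c(0, 3.4, 3.6), y = 0, z = 0,
        b = NA_real_, stringsAsFactors = FALSE)
    cat_ref <- data.frame(structure_id = "t", chain_id = "A",
                          residue_number = 1L, insertion_code = "",
                          amino_acid = "HIS", role = "catalytic")
    out <- expandActiveSite(at, "A", cat_ref, cutoff = 3.5)
    expect_equal(out$residue_number, c(1L, 2L))
    expect_equal(out$role, c("catalytic", "neighbor"))

    # catalytic set = whole chain -> whole chain, all catalytic
    all_cat <- data.frame(structure_id = "t", chain_id = "A",
                          residue_number = 1:3, insertion_code = "",
                          amino_acid = "UNK", role = "catalytic")
    whole <- expandActiveSite(at, "A", all_cat, cutoff = 3.5)
    expect_equal(whole$residue_number, 1:3)
    expect_true(all(whole$role == "catalytic"))

    expect_error(expandActiveSite(at, "A", cat_ref, cutoff = -1),
                 "cutoff")
    missing_cat <- transform(cat_ref, residue_number = 99L)
    expect_error(expandActiveSite(at, "A", missing_cat), "not found")
})

test_that("expansion equals brute-force all-pairs distances", {
    for (seed in 1:25) {
        set.seed(seed)
        n_res <- sample(4:12, 1)
        rows <- lapply(seq_len(n_res), function(r) {
            k <- sample(2:4, 1)
            data.frame(type = "ATOM",
                       elety = c("N", "CA", "C", "O")[seq_len(k)],
                       elesy = c("N", "C", "C", "O")[seq_len(k)],
                       resid = "GLY", chain = "A", resno = r, insert = "",
                       alt = "", x = runif(k, 0, 15), y = runif(k, 0, 15),
                       z = runif(k, 0, 15), b = NA_real_,
                       stringsAsFactors = FALSE)
        })
        at <- do.call(rbind, rows)
        cat_resno <- sort(sample(seq_len(n_res), sample(1:2, 1)))
        cat_ref <- data.frame(structure_id = "t", chain_id = "A",
                              residue_number = cat_resno,
                              insertion_code = "", amino_acid = "GLY",
                              role = "catalytic")
        got <- expandActiveSite(at, "A", cat_ref, cutoff = 3.5)
        expect_equal(sort(paste(got$residue_number, got$insertion_code)),
                     expand_oracle(at, cat_resno, 3.5))
        # invariance under atom-order permutation
        perm <- at[sample(nrow(at)), ]
        got_perm <- expandActiveSite(perm, "A", cat_ref, cutoff = 3.5)
        expect_identical(got_perm, got)
    }
})

make_entry_specs <- function(fx) fx$entry_specs

test_that("buildReferenceDB assembles, counts and is deterministic", {
    fx <- generatePipelineFixture(n_classes = 3, residues_per_site = 3,
                                  seed = 4)
    backend <- mockEmbeddingBackend(dimension = 16, seed = 2)
    db1 <- buildReferenceDB(fx$entry_specs, backend)
    db2 <- buildReferenceDB(fx$entry_specs, backend)
    expect_equal(nrow(flatRefs(db1)), 9L)
    expect_length(classIndex(db1), 3L)
    expect_identical(flatVectors(db1), flatVectors(db2))
    expect_true(validObject(db1, test = TRUE))
    # every flat row belongs to exactly one entry
    expect_equal(sort(unlist(classIndex(db1), use.names = FALSE)), 1:9)

    # duplicate function id with conflicting EC is rejected
    specs <- fx$entry_specs
    specs[[2]]$function_id <- specs[[1]]$function_id  # EC differs
    expect_error(buildReferenceDB(specs, backend), "EC")
})

test_that("build report records skipped entries when not failing fast", {
    fx <- generatePipelineFixture(n_classes = 2, seed = 6)
    specs <- fx$entry_specs
    specs[[2]]$chain <- "Z"   # unbuildable
    backend <- mockEmbeddingBackend(dimension = 8, seed = 1)
    expect_error(buildReferenceDB(specs, backend), "failed")
    expect_warning(db <- buildReferenceDB(specs, backend,
                                          fail_fast = FALSE),
                   "skipping")
    rep <- attr(db, "build_report")
    expect_equal(rep$status, c("ok", "skipped"))
    expect_length(dbEntries(db), 1L)
})

test_that("database and manifest round-trips preserve everything", {
    fx <- generatePipelineFixture(n_classes = 2, seed = 8)
    backend <- mockEmbeddingBackend(dimension = 8, seed = 3)
    db <- buildReferenceDB(fx$entry_specs, backend)
    path <- withr::local_tempfile(fileext = ".rds")
    saveReferenceDB(db, path)
    back <- loadReferenceDB(path)
    expect_identical(flatVectors(back), flatVectors(db))
    expect_identical(flatRefs(back), flatRefs(db))
    expect_identical(flatClass(back), flatClass(db))

    # version mismatch rejected
    obj <- readRDS(path)
    obj$version <- 999L
    saveRDS(obj, path)
    expect_error(loadReferenceDB(path), "version")

    # manifest + PDB file round-trip through the standard formats
    dir <- withr::local_tempdir()
    for (spec in fx$entry_specs)
        writeStructurePdb(spec$structure,
                          file.path(dir, paste0(spec$structure_id, ".pdb")))
    man <- data.frame(
        function_id = vapply(fx$entry_specs, `[[`, "", "function_id"),
        ec_number = vapply(fx$entry_specs, `[[`, "", "ec_number"),
        structure_path = paste0(vapply(fx$entry_specs, `[[`, "",
                                       "structure_id"), ".pdb"),
        chain = "A",
        catalytic = vapply(fx$entry_specs, `[[`, "", "catalytic"))
    man_path <- file.path(dir, "manifest.tsv")
    write.table(man, man_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    specs2 <- readEntryManifest(man_path)
    db2 <- buildReferenceDB(specs2, backend)
    expect_equal(nrow(flatRefs(db2)), nrow(flatRefs(db)))
    expect_equal(names(classIndex(db2)), names(classIndex(db)))
    # residue identity survives the PDB round trip (author numbering)
    expect_equal(flatRefs(db2)$residue_number,
                 flatRefs(db)$residue_number)
})
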