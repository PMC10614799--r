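# Kabsch superposition, catalytic matching and the structural filters.

test_that("kabsch recovers rigid transforms exactly", {
    set.seed(2)
    X <- matrix(rnorm(30, sd = 5), 10, 3)
    same <- kabsch(X, X)
    expect_equal(same$rmsd, 0, tolerance = 1e-12)
    expect_equal(det(same$rotation), 1, tolerance = 1e-9)

    ts <- generateToySites(5, 4, noise_sd = 0, seed = 8)
    k <- kabsch(ts$ref_coords, ts$query_coords)
    expect_lt(k$rmsd, 1e-9)
    expect_equal(det(k$rotation), 1, tolerance = 1e-9)
    # the returned transform reproduces the reference coordinates
    fitted <- ts$query_coords %*% t(k$rotation) +
        matrix(k$translation, nrow(ts$ref_coords), 3, byrow = TRUE)
    expect_equal(fitted, ts$ref_coords, tolerance = 1e-6)

    expect_error(kabsch(X[1, , drop = FALSE], X[1, , drop = FALSE]),
                 "two")
})

test_that("kabsch agrees with an independent superposition oracle", {
    for (seed in 1:15) {
        ts <- generateToySites(7, 3, noise_sd = 0.5, seed = seed)
        got <- kabsch(ts$ref_coords, ts$query_coords)$rmsd
        ora <- kabsch_rmsd_oracle(ts$ref_coords, ts$query_coords)
        expect_equal(got, ora, tolerance = 1e-9)
        # symmetry
        expect_equal(kabsch(ts$query_coords, ts$ref_coords)$rmsd, got,
                     tolerance = 1e-9)
    }
})

test_that("kabsch handles degenerate collinear points", {
    X <- cbind(1:5, 0, 0)
    Y <- cbind(0, 1:5, 0)   # same line, rotated
    k <- kabsch(X, Y)
    expect_lt(k$rmsd, 1e-9)
    expect_equal(det(k$rotation), 1, tolerance = 1e-9)
})

test_that("rmsd is invariant to rigid pre-transformation and grows with noise", {
    ts0 <- generateToySites(6, 4, noise_sd = 0.3, seed = 4)
    base <- kabsch(ts0$ref_coords, ts0$query_coords)$rmsd
    # pre-rotate the reference: rmsd unchanged
    R <- sitenrich:::.randomRotation()
    pre <- ts0$ref_coords %*% t(R) + 3
    expect_equal(kabsch(pre, ts0$query_coords)$rmsd, base,
                 tolerance = 1e-9)

    # mean rmsd is monotone in the noise scale
    mean_rmsd <- vapply(c(0.1, 0.5, 2), function(s) {
        mean(vapply(1:20, function(i)
            kabsch(generateToySites(6, 4, noise_sd = s,
                                    seed = 100 + i)$ref_coords,
                   generateToySites(6, 4, noise_sd = s,
                                    seed = 100 + i)$query_coords)$rmsd,
            0))
    }, 0)
    expect_false(is.unsorted(mean_rmsd))
})

# Build one annotated pipeline fixture shared by the matching tests.
fixture_with_predictions <- function(seed = 11, noise_sd = 0.2,
                                     relabel_one = FALSE) {
    fx <- generatePipelineFixture(seed = seed, noise_sd = noise_sd)
    if (relabel_one) {
        # mutate one catalytic residue type in the query structure (the
        # threonine-for-histidine situation): exact amino-acid matching
        # must drop that pair
        qat <- fx$structures[["QUERY"]]
        target <- qat$resno == 101L
        qat$resid[target] <- ifelse(qat$resid[target][1] == "THR",
                                    "ALA", "THR")
        fx$structures[["QUERY"]] <- qat
    }
    backend <- mockEmbeddingBackend(dimension = 32, seed = 5)
    db <- buildReferenceDB(fx$entry_specs, backend)
    qat <- fx$structures[["QUERY"]]
    qres <- structureResidues(qat, structure_id = "QUERY")
    qtab <- mockEmbed(qat, "A", qres, dimension = 32, seed = 5)
    corpus <- lapply(names(fx$null_structures), function(nid) {
        at <- fx$null_structures[[nid]]
        list(table = mockEmbed(at, "A",
                               structureResidues(at, structure_id = nid),
                               dimension = 32, seed = 5),
             function_ids = character(0), id = nid)
    })
    bg <- buildBackground(db, corpus, min_size = 10)
    preds <- annotateProtein(qtab, db, bg, alpha = 0.25)
    list(fx = fx, db = db, preds = preds)
}

test_that("catalytic matching requires exact amino-acid identity", {
    f <- fixture_with_predictions()
    pred <- f$preds[f$preds$function_id == "class_1", ]
    entry <- dbEntries(f$db)[[1]]
    m <- matchCatalytic(pred, entry, f$db, attr(f$preds, "ranked"),
                        attr(f$preds, "query"), attr(f$preds, "row_map"))
    expect_equal(m@coverage, 1.0)
    expect_equal(nrow(m@pairs), 4L)
    expect_true(all(m@pairs$ref_aa == m@pairs$query_aa))
    # one-to-one on both sides
    expect_false(anyDuplicated(m@pairs$query_resno) > 0)

    # a type substitution in the query removes exactly that pair
    f2 <- fixture_with_predictions(relabel_one = TRUE)
    pred2 <- f2$preds[f2$preds$function_id == "class_1", ]
    m2 <- matchCatalytic(pred2, dbEntries(f2$db)[[1]], f2$db,
                         attr(f2$preds, "ranked"),
                         attr(f2$preds, "query"),
                         attr(f2$preds, "row_map"))
    expect_equal(m2@coverage, 3 / 4)
    expect_false(101L %in% m2@pairs$query_resno)

    # empty leading edge -> zero coverage
    pred_empty <- pred
    pred_empty$leading_edge_db <- list(integer(0))
    m3 <- matchCatalytic(pred_empty, entry, f$db, attr(f$preds, "ranked"),
                         attr(f$preds, "query"), attr(f$preds, "row_map"))
    expect_equal(m3@coverage, 0)
})

test_that("catalytic RMSD reflects the planted coordinate noise", {
    f <- fixture_with_predictions(noise_sd = 0)
    pred <- f$preds[f$preds$function_id == "class_1", ]
    entry <- dbEntries(f$db)[[1]]
    m <- matchCatalytic(pred, entry, f$db, attr(f$preds, "ranked"),
                        attr(f$preds, "query"), attr(f$preds, "row_map"))
    m <- catalyticRmsd(m, f$fx$structures[[entry@pdbId]],
                       f$fx$structures[["QUERY"]])
    expect_lt(m@rmsd, 1e-6)   # noiseless rigid copy

    f2 <- fixture_with_predictions(noise_sd = 0.5)
    pred2 <- f2$preds[f2$preds$function_id == "class_1", ]
    m2 <- matchCatalytic(pred2, dbEntries(f2$db)[[1]], f2$db,
                         attr(f2$preds, "ranked"), attr(f2$preds, "query"),
                         attr(f2$preds, "row_map"))
    m2 <- catalyticRmsd(m2, f2$fx$structures[["SYNREF01"]],
                        f2$fx$structures[["QUERY"]])
    expect_gt(m2@rmsd, 0.1)
    expect_lt(m2@rmsd, 3)
})

test_that("filters use inclusive coverage and strict RMSD boundaries", {
    mk <- function(coverage, n_pairs, rmsd) {
        pairs <- data.frame(
            ref_chain = rep("A", n_pairs), ref_resno = seq_len(n_pairs),
            ref_icode = "", ref_aa = "HIS", query_chain = "A",
            query_resno = 100L + seq_len(n_pairs), query_icode = "",
            query_aa = "HIS", similarity = 1,
            stringsAsFactors = FALSE)
        new("CatalyticMatch", pairs = pairs, coverage = coverage,
            nReference = max(4L, n_pairs),
            rmsd = if (n_pairs >= 2) rmsd else NA_real_)
    }
    pass <- applyFilters(mk(0.75, 3L, 1.2))
    expect_true(pass$pass)
    expect_length(pass$reasons, 0L)

    cov_fail <- applyFilters(mk(0.5, 3L, 1.2))
    expect_false(cov_fail$pass)
    expect_equal(cov_fail$reasons, "coverage")

    # rmsd exactly at the bound fails (strict <)
    rmsd_fail <- applyFilters(mk(1.0, 2L, 5.0))
    expect_false(rmsd_fail$pass)
    expect_equal(rmsd_fail$reasons, "rmsd")

    pair_fail <- applyFilters(mk(0.8, 1L, NA))
    expect_false(pair_fail$pass)
    expect_true(all(c("pairs", "rmsd") %in% pair_fail$reasons))
})

test_that("the filter report confirms a planted site and rejects noise", {
    f <- fixture_with_predictions(noise_sd = 0.2)
    rep <- filterPredictions(f$preds, f$db, f$fx$structures, "QUERY",
                             significant_only = FALSE)
    planted <- rep[rep$function_id == "class_1", ]
    expect_true(planted$pass)
    expect_equal(planted$coverage, 1.0)
    expect_lt(planted$rmsd, 5)
    others <- rep[rep$function_id != "class_1", ]
    expect_false(any(others$pass))

    # huge coordinate noise breaks the RMSD condition
    ts <- generateToySites(4, 4, noise_sd = 10, seed = 1)
    m <- new("CatalyticMatch",
             pairs = data.frame(ref_chain = "A", ref_resno = 1:4,
                                ref_icode = "", ref_aa = "HIS",
                                query_chain = "A", query_resno = 1:4,
                                query_icode = "", query_aa = "HIS",
                                similarity = 1),
             coverage = 1, nReference = 4L,
             rmsd = kabsch(ts$ref_coords, ts$query_coords)$rmsd)
    verdict <- applyFilters(m)
    expect_false(verdict$pass)
    expect_true("rmsd" %in% verdict$reasons)
})
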