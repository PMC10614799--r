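# The enrichment statistic, significance machinery and the annotation
# pipeline.

test_that("running sum reproduces hand-worked values", {
    rs <- runningSum(c(TRUE, FALSE, FALSE, TRUE), rep(1, 4), exponent = 0)
    expect_equal(rs$S, c(0.5, 0.0, -0.5, 0.0))
    expect_equal(rs$es, 0.5)
    expect_equal(rs$peak_index, 1L)

    # perfect enrichment / depletion with arbitrary positive weights
    w <- c(0.9, 0.7, 0.4, 0.2)
    expect_equal(runningSum(c(TRUE, TRUE, FALSE, FALSE), w)$es, 1.0)
    expect_equal(runningSum(c(FALSE, FALSE, TRUE, TRUE), w)$es, -1.0)

    # telescoping: the normalised sum returns to zero
    set.seed(1)
    mem <- c(rep(TRUE, 5), rep(FALSE, 10))[sample(15)]
    rs2 <- runningSum(mem, runif(15))
    expect_lt(abs(rs2$S[15]), 1e-9)

    expect_error(runningSum(rep(TRUE, 4), rep(1, 4)), "degenerate")
    expect_error(runningSum(rep(FALSE, 4), rep(1, 4)), "degenerate")
    expect_error(runningSum(c(TRUE, FALSE), c(0, 1)), "zero")
})

test_that("running sum agrees with the brute-force oracle", {
    set.seed(42)
    for (i in 1:200) {
        N <- sample(3:200, 1)
        n_hit <- sample(seq_len(N - 1), 1)
        mem <- rep(FALSE, N)
        mem[sample(N, n_hit)] <- TRUE
        w <- sort(runif(N, -1, 1), decreasing = TRUE)
        p <- sample(c(0, 1, 2), 1)
        if (sum(abs(w[mem])^p) == 0) next
        got <- runningSum(mem, w, p)
        ora <- running_sum_oracle(mem, w, p)
        expect_equal(got$S, ora$S, tolerance = 1e-12)
        expect_equal(abs(got$es), max(abs(ora$S)), tolerance = 1e-12)
        top2 <- sort(abs(ora$S), decreasing = TRUE)[1:2]
        if (length(ora$S) < 2 || top2[1] - top2[2] > 1e-9) {
            expect_equal(got$es, ora$es, tolerance = 1e-12)
            expect_equal(got$peak_index, ora$peak_index)
        }
        expect_true(got$es >= -1 - 1e-12 && got$es <= 1 + 1e-12)
    }
})

test_that("running sum agrees with an independent GSEA implementation", {
    set.seed(7)
    for (i in 1:25) {
        N <- sample(10:100, 1)
        stats <- sort(runif(N, 0.01, 1), decreasing = TRUE)
        sel <- sort(sample(N, sample(2:(N - 2), 1)))
        mem <- seq_len(N) %in% sel
        es <- runningSum(mem, stats, exponent = 1)$es
        ref <- fgsea::calcGseaStat(stats, sel, gseaParam = 1)
        expect_equal(es, ref, tolerance = 1e-9)
    }
})

test_that("leading edge follows the positive-peak convention", {
    mem <- c(TRUE, FALSE, FALSE, TRUE)
    rs <- runningSum(mem, rep(1, 4), exponent = 0)
    expect_equal(leadingEdge(rs$S, mem, rs$peak_index, rs$es), 1L)

    # perfect enrichment: all in-class members
    mem2 <- c(TRUE, TRUE, FALSE, FALSE)
    rs2 <- runningSum(mem2, rep(1, 4))
    expect_equal(leadingEdge(rs2$S, mem2, rs2$peak_index, rs2$es), c(1L, 2L))

    # depletion gives no annotation
    mem3 <- c(FALSE, FALSE, TRUE, TRUE)
    rs3 <- runningSum(mem3, rep(1, 4))
    expect_equal(leadingEdge(rs3$S, mem3, rs3$peak_index, rs3$es),
                 integer(0))

    # alternative convention: members whose own score reaches the score
    # at the peak
    mem4 <- c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)
    w4 <- c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1)
    rs4 <- runningSum(mem4, w4)
    expect_equal(rs4$peak_index, 3L)
    expect_equal(leadingEdge(rs4$S, mem4, rs4$peak_index, rs4$es,
                             mode = "score", weights = w4), c(1L, 3L))
    expect_error(leadingEdge(rs4$S, mem4, rs4$peak_index, rs4$es,
                             mode = "score"), "weights")
})

test_that("empirical p-values count the upper tail", {
    expect_equal(empiricalPvalue(0.9, c(0.1, 0.2, 0.3, 0.95),
                                 pseudocount = FALSE), 0.25)
    expect_equal(empiricalPvalue(2, runif(99), pseudocount = TRUE), 0.01)
    D <- c(0.5, 0.6, 0.7)
    expect_equal(empiricalPvalue(0.4, D, pseudocount = FALSE), 1.0)
    expect_equal(empiricalPvalue(min(D), D, pseudocount = FALSE), 1.0)
    expect_error(empiricalPvalue(1, numeric(0)), "no background")
})

test_that("BH adjustment matches the step-up oracle exactly", {
    expect_equal(bhFdr(c(0.005, 0.049, 0.05)), c(0.015, 0.05, 0.05))
    expect_equal(bhFdr(0.42), 0.42)
    expect_equal(bhFdr(rep(0.2, 5)), rep(0.2, 5))
    set.seed(3)
    for (i in 1:50) {
        m <- sample(1:10, 1)
        p <- round(runif(m), 3)
        q <- bhFdr(p)
        expect_equal(q, bh_oracle(p), tolerance = 1e-14)
        # monotone: p_i <= p_j implies q_i <= q_j
        o <- order(p)
        expect_false(is.unsorted(q[o]))
    }
    expect_error(bhFdr(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("backgrounds collect nulls per class and respect labels", {
    spec <- toy_spec(n_classes = 3, query_length = 20)
    ref <- generateReference(spec)
    corpus <- generateNullCorpus(spec, 10, seed = 100)
    bg <- buildBackground(ref$db, corpus, min_size = 5)
    expect_setequal(backgroundClasses(bg), names(classIndex(ref$db)))
    expect_true(all(lengths(bg@dist) == 10))

    # a protein annotated with class_1 is excluded from class_1's nulls
    corpus[[1]]$function_ids <- "class_1"
    bg2 <- buildBackground(ref$db, corpus, min_size = 5)
    expect_length(backgroundFor(bg2, "class_1"), 9L)
    expect_length(backgroundFor(bg2, "class_2"), 10L)

    # null scores equal annotate-mode enrichment scores, protein by protein
    pseudo_bg <- BackgroundDistributions(
        dist = setNames(lapply(1:3, function(i) rep(0, 5)),
                        names(classIndex(ref$db))),
        provenance = character(0), minSize = 5L, statistic = "ks")
    es_by_class <- lapply(corpus, function(prot)
        annotateProtein(prot$table, ref$db, pseudo_bg, exclude_self = TRUE))
    for (cl in backgroundClasses(bg2)) {
        expected <- vapply(seq_along(corpus), function(k) {
            res <- es_by_class[[k]]
            res$es[res$function_id == cl]
        }, 0)
        keep <- !vapply(corpus, function(p) cl %in% p$function_ids,
                        logical(1))
        expect_equal(backgroundFor(bg2, cl), expected[keep])
    }

    # classes with too few nulls are excluded with a warning
    expect_warning(bg3 <- buildBackground(ref$db, corpus[1:3],
                                          min_size = 50),
                   "excluded")
    expect_length(backgroundClasses(bg3), 0L)
})

test_that("planted functional sites are recovered and mapped back", {
    spec <- toy_spec()
    ref <- generateReference(spec)
    corpus <- generateNullCorpus(spec, 80, seed = 500)
    bg <- buildBackground(ref$db, corpus, min_size = 50)
    planted <- data.frame(class = "class_3", position = c(7, 8, 9, 10))
    q <- generateQuery(spec, ref$centroids, seed = 901, planted = planted)
    res <- annotateProtein(q$table, ref$db, bg, alpha = 0.05)
    expect_equal(res$function_id[1], "class_3")
    expect_lte(res$p_value[1], 0.05)
    mapped <- residueRefs(q$table)$residue_number[
        res$leading_edge_query[[1]]]
    # every mapped residue is a planted one (precision 1) and the planted
    # site is recovered nearly completely (the db -> query best-match map
    # is many-to-one, so full coverage is not guaranteed)
    expect_true(all(mapped %in% planted$position))
    expect_gte(length(intersect(planted$position, mapped)), 3L)
    # results sorted by q then es
    expect_false(is.unsorted(res$q_value))
})

test_that("a query identical to a reference site attains es = 1", {
    spec <- toy_spec(n_classes = 4)
    ref <- generateReference(spec)
    entry <- dbEntries(ref$db)[[2]]
    q <- entry@embeddings     # the site itself as the query
    corpus <- generateNullCorpus(spec, 60, seed = 321)
    bg <- buildBackground(ref$db, corpus, min_size = 50)
    res <- annotateProtein(q, ref$db, bg, exclude_self = FALSE)
    expect_equal(res$es[res$function_id == entry@functionId], 1.0)

    # with self-exclusion its own rows are removed instead
    res2 <- annotateProtein(q, ref$db, bg, exclude_self = TRUE)
    le <- res2$leading_edge_db[[which(res2$function_id ==
                                      entry@functionId)]]
    own <- which(flatRefs(ref$db)$structure_id == entry@pdbId)
    expect_length(intersect(le, own), 0L)
})

test_that("pure-noise queries yield no significant calls at alpha 0.001", {
    spec <- toy_spec()
    ref <- generateReference(spec)
    corpus <- generateNullCorpus(spec, 100, seed = 4000)
    bg <- buildBackground(ref$db, corpus, min_size = 50)
    hits <- 0
    for (i in 1:20) {
        q <- generateQuery(spec, ref$centroids, seed = 60000 + i,
                           planted = NULL)
        res <- annotateProtein(q$table, ref$db, bg)
        hits <- hits + any(res$significant)
    }
    expect_lte(hits, 1)
})

test_that("prediction tables are written deterministically", {
    spec <- toy_spec(n_classes = 2)
    ref <- generateReference(spec)
    corpus <- generateNullCorpus(spec, 60, seed = 11)
    bg <- buildBackground(ref$db, corpus, min_size = 50)
    q <- generateQuery(spec, ref$centroids, seed = 2,
                       planted = data.frame(class = "class_1",
                                            position = 1:3))
    res <- annotateProtein(q$table, ref$db, bg)
    t1 <- withr::local_tempfile(fileext = ".tsv")
    t2 <- withr::local_tempfile(fileext = ".tsv")
    writePredictions(res, t1, "tsv")
    writePredictions(res, t2, "tsv")
    expect_identical(readLines(t1), readLines(t2))
    j <- withr::local_tempfile(fileext = ".json")
    writePredictions(res, j, "json")
    parsed <- jsonlite::read_json(j, simplifyVector = TRUE)
    expect_equal(parsed$function_id[1], res$function_id[1])
})
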