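test_that("representative annotation applies the 75%/75% rule inclusively", {
    ann <- annotationMap(
        members = data.frame(
            protein = c("p1", "p2", "p3", "p4"),
            species = c("tax1", "tax1", "tax2", "tax2"),
            family = "OG1"),
        terms = data.frame(protein = c("p1", "p2", "p3",   # T1 on 3 of 4
                                       "p1", "p2"),        # T2 on 2 of 4
                           term = c("T1", "T1", "T1", "T2", "T2")))
    fa <- assignFamilyAnnotations(ann)
    expect_equal(fa$OG1, "T1")      # 0.75 proteins, 1.0 taxa: kept at boundary
    # T2 fails the protein fraction (0.5) and is dropped
    expect_false("T2" %in% fa$OG1)
    # taxon fraction can fail even when the protein fraction passes
    ann2 <- annotationMap(
        members = data.frame(protein = sprintf("q%d", 1:4),
                             species = c("t1", "t1", "t1", "t2"),
                             family = "OG2"),
        terms = data.frame(protein = c("q1", "q2", "q3"), term = "T3"))
    expect_null(assignFamilyAnnotations(ann2)$OG2)   # 3/4 proteins, 1/2 taxa
    expect_equal(assignFamilyAnnotations(ann2, taxonFrac = 0.5)$OG2, "T3")
})

test_that("singleton inference annotates unclustered proteins", {
    ann <- annotationMap(
        members = data.frame(protein = c("p1", "lonely"),
                             species = c("t1", "t2"),
                             family = c("OG1", NA)),
        terms = data.frame(protein = c("lonely"), term = "T9"))
    expect_null(assignFamilyAnnotations(ann)$lonely)
    fa <- assignFamilyAnnotations(ann, inferSingletons = TRUE)
    expect_equal(fa$lonely, "T9")
})

test_that("fisherExact handles symmetric, ordinary and zero-cell tables", {
    fe <- fisherExact(c(5, 5, 5, 5))
    expect_equal(fe$oddsRatio, 1)
    expect_equal(fe$p, 1)
    fe2 <- fisherExact(c(10, 20, 30, 40))
    expect_equal(fe2$oddsRatio, (10 * 40) / (20 * 30))
    expect_equal(fe2$p, bruteFisherP(10, 20, 30, 40), tolerance = 1e-12)
    expect_equal(fe2$p, stats::fisher.test(matrix(c(10, 30, 20, 40),
                                                  2))$p.value,
                 tolerance = 1e-9)
    fe3 <- fisherExact(c(0, 10, 10, 0))
    expect_true(fe3$continuity)
    expect_equal(fe3$oddsRatio, (0.5 * 0.5) / (10.5 * 10.5))
    expect_equal(fe3$p, bruteFisherP(0, 10, 10, 0), tolerance = 1e-12)
    fe4 <- fisherExact(c(0, 0, 3, 4))     # degenerate margin
    expect_equal(fe4$p, 1)
    expect_true(fe4$degenerate && is.na(fe4$oddsRatio))
    expect_error(fisherExact(c(0, 0, 0, 0)), "empty")
})

test_that("fisherExact matches enumeration and fisher.test on random tables", {
    set.seed(7)
    for (i in 1:150) {
        n <- sample(4:60, 1)
        cuts <- sort(sample(0:n, 3, replace = TRUE))
        tab <- c(cuts[1], cuts[2] - cuts[1], cuts[3] - cuts[2],
                 n - cuts[3])
        fe <- fisherExact(tab)
        expect_equal(fe$p, bruteFisherP(tab[1], tab[2], tab[3], tab[4]),
                     tolerance = 1e-10)
        expect_equal(fe$p, stats::fisher.test(
            matrix(tab, 2, byrow = TRUE))$p.value, tolerance = 1e-7)
    }
})

test_that("bhAdjust implements the step-up formula", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bhAdjust(0.2), 0.2)
    expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
    expect_error(bhAdjust(c(0.1, 1.2)), "\\[0, 1\\]")
    # order invariance and per-coordinate monotonicity
    p <- c(0.003, 0.4, 0.04, 0.9, 0.11)
    o <- sample(5)
    expect_equal(bhAdjust(p)[o], bhAdjust(p[o]))
    p2 <- p; p2[3] <- 0.02
    expect_true(all(bhAdjust(p2) <= bhAdjust(p) + 1e-12))
})

test_that("termEnrichment flags a planted term and respects the universe", {
    background <- sprintf("F%04d", 1:1000)
    famAnn <- setNames(lapply(seq_along(background), function(i)
        c("TALL", if (i <= 50) "TX", if (i > 300 && i <= 330) "TY")),
        background)
    target <- background[1:50]       # exactly the TX families
    res <- termEnrichment(target, background, famAnn)
    tx <- res[res$term == "TX", ]
    expect_true(tx$flagged && tx$q <= 0.05)
    expect_equal(c(tx$a, tx$b, tx$c, tx$d), c(50, 0, 0, 950))
    # a term carried by every family is degenerate and never flagged
    tall <- res[res$term == "TALL", ]
    expect_false(tall$flagged)
    expect_equal(tall$p, 1)
    # enlarging the universe with term-free families changes only b and d
    res2 <- termEnrichment(target, c(background, sprintf("X%d", 1:200)),
                           famAnn)
    tx2 <- res2[res2$term == "TX", ]
    expect_equal(c(tx2$a, tx2$c), c(tx$a, tx$c))
    expect_equal(tx2$d, tx$d + 200)
    expect_error(termEnrichment(character(0), background, famAnn), "empty")
    expect_error(termEnrichment("nope", background, famAnn), "subset")
})

test_that("termEnrichment is calibrated under a random target", {
    set.seed(11)
    background <- sprintf("F%04d", 1:400)
    famAnn <- lapply(background, function(f)
        sprintf("T%02d", which(runif(12) < 0.2)))
    names(famAnn) <- background
    flaggedFrac <- replicate(40, {
        target <- sample(background, 60)
        res <- termEnrichment(target, background, famAnn)
        mean(res$flagged)
    })
    expect_lte(mean(flaggedFrac), 0.05)
})
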