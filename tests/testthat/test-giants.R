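# build a BranchShiftTable directly from a flag/p matrix for fast tests
mkShifts <- function(p, alpha = 0.05) {
    methods::new("BranchShiftTable", p = p, flag = p < alpha,
                 transitionProb = p, alpha = alpha)
}

test_that("shifted sets match direct enumeration on a hand-built table", {
    p <- matrix(1, 3, 4, dimnames = list(c("f1", "f2", "f3"), 1:4))
    p["f1", c("1", "3")] <- 0.01     # shifts on branches 1 (giant) and 3
    p["f2", "1"] <- 0.02             # shift only on the giant branch
    sh <- mkShifts(p)
    tr <- tree5()
    giant <- branchSet(tr, 1L, "giant")
    ss <- shiftedSets(sh, giant)
    expect_setequal(ss$allShifted, c("f1", "f2"))
    expect_setequal(ss$perSet$giant, c("f1", "f2"))
    expect_equal(ss$exclusive$giant, "f2")
    expect_equal(ss$meanShiftBranches, 1.5)
    expect_true(all(ss$exclusive$giant %in% ss$perSet$giant))
    expect_true(all(ss$perSet$giant %in% ss$allShifted))
    # no flags anywhere -> all sets empty
    ss0 <- shiftedSets(mkShifts(matrix(1, 2, 4,
        dimnames = list(c("a", "b"), 1:4))), giant)
    expect_length(ss0$allShifted, 0)
    expect_length(ss0$perSet$giant, 0)
    expect_error(shiftedSets(sh, branchSet(tr, 8L, "bad")), "unknown")
})

test_that("branch-set enrichment builds the right 2x2 on both universes", {
    set.seed(1)
    fam <- sprintf("f%03d", 1:300)
    p <- matrix(1, 300, 6, dimnames = list(fam, 1:6))
    p[1:60, 1] <- 0.01               # giant-branch shifts
    p[41:120, 4] <- 0.01             # background shifts, overlapping
    sh <- mkShifts(p)
    cancer <- fam[c(1:30, 200:220)]
    resAll <- branchSetEnrichment(sh, 1L, cancer, "all_families")
    expect_equal(sum(resAll$table), 300)
    expect_equal(resAll$table["in", "has"], 30)
    resShift <- branchSetEnrichment(sh, 1L, cancer, "all_shifted")
    expect_equal(sum(resShift$table), 120)   # universe = shifted families
    expect_gt(resShift$oddsRatio, 1)
    # focal = all branches makes the margin degenerate on all_shifted
    deg <- branchSetEnrichment(sh, c(1L, 4L), cancer, "all_shifted")
    expect_true(deg$degenerate)
    expect_equal(deg$p, 1)
    expect_error(sisterControl(sh, integer(0), cancer), "empty sister")
})

test_that("enrichment test is calibrated and powered on synthetic labels", {
    set.seed(42)
    fam <- sprintf("f%04d", 1:1000)
    rejNull <- replicate(60, {
        p <- matrix(1, 1000, 8, dimnames = list(fam, 1:8))
        p[runif(1000) < 0.25, 1] <- 0.01
        p[runif(1000) < 0.25, 5] <- 0.01
        cancer <- fam[runif(1000) < 0.15]    # independent of shifts
        branchSetEnrichment(mkShifts(p), 1L, cancer, "all_shifted")$p
    })
    expect_lte(mean(rejNull <= 0.05), 0.13)  # ~ alpha, 60 replicates
    rejAlt <- replicate(30, {
        sh <- runif(1000) < 0.25
        p <- matrix(1, 1000, 8, dimnames = list(fam, 1:8))
        p[sh, 1] <- 0.01
        p[runif(1000) < 0.25, 5] <- 0.01
        cancer <- fam[runif(1000) < ifelse(sh, 0.35, 0.10)]
        branchSetEnrichment(mkShifts(p), 1L, cancer, "all_shifted")$p
    })
    expect_gte(mean(rejAlt <= 0.05), 0.8)
})

test_that("permutation null is deterministic and rank-based", {
    set.seed(5)
    fam <- sprintf("f%04d", 1:800)
    p <- matrix(1, 800, 30, dimnames = list(fam, 1:30))
    sh <- runif(800) < 0.3
    p[sh, 1] <- 0.01; p[sh, 2] <- 0.01
    p[runif(800) < 0.3, 10] <- 0.01
    p[runif(800) < 0.3, 20] <- 0.01
    cancer <- fam[runif(800) < ifelse(sh, 0.4, 0.1)]
    shifts <- mkShifts(p)
    pn1 <- permutationNull(shifts, c(1L, 2L), cancer, k = 2,
                           nPerm = 100, seed = 9)
    pn2 <- permutationNull(shifts, c(1L, 2L), cancer, k = 2,
                           nPerm = 100, seed = 9)
    expect_identical(pn1$nullOR, pn2$nullOR)
    expect_equal(pn1$p, mean(pn1$nullOR >= pn1$observedOR))
    # rank-based p is invariant to a monotone transform of the statistic
    expect_equal(pn1$p, mean(log(pn1$nullOR) >= log(pn1$observedOR)))
    # the planted effect is beaten only by draws overlapping the focal
    # pair, which enter the null by design (~13% of draws)
    expect_lte(pn1$p, 0.3)
    expect_error(permutationNull(shifts, 1L, cancer, nPerm = 0),
                 "nPerm")
    expect_error(permutationNull(shifts, 1L, cancer, k = 99), "k")
})

test_that("interaction model recovers coefficients and reduces to OLS", {
    sim <- simulateRateTable(nFamilies = 200, nBranches = 12, nGiant = 3,
                             coefs = c(0.02, 0.02, 0, 0.01),
                             sdFamily = 0.05, sdResid = 0.02,
                             fractionCancer = 0.3, seed = 4)
    im <- interactionModel(sim$rates, sim$giant, sim$cancer)
    est <- setNames(im$coefficients$estimate, im$coefficients$term)
    expect_equal(unname(est["giant"]), 0.02, tolerance = 0.25)
    expect_equal(unname(est["giant:cancer"]), 0.01, tolerance = 0.5)
    expect_lt(im$coefficients$p[im$coefficients$term == "giant"], 1e-4)
    # zero random-intercept variance: coefficients equal OLS exactly
    sim0 <- simulateRateTable(nFamilies = 80, nBranches = 8, nGiant = 2,
                              sdFamily = 0, sdResid = 0.03, seed = 6)
    im0 <- interactionModel(sim0$rates, sim0$giant, sim0$cancer)
    df <- data.frame(y = sim0$rates$rate,
                     giant = as.numeric(sim0$rates$branch %in% sim0$giant),
                     cancer = as.numeric(sim0$rates$family %in% sim0$cancer))
    ols <- coef(lm(y ~ giant * cancer, df))
    expect_equal(unname(im0$coefficients$estimate), unname(ols),
                 tolerance = 1e-6)
    expect_lt(im0$varFamily, 1e-8)
    # rank-deficient designs are refused with the collinear term named
    sim2 <- simulateRateTable(seed = 7, fractionCancer = 0)
    expect_error(interactionModel(sim2$rates, sim2$giant, character(0)),
                 "cancer")
})

test_that("rate ratios match hand arithmetic and degenerate cleanly", {
    rates <- data.frame(
        family = rep(c("f1", "f2"), each = 4),
        branch = rep(1:4, 2),
        rate = c(0.4, 0.2, 0.1, 0.1,    # f1 (cancer)
                 0.2, 0.2, 0.1, 0.3))   # f2
    rr <- rateRatio(rates, giant = 1:2, cancer = "f1")
    expect_equal(rr["cancer", "ratio"], mean(c(0.4, 0.2)) / mean(c(0.1, 0.1)))
    expect_equal(rr["noncancer", "ratio"], mean(c(0.2, 0.2)) / mean(c(0.1, 0.3)))
    flat <- rates; flat$rate <- 0.2
    expect_equal(rateRatio(flat, 1:2, "f1")$ratio, c(1, 1))
    zero <- rates; zero$rate[zero$family == "f1" & zero$branch > 2] <- 0
    expect_equal(rateRatio(zero, 1:2, "f1")["cancer", "ratio"], Inf)
    expect_error(rateRatio(rates, integer(0), "f1"), "giant")
})

test_that("generator interaction effect propagates to the rate ratios", {
    sim <- simulateRateTable(nFamilies = 300, nBranches = 10, nGiant = 3,
                             coefs = c(0.02, 0.02, 0, 0.015),
                             sdFamily = 0.02, sdResid = 0.01, seed = 9)
    rr <- rateRatio(sim$rates, sim$giant, sim$cancer)
    expect_gt(rr["cancer", "ratio"], rr["noncancer", "ratio"])
})
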