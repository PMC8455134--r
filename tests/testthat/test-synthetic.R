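test_that("presence simulation honours the no-loss and full-loss limits", {
    tr <- simulateTimeTree(8, seed = 2)
    cfg0 <- simConfig(seed = 5, nFamilies = 200, originRate = 0.05,
                      lossProbability = 0)
    sim0 <- simulatePresence(tr, cfg0)
    # without loss, a family is present in exactly the tips below its origin
    for (i in seq_len(50)) {
        below <- tipLabels(tr)[match(
            intersect(tr@tipsBelow[[sim0$truth$origin[i]]], tipIds(tr)),
            tipIds(tr))]
        expect_setequal(colnames(sim0$presence)[sim0$presence[i, ]], below)
    }
    # with certain loss, only tip-origin families can be observed
    cfg1 <- simConfig(seed = 5, nFamilies = 50, originRate = 0.05,
                      lossProbability = 1)
    sim1 <- simulatePresence(tr, cfg1)
    expect_true(all(tr@isTip[sim1$truth$origin]))
    expect_true(all(rowSums(sim1$presence) == 1))
    expect_error(simulatePresence(tr, simConfig(seed = 1, originRate = 0)),
                 "originRate")
})

test_that("presence matrices are consistent with their loss truth", {
    tr <- simulateTimeTree(10, seed = 3)
    cfg <- simConfig(seed = 9, nFamilies = 300, originRate = 0.05,
                     lossProbability = 0.25)
    sim <- simulatePresence(tr, cfg)
    tips <- tipIds(tr)
    for (i in seq_len(nrow(sim$presence))) {
        o <- sim$truth$origin[[i]]
        lost <- sim$truth$losses[[i]]
        expected <- vapply(tips, function(tp) {
            path <- ancestorPath(tr, tp)
            o %in% path && !any(lost %in% path)
        }, TRUE)
        expect_equal(unname(sim$presence[i, ]), expected)
    }
})

test_that("generators are deterministic under a fixed seed", {
    tr <- simulateTimeTree(8, seed = 2)
    cfg <- simConfig(seed = 77, nFamilies = 100, lossProbability = 0.2)
    expect_identical(simulatePresence(tr, cfg), simulatePresence(tr, cfg))
    expect_identical(simulateCounts(tr, cfg), simulateCounts(tr, cfg))
    l1 <- simulateLabels(simulateCounts(tr, cfg)$counts, NULL, cfg)
    l2 <- simulateLabels(simulateCounts(tr, cfg)$counts, NULL, cfg)
    expect_identical(setFamilies(l1$cancer), setFamilies(l2$cancer))
    expect_identical(simulateTimeTree(9, seed = 4)@brlen,
                     simulateTimeTree(9, seed = 4)@brlen)
})

test_that("count simulation matches the kernel's analytic moments", {
    tr <- readNewick("(A:50,B:50);")
    # frozen evolution: lambda = 0 keeps every tip at the root size
    cfg0 <- simConfig(seed = 4, nFamilies = 200, lambdaBackground = 0,
                      conditionMinSpecies = 0)
    m0 <- famCounts(simulateCounts(tr, cfg0)$counts)
    expect_true(all(m0[, 1] == m0[, 2]))
    # martingale: with s_root = 2 the mean tip size stays 2
    cfg <- simConfig(seed = 6, nFamilies = 5000, lambdaBackground = 0.004,
                     rootPrior = list(type = "point", size = 2),
                     conditionMinSpecies = 0, sMax = 60)
    sim <- simulateCounts(tr, cfg)
    m <- famCounts(sim$counts)
    se <- sd(m) / sqrt(length(m))
    expect_lt(abs(mean(m) - 2), 4 * se)
    # count/presence consistency: size zero iff absent
    expect_identical(m > 0, presenceMatrix(sim$counts))
})

test_that("a giant-branch multiplier inflates variance on giant tips", {
    tr <- readNewick("(A:60,B:60);")
    giant <- nodeId(tr, "A")
    cfg <- simConfig(seed = 13, nFamilies = 4000, lambdaBackground = 0.004,
                     giantMultiplier = 2, fractionShifted = 1,
                     giantBranches = giant,
                     rootPrior = list(type = "point", size = 3),
                     conditionMinSpecies = 0, sMax = 80)
    m <- famCounts(simulateCounts(tr, cfg)$counts)
    # var(c - s) grows linearly in lambda for the equal-rates kernel
    vG <- var(m[, "A"] - 3)
    vB <- var(m[, "B"] - 3)
    expect_gt(vG, 1.5 * vB)
})

test_that("cancer labels tilt toward shifted families at the set rate", {
    tr <- simulateTimeTree(8, seed = 2)
    giant <- tipIds(tr)[1:2]
    cfg <- simConfig(seed = 15, nFamilies = 4000, lambdaBackground = 0.001,
                     giantBranches = giant, fractionShifted = 0.3,
                     fractionCancer = 0.2, effectOdds = 6, sMax = 40)
    sim <- simulateCounts(tr, cfg)
    lab <- simulateLabels(sim$counts, sim$truth, cfg)
    can <- familyIds(sim$counts) %in% setFamilies(lab$cancer)
    sh <- sim$truth$shifted
    expect_gt(mean(can[sh]), 2 * mean(can[!sh]))
    expect_lt(abs(mean(can) - 0.2), 0.03)
    # effect 1 leaves the label independent of the shift truth
    cfg1 <- simConfig(seed = 16, nFamilies = 4000,
                      lambdaBackground = 0.001, giantBranches = giant,
                      fractionShifted = 0.3, fractionCancer = 0.2,
                      effectOdds = 1, sMax = 40)
    sim1 <- simulateCounts(tr, cfg1)
    lab1 <- simulateLabels(sim1$counts, sim1$truth, cfg1)
    can1 <- familyIds(sim1$counts) %in% setFamilies(lab1$cancer)
    chi <- suppressWarnings(chisq.test(table(can1, sim1$truth$shifted)))
    expect_gt(chi$p.value, 0.01)
    expect_error(simulateLabels(sim$counts, sim$truth,
                                simConfig(seed = 1, fractionCancer = 0)),
                 "empty cancer set")
})

test_that("annotation maps from the generator are structurally valid", {
    tr <- simulateTimeTree(6, seed = 2)
    cfg <- simConfig(seed = 21, nFamilies = 80, lambdaBackground = 0.001,
                     nTerms = 10, termFreq = 0.2)
    sim <- simulateCounts(tr, cfg)
    lab <- simulateLabels(sim$counts, sim$truth, cfg)
    ann <- lab$annotations
    # one protein per simulated gene copy
    expect_equal(nrow(ann@members), sum(famCounts(sim$counts)))
    expect_true(all(ann@terms$protein %in% ann@members$protein))
    expect_true(all(setFamilies(lab$cancer) %in% familyIds(sim$counts)))
})
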