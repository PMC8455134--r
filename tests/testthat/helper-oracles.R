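# Shared fixtures and independent oracles used across the suite.

# five-tip reference tree: ((A,B),((C,D),E))
tree5 <- function() readNewick("((A:1,B:1):1,((C:1,D:1):1,E:2):1);")

# exhaustive minimum-loss count for a single-gain / any-loss history:
# try every origin whose subtree holds all possessing tips and count the
# maximal absent subtrees under it
bruteDollo <- function(tree, presentTips) {
    stopifnot(length(presentTips) >= 1)
    presentIds <- nodeId(tree, presentTips)
    best <- NULL
    for (o in seq_len(nNodes(tree))) {
        below <- tree@tipsBelow[[o]]
        if (!all(presentIds %in% below)) next
        hasTip <- logical(nNodes(tree))
        for (v in subtreeNodes(tree, o))
            hasTip[v] <- if (tree@isTip[v]) v %in% presentIds
                         else any(hasTip[tree@children[[v]]])
        losses <- sum(vapply(setdiff(subtreeNodes(tree, o), o),
                             function(v) !hasTip[v] &&
                                 hasTip[tree@parent[v]], TRUE))
        if (is.null(best) || losses < best$losses)
            best <- list(origin = o, losses = losses)
    }
    best
}

# exact two-sided Fisher p by explicit enumeration over tables with the
# observed margins, point probabilities from log-factorials
bruteFisherP <- function(a, b, c, d) {
    m <- a + b; n <- c + d; k <- a + c
    lo <- max(0, k - n); hi <- min(k, m)
    logp <- vapply(lo:hi, function(x)
        lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k), 0)
    p <- exp(logp)
    pObs <- exp(lchoose(m, a) + lchoose(n, k - a) - lchoose(m + n, k))
    min(1, sum(p[p <= pObs * (1 + 1e-7)]))
}

# brute-force family likelihood: enumerate all internal-node size
# combinations 0..sMax, multiply kernel transition probabilities, weight
# by the root prior, and divide by P(>= minSpecies tips non-zero)
bruteLoglik <- function(countsRow, tree, model) {
    sMax <- model@sMax
    internals <- which(!tree@isTip)
    tips <- tipIds(tree)
    prior <- GeneFamEvo:::.rootPriorVec(model)
    mats <- GeneFamEvo:::.branchMatrices(tree, model)
    prOfData <- function(tipSizes) {
        states <- integer(nNodes(tree))
        states[tips] <- tipSizes
        total <- 0
        grid <- do.call(expand.grid, rep(list(0:sMax), length(internals)))
        for (r in seq_len(nrow(grid))) {
            states[internals] <- as.integer(grid[r, ])
            pr <- prior[states[rootNode(tree)] + 1]
            for (v in branchIds(tree))
                pr <- pr * mats[[v]][states[tree@parent[v]] + 1,
                                     states[v] + 1]
            total <- total + pr
        }
        total
    }
    num <- prOfData(countsRow[match(tipLabels(tree), names(countsRow))])
    # ascertainment: P(>= minSpecies tips non-zero), enumerating internal
    # states and treating each tip's extinction marginally (supports
    # minSpecies <= 2, as in the package default)
    minSp <- model@conditionMinSpecies
    pAsc <- 1
    if (minSp > 0) {
        patProb <- function(zeroTip) {
            # zeroTip: per-tip TRUE = forced extinct, FALSE = forced alive
            states <- integer(nNodes(tree))
            total <- 0
            grid <- do.call(expand.grid,
                            rep(list(0:sMax), length(internals)))
            for (r in seq_len(nrow(grid))) {
                states[internals] <- as.integer(grid[r, ])
                pr <- prior[states[rootNode(tree)] + 1]
                for (v in setdiff(branchIds(tree), tips))
                    pr <- pr * mats[[v]][states[tree@parent[v]] + 1,
                                         states[v] + 1]
                for (i in seq_along(tips)) {
                    p0 <- mats[[tips[i]]][states[tree@parent[tips[i]]] + 1,
                                          1]
                    pr <- pr * if (zeroTip[i]) p0 else (1 - p0)
                }
                total <- total + pr
            }
            total
        }
        pAllZero <- patProb(rep(TRUE, length(tips)))
        pOne <- 0
        if (minSp >= 2)
            for (j in seq_along(tips)) {
                z <- rep(TRUE, length(tips)); z[j] <- FALSE
                pOne <- pOne + patProb(z)
            }
        pAsc <- 1 - pAllZero - pOne
    }
    log(num) - log(pAsc)
}

# Gillespie simulation of the linear birth-death process (per-capita birth
# and death rate lambda), independent of the closed-form kernel
gillespieBD <- function(s0, lambda, t, nRep) {
    vapply(seq_len(nRep), function(i) {
        s <- s0; now <- 0
        repeat {
            if (s == 0) return(0L)
            rate <- 2 * lambda * s
            now <- now + stats::rexp(1, rate)
            if (now > t) return(as.integer(s))
            s <- s + sample(c(1L, -1L), 1)
        }
    }, 0L)
}

# random count fixture on a fixed tree
smallCountFixture <- function(seed = 1) {
    tr <- readNewick("((A:10,B:10):15,(C:20,D:20):5);")
    set.seed(seed)
    m <- matrix(rpois(4 * 6, 2), 6, 4,
                dimnames = list(sprintf("OG%d", 1:6), c("A", "B", "C", "D")))
    storage.mode(m) <- "integer"
    list(tree = tr, counts = familyCountTable(m))
}
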