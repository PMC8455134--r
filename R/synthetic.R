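# Seeded generators for trees, presence/absence matrices, count tables,
# annotations and cancer labels with known ground truth, so every
# downstream stage has a parameter-recovery test without external data.

#' Simulation configuration
#'
#' Bundles and validates every generator parameter.  The defaults describe
#' a desk-scale vertebrate-like study: a global family-size rate of
#' 0.0006092 gains/losses per gene per My with a twofold multiplier on
#' giant branches, per-branch loss probability 0.1 for the presence
#' process, a geometric(0.5) root-size prior, and a cancer-label fraction
#' of 0.05.
#'
#' @param seed mandatory integer RNG seed.
#' @param nFamilies number of families to emit.
#' @param originRate origins per My per branch for the presence process.
#' @param lossProbability per-branch Bernoulli loss probability.
#' @param lossPerMy if TRUE, \code{lossProbability} is a per-My rate and
#'   the per-branch probability is \code{1 - exp(-rate t)}.
#' @param lambdaBackground background birth-death rate (per gene per My).
#' @param giantMultiplier rate multiplier applied on giant branches to
#'   shifted families.
#' @param fractionShifted fraction of families whose giant-branch rate is
#'   multiplied (the ground-truth "shifted" families).
#' @param sMax size-truncation bound for the count process.
#' @param rootPrior root-size prior, as in [bdModel()]; geometric is
#'   conditioned on size >= 1.
#' @param giantBranches a [BranchSet-class] or integer branch IDs (may be
#'   empty: no giant effect).
#' @param conditionMinSpecies keep only families present in at least this
#'   many species in [simulateCounts()] (default 2, mirroring the input
#'   filter; 0 disables the conditioning).
#' @param fractionCancer expected fraction of families labelled cancer.
#' @param effectOdds odds multiplier linking the cancer label to the
#'   ground-truth shifted families (1 = independent).
#' @param nTerms number of annotation terms.
#' @param termFreq per-term probability that a protein carries the term.
#' @param maxRetries cap on redraw rounds when families are discarded.
#' @return a validated list of class \code{"SimConfig"}.
#' @export
simConfig <- function(seed, nFamilies = 2000L, originRate = 0.5,
                      lossProbability = 0.1, lossPerMy = FALSE,
                      lambdaBackground = 0.0006092, giantMultiplier = 2,
                      fractionShifted = 0.25, sMax = 100L,
                      rootPrior = list(type = "geometric", p = 0.5),
                      giantBranches = integer(0),
                      conditionMinSpecies = 2L, fractionCancer = 0.05,
                      effectOdds = 3, nTerms = 50L, termFreq = 0.05,
                      maxRetries = 200L) {
    if (missing(seed)) stop("seed is mandatory")
    if (is(giantBranches, "BranchSet")) giantBranches <-
        setBranches(giantBranches)
    cfg <- list(seed = as.integer(seed), nFamilies = as.integer(nFamilies),
                originRate = originRate, lossProbability = lossProbability,
                lossPerMy = lossPerMy, lambdaBackground = lambdaBackground,
                giantMultiplier = giantMultiplier,
                fractionShifted = fractionShifted, sMax = as.integer(sMax),
                rootPrior = rootPrior,
                giantBranches = as.integer(giantBranches),
                conditionMinSpecies = as.integer(conditionMinSpecies),
                fractionCancer = fractionCancer, effectOdds = effectOdds,
                nTerms = as.integer(nTerms), termFreq = termFreq,
                maxRetries = as.integer(maxRetries))
    with(cfg, {
        stopifnot(nFamilies >= 1, originRate >= 0, lambdaBackground >= 0,
                  giantMultiplier >= 0, sMax >= 1,
                  lossProbability >= 0,
                  lossPerMy || lossProbability <= 1,
                  fractionShifted >= 0, fractionShifted <= 1,
                  fractionCancer >= 0, fractionCancer <= 1,
                  effectOdds >= 0, termFreq >= 0, termFreq <= 1)
    })
    structure(cfg, class = "SimConfig")
}

#' @export
print.SimConfig <- function(x, ...) {
    cat("SimConfig:\n")
    for (k in names(x))
        cat(sprintf("  %s = %s\n", k, paste(format(unlist(x[[k]])),
                                            collapse = " ")))
    invisible(x)
}

#' Simulate an ultrametric time-calibrated tree
#'
#' A coalescent topology rescaled to a fixed root depth, standing in for a
#' time-calibrated species tree.
#'
#' @param nTips number of tips.
#' @param seed RNG seed.
#' @param depth root-to-tip depth in My (default 450, an early-vertebrate
#'   scale).
#' @return a [TimeTree-class] with tips \code{sp01, sp02, ...}.
#' @export
simulateTimeTree <- function(nTips, seed, depth = 450) {
    phy <- .withSeed(seed, ape::rcoal(nTips,
        tip.label = sprintf("sp%02d", seq_len(nTips))))
    phy$edge.length <- phy$edge.length * depth /
        max(ape::node.depth.edgelength(phy))
    .phyloToTimeTree(phy)
}

.lossProb <- function(cfg, t) {
    if (cfg$lossPerMy) 1 - exp(-cfg$lossProbability * t)
    else rep(cfg$lossProbability, length(t))
}

#' Simulate presence/absence under single origin and multiple loss
#'
#' Each branch spawns a Poisson number of new families (rate
#' \code{originRate} per My); a family is present at its origin node
#' (the branch's child) and propagates tipward, with each strictly
#' descendant branch independently losing it with the configured
#' probability; below a loss the family is absent throughout.  Families
#' surviving at no tip are unobservable and are discarded; drawing
#' continues until \code{nFamilies} observable families are collected.
#'
#' @param tree a [TimeTree-class].
#' @param cfg a [simConfig()] configuration.
#' @return list with \code{presence} (logical families x species matrix)
#'   and \code{truth} (list: \code{origin} named integer origin node per
#'   family, \code{losses} list of realised loss branches per family).
#' @export
simulatePresence <- function(tree, cfg) {
    if (cfg$originRate <= 0) stop("originRate must be > 0 to produce families")
    .withSeed(cfg$seed, {
        br <- branchIds(tree)
        tips <- tipIds(tree)
        n <- nNodes(tree)
        lossP <- numeric(n)
        lossP[br] <- .lossProb(cfg, tree@brlen[br])
        presence <- matrix(FALSE, 0, length(tips))
        origins <- integer(0)
        losses <- list()
        tries <- 0L
        while (length(origins) < cfg$nFamilies) {
            tries <- tries + 1L
            if (tries > cfg$maxRetries)
                stop("could not produce ", cfg$nFamilies,
                     " observable families in ", cfg$maxRetries, " rounds")
            nOrig <- stats::rpois(length(br), cfg$originRate * tree@brlen[br])
            for (i in seq_along(br)) {
                if (nOrig[i] == 0L) next
                for (rep in seq_len(nOrig[i])) {
                    o <- br[i]
                    pres <- logical(n)
                    pres[o] <- TRUE
                    lost <- integer(0)
                    for (v in rev(subtreeNodes(tree, o))) { # parents first
                        if (v == o || !pres[tree@parent[v]]) next
                        if (stats::runif(1) < lossP[v]) lost <- c(lost, v)
                        else pres[v] <- TRUE
                    }
                    if (!any(pres[tips])) next    # unobservable: discard
                    presence <- rbind(presence, pres[tips])
                    origins <- c(origins, o)
                    losses <- c(losses, list(sort(lost)))
                }
            }
        }
        keep <- seq_len(cfg$nFamilies)
        presence <- presence[keep, , drop = FALSE]
        dimnames(presence) <- list(sprintf("F%05d", keep), tipLabels(tree))
        origins <- stats::setNames(origins[keep], rownames(presence))
        losses <- stats::setNames(losses[keep], rownames(presence))
        list(presence = presence,
             truth = list(origin = origins, losses = losses))
    })
}

# sample child sizes from the truncated renormalised kernel rows; uses the
# caller's RNG stream
.sampleKernel <- function(P, s) {
    out <- integer(length(s))
    for (sv in unique(s)) {
        sel <- s == sv
        out[sel] <- sample.int(ncol(P), sum(sel), replace = TRUE,
                               prob = P[sv + 1L, ]) - 1L
    }
    out
}

.sampleRoot <- function(n, rootPrior, sMax) {
    if (rootPrior$type == "point") return(rep(rootPrior$size, n))
    p <- if (is.null(rootPrior$p)) 0.5 else rootPrior$p
    pr <- stats::dgeom(0:(sMax - 1), p)
    sample.int(sMax, n, replace = TRUE, prob = pr)
}

# simulate a count table from a fitted BDModel, conditioned like the
# likelihood; uses the caller's RNG stream
.simulateFromModel <- function(tree, model, nFam) {
    n <- nNodes(tree)
    tips <- tipIds(tree)
    mats <- .branchMatrices(tree, model)
    got <- 0L
    out <- matrix(0L, nFam, length(tips))
    tries <- 0L
    while (got < nFam) {
        tries <- tries + 1L
        if (tries > 200L) stop("conditioning rejection cap reached")
        nb <- max(nFam - got, 32L)
        sizes <- matrix(0L, nb, n)
        sizes[, rootNode(tree)] <- .sampleRoot(nb, model@rootPrior,
                                               model@sMax)
        for (v in rev(seq_len(n))) {     # pre-order
            if (v == rootNode(tree)) next
            sizes[, v] <- .sampleKernel(mats[[v]], sizes[, tree@parent[v]])
        }
        ok <- rowSums(sizes[, tips, drop = FALSE] > 0) >=
            model@conditionMinSpecies
        nTake <- min(sum(ok), nFam - got)
        if (nTake > 0) {
            out[got + seq_len(nTake), ] <-
                sizes[which(ok)[seq_len(nTake)], tips]
            got <- got + nTake
        }
    }
    dimnames(out) <- list(sprintf("F%05d", seq_len(nFam)), tipLabels(tree))
    familyCountTable(out)
}

#' Simulate gene-family size evolution on the tree
#'
#' Root sizes are drawn from the root prior (geometric conditioned on
#' size >= 1 by default); each child size is sampled exactly from the
#' truncated birth-death transition kernel of the branch — the same kernel
#' the likelihood uses, so parameter-recovery tests exercise the estimator
#' alone.  A configurable fraction of families is "shifted": their rate on
#' giant branches is \code{lambdaBackground * giantMultiplier}; all other
#' rates are \code{lambdaBackground}.  Families present in fewer than
#' \code{conditionMinSpecies} species are redrawn (set 0 to disable).
#'
#' @param tree a [TimeTree-class].
#' @param cfg a [simConfig()] configuration.
#' @return list with \code{counts} (a [FamilyCountTable-class]) and
#'   \code{truth} (list: \code{nodeSizes} families x nodes matrix,
#'   \code{shifted} named logical, \code{lambda} named per-class rates).
#' @export
simulateCounts <- function(tree, cfg) {
    .withSeed(cfg$seed + 1L, {
        n <- nNodes(tree)
        tips <- tipIds(tree)
        giant <- intersect(cfg$giantBranches, branchIds(tree))
        lamBg <- cfg$lambdaBackground
        lamG <- lamBg * cfg$giantMultiplier
        matsBg <- vector("list", n)
        matsG <- vector("list", n)
        for (v in branchIds(tree)) {
            matsBg[[v]] <- transitionMatrix(lamBg, tree@brlen[v], cfg$sMax)
            matsG[[v]] <- if (v %in% giant)
                transitionMatrix(lamG, tree@brlen[v], cfg$sMax)
            else matsBg[[v]]
        }
        nFam <- cfg$nFamilies
        sizes <- matrix(0L, 0, n)
        shifted <- logical(0)
        tries <- 0L
        while (nrow(sizes) < nFam) {
            tries <- tries + 1L
            if (tries > cfg$maxRetries)
                stop("conditioning rejection cap reached")
            nb <- max(nFam - nrow(sizes), 32L)
            sh <- if (length(giant))
                stats::runif(nb) < cfg$fractionShifted else rep(FALSE, nb)
            sz <- matrix(0L, nb, n)
            sz[, rootNode(tree)] <- .sampleRoot(nb, cfg$rootPrior, cfg$sMax)
            for (v in rev(seq_len(n))) {
                if (v == rootNode(tree)) next
                if (any(sh) && !is.null(matsG[[v]]) &&
                    !identical(matsG[[v]], matsBg[[v]])) {
                    sz[sh, v] <- .sampleKernel(matsG[[v]],
                                               sz[sh, tree@parent[v]])
                    sz[!sh, v] <- .sampleKernel(matsBg[[v]],
                                                sz[!sh, tree@parent[v]])
                } else {
                    sz[, v] <- .sampleKernel(matsBg[[v]],
                                             sz[, tree@parent[v]])
                }
            }
            ok <- rowSums(sz[, tips, drop = FALSE] > 0) >=
                cfg$conditionMinSpecies
            sizes <- rbind(sizes, sz[ok, , drop = FALSE])
            shifted <- c(shifted, sh[ok])
        }
        sizes <- sizes[seq_len(nFam), , drop = FALSE]
        shifted <- shifted[seq_len(nFam)]
        fam <- sprintf("F%05d", seq_len(nFam))
        counts <- sizes[, tips, drop = FALSE]
        dimnames(counts) <- list(fam, tipLabels(tree))
        rownames(sizes) <- fam
        lam <- c(background = lamBg, giant = lamG)
        list(counts = familyCountTable(counts),
             truth = list(nodeSizes = sizes,
                          shifted = stats::setNames(shifted, fam),
                          lambda = lam, giantBranches = giant))
    })
}

#' Simulate cancer labels and annotation terms
#'
#' Cancer labels are Bernoulli per family with the odds tilted by
#' \code{effectOdds} toward the ground-truth shifted families, while the
#' overall expected labelled fraction is held at \code{fractionCancer}
#' (the baseline probability is solved numerically).  One protein is
#' emitted per gene copy (or per present species when only presence is
#' available) and terms are drawn independently per protein with
#' probability \code{termFreq}.
#'
#' @param counts a [FamilyCountTable-class] (or presence matrix).
#' @param truth the \code{truth} component of [simulateCounts()] (needs
#'   \code{shifted}); pass \code{NULL} to label independently.
#' @param cfg a [simConfig()] configuration.
#' @return list with \code{cancer} (a [GeneSet-class]) and
#'   \code{annotations} (an [AnnotationMap-class]).
#' @export
simulateLabels <- function(counts, truth, cfg) {
    if (cfg$fractionCancer <= 0)
        stop("fractionCancer = 0 yields an empty cancer set")
    m <- if (is(counts, "FamilyCountTable")) famCounts(counts) else counts
    fam <- rownames(m)
    shifted <- if (is.null(truth)) rep(FALSE, length(fam))
               else truth$shifted[fam]
    shifted[is.na(shifted)] <- FALSE
    fs <- mean(shifted)
    e <- cfg$effectOdds
    target <- cfg$fractionCancer
    tilt <- function(p0) { o <- e * p0 / (1 - p0); o / (1 + o) }
    p0 <- if (fs == 0 || e == 1) target else
        stats::uniroot(function(p0) (1 - fs) * p0 + fs * tilt(p0) - target,
                       c(1e-12, 1 - 1e-12))$root
    .withSeed(cfg$seed + 2L, {
        pc <- ifelse(shifted, tilt(p0), p0)
        cancer <- fam[stats::runif(length(fam)) < pc]
        if (!length(cancer))     # tiny sets can miss; keep the contract
            cancer <- fam[which.max(pc)]
        members <- do.call(rbind, lapply(seq_along(fam), function(i) {
            sp <- colnames(m)[m[i, ] > 0]
            nProt <- m[i, m[i, ] > 0]
            data.frame(protein = sprintf("%s_%s_p%d",
                           fam[i], rep(sp, nProt),
                           unlist(lapply(nProt, seq_len))),
                       species = rep(sp, nProt), family = fam[i])
        }))
        termIds <- sprintf("T%03d", seq_len(cfg$nTerms))
        hits <- which(matrix(stats::runif(nrow(members) * cfg$nTerms) <
                             cfg$termFreq, nrow(members)), arr.ind = TRUE)
        terms <- data.frame(protein = members$protein[hits[, 1]],
                            term = termIds[hits[, 2]])
        list(cancer = geneSet(cancer, "cancer"),
             annotations = annotationMap(members, terms))
    })
}

#' Simulate per-(family, branch) rates from a known interaction model
#'
#' Generates a branch-rate table directly from the random-intercept linear
#' model \code{rate = b0 + b_giant G + b_cancer C + b_int G C + u_family +
#' e}, for calibration and coverage tests of [interactionModel()].
#'
#' @param nFamilies,nBranches table dimensions.
#' @param nGiant number of giant branches (the first \code{nGiant} branch
#'   IDs).
#' @param coefs numeric length 4: intercept, giant, cancer, interaction.
#' @param sdFamily random-intercept standard deviation.
#' @param sdResid residual standard deviation.
#' @param fractionCancer fraction of families labelled cancer.
#' @param seed RNG seed.
#' @return list with \code{rates} (data.frame family/branch/rate),
#'   \code{giant} (branch IDs), \code{cancer} (family IDs), \code{coefs}.
#' @export
simulateRateTable <- function(nFamilies = 150L, nBranches = 12L,
                              nGiant = 3L,
                              coefs = c(0.02, 0.02, 0, 0.01),
                              sdFamily = 0.05, sdResid = 0.02,
                              fractionCancer = 0.3, seed = 1L) {
    .withSeed(seed, {
        fam <- sprintf("F%05d", seq_len(nFamilies))
        cancer <- fam[stats::runif(nFamilies) < fractionCancer]
        u <- stats::rnorm(nFamilies, 0, sdFamily)
        giant <- seq_len(nGiant)
        g <- rep(seq_len(nBranches) %in% giant, each = nFamilies)
        cc <- rep(fam %in% cancer, times = nBranches)
        mu <- coefs[1] + coefs[2] * g + coefs[3] * cc + coefs[4] * g * cc +
            rep(u, times = nBranches)
        rates <- data.frame(
            family = rep(fam, times = nBranches),
            branch = rep(seq_len(nBranches), each = nFamilies),
            rate = mu + stats::rnorm(nFamilies * nBranches, 0, sdResid))
        list(rates = rates, giant = giant, cancer = cancer, coefs = coefs)
    })
}
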