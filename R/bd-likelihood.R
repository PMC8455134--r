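# Pruning likelihood of gene-family counts under the birth-death kernel,
# with a truncated-geometric root prior and ascertainment conditioning on
# the family being observed in >= conditionMinSpecies tips.

#' Construct a birth-death model
#'
#' @param tree a [TimeTree-class].
#' @param lambda named numeric rate per branch class (per gene per My); a
#'   single unnamed value is taken as the rate of a single class
#'   \code{"all"}.
#' @param classes named character vector mapping branch IDs (child node
#'   IDs, as names) to class names; \code{NULL} puts every branch in class
#'   \code{"all"}.
#' @param sMax size-truncation bound (default 100).
#' @param rootPrior list: \code{list(type = "geometric", p = 0.5)}
#'   (truncated to \code{1..sMax}) or \code{list(type = "point", size = k)}.
#' @param conditionMinSpecies ascertainment: condition the likelihood on
#'   the family being non-extinct in at least this many tips (default 2,
#'   mirroring the at-least-two-species input filter).
#' @return a [BDModel-class].
#' @export
bdModel <- function(tree, lambda, classes = NULL, sMax = 100L,
                    rootPrior = list(type = "geometric", p = 0.5),
                    conditionMinSpecies = 2L) {
    if (is.null(names(lambda))) {
        stopifnot(length(lambda) == 1)
        names(lambda) <- "all"
    }
    if (is.null(classes)) {
        classes <- rep(names(lambda)[1], length(branchIds(tree)))
        names(classes) <- as.character(branchIds(tree))
    }
    if (!setequal(names(classes), as.character(branchIds(tree))))
        stop("classes must map every non-root branch exactly once")
    methods::new("BDModel", lambda = lambda, classMap = classes,
                 sMax = as.integer(sMax), rootPrior = rootPrior,
                 conditionMinSpecies = as.integer(conditionMinSpecies))
}

setMethod("show", "BDModel", function(object) {
    cat(sprintf("BDModel: sMax=%d, root prior %s, condition >= %d tips\n",
                object@sMax, object@rootPrior$type,
                object@conditionMinSpecies))
    for (cl in names(object@lambda))
        cat(sprintf("  lambda[%s] = %.6g (%d branches)\n", cl,
                    object@lambda[cl], sum(object@classMap == cl)))
})

.rootPriorVec <- function(model) {
    sMax <- model@sMax
    rp <- model@rootPrior
    pr <- numeric(sMax + 1)
    if (rp$type == "geometric") {
        p <- if (is.null(rp$p)) 0.5 else rp$p
        pr[-1] <- stats::dgeom(0:(sMax - 1), p)
        pr <- pr / sum(pr)
    } else if (rp$type == "point") {
        pr[rp$size + 1] <- 1
    } else stop("unknown root prior type: ", rp$type)
    pr
}

.branchMatrices <- function(tree, model) {
    mats <- vector("list", nNodes(tree))
    for (v in branchIds(tree))
        mats[[v]] <- transitionMatrix(model@lambda[[model@classMap[[
            as.character(v)]]]], tree@brlen[v], model@sMax)
    mats
}

# Felsenstein pruning over sizes 0..sMax for a batch of "families" given as
# tip partial-likelihood matrices.  tipL: list indexed by tip node ID, each
# an (sMax+1) x nFam matrix.  Returns list(lik = numeric nFam of
# root-summed likelihoods on the scaled ladder, logScale = numeric nFam).
.prune <- function(tipL, tree, mats, priorVec) {
    n <- nNodes(tree)
    nFam <- ncol(tipL[[tipIds(tree)[1]]])
    L <- vector("list", n)
    logScale <- numeric(nFam)
    for (v in seq_len(n)) {
        if (tree@isTip[v]) { L[[v]] <- tipL[[v]]; next }
        acc <- NULL
        for (w in tree@children[[v]]) {
            contrib <- mats[[w]] %*% L[[w]]
            acc <- if (is.null(acc)) contrib else acc * contrib
            L[w] <- list(NULL)
        }
        mx <- colSums(acc)             # cheap positive scaling constant
        mx[mx <= 0] <- 1
        L[[v]] <- acc / rep(mx, each = nrow(acc))
        logScale <- logScale + log(mx)
    }
    list(lik = as.numeric(priorVec %*% L[[rootNode(tree)]]),
         logScale = logScale)
}

# log of P(family observed in >= minSpecies tips) under model + prior
.ascertainmentLogP <- function(tree, model, mats = NULL, priorVec = NULL) {
    minSp <- model@conditionMinSpecies
    if (minSp <= 0) return(0)
    if (is.null(mats)) mats <- .branchMatrices(tree, model)
    if (is.null(priorVec)) priorVec <- .rootPriorVec(model)
    sMax <- model@sMax
    tips <- tipIds(tree)
    nt <- length(tips)
    ncol <- 1L + if (minSp >= 2) nt else 0L
    e0 <- c(1, numeric(sMax))
    ePos <- c(0, rep(1, sMax))
    tipL <- vector("list", nNodes(tree))
    for (i in seq_along(tips)) {
        m <- matrix(e0, sMax + 1, ncol)
        if (minSp >= 2) m[, 1L + i] <- ePos   # column i+1: only tip i non-zero
        tipL[[tips[i]]] <- m
    }
    pr <- .prune(tipL, tree, mats, priorVec)
    p <- pr$lik * exp(pr$logScale)
    pExcluded <- sum(p)      # all-zero plus (if minSp >= 2) each only-one case
    log1p(-min(pExcluded, 1 - 1e-300))
}

#' Pruning log-likelihood of gene-family counts
#'
#' Computes the log-likelihood of each family's tip counts under a
#' [BDModel-class]: Felsenstein pruning over sizes \code{0..sMax} with the
#' truncated kernel, summing the root state over the root prior, divided
#' by the probability that a family is observed in at least
#' \code{conditionMinSpecies} tips (ascertainment matching the input
#' filter).
#'
#' @param counts a [FamilyCountTable-class], a counts matrix with species
#'   columns, or a single named count vector.
#' @param tree a [TimeTree-class].
#' @param model a [BDModel-class].
#' @return named numeric of per-family log-likelihoods, with the sum as
#'   attribute \code{"total"}.
#' @export
familyLoglik <- function(counts, tree, model) {
    m <- if (is(counts, "FamilyCountTable")) famCounts(counts)
         else if (is.null(dim(counts))) t(as.matrix(counts))
         else counts
    tl <- tipLabels(tree)
    idx <- match(tl, colnames(m))
    if (anyNA(idx)) stop("counts lack species: ",
                         paste(tl[is.na(idx)], collapse = ", "))
    m <- m[, idx, drop = FALSE]
    sMax <- model@sMax
    if (any(m > sMax))
        stop("count exceeds sMax = ", sMax, "; filter or raise sMax")
    if (any(rowSums(m > 0) < model@conditionMinSpecies))
        stop("family present in fewer than conditionMinSpecies species; ",
             "apply filterForBD() first")
    mats <- .branchMatrices(tree, model)
    priorVec <- .rootPriorVec(model)
    nFam <- nrow(m)
    tips <- tipIds(tree)
    tipL <- vector("list", nNodes(tree))
    for (i in seq_along(tips)) {
        tm <- matrix(0, sMax + 1, nFam)
        tm[cbind(m[, i] + 1L, seq_len(nFam))] <- 1
        tipL[[tips[i]]] <- tm
    }
    pr <- .prune(tipL, tree, mats, priorVec)
    ll <- log(pr$lik) + pr$logScale -
        .ascertainmentLogP(tree, model, mats, priorVec)
    names(ll) <- rownames(m)
    attr(ll, "total") <- sum(ll)
    ll
}
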