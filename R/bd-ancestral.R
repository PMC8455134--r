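# Marginal ancestral family sizes by the up-down (inside-outside)
# algorithm, exact per-branch shift tests, and branch-wise rates.

#' Marginal ancestral family sizes
#'
#' @slot modes integer matrix families x nodes: marginal posterior mode
#'   size per node (ties broken toward the smaller size); at tips the
#'   observed count.
#' @slot marginals list (possibly empty): per family, an
#'   \code{(sMax+1) x nNodes} matrix of full marginal distributions.
#' @slot tree the [TimeTree-class].
#' @seealso [ancestralStates()]
#' @export
setClass("AncestralSizes", representation(
    modes = "matrix", marginals = "list", tree = "TimeTree"))

setMethod("show", "AncestralSizes", function(object) {
    cat(sprintf("AncestralSizes: %d families x %d nodes%s\n",
                nrow(object@modes), ncol(object@modes),
                if (length(object@marginals)) " (full marginals stored)"
                else ""))
})

#' Marginal posterior ancestral sizes per internal node
#'
#' Runs the up-down (outside) algorithm under the same kernel, root prior
#' and truncation as the likelihood: the marginal posterior of each
#' internal node's size given all tip counts is the normalised elementwise
#' product of its inside and outside vectors.  The reported size is the
#' posterior mode, ties broken toward the smaller size; the tip
#' "reconstruction" equals the observed count.
#'
#' @param counts a filtered [FamilyCountTable-class] (or counts matrix).
#' @param tree a [TimeTree-class].
#' @param model a [BDModel-class] (typically from [fitLambda()]).
#' @param storeMarginals keep the full per-node marginal distributions
#'   (memory grows as families x nodes x sMax; default FALSE).
#' @return an [AncestralSizes-class].
#' @export
ancestralStates <- function(counts, tree, model, storeMarginals = FALSE) {
    m <- .prepCounts(counts, tree)
    sMax <- model@sMax
    if (any(m > sMax)) stop("count exceeds sMax")
    n <- nNodes(tree)
    nFam <- nrow(m)
    tips <- tipIds(tree)
    mats <- .branchMatrices(tree, model)
    priorVec <- .rootPriorVec(model)

    L <- vector("list", n)       # inside vectors (column-normalised)
    contrib <- vector("list", n) # P_w %*% L_w per non-root node w
    for (i in seq_along(tips)) {
        tm <- matrix(0, sMax + 1, nFam)
        tm[cbind(m[, i] + 1L, seq_len(nFam))] <- 1
        L[[tips[i]]] <- tm
    }
    for (v in seq_len(n)) {
        if (!tree@isTip[v]) {
            acc <- NULL
            for (w in tree@children[[v]]) {
                cw <- mats[[w]] %*% L[[w]]
                cw <- cw / rep(pmax(colSums(cw), 1e-300), each = nrow(cw))
                contrib[[w]] <- cw
                acc <- if (is.null(acc)) cw else acc * cw
            }
            L[[v]] <- acc
        }
    }

    O <- vector("list", n)       # outside vectors (column-normalised)
    O[[rootNode(tree)]] <- matrix(priorVec, sMax + 1, nFam)
    for (v in rev(seq_len(n))) { # pre-order: parents before children
        if (tree@isTip[v]) next
        kids <- tree@children[[v]]
        for (w in kids) {
            pre <- O[[v]]
            for (u in setdiff(kids, w)) pre <- pre * contrib[[u]]
            Ow <- crossprod(mats[[w]], pre)     # t(P_w) %*% pre
            O[[w]] <- Ow / rep(pmax(colSums(Ow), 1e-300), each = nrow(Ow))
        }
    }

    modes <- matrix(0L, nFam, n,
                    dimnames = list(rownames(m), NULL))
    marginals <- if (storeMarginals)
        lapply(seq_len(nFam), function(f) matrix(0, sMax + 1, n)) else list()
    for (v in seq_len(n)) {
        if (tree@isTip[v]) {
            modes[, v] <- m[, match(v, tips)]
            if (storeMarginals)
                for (f in seq_len(nFam))
                    marginals[[f]][m[f, match(v, tips)] + 1L, v] <- 1
            next
        }
        post <- O[[v]] * L[[v]]
        post <- sweep(post, 2L, colSums(post), "/")
        modes[, v] <- max.col(t(post), ties.method = "first") - 1L
        if (storeMarginals)
            for (f in seq_len(nFam)) marginals[[f]][, v] <- post[, f]
    }
    if (storeMarginals && !is.null(rownames(m)))
        names(marginals) <- rownames(m)
    methods::new("AncestralSizes", modes = modes, marginals = marginals,
                 tree = tree)
}

#' @describeIn ancestralStates the families x nodes matrix of
#'   reconstructed (mode) sizes.
#' @param anc an [AncestralSizes-class].
#' @export
ancestralModes <- function(anc) anc@modes

#' Exact per-branch shift tests on reconstructed size transitions
#'
#' For each branch, the reconstructed parent-to-child transition
#' \code{(s, c)} is scored against the fitted kernel row for that branch:
#' the p-value sums the probabilities of all child states no more likely
#' than the observed one (probability-ordering exact test; \code{p = 1}
#' when the row is a point mass at the observed state).  Branches with
#' \code{p < alpha} are flagged as rate shifts.
#'
#' @param anc an [AncestralSizes-class].
#' @param tree a [TimeTree-class].
#' @param model the fitted [BDModel-class].
#' @param alpha flag threshold (default 0.05).
#' @return a [BranchShiftTable-class].
#' @export
branchShiftPvalues <- function(anc, tree = anc@tree, model, alpha = 0.05) {
    modes <- anc@modes
    br <- branchIds(tree)
    nFam <- nrow(modes)
    P <- matrix(NA_real_, nFam, length(br),
                dimnames = list(rownames(modes), as.character(br)))
    TP <- P
    for (j in seq_along(br)) {
        v <- br[j]
        mat <- transitionMatrix(model@lambda[[model@classMap[[
            as.character(v)]]]], tree@brlen[v], model@sMax)
        s <- modes[, tree@parent[v]]
        cc <- modes[, v]
        for (sv in unique(s)) {
            row <- mat[sv + 1L, ]
            tail <- .rowTailP(row)
            sel <- s == sv
            P[sel, j] <- tail[cc[sel] + 1L]
            TP[sel, j] <- row[cc[sel] + 1L]
        }
    }
    methods::new("BranchShiftTable", p = P, flag = P < alpha,
                 transitionProb = TP, alpha = alpha)
}

setMethod("show", "BranchShiftTable", function(object) {
    cat(sprintf(
        "BranchShiftTable: %d families x %d branches; %d flags at p < %g\n",
        nrow(object@p), ncol(object@p), sum(object@flag), object@alpha))
})

#' @describeIn branchShiftPvalues the families x branches p-value matrix.
#' @param x a [BranchShiftTable-class].
#' @export
shiftPvalues <- function(x) x@p

#' @describeIn branchShiftPvalues the families x branches flag matrix.
#' @export
shiftFlags <- function(x) x@flag

#' Branch-wise rates of gene-family size evolution
#'
#' The rate on a branch is the absolute difference between the
#' reconstructed (or observed, at tips) parent and child family sizes
#' divided by the branch duration, in copies per My.
#'
#' @param anc an [AncestralSizes-class].
#' @param tree a [TimeTree-class].
#' @return a long data.frame with columns \code{family}, \code{branch}
#'   (child node ID), \code{parentSize}, \code{childSize}, \code{rate}.
#' @export
branchRates <- function(anc, tree = anc@tree) {
    modes <- anc@modes
    br <- branchIds(tree)
    fam <- rownames(modes)
    if (is.null(fam)) fam <- as.character(seq_len(nrow(modes)))
    out <- do.call(rbind, lapply(br, function(v)
        data.frame(family = fam, branch = v,
                   parentSize = modes[, tree@parent[v]],
                   childSize = modes[, v],
                   rate = abs(modes[, tree@parent[v]] - modes[, v]) /
                       tree@brlen[v])))
    rownames(out) <- NULL
    out
}
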