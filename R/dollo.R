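# Dollo parsimony: single-origin / multiple-loss mapping of gene families
# onto the species tree, per-node gain/loss/core accounting, the input
# filter for the birth-death stage, and the ohnolog-splitting audit.

.ancestorMatrix <- function(tree) {
    n <- nNodes(tree)
    A <- matrix(FALSE, n, n)      # A[v, a]: a is ancestor-or-self of v
    for (v in seq_len(n)) A[v, ancestorPath(tree, v)] <- TRUE
    A
}

.tipPresence <- function(presence, tree) {
    # presence: logical matrix families x species (colnames = species)
    tl <- tipLabels(tree)
    if (is.null(colnames(presence)))
        stop("presence matrix must carry species colnames")
    idx <- match(tl, colnames(presence))
    if (anyNA(idx))
        stop("species missing from presence matrix: ",
             paste(tl[is.na(idx)], collapse = ", "))
    m <- presence[, idx, drop = FALSE]
    colnames(m) <- tl
    m
}

#' Infer the origin node of one gene family
#'
#' Under single-origin (Dollo) parsimony with gains costed above any number
#' of losses, the minimum-loss origin is the MRCA of the tips possessing
#' the family; a single-tip family originates on that tip's own branch.
#'
#' @param presence logical vector named by species, or a character vector
#'   of species possessing the family.
#' @param tree a [TimeTree-class].
#' @return the origin node ID.
#' @examples
#' tr <- readNewick("((A:1,B:1):1,((C:1,D:1):1,E:2):1);")
#' inferOrigin(c("A", "B", "D"), tr) == rootNode(tr)
#' @export
inferOrigin <- function(presence, tree) {
    sp <- if (is.logical(presence)) names(presence)[presence]
          else as.character(presence)
    if (!length(sp)) stop("family absent from every species")
    mrcaNode(tree, nodeId(tree, sp))
}

#' Dollo reconstruction of origins and losses for all families
#'
#' Maps every family onto the tree assuming a single origin and any number
#' of losses: the origin is the MRCA of possessing tips, a node is present
#' iff it lies in the origin's subtree and at least one tip in its subtree
#' possesses the family, and the loss branches are exactly the maximal
#' absent subtrees under the origin.  The number of losses is minimal given
#' a single gain.
#'
#' @param presence logical families-x-species matrix (see
#'   [presenceMatrix()]) or a [FamilyCountTable-class].
#' @param tree a [TimeTree-class].
#' @return a [DolloReconstruction-class].
#' @export
dolloReconstruct <- function(presence, tree) {
    if (is(presence, "FamilyCountTable")) presence <- presenceMatrix(presence)
    tipP <- .tipPresence(presence, tree)
    nf <- nrow(tipP)
    n <- nNodes(tree)
    tips <- tipIds(tree)
    if (any(rowSums(tipP) == 0))
        stop("all-absent family: ",
             paste(utils::head(rownames(tipP)[rowSums(tipP) == 0], 5),
                   collapse = ", "))

    anyBelow <- matrix(FALSE, nf, n)
    countBelow <- matrix(0L, nf, n)
    anyBelow[, tips] <- tipP
    countBelow[, tips] <- tipP
    for (v in seq_len(n)[-tips]) {    # post-order IDs: children come first
        kids <- tree@children[[v]]
        anyBelow[, v] <- rowSums(anyBelow[, kids, drop = FALSE]) > 0
        countBelow[, v] <- rowSums(countBelow[, kids, drop = FALSE])
    }
    total <- countBelow[, rootNode(tree)]
    # origin = minimal-ID node whose subtree holds every possessing tip
    origin <- max.col(countBelow == total, ties.method = "first")
    names(origin) <- rownames(tipP)

    A <- .ancestorMatrix(tree)
    inOrigin <- t(A[, origin, drop = FALSE])     # nf x n
    pres <- inOrigin & anyBelow
    rownames(pres) <- rownames(tipP)

    nonroot <- branchIds(tree)
    lossMat <- matrix(FALSE, nf, n)
    lossMat[, nonroot] <- pres[, tree@parent[nonroot], drop = FALSE] &
        !pres[, nonroot, drop = FALSE]
    losses <- apply(lossMat, 1L, which, simplify = FALSE)
    names(losses) <- rownames(tipP)

    methods::new("DolloReconstruction", origin = origin, presence = pres,
                 losses = losses, tree = tree)
}

#' @describeIn dolloReconstruct origin node ID per family.
#' @param rec a [DolloReconstruction-class].
#' @export
familyOrigins <- function(rec) rec@origin

#' @describeIn dolloReconstruct number of losses per family.
#' @export
familyLossCounts <- function(rec) lengths(rec@losses)

setMethod("show", "DolloReconstruction", function(object) {
    cat(sprintf("DolloReconstruction: %d families on %d-tip tree\n",
                length(object@origin), nTips(object@tree)))
    cat(sprintf("  %d total loss events; %d families with >= 1 loss\n",
                sum(lengths(object@losses)),
                sum(lengths(object@losses) > 0)))
})

#' Per-node gain/loss/core accounting
#'
#' Computes, for every node/branch, the totals used to annotate a
#' gains-and-losses tree figure: families present at the node, families
#' that originated on its branch (novel), families lost on its branch
#' (total, and stratified by the origin node of the lost family), losses
#' unique to the branch tree-wide, families conserved in every descendant
#' tip (core), and novel families that are also core (novel core).  The
#' flow identity \code{total(child) = total(parent) - lost + novel} holds
#' on every branch.
#'
#' @param rec a [DolloReconstruction-class].
#' @param tree a [TimeTree-class]; defaults to the reconstruction's tree.
#' @return a data.frame with one row per node (columns \code{node},
#'   \code{label}, \code{parent}, \code{isTip}, \code{branchLength},
#'   \code{totalPresent}, \code{novel}, \code{lost}, \code{uniqueLost},
#'   \code{core}, \code{novelCore}); the branch-by-origin loss matrix is
#'   attached as attribute \code{"lostByOrigin"}.
#' @export
nodeSummaries <- function(rec, tree = rec@tree) {
    n <- nNodes(tree)
    nf <- length(rec@origin)
    pres <- rec@presence
    tipP <- pres[, tipIds(tree), drop = FALSE]

    totalPresent <- colSums(pres)
    novel <- tabulate(rec@origin, nbins = n)

    lossN <- lengths(rec@losses)
    lost <- integer(n); uniqueLost <- integer(n)
    lostByOrigin <- matrix(0L, n, n,
                           dimnames = list(branch = NULL, origin = NULL))
    for (f in seq_len(nf)) {
        lb <- rec@losses[[f]]
        if (!length(lb)) next
        lost[lb] <- lost[lb] + 1L
        lostByOrigin[lb, rec@origin[f]] <- lostByOrigin[lb, rec@origin[f]] + 1L
        if (length(lb) == 1L) uniqueLost[lb] <- uniqueLost[lb] + 1L
    }

    core <- integer(n); novelCore <- integer(n)
    tips <- tipIds(tree)
    for (v in seq_len(n)) {
        tv <- match(tree@tipsBelow[[v]], tips)
        isCore <- rowSums(tipP[, tv, drop = FALSE]) == length(tv)
        core[v] <- sum(isCore)
        novelCore[v] <- sum(isCore & rec@origin == v)
    }

    out <- data.frame(
        node = seq_len(n), label = nodeLabels(tree),
        parent = tree@parent, isTip = tree@isTip,
        branchLength = tree@brlen,
        totalPresent = totalPresent, novel = novel, lost = lost,
        uniqueLost = uniqueLost, core = core, novelCore = novelCore)
    attr(out, "lostByOrigin") <- lostByOrigin
    out
}

#' Filter families for birth-death rate estimation
#'
#' Keeps families that were already present in a chosen ancestor (their
#' Dollo origin is that node or one of its ancestors), are present in at
#' least \code{minSpecies} species, and never exceed \code{maxCopies}
#' copies in any single species (large families have too large a variance
#' for stable rate estimation).
#'
#' @param counts a [FamilyCountTable-class].
#' @param rec a [DolloReconstruction-class] covering the same families.
#' @param ancestor node ID (or label) of the focal ancestor.
#' @param maxCopies maximum per-species copy number retained (default 100,
#'   inclusive).
#' @param minSpecies minimum number of species with the family (default 2).
#' @return the filtered [FamilyCountTable-class].
#' @export
filterForBD <- function(counts, rec, ancestor, maxCopies = 100,
                        minSpecies = 2) {
    tree <- rec@tree
    if (is.character(ancestor)) ancestor <- nodeId(tree, ancestor)
    if (ancestor < 1 || ancestor > nNodes(tree))
        stop("ancestor not in tree")
    m <- famCounts(counts)
    org <- rec@origin[match(rownames(m), names(rec@origin))]
    if (anyNA(org)) stop("reconstruction does not cover all families")
    okOrigin <- org %in% ancestorPath(tree, ancestor)
    okSpecies <- rowSums(m > 0) >= minSpecies
    okSize <- apply(m, 1L, max) <= maxCopies
    counts[okOrigin & okSpecies & okSize, , drop = FALSE]
}

#' Ohnolog-splitting audit of a gene-family partition
#'
#' Compares this package's gene-to-family assignment against an independent
#' reference partition (e.g. ohnolog families from a synteny-aware
#' analysis).  A reference family is "split" iff its member genes (over the
#' shared gene namespace) land in more than one of our families.  The focal
#' overlap counts focal families containing at least one gene of a split
#' reference family; the percentage is that overlap over the focal set
#' size.
#'
#' @param ourPartition named character vector: gene ID -> our family ID.
#' @param referencePartition named character vector: gene ID -> reference
#'   (ohnolog) family ID.
#' @param focalFamilies a [GeneSet-class] or character vector of our family
#'   IDs (e.g. the families novel at a focal ancestor).
#' @return a list with \code{nReferenceFamilies}, \code{nUnsplit},
#'   \code{nSplit}, \code{focalOverlap}, \code{focalSplitPercent}.
#' @export
splitReport <- function(ourPartition, referencePartition, focalFamilies) {
    if (is(focalFamilies, "GeneSet")) focalFamilies <- setFamilies(focalFamilies)
    genes <- intersect(names(ourPartition), names(referencePartition))
    if (!length(genes)) stop("empty intersection of gene namespaces")
    ours <- ourPartition[genes]
    refs <- referencePartition[genes]
    nOur <- tapply(ours, refs, function(x) length(unique(x)))
    split <- names(nOur)[nOur > 1]
    splitGenes <- genes[refs %in% split]
    focalOverlap <- sum(focalFamilies %in% ours[splitGenes])
    list(nReferenceFamilies = length(nOur),
         nUnsplit = sum(nOur == 1),
         nSplit = length(split),
         focalOverlap = focalOverlap,
         focalSplitPercent = 100 * focalOverlap / length(focalFamilies))
}
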