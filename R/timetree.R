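# TimeTree construction, Newick IO, and tree accessors.

.phyloToTimeTree <- function(phy) {
    ntip <- length(phy$tip.label)
    n <- ntip + phy$Nnode
    ch <- vector("list", n)
    for (i in seq_len(nrow(phy$edge))) {
        p <- phy$edge[i, 1L]
        ch[[p]] <- c(ch[[p]], phy$edge[i, 2L])
    }
    rootApe <- ntip + 1L
    post <- integer(0)
    visit <- function(v) {
        for (w in ch[[v]]) visit(w)
        post <<- c(post, v)
    }
    visit(rootApe)
    newId <- integer(n)
    newId[post] <- seq_len(n)

    parent <- integer(n)
    brlen <- rep(NA_real_, n)
    for (i in seq_len(nrow(phy$edge))) {
        cid <- newId[phy$edge[i, 2L]]
        parent[cid] <- newId[phy$edge[i, 1L]]
        brlen[cid] <- phy$edge.length[i]
    }
    children2 <- vector("list", n)
    for (v in seq_len(n)) children2[[newId[v]]] <- sort(newId[ch[[v]]])

    label <- character(n)
    label[newId[seq_len(ntip)]] <- phy$tip.label
    intLab <- phy$node.label
    for (v in seq_len(phy$Nnode)) {
        id <- newId[ntip + v]
        lab <- if (!is.null(intLab) && !is.na(intLab[v]) && nzchar(intLab[v]))
            intLab[v] else sprintf("N%d", id)
        label[id] <- lab
    }
    isTip <- lengths(children2) == 0L

    tipsBelow <- vector("list", n)
    for (v in seq_len(n)) {        # post-order IDs: children precede parents
        tipsBelow[[v]] <- if (isTip[v]) v else
            sort(unlist(tipsBelow[children2[[v]]], use.names = FALSE))
    }
    methods::new("TimeTree", parent = parent, children = children2,
                 brlen = brlen, label = label, isTip = isTip,
                 root = newId[rootApe], tipsBelow = tipsBelow)
}

#' Read a rooted, time-calibrated Newick tree
#'
#' Parses a standard Newick file (branch lengths in My) into a
#' [TimeTree-class] with deterministic post-order node IDs.  Tip labels are
#' preserved verbatim.
#'
#' @param path path to a Newick file, or a Newick string containing \code{;}.
#' @param allowPolytomy allow a basal (or internal) polytomy; by default a
#'   non-binary root is rejected.
#' @param zeroEpsilon \code{NULL} (default) rejects zero-length branches;
#'   a positive number substitutes that duration for zero-length branches.
#' @return a [TimeTree-class].
#' @examples
#' tr <- readNewick("((A:1,B:1):1,C:2);")
#' nTips(tr)
#' @export
readNewick <- function(path, allowPolytomy = FALSE, zeroEpsilon = NULL) {
    phy <- if (grepl(";", path, fixed = TRUE)) {
        ape::read.tree(text = path)
    } else {
        if (!file.exists(path)) stop("cannot read tree file: ", path)
        ape::read.tree(path)
    }
    if (is.null(phy)) stop("failed to parse Newick input")
    if (anyDuplicated(phy$tip.label))
        stop("duplicate tip labels: ",
             paste(unique(phy$tip.label[duplicated(phy$tip.label)]),
                   collapse = ", "))
    if (is.null(phy$edge.length) || anyNA(phy$edge.length))
        stop("every branch must carry a branch length (My)")
    if (!ape::is.rooted(phy) && !allowPolytomy)
        stop("tree must be rooted; basal polytomy rejected ",
             "(set allowPolytomy = TRUE to keep it)")
    zero <- phy$edge.length <= 0
    if (any(zero)) {
        if (is.null(zeroEpsilon))
            stop(sum(zero), " branch(es) with non-positive length; ",
                 "supply zeroEpsilon to substitute a small duration")
        if (zeroEpsilon <= 0) stop("zeroEpsilon must be > 0")
        phy$edge.length[zero] <- zeroEpsilon
    }
    .phyloToTimeTree(phy)
}

#' Convert a TimeTree back to an ape phylo object
#'
#' @param tree a [TimeTree-class].
#' @return an object of class \code{phylo}.
#' @export
asPhylo <- function(tree) {
    stopifnot(is(tree, "TimeTree"))
    n <- nNodes(tree)
    tips <- which(tree@isTip)
    internals <- which(!tree@isTip)
    # ape convention: tips are 1..ntip, root is ntip+1
    apeId <- integer(n)
    apeId[tips] <- seq_along(tips)
    ord <- c(tree@root, setdiff(rev(internals), tree@root))
    apeId[ord] <- length(tips) + seq_along(ord)
    nonroot <- setdiff(seq_len(n), tree@root)
    edge <- cbind(apeId[tree@parent[nonroot]], apeId[nonroot])
    phy <- list(edge = edge, edge.length = tree@brlen[nonroot],
                Nnode = length(internals),
                tip.label = tree@label[tips])
    class(phy) <- "phylo"
    ape::reorder.phylo(phy, "cladewise")
}

#' Write a TimeTree as Newick
#'
#' @param tree a [TimeTree-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeNewick <- function(tree, path) {
    ape::write.tree(asPhylo(tree), file = path)
    invisible(path)
}

#' @describeIn readNewick number of nodes (tips + internal) in the tree.
#' @param tree a [TimeTree-class].
#' @export
nNodes <- function(tree) length(tree@parent)

#' @describeIn readNewick number of tips.
#' @export
nTips <- function(tree) sum(tree@isTip)

#' @describeIn readNewick species labels of the tips, ordered by node ID.
#' @export
tipLabels <- function(tree) tree@label[tree@isTip]

#' @describeIn readNewick integer IDs of the tip nodes.
#' @export
tipIds <- function(tree) which(tree@isTip)

#' @describeIn readNewick the root node ID.
#' @export
rootNode <- function(tree) tree@root

#' @describeIn readNewick named branch durations (My), indexed by child node
#'   ID; the root is excluded.
#' @export
branchDurations <- function(tree) {
    b <- tree@brlen
    names(b) <- as.character(seq_along(b))
    b[-tree@root]
}

#' @describeIn readNewick all branch IDs (every node except the root).
#' @export
branchIds <- function(tree) setdiff(seq_len(nNodes(tree)), tree@root)

#' @describeIn readNewick node labels ordered by node ID.
#' @export
nodeLabels <- function(tree) tree@label

#' Map node labels to node IDs
#'
#' @param tree a [TimeTree-class].
#' @param labels character node labels (species names for tips, internal
#'   labels such as \code{"N9"} otherwise).
#' @return integer node IDs.
#' @export
nodeId <- function(tree, labels) {
    id <- match(labels, tree@label)
    if (anyNA(id))
        stop("unknown node label(s): ",
             paste(labels[is.na(id)], collapse = ", "))
    id
}

#' Most recent common ancestor of a set of nodes
#'
#' @param tree a [TimeTree-class].
#' @param ids integer node IDs (typically tips).
#' @return the MRCA node ID.
#' @export
mrcaNode <- function(tree, ids) {
    stopifnot(length(ids) >= 1)
    path <- function(v) {
        p <- v
        while (tree@parent[v] != 0L) { v <- tree@parent[v]; p <- c(p, v) }
        p
    }
    common <- path(ids[1])
    for (v in ids[-1]) common <- common[common %in% path(v)]
    common[1]
}

#' @describeIn mrcaNode node IDs on the path from \code{id} to the root
#'   (inclusive of both).
#' @param id a single node ID.
#' @export
ancestorPath <- function(tree, id) {
    p <- id
    while (tree@parent[id] != 0L) { id <- tree@parent[id]; p <- c(p, id) }
    p
}

#' @describeIn mrcaNode all node IDs in the subtree of \code{id} (itself
#'   included), in post-order.
#' @export
subtreeNodes <- function(tree, id) {
    out <- integer(0)
    visit <- function(v) {
        for (w in tree@children[[v]]) visit(w)
        out <<- c(out, v)
    }
    visit(id)
    out
}

setMethod("show", "TimeTree", function(object) {
    cat(sprintf("TimeTree: %d tips, %d nodes, depth %.4g My\n",
                nTips(object), nNodes(object), treeDepth(object)))
    tl <- tipLabels(object)
    cat("tips: ", paste(utils::head(tl, 6), collapse = ", "),
        if (length(tl) > 6) ", ..." else "", "\n", sep = "")
})

#' @describeIn readNewick maximum root-to-tip path length (My).
#' @export
treeDepth <- function(tree) {
    depth <- numeric(nNodes(tree))
    for (v in rev(seq_len(nNodes(tree)))) {   # pre-order: parents first
        if (v == tree@root) next
        depth[v] <- depth[tree@parent[v]] + tree@brlen[v]
    }
    max(depth[tree@isTip])
}
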