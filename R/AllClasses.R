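#' @import methods
NULL

#' Time-calibrated species tree
#'
#' A rooted species tree with branch durations in millions of years (My) and
#' deterministic integer node IDs assigned by post-order traversal (every
#' child precedes its parent; the root carries the largest ID).  A branch is
#' identified by its child node, so the root has no branch.
#'
#' @slot parent integer vector, one entry per node; \code{0} at the root.
#' @slot children list of integer vectors of child node IDs (empty for tips).
#' @slot brlen numeric branch duration (My) of the branch leading to each
#'   node; \code{NA} at the root; strictly positive elsewhere.
#' @slot label character node labels; tip labels are the species names and
#'   are unique, internal labels default to \code{"N<id>"}.
#' @slot isTip logical, one entry per node.
#' @slot root integer ID of the root node.
#' @slot tipsBelow list of integer vectors: the tip IDs contained in the
#'   subtree rooted at each node (a tip contains itself).
#'
#' @seealso [readNewick()], [writeNewick()]
#' @export
setClass("TimeTree", representation(
    parent   = "integer",
    children = "list",
    brlen    = "numeric",
    label    = "character",
    isTip    = "logical",
    root     = "integer",
    tipsBelow = "list"
))

setValidity("TimeTree", function(object) {
    n <- length(object@parent)
    msg <- character(0)
    if (length(object@brlen) != n || length(object@label) != n ||
        length(object@isTip) != n || length(object@children) != n)
        msg <- c(msg, "slot lengths disagree")
    if (sum(object@parent == 0L) != 1L)
        msg <- c(msg, "exactly one root (parent == 0) required")
    if (length(object@root) != 1L || object@parent[object@root] != 0L)
        msg <- c(msg, "root slot does not point at the parentless node")
    tl <- object@label[object@isTip]
    if (anyDuplicated(tl))
        msg <- c(msg, "duplicate tip labels")
    bl <- object@brlen[-object@root]
    if (any(!is.finite(bl)) || any(bl <= 0))
        msg <- c(msg, "branch durations must be finite and strictly positive")
    if (length(msg)) msg else TRUE
})

#' Orthogroup-by-species gene count table
#'
#' Non-negative integer counts of gene copies per gene family (orthogroup,
#' rows) and species (columns).  Presence is defined as count > 0.
#'
#' @slot counts integer matrix with unique family IDs as rownames and
#'   species labels as colnames.
#'
#' @seealso [readGeneCounts()], [presenceMatrix()]
#' @export
setClass("FamilyCountTable", representation(counts = "matrix"))

setValidity("FamilyCountTable", function(object) {
    m <- object@counts
    msg <- character(0)
    if (is.null(rownames(m)) || is.null(colnames(m)))
        msg <- c(msg, "counts must carry family rownames and species colnames")
    else if (anyDuplicated(rownames(m)))
        msg <- c(msg, "family IDs must be unique")
    if (!is.numeric(m) || any(!is.finite(m)) || any(m < 0) || any(m != round(m)))
        msg <- c(msg, "counts must be finite non-negative integers")
    if (length(msg)) msg else TRUE
})

#' Protein-level annotation and family membership map
#'
#' Maps protein IDs to their (species, family) membership and to a set of
#' opaque annotation term IDs (e.g. GO or Pfam accessions).
#'
#' @slot members data.frame with columns \code{protein}, \code{species},
#'   \code{family}; each protein appears at most once.
#' @slot terms data.frame with columns \code{protein}, \code{term}.
#' @export
setClass("AnnotationMap", representation(members = "data.frame",
                                         terms = "data.frame"))

setValidity("AnnotationMap", function(object) {
    msg <- character(0)
    if (!all(c("protein", "species", "family") %in% colnames(object@members)))
        msg <- c(msg, "members needs protein/species/family columns")
    else if (anyDuplicated(object@members$protein))
        msg <- c(msg, "a protein may map to at most one family")
    if (!all(c("protein", "term") %in% colnames(object@terms)))
        msg <- c(msg, "terms needs protein/term columns")
    if (length(msg)) msg else TRUE
})

#' Named set of gene families
#'
#' @slot name character set name (e.g. \code{"cancer"}).
#' @slot families character vector of family IDs, duplicates collapsed.
#' @export
setClass("GeneSet", representation(name = "character", families = "character"))

setValidity("GeneSet", function(object) {
    if (anyDuplicated(object@families)) "duplicate family IDs" else TRUE
})

#' Named set of branches of a TimeTree
#'
#' Branches are identified by their child node ID.
#'
#' @slot name character set name (e.g. \code{"giant"}).
#' @slot branches integer vector of child-node IDs, no duplicates, never the
#'   root.
#' @export
setClass("BranchSet", representation(name = "character", branches = "integer"))

setValidity("BranchSet", function(object) {
    if (anyDuplicated(object@branches)) "duplicate branch IDs" else TRUE
})

#' Dollo parsimony reconstruction of family origins and losses
#'
#' Single-origin / multiple-loss mapping of each gene family onto the tree:
#' the origin is the MRCA of the tips possessing the family, a node is
#' present iff it lies in the origin's subtree and at least one tip below it
#' has the family, and losses are the branches whose parent is present but
#' whose child is not (the maximal absent subtrees).  This minimises the
#' number of losses given a single gain.
#'
#' @slot origin named integer vector: origin node ID per family.
#' @slot presence logical matrix, families x nodes.
#' @slot losses list of integer vectors: loss branches (child node IDs) per
#'   family.
#' @slot tree the [TimeTree-class] the reconstruction lives on.
#' @seealso [dolloReconstruct()], [nodeSummaries()]
#' @export
setClass("DolloReconstruction", representation(
    origin = "integer", presence = "matrix", losses = "list",
    tree = "TimeTree"))

setValidity("DolloReconstruction", function(object) {
    n <- length(object@origin)
    if (nrow(object@presence) != n || length(object@losses) != n)
        "per-family slots disagree in length" else TRUE
})

#' Birth-death model of gene-family size
#'
#' The linear birth-death process with equal per-gene birth and death rate
#' \eqn{\lambda} (gains/losses per gene per My).  Each branch belongs to one
#' rate class; the transition kernel over sizes \code{0..sMax} is truncated
#' and row-renormalised, with size 0 absorbing.
#'
#' @slot lambda named numeric rate per class.
#' @slot classMap named character: class of the branch leading to each
#'   non-root node (names are node IDs).
#' @slot sMax integer truncation bound on family size (default 100).
#' @slot rootPrior list describing the root-size prior; default geometric
#'   with \code{p = 0.5} truncated to \code{1..sMax}.
#' @slot conditionMinSpecies integer: the likelihood is conditioned on the
#'   family being non-extinct in at least this many tips (ascertainment
#'   matching the input filter; default 2).
#' @seealso [bdModel()], [fitLambda()]
#' @export
setClass("BDModel", representation(
    lambda = "numeric", classMap = "character", sMax = "integer",
    rootPrior = "list", conditionMinSpecies = "integer"))

setValidity("BDModel", function(object) {
    msg <- character(0)
    if (any(object@lambda < 0) || any(!is.finite(object@lambda)))
        msg <- c(msg, "lambda must be finite and >= 0")
    if (is.null(names(object@lambda)))
        msg <- c(msg, "lambda must be named by class")
    if (!all(object@classMap %in% names(object@lambda)))
        msg <- c(msg, "every branch class must have a lambda")
    if (object@sMax < 1) msg <- c(msg, "sMax must be >= 1")
    if (length(msg)) msg else TRUE
})

#' Maximum-likelihood fit of a birth-death model
#'
#' @slot model the fitted [BDModel-class].
#' @slot logLik total log-likelihood at the optimum.
#' @slot perFamilyLogLik named numeric per-family log-likelihood.
#' @slot convergence logical: TRUE when the optimiser converged and the
#'   multi-start replicates agreed.
#' @slot details list of optimiser diagnostics (starts, spread, evals).
#' @export
setClass("BDFit", representation(
    model = "BDModel", logLik = "numeric", perFamilyLogLik = "numeric",
    convergence = "logical", details = "list"))

#' Per-branch exact shift tests of reconstructed size transitions
#'
#' @slot p numeric matrix families x branches: exact two-sided
#'   (probability-ordering) tail probability of the reconstructed
#'   parent-to-child transition under the fitted kernel.
#' @slot flag logical matrix: \code{p < alpha}.
#' @slot transitionProb numeric matrix: kernel probability of the observed
#'   reconstructed transition.
#' @slot alpha numeric flag threshold (default 0.05).
#' @export
setClass("BranchShiftTable", representation(
    p = "matrix", flag = "matrix", transitionProb = "matrix",
    alpha = "numeric"))
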