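# Cancer-gene x gigantism analyses: shifted-family sets, branch-set
# enrichment with sister-branch control and a random-branch permutation
# null, the random-intercept interaction model, and rate-ratio summaries.

.famShiftedOn <- function(shifts, branches) {
    flag <- shifts@flag[, as.character(branches), drop = FALSE]
    rownames(shifts@flag)[rowSums(flag, na.rm = TRUE) > 0]
}

#' Shifted-family sets relative to branch sets
#'
#' From a [BranchShiftTable-class], collects the families with a flagged
#' shift on at least one branch anywhere (all-shifted), on at least one
#' branch of each supplied set (per-set), and on set branches only
#' (exclusive), plus the mean number of independent shift branches per
#' shifted family.
#'
#' @param shifts a [BranchShiftTable-class].
#' @param sets list of [BranchSet-class] (or a single one).
#' @return list with \code{allShifted}, \code{perSet} (named list),
#'   \code{exclusive} (named list), \code{meanShiftBranches}.
#' @export
shiftedSets <- function(shifts, sets = list()) {
    if (is(sets, "BranchSet")) sets <- list(sets)
    branchPool <- as.integer(colnames(shifts@flag))
    nShift <- rowSums(shifts@flag, na.rm = TRUE)
    allShifted <- rownames(shifts@flag)[nShift > 0]
    perSet <- list(); exclusive <- list()
    for (bs in sets) {
        if (!all(setBranches(bs) %in% branchPool))
            stop("unknown branch in set '", bs@name, "'")
        inSet <- .famShiftedOn(shifts, setBranches(bs))
        outSet <- .famShiftedOn(shifts,
                                setdiff(branchPool, setBranches(bs)))
        perSet[[bs@name]] <- inSet
        exclusive[[bs@name]] <- setdiff(inSet, outSet)
    }
    list(allShifted = allShifted, perSet = perSet, exclusive = exclusive,
         meanShiftBranches = mean(nShift[nShift > 0]))
}

.enrichmentTable <- function(shifts, focalBranches, cancerFams, universe) {
    uni <- switch(universe,
        all_families = rownames(shifts@flag),
        all_shifted = rownames(shifts@flag)[
            rowSums(shifts@flag, na.rm = TRUE) > 0],
        stop("universe must be 'all_families' or 'all_shifted'"))
    if (!length(uni)) stop("empty universe")
    hit <- uni %in% .famShiftedOn(shifts, focalBranches)
    can <- uni %in% cancerFams
    c(a = sum(hit & can), b = sum(hit & !can),
      c = sum(!hit & can), d = sum(!hit & !can))
}

#' Cancer-gene enrichment of families shifted on a branch set
#'
#' Builds the 2x2 table (shifted on a focal branch vs not) x (cancer vs
#' not) over the chosen universe and applies [fisherExact()].  With
#' \code{universe = "all_families"} the comparison is against every family
#' in the shift table; with \code{"all_shifted"} it is against the
#' families that shifted on any branch.
#'
#' @param shifts a [BranchShiftTable-class].
#' @param focal a [BranchSet-class] (or integer branch IDs).
#' @param cancer a [GeneSet-class] or character family IDs.
#' @param universe \code{"all_shifted"} (default) or \code{"all_families"}.
#' @return the [fisherExact()] result, with the universe and set sizes
#'   attached as \code{"universe"}/\code{"nUniverse"} attributes.
#' @export
branchSetEnrichment <- function(shifts, focal, cancer,
                                universe = c("all_shifted",
                                             "all_families")) {
    universe <- match.arg(universe)
    if (is(focal, "BranchSet")) focal <- setBranches(focal)
    if (is(cancer, "GeneSet")) cancer <- setFamilies(cancer)
    tab <- .enrichmentTable(shifts, focal, cancer, universe)
    out <- fisherExact(tab)
    attr(out, "universe") <- universe
    attr(out, "nUniverse") <- sum(tab)
    out
}

#' @describeIn branchSetEnrichment identical contract with the
#'   non-giant sister branch set as the focal set (specificity control).
#' @param sister a [BranchSet-class] of the sister branches.
#' @export
sisterControl <- function(shifts, sister, cancer,
                          universe = c("all_shifted", "all_families")) {
    if (is(sister, "BranchSet") && !length(setBranches(sister)))
        stop("empty sister set")
    if (!is(sister, "BranchSet") && !length(sister))
        stop("empty sister set")
    branchSetEnrichment(shifts, sister, cancer, universe)
}

#' Random-branch permutation null for branch-set enrichment
#'
#' Draws \code{nPerm} sets of \code{k} distinct branches uniformly from
#' all branches of the tree (tips and internals; the root has no branch),
#' recomputes the shifted-family set and its cancer odds ratio on the same
#' universe for each draw, and compares the observed odds ratio to this
#' null: \code{p = #\{null OR >= observed\} / nPerm}.  Degenerate permuted
#' tables contribute OR = 1 and are counted.
#'
#' @param shifts a [BranchShiftTable-class].
#' @param focal the observed [BranchSet-class] (or branch IDs).
#' @param cancer a [GeneSet-class] or character family IDs.
#' @param tree the [TimeTree-class]; restricts the branch pool to the
#'   tree's branches (default NULL: every branch in the shift table).
#' @param k branches per draw (default the focal set size).
#' @param nPerm number of permutations (default 100).
#' @param seed RNG seed.
#' @param universe as in [branchSetEnrichment()].
#' @return list with \code{observedOR}, \code{nullOR} (length
#'   \code{nPerm}), \code{p}, \code{nDegenerate}, \code{k}, \code{nPerm}.
#' @export
permutationNull <- function(shifts, focal, cancer, tree = NULL, k = NULL,
                            nPerm = 100L, seed = 1L,
                            universe = c("all_shifted", "all_families")) {
    universe <- match.arg(universe)
    if (nPerm < 1) stop("nPerm must be >= 1")
    if (is(focal, "BranchSet")) focal <- setBranches(focal)
    if (is(cancer, "GeneSet")) cancer <- setFamilies(cancer)
    if (is.null(k)) k <- length(focal)
    pool <- as.integer(colnames(shifts@flag))
    if (!is.null(tree)) pool <- intersect(pool, branchIds(tree))
    if (k > length(pool)) stop("k exceeds the number of branches")
    sampleOR <- function(branches) {
        tab <- .enrichmentTable(shifts, branches, cancer, universe)
        fe <- fisherExact(tab)
        if (fe$degenerate) NA_real_ else fe$oddsRatio
    }
    observed <- branchSetEnrichment(shifts, focal, cancer, universe)
    nullOR <- .withSeed(seed, vapply(seq_len(nPerm), function(i)
        sampleOR(sample(pool, k)), 0))
    nDegenerate <- sum(is.na(nullOR))
    nullOR[is.na(nullOR)] <- 1
    obsOR <- if (observed$degenerate) 1 else observed$oddsRatio
    list(observedOR = obsOR, nullOR = nullOR,
         p = mean(nullOR >= obsOR), nDegenerate = nDegenerate,
         k = k, nPerm = nPerm)
}

#' Random-intercept interaction model of branch rates
#'
#' Fits \code{rate ~ giant * cancer + (1 | family)} by maximum likelihood
#' (lme4), where \code{giant} marks observations on branches leading to
#' giant taxa and \code{cancer} marks cancer-related families.  Wald tests
#' use a standard-normal reference.  When the fitted random-intercept
#' variance is zero the coefficients coincide with ordinary least squares.
#'
#' @param rates data.frame from [branchRates()] (columns \code{family},
#'   \code{branch}, \code{rate}), typically restricted to shifted
#'   families.
#' @param giant a [BranchSet-class] or integer branch IDs.
#' @param cancer a [GeneSet-class] or character family IDs.
#' @param logTransform model \code{log1p(rate)} instead of the raw rate
#'   (default FALSE).
#' @return list with \code{coefficients} (data.frame: term, estimate, se,
#'   z, p), \code{varFamily}, \code{varResidual}, \code{fit} (the merMod).
#' @export
interactionModel <- function(rates, giant, cancer, logTransform = FALSE) {
    if (is(giant, "BranchSet")) giant <- setBranches(giant)
    if (is(cancer, "GeneSet")) cancer <- setFamilies(cancer)
    df <- data.frame(
        y = if (logTransform) log1p(rates$rate) else rates$rate,
        giant = as.numeric(rates$branch %in% giant),
        cancer = as.numeric(rates$family %in% cancer),
        family = factor(rates$family))
    if (length(unique(df$family)) < 2) stop("need >= 2 families")
    if (length(unique(df$giant)) < 2)
        stop("design is rank deficient: term 'giant' is constant")
    if (length(unique(df$cancer)) < 2)
        stop("design is rank deficient: term 'cancer' is constant")
    fit <- suppressMessages(lme4::lmer(
        y ~ giant * cancer + (1 | family), data = df, REML = FALSE,
        control = lme4::lmerControl(check.conv.singular = "ignore")))
    sm <- summary(fit)$coefficients
    co <- data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                     se = sm[, "Std. Error"], z = sm[, "t value"],
                     p = 2 * stats::pnorm(-abs(sm[, "t value"])),
                     row.names = NULL)
    vc <- as.data.frame(lme4::VarCorr(fit))
    list(coefficients = co,
         varFamily = vc$vcov[vc$grp == "family"],
         varResidual = vc$vcov[vc$grp == "Residual"],
         fit = fit)
}

#' Giant-vs-background rate ratios by cancer stratum
#'
#' For each family stratum (cancer / non-cancer), the ratio of the mean
#' per-(family, branch) rate over giant branches to the mean over all
#' other branches.
#'
#' @param rates data.frame from [branchRates()].
#' @param giant a [BranchSet-class] or integer branch IDs.
#' @param cancer a [GeneSet-class] or character family IDs.
#' @return data.frame with rows \code{cancer} and \code{noncancer}:
#'   \code{meanGiant}, \code{meanOther}, \code{ratio} (Inf flagged when
#'   the background mean is zero).
#' @export
rateRatio <- function(rates, giant, cancer) {
    if (is(giant, "BranchSet")) giant <- setBranches(giant)
    if (is(cancer, "GeneSet")) cancer <- setFamilies(cancer)
    g <- rates$branch %in% giant
    cc <- rates$family %in% cancer
    if (!any(g) || all(g)) stop("need both giant and non-giant branches")
    one <- function(sel) {
        mg <- mean(rates$rate[sel & g])
        mo <- mean(rates$rate[sel & !g])
        data.frame(meanGiant = mg, meanOther = mo,
                   ratio = if (mo == 0) Inf else mg / mo)
    }
    out <- rbind(one(cc), one(!cc))
    rownames(out) <- c("cancer", "noncancer")
    out
}
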