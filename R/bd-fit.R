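# Maximum-likelihood estimation of birth-death rates per branch class, and
# the parametric-bootstrap likelihood-ratio test between nested rate models.

.prepCounts <- function(counts, tree) {
    m <- if (is(counts, "FamilyCountTable")) famCounts(counts) else counts
    idx <- match(tipLabels(tree), colnames(m))
    if (anyNA(idx)) stop("counts lack species present in the tree")
    m[, idx, drop = FALSE]
}

# closure computing the total conditioned log-likelihood for a lambda
# vector, with tip indicators built once
.makeLoglikFn <- function(m, tree, template) {
    sMax <- template@sMax
    priorVec <- .rootPriorVec(template)
    nFam <- nrow(m)
    tips <- tipIds(tree)
    tipL <- vector("list", nNodes(tree))
    for (i in seq_along(tips)) {
        tm <- matrix(0, sMax + 1, nFam)
        tm[cbind(m[, i] + 1L, seq_len(nFam))] <- 1
        tipL[[tips[i]]] <- tm
    }
    function(lambda, perFamily = FALSE) {
        mod <- template
        mod@lambda <- lambda
        mats <- .branchMatrices(tree, mod)
        pr <- .prune(tipL, tree, mats, priorVec)
        ll <- log(pr$lik) + pr$logScale -
            .ascertainmentLogP(tree, mod, mats, priorVec)
        if (perFamily) { names(ll) <- rownames(m); ll } else sum(ll)
    }
}

#' Fit birth-death rates by maximum likelihood
#'
#' Maximises the summed conditioned pruning log-likelihood over one rate
#' per branch class by bounded derivative-free optimisation on the log
#' scale (Brent search for a single class, cyclic coordinate descent with
#' seeded multi-start for several classes).
#'
#' @param counts a [FamilyCountTable-class] (already filtered, see
#'   [filterForBD()]).
#' @param tree a [TimeTree-class].
#' @param classes named character branch-to-class map (names are branch
#'   IDs); \code{NULL} fits a single global rate.
#' @param sMax,rootPrior,conditionMinSpecies see [bdModel()].
#' @param nStarts number of random optimiser starts for multi-class fits
#'   (default 5).
#' @param seed seed for the start draws.
#' @param lower,upper box bounds on each rate (per gene per My).
#' @param tol optimiser tolerance on the log-rate scale (default 1e-6).
#' @return a [BDFit-class].
#' @export
fitLambda <- function(counts, tree, classes = NULL, sMax = 100L,
                      rootPrior = list(type = "geometric", p = 0.5),
                      conditionMinSpecies = 2L, nStarts = 5L, seed = 1L,
                      lower = 1e-7, upper = 1, tol = 1e-6) {
    m <- .prepCounts(counts, tree)
    if (!nrow(m)) stop("no families to fit")
    cls <- if (is.null(classes)) "all" else unique(unname(classes))
    template <- bdModel(tree, stats::setNames(rep(1e-3, length(cls)), cls),
                        classes = classes, sMax = sMax,
                        rootPrior = rootPrior,
                        conditionMinSpecies = conditionMinSpecies)
    fn <- .makeLoglikFn(m, tree, template)
    k <- length(cls)
    mkLambda <- function(loglam) stats::setNames(exp(loglam), cls)

    negll <- function(x) -fn(mkLambda(x))
    if (k == 1L) {
        opt <- stats::optimize(negll, interval = log(c(lower, upper)),
                               tol = tol)
        best <- list(par = opt$minimum, value = opt$objective,
                     convergence = 0L)
        spread <- 0
        nUsed <- 1L
    } else {
        # cyclic coordinate descent: each coordinate solved by bounded
        # golden-section search; deterministic given the seeded starts
        descend <- function(x0) {
            x <- x0
            val <- negll(x)
            for (sweep in 1:12) {
                old <- val
                for (d in seq_len(k)) {
                    o <- stats::optimize(function(z) {
                        x2 <- x; x2[d] <- z; negll(x2)
                    }, interval = log(c(lower, upper)), tol = tol)
                    if (o$objective < val) { x[d] <- o$minimum
                                             val <- o$objective }
                }
                if (old - val < max(1e-8, tol / 10)) break
            }
            list(par = x, value = val, convergence = 0L)
        }
        starts <- .withSeed(seed, replicate(max(nStarts - 1L, 0L),
            stats::runif(k, log(lower * 10), log(upper / 10)),
            simplify = FALSE))
        starts <- c(list(rep(log(1e-3), k)), starts)
        fits <- lapply(starts, descend)
        vals <- vapply(fits, `[[`, 0, "value")
        best <- fits[[which.min(vals)]]
        spread <- max(vals) - min(vals)
        nUsed <- length(starts)
    }
    lambda <- mkLambda(best$par)
    perFam <- fn(lambda, perFamily = TRUE)
    model <- template
    model@lambda <- lambda
    methods::new("BDFit", model = model, logLik = sum(perFam),
                 perFamilyLogLik = perFam,
                 convergence = best$convergence == 0L,
                 details = list(nStarts = nUsed, startSpread = spread,
                                optim = best[c("par", "value",
                                               "convergence")]))
}

setMethod("show", "BDFit", function(object) {
    cat(sprintf("BDFit: logLik = %.4f over %d families%s\n", object@logLik,
                length(object@perFamilyLogLik),
                if (object@convergence) "" else "  [NOT CONVERGED]"))
    for (cl in names(object@model@lambda))
        cat(sprintf("  lambda[%s] = %.6g\n", cl, object@model@lambda[cl]))
})

#' @describeIn fitLambda fitted rates of a [BDFit-class].
#' @param fit a [BDFit-class].
#' @export
fittedLambda <- function(fit) fit@model@lambda

#' Parametric-bootstrap likelihood-ratio test between nested rate models
#'
#' Fits the null and alternative branch-class models to the observed
#' counts, then simulates \code{nReps} datasets of equal family count from
#' the fitted null model (same generative kernel, same ascertainment),
#' refits both models to each replicate, and compares the observed
#' \code{2 (lnL_alt - lnL_null)} to the simulated null distribution:
#' \code{p = #\{null >= observed\} / nReps}.  An observed statistic larger
#' than every replicate is reported as \code{p = 0} with attribute
#' \code{"pLessThan" = 1/nReps}.
#'
#' @param counts a filtered [FamilyCountTable-class].
#' @param tree a [TimeTree-class].
#' @param nullClasses branch-class map of the null model (NULL = one rate).
#' @param altClasses branch-class map of the alternative model; the null
#'   must be nested in it.
#' @param nReps number of bootstrap replicates (default 500).
#' @param seed RNG seed for the replicate simulations and refits.
#' @param nStarts optimiser starts per refit (default 1; the observed-data
#'   fits use \code{nStartsObserved}).
#' @param nStartsObserved optimiser starts for the observed fits.
#' @param sMax,rootPrior,conditionMinSpecies see [bdModel()].
#' @param lower,upper rate bounds passed to [fitLambda()].
#' @param tol optimiser tolerance for the replicate refits (default 1e-4;
#'   the observed-data fits use a tenfold tighter tolerance).
#' @return list with \code{observed} (2 delta lnL), \code{null} (numeric
#'   vector of replicate statistics), \code{p}, \code{nDropped},
#'   \code{nullFit}, \code{altFit}.
#' @export
lrtBootstrap <- function(counts, tree, nullClasses = NULL, altClasses,
                         nReps = 500L, seed = 1L, nStarts = 1L,
                         nStartsObserved = 5L, sMax = 100L,
                         rootPrior = list(type = "geometric", p = 0.5),
                         conditionMinSpecies = 2L, lower = 1e-7,
                         upper = 1, tol = 1e-4) {
    if (nReps < 1) stop("nReps must be >= 1")
    fit0 <- fitLambda(counts, tree, classes = nullClasses, sMax = sMax,
                      rootPrior = rootPrior,
                      conditionMinSpecies = conditionMinSpecies,
                      nStarts = nStartsObserved, seed = seed,
                      lower = lower, upper = upper, tol = tol / 10)
    fit1 <- fitLambda(counts, tree, classes = altClasses, sMax = sMax,
                      rootPrior = rootPrior,
                      conditionMinSpecies = conditionMinSpecies,
                      nStarts = nStartsObserved, seed = seed,
                      lower = lower, upper = upper, tol = tol / 10)
    observed <- 2 * (fit1@logLik - fit0@logLik)
    nFam <- nrow(.prepCounts(counts, tree))

    stats <- rep(NA_real_, nReps)
    .withSeed(seed, {
        for (r in seq_len(nReps)) {
            sim <- .simulateFromModel(tree, fit0@model, nFam)
            f0 <- fitLambda(sim, tree, classes = nullClasses, sMax = sMax,
                            rootPrior = rootPrior,
                            conditionMinSpecies = conditionMinSpecies,
                            nStarts = nStarts, seed = seed + r,
                            lower = lower, upper = upper, tol = tol)
            f1 <- fitLambda(sim, tree, classes = altClasses, sMax = sMax,
                            rootPrior = rootPrior,
                            conditionMinSpecies = conditionMinSpecies,
                            nStarts = nStarts, seed = seed + r,
                            lower = lower, upper = upper, tol = tol)
            if (f0@convergence && f1@convergence)
                stats[r] <- 2 * (f1@logLik - f0@logLik)
        }
    })
    nDropped <- sum(is.na(stats))
    stats <- stats[!is.na(stats)]
    if (!length(stats)) stop("no bootstrap replicate converged")
    p <- mean(stats >= observed - 1e-9)
    out <- list(observed = observed, null = stats, p = p,
                nDropped = nDropped, nullFit = fit0, altFit = fit1)
    if (p == 0) attr(out, "pLessThan") <- 1 / length(stats)
    out
}
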