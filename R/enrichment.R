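# Representative family annotation (75%/75% rule), two-sided exact 2x2
# tests, Benjamini-Hochberg correction, and term enrichment of family sets.

#' Representative annotation of gene families
#'
#' A term is assigned to a family iff at least \code{proteinFrac} of the
#' family's proteins carry the term AND at least \code{taxonFrac} of the
#' taxa in the family have at least one protein carrying it (both
#' thresholds inclusive; defaults 0.75/0.75).  With
#' \code{inferSingletons}, proteins without a family become single-protein
#' families inheriting their own terms.
#'
#' @param ann an [AnnotationMap-class]; unclustered proteins may carry an
#'   \code{NA} family.
#' @param proteinFrac minimum fraction of proteins with the term.
#' @param taxonFrac minimum fraction of taxa with >= 1 annotated protein.
#' @param inferSingletons treat unclustered proteins as singleton families.
#' @return named list: family ID -> character vector of representative
#'   terms (families with no surviving term are absent).
#' @export
assignFamilyAnnotations <- function(ann, proteinFrac = 0.75,
                                    taxonFrac = 0.75,
                                    inferSingletons = FALSE) {
    mem <- ann@members
    if (inferSingletons) {
        un <- is.na(mem$family)
        mem$family[un] <- mem$protein[un]
    } else {
        mem <- mem[!is.na(mem$family), , drop = FALSE]
    }
    if (!nrow(mem)) return(stats::setNames(list(), character(0)))
    famSize <- table(mem$family)
    famTaxa <- tapply(mem$species, mem$family,
                      function(x) length(unique(x)))

    tt <- merge(unique(ann@terms), mem, by = "protein")
    if (!nrow(tt)) return(stats::setNames(list(), character(0)))
    key <- paste(tt$family, tt$term, sep = "\r")
    nProt <- tapply(tt$protein, key, function(x) length(unique(x)))
    nTaxa <- tapply(tt$species, key, function(x) length(unique(x)))
    parts <- strsplit(names(nProt), "\r", fixed = TRUE)
    fam <- vapply(parts, `[`, "", 1L)
    term <- vapply(parts, `[`, "", 2L)
    keep <- nProt / as.numeric(famSize[fam]) >= proteinFrac &
            nTaxa / as.numeric(famTaxa[fam]) >= taxonFrac
    split(term[keep], fam[keep])
}

# two-sided p-values (probability-ordering rule) for every possible count
# a in a 2x2 table with margins (m = a+b, n = c+d, k = a+c): the standard
# exact-test convention of summing hypergeometric point probabilities not
# exceeding that of the observed table.
.fisherRowP <- function(m, n, k) {
    lo <- max(0L, k - n)
    hi <- min(k, m)
    x <- lo:hi
    d <- stats::dhyper(x, m, n, k)
    relErr <- 1 + 1e-7
    p <- vapply(d, function(d0) sum(d[d <= d0 * relErr]), 0)
    p <- pmin(p, 1)
    names(p) <- as.character(x)
    p
}

#' Two-sided Fisher exact test of a 2x2 table
#'
#' The p-value sums hypergeometric point probabilities not exceeding that
#' of the observed table (the probability-ordering rule).  The reported
#' odds ratio is the sample odds ratio \code{(a d)/(b c)}, with a 0.5
#' continuity correction applied to every cell when any cell is zero; a
#' degenerate margin yields \code{p = 1} and an undefined-flagged odds
#' ratio.
#'
#' @param tab a 2x2 matrix, or a length-4 vector \code{c(a, b, c, d)} read
#'   row-wise (rows: in-set/out-set; columns: has-/lacks-property).
#' @return list with \code{table}, \code{oddsRatio}, \code{p},
#'   \code{continuity} (logical), \code{degenerate} (logical).
#' @examples
#' fisherExact(c(10, 20, 30, 40))
#' @export
fisherExact <- function(tab) {
    if (is.matrix(tab)) tab <- as.vector(t(tab))
    stopifnot(length(tab) == 4, all(tab >= 0), all(tab == round(tab)))
    a <- tab[1]; b <- tab[2]; c <- tab[3]; d <- tab[4]
    if (a + b + c + d == 0) stop("empty contingency table")
    degenerate <- (a + b == 0) || (c + d == 0) || (a + c == 0) || (b + d == 0)
    continuity <- any(tab == 0)
    oddsRatio <- if (degenerate) NA_real_
        else if (continuity) ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
        else (a * d) / (b * c)
    p <- if (degenerate) 1 else {
        pv <- .fisherRowP(a + b, c + d, a + c)
        unname(pv[as.character(a)])
    }
    list(table = matrix(tab, 2, 2, byrow = TRUE,
                        dimnames = list(c("in", "out"), c("has", "lacks"))),
         oddsRatio = oddsRatio, p = p,
         continuity = continuity, degenerate = degenerate)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return q-values in the input order:
#'   \code{q_(i) = min_(j >= i) min(1, p_(j) m / j)}.
#' @export
bhAdjust <- function(p) {
    if (any(p < 0 | p > 1, na.rm = TRUE) || anyNA(p))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Term enrichment of a family set against a background universe
#'
#' One 2x2 table per annotation term (in-target x has-term, over the
#' background universe), tested with [fisherExact()] and BH-adjusted
#' within this comparison.  The universe is whatever the caller supplies:
#' all families, or only annotated families.
#'
#' @param target a [GeneSet-class] or character vector of family IDs; must
#'   be a subset of \code{background}.
#' @param background character vector: the family universe.
#' @param famAnn named list family -> terms, from
#'   [assignFamilyAnnotations()].
#' @param alpha flag threshold on the adjusted p (default 0.05).
#' @return data.frame with one row per term: \code{term}, \code{a},
#'   \code{b}, \code{c}, \code{d}, \code{oddsRatio}, \code{p}, \code{q},
#'   \code{flagged}, sorted by \code{q}.
#' @export
termEnrichment <- function(target, background, famAnn, alpha = 0.05) {
    if (is(target, "GeneSet")) target <- setFamilies(target)
    if (!length(target)) stop("empty target set")
    if (!all(target %in% background))
        stop("target must be a subset of the background universe")
    famAnn <- famAnn[names(famAnn) %in% background]
    terms <- sort(unique(unlist(famAnn, use.names = FALSE)))
    if (!length(terms))
        return(data.frame(term = character(0), a = integer(0),
                          b = integer(0), c = integer(0), d = integer(0),
                          oddsRatio = numeric(0), p = numeric(0),
                          q = numeric(0), flagged = logical(0)))
    inTarget <- background %in% target
    hasTerm <- matrix(FALSE, length(background), length(terms),
                      dimnames = list(background, terms))
    for (f in names(famAnn)) hasTerm[f, famAnn[[f]]] <- TRUE

    res <- lapply(terms, function(tm) {
        ht <- hasTerm[, tm]
        a <- sum(inTarget & ht); b <- sum(inTarget & !ht)
        c <- sum(!inTarget & ht); d <- sum(!inTarget & !ht)
        fe <- fisherExact(c(a, b, c, d))
        data.frame(term = tm, a = a, b = b, c = c, d = d,
                   oddsRatio = fe$oddsRatio, p = fe$p)
    })
    out <- do.call(rbind, res)
    out$q <- bhAdjust(out$p)
    out$flagged <- out$q <= alpha
    out[order(out$q, out$p), , drop = FALSE]
}
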