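# Transition kernel of the linear birth-death process with equal per-gene
# birth and death rate lambda.  With alpha = lambda*t / (1 + lambda*t),
#
#   P(c | s) = sum_{j=0}^{min(s,c)} C(s,j) C(s+c-j-1, s-1)
#              alpha^(s+c-2j) (1-2*alpha)^j          for s >= 1,
#   P(c | 0) = 1{c = 0}                              (extinction absorbs).
#
# Terms are evaluated in log space; when 1 - 2*alpha < 0 the j-terms
# alternate in sign and a signed log-sum is used.

.bdAlpha <- function(lambda, t) {
    lt <- lambda * t
    lt / (1 + lt)
}

# probabilities P(c | s) for c = 0..cmax, exact (untruncated) formula
.kernelRow <- function(s, alpha, cmax) {
    cs <- 0:cmax
    if (s == 0) {
        out <- numeric(cmax + 1)
        out[1] <- 1
        return(out)
    }
    if (alpha == 0) {
        out <- numeric(cmax + 1)
        if (s <= cmax) out[s + 1] <- 1
        return(out)
    }
    one2a <- 1 - 2 * alpha
    js <- 0:s
    logA <- outer(cs, js, function(c, j)
        lchoose(s, j) + lchoose(s + c - j - 1, s - 1) +
        (s + c - 2 * j) * log(alpha))
    logA[outer(cs, js, function(c, j) j > pmin(s, c))] <- -Inf
    if (one2a > 0) {
        logA <- logA + rep(js * log(one2a), each = length(cs))
        mx <- apply(logA, 1L, max)
        mx[!is.finite(mx)] <- 0
        out <- rowSums(exp(logA - mx)) * exp(mx)
    } else if (one2a == 0) {
        out <- exp(logA[, 1L])
    } else {
        logA <- logA + rep(js * log(-one2a), each = length(cs))
        sgn <- rep((-1)^js, each = length(cs))
        dim(sgn) <- dim(logA)
        mx <- apply(logA, 1L, max)
        mx[!is.finite(mx)] <- 0
        out <- rowSums(sgn * exp(logA - mx)) * exp(mx)
    }
    pmax(out, 0)
}

#' Birth-death size transition probability
#'
#' Probability that a family of \code{s} gene copies in the parent has
#' \code{c} copies in the child after a branch of duration \code{t} under
#' the equal-rate linear birth-death process with rate \code{lambda}
#' (gains/losses per gene per My).  Size 0 is absorbing.
#'
#' @param s parent size (integer >= 0).
#' @param c child size (integer >= 0), may be a vector.
#' @param lambda birth-death rate (per gene per My), >= 0.
#' @param t branch duration (My), >= 0.
#' @return numeric probability (vectorised over \code{c}).
#' @examples
#' transitionProb(1, 0, lambda = 0.01, t = 10)  # = alpha
#' @export
transitionProb <- function(s, c, lambda, t) {
    stopifnot(s >= 0, all(c >= 0), lambda >= 0, t >= 0)
    alpha <- .bdAlpha(lambda, t)
    row <- .kernelRow(s, alpha, max(c))
    row[c + 1]
}

.kernelCache <- new.env(parent = emptyenv())

# Precomputed (s, c, j) summation index for building a full truncated
# kernel matrix in one vectorised pass; cached per sMax.
.kernelIndex <- function(sMax) {
    key <- as.character(sMax)
    hit <- .kernelCache[[paste0("idx|", key)]]
    if (!is.null(hit)) return(hit)
    Sl <- Cl <- Jl <- vector("list", sMax + 1)
    for (j in 0:sMax) {
        r <- j:sMax
        Sl[[j + 1]] <- rep(r, each = length(r))
        Cl[[j + 1]] <- rep(r, times = length(r))
        Jl[[j + 1]] <- rep.int(j, length(r)^2)
    }
    S <- unlist(Sl); C <- unlist(Cl); J <- unlist(Jl)
    keep <- S >= 1
    S <- S[keep]; C <- C[keep]; J <- J[keep]
    idx <- list(
        J = J,
        E = S + C - 2 * J,
        lch = lchoose(S, J) + lchoose(S + C - J - 1, S - 1),
        G = (S - 1) * (sMax + 1) + C + 1)
    .kernelCache[[paste0("idx|", key)]] <- idx
    idx
}

.kernelMatrix <- function(alpha, sMax) {
    P <- matrix(0, sMax + 1, sMax + 1)
    P[1, 1] <- 1
    if (alpha == 0) {
        diag(P) <- 1
        return(P)
    }
    idx <- .kernelIndex(sMax)
    la <- log(alpha)
    one2a <- 1 - 2 * alpha
    terms <- if (one2a > 0) {
        exp(idx$lch + idx$E * la + idx$J * log(one2a))
    } else if (one2a == 0) {
        ifelse(idx$J == 0, exp(idx$lch + idx$E * la), 0)
    } else {
        (-1)^idx$J * exp(idx$lch + idx$E * la + idx$J * log(-one2a))
    }
    v <- rowsum(terms, idx$G)       # groups are contiguous and complete
    P[-1, ] <- matrix(pmax(v, 0), sMax, sMax + 1, byrow = TRUE)
    P
}

#' Truncated, row-renormalised transition matrix
#'
#' Kernel over sizes \code{0..sMax}; each row is renormalised to sum to 1
#' after truncation and the pre-renormalisation deficit is attached as
#' attribute \code{"deficit"} for monitoring.
#'
#' @param lambda birth-death rate (per gene per My).
#' @param t branch duration (My).
#' @param sMax truncation bound.
#' @param renormalize renormalise rows after truncation (default TRUE).
#' @return an \code{(sMax+1) x (sMax+1)} matrix, rows = parent size,
#'   columns = child size (both 0-based).
#' @export
transitionMatrix <- function(lambda, t, sMax, renormalize = TRUE) {
    key <- sprintf("%.17g|%.17g|%d|%d", lambda, t, sMax, renormalize)
    hit <- .kernelCache[[key]]
    if (!is.null(hit)) return(hit)
    alpha <- .bdAlpha(lambda, t)
    P <- .kernelMatrix(alpha, sMax)
    deficit <- 1 - rowSums(P)
    if (renormalize) P <- P / rowSums(P)
    attr(P, "deficit") <- deficit
    if (length(ls(.kernelCache)) > 512)
        rm(list = ls(.kernelCache), envir = .kernelCache)
    .kernelCache[[key]] <- P
    P
}

# two-sided tail probabilities (probability-ordering rule) for every child
# state of one kernel row
.rowTailP <- function(row) {
    relErr <- 1 + 1e-7
    srt <- sort(row)
    cs <- cumsum(srt)
    # each state gets the cumulative mass of all states whose probability
    # is <= its own (within relative tolerance, so ties share the mass)
    idx <- vapply(row, function(x) sum(srt <= x * relErr), 0L)
    out <- ifelse(idx == 0L, 0, cs[pmax(idx, 1L)])
    pmin(out, 1)
}
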