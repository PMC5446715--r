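# Iteratively reweighted SVA with an explicit convergence criterion.
#
# Iteration state is the probe-weight vector; each pass (i) scores every
# probe for association with the current SVs (p_gamma) and with the primary
# variable given the SVs (p_b) via QR-accelerated nested F-tests, (ii) maps
# both p-value vectors through the empirical-Bayes lfdr, (iii) rebuilds the
# weights w = p_gamma * (1 - p_b^alpha), and (iv) takes the top K right
# singular vectors of the reweighted, row-centered data matrix. For p >> n
# the SVD is obtained from the n x n cross-product, so each pass is O(n p)
# plus an O(n^3) eigendecomposition.

.fixSigns <- function(V) {
    for (j in seq_len(ncol(V))) {
        i <- which.max(abs(V[, j]))
        if (V[i, j] < 0) V[, j] <- -V[, j]
    }
    V
}

.topRightSingular <- function(X, K) {
    # right singular vectors of X (probes x samples) via the sample
    # cross-product; X is assumed row-centered by the caller
    ev <- eigen(crossprod(X), symmetric = TRUE)
    .fixSigns(ev$vectors[, seq_len(K), drop = FALSE])
}

.spearman <- function(a, b) {
    ra <- rank(a); rb <- rank(b)
    if (sd(ra) == 0 || sd(rb) == 0)
        return(as.numeric(isTRUE(all.equal(a, b))))
    cor(ra, rb)
}

#' Estimate surrogate variables by iteratively reweighted SVD
#'
#' Estimates K surrogate variables (SVs) capturing unmodeled structure --
#' cell-mixture composition, batches -- in a methylation matrix, for use as
#' adjustment covariates in per-CpG association tests. Two modes are
#' provided: \code{"smart"} iterates until the Spearman correlation between
#' consecutive probe-weight vectors exceeds \code{corrThreshold} (softening
#' the primary-variable probabilities with the power transform
#' \code{p_b^alpha}), while \code{"classic"} reproduces traditional SVA:
#' exactly \code{B} reweighting passes with \code{alpha = 1} and no
#' convergence check.
#'
#' @param Y a \linkS4class{MethylationSet} (M-values are used) or a numeric
#'   probes x samples matrix of M-values.
#' @param design a \linkS4class{DesignPair}, or a vector/matrix giving the
#'   primary variable (a design with an intercept-only null model is then
#'   built via \code{\link{designPair}}).
#' @param K number of surrogate variables; when \code{NULL} it is estimated
#'   by \code{\link{estimateComponentsRMT}} on the full-model residuals.
#'   Must satisfy \code{1 <= K <= n - k_full - 1}.
#' @param alpha power-transform exponent in (0, 1] applied to the
#'   primary-variable probabilities; 0.25 balances convergence speed against
#'   staying clear of the PCA-like local optima reached for very small
#'   alpha. Forced to 1 in classic mode.
#' @param mode \code{"smart"} (converge on the weights) or \code{"classic"}
#'   (fixed iteration count).
#' @param B iteration count for classic mode (the traditional default is 5).
#' @param corrThreshold Spearman correlation between consecutive weight
#'   vectors above which the smart iteration stops.
#' @param maxIter iteration cap for smart mode; hitting it yields a warning
#'   and \code{converged = FALSE}, not an error, so non-converged states can
#'   be inspected.
#' @param soften \code{"always"} applies \code{p_b^alpha} in every
#'   iteration; \code{"first"} only in the first pass (alpha = 1 after).
#' @return An \linkS4class{SVAFit}.
#' @examples
#' set.seed(7)
#' n <- 30; p <- 400
#' g <- rnorm(n)                                # hidden factor
#' Y <- matrix(rnorm(p * n, sd = 0.5), p, n)
#' Y[1:120, ] <- Y[1:120, ] + outer(rnorm(120), g)
#' fit <- smartSVA(Y, rbinom(n, 1, 0.5), K = 1)
#' abs(cor(surrogates(fit)[, 1], g))
#' @export
smartSVA <- function(Y, design, K = NULL, alpha = 0.25,
                     mode = c("smart", "classic"), B = 5L,
                     corrThreshold = 0.999, maxIter = 100L,
                     soften = c("always", "first")) {
    mode <- match.arg(mode)
    soften <- match.arg(soften)
    if (is(Y, "MethylationSet")) Y <- mValues(Y)
    Y <- as.matrix(Y)
    if (!is(design, "DesignPair")) design <- designPair(design)
    n <- ncol(Y)
    if (nrow(design@full) != n)
        stop("design rows must match the sample count")
    kFull <- ncol(design@full)
    if (n < kFull + 2L)
        stop("need at least k_full + 2 samples")
    if (mode == "classic") alpha <- 1
    qFull <- .orthoBasis(design@full)
    qNull <- .orthoBasis(design@null)
    if (is.null(K)) {
        K <- max(1L, estimateComponentsRMT(Y, design@full))
    }
    K <- as.integer(K)
    if (K < 1L || K > n - kFull - 1L)
        stop(sprintf("K must lie in [1, %d] (n - k_full - 1), got %d",
                     n - kFull - 1L, K))

    # initialization: SVD of the full-model residuals
    Yr <- Y - (Y %*% qFull) %*% t(qFull)
    sv <- .topRightSingular(Yr - rowMeans(Yr), K)
    Yc <- Y - rowMeans(Y)

    nIterTarget <- if (mode == "classic") as.integer(B) else as.integer(maxIter)
    if (nIterTarget < 1L) stop("iteration count must be >= 1")
    wPrev <- NULL
    corrHist <- numeric(0)
    converged <- FALSE
    it <- 0L
    w <- rep(1, nrow(Y))
    while (it < nIterTarget) {
        it <- it + 1L
        qBig <- .orthoBasis(cbind(design@full, sv))
        qNullSv <- .orthoBasis(cbind(design@null, sv))
        # [full, SV] spans [null, SV, primary]: one big basis serves both tests
        fGamma <- probeFPvalues(Y, qBig, qFull)
        fB <- probeFPvalues(Y, qBig, qNullSv)
        degen <- fGamma$degenerate | fB$degenerate
        ok <- !degen
        pGamma <- numeric(nrow(Y))
        pB <- rep(1, nrow(Y))
        pGamma[ok] <- 1 - empiricalBayesLfdr(fGamma$pvalue[ok])
        pB[ok] <- 1 - empiricalBayesLfdr(fB$pvalue[ok])
        a <- if (soften == "first" && it > 1L) 1 else alpha
        w <- computeWeights(pGamma, pB, a)
        w[degen] <- 0
        if (!is.null(wPrev)) {
            rho <- .spearman(wPrev, w)
            corrHist <- c(corrHist, rho)
            if (mode == "smart" && !is.na(rho) && rho > corrThreshold) {
                sv <- .topRightSingular(w * Yc, K)
                converged <- TRUE
                break
            }
        }
        sv <- .topRightSingular(w * Yc, K)
        wPrev <- w
    }
    if (mode == "smart" && !converged)
        warning(sprintf(
            "reweighted SVA did not converge in %d iterations (last weight correlation %.4f)",
            it, if (length(corrHist)) corrHist[length(corrHist)] else NA_real_))
    new("SVAFit", sv = sv, weights = as.numeric(w), nIter = it,
        converged = converged, weightCorr = corrHist,
        alpha = as.numeric(alpha), K = K, mode = mode)
}

#' Accessors for SVAFit
#'
#' @param x an \linkS4class{SVAFit}.
#' @return \code{surrogates}: the samples x K matrix of surrogate variables;
#'   \code{probeWeights}: the final per-probe weight vector.
#' @export
surrogates <- function(x) {
    stopifnot(is(x, "SVAFit"))
    x@sv
}

#' @rdname surrogates
#' @export
probeWeights <- function(x) {
    stopifnot(is(x, "SVAFit"))
    x@weights
}

setMethod("show", "SVAFit", function(object) {
    cat(sprintf("SVAFit [%s]: %d surrogate variables, %d samples\n",
        object@mode, object@K, nrow(object@sv)))
    cat(sprintf("  iterations: %d, converged: %s, alpha: %g\n",
        object@nIter, object@converged, object@alpha))
    if (length(object@weightCorr))
        cat(sprintf("  last weight rank-correlation: %.6f\n",
            object@weightCorr[length(object@weightCorr)]))
})
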