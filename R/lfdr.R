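#' Empirical-Bayes local false discovery rate from p-values
#'
#' Estimates, for each test, the posterior probability of being null given
#' its p-value, using the standard probit-scale density construction:
#' transform \code{z = qnorm(p)}, estimate the marginal density f(z) by
#' Gaussian kernel density estimation, estimate the null proportion pi0 by
#' the fraction of p-values above 0.8 divided by 0.2 (capped at 1), and set
#' \code{lfdr = pi0 * dnorm(z) / f(z)}, clipped to [0, 1]. A final
#' running-maximum pass in order of increasing p enforces that the lfdr is
#' nondecreasing in the p-value.
#'
#' Inside the reweighted SVA iteration the caller maps these to probe
#' probabilities as \code{p_gamma = 1 - lfdr(p)} (probability of being
#' affected by unmodeled factors) and \code{p_b = 1 - lfdr(p)} (probability
#' of being affected by the primary variable given the current surrogate
#' variables).
#'
#' @param pvals numeric vector of p-values in (0, 1]; at least 20 values are
#'   required for the density estimate to be meaningful. Exact zeros are
#'   floored at the smallest positive double before the probit transform.
#' @param adjust bandwidth multiplier passed to \code{\link[stats]{density}};
#'   the default oversmooths slightly, which stabilises the tails.
#' @return Numeric vector of local FDR values in [0, 1], with attribute
#'   \code{"pi0"} carrying the estimated null proportion.
#' @examples
#' set.seed(1)
#' l <- empiricalBayesLfdr(runif(2000))
#' mean(l)            # ~ 1: everything looks null
#' attr(l, "pi0")
#' @export
empiricalBayesLfdr <- function(pvals, adjust = 1.5) {
    if (length(pvals) < 20L)
        stop("at least 20 p-values are required for lfdr estimation")
    if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1))
        stop("p-values must lie in (0, 1]")
    p <- pmax(pvals, .Machine$double.xmin)
    pi0 <- min(1, mean(p > 0.8) / 0.2)
    z <- qnorm(p)
    dens <- density(z, adjust = adjust, n = 512)
    fz <- approx(dens$x, dens$y, xout = z, rule = 2)$y
    lfdr <- pi0 * dnorm(z) / fz
    lfdr[lfdr > 1] <- 1
    lfdr[lfdr < 0] <- 0
    o <- order(p)
    lfdr[o] <- cummax(lfdr[o])
    lfdr[lfdr > 1] <- 1
    attr(lfdr, "pi0") <- pi0
    lfdr
}

#' Probe weights from null/alternative probabilities
#'
#' The weight of probe j is \code{w_j = p_gamma_j * (1 - p_b_j^alpha)}:
#' probes likely driven by unmodeled factors but not by the primary
#' variable receive high weight in the next weighted SVD. \code{alpha = 1}
#' gives the classic SVA weight \code{p_gamma * (1 - p_b)}; smaller alpha
#' softens an unreliable early estimate of \code{p_b} (the recommended
#' default in the fitting routine is 0.25).
#'
#' @param pGamma numeric in [0,1], probability each probe is affected by
#'   unmodeled factors.
#' @param pB numeric in [0,1], probability each probe is affected by the
#'   primary variable conditional on the current surrogate variables.
#' @param alpha power-transform exponent in (0, 1].
#' @return Numeric weight vector in [0, 1].
#' @examples
#' computeWeights(0.5, 0.5, 1)       # 0.25
#' computeWeights(0.5, 0.0625, 0.25) # 0.25
#' @export
computeWeights <- function(pGamma, pB, alpha = 1) {
    if (length(alpha) != 1L || !is.finite(alpha) || alpha <= 0 || alpha > 1)
        stop("alpha must lie in (0, 1]")
    if (any(pGamma < 0 | pGamma > 1) || any(pB < 0 | pB > 1))
        stop("probabilities must lie in [0, 1]")
    w <- pGamma * (1 - pB^alpha)
    pmin(pmax(w, 0), 1)
}
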