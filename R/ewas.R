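# Per-CpG association testing and the evaluation metrics used to score
# adjustment methods on simulated data.

#' Per-CpG linear-model association tests
#'
#' Ordinary least squares of each probe's M-values on
#' \code{[intercept, adjustment, phenotype]}, with a two-sided t-test on the
#' phenotype coefficient. All probes are fit through a single QR
#' decomposition of the design, so the cost is linear in the probe count.
#' Benjamini--Hochberg and Bonferroni decisions at \code{level} are
#' attached.
#'
#' @param Y a \linkS4class{MethylationSet} (M-values are used) or numeric
#'   probes x samples M-value matrix.
#' @param phenotype numeric length-n primary variable (e.g. 0/1 group).
#' @param adjust optional n x K numeric matrix of adjustment covariates
#'   (surrogate variables, principal components, true proportions + batch
#'   indicators, ...). \code{NULL} fits the unadjusted model.
#' @param method character label stored on the result.
#' @param level nominal error level for both multiple-testing procedures.
#' @return An \linkS4class{EwasFit}.
#' @details Probes with zero residual variance under the full model are
#'   flagged \code{degenerate} and given p = 1. A jointly rank-deficient
#'   design is an error naming the collinear columns.
#' @examples
#' sim <- simulateMethylation(simConfig(p = 200, n = 30, seed = 1))
#' ew <- fitEwas(sim, truth(sim)@phenotype)
#' sum(ew@rejectFDR)
#' @export
fitEwas <- function(Y, phenotype, adjust = NULL, method = "unadjusted",
                    level = 0.05) {
    if (is(Y, "MethylationSet")) Y <- mValues(Y)
    Y <- as.matrix(Y)
    n <- ncol(Y)
    X <- cbind(intercept = rep(1, n))
    if (!is.null(adjust)) {
        adjust <- as.matrix(adjust)
        if (is.null(colnames(adjust)))
            colnames(adjust) <- paste0("adj", seq_len(ncol(adjust)))
        X <- cbind(X, adjust)
    }
    X <- cbind(X, phenotype = as.numeric(phenotype))
    k <- ncol(X)
    if (n - k < 1L) stop("no residual degrees of freedom")
    d <- qr(X)
    if (d$rank < k) {
        bad <- d$pivot[(d$rank + 1L):k]
        stop("collinear design column(s): ",
             paste(colnames(X)[bad], collapse = ", "))
    }
    fit <- lm.fit(X, t(Y))
    coefs <- fit$coefficients["phenotype", ]
    res <- fit$residuals                       # n x p
    rss <- colSums(res^2)
    sigma2 <- rss / (n - k)
    xtxInv <- chol2inv(qr.R(d))
    j <- which(colnames(X) == "phenotype")
    se <- sqrt(sigma2 * xtxInv[j, j])
    degenerate <- rss <= .Machine$double.eps * pmax(rowSums(Y^2), 1)
    tstat <- coefs / se
    pv <- 2 * pt(abs(tstat), df = n - k, lower.tail = FALSE)
    pv[degenerate] <- 1
    pv <- pmin(pmax(pv, .Machine$double.xmin), 1)
    bh <- adjustBH(pv, level = level)
    bf <- adjustBonferroni(pv, level = level)
    probeIds <- rownames(Y)
    if (is.null(probeIds)) probeIds <- sprintf("cg%06d", seq_len(nrow(Y)))
    new("EwasFit", probeIds = probeIds, estimate = as.numeric(coefs),
        pvalue = as.numeric(pv), qvalueBH = bh$adjusted,
        rejectFDR = bh$reject, rejectBonf = bf$reject,
        degenerate = as.logical(degenerate), method = method,
        level = level)
}

#' Genomic inflation factor
#'
#' Converts each p-value to its upper-tail 1-df chi-square quantile and
#' returns lambda = median(chi^2) / 0.456. The denominator is the printed
#' convention for the null median of a 1-df chi-square (the exact value is
#' 0.45494), so perfectly uniform p-values give lambda ~ 0.998, not 1.
#' Lambda well above 1 signals systematic test-statistic inflation.
#'
#' @param pvals numeric p-values in (0, 1].
#' @param restrictTo optional index or logical vector selecting the probes
#'   that enter the median (typically the non-DMPs on simulated data).
#' @return The scalar inflation factor.
#' @examples
#' genomicInflation(runif(10000))  # ~ 1
#' @export
genomicInflation <- function(pvals, restrictTo = NULL) {
    if (!is.null(restrictTo)) pvals <- pvals[restrictTo]
    if (length(pvals) == 0) stop("no p-values to compute inflation from")
    chisq <- qchisq(pvals, df = 1, lower.tail = FALSE)
    median(chisq) / 0.456
}

#' Multiple-testing decisions
#'
#' \code{adjustBH} runs the Benjamini--Hochberg step-up procedure (via
#' \code{\link[stats]{p.adjust}}) and rejects adjusted values at or below
#' \code{level}; \code{adjustBonferroni} rejects raw p-values strictly below
#' \code{level / m}. The Bonferroni rejection set is always a subset of the
#' BH set at the same level.
#'
#' @param pvals numeric p-values in [0, 1].
#' @param level nominal error level.
#' @return \code{adjustBH}: list with \code{adjusted} and logical
#'   \code{reject}; \code{adjustBonferroni}: list with logical
#'   \code{reject}.
#' @export
adjustBH <- function(pvals, level = 0.05) {
    adj <- p.adjust(pvals, method = "BH")
    list(adjusted = adj, reject = adj <= level)
}

#' @rdname adjustBH
#' @export
adjustBonferroni <- function(pvals, level = 0.05) {
    list(reject = pvals < level / length(pvals))
}

#' Score an EWAS run against simulation truth
#'
#' @param result an \linkS4class{EwasFit}.
#' @param truth a \linkS4class{SimulationTruth} with matching probe count.
#' @param components optional n x K matrix of the adjustment components used
#'   (for the cell-composition adjusted R-squared; NA when omitted).
#' @return An \linkS4class{EvaluationReport} with: genomic inflation on the
#'   non-DMPs; observed FDR = false discoveries / max(discoveries, 1) on the
#'   BH set; the family-wise error indicator (any non-DMP past Bonferroni);
#'   true positive rates after BH and Bonferroni (NA when no DMPs were
#'   planted); and the components' adjusted R-squared for the true
#'   proportions.
#' @export
scoreRun <- function(result, truth, components = NULL) {
    stopifnot(is(result, "EwasFit"), is(truth, "SimulationTruth"))
    m <- length(result@pvalue)
    dmp <- truth@dmpIndex
    if (length(dmp) && max(dmp) > m)
        stop("probe sets of result and truth do not align")
    isDmp <- logical(m); isDmp[dmp] <- TRUE
    rejBH <- which(result@rejectFDR)
    rejBF <- which(result@rejectBonf)
    fdr <- sum(!isDmp[rejBH]) / max(length(rejBH), 1)
    fwe <- any(!isDmp[rejBF])
    tprF <- if (length(dmp)) sum(isDmp[rejBH]) / length(dmp) else NA_real_
    tprB <- if (length(dmp)) sum(isDmp[rejBF]) / length(dmp) else NA_real_
    lam <- genomicInflation(result@pvalue, restrictTo = !isDmp)
    r2 <- if (is.null(components)) NA_real_
          else cellCompR2(components, truth@proportions)
    new("EvaluationReport", lambdaNonDMP = lam, observedFDR = fdr,
        fweIndicator = fwe, tprFDR = tprF, tprBonf = tprB,
        r2CellComp = r2, nDiscoveries = length(rejBH),
        method = result@method)
}

#' Cell-composition variance explained by components
#'
#' Multivariate adjusted R-squared of a component matrix (surrogate
#' variables or principal components) for the true cell proportions, via
#' canonical correlation analysis. The last proportion column is dropped
#' (simplex redundancy), the canonical correlations rho_i between the two
#' blocks are computed, the joint R-squared is \code{1 - prod(1 - rho_i^2)},
#' and an Ezekiel-style correction penalises the component count:
#' \code{adjR2 = 1 - (1 - R2) * (n - 1) / (n - K - 1)}. The statistic is
#' invariant under invertible linear transforms of either block.
#'
#' @param components numeric n x K matrix.
#' @param B numeric n x q matrix of proportions (rows on the simplex).
#' @return The adjusted R-squared (at most 1; can be negative for useless
#'   components).
#' @examples
#' B <- matrix(rgamma(50 * 4, 2), 50); B <- B / rowSums(B)
#' cellCompR2(B[, 1:3] %*% matrix(rnorm(9), 3), B)  # ~ 1
#' @export
cellCompR2 <- function(components, B) {
    components <- as.matrix(components)
    B <- as.matrix(B)
    n <- nrow(components)
    K <- ncol(components)
    if (K < 1L) stop("need at least one component")
    if (nrow(B) != n) stop("components and proportions disagree on n")
    if (n <= K + ncol(B))
        stop("need n > K + q samples for the canonical-correlation R-squared")
    Bred <- B[, -ncol(B), drop = FALSE]
    rho <- cancor(components, Bred)$cor
    r2 <- 1 - prod(1 - rho^2)
    1 - (1 - r2) * (n - 1) / (n - K - 1)
}

setMethod("show", "EwasFit", function(object) {
    cat(sprintf("EwasFit [%s]: %d probes, %d BH discoveries, %d Bonferroni (level %g)\n",
        object@method, length(object@pvalue), sum(object@rejectFDR),
        sum(object@rejectBonf), object@level))
})

setMethod("show", "EvaluationReport", function(object) {
    cat(sprintf("EvaluationReport [%s]\n", object@method))
    cat(sprintf("  lambda (non-DMP): %.3f\n", object@lambdaNonDMP))
    cat(sprintf("  observed FDR: %.3f  (%d discoveries)\n",
        object@observedFDR, object@nDiscoveries))
    cat(sprintf("  FWE indicator: %s\n", object@fweIndicator))
    cat(sprintf("  TPR (FDR / Bonferroni): %.3f / %.3f\n",
        object@tprFDR, object@tprBonf))
    cat(sprintf("  cell-composition adj. R2: %.3f\n", object@r2CellComp))
})
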