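#' Estimate the number of significant components by random matrix theory
#'
#' Counts the eigenvalues of the sample covariance of the standardized data
#' that exceed the Marchenko--Pastur upper edge, the analytic maximum
#' eigenvalue expected from a pure-noise matrix of the same shape. The data
#' are optionally residualized against a design, then each sample (column)
#' is standardized to mean 0 and variance 1 across probes -- sample-wise
#' scaling preserves the between-probe variance differences that carry the
#' structure -- and the eigenvalues of the n x n sample covariance scaled by
#' 1/p are compared with \code{sigma2 * (1 + sqrt(n/p))^2}, where
#' \code{sigma2} is the grand variance of the standardized entries (~1) and
#' gamma = n/p is the aspect ratio (no Tracy--Widom correction).
#'
#' @param Y a \linkS4class{MethylationSet} (M-values are used) or numeric
#'   probes x samples matrix; requires p > n and n >= 10.
#' @param design optional design matrix to residualize against first
#'   (typically the full model, so the primary variable does not count as a
#'   component).
#' @return Integer K >= 0, the estimated number of non-noise components.
#'   Deterministic: no randomness is involved.
#' @details Zero-variance probes are dropped (with a message reporting the
#'   count) before standardization; if every probe is constant the estimate
#'   is undefined and an error is raised.
#' @examples
#' set.seed(1)
#' Y <- matrix(rnorm(2000 * 40), 2000, 40)
#' estimateComponentsRMT(Y)   # ~0: pure noise
#' @export
estimateComponentsRMT <- function(Y, design = NULL) {
    if (is(Y, "MethylationSet")) Y <- mValues(Y)
    Y <- as.matrix(Y)
    p <- nrow(Y); n <- ncol(Y)
    if (p <= n) stop("RMT estimation requires more probes than samples")
    if (n < 10L) stop("RMT estimation requires at least 10 samples")
    if (!is.null(design)) {
        # residualizing leaves the data in an (n - k)-dimensional sample
        # subspace; rotate onto an orthonormal basis of the complement so
        # the noise part stays white and the aspect ratio is n - k over p
        Q <- .orthoBasis(as.matrix(design))
        qc <- qr.Q(qr(Q), complete = TRUE)[, -seq_len(ncol(Q)), drop = FALSE]
        Y <- Y %*% qc
        n <- ncol(Y)
    }
    mu <- rowMeans(Y)
    s2 <- rowSums((Y - mu)^2) / (n - 1L)
    keep <- s2 > 0
    if (!any(keep)) stop("all probes have zero variance")
    if (!all(keep))
        message(sum(!keep), " zero-variance probe(s) dropped before RMT estimation")
    X <- scale(Y[keep, , drop = FALSE])
    pEff <- nrow(X)
    sigma2 <- var(as.vector(X))
    ev <- eigen(crossprod(X) / pEff, symmetric = TRUE, only.values = TRUE)$values
    edge <- sigma2 * (1 + sqrt(n / pEff))^2
    sum(ev > edge)
}
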