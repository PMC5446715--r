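# QR-based projection machinery shared by the SVA iterations and the EWAS
# fits. All per-probe statistics are computed from residual sums of squares
# obtained through one orthonormal basis per design, so the total cost is
# O(n p) per call at a fixed column count.

#' Orthonormal basis of a design's column space
#'
#' @param X numeric matrix with n rows, full column rank.
#' @return Matrix Q, n x ncol(X), with orthonormal columns spanning the
#'   column space of X.
#' @details Rank deficiency is a hard error naming the offending columns:
#'   silently dropping collinear columns would change the degrees of
#'   freedom of every downstream F-test.
#' @keywords internal
.orthoBasis <- function(X) {
    X <- as.matrix(X)
    d <- qr(X)
    if (d$rank < ncol(X)) {
        bad <- d$pivot[(d$rank + 1L):ncol(X)]
        nm <- colnames(X)
        lbl <- if (is.null(nm)) as.character(bad) else nm[bad]
        stop("design matrix is rank deficient; collinear column(s): ",
             paste(lbl, collapse = ", "))
    }
    qr.Q(d)
}

#' Residualize probes against a design matrix
#'
#' Projects every probe (row of \code{Y}) off the column space of \code{X}
#' using a single QR decomposition of the design, i.e.
#' \code{residual = Y - (Y Q) t(Q)}. Equivalent to running an ordinary
#' least-squares fit per probe and keeping the residuals, at a cost linear
#' in the probe count.
#'
#' @param Y numeric matrix, probes x samples, or a
#'   \linkS4class{MethylationSet} (M-values are used).
#' @param X design matrix with one row per sample; full column rank.
#' @return List with \code{residual} (probes x samples) and \code{Q}, the
#'   orthonormal basis of \code{X}'s column space (reusable across calls).
#' @examples
#' Y <- matrix(rnorm(40), 4, 10)
#' r <- qrResidualize(Y, cbind(1, rnorm(10)))
#' max(abs(r$residual %*% r$Q))  # ~ 0
#' @export
qrResidualize <- function(Y, X) {
    if (is(Y, "MethylationSet")) Y <- mValues(Y)
    Q <- .orthoBasis(X)
    if (nrow(Q) != ncol(Y))
        stop("design row count must equal the sample count")
    list(residual = Y - (Y %*% Q) %*% t(Q), Q = Q)
}

#' Vectorized nested-model F-test p-values
#'
#' Computes, for every probe at once, the F statistic comparing two nested
#' linear models given by precomputed orthonormal bases of their design
#' column spaces, and converts it to an upper-tail p-value with
#' (k_big - k_small, n - k_big) degrees of freedom. This is the hot path of
#' the reweighted SVA iteration.
#'
#' @param Y numeric matrix, probes x samples.
#' @param qBig,qSmall orthonormal bases (from \code{\link{qrResidualize}} or
#'   \code{qr.Q}) of the big and small design column spaces; the small space
#'   must be nested in the big one.
#' @return List with \code{stat} (F statistics), \code{pvalue} and
#'   \code{degenerate} (probes with ~zero residual variance under the big
#'   model, whose p-value is set to 1).
#' @export
probeFPvalues <- function(Y, qBig, qSmall) {
    n <- ncol(Y)
    kBig <- ncol(qBig); kSmall <- ncol(qSmall)
    if (kBig <= kSmall)
        stop("the big model must have more columns than the small model")
    df2 <- n - kBig
    if (df2 < 1L)
        stop("no residual degrees of freedom under the big model")
    tot <- rowSums(Y^2)
    rssSmall <- tot - rowSums((Y %*% qSmall)^2)
    rssBig <- tot - rowSums((Y %*% qBig)^2)
    # projections can undershoot by rounding; clamp at zero
    rssSmall <- pmax(rssSmall, 0)
    rssBig <- pmax(rssBig, 0)
    df1 <- kBig - kSmall
    tiny <- .Machine$double.eps * pmax(tot, 1)
    # 0/0 probes: no variance left under either model (constant or fully
    # explained by the small design) -- flagged, p forced to 1
    degenerate <- rssBig <= tiny & rssSmall <= tiny
    fstat <- ((rssSmall - rssBig) / df1) / (rssBig / df2)
    fstat[fstat < 0] <- 0
    fstat[degenerate] <- 0
    p <- pf(fstat, df1, df2, lower.tail = FALSE)
    p[degenerate] <- 1
    p <- pmax(p, .Machine$double.xmin)
    list(stat = fstat, pvalue = p, degenerate = degenerate)
}
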