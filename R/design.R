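#' Build nested full/null design matrices for SVA and association testing
#'
#' The full model is \code{[intercept, covariates, primary]}; the null model
#' drops the primary-variable columns. Factors in \code{primary} or
#' \code{covariates} are expanded to treatment-coded indicator columns.
#'
#' @param primary numeric vector, factor, or matrix: the variable(s) of
#'   interest (e.g. a 0/1 group indicator).
#' @param covariates optional numeric vector, factor, matrix or data.frame of
#'   adjustment covariates (no intercept; one is added).
#' @return A \linkS4class{DesignPair}.
#' @examples
#' dp <- designPair(rep(0:1, each = 5))
#' dim(dp@full); dim(dp@null)
#' @export
designPair <- function(primary, covariates = NULL) {
    toCols <- function(x, prefix) {
        if (is.null(x)) return(NULL)
        if (is.matrix(x)) {
            if (is.null(colnames(x)))
                colnames(x) <- paste0(prefix, seq_len(ncol(x)))
            return(x)
        }
        if (is.data.frame(x))
            return(stats::model.matrix(~ ., data = x)[, -1, drop = FALSE])
        if (is.factor(x) || is.character(x)) {
            f <- factor(x)
            mm <- stats::model.matrix(~ f)[, -1, drop = FALSE]
            colnames(mm) <- paste0(prefix, levels(f)[-1])
            return(mm)
        }
        matrix(as.numeric(x), ncol = 1, dimnames = list(NULL, prefix))
    }
    P <- toCols(primary, "primary")
    C <- toCols(covariates, "cov")
    n <- nrow(P)
    null <- cbind(intercept = rep(1, n), C)
    full <- cbind(null, P)
    new("DesignPair", full = full, null = null,
        primaryCols = as.integer(ncol(null) + seq_len(ncol(P))))
}
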