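#' Construct a MethylationSet
#'
#' @param values numeric matrix, probes as rows and samples as columns.
#' @param scale \code{"M"} (log2-odds) or \code{"beta"} (proportions in (0,1)).
#' @param probeIds,sampleIds optional identifier vectors; taken from
#'   \code{dimnames(values)} when omitted and generated when absent there too.
#' @return A \linkS4class{MethylationSet}.
#' @examples
#' m <- matrix(rnorm(12), 4, 3)
#' ms <- MethylationSet(m, scale = "M")
#' methScale(ms)
#' range(betaValues(ms))
#' @export
MethylationSet <- function(values, scale = c("M", "beta"),
                           probeIds = NULL, sampleIds = NULL) {
    scale <- match.arg(scale)
    values <- as.matrix(values)
    if (is.null(probeIds))
        probeIds <- rownames(values)
    if (is.null(probeIds))
        probeIds <- sprintf("cg%06d", seq_len(nrow(values)))
    if (is.null(sampleIds))
        sampleIds <- colnames(values)
    if (is.null(sampleIds))
        sampleIds <- sprintf("S%03d", seq_len(ncol(values)))
    dimnames(values) <- list(probeIds, sampleIds)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(meth = values))
    new("MethylationSet", se, methScale = scale)
}

#' Beta-value / M-value conversion
#'
#' M-values are the log2-odds of the methylation proportion:
#' \code{m = log2(beta / (1 - beta))}; the inverse is the logistic map
#' \code{beta = 2^m / (2^m + 1)}. The two maps are mutual inverses to
#' numerical precision and are applied elementwise.
#'
#' @param beta numeric, strictly in (0, 1).
#' @param m numeric, finite.
#' @return The converted values, same shape as the input.
#' @examples
#' betaToM(0.5)   # 0
#' betaToM(0.8)   # 2
#' mToBeta(betaToM(0.31)) # 0.31
#' @export
betaToM <- function(beta) {
    if (any(!is.finite(beta)) || any(beta <= 0) || any(beta >= 1))
        stop("beta-values must lie strictly in (0, 1)")
    log2(beta / (1 - beta))
}

#' @rdname betaToM
#' @export
mToBeta <- function(m) {
    if (any(!is.finite(m)))
        stop("M-values must be finite")
    # plogis on the natural-log scale: beta = 1 / (1 + 2^-m)
    plogis(m * log(2))
}

#' Accessors for MethylationSet
#'
#' \code{methScale} returns the storage scale; \code{mValues} and
#' \code{betaValues} return the matrix on the requested scale, converting
#' if necessary.
#'
#' @param x a \linkS4class{MethylationSet}.
#' @return \code{methScale}: \code{"M"} or \code{"beta"}; the others a
#'   numeric matrix, probes x samples.
#' @export
methScale <- function(x) {
    stopifnot(is(x, "MethylationSet"))
    x@methScale
}

#' @rdname methScale
#' @export
mValues <- function(x) {
    stopifnot(is(x, "MethylationSet"))
    v <- SummarizedExperiment::assay(x, "meth")
    if (x@methScale == "M") v else betaToM(v)
}

#' @rdname methScale
#' @export
betaValues <- function(x) {
    stopifnot(is(x, "MethylationSet"))
    v <- SummarizedExperiment::assay(x, "meth")
    if (x@methScale == "beta") v else mToBeta(v)
}

setMethod("show", "MethylationSet", function(object) {
    cat(sprintf("%s: %d probes x %d samples [%s scale]\n",
        class(object), nrow(object), ncol(object), object@methScale))
    callNextMethod()
})
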