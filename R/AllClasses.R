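#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay
#' @importFrom S4Vectors DataFrame metadata "metadata<-"
#' @importFrom stats approx cancor cor density dnorm lm.fit median
#'   p.adjust pf plogis pnorm pt qchisq qnorm rbinom rgamma rnorm runif
#'   sd var
#' @importFrom utils packageVersion
NULL

#' MethylationSet: a probes x samples methylation container
#'
#' A thin extension of \linkS4class{SummarizedExperiment} holding a single
#' methylation assay (named \code{"meth"}) together with an explicit scale
#' tag: \code{"M"} for log2-odds M-values or \code{"beta"} for methylation
#' proportions in (0,1). All statistics in this package are computed on
#' M-values; \code{\link{mValues}} and \code{\link{betaValues}} convert on
#' the fly so a set can be stored on either scale.
#'
#' @slot methScale character, \code{"M"} or \code{"beta"}.
#' @seealso \code{\link{MethylationSet}}, \code{\link{mValues}},
#'   \code{\link{betaValues}}, \code{\link{methScale}}
#' @export
setClass("MethylationSet",
    contains = "SummarizedExperiment",
    representation(methScale = "character"))

.validMethylationSet <- function(object) {
    msg <- NULL
    v <- SummarizedExperiment::assay(object, "meth")
    if (!is.numeric(v))
        msg <- c(msg, "assay 'meth' must be numeric")
    if (nrow(v) < 2L || ncol(v) < 3L)
        msg <- c(msg, "need at least 2 probes and 3 samples")
    if (anyNA(v) || any(!is.finite(v)))
        msg <- c(msg, "missing or non-finite methylation values are not allowed")
    sc <- object@methScale
    if (length(sc) != 1L || !sc %in% c("M", "beta"))
        msg <- c(msg, "methScale must be one of 'M', 'beta'")
    else if (sc == "beta" && !anyNA(v) && (any(v <= 0) || any(v >= 1)))
        msg <- c(msg, "beta-values must lie strictly in (0, 1)")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "probe identifiers must be unique")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "sample identifiers must be unique")
    if (is.null(msg)) TRUE else msg
}
setValidity("MethylationSet", .validMethylationSet)

#' SVAFit: result of an iteratively reweighted SVA fit
#'
#' @slot sv numeric matrix, samples x K, columns orthonormal; the estimated
#'   surrogate variables. The sign of each column is fixed by forcing its
#'   largest-magnitude entry positive.
#' @slot weights numeric vector in [0,1], one per probe: the final
#'   empirical-Bayes probe weights.
#' @slot nIter integer, iterations actually run.
#' @slot converged logical, whether the rank-correlation stopping rule fired
#'   (always \code{FALSE} bookkeeping-wise in fixed-iteration classic mode).
#' @slot weightCorr numeric, Spearman correlation between consecutive weight
#'   vectors, one entry per iteration after the first.
#' @slot alpha numeric, the power-transform exponent applied to the
#'   primary-variable probabilities.
#' @slot K integer, number of surrogate variables.
#' @slot mode character, \code{"smart"} or \code{"classic"}.
#' @seealso \code{\link{smartSVA}}, \code{\link{surrogates}},
#'   \code{\link{probeWeights}}
#' @export
setClass("SVAFit",
    representation(sv = "matrix", weights = "numeric", nIter = "integer",
                   converged = "logical", weightCorr = "numeric",
                   alpha = "numeric", K = "integer", mode = "character"))

setValidity("SVAFit", function(object) {
    msg <- NULL
    if (object@K < 1L)
        msg <- c(msg, "K must be >= 1")
    if (ncol(object@sv) != object@K)
        msg <- c(msg, "sv must have K columns")
    g <- crossprod(object@sv)
    if (max(abs(g - diag(ncol(g)))) > 1e-8)
        msg <- c(msg, "surrogate variable columns must be orthonormal (tol 1e-8)")
    if (any(object@weights < 0 | object@weights > 1))
        msg <- c(msg, "weights must lie in [0, 1]")
    if (is.null(msg)) TRUE else msg
})

#' DesignPair: nested full/null model matrices for association testing
#'
#' Holds the full model matrix (intercept, adjustment covariates and the
#' primary variable) and the null model matrix (intercept and adjustment
#' covariates only), plus the indices of the primary-variable columns
#' within the full matrix. The null column space must be a subspace of the
#' full one and both matrices must have full column rank.
#'
#' @slot full numeric matrix, n x k_full.
#' @slot null numeric matrix, n x k_null.
#' @slot primaryCols integer, indices of the primary columns in \code{full}.
#' @seealso \code{\link{designPair}}
#' @export
setClass("DesignPair",
    representation(full = "matrix", null = "matrix", primaryCols = "integer"))

setValidity("DesignPair", function(object) {
    msg <- NULL
    if (nrow(object@full) != nrow(object@null))
        msg <- c(msg, "full and null must have the same number of rows")
    if (ncol(object@null) < 1L)
        msg <- c(msg, "null model needs at least an intercept column")
    if (ncol(object@full) <= ncol(object@null))
        msg <- c(msg, "full model must have more columns than the null model")
    if (length(object@primaryCols) != ncol(object@full) - ncol(object@null))
        msg <- c(msg, "primaryCols must index the extra columns of full")
    qf <- qr(object@full)
    if (qf$rank < ncol(object@full))
        msg <- c(msg, "full model matrix is rank deficient")
    else {
        # nesting: null columns must be reproduced by projection onto full
        Q <- qr.Q(qf)
        resid <- object@null - Q %*% crossprod(Q, object@null)
        if (max(abs(resid)) > 1e-8)
            msg <- c(msg, "null column space is not nested in the full column space")
    }
    if (is.null(msg)) TRUE else msg
})

#' CellPanel: per-cell-type mean methylation profiles
#'
#' Mean M-value profiles for q purified cell types generated along a fixed
#' differentiation tree (one reference profile, two progenitors, four
#' subtypes per progenitor in the default two-lineage leukocyte panel).
#'
#' @slot profiles numeric matrix, probes x q, columns named by cell type.
#' @slot lineage character vector length q mapping each subtype to its
#'   progenitor.
#' @slot reference numeric vector, the root (stem-cell) profile.
#' @export
setClass("CellPanel",
    representation(profiles = "matrix", lineage = "character",
                   reference = "numeric"))

setValidity("CellPanel", function(object) {
    msg <- NULL
    if (ncol(object@profiles) != length(object@lineage))
        msg <- c(msg, "one lineage label per panel column is required")
    if (nrow(object@profiles) != length(object@reference))
        msg <- c(msg, "reference profile length must match the probe count")
    if (is.null(colnames(object@profiles)))
        msg <- c(msg, "panel columns must be named")
    if (is.null(msg)) TRUE else msg
})

#' SimulationTruth: ground truth attached to a simulated dataset
#'
#' @slot proportions numeric matrix, samples x q; rows on the simplex.
#' @slot dmpIndex integer, probe indices of the true DMPs.
#' @slot dmpEffect numeric, M-scale effect size per DMP.
#' @slot batch integer, batch label per sample.
#' @slot phenotype numeric, 0/1 group indicator or continuous phenotype.
#' @slot foldChanges numeric length q, the per-subtype log2 fold changes
#'   linking the phenotype to the mean cell proportions.
#' @export
setClass("SimulationTruth",
    representation(proportions = "matrix", dmpIndex = "integer",
                   dmpEffect = "numeric", batch = "integer",
                   phenotype = "numeric", foldChanges = "numeric"))

setValidity("SimulationTruth", function(object) {
    msg <- NULL
    B <- object@proportions
    if (any(B < 0))
        msg <- c(msg, "cell proportions must be nonnegative")
    if (max(abs(rowSums(B) - 1)) > 1e-12)
        msg <- c(msg, "each row of the proportion matrix must sum to 1")
    if (length(object@dmpEffect) != length(object@dmpIndex))
        msg <- c(msg, "one effect size per DMP is required")
    if (length(object@batch) != nrow(B) || length(object@phenotype) != nrow(B))
        msg <- c(msg, "batch and phenotype must have one entry per sample")
    if (is.null(msg)) TRUE else msg
})

#' SimulatedMethylation: a MethylationSet with attached ground truth
#'
#' Returned by \code{\link{simulateMethylation}}. Behaves as a
#' \linkS4class{MethylationSet} (beta scale by default, M-value view via
#' \code{\link{mValues}}) and carries the \linkS4class{SimulationTruth} and
#' the fully resolved simulation configuration.
#'
#' @slot truth a \linkS4class{SimulationTruth}.
#' @slot simConfig list, the resolved configuration including the seed.
#' @export
setClass("SimulatedMethylation",
    contains = "MethylationSet",
    representation(truth = "SimulationTruth", simConfig = "list"))

#' EwasFit: per-probe association results for one adjustment method
#'
#' @slot probeIds character, probe identifiers.
#' @slot estimate numeric, per-probe coefficient of the primary variable.
#' @slot pvalue numeric, two-sided p-value for that coefficient.
#' @slot qvalueBH numeric, Benjamini-Hochberg adjusted p-values.
#' @slot rejectFDR logical, BH rejection at \code{level}.
#' @slot rejectBonf logical, Bonferroni rejection at \code{level}.
#' @slot degenerate logical, probes with zero residual variance (p set to 1).
#' @slot method character label (\code{"unadjusted"}, \code{"pca"},
#'   \code{"sva_classic"}, \code{"smartsva"}, \code{"perfect"}, ...).
#' @slot level numeric, the nominal error level used for both rejections.
#' @export
setClass("EwasFit",
    representation(probeIds = "character", estimate = "numeric",
                   pvalue = "numeric", qvalueBH = "numeric",
                   rejectFDR = "logical", rejectBonf = "logical",
                   degenerate = "logical", method = "character",
                   level = "numeric"))

setValidity("EwasFit", function(object) {
    msg <- NULL
    if (any(object@pvalue < 0 | object@pvalue > 1))
        msg <- c(msg, "p-values must lie in [0, 1]")
    if (any(object@qvalueBH + 1e-12 < object@pvalue))
        msg <- c(msg, "BH-adjusted values cannot be smaller than raw p-values")
    if (any(object@rejectBonf & !object@rejectFDR))
        msg <- c(msg, "Bonferroni rejections must be a subset of BH rejections")
    if (is.null(msg)) TRUE else msg
})

#' EvaluationReport: scores of one EWAS run against simulation truth
#'
#' @slot lambdaNonDMP numeric, genomic inflation factor on non-DMP probes.
#' @slot observedFDR numeric, false discoveries / max(discoveries, 1) on the
#'   BH rejection set.
#' @slot fweIndicator logical, whether any non-DMP survived Bonferroni.
#' @slot tprFDR numeric, true positive rate after BH (NA when no DMPs).
#' @slot tprBonf numeric, true positive rate after Bonferroni (NA likewise).
#' @slot r2CellComp numeric, canonical-correlation adjusted R-squared of the
#'   adjustment components for the true proportions (NA when no components).
#' @slot nDiscoveries integer, BH discoveries count.
#' @slot method character, method label carried over from the fit.
#' @export
setClass("EvaluationReport",
    representation(lambdaNonDMP = "numeric", observedFDR = "numeric",
                   fweIndicator = "logical", tprFDR = "numeric",
                   tprBonf = "numeric", r2CellComp = "numeric",
                   nDiscoveries = "integer", method = "character"))

#' BenchmarkGrid: aggregated metrics over a scenario grid
#'
#' @slot perRep data.frame, one row per scenario x replicate x method with
#'   every metric of \linkS4class{EvaluationReport}.
#' @slot summary data.frame, per scenario x method means and standard errors.
#' @slot nReps integer, replicates per scenario.
#' @export
setClass("BenchmarkGrid",
    representation(perRep = "data.frame", summary = "data.frame",
                   nReps = "integer"))
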