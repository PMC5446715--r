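# Benchmark harness: simulate -> adjust -> test -> score, over a grid of
# signal densities and confounding strengths, for a panel of adjustment
# methods. Mirrors the usual simulation design for reference-free
# cell-mixture correction: "unadjusted", PCA, classic fixed-iteration SVA
# (B = 5), the convergence-controlled reweighted SVA, and the "Perfect"
# upper bound that adjusts for the true proportions and batch labels.

.benchMethods <- c("unadjusted", "pca", "sva_classic", "smartsva", "perfect")

#' Evaluate adjustment methods on one simulated dataset
#'
#' Fits the requested adjustment methods on a simulated dataset, runs the
#' per-CpG association tests and scores each against the truth. The number
#' of components K is shared across PCA and both SVA flavours and is
#' estimated by \code{\link{estimateComponentsRMT}} on the full-model
#' residuals unless given.
#'
#' @param sim a \linkS4class{SimulatedMethylation}.
#' @param methods subset of \code{c("unadjusted", "pca", "sva_classic",
#'   "smartsva", "perfect")}.
#' @param K number of components; \code{NULL} = RMT estimate (floored at 1).
#' @param level nominal error level for the multiple-testing decisions.
#' @param alpha power-transform exponent for the smart fit.
#' @param B iteration count for classic SVA.
#' @return Named list of \linkS4class{EvaluationReport}s, with attributes
#'   \code{"K"} and \code{"converged"} (smart-fit convergence flag).
#' @export
evaluateMethods <- function(sim, methods = .benchMethods, K = NULL,
                            level = 0.05, alpha = 0.25, B = 5L) {
    methods <- match.arg(methods, .benchMethods, several.ok = TRUE)
    M <- mValues(sim)
    tr <- truth(sim)
    pheno <- tr@phenotype
    design <- designPair(pheno)
    if (is.null(K))
        K <- max(1L, estimateComponentsRMT(M, design@full))
    converged <- NA
    out <- list()
    for (m in methods) {
        comp <- switch(m,
            unadjusted = NULL,
            pca = .topRightSingular(M - rowMeans(M), K),
            sva_classic = surrogates(
                smartSVA(M, design, K = K, mode = "classic", B = B)),
            smartsva = {
                fit <- suppressWarnings(
                    smartSVA(M, design, K = K, alpha = alpha))
                converged <- fit@converged
                surrogates(fit)
            },
            perfect = {
                q <- ncol(tr@proportions)
                bI <- stats::model.matrix(~ factor(tr@batch))[, -1, drop = FALSE]
                cbind(tr@proportions[, -q, drop = FALSE], bI)
            })
        ew <- fitEwas(M, pheno, adjust = comp, method = m, level = level)
        out[[m]] <- scoreRun(ew, tr, components = comp)
    }
    attr(out, "K") <- K
    attr(out, "converged") <- converged
    out
}

#' Run the scenario-grid benchmark
#'
#' Crosses signal density (DMP fraction \code{piG}) with confounding
#' strength (\code{sigmaF}), simulates \code{nReps} replicates per
#' scenario, evaluates every requested method on each, and aggregates
#' per-scenario means and standard errors (sd / sqrt(nReps)). The observed
#' FWER of a scenario is the mean of the per-replicate family-wise error
#' indicator. Replicates that fail are recorded and excluded with a logged
#' count.
#'
#' @param piG,sigmaF scenario grid values (all combinations are run).
#' @param nReps replicates per scenario (>= 2).
#' @param baseConfig a \code{\link{simConfig}} supplying everything except
#'   \code{piG}, \code{sigmaF} and the seed.
#' @param methods methods to evaluate (see \code{\link{evaluateMethods}}).
#' @param seed master seed; each scenario x replicate derives its own
#'   simulation seed from it.
#' @param level nominal error level.
#' @return A \linkS4class{BenchmarkGrid}.
#' @examples
#' \donttest{
#' bg <- runBenchmark(piG = 0.01, sigmaF = c(0, 0.6), nReps = 2,
#'                    baseConfig = simConfig(p = 500, n = 40),
#'                    methods = c("unadjusted", "smartsva"), seed = 1)
#' bg@summary
#' }
#' @export
runBenchmark <- function(piG = c(0.001, 0.01, 0.1),
                         sigmaF = c(0, 0.3, 0.6),
                         nReps = 20L,
                         baseConfig = simConfig(),
                         methods = .benchMethods,
                         seed = 1L, level = 0.05) {
    if (nReps < 2L) stop("need at least 2 replicates per scenario")
    grid <- expand.grid(piG = piG, sigmaF = sigmaF,
                        KEEP.OUT.ATTRS = FALSE)
    rows <- list()
    nFail <- 0L
    for (s in seq_len(nrow(grid))) {
        for (r in seq_len(nReps)) {
            cfg <- baseConfig
            cfg$signal$piG <- grid$piG[s]
            cfg$confounding$sigmaF <- grid$sigmaF[s]
            cfg$seed <- as.integer(
                (seed * 131L + s * 100003L + r * 7919L) %%
                    (.Machine$integer.max - 1L)) + 1L
            rep <- tryCatch({
                sim <- simulateMethylation(cfg)
                ev <- evaluateMethods(sim, methods = methods, level = level)
                lapply(names(ev), function(m) {
                    e <- ev[[m]]
                    data.frame(piG = grid$piG[s], sigmaF = grid$sigmaF[s],
                               rep = r, method = m, K = attr(ev, "K"),
                               converged = attr(ev, "converged"),
                               lambdaNonDMP = e@lambdaNonDMP,
                               observedFDR = e@observedFDR,
                               fwe = e@fweIndicator,
                               tprFDR = e@tprFDR, tprBonf = e@tprBonf,
                               r2CellComp = e@r2CellComp,
                               nDiscoveries = e@nDiscoveries)
                })
            }, error = function(e) {
                nFail <<- nFail + 1L
                message(sprintf("replicate failed (piG=%g, sigmaF=%g, rep %d): %s",
                                grid$piG[s], grid$sigmaF[s], r, conditionMessage(e)))
                NULL
            })
            if (!is.null(rep)) rows <- c(rows, rep)
        }
    }
    if (nFail > 0)
        message(nFail, " replicate(s) failed and were excluded")
    perRep <- do.call(rbind, rows)
    metrics <- c("lambdaNonDMP", "observedFDR", "fwe", "tprFDR", "tprBonf",
                 "r2CellComp", "nDiscoveries", "K")
    agg <- do.call(rbind, lapply(
        split(perRep, list(perRep$piG, perRep$sigmaF, perRep$method),
              drop = TRUE),
        function(d) {
            out <- data.frame(piG = d$piG[1], sigmaF = d$sigmaF[1],
                              method = d$method[1], nReps = nrow(d))
            for (mc in metrics) {
                x <- as.numeric(d[[mc]])
                out[[paste0(mc, "_mean")]] <- mean(x, na.rm = TRUE)
                out[[paste0(mc, "_se")]] <- sd(x, na.rm = TRUE) / sqrt(sum(!is.na(x)))
            }
            out
        }))
    rownames(agg) <- NULL
    new("BenchmarkGrid", perRep = perRep, summary = agg,
        nReps = as.integer(nReps))
}

setMethod("show", "BenchmarkGrid", function(object) {
    cat(sprintf("BenchmarkGrid: %d scenario x method cells, %d reps each\n",
        nrow(object@summary), object@nReps))
    print(utils::head(object@summary[, c("piG", "sigmaF", "method",
        "lambdaNonDMP_mean", "observedFDR_mean", "tprFDR_mean")], 10))
})
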