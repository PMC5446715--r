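# Cell-mixture methylation simulator.
#
# The generative model: bulk methylation is a convex mixture of q cell-type
# profiles, Y = A B^T + E on the beta scale, with the cell-type panel A
# built along a two-lineage differentiation tree and the per-sample
# proportions B drawn from a Dirichlet whose mean is tied to the phenotype
# through per-subtype log2 fold changes (the confounding dial). All
# methylation variability -- lineage differences, individual signatures,
# phenotype effects, batch shifts, measurement error -- is added on the
# M-value scale; mixing happens on the beta scale.

#' Simulation configuration with study defaults
#'
#' Returns the fully resolved configuration list for
#' \code{\link{simulateMethylation}}. The defaults describe a blood-like
#' EWAS: 10,000 CpGs, 100 samples in two equal groups, eight leukocyte
#' subtypes from two lineages, a bimodal three-component M-value mixture
#' for the stem-cell reference, 5\% of probes perturbed per
#' differentiation step, 5\% individual-specific probes, Dirichlet
#' proportions with concentration 50, five balanced batches, and moderate
#' measurement noise. Signal density \code{piG}, confounding strength
#' \code{sigmaF} and the phenotype type are the dials a study varies.
#'
#' @param p,n probe and sample counts.
#' @param q number of cell types (8 for the default two-lineage panel).
#' @param mixture list: \code{means}, \code{sds}, \code{probs} of the
#'   three-component normal mixture for the reference profile (M scale),
#'   representing hypo-, hemi- and hyper-methylated CpGs.
#' @param lineage list: \code{piC}, fraction of probes perturbed at each
#'   differentiation step, and \code{sigmaC}, the sd of those shifts.
#' @param individual list: \code{piI}, \code{sigmaI} -- per sample x subtype
#'   individual-specific methylation differences.
#' @param signal list: \code{piG} (DMP fraction), \code{sigmaG} (M-scale
#'   effect sd), \code{shared} (one effect per DMP shared by all subtypes).
#' @param proportions list: \code{piP} (mean proportions, must sum to 1)
#'   and \code{phi} (Dirichlet concentration; larger = less sample-to-sample
#'   variability).
#' @param confounding list: \code{sigmaF}, sd of the per-subtype log2 fold
#'   change linking phenotype to mean proportions (0 = no confounding).
#' @param batch list: \code{nB} batches, \code{sigmaB} shift sd,
#'   \code{fraction} of probes a batch shift touches.
#' @param noise list: \code{sigmaE}, M-scale measurement error sd.
#' @param phenotype \code{"binary"} (two equal groups) or
#'   \code{"continuous"} (standard normal).
#' @param seed integer seed; the whole simulation is a deterministic
#'   function of the resolved configuration.
#' @return A named list (the resolved configuration).
#' @export
simConfig <- function(p = 10000L, n = 100L, q = 8L,
                      mixture = list(means = c(-4, 0, 4),
                                     sds = c(0.6, 0.6, 0.6),
                                     probs = c(0.45, 0.10, 0.45)),
                      lineage = list(piC = 0.10, sigmaC = 3.0),
                      individual = list(piI = 0.05, sigmaI = 0.5),
                      signal = list(piG = 0.01, sigmaG = 1.0, shared = TRUE),
                      proportions = list(
                          piP = c(Gran = 0.35, Mono = 0.10, Eos = 0.10,
                                  Baso = 0.05, CD4T = 0.15, CD8T = 0.10,
                                  Bcell = 0.10, NK = 0.05),
                          phi = 20),
                      confounding = list(sigmaF = 0),
                      batch = list(nB = 5L, sigmaB = 0.3, fraction = 1.0),
                      noise = list(sigmaE = 0.3),
                      phenotype = c("binary", "continuous"),
                      seed = 1L) {
    cfg <- list(p = as.integer(p), n = as.integer(n), q = as.integer(q),
                mixture = mixture, lineage = lineage, individual = individual,
                signal = signal, proportions = proportions,
                confounding = confounding, batch = batch, noise = noise,
                phenotype = match.arg(phenotype), seed = as.integer(seed))
    .validateSimConfig(cfg)
    cfg
}

.validateSimConfig <- function(cfg) {
    with(cfg, {
        stopifnot(p >= 2, n >= 3, q >= 2)
        if (abs(sum(mixture$probs) - 1) > 1e-12)
            stop("mixture probabilities must sum to 1")
        if (abs(sum(proportions$piP) - 1) > 1e-12)
            stop("mean cell proportions must sum to 1")
        if (length(proportions$piP) != q)
            stop("piP must have one entry per cell type")
        fr <- c(lineage$piC, individual$piI, signal$piG, batch$fraction)
        if (any(fr < 0 | fr > 1))
            stop("fractions must lie in [0, 1]")
        sds <- c(mixture$sds, lineage$sigmaC, individual$sigmaI,
                 signal$sigmaG, confounding$sigmaF, batch$sigmaB, noise$sigmaE)
        if (any(sds < 0)) stop("standard deviations must be >= 0")
        if (proportions$phi <= 0) stop("Dirichlet concentration phi must be > 0")
        if (batch$nB < 1) stop("need at least one batch")
    })
    invisible(TRUE)
}

#' Draw a reference (stem-cell) methylation profile
#'
#' Each probe is independently assigned to one of three normal components
#' (hypo-, hemi-, hyper-methylated) with the configured probabilities, and
#' its M-value drawn from that component. Component labels are attached as
#' attribute \code{"component"}.
#'
#' @param config a \code{\link{simConfig}} list.
#' @return Numeric length-p M-value vector with attribute \code{"component"}.
#' @export
sampleReferenceProfile <- function(config) {
    mx <- config$mixture
    comp <- sample.int(3L, config$p, replace = TRUE, prob = mx$probs)
    ref <- rnorm(config$p, mean = mx$means[comp], sd = mx$sds[comp])
    attr(ref, "component") <- comp
    ref
}

#' Differentiate a methylation profile
#'
#' A uniformly random subset of \code{round(piC * p)} probes receives an
#' additive N(0, sigmaC^2) shift; all other probes are copied unchanged.
#'
#' @param parent numeric length-p M-value vector.
#' @param piC fraction of probes perturbed, in [0, 1].
#' @param sigmaC sd of the perturbation.
#' @return The child profile, same length as \code{parent}.
#' @export
differentiateProfile <- function(parent, piC, sigmaC) {
    p <- length(parent)
    nCh <- round(piC * p)
    child <- parent
    if (nCh > 0) {
        idx <- sample.int(p, nCh)
        child[idx] <- child[idx] + rnorm(nCh, 0, sigmaC)
    }
    child
}

#' Build the cell-type mean-methylation panel
#'
#' Generates the panel along the default two-lineage tree: one reference
#' (stem cell) profile, two progenitors derived from it, and four subtypes
#' per progenitor, each derivation a \code{\link{differentiateProfile}}
#' step with the configured \code{piC}, \code{sigmaC}. Column order follows
#' \code{names(config$proportions$piP)}: the first four subtypes belong to
#' the first progenitor (myeloid), the last four to the second (lymphoid).
#'
#' @param config a \code{\link{simConfig}} list (requires \code{q = 8}).
#' @return A \linkS4class{CellPanel}.
#' @export
buildCellPanel <- function(config) {
    if (config$q != 8L)
        stop("the default differentiation tree requires q = 8 cell types")
    piC <- config$lineage$piC
    sC <- config$lineage$sigmaC
    ref <- sampleReferenceProfile(config)
    prog <- list(myeloid = differentiateProfile(ref, piC, sC),
                 lymphoid = differentiateProfile(ref, piC, sC))
    nms <- names(config$proportions$piP)
    if (is.null(nms)) nms <- paste0("ct", seq_len(8))
    A <- matrix(0, config$p, 8L, dimnames = list(NULL, nms))
    lineage <- rep(c("myeloid", "lymphoid"), each = 4L)
    for (k in seq_len(8L))
        A[, k] <- differentiateProfile(prog[[lineage[k]]], piC, sC)
    new("CellPanel", profiles = A, lineage = lineage,
        reference = as.numeric(ref))
}

.rdirichlet <- function(alpha) {
    g <- rgamma(length(alpha), shape = alpha, rate = 1)
    g / sum(g)
}

#' Draw phenotype-linked cell proportions
#'
#' Sample i's proportions are Dirichlet with concentration
#' \code{mean_i * phi}. For a binary phenotype, group-0 samples use the
#' baseline mean \code{piP} and group-1 samples use
#' \code{piP * 2^f} renormalized, with the per-subtype log2 fold changes
#' \code{f ~ N(0, sigmaF^2)} drawn once per run. For a continuous phenotype
#' the log2 fold change scales linearly with the phenotype value:
#' \code{mean_i = piP * 2^(f * x_i)} renormalized.
#'
#' @param config a \code{\link{simConfig}} list.
#' @param phenotype numeric length-n vector (0/1 or continuous).
#' @param foldChanges optional length-q log2 fold changes; drawn from
#'   N(0, sigmaF^2) when \code{NULL}.
#' @return n x q matrix of proportions (rows on the simplex), with
#'   attribute \code{"foldChanges"}.
#' @export
sampleCellProportions <- function(config, phenotype, foldChanges = NULL) {
    q <- config$q
    piP <- config$proportions$piP
    phi <- config$proportions$phi
    if (is.null(foldChanges))
        foldChanges <- rnorm(q, 0, config$confounding$sigmaF)
    n <- length(phenotype)
    B <- matrix(0, n, q, dimnames = list(NULL, names(piP)))
    for (i in seq_len(n)) {
        m <- piP * 2^(foldChanges * phenotype[i])
        m <- m / sum(m)
        B[i, ] <- .rdirichlet(m * phi)
    }
    attr(B, "foldChanges") <- foldChanges
    B
}

#' Designate DMPs and draw their effect sizes
#'
#' Selects a uniformly random probe subset of size \code{round(piG * p)} as
#' differentially methylated positions and draws each DMP's M-scale effect
#' from N(0, sigmaG^2). With \code{shared = TRUE} (default) one effect per
#' DMP applies to every subtype; otherwise each subtype gets an independent
#' draw.
#'
#' @param config a \code{\link{simConfig}} list.
#' @return List with \code{dmpIndex} (sorted integer indices) and
#'   \code{effect} (a \code{length(dmpIndex) x q} matrix of M-scale
#'   effects; identical columns in the shared case).
#' @export
plantPhenotypeEffects <- function(config) {
    nD <- round(config$signal$piG * config$p)
    if (nD == 0)
        return(list(dmpIndex = integer(0),
                    effect = matrix(0, 0, config$q)))
    idx <- sort(sample.int(config$p, nD))
    if (isTRUE(config$signal$shared)) {
        delta <- rnorm(nD, 0, config$signal$sigmaG)
        eff <- matrix(delta, nD, config$q)
    } else {
        eff <- matrix(rnorm(nD * config$q, 0, config$signal$sigmaG),
                      nD, config$q)
    }
    list(dmpIndex = idx, effect = eff)
}

#' Simulate a cell-mixture methylation dataset with known truth
#'
#' Runs the full generative pipeline: build the cell panel, assign the
#' phenotype (two equal groups, or standard-normal draws), draw
#' phenotype-linked proportions, plant DMP effects, add individual-specific
#' differences per sample x subtype, mix the subtype beta-value profiles by
#' the proportions, then add batch shifts and measurement error on the
#' M-value scale. Samples are assigned to batches round-robin after a
#' random permutation, so batch is independent of phenotype by design.
#'
#' @param config a \code{\link{simConfig}} list; \code{config$seed} makes
#'   the result a deterministic function of the configuration.
#' @return A \linkS4class{SimulatedMethylation} (beta scale; use
#'   \code{\link{mValues}} for the M view) carrying the
#'   \linkS4class{SimulationTruth} in \code{truth(x)}.
#' @examples
#' sim <- simulateMethylation(simConfig(p = 300, n = 20, seed = 3))
#' dim(sim); head(truth(sim)@proportions)
#' @export
simulateMethylation <- function(config) {
    .validateSimConfig(config)
    set.seed(config$seed)
    p <- config$p; n <- config$n; q <- config$q
    panel <- buildCellPanel(config)

    phenotype <- if (config$phenotype == "binary")
        rep(c(0, 1), c(floor(n / 2), ceiling(n / 2)))
    else rnorm(n)

    B <- sampleCellProportions(config, phenotype)
    f <- attr(B, "foldChanges")
    sig <- plantPhenotypeEffects(config)

    nI <- round(config$individual$piI * p)
    sI <- config$individual$sigmaI
    panelBeta <- mToBeta(panel@profiles)
    bulkBeta <- matrix(0, p, n)
    for (i in seq_len(n)) {
        # only the individually perturbed and DMP entries differ from the
        # panel; transform just those instead of the whole p x q matrix
        Bi <- panelBeta
        Mtouched <- panel@profiles
        touched <- matrix(FALSE, p, q)
        if (nI > 0 && sI > 0) {
            for (k in seq_len(q)) {
                idx <- sample.int(p, nI)
                Mtouched[idx, k] <- Mtouched[idx, k] + rnorm(nI, 0, sI)
                touched[idx, k] <- TRUE
            }
        }
        if (length(sig$dmpIndex) && phenotype[i] != 0) {
            Mtouched[sig$dmpIndex, ] <- Mtouched[sig$dmpIndex, ] +
                sig$effect * phenotype[i]
            touched[sig$dmpIndex, ] <- TRUE
        }
        if (any(touched))
            Bi[touched] <- mToBeta(Mtouched[touched])
        bulkBeta[, i] <- Bi %*% B[i, ]
    }

    M <- betaToM(bulkBeta)

    nB <- config$batch$nB
    batch <- integer(n)
    batch[sample.int(n)] <- rep_len(seq_len(nB), n)
    shift <- matrix(rnorm(p * nB, 0, config$batch$sigmaB), p, nB)
    frac <- config$batch$fraction
    if (frac < 1) {
        for (b in seq_len(nB)) {
            keep <- sample.int(p, round(frac * p))
            mask <- rep(0, p); mask[keep] <- 1
            shift[, b] <- shift[, b] * mask
        }
    }
    M <- M + shift[, batch] + matrix(rnorm(p * n, 0, config$noise$sigmaE), p, n)
    # |M| > 35 is beyond any array's dynamic range and would round to
    # beta = 0/1 exactly; clamp to keep the beta view strictly in (0,1)
    M <- pmin(pmax(M, -35), 35)

    probeIds <- sprintf("cg%06d", seq_len(p))
    sampleIds <- sprintf("S%03d", seq_len(n))
    beta <- mToBeta(M)
    dimnames(beta) <- list(probeIds, sampleIds)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(meth = beta),
        colData = S4Vectors::DataFrame(phenotype = phenotype,
                                       batch = factor(batch),
                                       row.names = sampleIds))
    truth <- new("SimulationTruth", proportions = B,
                 dmpIndex = as.integer(sig$dmpIndex),
                 dmpEffect = if (length(sig$dmpIndex)) rowMeans(sig$effect)
                             else numeric(0),
                 batch = batch, phenotype = as.numeric(phenotype),
                 foldChanges = as.numeric(f))
    new("SimulatedMethylation", se, methScale = "beta",
        truth = truth, simConfig = config)
}

#' @rdname simulateMethylation
#' @param x a \linkS4class{SimulatedMethylation}.
#' @export
truth <- function(x) {
    stopifnot(is(x, "SimulatedMethylation"))
    x@truth
}

setMethod("show", "SimulatedMethylation", function(object) {
    callNextMethod()
    cfg <- object@simConfig
    cat(sprintf("simulated: q = %d cell types, %d DMPs, sigmaF = %g, %s phenotype, seed %d\n",
        cfg$q, length(object@truth@dmpIndex), cfg$confounding$sigmaF,
        cfg$phenotype, cfg$seed))
})
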