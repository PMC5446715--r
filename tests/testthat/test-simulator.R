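test_that("reference profile follows the configured three-component mixture", {
    cfg <- simConfig(p = 20000, n = 10,
                     mixture = list(means = c(-4, 0, 4), sds = c(0, 0, 0),
                                    probs = c(0.45, 0.10, 0.45)))
    set.seed(61)
    ref <- sampleReferenceProfile(cfg)
    expect_true(all(ref %in% c(-4, 0, 4)))
    # component frequencies within 3 binomial sds of the mixing probabilities
    comp <- attr(ref, "component")
    for (j in 1:3) {
        ph <- mean(comp == j)
        pj <- cfg$mixture$probs[j]
        expect_lt(abs(ph - pj), 3 * sqrt(pj * (1 - pj) / cfg$p))
    }
})

test_that("the default mixture is bimodal on the beta scale", {
    cfg <- simConfig(p = 20000, n = 10)
    set.seed(62)
    b <- mToBeta(sampleReferenceProfile(cfg))
    expect_lt(mean(b > 0.25 & b < 0.75), 0.2)
})

test_that("differentiation perturbs exactly the configured probe fraction", {
    set.seed(63)
    parent <- rnorm(5000)
    expect_identical(differentiateProfile(parent, 0, 1), parent)
    expect_identical(differentiateProfile(parent, 1, 0), parent)
    child <- differentiateProfile(parent, 0.2, 2)
    changed <- child != parent
    expect_identical(sum(changed), 1000L)
    # mean |shift| of a half-normal with sd 2 is 2*sqrt(2/pi)
    shifts <- abs(child[changed] - parent[changed])
    hm <- 2 * sqrt(2 / pi)
    se <- 2 * sqrt(1 - 2 / pi) / sqrt(sum(changed))
    expect_lt(abs(mean(shifts) - hm), 3 * se)
})

test_that("the cell panel follows the two-lineage tree", {
    cfg0 <- simConfig(p = 2000, n = 10,
                      lineage = list(piC = 0, sigmaC = 1))
    set.seed(64)
    panel0 <- buildCellPanel(cfg0)
    for (k in 1:8)
        expect_equal(unname(panel0@profiles[, k]), panel0@reference)

    cfg <- simConfig(p = 20000, n = 10, lineage = list(piC = 0.05, sigmaC = 1))
    set.seed(65)
    panel <- buildCellPanel(cfg)
    # sibling subtypes differ only where their own differentiation steps
    # touched: expected fraction 1 - (1 - piC)^2
    fr <- mean(panel@profiles[, 1] != panel@profiles[, 2])
    want <- 1 - (1 - 0.05)^2
    expect_lt(abs(fr - want), 3 * sqrt(want * (1 - want) / cfg$p))
    badq <- simConfig(p = 100, n = 10)
    badq$q <- 6L; badq$proportions$piP <- rep(1 / 6, 6)
    expect_error(buildCellPanel(badq), "q = 8")
})

test_that("cell proportions stay on the simplex and track the Dirichlet mean", {
    cfg <- simConfig(p = 100, n = 10, confounding = list(sigmaF = 0))
    set.seed(66)
    pheno <- rep(0:1, each = 5000)
    B <- sampleCellProportions(cfg, pheno)
    expect_lt(max(abs(rowSums(B) - 1)), 1e-12)
    expect_true(all(B >= 0))
    # with sigmaF = 0 both groups share the mean piP
    piP <- cfg$proportions$piP
    phi <- cfg$proportions$phi
    for (k in seq_along(piP)) {
        sdk <- sqrt(piP[k] * (1 - piP[k]) / (phi + 1))
        expect_lt(abs(mean(B[, k]) - piP[k]), 3 * sdk / sqrt(nrow(B)))
        d <- mean(B[pheno == 1, k]) - mean(B[pheno == 0, k])
        expect_lt(abs(d), 3 * sdk * sqrt(2 / 5000))
    }
})

test_that("confounding strength monotonically increases the phenotype-composition correlation", {
    cc <- vapply(c(0, 0.3, 0.6), function(sF) {
        cfg <- simConfig(p = 100, n = 10, confounding = list(sigmaF = sF))
        set.seed(67)
        pheno <- rep(0:1, each = 500)
        B <- sampleCellProportions(cfg, pheno)
        max(cancor(matrix(pheno), B[, -ncol(B)])$cor)
    }, numeric(1))
    expect_true(all(diff(cc) > 0))
})

test_that("DMP planting respects density, sharing and the zero-signal edge cases", {
    cfg <- simConfig(p = 4000, n = 10, signal = list(piG = 0.01, sigmaG = 1,
                                                     shared = TRUE))
    set.seed(68)
    sig <- plantPhenotypeEffects(cfg)
    expect_length(sig$dmpIndex, 40L)
    expect_equal(sig$effect[, 1], sig$effect[, 8])
    cfg0 <- simConfig(p = 4000, n = 10, signal = list(piG = 0, sigmaG = 1,
                                                      shared = TRUE))
    expect_length(plantPhenotypeEffects(cfg0)$dmpIndex, 0L)
    cfgZ <- simConfig(p = 4000, n = 10, signal = list(piG = 0.01, sigmaG = 0,
                                                      shared = TRUE))
    set.seed(69)
    sigZ <- plantPhenotypeEffects(cfgZ)
    expect_length(sigZ$dmpIndex, 40L)
    expect_true(all(sigZ$effect == 0))
})

test_that("a shared M-scale effect survives beta-scale mixing with limited attenuation", {
    # forward computation through the mixing pipeline: add delta = 1 to all
    # subtypes at a probe with betas in (0.2, 0.8); the realized bulk
    # M-scale difference stays within 15% of delta
    set.seed(70)
    B <- matrix(rgamma(8, 20), 1); B <- B / sum(B)
    for (m0 in seq(betaToM(0.2), betaToM(0.8), length.out = 7)) {
        ms <- m0 + rnorm(8, 0, 0.3)
        bulk0 <- betaToM(sum(mToBeta(ms) * B))
        bulk1 <- betaToM(sum(mToBeta(ms + 1) * B))
        expect_lt(abs((bulk1 - bulk0) - 1), 0.15)
    }
})

test_that("simulation is a deterministic function of the seed", {
    cfg <- tinyConfig(seed = 71)
    s1 <- simulateMethylation(cfg)
    s2 <- simulateMethylation(cfg)
    expect_identical(betaValues(s1), betaValues(s2))
    expect_identical(truth(s1)@proportions, truth(s2)@proportions)
    s3 <- simulateMethylation(tinyConfig(seed = 72))
    expect_false(identical(betaValues(s1), betaValues(s3)))
})

test_that("the fully degenerate configuration collapses to identical samples", {
    cfg <- simConfig(p = 200, n = 10, seed = 73,
                     mixture = list(means = c(-4, 0, 4), sds = c(0, 0, 0),
                                    probs = c(0.45, 0.1, 0.45)),
                     lineage = list(piC = 0, sigmaC = 0),
                     individual = list(piI = 0, sigmaI = 0),
                     signal = list(piG = 0, sigmaG = 0, shared = TRUE),
                     batch = list(nB = 5L, sigmaB = 0, fraction = 1),
                     noise = list(sigmaE = 0))
    sim <- simulateMethylation(cfg)
    b <- betaValues(sim)
    expect_lt(max(apply(b, 1, function(x) diff(range(x)))), 1e-12)
})

test_that("bulk beta is a convex combination of the subtype profiles", {
    # with individual effects, batch and noise switched off, every bulk
    # value must lie between the per-probe min and max of the panel betas
    cfg <- simConfig(p = 500, n = 12, seed = 74,
                     individual = list(piI = 0, sigmaI = 0),
                     signal = list(piG = 0, sigmaG = 0, shared = TRUE),
                     batch = list(nB = 3L, sigmaB = 0, fraction = 1),
                     noise = list(sigmaE = 0))
    sim <- simulateMethylation(cfg)
    set.seed(cfg$seed)
    panel <- buildCellPanel(cfg)      # same RNG stream -> same panel
    pb <- mToBeta(panel@profiles)
    lo <- apply(pb, 1, min); hi <- apply(pb, 1, max)
    b <- betaValues(sim)
    expect_true(all(b >= lo - 1e-9 & b <= hi + 1e-9))
})

test_that("batch structure dominates the principal components when batch noise is large", {
    cfg <- simConfig(p = 2000, n = 60, seed = 75,
                     batch = list(nB = 5L, sigmaB = 1.5, fraction = 1),
                     noise = list(sigmaE = 0.05))
    sim <- simulateMethylation(cfg)
    M <- mValues(sim); Mc <- M - rowMeans(M)
    pc <- svd(Mc, nu = 0, nv = 2)$v
    sil <- cluster::silhouette(truth(sim)@batch, dist(pc))
    expect_gt(mean(sil[, "sil_width"]), 0.5)
})

test_that("batches are balanced and independent of phenotype by construction", {
    sim <- simulateMethylation(tinyConfig(p = 300, n = 40, seed = 76))
    tr <- truth(sim)
    expect_true(all(table(tr@batch) == 8))
    expect_identical(sort(unique(tr@batch)), 1:5)
})

test_that("with no planted signal the Perfect-adjusted tests are uniform", {
    pv <- unlist(lapply(1:3, function(r) {
        cfg <- simConfig(p = 1500, n = 60, seed = 770 + r,
                         signal = list(piG = 0, sigmaG = 1, shared = TRUE),
                         confounding = list(sigmaF = 0.6))
        sim <- simulateMethylation(cfg)
        tr <- truth(sim)
        q <- ncol(tr@proportions)
        adj <- cbind(tr@proportions[, -q],
                     stats::model.matrix(~ factor(tr@batch))[, -1])
        fitEwas(sim, tr@phenotype, adjust = adj)@pvalue
    }))
    expect_gt(suppressWarnings(ks.test(pv, "punif")$p.value), 0.01)
})

test_that("continuous phenotypes drive proportions and signal linearly", {
    cfg <- tinyConfig(p = 500, n = 40, seed = 78, phenotype = "continuous")
    cfg$confounding$sigmaF <- 0.6
    sim <- simulateMethylation(cfg)
    tr <- truth(sim)
    expect_gt(sd(tr@phenotype), 0.5)      # standard normal draws
    expect_false(all(tr@phenotype %in% c(0, 1)))
    expect_lt(max(abs(rowSums(tr@proportions) - 1)), 1e-12)
})

test_that("configuration validation rejects malformed inputs", {
    expect_error(simConfig(p = 100, n = 10,
                           proportions = list(piP = rep(0.2, 8), phi = 50)),
                 "sum to 1")
    expect_error(simConfig(p = 100, n = 10,
                           proportions = list(piP = c(0.3, 0.7), phi = 50)),
                 "one entry per cell type")
    cfg <- simConfig(p = 100, n = 10)
    cfg$proportions$phi <- -1
    expect_error(iwsva:::.validateSimConfig(cfg), "phi")
    expect_error(simConfig(p = 100, n = 10,
                           signal = list(piG = 1.5, sigmaG = 1, shared = TRUE)),
                 "fractions")
})
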