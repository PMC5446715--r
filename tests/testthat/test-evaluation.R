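test_that("vectorized EWAS matches the per-probe regression oracle", {
    set.seed(81)
    n <- 30
    Y <- matrix(rnorm(80 * n), 80, n)
    pheno <- rbinom(n, 1, 0.5)
    adj <- matrix(rnorm(2 * n), n, 2)
    ew <- fitEwas(Y, pheno, adjust = adj)
    want <- oracleEwas(Y, pheno, adjust = adj)
    expect_lt(max(abs(ew@estimate - want[, "estimate"])), 1e-8)
    expect_lt(max(abs(ew@pvalue - want[, "pvalue"])), 1e-8)
})

test_that("a planted coefficient is recovered within sampling error", {
    set.seed(82)
    n <- 100
    pheno <- rbinom(n, 1, 0.5)
    Y <- matrix(rnorm(50 * n, sd = 0.1), 50, n)
    Y[1, ] <- Y[1, ] + pheno            # delta = 1 on probe 1
    ew <- fitEwas(Y, pheno)
    se <- 0.1 * sqrt(1 / sum(pheno == 1) + 1 / sum(pheno == 0))
    expect_lt(abs(ew@estimate[1] - 1), 3 * se)
    expect_true(ew@rejectBonf[1])
})

test_that("EWAS rejects collinear adjustments with a useful error", {
    set.seed(83)
    Y <- matrix(rnorm(40), 4, 10)
    pheno <- rep(0:1, 5)
    expect_error(fitEwas(Y, pheno, adjust = cbind(dup = pheno)), "collinear")
})

test_that("genomic inflation uses the printed 0.456 denominator", {
    lamHalf <- genomicInflation(rep(0.5, 11))
    expect_equal(lamHalf, qchisq(0.5, 1, lower.tail = FALSE) / 0.456,
                 tolerance = 1e-12)
    expect_equal(lamHalf, 0.99766, tolerance = 1e-4)
    # uniform grid -> lambda approaches the same constant
    m <- 100000
    grid <- (seq_len(m) - 0.5) / m
    expect_equal(genomicInflation(grid), 0.99766, tolerance = 1e-3)
    # halving the p-values strictly increases lambda
    set.seed(84)
    pv <- runif(500)
    expect_gt(genomicInflation(pv / 2), genomicInflation(pv))
    # restriction selects the probes entering the median
    expect_equal(genomicInflation(c(rep(1e-8, 5), rep(0.5, 11)),
                                  restrictTo = 6:16), lamHalf)
    expect_error(genomicInflation(numeric(0)), "no p-values")
})

test_that("BH and Bonferroni decisions match hand computation and nest", {
    p <- c(0.01, 0.02, 0.03, 0.5)
    bh <- adjustBH(p)
    expect_equal(bh$adjusted, c(0.04, 0.04, 0.04, 0.5))
    expect_identical(bh$reject, c(TRUE, TRUE, TRUE, FALSE))
    expect_identical(adjustBonferroni(p)$reject, c(TRUE, FALSE, FALSE, FALSE))

    ones <- adjustBH(rep(1, 6))
    expect_true(all(ones$adjusted == 1) && !any(ones$reject))
    expect_equal(adjustBH(0.03)$adjusted, 0.03)
    expect_identical(adjustBonferroni(0.03)$reject, TRUE)

    # Bonferroni set is contained in the BH set on arbitrary inputs
    set.seed(85)
    for (r in 1:20) {
        pv <- runif(200)^sample(1:4, 1)
        expect_true(all(adjustBH(pv)$reject[adjustBonferroni(pv)$reject]))
    }
})

test_that("run scoring counts discoveries against the truth correctly", {
    mkFit <- function(m, rejBH, rejBF) {
        pv <- rep(0.5, m); pv[rejBH] <- 1e-6
        new("EwasFit", probeIds = as.character(seq_len(m)),
            estimate = numeric(m), pvalue = pv,
            qvalueBH = pmax(pv, 1e-6),
            rejectFDR = seq_len(m) %in% rejBH,
            rejectBonf = seq_len(m) %in% rejBF,
            degenerate = logical(m), method = "test", level = 0.05)
    }
    mkTruth <- function(m, dmp, n = 10) {
        B <- matrix(1 / 4, n, 4)
        new("SimulationTruth", proportions = B, dmpIndex = as.integer(dmp),
            dmpEffect = rep(1, length(dmp)), batch = rep(1:2, n / 2),
            phenotype = rep(0:1, n / 2), foldChanges = numeric(4))
    }
    # rejections exactly the DMP set
    r1 <- scoreRun(mkFit(50, 1:20, 1:20), mkTruth(50, 1:20))
    expect_equal(r1@observedFDR, 0)
    expect_equal(r1@tprFDR, 1)
    expect_false(r1@fweIndicator)
    # no rejections: the max(discoveries, 1) guard
    r2 <- scoreRun(mkFit(50, integer(0), integer(0)), mkTruth(50, 1:20))
    expect_equal(r2@observedFDR, 0)
    expect_equal(r2@tprFDR, 0)
    # 10 rejections, 7 true, 20 DMPs
    r3 <- scoreRun(mkFit(50, c(1:7, 31:33), c(1:2, 31)), mkTruth(50, 1:20))
    expect_equal(r3@observedFDR, 0.3)
    expect_equal(r3@tprFDR, 0.35)
    expect_true(r3@fweIndicator)
    # empty DMP set: TPR undefined
    r4 <- scoreRun(mkFit(50, 1:3, integer(0)), mkTruth(50, integer(0)))
    expect_true(is.na(r4@tprFDR))
    expect_equal(r4@observedFDR, 1)
    expect_error(scoreRun(mkFit(50, 1:3, integer(0)), mkTruth(50, c(1:20, 60))),
                 "do not align")
})

test_that("cell-composition R2 has the right endpoints", {
    set.seed(86)
    n <- 200
    B <- matrix(rgamma(n * 5, 2), n); B <- B / rowSums(B)
    # components an invertible transform of the proportion block
    comp <- B[, 1:4] %*% matrix(rnorm(16), 4) + 5
    expect_gt(cellCompR2(comp, B), 0.999)
    # independent noise explains nothing
    set.seed(87)
    expect_lt(cellCompR2(matrix(rnorm(1000 * 5), 1000, 5),
                         {BB <- matrix(rgamma(1000 * 5, 2), 1000)
                          BB / rowSums(BB)}), 0.05)
    expect_error(cellCompR2(matrix(rnorm(12), 6, 2), B[1:6, ]),
                 "n > K \\+ q")
})

test_that("single-component canonical R2 equals the regression R-squared", {
    set.seed(88)
    n <- 80
    B <- matrix(rgamma(n * 4, 3), n); B <- B / rowSums(B)
    comp <- B[, 1] + rnorm(n, sd = 0.05)
    rho2 <- summary(lm(comp ~ B[, -4]))$r.squared
    adj <- 1 - (1 - rho2) * (n - 1) / (n - 1 - 1)
    expect_equal(cellCompR2(matrix(comp), B), adj, tolerance = 1e-10)
})

test_that("duplicating a component never increases the unadjusted canonical R2", {
    set.seed(89)
    n <- 60
    B <- matrix(rgamma(n * 4, 3), n); B <- B / rowSums(B)
    comp <- matrix(rnorm(n * 3), n)
    r2 <- function(cp) 1 - prod(1 - cancor(cp, B[, -4])$cor^2)
    expect_lte(r2(cbind(comp, comp[, 1] + comp[, 2])), r2(comp) + 1e-10)
})
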