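# Independent slow-path oracles: one-probe-at-a-time model fits used to
# check the vectorized QR implementations.

# nested-model F-test per probe via lm + anova
oracleFPvalues <- function(Y, Xbig, Xsmall) {
    t(apply(Y, 1L, function(y) {
        f0 <- lm(y ~ Xsmall - 1)
        f1 <- lm(y ~ Xbig - 1)
        a <- anova(f0, f1)
        c(stat = a$F[2], pvalue = a$`Pr(>F)`[2])
    }))
}

# per-probe OLS of y on [X, phenotype]; coefficient and two-sided p-value
oracleEwas <- function(Y, phenotype, adjust = NULL) {
    n <- ncol(Y)
    X <- cbind(1, adjust, phenotype)
    t(apply(Y, 1L, function(y) {
        f <- lm(y ~ X - 1)
        s <- summary(f)$coefficients
        c(estimate = s[nrow(s), 1], pvalue = s[nrow(s), 4])
    }))
}

# per-probe OLS residuals, one probe at a time
oracleResiduals <- function(Y, X) {
    t(apply(Y, 1L, function(y) residuals(lm(y ~ X - 1))))
}

# small, fast simulation configuration for structural tests
tinyConfig <- function(p = 400L, n = 24L, seed = 1L, ...) {
    cfg <- simConfig(p = p, n = n, seed = seed, ...)
    cfg
}

# planted single-factor matrix: loadings on a probe subset + iid noise
plantedFactor <- function(p, n, frac = 0.3, noiseSd = 0.5, seed = 1) {
    set.seed(seed)
    g <- rnorm(n)
    nl <- round(frac * p)
    Y <- matrix(rnorm(p * n, sd = noiseSd), p, n)
    Y[seq_len(nl), ] <- Y[seq_len(nl), ] + outer(rnorm(nl), g)
    list(Y = Y, g = g)
}
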