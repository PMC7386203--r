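test_that("fdrAdjust reproduces step-up q-values and their invariants", {
    expect_equal(fdrAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
    expect_equal(fdrAdjust(c(1, 1, 1)), c(1, 1, 1))
    expect_equal(fdrAdjust(0.2), 0.2)
    p <- c(0.001, 0.2, 0.04, 0.9, 0.015)
    q <- fdrAdjust(p)
    expect_true(all(q >= p))
    # invariant to gene ordering
    o <- c(3, 1, 5, 2, 4)
    expect_equal(fdrAdjust(p[o]), q[o])
    expect_error(fdrAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
    expect_error(fdrAdjust(c(0.5, NA)), "missing")
})

test_that("cohensD is the pooled standardized mean difference", {
    expect_equal(cohensD(c(1, 2, 3, 1, 2, 3), c(1, 1, 1, 0, 0, 0)), 0)
    expect_warning(d <- cohensD(c(0, 0, 1, 1), c(1, 1, 0, 0)), "pooled")
    expect_true(is.nan(d))
    expect_error(cohensD(1:4, c(1, 1, 1, 1)), "non-empty")
    set.seed(31)
    sc <- c(rnorm(10000, 0.4, 0.1), rnorm(10000, 0.5, 0.1))
    lab <- rep(c(1, 0), each = 10000)
    expect_equal(cohensD(sc, lab), -1, tolerance = 0.05)
})

test_that("categorical phenotypes split one-vs-rest", {
    y <- c(a = "x", b = "y", c = "x", d = "z")
    out <- splitCategorical(y)
    expect_named(out, c("x", "y", "z"))
    expect_equal(out$x, c(a = 1, b = 0, c = 1, d = 0))
    two <- splitCategorical(c(s1 = "m", s2 = "f"))
    expect_equal(unname(two$m + two$f), c(1, 1))
    expect_error(splitCategorical(c("only", "only")), "2 categories")
    f <- factor(c("a", "b"), levels = c("a", "b", "ghost"))
    expect_error(splitCategorical(f), "ghost")
})

test_that("testGene flags score vectors with no usable variance", {
    set.seed(1)
    y <- rnorm(100)
    out <- testGene(D = rep(1, 100), y = y, model = "dominant")
    expect_identical(out$p, 1)
    expect_identical(out$flag, "degenerate")
    outB <- testGene(D = rep(1, 100), y = as.numeric(y > 0),
                     model = "dominant", kind = "binary")
    expect_identical(outB$flag, "degenerate")
    expect_error(testGene(D = NULL, y = y, model = "dominant"), "requires")
})

test_that("generalized test collapses to 1 df when D and R coincide", {
    set.seed(2)
    D <- runif(500)
    y <- 0.4 * D + rnorm(500)
    C <- cbind(rnorm(500), rnorm(500))
    pDom <- testGene(D = D, y = y, covariates = C, model = "dominant")$p
    gen <- testGene(D = D, R = D, y = y, covariates = C,
                    model = "generalized")
    expect_equal(gen$p, pDom, tolerance = 1e-9)
    expect_identical(gen$flag, "collinear")
})

test_that("continuous tests match R's reference lm machinery", {
    set.seed(3)
    n <- 300
    D <- runif(n); R <- pmin(1, D + runif(n, 0, 0.3))
    C <- cbind(age = rnorm(n), pc1 = rnorm(n))
    y <- 0.5 * D - 0.3 * R + 0.2 * C[, 1] + rnorm(n)
    ref <- summary(lm(y ~ C + D))
    out <- testGene(D = D, y = y, covariates = C, model = "dominant")
    expect_equal(out$p, unname(ref$coefficients["D", 4]), tolerance = 1e-10)
    expect_equal(unname(out$beta["D"]),
                 unname(ref$coefficients["D", 1]), tolerance = 1e-10)
    full <- lm(y ~ C + D + R)
    refF <- anova(lm(y ~ C), full)
    gen <- testGene(D = D, R = R, y = y, covariates = C,
                    model = "generalized")
    expect_equal(gen$p, refF$`Pr(>F)`[2], tolerance = 1e-10)
})

test_that("binary tests match R's reference glm machinery", {
    set.seed(4)
    n <- 600
    D <- runif(n); R <- runif(n)
    C <- cbind(cov = rnorm(n))
    eta <- -1 + 1.5 * D + 0.3 * C[, 1]
    y <- rbinom(n, 1, plogis(eta))
    ref <- summary(glm(y ~ C + D, family = binomial()))
    out <- testGene(D = D, y = y, covariates = C, model = "dominant",
                    kind = "binary")
    expect_equal(out$p, unname(ref$coefficients["D", 4]), tolerance = 1e-6)
    refLrt <- anova(glm(y ~ C, family = binomial()),
                    glm(y ~ C + D + R, family = binomial()), test = "LRT")
    gen <- testGene(D = D, R = R, y = y, covariates = C,
                    model = "generalized", kind = "binary")
    expect_equal(gen$p, refLrt$`Pr(>Chi)`[2], tolerance = 1e-6)
})

test_that("logistic separation is flagged and reported at p = 1", {
    D <- c(rep(0, 20), rep(1, 20))
    y <- c(rep(0, 20), rep(1, 20))
    out <- testGene(D = D, y = y, model = "dominant", kind = "binary")
    expect_identical(out$flag, "separation")
    expect_identical(out$p, 1)
})

smallScores <- function(nGenes = 5, n = 40, seed = 8) {
    set.seed(seed)
    D <- matrix(runif(nGenes * n, 0.3, 1), nGenes, n,
                dimnames = list(paste0("G", seq_len(nGenes)),
                                paste0("S", seq_len(n))))
    R <- D + matrix(runif(nGenes * n, 0, 0.2), nGenes, n)
    R[R > 1] <- 1
    GeneScores(D, R, nVariants = rep(3L, nGenes))
}

test_that("runPWAS validates alignment and returns an empty frame for zero genes", {
    gs <- smallScores()
    y <- rnorm(40); names(y) <- paste0("S", 1:40)
    bad <- y; names(bad)[1] <- "NOT_A_SAMPLE"
    expect_error(runPWAS(gs, bad), "NOT_A_SAMPLE")
    res0 <- runPWAS(gs[integer(0), ], y)
    expect_s3_class(res0, "data.frame")
    expect_identical(nrow(res0), 0L)
})

test_that("runPWAS recovers a planted binary association with the right sign", {
    # common variants so the recessive column is well populated and the
    # logistic fit is regular
    co <- simulateCohort(nSamples = 1500, nGenes = 30,
                         alleleFreqRange = c(0.05, 0.2), seed = 15)
    gs <- suppressMessages(buildGeneScores(co$genotypes))
    g <- plantableGene(gs, "recessive")
    # negative beta: cases carry more damaged (lower) recessive scores
    pl <- plantAssociation(gs, g, "recessive", beta = -0.5,
                           kind = "binary", prevalence = 0.25, seed = 44)
    res <- runPWAS(gs, pl$phenotype, covariates = co$covariates,
                   kind = "binary")
    row <- res[res$gene_id == g, ]
    expect_lt(row$q_recessive, 0.05)
    expect_lt(row$effect_recessive, 0)
    expect_true(row$significant_recessive)
})

test_that("an uninformative covariate does not systematically shift p-values", {
    set.seed(71)
    n <- 300; reps <- 100
    C <- cbind(rnorm(n))
    deltas <- replicate(reps, {
        D <- runif(n)
        y <- rnorm(n)
        p1 <- testGene(D = D, y = y, covariates = C,
                       model = "dominant")$p
        p2 <- testGene(D = D, y = y, covariates = cbind(C, rnorm(n)),
                       model = "dominant")$p
        qnorm(p1) - qnorm(p2)
    })
    # paired comparison across simulated genes: no systematic shift
    expect_gt(stats::wilcox.test(deltas)$p.value, 0.01)
    expect_lt(abs(mean(deltas)), 0.05)
})

test_that("logistic type-I error stays near nominal on null phenotypes", {
    set.seed(99)
    n <- 400; reps <- 200
    hits <- 0
    for (r in seq_len(reps)) {
        D <- runif(n)
        y <- rbinom(n, 1, 0.3)
        p <- testGene(D = D, y = y, model = "dominant", kind = "binary")$p
        if (p < 0.05) hits <- hits + 1
    }
    expect_gte(hits / reps, 0.01)
    expect_lte(hits / reps, 0.10)
})
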