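test_that("retentionProb follows the genotype-weighted damage model", {
    expect_equal(retentionProb(0.5, 0, 1, 0, mu = 1), 0.5)
    expect_equal(retentionProb(0.5, 0, 0, 1, mu = 0), 0.25)
    expect_equal(retentionProb(0.5, 0, 0, 1, mu = 0.5), 0.375)
    expect_equal(retentionProb(0.3, 1, 0, 0, mu = 0), 1)
    # against the enumeration oracle across a grid
    for (s in c(0, 0.25, 0.5, 0.75, 1))
        for (g in 0:2)
            for (mu in c(0, 0.5, 1)) {
                tr <- hardTriplet(g)
                expect_equal(retentionProb(s, tr["p0", ], tr["p1", ],
                                           tr["p2", ], mu),
                             unname(oracleGeneRetention(s, g, mu)["p0"]),
                             tolerance = 1e-12, ignore_attr = TRUE)
            }
    expect_error(retentionProb(1.2, 0, 1, 0, 1), "\\[0, 1\\]")
    expect_error(retentionProb(0.5, 0.5, 0.2, 0.2, 1), "sum to 1")
})

test_that("singleHitProb matches the exactly-one-hit enumeration", {
    expect_equal(singleHitProb(0.4, 0, 1, 0, mu = 0), 0.6)
    expect_equal(singleHitProb(0.4, 0, 1, 0, mu = 1), 0.6)
    # fully dependent homozygote cannot produce exactly one hit
    expect_equal(singleHitProb(0.5, 0, 0, 1, mu = 1), 0)
    expect_equal(singleHitProb(0.5, 0, 0, 1, mu = 0), 0.5)
    for (s in c(0, 0.25, 0.5, 0.75, 1))
        for (g in 0:2)
            for (mu in c(0, 0.5, 1)) {
                tr <- hardTriplet(g)
                oc <- oracleGeneRetention(s, g, mu)
                expect_equal(singleHitProb(s, tr["p0", ], tr["p1", ],
                                           tr["p2", ], mu),
                             unname(oc["p01"] - oc["p0"]),
                             tolerance = 1e-12, ignore_attr = TRUE)
            }
})

test_that("dominantScore interpolates between product and minimum", {
    expect_equal(dominantScore(0.5, p = 3), 0.5)
    expect_equal(dominantScore(c(0.8, 0.5), p = 1), 0.4)
    expect_equal(dominantScore(c(0.8, 0.5), p = Inf), 0.5)
    # frozen value from a 50-digit arithmetic oracle
    expect_equal(dominantScore(c(0.8, 0.5), p = 1.25),
                 0.43839600698903855, tolerance = 1e-14)
    expect_identical(dominantScore(c(0.9, 0, 0.7), p = 1.25), 0)
    expect_error(dominantScore(numeric(0), p = 1), "non-empty")
    expect_error(dominantScore(c(0.5, 1.5), p = 1), "\\[0, 1\\]")
})

test_that("dominantScore at huge finite p converges to the max-norm branch", {
    set.seed(5)
    for (r in 1:20) {
        x <- runif(sample(1:6, 1), min = 0.01, max = 1)
        expect_equal(dominantScore(x, p = 1e6), dominantScore(x, p = Inf),
                     tolerance = 1e-6)
    }
})

test_that("recessiveScore hits all four limit cases", {
    # (a) two zeros
    expect_identical(recessiveScore(c(0, 0), c(1, 1), p = 1.25, q = 3), 0)
    expect_identical(recessiveScore(c(0, 0.5, 0), c(1, 0.5, 1),
                                    p = Inf, q = 3), 0)
    # (b) exactly one zero, p > 1 -> y_i
    expect_equal(recessiveScore(c(0, 0.8), c(0.7, 0.2), p = 1.25, q = 3),
                 0.7)
    # (c) exactly one zero, p = 1 -> y_i * prod of other x
    expect_equal(recessiveScore(c(0, 0.8, 0.5), c(0.7, 0.2, 0.5),
                                p = 1, q = 1), 0.7 * 0.8 * 0.5)
    # (d) all nonzero -> (1 + zeta_q) * D_p
    x <- c(0.9, 0.6); y <- c(0.1, 0.3)
    zeta <- (sum((y / x)^3))^(1 / 3)
    expect_equal(recessiveScore(x, y, p = 1, q = 3),
                 min(1, (1 + zeta) * prod(x)))
    expect_error(recessiveScore(c(0.5), c(0.5, 0.5), p = 1, q = 1),
                 "same length")
})

test_that("a single heterozygous variant can never yield two hits (R = 1)", {
    for (s in c(0.01, 0.1, 0.25, 0.5, 0.75, 0.99, 1)) {
        x <- retentionProb(s, 0, 1, 0, mu = 0.5)
        y <- singleHitProb(s, 0, 1, 0, mu = 0.5)
        expect_identical(recessiveScore(x, y, p = Inf, q = 3), 1)
        expect_identical(recessiveScore(x, y, p = 1, q = 1), 1)
    }
})

test_that("homozygous variant at mu = 0.5 follows the closed form 1.5s - 0.5s^2", {
    for (s in c(0.1, 0.25, 0.5, 0.8, 1)) {
        x <- retentionProb(s, 0, 0, 1, mu = 0.5)
        y <- singleHitProb(s, 0, 0, 1, mu = 0.5)
        expect_equal(recessiveScore(x, y, p = Inf, q = 3),
                     min(1, 1.5 * s - 0.5 * s^2), tolerance = 1e-12)
    }
    # the worked value: s = 0.5 -> x = 0.375, y = 0.25, R = 0.625
    expect_equal(recessiveScore(0.375, 0.25, p = Inf, q = 3), 0.625)
})

test_that("recessive score exceeding 1 is clipped back to the unit interval", {
    # many mildly-damaging het variants inflate (1 + zeta_q) D_p above 1
    x <- rep(0.9, 10); y <- rep(0.1, 10)
    raw <- (1 + pNorm(y / x, 3)) * min(x)
    expect_gt(raw, 1)
    expect_identical(recessiveScore(x, y, p = Inf, q = 3), 1)
})

test_that("aggregation at p = q = 1, mu = 0 equals the enumeration oracle", {
    grid <- c(0, 0.25, 0.5, 0.75, 1)
    for (k in 1:2) {
        sCombos <- as.matrix(expand.grid(rep(list(grid), k)))
        gCombos <- as.matrix(expand.grid(rep(list(0:2), k)))
        for (i in seq_len(nrow(sCombos)))
            for (j in seq_len(nrow(gCombos))) {
                ss <- sCombos[i, ]; gg <- gCombos[j, ]
                tr <- hardTriplet(gg)
                x <- retentionProb(ss, tr["p0", ], tr["p1", ], tr["p2", ], 0)
                y <- singleHitProb(ss, tr["p0", ], tr["p1", ], tr["p2", ], 0)
                oc <- oracleGeneRetention(ss, gg, 0)
                expect_equal(dominantScore(x, p = 1), unname(oc["p0"]),
                             tolerance = 1e-12, ignore_attr = TRUE)
                expect_equal(recessiveScore(x, y, p = 1, q = 1),
                             min(1, unname(oc["p01"])),
                             tolerance = 1e-12, ignore_attr = TRUE)
            }
    }
})

test_that("dominant score is monotone in scores and genotype dosage", {
    set.seed(42)
    for (r in 1:50) {
        k <- sample(1:4, 1)
        s <- runif(k, 0.05, 0.95)
        g <- sample(0:2, k, replace = TRUE)
        tr <- hardTriplet(g)
        x <- retentionProb(s, tr["p0", ], tr["p1", ], tr["p2", ], mu = 0.5)
        d0 <- dominantScore(x, p = 1.25)
        # raising a score cannot lower D
        s2 <- s; i <- sample(k, 1); s2[i] <- min(1, s2[i] + 0.3)
        x2 <- retentionProb(s2, tr["p0", ], tr["p1", ], tr["p2", ], mu = 0.5)
        expect_gte(dominantScore(x2, p = 1.25), d0 - 1e-12)
        # moving dosage mass from p0 to p2 cannot raise D
        x3 <- x
        x3[i] <- retentionProb(s[i], 0, 0, 1, mu = 0.5)
        expect_lte(dominantScore(x3, p = 1.25), d0 + 1e-12)
    }
})

makeGp <- function(variants, g) {
    # g: variants x samples matrix of hard allele counts
    p0 <- matrix(as.numeric(g == 0), nrow(g), ncol(g))
    p1 <- matrix(as.numeric(g == 1), nrow(g), ncol(g))
    p2 <- matrix(as.numeric(g == 2), nrow(g), ncol(g))
    colnames(p0) <- paste0("S", seq_len(ncol(g)))
    GenotypeProbs(p0, p1, p2, variants, sampleIds = colnames(p0))
}

test_that("buildGeneScores handles reference, LoF and compound-het samples", {
    v <- data.frame(
        variant_key = c("1:10:A:G", "1:20:C:T", "1:30:G:A"),
        gene_id = c("G1", "G1", "G2"),
        consequence = c("nonsense", "nonsense", "missense"),
        score = c(0, 0, 0.5), stringsAsFactors = FALSE)
    # samples: ref everywhere; hom LoF; compound het (two het LoF in G1)
    g <- cbind(c(0, 0, 0), c(2, 0, 0), c(1, 1, 0))
    gs <- buildGeneScores(makeGp(v, g), AggregationParams())
    D <- dominantScores(gs); R <- recessiveScores(gs)
    expect_equal(unname(D["G1", 1]), 1)
    expect_equal(unname(R["G1", 1]), 1)
    expect_equal(unname(D["G1", 2]), 0)   # homozygous LoF
    expect_equal(unname(R["G1", 2]), 0)
    expect_equal(unname(D["G1", 3]), 0)   # compound het: one hit certain
    expect_equal(unname(R["G1", 3]), 0)   # ...and so is the second
    # untouched gene scores exactly 1 everywhere
    expect_equal(unname(D["G2", ]), c(1, 1, 1))
    expect_equal(unname(R["G2", ]), c(1, 1, 1))
})

test_that("buildGeneScores applies per-model mu and supports variant-free genes", {
    v <- data.frame(variant_key = "1:10:A:G", gene_id = "G1",
                    consequence = "missense", score = 0.5,
                    stringsAsFactors = FALSE)
    gp <- makeGp(v, matrix(2, 1, 1))   # one homozygous sample
    par <- AggregationParams(muD = 1, pD = 1.25, muR = 0, pR = Inf, qR = 3)
    gs <- buildGeneScores(gp, par, geneIds = c("G1", "G_empty"))
    # dominant x uses muD = 1 (gives s), recessive x uses muR = 0 (gives s^2)
    expect_equal(unname(dominantScores(gs)["G1", 1]), 0.5)
    expect_equal(unname(recessiveScores(gs)["G1", 1]),
                 min(1, 0.25 + 2 * 0.5 * 0.5))   # x + y at k = 1
    expect_equal(unname(dominantScores(gs)["G_empty", 1]), 1)
    expect_equal(unname(recessiveScores(gs)["G_empty", 1]), 1)
    expect_error(buildGeneScores(gp, par, geneIds = "OTHER"), "G1")
})

test_that("matrix aggregation agrees with the scalar operations", {
    set.seed(9)
    par <- AggregationParams()
    for (r in 1:20) {
        k <- sample(1:5, 1)
        v <- data.frame(variant_key = sprintf("1:%d:A:G", 1:k * 10),
                        gene_id = "G1",
                        consequence = "missense",
                        score = round(runif(k), 3),
                        stringsAsFactors = FALSE)
        g <- matrix(sample(0:2, k * 3, replace = TRUE,
                           prob = c(.6, .3, .1)), k, 3)
        gs <- buildGeneScores(makeGp(v, g), par)
        for (j in 1:3) {
            tr <- hardTriplet(g[, j])
            xD <- retentionProb(v$score, tr["p0", ], tr["p1", ],
                                tr["p2", ], par@muD)
            xR <- retentionProb(v$score, tr["p0", ], tr["p1", ],
                                tr["p2", ], par@muR)
            y <- singleHitProb(v$score, tr["p0", ], tr["p1", ],
                               tr["p2", ], par@muR)
            expect_equal(unname(dominantScores(gs)["G1", j]),
                         dominantScore(xD, par@pD), tolerance = 1e-12)
            expect_equal(unname(recessiveScores(gs)["G1", j]),
                         recessiveScore(xR, y, par@pR, par@qR),
                         tolerance = 1e-12)
        }
    }
})

test_that("missing genotype calls leave the gene fully functional", {
    v <- data.frame(variant_key = c("1:10:A:G", "1:20:C:T"),
                    gene_id = "G1", consequence = "nonsense", score = 0,
                    stringsAsFactors = FALSE)
    # sample 1: missing call encoded as (1,0,0) at both variants
    gp <- makeGp(v, matrix(c(0, 0, 1, 0), 2, 2))
    gs <- buildGeneScores(gp)
    expect_equal(unname(dominantScores(gs)["G1", 1]), 1)
    expect_equal(unname(recessiveScores(gs)["G1", 1]), 1)
    expect_equal(unname(dominantScores(gs)["G1", 2]), 0)
})
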