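#' Simulated genetic effect of one gene
#'
#' Builds the latent genetic effect x of a gene on a phenotype from its
#' dominant and recessive score columns: the dominant column, the
#' recessive column, or (for additive inheritance) the standardized sum of
#' the two standardized columns. The result is standardized to mean 0 and
#' standard deviation 1 across the cohort, so that the effect size beta in
#' \code{\link{simulatePhenotype}} is on a common scale regardless of the
#' gene's score distribution.
#'
#' @param dom,rec Numeric score vectors in [0, 1] (one gene's dominant and
#'   recessive columns across samples).
#' @param inheritance One of \code{"dominant"}, \code{"recessive"},
#'   \code{"additive"}.
#' @return Standardized numeric vector (mean 0, sd 1).
#' @export
simulateGeneEffect <- function(dom, rec,
                               inheritance = c("dominant", "recessive",
                                               "additive")) {
    inheritance <- match.arg(inheritance)
    if (length(dom) != length(rec))
        stop("'dom' and 'rec' must have the same length")
    std <- function(v, what) {
        s <- sd(v)
        # tolerance well above accumulated floating-point noise on [0, 1]
        # scores, so columns without true variability are rejected
        if (!is.finite(s) || s < 1e-8)
            stop(sprintf("%s score column has zero variance; gene unusable for simulation", what))
        (v - mean(v)) / s
    }
    switch(inheritance,
        dominant = std(dom, "dominant"),
        recessive = std(rec, "recessive"),
        additive = std(std(dom, "dominant") + std(rec, "recessive"),
                       "additive"))
}

#' Simulate a phenotype from a standardized genetic effect
#'
#' Continuous phenotypes follow \code{y = beta * x + N(0, 1)} per sample.
#' Binary phenotypes use a liability threshold: the same latent y is
#' dichotomized at the upper \code{prevalence} quantile of its theoretical
#' distribution N(0, 1 + beta^2), so the expected case fraction equals
#' \code{prevalence}.
#'
#' @param x Standardized genetic effect (from
#'   \code{\link{simulateGeneEffect}}).
#' @param beta Effect size of the gene.
#' @param kind \code{"continuous"} or \code{"binary"}.
#' @param prevalence Expected case fraction for binary phenotypes
#'   (default 0.1).
#' @param seed Integer seed; output is deterministic given the seed.
#' @return Numeric phenotype vector (0/1 for binary), named like \code{x}.
#' @export
#' @examples
#' x <- simulateGeneEffect(runif(100), runif(100), "dominant")
#' y <- simulatePhenotype(x, beta = 0.5, kind = "continuous", seed = 1)
simulatePhenotype <- function(x, beta, kind = c("continuous", "binary"),
                              prevalence = 0.1, seed = NULL) {
    kind <- match.arg(kind)
    stopifnot(is.numeric(x), length(x) >= 1, is.numeric(beta),
              length(beta) == 1L, is.finite(beta))
    if (kind == "binary" && (prevalence <= 0 || prevalence >= 1))
        stop("'prevalence' must lie in (0, 1)")
    y <- .maybeWithSeed(seed, beta * x + rnorm(length(x)))
    if (kind == "binary") {
        thr <- qnorm(1 - prevalence, mean = 0, sd = sqrt(1 + beta^2))
        y <- as.numeric(y > thr)
    }
    names(y) <- names(x)
    y
}

# Rebuild the dominant/recessive columns of a single gene for a subset of
# samples, optionally with perturbed variant scores. Used by the power
# simulation so that score noise propagates through the aggregation.
.geneColumns <- function(genotypes, rows, sampleIdx, scores, params) {
    P0 <- assay(genotypes, "p0")[rows, sampleIdx, drop = FALSE]
    P1 <- assay(genotypes, "p1")[rows, sampleIdx, drop = FALSE]
    P2 <- assay(genotypes, "p2")[rows, sampleIdx, drop = FALSE]
    .aggregateGene(P0, P1, P2, scores, params)
}

#' Estimate statistical power by simulation
#'
#' Estimates, as a function of cohort size, the power of the gene-level
#' association test under a chosen inheritance mode, effect size and
#' variant-score noise level. Each replicate picks a gene at random from
#' the pool, subsamples the cohort, perturbs the gene's variant effect
#' scores with Gaussian noise of sd \code{epsilon} (clipped to [0, 1]),
#' rebuilds the gene's dominant and recessive scores from the perturbed
#' variant scores, simulates a phenotype from the matching standardized
#' gene effect, and runs the matching association test (dominant
#' inheritance is tested by the dominant model, recessive by the
#' recessive model, additive by the generalized model). Power is the
#' fraction of replicates significant at \code{alpha}, with a 95% Wilson
#' confidence interval.
#'
#' @param genotypes A \linkS4class{GenotypeProbs} gene pool (scored
#'   variants in \code{rowData}).
#' @param params \linkS4class{AggregationParams} used to rebuild scores.
#' @param covariates Optional covariate matrix (sample rownames) included
#'   in every test.
#' @param inheritance \code{"dominant"}, \code{"recessive"} or
#'   \code{"additive"}.
#' @param beta Effect size of the simulated gene.
#' @param epsilon Standard deviation of the Gaussian noise added to the
#'   gene's variant effect scores before aggregation (0 = no noise).
#' @param cohortSizes Integer vector of cohort sizes; each must not
#'   exceed the number of available samples.
#' @param nReplicates Replicates per cohort size (>= 20 recommended for a
#'   meaningful confidence interval).
#' @param kind Phenotype kind, \code{"continuous"} or \code{"binary"}.
#' @param alpha Per-test significance level inside the power loop
#'   (default 0.05; single-gene design).
#' @param prevalence Case prevalence for binary phenotypes.
#' @param seed Integer seed; the full power table is deterministic given
#'   the seed.
#' @return A \code{data.frame} with one row per cohort size: power
#'   estimate, Wilson 95% CI, and the simulation settings.
#' @export
estimatePower <- function(genotypes, params = AggregationParams(),
                          covariates = NULL,
                          inheritance = c("dominant", "recessive",
                                          "additive"),
                          beta, epsilon = 0, cohortSizes,
                          nReplicates = 50,
                          kind = c("continuous", "binary"),
                          alpha = 0.05, prevalence = 0.1, seed = NULL) {
    stopifnot(is(genotypes, "GenotypeProbs"))
    inheritance <- match.arg(inheritance)
    kind <- match.arg(kind)
    stopifnot(is.numeric(beta), length(beta) == 1L, is.finite(beta),
              is.numeric(epsilon), length(epsilon) == 1L, epsilon >= 0,
              alpha > 0, alpha < 1)
    cohortSizes <- as.integer(cohortSizes)
    nAvail <- ncol(genotypes)
    if (any(cohortSizes < 2L) || any(cohortSizes > nAvail))
        stop(sprintf("cohort sizes must lie in [2, %d] (available samples)", nAvail))
    if (nReplicates < 20)
        warning("fewer than 20 replicates gives a wide confidence interval")
    rd <- rowData(genotypes)
    scores <- rd$score
    if (is.null(scores) || anyNA(scores))
        stop("all variants must carry effect scores")
    geneRows <- split(seq_len(nrow(genotypes)), as.character(rd$gene_id))
    model <- switch(inheritance, dominant = "dominant",
                    recessive = "recessive", additive = "generalized")

    .maybeWithSeed(seed, {
        out <- lapply(cohortSizes, function(nc) {
            hits <- 0L
            for (r in seq_len(nReplicates)) {
                sampleIdx <- sample.int(nAvail, nc)
                x <- NULL
                for (try in seq_len(50L)) {
                    rows <- geneRows[[sample.int(length(geneRows), 1L)]]
                    sc <- scores[rows]
                    if (epsilon > 0)
                        sc <- .clip01(sc + rnorm(length(sc), 0, epsilon))
                    agg <- .geneColumns(genotypes, rows, sampleIdx, sc,
                                        params)
                    x <- tryCatch(
                        simulateGeneEffect(agg$D, agg$R, inheritance),
                        error = function(e) NULL)
                    if (!is.null(x)) break
                }
                if (is.null(x))
                    stop("could not draw a gene with non-constant scores in 50 attempts")
                y <- simulatePhenotype(x, beta, kind,
                                       prevalence = prevalence)
                names(y) <- colnames(genotypes)[sampleIdx]
                C <- if (is.null(covariates)) NULL else
                    covariates[names(y), , drop = FALSE]
                tst <- testGene(D = agg$D, R = agg$R, y = y,
                                covariates = C, model = model, kind = kind)
                if (tst$p < alpha) hits <- hits + 1L
            }
            ci <- wilsonInterval(hits, nReplicates)
            data.frame(cohort_size = nc, power = ci[["estimate"]],
                       ci_lo = ci[["lo"]], ci_hi = ci[["hi"]],
                       n_replicates = nReplicates,
                       inheritance = inheritance, beta = beta,
                       epsilon = epsilon, alpha = alpha,
                       stringsAsFactors = FALSE)
        })
        do.call(rbind, out)
    })
}
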