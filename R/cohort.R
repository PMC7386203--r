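#' @importFrom stats rbeta rbinom rlnorm rpois runif
NULL

#' Simulate a fully synthetic cohort
#'
#' Generates gene architectures, scored variants, Hardy-Weinberg
#' genotypes and covariates for a cohort, so the whole pipeline can be
#' exercised without external data. Variant counts per gene follow a
#' log-normal distribution (default mean about 36 variants per gene,
#' emulating the typical number of non-synonymous variants affecting a
#' protein-coding gene in a large biobank); alternate allele frequencies
#' are drawn log-uniformly from \code{alleleFreqRange}; genotypes are
#' sampled as Binomial(2, f) allele counts (Hardy-Weinberg); missense
#' scores are Beta-distributed, loss-of-function classes score exactly 0,
#' and in-frame indels get rule-based scores from Poisson residue counts.
#' Covariates are standard normal. Variants are independent (no linkage
#' disequilibrium is simulated).
#'
#' @param nSamples,nGenes Cohort dimensions.
#' @param variantsPerGene Named numeric vector \code{c(meanlog=, sdlog=)}
#'   of the log-normal variant-count distribution (counts are rounded and
#'   floored at 1).
#' @param alleleFreqRange Length-2 vector (min, max) of alternate allele
#'   frequencies, within (0, 0.5].
#' @param consequenceMix Named proportions over the five consequence
#'   classes (must sum to 1).
#' @param missenseShape Length-2 Beta(a, b) shape parameters of the
#'   missense score distribution.
#' @param nCovariates Number of standard-normal covariates.
#' @param seed Integer seed; the cohort is deterministic given the seed.
#' @return A list with elements \code{genotypes}
#'   (\linkS4class{GenotypeProbs} with scored variants in rowData),
#'   \code{variants} (data.frame) and \code{covariates} (matrix with
#'   sample rownames).
#' @export
#' @examples
#' cohort <- simulateCohort(nSamples = 50, nGenes = 3, seed = 1)
#' cohort$genotypes
simulateCohort <- function(nSamples, nGenes,
                           variantsPerGene = c(meanlog = log(36) - 0.5,
                                               sdlog = 1),
                           alleleFreqRange = c(0.001, 0.05),
                           consequenceMix = c(missense = 0.85,
                                              nonsense = 0.05,
                                              frameshift = 0.05,
                                              canonical_splice = 0.03,
                                              inframe_indel = 0.02),
                           missenseShape = c(0.5, 0.5),
                           nCovariates = 5, seed = NULL) {
    stopifnot(nSamples >= 1, nGenes >= 1, nCovariates >= 0)
    if (any(alleleFreqRange <= 0) || any(alleleFreqRange > 0.5) ||
        alleleFreqRange[1] > alleleFreqRange[2])
        stop("'alleleFreqRange' must be an increasing pair within (0, 0.5]")
    if (!setequal(names(consequenceMix), consequenceClasses()))
        stop("'consequenceMix' must name exactly the five consequence classes")
    if (abs(sum(consequenceMix) - 1) > 1e-6)
        stop("'consequenceMix' proportions must sum to 1")
    .maybeWithSeed(seed, {
        geneIds <- sprintf("GENE%04d", seq_len(nGenes))
        kPerGene <- pmax(1L, as.integer(round(rlnorm(
            nGenes, variantsPerGene[["meanlog"]],
            variantsPerGene[["sdlog"]]))))
        m <- sum(kPerGene)
        if (m < 1) stop("infeasible cohort: zero variants")
        gid <- rep(geneIds, kPerGene)
        cons <- sample(names(consequenceMix), m, replace = TRUE,
                       prob = consequenceMix)
        # log-uniform allele frequencies
        lf <- runif(m, log(alleleFreqRange[1]), log(alleleFreqRange[2]))
        freq <- exp(lf)
        pos <- seq_len(m) * 100L
        refalt <- matrix(c("A", "G", "C", "T", "G", "A", "T", "C"),
                         ncol = 2, byrow = TRUE)
        ra <- refalt[(seq_len(m) - 1L) %% 4L + 1L, , drop = FALSE]
        variants <- data.frame(
            variant_key = sprintf("1:%d:%s:%s", pos, ra[, 1], ra[, 2]),
            gene_id = gid,
            consequence = cons,
            score = NA_real_,
            n_sub = NA_integer_, n_ins = NA_integer_, n_del = NA_integer_,
            allele_freq = freq,
            stringsAsFactors = FALSE)
        mis <- cons == "missense"
        variants$score[mis] <- rbeta(sum(mis), missenseShape[1],
                                     missenseShape[2])
        ind <- cons == "inframe_indel"
        variants$n_sub[ind] <- rpois(sum(ind), 2)
        variants$n_ins[ind] <- rpois(sum(ind), 1)
        variants$n_del[ind] <- rpois(sum(ind), 1)
        variants <- scoreVariants(variants)

        sampleIds <- sprintf("S%05d", seq_len(nSamples))
        g <- matrix(rbinom(m * nSamples, 2L, rep(freq, nSamples)),
                    nrow = m, ncol = nSamples)
        p0 <- matrix(as.numeric(g == 0L), m, nSamples)
        p1 <- matrix(as.numeric(g == 1L), m, nSamples)
        p2 <- matrix(as.numeric(g == 2L), m, nSamples)
        colnames(p0) <- sampleIds
        gp <- GenotypeProbs(p0, p1, p2, variants, sampleIds = sampleIds)

        covariates <- NULL
        if (nCovariates > 0) {
            covariates <- matrix(rnorm(nSamples * nCovariates),
                                 nSamples, nCovariates,
                                 dimnames = list(sampleIds,
                                     paste0("cov", seq_len(nCovariates))))
        }
        list(genotypes = gp, variants = variants, covariates = covariates)
    })
}

#' Plant a gene-phenotype association in a synthetic cohort
#'
#' Simulates a phenotype driven by one chosen gene under a chosen
#' inheritance mode and effect size, and returns the ground truth for
#' later assertion. The phenotype is generated by
#' \code{\link{simulatePhenotype}} on the gene's standardized effect
#' (\code{\link{simulateGeneEffect}}); a gene whose relevant score column
#' is constant (e.g. a gene with only heterozygous carriers has a
#' recessive column identically 1) is rejected.
#'
#' @param geneScores A \linkS4class{GeneScores} object for the cohort.
#' @param geneId The gene to plant the association in.
#' @param inheritance \code{"dominant"}, \code{"recessive"} or
#'   \code{"additive"}.
#' @param beta Effect size.
#' @param kind Phenotype kind.
#' @param prevalence Case prevalence for binary phenotypes.
#' @param seed Integer seed.
#' @return List with \code{phenotype} (named numeric vector) and
#'   \code{truth} (list recording gene_id, inheritance, beta, kind).
#' @export
plantAssociation <- function(geneScores, geneId,
                             inheritance = c("dominant", "recessive",
                                             "additive"),
                             beta, kind = c("continuous", "binary"),
                             prevalence = 0.1, seed = NULL) {
    stopifnot(is(geneScores, "GeneScores"))
    inheritance <- match.arg(inheritance)
    kind <- match.arg(kind)
    genes <- rowData(geneScores)$gene_id
    if (!geneId %in% genes)
        stop(sprintf("gene '%s' is not in the score matrices", geneId))
    i <- match(geneId, genes)
    dom <- dominantScores(geneScores)[i, ]
    rec <- recessiveScores(geneScores)[i, ]
    x <- simulateGeneEffect(dom, rec, inheritance)
    names(x) <- colnames(geneScores)
    phenotype <- simulatePhenotype(x, beta, kind, prevalence = prevalence,
                                   seed = seed)
    list(phenotype = phenotype,
         truth = list(gene_id = geneId, inheritance = inheritance,
                      beta = beta, kind = kind))
}
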