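#' Probability that a gene retains function given one variant
#'
#' For a variant with effect score \code{s} (the probability that the
#' protein retains its function given one hit) and genotype probabilities
#' \code{(p0, p1, p2)} of carrying 0, 1 or 2 alternate alleles, the gene
#' retains its function with probability
#' \deqn{x = p_0 \cdot 1 + p_1 \cdot s + p_2 \cdot (\mu s + (1-\mu) s^2),}
#' where \eqn{\mu \in [0,1]} interpolates between treating the two
#' homozygous hits as independent (\eqn{\mu = 0}, giving \eqn{s^2}) and
#' fully dependent (\eqn{\mu = 1}, giving \eqn{s}).
#'
#' All arguments are vectorized and recycled to a common length.
#'
#' @param s Variant effect score(s) in [0, 1].
#' @param p0,p1,p2 Genotype probabilities in [0, 1] (each triplet summing
#'   to 1).
#' @param mu Homozygous-dependence parameter in [0, 1].
#' @return Retention probability x in [0, 1].
#' @seealso \code{\link{singleHitProb}}, \code{\link{dominantScore}}
#' @export
#' @examples
#' retentionProb(0.5, 0, 1, 0, mu = 1)    # heterozygous: just s
#' retentionProb(0.5, 0, 0, 1, mu = 0)    # independent homozygous: s^2
retentionProb <- function(s, p0, p1, p2, mu) {
    .checkUnit(s, "s"); .checkUnit(mu, "mu")
    .checkTriplet(p0, p1, p2)
    .clip01(p0 * 1 + p1 * s + p2 * (mu * s + (1 - mu) * s^2))
}

#' Probability that a variant damages exactly one gene copy
#'
#' \deqn{y = p_1 (1 - s) + p_2 (1 - \mu) \, 2 s (1 - s).}
#' A heterozygous carrier damages one copy with probability \eqn{1 - s};
#' a homozygous carrier can damage exactly one copy only when the two hits
#' act independently (\eqn{2s(1-s)}, weighted by \eqn{1 - \mu}) -- under
#' full dependence the two copies are either both damaged or both intact.
#'
#' @inheritParams retentionProb
#' @return Single-hit probability y in [0, 1].
#' @export
#' @examples
#' singleHitProb(0.4, 0, 1, 0, mu = 0)    # heterozygous: 1 - s
#' singleHitProb(0.5, 0, 0, 1, mu = 1)    # fully dependent homozygous: 0
singleHitProb <- function(s, p0, p1, p2, mu) {
    .checkUnit(s, "s"); .checkUnit(mu, "mu")
    .checkTriplet(p0, p1, p2)
    .clip01(p1 * (1 - s) + p2 * (1 - mu) * 2 * s * (1 - s))
}

# tolerate floating-point excursions of ~1e-9 beyond the unit interval;
# callers clip after validation
.checkUnit <- function(x, nm) {
    if (!is.numeric(x) || anyNA(x) || any(x < -1e-9) || any(x > 1 + 1e-9))
        stop(sprintf("'%s' must be numeric in [0, 1]", nm))
    invisible(x)
}

.checkTriplet <- function(p0, p1, p2) {
    .checkUnit(p0, "p0"); .checkUnit(p1, "p1"); .checkUnit(p2, "p2")
    if (any(abs(p0 + p1 + p2 - 1) > 1e-6))
        stop("genotype probabilities (p0, p1, p2) must sum to 1")
    invisible(NULL)
}

#' Dominant gene effect score
#'
#' Aggregates the per-variant retention probabilities \eqn{x_1, \dots,
#' x_k} of one gene in one sample into the dominant score
#' \deqn{D = \exp\bigl(-\|(\log 1/x_1, \dots, \log 1/x_k)\|_p\bigr).}
#' At p = 1 this is the full-independence product \eqn{\prod x_i}; at
#' p = Inf it is \eqn{\min x_i} (the most damaging variant dominates).
#' Any \eqn{x_i = 0} forces D = 0.
#'
#' Callers are responsible for emitting 1 for genes with no variants; an
#' empty \code{x} is rejected.
#'
#' @param x Numeric vector of retention probabilities in [0, 1], length
#'   >= 1.
#' @param p Norm order in [1, Inf].
#' @return The dominant score D in [0, 1].
#' @export
#' @examples
#' dominantScore(c(0.8, 0.5), p = 1)     # 0.4
#' dominantScore(c(0.8, 0.5), p = Inf)   # 0.5
dominantScore <- function(x, p) {
    if (!length(x)) stop("'x' must be non-empty; variant-free genes score 1")
    .checkUnit(x, "x")
    x <- .clip01(x)
    stopifnot(length(p) == 1L, p >= 1)
    if (any(x == 0)) return(0)
    # log(1/x) as -log(x); zeros short-circuited above
    exp(-pNorm(-log(x), p))
}

#' Recessive gene effect score
#'
#' Aggregates per-variant retention probabilities \eqn{x_i} and single-hit
#' probabilities \eqn{y_i} into the recessive score -- the probability of
#' at most one damaging hit. When all \eqn{x_i \neq 0},
#' \deqn{R = (1 + \zeta_q) D_p, \qquad
#'       \zeta_q = \|(y_1/x_1, \dots, y_k/x_k)\|_q,}
#' with \eqn{D_p} as in \code{\link{dominantScore}}. Zeros in \code{x} are
#' resolved by the limit of that expression:
#' two or more zeros give 0; a single zero at position i gives \eqn{y_i}
#' when p > 1 and \eqn{y_i \prod_{j \neq i} x_j} when p = 1. With finite q
#' the product \eqn{(1+\zeta_q)D_p} can exceed 1 in some parameter
#' corners; the result is clipped to [0, 1] (scores are interpreted as
#' probabilities).
#'
#' @param x Retention probabilities in [0, 1], length k >= 1.
#' @param y Single-hit probabilities in [0, 1], same length as \code{x}.
#' @param p,q Norm orders in [1, Inf].
#' @return The recessive score R in [0, 1].
#' @export
#' @examples
#' # a single heterozygous variant can never produce two hits:
#' recessiveScore(x = 0.3, y = 0.7, p = Inf, q = 3)   # 1
recessiveScore <- function(x, y, p, q) {
    if (length(x) != length(y))
        stop("'x' and 'y' must have the same length")
    if (!length(x)) stop("'x' must be non-empty; variant-free genes score 1")
    .checkUnit(x, "x"); .checkUnit(y, "y")
    x <- .clip01(x); y <- .clip01(y)
    stopifnot(length(p) == 1L, p >= 1, length(q) == 1L, q >= 1)
    zero <- which(x == 0)
    if (length(zero) >= 2L) return(0)
    if (length(zero) == 1L) {
        i <- zero
        if (p > 1) return(y[i])
        return(y[i] * prod(x[-i]))
    }
    zeta <- pNorm(y / x, q)
    Dp <- exp(-pNorm(-log(x), p))
    .snapOne(min(1, (1 + zeta) * Dp))
}

# Scores within 1e-12 of 1 are 1 at modeling precision (e.g. a single
# heterozygous variant gives R = (1 + (1-s)/s) s = 1 analytically, but
# floating-point evaluation leaves it short by ~1e-16); snapping keeps
# genes with no true recessive variability exactly constant.
.snapOne <- function(r) {
    r[r > 1 - 1e-12] <- 1
    r
}

# Vectorized aggregation of one gene across all samples.
# P0/P1/P2 are k x n matrices, s is length k. Returns list(D, R, clipped).
.aggregateGene <- function(P0, P1, P2, s, params) {
    k <- nrow(P0); n <- ncol(P0)
    sD <- params@muD * s + (1 - params@muD) * s^2
    sR <- params@muR * s + (1 - params@muR) * s^2
    Xd <- P0 + P1 * s + P2 * sD
    Xr <- P0 + P1 * s + P2 * sR
    Y  <- P1 * (1 - s) + P2 * (1 - params@muR) * 2 * s * (1 - s)

    # dominant: zeros force D = 0, masked out of the norm
    zd <- Xd == 0
    Lx <- -log(Xd)
    Lx[zd] <- 0
    D <- exp(-.colPNorm(Lx, params@pD))
    D[colSums(zd) > 0L] <- 0

    # recessive: four-case limit expression
    zr <- Xr == 0
    nzero <- colSums(zr)
    R <- numeric(n)
    ok <- nzero == 0L
    if (any(ok)) {
        Xo <- Xr[, ok, drop = FALSE]
        ratio <- Y[, ok, drop = FALSE] / Xo
        zeta <- if (is.infinite(params@qR)) .colMax(ratio)
                else .colPNorm(ratio, params@qR)
        Dp <- exp(-.colPNorm(-log(Xo), params@pR))
        R[ok] <- (1 + zeta) * Dp
    }
    one <- which(nzero == 1L)
    for (j in one) {
        i <- which(zr[, j])
        R[j] <- if (params@pR > 1) Y[i, j] else Y[i, j] * prod(Xr[-i, j])
    }
    clipped <- sum(R > 1 + 1e-12)
    R <- .snapOne(.clip01(R))
    list(D = D, R = R, clipped = clipped)
}

#' Build dominant and recessive gene score matrices
#'
#' Converts per-variant effect scores plus per-sample genotype
#' probabilities into the two per-sample, per-gene effect score matrices.
#' For every sample x gene, the retention probabilities x are computed
#' with \code{muD} for the dominant matrix and recomputed with \code{muR}
#' for the recessive matrix (the single-hit probabilities y always use
#' \code{muR}); the dominant score is \code{\link{dominantScore}(x, pD)}
#' and the recessive score \code{\link{recessiveScore}(x, y, pR, qR)}.
#' Genes with no variants score exactly 1 in both matrices. Unphased data
#' are assumed: distinct variants are taken to hit distinct gene copies,
#' which is what makes compound heterozygosity visible to the recessive
#' model.
#'
#' @param genotypes A \linkS4class{GenotypeProbs} object whose
#'   \code{rowData} carries \code{gene_id} and a set \code{score} column.
#' @param params An \linkS4class{AggregationParams} object.
#' @param geneIds Optional character vector fixing the gene universe (and
#'   row order). Every variant's gene must be present in it; genes without
#'   variants get constant score 1.
#' @return A \linkS4class{GeneScores} object (genes x samples).
#' @export
#' @examples
#' v <- data.frame(variant_key = c("1:1:A:G", "1:2:C:T"),
#'                 gene_id = "G1",
#'                 consequence = c("missense", "nonsense"),
#'                 score = c(0.4, 0))
#' gp <- GenotypeProbs(p0 = matrix(c(1, 0), 2, 1),
#'                     p1 = matrix(c(0, 1), 2, 1),
#'                     p2 = matrix(0, 2, 1),
#'                     variants = v, sampleIds = "S1")
#' gs <- buildGeneScores(gp)
#' dominantScores(gs)
buildGeneScores <- function(genotypes, params = AggregationParams(),
                            geneIds = NULL) {
    stopifnot(is(genotypes, "GenotypeProbs"),
              is(params, "AggregationParams"))
    validObject(params)
    rd <- rowData(genotypes)
    s <- rd$score
    if (is.null(s) || anyNA(s))
        stop("all variants must have an effect score; run scoreVariants() first")
    if (any(s < 0 | s > 1)) stop("variant scores must lie in [0, 1]")
    gid <- as.character(rd$gene_id)
    if (is.null(geneIds)) {
        geneIds <- unique(gid)
    } else {
        geneIds <- as.character(geneIds)
        unknown <- setdiff(gid, geneIds)
        if (length(unknown))
            stop(sprintf("variant(s) reference gene(s) absent from 'geneIds': %s",
                         paste(utils::head(unknown, 5), collapse = ", ")))
    }
    n <- ncol(genotypes)
    m <- length(geneIds)
    P0 <- assay(genotypes, "p0")
    P1 <- assay(genotypes, "p1")
    P2 <- assay(genotypes, "p2")
    D <- matrix(1, m, n, dimnames = list(geneIds, colnames(genotypes)))
    R <- matrix(1, m, n, dimnames = list(geneIds, colnames(genotypes)))
    nv <- integer(m)
    idx <- split(seq_len(nrow(genotypes)), factor(gid, levels = geneIds))
    clipped <- 0L
    for (g in seq_len(m)) {
        rows <- idx[[g]]
        nv[g] <- length(rows)
        if (!length(rows)) next
        agg <- .aggregateGene(P0[rows, , drop = FALSE],
                              P1[rows, , drop = FALSE],
                              P2[rows, , drop = FALSE],
                              s[rows], params)
        D[g, ] <- agg$D
        R[g, ] <- agg$R
        clipped <- clipped + agg$clipped
    }
    if (clipped > 0)
        message(sprintf("recessive score exceeded 1 and was clipped for %d sample x gene value(s)", clipped))
    GeneScores(D, R, params = params, nVariants = nv)
}
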