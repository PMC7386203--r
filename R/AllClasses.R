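#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames rowData rowData<- colData
NULL

#' Supported protein-affecting consequence classes
#'
#' The five variant consequence classes handled by the scoring rules:
#' missense, nonsense, frameshift, canonical splice-site, and in-frame
#' indel. Nonsense, frameshift and canonical splice-site variants are
#' treated as complete loss of function.
#'
#' @return Character vector of class names.
#' @export
#' @examples
#' consequenceClasses()
consequenceClasses <- function() {
    c("missense", "nonsense", "frameshift", "canonical_splice",
      "inframe_indel")
}

.LOF_CLASSES <- c("nonsense", "frameshift", "canonical_splice")

# ---------------------------------------------------------------------------
# AggregationParams
# ---------------------------------------------------------------------------

#' @rdname AggregationParams
#' @export
setClass("AggregationParams",
    slots = c(muD = "numeric", pD = "numeric",
              muR = "numeric", pR = "numeric", qR = "numeric"),
    prototype = prototype(muD = 1, pD = 1.25, muR = 0.5, pR = Inf, qR = 3))

setValidity("AggregationParams", function(object) {
    msg <- character()
    for (nm in c("muD", "pD", "muR", "pR", "qR")) {
        v <- slot(object, nm)
        if (length(v) != 1L || is.na(v))
            msg <- c(msg, sprintf("'%s' must be a single non-NA number", nm))
    }
    if (length(msg)) return(msg)
    if (object@muD < 0 || object@muD > 1) msg <- c(msg, "'muD' must be in [0, 1]")
    if (object@muR < 0 || object@muR > 1) msg <- c(msg, "'muR' must be in [0, 1]")
    for (nm in c("pD", "pR", "qR"))
        if (slot(object, nm) < 1)
            msg <- c(msg, sprintf("'%s' must be >= 1 (Inf allowed)", nm))
    if (length(msg)) msg else TRUE
})

.asNormOrder <- function(x) {
    # config files encode the max-norm as the string "inf"
    if (is.character(x)) {
        if (tolower(x) %in% c("inf", "infinity")) return(Inf)
        return(as.numeric(x))
    }
    as.numeric(x)
}

#' Aggregation parameters for gene effect scores
#'
#' The five parameters of the dominant/recessive aggregation scheme. The
#' dominant score uses \code{muD} (dependence of the two homozygous hits)
#' and \code{pD} (the p-norm interpolating between full independence across
#' variants at p = 1 and full dependence at p = Inf). The recessive score
#' uses \code{muR}, \code{pR} and \code{qR} (the q-norm applied to the
#' single-hit/retention ratios). Defaults are the published values fitted
#' on known gene--phenotype associations: muD = 1, pD = 1.25, muR = 0.5,
#' pR = Inf, qR = 3. The strings \code{"inf"} / \code{"infinity"} are
#' accepted wherever Inf is admissible.
#'
#' @param muD,muR Homozygous-dependence parameters in [0, 1].
#' @param pD,pR,qR Norm orders in [1, Inf].
#' @return An \code{AggregationParams} object.
#' @export
#' @examples
#' AggregationParams()
#' AggregationParams(muD = 0, pD = 1, muR = 0, pR = 1, qR = 1)
AggregationParams <- function(muD = 1, pD = 1.25, muR = 0.5, pR = Inf,
                              qR = 3) {
    new("AggregationParams",
        muD = as.numeric(muD), pD = .asNormOrder(pD),
        muR = as.numeric(muR), pR = .asNormOrder(pR),
        qR = .asNormOrder(qR))
}

#' @describeIn AggregationParams Display method.
#' @param object An \code{AggregationParams} object.
#' @export
setMethod("show", "AggregationParams", function(object) {
    cat("AggregationParams\n")
    cat(sprintf("  dominant : muD = %g, pD = %g\n", object@muD, object@pD))
    cat(sprintf("  recessive: muR = %g, pR = %g, qR = %g\n",
                object@muR, object@pR, object@qR))
})

# ---------------------------------------------------------------------------
# GenotypeProbs
# ---------------------------------------------------------------------------

#' @rdname GenotypeProbs
#' @export
setClass("GenotypeProbs", contains = "SummarizedExperiment")

setValidity("GenotypeProbs", function(object) {
    msg <- character()
    need <- c("p0", "p1", "p2")
    if (!all(need %in% assayNames(object)))
        return("assays 'p0', 'p1', 'p2' are required")
    s <- assay(object, "p0") + assay(object, "p1") + assay(object, "p2")
    if (length(s) && max(abs(s - 1)) > 1e-6)
        msg <- c(msg, "genotype probability triplets must sum to 1 (tol 1e-6)")
    for (nm in need) {
        a <- assay(object, nm)
        if (length(a) && (min(a) < -1e-9 || max(a) > 1 + 1e-9)) {
            msg <- c(msg, sprintf("assay '%s' has entries outside [0, 1]", nm))
            break
        }
    }
    rd <- rowData(object)
    if (!all(c("variant_key", "gene_id") %in% colnames(rd)))
        msg <- c(msg, "rowData must contain 'variant_key' and 'gene_id'")
    if (length(msg)) msg else TRUE
})

#' Per-sample genotype probability triplets
#'
#' Container for genotype probabilities of bi-allelic protein-affecting
#' variants: for every variant (row) and sample (column), the probabilities
#' \code{p0}, \code{p1}, \code{p2} that the alternate allele occurs 0, 1 or
#' 2 times. Hard calls are the degenerate triplets (1,0,0), (0,1,0),
#' (0,0,1); a missing call is encoded as (1,0,0) (the variant is presumed
#' absent, which can only cost statistical power downstream). Triplets are
#' renormalized to sum to exactly 1 on construction; triplets whose raw sum
#' falls outside [0.99, 1.01] are rejected.
#'
#' The variant annotation (columns \code{variant_key}, \code{gene_id},
#' \code{consequence}, \code{score}, and the in-frame indel residue counts)
#' lives in \code{rowData}.
#'
#' @param p0,p1,p2 Numeric matrices (variants x samples) of allele-count
#'   probabilities.
#' @param variants A \code{data.frame} of variant annotation with at least
#'   \code{variant_key} and \code{gene_id}, one row per row of \code{p0}.
#' @param sampleIds Character vector of sample identifiers (defaults to
#'   \code{colnames(p0)}).
#' @return A \code{GenotypeProbs} object.
#' @export
#' @examples
#' v <- data.frame(variant_key = "1:100:A:G", gene_id = "G1",
#'                 consequence = "missense", score = 0.4)
#' gp <- GenotypeProbs(p0 = matrix(0, 1, 2), p1 = matrix(1, 1, 2),
#'                     p2 = matrix(0, 1, 2), variants = v,
#'                     sampleIds = c("S1", "S2"))
#' gp
GenotypeProbs <- function(p0, p1, p2, variants, sampleIds = colnames(p0)) {
    p0 <- as.matrix(p0); p1 <- as.matrix(p1); p2 <- as.matrix(p2)
    stopifnot(identical(dim(p0), dim(p1)), identical(dim(p0), dim(p2)))
    if (!is.data.frame(variants) && !is(variants, "DataFrame"))
        stop("'variants' must be a data.frame of variant annotation")
    if (nrow(variants) != nrow(p0))
        stop("'variants' must have one row per variant row of the matrices")
    if (is.null(sampleIds)) sampleIds <- paste0("S", seq_len(ncol(p0)))
    if (any(!is.finite(p0)) || any(!is.finite(p1)) || any(!is.finite(p2)))
        stop("genotype probabilities must be finite")
    if (min(p0, 1) < 0 || min(p1, 1) < 0 || min(p2, 1) < 0)
        stop("genotype probabilities must be non-negative")
    s <- p0 + p1 + p2
    bad <- which(s < 0.99 | s > 1.01)
    if (length(bad))
        stop(sprintf("%d genotype triplet(s) sum outside [0.99, 1.01]; first at matrix index %d",
                     length(bad), bad[1]))
    p0 <- p0 / s; p1 <- p1 / s; p2 <- p2 / s
    rd <- DataFrame(variants)
    se <- SummarizedExperiment(
        assays = list(p0 = p0, p1 = p1, p2 = p2),
        rowData = rd)
    rownames(se) <- rd$variant_key
    colnames(se) <- sampleIds
    new("GenotypeProbs", se)
}

#' @describeIn GenotypeProbs Display method.
#' @param object A \code{GenotypeProbs} object.
#' @export
setMethod("show", "GenotypeProbs", function(object) {
    cat(sprintf("GenotypeProbs: %d variants x %d samples\n",
                nrow(object), ncol(object)))
    gid <- rowData(object)$gene_id
    cat(sprintf("  genes: %d\n", length(unique(gid))))
    cs <- rowData(object)$consequence
    if (!is.null(cs)) {
        tab <- table(cs)
        cat("  consequences:",
            paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
    }
    invisible(NULL)
})

# ---------------------------------------------------------------------------
# GeneScores
# ---------------------------------------------------------------------------

#' @rdname GeneScores
#' @export
setClass("GeneScores", contains = "SummarizedExperiment")

setValidity("GeneScores", function(object) {
    msg <- character()
    if (!all(c("dominant", "recessive") %in% assayNames(object)))
        return("assays 'dominant' and 'recessive' are required")
    for (nm in c("dominant", "recessive")) {
        a <- assay(object, nm)
        if (length(a) && (min(a) < -1e-9 || max(a) > 1 + 1e-9)) {
            msg <- c(msg, sprintf("assay '%s' has entries outside [0, 1]", nm))
        }
    }
    if (length(msg)) msg else TRUE
})

#' Per-sample, per-gene functional effect scores
#'
#' Container for the two gene effect score matrices (genes x samples):
#' assay \code{"dominant"} holds D, the probability that the gene escapes
#' even a single damaging hit, and assay \code{"recessive"} holds R, the
#' probability of at most one damaging hit. Both are in [0, 1]; a gene
#' untouched by any variant in a sample scores exactly 1 (fully
#' functional). \code{rowData} records \code{gene_id} and
#' \code{n_variants}; \code{metadata(x)$params} keeps the
#' \linkS4class{AggregationParams} used.
#'
#' Usually produced by \code{\link{buildGeneScores}}; the constructor is
#' exported for round-tripping score matrices read from disk.
#'
#' @param dominant,recessive Numeric matrices (genes x samples) in [0, 1].
#' @param params An \linkS4class{AggregationParams} or NULL.
#' @param nVariants Optional integer vector of per-gene variant counts.
#' @return A \code{GeneScores} object.
#' @seealso \code{\link{buildGeneScores}}, \code{\link{dominantScores}},
#'   \code{\link{recessiveScores}}
#' @export
GeneScores <- function(dominant, recessive, params = NULL,
                       nVariants = NULL) {
    dominant <- as.matrix(dominant); recessive <- as.matrix(recessive)
    stopifnot(identical(dim(dominant), dim(recessive)))
    if (is.null(rownames(dominant)))
        stop("'dominant' must carry gene ids as rownames")
    rd <- DataFrame(gene_id = rownames(dominant))
    if (!is.null(nVariants)) rd$n_variants <- as.integer(nVariants)
    se <- SummarizedExperiment(
        assays = list(dominant = dominant, recessive = recessive),
        rowData = rd)
    metadata(se)$params <- params
    new("GeneScores", se)
}

#' @describeIn GeneScores Display method.
#' @param object A \code{GeneScores} object.
#' @export
setMethod("show", "GeneScores", function(object) {
    cat(sprintf("GeneScores: %d genes x %d samples\n",
                nrow(object), ncol(object)))
    d <- assay(object, "dominant"); r <- assay(object, "recessive")
    if (length(d))
        cat(sprintf("  mean dominant = %.4f, mean recessive = %.4f\n",
                    mean(d), mean(r)))
    p <- metadata(object)$params
    if (!is.null(p))
        cat(sprintf("  params: muD = %g, pD = %g, muR = %g, pR = %g, qR = %g\n",
                    p@muD, p@pD, p@muR, p@pR, p@qR))
    invisible(NULL)
})
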