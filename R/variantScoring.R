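#' Effect score of an in-frame indel
#'
#' Rule-based score from the numbers of substituted, inserted and deleted
#' amino acids: \code{max(0, 1 - (nSub*wSub + nIns*wIns + nDel*wDel))}.
#' Monotone decreasing in each count, exactly 1 when no residue is
#' affected, saturating at 0 (complete loss of function). The per-residue
#' weights default to 0.05 and are exposed so they can be recalibrated.
#'
#' @param nSub,nIns,nDel Non-negative integer counts of substituted,
#'   inserted and deleted amino acids (vectorized).
#' @param weights Named numeric vector with elements \code{sub},
#'   \code{ins}, \code{del}.
#' @return Effect score(s) in [0, 1].
#' @export
#' @examples
#' indelEffectScore(0, 0, 0)    # 1: no residue affected
#' indelEffectScore(2, 1, 3)
indelEffectScore <- function(nSub, nIns, nDel,
                             weights = c(sub = 0.05, ins = 0.05,
                                         del = 0.05)) {
    stopifnot(all(c("sub", "ins", "del") %in% names(weights)),
              all(weights >= 0))
    counts <- cbind(nSub, nIns, nDel)
    if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
        stop("indel residue counts must be non-negative integers")
    pmax(0, 1 - (nSub * weights[["sub"]] + nIns * weights[["ins"]] +
                 nDel * weights[["del"]]))
}

.checkVariantTable <- function(variants, requireScores = FALSE) {
    variants <- as.data.frame(variants)
    need <- c("variant_key", "gene_id", "consequence")
    miss <- setdiff(need, colnames(variants))
    if (length(miss))
        stop("variant table is missing column(s): ",
             paste(miss, collapse = ", "))
    bad <- setdiff(unique(as.character(variants$consequence)),
                   consequenceClasses())
    if (length(bad))
        stop("unknown consequence class(es): ", paste(bad, collapse = ", "))
    if (requireScores) {
        if (is.null(variants$score) || anyNA(variants$score))
            stop("all variants must have a set effect score")
        if (any(variants$score < 0 | variants$score > 1))
            stop("variant effect scores must lie in [0, 1]")
    }
    variants
}

#' Assign functional effect scores to variants
#'
#' Fills the \code{score} column of a variant table by consequence class:
#' nonsense, frameshift and canonical splice-site variants are assumed to
#' be complete loss of function and scored exactly 0; in-frame indels are
#' scored by \code{\link{indelEffectScore}} from their residue counts;
#' missense variants keep a pre-set score (e.g. the output of an external
#' machine-learning predictor supplied in the input table) or are scored
#' by the pluggable \code{missenseScorer}. Missense scores are clipped to
#' [0, 1].
#'
#' @param variants A \code{data.frame} with columns \code{variant_key},
#'   \code{gene_id}, \code{consequence}, optionally \code{score} and, for
#'   in-frame indels, \code{n_sub}, \code{n_ins}, \code{n_del}.
#' @param missenseScorer Optional function taking the data.frame of
#'   missense rows and returning one numeric score per row. When NULL,
#'   missense rows must already carry a score.
#' @param indelWeights Per-residue weights passed to
#'   \code{\link{indelEffectScore}}.
#' @return The variant table with the \code{score} column set for every
#'   row.
#' @export
#' @examples
#' v <- data.frame(variant_key = c("1:1:A:T", "1:5:C:G"),
#'                 gene_id = "G1",
#'                 consequence = c("nonsense", "missense"),
#'                 score = c(NA, 0.73))
#' scoreVariants(v)$score    # 0.00 and 0.73
scoreVariants <- function(variants, missenseScorer = NULL,
                          indelWeights = c(sub = 0.05, ins = 0.05,
                                           del = 0.05)) {
    variants <- .checkVariantTable(variants)
    if (is.null(variants$score)) variants$score <- NA_real_
    cons <- as.character(variants$consequence)

    variants$score[cons %in% .LOF_CLASSES] <- 0

    ind <- which(cons == "inframe_indel")
    if (length(ind)) {
        for (cc in c("n_sub", "n_ins", "n_del"))
            if (is.null(variants[[cc]]) || anyNA(variants[[cc]][ind]))
                stop("in-frame indels require 'n_sub', 'n_ins', 'n_del' counts")
        variants$score[ind] <- indelEffectScore(
            variants$n_sub[ind], variants$n_ins[ind], variants$n_del[ind],
            weights = indelWeights)
    }

    mis <- which(cons == "missense")
    if (length(mis)) {
        if (!is.null(missenseScorer)) {
            sc <- missenseScorer(variants[mis, , drop = FALSE])
            if (length(sc) != length(mis) || anyNA(sc))
                stop("'missenseScorer' must return one non-NA score per missense variant")
            variants$score[mis] <- .clip01(as.numeric(sc))
        } else if (anyNA(variants$score[mis])) {
            stop("missense variant(s) without a pre-set score and no 'missenseScorer' provided")
        } else {
            variants$score[mis] <- .clip01(variants$score[mis])
        }
    }
    variants
}

#' Shuffle variant effect scores (negative control)
#'
#' Permutes the multiset of effect scores uniformly at random across all
#' variants (globally, not within genes), destroying the score-to-variant
#' correspondence while conserving the score distribution and the
#' variant-to-gene mapping. Aggregating shuffled scores into gene scores
#' provides a negative control for association results driven by the
#' functional content of the scores.
#'
#' @param variants A scored variant table (all scores set).
#' @param seed Integer seed; the permutation is deterministic given the
#'   seed.
#' @return The variant table with permuted \code{score} column.
#' @export
shuffleScores <- function(variants, seed = NULL) {
    variants <- .checkVariantTable(variants, requireScores = TRUE)
    n <- nrow(variants)
    perm <- .maybeWithSeed(seed, sample.int(n))
    variants$score <- variants$score[perm]
    variants
}

#' Perturb variant effect scores with Gaussian noise
#'
#' Replaces each score s by s + N(0, epsilon^2), clipped back to [0, 1].
#' Used to probe the sensitivity of downstream association power to
#' inaccuracies of the upstream effect score predictor; epsilon = 0 is
#' the identity.
#'
#' @param variants A scored variant table.
#' @param epsilon Noise standard deviation, >= 0.
#' @param seed Integer seed for reproducible noise.
#' @return The variant table with perturbed scores.
#' @export
perturbScores <- function(variants, epsilon, seed = NULL) {
    variants <- .checkVariantTable(variants, requireScores = TRUE)
    if (!is.numeric(epsilon) || length(epsilon) != 1L || is.na(epsilon) ||
        epsilon < 0)
        stop("'epsilon' must be a single non-negative number")
    if (epsilon == 0) return(variants)
    n <- nrow(variants)
    noise <- .maybeWithSeed(seed, stats::rnorm(n, 0, epsilon))
    variants$score <- .clip01(variants$score + noise)
    variants
}
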