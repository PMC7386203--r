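#' @importFrom stats pf pchisq pnorm pt cor p.adjust rnorm qnorm
#'   binomial glm.control glm.fit complete.cases sd var quantile
NULL

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment across all tested genes. Applied separately
#' within each inheritance model's p-value column by
#' \code{\link{runPWAS}}, since each model yields its own q-values. Every
#' q-value is >= its p-value, and the adjustment is invariant to the
#' ordering of the input.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Vector of q-values, same length and order as \code{p}.
#' @export
#' @examples
#' fdrAdjust(c(0.01, 0.02, 0.03))   # all 0.03
fdrAdjust <- function(p) {
    if (!is.numeric(p)) stop("'p' must be numeric")
    if (anyNA(p) || any(p < 0 | p > 1))
        stop("p-values must lie in [0, 1] with no missing values")
    p.adjust(p, method = "BH")
}

#' Cohen's d between cases and controls
#'
#' Standardized mean difference in gene effect scores between cases
#' (label 1) and controls (label 0):
#' \code{(mean(cases) - mean(controls)) / pooledSD}. Negative d means the
#' cases carry lower (more damaged) scores.
#'
#' @param scores Numeric vector of gene effect scores.
#' @param labels Binary vector (0/1 or logical), 1 = case.
#' @return Cohen's d, or NaN (with a warning) when the pooled standard
#'   deviation is zero.
#' @export
#' @examples
#' cohensD(c(0.2, 0.3, 0.8, 0.9), c(1, 1, 0, 0))
cohensD <- function(scores, labels) {
    labels <- as.numeric(labels)
    if (length(scores) != length(labels))
        stop("'scores' and 'labels' must have the same length")
    if (anyNA(scores) || anyNA(labels) || !all(labels %in% c(0, 1)))
        stop("'labels' must be binary 0/1 with no missing values")
    n1 <- sum(labels == 1); n0 <- sum(labels == 0)
    if (n1 == 0 || n0 == 0) stop("both classes must be non-empty")
    m1 <- mean(scores[labels == 1]); m0 <- mean(scores[labels == 0])
    v1 <- if (n1 > 1) var(scores[labels == 1]) else 0
    v0 <- if (n0 > 1) var(scores[labels == 0]) else 0
    pooled <- sqrt(((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2))
    if (!is.finite(pooled) || pooled == 0) {
        warning("pooled standard deviation is zero; Cohen's d undefined")
        return(NaN)
    }
    (m1 - m0) / pooled
}

#' Split a categorical phenotype one-vs-rest
#'
#' Turns a categorical phenotype into one binary phenotype per category
#' (case = that category, control = all others), each of which can then be
#' tested with \code{\link{runPWAS}}.
#'
#' @param y Factor or character vector of category labels, optionally
#'   named by sample id.
#' @return Named list of binary 0/1 vectors, one per category.
#' @export
#' @examples
#' splitCategorical(c(a = "x", b = "y", c = "x", d = "z"))
splitCategorical <- function(y) {
    f <- as.factor(y)
    lev <- levels(f)
    if (length(lev) < 2L)
        stop("a categorical phenotype needs at least 2 categories")
    counts <- table(f)
    empty <- lev[counts == 0]
    if (length(empty))
        stop("category with zero members cannot be tested: ",
             paste(empty, collapse = ", "))
    out <- lapply(lev, function(l) {
        b <- as.numeric(f == l)
        names(b) <- names(y)
        b
    })
    names(out) <- lev
    out
}

# --- internal regression machinery ----------------------------------------

# Build the covariate design matrix: coerce, attach sample ids, add an
# intercept when no constant column exists, drop rank-deficient columns by
# pivoted QR (with a warning).
.prepCovariates <- function(covariates, sampleIds) {
    n <- length(sampleIds)
    if (is.null(covariates)) {
        C <- matrix(1, n, 1, dimnames = list(sampleIds, "intercept"))
        return(C)
    }
    C <- as.matrix(covariates)
    storage.mode(C) <- "double"
    if (anyNA(C)) stop("covariates must not contain missing values")
    if (!is.null(rownames(C))) {
        miss <- setdiff(sampleIds, rownames(C))
        if (length(miss))
            stop("covariate rows missing for sample(s): ",
                 paste(utils::head(miss, 5), collapse = ", "))
        C <- C[sampleIds, , drop = FALSE]
    } else {
        if (nrow(C) != n)
            stop("unnamed covariate matrix must have one row per sample")
        rownames(C) <- sampleIds
    }
    if (is.null(colnames(C))) colnames(C) <- paste0("cov", seq_len(ncol(C)))
    hasConst <- any(apply(C, 2, function(z) max(z) == min(z) && z[1] != 0))
    if (!hasConst) C <- cbind(intercept = 1, C)
    qrC <- qr(C)
    if (qrC$rank < ncol(C)) {
        keep <- qrC$pivot[seq_len(qrC$rank)]
        warning(sprintf("dropping %d collinear covariate column(s): %s",
                        ncol(C) - qrC$rank,
                        paste(colnames(C)[-keep], collapse = ", ")))
        C <- C[, sort(keep), drop = FALSE]
    }
    C
}

# OLS score test via Frisch-Waugh-Lovell: residualize phenotype and score
# columns against the covariates once, then F-test the score block.
# S: n x m matrix of score columns. Returns list(p, beta, flag).
.olsScoreTest <- function(S, rY, rss0, qrC, n) {
    rS <- qr.resid(qrC, S)
    scale2 <- pmax(colSums(S^2), 1)
    keep <- which(colSums(rS^2) / scale2 > 1e-10)
    beta <- rep(NA_real_, ncol(S))
    if (!length(keep))
        return(list(p = 1, beta = beta, flag = "degenerate"))
    rS <- rS[, keep, drop = FALSE]
    qs <- qr(rS)
    d <- qs$rank
    if (d == 0L)
        return(list(p = 1, beta = beta, flag = "degenerate"))
    r1 <- qr.resid(qs, rY)
    rss1 <- sum(r1^2)
    df2 <- n - qrC$rank - d
    if (df2 <= 0)
        return(list(p = 1, beta = beta, flag = "degenerate"))
    Fstat <- ((rss0 - rss1) / d) / (rss1 / df2)
    pval <- pf(Fstat, d, df2, lower.tail = FALSE)
    cf <- qr.coef(qs, rY)
    beta[keep] <- cf
    flag <- if (d < ncol(S)) "collinear" else "ok"
    list(p = max(min(pval, 1), 0), beta = beta, flag = flag)
}

# Logistic score test: Wald z for a single score term, likelihood-ratio
# chi^2 for the joint block. IRLS capped at 100 iterations;
# non-convergence or separation flags the gene and reports p = 1.
.logisticScoreTest <- function(S, y, C, fit0) {
    beta <- rep(NA_real_, ncol(S))
    X1 <- cbind(C, S)
    fit1 <- suppressWarnings(
        glm.fit(X1, y, family = binomial(),
                control = glm.control(maxit = 100)))
    d <- fit1$rank - fit0$rank
    if (d == 0L) return(list(p = 1, beta = beta, flag = "degenerate"))
    scoreIdx <- ncol(C) + seq_len(ncol(S))
    cf <- fit1$coefficients[scoreIdx]
    # separation / non-convergence: diverging fit or one score-sd shifting
    # the log-odds by an absurd amount; report p = 1 to protect the FDR
    scoreSd <- apply(S, 2, stats::sd)
    sep <- !fit1$converged || fit1$deviance < 1e-6 ||
        any(!is.finite(cf)) ||
        any(abs(cf) * scoreSd > 30, na.rm = TRUE)
    if (sep) return(list(p = 1, beta = beta, flag = "separation"))
    beta <- unname(cf)
    if (ncol(S) == 1L && d == 1L) {
        Rm <- qr.R(fit1$qr)
        piv <- fit1$qr$pivot[seq_len(fit1$rank)]
        V <- matrix(NA_real_, ncol(X1), ncol(X1))
        V[piv, piv] <- chol2inv(Rm[seq_len(fit1$rank), seq_len(fit1$rank),
                                   drop = FALSE])
        se <- sqrt(V[scoreIdx, scoreIdx])
        z <- cf / se
        pval <- 2 * pnorm(-abs(z))
    } else {
        lr <- fit0$deviance - fit1$deviance
        pval <- pchisq(max(lr, 0), df = d, lower.tail = FALSE)
    }
    list(p = max(min(pval, 1), 0), beta = beta,
         flag = if (d < ncol(S)) "collinear" else "ok")
}

#' Test one gene's effect scores against a phenotype
#'
#' Covariate-adjusted regression of the phenotype on a gene's dominant
#' and/or recessive effect scores. Continuous phenotypes use ordinary
#' least squares with a Wald t-test (single score term) or the 2-df
#' nested-model F-test (generalized model, null H0: betaD = betaR = 0);
#' binary phenotypes use logistic regression with a Wald z-test or a 2-df
#' likelihood-ratio test. A score vector with no variance left after
#' covariate adjustment is flagged \code{"degenerate"} and reported at
#' p = 1; so are logistic fits showing separation or non-convergence,
#' protecting FDR validity.
#'
#' @param D,R Numeric vectors of dominant / recessive scores (either may
#'   be NULL when the model does not use it).
#' @param y Phenotype vector (numeric; binary phenotypes coded 0/1).
#' @param covariates Covariate matrix (rows = samples); an intercept is
#'   added when absent, collinear columns are dropped with a warning.
#' @param model One of \code{"dominant"}, \code{"recessive"},
#'   \code{"generalized"}.
#' @param kind \code{"continuous"} or \code{"binary"}.
#' @return List with elements \code{p}, \code{beta} (named coefficients of
#'   the score terms, sign preserved), and \code{flag}.
#' @export
#' @examples
#' set.seed(1)
#' D <- runif(200); y <- -D + rnorm(200)
#' testGene(D = D, y = y, model = "dominant", kind = "continuous")$p
testGene <- function(D = NULL, R = NULL, y, covariates = NULL,
                     model = c("dominant", "recessive", "generalized"),
                     kind = c("continuous", "binary")) {
    model <- match.arg(model)
    kind <- match.arg(kind)
    needD <- model %in% c("dominant", "generalized")
    needR <- model %in% c("recessive", "generalized")
    if ((needD && is.null(D)) || (needR && is.null(R)))
        stop(sprintf("model '%s' requires the corresponding score vector(s)",
                     model))
    S <- switch(model,
        dominant = cbind(D = D),
        recessive = cbind(R = R),
        generalized = cbind(D = D, R = R))
    n <- length(y)
    if (nrow(S) != n) stop("score vectors and phenotype differ in length")
    sampleIds <- names(y)
    if (is.null(sampleIds)) sampleIds <- paste0("S", seq_len(n))
    C <- .prepCovariates(covariates, sampleIds)
    if (kind == "continuous") {
        qrC <- qr(C)
        rY <- qr.resid(qrC, y)
        res <- .olsScoreTest(S, rY, sum(rY^2), qrC, n)
    } else {
        if (!all(y %in% c(0, 1)))
            stop("binary phenotype must be coded 0/1")
        fit0 <- suppressWarnings(
            glm.fit(C, y, family = binomial(),
                    control = glm.control(maxit = 100)))
        res <- .logisticScoreTest(S, y, C, fit0)
    }
    names(res$beta) <- colnames(S)
    res
}

#' Run a proteome-wide association scan
#'
#' Tests every gene's dominant, recessive and generalized models against
#' the phenotype with covariate adjustment, attaches per-model
#' Benjamini-Hochberg q-values computed across all tested genes, and
#' reports standardized effect sizes: Cohen's d on the score column
#' between cases and controls for binary phenotypes, and the partial
#' Pearson correlation between the covariate-residualized score and
#' phenotype for continuous ones (its sign matches the regression
#' coefficient). Negative effect sizes mean the gene is more damaged in
#' cases (or in samples with larger phenotype values).
#'
#' @param geneScores A \linkS4class{GeneScores} object.
#' @param phenotype Numeric vector named by sample id (or in the column
#'   order of \code{geneScores}); binary phenotypes coded 0/1. Samples
#'   with missing phenotype are dropped before testing.
#' @param covariates Covariate matrix with sample rownames, or NULL.
#' @param kind \code{"continuous"} or \code{"binary"}. Categorical
#'   phenotypes should be pre-split with \code{\link{splitCategorical}}.
#' @param fdrThreshold FDR significance threshold for the per-model
#'   \code{significant_*} columns (default 0.05).
#' @return A \code{data.frame} with one row per gene, sorted by the
#'   generalized-model p-value: p/q-values for the three models,
#'   generalized-model coefficients \code{beta_D}/\code{beta_R},
#'   per-model effect sizes, flags, and significance indicators.
#' @export
runPWAS <- function(geneScores, phenotype, covariates = NULL,
                    kind = c("continuous", "binary"),
                    fdrThreshold = 0.05) {
    stopifnot(is(geneScores, "GeneScores"))
    kind <- match.arg(kind)
    if (fdrThreshold <= 0 || fdrThreshold >= 1)
        stop("'fdrThreshold' must lie in (0, 1)")
    ids <- colnames(geneScores)
    y <- phenotype
    if (!is.null(names(y))) {
        unknown <- setdiff(names(y), ids)
        if (length(unknown))
            stop("phenotype sample(s) absent from the score matrices: ",
                 paste(utils::head(unknown, 5), collapse = ", "))
        y <- y[!is.na(y)]
        ids <- intersect(ids, names(y))
        y <- y[ids]
    } else {
        if (length(y) != length(ids))
            stop("unnamed phenotype must have one value per sample column")
        names(y) <- ids
        keep <- !is.na(y)
        y <- y[keep]; ids <- ids[keep]
    }
    n <- length(y)
    if (n == 0L) stop("no samples left after dropping missing phenotypes")
    if (kind == "binary" && !all(y %in% c(0, 1)))
        stop("binary phenotype must be coded 0/1")

    Dm <- dominantScores(geneScores)[, ids, drop = FALSE]
    Rm <- recessiveScores(geneScores)[, ids, drop = FALSE]
    m <- nrow(Dm)
    genes <- rowData(geneScores)$gene_id
    nvar <- rowData(geneScores)$n_variants
    if (is.null(nvar)) nvar <- rep(NA_integer_, m)

    empty <- data.frame(
        gene_id = character(), n_samples = integer(), n_variants = integer(),
        p_dominant = numeric(), p_recessive = numeric(),
        p_generalized = numeric(), q_dominant = numeric(),
        q_recessive = numeric(), q_generalized = numeric(),
        beta_D = numeric(), beta_R = numeric(),
        effect_dominant = numeric(), effect_recessive = numeric(),
        flag_dominant = character(), flag_recessive = character(),
        flag_generalized = character(),
        significant_dominant = logical(), significant_recessive = logical(),
        significant_generalized = logical(),
        stringsAsFactors = FALSE)
    if (m == 0L) return(empty)

    C <- .prepCovariates(covariates, ids)
    if (kind == "continuous") {
        qrC <- qr(C)
        rY <- qr.resid(qrC, y)
        rss0 <- sum(rY^2)
        sdY <- sqrt(rss0)
    } else {
        fit0 <- suppressWarnings(
            glm.fit(C, y, family = binomial(),
                    control = glm.control(maxit = 100)))
    }

    pD <- pR <- pG <- numeric(m)
    bD <- bR <- eD <- eR <- rep(NA_real_, m)
    fD <- fR <- fG <- character(m)
    for (g in seq_len(m)) {
        Dg <- Dm[g, ]; Rg <- Rm[g, ]
        if (kind == "continuous") {
            tD <- .olsScoreTest(cbind(D = Dg), rY, rss0, qrC, n)
            tR <- .olsScoreTest(cbind(R = Rg), rY, rss0, qrC, n)
            tG <- .olsScoreTest(cbind(D = Dg, R = Rg), rY, rss0, qrC, n)
            rDg <- qr.resid(qrC, Dg)
            rRg <- qr.resid(qrC, Rg)
            eD[g] <- if (tD$flag == "degenerate") NA_real_ else
                sum(rDg * rY) / (sqrt(sum(rDg^2)) * sdY)
            eR[g] <- if (tR$flag == "degenerate") NA_real_ else
                sum(rRg * rY) / (sqrt(sum(rRg^2)) * sdY)
        } else {
            tD <- .logisticScoreTest(cbind(D = Dg), y, C, fit0)
            tR <- .logisticScoreTest(cbind(R = Rg), y, C, fit0)
            tG <- .logisticScoreTest(cbind(D = Dg, R = Rg), y, C, fit0)
            eD[g] <- if (sd(Dg) == 0) NA_real_ else
                suppressWarnings(cohensD(Dg, y))
            eR[g] <- if (sd(Rg) == 0) NA_real_ else
                suppressWarnings(cohensD(Rg, y))
        }
        pD[g] <- tD$p; pR[g] <- tR$p; pG[g] <- tG$p
        fD[g] <- tD$flag; fR[g] <- tR$flag; fG[g] <- tG$flag
        bD[g] <- tG$beta[1]; bR[g] <- tG$beta[2]
    }
    res <- data.frame(
        gene_id = as.character(genes), n_samples = n,
        n_variants = as.integer(nvar),
        p_dominant = pD, p_recessive = pR, p_generalized = pG,
        q_dominant = fdrAdjust(pD), q_recessive = fdrAdjust(pR),
        q_generalized = fdrAdjust(pG),
        beta_D = bD, beta_R = bR,
        effect_dominant = eD, effect_recessive = eR,
        flag_dominant = fD, flag_recessive = fR, flag_generalized = fG,
        stringsAsFactors = FALSE)
    res$significant_dominant <- res$q_dominant < fdrThreshold
    res$significant_recessive <- res$q_recessive < fdrThreshold
    res$significant_generalized <- res$q_generalized < fdrThreshold
    res[order(res$p_generalized, res$gene_id), , drop = FALSE]
}
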