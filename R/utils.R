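#' @importFrom withr with_seed
NULL

# Evaluate expr under a fixed RNG seed without disturbing the caller's RNG
# state; seed = NULL uses the current stream.
.maybeWithSeed <- function(seed, expr) {
    if (is.null(seed)) return(expr)
    withr::with_seed(as.integer(seed), expr)
}

#' p-norm of a non-negative vector
#'
#' Numerically stable \eqn{\ell_p} norm, factoring out the maximum so that
#' very large orders (p up to and including Inf) neither overflow nor
#' underflow; \code{pNorm(v, Inf)} is \code{max(v)}.
#'
#' @param v Non-negative numeric vector.
#' @param p Norm order in [1, Inf].
#' @return The norm as a single number.
#' @export
#' @examples
#' pNorm(c(3, 4), 2)      # 5
#' pNorm(c(3, 4), Inf)    # 4
pNorm <- function(v, p) {
    stopifnot(is.numeric(v), length(p) == 1L, p >= 1)
    if (!length(v)) return(0)
    if (any(v < 0)) stop("pNorm() is defined here for non-negative entries")
    m <- max(v)
    if (m == 0) return(0)
    if (is.infinite(p)) return(m)
    if (is.infinite(m)) return(Inf)
    m * sum((v / m)^p)^(1 / p)
}

# Column-wise p-norm of a non-negative k x n matrix (k small), stable for
# large p. Returns a length-n vector.
.colPNorm <- function(M, p) {
    k <- nrow(M)
    if (k == 0L) return(numeric(ncol(M)))
    cmax <- .colMax(M)
    if (is.infinite(p)) return(cmax)
    out <- numeric(ncol(M))
    pos <- cmax > 0
    if (any(pos)) {
        Ms <- M[, pos, drop = FALSE]
        Ms <- sweep(Ms, 2L, cmax[pos], "/")
        out[pos] <- cmax[pos] * colSums(Ms^p)^(1 / p)
    }
    out
}

# Fast column max / min for k x n matrices with small k.
.colMax <- function(M) {
    if (nrow(M) == 1L) return(as.numeric(M[1L, ]))
    do.call(pmax, lapply(seq_len(nrow(M)), function(i) M[i, ]))
}

.colMin <- function(M) {
    if (nrow(M) == 1L) return(as.numeric(M[1L, ]))
    do.call(pmin, lapply(seq_len(nrow(M)), function(i) M[i, ]))
}

#' Wilson score interval for a binomial proportion
#'
#' @param k Number of successes.
#' @param n Number of trials.
#' @param conf Confidence level (default 0.95).
#' @return Named numeric vector with elements \code{estimate}, \code{lo},
#'   \code{hi}.
#' @export
#' @examples
#' wilsonInterval(40, 50)
wilsonInterval <- function(k, n, conf = 0.95) {
    stopifnot(n >= 1, k >= 0, k <= n)
    z <- stats::qnorm(1 - (1 - conf) / 2)
    phat <- k / n
    denom <- 1 + z^2 / n
    centre <- (phat + z^2 / (2 * n)) / denom
    half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / denom
    c(estimate = phat, lo = max(0, centre - half), hi = min(1, centre + half))
}

.clip01 <- function(x) pmin(1, pmax(0, x))
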