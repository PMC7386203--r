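# Independent enumeration oracle for the aggregation core.
#
# A variant with effect score s carried on g allele copies produces
# damaging "hits". Under independence (mu = 0) each copy damages its gene
# copy independently with probability 1 - s; under full dependence
# (mu = 1) the two homozygous copies are either both damaged or both
# intact. The oracle enumerates the per-variant hit distribution over
# {0, 1, >=2} and convolves across variants (different variants hit
# different gene copies). Entirely independent of the package's
# norm-based formulas.

oracleVariantHits <- function(s, g, mu) {
    if (g == 0) return(c(1, 0, 0))
    if (g == 1) return(c(s, 1 - s, 0))
    dep <- c(s, 0, 1 - s)                      # both-or-neither
    ind <- c(s^2, 2 * s * (1 - s), (1 - s)^2)  # per-copy independent
    mu * dep + (1 - mu) * ind
}

# Returns c(p0 = P(zero hits), p01 = P(at most one hit)) for a gene with
# variant scores ss, hard genotypes gg (allele counts), dependence mu.
oracleGeneRetention <- function(ss, gg, mu) {
    ss <- unname(ss); gg <- unname(gg)
    dist <- c(1, 0, 0)
    for (i in seq_along(ss)) {
        v <- oracleVariantHits(ss[i], gg[i], mu)
        dist <- c(dist[1] * v[1],
                  dist[1] * v[2] + dist[2] * v[1],
                  0)
        dist[3] <- 1 - dist[1] - dist[2]
    }
    c(p0 = dist[1], p01 = dist[1] + dist[2])
}

# Hard genotype allele count -> probability triplet.
hardTriplet <- function(g) {
    rbind(p0 = as.numeric(g == 0), p1 = as.numeric(g == 1),
          p2 = as.numeric(g == 2))
}
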