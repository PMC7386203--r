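# Shared synthetic cohorts for the heavier end-to-end tests, built once
# per test run and cached. Seeds are fixed so every run sees the same
# cohorts.

.cohortCache <- new.env(parent = emptyenv())

.cached <- function(key, builder) {
    if (is.null(.cohortCache[[key]])) .cohortCache[[key]] <- builder()
    .cohortCache[[key]]
}

# n = 5000 x 200 genes: planted-signal recovery and the shuffle control.
plantedCohort <- function() {
    .cached("planted", function() {
        co <- simulateCohort(nSamples = 5000, nGenes = 200, seed = 202)
        gs <- suppressMessages(buildGeneScores(co$genotypes))
        list(cohort = co, scores = gs)
    })
}

# n = 2000 x 500 genes: type-I calibration.
nullCohort <- function() {
    .cached("null", function() {
        co <- simulateCohort(nSamples = 2000, nGenes = 500, seed = 101)
        gs <- suppressMessages(buildGeneScores(co$genotypes))
        list(cohort = co, scores = gs)
    })
}

# n = 8000 x 40 genes: power curves over cohort size.
powerPool <- function() {
    .cached("power", function() {
        simulateCohort(nSamples = 8000, nGenes = 40, seed = 303)
    })
}

# First gene (in id order) whose column under the given inheritance has
# genuine variability, so a phenotype can be planted in it.
plantableGene <- function(gs, inheritance = "recessive", minSd = 1e-3) {
    M <- if (inheritance == "dominant") dominantScores(gs)
         else recessiveScores(gs)
    sds <- apply(M, 1, stats::sd)
    ids <- SummarizedExperiment::rowData(gs)$gene_id
    ids[which(sds > minSd)[1]]
}

# Rebuild gene scores after replacing the variant score column.
rescoreCohort <- function(cohort, newScores) {
    gp <- cohort$genotypes
    SummarizedExperiment::rowData(gp)$score <- newScores
    suppressMessages(buildGeneScores(gp))
}
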