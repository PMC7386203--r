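#' @importFrom utils read.delim write.table head
#' @importFrom VariantAnnotation readVcf geno ref alt
#' @importFrom GenomicRanges seqnames start
#' @importFrom SummarizedExperiment rowRanges
NULL

#' Read or write a variant-effects table
#'
#' Tab-separated table with header columns \code{variant_key} (VCF-style
#' \code{CHROM:POS:REF:ALT}, 1-based position), \code{gene_id},
#' \code{consequence}, \code{score} (may be empty for non-missense rows),
#' and \code{n_sub}/\code{n_ins}/\code{n_del} (in-frame indels only).
#'
#' @param path File path.
#' @return \code{readVariantTable} returns a \code{data.frame};
#'   \code{writeVariantTable} returns \code{path} invisibly.
#' @export
readVariantTable <- function(path) {
    v <- read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
    .checkVariantTable(v)
}

#' @rdname readVariantTable
#' @param variants A variant table \code{data.frame}.
#' @export
writeVariantTable <- function(variants, path) {
    variants <- .checkVariantTable(variants)
    write.table(variants, path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}

.GT_MAP <- list(
    "0/0" = c(1, 0, 0), "0|0" = c(1, 0, 0),
    "0/1" = c(0, 1, 0), "1/0" = c(0, 1, 0),
    "0|1" = c(0, 1, 0), "1|0" = c(0, 1, 0),
    "1/1" = c(0, 0, 1), "1|1" = c(0, 0, 1),
    "./." = c(1, 0, 0), ".|." = c(1, 0, 0), "." = c(1, 0, 0))

.vcfVariantKeys <- function(vcf) {
    rr <- rowRanges(vcf)
    altList <- alt(vcf)
    nAlt <- lengths(altList)
    if (any(nAlt != 1L))
        stop("multi-allelic VCF record(s) found; decompose into bi-allelic records upstream (e.g. bcftools norm -m-)")
    sprintf("%s:%d:%s:%s", as.character(seqnames(rr)), start(rr),
            as.character(ref(vcf)), as.character(unlist(altList)))
}

#' Read genotypes into a GenotypeProbs object
#'
#' Three dialects are supported: \code{"vcf_gt"} (VCFv4.2 hard calls,
#' FORMAT field GT; 0/0, 0/1, 1/1 map to the degenerate triplets and
#' missing calls ./., treated as homozygous reference, can only cost
#' power downstream), \code{"vcf_gp"} (FORMAT field GP genotype
#' probability triplets, renormalized to sum 1; raw sums outside
#' [0.99, 1.01] are rejected; missing triplets become (1,0,0)), and
#' \code{"tsv_probs"} (long-format TSV with header
#' \code{sample_id variant_key p0 p1 p2}). Only bi-allelic records are
#' accepted; positions are 1-based as in VCF.
#'
#' @param path Path to the genotype file.
#' @param dialect One of \code{"vcf_gt"}, \code{"vcf_gp"},
#'   \code{"tsv_probs"}.
#' @param variants Optional variant-effects table; when given, variants
#'   are annotated by joining on \code{variant_key} (genotype records
#'   absent from the table are an error).
#' @return A \linkS4class{GenotypeProbs} object (variants x samples).
#' @export
readGenotypes <- function(path, dialect = c("vcf_gt", "vcf_gp",
                                            "tsv_probs"),
                          variants = NULL) {
    dialect <- match.arg(dialect)
    if (!file.exists(path)) stop("no such file: ", path)
    if (dialect == "tsv_probs") {
        tab <- read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
        need <- c("sample_id", "variant_key", "p0", "p1", "p2")
        miss <- setdiff(need, colnames(tab))
        if (length(miss))
            stop("probability TSV is missing column(s): ",
                 paste(miss, collapse = ", "))
        badRow <- which(!stats::complete.cases(tab[, c("p0", "p1", "p2")]))
        if (length(badRow))
            stop(sprintf("malformed probability record at line %d of %s",
                         badRow[1] + 1L, path))
        vkeys <- unique(tab$variant_key)
        sids <- unique(tab$sample_id)
        vi <- match(tab$variant_key, vkeys)
        si <- match(tab$sample_id, sids)
        mk <- function(col) {
            M <- matrix(NA_real_, length(vkeys), length(sids),
                        dimnames = list(vkeys, sids))
            M[cbind(vi, si)] <- tab[[col]]
            M[is.na(M)] <- c(p0 = 1, p1 = 0, p2 = 0)[[col]]
            M
        }
        p0 <- mk("p0"); p1 <- mk("p1"); p2 <- mk("p2")
    } else {
        vcf <- readVcf(path)
        vkeys <- .vcfVariantKeys(vcf)
        sids <- colnames(vcf)
        if (dialect == "vcf_gt") {
            gt <- geno(vcf)$GT
            if (is.null(gt)) stop("VCF has no GT FORMAT field")
            known <- names(.GT_MAP)
            bad <- which(!(gt %in% known))
            if (length(bad)) {
                i <- arrayInd(bad[1], dim(gt))
                stop(sprintf("unsupported GT '%s' at variant %s, sample %s",
                             gt[bad[1]], vkeys[i[1]], sids[i[2]]))
            }
            trip <- vapply(.GT_MAP[gt], identity, numeric(3))
            p0 <- matrix(trip[1, ], nrow(gt), ncol(gt))
            p1 <- matrix(trip[2, ], nrow(gt), ncol(gt))
            p2 <- matrix(trip[3, ], nrow(gt), ncol(gt))
        } else {
            gpList <- geno(vcf)$GP
            if (is.null(gpList)) stop("VCF has no GP FORMAT field")
            flat <- vapply(gpList, function(v) {
                if (length(v) != 3L || anyNA(v)) c(1, 0, 0) else v
            }, numeric(3))
            sums <- colSums(flat)
            bad <- which(sums < 0.99 | sums > 1.01)
            if (length(bad)) {
                i <- arrayInd(bad[1], dim(gpList))
                stop(sprintf("GP triplet sums to %.4f (outside [0.99, 1.01]) at variant %s, sample %s",
                             sums[bad[1]], vkeys[i[1]], sids[i[2]]))
            }
            p0 <- matrix(flat[1, ], nrow(gpList), ncol(gpList))
            p1 <- matrix(flat[2, ], nrow(gpList), ncol(gpList))
            p2 <- matrix(flat[3, ], nrow(gpList), ncol(gpList))
        }
        colnames(p0) <- sids
    }
    if (!is.null(variants)) {
        variants <- .checkVariantTable(variants)
        idx <- match(vkeys, variants$variant_key)
        if (anyNA(idx))
            stop("genotype record(s) absent from the variant table: ",
                 paste(head(vkeys[is.na(idx)], 5), collapse = ", "))
        vtab <- variants[idx, , drop = FALSE]
    } else {
        vtab <- data.frame(variant_key = vkeys, gene_id = NA_character_,
                           stringsAsFactors = FALSE)
    }
    GenotypeProbs(p0, p1, p2, vtab, sampleIds = sids)
}

#' Write genotypes as a VCFv4.2 file
#'
#' Emits bi-allelic records with a synthesized contig header, either as
#' hard GT calls (requires degenerate probability triplets) or as GP
#' probability triplets.
#'
#' @param genotypes A \linkS4class{GenotypeProbs} object.
#' @param path Output path.
#' @param field \code{"GT"} or \code{"GP"}.
#' @return \code{path}, invisibly.
#' @export
writeGenotypesVcf <- function(genotypes, path, field = c("GT", "GP")) {
    field <- match.arg(field)
    stopifnot(is(genotypes, "GenotypeProbs"))
    keys <- rowData(genotypes)$variant_key
    parts <- strsplit(keys, ":", fixed = TRUE)
    if (any(lengths(parts) != 4L))
        stop("variant keys must be CHROM:POS:REF:ALT")
    chrom <- vapply(parts, `[`, "", 1L)
    pos <- vapply(parts, `[`, "", 2L)
    refA <- vapply(parts, `[`, "", 3L)
    altA <- vapply(parts, `[`, "", 4L)
    P0 <- assay(genotypes, "p0")
    P1 <- assay(genotypes, "p1")
    P2 <- assay(genotypes, "p2")
    if (field == "GT") {
        hard <- (P0 %in% c(0, 1)) & (P1 %in% c(0, 1)) & (P2 %in% c(0, 1))
        if (!all(hard))
            stop("non-degenerate probability triplets cannot be written as GT; use field = \"GP\"")
        cells <- matrix("0/0", nrow(P0), ncol(P0))
        cells[P1 == 1] <- "0/1"
        cells[P2 == 1] <- "1/1"
    } else {
        cells <- matrix(sprintf("%.6g,%.6g,%.6g", P0, P1, P2),
                        nrow(P0), ncol(P0))
    }
    header <- c(
        "##fileformat=VCFv4.2",
        sprintf("##contig=<ID=%s>", unique(chrom)),
        if (field == "GT")
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"
        else
            "##FORMAT=<ID=GP,Number=G,Type=Float,Description=\"Genotype probabilities\">",
        paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                "INFO", "FORMAT", colnames(genotypes)), collapse = "\t"))
    body <- paste(chrom, pos, keys, refA, altA, ".", ".", ".", field,
                  apply(cells, 1, paste, collapse = "\t"), sep = "\t")
    writeLines(c(header, body), path)
    invisible(path)
}

#' Write and read gene effect score matrices
#'
#' One TSV per inheritance model: samples as rows (first column
#' \code{sample_id}), genes as columns, fixed scientific formatting.
#' \code{readGeneScores} reassembles a \linkS4class{GeneScores} object
#' from the two files.
#'
#' @param geneScores A \linkS4class{GeneScores} object.
#' @param path Output path for the chosen model's matrix.
#' @param model \code{"dominant"} or \code{"recessive"}.
#' @return \code{writeGeneScores} returns \code{path} invisibly;
#'   \code{readGeneScores} returns a \code{GeneScores} object.
#' @export
writeGeneScores <- function(geneScores, path,
                            model = c("dominant", "recessive")) {
    model <- match.arg(model)
    stopifnot(is(geneScores, "GeneScores"))
    M <- t(assay(geneScores, model))
    df <- data.frame(sample_id = rownames(M),
                     matrix(sprintf("%.6e", M), nrow(M), ncol(M)),
                     stringsAsFactors = FALSE, check.names = FALSE)
    colnames(df) <- c("sample_id", colnames(M))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

.readScoreMatrix <- function(path) {
    df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                     stringsAsFactors = FALSE)
    M <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(M) <- "double"
    rownames(M) <- df$sample_id
    t(M)   # back to genes x samples
}

#' @rdname writeGeneScores
#' @param dominantPath,recessivePath Paths of the two matrices written by
#'   \code{writeGeneScores}.
#' @param params Optional \linkS4class{AggregationParams} to attach.
#' @export
readGeneScores <- function(dominantPath, recessivePath, params = NULL) {
    D <- .readScoreMatrix(dominantPath)
    R <- .readScoreMatrix(recessivePath)
    if (!identical(dimnames(D), dimnames(R)))
        stop("dominant and recessive matrices disagree in samples or genes")
    GeneScores(D, R, params = params)
}

#' Write per-gene association summary statistics
#'
#' Deterministic column order, scientific notation with 6 significant
#' digits for the statistics, rows sorted by the generalized-model
#' p-value (the order produced by \code{\link{runPWAS}}). An empty result
#' set yields a header-only file.
#'
#' @param results The \code{data.frame} returned by \code{\link{runPWAS}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeResults <- function(results, path) {
    out <- results[order(results$p_generalized), , drop = FALSE]
    num <- vapply(out, is.numeric, logical(1)) &
        !colnames(out) %in% c("n_samples", "n_variants")
    for (j in which(num)) out[[j]] <- sprintf("%.5e", out[[j]])
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a phenotype or covariate TSV
#'
#' \code{readPhenotype} expects columns \code{sample_id} and
#' \code{value} and returns a named numeric vector;
#' \code{readCovariates} expects \code{sample_id} plus one column per
#' covariate and returns a numeric matrix with sample rownames.
#'
#' @param path File path.
#' @return Named numeric vector or matrix.
#' @export
readPhenotype <- function(path) {
    df <- read.delim(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    if (!all(c("sample_id", "value") %in% colnames(df)))
        stop("phenotype TSV needs columns 'sample_id' and 'value'")
    y <- as.numeric(df$value)
    names(y) <- df$sample_id
    y
}

#' @rdname readPhenotype
#' @export
readCovariates <- function(path) {
    df <- read.delim(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    if (!"sample_id" %in% colnames(df))
        stop("covariate TSV needs a 'sample_id' column")
    M <- as.matrix(df[, setdiff(colnames(df), "sample_id"), drop = FALSE])
    storage.mode(M) <- "double"
    rownames(M) <- df$sample_id
    M
}

#' Write a synthetic cohort to disk
#'
#' Emits \code{variants.tsv}, \code{genotypes.vcf} and
#' \code{covariates.tsv} (and, given a planted phenotype,
#' \code{phenotype.tsv} plus \code{truth.json}) into a directory.
#'
#' @param cohort The list returned by \code{\link{simulateCohort}}.
#' @param dir Output directory (created if missing).
#' @param genotypeField \code{"GT"} or \code{"GP"}.
#' @param phenotype Optional named phenotype vector.
#' @param truth Optional ground-truth list (from
#'   \code{\link{plantAssociation}}).
#' @return The directory path, invisibly.
#' @export
writeCohort <- function(cohort, dir, genotypeField = c("GT", "GP"),
                        phenotype = NULL, truth = NULL) {
    genotypeField <- match.arg(genotypeField)
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    writeVariantTable(cohort$variants, file.path(dir, "variants.tsv"))
    writeGenotypesVcf(cohort$genotypes, file.path(dir, "genotypes.vcf"),
                      field = genotypeField)
    if (!is.null(cohort$covariates)) {
        df <- data.frame(sample_id = rownames(cohort$covariates),
                         cohort$covariates, stringsAsFactors = FALSE)
        write.table(df, file.path(dir, "covariates.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
    }
    if (!is.null(phenotype)) {
        df <- data.frame(sample_id = names(phenotype), value = phenotype,
                         stringsAsFactors = FALSE)
        write.table(df, file.path(dir, "phenotype.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
    }
    if (!is.null(truth)) {
        jsonlite::write_json(truth, file.path(dir, "truth.json"),
                             auto_unbox = TRUE, digits = NA)
    }
    invisible(dir)
}
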