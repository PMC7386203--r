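#' @rdname dominantScores
#' @export
setGeneric("dominantScores", function(x) standardGeneric("dominantScores"))

#' @rdname dominantScores
#' @export
setGeneric("recessiveScores", function(x) standardGeneric("recessiveScores"))

#' @rdname dominantScores
#' @export
setGeneric("aggregationParams",
           function(x) standardGeneric("aggregationParams"))

#' Accessors for gene effect score matrices
#'
#' \code{dominantScores} and \code{recessiveScores} return the genes x
#' samples score matrices of a \linkS4class{GeneScores} object;
#' \code{aggregationParams} returns the \linkS4class{AggregationParams}
#' the scores were built with (or NULL).
#'
#' @param x A \linkS4class{GeneScores} object.
#' @return A numeric matrix (genes x samples), or an
#'   \code{AggregationParams} object for \code{aggregationParams}.
#' @name dominantScores
#' @export
setMethod("dominantScores", "GeneScores",
          function(x) assay(x, "dominant"))

#' @rdname dominantScores
#' @export
setMethod("recessiveScores", "GeneScores",
          function(x) assay(x, "recessive"))

#' @rdname dominantScores
#' @export
setMethod("aggregationParams", "GeneScores",
          function(x) metadata(x)$params)
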