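#' @rdname GeneModelSet-class
#' @param x a `GeneModelSet` (or, for the call/meta accessors, a
#'   `CohortCallSet` / `RecurrenceReport`).
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))

#' @rdname GeneModelSet-class
#' @export
setGeneric("geneFeatures", function(x) standardGeneric("geneFeatures"))

#' @rdname GeneModelSet-class
#' @export
setGeneric("homologPairs", function(x) standardGeneric("homologPairs"))

#' @rdname GeneModelSet-class
#' @export
setGeneric("mitoChrom", function(x) standardGeneric("mitoChrom"))

#' @rdname CohortCallSet-class
#' @export
setGeneric("fusionCalls", function(x) standardGeneric("fusionCalls"))

#' @rdname CohortCallSet-class
#' @export
setGeneric("sampleMeta", function(x) standardGeneric("sampleMeta"))

#' @rdname RecurrenceReport-class
#' @export
setGeneric("recurrenceTable", function(x) standardGeneric("recurrenceTable"))

#' @rdname RecurrenceReport-class
#' @export
setGeneric("cohortSizes", function(x) standardGeneric("cohortSizes"))

#' @rdname GeneModelSet-class
#' @export
setMethod("genes", "GeneModelSet", function(x) x@genes)

#' @rdname GeneModelSet-class
#' @export
setMethod("geneFeatures", "GeneModelSet", function(x) x@features)

#' @rdname GeneModelSet-class
#' @export
setMethod("homologPairs", "GeneModelSet", function(x) x@homologs)

#' @rdname GeneModelSet-class
#' @export
setMethod("mitoChrom", "GeneModelSet", function(x) x@mitoChrom)

#' @rdname CohortCallSet-class
#' @export
setMethod("fusionCalls", "CohortCallSet", function(x) x@calls)

#' @rdname CohortCallSet-class
#' @export
setMethod("sampleMeta", "CohortCallSet", function(x) x@sampleMeta)

#' @rdname RecurrenceReport-class
#' @export
setMethod("recurrenceTable", "RecurrenceReport", function(x) x@report)

#' @rdname RecurrenceReport-class
#' @export
setMethod("cohortSizes", "RecurrenceReport", function(x) x@cohortSizes)

setMethod("show", "GeneModelSet", function(object) {
  bt <- table(factor(S4Vectors::mcols(object@genes)$biotype, levels = .BIOTYPES))
  cat("GeneModelSet with", length(object@genes), "genes on",
      length(unique(as.character(GenomicRanges::seqnames(object@genes)))),
      "chromosomes (mito:", object@mitoChrom, ")\n")
  cat("  biotypes:", paste(names(bt), bt, sep = "=", collapse = " "), "\n")
  cat("  features:", length(object@features), "|", "homolog pairs:",
      nrow(object@homologs), "\n")
})

setMethod("show", "CallingParams", function(object) {
  cat("CallingParams: minAnchor=", object@minAnchor,
      "bp, minJunctionReads=", object@minJunctionReads,
      ", mitoChrom=", object@mitoChrom,
      ", mitoStrict=", object@mitoStrict,
      ", window=", object@window, "bp\n", sep = "")
})

setMethod("show", "CohortCallSet", function(object) {
  m <- object@sampleMeta
  cat("CohortCallSet:", nrow(object@calls), "calls of",
      length(unique(fusionKey(object@calls$gene5, object@calls$gene3))),
      "distinct fusions in", nrow(m), "samples\n")
  cat("  samples:", sum(m$cohort == "discovery"), "discovery /",
      sum(m$cohort == "validation"), "validation;",
      sum(m$tissue == "tumor"), "tumor /",
      sum(m$tissue == "normal"), "normal\n")
})

setMethod("show", "RecurrenceReport", function(object) {
  r <- object@report
  cat("RecurrenceReport:", nrow(r), "fusions,",
      sum(r$label == "recurrent"), "recurrent /",
      sum(r$label == "singleton"), "singleton\n")
  if (nrow(r)) {
    rec <- r[r$label == "recurrent", , drop = FALSE]
    tc <- table(factor(rec$tissue_class,
                       levels = c("tumor_only", "normal_only", "both")))
    cat("  recurrent tissue classes:",
        paste(names(tc), tc, sep = "=", collapse = " "), "\n")
  }
})
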