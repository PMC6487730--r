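#' Bundled RT-PCR validation-cohort example data
#'
#' Small plain-text tables shipped with the package: the sample
#' metadata of a published RT-PCR validation cohort of 14 HBV-related
#' HCC patients (11 tumor/adjacent-normal pairs plus three
#' multi-lesion patients: 14 normal and 17 tumor samples), and the
#' per-fusion supported-sample lists of the six fusions confirmed by
#' RT-PCR and Sanger sequencing in that cohort.  These are the worked
#' inputs for [supportRatios()].
#'
#' @return `exampleValidationCohort()` returns a list with `meta`
#'   (sample metadata data.frame) and `support` (one row per validated
#'   fusion; supporting normal/tumor sample ids are `/`-separated).
#' @examples
#' ex <- exampleValidationCohort()
#' s <- ex$support[ex$support$gene5 == "C15orf57", ]
#' samples <- unlist(strsplit(c(s$normal_samples, s$tumor_samples), "/"))
#' supportRatios(samples, ex$meta)
#' @export
exampleValidationCohort <- function() {
  meta <- readSampleMeta(system.file("extdata", "rtpcr_cohort_meta.tsv",
                                     package = "fusionscape",
                                     mustWork = TRUE))
  support <- utils::read.delim(
    system.file("extdata", "rtpcr_fusion_support.tsv",
                package = "fusionscape", mustWork = TRUE),
    stringsAsFactors = FALSE)
  list(meta = meta, support = support)
}

#' @rdname exampleValidationCohort
#' @return `exampleLibraryQc()` returns the raw / clean / uniquely
#'   mapped read-pair counts of the seven discovery libraries, ready
#'   for [qcPercentages()].
#' @export
exampleLibraryQc <- function() {
  utils::read.delim(system.file("extdata", "library_qc.tsv",
                                package = "fusionscape", mustWork = TRUE),
                    stringsAsFactors = FALSE)
}

#' Supporting samples of one validated fusion
#'
#' Convenience accessor: the supporting sample ids (normal and tumor
#' combined) of one fusion in the bundled validation-cohort table.
#'
#' @param gene5,gene3 partner gene symbols.
#' @return character vector of sample ids.
#' @export
exampleFusionSupport <- function(gene5, gene3) {
  ex <- exampleValidationCohort()
  row <- ex$support[ex$support$gene5 == gene5 & ex$support$gene3 == gene3, ]
  if (!nrow(row))
    stop("fusion not in the bundled support table: ", gene5, "-", gene3,
         call. = FALSE)
  samples <- unlist(strsplit(c(row$normal_samples, row$tumor_samples), "/",
                             fixed = TRUE))
  samples[nzchar(samples)]
}
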