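#' @import methods
#' @importFrom S4Vectors mcols mcols<- metadata metadata<-
#' @importFrom GenomicRanges GRanges seqnames start end strand findOverlaps
#' @importFrom IRanges IRanges
NULL

## biotype vocabulary used throughout; anything else collapses to "other"
.BIOTYPES <- c("protein_coding", "lncRNA", "pseudogene", "other")

## feature kinds carried by gene models
.FEATURE_KINDS <- c("exon", "five_prime_utr", "three_prime_utr", "domain")

#' GeneModelSet: gene models with feature-level annotation
#'
#' Container for a set of gene models: one genomic range per gene
#' (with `gene_id`, `gene_name` and `biotype` metadata columns), a
#' second range set holding sub-gene features (exons, UTRs and protein
#' domains, each tagged with the owning `gene_id`), an optional list of
#' homologous gene pairs used by the fusion-calling homolog filter, and
#' the name of the mitochondrial chromosome.
#'
#' @slot genes `GRanges`, one range per gene; mcols `gene_id`,
#'   `gene_name`, `biotype` (one of protein_coding, lncRNA, pseudogene,
#'   other).
#' @slot features `GRanges`; mcols `gene_id`, `kind` (exon,
#'   five_prime_utr, three_prime_utr, domain) and `label` (domain name,
#'   empty otherwise).
#' @slot homologs data.frame with columns `gene_a`, `gene_b`;
#'   unordered pairs treated as homologous.
#' @slot mitoChrom character(1), mitochondrial chromosome name.
#'
#' @seealso [readGtf()], [generateGeneModels()], [genes()],
#'   [geneFeatures()], [homologPairs()]
#' @export
setClass("GeneModelSet",
  slots = c(
    genes     = "GRanges",
    features  = "GRanges",
    homologs  = "data.frame",
    mitoChrom = "character"
  )
)

setValidity("GeneModelSet", function(object) {
  msg <- character()
  gm <- S4Vectors::mcols(object@genes)
  need <- c("gene_id", "gene_name", "biotype")
  if (!all(need %in% colnames(gm)))
    return(paste("genes mcols must contain", paste(need, collapse = ", ")))
  if (anyDuplicated(gm$gene_id))
    msg <- c(msg, "duplicated gene_id in genes")
  if (!all(gm$biotype %in% .BIOTYPES))
    msg <- c(msg, "biotype outside vocabulary (protein_coding/lncRNA/pseudogene/other)")
  fm <- S4Vectors::mcols(object@features)
  if (length(object@features)) {
    if (!all(c("gene_id", "kind") %in% colnames(fm)))
      return("features mcols must contain gene_id and kind")
    if (!all(fm$kind %in% .FEATURE_KINDS))
      msg <- c(msg, "feature kind outside vocabulary")
    if (!all(fm$gene_id %in% gm$gene_id))
      msg <- c(msg, "feature gene_id not present in genes")
    ## every feature interval must lie inside its gene's span
    idx <- match(fm$gene_id, gm$gene_id)
    ok <- as.character(GenomicRanges::seqnames(object@features)) ==
            as.character(GenomicRanges::seqnames(object@genes))[idx] &
          GenomicRanges::start(object@features) >= GenomicRanges::start(object@genes)[idx] &
          GenomicRanges::end(object@features) <= GenomicRanges::end(object@genes)[idx]
    if (!all(ok))
      msg <- c(msg, "feature interval outside its gene span")
    ## every gene needs at least one exon
    withEx <- unique(fm$gene_id[fm$kind == "exon"])
    if (!all(gm$gene_id %in% withEx))
      msg <- c(msg, "gene without exon feature")
  } else if (length(object@genes)) {
    msg <- c(msg, "gene models without any exon features")
  }
  if (nrow(object@homologs) &&
      !all(c("gene_a", "gene_b") %in% colnames(object@homologs)))
    msg <- c(msg, "homologs must have columns gene_a, gene_b")
  if (length(object@mitoChrom) != 1L || !nzchar(object@mitoChrom))
    msg <- c(msg, "mitoChrom must be a single non-empty chromosome name")
  if (length(msg)) msg else TRUE
})

#' CallingParams: fusion-calling filter parameters
#'
#' Thresholds of the chimeric-read filtering cascade: minimum anchor
#' length on each side of the junction, minimum junction-read support
#' per breakpoint pair, homologous pairs to discard, the mitochondrial
#' chromosome, and an optional breakpoint clustering window.
#'
#' @slot minAnchor integer(1), minimum aligned bases on each side of
#'   the junction (default 15 bp).
#' @slot minJunctionReads integer(1), minimum distinct junction reads
#'   per candidate (default 3).
#' @slot mitoChrom character(1), mitochondrial chromosome name
#'   (default "chrM").
#' @slot mitoStrict logical(1); `FALSE` (default) removes every
#'   candidate touching the mitochondrial chromosome, `TRUE` removes
#'   only mitochondrion-autosome candidates (literal reading, keeping
#'   mitochondrion-sex-chromosome pairs).
#' @slot window integer(1), breakpoint clustering window in bp;
#'   0 (default) groups on exact positions, as splice-mediated
#'   junctions recur at the identical coordinate.
#' @slot maxMismatches integer(1), recorded for provenance only: the
#'   per-read mismatch cap applied by the upstream aligner.
#' @seealso [callingParams()], [callFusions()]
#' @export
setClass("CallingParams",
  slots = c(
    minAnchor        = "integer",
    minJunctionReads = "integer",
    mitoChrom        = "character",
    mitoStrict       = "logical",
    window           = "integer",
    maxMismatches    = "integer"
  )
)

setValidity("CallingParams", function(object) {
  msg <- character()
  if (object@minAnchor < 1L) msg <- c(msg, "minAnchor must be >= 1")
  if (object@minJunctionReads < 1L) msg <- c(msg, "minJunctionReads must be >= 1")
  if (object@window < 0L) msg <- c(msg, "window must be >= 0")
  if (!nzchar(object@mitoChrom)) msg <- c(msg, "mitoChrom must be non-empty")
  if (length(msg)) msg else TRUE
})

#' CohortCallSet: per-sample fusion calls plus sample metadata
#'
#' @slot calls data.frame of fusion candidates with columns `gene5`,
#'   `gene3`, `chrom5`, `pos5`, `chrom3`, `pos3`, `junction_reads`,
#'   `sample_id`.
#' @slot sampleMeta data.frame with columns `sample_id`, `patient_id`,
#'   `tissue` (tumor/normal), `cohort` (discovery/validation).
#' @seealso [CohortCallSet()], [classifyRecurrence()], [clusterSamples()]
#' @export
setClass("CohortCallSet",
  slots = c(calls = "data.frame", sampleMeta = "data.frame")
)

setValidity("CohortCallSet", function(object) {
  msg <- character()
  needC <- c("gene5", "gene3", "junction_reads", "sample_id")
  if (!all(needC %in% colnames(object@calls)))
    return(paste("calls must contain columns", paste(needC, collapse = ", ")))
  needM <- c("sample_id", "patient_id", "tissue", "cohort")
  if (!all(needM %in% colnames(object@sampleMeta)))
    return(paste("sampleMeta must contain columns", paste(needM, collapse = ", ")))
  meta <- object@sampleMeta
  if (anyDuplicated(meta$sample_id))
    msg <- c(msg, "duplicated sample_id in sampleMeta")
  if (!all(meta$tissue %in% c("tumor", "normal")))
    msg <- c(msg, "tissue must be tumor or normal")
  if (!all(meta$cohort %in% c("discovery", "validation")))
    msg <- c(msg, "cohort must be discovery or validation")
  unknown <- setdiff(unique(object@calls$sample_id), meta$sample_id)
  if (length(unknown))
    msg <- c(msg, paste("calls reference unknown sample(s):",
                        paste(utils::head(unknown, 5), collapse = ", ")))
  if (nrow(object@calls) && any(object@calls$junction_reads < 1))
    msg <- c(msg, "junction_reads must be >= 1")
  if (nrow(object@calls) && any(object@calls$gene5 == object@calls$gene3))
    msg <- c(msg, "gene5 must differ from gene3")
  if (length(msg)) msg else TRUE
})

#' RecurrenceReport: cohort recurrence classification of fusions
#'
#' One row per distinct fusion (ordered gene pair) with its supporting
#' discovery/validation sample sets, the recurrence label, the tissue
#' class of its supporting samples, and cohort denominators recorded in
#' `cohortSizes`.
#'
#' @slot report data.frame, one row per fusion: `gene5`, `gene3`,
#'   `discovery_samples`, `validation_samples` (comma-separated ids),
#'   `n_discovery`, `n_validation`, `label` (recurrent/singleton),
#'   `tissue_class` (tumor_only/normal_only/both).
#' @slot cohortSizes named integer vector: numbers of discovery /
#'   validation samples, patients, tumor and normal samples.
#' @seealso [classifyRecurrence()], [tissuePartition()]
#' @export
setClass("RecurrenceReport",
  slots = c(report = "data.frame", cohortSizes = "integer")
)

setValidity("RecurrenceReport", function(object) {
  need <- c("gene5", "gene3", "n_discovery", "n_validation", "label",
            "tissue_class")
  if (!all(need %in% colnames(object@report)))
    return(paste("report must contain", paste(need, collapse = ", ")))
  r <- object@report
  if (nrow(r)) {
    okLabel <- r$label %in% c("recurrent", "singleton")
    if (!all(okLabel)) return("label must be recurrent or singleton")
    rule <- r$n_discovery >= 2L | (r$n_discovery == 1L & r$n_validation >= 1L)
    if (!all((r$label == "recurrent") == rule))
      return("label inconsistent with the recurrence rule")
  }
  TRUE
})
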