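## End-to-end orchestration: call -> recur -> annotate -> report, with
## provenance headers on every output and deterministic bytes for a
## fixed configuration.

.provenance <- function(params, seed) {
  c(fusionscape_version = as.character(utils::packageVersion("fusionscape")),
    seed = as.character(seed),
    min_anchor = as.character(params@minAnchor),
    min_junction_reads = as.character(params@minJunctionReads),
    mito_chrom = params@mitoChrom,
    mito_strict = as.character(params@mitoStrict),
    window = as.character(params@window))
}

.stage <- function(name, input, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed on %s: %s", name, input,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full fusion-landscape pipeline
#'
#' Stages run in order: per-sample fusion calling from chimeric
#' records, cohort recurrence classification, known-fusion database
#' annotation plus breakpoint annotation, and landscape summaries.
#' Every output table carries a `#key=value` provenance header
#' (package version, seed, calling thresholds); re-running the same
#' configuration reproduces identical bytes.  No file is written
#' outside `outDir`.
#'
#' @param outDir output directory (created if missing).
#' @param gtfPath path to the gene-model GTF.
#' @param chimericPaths named character vector of chimeric-record TSV
#'   paths, names are sample ids.
#' @param metaPath path to the sample-metadata TSV (may include
#'   validation samples absent from `chimericPaths`).
#' @param validationCallsPath optional fusion-call TSV contributing
#'   pre-called validation-cohort calls to the recurrence stage.
#' @param dbPaths character vector of known-fusion database TSV paths.
#' @param homologPath optional homolog-pair TSV overriding the (empty)
#'   pair list of the GTF.
#' @param params a [CallingParams-class].
#' @param unordered match fusions across samples as unordered pairs.
#' @param seed recorded in output headers (the pipeline itself is
#'   deterministic).
#' @return invisibly, a list of the stage results (`calls`, `report`,
#'   `annotations`, `summaries`).
#' @export
runPipeline <- function(outDir, gtfPath, chimericPaths, metaPath,
                        validationCallsPath = NULL,
                        dbPaths = character(), homologPath = NULL,
                        params = callingParams(), unordered = FALSE,
                        seed = 0L) {
  for (p in c(gtfPath, unname(chimericPaths), metaPath, validationCallsPath,
              dbPaths, homologPath)) {
    if (!file.exists(p))
      stop("configuration error: input path does not exist: ", p,
           call. = FALSE)
  }
  if (is.null(names(chimericPaths)) || any(!nzchar(names(chimericPaths))))
    stop("configuration error: chimericPaths must be named by sample id",
         call. = FALSE)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  prov <- .provenance(params, seed)

  models <- .stage("call", gtfPath, {
    m <- readGtf(gtfPath, mitoChrom = params@mitoChrom)
    if (!is.null(homologPath))
      m@homologs <- readHomologPairs(homologPath)
    m
  })
  calls <- .stage("call", paste(chimericPaths, collapse = ","), {
    perSample <- lapply(names(chimericPaths), function(sid) {
      callFusions(readChimeric(chimericPaths[[sid]]), models,
                  params = params, sampleId = sid)
    })
    do.call(rbind, perSample)
  })
  writeFusionTable(calls, file.path(outDir, "calls.tsv"), provenance = prov)

  meta <- .stage("recur", metaPath, readSampleMeta(metaPath))
  allCalls <- calls[, .FUSION_COLS]
  if (!is.null(validationCallsPath)) {
    vcalls <- .stage("recur", validationCallsPath,
                     readFusionTable(validationCallsPath))
    allCalls <- rbind(allCalls, vcalls[, .FUSION_COLS])
  }
  report <- .stage("recur", metaPath, {
    classifyRecurrence(CohortCallSet(allCalls, meta), unordered = unordered)
  })
  rep <- recurrenceTable(report)
  .writeTsv(rep, file.path(outDir, "recurrence.tsv"), provenance = prov)
  part <- tissuePartition(report)
  .writeTsv(part, file.path(outDir, "tissue_partition.tsv"),
            provenance = prov)

  annotations <- .stage("annotate", paste(dbPaths, collapse = ","), {
    dbs <- lapply(dbPaths, readKnownFusionDb)
    fus <- unique(rep[, c("gene5", "gene3")])
    ann <- if (nrow(fus) && length(dbs)) matchKnown(fus, dbs)
           else cbind(fus, category = character(nrow(fus)),
                      evidence = character(nrow(fus)))
    bp <- if (nrow(calls)) annotateBreakpoints(calls, models) else calls
    list(known = ann, breakpoints = bp)
  })
  .writeTsv(annotations$known, file.path(outDir, "annotations.tsv"),
            provenance = prov)

  summaries <- .stage("report", outDir, {
    typed <- if (nrow(calls)) classifyFusionType(calls, models) else calls
    ts <- if (nrow(calls)) fusionTypeSummary(typed) else
      list(types = data.frame(), chromosomal = data.frame())
    pc <- partnerCounts(allCalls)
    list(typed = typed, typeSummary = ts, partnerCounts = pc)
  })
  .writeTsv(summaries$partnerCounts, file.path(outDir, "partner_counts.tsv"),
            provenance = prov)
  if (nrow(summaries$typeSummary$types))
    .writeTsv(summaries$typeSummary$types,
              file.path(outDir, "type_summary.tsv"), provenance = prov)

  json <- list(
    provenance = as.list(prov),
    n_calls = nrow(calls),
    n_fusions = nrow(rep),
    n_recurrent = sum(rep$label == "recurrent"),
    n_singleton = sum(rep$label == "singleton"),
    tissue_partition = part)
  jsonlite::write_json(json, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(calls = calls, report = report, annotations = annotations,
                 summaries = summaries))
}
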