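## Cohort-level recurrence analysis: recurrence classification across a
## discovery cohort and an independent validation cohort, tissue
## partitioning, per-fusion support ratios, enrichment testing and
## sample clustering on shared-fusion profiles.

#' Classify cohort recurrence of fusions
#'
#' A fusion (ordered gene pair `gene5 >> gene3`; set `unordered = TRUE`
#' to collapse orientation) is *recurrent* when it occurs in at least
#' two discovery samples, or in exactly one discovery sample and also
#' in at least one validation sample.  Every other fusion is a
#' *singleton*.  The tissue class of each fusion summarises the tissues
#' of all its supporting samples: `tumor_only`, `normal_only` or
#' `both`.
#'
#' Classification is invariant to call order and to duplicate calls of
#' the same fusion within a sample.
#'
#' @param cohort a [CohortCallSet-class].
#' @param unordered if `TRUE`, match fusions across samples as
#'   unordered gene pairs.
#' @return a [RecurrenceReport-class].
#' @export
classifyRecurrence <- function(cohort, unordered = FALSE) {
  methods::validObject(cohort)
  calls <- fusionCalls(cohort)
  meta <- sampleMeta(cohort)
  sizes <- c(
    discovery  = sum(meta$cohort == "discovery"),
    validation = sum(meta$cohort == "validation"),
    patients   = length(unique(meta$patient_id)),
    tumor      = sum(meta$tissue == "tumor"),
    normal     = sum(meta$tissue == "normal"))
  if (!nrow(calls)) {
    rep <- data.frame(gene5 = character(), gene3 = character(),
                      discovery_samples = character(),
                      validation_samples = character(),
                      n_discovery = integer(), n_validation = integer(),
                      label = character(), tissue_class = character(),
                      stringsAsFactors = FALSE)
    return(methods::new("RecurrenceReport", report = rep,
                        cohortSizes = as.integer(stats::setNames(
                          sizes, names(sizes)))))
  }
  key <- if (unordered) unorderedKey(calls$gene5, calls$gene3)
         else fusionKey(calls$gene5, calls$gene3)
  uniq <- !duplicated(paste(key, calls$sample_id, sep = "\r"))
  calls <- calls[uniq, , drop = FALSE]
  key <- key[uniq]
  ord <- order(key, calls$sample_id)
  calls <- calls[ord, , drop = FALSE]; key <- key[ord]

  cohortOf <- meta$cohort[match(calls$sample_id, meta$sample_id)]
  tissueOf <- meta$tissue[match(calls$sample_id, meta$sample_id)]
  rows <- lapply(base::split(seq_len(nrow(calls)), key), function(idx) {
    disc <- unique(calls$sample_id[idx][cohortOf[idx] == "discovery"])
    val  <- unique(calls$sample_id[idx][cohortOf[idx] == "validation"])
    tis  <- unique(tissueOf[idx])
    data.frame(
      gene5 = calls$gene5[idx[1]], gene3 = calls$gene3[idx[1]],
      discovery_samples = paste(sort(disc), collapse = ","),
      validation_samples = paste(sort(val), collapse = ","),
      n_discovery = length(disc), n_validation = length(val),
      label = if (length(disc) >= 2L ||
                  (length(disc) == 1L && length(val) >= 1L))
                "recurrent" else "singleton",
      tissue_class = if (all(c("tumor", "normal") %in% tis)) "both"
                     else if ("normal" %in% tis) "normal_only"
                     else "tumor_only",
      stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, rows)
  rep <- rep[order(rep$gene5, rep$gene3), , drop = FALSE]
  rownames(rep) <- NULL
  methods::new("RecurrenceReport", report = rep,
               cohortSizes = as.integer(stats::setNames(sizes, names(sizes))))
}

#' Partition recurrent fusions by supporting tissue
#'
#' Counts recurrent fusions whose supporting samples are exclusively
#' tumor, exclusively adjacent normal, or both, and reports each count
#' as a one-decimal percentage of the recurrent total (half away from
#' zero).  The partition is exhaustive and disjoint, so counts sum to
#' the number of recurrent fusions.
#'
#' @param report a [RecurrenceReport-class] (or its `recurrenceTable`
#'   data.frame).
#' @return data.frame with columns `tissue_class`, `n`, `pct`.
#' @export
tissuePartition <- function(report) {
  r <- if (methods::is(report, "RecurrenceReport")) recurrenceTable(report)
       else report
  rec <- r[r$label == "recurrent", , drop = FALSE]
  lev <- c("tumor_only", "normal_only", "both")
  n <- as.integer(table(factor(rec$tissue_class, levels = lev)))
  pct <- if (nrow(rec)) roundHalfUp(100 * n / nrow(rec), 1) else rep(0, 3)
  data.frame(tissue_class = lev, n = n, pct = pct, stringsAsFactors = FALSE)
}

#' Support ratios of a fusion over a validation cohort
#'
#' Given the samples supporting one fusion and the cohort metadata,
#' computes the patient ratio (patients owning at least one supporting
#' sample over all patients), the normal-sample ratio and the
#' tumor-sample ratio.  Percentages are rounded half away from zero to
#' integers.
#'
#' @param supportingSamples character vector of supporting sample ids.
#' @param meta data.frame of sample metadata (`sample_id`,
#'   `patient_id`, `tissue`; see [readSampleMeta()]).
#' @return data.frame with one row per ratio (`patient`, `normal`,
#'   `tumor`) and columns `numerator`, `denominator`, `pct`.
#' @export
supportRatios <- function(supportingSamples, meta) {
  supportingSamples <- unique(supportingSamples)
  unknown <- setdiff(supportingSamples, meta$sample_id)
  if (length(unknown))
    stop("supporting sample(s) absent from metadata: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  sup <- meta[meta$sample_id %in% supportingSamples, , drop = FALSE]
  num <- c(patient = length(unique(sup$patient_id)),
           normal  = sum(sup$tissue == "normal"),
           tumor   = sum(sup$tissue == "tumor"))
  den <- c(patient = length(unique(meta$patient_id)),
           normal  = sum(meta$tissue == "normal"),
           tumor   = sum(meta$tissue == "tumor"))
  data.frame(ratio = names(num),
             numerator = as.integer(num),
             denominator = as.integer(den),
             pct = ifelse(den > 0, roundHalfUp(100 * num / den), 0),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact two-sided p-value for a 2x2 contingency table (rows:
#' recurrent / non-recurrent fusions; columns: validation-supported /
#' not): the sum of hypergeometric probabilities, over all tables with
#' the observed margins, of tables whose point probability does not
#' exceed that of the observed table (ties within 1e-7 relative
#' tolerance).  Delegates to [stats::fisher.test()], which implements
#' exactly this rule; the test suite checks it against an independent
#' full-enumeration oracle.
#'
#' @param a,b,c,d the four cell counts (first row `a`, `b`; second row
#'   `c`, `d`), or a 2x2 matrix as `a` with the rest missing.
#' @return the two-sided p-value in (0, 1].
#' @examples
#' fisherExact(15, 5, 23, 2311)   # recurrent-fusion enrichment layout
#' fisherExact(1, 1, 1, 1)        # symmetric margins -> 1
#' @export
fisherExact <- function(a, b, c, d) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == c(2L, 2L)))
    tab <- a
  } else {
    tab <- matrix(c(a, c, b, d), nrow = 2L)
  }
  if (any(tab < 0) || any(tab != floor(tab)))
    stop("contingency table must hold non-negative integers", call. = FALSE)
  if (sum(tab) == 0)
    stop("contingency table is all zero", call. = FALSE)
  stats::fisher.test(tab, alternative = "two.sided")$p.value
}

#' Cluster samples on shared-fusion profiles
#'
#' Builds the binary sample-by-fusion matrix restricted to fusions
#' present in at least `minSamples` of the clustered samples, computes
#' pairwise Jaccard distances and performs average-linkage hierarchical
#' clustering.  With `k` set, returns the flat cut as well.
#'
#' @param cohort a [CohortCallSet-class].
#' @param k number of flat clusters to cut (optional).
#' @param minSamples restrict to fusions seen in at least this many of
#'   the clustered samples (default 2; singleton fusions carry no
#'   between-sample signal).
#' @param cohortRole which cohort(s) to cluster (default discovery).
#' @return list with `matrix` (binary incidence), `dist`, `hclust`,
#'   and, when `k` is given, `clusters` (named integer vector).
#' @export
clusterSamples <- function(cohort, k = NULL, minSamples = 2L,
                           cohortRole = "discovery") {
  meta <- sampleMeta(cohort)
  samples <- meta$sample_id[meta$cohort %in% cohortRole]
  if (length(samples) < 2L)
    stop("need at least two samples to cluster", call. = FALSE)
  calls <- fusionCalls(cohort)
  calls <- calls[calls$sample_id %in% samples, , drop = FALSE]
  key <- fusionKey(calls$gene5, calls$gene3)
  inc <- table(calls$sample_id, key) > 0
  keep <- colSums(inc) >= minSamples
  m <- matrix(0L, nrow = length(samples), ncol = sum(keep),
              dimnames = list(samples, colnames(inc)[keep]))
  if (any(keep)) {
    sub <- inc[, keep, drop = FALSE]
    m[rownames(sub), ] <- sub + 0L
  }
  if (!ncol(m))
    stop("no fusion is shared by >= ", minSamples, " samples", call. = FALSE)
  d <- stats::dist(m, method = "binary")   # Jaccard distance on binary rows
  ## two samples with no shared fusions at all are maximally distant, not NaN
  d[is.na(d)] <- 1
  hc <- stats::hclust(d, method = "average")
  out <- list(matrix = m, dist = d, hclust = hc)
  if (!is.null(k)) out$clusters <- stats::cutree(hc, k = k)
  out
}
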