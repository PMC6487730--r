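## Descriptive statistics of the fusion landscape and qPCR fold-change
## arithmetic.

#' Classify fusion type by partner biotypes and chromosomes
#'
#' The type of a fusion is the unordered pair of its partner genes'
#' biotype classes (protein_coding / lncRNA / pseudogene / other; ten
#' unordered pairs are possible, whichever occur are reported), plus an
#' inter/intra-chromosomal label.
#'
#' @param calls data.frame of fusion candidates (`gene5`, `gene3`;
#'   `chrom5`/`chrom3` used when present, else chromosomes are looked
#'   up in `models`).
#' @param models a [GeneModelSet-class] providing biotypes, or a
#'   data.frame with columns `gene_id`, `chrom`, `biotype`.
#' @return `calls` with added columns `type` (e.g.
#'   `"lncRNA--protein_coding"`, alphabetical within the pair) and
#'   `chromosomal` (`inter`/`intra`).
#' @export
classifyFusionType <- function(calls, models) {
  if (methods::is(models, "GeneModelSet")) {
    g <- genes(models)
    info <- data.frame(gene_id = S4Vectors::mcols(g)$gene_id,
                       chrom = as.character(GenomicRanges::seqnames(g)),
                       biotype = S4Vectors::mcols(g)$biotype,
                       stringsAsFactors = FALSE)
  } else {
    info <- models
  }
  i5 <- match(calls$gene5, info$gene_id)
  i3 <- match(calls$gene3, info$gene_id)
  if (anyNA(i5) || anyNA(i3)) {
    miss <- unique(c(calls$gene5[is.na(i5)], calls$gene3[is.na(i3)]))
    stop("gene(s) absent from models: ", paste(utils::head(miss, 5),
                                               collapse = ", "), call. = FALSE)
  }
  b5 <- info$biotype[i5]; b3 <- info$biotype[i3]
  calls$type <- paste(pmin(b5, b3), pmax(b5, b3), sep = "--")
  c5 <- if ("chrom5" %in% colnames(calls)) calls$chrom5 else info$chrom[i5]
  c3 <- if ("chrom3" %in% colnames(calls)) calls$chrom3 else info$chrom[i3]
  calls$chromosomal <- ifelse(c5 == c3, "intra", "inter")
  calls
}

#' Per-sample fusion-type and chromosomal-class proportions
#'
#' @param typed output of [classifyFusionType()] (must carry
#'   `sample_id`).
#' @return list of two data.frames: `types` (sample_id, type,
#'   n, proportion) and `chromosomal` (sample_id, chromosomal, n,
#'   proportion); proportions sum to 1 within each sample.
#' @export
fusionTypeSummary <- function(typed) {
  one <- function(col) {
    tab <- as.data.frame(table(sample_id = typed$sample_id,
                               value = typed[[col]]),
                         stringsAsFactors = FALSE)
    names(tab)[2:3] <- c(col, "n")
    tab <- tab[tab$n > 0, , drop = FALSE]
    tot <- tapply(tab$n, tab$sample_id, sum)
    tab$proportion <- tab$n / as.numeric(tot[tab$sample_id])
    tab <- tab[order(tab$sample_id, tab[[col]]), , drop = FALSE]
    rownames(tab) <- NULL
    tab
  }
  list(types = one("type"), chromosomal = one("chromosomal"))
}

#' Partner-gene counts
#'
#' Number of distinct fusion partners per gene across a call set, in
#' deterministic descending order (count, then gene name).
#'
#' @param calls data.frame with columns `gene5`, `gene3`.
#' @return data.frame with columns `gene`, `n_partners`.
#' @export
partnerCounts <- function(calls) {
  if (!nrow(calls))
    return(data.frame(gene = character(), n_partners = integer(),
                      stringsAsFactors = FALSE))
  pairs <- unique(data.frame(a = c(calls$gene5, calls$gene3),
                             b = c(calls$gene3, calls$gene5),
                             stringsAsFactors = FALSE))
  cnt <- tapply(pairs$b, pairs$a, function(v) length(unique(v)))
  out <- data.frame(gene = names(cnt), n_partners = as.integer(cnt),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_partners, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Library QC percentages
#'
#' Clean-read and uniquely-mapped percentages of a sequencing library:
#' `100 * clean / raw` and `100 * unique / raw`, rounded half away
#' from zero to two decimals.
#'
#' @param sampleId sample identifier(s).
#' @param rawPairs,cleanPairs,uniqueMapped read(-pair) counts; must
#'   satisfy `uniqueMapped <= cleanPairs <= rawPairs`.
#' @return data.frame with columns `sample_id`, `raw_pairs`,
#'   `clean_pairs`, `clean_pct`, `unique_mapped`, `unique_pct`.
#' @examples
#' qcPercentages("S1", 43923285, 39103125, 37226847)
#' @export
qcPercentages <- function(sampleId, rawPairs, cleanPairs, uniqueMapped) {
  if (any(rawPairs < 1))
    stop("raw_pairs must be positive", call. = FALSE)
  if (any(cleanPairs > rawPairs))
    stop("clean_pairs cannot exceed raw_pairs", call. = FALSE)
  if (any(uniqueMapped > cleanPairs))
    stop("unique_mapped cannot exceed clean_pairs", call. = FALSE)
  if (any(c(cleanPairs, uniqueMapped) < 0))
    stop("read counts must be non-negative", call. = FALSE)
  data.frame(sample_id = sampleId,
             raw_pairs = rawPairs,
             clean_pairs = cleanPairs,
             clean_pct = roundHalfUp(100 * cleanPairs / rawPairs, 2),
             unique_mapped = uniqueMapped,
             unique_pct = roundHalfUp(100 * uniqueMapped / rawPairs, 2),
             stringsAsFactors = FALSE)
}

#' Biotype composition of a gene list
#'
#' Proportion of each biotype class among a supplied gene list (for
#' example, externally determined expressed genes).
#'
#' @param geneIds character vector of gene ids.
#' @param models a [GeneModelSet-class].
#' @return data.frame with columns `biotype`, `n`, `proportion`.
#' @export
biotypeComposition <- function(geneIds, models) {
  g <- genes(models)
  bt <- S4Vectors::mcols(g)$biotype[match(geneIds,
                                          S4Vectors::mcols(g)$gene_id)]
  if (anyNA(bt))
    stop("gene(s) absent from models: ",
         paste(utils::head(geneIds[is.na(bt)], 5), collapse = ", "),
         call. = FALSE)
  n <- as.integer(table(factor(bt, levels = .BIOTYPES)))
  data.frame(biotype = .BIOTYPES, n = n,
             proportion = if (length(geneIds)) n / length(geneIds) else 0,
             stringsAsFactors = FALSE)
}

#' Relative expression by the 2^-ddCt method
#'
#' Per replicate, the target gene's Ct is normalised against the
#' reference gene (GAPDH-style internal control) in both condition
#' arms: ddCt = (Ct_target_case - Ct_ref_case) -
#' (Ct_target_control - Ct_ref_control), and the fold change is
#' 2^-ddCt.  Replicates are summarised as mean +/- SEM of the fold
#' changes, with a Welch two-sided t-test on the log2 fold changes
#' (equivalently, on the per-arm dCt values) comparing case against
#' control.
#'
#' Control replicates are each normalised against the mean control
#' dCt, so the control fold-change average centres on 1.
#'
#' @param ctTargetCase,ctRefCase numeric vectors of Ct values for the
#'   target and reference gene in the case arm, one value per
#'   replicate.
#' @param ctTargetControl,ctRefControl same for the control arm.
#' @return list with `fold_changes` (per case replicate),
#'   `fold_change` (mean), `sem` (SEM of the fold changes across case
#'   replicates), `se_log2` (two-arm Welch standard error of the log2
#'   fold estimate, which also reflects reference-arm noise), `ddct`
#'   (mean), and `p_value` (Welch t, NA with fewer than 2 replicates
#'   per arm).
#' @examples
#' relativeExpression(20, 18, 24, 18)   # ddCt = -4 -> fold 16
#' @export
relativeExpression <- function(ctTargetCase, ctRefCase,
                               ctTargetControl, ctRefControl) {
  if (length(ctTargetCase) != length(ctRefCase) ||
      length(ctTargetControl) != length(ctRefControl))
    stop("target and reference Ct vectors must align per replicate",
         call. = FALSE)
  if (!length(ctTargetCase) || !length(ctTargetControl))
    stop("need at least one replicate per arm", call. = FALSE)
  dctCase <- ctTargetCase - ctRefCase
  dctCtrl <- ctTargetControl - ctRefControl
  ddct <- dctCase - mean(dctCtrl)
  fc <- 2^(-ddct)
  p <- if (length(dctCase) >= 2L && length(dctCtrl) >= 2L)
    stats::t.test(-dctCase, -dctCtrl, var.equal = FALSE)$p.value
  else NA_real_
  seLog2 <- if (length(dctCase) >= 2L && length(dctCtrl) >= 2L)
    sqrt(stats::var(dctCase) / length(dctCase) +
         stats::var(dctCtrl) / length(dctCtrl))
  else NA_real_
  list(fold_changes = fc,
       fold_change = mean(fc),
       sem = sem(fc),
       se_log2 = seLog2,
       ddct = mean(ddct),
       p_value = p)
}
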