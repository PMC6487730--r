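## Chimeric-record -> fusion-candidate calling.
##
## Filtering cascade: (1) assign each breakpoint to the unique gene
## containing it; (2) drop same-gene / ambiguous / intergenic reads;
## (3) drop split reads with an anchor below the minimum on either side;
## (4) group surviving split reads by (gene5, gene3, breakpoint5,
## breakpoint3); (5) keep groups with enough distinct junction reads;
## (6) drop homologous gene pairs; (7) drop mitochondrial candidates.
## Steps (3), (6), (7) are independent per-read / per-pair predicates,
## so their order does not change the result.

#' Construct fusion-calling parameters
#'
#' Defaults implement the standard chimeric-read filtering thresholds:
#' both anchors of a split read must cover at least 15 bp, a candidate
#' needs at least three distinct junction reads, fusions between
#' homologous genes are discarded, and candidates joining the
#' mitochondrial chromosome to the nuclear genome are removed.
#'
#' @param minAnchor minimum aligned bases on each side of the junction
#'   (bp).
#' @param minJunctionReads minimum distinct junction reads per
#'   candidate.
#' @param mitoChrom mitochondrial chromosome name.
#' @param mitoStrict if `TRUE`, remove only mitochondrion-autosome
#'   candidates (the literal rule); default `FALSE` also removes
#'   mitochondrion-sex-chromosome and mitochondrion-internal
#'   candidates.
#' @param window breakpoint clustering window in bp; 0 groups on exact
#'   positions.
#' @param maxMismatches per-read mismatch cap applied upstream by the
#'   aligner; recorded for provenance only.
#' @return a [CallingParams-class] object.
#' @examples
#' callingParams()
#' @export
callingParams <- function(minAnchor = 15L, minJunctionReads = 3L,
                          mitoChrom = "chrM", mitoStrict = FALSE,
                          window = 0L, maxMismatches = 2L) {
  methods::new("CallingParams",
               minAnchor = as.integer(minAnchor),
               minJunctionReads = as.integer(minJunctionReads),
               mitoChrom = mitoChrom,
               mitoStrict = isTRUE(mitoStrict),
               window = as.integer(window),
               maxMismatches = as.integer(maxMismatches))
}

## gene at each (chrom, pos): gene_id (NA if 0 or >1 genes) and hit count
.assignLocus <- function(chrom, pos, models) {
  g <- genes(models)
  known <- unique(as.character(GenomicRanges::seqnames(g)))
  unk <- setdiff(unique(chrom), known)
  if (length(unk))
    stop("unknown chromosome: ", paste(unk, collapse = ", "), call. = FALSE)
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  hits <- GenomicRanges::findOverlaps(q, g, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits)
  n <- tabulate(qh, nbins = length(q))
  gene <- rep(NA_character_, length(q))
  one <- which(n == 1L)
  gene[one] <- S4Vectors::mcols(g)$gene_id[
    S4Vectors::subjectHits(hits)[match(one, qh)]]
  list(gene = gene, n = n)
}

#' Assign chimeric reads to gene pairs
#'
#' Each breakpoint of a chimeric record is assigned the unique gene
#' whose span contains it.  A breakpoint covered by more than one gene
#' is ambiguous (the read is excluded downstream rather than
#' multi-assigned, to prevent double counting); a breakpoint covered by
#' none is intergenic.
#'
#' @param records data.frame of chimeric records ([readChimeric()]
#'   columns).
#' @param models a [GeneModelSet-class].
#' @return `records` with added columns `gene_a`, `gene_b` (NA when
#'   unassigned) and `status`, one of `paired`, `ambiguous_a`,
#'   `ambiguous_b`, `intergenic`.
#' @export
assignReads <- function(records, models) {
  if (!nrow(records)) {
    records$gene_a <- character(0); records$gene_b <- character(0)
    records$status <- character(0)
    return(records)
  }
  a <- .assignLocus(records$chrom_a, records$pos_a, models)
  b <- .assignLocus(records$chrom_b, records$pos_b, models)
  status <- ifelse(a$n > 1L, "ambiguous_a",
            ifelse(b$n > 1L, "ambiguous_b",
            ifelse(a$n == 0L | b$n == 0L, "intergenic", "paired")))
  records$gene_a <- a$gene
  records$gene_b <- b$gene
  records$status <- status
  records
}

## chain-link positions within `window` bp into clusters; representative
## position is the most frequent (ties -> smallest)
.clusterPositions <- function(pos, window) {
  o <- order(pos)
  p <- pos[o]
  newCl <- c(TRUE, diff(p) > window)
  cl <- cumsum(newCl)
  rep_pos <- vapply(split(p, cl), function(v) {
    tb <- table(v)
    as.integer(names(tb)[which.max(tb)])
  }, integer(1))
  out <- integer(length(pos))
  out[o] <- rep_pos[cl]
  out
}

#' Call fusion candidates from chimeric records
#'
#' Applies the full filtering cascade (see [callingParams()] for the
#' thresholds) and returns one candidate per surviving breakpoint-pair
#' group.  `junction_reads` counts distinct split-read ids in the
#' group; spanning pairs (junction type -1) never contribute to
#' `junction_reads` but are tallied per gene pair as auxiliary evidence
#' in `spanning_pairs`.
#'
#' @param records data.frame of chimeric records.
#' @param models a [GeneModelSet-class]; its interval index assigns
#'   reads to genes.
#' @param params a [CallingParams-class].
#' @param homologs data.frame of unordered homologous gene pairs
#'   (columns `gene_a`, `gene_b`); defaults to the pair list carried by
#'   `models`.
#' @param sampleId sample id stamped on the returned candidates.
#' @return data.frame of fusion candidates: `gene5`, `gene3`, `chrom5`,
#'   `pos5`, `chrom3`, `pos3`, `junction_reads`, `spanning_pairs`,
#'   `sample_id`, sorted by (gene5, gene3, pos5, pos3).  Empty input
#'   yields an empty frame.
#' @export
callFusions <- function(records, models, params = callingParams(),
                        homologs = homologPairs(models),
                        sampleId = "sample1") {
  methods::validObject(params)
  empty <- data.frame(gene5 = character(), gene3 = character(),
                      chrom5 = character(), pos5 = integer(),
                      chrom3 = character(), pos3 = integer(),
                      junction_reads = integer(), spanning_pairs = integer(),
                      sample_id = character(), stringsAsFactors = FALSE)
  if (!nrow(records)) return(empty)
  asn <- assignReads(records, models)
  asn <- asn[asn$status == "paired" & asn$gene_a != asn$gene_b, , drop = FALSE]
  if (!nrow(asn)) return(empty)

  splitReads <- asn[asn$junction_type >= 0L, , drop = FALSE]
  span  <- asn[asn$junction_type == -1L, , drop = FALSE]
  ## anchor filter applies per split read
  splitReads <- splitReads[splitReads$anchor_a >= params@minAnchor &
                           splitReads$anchor_b >= params@minAnchor, , drop = FALSE]
  if (!nrow(splitReads)) return(empty)

  pair <- fusionKey(splitReads$gene_a, splitReads$gene_b)
  if (params@window > 0L) {
    for (p in unique(pair)) {
      idx <- which(pair == p)
      splitReads$pos_a[idx] <- .clusterPositions(splitReads$pos_a[idx], params@window)
      splitReads$pos_b[idx] <- .clusterPositions(splitReads$pos_b[idx], params@window)
    }
  }
  grpKey <- paste(pair, splitReads$pos_a, splitReads$pos_b, sep = "\r")
  groups <- base::split(seq_len(nrow(splitReads)), grpKey)
  cand <- do.call(rbind, lapply(groups, function(idx) {
    r <- splitReads[idx, , drop = FALSE]
    data.frame(gene5 = r$gene_a[1], gene3 = r$gene_b[1],
               chrom5 = r$chrom_a[1], pos5 = r$pos_a[1],
               chrom3 = r$chrom_b[1], pos3 = r$pos_b[1],
               junction_reads = length(unique(r$read_id)),
               stringsAsFactors = FALSE)
  }))
  cand <- cand[cand$junction_reads >= params@minJunctionReads, , drop = FALSE]
  if (!nrow(cand)) return(empty)

  ## homologous-pair filter (unordered)
  if (nrow(homologs)) {
    hkeys <- unorderedKey(homologs$gene_a, homologs$gene_b)
    cand <- cand[!(unorderedKey(cand$gene5, cand$gene3) %in% hkeys), ,
                 drop = FALSE]
  }
  if (!nrow(cand)) return(empty)

  ## mitochondrial filter
  isMito5 <- cand$chrom5 == params@mitoChrom
  isMito3 <- cand$chrom3 == params@mitoChrom
  if (params@mitoStrict) {
    sex <- c("chrX", "chrY", "X", "Y")
    auto3 <- !isMito3 & !(cand$chrom3 %in% sex)
    auto5 <- !isMito5 & !(cand$chrom5 %in% sex)
    drop <- (isMito5 & auto3) | (isMito3 & auto5)
  } else {
    drop <- isMito5 | isMito3
  }
  cand <- cand[!drop, , drop = FALSE]
  if (!nrow(cand)) return(empty)

  ## auxiliary spanning-pair evidence per gene pair
  if (nrow(span)) {
    spKey <- fusionKey(span$gene_a, span$gene_b)
    spCount <- vapply(base::split(span$read_id, spKey),
                      function(v) length(unique(v)), integer(1))
    cand$spanning_pairs <- unname(spCount[fusionKey(cand$gene5, cand$gene3)])
    cand$spanning_pairs[is.na(cand$spanning_pairs)] <- 0L
  } else {
    cand$spanning_pairs <- 0L
  }
  cand$sample_id <- sampleId
  cand <- cand[order(cand$gene5, cand$gene3, cand$pos5, cand$pos3), ,
               drop = FALSE]
  rownames(cand) <- NULL
  cand
}
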