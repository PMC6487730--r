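## Cross-referencing fusions against curated known-fusion databases and
## annotating breakpoints against gene features (UTRs, exons, protein
## domains carried as genomic intervals).

.normSymbol <- function(x, aliases = NULL) {
  x <- gsub("\\s+", "", x)   # whitespace normalization; case-sensitive match
  if (!is.null(aliases) && nrow(aliases)) {
    i <- match(x, gsub("\\s+", "", aliases$alias))
    x[!is.na(i)] <- aliases$canonical[i[!is.na(i)]]
  }
  x
}

#' Match fusions against known-fusion databases
#'
#' Each fusion is matched against one or more database tables (columns
#' `source`, `gene_a`, `gene_b`, `disease`; see
#' [readKnownFusionDb()]).  Pair matching is unordered, since curated
#' databases list partners with inconsistent orientation conventions.
#' Categories partition every fusion set:
#' \describe{
#'   \item{disease_annotated}{the exact (unordered) gene pair occurs in
#'     at least one database;}
#'   \item{partner_annotated}{no pair match, but at least one partner
#'     gene occurs in some database fusion;}
#'   \item{novel}{neither.}
#' }
#' Gene symbols are compared case-sensitively after whitespace
#' normalization; an optional alias table (columns `alias`,
#' `canonical`) reconciles divergent naming before matching.
#'
#' @param fusions data.frame with columns `gene5`, `gene3`.
#' @param dbs a single database data.frame or a list of them.
#' @param aliases optional data.frame with columns `alias`,
#'   `canonical`.
#' @return data.frame: `gene5`, `gene3`, `category`, `evidence`
#'   (semicolon-separated `source:gene_a-gene_b:disease` strings, pair
#'   evidence first).
#' @export
matchKnown <- function(fusions, dbs, aliases = NULL) {
  if (is.data.frame(dbs)) dbs <- list(dbs)
  db <- if (length(dbs)) do.call(rbind, dbs) else
    data.frame(source = character(), gene_a = character(),
               gene_b = character(), disease = character())
  if (!nrow(db))
    warning("empty known-fusion database list: all fusions reported novel")
  dbA <- .normSymbol(db$gene_a, aliases)
  dbB <- .normSymbol(db$gene_b, aliases)
  dbPair <- unorderedKey(dbA, dbB)
  dbGenes <- c(dbA, dbB)
  g5 <- .normSymbol(fusions$gene5, aliases)
  g3 <- .normSymbol(fusions$gene3, aliases)
  qPair <- unorderedKey(g5, g3)

  category <- character(nrow(fusions))
  evidence <- character(nrow(fusions))
  for (i in seq_len(nrow(fusions))) {
    pairHit <- which(dbPair == qPair[i])
    if (length(pairHit)) {
      category[i] <- "disease_annotated"
      ev <- pairHit
    } else {
      geneHit <- which(dbA %in% c(g5[i], g3[i]) | dbB %in% c(g5[i], g3[i]))
      if (length(geneHit)) {
        category[i] <- "partner_annotated"
        ev <- geneHit
      } else {
        category[i] <- "novel"
        ev <- integer(0)
      }
    }
    evidence[i] <- paste(sprintf("%s:%s-%s:%s", db$source[ev],
                                 db$gene_a[ev], db$gene_b[ev],
                                 db$disease[ev]), collapse = ";")
  }
  data.frame(gene5 = fusions$gene5, gene3 = fusions$gene3,
             category = category, evidence = evidence,
             stringsAsFactors = FALSE)
}

#' Annotate a breakpoint against a gene's features
#'
#' Resolves which feature of `geneId` a genomic position falls in,
#' with priority UTR > exon > intron, and whether any protein-domain
#' interval (carried in genomic coordinates on the gene model) overlaps
#' the position.  Exons are numbered 1-based in transcription order,
#' i.e. against genomic coordinates on the minus strand.  A position
#' outside the gene span reports `outside_gene`.
#'
#' @param models a [GeneModelSet-class].
#' @param geneId gene id to annotate against.
#' @param chrom,pos breakpoint chromosome and 1-based position.
#' @return one-row data.frame: `gene_id`, `chrom`, `pos`,
#'   `feature_hit` (`five_prime_utr`, `three_prime_utr`, `exon(k)`,
#'   `intron`, `outside_gene`), `exon_index` (NA unless an exon hit),
#'   `domain_hits` (semicolon-separated labels), `domain_affected`.
#' @examples
#' # see the package vignette for worked breakpoint annotations
#' @export
annotateBreakpoint <- function(models, geneId, chrom, pos) {
  stopIfNot1Based(pos, "breakpoint position")
  g <- genes(models)
  gi <- which(S4Vectors::mcols(g)$gene_id == geneId)
  if (!length(gi))
    stop("gene not found in models: ", geneId, call. = FALSE)
  gChrom <- as.character(GenomicRanges::seqnames(g))[gi]
  gStrand <- as.character(GenomicRanges::strand(g))[gi]
  res <- data.frame(gene_id = geneId, chrom = chrom, pos = pos,
                    feature_hit = "outside_gene", exon_index = NA_integer_,
                    domain_hits = "", domain_affected = FALSE,
                    stringsAsFactors = FALSE)
  inside <- chrom == gChrom &&
    pos >= GenomicRanges::start(g)[gi] && pos <= GenomicRanges::end(g)[gi]
  if (!inside) return(res)

  f <- geneFeatures(models)
  fm <- S4Vectors::mcols(f)
  mine <- fm$gene_id == geneId
  fs <- GenomicRanges::start(f); fe <- GenomicRanges::end(f)
  hit <- mine & fs <= pos & fe >= pos

  ## domains are tested on the same genomic intervals, independently of
  ## the exon/UTR resolution
  domIdx <- which(hit & fm$kind == "domain")
  if (length(domIdx)) {
    res$domain_hits <- paste(fm$label[domIdx], collapse = ";")
    res$domain_affected <- TRUE
  }

  if (any(hit & fm$kind == "five_prime_utr")) {
    res$feature_hit <- "five_prime_utr"
  } else if (any(hit & fm$kind == "three_prime_utr")) {
    res$feature_hit <- "three_prime_utr"
  } else {
    exIdx <- which(mine & fm$kind == "exon")
    exIdx <- exIdx[order(fs[exIdx])]
    if (gStrand == "-") exIdx <- rev(exIdx)   # transcription order
    inEx <- which(fs[exIdx] <= pos & fe[exIdx] >= pos)
    if (length(inEx)) {
      res$feature_hit <- sprintf("exon(%d)", inEx[1])
      res$exon_index <- inEx[1]
    } else {
      res$feature_hit <- "intron"
    }
  }
  res
}

#' Annotate both breakpoints of each fusion candidate
#'
#' Convenience wrapper running [annotateBreakpoint()] on the 5' and 3'
#' breakpoints of every candidate in a call table.
#'
#' @param calls data.frame of fusion candidates ([callFusions()]
#'   columns).
#' @param models a [GeneModelSet-class].
#' @return `calls` with added columns `feature5`, `domain5_affected`,
#'   `feature3`, `domain3_affected`.
#' @export
annotateBreakpoints <- function(calls, models) {
  n <- nrow(calls)
  f5 <- character(n); d5 <- logical(n)
  f3 <- character(n); d3 <- logical(n)
  for (i in seq_len(n)) {
    a <- annotateBreakpoint(models, calls$gene5[i], calls$chrom5[i],
                            calls$pos5[i])
    b <- annotateBreakpoint(models, calls$gene3[i], calls$chrom3[i],
                            calls$pos3[i])
    f5[i] <- a$feature_hit; d5[i] <- a$domain_affected
    f3[i] <- b$feature_hit; d3[i] <- b$domain_affected
  }
  calls$feature5 <- f5; calls$domain5_affected <- d5
  calls$feature3 <- f3; calls$domain3_affected <- d3
  calls
}
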