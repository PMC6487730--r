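## Readers/writers for every format the pipeline touches.
## All coordinates are 1-based inclusive end to end: the chimeric dialect,
## fusion tables and GTF all use the same convention, so no conversion
## layer exists anywhere in the package.

.CHIM_COLS <- c("chrom_a", "pos_a", "strand_a", "chrom_b", "pos_b",
                "strand_b", "junction_type", "anchor_a", "anchor_b",
                "read_id")

.FUSION_COLS <- c("gene5", "gene3", "chrom5", "pos5", "chrom3", "pos3",
                  "junction_reads", "sample_id")

.META_COLS <- c("sample_id", "patient_id", "tissue", "cohort")

.DB_COLS <- c("source", "gene_a", "gene_b", "disease")

## strip provenance/comment lines ("#key=value") from the top of a TSV
.readTsvLines <- function(path) {
  lines <- readLines(path)
  lines[!startsWith(lines, "#")]
}

.writeTsv <- function(df, path, provenance = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(provenance))
    writeLines(sprintf("#%s=%s", names(provenance), unlist(provenance)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

.parseTsv <- function(path, expected, what) {
  lines <- .readTsvLines(path)
  if (!length(lines))
    stop(sprintf("%s file '%s' has no header line", what, path), call. = FALSE)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (!identical(header, expected))
    stop(sprintf("%s file '%s': unexpected columns [%s]; expected header: %s",
                 what, path, paste(header, collapse = ", "),
                 paste(expected, collapse = "\t")), call. = FALSE)
  if (length(lines) == 1L) {
    df <- as.data.frame(stats::setNames(rep(list(character()), length(expected)),
                                        expected))
    return(df)
  }
  utils::read.delim(text = lines, stringsAsFactors = FALSE,
                    colClasses = "character")
}

#' Map a raw biotype string onto the package vocabulary
#'
#' GENCODE-style biotypes outside \{protein_coding, lncRNA, pseudogene\}
#' collapse to `other`; `lincRNA` and the `*_pseudogene` subtypes map to
#' their parent class.
#'
#' @param biotype character vector of raw biotype strings.
#' @return character vector over protein_coding / lncRNA / pseudogene /
#'   other.
#' @examples
#' mapBiotype(c("protein_coding", "snoRNA", "lincRNA", "unprocessed_pseudogene"))
#' @export
mapBiotype <- function(biotype) {
  out <- rep("other", length(biotype))
  out[biotype %in% c("protein_coding")] <- "protein_coding"
  out[biotype %in% c("lncRNA", "lincRNA", "lnc_RNA")] <- "lncRNA"
  out[grepl("pseudogene", biotype, fixed = TRUE)] <- "pseudogene"
  out
}

#' Construct a GeneModelSet
#'
#' @param genes `GRanges` with mcols `gene_id`, `gene_name`, `biotype`.
#' @param features `GRanges` with mcols `gene_id`, `kind`, `label`.
#' @param homologs data.frame of unordered homologous pairs
#'   (`gene_a`, `gene_b`).
#' @param mitoChrom mitochondrial chromosome name.
#' @return a validated [GeneModelSet-class] object.
#' @export
GeneModelSet <- function(genes, features,
                         homologs = data.frame(gene_a = character(),
                                               gene_b = character()),
                         mitoChrom = "chrM") {
  if (is.null(S4Vectors::mcols(features)$label))
    S4Vectors::mcols(features)$label <- rep("", length(features))
  methods::new("GeneModelSet", genes = genes, features = features,
               homologs = homologs, mitoChrom = mitoChrom)
}

#' Read gene models from a GTF file
#'
#' Parses a GENCODE-style GTF (via `rtracklayer`) into a
#' [GeneModelSet-class].  Feature lines of type `exon`,
#' `five_prime_utr`, `three_prime_utr` and `domain` are attached to
#' their gene; gene spans come from `gene` lines when present, else
#' from the extent of the gene's features.  Biotypes are taken from the
#' `gene_biotype` (or `gene_type`) attribute and mapped onto the
#' package vocabulary with [mapBiotype()]; protein-domain intervals
#' travel on `domain` lines with a `label` attribute, in genomic
#' coordinates.
#'
#' A light structural pre-scan reports malformed lines (wrong column
#' count, non-integer or non-positive coordinates, end < start) with
#' their line number before parsing.
#'
#' @param path path to the GTF file.
#' @param mitoChrom mitochondrial chromosome name (default `"chrM"`).
#' @return a [GeneModelSet-class] (homolog list empty; see
#'   [readHomologPairs()]).
#' @export
readGtf <- function(path, mitoChrom = "chrM") {
  if (!file.exists(path)) stop("GTF file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9L)
      stop(sprintf("malformed GTF line %d: expected 9 tab-separated fields, got %d",
                   i, length(f)), call. = FALSE)
    st <- suppressWarnings(as.integer(f[4])); en <- suppressWarnings(as.integer(f[5]))
    if (is.na(st) || is.na(en))
      stop(sprintf("malformed GTF line %d: non-integer coordinates", i),
           call. = FALSE)
    if (st < 1L)
      stop(sprintf("malformed GTF line %d: start %d violates the 1-based convention",
                   i, st), call. = FALSE)
    if (en < st)
      stop(sprintf("malformed GTF line %d: end (%d) < start (%d)", i, en, st),
           call. = FALSE)
    if (!grepl("gene_id", f[9], fixed = TRUE))
      stop(sprintf("GTF line %d: missing gene_id attribute", i), call. = FALSE)
  }
  gr <- rtracklayer::import(path, format = "gtf")
  mc <- S4Vectors::mcols(gr)
  if (is.null(mc$gene_id))
    stop("GTF has no gene_id attribute", call. = FALSE)
  rawBt <- if (!is.null(mc$gene_biotype)) mc$gene_biotype
           else if (!is.null(mc$gene_type)) mc$gene_type
           else rep(NA_character_, length(gr))
  isGene <- as.character(mc$type) == "gene"
  featKinds <- .FEATURE_KINDS
  isFeat <- as.character(mc$type) %in% featKinds

  ids <- unique(mc$gene_id)
  if (any(isGene)) {
    g <- gr[isGene]
    gm <- S4Vectors::mcols(g)
    genes <- GenomicRanges::GRanges(
      GenomicRanges::seqnames(g),
      IRanges::IRanges(GenomicRanges::start(g), GenomicRanges::end(g)),
      strand = GenomicRanges::strand(g))
    S4Vectors::mcols(genes) <- S4Vectors::DataFrame(
      gene_id = gm$gene_id,
      gene_name = if (!is.null(gm$gene_name)) gm$gene_name else gm$gene_id,
      biotype = mapBiotype(ifelse(is.na(rawBt[isGene]), "", rawBt[isGene])))
  } else {
    ## derive spans from feature extents
    sp <- split(gr, mc$gene_id)
    rng <- unlist(range(sp))
    gid <- names(rng)
    bt <- rawBt[match(gid, mc$gene_id)]
    nm <- if (!is.null(mc$gene_name)) mc$gene_name[match(gid, mc$gene_id)] else gid
    genes <- rng
    names(genes) <- NULL
    S4Vectors::mcols(genes) <- S4Vectors::DataFrame(
      gene_id = gid, gene_name = nm,
      biotype = mapBiotype(ifelse(is.na(bt), "", bt)))
  }

  feats <- gr[isFeat]
  fm <- S4Vectors::mcols(feats)
  features <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(feats),
    IRanges::IRanges(GenomicRanges::start(feats), GenomicRanges::end(feats)),
    strand = GenomicRanges::strand(feats))
  S4Vectors::mcols(features) <- S4Vectors::DataFrame(
    gene_id = fm$gene_id,
    kind = as.character(fm$type),
    label = if (!is.null(fm$label)) ifelse(is.na(fm$label), "", fm$label)
            else rep("", length(feats)))
  GeneModelSet(genes = genes, features = features, mitoChrom = mitoChrom)
}

#' Write a GeneModelSet to GTF
#'
#' Deterministic writer: genes sorted by chromosome, start and
#' `gene_id`; each gene line is followed by its features sorted by
#' kind and start.  Emits `gene_biotype` and, for domains, `label`
#' attributes.
#'
#' @param models a [GeneModelSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGtf <- function(models, path) {
  g <- genes(models)
  gm <- S4Vectors::mcols(g)
  ord <- order(as.character(GenomicRanges::seqnames(g)),
               GenomicRanges::start(g), gm$gene_id)
  f <- geneFeatures(models)
  fm <- S4Vectors::mcols(f)
  lines <- character()
  for (i in ord) {
    gid <- gm$gene_id[i]
    attrs <- sprintf('gene_id "%s"; gene_name "%s"; gene_biotype "%s";',
                     gid, gm$gene_name[i], gm$biotype[i])
    lines <- c(lines, paste(
      as.character(GenomicRanges::seqnames(g))[i], "fusionscape", "gene",
      GenomicRanges::start(g)[i], GenomicRanges::end(g)[i], ".",
      as.character(GenomicRanges::strand(g))[i], ".", attrs, sep = "\t"))
    fi <- which(fm$gene_id == gid)
    fi <- fi[order(match(fm$kind[fi], .FEATURE_KINDS),
                   GenomicRanges::start(f)[fi])]
    for (j in fi) {
      fattrs <- attrs
      if (fm$kind[j] == "domain" && nzchar(fm$label[j]))
        fattrs <- paste0(attrs, sprintf(' label "%s";', fm$label[j]))
      lines <- c(lines, paste(
        as.character(GenomicRanges::seqnames(f))[j], "fusionscape",
        fm$kind[j], GenomicRanges::start(f)[j], GenomicRanges::end(f)[j],
        ".", as.character(GenomicRanges::strand(f))[j], ".", fattrs,
        sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read chimeric junction records
#'
#' Parses the package's 10-column chimeric-junction dialect, a subset
#' of STAR's `Chimeric.out.junction`: donor chromosome, position and
#' strand; acceptor chromosome, position and strand; junction type
#' (-1 for a spanning pair, >= 0 for a split read); aligned anchor
#' lengths on each side; read id.  Extra trailing columns are
#' tolerated and ignored, so real STAR output can be fed in directly.
#' Spanning pairs are parsed and flagged (`spanning` column) but carry
#' no junction-read weight downstream.
#'
#' @param path path to the tab-separated file; lines starting `#` are
#'   skipped.  An empty file yields an empty record set.
#' @return data.frame with columns `read_id`, `chrom_a`, `pos_a`,
#'   `strand_a`, `chrom_b`, `pos_b`, `strand_b`, `junction_type`,
#'   `anchor_a`, `anchor_b`, `spanning`.
#' @export
readChimeric <- function(path) {
  if (!file.exists(path)) stop("chimeric file not found: ", path, call. = FALSE)
  lines <- .readTsvLines(path)
  lines <- lines[nzchar(lines)]
  empty <- data.frame(read_id = character(), chrom_a = character(),
                      pos_a = integer(), strand_a = character(),
                      chrom_b = character(), pos_b = integer(),
                      strand_b = character(), junction_type = integer(),
                      anchor_a = integer(), anchor_b = integer(),
                      spanning = logical(), stringsAsFactors = FALSE)
  if (!length(lines)) return(empty)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 10L))
    stop(sprintf("chimeric line %d: expected >= 10 tab-separated fields, got %d",
                 which(nf < 10L)[1], nf[nf < 10L][1]), call. = FALSE)
  m <- do.call(rbind, lapply(parts, `[`, 1:10))
  asInt <- function(col, what) {
    v <- suppressWarnings(as.integer(m[, col]))
    if (anyNA(v))
      stop(sprintf("chimeric line %d: non-integer %s '%s'",
                   which(is.na(v))[1], what, m[is.na(v), col][1]),
           call. = FALSE)
    v
  }
  rec <- data.frame(
    read_id = m[, 10], chrom_a = m[, 1],
    pos_a = asInt(2, "position"), strand_a = m[, 3],
    chrom_b = m[, 4], pos_b = asInt(5, "position"), strand_b = m[, 6],
    junction_type = asInt(7, "junction type"),
    anchor_a = asInt(8, "anchor length"), anchor_b = asInt(9, "anchor length"),
    stringsAsFactors = FALSE)
  if (any(rec$pos_a < 1L) || any(rec$pos_b < 1L)) {
    bad <- which(rec$pos_a < 1L | rec$pos_b < 1L)[1]
    stop(sprintf("chimeric line %d: position < 1 violates the 1-based convention",
                 bad), call. = FALSE)
  }
  if (any(rec$anchor_a < 1L) || any(rec$anchor_b < 1L))
    stop("chimeric record with anchor < 1", call. = FALSE)
  if (!all(c(rec$strand_a, rec$strand_b) %in% c("+", "-")))
    stop("chimeric record with strand outside {+,-}", call. = FALSE)
  if (!all(nzchar(rec$chrom_a)) || !all(nzchar(rec$chrom_b)))
    stop("chimeric record with empty chromosome name", call. = FALSE)
  rec$spanning <- rec$junction_type == -1L
  rec
}

#' Write chimeric junction records
#'
#' Inverse of [readChimeric()]; rows are written in input order with an
#' optional `#key=value` provenance header.
#'
#' @param records data.frame as returned by [readChimeric()].
#' @param path output path.
#' @param provenance named character vector written as `#key=value`
#'   header lines.
#' @return `path`, invisibly.
#' @export
writeChimeric <- function(records, path, provenance = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(provenance))
    writeLines(sprintf("#%s=%s", names(provenance), unlist(provenance)), con)
  if (nrow(records)) {
    out <- records[, c("chrom_a", "pos_a", "strand_a", "chrom_b", "pos_b",
                       "strand_b", "junction_type", "anchor_a", "anchor_b",
                       "read_id")]
    utils::write.table(out, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read / write fusion call tables
#'
#' Fusion call tables are TSV with the fixed header `gene5 gene3
#' chrom5 pos5 chrom3 pos3 junction_reads sample_id`.  The writer
#' sorts rows by (gene5, gene3, sample_id) so output is deterministic;
#' write followed by read is the identity on all fields.
#'
#' @param calls data.frame of fusion candidates.
#' @param path file path.
#' @param provenance named character vector written as `#key=value`
#'   header lines.
#' @return `readFusionTable` returns the validated data.frame;
#'   `writeFusionTable` returns `path` invisibly.
#' @export
writeFusionTable <- function(calls, path, provenance = NULL) {
  stopifnot(all(.FUSION_COLS %in% colnames(calls)))
  out <- calls[, .FUSION_COLS]
  out <- out[order(out$gene5, out$gene3, out$sample_id, out$pos5, out$pos3), ,
             drop = FALSE]
  rownames(out) <- NULL
  .writeTsv(out, path, provenance)
}

#' @rdname writeFusionTable
#' @export
readFusionTable <- function(path) {
  df <- .parseTsv(path, .FUSION_COLS, "fusion table")
  for (col in c("pos5", "pos3", "junction_reads")) {
    v <- suppressWarnings(as.integer(df[[col]]))
    if (anyNA(v) && nrow(df))
      stop("fusion table: non-integer ", col, call. = FALSE)
    df[[col]] <- v
  }
  if (nrow(df)) {
    if (any(df$junction_reads < 1L))
      stop("fusion table: junction_reads must be >= 1", call. = FALSE)
    if (any(df$gene5 == df$gene3))
      stop("fusion table: gene5 must differ from gene3", call. = FALSE)
    stopIfNot1Based(df$pos5, "pos5"); stopIfNot1Based(df$pos3, "pos3")
  }
  df
}

#' Read / write sample metadata tables
#'
#' TSV with header `sample_id patient_id tissue cohort`; `tissue` is
#' tumor/normal and `cohort` discovery/validation.
#'
#' @param meta data.frame of sample metadata.
#' @param path file path.
#' @return `readSampleMeta` returns the validated data.frame.
#' @export
readSampleMeta <- function(path) {
  df <- .parseTsv(path, .META_COLS, "sample metadata")
  if (nrow(df)) {
    if (anyDuplicated(df$sample_id))
      stop("sample metadata: duplicated sample_id", call. = FALSE)
    if (!all(df$tissue %in% c("tumor", "normal")))
      stop("sample metadata: tissue must be tumor or normal", call. = FALSE)
    if (!all(df$cohort %in% c("discovery", "validation")))
      stop("sample metadata: cohort must be discovery or validation",
           call. = FALSE)
  }
  df
}

#' @rdname readSampleMeta
#' @export
writeSampleMeta <- function(meta, path) {
  stopifnot(all(.META_COLS %in% colnames(meta)))
  .writeTsv(meta[, .META_COLS], path)
}

#' Read a known-fusion database table
#'
#' TSV with header `source gene_a gene_b disease`, emulating exports of
#' curated fusion databases (ChiTaRS / ChimerDB / FusionCancer /
#' Mitelman style).  Duplicate (source, gene_a, gene_b, disease) rows
#' are collapsed with a warning.
#'
#' @param path file path.
#' @param source optional source name overriding the file's `source`
#'   column.
#' @return data.frame with columns source, gene_a, gene_b, disease.
#' @export
readKnownFusionDb <- function(path, source = NULL) {
  df <- .parseTsv(path, .DB_COLS, "known-fusion database")
  if (!is.null(source)) df$source <- source
  key <- do.call(paste, c(df[.DB_COLS], sep = "\r"))
  if (anyDuplicated(key)) {
    warning("known-fusion database '", path, "': duplicate rows collapsed")
    df <- df[!duplicated(key), , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Read a homologous-pair list
#'
#' Two-column TSV (`gene_a`, `gene_b`); pairs are unordered.
#'
#' @param path file path.
#' @return data.frame with columns gene_a, gene_b.
#' @export
readHomologPairs <- function(path) {
  df <- .parseTsv(path, c("gene_a", "gene_b"), "homolog pairs")
  df
}

#' @rdname readHomologPairs
#' @param pairs data.frame with columns gene_a, gene_b.
#' @export
writeHomologPairs <- function(pairs, path) {
  stopifnot(all(c("gene_a", "gene_b") %in% colnames(pairs)))
  .writeTsv(pairs[, c("gene_a", "gene_b")], path)
}

#' Construct a CohortCallSet
#'
#' @param calls data.frame of fusion calls (`gene5`, `gene3`,
#'   `chrom5`, `pos5`, `chrom3`, `pos3`, `junction_reads`,
#'   `sample_id`).
#' @param sampleMeta data.frame of sample metadata (`sample_id`,
#'   `patient_id`, `tissue`, `cohort`).
#' @return a validated [CohortCallSet-class].
#' @export
CohortCallSet <- function(calls, sampleMeta) {
  methods::new("CohortCallSet", calls = as.data.frame(calls),
               sampleMeta = as.data.frame(sampleMeta))
}
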