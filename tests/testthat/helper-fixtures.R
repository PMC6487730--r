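# Hand-built tiny gene models used across the calling/annotation tests:
# chr1: GX (1000-2000, +), GY (5000-6000, +)
# chr2: GZ (1000-3000, -), and an overlapping pair GO1/GO2 (10000-12000 /
#       11000-13000) to exercise ambiguous assignment
# chrX: GSX (2000-4000, +)
# chrM: GM (100-900, +)
# homologs: GH1 (chr1 8000-9000) ~ GH2 (chr2 5000-6000)
makeTinyModels <- function() {
  g <- data.frame(
    chrom = c("chr1", "chr1", "chr2", "chr2", "chr2", "chrX", "chrM",
              "chr1", "chr2"),
    start = c(1000, 5000, 1000, 10000, 11000, 2000, 100, 8000, 5000),
    end   = c(2000, 6000, 3000, 12000, 13000, 4000, 900, 9000, 6000),
    strand = c("+", "+", "-", "+", "+", "+", "+", "+", "+"),
    gene_id = c("GX", "GY", "GZ", "GO1", "GO2", "GSX", "GM", "GH1", "GH2"),
    biotype = c("protein_coding", "protein_coding", "lncRNA",
                "protein_coding", "pseudogene", "protein_coding",
                "other", "protein_coding", "protein_coding"),
    stringsAsFactors = FALSE)
  genes <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$start, g$end),
                                  strand = g$strand)
  S4Vectors::mcols(genes) <- S4Vectors::DataFrame(
    gene_id = g$gene_id, gene_name = g$gene_id, biotype = g$biotype)
  # one whole-span exon per gene keeps the fixture minimal
  features <- genes
  S4Vectors::mcols(features) <- S4Vectors::DataFrame(
    gene_id = g$gene_id, kind = "exon", label = "")
  GeneModelSet(genes = genes, features = features,
               homologs = data.frame(gene_a = "GH1", gene_b = "GH2",
                                     stringsAsFactors = FALSE),
               mitoChrom = "chrM")
}

# one chimeric record; defaults give a clean well-anchored split read
chim <- function(read_id, chrom_a, pos_a, chrom_b, pos_b,
                 anchor_a = 20L, anchor_b = 20L, junction_type = 0L,
                 strand_a = "+", strand_b = "+") {
  data.frame(read_id = read_id, chrom_a = chrom_a, pos_a = as.integer(pos_a),
             strand_a = strand_a, chrom_b = chrom_b,
             pos_b = as.integer(pos_b), strand_b = strand_b,
             junction_type = as.integer(junction_type),
             anchor_a = as.integer(anchor_a), anchor_b = as.integer(anchor_b),
             stringsAsFactors = FALSE)
}

# n identical-breakpoint junction reads for a gene pair
chimGroup <- function(prefix, n, chrom_a, pos_a, chrom_b, pos_b, ...) {
  do.call(rbind, lapply(seq_len(n), function(i)
    chim(sprintf("%s_%02d", prefix, i), chrom_a, pos_a, chrom_b, pos_b, ...)))
}

# independent full-enumeration oracle for the two-sided Fisher test:
# sum of hypergeometric point probabilities <= the observed one
# (1e-7 relative tie tolerance)
fisherOracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; k <- a + c
  xs <- max(0, k - r2):min(r1, k)
  p <- stats::dhyper(xs, r1, r2, k)
  pObs <- stats::dhyper(a, r1, r2, k)
  sum(p[p <= pObs * (1 + 1e-7)])
}

# naive reference fusion caller: O(records x genes) scan, filters applied
# in a different order than the production path (support threshold before
# the anchor filter is impossible -- anchors act per read -- so the
# reordering swaps the homolog/mito/support stages and assigns genes by
# linear search)
bruteForceCaller <- function(records, models, minAnchor = 15,
                             minJunctionReads = 3) {
  g <- genes(models)
  gm <- S4Vectors::mcols(g)
  chrom <- as.character(GenomicRanges::seqnames(g))
  st <- GenomicRanges::start(g); en <- GenomicRanges::end(g)
  geneAt <- function(ch, p) {
    hit <- which(chrom == ch & st <= p & en >= p)
    if (length(hit) == 1L) gm$gene_id[hit] else NA_character_
  }
  hom <- homologPairs(models)
  homKeys <- if (nrow(hom)) paste(pmin(hom$gene_a, hom$gene_b),
                                  pmax(hom$gene_a, hom$gene_b)) else character()
  rows <- list()
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    if (r$junction_type < 0) next
    ga <- geneAt(r$chrom_a, r$pos_a); gb <- geneAt(r$chrom_b, r$pos_b)
    if (is.na(ga) || is.na(gb) || ga == gb) next
    # mito and homolog predicates applied per read, before anchors
    if (r$chrom_a == "chrM" || r$chrom_b == "chrM") next
    if (paste(pmin(ga, gb), pmax(ga, gb)) %in% homKeys) next
    if (r$anchor_a < minAnchor || r$anchor_b < minAnchor) next
    rows[[length(rows) + 1L]] <- data.frame(
      gene5 = ga, gene3 = gb, pos5 = r$pos_a, pos3 = r$pos_b,
      read_id = r$read_id, stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(data.frame(gene5 = character(),
                                       gene3 = character(), pos5 = integer(),
                                       pos3 = integer(),
                                       junction_reads = integer()))
  df <- do.call(rbind, rows)
  key <- paste(df$gene5, df$gene3, df$pos5, df$pos3)
  out <- do.call(rbind, lapply(split(df, key), function(grp)
    data.frame(gene5 = grp$gene5[1], gene3 = grp$gene3[1],
               pos5 = grp$pos5[1], pos3 = grp$pos3[1],
               junction_reads = length(unique(grp$read_id)),
               stringsAsFactors = FALSE)))
  out <- out[out$junction_reads >= minJunctionReads, , drop = FALSE]
  out <- out[order(out$gene5, out$gene3, out$pos5, out$pos3), , drop = FALSE]
  rownames(out) <- NULL
  out
}
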