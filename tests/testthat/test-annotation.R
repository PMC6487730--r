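# gene models mirroring the published breakpoint vignettes:
# AP3D1-like: minus-strand gene whose 3' UTR (leftmost exon edge) holds the
# breakpoint, with the protein domain elsewhere; DCUN1D3-like: breakpoint in
# the third exon, inside a DUF298-style domain; SERPINA-like pair with both
# breakpoints in domains.
makeAnnoModels <- function() {
  g <- data.frame(
    chrom = c("chr19", "chr16", "chr14", "chr14"),
    start = c(1000, 1000, 1000, 9000),
    end   = c(5000, 7000, 5000, 12000),
    strand = c("-", "+", "+", "+"),
    gene_id = c("GA", "GB", "GC", "GD"),
    biotype = "protein_coding", stringsAsFactors = FALSE)
  genes <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$start, g$end),
                                  strand = g$strand)
  S4Vectors::mcols(genes) <- S4Vectors::DataFrame(
    gene_id = g$gene_id, gene_name = g$gene_id, biotype = g$biotype)
  f <- rbind(
    # GA (minus strand): exons 1000-1500, 2000-2500, 4000-5000; the
    # leftmost 1000-1200 stretch is the 3' UTR in transcription order
    data.frame(chrom = "chr19", start = c(1000, 2000, 4000),
               end = c(1500, 2500, 5000), strand = "-", gene_id = "GA",
               kind = "exon", label = ""),
    data.frame(chrom = "chr19", start = 1000, end = 1200, strand = "-",
               gene_id = "GA", kind = "three_prime_utr", label = ""),
    data.frame(chrom = "chr19", start = 2000, end = 2500, strand = "-",
               gene_id = "GA", kind = "domain", label = "DOM_A"),
    # GB (plus strand): four exons; third exon 4000-4500 carries a domain
    data.frame(chrom = "chr16", start = c(1000, 2000, 4000, 6000),
               end = c(1500, 2500, 4500, 7000), strand = "+", gene_id = "GB",
               kind = "exon", label = ""),
    data.frame(chrom = "chr16", start = 3900, end = 4600, strand = "+",
               gene_id = "GB", kind = "domain", label = "DUF298like"),
    # GC / GD: single exons fully covered by domains
    data.frame(chrom = "chr14", start = 1000, end = 5000, strand = "+",
               gene_id = "GC", kind = "exon", label = ""),
    data.frame(chrom = "chr14", start = 2000, end = 4000, strand = "+",
               gene_id = "GC", kind = "domain", label = "SERPIN_A"),
    data.frame(chrom = "chr14", start = 9000, end = 12000, strand = "+",
               gene_id = "GD", kind = "exon", label = ""),
    data.frame(chrom = "chr14", start = 10000, end = 11000, strand = "+",
               gene_id = "GD", kind = "domain", label = "SERPIN_B"))
  features <- GenomicRanges::GRanges(f$chrom, IRanges::IRanges(f$start, f$end),
                                     strand = f$strand)
  S4Vectors::mcols(features) <- S4Vectors::DataFrame(
    gene_id = f$gene_id, kind = f$kind, label = f$label)
  GeneModelSet(genes = genes, features = features, mitoChrom = "chrM")
}

test_that("breakpoints resolve to UTR, exon-in-domain, intron and outside-gene", {
  m <- makeAnnoModels()
  # 3' UTR hit without domain involvement
  a <- annotateBreakpoint(m, "GA", "chr19", 1100)
  expect_equal(a$feature_hit, "three_prime_utr")
  expect_false(a$domain_affected)
  # third exon inside a conserved domain
  b <- annotateBreakpoint(m, "GB", "chr16", 4200)
  expect_equal(b$feature_hit, "exon(3)")
  expect_true(b$domain_affected)
  expect_equal(b$domain_hits, "DUF298like")
  # UTR outranks exon at the same position
  expect_equal(annotateBreakpoint(m, "GA", "chr19", 1500)$feature_hit,
               "exon(3)")   # in the exon but past the UTR (minus strand)
  # intron and outside
  expect_equal(annotateBreakpoint(m, "GB", "chr16", 3000)$feature_hit,
               "intron")
  expect_equal(annotateBreakpoint(m, "GA", "chr19", 500)$feature_hit,
               "outside_gene")
  expect_equal(annotateBreakpoint(m, "GA", "chr1", 1100)$feature_hit,
               "outside_gene")
  expect_error(annotateBreakpoint(m, "NOPE", "chr19", 1100), "NOPE")
})

test_that("a fusion can truncate conserved domains on both sides", {
  m <- makeAnnoModels()
  c5 <- annotateBreakpoint(m, "GC", "chr14", 3000)
  c3 <- annotateBreakpoint(m, "GD", "chr14", 10500)
  expect_true(c5$domain_affected && c3$domain_affected)
  calls <- data.frame(gene5 = "GC", gene3 = "GD", chrom5 = "chr14",
                      pos5 = 3000L, chrom3 = "chr14", pos3 = 10500L,
                      junction_reads = 3L, sample_id = "S1",
                      stringsAsFactors = FALSE)
  ann <- annotateBreakpoints(calls, m)
  expect_true(ann$domain5_affected && ann$domain3_affected)
})

test_that("exon numbering is strand-aware but domain overlap is not", {
  m <- makeAnnoModels()
  # GA minus strand: genomic-leftmost exon is exon 3
  expect_equal(annotateBreakpoint(m, "GA", "chr19", 4500)$feature_hit,
               "exon(1)")
  # flip GA to plus strand: same position becomes exon 3; domains unmoved
  flipped <- m
  gi <- which(S4Vectors::mcols(genes(flipped))$gene_id == "GA")
  GenomicRanges::strand(flipped@genes)[gi] <- "+"
  before <- annotateBreakpoint(m, "GA", "chr19", 2200)
  after <- annotateBreakpoint(flipped, "GA", "chr19", 2200)
  expect_equal(before$feature_hit, "exon(2)")
  expect_equal(after$feature_hit, "exon(2)")
  expect_equal(annotateBreakpoint(flipped, "GA", "chr19", 4500)$feature_hit,
               "exon(3)")
  expect_equal(before$domain_affected, after$domain_affected)
})

test_that("database matching partitions fusions into disease/partner/novel", {
  dbA <- data.frame(source = "dbA",
                    gene_a = c("C15orf57", "LOC9610"),
                    gene_b = c("CBX3", "IGLJ3"),
                    disease = c("glioblastoma", "cholangiocarcinoma"),
                    stringsAsFactors = FALSE)
  dbB <- data.frame(source = "dbB", gene_a = "CBX3", gene_b = "OTHER",
                    disease = "melanoma", stringsAsFactors = FALSE)
  fus <- data.frame(gene5 = c("CBX3", "IGLV4-69", "DCUN1D3"),
                    gene3 = c("C15orf57", "IGLJ3", "GSG1L"),
                    stringsAsFactors = FALSE)
  ann <- matchKnown(fus, list(dbA, dbB))
  expect_equal(ann$category,
               c("disease_annotated", "partner_annotated", "novel"))
  # pair matching is unordered and the pair evidence is reported
  expect_match(ann$evidence[1], "glioblastoma")
  expect_match(ann$evidence[2], "IGLJ3")
  expect_equal(ann$evidence[3], "")
  # empty database list warns and reports everything novel
  expect_warning(allNovel <- matchKnown(fus, list()), "empty")
  expect_true(all(allNovel$category == "novel"))
})

test_that("aliases reconcile symbols and categories stay a partition", {
  db <- data.frame(source = "db", gene_a = "LOC9610", gene_b = "PARTNER",
                   disease = "ICC", stringsAsFactors = FALSE)
  fus <- data.frame(gene5 = "IGLJ3ALT", gene3 = "PARTNER",
                    stringsAsFactors = FALSE)
  plain <- matchKnown(fus, db)
  expect_equal(plain$category, "partner_annotated")  # via PARTNER only
  ali <- matchKnown(fus, db,
                    aliases = data.frame(alias = "IGLJ3ALT",
                                         canonical = "LOC9610",
                                         stringsAsFactors = FALSE))
  expect_equal(ali$category, "disease_annotated")
  # partition property on a generated fusion set
  g <- generateCohort(cohortSpec(seed = 5, nSingleton = 30,
                                 nSingletonWithValidation = 3,
                                 tissueSingletonVal = c(normal_only = 1,
                                                        tumor_only = 1,
                                                        both = 1)))
  fus2 <- unique(fusionCalls(g$cohort)[, c("gene5", "gene3")])
  ann2 <- matchKnown(fus2, db)
  expect_true(all(ann2$category %in%
                  c("disease_annotated", "partner_annotated", "novel")))
  expect_equal(nrow(ann2), nrow(fus2))
})
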