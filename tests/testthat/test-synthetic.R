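test_that("generator configuration is validated", {
  expect_error(simSpec(genesPerChromosome = 0), "configuration error")
  expect_error(simSpec(nChromosomes = 1), "configuration error")
  expect_error(simSpec(biotypeMix = c(protein_coding = 0.9, lncRNA = 0.2,
                                      pseudogene = 0, other = 0)),
               "sum to 1")
  expect_error(noiseSpec(nMito = -1), ">= 0")
  expect_error(plantedFusion("A", "B", 3,
                             anchorLengths = matrix(20, 2, 2)),
               "one row per junction read")
})

test_that("the same seed reproduces byte-identical models and reads", {
  spec <- simSpec(seed = 9)
  m1 <- generateGeneModels(spec)
  m2 <- generateGeneModels(spec)
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  writeGtf(m1, p1); writeGtf(m2, p2)
  expect_identical(readLines(p1), readLines(p2))
  s1 <- generateChimericReads(m1, spec)
  s2 <- generateChimericReads(m2, spec)
  expect_identical(s1$records, s2$records)
  expect_identical(s1$fusionTruth, s2$fusionTruth)
  # a different seed perturbs the layout
  m3 <- generateGeneModels(simSpec(seed = 10))
  expect_false(identical(GenomicRanges::start(genes(m1)),
                         GenomicRanges::start(genes(m3))))
})

test_that("biotype proportions track the requested mix within 1/n", {
  mix <- c(protein_coding = 0.8, lncRNA = 0.14, pseudogene = 0.05,
           other = 0.01)
  spec <- simSpec(seed = 1, nChromosomes = 2, genesPerChromosome = 10,
                  biotypeMix = mix)
  m <- generateGeneModels(spec)
  n <- length(genes(m))
  expect_equal(n, 20L)
  got <- table(S4Vectors::mcols(genes(m))$biotype)[names(mix)]
  got[is.na(got)] <- 0
  expect_true(all(abs(as.numeric(got) / n - mix) <= 1 / n + 1e-12))
  expect_equal(as.numeric(got[["protein_coding"]]), 16)
})

test_that("gene models are internally consistent", {
  m <- generateGeneModels(simSpec(seed = 4, nChromosomes = 4,
                                  genesPerChromosome = 8))
  g <- genes(m)
  # non-overlapping genes per chromosome
  byChrom <- split(g, as.character(GenomicRanges::seqnames(g)))
  for (gr in byChrom) {
    o <- order(GenomicRanges::start(gr))
    expect_true(all(GenomicRanges::start(gr)[o][-1] >
                    GenomicRanges::end(gr)[o][-length(gr)]))
  }
  # every gene has >= 1 exon, enforced by class validity
  expect_true(methods::validObject(m))
  # homolog pairs reference real nuclear genes
  hom <- homologPairs(m)
  ids <- S4Vectors::mcols(g)$gene_id
  expect_true(all(c(hom$gene_a, hom$gene_b) %in% ids))
})

test_that("planted fusions emit exactly the requested records at their breakpoints", {
  spec <- simSpec(seed = 2, nChromosomes = 3, genesPerChromosome = 5,
                  noise = noiseSpec(0, 0, 0, 0, 0))
  m <- generateGeneModels(spec)
  ids <- S4Vectors::mcols(genes(m))$gene_id
  chroms <- as.character(GenomicRanges::seqnames(genes(m)))
  nuc <- ids[chroms != "chrM"]
  spec$plantedFusions <- list(
    plantedFusion(nuc[1], nuc[2], 5,
                  anchorLengths = matrix(20L, 5, 2)))
  sim <- generateChimericReads(m, spec)
  expect_equal(nrow(sim$records), 5L)
  expect_equal(length(unique(sim$records$pos_a)), 1L)
  expect_equal(length(unique(sim$records$pos_b)), 1L)
  expect_true(all(sim$records$anchor_a == 20L & sim$records$anchor_b == 20L))
  expect_true(sim$fusionTruth$passes)
  # breakpoints land on exon boundaries of the right genes
  f <- geneFeatures(m)
  fm <- S4Vectors::mcols(f)
  ex1 <- fm$gene_id == nuc[1] & fm$kind == "exon"
  expect_true(sim$records$pos_a[1] %in% GenomicRanges::end(f)[ex1])

  # absent gene id is reported by name
  spec$plantedFusions <- list(plantedFusion("NOPE", nuc[2], 3))
  expect_error(generateChimericReads(m, spec), "NOPE")
})

test_that("noise classes match their definitions exactly", {
  spec <- simSpec(seed = 6, noise = noiseSpec(nShortAnchor = 13,
                                              nLowSupport = 7, nHomolog = 6,
                                              nMito = 4, nBackground = 11))
  m <- generateGeneModels(spec)
  sim <- generateChimericReads(m, spec)
  tt <- sim$readTruth
  rec <- sim$records
  expect_equal(as.vector(table(tt$class)[c("short_anchor", "low_support",
                                           "homolog", "mito", "background")]),
               c(13L, 7L, 6L, 4L, 11L))
  byClass <- function(cl) rec[rec$read_id %in% tt$read_id[tt$class == cl], ]
  sa <- byClass("short_anchor")
  expect_true(all(sa$anchor_a < 15 | sa$anchor_b < 15))
  mi <- byClass("mito")
  expect_equal(nrow(mi), 4L)
  expect_true(all(xor(mi$chrom_a == "chrM", mi$chrom_b == "chrM")))
  hom <- homologPairs(m)
  ho <- byClass("homolog")
  asn <- assignReads(ho, m)
  expect_true(all(paste(pmin(asn$gene_a, asn$gene_b),
                        pmax(asn$gene_a, asn$gene_b)) %in%
                  paste(pmin(hom$gene_a, hom$gene_b),
                        pmax(hom$gene_a, hom$gene_b))))
  bg <- assignReads(byClass("background"), m)
  expect_true(all(bg$status == "intergenic"))
})

test_that("cohort generator honours its plan and the recurrence rule", {
  spec <- cohortSpec(seed = 21, nValidationTumor = 10, nValidationNormal = 5,
                     nMultiDiscovery = 6, nMultiWithValidation = 4,
                     nSingleton = 40, nSingletonWithValidation = 6,
                     tissueMulti = c(tumor_only = 3, both = 3),
                     tissueSingletonVal = c(normal_only = 3, tumor_only = 2,
                                            both = 1))
  g <- generateCohort(spec)
  truth <- g$truth
  expect_equal(nrow(truth), 46L)
  expect_equal(sum(truth$label == "recurrent"), 12L)
  # the planned sample sets obey the rule they are labelled with
  expect_true(all((truth$n_discovery >= 2 |
                   (truth$n_discovery == 1 & truth$n_validation >= 1)) ==
                  (truth$label == "recurrent")))
  # determinism
  g2 <- generateCohort(spec)
  expect_identical(fusionCalls(g$cohort), fusionCalls(g2$cohort))
  # spec validation
  expect_error(cohortSpec(nMultiDiscovery = 3, nMultiWithValidation = 5),
               "cannot exceed")
  expect_error(cohortSpec(tissueMulti = c(tumor_only = 1, both = 1)),
               "sum to nMultiDiscovery")
})
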