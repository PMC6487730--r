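models <- makeTinyModels()

test_that("read assignment resolves paired, ambiguous and intergenic loci", {
  recs <- rbind(
    chim("r1", "chr1", 1500, "chr1", 5500),   # GX-GY paired
    chim("r2", "chr1", 1500, "chr1", 1600),   # both in GX
    chim("r3", "chr2", 11500, "chr1", 1500),  # GO1/GO2 overlap -> ambiguous
    chim("r4", "chr1", 3000, "chr1", 5500))   # intergenic donor
  asn <- assignReads(recs, models)
  expect_equal(asn$status, c("paired", "paired", "ambiguous_a", "intergenic"))
  expect_equal(asn$gene_a[1], "GX")
  expect_equal(asn$gene_b[1], "GY")
  expect_equal(asn$gene_a[2], asn$gene_b[2])
  expect_error(assignReads(chim("r", "chr99", 5, "chr1", 1500), models),
               "chr99")
})

test_that("the calling cascade applies support, anchor, homolog and mito filters", {
  good <- chimGroup("g", 3, "chr1", 1500, "chr1", 5500)
  cand <- callFusions(good, models)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$gene5, "GX")
  expect_equal(cand$gene3, "GY")
  expect_equal(cand$junction_reads, 3L)

  # one read with a 14 bp anchor drops out; the group shrinks below 3
  short <- good; short$anchor_a[1] <- 14L
  expect_equal(nrow(callFusions(short, models)), 0L)
  # at exactly 15 bp the read survives ("not less than 15")
  edge <- good; edge$anchor_a[1] <- 15L
  expect_equal(callFusions(edge, models)$junction_reads, 3L)

  # same-gene groups are never candidates
  same <- chimGroup("s", 5, "chr1", 1500, "chr1", 1600)
  expect_equal(nrow(callFusions(same, models)), 0L)

  # abundant mitochondrial support is still removed
  mito <- chimGroup("m", 10, "chrM", 300, "chr1", 1500)
  expect_equal(nrow(callFusions(mito, models)), 0L)
  # the strict variant removes chrM-autosome but keeps chrM-chrX
  mitoX <- chimGroup("x", 4, "chrM", 300, "chrX", 2500)
  strict <- callingParams(mitoStrict = TRUE)
  expect_equal(nrow(callFusions(mito, models, strict)), 0L)
  expect_equal(nrow(callFusions(mitoX, models, strict)), 1L)
  expect_equal(nrow(callFusions(mitoX, models)), 0L)

  # homologous pair is discarded regardless of support
  hom <- chimGroup("h", 6, "chr1", 8500, "chr2", 5500)
  expect_equal(nrow(callFusions(hom, models)), 0L)
  expect_equal(nrow(callFusions(hom, models,
                                homologs = data.frame(gene_a = character(),
                                                      gene_b = character()))),
               1L)
})

test_that("junction reads count distinct ids; spanning pairs are auxiliary only", {
  dup <- chimGroup("d", 3, "chr1", 1500, "chr1", 5500)
  dup$read_id[3] <- dup$read_id[2]
  expect_equal(nrow(callFusions(dup, models)), 0L)  # only 2 distinct ids

  grp <- chimGroup("g", 3, "chr1", 1500, "chr1", 5500)
  span <- chimGroup("p", 4, "chr1", 1400, "chr1", 5400, junction_type = -1)
  cand <- callFusions(rbind(grp, span), models)
  expect_equal(cand$junction_reads, 3L)
  expect_equal(cand$spanning_pairs, 4L)
  # spanning pairs alone never make a candidate
  expect_equal(nrow(callFusions(span, models)), 0L)
})

test_that("empty input and breakpoint windows behave as documented", {
  expect_equal(nrow(callFusions(chim("r", "chr1", 1500, "chr1", 5500)[0, ],
                                models)), 0L)
  # jittered breakpoints merge only when a window is allowed
  jit <- rbind(chim("j1", "chr1", 1500, "chr1", 5500),
               chim("j2", "chr1", 1501, "chr1", 5500),
               chim("j3", "chr1", 1500, "chr1", 5501))
  expect_equal(nrow(callFusions(jit, models)), 0L)
  cand <- callFusions(jit, models, callingParams(window = 2))
  expect_equal(cand$junction_reads, 3L)
  expect_equal(cand$pos5, 1500L)
})

test_that("raising thresholds never adds candidates (monotonicity)", {
  spec <- simSpec(seed = 31, nChromosomes = 4, genesPerChromosome = 40,
                  noise = noiseSpec(20, 20, 10, 10, 50))
  m <- generateGeneModels(spec)
  sim <- generateChimericReads(m, spec)
  key <- function(df) paste(df$gene5, df$gene3, df$pos5, df$pos3)
  base <- callFusions(sim$records, m)
  for (jr in c(4, 6)) {
    sub <- callFusions(sim$records, m, callingParams(minJunctionReads = jr))
    expect_true(all(key(sub) %in% key(base)))
  }
  for (an in c(20, 30)) {
    sub <- callFusions(sim$records, m, callingParams(minAnchor = an))
    expect_true(all(key(sub) %in% key(base)))
  }
})

test_that("production caller matches the naive reference caller on random inputs", {
  for (seed in c(11, 12, 13)) {
    spec <- simSpec(seed = seed, nChromosomes = 4, genesPerChromosome = 40,
                    noise = noiseSpec(20, 20, 10, 10, 50))
    m <- generateGeneModels(spec)
    sim <- generateChimericReads(m, spec)
    got <- callFusions(sim$records, m)
    ref <- bruteForceCaller(sim$records, m)
    expect_equal(got[, c("gene5", "gene3", "pos5", "pos3", "junction_reads")],
                 ref, ignore_attr = TRUE)
  }
})

test_that("the caller recovers exactly the planted-and-passing fusions", {
  spec <- simSpec(seed = 42)
  m <- generateGeneModels(spec)
  sim <- generateChimericReads(m, spec)
  cand <- callFusions(sim$records, m, sampleId = "S1")
  truth <- sim$fusionTruth
  expect_equal(sum(truth$passes), 14L)
  got <- paste(cand$gene5, cand$gene3, cand$pos5, cand$pos3)
  want <- with(truth[truth$passes, ], paste(gene5, gene3, pos5, pos3))
  expect_setequal(got, want)
  # junction-read support equals the planted good-anchor read count
  i <- match(got, want)
  expect_equal(cand$junction_reads, truth$n_good_reads[truth$passes][i])
  # no noise-class read supports any surviving candidate
  asn <- assignReads(sim$records, m)
  noiseIds <- sim$readTruth$read_id[sim$readTruth$class != "planted"]
  noisePairs <- unique(stats::na.omit(
    paste(asn$gene_a, asn$gene_b)[asn$read_id %in% noiseIds]))
  expect_false(any(paste(cand$gene5, cand$gene3) %in% noisePairs))
})
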