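simpleMeta <- data.frame(
  sample_id = c("S1", "S2", "S3", "V9"),
  patient_id = c("P1", "P1", "P2", "VP1"),
  tissue = c("normal", "tumor", "tumor", "tumor"),
  cohort = c("discovery", "discovery", "discovery", "validation"),
  stringsAsFactors = FALSE)

mkCalls <- function(...) {
  rows <- list(...)
  data.frame(gene5 = vapply(rows, `[[`, "", 1),
             gene3 = vapply(rows, `[[`, "", 2),
             chrom5 = "chr1", pos5 = 1L, chrom3 = "chr2", pos3 = 2L,
             junction_reads = 3L,
             sample_id = vapply(rows, `[[`, "", 3),
             stringsAsFactors = FALSE)
}

test_that("recurrence rule distinguishes multi-discovery, validation-echo and singleton", {
  calls <- mkCalls(c("A", "B", "S1"), c("A", "B", "S2"),   # 2 discovery
                   c("C", "D", "S1"),                      # singleton
                   c("E", "F", "S3"), c("E", "F", "V9"))   # 1 + validation
  rep <- recurrenceTable(classifyRecurrence(CohortCallSet(calls, simpleMeta)))
  lab <- setNames(rep$label, paste(rep$gene5, rep$gene3))
  expect_equal(lab[["A B"]], "recurrent")
  expect_equal(lab[["C D"]], "singleton")
  expect_equal(lab[["E F"]], "recurrent")
  # validation-only support without discovery is not recurrent
  vOnly <- mkCalls(c("G", "H", "V9"))
  rep2 <- recurrenceTable(classifyRecurrence(CohortCallSet(vOnly, simpleMeta)))
  expect_equal(rep2$label, "singleton")
})

test_that("classification ignores call order, duplicates and (optionally) orientation", {
  calls <- mkCalls(c("A", "B", "S1"), c("A", "B", "S2"), c("A", "B", "S2"),
                   c("C", "D", "S3"))
  r1 <- recurrenceTable(classifyRecurrence(CohortCallSet(calls, simpleMeta)))
  r2 <- recurrenceTable(classifyRecurrence(
    CohortCallSet(calls[rev(seq_len(nrow(calls))), ], simpleMeta)))
  expect_identical(r1, r2)
  expect_equal(r1$n_discovery[r1$gene5 == "A"], 2L)
  # reversed orientation counts as a different fusion unless unordered
  flip <- mkCalls(c("A", "B", "S1"), c("B", "A", "S2"))
  ordered <- recurrenceTable(classifyRecurrence(CohortCallSet(flip, simpleMeta)))
  expect_equal(ordered$label, c("singleton", "singleton"))
  unord <- recurrenceTable(classifyRecurrence(CohortCallSet(flip, simpleMeta),
                                              unordered = TRUE))
  expect_equal(unord$label, "recurrent")
  # calls naming an unknown sample are rejected
  bad <- mkCalls(c("A", "B", "NOSUCH"))
  expect_error(CohortCallSet(bad, simpleMeta), "unknown sample")
})

test_that("tissue partition is exhaustive, disjoint and reproduces the 43-fusion arithmetic", {
  rep <- data.frame(
    label = c(rep("recurrent", 43), rep("singleton", 10)),
    tissue_class = c(rep("tumor_only", 18), rep("normal_only", 12),
                     rep("both", 13), rep("tumor_only", 10)),
    stringsAsFactors = FALSE)
  part <- tissuePartition(rep)
  expect_equal(sum(part$n), 43L)
  expect_equal(part$pct[part$tissue_class == "normal_only"], 27.9)
  expect_equal(part$pct[part$tissue_class == "both"], 30.2)
  # degenerate: everything tumor-only
  allT <- data.frame(label = rep("recurrent", 5), tissue_class = "tumor_only",
                     stringsAsFactors = FALSE)
  pt <- tissuePartition(allT)
  expect_equal(pt$n, c(5L, 0L, 0L))
})

test_that("support ratios reproduce the validated-fusion percentages", {
  ex <- exampleValidationCohort()
  r1 <- supportRatios(exampleFusionSupport("RP11-476K15.1", "CTD-2015H3.2"),
                      ex$meta)
  expect_equal(r1$numerator, c(10L, 4L, 10L))
  expect_equal(r1$denominator, c(14L, 14L, 17L))
  expect_equal(r1$pct, c(71, 29, 59))
  r2 <- supportRatios(exampleFusionSupport("C15orf57", "CBX3"), ex$meta)
  expect_equal(r2$pct, c(100, 86, 76))
  r3 <- supportRatios(exampleFusionSupport("IGLV1-51", "IGLL5"), ex$meta)
  expect_equal(r3$numerator[r3$ratio == "normal"], 10L)
  # empty support set
  r0 <- supportRatios(character(), ex$meta)
  expect_equal(r0$numerator, c(0L, 0L, 0L))
  expect_equal(r0$pct, c(0, 0, 0))
  # numerators are monotone under adding supporting samples
  some <- supportRatios(c("N129", "C57"), ex$meta)
  more <- supportRatios(c("N129", "C57", "BN", "AC"), ex$meta)
  expect_true(all(more$numerator >= some$numerator))
  expect_error(supportRatios("NOSUCH", ex$meta), "NOSUCH")
})

test_that("fisherExact matches closed forms and the enumeration oracle", {
  expect_equal(fisherExact(1, 1, 1, 1), 1.0)
  expect_equal(fisherExact(3, 1, 2, 4), 110 / 210, tolerance = 1e-12)
  expect_lt(fisherExact(15, 5, 23, 2311), 2.2e-16)
  expect_error(fisherExact(0, 0, 0, 0), "all zero")
  expect_error(fisherExact(-1, 1, 1, 1), "non-negative")
  # random 2x2 tables with N <= 200 against full enumeration
  withr::with_seed(99, {
    for (i in 1:200) {
      n <- sample(4:200, 1)
      cells <- as.vector(stats::rmultinom(1, n, prob = stats::runif(4)))
      expect_equal(fisherExact(cells[1], cells[2], cells[3], cells[4]),
                   fisherOracle(cells[1], cells[2], cells[3], cells[4]),
                   tolerance = 1e-9)
    }
  })
})

test_that("sample clustering on shared fusions separates patients", {
  g <- generateCohort(cohortSpec(seed = 17))
  cl <- clusterSamples(g$cohort, k = 2)
  meta <- sampleMeta(g$cohort)
  pat <- meta$patient_id[match(names(cl$clusters), meta$sample_id)]
  expect_equal(length(unique(cl$clusters)), 2L)
  # cluster assignment refines the patient partition exactly
  expect_equal(length(unique(paste(pat, cl$clusters))), 2L)

  # identical fusion profiles sit at distance zero
  calls <- mkCalls(c("A", "B", "S1"), c("A", "B", "S2"),
                   c("C", "D", "S1"), c("C", "D", "S2"),
                   c("A", "B", "S3"))
  cc <- clusterSamples(CohortCallSet(calls, simpleMeta))
  dm <- as.matrix(cc$dist)
  expect_equal(dm["S1", "S2"], 0)
  expect_gt(dm["S1", "S3"], 0)
})
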