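# fusionscape

Cohort-level gene-fusion analysis from chimeric RNA-seq alignments, for
studies that compare tumor and adjacent normal tissue across a discovery
cohort and external validation samples (the design used to map the fusion
landscape of multifocal HBV-related hepatocellular carcinoma).

The package consumes the chimeric-junction records a spliced aligner emits
(a documented 10-column subset of STAR's `Chimeric.out.junction`; extra
columns are ignored) plus GENCODE-style gene models, and provides:

* **Fusion calling** (`callFusions`) under the standard filtering cascade:
  unique gene assignment of both breakpoints, anchors ≥ 15 bp on both
  sides of the junction, ≥ 3 distinct junction reads per breakpoint pair,
  removal of homologous-pair and mitochondrial-nuclear chimeras.
* **Recurrence classification** (`classifyRecurrence`): a fusion is
  recurrent when it occurs in ≥ 2 discovery samples, or in 1 discovery
  sample plus ≥ 1 validation sample; tissue partition
  (tumor-only / normal-only / both), per-fusion support ratios, Fisher
  exact enrichment of validation support, and Jaccard/average-linkage
  clustering of samples on shared fusions.
* **Annotation** (`matchKnown`, `annotateBreakpoint`): cross-referencing
  against known-fusion database tables (disease-annotated /
  partner-annotated / novel) and feature-level breakpoint resolution
  (5'/3' UTR, numbered exon, intron) with protein-domain overlap.
* **Landscape summaries** (`classifyFusionType`, `partnerCounts`,
  `qcPercentages`) and **2^−ΔΔCT relative expression**
  (`relativeExpression`) with a GAPDH-style internal control.
* **Seeded synthetic generators** (`generateGeneModels`,
  `generateChimericReads`, `generateCohort`) that plant fusions and
  calibrated noise classes with exact ground truth, so the whole pipeline
  is testable without controlled-access raw data.

Central data structures are Bioconductor-style S4 classes over `GRanges`
and call tables: `GeneModelSet`, `CallingParams`, `CohortCallSet`,
`RecurrenceReport`.  A thin command-line wrapper with `simulate`, `call`,
`recur`, `enrich`, `annotate`, `report`, `ddct` and `run` subcommands is
installed at `system.file("scripts", "fusionscape", package =
"fusionscape")`.

## Worked example

```r
library(fusionscape)

spec   <- simSpec(seed = 1)             # 20 planted fusions, 14 pass filters
models <- generateGeneModels(spec)
sim    <- generateChimericReads(models, spec)
cand   <- callFusions(sim$records, models, sampleId = "S1")
nrow(cand)
#> [1] 14

g   <- generateCohort(cohortSpec(seed = 1))   # 7 discovery + 79 validation samples
rep <- classifyRecurrence(g$cohort)
rep
#> RecurrenceReport: 2354 fusions, 43 recurrent / 2311 singleton
#>   recurrent tissue classes: tumor_only=18 normal_only=12 both=13
roundHalfUp(100 * 43 / 2354, 1)
#> [1] 1.8
tissuePartition(rep)
#>   tissue_class  n  pct
#> 1   tumor_only 18 41.9
#> 2  normal_only 12 27.9
#> 3         both 13 30.2
fisherExact(15, 5, 23, 2311)    # validation support: recurrent vs singleton
#> [1] 8.29199e-25

ex <- exampleValidationCohort()  # bundled 14-patient RT-PCR cohort
supportRatios(exampleFusionSupport("RP11-476K15.1", "CTD-2015H3.2"), ex$meta)
#>     ratio numerator denominator pct
#> 1 patient        10          14  71
#> 2  normal         4          14  29
#> 3   tumor        10          17  59

relativeExpression(20, 18, 24, 18)$fold_change   # ddCt = -4
#> [1] 16
```

So: of 2354 distinct fusions in the synthetic discovery cohort, 43 (1.8%)
are recurrent; recurrent fusions are strongly enriched for validation
support (p ≈ 8.3e−25, far below 2.2e−16); 27.9% of recurrent fusions are
seen only in adjacent normal tissue and 30.2% in both tissues; and the
bundled RT-PCR cohort reproduces the published support ratios of the
validated fusions exactly.

## Layout

```
R/                  implementation (S4 classes, calling, recurrence,
                    annotation, reporting, synthetic generators, pipeline)
inst/extdata/       bundled plain-text tables (RT-PCR cohort, library QC)
inst/scripts/       command-line wrapper
tests/testthat/     unit, property and acceptance tests
vignettes/          methods vignette
scripts/            acceptance script
```
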