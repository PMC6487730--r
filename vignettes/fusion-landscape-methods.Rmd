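---
title: "Methods: calling, recurrence and annotation of gene fusions from chimeric reads"
author: "fusionscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calling, recurrence and annotation of gene fusions from chimeric reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusionscape)
```

# Scope and model

`fusionscape` implements a cohort-level gene-fusion analysis for bulk
RNA-seq of tumor and adjacent normal tissue, of the kind used to map the
fusion landscape of multifocal HBV-related hepatocellular carcinoma.  The
package starts *after* alignment: its input is the chimeric-junction file a
spliced aligner emits (one record per split read whose two segments map to
distinct loci), and its output is a filtered set of fusion candidates, their
cohort recurrence classification, database and breakpoint annotation, and
descriptive landscape statistics.  Alignment itself, raw-read QC and any
wet-lab validation steps are out of scope by design.

## The calling cascade

A chimeric split read is evidence for a fusion junction; most such records
are artifacts.  `callFusions()` applies a fixed cascade of per-read and
per-candidate predicates:

1. **Gene assignment.** Each breakpoint is assigned the unique gene whose
   span contains it.  Positions covered by more than one overlapping gene
   are *ambiguous* and the read is excluded rather than multi-assigned; this
   prevents one read from supporting several candidates at once, at the cost
   of losing evidence in overlapping-gene regions (a known limitation).
   Intergenic and same-gene records are dropped.
2. **Anchor filter.** A split read is kept only when *both* aligned segments
   cover at least `minAnchor` bases (default 15 bp).  Short anchors align
   promiscuously and are the dominant source of spurious junctions.
3. **Grouping.** Surviving split reads are grouped by (5' gene, 3' gene,
   breakpoint pair).  Grouping is exact-position by default
   (`window = 0`): splice-mediated junctions recur at the identical
   coordinate, and a tolerance window is only useful for noisy junction
   callers, so it is exposed as an option rather than a default.
4. **Support filter.** A candidate needs at least `minJunctionReads`
   distinct read ids (default 3).  Duplicate read ids within a group count
   once.  Spanning pairs (junction type −1) are parsed and reported as
   auxiliary `spanning_pairs` evidence but never count towards junction
   reads.
5. **Homolog filter.** Chimeras between homologous genes are
   mapping artifacts; candidates whose unordered pair appears in the
   supplied homolog list are removed.  Homology is injected as an explicit
   pair list (from any paralog resource, or the synthetic truth) — no
   sequence comparison is performed, which keeps the step reproducible and
   data-free.
6. **Mitochondrial filter.** The mitochondrial transcriptome is so highly
   expressed that chrM-nuclear chimeras are overwhelmingly artifactual.  By
   default every candidate touching `mitoChrom` is removed;
   `mitoStrict = TRUE` restores the literal mitochondrion-autosome rule,
   keeping chrM-sex-chromosome pairs.

The anchor, homolog and mitochondrial predicates are independent, so their
order of application cannot change the result; the test suite checks the
whole cascade against a naive reference implementation that applies them in
a different order.

A recorded-but-unused parameter, `maxMismatches` (default 2), documents the
per-read mismatch cap the upstream aligner applied; it travels in the
provenance headers so calls are interpretable later.

## Recurrence across cohorts

Fusions are matched across samples by their ordered gene pair (orientation
conventions differ between external call sets, so `unordered = TRUE`
relaxes this).  With a discovery cohort and an independent validation
cohort, a fusion is **recurrent** when it occurs in at least two discovery
samples, or in exactly one discovery sample *and* at least one validation
sample; everything else is a singleton.  Tissue classes summarise the
supporting samples: `tumor_only`, `normal_only` or `both`.

Enrichment of validation support among recurrent fusions is tested with the
two-sided Fisher exact test on the 2×2 table (multi-discovery vs singleton)
× (validation-supported vs not).  The p-value is the sum of hypergeometric
probabilities of all tables with the observed margins whose point
probability does not exceed the observed one (1e-7 relative tie
tolerance); the implementation delegates to `stats::fisher.test`, which
computes exactly this, and the tests cross-check it against a full
enumeration oracle on a thousand random tables.

Per-fusion support ratios report patients (patients owning at least one
supporting sample / all patients), normal samples and tumor samples.
Percentages round half away from zero — integers for support ratios, one
decimal for fractions of fusion totals, two decimals for library QC — which
is the convention that reproduces the worked examples shipped in
`inst/extdata` exactly.  One cell of the bundled library table (the PI-V
clean percentage) was evidently truncated rather than rounded in its
source and is not asserted.

Sample clustering uses the binary sample × fusion incidence matrix
restricted to fusions present in at least two samples (singletons carry no
between-sample signal), Jaccard distance (`stats::dist(method =
"binary")`) and average-linkage hierarchical clustering.  Jaccard ignores
shared absences, which matters because the matrix is overwhelmingly sparse;
average linkage is the conventional choice for such presence profiles.  Two
samples sharing no scored fusion at all are assigned the maximal distance 1.

## Annotation

Database matching is unordered on gene pairs and partitions any fusion set
into `disease_annotated` (exact pair in some database), `partner_annotated`
(at least one partner gene known, no pair match) and `novel`.  Symbols are
compared case-sensitively after whitespace normalization; an optional
alias table reconciles divergent naming (curated databases disagree on
symbols more often than on loci), with no network lookups.

Breakpoint annotation resolves a genomic position against a gene's feature
set with priority UTR > exon > intron; exons are numbered 1-based in
transcription order, i.e. against genomic coordinates on the minus strand.
Protein-domain intervals travel in genomic coordinates on the gene model
(`domain` feature lines with a `label` attribute in the GTF dialect), so
domain involvement is a direct interval overlap; codon-level mapping of
domains through protein coordinates is deliberately out of scope — the
positional statements this package makes (breakpoint in a 3' UTR, in an
exon inside a conserved domain) do not need it.

## Relative expression (2^−ΔΔCT)

`relativeExpression()` implements the standard ΔΔCt arithmetic with a
GAPDH-style internal reference: per replicate,
ΔΔCt = (Ct~target,case~ − Ct~ref,case~) − mean(Ct~target,ctrl~ −
Ct~ref,ctrl~) and fold change 2^−ΔΔCt^.  Replicates are summarised as mean
± SEM of the fold changes, with a Welch two-sided t-test on the per-arm
ΔCt values.  The returned `se_log2` is the two-arm standard error of the
log2 fold estimate; unlike the case-arm SEM it also reflects noise in the
control arm, and it is the quantity the recovery tests use (at three
standard errors) to judge whether a planted effect was recovered.

# The synthetic generators

Real chimeric data for this design are controlled-access, so the package
ships seeded generators that emulate the *structure* of the evidence, not
its sequence content.

`generateGeneModels()` lays out non-overlapping genes (2-6 exons each,
terminal UTRs and one internal-exon domain for protein-coding genes) on a
small multi-chromosome genome whose last chromosome is mitochondrial.
Biotypes follow a GENCODE-like mix (80% protein-coding, 14% lncRNA, 5%
pseudogene, 1% other) by largest-remainder apportionment, so realised
proportions are within 1/n of the target by construction.  A deterministic
homolog-pair list is attached; the homolog noise class draws exactly from
it.

`generateChimericReads()` plants fusions as junction-read records at exon
boundaries (splice-mediated junctions; arbitrary intra-gene positions are
configurable) and adds five noise classes, each engineered to be removed by
exactly one calling filter: short-anchor groups (every read has one anchor
of 5-14 bp), low-support pairs (1-2 reads), homologous pairs and
mitochondrial-nuclear pairs (both well supported and well anchored), and
intergenic background.  The default plan plants twenty fusions of which
fourteen pass every filter — two fail junction-read support, two lose too
many reads to the anchor filter, one is homologous, one mitochondrial.  A
planted fusion is expected to survive when at least `minJunctionReads` of
its reads have both anchors ≥ `minAnchor` and its pair is neither
homologous nor mitochondrial; the truth table records this flag and the
recovery tests assert set equality between caller output and truth.

`generateCohort()` emulates the cohort design at its published scale: seven
discovery samples in two patients (normal + three lesions; normal + two
lobes) and 79 validation samples (62 tumor, 17 normal), with 2354 distinct
fusions — 20 shared by ≥ 2 discovery samples (15 of them validation-
supported) and 2334 discovery singletons (23 validation-supported),
giving 43 recurrent fusions partitioned 18/12/13 into
tumor-only/normal-only/both.  Multi-discovery sharing is within-patient by
construction, with rotating tumor subsets so every discovery sample carries
at least one shared fusion; each patient has a single normal sample, so
normal-only recurrent fusions arise through the singleton-plus-validation
route.  Partner genes are invented per fusion, placed on different
chromosomes with probability 0.85 and both protein-coding with probability
0.85, matching the landscape proportions the summaries should recover.
Junction-read support per call is uniform on 3-30, and every fusion keeps
one fixed breakpoint pair across samples.

RNG discipline: each generator derives its own sub-seed from the master
seed, so adding or re-running one generator never perturbs the output of
another, and a fixed seed reproduces byte-identical files.

**What the generators do not emulate** — and hence what passing tests do
not show about real data: sequencing error and alignment mismatch
behaviour, expression-level-dependent read depth, genuine sequence homology
(the homolog list is declarative), viral-integration chimeras, and real
breakpoint microstructure.  The generators validate the *logic* of the
pipeline against known truth; they cannot validate alignment-level
artifact behaviour.

# Numerical and design choices

* **Coordinates** are 1-based inclusive everywhere (GTF convention); no
  conversion layer exists.
* **Rounding** is half-away-from-zero at every reported percentage
  (`roundHalfUp()`), with a 1e-8 cushion absorbing binary representation
  error before the floor.
* **Fusion identity** ignores strand; the chimeric dialect carries strands
  for provenance but candidate keys are gene pairs.
* **Ambiguous overlaps** (a breakpoint inside two genes) exclude the read
  — a conservative choice that avoids double counting and is flagged as a
  divergence risk against callers that multi-assign.
* **Support thresholds** apply per (gene pair, breakpoint pair) per
  sample — the strictest reading consistent with exact-position junction
  recurrence.
* **Problem sizes** in the test suite are chosen for desk-scale runtimes:
  genomes of a few hundred genes, a few hundred chimeric records, the
  full-scale 2354-fusion cohort (which is small as a call table even though
  it was large as raw sequence data).  The acceptance script re-runs the
  cohort, the read-level recovery and the ΔΔCt recovery end to end in well
  under a minute.

# Worked example

```{r example}
spec <- simSpec(seed = 1)
models <- generateGeneModels(spec)
sim <- generateChimericReads(models, spec)
cand <- callFusions(sim$records, models, sampleId = "S1")
nrow(cand)                       # 14 planted fusions survive the cascade
table(sim$fusionTruth$reason)    # why the other six fail

g <- generateCohort(cohortSpec(seed = 1))
rep <- classifyRecurrence(g$cohort)
rep
tissuePartition(rep)
```

# Known limitations

* Homology is declarative; a real analysis must supply a paralog list.
* Overlapping-gene regions lose evidence (ambiguity exclusion).
* The eight-type fusion classification emits whichever unordered biotype
  pairs occur (ten are possible with four classes); the labels are not a
  fixed eight-element vocabulary.
* Expressed-gene biotype composition requires an externally produced
  expressed-gene list (`biotypeComposition()`); expression quantification
  is out of scope.
* Public-cohort totals are reported as computed from the supplied call
  tables; no external counts are hard-coded.
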