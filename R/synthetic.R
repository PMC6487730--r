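## Seeded synthetic-data generators.  They produce gene models, chimeric
## junction records with planted fusions plus calibrated noise classes,
## and multi-sample cohort call tables with known ground truth, so every
## downstream stage of the pipeline can be tested against an exact
## oracle without access to raw sequencing data.
##
## RNG discipline: one sub-seed per generator, derived from the master
## seed, so adding or re-running one generator never perturbs another.

#' Noise specification for the chimeric-read generator
#'
#' Each noise class targets exactly one calling filter: chimeras with
#' one anchor under 15 bp (anchor filter), gene pairs with fewer than
#' three junction reads (support filter), chimeras between genes listed
#' as homologs (homolog filter), chimeras joining the mitochondrial
#' chromosome to an autosome (mitochondrial filter), and random
#' intergenic background (gene-assignment step).  Counts are numbers of
#' chimeric records.
#'
#' @param nShortAnchor,nLowSupport,nHomolog,nMito,nBackground
#'   non-negative record counts per class.
#' @return a validated list of class `NoiseSpec`.
#' @export
noiseSpec <- function(nShortAnchor = 50L, nLowSupport = 50L,
                      nHomolog = 20L, nMito = 20L, nBackground = 200L) {
  x <- list(nShortAnchor = as.integer(nShortAnchor),
            nLowSupport = as.integer(nLowSupport),
            nHomolog = as.integer(nHomolog),
            nMito = as.integer(nMito),
            nBackground = as.integer(nBackground))
  if (any(unlist(x) < 0L))
    stop("noise counts must be >= 0", call. = FALSE)
  class(x) <- "NoiseSpec"
  x
}

#' Simulation specification
#'
#' Study conditions for the synthetic generators.  The defaults define
#' the reference scenario used throughout the test suite: a small
#' multi-chromosome genome with one mitochondrial chromosome, a
#' GENCODE-like biotype mix dominated by protein-coding genes, twenty
#' planted fusions of which fourteen survive the calling filters (two
#' fail the support threshold, two the anchor threshold, one the
#' homolog filter and one the mitochondrial filter), and the five noise
#' classes at 50/50/20/20/200 records.
#'
#' @param seed master RNG seed; fixed seed implies byte-identical
#'   output.
#' @param nChromosomes number of chromosomes, the last being the
#'   mitochondrial chromosome `chrM`.
#' @param genesPerChromosome genes laid out per chromosome.
#' @param biotypeMix named proportions over protein_coding / lncRNA /
#'   pseudogene / other, summing to 1 (within 1e-9).
#' @param plantedFusions optional list of planted fusions (see
#'   [plantedFusion()]); `NULL` uses the default twenty-fusion plan
#'   derived from the generated models.
#' @param noise a [noiseSpec()].
#' @return a validated list of class `SimSpec`.
#' @export
simSpec <- function(seed = 1L, nChromosomes = 6L, genesPerChromosome = 40L,
                    biotypeMix = c(protein_coding = 0.80, lncRNA = 0.14,
                                   pseudogene = 0.05, other = 0.01),
                    plantedFusions = NULL, noise = noiseSpec()) {
  if (nChromosomes < 2L)
    stop("configuration error: need at least 2 chromosomes (one mitochondrial)",
         call. = FALSE)
  if (genesPerChromosome < 1L)
    stop("configuration error: genesPerChromosome must be >= 1",
         call. = FALSE)
  if (!setequal(names(biotypeMix), .BIOTYPES))
    stop("biotypeMix must be named over ", paste(.BIOTYPES, collapse = "/"),
         call. = FALSE)
  if (abs(sum(biotypeMix) - 1) > 1e-9)
    stop("biotypeMix must sum to 1", call. = FALSE)
  x <- list(seed = as.integer(seed),
            nChromosomes = as.integer(nChromosomes),
            genesPerChromosome = as.integer(genesPerChromosome),
            biotypeMix = biotypeMix[.BIOTYPES],
            plantedFusions = plantedFusions,
            noise = noise)
  class(x) <- "SimSpec"
  x
}

#' Describe a planted fusion
#'
#' @param gene5,gene3 partner gene ids (5' and 3').
#' @param nJunctionReads number of junction reads to emit.
#' @param anchorLengths matrix with `nJunctionReads` rows and two
#'   columns (anchor bp on each side), or `NULL` for default anchors of
#'   20/20.
#' @param breakpoint5,breakpoint3 1-based genomic positions; `NA`
#'   places the breakpoint on an exon boundary of the gene
#'   (splice-mediated default).
#' @return list of class `PlantedFusion`.
#' @export
plantedFusion <- function(gene5, gene3, nJunctionReads,
                          anchorLengths = NULL,
                          breakpoint5 = NA_integer_,
                          breakpoint3 = NA_integer_) {
  if (is.null(anchorLengths))
    anchorLengths <- matrix(20L, nrow = nJunctionReads, ncol = 2L)
  anchorLengths <- matrix(as.integer(anchorLengths), ncol = 2L)
  if (nrow(anchorLengths) != nJunctionReads)
    stop("anchorLengths must have one row per junction read", call. = FALSE)
  structure(list(gene5 = gene5, gene3 = gene3,
                 nJunctionReads = as.integer(nJunctionReads),
                 anchorLengths = anchorLengths,
                 breakpoint5 = breakpoint5, breakpoint3 = breakpoint3),
            class = "PlantedFusion")
}

## largest-remainder apportionment of n genes over the biotype mix, so
## realised proportions are within 1/n of the target
.apportion <- function(n, mix) {
  raw <- n * mix
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    o <- order(raw - base, decreasing = TRUE)
    base[o[seq_len(left)]] <- base[o[seq_len(left)]] + 1
  }
  as.integer(base)
}

#' Generate synthetic gene models
#'
#' Lays out non-overlapping genes chromosome by chromosome (the last
#' chromosome is mitochondrial), each with 2-6 exons; protein-coding
#' genes get terminal UTRs and, when they have at least three exons, a
#' protein-domain interval over an internal exon.  Biotypes follow the
#' requested mix by largest-remainder apportionment (within 1/n of the
#' target).  A deterministic list of homologous gene pairs is attached;
#' the read generator's homolog noise class draws exactly from this
#' list.
#'
#' @param spec a [simSpec()].
#' @param nHomologPairs number of homologous pairs to designate;
#'   `NULL` (default) uses 8 pairs, reduced on genomes too small to
#'   spare the genes.
#' @return a [GeneModelSet-class].
#' @export
generateGeneModels <- function(spec, nHomologPairs = NULL) {
  stopifnot(inherits(spec, "SimSpec"))
  seeds <- subSeeds(spec$seed, 4L)
  chroms <- c(paste0("chr", seq_len(spec$nChromosomes - 1L)), "chrM")
  nGenes <- spec$nChromosomes * spec$genesPerChromosome

  withSeed(seeds[1], {
    counts <- .apportion(nGenes, spec$biotypeMix)
    biotypes <- sample(rep(.BIOTYPES, counts))

    gRows <- vector("list", nGenes)
    fRows <- list()
    gi <- 0L
    for (chrom in chroms) {
      cursor <- 1L
      for (k in seq_len(spec$genesPerChromosome)) {
        gi <- gi + 1L
        gap <- sample(5000:20000, 1L)
        len <- sample(2000:20000, 1L)
        start <- cursor + gap
        end <- start + len - 1L
        cursor <- end
        strand <- sample(c("+", "-"), 1L)
        id <- sprintf("SYNG%04d", gi)
        bt <- biotypes[gi]
        gRows[[gi]] <- data.frame(chrom = chrom, start = start, end = end,
                                  strand = strand, gene_id = id,
                                  gene_name = id, biotype = bt,
                                  stringsAsFactors = FALSE)
        ## exon chain spanning the gene
        nEx <- sample(2:6, 1L)
        cuts <- sort(sample(seq(start + 100L, end - 100L), 2L * (nEx - 1L)))
        exStart <- c(start, cuts[seq(2, length(cuts), by = 2)] + 1L)
        exEnd <- c(cuts[seq(1, length(cuts), by = 2)], end)
        ex <- data.frame(chrom = chrom, start = exStart, end = exEnd,
                         strand = strand, gene_id = id, kind = "exon",
                         label = "", stringsAsFactors = FALSE)
        fRows[[length(fRows) + 1L]] <- ex
        if (bt == "protein_coding") {
          ## terminal UTRs in transcription orientation
          w1 <- max(1L, min(200L, exEnd[1] - exStart[1]))
          wn <- max(1L, min(200L, exEnd[nEx] - exStart[nEx]))
          utrLeft <- data.frame(chrom = chrom, start = exStart[1],
                                end = exStart[1] + w1 - 1L, strand = strand,
                                gene_id = id,
                                kind = if (strand == "+") "five_prime_utr"
                                       else "three_prime_utr",
                                label = "", stringsAsFactors = FALSE)
          utrRight <- data.frame(chrom = chrom, start = exEnd[nEx] - wn + 1L,
                                 end = exEnd[nEx], strand = strand,
                                 gene_id = id,
                                 kind = if (strand == "+") "three_prime_utr"
                                        else "five_prime_utr",
                                 label = "", stringsAsFactors = FALSE)
          fRows[[length(fRows) + 1L]] <- rbind(utrLeft, utrRight)
          if (nEx >= 3L) {
            di <- sample(2:(nEx - 1L), 1L)
            fRows[[length(fRows) + 1L]] <- data.frame(
              chrom = chrom, start = exStart[di], end = exEnd[di],
              strand = strand, gene_id = id, kind = "domain",
              label = sprintf("DOM_%s", id), stringsAsFactors = FALSE)
          }
        }
      }
    }
    gdf <- do.call(rbind, gRows)
    fdf <- do.call(rbind, fRows)
  })

  genes <- GenomicRanges::GRanges(gdf$chrom,
                                  IRanges::IRanges(gdf$start, gdf$end),
                                  strand = gdf$strand)
  S4Vectors::mcols(genes) <- S4Vectors::DataFrame(
    gene_id = gdf$gene_id, gene_name = gdf$gene_name, biotype = gdf$biotype)
  features <- GenomicRanges::GRanges(fdf$chrom,
                                     IRanges::IRanges(fdf$start, fdf$end),
                                     strand = fdf$strand)
  S4Vectors::mcols(features) <- S4Vectors::DataFrame(
    gene_id = fdf$gene_id, kind = fdf$kind, label = fdf$label)

  ## homolog designation: disjoint nuclear gene pairs, reserved from the
  ## front of the id space so they are reproducible across runs
  nuclear <- gdf$gene_id[gdf$chrom != "chrM"]
  if (is.null(nHomologPairs))
    nHomologPairs <- min(8L, length(nuclear) %/% 6L)
  homologs <- withSeed(seeds[2], {
    picks <- sample(nuclear, 2L * nHomologPairs)
    data.frame(gene_a = picks[seq(1, length(picks), 2)],
               gene_b = picks[seq(2, length(picks), 2)],
               stringsAsFactors = FALSE)
  })
  GeneModelSet(genes = genes, features = features, homologs = homologs,
               mitoChrom = "chrM")
}

## an exon-boundary breakpoint inside a gene (splice-mediated default):
## donor side uses an exon end, acceptor side an exon start
.exonBoundary <- function(models, geneId, side) {
  f <- geneFeatures(models)
  fm <- S4Vectors::mcols(f)
  idx <- which(fm$gene_id == geneId & fm$kind == "exon")
  if (side == "donor") {
    sample(GenomicRanges::end(f)[idx], 1L)
  } else {
    sample(GenomicRanges::start(f)[idx], 1L)
  }
}

.geneInfo <- function(models, geneId) {
  g <- genes(models)
  i <- match(geneId, S4Vectors::mcols(g)$gene_id)
  if (is.na(i))
    stop("planted gene id absent from models: ", geneId, call. = FALSE)
  list(chrom = as.character(GenomicRanges::seqnames(g))[i],
       start = GenomicRanges::start(g)[i], end = GenomicRanges::end(g)[i],
       strand = as.character(GenomicRanges::strand(g))[i])
}

## the default 20-fusion plan: 14 pass every filter, 2 fail the junction
## -read threshold, 2 the anchor threshold, 1 the homolog filter and 1
## the mitochondrial filter
.defaultPlantedPlan <- function(models) {
  g <- genes(models)
  gm <- S4Vectors::mcols(g)
  chrom <- as.character(GenomicRanges::seqnames(g))
  hom <- homologPairs(models)
  homGenes <- unique(c(hom$gene_a, hom$gene_b))
  nuclear <- gm$gene_id[chrom != "chrM" & !(gm$gene_id %in% homGenes)]
  mito <- gm$gene_id[chrom == "chrM"][1]
  pool <- sample(nuclear, 39L)   # 19 nuclear pairs + 1 partner for chrM
  planted <- vector("list", 20L)
  for (i in 1:14) {   # clean passes
    n <- sample(3:10, 1L)
    planted[[i]] <- plantedFusion(pool[2 * i - 1], pool[2 * i], n,
      anchorLengths = matrix(sample(15:40, 2 * n, replace = TRUE), ncol = 2))
  }
  for (i in 15:16) {  # below the junction-read threshold
    n <- i - 14L      # 1 and 2 reads
    planted[[i]] <- plantedFusion(pool[2 * i - 1], pool[2 * i], n,
      anchorLengths = matrix(sample(15:40, 2 * n, replace = TRUE), ncol = 2))
  }
  for (i in 17:18) {  # anchors too short on enough reads to sink the group
    n <- 4L
    anch <- matrix(sample(15:40, 2 * n, replace = TRUE), ncol = 2)
    anch[1:2, 1] <- sample(5:14, 2L, replace = TRUE)   # 2 good reads remain
    planted[[i]] <- plantedFusion(pool[2 * i - 1], pool[2 * i], n,
                                  anchorLengths = anch)
  }
  ## homologous pair
  n <- 5L
  planted[[19]] <- plantedFusion(hom$gene_a[1], hom$gene_b[1], n,
    anchorLengths = matrix(sample(15:40, 2 * n, replace = TRUE), ncol = 2))
  ## mitochondrial pair
  n <- 6L
  planted[[20]] <- plantedFusion(mito, pool[39], n,
    anchorLengths = matrix(sample(15:40, 2 * n, replace = TRUE), ncol = 2))
  planted
}

#' Generate chimeric junction records with planted fusions and noise
#'
#' Emits, for every planted fusion, exactly its requested number of
#' junction-read records at its two breakpoints with the stated anchor
#' lengths, then appends the five noise classes of `spec$noise`.  The
#' returned truth tables label every record and state, per planted
#' fusion, whether it should survive the calling filters (at least
#' `minJunctionReads` reads whose anchors are both >= `minAnchor`,
#' pair neither homologous nor mitochondrial).
#'
#' @param models a [GeneModelSet-class] from [generateGeneModels()].
#' @param spec the [simSpec()] used to generate `models` (its seed
#'   drives an independent RNG stream for reads).
#' @param minAnchor,minJunctionReads thresholds used to compute the
#'   expected-survivor flag in the fusion-level truth table; defaults
#'   match [callingParams()].
#' @return list with `records` (chimeric data.frame, [readChimeric()]
#'   columns), `readTruth` (read_id, class, fusion), and `fusionTruth`
#'   (gene5, gene3, pos5, pos3, n_reads, n_good_reads, passes, reason).
#' @export
generateChimericReads <- function(models, spec, minAnchor = 15L,
                                  minJunctionReads = 3L) {
  stopifnot(inherits(spec, "SimSpec"))
  seeds <- subSeeds(spec$seed, 4L)
  g <- genes(models)
  gm <- S4Vectors::mcols(g)
  chromOf <- stats::setNames(as.character(GenomicRanges::seqnames(g)),
                             gm$gene_id)
  strandOf <- stats::setNames(as.character(GenomicRanges::strand(g)),
                              gm$gene_id)
  hom <- homologPairs(models)
  homKeys <- unorderedKey(hom$gene_a, hom$gene_b)

  recs <- list(); truth <- list(); fTruth <- list()
  ridCounter <- 0L
  nextIds <- function(n) {
    ids <- sprintf("R%06d", ridCounter + seq_len(n))
    ridCounter <<- ridCounter + n
    ids
  }
  emit <- function(gene5, gene3, pos5, pos3, anchors, class, fusion = "") {
    n <- nrow(anchors)
    ids <- nextIds(n)
    recs[[length(recs) + 1L]] <<- data.frame(
      read_id = ids,
      chrom_a = chromOf[[gene5]], pos_a = pos5, strand_a = strandOf[[gene5]],
      chrom_b = chromOf[[gene3]], pos_b = pos3, strand_b = strandOf[[gene3]],
      junction_type = 0L, anchor_a = anchors[, 1], anchor_b = anchors[, 2],
      stringsAsFactors = FALSE)
    truth[[length(truth) + 1L]] <<- data.frame(
      read_id = ids, class = class, fusion = fusion,
      stringsAsFactors = FALSE)
  }

  withSeed(seeds[3], {
    planted <- spec$plantedFusions
    if (is.null(planted)) planted <- .defaultPlantedPlan(models)
    for (pf in planted) {
      i5 <- .geneInfo(models, pf$gene5)   # errors on absent gene id
      i3 <- .geneInfo(models, pf$gene3)
      pos5 <- if (is.na(pf$breakpoint5))
        .exonBoundary(models, pf$gene5, "donor") else pf$breakpoint5
      pos3 <- if (is.na(pf$breakpoint3))
        .exonBoundary(models, pf$gene3, "acceptor") else pf$breakpoint3
      if (pos5 < i5$start || pos5 > i5$end)
        stop("breakpoint5 outside gene span of ", pf$gene5, call. = FALSE)
      if (pos3 < i3$start || pos3 > i3$end)
        stop("breakpoint3 outside gene span of ", pf$gene3, call. = FALSE)
      fid <- fusionKey(pf$gene5, pf$gene3)
      if (pf$nJunctionReads > 0L)
        emit(pf$gene5, pf$gene3, pos5, pos3, pf$anchorLengths,
             class = "planted", fusion = fid)
      nGood <- sum(pf$anchorLengths[, 1] >= minAnchor &
                   pf$anchorLengths[, 2] >= minAnchor)
      isHom <- unorderedKey(pf$gene5, pf$gene3) %in% homKeys
      isMito <- chromOf[[pf$gene5]] == mitoChrom(models) ||
                chromOf[[pf$gene3]] == mitoChrom(models)
      passes <- nGood >= minJunctionReads && !isHom && !isMito
      reason <- if (passes) "passes"
                else if (isHom) "homolog"
                else if (isMito) "mito"
                else if (nGood < minJunctionReads &&
                         pf$nJunctionReads >= minJunctionReads) "short_anchor"
                else "low_support"
      fTruth[[length(fTruth) + 1L]] <- data.frame(
        gene5 = pf$gene5, gene3 = pf$gene3, pos5 = pos5, pos3 = pos3,
        n_reads = pf$nJunctionReads, n_good_reads = nGood,
        passes = passes, reason = reason, stringsAsFactors = FALSE)
    }
  })

  withSeed(seeds[4], {
    plantedGenes <- unique(unlist(lapply(fTruth, function(x)
      c(x$gene5, x$gene3))))
    chrom <- as.character(GenomicRanges::seqnames(g))
    homGenes <- unique(c(hom$gene_a, hom$gene_b))
    freePool <- setdiff(gm$gene_id[chrom != "chrM"],
                        c(plantedGenes, homGenes))
    freePool <- sample(freePool)
    poolAt <- 0L
    takePair <- function() {
      poolAt <<- poolAt + 2L
      if (poolAt > length(freePool))
        stop("not enough free genes for noise generation; increase ",
             "genesPerChromosome", call. = FALSE)
      freePool[c(poolAt - 1L, poolAt)]
    }
    goodAnchors <- function(n)
      matrix(sample(15:40, 2 * n, replace = TRUE), ncol = 2)

    ## short-anchor chimeras: groups of >= 3 records, every record one
    ## short anchor, so the class isolates the anchor filter
    left <- spec$noise$nShortAnchor
    while (left > 0L) {
      n <- min(left, sample(3:5, 1L)); left <- left - n
      pr <- takePair()
      anch <- goodAnchors(n)
      anch[, sample(1:2, 1L)] <- sample(5:14, n, replace = TRUE)
      emit(pr[1], pr[2],
           .exonBoundary(models, pr[1], "donor"),
           .exonBoundary(models, pr[2], "acceptor"),
           anch, class = "short_anchor")
    }
    ## low-support chimeras: 1-2 well-anchored records per gene pair
    left <- spec$noise$nLowSupport
    while (left > 0L) {
      n <- min(left, sample(1:2, 1L)); left <- left - n
      pr <- takePair()
      emit(pr[1], pr[2],
           .exonBoundary(models, pr[1], "donor"),
           .exonBoundary(models, pr[2], "acceptor"),
           goodAnchors(n), class = "low_support")
    }
    ## homologous-pair chimeras: well supported, well anchored, doomed
    ## by the homolog list alone
    left <- spec$noise$nHomolog
    hi <- 0L
    while (left > 0L) {
      n <- min(left, sample(3:5, 1L)); left <- left - n
      hi <- hi %% nrow(hom) + 1L
      emit(hom$gene_a[hi], hom$gene_b[hi],
           .exonBoundary(models, hom$gene_a[hi], "donor"),
           .exonBoundary(models, hom$gene_b[hi], "acceptor"),
           goodAnchors(n), class = "homolog")
    }
    ## mitochondrial chimeras: chrM gene joined to a nuclear gene
    mitoGenes <- gm$gene_id[chrom == "chrM"]
    left <- spec$noise$nMito
    while (left > 0L) {
      n <- min(left, sample(3:4, 1L)); left <- left - n
      mg <- sample(mitoGenes, 1L)
      pr <- takePair()
      emit(mg, pr[1],
           .exonBoundary(models, mg, "donor"),
           .exonBoundary(models, pr[1], "acceptor"),
           goodAnchors(n), class = "mito")
    }
    ## intergenic background: loci in the gaps between genes
    nBg <- spec$noise$nBackground
    if (nBg > 0L) {
      gapPos <- function(k) {
        gi <- sample(which(chrom != "chrM"), k, replace = TRUE)
        ## gene layout leaves >= 5 kb before each gene start
        list(chrom = chrom[gi],
             pos = GenomicRanges::start(g)[gi] -
                   sample(500:4500, k, replace = TRUE))
      }
      a <- gapPos(nBg); b <- gapPos(nBg)
      ids <- nextIds(nBg)
      recs[[length(recs) + 1L]] <- data.frame(
        read_id = ids, chrom_a = a$chrom, pos_a = a$pos,
        strand_a = sample(c("+", "-"), nBg, replace = TRUE),
        chrom_b = b$chrom, pos_b = b$pos,
        strand_b = sample(c("+", "-"), nBg, replace = TRUE),
        junction_type = 0L,
        anchor_a = sample(15:40, nBg, replace = TRUE),
        anchor_b = sample(15:40, nBg, replace = TRUE),
        stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <- data.frame(
        read_id = ids, class = "background", fusion = "",
        stringsAsFactors = FALSE)
    }
  })

  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  readTruth <- do.call(rbind, truth)
  rownames(readTruth) <- NULL
  fusionTruth <- do.call(rbind, fTruth)
  rownames(fusionTruth) <- NULL
  list(records = records, readTruth = readTruth, fusionTruth = fusionTruth)
}
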