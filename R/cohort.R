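## Multi-sample cohort call-table generator with known recurrence truth.
##
## The default plan emulates a two-patient, seven-sample discovery
## design (patient P1: normal + primary + metastasis + portal-vein
## thrombus; patient P2: normal + left + right lobe) validated against
## 79 external samples (62 tumor / 17 normal), with 2354 distinct
## fusions: 20 shared by at least two discovery samples (15 of them
## also seen in validation) and 2334 discovery singletons (23 seen in
## validation).  Under the recurrence rule that yields 43 recurrent
## fusions, partitioned 18 tumor-only / 12 normal-only / 13 both by
## supporting tissue.  Multi-discovery sharing is within-patient only,
## so clustering discovery samples on shared fusions separates the two
## patients.

#' Cohort simulation specification
#'
#' @param seed master RNG seed.
#' @param nValidationTumor,nValidationNormal validation cohort
#'   composition.
#' @param nMultiDiscovery fusions planted in >= 2 discovery samples.
#' @param nMultiWithValidation how many of those also get validation
#'   support.
#' @param nSingleton fusions planted in exactly one discovery sample.
#' @param nSingletonWithValidation how many singletons also get
#'   validation support (these become recurrent under the rule).
#' @param tissueMulti named counts over tumor_only/both for the
#'   multi-discovery fusions (each patient has a single normal sample,
#'   so a within-patient multi fusion cannot be normal-only).
#' @param tissueSingletonVal named counts over
#'   tumor_only/normal_only/both for the validation-supported
#'   singletons.
#' @param pInter probability that a fusion's partner genes sit on
#'   different chromosomes (the inter-chromosomal fraction).
#' @param pCoding probability that a fusion joins two protein-coding
#'   genes.
#' @return validated list of class `CohortSpec`.
#' @export
cohortSpec <- function(seed = 1L,
                       nValidationTumor = 62L, nValidationNormal = 17L,
                       nMultiDiscovery = 20L, nMultiWithValidation = 15L,
                       nSingleton = 2334L, nSingletonWithValidation = 23L,
                       tissueMulti = c(tumor_only = 10L, both = 10L),
                       tissueSingletonVal = c(normal_only = 12L,
                                              tumor_only = 8L, both = 3L),
                       pInter = 0.85, pCoding = 0.85) {
  if (nMultiWithValidation > nMultiDiscovery)
    stop("nMultiWithValidation cannot exceed nMultiDiscovery", call. = FALSE)
  if (nSingletonWithValidation > nSingleton)
    stop("nSingletonWithValidation cannot exceed nSingleton", call. = FALSE)
  if (sum(tissueMulti) != nMultiDiscovery)
    stop("tissueMulti must sum to nMultiDiscovery", call. = FALSE)
  if (sum(tissueSingletonVal) != nSingletonWithValidation)
    stop("tissueSingletonVal must sum to nSingletonWithValidation",
         call. = FALSE)
  if (any(c(nValidationTumor, nValidationNormal) < 0))
    stop("validation counts must be >= 0", call. = FALSE)
  x <- list(seed = as.integer(seed),
            nValidationTumor = as.integer(nValidationTumor),
            nValidationNormal = as.integer(nValidationNormal),
            nMultiDiscovery = as.integer(nMultiDiscovery),
            nMultiWithValidation = as.integer(nMultiWithValidation),
            nSingleton = as.integer(nSingleton),
            nSingletonWithValidation = as.integer(nSingletonWithValidation),
            tissueMulti = tissueMulti, tissueSingletonVal = tissueSingletonVal,
            pInter = pInter, pCoding = pCoding)
  class(x) <- "CohortSpec"
  x
}

.discoveryMeta <- function() {
  data.frame(
    sample_id  = c("P1-N", "P1-P", "P1-M", "P1-V", "P2-N", "P2-L", "P2-R"),
    patient_id = c(rep("P1", 4), rep("P2", 3)),
    tissue     = c("normal", "tumor", "tumor", "tumor",
                   "normal", "tumor", "tumor"),
    cohort     = "discovery",
    stringsAsFactors = FALSE)
}

#' Generate a synthetic cohort call set with recurrence ground truth
#'
#' Builds the sample metadata, invents one gene pair per planned
#' fusion (with chromosome placement controlling the inter/intra mix
#' and biotypes controlling the fusion-type mix), assigns each fusion
#' its planned discovery/validation supporting samples, and emits the
#' per-sample call table.  Every fusion keeps one fixed breakpoint pair
#' across samples (splice-mediated junctions recur at the identical
#' coordinate).
#'
#' @param spec a [cohortSpec()].
#' @return list with `cohort` (a [CohortCallSet-class]), `truth`
#'   (per-fusion data.frame: gene5, gene3, label, tissue_class,
#'   n_discovery, n_validation) and `genes` (gene_id, chrom, biotype,
#'   usable with [classifyFusionType()]).
#' @export
generateCohort <- function(spec = cohortSpec()) {
  stopifnot(inherits(spec, "CohortSpec"))
  seeds <- subSeeds(spec$seed, 2L)
  disc <- .discoveryMeta()
  nVal <- spec$nValidationTumor + spec$nValidationNormal
  val <- if (nVal > 0) data.frame(
    sample_id = sprintf("V%03d", seq_len(nVal)),
    patient_id = sprintf("VP%03d", seq_len(nVal)),
    tissue = c(rep("tumor", spec$nValidationTumor),
               rep("normal", spec$nValidationNormal)),
    cohort = "validation", stringsAsFactors = FALSE)
  else disc[0, ]
  meta <- rbind(disc, val)

  nFus <- spec$nMultiDiscovery + spec$nSingleton
  withSeed(seeds[1], {
    ## per-fusion genes, chromosomes, biotypes and breakpoints
    gene5 <- sprintf("FG%04dA", seq_len(nFus))
    gene3 <- sprintf("FG%04dB", seq_len(nFus))
    chr5 <- sample(paste0("chr", 1:22), nFus, replace = TRUE)
    inter <- stats::runif(nFus) < spec$pInter
    chr3 <- ifelse(inter,
                   sample(paste0("chr", 1:22), nFus, replace = TRUE), chr5)
    ## resample collisions so "inter" fusions really change chromosome
    while (any(bad <- inter & chr3 == chr5))
      chr3[bad] <- sample(paste0("chr", 1:22), sum(bad), replace = TRUE)
    coding <- stats::runif(nFus) < spec$pCoding
    other <- c("lncRNA", "pseudogene", "other")
    bio5 <- ifelse(coding, "protein_coding",
                   sample(other, nFus, replace = TRUE))
    bio3 <- ifelse(coding, "protein_coding",
                   sample(other, nFus, replace = TRUE))
    pos5 <- sample.int(2e8, nFus); pos3 <- sample.int(2e8, nFus)
  })

  geneTab <- data.frame(
    gene_id = c(gene5, gene3), chrom = c(chr5, chr3),
    biotype = c(bio5, bio3), stringsAsFactors = FALSE)

  discTumor <- base::split(disc$sample_id[disc$tissue == "tumor"],
                           disc$patient_id[disc$tissue == "tumor"])
  discNormal <- stats::setNames(disc$sample_id[disc$tissue == "normal"],
                                disc$patient_id[disc$tissue == "normal"])
  valTumor <- val$sample_id[val$tissue == "tumor"]
  valNormal <- val$sample_id[val$tissue == "normal"]

  withSeed(seeds[2], {
    support <- vector("list", nFus)
    tclass <- character(nFus)
    label <- character(nFus)

    ## multi-discovery fusions: within-patient sample sets.  Class
    ## quotas are split as evenly as possible across patients, and
    ## tumor subsets rotate so every discovery sample is covered by at
    ## least one shared fusion (both-class fusions carry the patient's
    ## normal).  normal_only multi fusions, if requested, take every
    ## discovery normal (each patient has exactly one).
    patients <- names(discTumor)
    quotas <- spec$tissueMulti
    nNormOnly <- if ("normal_only" %in% names(quotas))
      quotas[["normal_only"]] else 0L
    perPatient <- quotas[setdiff(names(quotas), "normal_only")]
    i <- 0L
    for (pi in seq_along(patients)) {
      pat <- patients[pi]
      tum <- discTumor[[pat]]
      rot <- 0L
      for (cls in names(perPatient)) {
        m <- perPatient[[cls]]
        mine <- m %/% length(patients) +
          as.integer(pi <= m %% length(patients))
        for (r in seq_len(mine)) {
          i <- i + 1L
          k <- sample(seq_along(tum), 1L)
          if (cls == "tumor_only") k <- max(k, 2L)
          s <- tum[((rot + 0:(k - 1L)) %% length(tum)) + 1L]
          rot <- rot + 1L
          if (cls == "both") s <- c(discNormal[[pat]], s)
          support[[i]] <- s
          tclass[i] <- cls
          label[i] <- "recurrent"
        }
      }
    }
    for (r in seq_len(nNormOnly)) {
      i <- i + 1L
      support[[i]] <- unname(discNormal)
      tclass[i] <- "normal_only"
      label[i] <- "recurrent"
    }
    ## attach validation echoes to the first nMultiWithValidation
    for (i in seq_len(spec$nMultiWithValidation)) {
      cls <- tclass[i]
      vpool <- switch(cls, tumor_only = valTumor, both = val$sample_id,
                      normal_only = valNormal)
      if (length(vpool))
        support[[i]] <- c(support[[i]],
                          sample(vpool, min(length(vpool),
                                            sample(1:3, 1L))))
    }

    ## singleton fusions with validation support (recurrent via rule)
    svClasses <- sample(rep(names(spec$tissueSingletonVal),
                            spec$tissueSingletonVal))
    for (j in seq_len(spec$nSingletonWithValidation)) {
      i <- spec$nMultiDiscovery + j
      cls <- svClasses[j]
      if (cls == "normal_only") {
        dS <- sample(unname(discNormal), 1L)
        vS <- sample(valNormal, sample(1:2, 1L))
      } else if (cls == "tumor_only") {
        dS <- sample(unlist(discTumor), 1L)
        vS <- sample(valTumor, sample(1:2, 1L))
      } else {   # both: one discovery tissue + the other via validation
        dS <- sample(unlist(discTumor), 1L)
        vS <- sample(valNormal, 1L)
      }
      support[[i]] <- c(dS, vS)
      tclass[i] <- cls
      label[i] <- "recurrent"
    }

    ## pure singletons: one discovery sample, no validation echo
    nPure <- spec$nSingleton - spec$nSingletonWithValidation
    pureSamples <- sample(disc$sample_id, nPure, replace = TRUE)
    for (j in seq_len(nPure)) {
      i <- spec$nMultiDiscovery + spec$nSingletonWithValidation + j
      support[[i]] <- pureSamples[j]
      tclass[i] <- if (disc$tissue[match(pureSamples[j], disc$sample_id)] ==
                       "normal") "normal_only" else "tumor_only"
      label[i] <- "singleton"
    }

    jr <- lapply(lengths(support), function(k) sample(3:30, k, replace = TRUE))
  })

  calls <- data.frame(
    gene5 = rep(gene5, lengths(support)),
    gene3 = rep(gene3, lengths(support)),
    chrom5 = rep(chr5, lengths(support)),
    pos5 = rep(pos5, lengths(support)),
    chrom3 = rep(chr3, lengths(support)),
    pos3 = rep(pos3, lengths(support)),
    junction_reads = unlist(jr),
    sample_id = unlist(support),
    stringsAsFactors = FALSE)
  truth <- data.frame(
    gene5 = gene5, gene3 = gene3, label = label, tissue_class = tclass,
    n_discovery = vapply(support, function(s)
      sum(s %in% disc$sample_id), integer(1)),
    n_validation = vapply(support, function(s)
      sum(s %in% val$sample_id), integer(1)),
    stringsAsFactors = FALSE)
  list(cohort = CohortCallSet(calls, meta), truth = truth, genes = geneTab)
}
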