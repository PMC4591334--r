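# Default emulation targets for the synthetic cohort: twenty loci planted at
# the case/control ratios and control-group mean levels (counts per million
# mappable reads) typical of a plasma-exosome AD screening cohort. Means span
# ~0.7 to ~5000 CPM.
.defaultPlantedRatios <- c(
  "miR-185-5p" = 0.546, "miR-342-3p" = 0.621, "miR-141-3p" = 0.577,
  "miR-548at-5p" = 3.238, "miR-342-5p" = 0.702, "miR-4772-3p" = 0.496,
  "miR-23b-3p" = 0.754, "miR-138-5p" = 1.177, "miR-24-3p" = 0.639,
  "miR-29b-3p" = 0.682, "miR-3916" = 0.244, "miR-125b-5p" = 0.732,
  "miR-338-3p" = 0.652, "miR-3065-5p" = 0.687, "miR-139-5p" = 0.594,
  "miR-152-3p" = 0.651, "miR-150-5p" = 0.750, "miR-5001-3p" = 2.954,
  "miR-659-5p" = 2.939, "miR-3613-3p" = 0.406
)

.defaultPlantedMeans <- c(
  "miR-185-5p" = 44.08, "miR-342-3p" = 547.94, "miR-141-3p" = 96.00,
  "miR-548at-5p" = 0.73, "miR-342-5p" = 196.86, "miR-4772-3p" = 10.96,
  "miR-23b-3p" = 378.79, "miR-138-5p" = 12.42, "miR-24-3p" = 33.89,
  "miR-29b-3p" = 51.61, "miR-3916" = 5.21, "miR-125b-5p" = 147.98,
  "miR-338-3p" = 41.49, "miR-3065-5p" = 72.52, "miR-139-5p" = 61.22,
  "miR-152-3p" = 76.97, "miR-150-5p" = 5076.62, "miR-5001-3p" = 1.56,
  "miR-659-5p" = 1.74, "miR-3613-3p" = 2.16
)

# Co-expression cliques are observed among well-measured loci, so default
# module members get fixed moderate-to-high baseline levels (20-500 CPM);
# heavy zero-inflation at low counts would otherwise attenuate the planted
# rank correlations.
.defaultModuleMeans <- setNames(
  round(exp(seq(log(20), log(500), length.out = 33)), 2),
  sprintf("miR-sim-%03d", 1:33))

.defaultModules <- function() list(
  list(loci = sprintf("miR-sim-%03d", 1:25),  group = "both",    loading = 0.9),
  list(loci = sprintf("miR-sim-%03d", 26:29), group = "AD",      loading = 0.9),
  list(loci = sprintf("miR-sim-%03d", 30:33), group = "control", loading = 0.9)
)

#' Configuration of the synthetic cohort generator
#'
#' Holds every parameter of [simulateCohort()]. The defaults describe the
#' study conditions the package is designed around: 35 samples per group,
#' 465 mature miRNA loci with log-normally distributed baseline levels on the
#' counts-per-million scale, negative-binomial counts (size 10), twenty loci
#' planted at case/control ratios between 0.24 and 3.2, three planted
#' correlated modules (a 25-locus clique present in both groups and two
#' 4-locus single-group cliques), an exogenous spike-in locus and a stable
#' abundant endogenous reference locus, and 30% technical-replicate noise.
#'
#' @slot nPerGroup samples per diagnostic group.
#' @slot nLoci total number of miRNA loci (planted + spike + reference +
#'   background).
#' @slot locusMeanMedian,locusMeanLogSD log-normal law for background locus
#'   means, on the CPM scale.
#' @slot dispersion negative-binomial size parameter of biological loci.
#' @slot spikeDispersion size parameter of the spike-in and reference loci
#'   (larger = less overdispersed, as expected for a pipetted spike).
#' @slot plantedDe named AD/control ratios of differentially expressed loci.
#' @slot plantedMeans named fixed control-group CPM means (loci not listed
#'   draw their mean from the log-normal law).
#' @slot plantedModules list of `list(loci=, group=, loading=)`; `loading` is
#'   the latent pairwise correlation shared by module members within the
#'   target group(s) (Gaussian copula over the NB marginals).
#' @slot sequencesPerLocus isomiR variants per locus; loci with baseline mean
#'   below `singleVariantBelow` CPM express a single variant.
#' @slot singleVariantBelow CPM threshold below which a locus has one variant.
#' @slot mappableMedian,mappableLogSD log-normal law of per-sample
#'   genome-mappable read totals.
#' @slot spikeLocusId,spikeMean,referenceLocusId,referenceMean spike-in and
#'   endogenous reference loci (group-independent means).
#' @slot replicateCv coefficient of variation of technical-replicate noise.
#' @slot seed integer seed; identical config + seed gives bit-identical
#'   output.
#' @seealso [simulateCohort()]
#' @export
setClass("SimConfig", slots = c(
  nPerGroup = "integer", nLoci = "integer",
  locusMeanMedian = "numeric", locusMeanLogSD = "numeric",
  dispersion = "numeric", spikeDispersion = "numeric",
  plantedDe = "numeric", plantedMeans = "numeric", plantedModules = "list",
  sequencesPerLocus = "integer", singleVariantBelow = "numeric",
  mappableMedian = "numeric", mappableLogSD = "numeric",
  spikeLocusId = "character", spikeMean = "numeric",
  referenceLocusId = "character", referenceMean = "numeric",
  replicateCv = "numeric", seed = "integer"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nPerGroup < 2L) msg <- c(msg, "nPerGroup must be >= 2")
  if (length(object@plantedDe) && any(object@plantedDe <= 0))
    msg <- c(msg, "all planted ratios must be > 0")
  if (is.null(names(object@plantedDe)) && length(object@plantedDe))
    msg <- c(msg, "plantedDe must be named by locus")
  if (object@replicateCv < 0) msg <- c(msg, "replicateCv must be >= 0")
  if (object@sequencesPerLocus < 1L)
    msg <- c(msg, "sequencesPerLocus must be >= 1")
  if (object@locusMeanMedian <= 0 || object@locusMeanLogSD < 0 ||
      object@mappableMedian <= 0 || object@mappableLogSD < 0)
    msg <- c(msg, "invalid log-normal law parameters")
  if (object@dispersion <= 0 || object@spikeDispersion <= 0)
    msg <- c(msg, "dispersion (NB size) must be > 0")
  for (m in object@plantedModules) {
    if (!all(c("loci", "group", "loading") %in% names(m)) ||
        !m$group %in% c("AD", "control", "both") ||
        m$loading < 0 || m$loading > 1)
      msg <- c(msg, "modules need loci, group in {AD, control, both}, loading in [0,1]")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname SimConfig-class
#' @param nPerGroup,nLoci,locusMeanMedian,locusMeanLogSD,dispersion,spikeDispersion,plantedDe,plantedMeans,plantedModules,sequencesPerLocus,singleVariantBelow,mappableMedian,mappableLogSD,spikeLocusId,spikeMean,referenceLocusId,referenceMean,replicateCv,seed
#'   see the corresponding slots.
#' @return a validated `SimConfig`.
#' @examples
#' cfg <- simConfig(nPerGroup = 5L, nLoci = 40L, seed = 7L)
#' @export
simConfig <- function(nPerGroup = 35L, nLoci = 465L,
                      locusMeanMedian = 10, locusMeanLogSD = 2,
                      dispersion = 10, spikeDispersion = 50,
                      plantedDe = .defaultPlantedRatios,
                      plantedMeans = c(.defaultPlantedMeans,
                                       .defaultModuleMeans),
                      plantedModules = .defaultModules(),
                      sequencesPerLocus = 3L, singleVariantBelow = 10,
                      mappableMedian = 5e6, mappableLogSD = 0.4,
                      spikeLocusId = "ath-miR-159a", spikeMean = 800,
                      referenceLocusId = "hsa-miR-486-5p",
                      referenceMean = 2000,
                      replicateCv = 0.30, seed = 1L) {
  new("SimConfig",
      nPerGroup = as.integer(nPerGroup), nLoci = as.integer(nLoci),
      locusMeanMedian = locusMeanMedian, locusMeanLogSD = locusMeanLogSD,
      dispersion = dispersion, spikeDispersion = spikeDispersion,
      plantedDe = plantedDe, plantedMeans = plantedMeans,
      plantedModules = plantedModules,
      sequencesPerLocus = as.integer(sequencesPerLocus),
      singleVariantBelow = singleVariantBelow,
      mappableMedian = mappableMedian, mappableLogSD = mappableLogSD,
      spikeLocusId = spikeLocusId, spikeMean = spikeMean,
      referenceLocusId = referenceLocusId, referenceMean = referenceMean,
      replicateCv = replicateCv, seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", 2L * object@nPerGroup, "samples (",
      object@nPerGroup, "per group ),", object@nLoci, "loci,",
      length(object@plantedDe), "planted DE loci,",
      length(object@plantedModules), "modules, seed", object@seed, "\n")
})

#' Simulate a case/control small-RNA sequencing cohort
#'
#' Draws a sequence-level raw count table with the statistical structure the
#' downstream analysis assumes. Per locus, counts are negative binomial with
#' expectation `baselineCPM * ratio[group] * mappableReads / 1e6`, so the
#' control-group expected CPM equals the drawn locus mean and library-size
#' effects are present before normalization. Correlated modules are planted
#' through a Gaussian copula: module members share a latent factor inside the
#' target group(s) (pairwise latent correlation = `loading`), which induces
#' positive Spearman correlation while preserving the NB marginals. The locus
#' count is then split multinomially over isomiR sequence variants with
#' locus-specific variant proportions, exercising the locus-summation step.
#'
#' @param config a [SimConfig-class].
#' @return `list(counts = MirCountSet, truth = SimTruth)`. Sample metadata
#'   (group, sex, age, prep batch, mappable reads) is in
#'   `colData(counts)`.
#' @examples
#' sim <- simulateCohort(simConfig(nPerGroup = 4L, nLoci = 30L, seed = 3L))
#' sim$counts
#' @export
simulateCohort <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  set.seed(config@seed)
  nG <- config@nPerGroup
  n <- 2L * nG

  special <- unique(c(names(config@plantedDe), names(config@plantedMeans),
                      config@spikeLocusId, config@referenceLocusId))
  nBack <- config@nLoci - length(special)
  if (nBack < 0L)
    stop("nLoci smaller than the number of planted/special loci")
  backNames <- if (nBack > 0L) {
    cand <- sprintf("miR-sim-%03d", seq_len(nBack + length(special)))
    setdiff(cand, special)[seq_len(nBack)]
  } else character()
  loci <- c(special, backNames)

  modLoci <- unlist(lapply(config@plantedModules, `[[`, "loci"))
  if (!all(modLoci %in% loci))
    stop("planted module loci are not a subset of the simulated loci")

  # baseline control-group means on the CPM scale
  baseMean <- setNames(rep(NA_real_, length(loci)), loci)
  baseMean[names(config@plantedMeans)] <- config@plantedMeans
  baseMean[config@spikeLocusId] <- config@spikeMean
  baseMean[config@referenceLocusId] <- config@referenceMean
  free <- names(baseMean)[is.na(baseMean)]
  baseMean[free] <- rlnorm(length(free), meanlog = log(config@locusMeanMedian),
                           sdlog = config@locusMeanLogSD)

  ratio <- setNames(rep(1, length(loci)), loci)
  ratio[names(config@plantedDe)] <- config@plantedDe

  # sample metadata: sex/age matched pairs, two balanced prep batches
  group <- factor(rep(c("AD", "control"), each = nG),
                  levels = c("AD", "control"))
  ids <- c(sprintf("AD%02d", seq_len(nG)), sprintf("C%02d", seq_len(nG)))
  sex <- rep(rep_len(c("F", "M"), nG), 2L)
  age <- rep(sample(50:75, nG, replace = TRUE), 2L)
  batch <- rep(rep_len(c("B1", "B2"), nG), 2L)
  mappable <- round(rlnorm(n, meanlog = log(config@mappableMedian),
                           sdlog = config@mappableLogSD))

  # latent Gaussian field; overwrite module members with shared-factor mix
  factors <- lapply(config@plantedModules, function(m) rnorm(n))
  z <- matrix(rnorm(length(loci) * n), nrow = length(loci),
              dimnames = list(loci, ids))
  for (k in seq_along(config@plantedModules)) {
    m <- config@plantedModules[[k]]
    sel <- if (m$group == "both") rep(TRUE, n) else group == m$group
    lam <- m$loading
    z[m$loci, sel] <- sqrt(lam) * rep(factors[[k]][sel],
                                      each = length(m$loci)) +
      sqrt(1 - lam) * z[m$loci, sel]
  }

  sizes <- rep(config@dispersion, length(loci))
  sizes[match(c(config@spikeLocusId, config@referenceLocusId), loci)] <-
    config@spikeDispersion
  mu <- outer(baseMean, mappable / 1e6)
  mu[, group == "AD"] <- mu[, group == "AD"] * ratio
  locusCounts <- matrix(qnbinom(pnorm(z), size = sizes, mu = mu),
                        nrow = length(loci), dimnames = list(loci, ids))

  # split locus counts into isomiR variants (fixed per-locus proportions)
  nv <- ifelse(baseMean < config@singleVariantBelow, 1L,
               config@sequencesPerLocus)
  props <- lapply(seq_along(loci), function(i) {
    if (nv[i] == 1L) return(1)
    g <- rgamma(nv[i], shape = 2)
    g / sum(g)
  })
  seqRows <- vector("list", length(loci))
  for (i in seq_along(loci)) {
    tot <- locusCounts[i, ]
    p <- props[[i]]
    v <- matrix(0L, nrow = nv[i], ncol = n)
    remaining <- tot
    pleft <- 1
    if (nv[i] > 1L) {
      for (k in seq_len(nv[i] - 1L)) {
        v[k, ] <- rbinom(n, size = remaining, prob = min(1, p[k] / pleft))
        remaining <- remaining - v[k, ]
        pleft <- pleft - p[k]
      }
    }
    v[nv[i], ] <- remaining
    rownames(v) <- paste0(loci[i], "_v", seq_len(nv[i]))
    seqRows[[i]] <- v
  }
  counts <- do.call(rbind, seqRows)
  storage.mode(counts) <- "integer"
  colnames(counts) <- ids
  locusOf <- rep(loci, nv)

  # plausible mature-miRNA-length nucleotide strings for each variant
  seqLen <- sample(18:24, nrow(counts), replace = TRUE)
  nt <- vapply(seqLen, function(L)
    paste(sample(c("A", "C", "G", "U"), L, replace = TRUE), collapse = ""),
    character(1))

  cd <- DataFrame(sample_id = ids, group = group, sex = sex, age = age,
                  prep_batch = batch, mappable_reads = mappable,
                  row.names = ids)
  cs <- MirCountSet(counts, sampleData = cd, locus = locusOf)
  rowData(cs)$sequence <- nt
  metadata(cs)$simSeed <- config@seed

  truth <- new("SimTruth", deRatios = config@plantedDe,
               modules = config@plantedModules,
               informative = as.character(names(config@plantedDe)),
               spike = config@spikeLocusId)
  list(counts = cs, truth = truth)
}

#' Simulate a technical replicate of a count table
#'
#' Resamples every count with multiplicative log-normal noise of the given
#' coefficient of variation (mean 1, so zero counts stay zero and expectation
#' is preserved), then rounds to integers — emulating a re-sequencing run of
#' the same RNA samples.
#'
#' @param x a raw-count `MirCountSet` or a non-negative count matrix.
#' @param replicateCv coefficient of variation of the noise factor
#'   (default 0.30).
#' @param seed integer seed.
#' @return an object of the same kind as `x` with perturbed counts.
#' @examples
#' m <- matrix(1000L, 2, 4, dimnames = list(c("a", "b"), paste0("s", 1:4)))
#' simulateTechnicalReplicate(m, 0.3, seed = 1)
#' @export
simulateTechnicalReplicate <- function(x, replicateCv = 0.30, seed = 1L) {
  if (replicateCv < 0) stop("replicateCv must be >= 0")
  m <- if (is(x, "MirCountSet")) assay(x, "counts") else as.matrix(x)
  if (any(m < 0)) stop("counts must be non-negative")
  if (replicateCv == 0) {
    out <- round(m)
  } else {
    set.seed(as.integer(seed))
    s2 <- log(1 + replicateCv^2)
    f <- matrix(rlnorm(length(m), meanlog = -s2 / 2, sdlog = sqrt(s2)),
                nrow = nrow(m))
    out <- round(m * f)
  }
  storage.mode(out) <- "integer"
  if (is(x, "MirCountSet")) {
    y <- x
    assay(y, "counts") <- out
    validObject(y)
    y
  } else out
}

#' Agreement between a count table and its technical replicate
#'
#' For every row whose original mean is at least `minMean`, summarizes the
#' per-cell relative differences `(replicate - original) / original` over
#' cells with a positive original count. The root-mean-square column is the
#' 1-sd relative difference ("plus or minus X percent" scatter); the
#' mean-absolute column is reported alongside.
#'
#' @param x,replicate matching count tables (`MirCountSet` or matrix).
#' @param minMean only rows with original mean >= `minMean` are summarized.
#' @return `data.frame(id, mean, rmsRelDiff, meanAbsRelDiff)` with one row per
#'   retained locus/sequence.
#' @export
replicateAgreement <- function(x, replicate, minMean = 50) {
  a <- if (is(x, "MirCountSet")) assay(x, "counts") else as.matrix(x)
  b <- if (is(replicate, "MirCountSet")) assay(replicate, "counts")
       else as.matrix(replicate)
  if (!identical(dim(a), dim(b))) stop("tables must have identical shape")
  keep <- rowMeans(a) >= minMean
  a <- a[keep, , drop = FALSE]; b <- b[keep, , drop = FALSE]
  rel <- (b - a) / a
  rel[a == 0] <- NA
  data.frame(
    id = rownames(a),
    mean = rowMeans(a),
    rmsRelDiff = sqrt(rowMeans(rel^2, na.rm = TRUE)),
    meanAbsRelDiff = rowMeans(abs(rel), na.rm = TRUE),
    row.names = NULL
  )
}
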