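# Small simulated cohorts reused across tests (kept modest so the default
# suite stays fast). Built in code; no fixture files.

smallConfig <- function(seed = 1L, nPerGroup = 10L, nLoci = 60L, ...) {
  simConfig(
    nPerGroup = nPerGroup, nLoci = nLoci,
    plantedDe = c("miR-de-1" = 0.5, "miR-de-2" = 2.0),
    plantedMeans = c("miR-de-1" = 200, "miR-de-2" = 150),
    plantedModules = list(
      list(loci = sprintf("miR-sim-%03d", 1:5), group = "AD", loading = 0.8)
    ),
    seed = seed, ...)
}

smallCohort <- function(seed = 1L, ...) simulateCohort(smallConfig(seed, ...))

# toy locus-level MirCountSet from an explicit matrix
toyLocusSet <- function(m, groups, normalization = "cpm_mappable") {
  cd <- data.frame(sample_id = colnames(m), group = groups,
                   mappable_reads = rep(1e6, ncol(m)))
  MirCountSet(m, sampleData = cd, locus = rownames(m),
              normalization = normalization, level = "locus")
}
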