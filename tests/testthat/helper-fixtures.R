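# Shared fixtures: everything is generated in code at test time.

# Small study used by several suites: ~120 phenotyped animals, genotypes.
tinyStudy <- function(seed = 11L, ...) {
  simulateStudy(tinyConfig(seed = seed, ...))
}

tinyConfig <- function(seed = 11L, ...) {
  args <- list(nFounders = 24L, littersPerGeneration = 10L,
               progenyPerLitter = 6L, nGenerations = 2L,
               batchesPerGeneration = 5L, nSnps = 80L, nChr = 4L,
               nGenotyped = 50L, hsFractionTarget = 0.4, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(simConfig, args)
}

# Weather series with an exactly prescribed daily THI (rh = 100 makes the
# humidity bracket vanish, so tmax = (thi - 32)/1.8 gives THI exactly).
weatherWithThi <- function(thiValues, farm = 1L,
                           start = as.Date("2012-01-01")) {
  data.frame(farm = farm,
             date = start + seq_along(thiValues) - 1L,
             tmax_c = (thiValues - 32) / 1.8,
             rhmin_pct = 100)
}

# Founder-only pedigree (unrelated animals).
founderPedigree <- function(n) pedigree(seq_len(n), rep(0L, n), rep(0L, n))

# The published variance components of the two carcass-weight traits (kg^2),
# genetic correlation 0.63.
publishedVC <- function() {
  varianceComponents(c("HS", "NHS"),
    varA = matrix(c(84.697, 0.63 * sqrt(84.697 * 60.173),
                    0.63 * sqrt(84.697 * 60.173), 60.173), 2),
    varLitter = c(31.736, 30.791), varE = c(216.69, 210.69))
}

# Configuration of the parameter-recovery experiment: a three-generation
# pedigree of a few thousand animals at the printed variance-component
# truths, with a balanced trait split and repeat matings so the desk-scale
# design carries enough information about both traits (see the methods
# vignette).
recoveryConfig <- function(seed) {
  simConfig(seed = seed, nSnps = 0L, hsFractionTarget = 0.5,
            hsFractionFarm = c(0.5, 0.5),
            progenyPerLitter = 6L, littersPerGeneration = 250L,
            nFounders = 300L, batchesPerGeneration = 15L, ageSd = 6,
            repeatMating = TRUE)
}
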