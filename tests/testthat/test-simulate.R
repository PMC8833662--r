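test_that("minimal pedigree has founders as the child's parents", {
  cfg <- simConfig(nFounders = 2L, nGenerations = 1L,
                   littersPerGeneration = 1L, progenyPerLitter = 1L,
                   batchesPerGeneration = 1L, seed = 3L)
  ped <- simulatePedigree(cfg)
  expect_equal(nAnimals(ped), 3L)
  expect_setequal(c(ped@sire[3], ped@dam[3]), c(1L, 2L))
})

test_that("pedigrees are topologically ordered and seed-deterministic", {
  cfg <- tinyConfig(seed = 21L)
  ped <- simulatePedigree(cfg)
  known <- ped@sire != 0L
  expect_true(all(ped@sire[known] < ped@id[known]))
  known <- ped@dam != 0L
  expect_true(all(ped@dam[known] < ped@id[known]))
  ped2 <- simulatePedigree(tinyConfig(seed = 21L))
  expect_identical(ped, ped2)
  out1 <- simulateStudy(tinyConfig(seed = 22L))
  out2 <- simulateStudy(tinyConfig(seed = 22L))
  expect_identical(out1@phenotypes, out2@phenotypes)
  expect_identical(out1@trueBV, out2@trueBV)
  expect_identical(out1@genotypes@dosages, out2@genotypes@dosages)
})

test_that("gene drop is Mendelian-consistent", {
  out <- tinyStudy(seed = 31L)
  ped <- out@pedigree
  d <- simulateGenotypes(ped, tinyConfig(seed = 31L))@dosages
  s <- match(ped@sire, ped@id); dm <- match(ped@dam, ped@id)
  both <- which(!is.na(s) & !is.na(dm))
  for (i in both) {
    lo <- (d[s[i], ] == 2) + (d[dm[i], ] == 2)
    hi <- 2 - (d[s[i], ] == 0) - (d[dm[i], ] == 0)
    expect_true(all(d[i, ] >= lo & d[i, ] <= hi))
  }
})

test_that("founder allele frequencies respect the configured MAF band", {
  cfg <- simConfig(nFounders = 400L, nGenerations = 1L,
                   littersPerGeneration = 1L, progenyPerLitter = 1L,
                   nSnps = 4000L, nChr = 4L, mafLow = 0.05, mafHigh = 0.5,
                   seed = 9L)
  ped <- simulatePedigree(cfg)
  g <- simulateGenotypes(ped, cfg)
  p <- colMeans(g@dosages[seq_len(400), ]) / 2
  se3 <- 3 * sqrt(0.25 / 800)
  expect_gt(min(p), 0.05 - se3)
  expect_lt(max(p), 0.50 + se3)
  expect_equal(mean(p), 0.275, tolerance = 0.02)
  expect_false(any(vapply(split(g@map$pos, g@map$chr), is.unsorted,
                          logical(1), strictly = TRUE)))
})

test_that("breeding values are independent across traits when the covariance is zero", {
  ped <- founderPedigree(5000)
  cfg <- simConfig(trueCovA = 0, seed = 13L)
  bv <- simulateBreedingValues(ped, cfg = cfg)$bv
  expect_lt(abs(cor(bv[, "HS"], bv[, "NHS"])), 0.05)
})

test_that("Mendelian-sampling variance is half the genetic variance in non-inbred pedigrees", {
  n <- 1500
  ped <- pedigree(1:(3 * n),
                  c(rep(0L, 2 * n), seq_len(n)),
                  c(rep(0L, 2 * n), n + seq_len(n)))
  cfg <- simConfig(seed = 17L)
  bv <- simulateBreedingValues(ped, cfg = cfg)$bv
  kid <- 2 * n + seq_len(n)
  ms <- bv[kid, ] - (bv[seq_len(n), ] + bv[n + seq_len(n), ]) / 2
  expect_equal(var(ms[, "HS"]), 84.697 / 2, tolerance = 0.12)
  expect_equal(var(ms[, "NHS"]), 60.173 / 2, tolerance = 0.12)
})

test_that("realized founder genetic correlation matches the configured 0.63", {
  ped <- founderPedigree(5000)
  bv <- simulateBreedingValues(ped, cfg = simConfig(seed = 19L))$bv
  expect_equal(cor(bv[, "HS"], bv[, "NHS"]), 0.63, tolerance = 0.05)
})

test_that("flat cool weather yields NHS everywhere; hot weather all HS", {
  cfg <- simConfig(tempAmplitude = 0, weatherNoiseSd = 0, rhNoiseSd = 0,
                   rhMean = 50, seed = 23L)
  days <- 0:400
  wCool <- simulateWeather(cfg, days = days, tempMean = c(20, 20))
  expect_true(all(wCool$tmax_c == 20))
  hl <- heatLoad30d(wCool, 1, as.Date("2010-01-01") + 200)
  expect_lt(hl, 78)
  wHot <- simulateWeather(cfg, days = days, tempMean = c(40, 40))
  expect_equal(unique(thi(wHot$tmax_c, wHot$rhmin_pct)), 91.35)
  expect_equal(heatLoad30d(wHot, 2, as.Date("2010-01-01") + 200), 91.35)
})

test_that("default study conditions give roughly the published record structure", {
  out <- simulateStudy(simConfig(seed = 29L, nSnps = 0L))
  ph <- out@phenotypes
  expect_lt(abs(mean(ph$trait == "HS") - 0.144), 0.05)
  # the hotter farm carries the larger share of heat-stress records
  hsByFarm <- tapply(ph$trait == "HS", ph$farm, mean)
  expect_gt(hsByFarm[["1"]], hsByFarm[["2"]])
  # heat-stressed carcasses are lighter on average
  expect_lt(mean(ph$hcw_kg[ph$trait == "HS"]),
            mean(ph$hcw_kg[ph$trait == "NHS"]))
  expect_equal(mean(ph$age_d), 185, tolerance = 0.01)
})

test_that("phenotypes reduce to breeding values when every other component is null", {
  cfg <- tinyConfig(seed = 37L, nSnps = 0L,
                    trueVarLitter = c(0, 0), trueVarE = c(0, 0),
                    cgSd = 0, sexEffect = 0, ageSlope = 0,
                    meanNHS = 0, hsShift = 0)
  out <- simulateStudy(cfg)
  ph <- out@phenotypes
  bv <- out@trueBV[cbind(match(ph$animal, rownames(out@trueBV)),
                         match(ph$trait, c("HS", "NHS")))]
  expect_equal(ph$hcw_kg, bv, tolerance = 1e-10)
})

test_that("the age regression acts linearly with the configured slope", {
  cfg <- tinyConfig(seed = 41L, nSnps = 0L, trueVarA = c(0, 0), trueCovA = 0,
                    trueVarLitter = c(0, 0), trueVarE = c(0, 0),
                    cgSd = 0, sexEffect = 0, ageSlope = 0.5,
                    meanNHS = 0, hsShift = 0)
  out <- simulateStudy(cfg)
  ph <- out@phenotypes
  expect_equal(ph$hcw_kg, 0.5 * (ph$age_d - 185), tolerance = 1e-10)
  # two records differing by 10 d differ by 5 kg
  expect_equal(ph$hcw_kg[1] - ph$hcw_kg[2],
               0.5 * (ph$age_d[1] - ph$age_d[2]))
})

test_that("no animal carries records on both traits", {
  out <- tinyStudy(seed = 43L)
  expect_false(anyDuplicated(out@phenotypes$animal) > 0)
})

test_that("QTL mode plants effects and keeps the genetic variance calibrated", {
  cfg <- tinyConfig(seed = 47L, nQtl = 5L, qtlVarFrac = 0.8)
  out <- simulateStudy(cfg)
  expect_equal(nrow(out@truth$qtl), 5L)
  v <- var(out@trueBV[, "HS"])
  expect_equal(v, 84.697, tolerance = 0.5)
})
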