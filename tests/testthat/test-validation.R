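test_that("the date split keeps cutoff-day records in the reduced set", {
  ph <- data.frame(animal = 1:3, hcw_kg = 90,
                   slaughter_date = as.Date("2013-10-01") + c(-1, 0, 1))
  sp <- splitByDate(ph, "2013-10-01")
  expect_equal(sp$reduced$animal, c(1, 2))   # "after" is strict
  expect_equal(sp$complete$animal, 1:3)
  spEmpty <- splitByDate(ph[0, ], "2013-10-01")
  expect_equal(nrow(spEmpty$reduced), 0)
  expect_equal(nrow(spEmpty$complete), 0)
})

test_that("validation sires satisfy both progeny conditions", {
  # sires 1, 2, 3; sire 1: 200 late progeny; sire 2: 199 late progeny;
  # sire 3: 500 late progeny but 1 early one
  nk <- c(200, 199, 501)
  ped <- data.frame(animal = c(1:3, 10 + seq_len(sum(nk))),
                    sire = c(0, 0, 0, rep(1:3, nk)),
                    dam = 0)
  late <- as.Date("2014-01-01"); early <- as.Date("2013-01-01")
  ph <- data.frame(animal = 10 + seq_len(sum(nk)), hcw_kg = 90,
                   slaughter_date = late)
  ph$slaughter_date[ph$animal == max(ph$animal)] <- early  # one of sire 3
  sp <- splitByDate(ph, "2013-10-01")
  sel <- selectValidationSires(ped, sp$reduced, sp$complete,
                               minProgeny = 200L)
  expect_equal(sel, 1L)
  expect_warning(selectValidationSires(ped, sp$complete, sp$complete, 200L),
                 "no sires")
})

test_that("validation accuracy is the Pearson correlation over all four pairings", {
  mkSol <- function(hs, nhs) {
    n <- length(hs)
    new("SolutionSet", fixed = data.frame(),
        litter = data.frame(),
        animal = data.frame(animal = rep(1:n, each = 2),
                            trait = rep(c("HS", "NHS"), n),
                            solution = as.vector(rbind(hs, nhs))),
        residualNorm = 0)
  }
  set.seed(7)
  hs <- rnorm(5); nhs <- rnorm(5)
  solR <- mkSol(hs, nhs)
  solC <- mkSol(hs, -nhs)
  acc <- validationAccuracy(solR, solC, sires = 1:5)
  expect_equal(nrow(acc), 4)
  expect_setequal(acc$type, c("homo", "hetero"))
  homoHS <- acc$r[acc$ebvTrait == "HS" & acc$tbvTrait == "HS"]
  expect_equal(homoHS, 1)
  homoNHS <- acc$r[acc$ebvTrait == "NHS" & acc$tbvTrait == "NHS"]
  expect_equal(homoNHS, -1)
  het <- acc$r[acc$ebvTrait == "HS" & acc$tbvTrait == "NHS"]
  expect_equal(het, cor(hs, -nhs))
  expect_error(validationAccuracy(solR, solC, sires = 1:2), "at least 3")
  solZ <- mkSol(rep(1, 5), nhs)
  warns <- capture_warnings(accZ <- validationAccuracy(solZ, solC, 1:5))
  expect_match(warns, "zero variance", all = TRUE)
  expect_true(anyNA(accZ$r))
})

test_that("no record after the cutoff influences reduced-data solutions", {
  out <- tinyStudy(seed = 111L, nSnps = 0L)
  ph <- out@phenotypes
  cutoff <- as.Date(quantile(as.numeric(ph$slaughter_date), 0.6),
                    origin = "1970-01-01")
  sp <- splitByDate(ph, cutoff)
  aInv <- makeAInverse(out@pedigree)
  vc <- publishedVC()
  s1 <- solveBLUP(buildMME(modelSpec(), sp$reduced, aInv, vc))
  # tamper with every post-cutoff record and re-split: identical solutions
  ph2 <- ph
  late <- as.Date(ph2$slaughter_date) > cutoff
  ph2$hcw_kg[late] <- ph2$hcw_kg[late] + 1000
  sp2 <- splitByDate(ph2, cutoff)
  s2 <- solveBLUP(buildMME(modelSpec(), sp2$reduced, aInv, vc))
  expect_identical(breedingValues(s1), breedingValues(s2))
})

test_that("homo-correlations dominate hetero-correlations on average when rg < 1", {
  set.seed(123)
  accs <- replicate(10, {
    out <- simulateStudy(tinyConfig(seed = sample.int(1e6, 1), nSnps = 0L,
                                    nFounders = 40L,
                                    littersPerGeneration = 24L,
                                    progenyPerLitter = 6L,
                                    hsFractionTarget = 0.5))
    ph <- out@phenotypes
    aInv <- makeAInverse(out@pedigree)
    vc <- publishedVC()
    sol <- solveBLUP(buildMME(modelSpec(), ph, aInv, vc))
    bv <- breedingValues(sol)
    sires <- unique(out@pedigree@sire[out@pedigree@sire != 0L])
    ids <- intersect(sires, bv$animal)
    ebvHS <- bv$solution[bv$trait == "HS"][match(ids, bv$animal[bv$trait == "HS"])]
    ebvNHS <- bv$solution[bv$trait == "NHS"][match(ids, bv$animal[bv$trait == "NHS"])]
    tbv <- out@trueBV[match(ids, rownames(out@trueBV)), ]
    c(homo = cor(ebvHS, tbv[, "HS"]), hetero = cor(ebvNHS, tbv[, "HS"]))
  })
  expect_gt(mean(accs["homo", ]), mean(accs["hetero", ]))
})

test_that("genotype ingestion rejects malformed files with the line number", {
  f <- tempfile(); fm <- tempfile()
  writeLines(c("1 0120", "2 0units", "3 0110"), f)
  write.table(data.frame(snp = paste0("s", 1:4), chr = 1, pos = 1:4 * 50),
              fm, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(readGenotypes(f, fm), "line 2")
  writeLines(c("1 0120", "2 01", "3 0110"), f)
  expect_error(readGenotypes(f, fm), "differing SNP counts")
})

test_that("genotype and phenotype files round-trip", {
  out <- tinyStudy(seed = 113L)
  g <- out@genotypes
  f <- tempfile(); fm <- tempfile()
  writeGenotypes(g, f, fm)
  g2 <- readGenotypes(f, fm)
  expect_equal(g2@ids, g@ids)
  expect_equal(g2@dosages, g@dosages, ignore_attr = TRUE)
  expect_equal(g2@map$pos, g@map$pos)
  fp <- tempfile()
  writePhenotypes(out@phenotypes, fp)
  ph2 <- readPhenotypes(fp)
  expect_equal(ph2$hcw_kg, out@phenotypes$hcw_kg, tolerance = 1e-12)
  expect_equal(as.Date(ph2$slaughter_date), out@phenotypes$slaughter_date)
})

test_that("the pipeline runs end-to-end, deterministically, with artifacts", {
  outDir <- tempfile("pipe")
  cfgList <- list(
    sim = list(nFounders = 40L, littersPerGeneration = 18L,
               progenyPerLitter = 6L, nGenerations = 2L,
               batchesPerGeneration = 6L, nSnps = 120L, nChr = 3L,
               nGenotyped = 80L, hsFractionTarget = 0.4, seed = 5L),
    runReml = FALSE,
    varianceComponents = publishedVC(),
    gwasMethod = "quadratic", gwasIters = 2L, windowSize = 10L,
    minProgeny = 5L, seed = 5L)
  res <- suppressMessages(runPipeline(cfgList, outDir))
  for (f in c("pedigree.tsv", "phenotypes.csv", "weather.csv",
              "genotypes.txt", "map.tsv", "truth.json", "qc_report.json",
              "variance_components.json", "solutions.tsv",
              "snp_effects.tsv", "windows.tsv", "peaks.tsv", "config.json",
              "log.txt"))
    expect_true(file.exists(file.path(outDir, f)), label = f)
  expect_s4_class(res$varianceComponents, "VarianceComponents")
  expect_false(is.null(res$gwas))
  # a rerun with the same config and seed is bit-identical on the artifacts
  outDir2 <- tempfile("pipe")
  res2 <- suppressMessages(runPipeline(cfgList, outDir2))
  for (f in c("solutions.tsv", "snp_effects.tsv", "phenotypes.csv"))
    expect_identical(readLines(file.path(outDir, f)),
                     readLines(file.path(outDir2, f)), label = f)
})

test_that("the pipeline oracle mode G := A22 makes ssGBLUP collapse to BLUP", {
  outDir <- tempfile("pipeA22")
  cfgList <- list(
    sim = list(nFounders = 30L, littersPerGeneration = 12L,
               progenyPerLitter = 5L, nGenerations = 2L,
               batchesPerGeneration = 4L, nSnps = 80L, nChr = 2L,
               nGenotyped = 50L, hsFractionTarget = 0.4, seed = 9L),
    runReml = FALSE, varianceComponents = publishedVC(),
    gSource = "A22", validate = FALSE, seed = 9L)
  res <- suppressMessages(runPipeline(cfgList, outDir))
  expect_equal(breedingValues(res$solutions$ebv)$solution,
               breedingValues(res$solutions$gebv)$solution, tolerance = 1e-6)
})
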