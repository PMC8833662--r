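# Random post-QC genotypes for backsolve checks.
randomGeno <- function(seed = 91L, n = 30L, m = 60L, nChr = 3L) {
  set.seed(seed)
  p <- runif(m, 0.1, 0.5)
  d <- sapply(p, function(pp) rbinom(n, 2, pp))
  keep <- apply(d, 2, function(x) length(unique(x)) > 1L)
  d <- d[, keep]
  m <- ncol(d)
  genotypeData(seq_len(n), d,
               data.frame(snp = sprintf("s%03d", seq_len(m)),
                          chr = rep(seq_len(nChr), length.out = m)[order(rep(seq_len(nChr), length.out = m))],
                          pos = as.vector(sapply(seq_len(nChr), function(ch)
                            sort(sample.int(1e6, sum(rep(seq_len(nChr), length.out = m) == ch)))))))
}

test_that("backsolving satisfies the reconstruction identity at alpha = 1", {
  geno <- randomGeno()
  set.seed(92)
  a <- setNames(rnorm(30, 0, 5), geno@ids)
  # centering by observed frequencies leaves the all-ones vector in the null
  # space of M D M'; fixed external frequencies keep the bracket full-rank
  freq <- rep(0.35, nrow(geno@map))
  gres <- makeG(geno, freq = freq, alpha = 1)
  eff <- backsolveSnpEffects(geno, a, gres = gres)
  M <- sweep(geno@dosages, 2, 2 * freq, "-")
  rec <- as.numeric(M %*% eff$effect)
  expect_lt(sqrt(sum((rec - a)^2)) / sqrt(sum(a^2)), 1e-6)
  # zero GEBVs give zero effects
  eff0 <- backsolveSnpEffects(geno, a * 0, gres = gres)
  expect_equal(eff0$effect, rep(0, nrow(geno@map)))
  # with observed frequencies the bracket is singular and the error advises blending
  expect_error(backsolveSnpEffects(geno, a, alpha = 1), "blend")
})

test_that("the scalar backsolve case reduces to the GEBV itself", {
  # one animal, one SNP, centered content m = 1 (dosage 2 at frequency 0.5)
  geno <- genotypeData(1L, matrix(2, 1, 1),
                       data.frame(snp = "s1", chr = 1, pos = 10))
  gres <- makeG(geno, freq = 0.5, alpha = 1)
  eff <- backsolveSnpEffects(geno, c("1" = 3.2), gres = gres)
  expect_equal(eff$effect, 3.2)
})

test_that("weighted backsolve matches the weighted definition", {
  geno <- randomGeno(seed = 93L)
  set.seed(94)
  a <- setNames(rnorm(30, 0, 5), geno@ids)
  w <- runif(nrow(geno@map), 0.5, 2)
  freq <- rep(0.4, nrow(geno@map))
  gres <- makeG(geno, weights = w, freq = freq, alpha = 1)
  eff <- backsolveSnpEffects(geno, a, weights = w, gres = gres)
  M <- sweep(geno@dosages, 2, 2 * freq, "-")
  uOracle <- w * as.numeric(crossprod(M, solve(gres$G * gres$denom, a)))
  expect_equal(eff$effect, uOracle, tolerance = 1e-10)
  # reconstruction still holds with weights
  expect_lt(max(abs(as.numeric(M %*% eff$effect) - a)), 1e-6 * max(abs(a)))
})

test_that("quadratic weights square, floor and renormalize", {
  expect_equal(weightQuadratic(0.5, normalize = FALSE), 0.25)
  expect_equal(weightQuadratic(0, normalize = FALSE), 1e-8)
  d <- weightQuadratic(c(1, 2, 3))
  expect_equal(d / d[1], c(1, 4, 9))
  expect_equal(sum(d), 3)           # trace(D) = number of SNPs
})

test_that("nonlinear-A weights follow the capped exponential with either constant", {
  u <- c(1, 1, 2)
  s <- sd(u)
  for (ct in c(1.125, 1.25)) {
    d <- weightNonlinearA(u, varA = 1, denom = 2, ct = ct, normalize = FALSE)
    expect_equal(d, 0.5 * ct^(abs(u) / s - 2), tolerance = 1e-12)
  }
  # an effect at exactly 2 sd gets the base weight varA/denom (exponent 0)
  u2 <- c(5, 1, -1, -2, -3)
  s2 <- sd(u2)
  d2 <- weightNonlinearA(u2 / s2 * 2 * s2, varA = 3, denom = 2,
                         normalize = FALSE)
  expect_equal(d2, 1.5 * 1.125^(abs(u2) / s2 - 2), tolerance = 1e-12)
  # exponent capped at 5
  u3 <- c(rep(c(-1, 1), 250), 100)
  d3 <- weightNonlinearA(u3, varA = 1, denom = 1, ct = 1.125,
                         normalize = FALSE)
  expect_equal(max(d3), 1.125^5)
  expect_error(weightNonlinearA(rep(1, 5), 1, 1), "degenerate")
})

test_that("window variances match a brute-force enumeration and sum rules", {
  # all-equal variances: every 20-SNP window on a 100-SNP chromosome = 20%
  geno <- data.frame(snp = sprintf("s%03d", 1:100), chr = 1, pos = 1:100)
  eff <- data.frame(geno, freq = 0.5, weight = 1, effect = 1)
  w <- windowVariances(eff, windowSize = 20)
  expect_equal(nrow(w), 81)
  expect_true(all(abs(w$pct - 20) < 1e-10))
  # single nonzero SNP: exactly 20 windows nonzero, each 100%
  eff2 <- eff; eff2$effect <- 0; eff2$effect[50] <- 2
  w2 <- windowVariances(eff2, windowSize = 20)
  expect_equal(sum(w2$pct > 0), 20)
  expect_true(all(w2$pct[w2$pct > 0] == 100))
  # per-SNP variance fractions sum to 100% over the genome
  sv <- snpVariances(eff2)
  expect_equal(100 * sum(sv$varSnp) / sum(sv$varSnp), 100)
  set.seed(95)
  eff$effect <- rnorm(100)
  sv <- snpVariances(eff)
  expect_equal(sum(100 * sv$varSnp / sum(sv$varSnp)), 100)
})

test_that("windows never span chromosomes and truncate short ones with a warning", {
  set.seed(96)
  map <- data.frame(snp = sprintf("s%03d", 1:70),
                    chr = rep(c(1, 2, 3), c(40, 25, 5)),
                    pos = c(sort(sample.int(9e5, 40)),
                            sort(sample.int(9e5, 25)),
                            sort(sample.int(9e5, 5))))
  eff <- data.frame(map, freq = runif(70, 0.1, 0.5), weight = 1,
                    effect = rnorm(70))
  expect_warning(w <- windowVariances(eff, windowSize = 20), "truncated")
  # brute-force oracle
  sv <- snpVariances(eff)
  tot <- sum(sv$varSnp)
  oracle <- list()
  for (ch in c(1, 2, 3)) {
    e <- sv[sv$chr == ch, ]
    starts <- if (nrow(e) < 20) 1 else seq_len(nrow(e) - 19)
    for (st in starts) {
      en <- min(st + 19, nrow(e))
      oracle[[length(oracle) + 1L]] <-
        data.frame(chr = ch, startBp = e$pos[st], endBp = e$pos[en],
                   pct = 100 * sum(e$varSnp[st:en]) / tot)
    }
  }
  oracle <- do.call(rbind, oracle)
  expect_equal(w[c("chr", "startBp", "endBp", "pct")], oracle,
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("the trait-difference scan is |HS - NHS| on a shared frame", {
  eff <- data.frame(snp = sprintf("s%03d", 1:50), chr = 1, pos = 1:50,
                    freq = 0.3, weight = 1, effect = rnorm(50))
  wHS <- windowVariances(eff, windowSize = 10)
  dd <- traitDifference(wHS, wHS)
  expect_true(all(dd$absDiff == 0))
  effN <- eff; effN$effect <- 0
  wN <- windowVariances(effN, windowSize = 10)
  dd2 <- traitDifference(wHS, wN)
  expect_equal(dd2$absDiff, wHS$pct)
  wOther <- windowVariances(eff, windowSize = 12)
  expect_error(traitDifference(wHS, wOther), "frame")
})

test_that("peaks merge overlapping supra-threshold windows", {
  w <- data.frame(window = 1:6, chr = c(1, 1, 1, 14, 14, 2),
                  startSnp = "s", endSnp = "s",
                  startBp = c(100, 150, 900, 100, 140, 100),
                  endBp = c(300, 350, 1100, 300, 340, 300),
                  startIdx = c(1, 2, 9, 1, 2, 1),
                  endIdx = c(3, 4, 11, 3, 4, 3),
                  pct = c(1.4, 1.2, 0.5, 1.3, 1.25, 0.7))
  p <- peakReport(w, thresholdPct = 0.8)
  expect_equal(nrow(p), 2)                      # chr 1 and chr 14
  expect_equal(p$chr, c(1, 14))
  expect_equal(p$maxPct, c(1.4, 1.3))
  expect_equal(p$nWindows, c(2L, 2L))
  expect_equal(p$endBp, c(350, 340))            # merged spans
  expect_equal(nrow(peakReport(w, thresholdPct = 2)), 0)
})

test_that("independent chromosome segments follow 2NeL/log(2NeL)", {
  seg <- chromosomeSegments(55, 19)
  expect_equal(seg$q, 2090 / log(2090))
  expect_equal(round(seg$q, 1), 273.4)
  x <- exp(1) / 2
  expect_equal(chromosomeSegments(1, x)$q, exp(1))
  expect_error(chromosomeSegments(0.01, 1), "exceed")
})

test_that("iterative weighting starts unweighted and preserves trace", {
  out <- tinyStudy(seed = 97L)
  geno <- qcGenotypes(out@genotypes)$genotypes
  vc <- publishedVC()
  m <- modelSpec(traits = "NHS")
  ph <- out@phenotypes
  iters <- iterateWeights(m, ph, out@pedigree, geno, vc,
                          method = "quadratic", nIters = 3L)
  nsnp <- nrow(geno@map)
  expect_equal(iters[[1]]$weights, rep(1, nsnp))
  for (k in 2:3)
    expect_equal(sum(iters[[k]]$weights), nsnp, tolerance = 1e-10)
  # iteration 1 is exactly the unweighted single-step analysis
  aInv <- makeAInverse(out@pedigree)
  A22 <- makeA22(out@pedigree, geno@ids)
  gres <- makeG(geno, alpha = 0.95, A22 = A22)
  hInv <- makeHInverse(aInv, gres$G, A22)
  direct <- solveBLUP(buildMME(m, ph, hInv, vc))
  expect_equal(breedingValues(iters[[1]]$solutions)$solution,
               breedingValues(direct)$solution, tolerance = 1e-8)
  # weights change after the first update
  expect_gt(sd(iters[[2]]$weights), 0)
})

test_that("quadratic weighting concentrates on planted major QTL", {
  cfg <- tinyConfig(seed = 101L, nQtl = 2L, qtlVarFrac = 0.95, qtlDecay = 1,
                    nSnps = 120L, nChr = 3L, nFounders = 40L,
                    littersPerGeneration = 20L, progenyPerLitter = 6L,
                    nGenotyped = 160L, trueVarE = c(30, 30),
                    trueVarLitter = c(5, 5))
  out <- simulateStudy(cfg)
  geno <- qcGenotypes(out@genotypes)$genotypes
  vc <- publishedVC()
  iters <- iterateWeights(modelSpec(traits = "NHS"), out@phenotypes,
                          out@pedigree, geno, vc, method = "quadratic",
                          nIters = 2L)
  w2 <- iters[[2]]$weights
  qtlSnps <- out@truth$qtl$snp
  hit <- geno@map$snp %in% qtlSnps
  # mass on the QTL columns far exceeds their uniform share
  expect_gt(sum(w2[hit]) / sum(w2), 4 * mean(hit))
})
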