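#' Simulation configuration
#'
#' Holds every knob of the synthetic-data generator. The defaults encode the
#' statistical structure of the commercial crossbred population the pipeline
#' is designed for, scaled to desk size: a ~3,000-animal three-generation
#' pedigree on two farms, carcass-weight records split roughly 14%/86% into
#' heat-stress (HS) / non-heat-stress (NHS) by the 30-day mean THI against a
#' threshold of 78, genetic/litter/residual variances of
#' 84.697/31.736/216.69 kg^2 (HS) and 60.173/30.791/210.69 kg^2 (NHS), and a
#' genetic correlation of 0.63 (covariance 0.63*sqrt(84.697*60.173)).
#'
#' @slot nFounders,nGenerations,littersPerGeneration,progenyPerLitter pedigree shape.
#' @slot nSnps,nChr,nQtl,qtlVarFrac,qtlDecay,mafLow,mafHigh genome shape; nQtl = 0
#'   selects the infinitesimal model, nQtl > 0 plants marker QTL with
#'   geometrically decaying effects carrying `qtlVarFrac` of the genetic variance.
#' @slot trueVarA,trueCovA,trueVarLitter,trueVarE simulation truths, kg^2
#'   (2-vectors ordered HS, NHS; scalar covariance).
#' @slot hsFractionTarget overall target fraction of HS records.
#' @slot nFarms,farmShare,hsFractionFarm farm number, record shares and
#'   per-farm HS target fractions (weather calibration).
#' @slot thiThreshold,windowDays trait-assignment rule.
#' @slot meanNHS,hsShift,ageMean,ageSd,ageSlope,sexEffect,cgSd phenotype scale:
#'   baseline NHS mean (kg), additive shift applied to HS records (kg), slaughter
#'   age distribution (d), age regression (kg/d), sex effect (kg), SD of
#'   contemporary-group effects (kg).
#' @slot tempAmplitude,rhMean,weatherNoiseSd,rhNoiseSd seasonal weather shape
#'   (deg C amplitude, % humidity, daily noise SDs).
#' @slot generationSpacingDays,birthWindowDays litter timing: generation g
#'   litters are born in a window of `birthWindowDays` starting
#'   `(g-1)*generationSpacingDays` after the study origin.
#' @slot batchesPerGeneration farrowing batches per generation: litters are
#'   grouped into batches spread evenly over the birth window, and each sire
#'   serves several litters within a batch (weekly farrowing groups create
#'   the cross-litter half-sib structure and well-filled contemporary groups
#'   seen in commercial data).
#' @slot nGenotyped number of animals carried into the genotype file
#'   (all breeders plus a random fill of phenotyped animals).
#' @slot seed integer RNG seed.
#' @export
setClass("SimConfig",
  representation(
    nFounders = "integer", nGenerations = "integer",
    littersPerGeneration = "integer", progenyPerLitter = "integer",
    nSnps = "integer", nChr = "integer", nQtl = "integer",
    qtlVarFrac = "numeric", qtlDecay = "numeric",
    mafLow = "numeric", mafHigh = "numeric",
    trueVarA = "numeric", trueCovA = "numeric",
    trueVarLitter = "numeric", trueVarE = "numeric",
    hsFractionTarget = "numeric", nFarms = "integer",
    farmShare = "numeric", hsFractionFarm = "numeric",
    thiThreshold = "numeric", windowDays = "integer",
    meanNHS = "numeric", hsShift = "numeric",
    ageMean = "numeric", ageSd = "numeric", ageSlope = "numeric",
    sexEffect = "numeric", cgSd = "numeric",
    tempAmplitude = "numeric", rhMean = "numeric",
    weatherNoiseSd = "numeric", rhNoiseSd = "numeric",
    generationSpacingDays = "integer", birthWindowDays = "integer",
    batchesPerGeneration = "integer", repeatMating = "logical",
    nGenotyped = "integer", seed = "integer"))

setValidity("SimConfig", function(object) {
  if (object@nFounders < 2L || object@nGenerations < 1L)
    return("need at least 2 founders and 1 generation")
  if (object@littersPerGeneration < 1L || object@progenyPerLitter < 1L)
    return("litters and progeny per litter must be positive")
  if (!(object@mafLow > 0 && object@mafLow <= object@mafHigh &&
        object@mafHigh <= 0.5))
    return("need 0 < mafLow <= mafHigh <= 0.5")
  if (any(object@trueVarA < 0) || any(object@trueVarLitter < 0) ||
      any(object@trueVarE < 0))
    return("variances must be non-negative")
  if (object@trueCovA^2 > prod(object@trueVarA) + 1e-8)
    return("trueCovA^2 must not exceed the product of the genetic variances")
  if (object@hsFractionTarget < 0 || object@hsFractionTarget > 1)
    return("hsFractionTarget must lie in [0,1]")
  if (length(object@farmShare) != object@nFarms ||
      length(object@hsFractionFarm) != object@nFarms)
    return("farmShare and hsFractionFarm need one entry per farm")
  if (abs(sum(object@farmShare) - 1) > 1e-8)
    return("farmShare must sum to 1")
  TRUE
})

#' Construct a SimConfig
#'
#' All arguments default to the study conditions described in
#' [SimConfig-class]; override any subset.
#'
#' @param nFounders,nGenerations,littersPerGeneration,progenyPerLitter pedigree shape.
#' @param nSnps,nChr,nQtl,qtlVarFrac,qtlDecay,mafLow,mafHigh genome shape.
#' @param trueVarA,trueCovA,trueVarLitter,trueVarE simulation truths (kg^2).
#' @param hsFractionTarget,nFarms,farmShare,hsFractionFarm record structure.
#' @param thiThreshold,windowDays trait-assignment rule.
#' @param meanNHS,hsShift,ageMean,ageSd,ageSlope,sexEffect,cgSd phenotype scale.
#' @param tempAmplitude,rhMean,weatherNoiseSd,rhNoiseSd weather shape.
#' @param generationSpacingDays,birthWindowDays litter timing.
#' @param batchesPerGeneration farrowing batches per generation.
#' @param repeatMating rebreed each dam to the same sire across parities
#'   (cross-litter full-sib structure; default FALSE, commercial rotation).
#' @param nGenotyped genotyped-subset size.
#' @param seed integer RNG seed.
#' @return A validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(seed = 42)
#' cfg@trueVarA
#' @export
simConfig <- function(nFounders = 240L, nGenerations = 3L,
                      littersPerGeneration = 100L, progenyPerLitter = 9L,
                      nSnps = 1200L, nChr = 18L, nQtl = 0L,
                      qtlVarFrac = 0.9, qtlDecay = 0.7,
                      mafLow = 0.05, mafHigh = 0.5,
                      trueVarA = c(84.697, 60.173),
                      trueCovA = 0.63 * sqrt(84.697 * 60.173),
                      trueVarLitter = c(31.736, 30.791),
                      trueVarE = c(216.69, 210.69),
                      hsFractionTarget = 0.144, nFarms = 2L,
                      farmShare = c(0.62, 0.38),
                      hsFractionFarm = c(0.208, 0.040),
                      thiThreshold = 78, windowDays = 30L,
                      meanNHS = 94.2, hsShift = -4.3,
                      ageMean = 185, ageSd = 8, ageSlope = 0.5,
                      sexEffect = 1.5, cgSd = 4,
                      tempAmplitude = 11, rhMean = 55,
                      weatherNoiseSd = 1.5, rhNoiseSd = 5,
                      generationSpacingDays = 365L, birthWindowDays = 365L,
                      batchesPerGeneration = 20L, repeatMating = FALSE,
                      nGenotyped = 400L, seed = 1L) {
  new("SimConfig",
      nFounders = as.integer(nFounders), nGenerations = as.integer(nGenerations),
      littersPerGeneration = as.integer(littersPerGeneration),
      progenyPerLitter = as.integer(progenyPerLitter),
      nSnps = as.integer(nSnps), nChr = as.integer(nChr), nQtl = as.integer(nQtl),
      qtlVarFrac = qtlVarFrac, qtlDecay = qtlDecay,
      mafLow = mafLow, mafHigh = mafHigh,
      trueVarA = trueVarA, trueCovA = trueCovA,
      trueVarLitter = trueVarLitter, trueVarE = trueVarE,
      hsFractionTarget = hsFractionTarget, nFarms = as.integer(nFarms),
      farmShare = farmShare, hsFractionFarm = hsFractionFarm,
      thiThreshold = thiThreshold, windowDays = as.integer(windowDays),
      meanNHS = meanNHS, hsShift = hsShift,
      ageMean = ageMean, ageSd = ageSd, ageSlope = ageSlope,
      sexEffect = sexEffect, cgSd = cgSd,
      tempAmplitude = tempAmplitude, rhMean = rhMean,
      weatherNoiseSd = weatherNoiseSd, rhNoiseSd = rhNoiseSd,
      generationSpacingDays = as.integer(generationSpacingDays),
      birthWindowDays = as.integer(birthWindowDays),
      batchesPerGeneration = as.integer(batchesPerGeneration),
      repeatMating = isTRUE(repeatMating),
      nGenotyped = as.integer(nGenotyped), seed = as.integer(seed))
}

#' @export
setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nFounders, "founders,", object@nGenerations,
      "generations x", object@littersPerGeneration, "litters x",
      object@progenyPerLitter, "progeny;",
      object@nSnps, "SNPs on", object@nChr, "chromosomes",
      if (object@nQtl > 0L) paste0("(", object@nQtl, " QTL)") else "(infinitesimal)",
      "\n  truths: varA =", paste(object@trueVarA, collapse = "/"),
      " covA =", round(object@trueCovA, 3),
      " seed =", object@seed, "\n")
})

## Study calendar origin; all day indices are relative to this date.
SIM_ORIGIN <- as.Date("2010-01-01")

#' Output bundle of a full simulation
#'
#' @slot pedigree [Pedigree-class] with meta columns sex, farm, birthDay,
#'   litter, generation, isBreeder.
#' @slot genotypes [GenotypeData-class] of the genotyped subset, or NULL.
#' @slot weather data.frame (farm, date, tmax_c, rhmin_pct).
#' @slot phenotypes data.frame, one record per slaughtered animal.
#' @slot trueBV matrix (pedigree animals x traits HS, NHS), kg.
#' @slot truth list of generating parameters (and QTL positions/effects if any).
#' @slot config the [SimConfig-class] used.
#' @export
setClass("SimOutput",
  representation(pedigree = "Pedigree", genotypes = "ANY",
                 weather = "data.frame", phenotypes = "data.frame",
                 trueBV = "matrix", truth = "list", config = "SimConfig"))

setValidity("SimOutput", function(object) {
  ids <- object@pedigree@id
  if (nrow(object@phenotypes) &&
      !all(object@phenotypes$animal %in% ids))
    return("every phenotyped animal must appear in the pedigree")
  if (anyDuplicated(object@phenotypes$animal))
    return("each animal may have at most one phenotype record")
  if (!is.null(object@genotypes) && !all(object@genotypes@ids %in% ids))
    return("every genotyped animal must appear in the pedigree")
  TRUE
})

#' @export
setMethod("show", "SimOutput", function(object) {
  cat("SimOutput:\n  ")
  show(object@pedigree)
  cat(" ", nrow(object@phenotypes), "phenotype records (",
      sprintf("%.1f%% HS", 100 * mean(object@phenotypes$trait == "HS")), ")\n")
  if (!is.null(object@genotypes)) { cat("  "); show(object@genotypes) }
})

#' Simulate a multi-generation two-pool pedigree
#'
#' Founders are split into a sire pool and a dam pool (the three-breed
#' terminal cross is collapsed to two pools; breed effects are absorbed by
#' contemporary groups downstream). Each generation mates sampled sires to
#' dams cycling through parities 1-3; non-promoted progeny are the slaughter
#' animals. Litter codes combine dam and parity.
#'
#' @param cfg a [SimConfig-class].
#' @return A [Pedigree-class] with meta columns sex, farm, birthDay, litter,
#'   generation, isBreeder.
#' @examples
#' ped <- simulatePedigree(simConfig(nFounders = 10L, littersPerGeneration = 4L,
#'                                   progenyPerLitter = 3L, nGenerations = 2L))
#' @export
simulatePedigree <- function(cfg) {
  stopifnot(is(cfg, "SimConfig"))
  set.seed(cfg@seed + 101L)
  nF <- cfg@nFounders
  nSiresF <- max(1L, min(nF - 1L, round(nF / 6)))
  id <- seq_len(nF)
  sire <- dam <- rep(0L, nF)
  sex <- c(rep("M", nSiresF), rep("F", nF - nSiresF))
  farm <- sample.int(cfg@nFarms, nF, replace = TRUE, prob = cfg@farmShare)
  birthDay <- rep(-cfg@generationSpacingDays %/% 2L, nF)
  litter <- rep(NA_character_, nF)
  generation <- rep(0L, nF)

  prevMales <- id[sex == "M"]
  prevFemales <- id[sex == "F"]
  nextId <- nF + 1L
  for (g in seq_len(cfg@nGenerations)) {
    nLit <- cfg@littersPerGeneration
    nSires <- max(2L, ceiling(nLit / 4))
    nDams <- max(1L, ceiling(nLit / 2))
    sires <- resample(prevMales, min(nSires, length(prevMales)))
    dams <- resample(prevFemales, min(nDams, length(prevFemales)))
    # farrowing batches: litters grouped in time, each sire serving ~2
    # litters within a batch -> cross-litter half-sibs inside a season
    nB <- min(cfg@batchesPerGeneration, nLit)
    batch <- sort(rep_len(seq_len(nB), nLit))
    batchDay <- round((seq_len(nB) - 0.5) / nB * cfg@birthWindowDays) +
      sample(-3:3, nB, replace = TRUE)
    litSire <- integer(nLit)
    for (b in seq_len(nB)) {
      lb <- which(batch == b)
      sb <- resample(sires, min(length(sires), max(1L, ceiling(length(lb) / 2))))
      sb <- rep_len(sb, length(lb))
      litSire[lb] <- sb[sample.int(length(sb))]
    }
    litDam <- dams[((seq_len(nLit) - 1L) %% length(dams)) + 1L]
    parity <- ((seq_len(nLit) - 1L) %/% length(dams)) + 1L
    if (cfg@repeatMating) {
      # dam keeps her first sire across parities
      first <- match(litDam, litDam)
      litSire <- litSire[first]
    }
    litFarm <- sample.int(cfg@nFarms, nLit, replace = TRUE, prob = cfg@farmShare)
    litBirth <- (g - 1L) * cfg@generationSpacingDays +
      pmax(0L, pmin(cfg@birthWindowDays - 1L, batchDay[batch]))
    for (l in seq_len(nLit)) {
      np <- cfg@progenyPerLitter
      kid <- seq.int(nextId, length.out = np)
      id <- c(id, kid)
      sire <- c(sire, rep(litSire[l], np))
      dam <- c(dam, rep(litDam[l], np))
      sex <- c(sex, sample(c("M", "F"), np, replace = TRUE))
      farm <- c(farm, rep(litFarm[l], np))
      birthDay <- c(birthDay, rep(litBirth[l], np))
      litter <- c(litter, rep(sprintf("d%d_p%d", litDam[l], parity[l]), np))
      generation <- c(generation, rep(g, np))
      nextId <- nextId + np
    }
    thisGen <- id[generation == g]
    prevMales <- thisGen[sex[match(thisGen, id)] == "M"]
    prevFemales <- thisGen[sex[match(thisGen, id)] == "F"]
  }
  isBreeder <- id %in% c(sire, dam)
  pedigree(id, sire, dam,
           meta = data.frame(sex = sex, farm = farm, birthDay = birthDay,
                             litter = litter, generation = generation,
                             isBreeder = isBreeder))
}

#' Gene-drop SNP genotypes through a pedigree
#'
#' Founder allele frequencies are drawn uniformly in `[mafLow, mafHigh]` and
#' founder dosages are Binomial(2, p). Each descendant receives one allele
#' from each parent, sampled Bernoulli(dosage/2); alleles of unknown parents
#' are drawn at the founder frequency. Loci are unlinked.
#'
#' @param ped a [Pedigree-class].
#' @param cfg a [SimConfig-class].
#' @return A [GenotypeData-class] covering all pedigree animals.
#' @export
simulateGenotypes <- function(ped, cfg) {
  stopifnot(is(ped, "Pedigree"), is(cfg, "SimConfig"))
  set.seed(cfg@seed + 202L)
  n <- nAnimals(ped)
  m <- cfg@nSnps
  p <- runif(m, cfg@mafLow, cfg@mafHigh)
  dos <- matrix(0, n, m)
  idx <- match(ped@id, ped@id)  # identity; parents located by match below
  sireIdx <- match(ped@sire, ped@id)  # NA where unknown
  damIdx <- match(ped@dam, ped@id)
  for (i in seq_len(n)) {
    aS <- if (is.na(sireIdx[i])) rbinom(m, 1L, p) else rbinom(m, 1L, dos[sireIdx[i], ] / 2)
    aD <- if (is.na(damIdx[i])) rbinom(m, 1L, p) else rbinom(m, 1L, dos[damIdx[i], ] / 2)
    dos[i, ] <- aS + aD
  }
  perChr <- rep(m %/% cfg@nChr, cfg@nChr)
  extra <- m - sum(perChr)
  if (extra > 0) perChr[seq_len(extra)] <- perChr[seq_len(extra)] + 1L
  chr <- rep(seq_len(cfg@nChr), perChr)
  pos <- unlist(lapply(perChr, function(k) sort(sample.int(1.08e8, k))),
                use.names = FALSE)
  map <- data.frame(snp = sprintf("snp%05d", seq_len(m)), chr = chr, pos = pos)
  genotypeData(ped@id, dos, map)
}

#' Subset genotypes by animal and/or SNP
#' @param geno a [GenotypeData-class].
#' @param ids animal ids to keep (default all).
#' @param snps SNP column indices to keep (default all).
#' @return A [GenotypeData-class].
#' @export
subsetGenotypes <- function(geno, ids = geno@ids, snps = seq_len(nrow(geno@map))) {
  keep <- match(ids, geno@ids)
  if (anyNA(keep)) stop("unknown animal ids in genotype subset")
  genotypeData(geno@ids[keep], geno@dosages[keep, snps, drop = FALSE],
               geno@map[snps, , drop = FALSE])
}

#' Inbreeding coefficients from a pedigree
#'
#' Diagonal of the numerator relationship matrix minus 1, by the tabular
#' method (see [makeA]).
#' @param ped a [Pedigree-class].
#' @return Numeric vector of F, one per animal.
#' @export
inbreeding <- function(ped) {
  diag(makeA(ped)) - 1
}

#' Simulate true breeding values
#'
#' Infinitesimal mode (`nQtl = 0`): bivariate breeding values follow the
#' pedigree, `a_i = (a_sire + a_dam)/2 + m_i`, with Mendelian-sampling
#' covariance `(1/2)(1 - (F_s + F_d)/2) * G0` where `G0` is the 2x2 genetic
#' covariance matrix built from `trueVarA` and `trueCovA`. QTL mode
#' (`nQtl > 0`): `nQtl` markers carry geometrically decaying effects with
#' cross-trait correlation implied by `trueCovA`, scaled to `qtlVarFrac` of
#' each genetic variance; the remainder is polygenic through the pedigree.
#'
#' @param ped a [Pedigree-class].
#' @param geno a [GenotypeData-class] covering the pedigree (required in QTL
#'   mode, ignored otherwise).
#' @param cfg a [SimConfig-class].
#' @return List: `bv` matrix (animals x HS/NHS, kg); `qtl` NULL or a
#'   data.frame (snp, chr, pos, effHS, effNHS).
#' @export
simulateBreedingValues <- function(ped, geno = NULL, cfg) {
  stopifnot(is(ped, "Pedigree"), is(cfg, "SimConfig"))
  G0 <- matrix(c(cfg@trueVarA[1], cfg@trueCovA, cfg@trueCovA, cfg@trueVarA[2]), 2)
  ev <- eigen(G0, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    stop("genetic covariance matrix is not positive semi-definite")
  set.seed(cfg@seed + 303L)
  qtl <- NULL
  polyG0 <- G0
  n <- nAnimals(ped)
  bv <- matrix(0, n, 2, dimnames = list(ped@id, TRAITS))
  if (cfg@nQtl > 0L) {
    if (is.null(geno)) stop("QTL mode requires genotypes")
    m <- nrow(geno@map)
    qidx <- sort(sample.int(m, min(cfg@nQtl, m)))
    mag <- cfg@qtlDecay^(seq_along(qidx) - 1)
    rg <- cfg@trueCovA / sqrt(prod(cfg@trueVarA))
    L <- chol(matrix(c(1, rg, rg, 1), 2))
    beta <- (matrix(rnorm(2 * length(qidx)), ncol = 2) %*% L) * mag
    Mq <- scale(geno@dosages[match(ped@id, geno@ids), qidx, drop = FALSE],
                scale = FALSE)
    gq <- Mq %*% beta
    for (t in 1:2) {
      tgt <- cfg@qtlVarFrac * cfg@trueVarA[t]
      s <- if (var(gq[, t]) > 0) sqrt(tgt / var(gq[, t])) else 0
      gq[, t] <- gq[, t] * s
      beta[, t] <- beta[, t] * s
    }
    bv <- bv + gq
    qtl <- data.frame(geno@map[qidx, ], effHS = beta[, 1], effNHS = beta[, 2])
    polyG0 <- (1 - cfg@qtlVarFrac) * G0
  }
  # polygenic part through the pedigree; eigen square root handles PSD
  # (including zero-variance) genetic covariance matrices
  es <- eigen(polyG0, symmetric = TRUE)
  Lp <- diag(sqrt(pmax(es$values, 0)), 2) %*% t(es$vectors)
  Fi <- inbreeding(ped)
  sireIdx <- match(ped@sire, ped@id)
  damIdx <- match(ped@dam, ped@id)
  poly <- matrix(0, n, 2)
  z <- matrix(rnorm(2 * n), n, 2)
  for (i in seq_len(n)) {
    s <- sireIdx[i]; d <- damIdx[i]
    pa <- c(0, 0); k <- 1
    if (!is.na(s) && !is.na(d)) {
      pa <- (poly[s, ] + poly[d, ]) / 2
      k <- 0.5 - 0.25 * (Fi[s] + Fi[d])
    } else if (!is.na(s)) {
      pa <- poly[s, ] / 2; k <- 0.75 - 0.25 * Fi[s]
    } else if (!is.na(d)) {
      pa <- poly[d, ] / 2; k <- 0.75 - 0.25 * Fi[d]
    }
    poly[i, ] <- pa + sqrt(k) * drop(z[i, ] %*% Lp)
  }
  list(bv = bv + poly, qtl = qtl)
}

## THI amplitude/mean calibration: for a sinusoidal tmax with amplitude amp at
## humidity rh, daily THI is a sinusoid with slope 1.8*(1-k), k = 0.55-0.0055*rh.
## The 30-day running mean shrinks the amplitude by sinc(pi*w/365.25); choosing
## the annual mean so that the running-mean THI exceeds the threshold for a
## fraction f of the year gives mean = thr - cos(pi*f) * shrunkAmplitude.
calibrateTempMean <- function(fracHS, cfg) {
  k <- 0.55 - 0.0055 * cfg@rhMean
  slope <- 1.8 * (1 - k)
  shrink <- {
    x <- pi * cfg@windowDays / 365.25
    if (x == 0) 1 else sin(x) / x
  }
  athi <- slope * cfg@tempAmplitude * shrink
  mthi <- if (athi == 0) {
    # flat climate: put the mean just below threshold unless everything is HS
    if (fracHS >= 1) cfg@thiThreshold + 1 else cfg@thiThreshold - 1
  } else cfg@thiThreshold - cos(pi * min(max(fracHS, 0), 1)) * athi
  (mthi - 32 - 26 * k) / (1.8 * (1 - k))
}

#' Simulate daily farm weather
#'
#' Sinusoidal seasonal maximum temperature (peak mid-July) with daily noise
#' and near-constant minimum relative humidity. Per-farm annual means are
#' calibrated analytically so the 30-day mean THI exceeds the threshold for
#' approximately the per-farm target fraction of the year, letting one farm
#' carry a much larger share of heat-stress records than the other.
#'
#' @param cfg a [SimConfig-class].
#' @param days integer day indices (relative to the study origin) to cover.
#' @param tempMean optional per-farm annual mean tmax override (deg C);
#'   default NULL calibrates from `hsFractionFarm`.
#' @return data.frame (farm, date, tmax_c, rhmin_pct), no gaps.
#' @export
simulateWeather <- function(cfg, days = NULL, tempMean = NULL) {
  stopifnot(is(cfg, "SimConfig"))
  set.seed(cfg@seed + 404L)
  if (is.null(days)) {
    lastBirth <- (cfg@nGenerations - 1L) * cfg@generationSpacingDays +
      cfg@birthWindowDays
    days <- seq.int(-cfg@generationSpacingDays %/% 2L - cfg@windowDays - 10L,
                    lastBirth + cfg@ageMean + 8 * cfg@ageSd + 10L)
  }
  if (length(days) < 365) warning("less than one year of weather simulated")
  # rescale farm fractions so the record-share-weighted mean hits the target
  fr <- cfg@hsFractionFarm
  w <- sum(cfg@farmShare * fr)
  if (w > 0) fr <- pmin(1, fr * cfg@hsFractionTarget / w)
  if (is.null(tempMean))
    tempMean <- vapply(fr, calibrateTempMean, numeric(1), cfg = cfg)
  out <- do.call(rbind, lapply(seq_len(cfg@nFarms), function(f) {
    seas <- tempMean[f] +
      cfg@tempAmplitude * cos(2 * pi * (days - 195) / 365.25)
    data.frame(farm = f, date = SIM_ORIGIN + days,
               tmax_c = seas + rnorm(length(days), 0, cfg@weatherNoiseSd),
               rhmin_pct = pmin(100, pmax(0,
                 cfg@rhMean + rnorm(length(days), 0, cfg@rhNoiseSd))))
  }))
  rownames(out) <- NULL
  out
}

#' Simulate phenotype records
#'
#' Generates one hot-carcass-weight record per non-breeder animal using the
#' additive record model: contemporary group (year-week-farm of slaughter) +
#' sex + age regression + litter + animal + residual, with the trait (HS/NHS)
#' realized from the 30-day mean THI before the animal's slaughter date and a
#' fixed heat-load shift applied to HS records. Litter and residual effects
#' are drawn independently per trait (traits are never co-observed).
#'
#' @param trueBV matrix of breeding values (animals x HS/NHS) as from
#'   [simulateBreedingValues()].
#' @param ped a [Pedigree-class] with simulator meta columns.
#' @param weather data.frame from [simulateWeather()]; must cover every
#'   slaughter date minus `windowDays`.
#' @param cfg a [SimConfig-class].
#' @return data.frame (animal, hcw_kg, trait, mean_thi_30d, farm, sex, litter,
#'   age_d, slaughter_date, cg).
#' @export
simulatePhenotypes <- function(trueBV, ped, weather, cfg) {
  stopifnot(is(ped, "Pedigree"), is(cfg, "SimConfig"))
  set.seed(cfg@seed + 505L)
  meta <- ped@meta
  rec <- which(!meta$isBreeder & meta$generation > 0L)
  nr <- length(rec)
  age <- round(rnorm(nr, cfg@ageMean, cfg@ageSd))
  slDay <- meta$birthDay[rec] + age
  slDate <- SIM_ORIGIN + slDay
  farm <- meta$farm[rec]
  # vectorized 30-day mean THI via per-farm cumulative sums
  mthi <- numeric(nr)
  for (f in unique(farm)) {
    wf <- weather[weather$farm == f, ]
    wf <- wf[order(wf$date), ]
    need <- range(slDay[farm == f])
    cover <- as.integer(range(wf$date) - SIM_ORIGIN)
    if (cover[1] > need[1] - cfg@windowDays || cover[2] < need[2] - 1L)
      stop("weather does not cover the heat-load window for every slaughter date")
    dthi <- thi(wf$tmax_c, wf$rhmin_pct)
    cs <- c(0, cumsum(dthi))
    d0 <- as.integer(wf$date[1] - SIM_ORIGIN)
    i <- slDay[farm == f] - d0          # index of slaughter day in wf (1-based: +1)
    mthi[farm == f] <- (cs[i + 1] - cs[i + 1 - cfg@windowDays]) / cfg@windowDays
  }
  trait <- assignTrait(mthi, cfg@thiThreshold)
  year <- format(slDate, "%G")
  week <- format(slDate, "%V")
  cg <- sprintf("f%d_%s_w%s", farm, year, week)
  cgLevels <- unique(cg)
  cgEff <- setNames(rnorm(length(cgLevels), 0, cfg@cgSd), cgLevels)
  litterIds <- meta$litter[rec]
  litLevels <- unique(litterIds)
  litEff <- matrix(rnorm(2 * length(litLevels)), ncol = 2) *
    rep(sqrt(cfg@trueVarLitter), each = length(litLevels))
  rownames(litEff) <- litLevels
  ti <- match(trait, TRAITS)
  bvIdx <- match(ped@id[rec], rownames(trueBV))
  e <- rnorm(nr, 0, sqrt(cfg@trueVarE)[ti])
  hcw <- cfg@meanNHS + cfg@hsShift * (trait == "HS") +
    cgEff[cg] + cfg@sexEffect * (meta$sex[rec] == "M") +
    cfg@ageSlope * (age - cfg@ageMean) +
    litEff[cbind(match(litterIds, litLevels), ti)] +
    trueBV[cbind(bvIdx, ti)] + e
  data.frame(animal = ped@id[rec], hcw_kg = as.numeric(hcw), trait = trait,
             mean_thi_30d = mthi, farm = farm, sex = meta$sex[rec],
             litter = litterIds, age_d = age, slaughter_date = slDate,
             cg = cg, row.names = NULL)
}

#' Run the full synthetic-data generator
#'
#' Sequences pedigree, genotypes (when `nSnps > 0`), breeding values, weather
#' and phenotypes under a single seed; the result is bit-identical for
#' identical configurations.
#'
#' @param cfg a [SimConfig-class].
#' @return A [SimOutput-class].
#' @examples
#' out <- simulateStudy(simConfig(nFounders = 20L, littersPerGeneration = 6L,
#'   progenyPerLitter = 4L, nGenerations = 2L, nSnps = 50L, nChr = 2L,
#'   nGenotyped = 30L, seed = 7L))
#' out
#' @export
simulateStudy <- function(cfg) {
  ped <- simulatePedigree(cfg)
  genoFull <- NULL
  if (cfg@nSnps > 0L) genoFull <- simulateGenotypes(ped, cfg)
  bvres <- simulateBreedingValues(ped, genoFull, cfg)
  weather <- simulateWeather(cfg)
  phen <- simulatePhenotypes(bvres$bv, ped, weather, cfg)
  geno <- NULL
  if (!is.null(genoFull)) {
    set.seed(cfg@seed + 606L)
    breeders <- ped@id[ped@meta$isBreeder]
    pool <- setdiff(phen$animal, breeders)
    extra <- max(0L, cfg@nGenotyped - length(breeders))
    gids <- sort(c(breeders, sample(pool, min(extra, length(pool)))))
    geno <- subsetGenotypes(genoFull, gids)
  }
  truth <- list(varA = cfg@trueVarA, covA = cfg@trueCovA,
                varLitter = cfg@trueVarLitter, varE = cfg@trueVarE,
                qtl = bvres$qtl)
  new("SimOutput", pedigree = ped, genotypes = geno, weather = weather,
      phenotypes = phen, trueBV = bvres$bv, truth = truth, config = cfg)
}

## sample() without the length-1 surprise
resample <- function(x, n) x[sample.int(length(x), n)]
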