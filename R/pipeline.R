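pipelineDefaults <- function() list(
  simulate = TRUE,
  sim = list(),                     # simConfig() overrides, or a SimConfig
  inputs = list(),                  # file paths when simulate = FALSE
  thiThreshold = 78, windowDays = 30L,
  mafMin = 0.05, callrateMin = 0.9, outlierSd = 4,
  alpha = 0.95, gSource = "genomic",  # "A22" forces G := A22 (oracle mode)
  runReml = TRUE, varianceComponents = NULL,
  gwasMethod = "none", gwasIters = 1L, windowSize = 20L,
  peakThresholdPct = 0.8, ct = 1.125,
  validate = TRUE, cutoffDate = NULL, cutoffQuantile = 0.66,
  minProgeny = 200L,
  seed = 1L)

readPipelineConfig <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading a config file requires the yaml package")
    config <- yaml::read_yaml(config)
  }
  def <- pipelineDefaults()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  def[names(config)] <- config
  def
}

#' Run the full evaluation pipeline
#'
#' Sequences the stages end-to-end: simulate (or ingest flat files) ->
#' heat-load trait assignment and QC -> relationship matrices -> AIREML
#' variance components -> pedigree BLUP and single-step GBLUP -> (optionally
#' weighted) single-step GWAS with moving-window scans and the
#' trait-difference statistic -> reduced/complete validation. Every stage's
#' outputs, a log with stage timings and a config snapshot are persisted
#' under `outDir`; a rerun with the same config and seed is bit-identical.
#'
#' @param config named list of settings (or path to a YAML file). Keys and
#'   defaults: `simulate` (TRUE), `sim` (list of [simConfig()] overrides),
#'   `inputs` (paths pedigree/phenotypes/genotypes/map/weather when
#'   `simulate = FALSE`), `thiThreshold` (78), `windowDays` (30), `mafMin`
#'   (0.05), `callrateMin` (0.9), `outlierSd` (4), `alpha` (0.95), `gSource`
#'   ("genomic"; "A22" replaces G by the pedigree submatrix, an equivalence
#'   oracle), `runReml` (TRUE) / `varianceComponents`, `gwasMethod` ("none"),
#'   `gwasIters` (1), `windowSize` (20), `peakThresholdPct` (0.8), `ct`
#'   (1.125), `validate` (TRUE), `cutoffDate` (NULL = `cutoffQuantile` of
#'   slaughter dates), `minProgeny` (200), `seed` (1).
#' @param outDir artifact directory (created if needed).
#' @return Invisibly, a list with the main in-memory results (data, variance
#'   components, solution sets, GWAS tables, validation report).
#' @export
runPipeline <- function(config = list(), outDir = tempfile("thermoGBLUP")) {
  cfg <- readPipelineConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logFile <- file.path(outDir, "log.txt")
  cat("", file = logFile)
  logmsg <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S "), sprintf(...))
    cat(line, "\n", file = logFile, append = TRUE)
    message(line)
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    r <- tryCatch(force(expr), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    logmsg("stage %-13s done in %.1fs", name, proc.time()[["elapsed"]] - t0)
    r
  }
  snap <- cfg
  snap$sim <- if (is(cfg$sim, "SimConfig")) "SimConfig object" else cfg$sim
  snap$varianceComponents <- if (is.null(cfg$varianceComponents)) NULL else "supplied"
  jsonlite::write_json(snap, file.path(outDir, "config.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)

  ## --- simulate / ingest -------------------------------------------------
  res <- list()
  dat <- stage("ingest", {
    if (isTRUE(cfg$simulate)) {
      sc <- if (is(cfg$sim, "SimConfig")) cfg$sim else
        do.call(simConfig, c(cfg$sim, if (!"seed" %in% names(cfg$sim))
          list(seed = cfg$seed)))
      out <- simulateStudy(sc)
      writePedigree(out@pedigree, file.path(outDir, "pedigree.tsv"))
      writePhenotypes(out@phenotypes, file.path(outDir, "phenotypes.csv"))
      writeWeather(out@weather, file.path(outDir, "weather.csv"))
      if (!is.null(out@genotypes))
        writeGenotypes(out@genotypes, file.path(outDir, "genotypes.txt"),
                       file.path(outDir, "map.tsv"))
      writeTruth(out, file.path(outDir, "truth.json"))
      list(pedTable = data.frame(animal = out@pedigree@id,
                                 sire = out@pedigree@sire,
                                 dam = out@pedigree@dam),
           phenotypes = out@phenotypes, weather = out@weather,
           genotypes = out@genotypes, sim = out)
    } else {
      ii <- cfg$inputs
      need <- c("pedigree", "phenotypes", "weather")
      if (!all(need %in% names(ii)))
        stop("inputs must name pedigree, phenotypes and weather files")
      list(pedTable = readPedigree(ii$pedigree),
           phenotypes = readPhenotypes(ii$phenotypes),
           weather = readWeather(ii$weather),
           genotypes = if (!is.null(ii$genotypes))
             readGenotypes(ii$genotypes, ii$map) else NULL,
           sim = NULL)
    }
  })

  ## --- heat load + QC ----------------------------------------------------
  clean <- stage("heatload_qc", {
    ph <- assignTraits(dat$phenotypes, dat$weather,
                       threshold = cfg$thiThreshold,
                       windowDays = cfg$windowDays)
    cl <- cleanRecords(ph, dat$pedTable, outlierSd = cfg$outlierSd)
    geno <- NULL
    if (!is.null(dat$genotypes)) {
      g <- qcGenotypes(dat$genotypes, mafMin = cfg$mafMin,
                       callrateMin = cfg$callrateMin)
      geno <- g$genotypes
      jsonlite::write_json(list(
        genotypes = list(nIn = as.list(g$report@nIn),
                         nOut = as.list(g$report@nOut)),
        records = list(nIn = as.list(cl$report@nIn),
                       nOut = as.list(cl$report@nOut))),
        file.path(outDir, "qc_report.json"), auto_unbox = TRUE, digits = NA)
    }
    writePhenotypes(cl$phenotypes, file.path(outDir, "phenotypes_clean.csv"))
    list(phenotypes = cl$phenotypes, pedTable = cl$pedigree, geno = geno,
         report = cl$report)
  })

  ## --- relationships -----------------------------------------------------
  rel <- stage("relationships", {
    ped <- pedigreeFromTable(clean$pedTable)
    A <- makeA(ped)
    aInv <- makeAInverse(ped)
    G <- A22 <- Hinv <- NULL
    if (!is.null(clean$geno)) {
      A22 <- makeA22(ped, clean$geno@ids)
      G <- if (identical(cfg$gSource, "A22")) A22 else
        makeG(clean$geno, alpha = cfg$alpha, A22 = A22)$G
      Hinv <- makeHInverse(aInv, G, A22, genoIds = clean$geno@ids)
    }
    list(ped = ped, A = A, aInv = aInv, A22 = A22, G = G, Hinv = Hinv)
  })

  ## --- variance components -----------------------------------------------
  vc <- stage("aireml", {
    v <- if (!is.null(cfg$varianceComponents)) cfg$varianceComponents
    else if (isTRUE(cfg$runReml))
      aireml(clean$phenotypes, rel$A)
    else stop("runReml = FALSE requires varianceComponents")
    jsonlite::write_json(list(
      traits = v@traits, varA = as.data.frame(v@varA),
      varLitter = as.list(v@varLitter), varE = as.list(v@varE),
      se = as.list(v@se),
      heritability = lapply(setNames(v@traits, v@traits),
                            function(tr) heritability(v, tr)),
      geneticCorrelation = if (length(v@traits) == 2L)
        geneticCorrelation(v) else NULL,
      converged = v@converged, iterations = v@iterations),
      file.path(outDir, "variance_components.json"),
      auto_unbox = TRUE, null = "null", digits = NA)
    v
  })

  ## --- BLUP / ssGBLUP ----------------------------------------------------
  model <- modelSpec(traits = intersect(c("HS", "NHS"),
                                        unique(clean$phenotypes$trait)))
  sols <- stage("blup", {
    ebv <- solveBLUP(buildMME(model, clean$phenotypes, rel$aInv, vc))
    gebv <- if (!is.null(rel$Hinv))
      solveBLUP(buildMME(model, clean$phenotypes, rel$Hinv, vc)) else NULL
    s <- if (is.null(gebv)) ebv else gebv
    tab <- rbind(cbind(effect = "animal",
                       breedingValues(s)[c("trait", "animal", "solution")]))
    write.table(tab, file.path(outDir, "solutions.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    list(ebv = ebv, gebv = gebv)
  })

  ## --- GWAS ---------------------------------------------------------------
  gwas <- NULL
  if (!is.null(clean$geno) && !identical(cfg$gSource, "A22"))
    gwas <- stage("gwas", {
      perTrait <- lapply(model$traits, function(tr) {
        m1 <- modelSpec(traits = tr)
        iterateWeights(m1, clean$phenotypes, rel$ped, clean$geno, vc,
                       method = cfg$gwasMethod, nIters = cfg$gwasIters,
                       alpha = cfg$alpha, ct = cfg$ct)
      })
      names(perTrait) <- model$traits
      last <- lapply(perTrait, function(x) x[[length(x)]]$effects[[1]])
      win <- lapply(last, windowVariances, windowSize = cfg$windowSize)
      eff <- do.call(rbind, lapply(model$traits, function(tr)
        cbind(trait = tr, snpVariances(last[[tr]]))))
      write.table(eff, file.path(outDir, "snp_effects.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      diffScan <- peaks <- NULL
      if (length(model$traits) == 2L) {
        diffScan <- traitDifference(win[["HS"]], win[["NHS"]])
        write.table(diffScan, file.path(outDir, "windows.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        peaks <- peakReport(diffScan, cfg$peakThresholdPct, pctCol = "absDiff")
        write.table(peaks, file.path(outDir, "peaks.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
      }
      list(iterations = perTrait, windows = win, difference = diffScan,
           peaks = peaks)
    })

  ## --- validation ---------------------------------------------------------
  validation <- NULL
  if (isTRUE(cfg$validate))
    validation <- stage("validate", {
      ph <- clean$phenotypes
      cutoff <- if (!is.null(cfg$cutoffDate)) as.Date(cfg$cutoffDate) else
        as.Date(quantile(as.numeric(as.Date(ph$slaughter_date)),
                         cfg$cutoffQuantile), origin = "1970-01-01")
      sp <- splitByDate(ph, cutoff)
      sires <- selectValidationSires(rel$ped, sp$reduced, sp$complete,
                                     minProgeny = cfg$minProgeny)
      rep <- NULL
      if (length(sires) >= 3L) {
        Kinv <- if (!is.null(rel$Hinv)) rel$Hinv else rel$aInv
        solRed <- solveBLUP(buildMME(model, sp$reduced, Kinv, vc))
        solCom <- if (!is.null(sols$gebv)) sols$gebv else sols$ebv
        rep <- validationAccuracy(solRed, solCom, sires,
                                  traits = model$traits)
        write.table(rep, file.path(outDir, "validation.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
      } else logmsg("validation skipped: only %d eligible sires", length(sires))
      list(cutoff = cutoff, sires = sires, report = rep)
    })

  logmsg("pipeline complete: %s", outDir)
  invisible(list(outDir = outDir, data = clean, relationships = rel,
                 varianceComponents = vc, solutions = sols, gwas = gwas,
                 validation = validation, config = cfg))
}
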