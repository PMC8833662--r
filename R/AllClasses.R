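#' @import methods
#' @importFrom Matrix sparseMatrix forceSymmetric
#' @importFrom stats rnorm rbinom runif var sd cor model.matrix setNames quantile
#' @importFrom utils head tail read.table write.table read.csv write.csv
NULL

TRAITS <- c("HS", "NHS")

#' Pedigree of animals with sire and dam links
#'
#' Ordered pedigree with integer animal ids and parent ids (0 = unknown).
#' Parents must precede their offspring, which also guarantees acyclicity.
#' The `meta` slot carries optional per-animal covariates produced by the
#' simulator (farm, sex, birth date, litter code, breeder flag).
#'
#' @slot id integer animal ids, strictly increasing.
#' @slot sire,dam integer parent ids; 0 codes an unknown parent.
#' @slot meta data.frame with one row per animal (possibly 0 columns).
#' @export
setClass("Pedigree",
  representation(id = "integer", sire = "integer", dam = "integer",
                 meta = "data.frame"),
  prototype(id = integer(), sire = integer(), dam = integer(),
            meta = data.frame()))

setValidity("Pedigree", function(object) {
  n <- length(object@id)
  if (length(object@sire) != n || length(object@dam) != n)
    return("id, sire and dam must have equal length")
  if (n == 0L) return(TRUE)
  if (anyDuplicated(object@id)) return("duplicate animal ids")
  if (is.unsorted(object@id, strictly = TRUE))
    return("animal ids must be strictly increasing")
  for (p in list(object@sire, object@dam)) {
    known <- p != 0L
    if (any(p[known] >= object@id[known]))
      return("parents must precede offspring (parent id < animal id)")
    if (!all(p[known] %in% object@id))
      return("parent id not present in pedigree")
  }
  if (nrow(object@meta) > 0L && nrow(object@meta) != n)
    return("meta must have one row per animal")
  TRUE
})

#' Construct a Pedigree
#'
#' @param id,sire,dam integer vectors; 0 codes an unknown parent.
#' @param meta optional data.frame of per-animal covariates.
#' @return A [Pedigree-class] object.
#' @examples
#' pedigree(1:3, c(0L, 0L, 1L), c(0L, 0L, 2L))
#' @export
pedigree <- function(id, sire, dam, meta = data.frame()) {
  new("Pedigree", id = as.integer(id), sire = as.integer(sire),
      dam = as.integer(dam), meta = meta)
}

#' @describeIn pedigree number of animals in the pedigree
#' @param x a Pedigree
#' @export
nAnimals <- function(x) length(x@id)

#' @export
setMethod("show", "Pedigree", function(object) {
  n <- nAnimals(object)
  founders <- sum(object@sire == 0L & object@dam == 0L)
  cat("Pedigree with", n, "animals (", founders, "founders )\n")
  if (ncol(object@meta)) cat("  meta columns:",
                             paste(colnames(object@meta), collapse = ", "), "\n")
})

#' SNP genotypes with map
#'
#' Dosage matrix (animals x SNPs, values 0/1/2, NA = missing before QC,
#' possibly fractional after mean imputation) together with a physical map.
#'
#' @slot ids integer animal ids (rows of `dosages`).
#' @slot dosages numeric matrix, animals x SNPs.
#' @slot map data.frame with columns snp, chr, pos (bp, 1-based,
#'   strictly increasing within chromosome).
#' @export
setClass("GenotypeData",
  representation(ids = "integer", dosages = "matrix", map = "data.frame"))

setValidity("GenotypeData", function(object) {
  if (nrow(object@dosages) != length(object@ids))
    return("one dosage row per animal id required")
  if (ncol(object@dosages) != nrow(object@map))
    return("one map row per SNP column required")
  if (!all(c("snp", "chr", "pos") %in% colnames(object@map)))
    return("map needs columns snp, chr, pos")
  d <- object@dosages
  if (any(!is.na(d) & (d < 0 | d > 2)))
    return("dosages must lie in [0, 2] or be NA")
  bad <- vapply(split(object@map$pos, object@map$chr),
                function(p) is.unsorted(p, strictly = TRUE), logical(1))
  if (any(bad)) return("map positions must be strictly increasing per chromosome")
  TRUE
})

#' Construct a GenotypeData object
#' @param ids integer animal ids.
#' @param dosages matrix of allele dosages (animals x SNPs).
#' @param map data.frame with columns snp, chr, pos.
#' @return A [GenotypeData-class] object.
#' @export
genotypeData <- function(ids, dosages, map) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  new("GenotypeData", ids = as.integer(ids), dosages = dosages,
      map = as.data.frame(map))
}

#' @describeIn genotypeData observed allele frequencies (counted allele), per SNP
#' @param x a GenotypeData
#' @export
alleleFreq <- function(x) colMeans(x@dosages, na.rm = TRUE) / 2

#' @export
setMethod("show", "GenotypeData", function(object) {
  cat("GenotypeData:", length(object@ids), "animals x",
      nrow(object@map), "SNPs on",
      length(unique(object@map$chr)), "chromosomes\n")
  miss <- mean(is.na(object@dosages))
  if (miss > 0) cat(sprintf("  missing dosages: %.2f%%\n", 100 * miss))
})

#' Variance components of the (two-)trait animal model
#'
#' Holds the additive-genetic covariance matrix between traits, the litter and
#' residual variances per trait (cross-trait litter and residual covariances
#' are structurally zero: an animal is slaughtered once, so the traits are
#' never co-observed), and REML convergence metadata.
#'
#' @slot traits character vector of trait labels ("HS", "NHS").
#' @slot varA genetic (co)variance matrix, kg^2.
#' @slot varLitter,varE per-trait litter and residual variances, kg^2.
#' @slot se approximate standard errors (from the inverse AI matrix), may be empty.
#' @slot converged logical; @slot iterations integer; @slot logLik restricted logL.
#' @export
setClass("VarianceComponents",
  representation(traits = "character", varA = "matrix", varLitter = "numeric",
                 varE = "numeric", se = "numeric", converged = "logical",
                 iterations = "integer", logLik = "numeric"),
  prototype(se = numeric(), converged = NA, iterations = 0L, logLik = NA_real_))

setValidity("VarianceComponents", function(object) {
  t <- length(object@traits)
  if (!all(dim(object@varA) == c(t, t))) return("varA must be traits x traits")
  if (length(object@varLitter) != t || length(object@varE) != t)
    return("varLitter and varE must have one entry per trait")
  if (any(diag(object@varA) < 0) || any(object@varLitter < 0) ||
      any(object@varE < 0))
    return("variances must be non-negative")
  if (t == 2L) {
    lim <- sqrt(prod(diag(object@varA)))
    if (abs(object@varA[1, 2]) > lim + 1e-8 * max(lim, 1))
      return("genetic covariance exceeds Cauchy-Schwarz bound")
    if (abs(object@varA[1, 2] - object@varA[2, 1]) > 1e-12 * max(1, lim))
      return("varA must be symmetric")
  }
  TRUE
})

#' Construct a VarianceComponents object
#'
#' @param traits trait labels, e.g. `c("HS","NHS")`.
#' @param varA genetic (co)variance matrix (or scalar for one trait), kg^2.
#' @param varLitter,varE per-trait litter and residual variances, kg^2.
#' @param se,converged,iterations,logLik optional REML metadata.
#' @return A [VarianceComponents-class] object.
#' @examples
#' varianceComponents(c("HS","NHS"),
#'   varA = matrix(c(84.697, 44.97, 44.97, 60.173), 2),
#'   varLitter = c(31.736, 30.791), varE = c(216.69, 210.69))
#' @export
varianceComponents <- function(traits, varA, varLitter, varE,
                               se = numeric(), converged = NA,
                               iterations = 0L, logLik = NA_real_) {
  varA <- as.matrix(varA)
  dimnames(varA) <- list(traits, traits)
  new("VarianceComponents", traits = traits, varA = varA,
      varLitter = setNames(as.numeric(varLitter), traits),
      varE = setNames(as.numeric(varE), traits), se = se,
      converged = converged, iterations = as.integer(iterations),
      logLik = logLik)
}

#' @export
setMethod("show", "VarianceComponents", function(object) {
  cat("VarianceComponents for trait(s):", paste(object@traits, collapse = ", "), "\n")
  cat("  genetic (co)variance matrix [kg^2]:\n")
  print(round(object@varA, 4))
  cat("  litter variance:  ", paste(round(object@varLitter, 4), collapse = "  "), "\n")
  cat("  residual variance:", paste(round(object@varE, 4), collapse = "  "), "\n")
  for (tr in object@traits)
    cat(sprintf("  h2(%s) = %.4f\n", tr, heritability(object, tr)))
  if (length(object@traits) == 2L)
    cat(sprintf("  genetic correlation = %.4f\n", geneticCorrelation(object)))
  if (!is.na(object@converged))
    cat(sprintf("  REML: %s in %d iterations, logL = %.4f\n",
                if (object@converged) "converged" else "NOT converged",
                object@iterations, object@logLik))
})

#' Solutions of the mixed model equations
#'
#' @slot fixed data.frame (effect, level, trait, solution).
#' @slot litter data.frame (litter, trait, solution).
#' @slot animal data.frame (animal, trait, solution) — EBV/GEBV in kg.
#' @slot residualNorm relative residual norm of the solved system.
#' @export
setClass("SolutionSet",
  representation(fixed = "data.frame", litter = "data.frame",
                 animal = "data.frame", residualNorm = "numeric"))

#' @export
setMethod("show", "SolutionSet", function(object) {
  cat("SolutionSet:", nrow(object@fixed), "fixed,", nrow(object@litter),
      "litter,", nrow(object@animal), "animal solutions",
      sprintf("(rel. residual %.2e)\n", object@residualNorm))
})

#' Breeding values of a solution set
#' @param x a [SolutionSet-class]
#' @param trait optional trait label to subset
#' @return data.frame (animal, trait, solution)
#' @export
breedingValues <- function(x, trait = NULL) {
  bv <- x@animal
  if (!is.null(trait)) bv <- bv[bv$trait == trait, , drop = FALSE]
  bv
}

#' Quality-control report
#'
#' Counts in/out per item class plus a table of removals with reasons.
#' @slot nIn,nOut named integer counts (snps, animals, records as applicable).
#' @slot removed data.frame (item, type, reason).
#' @export
setClass("QCReport",
  representation(nIn = "integer", nOut = "integer", removed = "data.frame"))

setValidity("QCReport", function(object) {
  if (!identical(names(object@nIn), names(object@nOut)))
    return("nIn and nOut must cover the same item classes")
  if (any(object@nOut > object@nIn)) return("out counts cannot exceed in counts")
  TRUE
})

#' @export
setMethod("show", "QCReport", function(object) {
  cat("QCReport:\n")
  for (k in names(object@nIn))
    cat(sprintf("  %-8s %d in -> %d out (%d removed)\n", k,
                object@nIn[[k]], object@nOut[[k]],
                object@nIn[[k]] - object@nOut[[k]]))
  if (nrow(object@removed)) {
    tab <- table(object@removed$reason)
    for (r in names(tab)) cat("   -", r, ":", tab[[r]], "\n")
  }
})
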