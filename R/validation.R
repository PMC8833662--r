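#' Split phenotype records at a cutoff date
#'
#' The reduced set keeps records dated on or before the cutoff ("after" is
#' strict); the complete set is all records.
#'
#' @param phenotypes data.frame with a `slaughter_date` column.
#' @param cutoff cutoff date (Date or coercible).
#' @return List `reduced`, `complete`.
#' @export
splitByDate <- function(phenotypes, cutoff) {
  cutoff <- as.Date(cutoff)
  list(reduced = phenotypes[as.Date(phenotypes$slaughter_date) <= cutoff, ,
                            drop = FALSE],
       complete = phenotypes)
}

#' Select validation sires
#'
#' Sires with at least `minProgeny` progeny holding records in the complete
#' data but no progeny with records in the reduced data, in deterministic
#' (ascending id) order.
#'
#' @param ped a [Pedigree-class] (or data.frame with animal, sire columns).
#' @param reduced,complete phenotype data.frames from [splitByDate()].
#' @param minProgeny progeny threshold (default 200).
#' @return Integer vector of sire ids (possibly empty, with a warning).
#' @export
selectValidationSires <- function(ped, reduced, complete, minProgeny = 200L) {
  sireOf <- if (is(ped, "Pedigree")) setNames(ped@sire, ped@id)
            else setNames(ped$sire, ped$animal)
  sC <- sireOf[as.character(complete$animal)]
  sR <- sireOf[as.character(reduced$animal)]
  nC <- table(sC[!is.na(sC) & sC != 0])
  inR <- unique(sR[!is.na(sR) & sR != 0])
  sel <- sort(as.integer(names(nC)[nC >= minProgeny &
                                   !(names(nC) %in% as.character(inR))]))
  if (!length(sel)) warning("no sires satisfy the validation design")
  sel
}

#' Validation accuracies (homo- and hetero-correlations)
#'
#' Pearson correlation, over the validation sires, between reduced-data EBVs
#' and the complete-data benchmark GEBVs ("TBV"), for all four trait
#' pairings: same-trait pairings are the homo-correlations, crossed pairings
#' the hetero-correlations.
#'
#' @param solReduced,solComplete [SolutionSet-class] objects from the reduced
#'   and complete runs (the complete run is conventionally the two-trait
#'   unweighted single-step analysis).
#' @param sires validation sire ids (>= 3).
#' @param traits trait labels to pair (default HS, NHS).
#' @return data.frame (ebvTrait, tbvTrait, type, r, n); `r` is NA with a
#'   warning when a vector has zero variance.
#' @export
validationAccuracy <- function(solReduced, solComplete, sires,
                               traits = c("HS", "NHS")) {
  if (length(sires) < 3L) stop("need at least 3 validation sires")
  grab <- function(sol, tr) {
    bv <- breedingValues(sol, tr)
    v <- setNames(bv$solution, bv$animal)[as.character(sires)]
    if (anyNA(v)) stop("missing solutions for some validation sires")
    v
  }
  out <- expand.grid(ebvTrait = traits, tbvTrait = traits,
                     stringsAsFactors = FALSE)
  out$type <- ifelse(out$ebvTrait == out$tbvTrait, "homo", "hetero")
  out$r <- NA_real_
  out$n <- length(sires)
  for (i in seq_len(nrow(out))) {
    e <- grab(solReduced, out$ebvTrait[i])
    t <- grab(solComplete, out$tbvTrait[i])
    if (sd(e) == 0 || sd(t) == 0) {
      warning("zero variance in a validation vector; correlation undefined")
    } else out$r[i] <- cor(e, t)
  }
  out
}
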