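#' Genotype quality control
#'
#' Applies the study's marker cleaning rules in a fixed, reproducible order:
#' (1) drop animals with call rate below `callrateMin`; (2) drop SNPs with
#' call rate below `callrateMin` among surviving animals; (3) drop SNPs that
#' are monomorphic or have minor allele frequency below `mafMin` (frequencies
#' computed on surviving animals). Remaining missing dosages are imputed to
#' twice the observed allele frequency.
#'
#' @param geno a [GenotypeData-class]; missing dosages coded NA.
#' @param mafMin minimum minor allele frequency (default 0.05).
#' @param callrateMin minimum SNP and animal call rate (default 0.9).
#' @return List: `genotypes` (cleaned [GenotypeData-class]) and
#'   `report` (a [QCReport-class]).
#' @export
qcGenotypes <- function(geno, mafMin = 0.05, callrateMin = 0.9) {
  stopifnot(is(geno, "GenotypeData"))
  d <- geno@dosages
  removed <- data.frame(item = character(), type = character(),
                        reason = character())
  crAnimal <- rowMeans(!is.na(d))
  dropA <- crAnimal < callrateMin
  if (any(dropA))
    removed <- rbind(removed, data.frame(
      item = as.character(geno@ids[dropA]), type = "animal",
      reason = "animal call rate < min"))
  d2 <- d[!dropA, , drop = FALSE]
  crSnp <- colMeans(!is.na(d2))
  dropCall <- crSnp < callrateMin
  p <- colMeans(d2, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  mono <- !dropCall & (is.nan(p) | p <= 0 | p >= 1)
  lowMaf <- !dropCall & !mono & maf < mafMin
  for (ix in list(list(dropCall, "SNP call rate < min"),
                  list(mono, "monomorphic"),
                  list(lowMaf, "MAF < min"))) {
    if (any(ix[[1]]))
      removed <- rbind(removed, data.frame(
        item = geno@map$snp[ix[[1]]], type = "snp", reason = ix[[2]]))
  }
  keepSnp <- !(dropCall | mono | lowMaf)
  if (!any(keepSnp) || !any(!dropA))
    stop("no SNPs or animals survive genotype QC")
  d3 <- d2[, keepSnp, drop = FALSE]
  p3 <- colMeans(d3, na.rm = TRUE) / 2
  for (j in seq_len(ncol(d3))) {
    na <- is.na(d3[, j])
    if (any(na)) d3[na, j] <- 2 * p3[j]
  }
  report <- new("QCReport",
    nIn = c(snps = ncol(d), animals = nrow(d)),
    nOut = c(snps = ncol(d3), animals = nrow(d3)),
    removed = removed)
  list(genotypes = genotypeData(geno@ids[!dropA], d3,
                                geno@map[keepSnp, , drop = FALSE]),
       report = report)
}

## detect animals that appear in their own ancestry (pedigree conflict)
findPedigreeCycles <- function(id, sire, dam) {
  sireIdx <- match(sire, id)
  damIdx <- match(dam, id)
  bad <- logical(length(id))
  for (i in seq_along(id)) {
    seen <- integer()
    stack <- c(sireIdx[i], damIdx[i])
    stack <- stack[!is.na(stack)]
    while (length(stack)) {
      j <- stack[[1]]; stack <- stack[-1]
      if (j == i) { bad[i] <- TRUE; break }
      if (j %in% seen) next
      seen <- c(seen, j)
      up <- c(sireIdx[j], damIdx[j])
      stack <- c(stack, up[!is.na(up)])
    }
  }
  bad
}

#' Clean phenotype records and pedigree
#'
#' Applies the study's record cleaning rules: phenotyped animals with both
#' parents unknown are dropped; animals involved in pedigree conflicts
#' (appearing in their own ancestry, or duplicated ids with differing
#' parents) are dropped from the pedigree and their records with them;
#' records more than `outlierSd` standard deviations from the phenotype mean
#' are dropped (two-sided, per trait by default).
#'
#' @param phenotypes data.frame with columns animal, hcw_kg and (if
#'   `perTrait`) trait.
#' @param pedigreeTable data.frame with columns animal, sire, dam (0 =
#'   unknown); may contain duplicates/conflicts, unlike [Pedigree-class].
#' @param outlierSd outlier cut in SD units (default 4).
#' @param perTrait compute the outlier mean/SD per trait (default TRUE) or
#'   pooled.
#' @return List: `phenotypes`, `pedigree` (cleaned data.frames) and `report`
#'   (a [QCReport-class]).
#' @export
cleanRecords <- function(phenotypes, pedigreeTable, outlierSd = 4,
                         perTrait = TRUE) {
  removed <- data.frame(item = character(), type = character(),
                        reason = character())
  ped <- pedigreeTable
  dup <- duplicated(ped$animal) | duplicated(ped$animal, fromLast = TRUE)
  conflictDup <- unique(ped$animal[dup][
    vapply(ped$animal[dup], function(a) {
      rows <- ped[ped$animal == a, c("sire", "dam")]
      nrow(unique(rows)) > 1L
    }, logical(1))])
  ped <- ped[!ped$animal %in% conflictDup, , drop = FALSE]
  ped <- ped[!duplicated(ped$animal), , drop = FALSE]
  cyc <- findPedigreeCycles(ped$animal, ped$sire, ped$dam)
  conflictCyc <- ped$animal[cyc]
  ped <- ped[!cyc, , drop = FALSE]
  # sever links to removed animals
  gone <- c(conflictDup, conflictCyc)
  ped$sire[ped$sire %in% gone] <- 0L
  ped$dam[ped$dam %in% gone] <- 0L
  if (length(conflictDup))
    removed <- rbind(removed, data.frame(item = as.character(conflictDup),
      type = "animal", reason = "duplicate id with conflicting parents"))
  if (length(conflictCyc))
    removed <- rbind(removed, data.frame(item = as.character(conflictCyc),
      type = "animal", reason = "animal in its own ancestry"))

  ph <- phenotypes
  nRecIn <- nrow(ph)
  drop1 <- ph$animal %in% gone
  bothMissing <- with(ped[match(ph$animal, ped$animal), ],
                      sire == 0L & dam == 0L)
  bothMissing[is.na(bothMissing)] <- TRUE   # not in pedigree at all
  drop2 <- !drop1 & bothMissing
  if (any(drop2))
    removed <- rbind(removed, data.frame(item = as.character(ph$animal[drop2]),
      type = "record", reason = "both parents unknown"))
  ph <- ph[!(drop1 | drop2), , drop = FALSE]

  grp <- if (perTrait && "trait" %in% colnames(ph)) ph$trait else rep("all", nrow(ph))
  out <- logical(nrow(ph))
  for (g in unique(grp)) {
    i <- grp == g
    m <- mean(ph$hcw_kg[i]); s <- sd(ph$hcw_kg[i])
    if (is.finite(s) && s > 0)
      out[i] <- abs(ph$hcw_kg[i] - m) > outlierSd * s
  }
  if (any(out))
    removed <- rbind(removed, data.frame(item = as.character(ph$animal[out]),
      type = "record", reason = sprintf("outlier beyond %g SD", outlierSd)))
  ph <- ph[!out, , drop = FALSE]

  report <- new("QCReport",
    nIn = c(records = nRecIn, animals = nrow(pedigreeTable)),
    nOut = c(records = nrow(ph), animals = nrow(ped)),
    removed = removed)
  list(phenotypes = ph, pedigree = ped, report = report)
}
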