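#' Backsolve SNP effects from breeding values
#'
#' Recovers per-SNP allele-substitution effects from the GEBVs of the
#' genotyped animals: `u = D M' [M D M']^-1 a`, with M the centered dosage
#' matrix and D the SNP-weight diagonal. At `alpha = 1` the bracket is the
#' raw `M D M'` and the reconstruction identity `M u = a` holds exactly;
#' with blending (`alpha < 1`) the blended `G* (2 sum pq)` replaces the
#' bracket so the system stays invertible.
#'
#' @param geno post-QC [GenotypeData-class].
#' @param ahat named numeric vector of (G)EBVs for the genotyped animals
#'   (names = animal ids), or a data.frame (animal, solution).
#' @param weights SNP weight diagonal d (default 1).
#' @param alpha blending weight passed to [makeG()] (default 1 = raw).
#' @param A22 pedigree submatrix, required when `alpha < 1`.
#' @param gres optional precomputed result of [makeG()] (saves the rebuild).
#' @param trait,iteration,method labels attached to the returned table.
#' @return data.frame (snp, chr, pos, freq, weight, effect) with attributes
#'   `trait`, `iteration`, `method`.
#' @export
backsolveSnpEffects <- function(geno, ahat, weights = NULL, alpha = 1,
                                A22 = NULL, gres = NULL,
                                trait = NA_character_, iteration = 1L,
                                method = "none") {
  stopifnot(is(geno, "GenotypeData"))
  if (is.data.frame(ahat))
    ahat <- setNames(ahat$solution, ahat$animal)
  a <- ahat[as.character(geno@ids)]
  if (anyNA(a)) stop("breeding values missing for some genotyped animals")
  if (is.null(weights)) weights <- rep(1, nrow(geno@map))
  if (is.null(gres))
    gres <- makeG(geno, weights = weights, alpha = alpha, A22 = A22)
  M <- sweep(geno@dosages, 2L, 2 * gres$freq, "-")
  bracket <- gres$G * gres$denom
  sol <- tryCatch(solve(bracket, a), error = function(e)
    stop("M D M' is singular; blend with A22 (alpha < 1): ",
         conditionMessage(e)))
  u <- weights * as.numeric(crossprod(M, sol))
  out <- data.frame(snp = geno@map$snp, chr = geno@map$chr,
                    pos = geno@map$pos, freq = gres$freq, weight = weights,
                    effect = u, row.names = NULL)
  attr(out, "trait") <- trait
  attr(out, "iteration") <- iteration
  attr(out, "method") <- method
  out
}

#' Per-SNP variance
#'
#' `v_s = u_s^2 * 2 p_s (1 - p_s)`; the fractions `v_s / sum(v)` add to 1
#' over the genome.
#'
#' @param effects a SNP-effect table from [backsolveSnpEffects()].
#' @return The table with a `varSnp` column appended.
#' @export
snpVariances <- function(effects) {
  effects$varSnp <- effects$effect^2 * 2 * effects$freq * (1 - effects$freq)
  effects
}

#' Quadratic SNP weights
#'
#' `d_s = u_s^2` (no allele-frequency factor), floored at `eps` and then
#' rescaled so the trace of D equals the number of SNPs (total-variance
#' conservation).
#'
#' @param u SNP effects.
#' @param eps floor applied to zero weights (default 1e-8).
#' @param normalize rescale to trace = number of SNPs (default TRUE).
#' @return Positive weight vector.
#' @export
weightQuadratic <- function(u, eps = 1e-8, normalize = TRUE) {
  d <- pmax(u^2, eps)
  if (normalize) d <- d * length(d) / sum(d)
  d
}

#' Nonlinear "A" SNP weights
#'
#' `d_s = [sigma2_a / (2 sum p q)] * CT^min(|u_s|/sd(u) - 2, 5)`: the
#' departure-from-normality constant CT defaults to 1.125 and the exponent is
#' capped at 5 to avoid extreme weights. Weights are floored and rescaled to
#' trace = number of SNPs.
#'
#' @param u SNP effects; `sd(u)` must be positive.
#' @param varA additive genetic variance of the trait.
#' @param denom `2 sum p q` scaling from [makeG()].
#' @param ct constant (default 1.125).
#' @param capExp exponent cap (default 5).
#' @param eps,normalize as in [weightQuadratic()].
#' @return Positive weight vector.
#' @export
weightNonlinearA <- function(u, varA, denom, ct = 1.125, capExp = 5,
                             eps = 1e-8, normalize = TRUE) {
  s <- sd(u)
  if (!is.finite(s) || s <= 0) stop("sd of SNP effects is zero; degenerate effects")
  d <- (varA / denom) * ct^pmin(abs(u) / s - 2, capExp)
  d <- pmax(d, eps)
  if (normalize) d <- d * length(d) / sum(d)
  d
}

#' Iterative SNP weighting for single-step GWAS
#'
#' Iteration 1 uses D = I (the unweighted analysis); each later iteration
#' rebuilds G with the updated weights, re-solves the single-step GEBVs and
#' re-backsolves SNP effects. The weights for the next iteration are derived
#' from the effects of `weightTrait`.
#'
#' @param model a [modelSpec()] (its traits are solved jointly; weights come
#'   from `weightTrait`).
#' @param data cleaned phenotype data.frame.
#' @param ped a [Pedigree-class].
#' @param geno post-QC [GenotypeData-class].
#' @param vc a [VarianceComponents-class].
#' @param method "none", "quadratic" or "nonlinearA".
#' @param nIters number of iterations (>= 1).
#' @param weightTrait trait whose effects drive the weights (default first
#'   model trait).
#' @param alpha G blending weight (default 0.95).
#' @param ct nonlinear-A constant (default 1.125).
#' @return List with one element per iteration: `weights`, `solutions` (a
#'   [SolutionSet-class]), `effects` (list of SNP-effect tables per trait).
#' @export
iterateWeights <- function(model, data, ped, geno, vc,
                           method = c("none", "quadratic", "nonlinearA"),
                           nIters = 1L, weightTrait = model$traits[1],
                           alpha = 0.95, ct = 1.125) {
  method <- match.arg(method)
  stopifnot(nIters >= 1L)
  aInv <- makeAInverse(ped)
  A22 <- makeA22(ped, geno@ids)
  D <- rep(1, nrow(geno@map))
  out <- vector("list", nIters)
  for (k in seq_len(nIters)) {
    gres <- makeG(geno, weights = D, alpha = alpha, A22 = A22)
    Hinv <- makeHInverse(aInv, gres$G, A22)
    sol <- solveBLUP(buildMME(model, data, Hinv, vc))
    effects <- lapply(model$traits, function(tr) {
      bv <- breedingValues(sol, tr)
      bv <- bv[bv$animal %in% geno@ids, ]
      backsolveSnpEffects(geno, bv, weights = D, gres = gres, trait = tr,
                          iteration = k, method = method)
    })
    names(effects) <- model$traits
    out[[k]] <- list(weights = D, solutions = sol, effects = effects)
    if (k < nIters && method != "none") {
      u <- effects[[weightTrait]]$effect
      D <- switch(method,
        quadratic = weightQuadratic(u),
        nonlinearA = weightNonlinearA(u, vc@varA[weightTrait, weightTrait],
                                      gres$denom, ct = ct))
    }
  }
  out
}

#' Moving-window percentages of genetic variance
#'
#' Sums the per-SNP variances `u^2 2p(1-p)` over moving windows of
#' `windowSize` consecutive SNPs (advancing by `step`, never spanning
#' chromosomes) and expresses each window as a percent of the total summed
#' over all SNPs. A chromosome with fewer SNPs than the window yields a
#' single truncated window, with a warning.
#'
#' @param effects SNP-effect table (sorted by chr, pos as produced by the
#'   backsolve).
#' @param windowSize number of SNPs per window (default 20).
#' @param step window advance in SNPs (default 1).
#' @return data.frame (window, chr, startSnp, endSnp, startBp, endBp, pct).
#' @export
windowVariances <- function(effects, windowSize = 20L, step = 1L) {
  eff <- snpVariances(effects)
  if (is.unsorted(order(eff$chr, eff$pos))) eff <- eff[order(eff$chr, eff$pos), ]
  total <- sum(eff$varSnp)
  res <- list()
  for (ch in unique(eff$chr)) {
    e <- eff[eff$chr == ch, , drop = FALSE]
    m <- nrow(e)
    if (m < windowSize) {
      warning("chromosome ", ch, " has fewer than ", windowSize,
              " SNPs; one truncated window")
      starts <- 1L; ends <- m
    } else {
      starts <- seq.int(1L, m - windowSize + 1L, by = step)
      ends <- starts + windowSize - 1L
    }
    cs <- c(0, cumsum(e$varSnp))
    res[[length(res) + 1L]] <- data.frame(
      chr = ch, startSnp = e$snp[starts], endSnp = e$snp[ends],
      startBp = e$pos[starts], endBp = e$pos[ends],
      startIdx = starts, endIdx = ends,
      pct = if (total > 0) 100 * (cs[ends + 1L] - cs[starts]) / total else 0)
  }
  out <- do.call(rbind, res)
  out <- cbind(window = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Trait-difference thermotolerance scan
#'
#' Absolute difference of the window percentages of the two traits on an
#' identical window frame; peaks in |HS - NHS| mark regions whose effect
#' changes with heat load.
#'
#' @param windowsHS,windowsNHS window tables from [windowVariances()] built
#'   on the same map and window size.
#' @return The window frame with columns pctHS, pctNHS and absDiff.
#' @export
traitDifference <- function(windowsHS, windowsNHS) {
  key <- c("chr", "startSnp", "endSnp", "startBp", "endBp")
  if (nrow(windowsHS) != nrow(windowsNHS) ||
      !identical(windowsHS[key], windowsNHS[key]))
    stop("window frames differ; compute both scans on the same map and window size")
  out <- windowsHS
  names(out)[names(out) == "pct"] <- "pctHS"
  out$pctNHS <- windowsNHS$pct
  out$absDiff <- abs(out$pctHS - out$pctNHS)
  out
}

#' Call peaks above a variance-explained threshold
#'
#' Windows above the threshold are merged into peaks wherever their SNP
#' ranges overlap on the same chromosome (maximal runs of overlapping
#' supra-threshold windows).
#'
#' @param windows a window table ([windowVariances()] or [traitDifference()]).
#' @param thresholdPct percent threshold (default 0.8).
#' @param pctCol column holding the statistic (default "pct"; use "absDiff"
#'   for the difference scan).
#' @return data.frame (chr, startBp, endBp, maxPct, nWindows); empty if no
#'   window exceeds the threshold.
#' @export
peakReport <- function(windows, thresholdPct = 0.8, pctCol = "pct") {
  hot <- windows[windows[[pctCol]] > thresholdPct, , drop = FALSE]
  empty <- data.frame(chr = integer(), startBp = numeric(), endBp = numeric(),
                      maxPct = numeric(), nWindows = integer())
  if (!nrow(hot)) return(empty)
  hot <- hot[order(hot$chr, hot$startIdx), ]
  peaks <- list()
  cur <- hot[1, ]
  curMax <- cur[[pctCol]]; curN <- 1L
  flush <- function(cur, curMax, curN)
    data.frame(chr = cur$chr, startBp = cur$startBp, endBp = cur$endBp,
               maxPct = curMax, nWindows = curN)
  for (i in seq_len(nrow(hot))[-1]) {
    w <- hot[i, ]
    if (w$chr == cur$chr && w$startIdx <= cur$endIdx) {
      cur$endIdx <- max(cur$endIdx, w$endIdx)
      cur$endBp <- max(cur$endBp, w$endBp)
      curMax <- max(curMax, w[[pctCol]])
      curN <- curN + 1L
    } else {
      peaks[[length(peaks) + 1L]] <- flush(cur, curMax, curN)
      cur <- w; curMax <- w[[pctCol]]; curN <- 1L
    }
  }
  peaks[[length(peaks) + 1L]] <- flush(cur, curMax, curN)
  out <- do.call(rbind, peaks)
  rownames(out) <- NULL
  out
}

#' Independent chromosome segments
#'
#' `q = 2 Ne L / log(2 Ne L)` (natural log), the effective number of
#' independently segregating genome segments for effective population size
#' Ne and genome length L in Morgans.
#'
#' @param Ne effective population size (> 0).
#' @param L genome length in Morgans (> 0).
#' @param base logarithm base (default `exp(1)`).
#' @return List (Ne, L, q).
#' @examples
#' chromosomeSegments(55, 19)  # q = 2090/ln(2090) = 273.4
#' @export
chromosomeSegments <- function(Ne, L, base = exp(1)) {
  stopifnot(Ne > 0, L > 0)
  x <- 2 * Ne * L
  if (x <= 1) stop("2*Ne*L must exceed 1")
  list(Ne = Ne, L = L, q = x / log(x, base = base))
}
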