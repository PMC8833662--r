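#' Numerator relationship matrix (tabular method)
#'
#' Builds the pedigree relationship matrix A by the tabular recursion:
#' `A[i,j] = (A[sire(i),j] + A[dam(i),j])/2` for j < i and
#' `A[i,i] = 1 + A[sire(i),dam(i)]/2`, with unknown-parent contributions
#' omitted. Diagonal elements are `1 + F` (F = inbreeding coefficient).
#'
#' @param ped a [Pedigree-class] (parents precede offspring, so the recursion
#'   is well-defined; cycles are impossible by construction/validity).
#' @return Dense symmetric matrix with dimnames = animal ids.
#' @examples
#' p <- pedigree(1:3, c(0L,0L,1L), c(0L,0L,2L))
#' makeA(p)
#' @export
makeA <- function(ped) {
  stopifnot(is(ped, "Pedigree"))
  n <- nAnimals(ped)
  s <- match(ped@sire, ped@id)
  d <- match(ped@dam, ped@id)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    if (i > 1L) {
      j <- seq_len(i - 1L)
      aij <- numeric(i - 1L)
      if (!is.na(s[i])) aij <- aij + 0.5 * A[s[i], j]
      if (!is.na(d[i])) aij <- aij + 0.5 * A[d[i], j]
      A[i, j] <- aij
      A[j, i] <- aij
    }
    A[i, i] <- 1 + if (!is.na(s[i]) && !is.na(d[i])) 0.5 * A[s[i], d[i]] else 0
  }
  dimnames(A) <- list(ped@id, ped@id)
  A
}

#' Pedigree submatrix over the genotyped animals
#'
#' A22 is obtained by subsetting the tabular A; at desk scale this is exact
#' and cheap. (The contract is the submatrix itself, so a recursion-based
#' method may replace the construction for larger pedigrees.)
#'
#' @param ped a [Pedigree-class].
#' @param ids animal ids of the genotyped subset.
#' @return Dense symmetric matrix over `ids`, in the order given.
#' @export
makeA22 <- function(ped, ids) {
  idx <- match(ids, ped@id)
  if (anyNA(idx)) stop("genotyped ids must be a subset of the pedigree")
  makeA(ped)[idx, idx, drop = FALSE]
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules with inbreeding: each animal contributes
#' `alpha_i = 1/m_i` to the (i,i) element, `-alpha_i/2` to (i,parent) and
#' `alpha_i/4` to each (parent,parent) pair, where the Mendelian-sampling
#' variance is `m_i = 1/2 - (F_s + F_d)/4` with both parents known,
#' `3/4 - F_p/4` with one, and 1 with none. Inbreeding coefficients come
#' from the tabular A diagonal.
#'
#' @param ped a [Pedigree-class].
#' @return Sparse symmetric Matrix (dsCMatrix) with dimnames = animal ids.
#' @export
makeAInverse <- function(ped) {
  stopifnot(is(ped, "Pedigree"))
  n <- nAnimals(ped)
  s <- match(ped@sire, ped@id)
  d <- match(ped@dam, ped@id)
  Fi <- inbreeding(ped)
  m <- ifelse(!is.na(s) & !is.na(d), 0.5 - 0.25 * (Fi[ifelse(is.na(s), 1L, s)] +
                                                   Fi[ifelse(is.na(d), 1L, d)]),
       ifelse(!is.na(s), 0.75 - 0.25 * Fi[ifelse(is.na(s), 1L, s)],
       ifelse(!is.na(d), 0.75 - 0.25 * Fi[ifelse(is.na(d), 1L, d)], 1)))
  alpha <- 1 / m
  ii <- c(); jj <- c(); xx <- c()
  add <- function(i, j, x) { ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, x) }
  add(seq_len(n), seq_len(n), alpha)
  for (p in list(s, d)) {
    k <- which(!is.na(p))
    add(k, p[k], -alpha[k] / 2)
    add(p[k], k, -alpha[k] / 2)
    add(p[k], p[k], alpha[k] / 4)
  }
  both <- which(!is.na(s) & !is.na(d))
  add(s[both], d[both], alpha[both] / 4)
  add(d[both], s[both], alpha[both] / 4)
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               dimnames = list(ped@id, ped@id))
  Matrix::forceSymmetric(Ainv)
}

#' Genomic relationship matrix
#'
#' VanRaden's G with optional SNP weights: `G = M D M' / (2 sum p q)` where
#' M is the dosage matrix centered by twice the allele frequency and D a
#' positive diagonal of SNP weights (D = I gives every SNP equal
#' contribution). The raw G is blended with the pedigree submatrix,
#' `G* = alpha G + (1 - alpha) A22`, to guarantee invertibility; `alpha = 1`
#' returns the raw definition.
#'
#' @param geno a post-QC [GenotypeData-class] (no missing dosages).
#' @param weights per-SNP weight diagonal d (default all 1).
#' @param freq allele frequencies used for centering and scaling; default the
#'   observed frequencies in the genotyped set.
#' @param alpha blending weight on the genomic part (default 0.95).
#' @param A22 pedigree submatrix over the genotyped animals (same order);
#'   required when `alpha < 1`.
#' @return List: `G` (blended), `Graw`, `denom` (= 2 sum p q), `freq`,
#'   `alpha`.
#' @export
makeG <- function(geno, weights = NULL, freq = NULL, alpha = 0.95, A22 = NULL) {
  stopifnot(is(geno, "GenotypeData"))
  d <- geno@dosages
  if (anyNA(d)) stop("genotypes must be QC'd/imputed before building G")
  if (is.null(freq)) freq <- colMeans(d) / 2
  if (any(freq <= 0 | freq >= 1))
    stop("allele frequencies must lie strictly in (0, 1); run QC first")
  if (is.null(weights)) weights <- rep(1, ncol(d))
  if (any(weights <= 0)) stop("SNP weights must be positive")
  denom <- 2 * sum(freq * (1 - freq))
  if (denom <= 0) stop("2*sum(p*q) is zero; no polymorphic SNPs")
  M <- sweep(d, 2L, 2 * freq, "-")
  Graw <- tcrossprod(sweep(M, 2L, weights, "*"), M) / denom
  dimnames(Graw) <- list(geno@ids, geno@ids)
  if (alpha < 1) {
    if (is.null(A22)) stop("blending (alpha < 1) requires A22")
    stopifnot(all(dim(A22) == dim(Graw)))
    G <- alpha * Graw + (1 - alpha) * A22
  } else G <- Graw
  list(G = G, Graw = Graw, denom = denom, freq = freq, alpha = alpha)
}

#' Inverse of the single-step relationship matrix
#'
#' `H^-1 = A^-1 + [0 0; 0 G^-1 - A22^-1]` with the nonzero block placed on
#' the genotyped animals, pedigree order preserved.
#'
#' @param aInv sparse A-inverse over the full pedigree (from [makeAInverse]).
#' @param G (blended) genomic relationship matrix over the genotyped animals.
#' @param A22 pedigree submatrix over the same animals, same order.
#' @param genoIds animal ids of the genotyped subset (default: dimnames of G).
#' @return Sparse symmetric Matrix over the pedigree.
#' @export
makeHInverse <- function(aInv, G, A22, genoIds = rownames(G)) {
  if (is.null(genoIds)) stop("genotyped animal ids required")
  idx <- match(genoIds, rownames(aInv))
  if (anyNA(idx)) stop("genotyped ids must be a subset of the pedigree")
  if (length(idx) == 0L) return(aInv)
  Ginv <- tryCatch(solve(G),
    error = function(e) stop("G is singular; blend with A22 (alpha < 1): ",
                             conditionMessage(e)))
  delta <- Ginv - solve(A22)
  n <- nrow(aInv)
  ng <- length(idx)
  D <- Matrix::sparseMatrix(i = rep(idx, ng), j = rep(idx, each = ng),
                            x = as.numeric(delta), dims = c(n, n),
                            dimnames = dimnames(aInv))
  Matrix::forceSymmetric(aInv + D)
}

#' Export a symmetric matrix in coordinate text form
#'
#' Writes the lower triangle as `i j value` rows (1-based ids via the row
#' names), mirroring the conventions of common mixed-model tools.
#'
#' @param m matrix (dense or sparse) with row names giving ids.
#' @param file output path.
#' @param tol entries with |value| <= tol are skipped (default 0).
#' @export
writeMatrixCoo <- function(m, file, tol = 0) {
  m <- as(as(m, "generalMatrix"), "TsparseMatrix")
  keep <- m@i >= m@j & abs(m@x) > tol
  ids <- rownames(m)
  df <- data.frame(i = ids[m@i[keep] + 1L], j = ids[m@j[keep] + 1L],
                   value = m@x[keep])
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
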