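#' Model specification for the (two-)trait animal model
#'
#' Describes the record model: contemporary group, sex and an age regression
#' as fixed effects, litter and animal as random effects, and the source of
#' the animal relationship structure.
#'
#' @param traits trait subset: "HS", "NHS" or both.
#' @param fixed fixed effects among "cg", "sex", "age" (age enters as a
#'   covariate with one regression per trait).
#' @param random random effects among "litter", "animal".
#' @param relationship "pedigree" or "single-step" (informational; the
#'   relationship inverse itself is passed to [buildMME()]).
#' @return A list of class `modelSpec`.
#' @export
modelSpec <- function(traits = c("HS", "NHS"),
                      fixed = c("cg", "sex", "age"),
                      random = c("litter", "animal"),
                      relationship = c("pedigree", "single-step")) {
  stopifnot(all(traits %in% c("HS", "NHS")), !anyDuplicated(traits),
            all(fixed %in% c("cg", "sex", "age")),
            all(random %in% c("litter", "animal")))
  structure(list(traits = traits, fixed = fixed, random = random,
                 relationship = match.arg(relationship)),
            class = "modelSpec")
}

## Column catalogue for the sparse design: each entry is (type, effect,
## level, trait); fixed factors lose their first level for identifiability.
buildDesign <- function(model, data, animalIds) {
  traits <- model$traits
  data <- data[data$trait %in% traits, , drop = FALSE]
  if (!nrow(data)) stop("no records for the requested trait(s)")
  need <- c("hcw_kg", "trait",
            intersect(c("cg", "sex"), model$fixed),
            if ("age" %in% model$fixed) "age_d",
            if ("litter" %in% model$random) "litter",
            if ("animal" %in% model$random) "animal")
  miss <- setdiff(need, colnames(data))
  if (length(miss)) stop("data lacks columns: ", paste(miss, collapse = ", "))
  nrec <- nrow(data)
  ageC <- if ("age" %in% model$fixed) mean(data$age_d) else NA_real_

  cols <- data.frame(type = character(), effect = character(),
                     level = character(), trait = character())
  ti <- jj <- xx <- list()
  k <- 0L
  addCol <- function(type, effect, level, trait, rows, x) {
    k <<- k + 1L
    cols[k, ] <<- list(type, effect, level, trait)
    ti[[k]] <<- rows; xx[[k]] <<- x
  }
  for (tr in traits) {
    rt <- which(data$trait == tr)
    addCol("fixed", "mu", "", tr, rt, rep(1, length(rt)))
    for (f in intersect(c("cg", "sex"), model$fixed)) {
      lev <- sort(unique(data[[f]][rt]))
      for (l in lev[-1]) {
        r <- rt[data[[f]][rt] == l]
        addCol("fixed", f, as.character(l), tr, r, rep(1, length(r)))
      }
    }
    if ("age" %in% model$fixed)
      addCol("fixed", "age", "", tr, rt, data$age_d[rt] - ageC)
  }
  if ("litter" %in% model$random) {
    for (tr in traits) {
      rt <- which(data$trait == tr)
      for (l in sort(unique(data$litter[rt]))) {
        r <- rt[data$litter[rt] == l]
        addCol("litter", "litter", as.character(l), tr, r, rep(1, length(r)))
      }
    }
  }
  nFL <- k
  if ("animal" %in% model$random) {
    # animal-major ordering (traits within animal) to match kron(Kinv, G0inv)
    nt <- length(traits)
    aIdx <- match(data$animal, animalIds)
    if (anyNA(aIdx)) stop("records refer to animals absent from the relationship matrix")
    animCols <- data.frame(type = "animal", effect = "animal",
                           level = as.character(rep(animalIds, each = nt)),
                           trait = rep(traits, length(animalIds)))
    cols <- rbind(cols, animCols)
  }
  ii <- unlist(ti); jv <- rep.int(seq_len(nFL), lengths(ti)); xv <- unlist(xx)
  if ("animal" %in% model$random) {
    nt <- length(traits)
    ii <- c(ii, seq_len(nrec))
    jv <- c(jv, nFL + (match(data$animal, animalIds) - 1L) * nt +
               match(data$trait, traits))
    xv <- c(xv, rep(1, nrec))
  }
  Tm <- Matrix::sparseMatrix(i = ii, j = jv, x = xv,
                             dims = c(nrec, nrow(cols)))
  list(Tm = Tm, cols = cols, data = data, ageCenter = ageC)
}

#' Assemble Henderson's mixed model equations
#'
#' Builds the symmetric sparse coefficient matrix and right-hand side of the
#' (two-)trait animal model: fixed blocks, litter blocks with `I / sigma2_l`
#' per trait, and an animal block `Kinv (x) inv(G0)` (Kronecker with the 2x2
#' genetic covariance) or `Kinv / sigma2_a` for a single trait. Residual
#' weighting is per trait; each record belongs to exactly one trait so traits
#' never share a residual. The first level of each fixed factor is
#' constrained to zero for identifiability; the age covariate is centered.
#'
#' @param model a [modelSpec()].
#' @param data phenotype data.frame (columns hcw_kg, trait and those named by
#'   the model).
#' @param Kinv sparse relationship inverse (A-inverse or H-inverse) over all
#'   animals, dimnames = ids; required when "animal" is a random effect.
#' @param vc a [VarianceComponents-class] covering the model traits.
#' @return List of class `mmeSystem`: `C`, `rhs`, `cols` (equation labels),
#'   `traits`, `nRecords`, `ageCenter`.
#' @export
buildMME <- function(model, data, Kinv = NULL, vc) {
  stopifnot(inherits(model, "modelSpec"), is(vc, "VarianceComponents"))
  traits <- model$traits
  if (!all(traits %in% vc@traits))
    stop("variance components do not cover the model traits")
  animalIds <- if ("animal" %in% model$random) {
    if (is.null(Kinv)) stop("animal effect requires a relationship inverse")
    rownames(Kinv)
  } else character()
  des <- buildDesign(model, data, animalIds)
  d <- des$data
  rInv <- 1 / vc@varE[d$trait]
  Tw <- des$Tm * rInv      # row-scaled
  C <- Matrix::crossprod(des$Tm, Tw)
  rhs <- as.numeric(Matrix::crossprod(des$Tm, rInv * d$hcw_kg))

  cols <- des$cols
  if ("litter" %in% model$random) {
    i <- which(cols$type == "litter")
    lv <- 1 / vc@varLitter[cols$trait[i]]
    C[cbind(i, i)] <- C[cbind(i, i)] + lv
  }
  if ("animal" %in% model$random) {
    i0 <- which(cols$type == "animal")[1] - 1L
    G0 <- vc@varA[traits, traits, drop = FALSE]
    ch <- tryCatch(chol(G0), error = function(e)
      stop("genetic covariance matrix is not positive definite"))
    G0inv <- chol2inv(ch)
    Ablock <- Matrix::kronecker(Kinv, G0inv)
    n <- nrow(C)
    pad <- function(M, at) {
      idx <- seq.int(at + 1L, at + nrow(M))
      out <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                  dims = c(n, n))
      Mt <- as(as(M, "generalMatrix"), "TsparseMatrix")
      Matrix::sparseMatrix(i = idx[Mt@i + 1L], j = idx[Mt@j + 1L], x = Mt@x,
                           dims = c(n, n))
    }
    C <- C + pad(Ablock, i0)
  }
  structure(list(C = Matrix::forceSymmetric(C), rhs = rhs, cols = cols,
                 traits = traits, nRecords = nrow(d),
                 ageCenter = des$ageCenter),
            class = "mmeSystem")
}

#' Solve the mixed model equations
#'
#' Direct sparse factorization of the assembled system; the contract is the
#' residual norm, `||C s - rhs|| / ||rhs|| <= tol`.
#'
#' @param system an `mmeSystem` from [buildMME()].
#' @param tol relative residual tolerance (default 1e-8).
#' @return A [SolutionSet-class].
#' @export
solveBLUP <- function(system, tol = 1e-8) {
  stopifnot(inherits(system, "mmeSystem"))
  C <- system$C
  sol <- tryCatch(
    as.numeric(Matrix::solve(C, system$rhs)),
    error = function(e) stop("mixed model equations could not be solved ",
                             "(singular system?): ", conditionMessage(e)))
  denom <- sqrt(sum(system$rhs^2))
  res <- if (denom > 0)
    sqrt(sum((as.numeric(C %*% sol) - system$rhs)^2)) / denom else 0
  if (!is.finite(res) || res > tol)
    stop(sprintf("solver residual %.3e exceeds tolerance %.1e", res, tol))
  cols <- system$cols
  cols$solution <- sol
  f <- cols[cols$type == "fixed", c("effect", "level", "trait", "solution")]
  l <- cols[cols$type == "litter", c("level", "trait", "solution")]
  names(l)[1] <- "litter"
  a <- cols[cols$type == "animal", c("level", "trait", "solution")]
  names(a)[1] <- "animal"
  a$animal <- as.integer(a$animal)
  rownames(f) <- rownames(l) <- rownames(a) <- NULL
  new("SolutionSet", fixed = f, litter = l, animal = a, residualNorm = res)
}
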