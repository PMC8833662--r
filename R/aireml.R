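#' Narrow-sense heritability
#'
#' `h2 = sigma2_a / (sigma2_a + sigma2_l + sigma2_e)` for the requested trait.
#'
#' @param vc a [VarianceComponents-class].
#' @param trait trait label ("HS" or "NHS"); defaults to the first trait.
#' @return Heritability (proportion).
#' @examples
#' vc <- varianceComponents(c("HS","NHS"),
#'   matrix(c(84.697, 44.97, 44.97, 60.173), 2),
#'   c(31.736, 30.791), c(216.69, 210.69))
#' heritability(vc, "HS")   # 0.2542 -> reported as 0.25
#' heritability(vc, "NHS")  # 0.1995 -> reported as 0.20
#' @export
heritability <- function(vc, trait = vc@traits[1]) {
  stopifnot(is(vc, "VarianceComponents"), trait %in% vc@traits)
  den <- vc@varA[trait, trait] + vc@varLitter[trait] + vc@varE[trait]
  if (den <= 0) stop("zero phenotypic variance")
  as.numeric(vc@varA[trait, trait] / den)
}

#' Genetic correlation between the heat-stress and non-heat-stress traits
#'
#' `rg = cov_a(HS,NHS) / sqrt(sigma2_a(HS) * sigma2_a(NHS))`, clamped to
#' \[-1, 1\] for reporting.
#'
#' @param vc a two-trait [VarianceComponents-class].
#' @return Genetic correlation.
#' @export
geneticCorrelation <- function(vc) {
  stopifnot(is(vc, "VarianceComponents"), length(vc@traits) == 2L)
  v <- diag(vc@varA)
  if (any(v <= 0)) stop("genetic variances must be positive")
  max(-1, min(1, vc@varA[1, 2] / sqrt(prod(v))))
}

## Parameter descriptor for the REML engine: names + mapping into a
## VarianceComponents object.
remlParamNames <- function(traits, random) {
  nm <- character()
  if ("animal" %in% random)
    nm <- c(nm, if (length(traits) == 2L) c("aHS", "aNHS", "aCov")
                else paste0("a", traits))
  if ("litter" %in% random) nm <- c(nm, paste0("l", traits))
  c(nm, paste0("e", traits))
}

remlParamToVC <- function(theta, traits, random, ...) {
  t2 <- length(traits) == 2L
  varA <- matrix(0, length(traits), length(traits))
  if ("animal" %in% random) {
    if (t2) {
      varA <- matrix(c(theta[["aHS"]], theta[["aCov"]],
                       theta[["aCov"]], theta[["aNHS"]]), 2)
    } else varA[1, 1] <- theta[[paste0("a", traits)]]
  }
  vl <- if ("litter" %in% random)
    vapply(traits, function(tr) theta[[paste0("l", tr)]], numeric(1))
  else rep(0, length(traits))
  ve <- vapply(traits, function(tr) theta[[paste0("e", tr)]], numeric(1))
  varianceComponents(traits, varA, vl, ve, ...)
}

## Dense fixed-effect design with rank repair (drops aliased columns).
denseFixedDesign <- function(data, traits, fixed) {
  blocks <- lapply(traits, function(tr) {
    rt <- data$trait == tr
    X <- matrix(1, sum(rt), 1)
    cn <- paste0("mu.", tr)
    for (f in intersect(c("cg", "sex"), fixed)) {
      v <- factor(data[[f]][rt])
      if (nlevels(v) > 1L) {
        Xf <- model.matrix(~v)[, -1, drop = FALSE]
        X <- cbind(X, Xf)
        cn <- c(cn, paste0(f, ".", tr, ".", levels(v)[-1]))
      }
    }
    if ("age" %in% fixed) {
      X <- cbind(X, data$age_d[rt] - mean(data$age_d))
      cn <- c(cn, paste0("age.", tr))
    }
    colnames(X) <- cn
    X
  })
  n <- nrow(data)
  X <- matrix(0, n, sum(vapply(blocks, ncol, 1L)))
  cn <- character(0)
  at <- 0L
  for (k in seq_along(traits)) {
    rt <- which(data$trait == traits[k])
    X[rt, at + seq_len(ncol(blocks[[k]]))] <- blocks[[k]]
    cn <- c(cn, colnames(blocks[[k]]))
    at <- at + ncol(blocks[[k]])
  }
  colnames(X) <- cn
  q <- qr(X)
  if (q$rank < ncol(X)) X <- X[, q$pivot[seq_len(q$rank)], drop = FALSE]
  X
}

#' Estimate variance components by average-information REML
#'
#' Fits the (two-)trait animal model by REML on the phenotypic covariance
#' parameterization: `V(theta) = sum_k theta_k V_k`, with additive-genetic
#' structure `K (x) G0` (cross-trait genetic covariance estimated), litter
#' and residual variances per trait (cross-trait litter/residual covariances
#' structurally zero). Updates are average-information steps,
#' `AI[k,l] = y'P V_k P V_l P y / 2`, guarded by backtracking: a step is
#' halved until the parameters are admissible and the restricted
#' log-likelihood does not decrease, so accepted iterations are monotone.
#' Variances are bounded below by `1e-8` times the phenotypic variance and
#' the genetic correlation is kept inside (-1, 1).
#'
#' @param data phenotype data.frame (columns hcw_kg, trait, and those
#'   required by `fixed`/`random`).
#' @param kinship dense relationship matrix (A, or H for single-step) with
#'   dimnames = animal ids; required when "animal" is in `random`. (The
#'   y-space formulation uses the relationship matrix itself rather than its
#'   inverse; invert an H-inverse at desk scale if that is what you hold.)
#' @param traits trait subset ("HS", "NHS" or both).
#' @param fixed,random effect sets as in [modelSpec()].
#' @param start optional named start vector (see `remlParamNames`); default
#'   splits the per-trait phenotypic variance 0.3/0.1/0.6 into
#'   animal/litter/residual and starts the genetic correlation at 0.5.
#' @param maxIter iteration cap (default 200).
#' @param tolParam relative parameter-change convergence bound (default 1e-8).
#' @param tolGrad gradient convergence bound (default 1e-6).
#' @param verbose print the likelihood trajectory.
#' @return A [VarianceComponents-class] with SEs from the inverse AI matrix,
#'   convergence flag, iteration count and restricted log-likelihood.
#' @export
aireml <- function(data, kinship = NULL, traits = c("HS", "NHS"),
                   fixed = c("cg", "sex", "age"),
                   random = c("litter", "animal"),
                   start = NULL, maxIter = 200L, tolParam = 1e-8,
                   tolGrad = 1e-6, verbose = FALSE) {
  traits <- traits[traits %in% unique(data$trait)]
  if (!length(traits)) stop("no records for the requested traits")
  data <- data[data$trait %in% traits, , drop = FALSE]
  data <- data[order(match(data$trait, traits)), , drop = FALSE]
  n <- nrow(data)
  y <- data$hcw_kg
  useA <- "animal" %in% random
  useL <- "litter" %in% random
  if (useL) {
    if (!"litter" %in% colnames(data)) stop("litter effect requires a litter column")
    if (all(table(data$litter) < 2L))
      stop("litter effect requires litters with at least 2 records")
  }
  K <- NULL
  if (useA) {
    if (is.null(kinship)) stop("animal effect requires a relationship matrix")
    idx <- match(data$animal, rownames(kinship))
    if (anyNA(idx)) stop("records refer to animals absent from the kinship matrix")
    K <- as.matrix(kinship)[idx, idx, drop = FALSE]
  }
  X <- denseFixedDesign(data, traits, fixed)
  pn <- remlParamNames(traits, random)
  tIdx <- lapply(traits, function(tr) which(data$trait == tr))
  names(tIdx) <- traits
  # sparse same-litter-same-trait patterns
  Wlit <- if (useL) lapply(traits, function(tr) {
    i <- tIdx[[tr]]
    f <- factor(data$litter[i])
    Matrix::sparseMatrix(i = i, j = as.integer(f), x = 1,
                         dims = c(n, nlevels(f)))
  }) else NULL
  if (useL) names(Wlit) <- traits

  vp <- vapply(traits, function(tr) var(y[tIdx[[tr]]]), numeric(1))
  lb <- 1e-8 * max(vp)
  theta <- if (!is.null(start)) {
    stopifnot(all(pn %in% names(start)))
    start[pn]
  } else {
    th <- c()
    if (useA) {
      a <- (if (useL) 0.3 else 0.35) * vp
      th <- if (length(traits) == 2L)
        c(aHS = a[[1]], aNHS = a[[2]], aCov = 0.5 * sqrt(prod(a))) else
        setNames(a, paste0("a", traits))
    }
    if (useL) th <- c(th, setNames(0.1 * vp, paste0("l", traits)))
    c(th, setNames((if (useA) 0.6 else 0.9) * vp, paste0("e", traits)))
  }
  admissible <- function(th) {
    v <- th[setdiff(pn, "aCov")]
    if (any(v < lb)) return(FALSE)
    if ("aCov" %in% pn &&
        abs(th[["aCov"]]) > (1 - 1e-6) * sqrt(th[["aHS"]] * th[["aNHS"]]))
      return(FALSE)
    TRUE
  }
  project <- function(th) {
    for (k in setdiff(pn, "aCov")) th[[k]] <- max(th[[k]], lb)
    if ("aCov" %in% pn) {
      lim <- (1 - 1e-6) * sqrt(th[["aHS"]] * th[["aNHS"]])
      th[["aCov"]] <- max(-lim, min(lim, th[["aCov"]]))
    }
    th
  }

  # records are sorted by trait, so trait blocks of V are contiguous
  blockIdx <- lapply(traits, function(tr) range(tIdx[[tr]]))
  names(blockIdx) <- traits
  litLin <- NULL
  if (useL) {
    # linear indices of the same-litter-same-trait pattern, per trait
    litLin <- lapply(traits, function(tr) {
      Wt <- as(Matrix::tcrossprod(Wlit[[tr]]), "TsparseMatrix")
      (as.numeric(Wt@j) * n + Wt@i) + 1
    })
    names(litLin) <- traits
  }
  buildV <- function(th) {
    V <- matrix(0, n, n)
    if (useA) {
      if (length(traits) == 2L) {
        i1 <- seq.int(blockIdx[[1]][1], blockIdx[[1]][2])
        i2 <- seq.int(blockIdx[[2]][1], blockIdx[[2]][2])
        V[i1, i1] <- th[[paste0("a", traits[1])]] * K[i1, i1]
        V[i2, i2] <- th[[paste0("a", traits[2])]] * K[i2, i2]
        V[i1, i2] <- th[["aCov"]] * K[i1, i2]
        V[i2, i1] <- th[["aCov"]] * K[i2, i1]
      } else V <- th[[paste0("a", traits)]] * K
    }
    if (useL) for (tr in traits)
      V[litLin[[tr]]] <- V[litLin[[tr]]] + th[[paste0("l", tr)]]
    dg <- th[paste0("e", data$trait)]
    diag(V) <- diag(V) + as.numeric(dg)
    V
  }
  # cheap evaluation for line-search candidates: chol + triangular solves
  cheapLL <- function(th) {
    V <- buildV(th)
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Z <- backsolve(ch, cbind(X, y), transpose = TRUE)
    p <- ncol(X)
    Zx <- Z[, seq_len(p), drop = FALSE]
    Zy <- Z[, p + 1L]
    B <- crossprod(Zx)
    chB <- tryCatch(chol(B), error = function(e) NULL)
    if (is.null(chB)) return(NULL)
    bx <- backsolve(chB, crossprod(Zx, Zy), transpose = TRUE)
    yPy <- sum(Zy^2) - sum(bx^2)
    ll <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chB))) + yPy)
    list(ll = ll, ch = ch, chB = chB)
  }
  # full pieces for the gradient/AI step, reusing the factorizations
  fullPieces <- function(cheap) {
    Vinv <- chol2inv(cheap$ch)
    VinvX <- Vinv %*% X
    Binv <- chol2inv(cheap$chB)
    Py <- Vinv %*% y - VinvX %*% (Binv %*% crossprod(VinvX, y))
    list(ll = cheap$ll, Vinv = Vinv, VinvX = VinvX, Binv = Binv,
         Py = as.numeric(Py))
  }
  # V_k %*% v and tr(P V_k) helpers
  Vkv <- function(k, v) {
    out <- numeric(n)
    if (k %in% c("aHS", "aNHS")) {
      tr <- if (k == "aHS") "HS" else "NHS"
      i <- tIdx[[tr]]
      out[i] <- K[i, i, drop = FALSE] %*% v[i]
    } else if (k == "aCov") {
      i <- tIdx[["HS"]]; j <- tIdx[["NHS"]]
      out[i] <- K[i, j, drop = FALSE] %*% v[j]
      out[j] <- K[j, i, drop = FALSE] %*% v[i]
    } else if (startsWith(k, "a")) {
      out <- as.numeric(K %*% v)
    } else if (startsWith(k, "l")) {
      W <- Wlit[[sub("^l", "", k)]]
      out <- as.numeric(W %*% Matrix::crossprod(W, v))
    } else {
      i <- tIdx[[sub("^e", "", k)]]
      out[i] <- v[i]
    }
    out
  }
  trPVk <- function(k, P) {
    if (k %in% c("aHS", "aNHS")) {
      tr <- if (k == "aHS") "HS" else "NHS"
      i <- tIdx[[tr]]
      sum(P[i, i] * K[i, i])
    } else if (k == "aCov") {
      i <- tIdx[["HS"]]; j <- tIdx[["NHS"]]
      2 * sum(P[i, j] * K[i, j])
    } else if (startsWith(k, "a")) {
      sum(P * K)
    } else if (startsWith(k, "l")) {
      W <- Wlit[[sub("^l", "", k)]]
      PW <- P %*% W
      sum(W * PW)
    } else {
      i <- tIdx[[sub("^e", "", k)]]
      sum(diag(P)[i])
    }
  }

  conv <- FALSE
  it <- 0L
  AI <- NULL
  traj <- numeric()
  cheap0 <- cheapLL(theta)
  if (is.null(cheap0)) stop("starting values give a singular covariance matrix")
  pieces <- fullPieces(cheap0)
  grad <- rep(NA_real_, length(pn))
  prevLL <- -Inf
  while (it < maxIter) {
    it <- it + 1L
    P <- pieces$Vinv - pieces$VinvX %*% tcrossprod(pieces$Binv, pieces$VinvX)
    Py <- pieces$Py
    Wk <- vapply(pn, function(k) Vkv(k, Py), numeric(n))
    trk <- vapply(pn, function(k) trPVk(k, P), numeric(1))
    grad <- -0.5 * (trk - colSums(Wk * Py))
    PW <- P %*% Wk
    AI <- 0.5 * crossprod(Wk, PW)
    step <- tryCatch(solve(AI, grad), error = function(e) grad / max(diag(AI)))
    # trust region: a near-singular AI matrix can propose astronomically
    # large steps that no amount of halving recovers from
    rel <- max(abs(step) / pmax(abs(theta), 1))
    if (is.finite(rel) && rel > 5) step <- step * (5 / rel)
    lambda <- 1
    accepted <- FALSE
    for (half in 1:30) {
      cand <- project(theta + lambda * step)
      names(cand) <- pn
      if (admissible(cand)) {
        pc <- cheapLL(cand)
        if (!is.null(pc) && pc$ll >= pieces$ll - 1e-10) {
          relchg <- max(abs(cand - theta) / pmax(abs(theta), 1))
          theta <- cand
          prevLL <- pieces$ll
          pieces <- fullPieces(pc)
          traj <- c(traj, pc$ll)
          accepted <- TRUE
          if (verbose)
            message(sprintf("it %d  logL %.6f  maxrel %.2e", it, pc$ll, relchg))
          if (relchg < tolParam || max(abs(grad)) < tolGrad) conv <- TRUE
          # stagnation: likelihood and parameters have stopped moving
          if (pieces$ll - prevLL < 1e-9 && relchg < 1e-6) conv <- TRUE
          break
        }
      }
      lambda <- lambda / 2
    }
    if (!accepted) { conv <- max(abs(grad)) < 1e-3; break }
    if (conv) break
  }
  if (!conv && it >= maxIter)
    warning("AIREML did not converge in ", maxIter,
            " iterations (max |gradient| = ", format(max(abs(grad))), ")")
  se <- tryCatch(sqrt(pmax(diag(solve(AI)), 0)), error = function(e)
    rep(NA_real_, length(pn)))
  names(se) <- pn
  vcOut <- remlParamToVC(theta, traits, random, se = se, converged = conv,
                         iterations = it, logLik = pieces$ll)
  attr(vcOut, "AI") <- AI        # average-information matrix for SE propagation
  attr(vcOut, "trajectory") <- traj  # accepted restricted logL values
  vcOut
}
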