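#' @include AllClasses.R
NULL

## Parallel ICA: joint Infomax decomposition of the lesion modality with a
## coupling term that increases the correlation between the best-matched
## lesion loadings and the (scalar) HRV covariate. The covariate modality is
## degenerate (a single feature), so its "loading" is the covariate itself
## and the coupling term acts directly on the lesion mixing matrix.

## Sphericity statistic of the trailing eigenvalues: n_obs * (m - k) *
## log(arithmetic/geometric mean) of eigenvalues k+1..m.
sphericityStat <- function(ev, k, nObs) {
  lam <- ev[(k + 1):length(ev)]
  nObs * length(lam) * log(mean(lam) / exp(mean(log(lam))))
}

#' Estimate the component count from the eigenvalue spectrum
#'
#' Information-theoretic order selection on the subject-covariance
#' eigenvalues: an AIC-style criterion (sphericity of the trailing
#' eigenvalues plus a 2k(2m - k) parameter penalty) with a finite-sample
#' modification. With far fewer subjects than voxels the sample eigenvalues
#' of a pure-noise covariance are themselves spread out
#' (Marchenko-Pastur), which the textbook criterion mistakes for signal, so
#' the expected null sphericity (estimated from white-noise spectra of the
#' same shape) is subtracted before minimization. The result is stabilized
#' as the median over 5 feature-resampled runs.
#'
#' @param modality subjects x features numeric matrix.
#' @param maxK upper bound on k (default subjects - 1).
#' @param nRuns resampled runs (default 5).
#' @param seed RNG seed.
#' @return integer component count (>= 1, <= subjects - 1).
#' @export
estimateComponentCount <- function(modality, maxK = NULL, nRuns = 5L,
                                   seed = 1L) {
  X <- as.matrix(modality)
  n <- nrow(X); q <- ncol(X)
  if (n < 3L) stop("need at least 3 subjects")
  if (is.null(maxK)) maxK <- n - 1L
  maxK <- min(maxK, n - 1L)

  evalsOf <- function(M) {
    Mc <- sweep(M, 2, colMeans(M))
    ev <- eigen(tcrossprod(Mc) / ncol(M), symmetric = TRUE,
                only.values = TRUE)$values
    pmax(ev, .Machine$double.eps)
  }

  kMax <- min(maxK, n - 3L)
  if (kMax < 1L) return(1L)

  set.seed(seed)
  noiseRef <- replicate(2, matrix(rnorm(n * q), n), simplify = FALSE)
  pickK <- function(cols) {
    ev <- evalsOf(X[, cols, drop = FALSE])
    # null sphericity from white-noise spectra resampled the same way
    nullStat <- rowMeans(vapply(noiseRef, function(Nz) {
      evn <- evalsOf(Nz[, cols, drop = FALSE])
      vapply(0:kMax, sphericityStat, numeric(1), ev = evn, nObs = q)
    }, numeric(kMax + 1)))
    m <- length(ev)
    crit <- vapply(0:kMax, function(k) {
      2 * (sphericityStat(ev, k, q) - nullStat[k + 1]) + 2 * k * (2 * m - k)
    }, numeric(1))
    if (!all(is.finite(crit))) return(1)
    (0:kMax)[which.min(crit)]
  }

  ks <- vapply(seq_len(nRuns), function(i) {
    cols <- sample.int(q, q, replace = TRUE)
    tryCatch(pickK(cols),
             error = function(e) { warning("degenerate covariance; k = 1"); 1 })
  }, numeric(1))
  max(1L, as.integer(round(median(ks))))
}

permutationP <- function(a, b, nPerm = 1000L) {
  robs <- abs(cor(a, b))
  cnt <- 0L
  for (i in seq_len(nPerm)) {
    if (abs(cor(a, sample(b))) >= robs) cnt <- cnt + 1L
  }
  (cnt + 1L) / (nPerm + 1L)
}

#' Fit a parallel ICA of lesion maps against an HRV covariate
#'
#' Infomax updates (natural gradient on the unmixing matrix of the whitened
#' lesion data) plus a coupling gradient step that increases the squared
#' correlation between the currently best-matched lesion loading column and
#' the covariate. The coupling learning rate is halved whenever the
#' correlation objective decreases. Convergence is declared when the update
#' norm drops below `tol` (default 1e-6) within `maxIter` (default 1000)
#' iterations; otherwise the best iterate is returned with
#' `converged = FALSE`.
#'
#' @param modality1 subjects x features lesion matrix (one row per subject,
#'   voxels flattened), or a list of [LesionMap-class] objects.
#' @param modality2 numeric covariate, one value per subject.
#' @param k component count (e.g. from [estimateComponentCount()]).
#' @param lrIca Infomax learning rate (default 0.05).
#' @param lrCouple initial coupling learning rate (default 0.05).
#' @param maxIter iteration cap (default 1000).
#' @param tol convergence tolerance on the update norm (default 1e-6).
#' @param nPerm permutations for the correlation p-values (default 1000).
#' @param seed RNG seed.
#' @return A [ComponentSet-class].
#' @export
fitParallelICA <- function(modality1, modality2, k, lrIca = 0.05,
                           lrCouple = 0.05, maxIter = 1000L, tol = 1e-6,
                           nPerm = 1000L, seed = 1L) {
  featureDim <- integer(0)
  if (is.list(modality1) && is(modality1[[1]], "LesionMap")) {
    featureDim <- dim(mapValues(modality1[[1]]))
    modality1 <- t(vapply(modality1, function(m) as.numeric(mapValues(m)),
                          numeric(prod(featureDim))))
  }
  X <- as.matrix(modality1)
  covariate <- as.numeric(modality2)
  n <- nrow(X); nv <- ncol(X)
  if (length(covariate) != n) stop("modalities must share subjects")
  if (k > n - 1L) stop("k must be <= subjects - 1")
  if (anyNA(X) || anyNA(covariate)) stop("missing values not allowed")

  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc, nu = k, nv = k)
  M <- sv$u %*% diag(sv$d[seq_len(k)], k) / sqrt(nv)   # subjects x k
  Y <- sqrt(nv) * t(sv$v)                              # k x features, whitened

  set.seed(seed)
  W <- diag(k) + matrix(rnorm(k * k, 0, 0.01), k)
  lrC <- lrCouple
  prevObj <- -Inf
  converged <- FALSE
  lrI <- lrIca
  for (it in seq_len(maxIter)) {
    # Infomax natural-gradient step (annealed so the updates settle)
    U <- W %*% Y
    G <- 1 - 2 / (1 + exp(-U))
    dW <- lrI * (diag(k) + (G %*% t(U)) / nv) %*% W
    W <- W + dW
    if (it > 100L) lrI <- lrI * 0.99

    # coupling step on the best-matched loading column
    B <- solve(W)
    A <- M %*% B
    rs <- as.numeric(cor(A, covariate))
    j <- which.max(abs(rs))
    obj <- rs[j]^2
    if (obj < prevObj) lrC <- lrC / 2          # adaptive adjustment
    prevObj <- obj
    a <- A[, j]
    ac <- a - mean(a); cc <- covariate - mean(covariate)
    na2 <- sum(ac^2)
    r <- sum(ac * cc) / sqrt(na2 * sum(cc^2))
    gA <- 2 * r * (cc / sqrt(na2 * sum(cc^2)) - r * ac / na2)
    Gm <- crossprod(M, gA) %*% t(replace(numeric(k), j, 1))
    dWc <- -lrC * t(B) %*% Gm %*% t(B)
    W <- W + dWc

    if (sqrt(sum(dW^2) + sum(dWc^2)) / sqrt(sum(W^2)) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    message("parallel ICA reached maxIter without meeting tol; returning best iterate")

  B <- solve(W)
  A1 <- M %*% B                 # subjects x k loadings
  S1 <- W %*% Y                 # k x features sources
  rs <- as.numeric(cor(A1, covariate))
  # resolve the ICA sign indeterminacy: orient each component so its loading
  # correlates non-negatively with the covariate
  flip <- rs < 0
  A1[, flip] <- -A1[, flip, drop = FALSE]
  S1[flip, ] <- -S1[flip, , drop = FALSE]
  rs <- as.numeric(cor(A1, covariate))
  ps <- vapply(seq_len(k), function(j) permutationP(A1[, j], covariate, nPerm),
               numeric(1))
  cc <- data.frame(component = seq_len(k), r = rs, p = ps)
  sel <- which(ps == min(ps))
  sel <- sel[which.max(abs(rs[sel]))]

  new("ComponentSet",
      loadings1 = A1, sources1 = S1,
      loadings2 = matrix(covariate, n, k), k = as.integer(k),
      crossCorr = cc, selectedPair = as.integer(sel),
      converged = converged, featureDim = as.integer(featureDim))
}

#' Convert the selected component's source map to a thresholded lesion map
#'
#' The selected lesion source is scaled by its standard deviation (z/t
#' units); voxels with value strictly greater than `tThresh` (default 3) are
#' retained, all others set to zero.
#'
#' @param cs a [ComponentSet-class] fitted from voxel data.
#' @param tThresh threshold in sd units (default 3); use `-Inf` to keep all.
#' @param voxelSize mm per axis for the output map.
#' @param gridShape optional 3-D dims; defaults to the dims recorded when
#'   the set was fitted from [LesionMap-class] input.
#' @return A [LesionMap-class]; empty (all zero) with a warning when no
#'   voxel survives.
#' @export
componentMap <- function(cs, tThresh = 3, voxelSize = c(2, 2, 2),
                         gridShape = NULL) {
  if (is.null(gridShape)) gridShape <- cs@featureDim
  if (!length(gridShape)) stop("gridShape needed when the set was not fitted from maps")
  src <- cs@sources1[selectedPair(cs), ]
  s <- sd(src)
  z <- if (s > 0) src / s else src
  z[!(z > tThresh)] <- 0
  if (all(z == 0) && is.finite(tThresh))
    warning("no voxel survives the threshold; returning an empty map")
  LesionMap(array(z, gridShape), voxelSize)
}
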