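# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Squared normalized PDC by direct complex arithmetic from a static
# coefficient array A [c, c, p] at normalized frequency f (cycles/sample).
oraclePDC <- function(A, fNorm) {
  cdim <- dim(A)[1]; p <- dim(A)[3]
  Abar <- diag(cdim) + 0i
  for (r in seq_len(p)) Abar <- Abar - A[, , r] * exp(-2i * pi * fNorm * r)
  M <- Mod(Abar)^2
  sweep(M, 2, colSums(M), "/")
}

# Least-squares VAR coefficients via stats::ar.ols, returned as [c, c, lag].
oracleVAR <- function(y, order) {
  fit <- ar.ols(t(y), aic = FALSE, order.max = order, demean = TRUE,
                intercept = TRUE)
  aperm(fit$ar, c(2, 3, 1))
}

# A stable bivariate VAR(2) used by several tests.
bivarVAR2 <- function() {
  A <- array(0, c(2, 2, 2))
  A[1, 1, 1] <- 0.5; A[2, 2, 1] <- 0.3; A[2, 1, 1] <- 0.4
  A[1, 2, 2] <- -0.3
  A
}

# Unidirectional bivariate VAR(1): channel 1 drives channel 2 at 0.5.
bivarDriver <- function(coupling = 0.5) {
  A <- array(0, c(2, 2, 1))
  diag(A[, , 1]) <- c(0.3, 0.2)
  A[2, 1, 1] <- coupling
  A
}

# Fast TPDC pipeline settings shared by surrogate-heavy tests.
fastPipeline <- function(order = 5L) {
  makeTPDCPipeline(order = order, nFreq = 16L, timeStride = 4L)
}
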