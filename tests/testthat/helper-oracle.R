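# Independent entropy oracle: eigenvalues of the 4x4 Hermitian density
# matrix obtained as roots of its characteristic polynomial, with the
# coefficients built by the Faddeev-LeVerrier recurrence and the quartic
# solved by polyroot(). Shares no code path with eigen()-based entropy.
charPolyEigenvalues <- function(rho) {
  A <- rho
  I4 <- diag(4) + 0i
  b <- numeric(4)
  M <- A
  b[1] <- -Re(sum(diag(M)))
  for (k in 2:4) {
    M <- A %*% (M + b[k - 1] * I4)
    b[k] <- -Re(sum(diag(M))) / k
  }
  roots <- polyroot(c(b[4], b[3], b[2], b[1], 1))
  sort(Re(roots), decreasing = TRUE)
}

oracleEntropy <- function(rho) {
  ev <- charPolyEigenvalues(rho)
  ev[ev < 0] <- 0
  p <- ev / sum(ev)
  -sum(ifelse(p > 0, p * log(p, base = 4), 0))
}

# Random Hermitian PSD unit-trace 4x4 matrix from an outer-product ensemble.
randomDensityMatrix <- function(n = 8) {
  ks <- matrix(complex(real = rnorm(4 * n), imaginary = rnorm(4 * n)), 4, n)
  rho <- ks %*% Conj(t(ks))
  rho <- (rho + Conj(t(rho))) / 2
  rho / Re(sum(diag(rho)))
}

# Random 4x4 unitary via QR of a complex Ginibre matrix.
randomUnitary <- function() {
  z <- matrix(complex(real = rnorm(16), imaginary = rnorm(16)), 4, 4)
  qr.Q(qr(z))
}
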