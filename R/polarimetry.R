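#' Vectorize a Jones matrix
#'
#' Lexicographic vectorization of a complex 2x2 Jones matrix: the 4-vector
#' `k = (J11, J12, J21, J22)` whose outer product `k k*` reproduces the
#' arrangement of the matrix elements. The norm of `k` equals the square root
#' of the matrix intensity (Frobenius norm), and the map is invertible via
#' [devectorizeJones]. The entropy computed downstream is invariant under any
#' fixed unitary change of this basis, so the lexicographic basis is
#' equivalent to the Pauli basis used elsewhere in polarimetric decomposition.
#'
#' @param J complex 2x2 matrix with finite entries.
#' @return complex 4-vector.
#' @export
vectorizeJones <- function(J) {
  if (!is.matrix(J) || !identical(dim(J), c(2L, 2L)))
    stop("J must be a 2x2 matrix")
  J <- as.complex(J)
  if (anyNA(J) || any(!is.finite(Re(J))) || any(!is.finite(Im(J))))
    stop("Jones matrix entries must be finite")
  c(J[1], J[3], J[2], J[4])  # row-major: J11, J12, J21, J22
}

#' @rdname vectorizeJones
#' @param k complex 4-vector from [vectorizeJones].
#' @export
devectorizeJones <- function(k) {
  stopifnot(length(k) == 4L)
  matrix(as.complex(k), 2, 2, byrow = TRUE)
}

#' Local density (coherency) matrix of a window of Jones vectors
#'
#' Accumulates the rank-4 density matrix
#' `rho = sum_i k_i k_i* / sum_i ||k_i||^2` from the vectorized Jones
#' matrices of a local window. The result is Hermitian, positive
#' semi-definite and unit-trace; its eigenvalue spectrum measures how many
#' distinct polarization transformations coexist in the window.
#'
#' @param ks complex `4 x n` matrix of column vectors (or a list of
#'   4-vectors); at least 4 samples are required for rank-4 statistics.
#' @return a [DensityMatrix-class].
#' @export
localDensityMatrix <- function(ks) {
  if (is.list(ks)) ks <- vapply(ks, as.complex, complex(4))
  if (!is.matrix(ks) || nrow(ks) != 4L)
    stop("ks must be a 4 x n matrix of vectorized Jones matrices")
  n <- ncol(ks)
  if (n < 4L)
    stop("rank-4 statistics need at least 4 samples; got ", n)
  power <- sum(Mod(ks)^2)
  if (power == 0)
    stop("all-zero window: density matrix undefined")
  rho <- (ks %*% Conj(t(ks))) / power
  rho <- (rho + Conj(t(rho))) / 2   # enforce exact Hermitian symmetry
  new("DensityMatrix", rho = rho, nSamples = as.integer(n))
}

#' Subtract the additive-noise bias from a density matrix
#'
#' Additive i.i.d. circular Gaussian detection noise of per-element variance
#' `noiseVariance` contributes, in expectation, an isotropic term
#' `f * I/4` to the normalized density matrix, where
#' `f = 4 * noiseVariance / meanSamplePower` is the fraction of the mean
#' per-sample power (summed over the four elements, noise included) that is
#' noise. The correction removes that expectation, clips any negative
#' eigenvalues to zero, and renormalizes the trace to one. With zero noise
#' the operation is the identity. When the estimated noise power meets or
#' exceeds the total power the voxel is signal-free: the maximally mixed
#' `I/4` is returned with `signalFree = TRUE`.
#'
#' @param dm a [DensityMatrix-class].
#' @param noiseVariance known per-element additive noise power (>= 0).
#' @param meanSamplePower mean measured power per sample in the window
#'   (sum of the four squared moduli, noise included).
#' @return a corrected [DensityMatrix-class] with `noiseCorrected = TRUE`.
#' @export
noiseBiasCorrect <- function(dm, noiseVariance, meanSamplePower) {
  stopifnot(is(dm, "DensityMatrix"))
  if (!is.finite(noiseVariance) || noiseVariance < 0)
    stop("noiseVariance must be known and non-negative")
  if (noiseVariance == 0)
    return(new("DensityMatrix", rho = dm@rho, nSamples = dm@nSamples,
               noiseCorrected = TRUE, signalFree = FALSE))
  f <- 4 * noiseVariance / meanSamplePower
  if (f >= 1) {
    warning("noise power exceeds total power: signal-free window")
    return(new("DensityMatrix", rho = diag(4) / 4 + 0i,
               nSamples = dm@nSamples, noiseCorrected = TRUE,
               signalFree = TRUE))
  }
  rho <- (dm@rho - f * diag(4) / 4) / (1 - f)
  # PSD re-projection: clip negative eigenvalues, renormalize trace
  es <- eigen(rho, symmetric = TRUE)
  ev <- pmax(Re(es$values), 0)
  rho <- es$vectors %*% diag(ev / sum(ev)) %*% Conj(t(es$vectors))
  rho <- (rho + Conj(t(rho))) / 2
  new("DensityMatrix", rho = rho, nSamples = dm@nSamples,
      noiseCorrected = TRUE, signalFree = FALSE)
}

#' Von Neumann entropy of a density matrix (log base 4)
#'
#' `H = -sum_i p_i log4 p_i` over the normalized eigenvalues `p_i` of the
#' 4x4 density matrix, with `0 log 0 = 0`. The base-4 logarithm scales the
#' result to `[0, 1]`: 0 for a completely uniform polarization property
#' (rank-1 matrix) and 1 for completely random polarization (maximally mixed
#' `I/4`).
#'
#' @param dm a [DensityMatrix-class] or a complex 4x4 Hermitian PSD matrix.
#' @return entropy in `[0, 1]`.
#' @export
vonNeumannEntropy <- function(dm) {
  rho <- if (is(dm, "DensityMatrix")) dm@rho else dm
  if (!is.matrix(rho) || !identical(dim(rho), c(4L, 4L)))
    stop("expected a 4x4 density matrix")
  ev <- Re(eigen(rho, symmetric = TRUE, only.values = TRUE)$values)
  tr <- sum(ev)
  if (tr <= 0) stop("density matrix has non-positive trace")
  if (min(ev) < -1e-8 * tr)
    stop("density matrix is not positive semi-definite")
  ev[ev < 0] <- 0                         # tiny eigen-solver negatives
  p <- ev / sum(ev)
  h <- -sum(ifelse(p > 0, p * log(p, base = 4), 0))
  if (h < -1e-9 || h > 1 + 1e-9)
    stop("entropy outside [0, 1] beyond floating-point tolerance")
  min(1, max(0, h))
}

#' Per-voxel noise-bias-corrected entropy of a Jones-matrix volume
#'
#' Slides a rectangular averaging kernel over every voxel of the volume,
#' accumulates the local density matrix from the vectorized Jones matrices,
#' subtracts the additive-noise bias (when the volume's noise variance is
#' known), and evaluates the von Neumann entropy (log base 4) of each
#' window. Edge voxels use the truncated window as long as it still holds at
#' least 4 samples; windows below that, or whose mean intensity sits less
#' than `snrFloorDb` above the noise floor (`4 x noiseVariance` per sample),
#' are marked invalid and carry the `NA` sentinel — noise-dominated voxels
#' have maximal entropy by construction and would masquerade as melanin.
#'
#' @param volume a [JonesVolume-class].
#' @param kernel integer halfwidths `(depth, lateral, frame)`; the default
#'   `c(1, 3, 0)` averages a 3 x 7 x 1 window (21 samples), small enough to
#'   preserve the thin RPE band.
#' @param snrFloorDb validity floor in dB above the noise floor (ignored for
#'   noise-free volumes).
#' @param correct subtract the noise bias? (default `TRUE`; no-op when the
#'   volume's noise variance is zero or unknown).
#' @return an [EntropyVolume-class].
#' @export
entropyVolume <- function(volume, kernel = c(1L, 3L, 0L), snrFloorDb = 5,
                          correct = TRUE) {
  stopifnot(is(volume, "JonesVolume"))
  kernel <- as.integer(kernel)
  if (length(kernel) != 3L || any(kernel < 0L))
    stop("kernel must be three non-negative halfwidths (depth, lateral, frame)")
  if (prod(2L * kernel + 1L) < 4L)
    stop("kernel too small: the full window must hold at least 4 samples")
  nv <- volume@noiseVariance
  if (is.na(nv)) nv <- 0
  res <- .entropyVolumeCpp(volume@data, dim(volume@data)[1:3], kernel,
                           nv, snrFloorDb, isTRUE(correct))
  new("EntropyVolume", entropy = res$entropy, valid = res$valid,
      kernel = kernel,
      provenance = list(noiseVariance = nv, snrFloorDb = snrFloorDb,
                        noiseCorrected = isTRUE(correct) && nv > 0,
                        seed = volume@seed))
}
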