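# Internal numeric helpers.

# Otsu threshold of a non-negative 1-D intensity vector (256-bin histogram,
# maximal between-class variance). Returns a threshold on the original scale.
.otsuThreshold <- function(x, nbins = 256L) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(rng[2])
  h <- tabulate(pmin(nbins, 1L + as.integer((x - rng[1]) / diff(rng) * nbins)),
                nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(nbins))
  muT <- mu[nbins]
  sigmaB <- (muT * omega - mu)^2 / (omega * (1 - omega))
  sigmaB[!is.finite(sigmaB)] <- 0
  k <- which.max(sigmaB)
  rng[1] + k / nbins * diff(rng)
}

# Runs of TRUE in a logical vector: matrix with columns start, end (inclusive).
.trueRuns <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

# Linear upsampling of a numeric vector to length n (endpoints preserved).
.upsample1 <- function(v, n) {
  if (length(v) == 1L) return(rep(v, n))
  stats::approx(seq(0, 1, length.out = length(v)), v,
                xout = seq(0, 1, length.out = n))$y
}

# Smooth zero-mean random field over (nf, nl, nd) with the given correlation
# length (voxels): coarse i.i.d. normals upsampled trilinearly, rescaled to
# unit standard deviation. Uses the current RNG stream.
.smoothField3 <- function(nf, nl, nd, corrLen) {
  nc <- function(n) max(2L, as.integer(ceiling(n / corrLen)) + 1L)
  cf <- nc(nf); cl <- nc(nl); cd <- nc(nd)
  coarse <- array(stats::rnorm(cf * cl * cd), dim = c(cf, cl, cd))
  # upsample one margin at a time
  a <- apply(coarse, c(2, 3), .upsample1, n = nf)            # (nf, cl, cd)
  a <- aperm(apply(a, c(1, 3), .upsample1, n = nl), c(2, 1, 3))  # (nf, nl, cd)
  a <- aperm(apply(a, c(1, 2), .upsample1, n = nd), c(2, 3, 1))  # (nf, nl, nd)
  s <- stats::sd(a)
  if (s > 0) a / s else a
}

# Running mean along the lateral axis of an (nf, nl, nd) array, with
# shrinking windows at the edges (no NA padding).
.lateralRunningMean <- function(arr, window) {
  k <- as.integer(window)
  if (k <= 1L) return(arr)
  h <- k %/% 2L
  nl <- dim(arr)[2]
  out <- arr
  for (f in seq_len(dim(arr)[1])) {
    sl <- arr[f, , , drop = TRUE]                      # nl x nd
    cs <- rbind(0, apply(sl, 2, cumsum))               # (nl + 1) x nd
    lo <- pmax(0L, seq_len(nl) - h - 1L)
    hi <- pmin(nl, seq_len(nl) + h)
    out[f, , ] <- (cs[hi + 1L, , drop = FALSE] -
                     cs[lo + 1L, , drop = FALSE]) / (hi - lo)
  }
  out
}

# Expand a scalar or (nf x nl) matrix to an (nf x nl) matrix.
.expandField <- function(x, nf, nl, what) {
  if (is.matrix(x)) {
    if (!identical(dim(x), c(nf, nl)))
      stop(sprintf("%s matrix must be %d x %d (frames x lateral)", what, nf, nl))
    x
  } else if (length(x) == 1L) {
    matrix(x, nf, nl)
  } else stop(sprintf("%s must be a scalar or a frames x lateral matrix", what))
}

# Population standard deviation (divide by n, not n - 1): ROIs are exhaustive
# pixel sets, not samples.
.popSd <- function(x) sqrt(mean((x - mean(x))^2))

# Moment skewness (population form).
.skewness <- function(x) {
  s <- .popSd(x)
  if (s == 0) return(0)
  mean((x - mean(x))^3) / s^3
}

# Evaluate a block of code with a private, seeded RNG stream, restoring the
# caller's stream afterwards so that package calls never perturb user code.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}
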