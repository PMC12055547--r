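# Preprocessing operators: median filtering (images), ideal band-pass (ECG),
# FastICA source separation (artifact removal), min-max scaling (records),
# k-means clustering (nutrition profiles). All operators are pure functions.

#' Median-filter an image
#'
#' Each pixel is replaced by the median of its `window` x `window`
#' neighbourhood; borders are reflect-padded so the output shape equals the
#' input shape.
#'
#' @param image numeric matrix.
#' @param window odd window size (>= 1); `window = 1` is the identity.
#' @return filtered matrix of the same shape.
#' @export
medianFilter <- function(image, window = 3L) {
  if (!is.matrix(image) || !is.numeric(image) || length(image) == 0)
    stopParam("image", "must be a non-empty numeric matrix")
  window <- checkCount(window, "window")
  if (window %% 2L == 0L) stopParam("window", "must be odd")
  if (window == 1L) return(image)
  r <- nrow(image); cc <- ncol(image); h <- (window - 1L) %/% 2L
  reflect <- function(i, nmax) {
    # reflect indices off the borders (1-based, edge not repeated beyond range)
    i <- ifelse(i < 1L, 2L - i, i)
    ifelse(i > nmax, 2L * nmax - i, i)
  }
  ri <- reflect(seq(1L - h, r + h), r)
  ci <- reflect(seq(1L - h, cc + h), cc)
  padded <- image[ri, ci, drop = FALSE]
  nb <- matrix(0, r * cc, window * window)
  col <- 0L
  for (dx in seq_len(window)) {
    for (dy in seq_len(window)) {
      col <- col + 1L
      nb[, col] <- as.vector(padded[dx:(dx + r - 1L), dy:(dy + cc - 1L)])
    }
  }
  matrix(apply(nb, 1L, median), r, cc)
}

#' Band-pass filter specification
#'
#' Ideal (brick-wall) filter: the frequency response is 1 on `[f1, f2]` and 0
#' elsewhere.
#'
#' @param f1,f2 lower/upper cutoff in Hz, `0 <= f1 < f2 <= fs/2`.
#' @param fs sampling frequency in Hz.
#' @export
bandpassSpec <- function(f1, f2, fs) {
  f1 <- checkNumber(f1, "f1", min = 0)
  f2 <- checkNumber(f2, "f2", min = 0)
  fs <- checkNumber(fs, "fs", min = 0, strict = TRUE)
  if (f1 >= f2) stopParam("f1", "must satisfy f1 < f2")
  if (f2 > fs / 2) stopParam("f2", "must not exceed the Nyquist frequency fs/2")
  structure(list(f1 = f1, f2 = f2, fs = fs), class = "bandpassSpec")
}

#' Apply an ideal band-pass filter
#'
#' Multiplies the discrete Fourier transform of the signal by the indicator of
#' `f1 <= |f| <= f2` and inverse-transforms. Bin-aligned in-band tones pass
#' with amplitude preserved; out-of-band bin-aligned tones are annihilated to
#' numerical precision.
#'
#' @param signal numeric vector (length >= 2).
#' @param spec a [bandpassSpec()].
#' @return filtered real signal, same length.
#' @export
bandpass <- function(signal, spec) {
  if (!inherits(spec, "bandpassSpec")) stopParam("spec", "must be a bandpassSpec")
  n <- length(signal)
  if (n < 2L) stopParam("signal", "must have length >= 2")
  freqs <- (seq_len(n) - 1L) / n * spec$fs
  freqs <- ifelse(freqs > spec$fs / 2, spec$fs - freqs, freqs) # |f|, aliased half
  H <- as.numeric(freqs >= spec$f1 & freqs <= spec$f2)
  Re(fft(fft(signal) * H, inverse = TRUE)) / n
}

#' FastICA blind source separation
#'
#' Deflation-based fixed-point iteration with the tanh contrast function on
#' whitened data; deterministic given `seed`. Recovers sources up to sign and
#' permutation.
#'
#' @param X channels x T matrix of mixed signals.
#' @param nComponents number of sources to extract (2 <= nComponents <= channels).
#' @param maxIter iteration cap per component.
#' @param tol convergence tolerance on the direction update.
#' @param seed RNG seed for the initial directions.
#' @return list with `S` (nComponents x T, unit-variance rows), `A` (estimated
#'   mixing matrix, channels x nComponents), `W` (unmixing in whitened space),
#'   `iterations` per component.
#' @export
icaSeparate <- function(X, nComponents, maxIter = 200L, tol = 1e-8, seed = 1L) {
  if (!is.matrix(X)) stopParam("X", "must be a channels x T matrix")
  ch <- nrow(X); Tn <- ncol(X)
  nComponents <- checkCount(nComponents, "nComponents", min = 2L)
  if (nComponents > ch) stopParam("nComponents", "cannot exceed the number of channels")
  if (Tn <= ch) stopParam("X", "needs T >> channels")
  center <- rowMeans(X)
  Xc <- X - center
  covX <- Xc %*% t(Xc) / Tn
  eig <- eigen(covX, symmetric = TRUE)
  keep <- seq_len(nComponents)
  Kw <- diag(1 / sqrt(eig$values[keep]), nComponents) %*% t(eig$vectors[, keep, drop = FALSE])
  Z <- Kw %*% Xc  # whitened, nComponents x T
  W <- matrix(0, nComponents, nComponents)
  iters <- integer(nComponents)
  withSeed(mixSeed(seed, 53L), {
    for (p in seq_len(nComponents)) {
      w <- rnorm(nComponents); w <- w / sqrt(sum(w^2))
      it <- 0L
      repeat {
        it <- it + 1L
        wz <- drop(crossprod(w, Z))       # w' Z, length T
        g <- tanh(wz)
        gp <- 1 - g^2
        wNew <- (Z %*% g) / Tn - mean(gp) * w
        wNew <- drop(wNew)
        if (p > 1L) {
          Wprev <- W[seq_len(p - 1L), , drop = FALSE]
          wNew <- wNew - drop(t(Wprev) %*% (Wprev %*% wNew))
        }
        wNew <- wNew / sqrt(sum(wNew^2))
        conv <- abs(abs(sum(wNew * w)) - 1) < tol
        w <- wNew
        if (conv) break
        if (it >= maxIter)
          stop(sprintf("convergence error: ICA component %d did not converge after %d iterations",
                       p, it), call. = FALSE)
      }
      W[p, ] <- w
      iters[p] <- it
    }
  })
  S <- W %*% Z
  # rows of S are unit variance (population) by whitening + unit-norm w
  A <- MASS_ginv(Kw) %*% t(W)  # channels x nComponents mixing estimate
  list(S = S, A = A, W = W, iterations = iters)
}

# Moore-Penrose pseudoinverse via SVD (avoids a MASS dependency for one call).
MASS_ginv <- function(M, tol = sqrt(.Machine$double.eps)) {
  s <- svd(M)
  pos <- s$d > max(tol * s$d[1], 0)
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Fit min-max scaling statistics
#'
#' Statistics are learned on the training split only and frozen; constant
#' features are flagged and map to 0.
#'
#' @param records numeric matrix (samples x features).
#' @return a `minmaxStats` list with `hMin`, `hMax`, `constantMask`.
#' @export
minmaxFit <- function(records) {
  if (!is.matrix(records)) records <- matrix(records, ncol = 1L)
  if (nrow(records) < 1L) stopParam("records", "needs at least one sample")
  hMin <- apply(records, 2L, min)
  hMax <- apply(records, 2L, max)
  structure(list(hMin = hMin, hMax = hMax, constantMask = hMin == hMax),
            class = "minmaxStats")
}

#' Apply min-max scaling
#'
#' `(x - hMin) / (hMax - hMin)`, constant features mapped to 0; values from
#' unseen data are clipped into `[0, 1]`.
#'
#' @param records numeric matrix (samples x features) or vector.
#' @param stats a `minmaxStats` from [minmaxFit()].
#' @return scaled matrix in `[0, 1]`.
#' @export
minmaxApply <- function(records, stats) {
  if (!inherits(stats, "minmaxStats")) stopParam("stats", "must come from minmaxFit()")
  if (!is.matrix(records)) records <- matrix(records, ncol = length(stats$hMin))
  if (ncol(records) != length(stats$hMin))
    stopParam("records", sprintf("feature count mismatch: got %d, stats have %d",
                                 ncol(records), length(stats$hMin)))
  range <- stats$hMax - stats$hMin
  range[stats$constantMask] <- 1
  out <- sweep(sweep(records, 2L, stats$hMin), 2L, range, "/")
  out[, stats$constantMask] <- 0
  pmin(pmax(out, 0), 1)
}

#' K-means clustering of nutrition profiles
#'
#' Lloyd iterations from k-means++ initialization. The within-cluster sum of
#' squares (inertia) is recorded at every iteration and is non-increasing;
#' iteration stops at an assignment fixpoint or `maxIter`. An emptied cluster
#' is re-seeded at the point farthest from its nearest centroid.
#'
#' @param x numeric matrix (samples x features).
#' @param k number of clusters (<= nrow(x)).
#' @param seed RNG seed for the k-means++ draw.
#' @param maxIter iteration cap.
#' @return a `clusterModel`: `k`, `centroids` (k x p), `assignments` (1-based),
#'   `inertia` (final J), `inertiaPath` (J per iteration).
#' @export
kmeansDiet <- function(x, k, seed = 1L, maxIter = 100L) {
  if (!is.matrix(x)) x <- as.matrix(x)
  n <- nrow(x)
  k <- checkCount(k, "k")
  if (k > n) stopParam("k", "cannot exceed the number of samples")
  sqDistTo <- function(centers) {
    # n x k matrix of squared Euclidean distances
    xn <- rowSums(x^2)
    cn <- rowSums(centers^2)
    outer(xn, cn, "+") - 2 * x %*% t(centers)
  }
  withSeed(mixSeed(seed, 97L), {
    # k-means++ seeding
    centers <- x[sample.int(n, 1L), , drop = FALSE]
    while (nrow(centers) < k) {
      d2 <- apply(sqDistTo(centers), 1L, min)
      d2 <- pmax(d2, 0)
      probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      centers <- rbind(centers, x[sample.int(n, 1L, prob = probs), ])
    }
    assign <- rep(0L, n)
    path <- numeric(0)
    for (it in seq_len(maxIter)) {
      d2 <- sqDistTo(centers)
      newAssign <- max.col(-d2, ties.method = "first")
      path <- c(path, sum(d2[cbind(seq_len(n), newAssign)]))
      if (identical(newAssign, assign)) break
      assign <- newAssign
      for (j in seq_len(k)) {
        members <- which(assign == j)
        if (length(members) == 0L) {
          far <- which.max(apply(d2, 1L, min))
          centers[j, ] <- x[far, ]
        } else {
          centers[j, ] <- colMeans(x[members, , drop = FALSE])
        }
      }
    }
    d2 <- sqDistTo(centers)
    assign <- max.col(-d2, ties.method = "first")
    J <- sum(d2[cbind(seq_len(n), assign)])
    structure(list(k = k, centroids = centers, assignments = assign,
                   inertia = J, inertiaPath = c(path, J)),
              class = "clusterModel")
  })
}

#' @export
print.clusterModel <- function(x, ...) {
  cat(sprintf("clusterModel: k = %d, inertia = %.6g (%d Lloyd iterations)\n",
              x$k, x$inertia, length(x$inertiaPath)))
  invisible(x)
}
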