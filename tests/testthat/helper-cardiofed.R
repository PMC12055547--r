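# Shared fixtures and oracles, all built in code.

# Component-wise relative error, absolute near zero.
relErr <- function(a, b) {
  max(abs(a - b) / pmax(abs(a), abs(b), 1))
}

# Central finite differences of f at x (slow; small problems only).
numGrad <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    e <- x
    e[i] <- x[i] + h
    up <- f(e)
    e[i] <- x[i] - h
    (up - f(e)) / (2 * h)
  }, numeric(1))
}

# A small fused model plus a matching random batch. Draws are rejected when a
# pre-activation sits within the finite-difference step of a ReLU kink, where
# central differences are not informative about the (one-sided) derivative.
tinyFusedCase <- function(seed, n = 5L, nOut = 3L, withBN = TRUE, withDropout = TRUE) {
  dims <- c(ecg = 3L, image = 4L, record = 2L, nutrition = 3L)
  hidden <- list(layerSpec(6L),
                 layerSpec(5L, batchNorm = withBN),
                 layerSpec(4L, dropout = if (withDropout) 0.3 else 0))
  for (try in 0:100) {
    s <- seed + 7919L * try
    model <- buildModel(nOut = nOut, modalityDims = dims, hidden = hidden,
                        dCommon = 6L, seed = s)
    set.seed(s + 1000L)
    X <- lapply(dims, function(d) matrix(rnorm(n * d), n, d))
    y <- sample(0:(nOut - 1L), n, replace = TRUE)
    fwd <- nnForward(model, X, mode = "train", seed = 99L)
    margin <- min(vapply(seq_along(hidden), function(l)
      min(abs(fwd$cache$layers[[l]]$preAct)), numeric(1)))
    if (margin > 2e-3) return(list(model = model, X = X, y = y))
  }
  stop("could not build a kink-safe case")
}

# Loss of a model (trainable parameters flattened) on a fixed batch; dropout
# masks pinned by the forward seed so finite differences are well defined.
lossAtFlat <- function(model, flat, X, y, lambda, fwdSeed = 99L) {
  m <- unflattenState(model, flat, "trainable")
  fwd <- nnForward(m, X, mode = "train", seed = fwdSeed)
  as.numeric(lossRegularized(fwd$output, y, m, lambda))
}

# Brute-force metric oracle straight from label pairs (independent of
# confusionCounts / metricReport internals).
bruteMetrics <- function(yTrue, yPred, nClasses) {
  n <- length(yTrue)
  per <- lapply(seq_len(nClasses) - 1L, function(cl) {
    tp <- sum(yTrue == cl & yPred == cl)
    fp <- sum(yTrue != cl & yPred == cl)
    fn <- sum(yTrue == cl & yPred != cl)
    tn <- sum(yTrue != cl & yPred != cl)
    dv <- function(a, b) if (b == 0) 0 else a / b
    prec <- dv(tp, tp + fp); sens <- dv(tp, tp + fn)
    spec <- dv(tn, tn + fp); npv <- dv(tn, tn + fn)
    f <- dv(2 * prec * sens, prec + sens)
    jac <- dv(tp, tp + fp + fn)
    den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / den
    c(prec = prec, sens = sens, spec = spec, npv = npv, f = f, jac = jac, mcc = mcc)
  })
  per <- do.call(rbind, per)
  acc <- mean(yTrue == yPred)
  list(accuracy = acc, precision = mean(per[, "prec"]),
       sensitivity = mean(per[, "sens"]), specificity = mean(per[, "spec"]),
       npv = mean(per[, "npv"]), f_measure = mean(per[, "f"]),
       jaccard = mean(per[, "jac"]), mcc = mean(per[, "mcc"]),
       hamming_loss = 1 - acc)
}
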