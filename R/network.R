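# From-scratch feed-forward network with cross-entropy + L2 loss and
# SGD-with-momentum, optionally fronted by the attention-fusion block so the
# whole model (projections, scorer, dense layers) trains end-to-end.
#
# Default architecture: five hidden layers 512/256/128/64/32, ReLU throughout,
# batch normalization on hidden layer 3 only, dropout 0.3 on hidden layer 4
# only, softmax output. He-normal initialization for ReLU layers, Xavier for
# linear/softmax layers; biases start at zero.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

#' Specify one dense layer
#'
#' @param width number of neurons.
#' @param activation `"relu"` or `"linear"` (softmax is reserved for the
#'   output layer).
#' @param batchNorm apply batch normalization before the activation.
#' @param dropout dropout rate in `[0, 1)`, applied after the activation at
#'   train time with inverted scaling (inference needs no rescale).
#' @export
layerSpec <- function(width, activation = "relu", batchNorm = FALSE, dropout = 0) {
  width <- checkCount(width, "width")
  if (!activation %in% c("relu", "linear"))
    stopParam("activation", "must be 'relu' or 'linear'")
  dropout <- checkNumber(dropout, "dropout", min = 0)
  if (dropout >= 1) stopParam("dropout", "must be < 1")
  list(width = width, activation = activation,
       batchNorm = isTRUE(batchNorm), dropout = dropout)
}

#' The default five-hidden-layer architecture
#'
#' 512/256/128/64/32 ReLU layers with batch normalization on the third hidden
#' layer and dropout 0.3 on the fourth.
#' @export
defaultLayers <- function() list(
  layerSpec(512L), layerSpec(256L), layerSpec(128L, batchNorm = TRUE),
  layerSpec(64L, dropout = 0.3), layerSpec(32L)
)

#' Training hyper-parameters
#'
#' @param eta learning rate (default 0.01).
#' @param gamma momentum factor in `[0, 1)` (default 0.9).
#' @param lambda L2 regularization coefficient (default 0.001), applied to
#'   weight matrices only (biases and batch-norm parameters excluded).
#' @param batchSize mini-batch size.
#' @param epochs local epochs per training call.
#' @param init `"auto"` (He for ReLU layers, Xavier otherwise), `"he"` or
#'   `"xavier"`.
#' @param etaInVelocity if TRUE (default) the velocity update is
#'   `v <- gamma v + eta (grad)`, so `gamma = 0` reduces exactly to plain SGD;
#'   FALSE uses the literal `v <- gamma v + grad; theta <- theta - v` form.
#' @param seed base RNG seed for shuffling and dropout.
#' @export
trainConfig <- function(eta = 0.01, gamma = 0.9, lambda = 0.001,
                        batchSize = 32L, epochs = 1L, init = "auto",
                        etaInVelocity = TRUE, seed = 1L) {
  stopifnot(eta >= 0, gamma >= 0, gamma < 1, lambda >= 0)
  list(eta = eta, gamma = gamma, lambda = lambda,
       batchSize = checkCount(batchSize, "batchSize"),
       epochs = checkCount(epochs, "epochs", min = 0L),
       init = init, etaInVelocity = isTRUE(etaInVelocity),
       seed = checkCount(seed, "seed", min = 0L))
}

#' Build a classification (or Q-value) model
#'
#' With `modalityDims` given, the model is the full fused pipeline: attention
#' fusion into `dCommon` dimensions feeding the dense stack. With a plain
#' `inputDim`, the dense stack consumes the input directly (this is the form
#' used as the Q-network).
#'
#' @param nOut number of output units (classes, or actions for a Q-network).
#' @param inputDim input width for an unfused model.
#' @param modalityDims named per-modality dimensions for a fused model.
#' @param hidden list of [layerSpec()]s; defaults to [defaultLayers()].
#' @param dCommon fusion projection width (fused models).
#' @param outputActivation `"softmax"` for classification, `"linear"` for
#'   Q-values.
#' @param init initialization scheme, see [trainConfig()].
#' @param seed RNG seed; identical seeds give identical parameters.
#' @param perModalityScorer see [fusionInit()].
#' @return a `cardioModel`.
#' @export
buildModel <- function(nOut, inputDim = NULL, modalityDims = NULL,
                       hidden = defaultLayers(), dCommon = 128L,
                       outputActivation = c("softmax", "linear"),
                       init = "auto", seed = 1L, perModalityScorer = FALSE) {
  outputActivation <- match.arg(outputActivation)
  nOut <- checkCount(nOut, "nOut")
  if (is.null(inputDim) == is.null(modalityDims))
    stopParam("inputDim", "give exactly one of inputDim or modalityDims")
  fusion <- NULL
  if (!is.null(modalityDims)) {
    fusion <- fusionInit(modalityDims, dCommon = dCommon, seed = seed,
                         perModalityScorer = perModalityScorer)
    inputDim <- fusion$dCommon
  }
  spec <- list(hidden = hidden, inputDim = as.integer(inputDim), nOut = nOut,
               outputActivation = outputActivation)
  model <- list(spec = spec, fusion = fusion, params = NULL,
                trainable = NULL, isWeight = NULL)
  class(model) <- "cardioModel"
  initParams(model, scheme = init, seed = seed)
}

#' (Re-)initialize model parameters
#'
#' He-normal (`sd = sqrt(2 / fanIn)`) for ReLU layers, Xavier-normal
#' (`sd = sqrt(2 / (fanIn + fanOut))`) for linear/softmax layers under the
#' `"auto"` scheme; biases zero; batch-norm scale 1 / shift 0 with zero-mean,
#' unit-variance running statistics. Deterministic per seed.
#'
#' @param model a `cardioModel`.
#' @param scheme `"auto"`, `"he"` or `"xavier"`.
#' @param seed RNG seed.
#' @return the model with fresh parameters.
#' @export
initParams <- function(model, scheme = "auto", seed = 1L) {
  if (!scheme %in% c("auto", "he", "xavier"))
    stopParam("scheme", "unknown scheme (use 'auto', 'he' or 'xavier')")
  spec <- model$spec
  withSeed(mixSeed(seed, 29L), {
    params <- list()
    trainable <- logical(0)
    isWeight <- logical(0)
    mark <- function(nm, tr, wt) {
      trainable[nm] <<- tr
      isWeight[nm] <<- wt
    }
    if (!is.null(model$fusion)) {
      model$fusion <- fusionInit(model$fusion$modalityDims,
                                 dCommon = model$fusion$dCommon, seed = seed,
                                 perModalityScorer = model$fusion$perModalityScorer)
      for (nm in names(model$fusion$params)) {
        params[[nm]] <- model$fusion$params[[nm]]
        mark(nm, TRUE, startsWith(nm, "P_") || startsWith(nm, "Wa"))
      }
    }
    widths <- c(spec$inputDim, vapply(spec$hidden, `[[`, integer(1), "width"), spec$nOut)
    acts <- c(vapply(spec$hidden, `[[`, character(1), "activation"), spec$outputActivation)
    for (l in seq_along(acts)) {
      fanIn <- widths[l]; fanOut <- widths[l + 1L]
      sdv <- switch(scheme,
        he = sqrt(2 / fanIn),
        xavier = sqrt(2 / (fanIn + fanOut)),
        auto = if (identical(acts[l], "relu")) sqrt(2 / fanIn) else sqrt(2 / (fanIn + fanOut)))
      wn <- sprintf("W%d", l); bn <- sprintf("b%d", l)
      params[[wn]] <- matrix(rnorm(fanIn * fanOut, sd = sdv), fanIn, fanOut)
      params[[bn]] <- numeric(fanOut)
      mark(wn, TRUE, TRUE); mark(bn, TRUE, FALSE)
      if (l <= length(spec$hidden) && spec$hidden[[l]]$batchNorm) {
        for (p in c("gamma", "beta", "rm", "rv")) {
          nm <- sprintf("%s%d", p, l)
          params[[nm]] <- switch(p, gamma = rep(1, fanOut), rv = rep(1, fanOut),
                                 rep(0, fanOut))
          mark(nm, p %in% c("gamma", "beta"), FALSE)
        }
      }
    }
    model$params <- params
    model$trainable <- trainable
    model$isWeight <- isWeight
    model
  })
}

#' @export
print.cardioModel <- function(x, ...) {
  widths <- vapply(x$spec$hidden, `[[`, integer(1), "width")
  cat(sprintf("cardioModel: %s -> [%s] -> %d (%s)%s | %d parameters\n",
              if (is.null(x$fusion)) sprintf("input %d", x$spec$inputDim)
              else sprintf("fusion(%s) -> %d", paste(x$fusion$modalities, collapse = "+"),
                           x$spec$inputDim),
              paste(widths, collapse = "/"), x$spec$nOut, x$spec$outputActivation,
              if (is.null(x$fusion)) "" else "",
              sum(lengths(x$params[names(which(x$trainable))]))))
  invisible(x)
}

syncFusionParams <- function(model) {
  # keep the embedded fusionParams' tensors in step with model$params
  if (is.null(model$fusion)) return(model)
  for (nm in names(model$fusion$params)) model$fusion$params[[nm]] <- model$params[[nm]]
  model
}

#' Model forward pass
#'
#' @param model a `cardioModel`.
#' @param inputs numeric matrix (n x inputDim) for an unfused model, or a
#'   named list of per-modality matrices for a fused model.
#' @param mode `"train"` (dropout active, batch-norm batch statistics,
#'   running statistics updated in the returned cache) or `"eval"`
#'   (deterministic).
#' @param seed optional RNG seed making train-mode dropout reproducible; when
#'   NULL masks are drawn from the current RNG stream.
#' @return list with `output` (n x nOut; rows sum to 1 under softmax),
#'   `cache` (for [nnBackward()]; includes updated running statistics), and
#'   `alpha` (attention weights, fused models only).
#' @export
nnForward <- function(model, inputs, mode = c("eval", "train"), seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) return(withSeed(seed, nnForward(model, inputs, mode)))
  spec <- model$spec
  fusionOut <- NULL
  if (!is.null(model$fusion)) {
    model <- syncFusionParams(model)
    if (!is.list(inputs)) stopParam("inputs", "fused model expects a named list of modality matrices")
    fusionOut <- attentionForward(inputs, model$fusion)
    A <- fusionOut$zFused
  } else {
    A <- asBatch(inputs)
    if (ncol(A) != spec$inputDim)
      stop(sprintf("shape mismatch: expected %d input features, got %d",
                   spec$inputDim, ncol(A)), call. = FALSE)
  }
  n <- nrow(A)
  p <- model$params
  nHidden <- length(spec$hidden)
  layers <- vector("list", nHidden + 1L)
  running <- list()
  for (l in seq_len(nHidden + 1L)) {
    hiddenSpec <- if (l <= nHidden) spec$hidden[[l]] else
      list(activation = spec$outputActivation, batchNorm = FALSE, dropout = 0)
    lin <- A %*% p[[sprintf("W%d", l)]] +
      matrix(p[[sprintf("b%d", l)]], n, ncol(p[[sprintf("W%d", l)]]), byrow = TRUE)
    lcache <- list(Aprev = A, lin = lin)
    h <- lin
    if (hiddenSpec$batchNorm) {
      if (mode == "train") {
        mu <- colMeans(lin)
        v <- colMeans(sweep(lin, 2L, mu)^2)
        running[[sprintf("rm%d", l)]] <-
          BN_MOMENTUM * p[[sprintf("rm%d", l)]] + (1 - BN_MOMENTUM) * mu
        running[[sprintf("rv%d", l)]] <-
          BN_MOMENTUM * p[[sprintf("rv%d", l)]] + (1 - BN_MOMENTUM) * v
      } else {
        mu <- p[[sprintf("rm%d", l)]]
        v <- p[[sprintf("rv%d", l)]]
      }
      xhat <- sweep(sweep(lin, 2L, mu), 2L, sqrt(v + BN_EPS), "/")
      h <- sweep(xhat, 2L, p[[sprintf("gamma%d", l)]], "*")
      h <- sweep(h, 2L, p[[sprintf("beta%d", l)]], "+")
      lcache$bn <- list(mu = mu, v = v, xhat = xhat, batch = mode == "train")
    }
    act <- if (l <= nHidden) hiddenSpec$activation else spec$outputActivation
    out <- switch(act,
      relu = pmax(h, 0),
      linear = h,
      softmax = rowSoftmax(h))
    lcache$preAct <- h
    if (mode == "train" && hiddenSpec$dropout > 0) {
      mask <- matrix(runif(length(out)) >= hiddenSpec$dropout, n, ncol(out))
      out <- out * mask / (1 - hiddenSpec$dropout)
      lcache$mask <- mask
    }
    layers[[l]] <- lcache
    A <- out
  }
  cache <- list(layers = layers, fusion = fusionOut, mode = mode, n = n,
                running = running, fingerprint = paramsFingerprint(p))
  list(output = A, cache = cache,
       alpha = if (!is.null(fusionOut)) fusionOut$alpha else NULL)
}

#' Regularized cross-entropy loss
#'
#' `L = mean cross-entropy + (lambda / 2) * ||W||^2`, the squared norm taken
#' over weight matrices only (biases and batch-norm parameters excluded).
#' Probabilities at the true class are clamped at 1e-12 (flagged).
#'
#' @param probs n x C matrix of class probabilities.
#' @param labels 0-based integer class labels.
#' @param model the `cardioModel` (for the weight norm); NULL with
#'   `lambda = 0` gives the bare cross-entropy.
#' @param lambda L2 coefficient.
#' @return scalar loss; clamping is reported via [getFlags()].
#' @export
lossRegularized <- function(probs, labels, model = NULL, lambda = 0.001) {
  probs <- asBatch(probs)
  n <- nrow(probs)
  if (length(labels) != n) stopParam("labels", "length must match rows of probs")
  if (any(labels < 0 | labels >= ncol(probs)))
    stopParam("labels", "class index out of range")
  p <- probs[cbind(seq_len(n), labels + 1L)]
  flags <- character(0)
  if (any(p < 1e-12)) {
    flags <- "probability_clamped"
    p <- pmax(p, 1e-12)
  }
  L <- -mean(log(p))
  if (lambda > 0) {
    if (is.null(model)) stopParam("model", "needed when lambda > 0")
    w2 <- sum(vapply(names(which(model$isWeight & model$trainable)),
                     function(nm) sum(model$params[[nm]]^2), numeric(1)))
    L <- L + lambda / 2 * w2
  }
  setFlags(L, flags)
}

#' Model backward pass
#'
#' Computes analytic gradients of the regularized loss for every trainable
#' tensor, including the softmax–cross-entropy shortcut, batch-norm,
#' reuse of the dropout masks drawn in the forward pass, and the attention
#' fusion parameters when present. Gradients are averaged over the
#' mini-batch; the `lambda * W` regularization term is included for weight
#' matrices, so the result is the gradient of [lossRegularized()].
#'
#' @param model a `cardioModel`.
#' @param cache cache from a matching train-mode [nnForward()] call.
#' @param labels 0-based class labels (softmax output), or NULL when
#'   `gradOutput` is supplied.
#' @param gradOutput explicit dL/dOutput (linear output head, e.g. Q-learning).
#' @param lambda L2 coefficient.
#' @param output the forward pass output (required with `labels`).
#' @return named list of gradients over the trainable tensors.
#' @export
nnBackward <- function(model, cache, labels = NULL, gradOutput = NULL,
                       lambda = 0.001, output = NULL) {
  if (cache$mode != "train")
    stop("backward pass requires a train-mode forward cache", call. = FALSE)
  if (!isTRUE(all.equal(cache$fingerprint, paramsFingerprint(model$params))))
    stop("stale cache: parameters changed since the forward pass", call. = FALSE)
  spec <- model$spec
  p <- model$params
  n <- cache$n
  nHidden <- length(spec$hidden)
  grads <- list()
  if (is.null(gradOutput)) {
    if (is.null(labels) || is.null(output))
      stopParam("labels", "supply labels+output, or gradOutput")
    if (spec$outputActivation != "softmax")
      stopParam("labels", "label-based backward requires a softmax output")
    dLin <- (output - oneHot(labels, spec$nOut)) / n  # softmax-CE shortcut
  } else {
    dLin <- asBatch(gradOutput)  # gradient w.r.t. the (linear) output
  }
  for (l in seq(nHidden + 1L, 1L)) {
    lcache <- cache$layers[[l]]
    hiddenSpec <- if (l <= nHidden) spec$hidden[[l]] else
      list(activation = spec$outputActivation, batchNorm = FALSE, dropout = 0)
    d <- dLin
    if (l <= nHidden || !is.null(gradOutput)) {
      # undo dropout and activation; for the softmax output layer the shortcut
      # already gives the gradient at the linear pre-activation
      if (!is.null(lcache$mask))
        d <- d * lcache$mask / (1 - hiddenSpec$dropout)
      act <- if (l <= nHidden) hiddenSpec$activation else spec$outputActivation
      if (act == "relu") d <- d * (lcache$preAct > 0)
      # linear: identity
    }
    if (hiddenSpec$batchNorm) {
      bn <- lcache$bn
      grads[[sprintf("gamma%d", l)]] <- colSums(d * bn$xhat)
      grads[[sprintf("beta%d", l)]] <- colSums(d)
      dxhat <- sweep(d, 2L, p[[sprintf("gamma%d", l)]], "*")
      if (bn$batch) {
        invStd <- 1 / sqrt(bn$v + BN_EPS)
        xc <- sweep(lcache$lin, 2L, bn$mu)
        dvar <- colSums(dxhat * xc) * (-0.5) * invStd^3
        dmu <- colSums(sweep(dxhat, 2L, -invStd, "*")) + dvar * colMeans(-2 * xc)
        d <- sweep(dxhat, 2L, invStd, "*") +
          sweep(xc, 2L, 2 * dvar / n, "*") +
          matrix(dmu / n, n, length(dmu), byrow = TRUE)
      } else {
        d <- sweep(dxhat, 2L, 1 / sqrt(bn$v + BN_EPS), "*")
      }
    }
    wn <- sprintf("W%d", l)
    grads[[wn]] <- crossprod(lcache$Aprev, d)
    grads[[sprintf("b%d", l)]] <- colSums(d)
    dLin <- d %*% t(p[[wn]])
  }
  if (!is.null(model$fusion)) {
    model <- syncFusionParams(model)
    fb <- attentionBackward(dLin, cache$fusion$cache, model$fusion)
    grads <- c(grads, fb$grads)
  }
  if (lambda > 0) {
    for (nm in names(which(model$isWeight & model$trainable)))
      grads[[nm]] <- grads[[nm]] + lambda * p[[nm]]
  }
  grads[names(which(model$trainable))]
}

#' Initialize momentum buffers
#' @param model a `cardioModel`.
#' @return named list of zero tensors matching the trainable parameters.
#' @export
velocityInit <- function(model) {
  lapply(model$params[names(which(model$trainable))], function(x) x * 0)
}

#' SGD-with-momentum update
#'
#' With `etaInVelocity = TRUE` (default): `v <- gamma v + eta g`,
#' `theta <- theta - v`, so `gamma = 0` reduces to plain SGD. The gradients
#' are expected to already contain the `lambda * theta` regularization term
#' (as returned by [nnBackward()]).
#'
#' @param model a `cardioModel`.
#' @param velocity buffers from [velocityInit()] (or a previous step).
#' @param grads gradients from [nnBackward()].
#' @param config a [trainConfig()].
#' @return list with updated `model` and `velocity`.
#' @export
sgdMomentumStep <- function(model, velocity, grads, config) {
  for (nm in names(velocity)) {
    g <- grads[[nm]]
    if (is.null(g)) stopParam("grads", paste("missing gradient for", nm))
    if (config$etaInVelocity) {
      velocity[[nm]] <- config$gamma * velocity[[nm]] + config$eta * g
      model$params[[nm]] <- model$params[[nm]] - velocity[[nm]]
    } else {
      velocity[[nm]] <- config$gamma * velocity[[nm]] + g
      model$params[[nm]] <- model$params[[nm]] - config$eta * velocity[[nm]]
    }
  }
  list(model = syncFusionParams(model), velocity = velocity)
}

commitRunningStats <- function(model, cache) {
  for (nm in names(cache$running)) model$params[[nm]] <- cache$running[[nm]]
  model
}

subsetInputs <- function(inputs, idx) {
  if (is.list(inputs)) lapply(inputs, function(m) m[idx, , drop = FALSE])
  else inputs[idx, , drop = FALSE]
}

inputCount <- function(inputs) {
  if (is.list(inputs)) nrow(inputs[[1L]]) else nrow(asBatch(inputs))
}

#' Train a model locally with mini-batch SGD + momentum
#'
#' Shuffled mini-batches, `epochs` passes, momentum buffers fresh at entry.
#' Deterministic given `seed` (shuffling and dropout masks both derive from
#' it). Aborts with a diagnostic if the loss becomes non-finite.
#'
#' @param model a `cardioModel`.
#' @param inputs feature matrix or named modality list.
#' @param labels 0-based class labels.
#' @param config a [trainConfig()].
#' @param epochs overrides `config$epochs` when given.
#' @param seed overrides `config$seed` when given.
#' @return list with `model` and `lossHistory` (one mean regularized loss per
#'   epoch).
#' @export
trainLocal <- function(model, inputs, labels, config, epochs = NULL, seed = NULL) {
  nE <- if (is.null(epochs)) config$epochs else checkCount(epochs, "epochs", 0L)
  sd0 <- if (is.null(seed)) config$seed else seed
  n <- inputCount(inputs)
  if (n == 0L) stopParam("inputs", "empty training set")
  velocity <- velocityInit(model)
  lossHistory <- numeric(0)
  withSeed(mixSeed(sd0, 7L), {
    for (e in seq_len(nE)) {
      perm <- sample.int(n)
      batches <- split(perm, ceiling(seq_along(perm) / config$batchSize))
      epochLoss <- 0
      for (b in batches) {
        bi <- subsetInputs(inputs, b)
        by <- labels[b]
        fwd <- nnForward(model, bi, mode = "train")
        L <- lossRegularized(fwd$output, by, model, config$lambda)
        if (!is.finite(L))
          stop(sprintf("divergence: non-finite loss in epoch %d", e), call. = FALSE)
        epochLoss <- epochLoss + as.numeric(L) * length(b)
        grads <- nnBackward(model, fwd$cache, labels = by,
                            lambda = config$lambda, output = fwd$output)
        model <- commitRunningStats(model, fwd$cache)
        upd <- sgdMomentumStep(model, velocity, grads, config)
        model <- upd$model
        velocity <- upd$velocity
      }
      lossHistory <- c(lossHistory, epochLoss / n)
    }
  })
  list(model = model, lossHistory = lossHistory)
}

#' Predict class probabilities (eval mode)
#' @param model a `cardioModel`.
#' @param inputs feature matrix or named modality list.
#' @return n x C probability matrix (or Q-value matrix for linear output).
#' @export
predictModel <- function(model, inputs) nnForward(model, inputs, mode = "eval")$output

#' Predict class labels (0-based)
#' @param model a `cardioModel`.
#' @param inputs feature matrix or named modality list.
#' @export
classify <- function(model, inputs) {
  max.col(predictModel(model, inputs), ties.method = "first") - 1L
}

# ---- parameter state <-> flat vector -----------------------------------------

#' Flatten model state to a numeric vector
#'
#' `what = "all"` includes every tensor (weights, biases, batch-norm scale /
#' shift and running statistics) — the state exchanged with the federation
#' server. `what = "trainable"` covers only tensors that receive gradients.
#'
#' @param model a `cardioModel`.
#' @param what `"all"` or `"trainable"`.
#' @export
flattenState <- function(model, what = c("all", "trainable")) {
  what <- match.arg(what)
  nms <- if (what == "all") names(model$params) else names(which(model$trainable))
  unlist(model$params[nms], use.names = FALSE)
}

#' Restore model state from a flat vector
#' @param model a `cardioModel` providing the shape template.
#' @param flat numeric vector from [flattenState()].
#' @param what `"all"` or `"trainable"` (must match the flattening).
#' @export
unflattenState <- function(model, flat, what = c("all", "trainable")) {
  what <- match.arg(what)
  nms <- if (what == "all") names(model$params) else names(which(model$trainable))
  pos <- 0L
  for (nm in nms) {
    len <- length(model$params[[nm]])
    v <- flat[pos + seq_len(len)]
    pos <- pos + len
    attributes(v) <- attributes(model$params[[nm]])
    model$params[[nm]] <- v
  }
  if (pos != length(flat))
    stopParam("flat", sprintf("length %d does not match model state (%d)",
                              length(flat), pos))
  syncFusionParams(model)
}

# Flatten a gradient/velocity list in trainable order.
flattenGrads <- function(model, grads) {
  unlist(grads[names(which(model$trainable))], use.names = FALSE)
}

#' Write a model checkpoint (JSON)
#'
#' Layer specification, fusion configuration and every parameter tensor are
#' serialized at full precision.
#' @param model a `cardioModel`.
#' @param path output file.
#' @export
writeCheckpoint <- function(model, path) {
  ck <- list(
    format = "cardiofed-model", version = 1L,
    spec = model$spec,
    fusion = if (is.null(model$fusion)) NULL else list(
      modalityDims = as.list(model$fusion$modalityDims),
      dCommon = model$fusion$dCommon,
      perModalityScorer = model$fusion$perModalityScorer),
    tensors = lapply(model$params, function(t)
      list(dim = if (is.matrix(t)) dim(t) else length(t), data = as.numeric(t))),
    trainable = as.list(model$trainable),
    isWeight = as.list(model$isWeight)
  )
  jsonlite::write_json(ck, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a model checkpoint written by [writeCheckpoint()]
#' @param path checkpoint file.
#' @return a `cardioModel`.
#' @export
readCheckpoint <- function(path) {
  if (!file.exists(path)) stop("format error: no checkpoint at ", path, call. = FALSE)
  ck <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(ck$format, "cardiofed-model"))
    stop("format error: not a cardiofed model checkpoint", call. = FALSE)
  hidden <- lapply(seq_len(nrow(ck$spec$hidden)), function(i) {
    h <- ck$spec$hidden[i, ]
    layerSpec(h$width, h$activation, h$batchNorm, h$dropout)
  })
  if (is.null(ck$fusion)) {
    model <- buildModel(nOut = ck$spec$nOut, inputDim = ck$spec$inputDim,
                        hidden = hidden, outputActivation = ck$spec$outputActivation)
  } else {
    model <- buildModel(nOut = ck$spec$nOut,
                        modalityDims = unlist(ck$fusion$modalityDims),
                        hidden = hidden, dCommon = ck$fusion$dCommon,
                        outputActivation = ck$spec$outputActivation,
                        perModalityScorer = isTRUE(ck$fusion$perModalityScorer))
  }
  for (nm in names(ck$tensors)) {
    t <- ck$tensors[[nm]]
    v <- as.numeric(t$data)
    if (length(t$dim) == 2L) v <- matrix(v, t$dim[1], t$dim[2])
    model$params[[nm]] <- v
  }
  syncFusionParams(model)
}
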