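# Federated orchestration: broadcast, local node updates, differential
# privacy on the shared updates, FedAvg aggregation, multi-round refinement
# with held-out validation.
#
# Nodes run sequentially in-process under a parallel-safe contract: node
# updates are independent of each other and of their order, and aggregation
# is order-invariant. The transport layer accepts parameter containers only —
# raw samples can never leave a node through it.

#' Differential-privacy configuration (Gaussian mechanism)
#'
#' The noise scale is the analytic Gaussian-mechanism calibration
#' `sigma = clipNorm * sqrt(2 log(1.25 / delta)) / epsilon`, computed once.
#' Each node's update is first clipped to L2 norm `clipNorm` (defining the
#' sensitivity) and then perturbed with i.i.d. `N(0, sigma^2)` noise per
#' coordinate.
#'
#' @param epsilon privacy budget (> 0); smaller = stronger privacy.
#' @param delta failure probability in (0, 1).
#' @param clipNorm L2 clipping bound C (> 0).
#' @param enabled FALSE disables the mechanism (identity).
#' @export
dpConfig <- function(epsilon = 1, delta = 1e-5, clipNorm = 1, enabled = TRUE) {
  epsilon <- checkNumber(epsilon, "epsilon", min = 0, strict = TRUE)
  if (delta <= 0 || delta >= 1) stopParam("delta", "must lie in (0, 1)")
  clipNorm <- checkNumber(clipNorm, "clipNorm", min = 0, strict = TRUE)
  sigma <- clipNorm * sqrt(2 * log(1.25 / delta)) / epsilon
  structure(list(epsilon = epsilon, delta = delta, clipNorm = clipNorm,
                 sigma = sigma, enabled = isTRUE(enabled)),
            class = "dpConfig")
}

#' Federation configuration
#'
#' @param K number of nodes.
#' @param rounds communication rounds C_r.
#' @param localEpochs local epochs T_N per round.
#' @param seed master seed; every stream (initialization, shuffling, dropout,
#'   DP noise) derives from it.
#' @export
federatedConfig <- function(K, rounds, localEpochs = 1L, seed = 1L) {
  list(K = checkCount(K, "K"), rounds = checkCount(rounds, "rounds", min = 0L),
       localEpochs = checkCount(localEpochs, "localEpochs", min = 0L),
       seed = checkCount(seed, "seed", min = 0L))
}

#' Parameter-update container (the only payload transport accepts)
#'
#' @param values bare numeric vector of flattened parameters (an update or an
#'   absolute parameter state).
#' @param nK number of training samples behind the update (FedAvg weight).
#' @param kind `"state"` (absolute parameters) or `"delta"` (difference from
#'   the broadcast global model).
#' @export
paramDelta <- function(values, nK, kind = c("state", "delta")) {
  kind <- match.arg(kind)
  if (!is.numeric(values) || !is.null(dim(values)) || is.list(values))
    stopParam("values", "must be a bare numeric vector of parameters")
  if (any(!is.finite(values)))
    stop("non-finite values in parameter update", call. = FALSE)
  structure(list(values = as.numeric(values),
                 nK = checkCount(nK, "nK"), kind = kind),
            class = "paramDelta")
}

#' Validate a payload at the transport boundary
#'
#' The transport layer moves parameter containers only. Anything else — in
#' particular objects carrying sample arrays (cohorts, modality matrices,
#' data frames) — is rejected, so raw patient data cannot leave a node.
#'
#' @param payload object a node attempts to send.
#' @return the payload, invisibly, if it is a valid `paramDelta`.
#' @export
transportValidate <- function(payload) {
  if (!inherits(payload, "paramDelta"))
    stop("transport rejected payload: only paramDelta parameter containers may leave a node",
         call. = FALSE)
  if (!is.numeric(payload$values) || is.list(payload$values))
    stop("transport rejected payload: parameter values must be a bare numeric vector",
         call. = FALSE)
  invisible(payload)
}

#' One node's local update (Algorithm: NodeUpdate)
#'
#' Copies the broadcast global model, runs `epochs` epochs of shuffled
#' mini-batch SGD-with-momentum on the node's shard, and returns the local
#' parameter state with the shard size as FedAvg weight. The node's data
#' never enters the returned payload.
#'
#' @param globalModel the broadcast `cardioModel`.
#' @param inputs node-local features (matrix or modality list).
#' @param labels node-local 0-based labels.
#' @param config a [trainConfig()].
#' @param epochs local epochs T_N.
#' @param seed RNG stream for this (round, node).
#' @return a [paramDelta()] of kind `"state"`.
#' @export
nodeUpdate <- function(globalModel, inputs, labels, config, epochs, seed) {
  n <- inputCount(inputs)
  if (n == 0L) stopParam("inputs", "node shard is empty")
  fit <- trainLocal(globalModel, inputs, labels, config,
                    epochs = epochs, seed = seed)
  paramDelta(flattenState(fit$model, "all"), nK = n, kind = "state")
}

#' Clip and noise a model update (Gaussian mechanism)
#'
#' The update is scaled to L2 norm at most `dp$clipNorm`, then i.i.d.
#' Gaussian noise with the config's calibrated `sigma` is added per
#' coordinate. Disabled configs return the update unchanged.
#'
#' @param delta a [paramDelta()] of kind `"delta"` (or a bare numeric vector).
#' @param dp a [dpConfig()].
#' @param seed RNG seed for the noise draw.
#' @return object of the same type, protected; attributes `normPre` /
#'   `normPost` record the clip.
#' @export
dpProtect <- function(delta, dp, seed = 1L) {
  if (!inherits(dp, "dpConfig")) stopParam("dp", "must come from dpConfig()")
  wrapped <- inherits(delta, "paramDelta")
  v <- if (wrapped) delta$values else delta
  if (!is.numeric(v)) stopParam("delta", "must be numeric")
  if (any(!is.finite(v))) stop("non-finite values in update", call. = FALSE)
  if (!dp$enabled) return(delta)
  nrm <- sqrt(sum(v^2))
  if (nrm > dp$clipNorm) v <- v * (dp$clipNorm / nrm)
  v <- withSeed(mixSeed(seed, 131L), v + rnorm(length(v), sd = dp$sigma))
  out <- if (wrapped) {
    delta$values <- v
    delta
  } else v
  attr(out, "normPre") <- nrm
  attr(out, "normPost") <- min(nrm, dp$clipNorm)
  out
}

#' Federated averaging (FedAvg)
#'
#' Sample-count-weighted mean of the parameter vectors:
#' `W = sum(nK * Wk) / sum(nK)`, elementwise. A single update is returned
#' unchanged (the weighted mean of one vector is that vector), which keeps
#' K = 1 aggregation an exact identity.
#'
#' @param updates list of [paramDelta()]s of consistent length.
#' @return numeric vector of aggregated parameters.
#' @export
fedavg <- function(updates) {
  if (length(updates) < 1L) stopParam("updates", "need at least one update")
  for (u in updates) transportValidate(u)
  lens <- vapply(updates, function(u) length(u$values), integer(1))
  if (length(unique(lens)) != 1L)
    stop("inconsistent update shapes in fedavg", call. = FALSE)
  ns <- vapply(updates, function(u) u$nK, numeric(1))
  if (sum(ns) == 0) stop("total sample count is zero in fedavg", call. = FALSE)
  if (length(updates) == 1L) return(updates[[1L]]$values)
  # canonical accumulation order (nK, then lexicographic on the values) so the
  # aggregate is bitwise invariant to the order nodes report in
  ord <- canonicalUpdateOrder(updates, ns)
  acc <- numeric(lens[1L])
  for (i in ord) acc <- acc + ns[i] * updates[[i]]$values
  acc / sum(ns[ord])
}

canonicalUpdateOrder <- function(updates, ns) {
  ord <- order(ns)
  lexLess <- function(a, b) {
    d <- which(a != b)
    if (length(d) == 0L) FALSE else a[d[1L]] < b[d[1L]]
  }
  # insertion sort on ties in nK (K is small)
  for (i in seq_along(ord)[-1L]) {
    j <- i
    while (j > 1L && ns[ord[j - 1L]] == ns[ord[j]] &&
           lexLess(updates[[ord[j]]]$values, updates[[ord[j - 1L]]]$values)) {
      tmp <- ord[j]; ord[j] <- ord[j - 1L]; ord[j - 1L] <- tmp
      j <- j - 1L
    }
  }
  ord
}

featuresInputs <- function(features) {
  if (inherits(features, "cohortFeatures")) {
    list(inputs = features$modalities, labels = features$labels,
         nClasses = features$nClasses)
  } else if (is.list(features) && !is.null(features$inputs) && !is.null(features$labels)) {
    list(inputs = features$inputs, labels = features$labels,
         nClasses = if (!is.null(features$nClasses)) features$nClasses
                    else max(features$labels) + 1L)
  } else stopParam("features", "must be a cohortFeatures or list(inputs, labels)")
}

defaultModelFor <- function(fi, hidden, dCommon, seed) {
  if (is.list(fi$inputs) && !is.matrix(fi$inputs)) {
    dims <- vapply(fi$inputs, ncol, integer(1))
    buildModel(nOut = fi$nClasses, modalityDims = dims, hidden = hidden,
               dCommon = dCommon, seed = seed)
  } else {
    buildModel(nOut = fi$nClasses, inputDim = ncol(fi$inputs), hidden = hidden,
               seed = seed)
  }
}

#' Run a federated training experiment
#'
#' Phase 1 broadcasts the initialized global model; each communication round
#' runs every node's local update (sequentially, under an order-invariant
#' contract), applies differential privacy to each node's update, aggregates
#' with sample-count-weighted FedAvg, and validates the refreshed global
#' model on the held-out set. Deterministic per seed when DP is disabled.
#'
#' @param features training data: a [cohortFeatures()] or `list(inputs, labels)`.
#' @param partition a [partitionCohort()] covering the training samples.
#' @param fedConfig a [federatedConfig()].
#' @param trainConfig a [trainConfig()].
#' @param dp a [dpConfig()] or NULL (off).
#' @param validation held-out data in the same form as `features` (optional).
#' @param hidden layer specification for the model (default [defaultLayers()]).
#' @param dCommon fusion width for multimodal features.
#' @param model optional pre-built `cardioModel` to start from (overrides
#'   `hidden` / `dCommon`).
#' @return a `federationRun`: `model` (final global model), `rounds` (list of
#'   per-round logs: node update norms pre/post clip, noise sigma, validation
#'   metrics, naive composed privacy spend `round * epsilon`), `config`.
#' @export
runFederation <- function(features, partition, fedConfig, trainConfig,
                          dp = NULL, validation = NULL,
                          hidden = defaultLayers(), dCommon = 128L,
                          model = NULL) {
  fi <- featuresInputs(features)
  if (!inherits(partition, "nodePartition"))
    stopParam("partition", "must come from partitionCohort()")
  shards <- partition$assignments
  if (length(shards) != fedConfig$K)
    stopParam("partition", sprintf("has %d nodes but fedConfig$K = %d",
                                   length(shards), fedConfig$K))
  covered <- sort(unlist(shards, use.names = FALSE))
  if (!identical(covered, seq_len(inputCount(fi$inputs))))
    stopParam("partition", "must cover the training samples exactly once")
  if (any(lengths(shards) == 0L))
    stopParam("partition", "every node needs a non-empty shard")
  if (is.null(model))
    model <- defaultModelFor(fi, hidden, dCommon, fedConfig$seed)
  vi <- if (!is.null(validation)) featuresInputs(validation) else NULL
  rounds <- vector("list", fedConfig$rounds)
  for (e in seq_len(fedConfig$rounds)) {
    globalFlat <- flattenState(model, "all")
    payloads <- vector("list", fedConfig$K)
    normsPre <- normsPost <- rep(NA_real_, fedConfig$K)
    for (k in seq_len(fedConfig$K)) {
      idx <- shards[[k]]
      upd <- nodeUpdate(model,
                        subsetInputs(fi$inputs, idx), fi$labels[idx],
                        trainConfig, epochs = fedConfig$localEpochs,
                        seed = mixSeed(fedConfig$seed, e, k))
      if (!is.null(dp) && dp$enabled) {
        dlt <- paramDelta(upd$values - globalFlat, nK = upd$nK, kind = "delta")
        dlt <- dpProtect(dlt, dp, seed = mixSeed(fedConfig$seed, e, k, 999L))
        normsPre[k] <- attr(dlt, "normPre")
        normsPost[k] <- attr(dlt, "normPost")
        upd <- paramDelta(globalFlat + dlt$values, nK = upd$nK, kind = "state")
      } else {
        normsPre[k] <- normsPost[k] <- sqrt(sum((upd$values - globalFlat)^2))
      }
      payloads[[k]] <- transportValidate(upd)
    }
    agg <- fedavg(payloads)
    model <- unflattenState(model, agg, "all")
    log <- list(round = e, nodeNormPre = normsPre, nodeNormPost = normsPost,
                sigma = if (!is.null(dp) && dp$enabled) dp$sigma else 0,
                epsilonSpent = if (!is.null(dp) && dp$enabled) e * dp$epsilon else 0)
    if (!is.null(vi)) {
      pred <- classify(model, vi$inputs)
      log$valAccuracy <- mean(pred == vi$labels)
      probs <- predictModel(model, vi$inputs)
      log$valLoss <- as.numeric(lossRegularized(probs, vi$labels, model,
                                                trainConfig$lambda))
      if (!is.finite(log$valLoss))
        stop(sprintf("divergence: non-finite validation loss at round %d", e),
             call. = FALSE)
    }
    rounds[[e]] <- log
  }
  structure(list(model = model, rounds = rounds,
                 config = list(fed = fedConfig, train = trainConfig, dp = dp)),
            class = "federationRun")
}

#' @export
print.federationRun <- function(x, ...) {
  acc <- vapply(x$rounds, function(r) r$valAccuracy %||% NA_real_, numeric(1))
  cat(sprintf("federationRun: K = %d, %d rounds, DP %s",
              x$config$fed$K, x$config$fed$rounds,
              if (!is.null(x$config$dp) && x$config$dp$enabled)
                sprintf("on (eps = %g)", x$config$dp$epsilon) else "off"))
  if (any(!is.na(acc)))
    cat(sprintf(" | final validation accuracy %.4f", tail(acc[!is.na(acc)], 1L)))
  cat("\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Centralized training with the federated schedule
#'
#' Reference path for the K = 1 equivalence check: the same number of rounds
#' and local epochs on the pooled data, with momentum reset at round
#' boundaries and the same derived RNG streams, but none of the federation
#' machinery (no transport, no aggregation).
#'
#' @param features training data as in [runFederation()].
#' @param fedConfig a [federatedConfig()] (K is ignored; schedule and seed used).
#' @param trainConfig a [trainConfig()].
#' @param hidden,dCommon,model model specification as in [runFederation()].
#' @return the trained `cardioModel`.
#' @export
trainCentral <- function(features, fedConfig, trainConfig,
                         hidden = defaultLayers(), dCommon = 128L,
                         model = NULL) {
  fi <- featuresInputs(features)
  if (is.null(model))
    model <- defaultModelFor(fi, hidden, dCommon, fedConfig$seed)
  for (e in seq_len(fedConfig$rounds)) {
    model <- trainLocal(model, fi$inputs, fi$labels, trainConfig,
                        epochs = fedConfig$localEpochs,
                        seed = mixSeed(fedConfig$seed, e, 1L))$model
  }
  model
}
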