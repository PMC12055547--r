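# Trainable softmax attention over modality feature vectors.
#
# Modality dimensions differ, so each modality is first projected by a
# trainable linear map P_i into a common d-dimensional space; a shared scorer
# (Wa, ba) produces one relevance score per modality, softmax-normalized into
# attention weights alpha, and the fused vector is the alpha-weighted sum of
# the projected modalities. Everything is differentiable; the analytic
# backward pass (including the softmax Jacobian coupling modalities) is
# provided for end-to-end training with the classifier.

paramsFingerprint <- function(params) {
  v <- unlist(params, use.names = FALSE)
  c(length(v), sum(v), sum(v * v))
}

#' Initialize attention-fusion parameters
#'
#' @param modalityDims named integer vector of per-modality feature dimensions.
#' @param dCommon common projection dimension (default 128).
#' @param seed RNG seed (Xavier-normal projections, zero biases and scorer).
#' @param perModalityScorer if TRUE each modality gets its own (Wa, ba); the
#'   default is a single scorer shared across modalities.
#' @return a `fusionParams` list of parameter tensors.
#' @export
fusionInit <- function(modalityDims, dCommon = 128L, seed = 1L,
                       perModalityScorer = FALSE) {
  if (is.null(names(modalityDims)) || any(names(modalityDims) == ""))
    stopParam("modalityDims", "must be a named vector")
  dCommon <- checkCount(dCommon, "dCommon")
  withSeed(mixSeed(seed, 17L), {
    params <- list()
    for (m in names(modalityDims)) {
      dIn <- checkCount(modalityDims[[m]], paste0("modalityDims$", m))
      sdv <- sqrt(2 / (dIn + dCommon))
      params[[paste0("P_", m)]] <- matrix(rnorm(dIn * dCommon, sd = sdv), dIn, dCommon)
      params[[paste0("bP_", m)]] <- numeric(dCommon)
    }
    if (perModalityScorer) {
      for (m in names(modalityDims)) {
        params[[paste0("Wa_", m)]] <- rnorm(dCommon, sd = sqrt(1 / dCommon))
        params[[paste0("ba_", m)]] <- 0
      }
    } else {
      params$Wa <- rnorm(dCommon, sd = sqrt(1 / dCommon))
      params$ba <- 0
    }
    structure(list(params = params,
                   modalities = names(modalityDims),
                   modalityDims = modalityDims,
                   dCommon = dCommon,
                   perModalityScorer = perModalityScorer),
              class = "fusionParams")
  })
}

asBatch <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = 1L)
}

#' Attention-fusion forward pass
#'
#' Computes `G_i = F_i P_i + bP_i`, scores `s_i = Wa' G_i + ba`, attention
#' weights `alpha = softmax(s)` (max-subtracted for stability) and the fused
#' representation `z_fused = sum_i alpha_i G_i`. The raw concatenation `z` is
#' returned as a diagnostic; the classifier consumes `z_fused`.
#'
#' @param features named list of per-modality feature vectors (or n x d_i
#'   matrices for a batch); every configured modality must be present.
#' @param fusion a `fusionParams` from [fusionInit()].
#' @return list with `zFused` (n x dCommon), `alpha` (n x nModalities, rows on
#'   the simplex), `z` (diagnostic concatenation) and `cache` for
#'   [attentionBackward()].
#' @export
attentionForward <- function(features, fusion) {
  if (!inherits(fusion, "fusionParams")) stopParam("fusion", "must come from fusionInit()")
  mods <- fusion$modalities
  missingMods <- setdiff(mods, names(features))
  if (length(missingMods))
    stop("missing modality: ", paste(missingMods, collapse = ", "), call. = FALSE)
  X <- lapply(mods, function(m) asBatch(features[[m]]))
  names(X) <- mods
  n <- nrow(X[[1L]])
  p <- fusion$params
  G <- list()
  S <- matrix(0, n, length(mods))
  for (j in seq_along(mods)) {
    m <- mods[j]
    if (ncol(X[[m]]) != fusion$modalityDims[[m]])
      stopParam(m, sprintf("expected %d features, got %d",
                           fusion$modalityDims[[m]], ncol(X[[m]])))
    G[[m]] <- X[[m]] %*% p[[paste0("P_", m)]] +
      matrix(p[[paste0("bP_", m)]], n, fusion$dCommon, byrow = TRUE)
    if (fusion$perModalityScorer) {
      S[, j] <- G[[m]] %*% p[[paste0("Wa_", m)]] + p[[paste0("ba_", m)]]
    } else {
      S[, j] <- G[[m]] %*% p$Wa + p$ba
    }
  }
  alpha <- rowSoftmax(S)
  colnames(alpha) <- mods
  zFused <- matrix(0, n, fusion$dCommon)
  for (j in seq_along(mods)) zFused <- zFused + alpha[, j] * G[[mods[j]]]
  cache <- list(X = X, G = G, alpha = alpha,
                fingerprint = paramsFingerprint(p))
  list(zFused = zFused, alpha = alpha,
       z = do.call(cbind, unname(X)), cache = cache)
}

#' Attention-fusion backward pass
#'
#' Exact analytic gradients of a scalar loss with respect to every fusion
#' parameter and every modality input, given the gradient at `zFused`. The
#' softmax Jacobian couples the modalities: perturbing one modality's score
#' moves every attention weight.
#'
#' @param gradOut gradient of the loss w.r.t. `zFused` (n x dCommon).
#' @param cache cache from the matching [attentionForward()] call.
#' @param fusion the same `fusionParams` used in the forward pass.
#' @return list with `grads` (named like `fusion$params`) and `gradFeatures`
#'   (named list of gradients w.r.t. each modality input).
#' @export
attentionBackward <- function(gradOut, cache, fusion) {
  if (!inherits(fusion, "fusionParams")) stopParam("fusion", "must come from fusionInit()")
  if (!isTRUE(all.equal(cache$fingerprint, paramsFingerprint(fusion$params))))
    stop("stale cache: fusion parameters changed since the forward pass", call. = FALSE)
  mods <- fusion$modalities
  p <- fusion$params
  gradOut <- asBatch(gradOut)
  n <- nrow(gradOut)
  alpha <- cache$alpha
  m <- length(mods)
  dalpha <- matrix(0, n, m)
  for (j in seq_len(m)) dalpha[, j] <- rowSums(gradOut * cache$G[[mods[j]]])
  ds <- alpha * (dalpha - rowSums(alpha * dalpha))
  grads <- list()
  gradFeatures <- list()
  if (!fusion$perModalityScorer) {
    dWa <- numeric(fusion$dCommon)
    dba <- 0
  }
  for (j in seq_len(m)) {
    mod <- mods[j]
    Wa <- if (fusion$perModalityScorer) p[[paste0("Wa_", mod)]] else p$Wa
    dG <- alpha[, j] * gradOut + outer(ds[, j], Wa)
    grads[[paste0("P_", mod)]] <- crossprod(cache$X[[mod]], dG)
    grads[[paste0("bP_", mod)]] <- colSums(dG)
    gradFeatures[[mod]] <- dG %*% t(p[[paste0("P_", mod)]])
    if (fusion$perModalityScorer) {
      grads[[paste0("Wa_", mod)]] <- drop(crossprod(cache$G[[mod]], ds[, j]))
      grads[[paste0("ba_", mod)]] <- sum(ds[, j])
    } else {
      dWa <- dWa + drop(crossprod(cache$G[[mod]], ds[, j]))
      dba <- dba + sum(ds[, j])
    }
  }
  if (!fusion$perModalityScorer) {
    grads$Wa <- dWa
    grads$ba <- dba
  }
  list(grads = grads, gradFeatures = gradFeatures)
}
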