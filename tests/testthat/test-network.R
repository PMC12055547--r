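test_that("forward pass produces calibrated probabilities deterministically", {
  m <- buildModel(nOut = 4L, inputDim = 3L, hidden = list(layerSpec(5L)), seed = 1)
  X <- matrix(rnorm(6 * 3), 6, 3)

  # all-zero parameters: ReLU kills the hidden signal, softmax of zeros is uniform
  m0 <- m
  for (nm in names(m0$params)) m0$params[[nm]] <- m0$params[[nm]] * 0
  expect_equal(nnForward(m0, X)$output, matrix(0.25, 6, 4), ignore_attr = TRUE)

  # eval mode is repeatable
  expect_identical(nnForward(m, X)$output, nnForward(m, X)$output)
  expect_equal(rowSums(nnForward(m, X)$output), rep(1, 6), tolerance = 1e-12)

  # single linear layer + softmax computable by hand
  ml <- buildModel(nOut = 2L, inputDim = 2L, hidden = list(), seed = 1)
  ml$params$W1 <- matrix(c(1, 3, 2, 4), 2, 2)  # [[1,2],[3,4]]
  ml$params$b1 <- c(0, 0)
  probs <- nnForward(ml, matrix(c(1, 0), 1))$output
  expect_equal(as.numeric(probs), exp(c(1, 2)) / sum(exp(c(1, 2))), tolerance = 1e-12)

  expect_error(nnForward(m, matrix(0, 2, 7)), "shape mismatch")
})

test_that("regularized loss matches its closed forms", {
  perfect <- diag(3)[c(1, 2, 3), ]
  expect_equal(as.numeric(lossRegularized(perfect, 0:2, lambda = 0)), 0,
               tolerance = 1e-9)
  uniform <- matrix(1 / 5, 4, 5)
  expect_equal(as.numeric(lossRegularized(uniform, c(0, 4, 2, 1), lambda = 0)),
               log(5), tolerance = 1e-12)

  # L = 1, lambda = 0.001, ||theta||^2 = 100 -> 1.05
  m <- buildModel(nOut = 2L, inputDim = 2L, hidden = list(), seed = 1)
  m$params$W1 <- matrix(5, 2, 2)  # ||W||^2 = 100
  probs <- matrix(c(exp(-1), 1 - exp(-1)), 1)
  expect_equal(as.numeric(lossRegularized(probs, 0L, m, 0.001)),
               1 + 0.001 / 2 * 100, tolerance = 1e-12)

  clamped <- lossRegularized(matrix(c(0, 1), 1), 0L, lambda = 0)
  expect_true("probability_clamped" %in% getFlags(clamped))
})

test_that("backpropagation matches finite differences on a 4-8-3 network", {
  set.seed(30)
  m <- buildModel(nOut = 3L, inputDim = 4L, hidden = list(layerSpec(8L)), seed = 7)
  X <- matrix(rnorm(5 * 4), 5, 4)
  y <- c(0L, 1L, 2L, 0L, 1L)
  lam <- 0.01
  fwd <- nnForward(m, X, mode = "train", seed = 99)
  ga <- unlist(
    nnBackward(m, fwd$cache, labels = y, lambda = lam, output = fwd$output),
    use.names = FALSE)
  flat <- flattenState(m, "trainable")
  gn <- numGrad(function(v) lossAtFlat(m, v, X, y, lam), flat)
  expect_lt(relErr(ga, gn), 1e-5)

  # the L2 contribution is exactly lambda * W
  g0 <- nnBackward(m, fwd$cache, labels = y, lambda = 0, output = fwd$output)
  g1 <- nnBackward(m, fwd$cache, labels = y, lambda = 0.5, output = fwd$output)
  expect_equal(g1$W1 - g0$W1, 0.5 * m$params$W1, tolerance = 1e-12)
  expect_equal(g1$b1, g0$b1, tolerance = 1e-15)  # biases are not regularized

  # zero input batch: first-layer weight gradients vanish, bias gradients do
  # not (biases set nonzero so the ReLU gates stay open)
  mB <- m
  mB$params$b1 <- seq(0.1, 0.8, length.out = 8)
  fwd0 <- nnForward(mB, matrix(0, 5, 4), mode = "train", seed = 1)
  gz <- nnBackward(mB, fwd0$cache, labels = y, lambda = 0, output = fwd0$output)
  expect_equal(sum(abs(gz$W1)), 0)
  expect_gt(sum(abs(gz$b1)), 0)

  # eval-mode cache is rejected
  fe <- nnForward(m, X, mode = "eval")
  expect_error(nnBackward(m, fe$cache, labels = y, output = fe$output),
               "train-mode")
})

test_that("momentum updates unroll exactly", {
  m <- buildModel(nOut = 1L, inputDim = 1L, hidden = list(),
                  outputActivation = "linear", seed = 1)
  m$params$W1 <- matrix(1); m$params$b1 <- 0
  v <- velocityInit(m)

  # gamma = 0: theta <- theta - eta * grad
  cfg <- trainConfig(eta = 0.01, gamma = 0, lambda = 0)
  up <- sgdMomentumStep(m, v, list(W1 = matrix(0.5), b1 = 0), cfg)
  expect_equal(as.numeric(up$model$params$W1), 0.995, tolerance = 1e-15)

  # gamma = 0.9, constant gradient g: v1 = 0.01 g, v2 = 0.019 g, theta2 = -0.029 g
  g <- 2
  m2 <- m; m2$params$W1 <- matrix(0)
  cfg2 <- trainConfig(eta = 0.01, gamma = 0.9, lambda = 0)
  st <- list(model = m2, velocity = velocityInit(m2))
  st <- sgdMomentumStep(st$model, st$velocity, list(W1 = matrix(g), b1 = 0), cfg2)
  expect_equal(as.numeric(st$velocity$W1), 0.01 * g, tolerance = 1e-15)
  st <- sgdMomentumStep(st$model, st$velocity, list(W1 = matrix(g), b1 = 0), cfg2)
  expect_equal(as.numeric(st$velocity$W1), 0.019 * g, tolerance = 1e-12)
  expect_equal(as.numeric(st$model$params$W1), -0.029 * g, tolerance = 1e-12)

  # zero gradient, zero velocity: fixpoint
  up3 <- sgdMomentumStep(m, velocityInit(m), list(W1 = matrix(0), b1 = 0), cfg2)
  expect_identical(up3$model$params$W1, m$params$W1)

  # literal form without eta in the velocity
  cfgL <- trainConfig(eta = 0.1, gamma = 0.5, lambda = 0, etaInVelocity = FALSE)
  upL <- sgdMomentumStep(m, velocityInit(m), list(W1 = matrix(1), b1 = 0), cfgL)
  expect_equal(as.numeric(upL$model$params$W1), 1 - 0.1 * 1, tolerance = 1e-15)
})

test_that("heavy-ball iterates on a quadratic bowl match the linear recursion", {
  # L = theta^2 / 2, grad = theta; [theta; v] evolves linearly
  eta <- 0.1; gam <- 0.6
  m <- buildModel(nOut = 1L, inputDim = 1L, hidden = list(),
                  outputActivation = "linear", seed = 1)
  m$params$W1 <- matrix(1); m$params$b1 <- 0
  cfg <- trainConfig(eta = eta, gamma = gam, lambda = 0)
  v <- velocityInit(m)
  A <- matrix(c(1 - eta, eta, -gam, gam), 2, 2)
  state <- c(1, 0)
  for (t in 1:50) {
    up <- sgdMomentumStep(m, v, list(W1 = m$params$W1, b1 = 0), cfg)
    m <- up$model; v <- up$velocity
    state <- A %*% state
    expect_equal(as.numeric(m$params$W1), state[1], tolerance = 1e-12)
    expect_equal(as.numeric(v$W1), state[2], tolerance = 1e-12)
  }
})

test_that("initialization schemes are deterministic with the stated variances", {
  m1 <- buildModel(nOut = 3L, inputDim = 10L, hidden = list(layerSpec(6L)), seed = 4)
  m2 <- buildModel(nOut = 3L, inputDim = 10L, hidden = list(layerSpec(6L)), seed = 4)
  expect_identical(m1$params, m2$params)
  expect_true(all(m1$params$b1 == 0) && all(m1$params$b2 == 0))

  he <- buildModel(nOut = 8L, inputDim = 512L, hidden = list(layerSpec(256L)),
                   init = "he", seed = 2)
  v <- var(as.numeric(he$params$W1))  # 512 * 256 > 1e5 draws, fan_in = 512
  expect_lt(abs(v - 2 / 512) / (2 / 512), 0.1)

  xa <- buildModel(nOut = 8L, inputDim = 512L, hidden = list(layerSpec(256L)),
                   init = "xavier", seed = 2)
  vx <- var(as.numeric(xa$params$W1))
  expect_lt(abs(vx - 2 / (512 + 256)) / (2 / (512 + 256)), 0.1)

  expect_error(buildModel(nOut = 2L, inputDim = 3L, init = "glorot"), "unknown scheme")
})

test_that("training drives the regularized loss down on separable data", {
  set.seed(44)
  n <- 120
  X <- rbind(matrix(rnorm(n, -3), n / 2, 2), matrix(rnorm(n, 3), n / 2, 2))
  y <- rep(0:1, each = n / 2)
  m <- buildModel(nOut = 2L, inputDim = 2L, hidden = list(layerSpec(8L)), seed = 3)
  fit <- trainLocal(m, X, y, trainConfig(batchSize = 16L), epochs = 30L, seed = 5)
  drops <- diff(fit$lossHistory)
  expect_lte(mean(drops > 0), 0.05)  # <= 5% violating steps
  expect_lt(tail(fit$lossHistory, 1), fit$lossHistory[1])
  expect_gt(mean(classify(fit$model, X) == y), 0.95)
})

test_that("full-batch single step with no momentum equals vanilla gradient descent", {
  set.seed(50)
  m <- buildModel(nOut = 2L, inputDim = 3L, hidden = list(layerSpec(4L)), seed = 8)
  X <- matrix(rnorm(20 * 3), 20, 3)
  y <- rep(0:1, 10)
  cfg <- trainConfig(eta = 0.05, gamma = 0, lambda = 0, batchSize = 20L)
  fit <- trainLocal(m, X, y, cfg, epochs = 1L, seed = 2)
  fwd <- nnForward(m, X, mode = "train")
  g <- nnBackward(m, fwd$cache, labels = y, lambda = 0, output = fwd$output)
  expect_equal(fit$model$params$W1, m$params$W1 - 0.05 * g$W1, tolerance = 1e-12)
  expect_equal(fit$model$params$b2, m$params$b2 - 0.05 * g$b2, tolerance = 1e-12)
})

test_that("checkpoints round-trip through JSON", {
  case <- tinyFusedCase(seed = 6)
  fit <- trainLocal(case$model, case$X, case$y, trainConfig(batchSize = 4L),
                    epochs = 2L, seed = 1)
  path <- withr::local_tempfile(fileext = ".json")
  writeCheckpoint(fit$model, path)
  back <- readCheckpoint(path)
  expect_equal(back$params, fit$model$params, tolerance = 1e-12)
  expect_equal(predictModel(back, case$X), predictModel(fit$model, case$X),
               tolerance = 1e-10)
  expect_error(readCheckpoint(withr::local_tempfile(fileext = ".json")), "format error")
})
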