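makeToyFeatures <- function(n, seed, inputDim = 6L) {
  set.seed(seed)
  y <- rep(0:1, length.out = n)
  X <- matrix(rnorm(n * inputDim), n, inputDim) + 2.5 * y
  list(inputs = X, labels = y, nClasses = 2L)
}

smallNet <- function() list(layerSpec(8L))

test_that("degenerate node updates return the broadcast parameters", {
  fi <- makeToyFeatures(20, 1)
  m <- buildModel(nOut = 2L, inputDim = 6L, hidden = smallNet(), seed = 2)
  cfg <- trainConfig(batchSize = 10L)
  g <- flattenState(m, "all")

  up0 <- nodeUpdate(m, fi$inputs, fi$labels, cfg, epochs = 0L, seed = 1)
  expect_identical(up0$values, g)  # T_N = 0 -> no change

  cfg0 <- trainConfig(eta = 0, batchSize = 10L)
  upE <- nodeUpdate(m, fi$inputs, fi$labels, cfg0, epochs = 2L, seed = 1)
  expect_identical(upE$values, g)  # eta = 0 -> no change

  expect_error(nodeUpdate(m, fi$inputs[0, , drop = FALSE], integer(0), cfg, 1L, 1),
               "empty")
})

test_that("a full-batch node update is one explicit gradient step", {
  fi <- makeToyFeatures(16, 3)
  m <- buildModel(nOut = 2L, inputDim = 6L, hidden = smallNet(), seed = 5)
  cfg <- trainConfig(eta = 0.02, gamma = 0, lambda = 0, batchSize = 16L)
  up <- nodeUpdate(m, fi$inputs, fi$labels, cfg, epochs = 1L, seed = 9)
  fwd <- nnForward(m, fi$inputs, mode = "train")
  g <- nnBackward(m, fwd$cache, labels = fi$labels, lambda = 0, output = fwd$output)
  expected <- flattenState(m, "trainable") -
    0.02 * unlist(g, use.names = FALSE)
  got <- unflattenState(m, up$values, "all")
  expect_equal(flattenState(got, "trainable"), expected, tolerance = 1e-12)
})

test_that("the Gaussian mechanism clips and noises as configured", {
  dp <- dpConfig(epsilon = 1, delta = 1e-5, clipNorm = 1)
  expect_equal(dp$sigma, sqrt(2 * log(1.25e5)), tolerance = 1e-12)

  off <- dpConfig(enabled = FALSE)
  v <- rnorm(100)
  expect_identical(dpProtect(v, off, seed = 1), v)

  big <- rep(1, 100)  # norm 10 -> clipped to norm 1 before noising
  set.seed(1)
  out <- dpProtect(big, dp, seed = 4)
  expect_equal(attr(out, "normPre"), 10)
  expect_equal(attr(out, "normPost"), 1)

  # noise is reproducible per seed and differs across seeds
  expect_identical(dpProtect(big, dp, seed = 4), out)
  expect_false(identical(dpProtect(big, dp, seed = 5), out))

  expect_error(dpProtect(c(1, NaN), dp, 1), "non-finite")
  expect_error(dpConfig(epsilon = 0), "epsilon")
  expect_error(dpConfig(delta = 1), "delta")
})

test_that("FedAvg computes the sample-weighted mean with exact identities", {
  pd <- function(v, n) paramDelta(v, n)
  expect_equal(fedavg(list(pd(1, 5), pd(3, 5))), 2)
  expect_equal(fedavg(list(pd(0, 1), pd(4, 3))), 3)  # weighted: (0*1 + 4*3)/4

  v <- rnorm(50)
  expect_identical(fedavg(list(pd(v, 7))), v)  # single update: exact identity

  # idempotence: identical updates aggregate to themselves (bitwise for
  # power-of-two weights, to rounding otherwise)
  expect_identical(fedavg(list(pd(v, 2), pd(v, 2))), v)
  expect_equal(fedavg(list(pd(v, 2), pd(v, 5), pd(v, 1))), v, tolerance = 1e-12)

  # order invariance is bitwise
  set.seed(7)
  ups <- list(pd(rnorm(200), 10), pd(rnorm(200), 25), pd(rnorm(200), 10))
  ref <- fedavg(ups)
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    expect_identical(fedavg(ups[perm]), ref)
  }

  expect_error(paramDelta(rnorm(5), 0), "nK")
  expect_error(fedavg(list(pd(rnorm(3), 1), pd(rnorm(4), 1))), "shapes")
})

test_that("transport accepts parameter containers only", {
  ok <- paramDelta(rnorm(10), 5)
  expect_invisible(transportValidate(ok))

  co <- generateCohort(cohortSpec(5, seed = 1))
  expect_error(transportValidate(co), "transport rejected")
  expect_error(transportValidate(list(ecg = co$ecg, labels = co$labels)),
               "transport rejected")
  expect_error(transportValidate(data.frame(x = 1)), "transport rejected")
  expect_error(transportValidate(co$records), "transport rejected")
  expect_error(paramDelta(data.frame(x = 1), 1), "bare numeric vector")
})

test_that("one FedAvg round of full-batch nodes equals one pooled step", {
  fi <- makeToyFeatures(30, 8)
  m <- buildModel(nOut = 2L, inputDim = 6L, hidden = smallNet(), seed = 4)
  cfg <- trainConfig(eta = 0.05, gamma = 0, lambda = 0, batchSize = 30L)
  shards <- list(1:10, 11:20, 21:30)
  ups <- lapply(shards, function(idx)
    nodeUpdate(m, fi$inputs[idx, ], fi$labels[idx],
               trainConfig(eta = 0.05, gamma = 0, lambda = 0, batchSize = 10L),
               epochs = 1L, seed = 3))
  agg <- fedavg(ups)
  pooled <- nodeUpdate(m, fi$inputs, fi$labels, cfg, epochs = 1L, seed = 3)
  expect_equal(agg, pooled$values, tolerance = 1e-10)
})

test_that("single-node federation reproduces centralized training bitwise", {
  co <- generateCohort(cohortSpec(60, seed = 17))
  f <- cohortFeatures(co)
  part <- partitionCohort(f$labels, K = 1, seed = 2)
  fed <- federatedConfig(K = 1, rounds = 3, localEpochs = 2, seed = 11)
  cfg <- trainConfig(batchSize = 16L)
  run <- runFederation(f, part, fed, cfg, hidden = smallNet(), dCommon = 8L)
  central <- trainCentral(f, fed, cfg, hidden = smallNet(), dCommon = 8L)
  expect_identical(flattenState(run$model, "all"), flattenState(central, "all"))
})

test_that("federation is deterministic per seed with DP off and logs rounds", {
  co <- generateCohort(cohortSpec(80, seed = 23))
  f <- cohortFeatures(co)
  fv <- cohortFeatures(generateCohort(cohortSpec(40, seed = 24)), stats = f$stats)
  part <- partitionCohort(f$labels, K = 4, seed = 2)
  fed <- federatedConfig(K = 4, rounds = 2, localEpochs = 1, seed = 6)
  cfg <- trainConfig(batchSize = 10L)
  r1 <- runFederation(f, part, fed, cfg, validation = fv,
                      hidden = smallNet(), dCommon = 8L)
  r2 <- runFederation(f, part, fed, cfg, validation = fv,
                      hidden = smallNet(), dCommon = 8L)
  expect_identical(flattenState(r1$model, "all"), flattenState(r2$model, "all"))
  expect_length(r1$rounds, 2L)
  expect_equal(r1$rounds[[2]]$round, 2L)
  expect_true(all(is.finite(r1$rounds[[1]]$nodeNormPre)))
  expect_true(is.finite(r1$rounds[[1]]$valAccuracy))

  # round logs carry the naive composed privacy spend when DP is on
  dp <- dpConfig(epsilon = 50, delta = 1e-5, clipNorm = 5)
  rd <- runFederation(f, part, fed, cfg, dp = dp, hidden = smallNet(), dCommon = 8L)
  expect_equal(vapply(rd$rounds, `[[`, numeric(1), "epsilonSpent"), c(50, 100))
  expect_true(all(unlist(lapply(rd$rounds, `[[`, "nodeNormPost")) <= 5 + 1e-9))
})

test_that("privacy noise degrades accuracy monotonically as epsilon shrinks", {
  co <- generateCohort(cohortSpec(300, seed = 31))
  f <- cohortFeatures(co)
  fv <- cohortFeatures(generateCohort(cohortSpec(150, seed = 32)), stats = f$stats)
  part <- partitionCohort(f$labels, K = 3, seed = 2)
  fed <- federatedConfig(K = 3, rounds = 10, localEpochs = 1, seed = 13)
  cfg <- trainConfig(batchSize = 25L)
  hid <- list(layerSpec(32L), layerSpec(16L))
  accAt <- function(dp) {
    run <- runFederation(f, part, fed, cfg, dp = dp, validation = fv,
                         hidden = hid, dCommon = 16L)
    run$rounds[[fed$rounds]]$valAccuracy
  }
  accOff <- accAt(NULL)
  # clip bound chosen near the typical raw update norm of this configuration
  accs <- vapply(c(0.1, 10, 100, 1000), function(eps)
    accAt(dpConfig(epsilon = eps, delta = 1e-5, clipNorm = 0.5)), numeric(1))
  expect_true(all(diff(accs) >= -0.02))       # monotone trend up in epsilon
  expect_gte(accs[3], accOff - 0.02)          # epsilon = 100 within 2 points
  expect_gte(accs[4], accOff - 0.02)
  expect_lt(accs[1], accOff - 0.1)            # small epsilon degrades sharply
})
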