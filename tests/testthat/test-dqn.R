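linearQNet <- function(nIn, nA, seed = 1) {
  buildModel(nOut = nA, inputDim = nIn, hidden = list(),
             outputActivation = "linear", seed = seed)
}

test_that("TD targets collapse to rewards for terminal or myopic updates", {
  q <- linearQNet(2L, 2L)
  tgt <- q
  batch <- list(s = diag(2), a = c(0L, 1L), r = c(1, 0),
                s2 = diag(2), done = c(TRUE, TRUE))
  cfg <- trainConfig(eta = 0.1, gamma = 0, lambda = 0)
  # terminal: y = r regardless of Q_target
  up <- qUpdate(batch, q, tgt, gammaRL = 0.9, cfg, velocityInit(q))
  # myopic gamma = 0 with done = FALSE gives the same targets
  batch$done <- c(FALSE, FALSE)
  up2 <- qUpdate(batch, q, tgt, gammaRL = 0, cfg, velocityInit(q))
  expect_equal(up$qModel$params, up2$qModel$params, tolerance = 1e-12)

  expect_error(qUpdate(list(s = batch$s[0, ], a = integer(0), r = numeric(0),
                            s2 = batch$s2[0, ], done = logical(0)),
                       q, tgt, 0.9, cfg, velocityInit(q)), "empty batch")
})

test_that("a hand-computed TD step updates exactly the taken actions", {
  # identity Q-network: Q(s) = s %*% W, W = I; states one-hot
  q <- linearQNet(2L, 2L)
  q$params$W1 <- diag(2)
  q$params$b1 <- c(0, 0)
  tgt <- q
  batch <- list(s = rbind(c(1, 0), c(0, 1)), a = c(0L, 1L), r = c(1, 0),
                s2 = rbind(c(1, 0), c(0, 1)), done = c(TRUE, TRUE))
  cfg <- trainConfig(eta = 0.1, gamma = 0, lambda = 0)
  up <- qUpdate(batch, q, tgt, gammaRL = 0.9, cfg, velocityInit(q))
  # Q(s1)[a=0] = 1 = r1 -> no error; Q(s2)[a=1] = 1, y = 0 -> tdErr = 1
  # dL/dQ[2,2] = 2 * 1 / 2 = 1; dW = s' dQ -> only W[2,2] moves: 1 - 0.1 * 1
  expect_equal(up$qModel$params$W1, matrix(c(1, 0, 0, 0.9), 2, 2), tolerance = 1e-12)
  expect_equal(up$qModel$params$b1, c(0, -0.1), tolerance = 1e-12)
  expect_equal(up$tdLoss, 0.5, tolerance = 1e-12)
})

test_that("epsilon-greedy selection is greedy, tie-broken low, and uniform at 1", {
  q <- linearQNet(3L, 3L)
  q$params$W1 <- rbind(c(0, 1, 0.5), c(0, 1, 0.5), c(0, 1, 0.5))
  s <- c(1, 0, 0)
  expect_equal(selectAction(s, q, epsilon = 0), 1L)  # argmax

  qt <- linearQNet(3L, 3L)
  qt$params$W1 <- matrix(0, 3, 3)  # all Q equal -> lowest action id
  expect_equal(selectAction(s, qt, epsilon = 0), 0L)

  draws <- withr::with_seed(3, vapply(1:10000, function(i)
    selectAction(s, q, epsilon = 1), integer(1)))
  freq <- tabulate(draws + 1L, 3L) / 10000
  # 3-sigma band for a uniform multinomial
  expect_true(all(abs(freq - 1 / 3) < 3 * sqrt((1 / 3) * (2 / 3) / 10000)))

  expect_error(selectAction(s, q, epsilon = 1.2), "\\[0, 1\\]")
})

test_that("the replay buffer overwrites FIFO at capacity and samples everything", {
  buf <- replayBuffer(5L, 2L)
  for (i in 1:8) bufferPush(buf, c(i, 0), i %% 3, i, c(0, i), FALSE)
  expect_equal(buf$size, 5L)
  # first three transitions (r = 1, 2, 3) were overwritten by 6, 7, 8
  expect_setequal(buf$r, c(6, 7, 8, 4, 5))

  covered <- withr::with_seed(8, {
    seen <- logical(5)
    for (i in 1:200) seen[match(bufferSample(buf, 2L)$r, buf$r)] <- TRUE
    seen
  })
  expect_true(all(covered))

  b <- withr::with_seed(1, bufferSample(buf, 5L))
  expect_equal(sort(b$r), sort(buf$r))  # without replacement within a batch
})

test_that("a single-state bandit learns to take the rewarded action", {
  mdp <- dietMDP(nStates = 2L, gammaRL = 0,
                 drift = c(0L, 0L), adherence = c(1, 0))  # reward 0.3 vs 0
  ag <- trainAgent(mdp, episodes = 150L,
                   config = trainConfig(eta = 0.1, gamma = 0.5, lambda = 0,
                                        batchSize = 16L, seed = 2),
                   episodeLength = 4L)
  expect_equal(ag$policy, c(0L, 0L))
  expect_length(ag$learningCurve, 150L)
})

test_that("an untrained agent's policy is the initialized network's argmax", {
  mdp <- dietMDP()
  ag <- trainAgent(mdp, episodes = 0L,
                   config = trainConfig(eta = 0.1, gamma = 0, lambda = 0, seed = 5))
  q0 <- buildModel(nOut = mdp$nActions, inputDim = mdp$nStates,
                   hidden = list(layerSpec(32L)), outputActivation = "linear",
                   seed = 5)
  expect_equal(ag$policy,
               max.col(predictModel(q0, diag(mdp$nStates)), ties.method = "first") - 1L)
})

test_that("value iteration solves the diet MDP to machine precision", {
  mdp <- dietMDP()
  vi <- valueIteration(mdp, tol = 1e-12)
  # Bellman residual at the fixed point
  Q <- mdp$R
  for (a in seq_len(mdp$nActions))
    Q[, a] <- mdp$R[, a] + mdp$gammaRL * mdp$T[, a, ] %*% vi$V
  expect_equal(apply(Q, 1, max), vi$V, tolerance = 1e-10)
  # healthier states favor gentler interventions under the default rewards
  expect_true(all(diff(vi$policy) >= 0))
  expect_equal(vi$policy[mdp$nStates], 2L)  # healthy: maintain
  expect_equal(vi$policy[1], 0L)            # sickest: intensive change
})

test_that("the trained greedy policy attains near-optimal value", {
  mdp <- dietMDP()
  vi <- valueIteration(mdp)
  ag <- trainAgent(mdp, episodes = 600L,
                   config = trainConfig(eta = 0.05, gamma = 0.9, lambda = 0,
                                        batchSize = 32L, seed = 4))
  # policy evaluation of the learned greedy policy
  P <- t(vapply(seq_len(mdp$nStates), function(s) mdp$T[s, ag$policy[s] + 1L, ],
                numeric(mdp$nStates)))
  r <- vapply(seq_len(mdp$nStates), function(s) mdp$R[s, ag$policy[s] + 1L],
              numeric(1))
  vPol <- solve(diag(mdp$nStates) - mdp$gammaRL * P, r)
  expect_true(all(vPol >= vi$V * 0.95 - 1e-9))  # within 5% of the optimum
})

test_that("target network syncs make the target equal the online network", {
  mdp <- dietMDP()
  cfg <- trainConfig(eta = 0.05, gamma = 0, lambda = 0, batchSize = 8L, seed = 9)
  q <- linearQNet(mdp$nStates, mdp$nActions, seed = 9)
  tgt <- q
  buf <- replayBuffer(100L, mdp$nStates)
  enc <- diag(mdp$nStates)
  withr::with_seed(10, {
    for (i in 1:40) {
      s <- sample.int(6, 1); a <- sample.int(3, 1) - 1L
      s2 <- which(mdp$T[s, a + 1L, ] == 1)
      bufferPush(buf, enc[s, ], a, mdp$R[s, a + 1L], enc[s2, ], FALSE)
    }
    v <- velocityInit(q)
    for (step in 1:10) {
      up <- qUpdate(bufferSample(buf, 8L), q, tgt, mdp$gammaRL, cfg, v)
      q <- up$qModel; v <- up$velocity
      if (step %% 5 == 0) tgt <- q  # sync
    }
  })
  expect_identical(tgt$params, q$params)
})

test_that("recommendations are gated on the classifier and ranked by Q", {
  mdp <- dietMDP()
  ag <- trainAgent(mdp, episodes = 400L,
                   config = trainConfig(eta = 0.05, gamma = 0.9, lambda = 0,
                                        batchSize = 32L, seed = 1))
  healthy <- healthState(systolicBP = 110, cholesterol = 160, bmi = 22)
  gated <- recommendDiet(healthy, ag$qModel, prediction = 0L)
  expect_equal(nrow(gated$recommendations), 0L)
  expect_match(gated$status, "no disease")

  sick <- healthState(systolicBP = 170, cholesterol = 300, bmi = 33)
  rec <- recommendDiet(sick, ag$qModel, prediction = 1L)
  expect_gt(nrow(rec$recommendations), 0L)
  expect_true(all(diff(rec$recommendations$q_value) <= 0))  # descending Q

  # raising only cholesterol promotes the fat/cholesterol-reduction action
  lowChol <- healthState(systolicBP = 130, cholesterol = 150, bmi = 24)
  hiChol <- healthState(systolicBP = 130, cholesterol = 310, bmi = 24)
  rankOf <- function(state) {
    r <- recommendDiet(state, ag$qModel, prediction = 1L)$recommendations
    which(r$action_id == 0L)
  }
  expect_lt(rankOf(hiChol), rankOf(lowChol))

  expect_error(healthState(systolicBP = 300, cholesterol = 200, bmi = 25),
               "physiologic bounds")
})
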