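# DQN-based diet recommendation: an agent maps a (discretized) patient health
# state to a dietary action, learning from reward feedback with experience
# replay and a periodically synced target network. Validated against exact
# value iteration on a small synthetic diet MDP with known dynamics.

#' Default dietary action set
#' @export
dietActions <- function() data.frame(
  action_id = 0:2,
  label = c("intensive overhaul: cut saturated fat & cholesterol",
            "moderate adjustment: more fiber and omega-3",
            "maintain current diet"),
  stringsAsFactors = FALSE
)

#' Reward specification for the diet agent
#'
#' Reward = `wHealth * (normalized biometric improvement) + wAdherence *
#' adherence`. Weights are non-negative and sum to one.
#'
#' @param wHealth weight on the health-improvement term (default 0.7).
#' @param wAdherence weight on the adherence term (default 0.3).
#' @export
rewardSpec <- function(wHealth = 0.7, wAdherence = 0.3) {
  if (wHealth < 0 || wAdherence < 0) stopParam("wHealth", "weights must be >= 0")
  if (abs(wHealth + wAdherence - 1) > 1e-9)
    stopParam("wHealth", "weights must sum to 1")
  list(wHealth = wHealth, wAdherence = wAdherence)
}

#' Synthetic diet MDP (ground-truth test environment)
#'
#' `nStates` discretized health levels (0 = worst). Three actions with
#' deterministic health drift and decreasing adherence: the intensive action
#' improves health fastest but has the lowest adherence, maintenance keeps
#' the level with full adherence. Reward follows [rewardSpec()]:
#' `wHealth * (s' - s) / (nStates - 1) + wAdherence * adherence(a)`.
#'
#' @param nStates number of health levels (default 6).
#' @param gammaRL discount factor in `[0, 1)`.
#' @param reward a [rewardSpec()].
#' @param drift integer health gain per action (one per action).
#' @param adherence adherence score per action in `[0, 1]`.
#' @return a `dietMDP`: transition tensor `T[s, a, s']` (rows over s' sum to
#'   1), reward table `R[s, a]`, `gammaRL`, `actions`.
#' @export
dietMDP <- function(nStates = 6L, gammaRL = 0.9, reward = rewardSpec(),
                    drift = c(2L, 1L, 0L), adherence = c(0.4, 0.7, 1.0)) {
  nStates <- checkCount(nStates, "nStates", min = 2L)
  if (gammaRL < 0 || gammaRL >= 1) stopParam("gammaRL", "must lie in [0, 1)")
  nA <- length(drift)
  Tr <- array(0, c(nStates, nA, nStates))
  R <- matrix(0, nStates, nA)
  for (s in seq_len(nStates)) {
    for (a in seq_len(nA)) {
      s2 <- min(s + drift[a], nStates)
      Tr[s, a, s2] <- 1
      R[s, a] <- reward$wHealth * (s2 - s) / (nStates - 1) +
        reward$wAdherence * adherence[a]
    }
  }
  structure(list(nStates = nStates, nActions = nA, T = Tr, R = R,
                 gammaRL = gammaRL, actions = dietActions()[seq_len(nA), ],
                 adherence = adherence),
            class = "dietMDP")
}

#' Exact value iteration on a diet MDP
#'
#' Independent ground-truth oracle for the learned policy.
#'
#' @param mdp a [dietMDP()].
#' @param tol convergence tolerance on the value sup-norm.
#' @param maxIter iteration cap.
#' @return list with `V` (optimal values), `policy` (0-based optimal action
#'   per state, lowest index on ties), `Q` (state x action).
#' @export
valueIteration <- function(mdp, tol = 1e-10, maxIter = 10000L) {
  V <- numeric(mdp$nStates)
  for (it in seq_len(maxIter)) {
    Q <- mdp$R
    for (a in seq_len(mdp$nActions))
      Q[, a] <- mdp$R[, a] + mdp$gammaRL * mdp$T[, a, ] %*% V
    Vnew <- apply(Q, 1L, max)
    if (max(abs(Vnew - V)) < tol) {
      V <- Vnew
      break
    }
    V <- Vnew
  }
  Q <- mdp$R
  for (a in seq_len(mdp$nActions))
    Q[, a] <- mdp$R[, a] + mdp$gammaRL * mdp$T[, a, ] %*% V
  list(V = V, policy = max.col(Q, ties.method = "first") - 1L, Q = Q)
}

#' Experience replay buffer
#'
#' FIFO ring buffer of `(s, a, r, s', done)` transitions; at capacity the
#' oldest transition is overwritten. Batches are sampled uniformly without
#' replacement within a batch.
#'
#' @param capacity maximum number of stored transitions.
#' @param stateDim state-vector dimension.
#' @export
replayBuffer <- function(capacity, stateDim) {
  capacity <- checkCount(capacity, "capacity")
  env <- new.env(parent = emptyenv())
  env$s <- matrix(0, capacity, stateDim)
  env$s2 <- matrix(0, capacity, stateDim)
  env$a <- integer(capacity)
  env$r <- numeric(capacity)
  env$done <- logical(capacity)
  env$size <- 0L
  env$cursor <- 0L
  env$capacity <- capacity
  class(env) <- "replayBuffer"
  env
}

#' Store one transition in a replay buffer
#' @param buffer a [replayBuffer()].
#' @param s,a,r,s2,done transition fields (`a` 0-based).
#' @export
bufferPush <- function(buffer, s, a, r, s2, done) {
  i <- (buffer$cursor %% buffer$capacity) + 1L
  buffer$s[i, ] <- s
  buffer$a[i] <- as.integer(a)
  buffer$r[i] <- r
  buffer$s2[i, ] <- s2
  buffer$done[i] <- isTRUE(done)
  buffer$cursor <- buffer$cursor + 1L
  buffer$size <- min(buffer$size + 1L, buffer$capacity)
  invisible(buffer)
}

#' Sample a batch of transitions (uniform, without replacement)
#' @param buffer a [replayBuffer()].
#' @param batchSize number of transitions (<= stored size).
#' @export
bufferSample <- function(buffer, batchSize) {
  if (buffer$size == 0L) stop("empty replay buffer", call. = FALSE)
  batchSize <- min(batchSize, buffer$size)
  idx <- sample.int(buffer$size, batchSize)
  list(s = buffer$s[idx, , drop = FALSE], a = buffer$a[idx],
       r = buffer$r[idx], s2 = buffer$s2[idx, , drop = FALSE],
       done = buffer$done[idx])
}

#' One DQN update step
#'
#' Temporal-difference targets `y = r + gammaRL * max_a' Qtarget(s', a') *
#' (1 - done)`; one SGD-with-momentum step on the mean squared error between
#' `Q(s, a)` and `y` (gradient flows only through the taken actions).
#'
#' @param batch a transition batch from [bufferSample()].
#' @param qModel the online Q-network (`cardioModel`, linear output).
#' @param targetModel the target network (same architecture).
#' @param gammaRL discount factor.
#' @param config a [trainConfig()] (lambda is ignored for the Q-network).
#' @param velocity momentum buffers (from [velocityInit()]).
#' @return list with updated `qModel`, `velocity`, and the batch `tdLoss`.
#' @export
qUpdate <- function(batch, qModel, targetModel, gammaRL, config, velocity) {
  n <- length(batch$a)
  if (n == 0L) stop("empty batch", call. = FALSE)
  qNext <- predictModel(targetModel, batch$s2)
  targets <- batch$r + gammaRL * apply(qNext, 1L, max) * (1 - as.numeric(batch$done))
  fwd <- nnForward(qModel, batch$s, mode = "train")
  q <- fwd$output
  taken <- cbind(seq_len(n), batch$a + 1L)
  tdErr <- q[taken] - targets
  gradOut <- matrix(0, n, ncol(q))
  gradOut[taken] <- 2 * tdErr / n
  grads <- nnBackward(qModel, fwd$cache, gradOutput = gradOut, lambda = 0)
  upd <- sgdMomentumStep(qModel, velocity, grads, config)
  list(qModel = upd$model, velocity = upd$velocity, tdLoss = mean(tdErr^2))
}

#' Epsilon-greedy action selection
#'
#' With probability `1 - epsilon` the argmax action (ties broken toward the
#' lowest action id); otherwise uniform over all actions.
#'
#' @param state state vector.
#' @param qModel the Q-network.
#' @param epsilon exploration rate in `[0, 1]`.
#' @param seed optional RNG seed; NULL draws from the current stream.
#' @return 0-based action id.
#' @export
selectAction <- function(state, qModel, epsilon, seed = NULL) {
  if (epsilon < 0 || epsilon > 1) stopParam("epsilon", "must lie in [0, 1]")
  if (!is.null(seed)) return(withSeed(seed, selectAction(state, qModel, epsilon)))
  q <- predictModel(qModel, matrix(state, nrow = 1L))
  nA <- ncol(q)
  if (epsilon > 0 && runif(1) < epsilon) sample.int(nA, 1L) - 1L
  else which.max(q) - 1L  # which.max takes the first (lowest id) on ties
}

#' Train a DQN agent on a diet MDP
#'
#' Epsilon-greedy exploration annealed linearly from `epsStart` to `epsEnd`
#' over the episodes, uniform experience replay, and a target network synced
#' every `syncEvery` gradient steps. States are one-hot encoded.
#'
#' @param env a [dietMDP()].
#' @param episodes number of training episodes.
#' @param config a [trainConfig()] (learning rate, momentum, batch size, seed).
#' @param episodeLength steps per episode.
#' @param hidden Q-network hidden layers.
#' @param capacity replay-buffer capacity.
#' @param syncEvery target-network sync period (gradient steps).
#' @param epsStart,epsEnd exploration annealing endpoints.
#' @return list with `qModel`, `policy` (greedy 0-based action per state),
#'   `learningCurve` (total reward per episode).
#' @export
trainAgent <- function(env, episodes, config = trainConfig(eta = 0.05, gamma = 0.9,
                                                           lambda = 0, batchSize = 32L),
                       episodeLength = 10L, hidden = list(layerSpec(32L)),
                       capacity = 5000L, syncEvery = 100L,
                       epsStart = 1, epsEnd = 0.05) {
  if (!inherits(env, "dietMDP")) stopParam("env", "must come from dietMDP()")
  nS <- env$nStates; nA <- env$nActions
  qModel <- buildModel(nOut = nA, inputDim = nS, hidden = hidden,
                       outputActivation = "linear", seed = config$seed)
  target <- qModel
  velocity <- velocityInit(qModel)
  buffer <- replayBuffer(capacity, nS)
  enc <- diag(nS)
  curve <- numeric(episodes)
  step <- 0L
  withSeed(mixSeed(config$seed, 41L), {
    for (ep in seq_len(episodes)) {
      eps <- if (episodes > 1L)
        epsStart + (epsEnd - epsStart) * (ep - 1L) / (episodes - 1L)
      else epsEnd
      s <- sample.int(nS, 1L)
      total <- 0
      for (tStep in seq_len(episodeLength)) {
        a <- selectAction(enc[s, ], qModel, eps)
        s2 <- sample.int(nS, 1L, prob = env$T[s, a + 1L, ])
        r <- env$R[s, a + 1L]
        done <- tStep == episodeLength
        bufferPush(buffer, enc[s, ], a, r, enc[s2, ], FALSE)
        total <- total + r
        s <- s2
        if (buffer$size >= config$batchSize) {
          batch <- bufferSample(buffer, config$batchSize)
          upd <- qUpdate(batch, qModel, target, env$gammaRL, config, velocity)
          qModel <- upd$qModel
          velocity <- upd$velocity
          step <- step + 1L
          if (step %% syncEvery == 0L) target <- qModel
          if (!is.finite(upd$tdLoss))
            stop(sprintf("divergence: non-finite TD loss at episode %d", ep),
                 call. = FALSE)
        }
        if (done) break
      }
      curve[ep] <- total
    }
  })
  qAll <- predictModel(qModel, enc)
  list(qModel = qModel, policy = max.col(qAll, ties.method = "first") - 1L,
       learningCurve = curve)
}

#' Normalize a patient health state
#'
#' Biometrics are mapped into `[0, 1]` by fixed physiologic bounds: systolic
#' blood pressure 90–200 mmHg, total cholesterol 120–320 mg/dL, BMI
#' 15–45 kg/m^2. Values outside the bounds are rejected.
#'
#' @param systolicBP systolic blood pressure in mmHg.
#' @param cholesterol total cholesterol in mg/dL.
#' @param bmi body-mass index in kg/m^2.
#' @param adherence adherence score in `[0, 1]`.
#' @param selfReport self-perceived wellbeing in `[0, 1]`.
#' @return a `healthState` with the normalized vector in `$normalized`.
#' @export
healthState <- function(systolicBP, cholesterol, bmi, adherence = 0.5,
                        selfReport = 0.5) {
  bounds <- list(systolicBP = c(90, 200), cholesterol = c(120, 320),
                 bmi = c(15, 45))
  vals <- c(systolicBP = systolicBP, cholesterol = cholesterol, bmi = bmi)
  for (nm in names(bounds)) {
    b <- bounds[[nm]]
    if (vals[nm] < b[1] || vals[nm] > b[2])
      stopParam(nm, sprintf("outside physiologic bounds [%g, %g]", b[1], b[2]))
  }
  if (adherence < 0 || adherence > 1) stopParam("adherence", "must lie in [0, 1]")
  if (selfReport < 0 || selfReport > 1) stopParam("selfReport", "must lie in [0, 1]")
  norm <- vapply(names(bounds), function(nm) {
    b <- bounds[[nm]]
    (vals[[nm]] - b[1]) / (b[2] - b[1])
  }, numeric(1))
  structure(list(raw = vals, adherence = adherence, selfReport = selfReport,
                 normalized = c(norm, adherence = adherence,
                                self_report = selfReport)),
            class = "healthState")
}

# Map a normalized health state onto a discrete MDP health level (0-based):
# higher biometric risk -> lower level.
healthLevel <- function(state, nStates) {
  risk <- mean(state$normalized[c("systolicBP", "cholesterol", "bmi")])
  min(max(floor((1 - risk) * nStates), 0), nStates - 1L)
}

#' Rank dietary recommendations for a patient
#'
#' Recommendations are gated on a positive disease prediction from the
#' classifier: a negative prediction returns no actions with a maintenance
#' status. Otherwise the patient's health state is discretized onto the
#' agent's state space and actions are ranked by Q value.
#'
#' @param state a [healthState()].
#' @param qModel a trained Q-network (from [trainAgent()]).
#' @param prediction 0-based predicted class from the classifier (0 = no
#'   disease).
#' @param nStates number of discrete health levels the agent was trained on.
#' @return list with `status`, `recommendations` (data.frame of actions in
#'   descending Q order, empty when gated), `healthLevel`.
#' @export
recommendDiet <- function(state, qModel, prediction, nStates = 6L) {
  if (!inherits(state, "healthState"))
    stopParam("state", "must be a normalized healthState()")
  if (any(state$normalized < 0 | state$normalized > 1))
    stopParam("state", "state is not normalized to [0, 1]")
  if (prediction == 0L) {
    return(list(status = "no disease detected: maintain current diet, no change recommended",
                recommendations = dietActions()[0, ], healthLevel = NA_integer_))
  }
  lvl <- healthLevel(state, nStates)
  enc <- numeric(nStates)
  enc[lvl + 1L] <- 1
  q <- drop(predictModel(qModel, matrix(enc, nrow = 1L)))
  acts <- dietActions()[seq_along(q), ]
  ord <- order(q, decreasing = TRUE)
  out <- acts[ord, ]
  out$q_value <- q[ord]
  rownames(out) <- NULL
  list(status = "disease detected: ranked dietary recommendations",
       recommendations = out, healthLevel = lvl)
}
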