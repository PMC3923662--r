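mdp <- build_default_mdp()

test_that("world-model learning follows the exponential-average closed forms", {
  alpha <- 0.1
  m <- mb_model(mdp, learning_params(alpha, 0.9), r0 = 0)
  m1 <- mb_update(m, "S_PRE", "exp", "S_CS", 0)
  expect_equal(m1$T["S_PRE", "exp", "S_CS"], alpha)
  expect_equal(sum(m1$T["S_PRE", "exp", ]), alpha)
  for (n in c(5, 20)) {
    mn <- m
    for (k in seq_len(n)) mn <- mb_update(mn, "S_US_CM", "eat", "S_END", 1)
    expect_equal(mn$T["S_US_CM", "eat", "S_END"], 1 - (1 - alpha)^n)
    expect_equal(mn$R["S_US_CM", "eat"], 1 - (1 - alpha)^n)
  }
})

test_that("planning on the true model matches backward-induction oracle", {
  for (gamma in c(0.5, 0.9, 0.95)) {
    m <- mb_model(mdp, learning_params(0.2, gamma))
    m <- learn_true_model(m, mdp)
    expect_lt(max(abs(m$Q - oracle_q(mdp, gamma))), 1e-9)
  }
  # hand-derived values on the true model at gamma = 0.9
  m <- learn_true_model(mb_model(mdp, learning_params(0.2, 0.9)), mdp)
  expect_equal(m$Q["S_CS", "goM"], 0.81, tolerance = 1e-8)
  expect_equal(m$Q["S_CS", "goL"], 0.729, tolerance = 1e-8)
  expect_equal(m$A["S_CS", "goM"], 0)
  expect_equal(m$A["S_CS", "goL"], -0.081, tolerance = 1e-8)
  # goal-tracking is plan-optimal under discounting
  expect_equal(names(which.max(m$Q["S_CS", c("goL", "goM", "exp")])), "goM")
  expect_true(all(m$A <= 1e-12))
})

test_that("feature-level prediction errors follow the TD rule", {
  v <- fmf_values(learning_params(0.1, 0.9), u = 0.2,
                  v0_magazine = 0, v0_food = 0)
  # terminal successor contributes no future value
  e <- fmf_rpe(v, mdp, "S_US_CM", "eat", 1, "S_END")
  expect_equal(e$delta, 1)
  expect_equal(e$feature, "Food")
  # direct substitution with nonzero values
  v$V[["Food"]] <- 0.9; v$V[["Magazine"]] <- 0.5
  e <- fmf_rpe(v, mdp, "S_CS_M", "eng", 0, "S_US_CM")
  expect_equal(e$delta, 0.9 * 0.9 - 0.5)
  # CS onset consults the best reachable feature value; None is pinned at 0
  v$V[["Lever"]] <- 0.8; v$V[["Magazine"]] <- 0.4
  e <- fmf_rpe(v, mdp, "S_PRE", "exp", 0, "S_CS")
  expect_equal(e$delta, 0.9 * 0.8)
  expect_equal(e$feature, "None")
})

test_that("feature updates touch only the focused feature; None never learns", {
  v <- fmf_values(learning_params(0.1, 0.9), u = 0.2, v0_food = 0)
  e <- structure(list(delta = 1, feature = "Food", event = "other"),
                 class = "rpe_event")
  v2 <- fmf_update(v, e)
  expect_equal(v2$V[["Food"]], 0.1)
  expect_equal(v2$V[c("None", "Lever", "Magazine")],
               v$V[c("None", "Lever", "Magazine")])
  e$feature <- "None"
  expect_equal(fmf_update(v, e)$V, v$V)
  # repeated consumption drives the food value to the reward magnitude
  for (k in 1:300) {
    e2 <- fmf_rpe(v, mdp, "S_US_CM", "eat", 1, "S_END")
    v <- fmf_update(v, e2)
  }
  expect_equal(v$V[["Food"]], 1, tolerance = 1e-9)
})

test_that("ITI decay depresses only the magazine value", {
  v <- fmf_values(learning_params(), u = 0.2, v0_magazine = 0.5, v0_food = 0.3)
  v2 <- fmf_iti_decay(v)
  expect_equal(v2$V[["Magazine"]], 0.4)
  expect_equal(v2$V[c("None", "Lever", "Food")], v$V[c("None", "Lever", "Food")])
  v$u <- 0
  expect_equal(fmf_iti_decay(v)$V, v$V)
  v$u <- 1
  expect_equal(fmf_iti_decay(v)$V[["Magazine"]], 0)
})

test_that("state-level Q-learning converges to the planner's values", {
  m <- mf_values(mdp, learning_params(0.1, 0.9), q0 = 0)
  out <- mf_update(m, "S_US_CM", "eat", 1, "S_END")
  expect_equal(out$delta, 1)
  expect_equal(out$model$Q["S_US_CM", "eat"], 0.1)
  # sweep all transitions repeatedly: converged Q equals the oracle
  tr <- mdp$transitions
  for (k in 1:400) for (i in seq_len(nrow(tr)))
    m <- mf_update(m, tr$state[i], tr$action[i], tr$reward[i],
                   tr$next_state[i])$model
  expect_lt(max(abs(m$Q - oracle_q(mdp, 0.9))), 1e-6)
  # at the fixed point the prediction error vanishes
  expect_lt(abs(mf_delta(m, "S_CS", "goM", 0, "S_CS_M")), 1e-6)
})

test_that("integration combines the systems as each variant prescribes", {
  params <- learning_params(0.1, 0.9)
  fmf <- fmf_values(params, v0_food = 0)
  fmf$V[["Lever"]] <- 0.6
  mb <- learn_true_model(mb_model(mdp, params), mdp)
  mf <- mf_values(mdp, params)
  mf$Q["S_CS", c("goL", "goM", "exp")] <- c(0.5, 0.7, 0.1)

  # degenerate weights
  expect_equal(integrate_values("model", 0, mdp, "S_CS", fmf = fmf, mb = mb),
               mb$A["S_CS", c("goL", "goM", "exp")])
  expect_equal(
    unname(integrate_values("model", 1, mdp, "S_CS", fmf = fmf, mb = mb)),
    unname(fmf$V[c("Lever", "Magazine", "None")]))
  # convex combination
  p <- integrate_values("model", 0.5, mdp, "S_CS", fmf = fmf, mb = mb)
  expect_equal(p[["goL"]], 0.5 * 0.6 + 0.5 * mb$A["S_CS", "goL"])
  # v1 swaps in the Model-Free advantage
  p1 <- integrate_values("v1", 0.5, mdp, "S_CS", fmf = fmf, mf = mf)
  expect_equal(p1[["goL"]], 0.5 * 0.6 + 0.5 * (0.5 - 0.7))
  # v2 gives the lever (only) a bonus of the best Q in the state
  p2 <- integrate_values("v2", 0.5, mdp, "S_CS", mf = mf)
  expect_equal(p2[["goL"]], 0.5 * (0.5 - 0.7) + 0.5 * 0.7)
  expect_equal(p2[["goM"]], 0)
  # v3 extends the bonus to the magazine
  p3 <- integrate_values("v3", 0.5, mdp, "S_CS", mf = mf)
  expect_equal(p3[["goM"]], 0.5 * 0.7)
  # v4 mixes the two advantages
  p4 <- integrate_values("v4", 0.25, mdp, "S_CS", mb = mb, mf = mf)
  expect_equal(p4[["goL"]],
               0.25 * (0.5 - 0.7) + 0.75 * mb$A["S_CS", "goL"])
  expect_error(integrate_values("v9", 0.5, mdp, "S_CS"), "variant")
})

test_that("softmax selection is normalised, symmetric and temperature-limited", {
  expect_equal(unname(softmax_policy(c(a = 1, b = 1, c = 1), 0.5)),
               rep(1 / 3, 3))
  p <- softmax_policy(c(a = 1, b = 0), 1)
  expect_equal(unname(p), c(0.731, 0.269), tolerance = 1e-3)
  # high temperature approaches indifference
  p_hot <- softmax_policy(c(a = 1, b = 0), 1e6)
  expect_equal(unname(p_hot), c(0.5, 0.5), tolerance = 1e-5)
  # property: normalisation and monotonicity over random value vectors
  set.seed(42)
  for (k in 1:50) {
    v <- stats::setNames(rnorm(4), letters[1:4])
    p <- softmax_policy(v, runif(1, 0.01, 5))
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_equal(order(p), order(v))
  }
  # sampling consumes exactly one uniform and respects probabilities
  expect_equal(sample_action(c(a = 0.2, b = 0.8), u = 0.1), "a")
  expect_equal(sample_action(c(a = 0.2, b = 0.8), u = 0.9), "b")
  expect_equal(sample_action(c(a = 0.2, b = 0.8), u = 1), "b")
})

test_that("feature values generalise across states and stay bounded", {
  params <- learning_params(0.2, 0.9)
  v <- fmf_values(params, u = 0.1, v0_food = 0)
  # an update generated at one state changes the value consulted at another
  before <- fmf_rpe(v, mdp, "S_CS", "goM", 0, "S_CS_M")$delta
  e <- fmf_rpe(v, mdp, "S_CS_M", "eng", 0, "S_US_CM")
  e$delta <- 0.5
  v <- fmf_update(v, e)   # revises V(Magazine) from a different state
  after <- fmf_rpe(v, mdp, "S_CS", "goM", 0, "S_CS_M")$delta
  expect_false(isTRUE(all.equal(before, after)))
  # boundedness over a full simulated run
  log <- run_agent(agent_config(omega = 0.7), schedule_spec(4, 25), seed = 8)
  expect_true(all(log$final$V >= 0 & log$final$V <= 1))
  expect_true(all(log$final$Q_mb >= 0 & log$final$Q_mb <= 1 + 1e-9))
})
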