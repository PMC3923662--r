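small_groups <- function(n = 3)
  default_groups(n_agents = n)

test_that("autoshaping aggregates engagement and RPE curves per group", {
  res <- run_autoshaping(small_groups(), schedule_spec(4, 25), seed = 2)
  eng <- res$engagement
  expect_setequal(unique(eng$group), c("ST", "IG", "GT"))
  expect_setequal(unique(eng$stimulus), c("lever", "magazine"))
  expect_equal(max(eng$block), 2)   # 100 trials in 50-trial blocks
  expect_true(all(eng$probability >= 0 & eng$probability <= 1))
  expect_true(all(eng$sem >= 0))
  rpe <- res$rpe
  expect_setequal(unique(rpe$event), c("CS", "US"))
  expect_equal(max(rpe$session), 4)
  # per-agent summaries and final snapshots are retained
  expect_length(res$agents$ST, 3)
  expect_named(res$agents$ST[[1]]$final$V,
               c("None", "Lever", "Magazine", "Food"))
})

test_that("group results are reproducible and order-independent", {
  a <- run_autoshaping(small_groups(), schedule_spec(2, 10), seed = 9)
  b <- run_autoshaping(small_groups(), schedule_spec(2, 10), seed = 9)
  expect_identical(a$engagement, b$engagement)
  # an agent's stream depends on (group seed, index), not on other agents
  one <- run_autoshaping(default_groups(n_agents = 1),
                         schedule_spec(2, 10), seed = 9)
  expect_equal(one$agents$ST[[1]]$lever_blocks,
               a$agents$ST[[1]]$lever_blocks)
})

test_that("conditioned-reinforcement probe ranks groups and baselines", {
  res <- run_autoshaping(small_groups(5), schedule_spec(6, 25), seed = 3)
  probe <- probe_conditioned_reinforcement(res)
  expect_equal(probe$p_engage_lever[probe$group == "UN"], 0.5)
  pst <- probe$p_engage_lever[probe$group == "ST"]
  pgt <- probe$p_engage_lever[probe$group == "GT"]
  expect_gt(pst, pgt)
  expect_gt(pgt, 0.5)
  # a feature-blind agent is exactly indifferent before training biases Q
  blind <- run_autoshaping(group_spec("Z", agent_config(omega = 0), 2),
                           schedule_spec(1, 2), seed = 1)
  pb <- probe_conditioned_reinforcement(blind)
  expect_equal(pb$p_engage_lever[pb$group == "Z"], 0.5, tolerance = 0.1)
})

test_that("feature-system contribution is zero without feature weighting", {
  res <- run_autoshaping(group_spec("Z", agent_config(omega = 0), 3),
                         schedule_spec(2, 10), seed = 4)
  ctr <- fmf_contribution(res)
  expect_equal(ctr$contribution, 0)
  expect_true(ctr$contribution <= 100)
})

test_that("systemic protocol runs drug and saline arms on matched seeds", {
  flu <- run_systemic_flu(small_groups(2)[c("ST", "GT")], dose = 100,
                          n_sessions = 3, n_drug_sessions = 2,
                          trials_per_session = 10, seed = 5)
  expect_s3_class(flu$flu, "autoshaping_result")
  expect_equal(flu$flu$agents$ST[[1]]$seed, flu$saline$agents$ST[[1]]$seed)
  # drug sessions near-uniform: all engagement probabilities far from 1
  es <- flu$flu$engagement_sessions
  expect_true(all(es$probability[es$session <= 2] < 0.7))
})

test_that("local-infusion protocol reports a tidy dose-response table", {
  lf <- run_local_flu(small_groups(2), doses = c(0, 1), pretrain_sessions = 2,
                      test_sessions = 2, trials_per_session = 10, seed = 6)
  dr <- lf$dose_response
  expect_equal(nrow(dr), 4)
  expect_setequal(unique(dr$measure), c("sign_tracking", "goal_tracking"))
  expect_true(all(dr$probability >= 0 & dr$probability <= 1))
  expect_error(run_local_flu(small_groups(2), doses = c(1, 2)), "doses")
})

test_that("ITI sweep returns converged deltas and population tendencies", {
  iti <- run_iti_manipulation(small_groups(2), u_values = c(0, 0.3),
                              schedule = schedule_spec(3, 10), seed = 7)
  expect_equal(iti$summary$u, c(0, 0.3))
  expect_true(all(c("us_delta", "cs_delta", "gt_prob", "st_prob") %in%
                    names(iti$summary)))
  expect_error(run_iti_manipulation(small_groups(2), u_values = c(0.1, 0.3)),
               "0")
})

test_that("variant groups run through the same protocol surface", {
  g4 <- group_spec("V4", agent_config(omega = 0.5, variant = "v4"), 2)
  res <- run_autoshaping(g4, schedule_spec(2, 10), seed = 8)
  expect_true(all(is.finite(res$rpe$mean_delta)))
  expect_null(res$agents$V4[[1]]$final$V)   # no feature learner in v4
})
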