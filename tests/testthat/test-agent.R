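test_that("compiled and reference engines produce identical runs", {
  for (cfg in list(agent_config(omega = 0.9),
                   agent_config(omega = 0.1, variant = "v4"),
                   agent_config(omega = 0.5, variant = "v2"))) {
    a <- run_agent(cfg, tiny_schedule(2, 8), seed = 99, engine = "cpp")
    b <- run_agent(cfg, tiny_schedule(2, 8), seed = 99, engine = "r")
    expect_identical(a$steps$action, b$steps$action)
    expect_identical(a$steps$state, b$steps$state)
    expect_equal(a$steps$delta, b$steps$delta, tolerance = 1e-12)
    expect_equal(a$trials$lever, b$trials$lever)
    expect_equal(a$trials$magazine, b$trials$magazine)
    if (!is.null(b$final$Q_mb))
      expect_equal(a$final$Q_mb, b$final$Q_mb, tolerance = 1e-12)
    if (!is.null(b$final$V))
      expect_equal(unname(a$final$V), unname(b$final$V), tolerance = 1e-12)
  }
})

test_that("runs are deterministic given a seed", {
  cfg <- agent_config(omega = 0.5)
  a <- run_agent(cfg, tiny_schedule(), seed = 3)
  b <- run_agent(cfg, tiny_schedule(), seed = 3)
  expect_identical(a$steps, b$steps)
  c <- run_agent(cfg, tiny_schedule(), seed = 4)
  expect_false(identical(a$steps$action, c$steps$action))
})

test_that("a fixed-seed trial reproduces its golden log", {
  log <- run_agent(agent_config(omega = 0.95), schedule_spec(1, 3),
                   seed = 424242)
  expect_equal(log$steps$action,
               c("exp", "goL", "eng", "goM", "eat",
                 "exp", "goM", "eng", "eat",
                 "exp", "exp", "exp", "goM", "eat"))
  expect_equal(log$steps$delta,
               c(0, 0, 0, 0, 1,
                 0, 0, 0.095, 0.9,
                 0.007942, 0, 0.1805, -0.0095, 0.81095),
               tolerance = 1e-12)
  expect_equal(log$trials$lever, c(TRUE, FALSE, FALSE))
  expect_equal(log$trials$magazine, c(FALSE, TRUE, FALSE))
  expect_equal(unname(log$final$V), c(0, 0, 0.00836, 0.2701450),
               tolerance = 1e-12)
})

test_that("engagement flags are mutually exclusive and event-locked", {
  log <- run_agent(agent_config(omega = 0.5), schedule_spec(4, 25), seed = 6)
  expect_false(any(log$trials$lever & log$trials$magazine))
  # one CS onset and exactly one food delivery per trial
  per_trial <- tapply(log$steps$event,
                      paste(log$steps$session, log$steps$trial),
                      function(ev) c(sum(ev == "CS_onset"),
                                     sum(ev == "US_delivery")))
  expect_true(all(vapply(per_trial, identical, logical(1), c(1L, 1L))))
})

test_that("a temperature-flattened agent engages the lever on a third of trials", {
  cfg <- agent_config(omega = 0.5, beta = 1e6)
  log <- run_agent(cfg, schedule_spec(8, 50), seed = 11)
  expect_lt(abs(mean(log$trials$lever) - 1 / 3), 0.07)
  expect_lt(abs(mean(log$trials$magazine) - 1 / 3), 0.07)
})

test_that("an inert drug condition leaves the run unchanged", {
  cfg <- agent_config(omega = 0.8)
  a <- run_agent(cfg, schedule_spec(2, 10, drug_condition()), seed = 5)
  b <- run_agent(cfg, schedule_spec(2, 10, drug_condition(0, "systemic")),
                 seed = 5)
  expect_identical(a$steps, b$steps)
})

test_that("learner snapshots flatten to plain key-value lists", {
  log <- run_agent(agent_config(omega = 0.5), tiny_schedule(), seed = 2)
  snap <- snapshot_to_list(log)
  expect_named(snap$V, c("None", "Lever", "Magazine", "Food"))
  expect_true(all(vapply(snap$Q_mb, is.numeric, logical(1))))
})
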