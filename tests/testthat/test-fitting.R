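test_that("objectives are least squares per stimulus", {
  tgt <- make_shape_target("ST", n_blocks = 2, block_size = 25)
  sched <- schedule_spec(2, 25)
  ob <- engagement_objectives(agent_config(omega = 0.9), tgt, sched,
                              reps = 3, seeds = 1:3)
  expect_named(ob, c("lever", "magazine"))
  expect_true(all(ob >= 0))
  expect_error(
    engagement_objectives(agent_config(), make_shape_target("ST", 5), sched),
    "blocks")
  # a temperature-flattened candidate engages each stimulus on 1/3 of
  # trials, so against a constant-1/2 target the per-block error is
  # (1/3 - 1/2)^2 up to Monte-Carlo error
  flat <- structure(list(lever = c(0.5, 0.5), magazine = c(0.5, 0.5),
                         block_size = 25, truth = NULL),
                    class = "target_curves")
  ob2 <- engagement_objectives(agent_config(beta = 1e6), flat, sched,
                               reps = 30, seeds = 100 + 1:30)
  expect_equal(unname(ob2[["lever"]]), 2 * (1 / 3 - 1 / 2)^2,
               tolerance = 0.25)
})

test_that("a candidate evaluated against its own curves scores near zero", {
  cfg <- agent_config(omega = 0.9)
  sched <- schedule_spec(4, 25)
  tgt <- make_target(cfg, sched, n_agents = 30, seed = 77)
  ob <- engagement_objectives(cfg, tgt, sched, reps = 30, seeds = 300 + 1:30)
  expect_lt(sum(ob), 0.02)
})

test_that("non-dominated sorting and crowding behave on known fronts", {
  obj <- rbind(c(1, 4), c(2, 3), c(3, 2), c(4, 1),   # the true front
               c(3, 3), c(5, 5))
  fronts <- signtrackr:::fast_nondominated_sort(obj)
  expect_setequal(fronts[[1]], 1:4)
  cd <- signtrackr:::crowding_distance(obj[1:4, ])
  expect_true(is.infinite(cd[1]) && is.infinite(cd[4]))
  expect_true(all(cd[2:3] < Inf))
})

test_that("a one-generation micro-fit returns a valid non-dominated front", {
  tgt <- make_shape_target("ST", n_blocks = 2, block_size = 25)
  fit <- fit_nsga2(tgt, param_names = "omega",
                   ga = ga_config(pop_size = 4, generations = 1, reps = 2),
                   schedule = schedule_spec(2, 25), seed = 3)
  expect_true(nrow(fit$front) >= 1)
  expect_true(all(fit$front$omega >= 0 & fit$front$omega <= 1))
  # brute-force non-domination check of the returned front
  obj <- as.matrix(fit$front[c("obj_lever", "obj_magazine")])
  for (i in seq_len(nrow(obj))) for (j in seq_len(nrow(obj))) {
    if (i != j) expect_false(signtrackr:::dominates(obj[i, ], obj[j, ]))
  }
  expect_named(fit$representative$params, "omega")
  # deterministic given the seed
  fit2 <- fit_nsga2(tgt, param_names = "omega",
                    ga = ga_config(pop_size = 4, generations = 1, reps = 2),
                    schedule = schedule_spec(2, 25), seed = 3)
  expect_identical(fit$front, fit2$front)
})

test_that("longer optimisation does not worsen the best summed objective", {
  tgt <- make_shape_target("GT", n_blocks = 2, block_size = 25)
  fit <- fit_nsga2(tgt, param_names = "omega",
                   ga = ga_config(pop_size = 8, generations = 10, reps = 2),
                   schedule = schedule_spec(2, 25), seed = 4)
  d <- fit$diagnostics$best_sum
  expect_lt(median(d[8:10]), median(d[1:3]) + 0.05)
})

test_that("recovery reports tabulate bias per fitted parameter", {
  fake <- list(param_names = c("omega", "u"),
               representative = list(params = c(omega = 0.75, u = 0.3)),
               front = data.frame(omega = c(0.7, 0.8), u = c(0.25, 0.35)))
  rep <- recovery_report(c(omega = 0.8, u = 0.3), fake)
  expect_equal(nrow(rep), 2)
  expect_equal(rep$bias[1], -0.05)
  expect_equal(rep$bias[2], 0)
  expect_equal(rep$front_min[1], 0.7)
})
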