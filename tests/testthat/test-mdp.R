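test_that("default task has the expected episodic topology", {
  mdp <- build_default_mdp()
  paths <- mdp_paths(mdp)
  lens <- sort(vapply(paths, function(p) length(p$actions), integer(1)))
  # goal-tracking path is the shortest; sign-tracking and exploration longer
  expect_equal(lens, c(4L, 5L, 5L))
  acts <- lapply(paths, function(p) paste(p$actions, collapse = " "))
  expect_true("exp goM eng eat" %in% acts)
  expect_true("exp goL eng goM eat" %in% acts)
  # every path collects exactly the food reward
  for (p in paths) {
    r <- sum(mapply(function(s, a) mdp_step(mdp, s, a)$reward,
                    p$states[-length(p$states)], p$actions))
    expect_equal(r, mdp$r_food)
  }
  # reward only on the consumption transition
  tr <- mdp$transitions
  i <- which(tr$reward != 0)
  expect_length(i, 1)
  expect_equal(unname(unlist(tr[i, c("state", "action")])),
               c("S_US_CM", "eat"))
})

test_that("transitions are deterministic and feature-tagged", {
  mdp <- build_default_mdp(r_food = 2)
  expect_equal(mdp_step(mdp, "S_US_CM", "eat"),
               list(next_state = "S_END", reward = 2, feature = "Food"))
  expect_equal(mdp_step(mdp, "S_CS", "goM"),
               list(next_state = "S_CS_M", reward = 0, feature = "Magazine"))
  expect_equal(mdp_step(mdp, "S_CS_M", "eng")$next_state, "S_US_CM")
  expect_equal(mdp_step(mdp, "S_PRE", "exp"),
               list(next_state = "S_CS", reward = 0, feature = "None"))
  expect_equal(mdp_step(mdp, "S_US_FAR", "goM")$next_state, "S_US_CM")
  expect_error(mdp_step(mdp, "S_PRE", "eat"), "illegal action")
  expect_setequal(actions_of(mdp, "S_CS"), c("goL", "goM", "exp"))
  expect_length(actions_of(mdp, "S_END"), 0)
})

test_that("event tagging marks CS onset and US delivery", {
  mdp <- build_default_mdp()
  expect_equal(event_tag(mdp, "S_PRE", "exp"), "CS_onset")
  expect_equal(event_tag(mdp, "S_CS_M", "eng"), "US_delivery")
  expect_equal(event_tag(mdp, "S_CS_L", "eng"), "US_delivery")
  expect_equal(event_tag(mdp, "S_CS_E", "exp"), "US_delivery")
  expect_equal(event_tag(mdp, "S_US_FAR", "goM"), "other")
  expect_equal(event_tag(mdp, "S_CS", "goL"), "other")
})

test_that("task round-trips through the plain config form", {
  mdp <- build_default_mdp(r_food = 1.5)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_mdp_config(mdp, path)
  back <- read_mdp_config(path)
  expect_equal(back$transitions, mdp$transitions)
  expect_equal(back$states, mdp$states)
  expect_equal(back$r_food, 1.5)
})

test_that("validation rejects malformed tasks", {
  mdp <- build_default_mdp()
  st <- mdp$states; tr <- mdp$transitions
  st2 <- st; st2$terminal[1] <- TRUE
  expect_error(new_mdp(st2, tr), "terminal")
  st3 <- st; st3$lever_available[6] <- TRUE
  expect_error(new_mdp(st3, tr), "never both")
  tr2 <- rbind(tr, tr[1, ])
  expect_error(new_mdp(st, tr2), "duplicate")
  tr3 <- tr; tr3$next_state[9] <- "S_PRE"   # cycle through the episode
  expect_error(new_mdp(st, tr3), "cycle")
})
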