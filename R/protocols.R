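#' Define a simulated group of rats
#'
#' @param label group label (`"ST"`, `"GT"`, `"IG"` or any custom string).
#' @param config the [agent_config()] template shared by all agents of the
#'   group.
#' @param n_agents number of simulated rats (default 14).
#' @return list of class `group_spec`.
#' @export
group_spec <- function(label, config, n_agents = 14) {
  stopifnot(is.character(label), length(label) == 1L, n_agents >= 1)
  if (!inherits(config, "agent_config")) stop("config must be an agent_config")
  structure(list(label = label, config = config,
                 n_agents = as.integer(n_agents)),
            class = "group_spec")
}

#' Default phenotype groups
#'
#' Three groups sharing every parameter except the integration weight:
#' sign-trackers (high omega), goal-trackers (low omega) and the
#' intermediate group. Varying omega alone is sufficient to span the
#' phenotype spectrum.
#'
#' @param omega_st,omega_ig,omega_gt integration weights of the three
#'   groups.
#' @param n_agents agents per group.
#' @param ... further arguments passed to [agent_config()] (shared).
#' @return named list of [group_spec()]s.
#' @export
default_groups <- function(omega_st = 0.95, omega_ig = 0.3, omega_gt = 0.03,
                           n_agents = 14, ...) {
  list(ST = group_spec("ST", agent_config(omega = omega_st, ...), n_agents),
       IG = group_spec("IG", agent_config(omega = omega_ig, ...), n_agents),
       GT = group_spec("GT", agent_config(omega = omega_gt, ...), n_agents))
}

# One seeded stream per agent, derived from (group seed, agent index), so
# group runs are reproducible and independent of agent order.
agent_seed <- function(group_seed, i) {
  as.integer((as.double(group_seed) * 1009 + i * 9973 + 12345) %% 2147483647)
}

group_seed <- function(master_seed, group_index) {
  as.integer((as.double(master_seed) * 7919 + group_index * 104729) %%
               2147483647)
}

sem <- function(x) stats::sd(x) / sqrt(length(x))

# Per-agent figure-level summaries of one session log.
summarize_agent <- function(log, block_size) {
  tr <- log$trials
  n <- nrow(tr)
  blk <- ceiling(seq_len(n) / block_size)
  lever_b <- tapply(tr$lever, blk, mean)
  mag_b <- tapply(tr$magazine, blk, mean)
  lever_s <- tapply(tr$lever, tr$session, mean)
  mag_s <- tapply(tr$magazine, tr$session, mean)
  cs <- us <- NULL
  if (!is.null(log$steps)) {
    st <- log$steps
    sessions <- sort(unique(st$session))
    cs <- vapply(sessions, function(ss)
      mean(st$delta_used[st$session == ss & st$event == "CS_onset"]),
      numeric(1))
    us <- vapply(sessions, function(ss) {
      d <- st$delta_used[st$session == ss & st$event == "US_delivery"]
      if (length(d)) mean(d) else NA_real_
    }, numeric(1))
  }
  list(lever_blocks = as.numeric(lever_b), mag_blocks = as.numeric(mag_b),
       lever_sessions = as.numeric(lever_s), mag_sessions = as.numeric(mag_s),
       cs_delta = cs, us_delta = us)
}

aggregate_group <- function(summaries, label) {
  n_blocks <- length(summaries[[1]]$lever_blocks)
  n_sessions <- length(summaries[[1]]$lever_sessions)
  lever <- do.call(rbind, lapply(summaries, `[[`, "lever_blocks"))
  mag <- do.call(rbind, lapply(summaries, `[[`, "mag_blocks"))
  eng <- rbind(
    data.frame(group = label, block = seq_len(n_blocks), stimulus = "lever",
               probability = colMeans(lever), sem = apply(lever, 2, sem)),
    data.frame(group = label, block = seq_len(n_blocks), stimulus = "magazine",
               probability = colMeans(mag), sem = apply(mag, 2, sem)))
  lever_s <- do.call(rbind, lapply(summaries, `[[`, "lever_sessions"))
  mag_s <- do.call(rbind, lapply(summaries, `[[`, "mag_sessions"))
  eng_s <- rbind(
    data.frame(group = label, session = seq_len(n_sessions),
               stimulus = "lever", probability = colMeans(lever_s),
               sem = apply(lever_s, 2, sem)),
    data.frame(group = label, session = seq_len(n_sessions),
               stimulus = "magazine", probability = colMeans(mag_s),
               sem = apply(mag_s, 2, sem)))
  rpe <- NULL
  if (!is.null(summaries[[1]]$cs_delta)) {
    cs <- do.call(rbind, lapply(summaries, `[[`, "cs_delta"))
    us <- do.call(rbind, lapply(summaries, `[[`, "us_delta"))
    rpe <- rbind(
      data.frame(group = label, session = seq_len(ncol(cs)), event = "CS",
                 mean_delta = colMeans(cs), sem = apply(cs, 2, sem)),
      data.frame(group = label, session = seq_len(ncol(us)), event = "US",
                 mean_delta = colMeans(us, na.rm = TRUE),
                 sem = apply(us, 2, function(x) sem(x[!is.na(x)]))))
  }
  list(engagement = eng, engagement_sessions = eng_s, rpe = rpe)
}

#' Run the autoshaping experiment for one or more groups
#'
#' Simulates every agent of every group independently (one seeded stream per
#' agent) over the schedule, and aggregates the figure-level metrics:
#' probability of engaging the lever / the magazine at least once per trial,
#' in 50-trial blocks and per session (mean and s.e.m. across agents), and
#' the session means of the dopamine-analogue reward prediction errors at CS
#' onset and US delivery.
#'
#' @param groups a [group_spec()] or (named) list of them.
#' @param schedule a [schedule_spec()].
#' @param seed master seed; per-group and per-agent streams are derived from
#'   it.
#' @param block_size trials per engagement block (default 50, i.e. two
#'   25-trial sessions).
#' @param engine simulation engine passed to [run_agent()].
#' @param record keep per-transition RPE logs (needed for the RPE curves).
#' @return list of class `autoshaping_result` with data.frames `engagement`
#'   (per block), `engagement_sessions`, `rpe` (per session), and the
#'   per-agent summaries and final learner snapshots under `$agents`.
#' @export
run_autoshaping <- function(groups, schedule = schedule_spec(), seed = 1L,
                            block_size = 50, engine = c("cpp", "r"),
                            record = TRUE) {
  engine <- match.arg(engine)
  if (inherits(groups, "group_spec")) groups <- list(groups)
  if (is.null(names(groups)))
    names(groups) <- vapply(groups, `[[`, character(1), "label")
  eng <- list(); eng_s <- list(); rpe <- list(); agents <- list()
  for (gi in seq_along(groups)) {
    g <- groups[[gi]]
    gseed <- group_seed(seed, gi)
    per_agent <- lapply(seq_len(g$n_agents), function(i) {
      log <- run_agent(g$config, schedule, seed = agent_seed(gseed, i),
                       engine = engine, record = record)
      c(summarize_agent(log, block_size),
        list(final = log$final, seed = log$seed))
    })
    agg <- aggregate_group(per_agent, g$label)
    eng[[gi]] <- agg$engagement
    eng_s[[gi]] <- agg$engagement_sessions
    rpe[[gi]] <- agg$rpe
    agents[[g$label]] <- per_agent
  }
  structure(list(engagement = do.call(rbind, eng),
                 engagement_sessions = do.call(rbind, eng_s),
                 rpe = if (record) do.call(rbind, rpe),
                 agents = agents, groups = groups, schedule = schedule,
                 seed = seed, block_size = block_size),
            class = "autoshaping_result")
}

#' Systemic flupentixol experiment
#'
#' Each phenotype group is run twice at the same per-agent seeds: a drug arm
#' receiving systemic flupentixol before each of the first `n_drug_sessions`
#' sessions and nothing on the final (test) session, and a saline arm
#' receiving nothing throughout. Systemic administration both elevates the
#' softmax temperature (masking the expression of any learned values) and
#' attenuates the reward prediction errors (blocking Feature-Model-Free
#' learning), while Model-Based learning proceeds untouched.
#'
#' @param groups groups to run (default sign- and goal-tracker phenotypes).
#' @param dose systemic dose; the default is saturating (full RPE blockade
#'   and a near-flat softmax).
#' @param n_sessions total sessions (last one is drug-free).
#' @param n_drug_sessions number of initial sessions under drug.
#' @param trials_per_session trials per session.
#' @param seed master seed (shared by both arms).
#' @param k_rpe,k_temp dose coefficients, see [drug_condition()].
#' @param ... passed to [run_autoshaping()].
#' @return list of class `systemic_flu_result` with `flu` and `saline`
#'   [run_autoshaping()] results and the drug condition used.
#' @export
run_systemic_flu <- function(groups = default_groups()[c("ST", "GT")],
                             dose = 100, n_sessions = 8, n_drug_sessions = 7,
                             trials_per_session = 25, seed = 1L,
                             k_rpe = 0.1, k_temp = 1, ...) {
  stopifnot(n_drug_sessions < n_sessions)
  drug <- drug_condition(dose, "systemic", k_rpe = k_rpe, k_temp = k_temp)
  none <- drug_condition()
  sched_flu <- schedule_spec(n_sessions, trials_per_session,
                             c(rep(list(drug), n_drug_sessions),
                               rep(list(none), n_sessions - n_drug_sessions)))
  sched_sal <- schedule_spec(n_sessions, trials_per_session, none)
  structure(list(flu = run_autoshaping(groups, sched_flu, seed = seed, ...),
                 saline = run_autoshaping(groups, sched_sal, seed = seed, ...),
                 drug = drug),
            class = "systemic_flu_result")
}

#' Local (intra-accumbens) flupentixol dose-response
#'
#' A mixed population (by default sign-trackers, goal-trackers and
#' intermediates) is first trained drug-free for the full autoshaping
#' schedule, then tested for additional sessions under intra-accumbens
#' flupentixol at each dose (dose 0 included). Local administration only
#' attenuates the reward prediction errors of the feature learner; its
#' behavioural effect therefore emerges through relearning during the test
#' sessions. The population sign-tracking (goal-tracking) probability is the
#' mean lever (magazine) engagement over all test trials pooled across the
#' whole population.
#'
#' @param groups population composition.
#' @param doses dose grid, ascending, including 0.
#' @param pretrain_sessions,test_sessions,trials_per_session schedule.
#' @param seed master seed; identical across doses so that each dose tests
#'   the same trained population.
#' @param k_rpe dose coefficient.
#' @param ... passed to [run_autoshaping()].
#' @return list of class `local_flu_result`; `$dose_response` has one row
#'   per dose and measure (`sign_tracking` / `goal_tracking`).
#' @export
run_local_flu <- function(groups = default_groups(),
                          doses = c(0, 0.2, 0.5, 2),
                          pretrain_sessions = 8, test_sessions = 16,
                          trials_per_session = 25, seed = 1L, k_rpe = 0.1,
                          ...) {
  stopifnot(length(doses) >= 2, !is.unsorted(doses), doses[1] == 0)
  none <- drug_condition()
  runs <- list(); rows <- list()
  n_test_trials <- test_sessions * trials_per_session
  for (d in doses) {
    drug <- drug_condition(d, "local_NAcc", k_rpe = k_rpe)
    sched <- schedule_spec(
      pretrain_sessions + test_sessions, trials_per_session,
      c(rep(list(none), pretrain_sessions), rep(list(drug), test_sessions)))
    res <- run_autoshaping(groups, sched, seed = seed, record = FALSE, ...)
    test_idx <- pretrain_sessions + seq_len(test_sessions)
    lever <- unlist(lapply(res$agents, function(g)
      vapply(g, function(a) mean(a$lever_sessions[test_idx]), numeric(1))))
    mag <- unlist(lapply(res$agents, function(g)
      vapply(g, function(a) mean(a$mag_sessions[test_idx]), numeric(1))))
    rows[[length(rows) + 1L]] <- data.frame(
      dose = d,
      measure = c("sign_tracking", "goal_tracking"),
      probability = c(mean(lever), mean(mag)),
      sem = c(sem(lever), sem(mag)))
    runs[[as.character(d)]] <- res
  }
  structure(list(dose_response = do.call(rbind, rows), runs = runs,
                 doses = doses, test_sessions = test_sessions),
            class = "local_flu_result")
}

# Integrated decision values at state s, rebuilt from an agent's final
# learner snapshots (same algebra as integrate_values()).
final_integrated <- function(final, config, mdp, s) {
  tab <- mdp_tables(mdp)
  si <- match(s, tab$state_ids)
  la <- which(tab$legal[si, ])
  feats <- FEATURES[tab$feature[si, la]]
  omega <- config$omega
  adv <- function(Q) {
    q <- Q[si, la]
    q - max(q)
  }
  P <- switch(config$variant,
    model = omega * unname(final$V[feats]) + (1 - omega) * final$A_mb[si, la],
    v1 = omega * unname(final$V[feats]) + (1 - omega) * adv(final$Q_mf),
    v2 = (1 - omega) * adv(final$Q_mf) +
      omega * ifelse(feats == "Lever", max(final$Q_mf[si, la]), 0),
    v3 = (1 - omega) * adv(final$Q_mf) +
      omega * ifelse(feats %in% c("Lever", "Magazine"),
                     max(final$Q_mf[si, la]), 0),
    v4 = omega * adv(final$Q_mf) + (1 - omega) * final$A_mb[si, la])
  stats::setNames(as.numeric(P), ACTIONS[la])
}

# Same, with the second system's motivational contribution ablated.
final_integrated_ablated <- function(final, config, mdp, s) {
  tab <- mdp_tables(mdp)
  si <- match(s, tab$state_ids)
  la <- which(tab$legal[si, ])
  omega <- config$omega
  adv <- function(Q) { q <- Q[si, la]; q - max(q) }
  P <- switch(config$variant,
    model = (1 - omega) * final$A_mb[si, la],
    v1 = (1 - omega) * adv(final$Q_mf),
    v2 = ,
    v3 = (1 - omega) * adv(final$Q_mf),
    v4 = (1 - omega) * final$A_mb[si, la])
  stats::setNames(as.numeric(P), ACTIONS[la])
}

#' Conditioned-reinforcement probe
#'
#' Value-based probe of the lever's acquired motivational pull: for each
#' trained agent, the probability of engaging the lever when the magazine
#' (and its actions) is absent, computed by applying the softmax to the
#' integrated values of `goL` versus `exp` at the choice state. An untrained
#' uniform-policy comparator (`UN`) scores 0.5 by construction.
#'
#' @param result an [run_autoshaping()] result.
#' @param mdp the task the agents were trained on.
#' @return data.frame with one row per group plus the `UN` baseline:
#'   mean and s.e.m. of P(engage lever).
#' @export
probe_conditioned_reinforcement <- function(result,
                                            mdp = build_default_mdp()) {
  choice <- choice_state(mdp)
  rows <- lapply(names(result$agents), function(lab) {
    cfg <- result$groups[[lab]]$config
    p <- vapply(result$agents[[lab]], function(a) {
      P <- final_integrated(a$final, cfg, mdp, choice)[c("goL", "exp")]
      unname(softmax_policy(P, cfg$beta)["goL"])
    }, numeric(1))
    data.frame(group = lab, p_engage_lever = mean(p), sem = sem(p))
  })
  rbind(do.call(rbind, rows),
        data.frame(group = "UN", p_engage_lever = 0.5, sem = 0))
}

#' Feature-system contribution to engagement
#'
#' Quantifies how much of each group's engagement with its favoured stimulus
#' is driven by the Feature-Model-Free (incentive-salience) values: the
#' group's favoured choice-state action is determined from its final-block
#' engagement, its full softmax probability P_full is compared with the
#' probability P_ablated recomputed after zeroing the feature-value
#' contribution for all actions, and the contribution is
#' 100 * (P_full - P_ablated) / P_full, averaged across agents.
#'
#' @param result an [run_autoshaping()] result.
#' @param mdp the task.
#' @return data.frame per group: favoured stimulus, mean engagement
#'   probability, mean contribution percentage and s.e.m. (NA when
#'   P_full = 0 for every agent).
#' @export
fmf_contribution <- function(result, mdp = build_default_mdp()) {
  choice <- choice_state(mdp)
  eng <- result$engagement
  last_block <- max(eng$block)
  rows <- lapply(names(result$agents), function(lab) {
    cfg <- result$groups[[lab]]$config
    el <- eng[eng$group == lab & eng$block == last_block, ]
    favoured <- if (el$probability[el$stimulus == "lever"] >=
                    el$probability[el$stimulus == "magazine"]) "lever"
                else "magazine"
    act <- if (favoured == "lever") "goL" else "goM"
    vals <- vapply(result$agents[[lab]], function(a) {
      pf <- softmax_policy(final_integrated(a$final, cfg, mdp, choice),
                           cfg$beta)[act]
      pa <- softmax_policy(final_integrated_ablated(a$final, cfg, mdp, choice),
                           cfg$beta)[act]
      c(pf, if (pf > 0) 100 * (pf - pa) / pf else NA_real_)
    }, numeric(2))
    data.frame(group = lab, favoured = favoured,
               p_engage = mean(vals[1, ]),
               contribution = mean(vals[2, ], na.rm = TRUE),
               sem = sem(vals[2, !is.na(vals[2, ])]))
  })
  do.call(rbind, rows)
}

# The choice state: the (unique) successor of the initial state.
choice_state <- function(mdp) {
  init <- mdp$states$id[mdp$states$initial]
  a <- actions_of(mdp, init)[1]
  mdp_step(mdp, init, a)$next_state
}

#' ITI-duration manipulation
#'
#' Re-runs the phenotype population at several values of the ITI decay
#' fraction u and reports, per u: the converged US-delivery and CS-onset
#' RPEs of the goal-tracker group (final-session means) and the pooled
#' population goal- and sign-tracking probabilities. The model predicts that
#' the persistent US-time dopamine burst of goal-trackers scales with the
#' ITI interaction with the magazine (shorter or magazine-free ITIs shrink
#' it) and that shorter ITIs shift the population toward goal-tracking,
#' because a less-depressed magazine value makes the feature system less
#' likely to favour the lever.
#'
#' @param groups the population to sweep (default phenotype groups); the
#'   ITI decay fraction of every group is overridden by each u value.
#' @param u_values grid of ITI decay fractions (0 included).
#' @param gt_label which group's RPE curves supply the US/CS deltas.
#' @param schedule training schedule (long enough to converge).
#' @param seed master seed, shared across u values.
#' @param ... passed to [run_autoshaping()].
#' @return list of class `iti_result`; `$summary` has one row per u:
#'   converged US and CS deltas of the goal-tracker group and the pooled
#'   population goal- and sign-tracking probabilities (final two sessions).
#' @export
run_iti_manipulation <- function(groups = default_groups(),
                                 u_values = c(0, 0.1, 0.3, 0.5),
                                 gt_label = "GT",
                                 schedule = schedule_spec(n_sessions = 12),
                                 seed = 1L, ...) {
  stopifnot(0 %in% u_values, gt_label %in% names(groups))
  runs <- list(); rows <- list()
  for (u in u_values) {
    gs <- lapply(groups, function(g) { g$config$u <- u; g })
    res <- run_autoshaping(gs, schedule, seed = seed, ...)
    last_s <- schedule$n_sessions
    rp <- res$rpe
    pool <- function(field, idx) mean(unlist(lapply(res$agents, function(g)
      vapply(g, function(a) mean(a[[field]][idx]), numeric(1)))))
    last_idx <- (last_s - 1):last_s
    rows[[length(rows) + 1L]] <- data.frame(
      u = u,
      us_delta = rp$mean_delta[rp$group == gt_label & rp$event == "US" &
                                 rp$session == last_s],
      cs_delta = rp$mean_delta[rp$group == gt_label & rp$event == "CS" &
                                 rp$session == last_s],
      gt_prob = pool("mag_sessions", last_idx),
      st_prob = pool("lever_sessions", last_idx))
    runs[[as.character(u)]] <- res
  }
  structure(list(summary = do.call(rbind, rows), runs = runs),
            class = "iti_result")
}
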