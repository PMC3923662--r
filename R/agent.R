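VARIANTS <- c("model", "v1", "v2", "v3", "v4")

#' Configuration of one simulated rat
#'
#' Bundles every parameter of one agent. All parameters are shared between
#' the two learning systems except the integration weight `omega`, which is
#' the phenotype dial: high omega weights the feature-value bonus
#' (sign-tracking), low omega weights the planner (goal-tracking).
#'
#' @param omega integration weight in [0, 1].
#' @param alpha learning rate in (0, 1] (shared by all learners).
#' @param gamma discount rate in [0, 1).
#' @param beta softmax selection temperature (> 0).
#' @param u ITI decay fraction in [0, 1].
#' @param v0_magazine,v0_food initial feature values (pretraining).
#' @param q0 initial Model-Free Q value (variants).
#' @param r0 initial learned reward value (Model-Based).
#' @param variant `"model"` (Model-Based + Feature-Model-Free) or one of
#'   `"v1"`-`"v4"` (see [integrate_values()]).
#' @param r_food reward magnitude of the food pellet.
#' @return list of class `agent_config`.
#' @export
agent_config <- function(omega = 0.5, alpha = 0.1, gamma = 0.95, beta = 0.1,
                         u = 0.12, v0_magazine = 0, v0_food = 0,
                         q0 = 0, r0 = 1, variant = "model", r_food = 1) {
  if (!is.numeric(omega) || length(omega) != 1L || is.na(omega) ||
      omega < 0 || omega > 1)
    stop("omega must be a single number in [0, 1]")
  stopifnot(alpha > 0, alpha <= 1, gamma >= 0, gamma < 1, beta > 0,
            u >= 0, u <= 1, r_food > 0)
  variant <- match.arg(variant, VARIANTS)
  structure(list(omega = omega, alpha = alpha, gamma = gamma, beta = beta,
                 u = u, v0_magazine = v0_magazine, v0_food = v0_food,
                 q0 = q0, r0 = r0, variant = variant, r_food = r_food),
            class = "agent_config")
}

#' Training schedule
#'
#' @param n_sessions number of sessions (>= 1).
#' @param trials_per_session trials per session (default 25, so two sessions
#'   form one 50-trial block).
#' @param drug a single [drug_condition()] applied to every session, or a
#'   list of conditions, one per session.
#' @return list of class `schedule_spec`; `$drug` is always a per-session
#'   list.
#' @export
schedule_spec <- function(n_sessions = 8, trials_per_session = 25,
                          drug = drug_condition()) {
  stopifnot(n_sessions >= 1, trials_per_session >= 1)
  if (inherits(drug, "drug_condition")) {
    drug <- rep(list(drug), n_sessions)
  }
  if (length(drug) != n_sessions)
    stop("drug must be one condition or one per session")
  structure(list(n_sessions = as.integer(n_sessions),
                 trials_per_session = as.integer(trials_per_session),
                 drug = drug),
            class = "schedule_spec")
}

#' Initialise an agent's learner state
#'
#' @param config an [agent_config()].
#' @param mdp the task; defaults to [build_default_mdp()] with the
#'   configured food reward.
#' @return list of class `agent_state` holding the task, the configuration
#'   and the learners the configured variant uses (`fmf`, `mb`, `mf`).
#' @export
init_agent <- function(config, mdp = build_default_mdp(config$r_food)) {
  params <- learning_params(config$alpha, config$gamma)
  use_fmf <- config$variant %in% c("model", "v1")
  use_mb <- config$variant %in% c("model", "v4")
  use_mf <- config$variant %in% c("v1", "v2", "v3", "v4")
  structure(list(
    mdp = mdp, config = config,
    fmf = if (use_fmf) fmf_values(params, config$u,
                                  config$v0_magazine, config$v0_food),
    mb = if (use_mb) mb_plan(mb_model(mdp, params, config$r0)),
    mf = if (use_mf) mf_values(mdp, params, config$q0)),
    class = "agent_state")
}

#' Run a single trial (one episode) and learn online
#'
#' Reference (pure R) implementation of one trial: the ITI decay is applied
#' once at episode start, then until the terminal state is reached the agent
#' selects an action by softmax over the integrated values (temperature
#' possibly drug-elevated), executes it, computes its reward prediction
#' error(s), attenuates them under the drug condition, and updates its
#' learners; the Model-Based system updates its world model and replans
#' every step. A trial counts as lever engagement if its food-delivery
#' transition was lever-focused, and as magazine engagement if
#' magazine-focused (the two are mutually exclusive).
#'
#' @param agent an `agent_state`.
#' @param drug a [drug_condition()].
#' @return list with the updated `agent`, a `log` data.frame (one row per
#'   transition: state, action, successor, feature, event, raw and applied
#'   RPE) and the engagement flags `lever`/`magazine`.
#' @export
run_trial <- function(agent, drug = drug_condition()) {
  mdp <- agent$mdp
  cfg <- agent$config
  tab <- mdp_tables(mdp)
  use_fmf <- !is.null(agent$fmf)
  use_mb <- !is.null(agent$mb)
  use_mf <- !is.null(agent$mf)
  beta_eff <- elevate_temperature(cfg$beta, drug)
  if (use_fmf) agent$fmf <- fmf_iti_decay(agent$fmf)
  s <- tab$state_ids[tab$init]
  lever <- FALSE; mag <- FALSE
  rows <- list()
  while (!tab$terminal[match(s, tab$state_ids)]) {
    P <- integrate_values(cfg$variant, cfg$omega, mdp, s,
                          fmf = agent$fmf, mb = agent$mb, mf = agent$mf)
    a <- sample_action(softmax_policy(P, beta_eff))
    out <- mdp_step(mdp, s, a)
    ev <- event_tag(mdp, s, a)
    delta <- NA_real_; delta_used <- NA_real_
    if (use_fmf) {
      e <- fmf_rpe(agent$fmf, mdp, s, a, out$reward, out$next_state)
      e_used <- e; e_used$delta <- attenuate_rpe(e$delta, drug)
      agent$fmf <- fmf_update(agent$fmf, e_used)
      delta <- e$delta; delta_used <- e_used$delta
    }
    if (use_mf) {
      d <- mf_delta(agent$mf, s, a, out$reward, out$next_state)
      d_used <- attenuate_rpe(d, drug)
      agent$mf <- mf_apply_delta(agent$mf, s, a, d_used)
      if (!use_fmf) { delta <- d; delta_used <- d_used }
    }
    if (use_mb) {
      agent$mb <- mb_plan(mb_update(agent$mb, s, a, out$next_state,
                                    out$reward))
    }
    if (ev == "US_delivery") {
      if (out$feature == "Lever") lever <- TRUE
      if (out$feature == "Magazine") mag <- TRUE
    }
    rows[[length(rows) + 1L]] <- data.frame(
      state = s, action = a, next_state = out$next_state,
      feature = out$feature, event = ev,
      delta = delta, delta_used = delta_used, stringsAsFactors = FALSE)
    s <- out$next_state
  }
  list(agent = agent, log = do.call(rbind, rows),
       lever = lever, magazine = mag)
}

# Cache of the default task (and its integer tables) per food reward, so
# repeated simulations (the fitter in particular) skip re-validation.
.task_cache <- new.env(parent = emptyenv())

default_task <- function(r_food = 1) {
  key <- paste0("r", r_food)
  m <- .task_cache[[key]]
  if (is.null(m)) {
    m <- build_default_mdp(r_food)
    attr(m, "tables") <- mdp_tables(m)
    .task_cache[[key]] <- m
  }
  m
}

# Resolve cfg into the flat list the C++ engine takes.
cfg_for_cpp <- function(config) {
  list(omega = config$omega, alpha = config$alpha, gamma = config$gamma,
       beta = config$beta, u = config$u,
       variant = match(config$variant, VARIANTS) - 1L,
       v0 = c(0, 0, config$v0_magazine, config$v0_food),
       q0 = config$q0, r0 = config$r0)
}

#' Simulate one agent over a full schedule
#'
#' Runs `schedule$n_sessions * trials_per_session` trials with online
#' learning and returns the full session log plus the final learner
#' snapshots. The default engine is the compiled inner loop; `engine = "r"`
#' runs the pure-R reference loop built from the exported operations. Both
#' engines consume the RNG identically (one uniform per action selection),
#' so they produce identical logs at the same seed.
#'
#' @param config an [agent_config()].
#' @param schedule a [schedule_spec()].
#' @param seed integer seed for this agent's random stream.
#' @param mdp the task (default task built from the config).
#' @param engine `"cpp"` or `"r"`.
#' @param record keep the per-transition RPE log (set `FALSE` inside the
#'   fitter to save memory).
#' @return list of class `session_log`: `trials` (one row per trial with
#'   engagement flags), `steps` (one row per transition with tagged RPEs,
#'   `NULL` if `record = FALSE`), and `final` learner snapshots (`V`, `T`,
#'   `R`, `Q_mb`, `A_mb`, `Q_mf`).
#' @export
run_agent <- function(config, schedule = schedule_spec(), seed = 1L,
                      mdp = default_task(config$r_food),
                      engine = c("cpp", "r"), record = TRUE) {
  engine <- match.arg(engine)
  stopifnot(inherits(config, "agent_config"), inherits(schedule, "schedule_spec"))
  tab <- mdp_tables(mdp)
  eta_rpe <- vapply(schedule$drug, function(d) d$eta_rpe, numeric(1))
  eta_temp <- vapply(schedule$drug, function(d) d$eta_temp, numeric(1))
  set.seed(as.integer(seed))
  if (engine == "cpp") {
    raw <- sim_agent_cpp(tab, cfg_for_cpp(config), schedule$n_sessions,
                         schedule$trials_per_session, eta_rpe, eta_temp,
                         record)
    trials <- data.frame(raw$trials, stringsAsFactors = FALSE)
    steps <- NULL
    if (record) {
      steps <- data.frame(
        session = raw$steps$session, trial = raw$steps$trial,
        step = raw$steps$step,
        state = tab$state_ids[raw$steps$state],
        action = ACTIONS[raw$steps$action],
        next_state = tab$state_ids[raw$steps$next_state],
        feature = FEATURES[raw$steps$feature],
        event = c("other", "CS_onset", "US_delivery")[raw$steps$event + 1L],
        delta = raw$steps$delta, delta_used = raw$steps$delta_used,
        stringsAsFactors = FALSE)
    }
    final <- list(V = stats::setNames(raw$V, FEATURES), T = raw$T, R = raw$R,
                  Q_mb = raw$Q_mb, A_mb = raw$A_mb, Q_mf = raw$Q_mf)
    dimnames(final$T) <- list(tab$state_ids, ACTIONS, tab$state_ids)
    for (nm in c("R", "Q_mb", "A_mb", "Q_mf"))
      dimnames(final[[nm]]) <- list(tab$state_ids, ACTIONS)
    # only report the learners this variant actually uses
    if (!config$variant %in% c("model", "v1")) final["V"] <- list(NULL)
    if (!config$variant %in% c("model", "v4"))
      final[c("T", "R", "Q_mb", "A_mb")] <- list(NULL)
    if (config$variant == "model") final["Q_mf"] <- list(NULL)
  } else {
    agent <- init_agent(config, mdp)
    trial_rows <- list(); step_rows <- list()
    for (ses in seq_len(schedule$n_sessions)) {
      for (tr in seq_len(schedule$trials_per_session)) {
        res <- run_trial(agent, schedule$drug[[ses]])
        agent <- res$agent
        trial_rows[[length(trial_rows) + 1L]] <- data.frame(
          session = ses, trial = tr, lever = res$lever,
          magazine = res$magazine)
        if (record) {
          lg <- res$log
          lg <- cbind(data.frame(session = ses, trial = tr,
                                 step = seq_len(nrow(lg))), lg)
          step_rows[[length(step_rows) + 1L]] <- lg
        }
      }
    }
    trials <- do.call(rbind, trial_rows)
    steps <- if (record) do.call(rbind, step_rows)
    final <- list(
      V = if (!is.null(agent$fmf)) agent$fmf$V else NULL,
      T = if (!is.null(agent$mb)) agent$mb$T else NULL,
      R = if (!is.null(agent$mb)) agent$mb$R else NULL,
      Q_mb = if (!is.null(agent$mb)) agent$mb$Q else NULL,
      A_mb = if (!is.null(agent$mb)) agent$mb$A else NULL,
      Q_mf = if (!is.null(agent$mf)) agent$mf$Q else NULL)
  }
  structure(list(trials = trials, steps = steps, final = final,
                 config = config, schedule = schedule, seed = seed),
            class = "session_log")
}

#' Serialize learner snapshots to a plain key-value list
#'
#' Flattens the final learner state of a [run_agent()] log into a plain
#' named list (suitable for YAML/JSON), for inspection and regression
#' fixtures.
#'
#' @param log a `session_log`.
#' @return a plain list of named numeric values.
#' @export
snapshot_to_list <- function(log) {
  fin <- log$final
  out <- list()
  if (!is.null(fin$V)) out$V <- as.list(fin$V)
  flatten <- function(M) {
    if (is.null(M)) return(NULL)
    keep <- which(M != 0, arr.ind = TRUE)
    vals <- as.list(M[M != 0])
    names(vals) <- paste(rownames(M)[keep[, 1]], colnames(M)[keep[, 2]],
                         sep = ".")
    vals
  }
  out$Q_mb <- flatten(fin$Q_mb)
  out$R <- flatten(fin$R)
  out$Q_mf <- flatten(fin$Q_mf)
  out
}
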