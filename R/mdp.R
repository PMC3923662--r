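# The feature vocabulary shared by the task and the learners. "None" is the
# null focus; its learned value is pinned at zero in every learner.
FEATURES <- c("None", "Lever", "Magazine", "Food")

# Fixed action enumeration; also the tie-break order for max operators.
ACTIONS <- c("goL", "goM", "eng", "exp", "eat")

#' Construct an autoshaping task MDP from explicit tables
#'
#' The task is data-driven: states, legal actions, deterministic transitions,
#' rewards and the feature-function are plain tables, so alternative
#' topologies can be loaded from configuration files. The constructor
#' validates the episodic structure (unique initial and terminal state,
#' acyclic transition graph, every path reaching the terminal state).
#'
#' @param states data.frame with columns `id`, `lever_available`,
#'   `food_available`, `close_to` (`"lever"`, `"magazine"` or `"none"`),
#'   `terminal`, `initial`.
#' @param transitions data.frame with columns `state`, `action`,
#'   `next_state`, `reward`, `feature`; one row per legal (state, action).
#' @param r_food reward magnitude delivered on food consumption.
#' @return an object of class `autoshaping_mdp`.
#' @seealso [build_default_mdp()]
#' @export
new_mdp <- function(states, transitions, r_food = 1.0) {
  stopifnot(is.data.frame(states), is.data.frame(transitions))
  needed_s <- c("id", "lever_available", "food_available", "close_to",
                "terminal", "initial")
  needed_t <- c("state", "action", "next_state", "reward", "feature")
  if (!all(needed_s %in% names(states)))
    stop("states table must have columns: ", paste(needed_s, collapse = ", "))
  if (!all(needed_t %in% names(transitions)))
    stop("transitions table must have columns: ", paste(needed_t, collapse = ", "))
  mdp <- structure(
    list(states = states[needed_s], transitions = transitions[needed_t],
         actions = intersect(ACTIONS, unique(transitions$action)),
         r_food = r_food),
    class = "autoshaping_mdp")
  validate_mdp(mdp)
  mdp
}

#' Default eight-state autoshaping task
#'
#' Builds the episodic MDP of one autoshaping trial. The agent starts in an
#' empty pre-CS state where it can only explore; the lever then appears and
#' the agent chooses between going to the lever (sign-tracking path), going
#' to the magazine (goal-tracking path) or continuing to explore. After the
#' engagement step the lever retracts and food is delivered into the
#' magazine; the agent reaches the magazine if needed, eats, and the episode
#' ends. The goal-tracking path reaches reward in 4 actions, the
#' sign-tracking and exploration paths in 5, which is what makes
#' goal-tracking the plan-optimal behaviour under discounting.
#'
#' Each legal (state, action) pair is mapped by the feature-function to the
#' stimulus the action is directed at (`Lever`, `Magazine`, `Food`) or
#' `None` for undirected exploration.
#'
#' @param r_food reward magnitude of the food pellet (dimensionless, > 0).
#' @return an `autoshaping_mdp`.
#' @examples
#' mdp <- build_default_mdp()
#' mdp_step(mdp, "S_CS", "goM")
#' @export
build_default_mdp <- function(r_food = 1.0) {
  stopifnot(is.numeric(r_food), length(r_food) == 1L, r_food > 0)
  states <- data.frame(
    id = c("S_PRE", "S_CS", "S_CS_L", "S_CS_M", "S_CS_E",
           "S_US_FAR", "S_US_CM", "S_END"),
    lever_available = c(FALSE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    food_available  = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE),
    close_to = c("none", "none", "lever", "magazine", "none",
                 "none", "magazine", "none"),
    terminal = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    initial  = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  transitions <- data.frame(
    state      = c("S_PRE", "S_CS", "S_CS", "S_CS", "S_CS_L", "S_CS_M",
                   "S_CS_E", "S_US_FAR", "S_US_CM"),
    action     = c("exp", "goL", "goM", "exp", "eng", "eng",
                   "exp", "goM", "eat"),
    next_state = c("S_CS", "S_CS_L", "S_CS_M", "S_CS_E", "S_US_FAR",
                   "S_US_CM", "S_US_FAR", "S_US_CM", "S_END"),
    reward     = c(0, 0, 0, 0, 0, 0, 0, 0, r_food),
    feature    = c("None", "Lever", "Magazine", "None", "Lever", "Magazine",
                   "None", "Food", "Food"),
    stringsAsFactors = FALSE)
  new_mdp(states, transitions, r_food = r_food)
}

#' Validate the episodic structure of a task MDP
#'
#' Checks: exactly one initial and one terminal state; lever and food never
#' simultaneously available; all transition endpoints are known states;
#' features are from the shared vocabulary; non-terminal states expose at
#' least one action; the transition graph is acyclic and every state
#' reachable from the initial state reaches the terminal state.
#'
#' @param mdp an `autoshaping_mdp`.
#' @return `mdp`, invisibly; errors describe the violated invariant.
#' @export
validate_mdp <- function(mdp) {
  st <- mdp$states; tr <- mdp$transitions
  if (sum(st$initial) != 1L) stop("exactly one initial state required")
  if (sum(st$terminal) != 1L) stop("exactly one terminal state required")
  if (any(st$lever_available & st$food_available))
    stop("lever_available and food_available must never both be TRUE")
  if (!all(tr$state %in% st$id) || !all(tr$next_state %in% st$id))
    stop("transitions reference unknown states")
  if (!all(tr$feature %in% FEATURES))
    stop("unknown feature in feature-function; allowed: ",
         paste(FEATURES, collapse = ", "))
  if (anyDuplicated(tr[c("state", "action")]))
    stop("duplicate (state, action) pair in transitions")
  nonterm <- st$id[!st$terminal]
  if (!all(nonterm %in% tr$state))
    stop("every non-terminal state must expose at least one action")
  if (any(tr$state == st$id[st$terminal]))
    stop("terminal state must not expose actions")
  # acyclicity + reachability of the terminal state via depth-first search
  paths <- mdp_paths(mdp)   # errors on cycles
  ends <- vapply(paths, function(p) p$states[length(p$states)], character(1))
  if (!all(ends == st$id[st$terminal]))
    stop("every path from the initial state must reach the terminal state")
  invisible(mdp)
}

#' Legal actions of a state
#'
#' @param mdp an `autoshaping_mdp`.
#' @param s state id.
#' @return character vector of legal action ids (fixed enumeration order);
#'   empty for the terminal state.
#' @export
actions_of <- function(mdp, s) {
  stopifnot(s %in% mdp$states$id)
  a <- mdp$transitions$action[mdp$transitions$state == s]
  intersect(ACTIONS, a)
}

#' Execute one deterministic task transition
#'
#' @param mdp an `autoshaping_mdp`.
#' @param s current (non-terminal) state id.
#' @param a action id, legal in `s`.
#' @return list with `next_state`, `reward` and `feature` (the stimulus the
#'   action focused on).
#' @export
mdp_step <- function(mdp, s, a) {
  i <- which(mdp$transitions$state == s & mdp$transitions$action == a)
  if (length(i) != 1L)
    stop("illegal action '", a, "' in state '", s,
         "': protocol bug, legal actions are ",
         paste(actions_of(mdp, s), collapse = ", "))
  tr <- mdp$transitions[i, ]
  list(next_state = tr$next_state, reward = tr$reward, feature = tr$feature)
}

#' Tag a transition as CS onset, US delivery or other
#'
#' CS onset is the transition out of the initial (empty) state, i.e. lever
#' appearance. US delivery is any transition entering a food-available state
#' from a CS-period (lever-available) state, i.e. lever retraction plus food
#' delivery. These are the two peri-event windows over which session RPE
#' means are computed, mirroring how phasic dopamine is summarised around CS
#' and US in voltammetry recordings.
#'
#' @param mdp an `autoshaping_mdp`.
#' @param s state id.
#' @param a legal action id.
#' @return one of `"CS_onset"`, `"US_delivery"`, `"other"`.
#' @export
event_tag <- function(mdp, s, a) {
  out <- mdp_step(mdp, s, a)
  st <- mdp$states
  from <- st[st$id == s, ]
  to <- st[st$id == out$next_state, ]
  if (from$initial) return("CS_onset")
  if (from$lever_available && to$food_available) return("US_delivery")
  "other"
}

#' Enumerate all episode paths of the task
#'
#' Depth-first enumeration of every action path from the initial state;
#' errors if a cycle is found (episodes must be finite-horizon).
#'
#' @param mdp an `autoshaping_mdp`.
#' @return list of paths, each a list with `states` (visited state ids) and
#'   `actions`.
#' @export
mdp_paths <- function(mdp) {
  start <- mdp$states$id[mdp$states$initial]
  out <- list()
  walk <- function(s, states, acts) {
    if (s %in% states[-length(states)])
      stop("cycle detected through state '", s, "'")
    as <- mdp$transitions$action[mdp$transitions$state == s]
    if (length(as) == 0L) {
      out[[length(out) + 1L]] <<- list(states = states, actions = acts)
      return(invisible(NULL))
    }
    for (a in intersect(ACTIONS, as)) {
      nxt <- mdp$transitions$next_state[
        mdp$transitions$state == s & mdp$transitions$action == a]
      walk(nxt, c(states, nxt), c(acts, a))
    }
  }
  walk(start, start, character(0))
  out
}

# Integer-indexed tables used by the simulation engines. Cached on the
# object after first computation.
mdp_tables <- function(mdp) {
  cached <- attr(mdp, "tables")
  if (!is.null(cached)) return(cached)
  sid <- mdp$states$id
  nS <- length(sid); nA <- length(ACTIONS)
  nxt <- matrix(0L, nS, nA, dimnames = list(sid, ACTIONS))
  rew <- matrix(0, nS, nA, dimnames = list(sid, ACTIONS))
  fea <- matrix(0L, nS, nA, dimnames = list(sid, ACTIONS))
  evt <- matrix(0L, nS, nA, dimnames = list(sid, ACTIONS))
  legal <- matrix(FALSE, nS, nA, dimnames = list(sid, ACTIONS))
  for (i in seq_len(nrow(mdp$transitions))) {
    tr <- mdp$transitions[i, ]
    si <- match(tr$state, sid); ai <- match(tr$action, ACTIONS)
    nxt[si, ai] <- match(tr$next_state, sid)
    rew[si, ai] <- tr$reward
    fea[si, ai] <- match(tr$feature, FEATURES)
    legal[si, ai] <- TRUE
    evt[si, ai] <- switch(event_tag(mdp, tr$state, tr$action),
                          CS_onset = 1L, US_delivery = 2L, 0L)
  }
  tab <- list(n_states = nS, n_actions = nA, state_ids = sid,
              next_state = nxt, reward = rew, feature = fea, event = evt,
              legal = legal, terminal = mdp$states$terminal,
              init = match(sid[mdp$states$initial], sid))
  tab
}

#' Convert a task MDP to or from a plain configuration list
#'
#' The configuration form holds the state and transition tables as plain
#' lists of records, suitable for YAML serialization, so alternative task
#' topologies can be versioned alongside protocol configs.
#'
#' @param mdp an `autoshaping_mdp`.
#' @return `mdp_to_config`: a plain list; `mdp_from_config`: an
#'   `autoshaping_mdp` rebuilt (and re-validated) from such a list.
#' @export
mdp_to_config <- function(mdp) {
  list(r_food = mdp$r_food,
       states = lapply(seq_len(nrow(mdp$states)),
                       function(i) as.list(mdp$states[i, ])),
       transitions = lapply(seq_len(nrow(mdp$transitions)),
                            function(i) as.list(mdp$transitions[i, ])))
}

#' @param config a list as produced by [mdp_to_config()].
#' @rdname mdp_to_config
#' @export
mdp_from_config <- function(config) {
  states <- do.call(rbind, lapply(config$states, as.data.frame))
  transitions <- do.call(rbind, lapply(config$transitions, as.data.frame))
  new_mdp(states, transitions, r_food = config$r_food)
}

#' Read or write a task MDP as a YAML document
#'
#' @param mdp an `autoshaping_mdp`.
#' @param path file path.
#' @return `read_mdp_config` returns the `autoshaping_mdp`;
#'   `write_mdp_config` returns `path` invisibly.
#' @export
write_mdp_config <- function(mdp, path) {
  yaml::write_yaml(mdp_to_config(mdp), path)
  invisible(path)
}

#' @rdname write_mdp_config
#' @export
read_mdp_config <- function(path) {
  mdp_from_config(yaml::read_yaml(path))
}

#' @export
print.autoshaping_mdp <- function(x, ...) {
  cat("Autoshaping task MDP:", nrow(x$states), "states,",
      nrow(x$transitions), "transitions, r_food =", x$r_food, "\n")
  cat("Paths from", x$states$id[x$states$initial], "to",
      x$states$id[x$states$terminal], ":",
      paste(vapply(mdp_paths(x), function(p) length(p$actions), integer(1)),
            collapse = "/"), "actions\n")
  invisible(x)
}
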