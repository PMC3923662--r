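# Brute-force finite-horizon backward induction on the true task tables.
# Independent of mb_plan(): recursion on horizon, no fixed-point iteration.
oracle_q <- function(mdp, gamma, horizon = 10L) {
  tab <- signtrackr:::mdp_tables(mdp)
  q <- matrix(0, tab$n_states, tab$n_actions,
              dimnames = list(tab$state_ids, colnames(tab$legal)))
  for (h in seq_len(horizon)) {
    q_new <- q
    for (s in seq_len(tab$n_states)) {
      for (a in seq_len(tab$n_actions)) {
        if (!tab$legal[s, a]) next
        ni <- tab$next_state[s, a]
        fut <- if (tab$terminal[ni] || !any(tab$legal[ni, ])) 0 else
          max(q[ni, tab$legal[ni, ]])
        q_new[s, a] <- tab$reward[s, a] + gamma * fut
      }
    }
    q <- q_new
  }
  q
}

# Feed every transition of the task to the Model-Based learner n times so
# that its T and R approach the true model.
learn_true_model <- function(m, mdp, n = 400L) {
  tr <- mdp$transitions
  for (k in seq_len(n)) {
    for (i in seq_len(nrow(tr))) {
      m <- mb_update(m, tr$state[i], tr$action[i], tr$next_state[i],
                     tr$reward[i])
    }
  }
  mb_plan(m)
}

# Small, fast configurations for structural tests.
tiny_schedule <- function(n_sessions = 2, trials = 5)
  schedule_spec(n_sessions, trials)
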