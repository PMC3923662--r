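#' Learning parameters shared by the learners
#'
#' @param alpha learning rate in (0, 1]: speed at which new experiences
#'   replace old ones.
#' @param gamma discount rate in [0, 1): preference for immediate over
#'   distant rewards.
#' @return list of class `learning_params`.
#' @export
learning_params <- function(alpha = 0.1, gamma = 0.9) {
  stopifnot(alpha > 0, alpha <= 1, gamma >= 0, gamma < 1)
  structure(list(alpha = alpha, gamma = gamma), class = "learning_params")
}

# ---------------------------------------------------------------------------
# Model-Based system: learned transition and reward model + planner.

#' Initialise a Model-Based learner
#'
#' The Model-Based system learns a transition function T(s, a, s') and a
#' reward function R(s, a) by exponential averaging, and plans action values
#' Q by value iteration on the learned model. Its output is the (negative)
#' advantage A(s, a) = Q(s, a) - max_a' Q(s, a').
#'
#' @param mdp an `autoshaping_mdp` (supplies the state/action space).
#' @param params a [learning_params()].
#' @param r0 initial value of the learned reward function.
#' @return list of class `mb_model` with members `T` (3-d array), `R`, `Q`,
#'   `A` and `params`.
#' @export
mb_model <- function(mdp, params = learning_params(), r0 = 0) {
  tab <- mdp_tables(mdp)
  sid <- tab$state_ids
  m <- list(
    T = array(0, dim = c(tab$n_states, tab$n_actions, tab$n_states),
              dimnames = list(sid, ACTIONS, sid)),
    R = matrix(r0, tab$n_states, tab$n_actions,
               dimnames = list(sid, ACTIONS)),
    Q = matrix(0, tab$n_states, tab$n_actions,
               dimnames = list(sid, ACTIONS)),
    A = matrix(0, tab$n_states, tab$n_actions,
               dimnames = list(sid, ACTIONS)),
    params = params, tab = tab)
  class(m) <- "mb_model"
  m$R[!tab$legal] <- 0
  m
}

#' Update the learned world model from one transition
#'
#' Exponential-average rules: T(s, a, x) moves toward the indicator of the
#' observed successor for every candidate successor x, and R(s, a) moves
#' toward the observed reward, both at rate alpha.
#'
#' @param m an `mb_model`.
#' @param s,a,s_next observed transition (state, action, successor ids).
#' @param r observed reward.
#' @return the updated `mb_model` (Q/A not yet refreshed; see [mb_plan()]).
#' @export
mb_update <- function(m, s, a, s_next, r) {
  si <- match(s, m$tab$state_ids); ai <- match(a, ACTIONS)
  ni <- match(s_next, m$tab$state_ids)
  if (!isTRUE(m$tab$legal[si, ai])) stop("illegal transition in mb_update")
  ind <- numeric(m$tab$n_states); ind[ni] <- 1
  m$T[si, ai, ] <- m$T[si, ai, ] + m$params$alpha * (ind - m$T[si, ai, ])
  m$R[si, ai] <- m$R[si, ai] + m$params$alpha * (r - m$R[si, ai])
  m
}

#' Plan action values on the learned model
#'
#' Solves Q(s, a) = R(s, a) + gamma * sum_s' T(s, a, s') max_a' Q(s', a') to
#' a fixed point by synchronous value iteration (terminal states contribute
#' zero future value), then refreshes the advantage A(s, a) =
#' Q(s, a) - max_a' Q(s, a'). On the acyclic default task the iteration
#' converges in a handful of sweeps.
#'
#' @param m an `mb_model`.
#' @param tol convergence tolerance on the sup-norm of the Q change.
#' @param max_iter iteration cap; exceeding it is an error.
#' @return the `mb_model` with `Q` and `A` refreshed.
#' @export
mb_plan <- function(m, tol = 1e-13, max_iter = 500L) {
  tab <- m$tab
  gamma <- m$params$gamma
  Q <- m$Q
  for (it in seq_len(max_iter)) {
    maxq <- numeric(tab$n_states)
    for (s in seq_len(tab$n_states)) {
      if (tab$terminal[s] || !any(tab$legal[s, ])) next
      maxq[s] <- max(Q[s, tab$legal[s, ]])
    }
    delta <- 0
    for (s in seq_len(tab$n_states)) {
      for (a in seq_len(tab$n_actions)) {
        if (!tab$legal[s, a]) next
        q <- m$R[s, a] + gamma * sum(m$T[s, a, ] * maxq)
        delta <- max(delta, abs(q - Q[s, a]))
        Q[s, a] <- q
      }
    }
    if (delta < tol) break
    if (it == max_iter) stop("value iteration did not converge")
  }
  m$Q <- Q
  for (s in seq_len(tab$n_states)) {
    if (!any(tab$legal[s, ])) { m$A[s, ] <- 0; next }
    best <- max(Q[s, tab$legal[s, ]])
    m$A[s, ] <- ifelse(tab$legal[s, ], Q[s, ] - best, 0)
  }
  m
}

# ---------------------------------------------------------------------------
# Feature-Model-Free system: TD values attached to stimuli, not states.

#' Initialise the Feature-Model-Free learner
#'
#' The Feature-Model-Free system keeps one value per stimulus (`Lever`,
#' `Magazine`, `Food`; `None` is pinned at zero), shared across all states
#' in which the stimulus occurs. Values are revised by a reward prediction
#' error each time an action focuses on the stimulus, and the magazine value
#' is additionally depressed at each episode start by the inter-trial
#' interval mechanism (see [fmf_iti_decay()]).
#'
#' @param params a [learning_params()].
#' @param u ITI-decay fraction in [0, 1]: how strongly unrewarded magazine
#'   checks during the inter-trial interval revise the magazine value.
#' @param v0_magazine,v0_food initial values (pretraining familiarisation).
#' @return list of class `fmf_values` with member `V` (named over features).
#' @export
fmf_values <- function(params = learning_params(), u = 0.12,
                       v0_magazine = 0, v0_food = 0) {
  stopifnot(u >= 0, u <= 1)
  V <- c(None = 0, Lever = 0, Magazine = v0_magazine, Food = v0_food)
  structure(list(V = V, params = params, u = u), class = "fmf_values")
}

#' Compute the feature-level reward prediction error of a transition
#'
#' delta = r + gamma * max over legal a' in s_next of V(f(s_next, a')) -
#' V(f(s, a)), where f is the task's feature-function; a terminal successor
#' contributes zero future value. This is the model's dopamine analogue.
#'
#' @param v an `fmf_values`.
#' @param mdp the task.
#' @param s,a the transition taken.
#' @param r observed reward.
#' @param s_next observed successor.
#' @return list of class `rpe_event`: `delta`, `feature` (the focused
#'   stimulus whose value generated the error) and `event` tag.
#' @export
fmf_rpe <- function(v, mdp, s, a, r, s_next) {
  feat <- mdp_step(mdp, s, a)$feature
  term <- mdp$states$terminal[mdp$states$id == s_next]
  fut <- if (term) 0 else {
    nxt_feats <- vapply(actions_of(mdp, s_next),
                        function(a2) mdp_step(mdp, s_next, a2)$feature,
                        character(1))
    max(v$V[nxt_feats])
  }
  structure(list(delta = unname(r + v$params$gamma * fut - v$V[[feat]]),
                 feature = feat, event = event_tag(mdp, s, a)),
            class = "rpe_event")
}

#' Apply one feature-value update
#'
#' Only the focused feature is revised: V(f) <- V(f) + alpha * delta. The
#' `None` feature is never modified, so an undirected action leaves all
#' values untouched (and the CS-onset prediction error can persist).
#'
#' @param v an `fmf_values`.
#' @param e an `rpe_event` from [fmf_rpe()] (possibly drug-attenuated).
#' @return the updated `fmf_values`.
#' @export
fmf_update <- function(v, e) {
  if (e$feature != "None")
    v$V[[e$feature]] <- v$V[[e$feature]] + v$params$alpha * e$delta
  v
}

#' Inter-trial-interval revision of the magazine value
#'
#' Applied exactly once at the start of each episode:
#' V(Magazine) <- (1 - u) * V(Magazine). This stands in for the unrewarded
#' magazine checks the animal makes during the inter-trial interval, which
#' the episodic task graph does not model explicitly. u = 0 means no ITI
#' interaction (identity); u = 1 wipes the magazine value entirely.
#'
#' @param v an `fmf_values`.
#' @return the decayed `fmf_values`.
#' @export
fmf_iti_decay <- function(v) {
  v$V[["Magazine"]] <- (1 - v$u) * v$V[["Magazine"]]
  v
}

# ---------------------------------------------------------------------------
# Classical state-level Model-Free learner (used by model variants 1-4).

#' Initialise a classical state-level Model-Free learner
#'
#' Q-learning over (state, action) pairs with the same single-RPE structure
#' as the feature learner but no generalization across states. Used by the
#' model variants; on the deterministic task its Q values converge to the
#' same optimum as the Model-Based planner's.
#'
#' @param mdp the task.
#' @param params a [learning_params()].
#' @param q0 initial Q value for legal pairs.
#' @return list of class `mf_values` with members `Q` and `params`.
#' @export
mf_values <- function(mdp, params = learning_params(), q0 = 0) {
  tab <- mdp_tables(mdp)
  Q <- matrix(0, tab$n_states, tab$n_actions,
              dimnames = list(tab$state_ids, ACTIONS))
  Q[tab$legal] <- q0
  structure(list(Q = Q, params = params, tab = tab), class = "mf_values")
}

#' One Q-learning update
#'
#' delta = r + gamma * max_a' Q(s_next, a') - Q(s, a) (terminal successors
#' contribute zero), then Q(s, a) <- Q(s, a) + alpha * delta'. The caller
#' may attenuate delta (drug) between computing and applying it by using
#' `apply_delta`.
#'
#' @param m an `mf_values`.
#' @param s,a,r,s_next the observed transition.
#' @return list with `model` (updated learner) and `delta` (the raw RPE).
#' @export
mf_update <- function(m, s, a, r, s_next) {
  e <- mf_delta(m, s, a, r, s_next)
  list(model = mf_apply_delta(m, s, a, e), delta = e)
}

#' @rdname mf_update
#' @export
mf_delta <- function(m, s, a, r, s_next) {
  tab <- m$tab
  si <- match(s, tab$state_ids); ai <- match(a, ACTIONS)
  ni <- match(s_next, tab$state_ids)
  if (!isTRUE(tab$legal[si, ai])) stop("illegal transition in mf_update")
  fut <- if (tab$terminal[ni] || !any(tab$legal[ni, ])) 0 else
    max(m$Q[ni, tab$legal[ni, ]])
  unname(r + m$params$gamma * fut - m$Q[si, ai])
}

#' @param delta the (possibly attenuated) RPE to apply.
#' @rdname mf_update
#' @export
mf_apply_delta <- function(m, s, a, delta) {
  si <- match(s, m$tab$state_ids); ai <- match(a, ACTIONS)
  m$Q[si, ai] <- m$Q[si, ai] + m$params$alpha * delta
  m
}

# Advantage of a state-action Q table restricted to legal actions.
q_advantage <- function(Q, legal, s_index) {
  la <- legal[s_index, ]
  A <- numeric(length(la))
  if (any(la)) A[la] <- Q[s_index, la] - max(Q[s_index, la])
  A
}

# ---------------------------------------------------------------------------
# Integration of the two systems and action selection.

#' Integrate system outputs into decision values
#'
#' For the main model the integrated value of a legal action a in state s is
#' the convex combination P(s, a) = omega * V(f(s, a)) +
#' (1 - omega) * A_MB(s, a): the feature value acts as a motivational bonus
#' on top of the planner's advantage, and omega sets the balance (high omega
#' favours sign-tracking, low omega goal-tracking). Variants:
#' \describe{
#'   \item{v1}{feature values + Model-Free advantage (replaces the planner).}
#'   \item{v2}{Model-Free advantage + an omega-weighted bonus
#'     max_a' Q_MF(s, a') for lever-directed actions only (asymmetric
#'     Pavlovian impetus).}
#'   \item{v3}{as v2 but the bonus applies to both lever- and
#'     magazine-directed actions (symmetric impetus).}
#'   \item{v4}{omega * A_MF + (1 - omega) * A_MB: two state-level advantages,
#'     no feature values.}
#' }
#'
#' @param variant `"model"`, `"v1"`, `"v2"`, `"v3"` or `"v4"`.
#' @param omega integration weight in [0, 1].
#' @param mdp the task.
#' @param s state id.
#' @param fmf an `fmf_values` (variants `model`, `v1`).
#' @param mb an `mb_model` with fresh Q/A (variants `model`, `v4`).
#' @param mf an `mf_values` (variants `v1`-`v4`).
#' @return named numeric vector of integrated values over the legal actions
#'   of `s`.
#' @export
integrate_values <- function(variant, omega, mdp, s,
                             fmf = NULL, mb = NULL, mf = NULL) {
  stopifnot(omega >= 0, omega <= 1)
  tab <- mdp_tables(mdp)
  si <- match(s, tab$state_ids)
  la <- which(tab$legal[si, ])
  feats <- FEATURES[tab$feature[si, la]]
  Vf <- if (!is.null(fmf)) unname(fmf$V[feats]) else NULL
  P <- switch(variant,
    model = omega * Vf + (1 - omega) * mb$A[si, la],
    v1 = omega * Vf + (1 - omega) * q_advantage(mf$Q, tab$legal, si)[la],
    v2 = ,
    v3 = {
      A <- q_advantage(mf$Q, tab$legal, si)[la]
      bonus_feats <- if (variant == "v2") "Lever" else c("Lever", "Magazine")
      maxq <- max(mf$Q[si, la])
      (1 - omega) * A + omega * ifelse(feats %in% bonus_feats, maxq, 0)
    },
    v4 = omega * q_advantage(mf$Q, tab$legal, si)[la] +
         (1 - omega) * mb$A[si, la],
    stop("unknown variant '", variant, "'"))
  stats::setNames(as.numeric(P), ACTIONS[la])
}

#' Softmax action probabilities
#'
#' prob(a) is proportional to exp(P(a) / beta) over the legal actions. A high
#' temperature beta makes all actions equiprobable; a low one makes the
#' highest-valued action almost exclusive.
#'
#' @param P named numeric vector of integrated values over legal actions.
#' @param beta selection temperature (> 0).
#' @return named probability vector summing to one.
#' @export
softmax_policy <- function(P, beta) {
  stopifnot(beta > 0, length(P) >= 1)
  w <- exp((P - max(P)) / beta)
  w / sum(w)
}

#' Sample an action from a probability vector
#'
#' Consumes exactly one uniform draw from the current RNG stream, so runs
#' are reproducible given a seed and the two simulation engines stay in
#' lockstep.
#'
#' @param probs named probability vector (from [softmax_policy()]).
#' @param u optional uniform variate; drawn from the RNG if missing.
#' @return the sampled action name.
#' @export
sample_action <- function(probs, u = stats::runif(1)) {
  i <- findInterval(u, cumsum(probs), left.open = TRUE) + 1L
  names(probs)[min(i, length(probs))]
}
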