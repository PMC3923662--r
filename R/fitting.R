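#' Genetic-algorithm settings for the NSGA-II fitter
#'
#' Defaults follow the published fitting procedure (population 200, 1000
#' generations, polynomial mutation at rate 0.1, simulated binary crossover
#' at rate 0.5); tests and recovery checks use reduced budgets.
#'
#' @param pop_size population size (even).
#' @param generations number of generations.
#' @param p_mut per-gene polynomial-mutation probability.
#' @param p_cross per-pair simulated-binary-crossover probability.
#' @param eta_c,eta_m SBX / mutation distribution indices.
#' @param reps simulated agents per candidate evaluation (default 14,
#'   matching the group size).
#' @return list of class `ga_config`.
#' @export
ga_config <- function(pop_size = 200, generations = 1000, p_mut = 0.1,
                      p_cross = 0.5, eta_c = 15, eta_m = 20, reps = 14) {
  stopifnot(pop_size >= 4, pop_size %% 2 == 0, generations >= 1,
            p_mut >= 0, p_mut <= 1, p_cross >= 0, p_cross <= 1, reps >= 1)
  structure(list(pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 p_mut = p_mut, p_cross = p_cross,
                 eta_c = eta_c, eta_m = eta_m, reps = as.integer(reps)),
            class = "ga_config")
}

#' Default box bounds for fitted parameters
#'
#' Rates, weights and initial values are bounded in [0, 1] (initial values
#' in [0, r_food] with the default unit reward), the temperature in
#' (0.01, 2].
#'
#' @return named list of `c(lower, upper)` pairs.
#' @export
default_param_bounds <- function() {
  list(omega = c(0, 1), alpha = c(0.005, 1), gamma = c(0, 0.99),
       beta = c(0.01, 2), u = c(0, 1), v0_magazine = c(0, 1),
       v0_food = c(0, 1), q0 = c(0, 1))
}

set_params <- function(template, names, values) {
  for (i in seq_along(names)) template[[names[i]]] <- values[i]
  validate <- agent_config
  do.call(validate, unclass(template))
}

#' Least-squares objectives of a candidate against target curves
#'
#' Simulates `reps` agents with the candidate configuration, averages their
#' per-block lever and magazine engagement curves, and returns the sum of
#' squared per-block differences to the target, separately per stimulus
#' (lever and magazine engagement are independent objectives).
#'
#' @param config candidate [agent_config()].
#' @param target a `target_curves` object (see [make_target()]).
#' @param schedule training schedule; must produce curves of the target's
#'   length.
#' @param reps number of simulated agents averaged per evaluation.
#' @param seeds optional integer vector of length `reps` fixing the agents'
#'   streams (common random numbers across candidates keep the fitter
#'   deterministic).
#' @return named numeric `c(lever, magazine)` of least-squares errors.
#' @export
engagement_objectives <- function(config, target, schedule = schedule_spec(),
                                  reps = 14, seeds = NULL) {
  if (is.null(seeds)) seeds <- seq_len(reps) + 1000L
  stopifnot(length(seeds) == reps)
  n_trials <- schedule$n_sessions * schedule$trials_per_session
  n_blocks <- ceiling(n_trials / target$block_size)
  if (n_blocks != length(target$lever))
    stop("schedule produces ", n_blocks, " blocks but target has ",
         length(target$lever))
  lever <- matrix(0, reps, n_blocks); mag <- matrix(0, reps, n_blocks)
  for (j in seq_len(reps)) {
    log <- run_agent(config, schedule, seed = seeds[j], record = FALSE)
    s <- summarize_agent(log, target$block_size)
    lever[j, ] <- s$lever_blocks; mag[j, ] <- s$mag_blocks
  }
  c(lever = sum((colMeans(lever) - target$lever)^2),
    magazine = sum((colMeans(mag) - target$magazine)^2))
}

# --- NSGA-II machinery -----------------------------------------------------

dominates <- function(a, b) all(a <= b) && any(a < b)

fast_nondominated_sort <- function(obj) {
  n <- nrow(obj)
  dominated_by <- vector("list", n)
  n_dom <- integer(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (dominates(obj[i, ], obj[j, ]))
        dominated_by[[i]] <- c(dominated_by[[i]], j)
      else if (dominates(obj[j, ], obj[i, ]))
        n_dom[i] <- n_dom[i] + 1L
    }
  }
  fronts <- list()
  current <- which(n_dom == 0L)
  while (length(current)) {
    fronts[[length(fronts) + 1L]] <- current
    nxt <- integer(0)
    for (i in current) {
      for (j in dominated_by[[i]]) {
        n_dom[j] <- n_dom[j] - 1L
        if (n_dom[j] == 0L) nxt <- c(nxt, j)
      }
    }
    current <- nxt
  }
  fronts
}

crowding_distance <- function(obj) {
  n <- nrow(obj)
  d <- numeric(n)
  for (m in seq_len(ncol(obj))) {
    o <- order(obj[, m])
    rng <- obj[o[n], m] - obj[o[1], m]
    d[o[1]] <- d[o[n]] <- Inf
    if (n > 2 && rng > 0)
      for (k in 2:(n - 1))
        d[o[k]] <- d[o[k]] + (obj[o[k + 1], m] - obj[o[k - 1], m]) / rng
  }
  d
}

tournament_pick <- function(rank, crowd) {
  n <- length(rank)
  i <- sample.int(n, 1); j <- sample.int(n, 1)
  if (rank[i] < rank[j]) return(i)
  if (rank[j] < rank[i]) return(j)
  if (crowd[i] >= crowd[j]) i else j
}

sbx_crossover <- function(p1, p2, lo, hi, eta, p_cross) {
  c1 <- p1; c2 <- p2
  if (stats::runif(1) <= p_cross) {
    for (k in seq_along(p1)) {
      if (stats::runif(1) > 0.5 || abs(p1[k] - p2[k]) < 1e-14) next
      u <- stats::runif(1)
      beta <- if (u <= 0.5) (2 * u)^(1 / (eta + 1)) else
        (1 / (2 * (1 - u)))^(1 / (eta + 1))
      x1 <- 0.5 * ((1 + beta) * p1[k] + (1 - beta) * p2[k])
      x2 <- 0.5 * ((1 - beta) * p1[k] + (1 + beta) * p2[k])
      c1[k] <- min(max(x1, lo[k]), hi[k])
      c2[k] <- min(max(x2, lo[k]), hi[k])
    }
  }
  rbind(c1, c2)
}

poly_mutate <- function(x, lo, hi, eta, p_mut) {
  for (k in seq_along(x)) {
    if (stats::runif(1) > p_mut) next
    u <- stats::runif(1)
    delta <- if (u < 0.5) (2 * u)^(1 / (eta + 1)) - 1 else
      1 - (2 * (1 - u))^(1 / (eta + 1))
    x[k] <- min(max(x[k] + delta * (hi[k] - lo[k]), lo[k]), hi[k])
  }
  x
}

# Evaluate candidates without disturbing the caller's RNG stream (each
# candidate evaluation reseeds per-agent streams).
evaluate_population <- function(pop, param_names, template, target, schedule,
                                reps, seeds) {
  saved <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", saved, envir = globalenv()))
  t(apply(pop, 1, function(x) {
    cfg <- set_params(template, param_names, x)
    engagement_objectives(cfg, target, schedule, reps, seeds)
  }))
}

#' Fit agent parameters to target engagement curves with NSGA-II
#'
#' Two-objective least-squares fit (lever curve, magazine curve) by the
#' elitist non-dominated-sorting genetic algorithm: binary tournament
#' selection on (rank, crowding distance), simulated binary crossover,
#' polynomial mutation, and elitist environmental selection by front and
#' crowding. Candidate evaluations are stochastic simulations; evaluation
#' streams are common to all candidates within a generation and re-drawn
#' between generations (with parents re-evaluated), so the fit is
#' deterministic given `seed` while survival averages over simulation
#' noise. The representative individual is chosen
#' automatically from the final front as the one minimising the sum of
#' min-max-normalised objectives.
#'
#' @param target a `target_curves` object.
#' @param param_names names of the parameters to fit (subset of
#'   [default_param_bounds()]).
#' @param ga a [ga_config()].
#' @param template base [agent_config()] providing all unfitted parameters.
#' @param bounds named list of `c(lower, upper)` per fitted parameter.
#' @param schedule training schedule used for candidate simulations.
#' @param seed seed for the genetic algorithm and the evaluation streams.
#' @return list of class `fit_result`: `front` (data.frame of non-dominated
#'   parameter vectors and objective pairs), `representative` (named list
#'   with config and objectives), `diagnostics` (per-generation best summed
#'   objective).
#' @export
fit_nsga2 <- function(target, param_names = "omega", ga = ga_config(),
                      template = agent_config(),
                      bounds = default_param_bounds(),
                      schedule = schedule_spec(), seed = 1L) {
  stopifnot(all(param_names %in% names(bounds)))
  lo <- vapply(bounds[param_names], `[`, numeric(1), 1)
  hi <- vapply(bounds[param_names], `[`, numeric(1), 2)
  stopifnot(all(is.finite(lo)), all(is.finite(hi)), all(lo < hi))
  npar <- length(param_names)
  # evaluation streams are fixed per generation: within a generation every
  # candidate sees the same simulated agents (common random numbers), and
  # re-drawing them each generation prevents elites from locking onto one
  # lucky noise realization of the stochastic objectives
  gen_seeds <- function(gen) vapply(seq_len(ga$reps), function(j)
    agent_seed(agent_seed(seed, gen), j + 7L), integer(1))
  set.seed(as.integer(seed))
  pop <- matrix(stats::runif(ga$pop_size * npar, lo, hi),
                ga$pop_size, npar, byrow = TRUE)
  obj <- evaluate_population(pop, param_names, template, target, schedule,
                             ga$reps, gen_seeds(0L))
  diag_best <- numeric(ga$generations)
  for (gen in seq_len(ga$generations)) {
    fronts <- fast_nondominated_sort(obj)
    rank <- integer(nrow(pop))
    for (fi in seq_along(fronts)) rank[fronts[[fi]]] <- fi
    crowd <- numeric(nrow(pop))
    for (f in fronts) crowd[f] <- crowding_distance(obj[f, , drop = FALSE])
    children <- matrix(0, ga$pop_size, npar)
    for (k in seq_len(ga$pop_size / 2)) {
      p1 <- pop[tournament_pick(rank, crowd), ]
      p2 <- pop[tournament_pick(rank, crowd), ]
      cc <- sbx_crossover(p1, p2, lo, hi, ga$eta_c, ga$p_cross)
      children[2 * k - 1, ] <- poly_mutate(cc[1, ], lo, hi, ga$eta_m, ga$p_mut)
      children[2 * k, ] <- poly_mutate(cc[2, ], lo, hi, ga$eta_m, ga$p_mut)
    }
    seeds_g <- gen_seeds(gen)
    all_pop <- rbind(pop, children)
    # parents are re-evaluated on the generation's fresh streams alongside
    # their children, so survival reflects average rather than lucky fitness
    all_obj <- evaluate_population(all_pop, param_names, template, target,
                                   schedule, ga$reps, seeds_g)
    fronts <- fast_nondominated_sort(all_obj)
    sel <- integer(0)
    for (f in fronts) {
      if (length(sel) + length(f) <= ga$pop_size) {
        sel <- c(sel, f)
      } else {
        cd <- crowding_distance(all_obj[f, , drop = FALSE])
        sel <- c(sel, f[order(cd, decreasing = TRUE)[
          seq_len(ga$pop_size - length(sel))]])
        break
      }
    }
    pop <- all_pop[sel, , drop = FALSE]
    obj <- all_obj[sel, , drop = FALSE]
    diag_best[gen] <- min(rowSums(obj))
  }
  front_idx <- fast_nondominated_sort(obj)[[1]]
  front_pop <- pop[front_idx, , drop = FALSE]
  front_obj <- obj[front_idx, , drop = FALSE]
  # representative: min sum of min-max normalised objectives
  norm <- apply(front_obj, 2, function(o) {
    r <- max(o) - min(o)
    if (r > 0) (o - min(o)) / r else o * 0
  })
  if (is.null(dim(norm))) norm <- matrix(norm, nrow = 1)
  rep_i <- which.min(rowSums(norm))
  front <- data.frame(front_pop, front_obj)
  names(front) <- c(param_names, "obj_lever", "obj_magazine")
  representative <- list(
    params = stats::setNames(as.numeric(front_pop[rep_i, ]), param_names),
    config = set_params(template, param_names, front_pop[rep_i, ]),
    objectives = stats::setNames(as.numeric(front_obj[rep_i, ]),
                                 c("lever", "magazine")))
  structure(list(front = front, representative = representative,
                 diagnostics = data.frame(generation = seq_len(ga$generations),
                                          best_sum = diag_best),
                 param_names = param_names, ga = ga, seed = seed),
            class = "fit_result")
}

#' Parameter-recovery report
#'
#' Tabulates recovered-versus-true values for each fitted parameter of a
#' synthetic-target fit: the representative's estimate, its bias, and the
#' range the parameter spans on the Pareto front.
#'
#' @param true_params named numeric vector of generating values.
#' @param fit a [fit_nsga2()] result.
#' @return data.frame with one row per fitted parameter.
#' @export
recovery_report <- function(true_params, fit) {
  stopifnot(all(fit$param_names %in% names(true_params)))
  do.call(rbind, lapply(fit$param_names, function(p) {
    est <- fit$representative$params[[p]]
    data.frame(parameter = p, true = unname(true_params[[p]]),
               recovered = est, bias = est - unname(true_params[[p]]),
               front_min = min(fit$front[[p]]),
               front_max = max(fit$front[[p]]))
  }))
}
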