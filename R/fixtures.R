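#' Generate a synthetic target from a known configuration
#'
#' Simulates a group of agents at a known (generating) configuration,
#' averages their per-block lever and magazine engagement curves, and
#' optionally adds truncated Gaussian noise per block. The generating truth
#' is attached for parameter-recovery experiments. These curves stand in
#' for behavioural engagement data in fitting tests.
#'
#' @param config generating [agent_config()].
#' @param schedule training schedule.
#' @param n_agents agents averaged into the curves (default 14).
#' @param noise_sd per-block Gaussian noise standard deviation (>= 0);
#'   noisy curves are truncated to [0, 1].
#' @param seed seed for the simulations and the noise.
#' @param block_size trials per block.
#' @return list of class `target_curves`: `lever`, `magazine`,
#'   `block_size`, and `truth` (generating config and seed).
#' @export
make_target <- function(config = agent_config(omega = 0.8),
                        schedule = schedule_spec(), n_agents = 14,
                        noise_sd = 0, seed = 1L, block_size = 50) {
  stopifnot(noise_sd >= 0)
  res <- run_autoshaping(group_spec("gen", config, n_agents), schedule,
                         seed = seed, block_size = block_size,
                         record = FALSE)
  eng <- res$engagement
  lever <- eng$probability[eng$stimulus == "lever"]
  mag <- eng$probability[eng$stimulus == "magazine"]
  if (noise_sd > 0) {
    set.seed(as.integer(seed) + 1L)
    lever <- pmin(1, pmax(0, lever + stats::rnorm(length(lever), 0, noise_sd)))
    mag <- pmin(1, pmax(0, mag + stats::rnorm(length(mag), 0, noise_sd)))
  }
  structure(list(lever = as.numeric(lever), magazine = as.numeric(mag),
                 block_size = block_size,
                 truth = list(config = config, seed = seed,
                              n_agents = n_agents, noise_sd = noise_sd)),
            class = "target_curves")
}

#' Stylised phenotype-shaped target curves
#'
#' Model-free smoke targets for end-to-end fitting tests: a logistic rising
#' curve for the phenotype's favoured stimulus and a matching decaying curve
#' for the other, without trusting the simulator under test. The
#' sign-tracker and goal-tracker shapes are mirror assignments of the same
#' two curves.
#'
#' @param phenotype `"ST"` (lever rises) or `"GT"` (magazine rises).
#' @param n_blocks number of 50-trial blocks (>= 2).
#' @param block_size trials per block.
#' @return a `target_curves` object.
#' @export
make_shape_target <- function(phenotype = c("ST", "GT"), n_blocks = 4,
                              block_size = 50) {
  phenotype <- match.arg(phenotype)
  stopifnot(n_blocks >= 2)
  x <- seq(-2.5, 2.5, length.out = n_blocks)
  rising <- 0.05 + 0.85 * stats::plogis(x)
  decaying <- 0.05 + 0.85 * stats::plogis(-x)
  structure(list(
    lever = if (phenotype == "ST") rising else decaying,
    magazine = if (phenotype == "ST") decaying else rising,
    block_size = block_size,
    truth = list(phenotype = phenotype)),
    class = "target_curves")
}

#' Write or read target curves as CSV
#'
#' One row per block with the declared block size.
#'
#' @param target a `target_curves` object.
#' @param path file path.
#' @return `read_target` returns the `target_curves`; `write_target`
#'   returns `path` invisibly.
#' @export
write_target <- function(target, path) {
  df <- data.frame(block = seq_along(target$lever), lever = target$lever,
                   magazine = target$magazine,
                   block_size = target$block_size)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_target
#' @export
read_target <- function(path) {
  df <- utils::read.csv(path)
  needed <- c("block", "lever", "magazine", "block_size")
  if (!all(needed %in% names(df)))
    stop("target CSV must have columns: ", paste(needed, collapse = ", "))
  structure(list(lever = df$lever, magazine = df$magazine,
                 block_size = df$block_size[1], truth = NULL),
            class = "target_curves")
}
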