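#' Configuration for an informed-walk run
#'
#' Defaults reproduce the published run: 300 restarts (independent walkers)
#' of 1000 iterations each, a 70% probability of taking the informed pathway
#' branch, and Levy-flight constraints derived from the network size N -
#' flights are triggered when the sampled step length reaches `ceil(ln N)`
#' and are capped at `ceil(sqrt(N))` steps. N-dependent fields left `NULL`
#' are resolved against the network at run time.
#'
#' @param n_walkers Number of independent walkers (restarts).
#' @param n_iterations Iterations (movement rounds) per walker.
#' @param p_informed Probability of the informed pathway-transition branch;
#'   the complementary branch samples uniformly over all pathways.
#' @param levy_exponent Power-law exponent mu (> 1) of the discrete step-length
#'   distribution `P(s) proportional to s^-mu`.
#' @param levy_trigger Minimum sampled step length that actually triggers a
#'   flight; smaller samples are no-ops. Default `ceil(ln N)`.
#' @param levy_max_steps Support cap of the step-length distribution.
#'   Default `ceil(sqrt(N))`.
#' @param distance_mode `"inverse_weight"` (edge length 1/w: strong
#'   association = short distance; default) or `"hop_count"` (unit lengths).
#' @param seed Integer seed; one independent RNG stream is derived per walker,
#'   so results are invariant to walker execution order.
#' @return A list of class `walk_config`.
#' @export
walk_config <- function(n_walkers = 300, n_iterations = 1000, p_informed = 0.7,
                        levy_exponent = 2, levy_trigger = NULL,
                        levy_max_steps = NULL,
                        distance_mode = c("inverse_weight", "hop_count"),
                        seed = 1) {
  distance_mode <- match.arg(distance_mode)
  if (n_walkers < 1 || n_iterations < 0) {
    abort("n_walkers must be >= 1 and n_iterations >= 0")
  }
  if (p_informed < 0 || p_informed > 1) abort("p_informed must lie in [0, 1]")
  if (levy_exponent <= 1) abort("levy_exponent must exceed 1")
  if (!is.null(levy_trigger) && levy_trigger < 1) {
    abort("levy_trigger must be a positive integer")
  }
  if (!is.null(levy_max_steps) && levy_max_steps < 1) {
    abort("levy_max_steps must be a positive integer")
  }
  structure(list(n_walkers = as.integer(n_walkers),
                 n_iterations = as.integer(n_iterations),
                 p_informed = p_informed,
                 levy_exponent = levy_exponent,
                 levy_trigger = levy_trigger,
                 levy_max_steps = levy_max_steps,
                 distance_mode = distance_mode,
                 seed = as.integer(seed)),
            class = "walk_config")
}

# fill N-dependent defaults against a concrete network
resolve_walk_config <- function(cfg, n_nodes) {
  cfg$levy_trigger <- as.integer(cfg$levy_trigger %||%
                                   max(1, ceiling(log(n_nodes))))
  cfg$levy_max_steps <- as.integer(cfg$levy_max_steps %||%
                                     max(1, ceiling(sqrt(n_nodes))))
  cfg
}
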