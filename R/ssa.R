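#' Simulate one exact stochastic trajectory
#'
#' Statistically exact sample of the continuous-time Markov jump process
#' defined by the network's propensities and integer stoichiometry
#' (direct-method stochastic simulation in compiled code). The state is
#' recorded at each requested time as the value holding immediately
#' before/at that time. Propensities are evaluated from the rate laws as
#' written; a reaction whose firing would drive any copy number negative
#' contributes zero propensity, so sampled states never go negative. When
#' all propensities vanish the state is frozen to the final time.
#'
#' @inheritParams validate_parameters
#' @param init named nonnegative integer initial state (defaults to the
#'   network's initial state).
#' @param times strictly increasing nonnegative measurement times
#'   (minutes); time 0 records the initial state.
#' @param seed integer seed of the trajectory's private RNG stream (does
#'   not touch R's RNG).
#' @return Matrix (time x species) with the times as rownames, of class
#'   `ssa_trajectory` with attributes `times` and `seed`.
#' @examples
#' net <- constitutive_model()
#' x <- simulate_trajectory(net, net$nominal, times = c(50, 100, 200),
#'                          seed = 1)
#' @export
simulate_trajectory <- function(network, params, init = NULL, times,
                                seed) {
  p <- validate_parameters(network, params)
  if (is.null(init)) init <- network$initial_state
  init <- resolve_state(network, init)
  if (any(init < 0) || any(init != round(init)))
    stop("init must be nonnegative integers", call. = FALSE)
  if (any(diff(times) <= 0) || any(times < 0))
    stop("times must be strictly increasing and nonnegative",
         call. = FALSE)
  m <- .simulate_trajectory_cpp(network$cxx, as.numeric(p), init,
                                as.numeric(times), as.double(seed))
  dimnames(m) <- list(times, network$species)
  structure(m, times = as.numeric(times), seed = seed,
            class = c("ssa_trajectory", class(m)))
}

#' Simulate an ensemble of stochastic trajectories
#'
#' `ns` independent trajectories sharing times and initial state. Member
#' `j` runs on an RNG stream derived deterministically from
#' `(base_seed, j)`, so the ensemble is reproducible and the first `ns`
#' members of a larger ensemble with the same base seed are identical.
#'
#' @inheritParams simulate_trajectory
#' @param ns number of trajectories (>= 1).
#' @param base_seed integer seed from which member streams are derived.
#' @return Object of class `ssa_ensemble`: 3-d array
#'   (time x species x member) with `times`, `base_seed` attributes.
#' @export
simulate_ensemble <- function(network, params, init = NULL, times, ns,
                              base_seed) {
  p <- validate_parameters(network, params)
  if (is.null(init)) init <- network$initial_state
  init <- resolve_state(network, init)
  if (any(init < 0) || any(init != round(init)))
    stop("init must be nonnegative integers", call. = FALSE)
  if (any(diff(times) <= 0) || any(times < 0))
    stop("times must be strictly increasing and nonnegative",
         call. = FALSE)
  if (ns < 1L) stop("ns must be >= 1", call. = FALSE)
  a <- .simulate_ensemble_cpp(network$cxx, as.numeric(p), init,
                              as.numeric(times), as.integer(ns),
                              as.double(base_seed))
  dimnames(a) <- list(times, network$species, NULL)
  structure(a, times = as.numeric(times), base_seed = base_seed,
            class = c("ssa_ensemble", class(a)))
}

#' Observable values of an ensemble, per time point
#'
#' Maps every ensemble member through the observation map
#' (`phi * sum(observable species)`), yielding one list of single-cell
#' observable values per measurement time -- the simulated counterpart of
#' a flow-cytometry event table.
#'
#' @param ensemble an `ssa_ensemble`.
#' @param network the network it was simulated from.
#' @param observable,phi optional overrides of the network's observation
#'   map.
#' @return An [event_table()].
#' @export
apply_observation <- function(ensemble, network,
                              observable = network$observable,
                              phi = network$phi) {
  vals <- observe(network, unclass(ensemble), observable = observable,
                  phi = phi)
  times <- attr(ensemble, "times")
  event_table(times, lapply(seq_along(times), function(i) vals[i, ]))
}

#' Write a trajectory as CSV
#'
#' One row per sampled time, one column per species, for external
#' plotting.
#'
#' @param trajectory an `ssa_trajectory`.
#' @param path output file path.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  df <- data.frame(time = attr(trajectory, "times"),
                   unclass(trajectory)[, , drop = FALSE],
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
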