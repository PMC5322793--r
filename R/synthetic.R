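#' Generate an in-silico single-cell dataset by stochastic simulation
#'
#' Runs an ensemble at known ("true") parameters and maps it through the
#' observation map, producing the event table of a simulated validation
#' experiment. Defaults reproduce the constitutive-circuit setting:
#' `theta = (5, 0.03, 0.1, 0.03)`, both species starting at zero, 10000
#' repetitions observed at 50, 100, 150 and 200 minutes; the final-time
#' protein distribution then has its mode near 543 a.u.
#'
#' @param network a [reaction_network()] (default [constitutive_model()]).
#' @param params true parameter values (default: the network's nominal
#'   set).
#' @param n_runs number of single-cell trajectories (>= 100).
#' @param times measurement times in minutes.
#' @param init initial state (default: network default).
#' @param seed ensemble base seed.
#' @return An [event_table()] with `nm = n_runs` at every time point.
#' @export
generate_insilico_data <- function(network = constitutive_model(),
                                   params = network$nominal,
                                   n_runs = 10000L,
                                   times = c(50, 100, 150, 200),
                                   init = NULL, seed = 1L) {
  if (n_runs < 100L) stop("n_runs must be >= 100", call. = FALSE)
  ens <- simulate_ensemble(network, params, init = init, times = times,
                           ns = n_runs, base_seed = seed)
  apply_observation(ens, network)
}

#' Surrogate flow-cytometry specification
#'
#' Parametric stand-in for a time-resolved flow-cytometry experiment on
#' a bistable gene-expression system: at each measurement time the
#' single-cell intensities are drawn from a two-component log-normal
#' mixture whose high-expression weight rises logistically in time
#' (switch-like population transition), while the component locations
#' stay at the basal and induced expression levels. The `locations` are
#' modal intensities (the histogram peak of each component), which is
#' the quantity the mode-matching precondition consumes; with location
#' `m` and log-dispersion `sdlog` the underlying log-normal has
#' `meanlog = log(m) + sdlog^2`.
#'
#' @param times measurement times (minutes).
#' @param nm cells per time point (>= 100).
#' @param locations modal intensities (a.u.) of the mixture components,
#'   ascending; defaults 77 and 1000, the basal/induced modes of the
#'   IRF7 response at 48 h.
#' @param sdlog log-scale dispersion of each component.
#' @param final_weight weight of the high component at the last time.
#' @param midpoint,scale logistic midpoint and time scale (minutes) of
#'   the weight trajectory.
#' @param weights optional explicit per-time weights of the high
#'   component, overriding the logistic trajectory.
#' @param seed RNG seed.
#' @return An object of class `surrogate_spec`.
#' @export
surrogate_spec <- function(times = c(0, 240, 480, 960, 1440, 2880),
                           nm = 10000L, locations = c(77, 1000),
                           sdlog = 0.35, final_weight = 0.5,
                           midpoint = 1000, scale = 250, weights = NULL,
                           seed = 1L) {
  if (nm < 100L) stop("nm must be >= 100", call. = FALSE)
  if (any(locations <= 0)) stop("locations must be positive",
                                call. = FALSE)
  if (is.unsorted(locations))
    stop("locations must be ascending", call. = FALSE)
  if (!is.null(weights)) {
    stopifnot(length(weights) == length(times), all(weights >= 0),
              all(weights <= 1))
  }
  structure(list(times = times, nm = as.integer(nm),
                 locations = locations, sdlog = sdlog,
                 final_weight = final_weight, midpoint = midpoint,
                 scale = scale, weights = weights, seed = seed),
            class = "surrogate_spec")
}

# weight of the high component at time t, normalized to hit final_weight
# exactly at the last measurement time
surrogate_weights <- function(spec) {
  w <- 1 / (1 + exp(-(spec$times - spec$midpoint) / spec$scale))
  spec$final_weight * w / w[length(w)]
}

#' Generate a surrogate flow-cytometry event table
#'
#' Draws the two-component log-normal mixture defined by a
#' [surrogate_spec()]. With the default specification the final-time
#' distribution is bimodal with modes recovered near 77 and 1000 a.u.
#' and early time points dominated by the basal component. A
#' single-location specification yields unimodal data.
#'
#' @param spec a [surrogate_spec()].
#' @return An [event_table()].
#' @export
generate_flow_surrogate <- function(spec = surrogate_spec()) {
  q <- length(spec$locations)
  meanlog <- log(spec$locations) + spec$sdlog^2
  w_high <- if (!is.null(spec$weights)) spec$weights
            else if (q == 2L) surrogate_weights(spec)
            else rep(0, length(spec$times))
  with_seed(spec$seed, {
    vals <- lapply(seq_along(spec$times), function(i) {
      if (q == 1L) {
        v <- stats::rlnorm(spec$nm, meanlog, spec$sdlog)
      } else {
        hi <- stats::runif(spec$nm) < w_high[i]
        v <- stats::rlnorm(spec$nm, meanlog[1 + hi], spec$sdlog)
      }
      v
    })
    event_table(spec$times, vals)
  })
}
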