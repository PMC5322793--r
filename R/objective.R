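#' Fitting configuration
#'
#' Bundles everything an objective evaluation needs besides the candidate
#' parameters: the stochastic repetition count, the precondition band,
#' the binning policy and the initial state.
#'
#' @param ns stochastic repetitions per accepted candidate (default 1000,
#'   the validated repetition count for these models).
#' @param precondition a [precondition_config()].
#' @param L bin count; `NULL` applies the square-root rule to the
#'   measured sample size and reuses that `L` for the simulated PDFs
#'   regardless of `ns`.
#' @param init initial state for the simulations; `NULL` uses the
#'   network default.
#' @param find_modes_args list of overrides for [find_modes()].
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(ns = 1000L, precondition = precondition_config(),
                       L = NULL, init = NULL, find_modes_args = list()) {
  stopifnot(ns >= 1L)
  structure(list(ns = as.integer(ns), precondition = precondition, L = L,
                 init = init, find_modes_args = find_modes_args),
            class = "fit_config")
}

# Reference binning of the measured data: edges and L are computed once
# from the experimental events and reused for every simulated PDF.
reference_binning <- function(data, config) {
  L <- if (is.null(config$L)) bin_count(min(data$nm)) else config$L
  pe <- build_distributions(data, L = L)
  list(L = L, pe = pe, edges = lapply(pe$bins, `[[`, "edges"))
}

#' Conditional objective: precondition, then distribution distance
#'
#' The workhorse of the fitting loop. For a candidate parameter set it
#' (1) locates the ODE steady states and their stability, (2) tests the
#' deterministic precondition against the measured modes, and only if
#' that passes (3) runs the stochastic ensemble, maps it through the
#' observation map, bins it on the measured reference grid and returns
#' the squared-difference distance [objective_F()]. Rejected candidates
#' receive the finite penalty value without any stochastic simulation;
#' simulation failures are also penalized (with a diagnostic) rather
#' than raised, so optimization loops keep going.
#'
#' @inheritParams validate_parameters
#' @param data an [event_table()] of measured single-cell values.
#' @param modes ascending mode locations of the measured final-time
#'   distribution (numeric or [find_modes()] result).
#' @param config a [fit_config()].
#' @param seed integer seed for the ensemble of this evaluation.
#' @param binning internal: precomputed reference binning of `data`.
#' @return List with `value`, `precondition` (a `precondition_result`),
#'   and `diagnostics` (`n_ssa` trajectories run, `error` message or
#'   `NA`).
#' @export
objective_Fcond <- function(network, params, data, modes,
                            config = fit_config(), seed = 1L,
                            binning = NULL) {
  if (inherits(modes, "mode_set")) modes <- modes$location
  p <- validate_parameters(network, params)
  sss <- find_steady_states(network, p,
                            tolerances = config$precondition$tolerances)
  pre <- check_precondition(sss, modes, network, config$precondition)
  if (!pre$passed)
    return(list(value = config$precondition$penalty, precondition = pre,
                diagnostics = list(n_ssa = 0L, error = NA_character_)))
  if (is.null(binning)) binning <- reference_binning(data, config)
  res <- tryCatch({
    ens <- simulate_ensemble(network, p, init = config$init,
                             times = data$times, ns = config$ns,
                             base_seed = seed)
    sim <- apply_observation(ens, network)
    ps <- build_distributions(sim, L = binning$L, edges = binning$edges)
    list(value = objective_F(binning$pe, ps),
         diagnostics = list(n_ssa = config$ns, error = NA_character_))
  }, error = function(e)
    list(value = config$precondition$penalty,
         diagnostics = list(n_ssa = NA_integer_,
                            error = conditionMessage(e))))
  list(value = res$value, precondition = pre,
       diagnostics = res$diagnostics)
}
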