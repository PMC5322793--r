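#' ODE right-hand side of a reaction network
#'
#' Deterministic (mean-field) rate of change: stoichiometry matrix times
#' the propensity vector, with the rate laws evaluated as written on a
#' continuous state. Promoter occupancies are treated as continuous in
#' \eqn{[0,1]} in this regime.
#'
#' @inheritParams validate_parameters
#' @param state named or ordered numeric state (finite; may be
#'   non-integer).
#' @return Named numeric derivative vector.
#' @export
ode_rhs <- function(network, state, params) {
  st <- resolve_state(network, state)
  if (any(!is.finite(st))) stop("state must be finite", call. = FALSE)
  p <- validate_parameters(network, params)
  d <- .ode_rhs_cpp(network$cxx, st, as.numeric(p))
  names(d) <- network$species
  d
}

#' Jacobian of the ODE right-hand side
#'
#' Central finite differences with relative step `1e-6` (absolute floor 1
#' per component).
#'
#' @inheritParams ode_rhs
#' @return Square numeric matrix with species dimnames.
#' @export
ode_jacobian <- function(network, state, params) {
  st <- resolve_state(network, state)
  p <- validate_parameters(network, params)
  J <- .ode_jac_cpp(network$cxx, st, as.numeric(p))
  dimnames(J) <- list(network$species, network$species)
  J
}

#' Steady-state tolerances
#'
#' @param residual accept a root when the max-norm of the right-hand side
#'   falls below this value.
#' @param eigen a fixed point is stable when the maximal real part of its
#'   Jacobian eigenvalues is below `-eigen`; borderline (near-zero or
#'   oscillatory-marginal) points are not counted as stable.
#' @param dedup relative distance below which two roots are merged (an
#'   absolute floor of `1e-8` keeps genuinely distinct fixed points that
#'   sit close to the origin apart).
#' @param negative roots with a component below `-negative` are discarded
#'   as non-physical; smaller negative round-off is clamped to zero.
#' @return A list of tolerances.
#' @export
steady_state_tolerances <- function(residual = 1e-9, eigen = 1e-9,
                                    dedup = 1e-6, negative = 1e-8) {
  list(residual = residual, eigen = eigen, dedup = dedup,
       negative = negative)
}

# Fixed multi-start lattice: exact origin, all-ones, all-ones with each
# single species zeroed, the default initial state, and 20 seeded
# log-uniform states in [1e-3, 1e4].  Zero is special: absorbing boundaries
# (an unstimulated branch with a species exactly at 0) are Newton-invariant
# subspaces only reachable from starts lying in them, while autocatalytic
# species pull any positive start towards the stimulated branch.
default_starts <- function(network, n_random = 20L, seed = 20190901L) {
  nsp <- length(network$species)
  ones <- rep(1, nsp)
  zeroed <- t(vapply(seq_len(nsp), function(i) { v <- ones; v[i] <- 0; v },
                     numeric(nsp)))
  rand <- with_seed(seed, matrix(10^stats::runif(n_random * nsp, -3, 4),
                                 nrow = n_random))
  m <- rbind(rep(0, nsp), ones, zeroed, network$initial_state, rand)
  dimnames(m) <- NULL
  m
}

#' Locate the steady states of a network
#'
#' Multi-start damped Newton iteration on the ODE right-hand side. Each
#' start is iterated to a root (or discarded on stagnation), non-physical
#' roots (negative beyond tolerance) are dropped, duplicates are merged,
#' and every surviving fixed point is classified by the maximal real part
#' of its Jacobian eigenvalues.
#'
#' @inheritParams validate_parameters
#' @param starts matrix of start states (rows); default: a fixed lattice of
#'   origin, unit, zeroed-unit, default-initial and 20 seeded log-uniform
#'   states.
#' @param tolerances see [steady_state_tolerances()].
#' @return An object of class `steady_state_set`: list with `states`
#'   (matrix, one row per fixed point), `lambda_max`, `stable`, `residual`,
#'   and `n_stable`. An empty set (no converged root) is returned as such,
#'   not an error.
#' @examples
#' net <- constitutive_model()
#' find_steady_states(net, net$nominal)
#' @export
find_steady_states <- function(network, params, starts = NULL,
                               tolerances = steady_state_tolerances()) {
  p <- validate_parameters(network, params)
  if (is.null(starts)) starts <- default_starts(network)
  if (is.null(dim(starts))) starts <- matrix(starts, nrow = 1)
  if (nrow(starts) < 1L) stop("at least one start is required", call. = FALSE)
  res <- .newton_multistart_cpp(network$cxx, as.numeric(p), starts,
                                tolerances$residual, 200L)
  keep <- which(res$conv)
  states <- NULL
  resid <- numeric()
  for (i in keep) {
    x <- res$roots[i, ]
    if (any(x < -tolerances$negative)) next       # non-physical
    x[x < 0] <- 0
    # componentwise merge criterion: a whole-state norm would absorb a
    # genuinely distinct fixed point sitting near an absorbing boundary
    # (e.g. the unstimulated branch at species = 0) into a close-by root
    dup <- FALSE
    if (!is.null(states)) {
      for (r in seq_len(nrow(states))) {
        lim <- pmax(1e-8, tolerances$dedup * pmax(abs(x), abs(states[r, ])))
        if (all(abs(x - states[r, ]) <= lim)) { dup <- TRUE; break }
      }
    }
    if (!dup) {
      states <- rbind(states, x)
      resid <- c(resid, res$resid[i])
    }
  }
  if (is.null(states)) {
    out <- list(states = matrix(numeric(0), 0, length(network$species),
                                dimnames = list(NULL, network$species)),
                lambda_max = numeric(0), stable = logical(0),
                residual = numeric(0), n_stable = 0L,
                species = network$species)
    class(out) <- "steady_state_set"
    return(out)
  }
  colnames(states) <- network$species
  rownames(states) <- NULL
  lam <- vapply(seq_len(nrow(states)), function(r)
    .eig_max_real_cpp(network$cxx, states[r, ], as.numeric(p)), numeric(1))
  stable <- is.finite(lam) & lam < -tolerances$eigen
  ord <- order(lam)                             # most stable first
  out <- list(states = states[ord, , drop = FALSE], lambda_max = lam[ord],
              stable = stable[ord], residual = resid[ord],
              n_stable = sum(stable), species = network$species)
  class(out) <- "steady_state_set"
  out
}

#' Stability of a fixed point
#'
#' @inheritParams ode_rhs
#' @param state a converged fixed point.
#' @param tol_eig stability margin; stable means
#'   `lambda_max < -tol_eig`.
#' @return List with `lambda_max` and logical `stable`. A non-finite
#'   Jacobian yields `stable = FALSE` with `lambda_max = Inf`.
#' @export
classify_stability <- function(network, state, params, tol_eig = 1e-9) {
  st <- resolve_state(network, state)
  p <- validate_parameters(network, params)
  lam <- .eig_max_real_cpp(network$cxx, st, as.numeric(p))
  list(lambda_max = lam, stable = is.finite(lam) && lam < -tol_eig)
}

#' @export
print.steady_state_set <- function(x, digits = 4, ...) {
  cat(sprintf("Steady states: %d found, %d stable\n",
              nrow(x$states), x$n_stable))
  if (nrow(x$states)) {
    df <- as.data.frame(round(x$states, digits))
    df$lambda_max <- signif(x$lambda_max, 3)
    df$stable <- x$stable
    print(df, row.names = FALSE)
  }
  invisible(x)
}

#' Tabular/JSON steady-state report
#'
#' @param sss a `steady_state_set`.
#' @param network the network it came from (for the observation map).
#' @param path optional path; when given, the report is written as JSON.
#' @return A data frame (one row per fixed point, plus the mapped
#'   observable), invisibly when written.
#' @export
steady_state_report <- function(sss, network, path = NULL) {
  df <- as.data.frame(sss$states)
  df$observable <- if (nrow(df)) apply(sss$states, 1, function(s)
    observe(network, stats::setNames(s, network$species))) else numeric(0)
  df$lambda_max <- sss$lambda_max
  df$stable <- sss$stable
  if (!is.null(path)) {
    jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
    return(invisible(df))
  }
  df
}

#' Precondition configuration
#'
#' Acceptance band of the deterministic precondition: mode `k` of the
#' measured distribution must satisfy
#' `beta_low[k] * h(X*_k) <= alpha_k <= beta_up[k] * h(X*_k)` where
#' `h(X*_k)` is the k-th stable steady state mapped through the
#' observation map. The `penalty` is the finite stand-in for the
#' infinitely bad objective assigned to rejected candidates, chosen far
#' above any attainable distribution distance so optimizers can still
#' rank rejected candidates deterministically.
#'
#' @param beta_low,beta_up scalars or per-mode vectors with
#'   `0 <= beta_low <= 1 <= beta_up`.
#' @param penalty objective value for rejected candidates.
#' @param tolerances steady-state tolerances, see
#'   [steady_state_tolerances()].
#' @return An object of class `precondition_config`.
#' @export
precondition_config <- function(beta_low = 0.95, beta_up = 1.05,
                                penalty = 1e12,
                                tolerances = steady_state_tolerances()) {
  if (any(beta_low < 0) || any(beta_low > 1) || any(beta_up < 1))
    stop("need 0 <= beta_low <= 1 <= beta_up", call. = FALSE)
  structure(list(beta_low = beta_low, beta_up = beta_up, penalty = penalty,
                 tolerances = tolerances), class = "precondition_config")
}

#' Deterministic precondition test
#'
#' Checks whether the stable steady states of the ODE regime, mapped to
#' observation units, match the modes of the measured distribution: the
#' count of stable states must equal the number of modes, and after
#' sorting both ascending, each mode must lie within the relative band
#' around its paired steady state.
#'
#' @param sss a `steady_state_set` from [find_steady_states()].
#' @param modes ascending numeric vector of mode locations (a.u.), or a
#'   `mode_set` from [find_modes()].
#' @param network network supplying the observation map.
#' @param config a [precondition_config()].
#' @return An object of class `precondition_result`: `passed`, `reason`
#'   (`"ok"`, `"count mismatch"`, `"out of range"`, `"no stable state"`,
#'   `"unstable or oscillatory"`), and the per-mode pairing table.
#' @export
check_precondition <- function(sss, modes, network,
                               config = precondition_config()) {
  if (inherits(modes, "mode_set")) modes <- modes$location
  if (is.unsorted(modes)) stop("modes must be ascending", call. = FALSE)
  q <- length(modes)
  stopifnot(q >= 1L)
  blo <- rep_len(config$beta_low, q)
  bup <- rep_len(config$beta_up, q)
  fail <- function(reason) structure(
    list(passed = FALSE, reason = reason, n_stable = sss$n_stable,
         n_modes = q, pairs = NULL), class = "precondition_result")
  if (nrow(sss$states) == 0L) return(fail("no stable state"))
  if (sss$n_stable == 0L) return(fail("unstable or oscillatory"))
  if (sss$n_stable != q) return(fail("count mismatch"))
  h <- apply(sss$states[sss$stable, , drop = FALSE], 1, function(s)
    observe(network, stats::setNames(s, network$species)))
  h <- sort(h)
  lower <- blo * h
  upper <- bup * h
  ok <- lower <= modes & modes <= upper
  pairs <- data.frame(mode = modes, steady_state = h, lower = lower,
                      upper = upper, within = ok)
  structure(list(passed = all(ok),
                 reason = if (all(ok)) "ok" else "out of range",
                 n_stable = sss$n_stable, n_modes = q, pairs = pairs),
            class = "precondition_result")
}

#' @export
print.precondition_result <- function(x, ...) {
  cat(sprintf("Deterministic precondition: %s (%s)\n",
              if (x$passed) "PASSED" else "not passed", x$reason))
  cat(sprintf("  stable steady states: %d, modes: %d\n", x$n_stable,
              x$n_modes))
  if (!is.null(x$pairs)) print(x$pairs, row.names = FALSE)
  invisible(x)
}
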