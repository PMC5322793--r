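#' Fit a stochastic reaction-network model to distribution data
#'
#' Main fitting entry point. Extracts the modes of the measured
#' final-time distribution, then minimizes the conditional objective
#' [objective_Fcond()] over the parameter space with the chosen
#' optimizer: `"rs"` (random search, the default) or `"ga"` (genetic
#' algorithm with elitism, uniform crossover and uniform-resample
#' mutation). Every candidate is screened by the deterministic
#' precondition before any stochastic simulation is spent on it.
#'
#' @param network a [reaction_network()].
#' @param data an [event_table()] of measured single-cell values.
#' @param method `"rs"` or `"ga"`.
#' @param space a [parameter_space()]; default
#'   [default_parameter_space()] of the network.
#' @param config a [fit_config()].
#' @param seed integer; all randomness of the fit flows from it.
#' @param n_iter random-search iteration count (ignored for `"ga"`).
#' @param ga a [ga_config()] (ignored for `"rs"`).
#' @param modes optional explicit mode locations; default: detected from
#'   the final-time distribution of `data` by [find_modes()].
#' @return An object of class `stochfit`; see [coef.stochfit()],
#'   [summary.stochfit()], [plot.stochfit()], [simulate.stochfit()],
#'   [residuals.stochfit()].
#' @examples
#' \donttest{
#' net <- constitutive_model()
#' dat <- generate_insilico_data(n_runs = 500, seed = 7)
#' fit <- stochfit(net, dat, n_iter = 50, config = fit_config(ns = 100),
#'                 seed = 1)
#' coef(fit)
#' }
#' @export
stochfit <- function(network, data, method = c("rs", "ga"),
                     space = default_parameter_space(network),
                     config = fit_config(), seed = 1L, n_iter = 1000L,
                     ga = ga_config(), modes = NULL) {
  method <- match.arg(method)
  if (method == "rs")
    random_search(network, space, data, n_iter = n_iter, config = config,
                  seed = seed, modes = modes)
  else
    genetic_algorithm(network, space, data, ga = ga, config = config,
                      seed = seed, modes = modes)
}

detect_modes <- function(data, config) {
  binning <- reference_binning(data, config)
  do.call(find_modes, c(list(binning$pe), config$find_modes_args))
}

new_stochfit <- function(network, space, data, modes, config, method,
                         seed, trace, best_index, best_params, best_dist,
                         extra = list()) {
  res <- list(
    network = network, space = space, data = data,
    modes = if (inherits(modes, "mode_set")) modes$location else modes,
    config = config, method = method, seed = seed, trace = trace,
    best_index = best_index, best_params = best_params,
    best_value = trace$value[best_index],
    pass_rate = mean(trace$passed), n_eval = nrow(trace),
    best_dist = best_dist)
  res[names(extra)] <- extra
  class(res) <- "stochfit"
  res
}

#' Random-search optimization under the deterministic precondition
#'
#' Draws `n_iter` independent parameter sets uniformly within the bounds
#' (fixed parameters held), scores each with [objective_Fcond()], and
#' returns the best. Fully reproducible from `seed`.
#'
#' @inheritParams stochfit
#' @param n_iter number of candidates (>= 1).
#' @return A `stochfit` object with the full evaluation trace.
#' @export
random_search <- function(network, space, data, n_iter = 1000L,
                          config = fit_config(), seed = 1L, modes = NULL) {
  if (n_iter < 1L) stop("n_iter must be >= 1", call. = FALSE)
  if (is.null(modes)) modes <- detect_modes(data, config)
  mloc <- if (inherits(modes, "mode_set")) modes$location else modes
  binning <- reference_binning(data, config)
  draws <- with_seed(derive_seed(seed, 0L), t(replicate(n_iter,
    sample_space(space), simplify = TRUE)))
  free <- names(space$lower)
  best_value <- Inf; best_index <- NA_integer_
  best_params <- NULL; best_dist <- NULL
  value <- numeric(n_iter); passed <- logical(n_iter)
  n_ssa <- integer(n_iter)
  for (i in seq_len(n_iter)) {
    th <- draws[i, ]
    ev <- objective_Fcond(network, th, data, mloc, config = config,
                          seed = derive_seed(seed, i), binning = binning)
    value[i] <- ev$value
    passed[i] <- ev$precondition$passed
    n_ssa[i] <- ifelse(is.na(ev$diagnostics$n_ssa), 0L,
                       ev$diagnostics$n_ssa)
    if (ev$value < best_value) {
      best_value <- ev$value; best_index <- i
      best_params <- th
      best_dist <- if (passed[i])
        simulated_pdf(network, th, data, config, derive_seed(seed, i),
                      binning) else NULL
    }
  }
  trace <- data.frame(eval = seq_len(n_iter), value = value,
                      passed = passed, n_ssa = n_ssa,
                      eval_seed = vapply(seq_len(n_iter), function(i)
                        derive_seed(seed, i), integer(1)))
  trace <- cbind(trace, as.data.frame(draws[, free, drop = FALSE]))
  new_stochfit(network, space, data, modes, config, "rs", seed, trace,
               best_index, best_params, best_dist)
}

# re-simulate the binned PDF of one candidate at its recorded seed
simulated_pdf <- function(network, params, data, config, seed, binning) {
  ens <- simulate_ensemble(network, params, init = config$init,
                           times = data$times, ns = config$ns,
                           base_seed = seed)
  build_distributions(apply_observation(ens, network), L = binning$L,
                      edges = binning$edges)
}

#' Genetic-algorithm configuration
#'
#' Adaptive-population genetic algorithm: a large screening generation
#' followed by small refinement generations. Selection is truncation by
#' rank (elitism rate `epsilon`), offspring genes come from either
#' parent with probability 1/2 (uniform crossover), and each gene
#' mutates with probability `mu` by uniform resampling within its
#' bounds. The best individual is always carried over unchanged.
#'
#' @param initial_size screening-generation population (default 3000).
#' @param size subsequent population size (default 20).
#' @param generations refinement generations after the screening one
#'   (default 5).
#' @param epsilon elitism rate in (0, 1) (default 0.4).
#' @param mu per-gene mutation probability in \[0, 1\] (default 0.2).
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(initial_size = 3000L, size = 20L, generations = 5L,
                      epsilon = 0.4, mu = 0.2) {
  if (!(epsilon > 0 && epsilon < 1)) stop("need 0 < epsilon < 1",
                                          call. = FALSE)
  if (!(mu >= 0 && mu <= 1)) stop("need 0 <= mu <= 1", call. = FALSE)
  if (initial_size < 2L || size < 2L) stop("population sizes must be >= 2",
                                           call. = FALSE)
  if (generations < 1L) stop("generations must be >= 1", call. = FALSE)
  structure(list(initial_size = as.integer(initial_size),
                 size = as.integer(size),
                 generations = as.integer(generations),
                 epsilon = epsilon, mu = mu), class = "ga_config")
}

#' Genetic-algorithm optimization under the deterministic precondition
#'
#' Generation 0 is sampled uniformly within the bounds with the (large)
#' screening population; each later generation ranks the population by
#' conditional objective value (ties broken by earlier evaluation),
#' keeps the top `ceiling(epsilon * N)` as parents, and builds the next
#' population from the carried-over best individual plus offspring from
#' uniform crossover of random parent pairs and per-gene uniform
#' mutation. Penalized (precondition-failing) individuals can only
#' become parents when fewer passing individuals exist than parent
#' slots.
#'
#' @inheritParams stochfit
#' @param ga a [ga_config()].
#' @return A `stochfit` object; the trace carries a `generation` column
#'   and `generation_best` records the running best per generation.
#' @export
genetic_algorithm <- function(network, space, data, ga = ga_config(),
                              config = fit_config(), seed = 1L,
                              modes = NULL) {
  if (is.null(modes)) modes <- detect_modes(data, config)
  mloc <- if (inherits(modes, "mode_set")) modes$location else modes
  binning <- reference_binning(data, config)
  free <- names(space$lower)
  d <- length(free)

  eval_count <- 0L
  trace_rows <- list()
  best <- list(value = Inf, params = NULL, index = NA_integer_,
               seed = NA_integer_)
  evaluate <- function(th, gen) {
    eval_count <<- eval_count + 1L
    es <- derive_seed(seed, eval_count)
    ev <- objective_Fcond(network, th, data, mloc, config = config,
                          seed = es, binning = binning)
    trace_rows[[eval_count]] <<- data.frame(
      eval = eval_count, generation = gen, value = ev$value,
      passed = ev$precondition$passed,
      n_ssa = ifelse(is.na(ev$diagnostics$n_ssa), 0L,
                     ev$diagnostics$n_ssa),
      eval_seed = es, t(th[free]))
    if (ev$value < best$value)
      best <<- list(value = ev$value, params = th, index = eval_count,
                    seed = es)
    ev$value
  }

  # generation 0: uniform screening population
  pop <- with_seed(derive_seed(seed, 0L),
                   t(replicate(ga$initial_size, sample_space(space))))
  fitness <- vapply(seq_len(nrow(pop)), function(i)
    evaluate(pop[i, ], 0L), numeric(1))
  generation_best <- min(fitness)

  for (gen in seq_len(ga$generations)) {
    N <- nrow(pop)
    # elitism operates at the scale of the (small) working population:
    # the screening generation is ranked but contributes the same number
    # of parents as any later generation
    n_parents <- min(N, ceiling(ga$epsilon * ga$size))
    if (n_parents < 2L && N >= 2L) n_parents <- 2L
    ord <- order(fitness, seq_len(N))      # rank; ties by evaluation order
    parents <- pop[ord[seq_len(n_parents)], , drop = FALSE]
    if (nrow(parents) < 2L)
      stop("fewer than 2 parents after elitism", call. = FALSE)
    elite <- pop[ord[1L], ]
    elite_fit <- fitness[ord[1L]]
    n_off <- ga$size - 1L
    nc <- ncol(parents)
    free_idx <- match(free, colnames(parents))
    offspring <- with_seed(derive_seed(seed, 100000L + gen), {
      t(vapply(seq_len(n_off), function(k) {
        pair <- sample.int(nrow(parents), 2L, replace = FALSE)
        pick <- stats::runif(nc) < 0.5
        child <- ifelse(pick, parents[pair[1L], ], parents[pair[2L], ])
        mut_free <- stats::runif(d) < ga$mu
        if (any(mut_free)) {
          idx <- free_idx[mut_free]
          child[idx] <- stats::runif(length(idx),
                                     space$lower[free[mut_free]],
                                     space$upper[free[mut_free]])
        }
        names(child) <- colnames(parents)
        child
      }, numeric(nc)))
    })
    pop <- rbind(elite, offspring, deparse.level = 0)
    colnames(pop) <- c(free, names(space$fixed))
    off_fit <- vapply(seq_len(n_off), function(k)
      evaluate(pop[k + 1L, ], gen), numeric(1))
    fitness <- c(elite_fit, off_fit)       # elite keeps its recorded value
    generation_best <- c(generation_best,
                         min(generation_best[length(generation_best)],
                             min(fitness)))
  }

  trace <- do.call(rbind, trace_rows)
  rownames(trace) <- NULL
  best_dist <- if (is.finite(best$value) &&
                   best$value < config$precondition$penalty)
    simulated_pdf(network, best$params, data, config, best$seed, binning)
  else NULL
  new_stochfit(network, space, data, modes, config, "ga", seed, trace,
               best$index, best$params, best_dist,
               extra = list(ga = ga, generation_best = generation_best))
}

# ---------------------------------------------------------------------------
# S3 methods for fitted objects
# ---------------------------------------------------------------------------

#' @export
print.stochfit <- function(x, ...) {
  cat(sprintf("Stochastic distribution fit (%s)\n",
              if (x$method == "rs") "random search" else
                "genetic algorithm"))
  cat(sprintf("  model: %s\n", x$network$description))
  cat(sprintf("  evaluations: %d, precondition pass rate: %.2f%%\n",
              x$n_eval, 100 * x$pass_rate))
  cat(sprintf("  modes matched (a.u.): %s\n",
              paste(signif(x$modes, 6), collapse = ", ")))
  if (is.finite(x$best_value) &&
      x$best_value < x$config$precondition$penalty) {
    cat(sprintf("  best objective F = %.6g\n", x$best_value))
    cat("  best parameters:\n")
    th <- coef(x)
    for (nm in names(th)) cat(sprintf("    %-14s %g\n", nm, th[nm]))
  } else {
    cat("  no candidate passed the deterministic precondition\n")
  }
  invisible(x)
}

#' Extract the fitted parameters
#'
#' @param object a `stochfit` object.
#' @param all if `TRUE`, include the fixed parameters.
#' @param ... unused.
#' @return Named numeric vector of the best parameter set (free
#'   parameters only by default).
#' @export
coef.stochfit <- function(object, all = FALSE, ...) {
  if (is.null(object$best_params)) return(NULL)
  if (all) object$best_params
  else object$best_params[names(object$space$lower)]
}

#' Summarize a fit
#'
#' @inheritParams coef.stochfit
#' @return A `summary.stochfit` list: best parameters and objective,
#'   evaluation counts, precondition ledger (pass counts and failure
#'   reasons are recoverable from the trace), and per-generation best
#'   values for GA fits.
#' @export
summary.stochfit <- function(object, ...) {
  s <- list(method = object$method, n_eval = object$n_eval,
            n_passed = sum(object$trace$passed),
            pass_rate = object$pass_rate,
            n_ssa_total = sum(object$trace$n_ssa),
            best_value = object$best_value, best = coef(object),
            modes = object$modes, seed = object$seed,
            generation_best = object$generation_best)
  class(s) <- "summary.stochfit"
  s
}

#' @export
print.summary.stochfit <- function(x, ...) {
  cat(sprintf("%s fit: %d evaluations, %d passed the precondition (%.2f%%)\n",
              if (x$method == "rs") "Random-search" else
                "Genetic-algorithm",
              x$n_eval, x$n_passed, 100 * x$pass_rate))
  cat(sprintf("  stochastic trajectories spent: %d\n", x$n_ssa_total))
  cat(sprintf("  best objective: %.6g\n", x$best_value))
  if (!is.null(x$generation_best))
    cat("  best per generation:",
        paste(signif(x$generation_best, 4), collapse = " -> "), "\n")
  if (!is.null(x$best)) {
    cat("  best parameters:\n")
    for (nm in names(x$best)) cat(sprintf("    %-14s %g\n", nm,
                                          x$best[nm]))
  }
  invisible(x)
}

#' Plot the optimization trace
#'
#' Objective value of the accepted (precondition-passing) evaluations
#' against evaluation index, with the running best overlaid; penalized
#' evaluations are omitted (their value is the penalty sentinel).
#'
#' @param x a `stochfit` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.stochfit <- function(x, ...) {
  tr <- x$trace
  ok <- tr$passed & tr$value < x$config$precondition$penalty
  if (!any(ok)) {
    plot(tr$eval, rep(1, nrow(tr)), type = "n",
         xlab = "evaluation", ylab = "objective F", ...)
    legend("center", legend = "no accepted evaluations", bty = "n")
    return(invisible(x))
  }
  plot(tr$eval[ok], tr$value[ok], log = "y", xlab = "evaluation",
       ylab = "objective F", pch = 16, cex = 0.6, ...)
  run_best <- cummin(ifelse(ok, tr$value, Inf))
  lines(tr$eval, run_best, col = 2, lwd = 2)
  legend("topright", legend = c("accepted evaluation", "running best"),
         pch = c(16, NA), lty = c(NA, 1), col = c(1, 2), bty = "n")
  invisible(x)
}

#' Simulate from the fitted model
#'
#' Runs a stochastic ensemble at the fitted parameters and returns the
#' simulated single-cell event table at the data's measurement times.
#'
#' @param object a `stochfit` object.
#' @param nsim number of trajectories (default: the fit's `ns`).
#' @param seed ensemble base seed (default: the seed recorded for the
#'   best evaluation, reproducing the winning ensemble).
#' @param ... unused.
#' @return An [event_table()].
#' @export
simulate.stochfit <- function(object, nsim = object$config$ns,
                              seed = NULL, ...) {
  if (is.null(object$best_params))
    stop("no accepted candidate to simulate from", call. = FALSE)
  if (is.null(seed)) {
    tr <- object$trace
    seed <- tr$eval_seed[object$best_index]
  }
  ens <- simulate_ensemble(object$network, object$best_params,
                           init = object$config$init,
                           times = object$data$times, ns = nsim,
                           base_seed = seed)
  apply_observation(ens, object$network)
}

#' Distribution residuals of the fit
#'
#' Per-time-point difference between the measured and the best-fit
#' simulated binned PDFs (`P_e - P_s` on the shared grid).
#'
#' @param object a `stochfit` object.
#' @param ... unused.
#' @return List with one numeric vector of mass differences per time
#'   point, named by time.
#' @export
residuals.stochfit <- function(object, ...) {
  if (is.null(object$best_dist))
    stop("no accepted candidate: residuals are undefined", call. = FALSE)
  binning <- reference_binning(object$data, object$config)
  out <- lapply(seq_along(binning$pe$bins), function(i)
    binning$pe$bins[[i]]$mass - object$best_dist$bins[[i]]$mass)
  names(out) <- object$data$times
  out
}
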