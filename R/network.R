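#' Rate-law constructors
#'
#' A reaction network couples integer stoichiometry with a typed rate law per
#' reaction. Four law families cover mass-action kinetics plus the saturable
#' and promoter-gating forms used by the bundled gene-expression models. Each
#' constructor records the parameter names it consumes and the species it
#' reads; values are resolved at evaluation time from the [parameter
#' set][validate_parameters] and state vector.
#'
#' * `rate_mass_action(k, species)` -- \eqn{k \prod_i x_i} over the listed
#'   species (repeats allowed and multiplied as written, e.g. `c("P","P")`
#'   gives \eqn{k x_P^2}); an empty species list is a zeroth-order source.
#' * `rate_hill(vmax, k, n, species)` -- \eqn{V x^n / (K^n + x^n)}.
#' * `rate_gated_source(k, gate)` -- \eqn{k (1 - x_g)}, a source active only
#'   while the gating species (a promoter occupancy in \eqn{[0,1]}) is off.
#' * `rate_promoter_activation(kon, ka_a, ka_b, a, b, gate)` --
#'   \eqn{k_{on}\, AB / (k_a k_b + k_a A + k_b B + AB)\,(1 - x_g)}, the
#'   two-ligand saturable promoter activation law.
#'
#' @param k,vmax,kon,ka_a,ka_b names of the rate parameters (character).
#' @param n name of the Hill-coefficient parameter.
#' @param species,a,b,gate species names read by the law.
#' @return An object of class `rate_law`.
#' @seealso [reaction_network()]
#' @export
rate_mass_action <- function(k, species = character()) {
  structure(list(type = 1L, par = k, sp = species,
                 text = if (length(species) == 0) k
                        else paste(c(k, species), collapse = " * ")),
            class = "rate_law")
}

#' @rdname rate_mass_action
#' @export
rate_hill <- function(vmax, k, n, species) {
  structure(list(type = 2L, par = c(vmax, k, n), sp = species,
                 text = sprintf("%s * %s^%s / (%s^%s + %s^%s)",
                                vmax, species, n, k, n, species, n)),
            class = "rate_law")
}

#' @rdname rate_mass_action
#' @export
rate_gated_source <- function(k, gate) {
  structure(list(type = 3L, par = k, sp = gate,
                 text = sprintf("%s * (1 - %s)", k, gate)),
            class = "rate_law")
}

#' @rdname rate_mass_action
#' @export
rate_promoter_activation <- function(kon, ka_a, ka_b, a, b, gate) {
  structure(list(type = 4L, par = c(kon, ka_a, ka_b), sp = c(a, b, gate),
                 text = sprintf(
                   "%s * (%s * %s) / (%s * %s + %s * %s + %s * %s + %s * %s) * (1 - %s)",
                   kon, a, b, ka_a, ka_b, ka_a, a, ka_b, b, a, b, gate)),
            class = "rate_law")
}

#' Define a reaction network
#'
#' Builds a stochastic reaction network: an ordered species list, a set of
#' reactions (integer stoichiometric change + [rate law][rate_mass_action]),
#' the parameter names, a default initial copy-number state, and the
#' observation map that projects a state onto the measured quantity.
#'
#' @param species character vector of unique species names.
#' @param reactions named list; each element is a list with components
#'   `change` (named integer vector of stoichiometric changes, names must be
#'   species) and `rate` (a `rate_law`).
#' @param parameters character vector of parameter names.
#' @param initial_state named numeric vector of default initial copy numbers.
#' @param observable character vector of species summed by the observation
#'   map (default: all species).
#' @param phi scale factor of the observation map (arbitrary units per
#'   molecule), must be positive.
#' @param nominal optional named numeric vector of reference parameter values.
#' @param description optional one-line description.
#' @return An object of class `reaction_network`.
#' @examples
#' net <- reaction_network(
#'   species = "X",
#'   reactions = list(
#'     birth = list(change = c(X = 1), rate = rate_mass_action("kb")),
#'     death = list(change = c(X = -1), rate = rate_mass_action("kd", "X"))),
#'   parameters = c("kb", "kd"),
#'   initial_state = c(X = 0))
#' evaluate_propensities(net, c(X = 10), c(kb = 5, kd = 0.1))
#' @export
reaction_network <- function(species, reactions, parameters, initial_state,
                             observable = species, phi = 1,
                             nominal = NULL, description = "") {
  stopifnot(is.character(species), length(species) >= 1L)
  if (anyDuplicated(species))
    stop("species names must be unique", call. = FALSE)
  if (is.null(names(reactions)) || any(!nzchar(names(reactions))))
    stop("every reaction must be named", call. = FALSE)
  stoich <- matrix(0L, nrow = length(species), ncol = length(reactions),
                   dimnames = list(species, names(reactions)))
  type <- integer(length(reactions))
  spidx <- paridx <- vector("list", length(reactions))
  texts <- character(length(reactions))
  for (j in seq_along(reactions)) {
    rx <- reactions[[j]]
    ch <- rx$change
    if (!all(names(ch) %in% species))
      stop(sprintf("reaction '%s': unknown species in stoichiometry",
                   names(reactions)[j]), call. = FALSE)
    if (any(ch != round(ch)))
      stop(sprintf("reaction '%s': stoichiometric changes must be integers",
                   names(reactions)[j]), call. = FALSE)
    stoich[names(ch), j] <- as.integer(ch)
    rl <- rx$rate
    if (!inherits(rl, "rate_law"))
      stop(sprintf("reaction '%s': rate must be a rate_law",
                   names(reactions)[j]), call. = FALSE)
    bad_sp <- setdiff(rl$sp, species)
    bad_par <- setdiff(rl$par, parameters)
    if (length(bad_sp))
      stop(sprintf("reaction '%s': rate law references unknown species: %s",
                   names(reactions)[j], paste(bad_sp, collapse = ", ")),
           call. = FALSE)
    if (length(bad_par))
      stop(sprintf("reaction '%s': rate law references unknown parameters: %s",
                   names(reactions)[j], paste(bad_par, collapse = ", ")),
           call. = FALSE)
    type[j] <- rl$type
    spidx[[j]] <- match(rl$sp, species) - 1L
    paridx[[j]] <- match(rl$par, parameters) - 1L
    texts[j] <- rl$text
  }
  if (!all(names(initial_state) %in% species) ||
      length(initial_state) != length(species))
    stop("initial_state must name every species exactly once", call. = FALSE)
  initial_state <- initial_state[species]
  if (!all(observable %in% species))
    stop("observable species must belong to the network", call. = FALSE)
  if (length(observable) == 0)
    stop("observable species set must be non-empty", call. = FALSE)
  if (!is.numeric(phi) || length(phi) != 1L || phi <= 0)
    stop("phi must be a single positive number", call. = FALSE)
  structure(list(
    species = species,
    reactions = stats::setNames(lapply(seq_along(reactions), function(j)
      list(change = stoich[, j], rate_text = texts[j],
           rate = reactions[[j]]$rate)), names(reactions)),
    parameters = parameters,
    initial_state = initial_state,
    observable = observable,
    phi = phi,
    nominal = nominal,
    description = description,
    cxx = list(stoich = stoich, type = type, sp = spidx, par = paridx)
  ), class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("Reaction network: %s\n", x$description))
  cat(sprintf("  %d species: %s\n", length(x$species),
              paste(x$species, collapse = ", ")))
  cat(sprintf("  %d reactions, %d parameters\n", length(x$reactions),
              length(x$parameters)))
  cat(sprintf("  observable: phi * (%s), phi = %g\n",
              paste(x$observable, collapse = " + "), x$phi))
  for (nm in names(x$reactions)) {
    ch <- x$reactions[[nm]]$change
    lhs <- ch[ch < 0]; rhs <- ch[ch > 0]
    fmt <- function(v) if (length(v) == 0) "0" else
      paste(ifelse(abs(v) == 1, names(v), paste0(abs(v), " ", names(v))),
            collapse = " + ")
    cat(sprintf("    %-14s %s -> %s   [%s]\n", nm, fmt(lhs), fmt(rhs),
                x$reactions[[nm]]$rate_text))
  }
  invisible(x)
}

#' Validate a parameter set against a network
#'
#' A parameter set is a named numeric vector covering exactly the network's
#' parameter names, finite and positive. Returns the values reordered to the
#' network's parameter order.
#'
#' @param network a [reaction_network()].
#' @param params named numeric vector.
#' @return Named numeric vector in network parameter order.
#' @export
validate_parameters <- function(network, params) {
  if (is.null(names(params)) ||
      !setequal(names(params), network$parameters) ||
      length(params) != length(network$parameters))
    stop("params must cover exactly the network's parameters: ",
         paste(network$parameters, collapse = ", "), call. = FALSE)
  p <- params[network$parameters]
  if (any(!is.finite(p)))
    stop("parameter values must be finite", call. = FALSE)
  p
}

#' Evaluate reaction propensities
#'
#' Evaluates every rate law of the network at a state, exactly as written
#' (no combinatorial correction of bimolecular laws).
#'
#' @inheritParams validate_parameters
#' @param state named or ordered numeric vector of nonnegative copy numbers.
#' @return Numeric vector of finite nonnegative propensities, one per
#'   reaction, in reaction order.
#' @export
evaluate_propensities <- function(network, state, params) {
  state <- resolve_state(network, state)
  if (any(state < 0))
    stop("state contains a negative copy number", call. = FALSE)
  p <- validate_parameters(network, params)
  a <- .propensities_cpp(network$cxx, as.numeric(state), as.numeric(p))
  names(a) <- names(network$reactions)
  a
}

resolve_state <- function(network, state) {
  if (!is.null(names(state))) {
    if (!setequal(names(state), network$species))
      stop("state must name every species of the network", call. = FALSE)
    state <- state[network$species]
  } else if (length(state) != length(network$species)) {
    stop("state length does not match the number of species", call. = FALSE)
  }
  as.numeric(state)
}

#' Map states to the measured observable
#'
#' The observation map sends a state to `phi * sum(observable species)`,
#' the model-side counterpart of a single-cell fluorescence readout.
#'
#' @inheritParams validate_parameters
#' @param states a state vector, a matrix with species columns, or a
#'   three-dimensional ensemble array (time x species x member) as returned
#'   by [simulate_ensemble()].
#' @param observable,phi override the network's observation map.
#' @return Observable values with the species dimension summed out.
#' @export
observe <- function(network, states, observable = network$observable,
                    phi = network$phi) {
  idx <- match(observable, network$species)
  if (anyNA(idx)) stop("unknown observable species", call. = FALSE)
  if (is.null(dim(states))) {
    st <- resolve_state(network, states)
    return(phi * sum(st[idx]))
  }
  d <- dim(states)
  if (length(d) == 2L) return(phi * rowSums(states[, idx, drop = FALSE]))
  if (length(d) == 3L) {
    out <- matrix(0, d[1], d[3])
    for (i in idx) out <- out + states[, i, ]
    return(phi * out)
  }
  stop("states must be a vector, matrix or 3-d array", call. = FALSE)
}

#' Export a network description as JSON
#'
#' Writes a human-readable JSON description (species, stoichiometry,
#' rate-law strings, parameters, observation map) for provenance.
#'
#' @inheritParams validate_parameters
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
network_to_json <- function(network, path = NULL) {
  desc <- list(
    description = network$description,
    species = network$species,
    parameters = network$parameters,
    nominal = as.list(network$nominal),
    initial_state = as.list(network$initial_state),
    observable = list(species = network$observable, phi = network$phi),
    reactions = lapply(network$reactions, function(r)
      list(change = as.list(r$change[r$change != 0]), rate = r$rate_text))
  )
  js <- jsonlite::toJSON(desc, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
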