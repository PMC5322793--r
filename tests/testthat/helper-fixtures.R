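# Shared fixtures, built lazily and cached for the session.

pure_birth_network <- function() {
  reaction_network(
    species = "X",
    reactions = list(birth = list(change = c(X = 1),
                                  rate = rate_mass_action("k"))),
    parameters = "k",
    initial_state = c(X = 0),
    description = "pure birth")
}

birth_death_network <- function() {
  reaction_network(
    species = "X",
    reactions = list(
      birth = list(change = c(X = 1), rate = rate_mass_action("kb")),
      death = list(change = c(X = -1), rate = rate_mass_action("kd", "X"))),
    parameters = c("kb", "kd"),
    initial_state = c(X = 0),
    description = "birth-death")
}

# analytic moments of the constitutive circuit started at (0, 0)
constitutive_mean_mrna <- function(theta, t)
  theta["theta1"] / theta["theta2"] * (1 - exp(-theta["theta2"] * t))

# protein mean for the equal-decay case theta2 == theta4
constitutive_mean_protein <- function(theta, t) {
  stopifnot(isTRUE(all.equal(unname(theta["theta2"]),
                             unname(theta["theta4"]))))
  a <- theta["theta1"] / theta["theta2"]
  cc <- theta["theta4"]
  unname(theta["theta3"] * a * ((1 - exp(-cc * t)) / cc - t * exp(-cc * t)))
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

insilico_reference <- function()
  cached("insilico10k", generate_insilico_data(seed = 1))

insilico_small <- function()
  cached("insilico3k", generate_insilico_data(n_runs = 3000, seed = 1))

surrogate_reference <- function()
  cached("surrogate", generate_flow_surrogate())
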