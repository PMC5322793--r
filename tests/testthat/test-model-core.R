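# Reaction networks, rate laws and propensity evaluation.

test_that("constitutive model evaluates its mass-action laws as written", {
  net <- constitutive_model()
  th <- net$nominal

  # zeroth-order transcription fires at theta1 from any state
  a0 <- evaluate_propensities(net, c(mRNA = 0, Protein = 0), th)
  expect_equal(unname(a0), c(5, 0, 0, 0))
  a <- evaluate_propensities(net, c(mRNA = 123, Protein = 7), th)
  expect_equal(unname(a["transcription"]), 5)

  # first-order decay and translation
  expect_equal(unname(evaluate_propensities(
    net, c(mRNA = 10, Protein = 0), th)["mRNA_decay"]), 0.3)
  expect_equal(unname(evaluate_propensities(
    net, c(mRNA = 166, Protein = 555), th)["translation"]), 16.6)

  # translation leaves mRNA unchanged and adds one protein
  ch <- net$reactions$translation$change
  expect_equal(unname(ch["mRNA"]), 0)
  expect_equal(unname(ch["Protein"]), 1)
})

test_that("IRF7 rate laws match direct evaluation of their formulas", {
  net <- irf7_model()
  th <- net$nominal
  a <- evaluate_propensities(net, net$initial_state, th)

  # saturated Hill activation at IFN = 150
  hill <- 6.135 * 150^2 / (0.0055^2 + 150^2)
  expect_equal(unname(a["IFN_amplification"]), hill, tolerance = 1e-12)
  expect_gt(hill, 6.134)  # effectively saturated

  # promoter activation vanishes at full occupancy (1 - Pa factor) and
  # without ISGF3
  st <- net$initial_state
  st["Pa"] <- 1; st["ISGF3"] <- 5; st["IRF7dimer"] <- 100
  expect_equal(unname(evaluate_propensities(
    net, st, th)["promoter_activation"]), 0)
  st["Pa"] <- 0; st["ISGF3"] <- 0
  expect_equal(unname(evaluate_propensities(
    net, st, th)["promoter_activation"]), 0)

  # basal transcription at an inactive promoter
  expect_equal(unname(a["transcription_basal"]), 0.0861)

  # printed product form of the dimerization law (no n(n-1)/2)
  st <- net$initial_state; st["IRF7phosp"] <- 7
  expect_equal(unname(evaluate_propensities(
    net, st, th)["dimerization"]), 0.602 * 49)

  # dimerization consumes exactly 2 monomers, produces 1 dimer
  ch <- net$reactions$dimerization$change
  expect_equal(unname(ch["IRF7phosp"]), -2)
  expect_equal(unname(ch["IRF7dimer"]), 1)
})

test_that("propensity evaluation validates its inputs", {
  net <- constitutive_model()
  expect_error(evaluate_propensities(net, c(mRNA = -1, Protein = 0),
                                     net$nominal), "negative")
  expect_error(evaluate_propensities(net, c(mRNA = 1, Protein = 0),
                                     c(theta1 = 5)), "parameters")
  expect_error(evaluate_propensities(net, c(mRNA = 1), net$nominal),
               "species|state")
})

test_that("stoichiometry times propensities equals the ODE right-hand side", {
  set.seed(7)
  for (net in list(constitutive_model(), irf7_model())) {
    stoich <- sapply(net$reactions, `[[`, "change")
    for (r in 1:10) {
      st <- stats::setNames(runif(length(net$species), 0, 50),
                            net$species)
      if ("Pa" %in% net$species) st["Pa"] <- runif(1)
      a <- evaluate_propensities(net, st, net$nominal)
      rhs <- ode_rhs(net, st, net$nominal)
      expect_equal(unname(drop(stoich %*% a)), unname(rhs),
                   tolerance = 1e-12)
    }
  }
})

test_that("network construction rejects malformed definitions", {
  expect_error(reaction_network(
    species = c("A", "A"),
    reactions = list(r = list(change = c(A = 1),
                              rate = rate_mass_action("k"))),
    parameters = "k", initial_state = c(A = 0, A = 0)), "unique")
  expect_error(reaction_network(
    species = "A",
    reactions = list(r = list(change = c(B = 1),
                              rate = rate_mass_action("k"))),
    parameters = "k", initial_state = c(A = 0)), "unknown species")
  expect_error(reaction_network(
    species = "A",
    reactions = list(r = list(change = c(A = 1),
                              rate = rate_mass_action("missing"))),
    parameters = "k", initial_state = c(A = 0)), "unknown parameters")
  expect_error(reaction_network(
    species = "A",
    reactions = list(r = list(change = c(A = 0.5),
                              rate = rate_mass_action("k"))),
    parameters = "k", initial_state = c(A = 0)), "integers")
})

test_that("JSON export carries the full model description", {
  net <- irf7_model()
  js <- network_to_json(net)
  doc <- jsonlite::fromJSON(js)
  expect_setequal(doc$species, net$species)
  expect_equal(length(doc$reactions), 13L)
  expect_equal(doc$initial_state$IFN, 150)
  expect_match(doc$reactions$dimerization$rate, "IRF7phosp \\* IRF7phosp")
  expect_equal(doc$observable$phi, 1)
})
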