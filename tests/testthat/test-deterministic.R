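# ODE steady states, stability classification and the deterministic
# precondition.

test_that("ODE right-hand side vanishes at the closed-form fixed point", {
  net <- constitutive_model()
  th <- net$nominal
  fp <- c(mRNA = unname(th["theta1"] / th["theta2"]),
          Protein = unname(th["theta1"] * th["theta3"] /
                             (th["theta2"] * th["theta4"])))
  expect_equal(unname(ode_rhs(net, fp, th)), c(0, 0), tolerance = 1e-10)

  # doubling a zeroth-order rate doubles its derivative contribution
  st <- c(mRNA = 3, Protein = 10)
  d1 <- ode_rhs(net, st, th)
  th2 <- th; th2["theta1"] <- 2 * th["theta1"]
  d2 <- ode_rhs(net, st, th2)
  expect_equal(unname(d2["mRNA"] - d1["mRNA"]), unname(th["theta1"]))
})

test_that("steady-state finder matches the constitutive closed forms", {
  net <- constitutive_model()
  set.seed(11)
  for (r in 1:50) {
    th <- c(theta1 = runif(1, 0.5, 20), theta2 = runif(1, 0.01, 0.1),
            theta3 = runif(1, 0.01, 0.5), theta4 = runif(1, 0.01, 0.1))
    ss <- find_steady_states(net, th)
    expect_equal(ss$n_stable, 1L)
    truth <- c(th["theta1"] / th["theta2"],
               th["theta1"] * th["theta3"] / (th["theta2"] * th["theta4"]))
    got <- ss$states[ss$stable, ]
    expect_lt(max(abs(got - truth) / truth), 1e-8)
  }
})

test_that("stability is read off the Jacobian eigenvalues", {
  net <- constitutive_model()
  th <- net$nominal
  ss <- find_steady_states(net, th)
  cl <- classify_stability(net, ss$states[1, ], th)
  # triangular Jacobian: eigenvalues are the decay rates
  expect_equal(cl$lambda_max, -0.03, tolerance = 1e-6)
  expect_true(cl$stable)

  # autocatalytic birth has an unstable fixed point at the origin
  auto <- reaction_network(
    species = "X",
    reactions = list(rep = list(change = c(X = 1),
                                rate = rate_mass_action("k", "X"))),
    parameters = "k", initial_state = c(X = 0))
  cl2 <- classify_stability(auto, c(X = 0), c(k = 0.7))
  expect_false(cl2$stable)
  expect_equal(cl2$lambda_max, 0.7, tolerance = 1e-5)
})

test_that("IRF7 nominal parameters give the basal and stimulated branches", {
  net <- irf7_model()
  ss <- find_steady_states(net, net$nominal)
  expect_equal(ss$n_stable, 2L)
  # residuals vanish at every reported fixed point
  for (r in seq_len(nrow(ss$states)))
    expect_lt(max(abs(ode_rhs(net, ss$states[r, ], net$nominal))), 1e-9)

  stable <- ss$states[ss$stable, , drop = FALSE]
  stim <- stable[which.max(stable[, "IFN"]), ]
  basal <- stable[which.min(stable[, "IFN"]), ]

  # stimulated branch: components not involving the promoter occupancy
  expect_equal(unname(stim["IFN"]), 124.70, tolerance = 1e-4)
  expect_equal(unname(stim["ISGF3"]), 22.00, tolerance = 1e-3)

  # basal branch
  expect_equal(unname(basal["IFN"]), 0)
  expect_equal(unname(basal["mRNA"]), 1.20, tolerance = 5e-3)
  expect_equal(unname(basal["IRF7"]), 13.62, tolerance = 1e-3)
  expect_equal(unname(basal["IRF7phosp"]), 6.62, tolerance = 1e-3)
  expect_equal(unname(basal["IRF7dimer"]), 60.19, tolerance = 1e-2)
  expect_equal(observe(net, basal), 80.43, tolerance = 1e-3)

  # both branches strictly attracting
  expect_lt(max(ss$lambda_max[ss$stable]), -1e-9)
})

test_that("the precondition brackets modes with stable steady states", {
  net <- constitutive_model()
  ss <- find_steady_states(net, net$nominal)  # protein* = 555.556

  ok <- check_precondition(ss, 543, net)
  expect_true(ok$passed)
  expect_equal(ok$pairs$lower, 0.95 * 555.5556, tolerance = 1e-4)
  expect_equal(ok$pairs$upper, 1.05 * 555.5556, tolerance = 1e-4)

  # two modes against one stable state: count mismatch
  two <- check_precondition(ss, c(100, 543), net)
  expect_false(two$passed)
  expect_equal(two$reason, "count mismatch")

  # mode outside the band
  out <- check_precondition(ss, 400, net)
  expect_false(out$passed)
  expect_equal(out$reason, "out of range")

  # no stable state
  auto <- reaction_network(
    species = "X",
    reactions = list(rep = list(change = c(X = 1),
                                rate = rate_mass_action("k", "X"))),
    parameters = "k", initial_state = c(X = 1))
  ssu <- find_steady_states(auto, c(k = 0.5))
  bad <- check_precondition(ssu, 10, auto)
  expect_false(bad$passed)
  expect_match(bad$reason, "no stable state|unstable")
})

test_that("widening the acceptance band never flips a pass to a fail", {
  net <- irf7_model()
  ss <- find_steady_states(net, net$nominal)
  set.seed(3)
  for (r in 1:25) {
    modes <- sort(c(runif(1, 40, 120), runif(1, 700, 1100)))
    blo <- runif(1, 0.5, 1); bup <- runif(1, 1, 1.5)
    res1 <- check_precondition(ss, modes, net,
                               precondition_config(blo, bup))
    res2 <- check_precondition(ss, modes, net,
                               precondition_config(blo * runif(1, 0.5, 1),
                                                   bup * runif(1, 1, 1.5)))
    if (res1$passed) expect_true(res2$passed)
  }
})

test_that("the steady-state report round-trips through JSON", {
  net <- irf7_model()
  ss <- find_steady_states(net, net$nominal)
  path <- withr::local_tempfile(fileext = ".json")
  steady_state_report(ss, net, path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(nrow(doc), nrow(ss$states))
  expect_equal(doc$IFN, unname(ss$states[, "IFN"]), tolerance = 1e-12)
  expect_equal(doc$stable, ss$stable)
})
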