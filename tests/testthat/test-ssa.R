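# Exact stochastic simulation: distributional correctness, reproducible
# seeding, physical invariants.

test_that("a pure-birth trajectory behaves like a Poisson process", {
  net <- pure_birth_network()
  x <- simulate_trajectory(net, c(k = 5), times = 200, seed = 4)
  # mean 1000, sd ~ 31.6: a single draw stays within 5 sigma
  expect_lt(abs(x[1, "X"] - 1000), 5 * sqrt(1000))
})

test_that("pure-birth counts pass a chi-square test against Poisson", {
  net <- pure_birth_network()
  ens <- simulate_ensemble(net, c(k = 5), times = 200, ns = 5000,
                           base_seed = 42)
  x <- ens[1, 1, ]
  # partition with expected counts >= 5 throughout
  qs <- qpois(seq(0.04, 0.96, by = 0.04), lambda = 1000)
  edges <- c(-Inf, unique(qs), Inf)
  obs <- table(cut(x, edges))
  pr <- diff(ppois(c(-Inf, unique(qs), Inf), lambda = 1000))
  gof <- suppressWarnings(chisq.test(as.vector(obs), p = pr))
  expect_gt(gof$p.value, 0.01)
})

test_that("simulation is exactly reproducible from its seed", {
  net <- constitutive_model()
  a <- simulate_trajectory(net, net$nominal, times = c(50, 150), seed = 9)
  b <- simulate_trajectory(net, net$nominal, times = c(50, 150), seed = 9)
  expect_identical(unclass(a), unclass(b))

  e1 <- simulate_ensemble(net, net$nominal, times = c(50, 150), ns = 12,
                          base_seed = 5)
  e2 <- simulate_ensemble(net, net$nominal, times = c(50, 150), ns = 12,
                          base_seed = 5)
  expect_identical(unclass(e1), unclass(e2))
})

test_that("growing an ensemble preserves its earlier members", {
  net <- constitutive_model()
  small <- simulate_ensemble(net, net$nominal, times = c(50, 150),
                             ns = 8, base_seed = 5)
  big <- simulate_ensemble(net, net$nominal, times = c(50, 150),
                           ns = 16, base_seed = 5)
  expect_identical(unclass(small)[, , 1:8], unclass(big)[, , 1:8])
  one <- simulate_ensemble(net, net$nominal, times = c(50, 150),
                           ns = 1, base_seed = 5)
  expect_identical(unclass(one)[, , 1], unclass(big)[, , 1])
})

test_that("ensemble moments match the linear birth-death theory", {
  net <- constitutive_model()
  th <- net$nominal
  ens <- simulate_ensemble(net, th, times = c(200, 400), ns = 1000,
                           base_seed = 7)
  m200 <- ens[1, 1, ]
  mu <- unname(constitutive_mean_mrna(th, 200))
  expect_lt(abs(mean(m200) - mu), 3 * sd(m200) / sqrt(1000))

  # stationary mRNA copy number is Poisson(theta1/theta2)
  m400 <- ens[2, 1, ]
  lambda <- unname(th["theta1"] / th["theta2"])
  expect_lt(abs(mean(m400) - lambda), 3 * sd(m400) / sqrt(1000))
  v <- var(m400)
  se_var <- sqrt((mean((m400 - mean(m400))^4) - v^2) / 1000)
  expect_lt(abs(v - lambda), 3 * se_var)

  # protein mean along the transient
  p200 <- ens[1, 2, ]
  expect_lt(abs(mean(p200) - constitutive_mean_protein(th, 200)),
            3 * sd(p200) / sqrt(1000))
})

test_that("sampled states stay physical in the IRF7 circuit", {
  net <- irf7_model()
  ens <- simulate_ensemble(net, net$nominal, times = c(30, 120, 300),
                           ns = 40, base_seed = 13)
  expect_true(all(ens >= 0))
  expect_true(all(ens[, "Pa", ] %in% c(0, 1)))
  expect_true(all(ens == round(ens)))
})

test_that("exhausted systems freeze at their final state", {
  death <- reaction_network(
    species = "X",
    reactions = list(d = list(change = c(X = -1),
                              rate = rate_mass_action("k", "X"))),
    parameters = "k", initial_state = c(X = 3))
  x <- simulate_trajectory(death, c(k = 10), times = c(50, 100, 1e6),
                           seed = 2)
  expect_equal(unname(x[, "X"]), c(0, 0, 0))
})

test_that("simulation inputs are validated", {
  net <- constitutive_model()
  expect_error(simulate_trajectory(net, net$nominal,
                                   init = c(mRNA = -1, Protein = 0),
                                   times = 10, seed = 1), "nonnegative")
  expect_error(simulate_trajectory(net, net$nominal,
                                   times = c(10, 5), seed = 1),
               "increasing")
  expect_error(simulate_ensemble(net, net$nominal, times = 10, ns = 0,
                                 base_seed = 1), "ns")
})

test_that("trajectories dump to CSV for external plotting", {
  net <- irf7_model()
  tr <- simulate_trajectory(net, net$nominal, times = c(10, 20, 30),
                            seed = 6)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(tr, path)
  df <- read.csv(path)
  expect_equal(names(df), c("time", net$species))
  expect_equal(df$time, c(10, 20, 30))
  expect_equal(df$IFN, unname(tr[, "IFN"]))
})

test_that("time zero records the initial state", {
  net <- irf7_model()
  x <- simulate_trajectory(net, net$nominal, times = c(0, 10), seed = 1)
  expect_equal(unname(x[1, ]), unname(net$initial_state))
})
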