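# Random search and the genetic algorithm over the parameter space.

small_fit <- function(seed = 1, n_iter = 80, ns = 60) {
  net <- constitutive_model()
  dat <- insilico_small()
  stochfit(net, dat, method = "rs", n_iter = n_iter,
           config = fit_config(ns = ns), seed = seed)
}

test_that("random search scores every candidate and keeps the best", {
  fit <- small_fit()
  expect_s3_class(fit, "stochfit")
  expect_equal(fit$n_eval, 80L)
  expect_equal(fit$best_value, min(fit$trace$value))
  # running minimum is non-increasing
  expect_true(all(diff(cummin(fit$trace$value)) <= 0))
  # every draw respects the bounds
  sp <- fit$space
  for (nm in names(sp$lower)) {
    expect_true(all(fit$trace[[nm]] >= sp$lower[nm]))
    expect_true(all(fit$trace[[nm]] <= sp$upper[nm]))
  }
  expect_error(random_search(constitutive_model(), fit$space,
                             insilico_small(), n_iter = 0), "n_iter")
})

test_that("failed preconditions never trigger stochastic simulation", {
  fit <- small_fit(seed = 3)
  tr <- fit$trace
  expect_true(any(!tr$passed))
  expect_true(all(tr$n_ssa[!tr$passed] == 0L))
  expect_true(all(tr$n_ssa[tr$passed] == 60L))
  expect_true(all(tr$value[!tr$passed] ==
                    fit$config$precondition$penalty))
})

test_that("identical seeds reproduce a fit bit-exactly", {
  f1 <- small_fit(seed = 11, n_iter = 40)
  f2 <- small_fit(seed = 11, n_iter = 40)
  expect_identical(f1$trace, f2$trace)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$best_value, f2$best_value)
})

test_that("fit accessors expose parameters, residuals and simulations", {
  fit <- small_fit(seed = 2)
  th <- coef(fit)
  expect_named(th, c("theta1", "theta3"))
  full <- coef(fit, all = TRUE)
  expect_equal(unname(full["theta2"]), 0.03)

  s <- summary(fit)
  expect_equal(s$n_eval, 80L)
  expect_output(print(s), "passed the precondition")

  res <- residuals(fit)
  expect_equal(length(res), 4L)
  # binned residuals sum to ~0 (both PDFs are normalized)
  for (r in res) expect_equal(sum(r), 0, tolerance = 1e-9)

  sim <- simulate(fit, nsim = 30)
  expect_s3_class(sim, "event_table")
  expect_equal(sim$nm, rep(30L, 4))
})

test_that("the genetic algorithm is elitist and respects its operators", {
  net <- constitutive_model()
  dat <- insilico_small()
  ga <- ga_config(initial_size = 120, size = 12, generations = 3,
                  epsilon = 0.4, mu = 0.2)
  fit <- stochfit(net, dat, method = "ga", config = fit_config(ns = 60),
                  ga = ga, seed = 5)
  expect_equal(fit$n_eval, 120L + 3L * 11L)
  # best per generation never deteriorates (elitist carry-over)
  expect_true(all(diff(fit$generation_best) <= 0))
  expect_equal(min(fit$trace$value), fit$best_value)

  # reproducibility
  fit2 <- stochfit(net, dat, method = "ga",
                   config = fit_config(ns = 60), ga = ga, seed = 5)
  expect_identical(fit$trace, fit2$trace)

  # with mutation off, offspring genes are copies of parent genes
  ga0 <- ga_config(initial_size = 60, size = 10, generations = 1,
                   epsilon = 0.5, mu = 0)
  f0 <- stochfit(net, dat, method = "ga", config = fit_config(ns = 40),
                 ga = ga0, seed = 9)
  tr <- f0$trace
  gen0 <- tr[tr$generation == 0, ]
  gen1 <- tr[tr$generation == 1, ]
  pool <- c(gen0$theta1, gen0$theta3)
  expect_true(all(gen1$theta1 %in% gen0$theta1))
  expect_true(all(gen1$theta3 %in% gen0$theta3))
})

test_that("degenerate genetic-algorithm configurations are rejected", {
  expect_error(ga_config(epsilon = 1), "epsilon")
  expect_error(ga_config(epsilon = 0), "epsilon")
  expect_error(ga_config(mu = 1.2), "mu")
  expect_error(ga_config(size = 1), "sizes")
  expect_error(ga_config(generations = 0), "generations")
})

test_that("repeated scaled-down fits recover the true rates", {
  net <- constitutive_model()
  dat <- insilico_reference()
  est <- t(vapply(1:20, function(s) {
    coef(stochfit(net, dat, method = "rs", n_iter = 300,
                  config = fit_config(ns = 300), seed = s))
  }, numeric(2)))
  expect_lt(abs(median(est[, "theta1"]) - 5) / 5, 0.10)
  expect_lt(abs(median(est[, "theta3"]) - 0.1) / 0.1, 0.10)
})
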