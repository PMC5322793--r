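# Histograms, mode detection and the squared-difference objective.

test_that("the square-root bin rule has a floor of two bins", {
  expect_equal(bin_count(10000), 100L)
  expect_equal(bin_count(4), 2L)
  expect_equal(bin_count(2), 2L)
  expect_error(bin_count(1), ">= 2")
})

test_that("binned PDFs are normalized histograms", {
  bp <- build_distributions(list(c(1, 2, 3, 4)), L = 2)
  expect_equal(bp$bins[[1]]$mass, c(0.5, 0.5))

  # degenerate time point carries all mass in one flagged bin
  dg <- build_distributions(list(rep(7, 10)), L = 5)
  expect_true(dg$bins[[1]]$degenerate)
  expect_equal(dg$bins[[1]]$mass, 1)

  # masses always sum to one
  set.seed(1)
  for (r in 1:10) {
    v <- rlnorm(200, 3, runif(1, 0.1, 1))
    bp <- build_distributions(list(v), L = sample(2:40, 1))
    expect_equal(sum(bp$bins[[1]]$mass), 1, tolerance = 1e-12)
  }
})

test_that("values outside reference edges are clipped into terminal bins", {
  ref <- build_distributions(list(c(0, 10)), L = 4)
  shifted <- build_distributions(list(c(-5, 2, 50)), L = 4,
                                 edges = lapply(ref$bins, `[[`, "edges"))
  m <- shifted$bins[[1]]$mass
  expect_equal(sum(m), 1, tolerance = 1e-12)
  expect_equal(m[1], 2 / 3)   # -5 clipped down, 2 in first bin
  expect_equal(m[4], 1 / 3)   # 50 clipped up
})

test_that("mode detection finds local maxima by prominence", {
  toy <- list(bins = list(list(
    edges = 0:5, centers = 0:4 + 0.5,
    mass = c(0.1, 0.4, 0.1, 0.3, 0.1), degenerate = FALSE)),
    L = 5L, times = 1)
  class(toy) <- "binned_pdf"
  md <- find_modes(toy, min_separation_bins = 2, smooth_bins = 1)
  expect_equal(md$q, 2L)
  expect_equal(md$location, c(1.5, 3.5))

  # a unimodal Gaussian sample yields one mode near its mean
  set.seed(5)
  v <- rnorm(10000, 50, 4)
  bp <- build_distributions(list(v), L = 40)
  md <- find_modes(bp)
  expect_equal(md$q, 1L)
  w <- diff(bp$bins[[1]]$edges[1:2])
  expect_lt(abs(md$location - mean(v)), 2 * w)

  # degenerate distributions cannot be searched
  dg <- build_distributions(list(rep(1, 5)), L = 3)
  expect_error(find_modes(dg), "degenerate")
})

test_that("the objective is a squared distance on a shared grid", {
  mk <- function(mass, edges = seq(0, 1, length.out = length(mass) + 1)) {
    structure(list(bins = list(list(
      edges = edges, centers = (edges[-1] + edges[-length(edges)]) / 2,
      mass = mass, degenerate = FALSE)), L = length(mass), times = 1),
      class = "binned_pdf")
  }
  a <- mk(c(1, 0)); b <- mk(c(0, 1)); c2 <- mk(c(0.25, 0.75))
  d <- mk(c(0.5, 0.5))
  expect_equal(objective_F(a, a), 0)
  expect_equal(objective_F(a, b), 2)
  expect_equal(objective_F(d, c2), 0.125)
  # symmetry
  expect_equal(objective_F(a, c2), objective_F(c2, a))
  expect_gte(objective_F(b, c2), 0)
  # mismatched grids are rejected
  e <- mk(c(0.5, 0.5), edges = c(0, 2, 4))
  expect_error(objective_F(a, e), "edges")
  f3 <- mk(c(0.2, 0.3, 0.5))
  expect_error(objective_F(a, f3), "bin count")
})

test_that("the observation map sums the observable species", {
  net <- irf7_model()
  st <- net$initial_state
  st["IRF7"] <- 10; st["IRF7phosp"] <- 2; st["IRF7dimer"] <- 3
  expect_equal(observe(net, st), 15)
  expect_equal(observe(net, st, phi = 2), 30)

  # total protein at the basal steady state
  basal <- st
  basal["IRF7"] <- 13.62; basal["IRF7phosp"] <- 6.62
  basal["IRF7dimer"] <- 60.19
  expect_equal(observe(net, basal), 80.43)

  # ensemble mapping produces one value list per time point
  ens <- simulate_ensemble(net, net$nominal, times = c(10, 20), ns = 5,
                           base_seed = 1)
  tab <- apply_observation(ens, net)
  expect_s3_class(tab, "event_table")
  expect_equal(tab$nm, c(5L, 5L))
  expect_equal(tab$values[[2]],
               unname(colSums(ens[2, c("IRF7", "IRF7phosp", "IRF7dimer"), ])))
})
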