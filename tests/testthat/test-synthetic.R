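test_that("category probabilities: logistic evaluation and simplex laws", {
  expect_equal(category_probabilities(0, 0), c("1" = 0.5, "2" = 0.5))

  # thresholds of the magnitude reported for intercept-only ordinal fits
  # of birth-size data; expected values from direct 1/(1+exp(-x)) algebra
  th <- c(-1.899, 0.096, 1.551)
  Fcdf <- function(x) 1 / (1 + exp(-x))
  expect_equal(unname(category_probabilities(th, 0)),
               c(Fcdf(th[1]), Fcdf(th[2]) - Fcdf(th[1]),
                 Fcdf(th[3]) - Fcdf(th[2]), 1 - Fcdf(th[3])))
  expect_equal(unname(round(category_probabilities(th, 0), 4)),
               c(0.1302, 0.3938, 0.3011, 0.1749))

  set.seed(3)
  for (rep in 1:20) {
    K <- sample(2:6, 1)
    th <- sort(rnorm(K - 1, sd = 2))
    eta <- rnorm(1, sd = 2)
    p <- category_probabilities(th, eta)
    expect_true(all(p >= 0))
    expect_equal(sum(p), 1)
    expect_true(all(diff(cumsum(p)) >= 0))
    # stochastic ordering: larger eta shifts mass to higher categories
    p2 <- category_probabilities(th, eta + 0.7)
    expect_true(all(cumsum(p2)[-K] < cumsum(p)[-K]))
  }
  expect_error(category_probabilities(c(1, 0), 0), "increasing")
})

test_that("ICAR sampler: constraint, determinism, degenerate variance", {
  g <- synthetic_nigeria_graph()
  f <- sample_icar_field(g, 1.0, seed = 4)
  expect_equal(sum(f), 0, tolerance = 1e-10)
  expect_identical(f, sample_icar_field(g, 1.0, seed = 4))
  expect_equal(sample_icar_field(g, 0, seed = 4), rep(0, 37))
  expect_error(sample_icar_field(g, -1, seed = 4), "non-negative")

  # per-component zero sums on a disconnected graph
  tri2 <- adjacency_graph(6, rbind(c(1, 2), c(2, 3), c(1, 3),
                                   c(4, 5), c(5, 6), c(4, 6)))
  f2 <- sample_icar_field(tri2, 2, seed = 8)
  expect_equal(sum(f2[1:3]), 0, tolerance = 1e-10)
  expect_equal(sum(f2[4:6]), 0, tolerance = 1e-10)

  # sampling leaves the caller's RNG stream untouched
  set.seed(99); before <- rnorm(3)
  set.seed(99); invisible(sample_icar_field(g, 1, seed = 1))
  expect_identical(rnorm(3), before)
})

test_that("simulate_dataset is reproducible and honours degenerate specs", {
  sp <- simulation_spec(n_obs = 300, seed = 10)
  d1 <- simulate_dataset(sp)
  d2 <- simulate_dataset(sp)
  expect_identical(d1$data, d2$data)
  expect_identical(d1$truth$f_str, d2$truth$f_str)
  expect_true(all(d1$data$region %in% d1$graph$labels))
  expect_true(all(d1$data$y %in% 1:4))
  expect_equal(d1$data$y_low, as.integer(d1$data$y == 1))

  expect_error(simulation_spec(thresholds = c(1, 0)), "increasing")
  expect_error(simulation_spec(tau2_str = -1), ">= 0")
  expect_error(
    simulation_spec(continuous = list(x = list(range = c(0, 1), f = "no"))),
    "not a function")
})

test_that("null spec recovers analytic category frequencies at n = 200000", {
  th <- c(0, 1, 2)
  sp <- simulation_spec(
    n_obs = 200000, thresholds = th, continuous = list(),
    categorical = list(), tau2_str = 0, tau2_unstr = 0,
    graph = make_lattice_graph(2, 2), seed = 123)
  ds <- simulate_dataset(sp)
  p <- category_probabilities(th, 0)
  obs <- tabulate(ds$data$y, 4) / 200000
  mc_se <- sqrt(p * (1 - p) / 200000)
  expect_true(all(abs(obs - p) <= 3 * mc_se))
})

test_that("binary reduction sign convention matches the closed form", {
  # K = 2, theta = 0, one balanced effect-coded covariate with gamma = 1:
  # P(y = 1 | coded +1) = F(theta - w) = plogis(-1)
  sp <- simulation_spec(
    n_obs = 100000, thresholds = 0, continuous = list(),
    categorical = list(v = list(levels = c("a", "b"), ref = "a",
                                probs = c(0.5, 0.5), gamma = c(b = 1))),
    tau2_str = 0, tau2_unstr = 0, graph = make_lattice_graph(2, 2),
    seed = 77)
  ds <- simulate_dataset(sp)
  pb <- mean(ds$data$y[ds$data$v == "b"] == 1)
  pa <- mean(ds$data$y[ds$data$v == "a"] == 1)
  expect_equal(pb, plogis(-1), tolerance = 0.01)
  expect_equal(pa, plogis(1), tolerance = 0.01)
})

test_that("dataset CSV writer/reader round-trips and validates regions", {
  ds <- simulate_dataset(simulation_spec(n_obs = 50, seed = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_ordinal_data(ds$data, path)
  back <- read_ordinal_data(path, graph = ds$graph)
  expect_equal(back$y, ds$data$y)
  expect_equal(back$sex, ds$data$sex)
  expect_equal(back$mage, ds$data$mage, tolerance = 1e-12)

  bad <- ds$data
  bad$region[1] <- "nowhere"
  pb <- withr::local_tempfile(fileext = ".csv")
  write_ordinal_data(bad, pb)
  expect_error(read_ordinal_data(pb, graph = ds$graph), "nowhere")
})
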