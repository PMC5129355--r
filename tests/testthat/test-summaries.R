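test_that("odds-ratio transform reproduces published values exactly", {
  r1 <- odds_ratio(0.159, c(0.063, 0.254))
  expect_equal(round(c(r1$or, r1$lower, r1$upper), 2), c(1.17, 1.07, 1.29))
  r2 <- odds_ratio(-0.234, c(-0.318, -0.150))
  expect_equal(round(c(r2$or, r2$lower, r2$upper), 2), c(0.79, 0.73, 0.86))
  r3 <- odds_ratio(-0.118, c(-0.199, -0.037))
  expect_equal(round(c(r3$or, r3$lower, r3$upper), 2), c(0.89, 0.82, 0.96))

  r0 <- odds_ratio(0, c(-0.1, 0.1))
  expect_identical(r0$or, 1)
  expect_equal(round(c(r0$lower, r0$upper), 2), c(0.90, 1.11))

  # strict monotonicity
  b <- sort(rnorm(20))
  expect_true(all(diff(vapply(b, function(x) odds_ratio(x)$or,
                              numeric(1))) > 0))
  expect_error(odds_ratio(0.1, c(0.3, 0.2)), "ordered")
})

test_that("information criteria: identities and deviance-based GCV", {
  a2 <- information_criteria(4990.1, 26.0, 7300)
  expect_equal(unname(a2["AIC"]), 5042.1)
  b2 <- information_criteria(19103.4, 26.0, 7300)
  expect_equal(unname(b2["AIC"]), 19155.4)
  a1 <- information_criteria(22449.4, 35.7, 27983)
  expect_equal(unname(round(a1["GCV"], 3)), 0.804)
  # internal identity AIC - (-2LL) = 2 df for arbitrary rows
  for (d in c(3.5, 26, 67.1))
    expect_equal(unname(information_criteria(1000, d, 5000)["AIC"]) - 1000,
                 2 * d)
  expect_equal(unname(information_criteria(1000, 10, 500)["BIC"]),
               1000 + 10 * log(500))
  expect_error(information_criteria(100, 600, 500), "smaller")
  expect_error(information_criteria(100, -1, 500), "positive")
})

test_that("descriptive table reproduces printed percentages", {
  tab <- descriptive_table(counts = c(4239, 10732, 7852, 5160),
                           denominator = 28647,
                           labels = c("low", "average", "large", "very large"))
  expect_equal(tab$percent, c(14.80, 37.46, 27.41, 18.01))
  expect_equal(sum(tab$count), 27983)

  one <- descriptive_table(y = rep("low", 7))
  expect_equal(one$percent, 100)
  expect_equal(one$count, 7)

  auto <- descriptive_table(y = c(1, 1, 2, 2))
  expect_equal(auto$percent, c(50, 50))
})

test_that("smooth curves satisfy band ordering and the centering constraint", {
  fx <- cached_m3_fit()
  cv <- smooth_curve(fx$fit, "mage")
  expect_true(all(cv$lo95 < cv$lo80))
  expect_true(all(cv$hi95 > cv$hi80))
  expect_true(all(cv$lo80 < cv$estimate & cv$estimate < cv$hi80))

  # fitted term over the data sums to zero (constraint by construction)
  b <- fx$fit$design$blocks[["mage"]]
  term_fit <- fx$fit$design$X[, c(b$u_idx, b$z_idx), drop = FALSE] %*%
    fx$fit$beta[c(b$u_idx, b$z_idx)]
  expect_lt(abs(sum(term_fit)), 1e-6)

  expect_error(smooth_curve(fx$fit, "nope"), "available")
})

test_that("U-shaped age effect is recovered by the geoadditive fit", {
  fx <- cached_m3_fit()
  cv <- smooth_curve(fx$fit, "mage")
  # truth 0.4 ((x - 32)/10)^2 has its minimum at 32
  expect_lt(abs(cv$x[which.min(cv$estimate)] - 32), (49 - 15) / 6)
})

test_that("region classification partitions regions by their intervals", {
  fx <- cached_m3_fit()
  for (w in c("structured", "unstructured", "total")) {
    cr <- classify_regions(fx$fit, w)
    expect_equal(nrow(cr), 37L)
    expect_false(anyNA(cr$class))
    expect_true(all((cr$class == "positive") == (cr$lower95 > 0)))
    expect_true(all((cr$class == "negative") == (cr$upper95 < 0)))
    expect_true(all((cr$class == "nonsignificant") ==
                      (cr$lower95 <= 0 & cr$upper95 >= 0)))
  }
})

test_that("null spatial simulation rarely flags regions (no correction)", {
  g <- synthetic_nigeria_graph()
  flagged <- numeric(0)
  for (r in 1:25) {
    sp <- simulation_spec(n_obs = 1200, thresholds = 0, continuous = list(),
                          categorical = list(), tau2_str = 0, tau2_unstr = 0,
                          graph = g, seed = 900 + r)
    ds <- simulate_dataset(sp)
    fit <- fit_binary(ds$data, model_terms(spatial = spatial_terms(g)),
                      response = "y_low")
    cr <- classify_regions(fit, "total")
    flagged <- c(flagged, mean(cr$class != "nonsignificant"))
  }
  expect_lte(mean(flagged), 0.05 + 0.03)
})

test_that("exports have the declared schemas", {
  fx <- cached_m3_fit()
  d <- withr::local_tempdir()
  p1 <- export_coefficients(fx$fit, file.path(d, "coef.tsv"))
  tab <- read.delim(p1)
  expect_equal(names(tab), c("term", "level", "estimate", "lower95",
                             "upper95", "OR", "OR_lower", "OR_upper"))
  expect_equal(exp(tab$estimate), tab$OR, tolerance = 1e-8)
  p2 <- export_curve(smooth_curve(fx$fit, "mbmi"), file.path(d, "curve.tsv"))
  expect_equal(names(read.delim(p2)),
               c("grid", "estimate", "lo80", "hi80", "lo95", "hi95"))
  p3 <- export_regions(classify_regions(fx$fit), file.path(d, "reg.tsv"))
  expect_equal(names(read.delim(p3)),
               c("region", "estimate", "lower95", "upper95", "class"))
})
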