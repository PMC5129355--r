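test_that("unpenalized binary fitter matches glm and the brute-force oracle", {
  set.seed(31)
  n <- 20
  df <- data.frame(v = rep(c("a", "b"), each = n / 2),
                   u = rep(c("x", "y"), times = n / 2))
  w <- drop(effect_code(df$v, fixed_term("v", c("a", "b"))) * 0.8)
  df$y <- rbinom(n, 1, plogis(-0.3 + w))
  tm <- model_terms(fixed = list(fixed_term("v", c("a", "b")),
                                 fixed_term("u", c("x", "y"))))
  fit <- fit_binary(df, tm)
  X <- cbind(1, effect_code(df$v, fixed_term("v", c("a", "b"))),
             effect_code(df$u, fixed_term("u", c("x", "y"))))
  ours <- c(fit$intercept$estimate, fit$fixed$estimate)
  expect_equal(ours, oracle_binary(df$y, X), tolerance = 1e-6,
               ignore_attr = TRUE)
  gl <- glm(df$y ~ X - 1, family = binomial)
  expect_equal(ours, unname(coef(gl)), tolerance = 1e-6)
  expect_true(fit$converged)
  # with no penalized terms, df is exactly the coefficient count
  expect_equal(fit$df, 3, tolerance = 1e-8)
  expect_equal(effective_df(fit), fit$df)
})

test_that("unpenalized cumulative fitter matches the brute-force oracle", {
  set.seed(32)
  n <- 30; K <- 3
  df <- data.frame(v = sample(c("a", "b"), n, replace = TRUE))
  wv <- drop(effect_code(df$v, fixed_term("v", c("a", "b"))) * 0.9)
  cp <- plogis(outer(-wv, c(-0.5, 0.8), `+`))
  u <- runif(n)
  df$y <- K - rowSums(u <= cp)
  tm <- model_terms(fixed = list(fixed_term("v", c("a", "b"))))
  fit <- fit_cumulative(df, tm, K = K)
  X <- effect_code(df$v, fixed_term("v", c("a", "b")))
  ref <- oracle_cumulative(df$y, X, K)
  expect_equal(c(fit$thresholds$estimate, fit$fixed$estimate), ref,
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_true(all(diff(fit$thresholds$estimate) > 0))
  # MASS::polr uses the same parameterization P(y<=j) = F(zeta_j - x'b)
  if (requireNamespace("MASS", quietly = TRUE)) {
    pl <- MASS::polr(factor(y) ~ v, data = df, method = "logistic")
    # polr's treatment dummy = 2 * effect-coded column
    expect_equal(fit$fixed$estimate * 2, unname(coef(pl)), tolerance = 1e-3)
  }
})

test_that("intercept-only cumulative fit equals the closed-form MLE", {
  set.seed(33)
  y <- sample(1:4, 400, replace = TRUE, prob = c(0.15, 0.37, 0.27, 0.21))
  fit <- fit_cumulative(data.frame(y = y), model_terms(), K = 4)
  cf <- cumsum(tabulate(y, 4))[1:3] / 400
  expect_equal(fit$thresholds$estimate, qlogis(cf), tolerance = 1e-6)
  expect_error(fit_cumulative(data.frame(y = c(1, 1, 3)), model_terms(), K = 3),
               "empty response category: 2")
})

test_that("K = 2 delegates to the binary reduction with consistent signs", {
  set.seed(34)
  n <- 600
  df <- data.frame(v = sample(c("a", "b"), n, replace = TRUE))
  w <- drop(effect_code(df$v, fixed_term("v", c("a", "b"))) * 0.7)
  df$y <- 1L + rbinom(n, 1, 1 - plogis(-w))   # P(y = 1) = F(0 - w)
  tm <- model_terms(fixed = list(fixed_term("v", c("a", "b"))))
  f2 <- fit_cumulative(df, tm, K = 2)
  expect_equal(f2$family, "cumulative")
  expect_equal(nrow(f2$thresholds), 1L)
  # positive cumulative coefficient must mean "towards higher category"
  expect_gt(f2$fixed$estimate, 0.3)
  X <- effect_code(df$v, fixed_term("v", c("a", "b")))
  ref <- oracle_cumulative(df$y, X, 2)
  expect_equal(c(f2$thresholds$estimate, f2$fixed$estimate), ref,
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("tau2 -> 0 collapses a second-order P-spline to its null space", {
  set.seed(35)
  n <- 400
  df <- data.frame(x = runif(n, 0, 1))
  df$y <- rbinom(n, 1, plogis(sin(2 * pi * df$x)))
  tm <- model_terms(smooth = list(pspline_term("x", inner_knots = 8)))
  fit <- fit_binary(df, tm, tau2 = 1e-8)
  cv <- smooth_curve(fit, "x", n_grid = 50)
  # straight line: second differences of the estimate vanish
  expect_lt(max(abs(diff(cv$estimate, differences = 2))), 1e-4)
  expect_lt(term_df(fit)[["x"]], 1.01)
})

test_that("REML recovers curvature and prunes a pure-noise smooth", {
  tau_sig <- c(); tau_noise <- c(); df_noise <- c(); rmse <- matrix(NA, 8, 2)
  for (r in 1:8) {
    set.seed(400 + r)
    n <- 900
    df <- data.frame(x = runif(n, -1, 1), z = runif(n, -1, 1))
    ftrue <- function(x) 1.2 * x^2
    fx <- ftrue(df$x) - mean(ftrue(df$x))   # z has no effect
    df$y <- rbinom(n, 1, plogis(fx))
    tm <- model_terms(smooth = list(pspline_term("x", inner_knots = 8),
                                    pspline_term("z", inner_knots = 8)))
    fit_b <- fit_binary(df, tm)
    tau_sig <- c(tau_sig, fit_b$tau2[["sm_x"]])
    tau_noise <- c(tau_noise, fit_b$tau2[["sm_z"]])
    df_noise <- c(df_noise, term_df(fit_b)[["z"]])
    # curve RMSE against truth: REML fit vs null-space-only (tau2 at floor)
    fit0 <- fit_binary(df, tm, tau2 = c(1e-8, 1e-8))
    grid_truth <- function(f) {
      cv <- smooth_curve(f, "x", n_grid = 40)
      tv <- ftrue(cv$x); tv <- tv - mean(ftrue(df$x))
      sqrt(mean((cv$estimate - tv)^2))
    }
    rmse[r, ] <- c(grid_truth(fit_b), grid_truth(fit0))
  }
  expect_gt(median(tau_sig), 1e-6)            # curvature keeps tau2 alive
  expect_lt(median(rmse[, 1]), median(rmse[, 2]))
  # pure-noise term: effective df near its null-space dimension (1)
  expect_lt(median(df_noise), 1.6)
})

test_that("binary fixed-effect intervals achieve near-nominal coverage", {
  hits <- 0L; total <- 0L
  gam <- c(0.5, -0.3)
  for (r in 1:40) {
    set.seed(500 + r)
    n <- 800
    df <- data.frame(v = sample(c("a", "b"), n, replace = TRUE),
                     u = sample(c("x", "y"), n, replace = TRUE))
    w <- drop(effect_code(df$v, fixed_term("v", c("a", "b")))) * gam[1] +
         drop(effect_code(df$u, fixed_term("u", c("x", "y")))) * gam[2]
    df$y <- rbinom(n, 1, plogis(-0.2 + w))
    fit <- fit_binary(df, model_terms(fixed = list(
      fixed_term("v", c("a", "b")), fixed_term("u", c("x", "y")))))
    hits <- hits + sum(fit$fixed$lower95 <= gam & gam <= fit$fixed$upper95)
    total <- total + 2L
  }
  expect_gte(hits / total, 0.85)
})

test_that("fitting is deterministic and logs its iterations", {
  ds <- simulate_dataset(simulation_spec(n_obs = 400, seed = 6))
  tm <- model_terms(fixed = list(fixed_term("sex", c("female", "male"))),
                    spatial = spatial_terms(ds$graph))
  f1 <- fit_binary(ds$data, tm, response = "y_low")
  f2 <- fit_binary(ds$data, tm, response = "y_low")
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$tau2, f2$tau2)
  expect_gt(length(f1$log), 0L)
  expect_true(all(grepl("outer|clamped|separation", f1$log)))
})

test_that("separation triggers the ridge fallback with a warning", {
  df <- data.frame(y = c(rep(0, 10), rep(1, 10)),
                   v = rep(c("a", "b"), each = 10))
  tm <- model_terms(fixed = list(fixed_term("v", c("a", "b"))))
  expect_warning(fit <- fit_binary(df, tm), "separation")
  expect_true(all(is.finite(fit$fixed$estimate)))
  expect_true(any(grepl("ridge", fit$log)))
})

test_that("effective df interpolates between null space and saturation", {
  set.seed(37)
  n <- 300
  df <- data.frame(x = runif(n))
  df$y <- rbinom(n, 1, 0.5)
  tm <- model_terms(smooth = list(pspline_term("x", inner_knots = 6)))
  lo <- fit_binary(df, tm, tau2 = 1e-8)
  hi <- fit_binary(df, tm, tau2 = 1e8)
  p_total <- ncol(lo$design$X)
  expect_lt(lo$df, 2.05)                  # intercept + linear null space
  expect_gt(hi$df, p_total - 0.1)
  expect_lt(hi$df, p_total + 1e-6)
  # dense-trace oracle at moderate tau2, rebuilt from scratch
  mid <- fit_binary(df, tm, tau2 = 0.5)
  X <- mid$design$X
  mu <- plogis(drop(X %*% mid$beta))
  W <- pmax(mu * (1 - mu), 1e-10)
  S <- rep(0, ncol(X)); S[mid$design$pen[[1]]$idx] <- 1 / 0.5
  H <- crossprod(X * W, X)
  expect_equal(mid$df, sum(diag(solve(H + diag(S), H))), tolerance = 1e-8)
})
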