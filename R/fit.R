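#' Model term collection
#'
#' Declarative description of the additive predictor
#' `w = v'gamma + sum f(x) + f_str(region) + f_unstr(region)`.
#'
#' @param fixed a [fixed_term()] or list of them.
#' @param smooth a [pspline_term()] or list of them.
#' @param spatial a [spatial_term()] or list of them (see [spatial_terms()]
#'   for the usual structured + unstructured pair).
#' @param region name of the region-label column in the data.
#' @return An object of class `model_terms`.
#' @export
model_terms <- function(fixed = list(), smooth = list(), spatial = list(),
                        region = "region") {
  as_list <- function(x, cls) {
    if (inherits(x, cls)) x <- list(x)
    if (!is.list(x) || !all(vapply(x, inherits, logical(1), cls)))
      stop_("expected ", cls, " objects")
    x
  }
  structure(list(fixed = as_list(fixed, "fixed_term"),
                 smooth = as_list(smooth, "pspline_term"),
                 spatial = as_list(spatial, "spatial_term"),
                 region = region),
            class = "model_terms")
}

# Assemble the full design: unpenalized columns first (intercept, effect
# codes, smooth null spaces), then the whitened penalized blocks.
build_design <- function(data, terms, intercept) {
  stopifnot(is.data.frame(data), inherits(terms, "model_terms"))
  n <- nrow(data)
  parts_u <- list(); parts_z <- list()
  blocks <- list(); pen <- list(); fixed_info <- NULL

  if (intercept)
    parts_u[["(Intercept)"]] <- matrix(1, n, 1L,
                                       dimnames = list(NULL, "(Intercept)"))

  for (ft in terms$fixed) {
    if (!ft$name %in% names(data)) stop_("column '", ft$name, "' not in data")
    M <- effect_code(data[[ft$name]], ft)
    parts_u[[paste0("fx_", ft$name)]] <- M
    fixed_info <- rbind(fixed_info,
                        data.frame(term = ft$name,
                                   level = setdiff(ft$levels, ft$ref),
                                   col = colnames(M),
                                   stringsAsFactors = FALSE))
  }

  smooth_prep <- list()
  for (st in terms$smooth) {
    if (!st$name %in% names(data)) stop_("column '", st$name, "' not in data")
    x <- data[[st$name]]
    if (!is.numeric(x)) stop_("smooth covariate '", st$name, "' must be numeric")
    st$range <- st$range %||% range(x)
    B <- bspline_basis(x, st)
    Kp <- difference_penalty(st$n_basis, st$penalty_order)
    cc <- center_constraint(B, Kp)
    rp <- reparameterize(cc$basis, cc$penalty)
    if (ncol(rp$Xu))
      colnames(rp$Xu) <- paste0(st$name, ":u", seq_len(ncol(rp$Xu)))
    colnames(rp$Z) <- paste0(st$name, ":z", seq_len(ncol(rp$Z)))
    parts_u[[paste0("sm_", st$name)]] <- rp$Xu
    smooth_prep[[st$name]] <- list(term = st, Zc = cc$transform,
                                   V0 = rp$null_basis, W = rp$whitener,
                                   Z = rp$Z)
  }

  region_ind <- function(graph) {
    lab <- trimws(as.character(data[[terms$region]]))
    idx <- match(lab, graph$labels)
    if (anyNA(idx))
      stop_("region label(s) not in graph: ",
            paste(unique(lab[is.na(idx)]), collapse = ", "))
    Ind <- matrix(0, n, graph$n_regions)
    Ind[cbind(seq_len(n), idx)] <- 1
    Ind
  }

  # penalized blocks, in declaration order: smooths first, then spatial
  for (nm in names(smooth_prep)) parts_z[[paste0("sm_", nm)]] <- smooth_prep[[nm]]$Z
  spatial_prep <- list()
  for (sp in terms$spatial) {
    if (!terms$region %in% names(data))
      stop_("region column '", terms$region, "' not in data")
    Ind <- region_ind(sp$graph)
    if (sp$kind == "structured") {
      rp <- reparameterize(Ind, mrf_penalty(sp$graph))
      colnames(rp$Z) <- paste0("spat_str:z", seq_len(ncol(rp$Z)))
      parts_z[["spat_str"]] <- rp$Z
      spatial_prep[["spat_str"]] <- list(graph = sp$graph, Wmat = rp$whitener)
    } else {
      colnames(Ind) <- paste0("spat_unstr:", sp$graph$labels)
      parts_z[["spat_unstr"]] <- Ind
      spatial_prep[["spat_unstr"]] <- list(graph = sp$graph)
    }
  }

  Xu <- do.call(cbind, c(parts_u, list(matrix(0, n, 0L))))
  Xz <- do.call(cbind, c(parts_z, list(matrix(0, n, 0L))))
  X <- cbind(Xu, Xz)
  p_u <- ncol(Xu)

  at <- p_u
  # column bookkeeping for penalized blocks
  for (nm in names(parts_z)) {
    q <- ncol(parts_z[[nm]])
    pen[[nm]] <- list(name = nm, idx = at + seq_len(q), q = q)
    at <- at + q
  }
  # per-term block metadata (for curves / maps)
  at_u <- if (intercept) 1L else 0L
  if (!is.null(fixed_info)) {
    fixed_info$idx <- at_u + seq_len(nrow(fixed_info))
    at_u <- at_u + nrow(fixed_info)
  }
  for (nm in names(smooth_prep)) {
    spp <- smooth_prep[[nm]]
    p0 <- ncol(spp$V0)
    blocks[[nm]] <- list(type = "smooth", term = spp$term, Zc = spp$Zc,
                         V0 = spp$V0, W = spp$W,
                         u_idx = if (p0) at_u + seq_len(p0) else integer(0),
                         z_idx = pen[[paste0("sm_", nm)]]$idx)
    at_u <- at_u + p0
  }
  for (nm in names(spatial_prep)) {
    blocks[[nm]] <- c(spatial_prep[[nm]],
                      list(type = nm, z_idx = pen[[nm]]$idx))
  }

  list(X = X, n = n, p_u = p_u, pen = unname(pen), blocks = blocks,
       fixed_info = fixed_info,
       intercept_idx = if (intercept) 1L else integer(0))
}

#' Fitting control parameters
#'
#' @param inner_tol,inner_maxit convergence tolerance (relative change of
#'   the penalized log-likelihood) and iteration cap of the penalized IWLS
#'   inner loop.
#' @param outer_tol,outer_maxit convergence tolerance (relative change of
#'   all coefficients and log-variances) and iteration cap of the outer
#'   variance-component loop.
#' @param tau2_floor lower clamp for variance components.
#' @param tau2_init starting value for every variance component.
#' @return A list of class `fit_control`.
#' @export
fit_control <- function(inner_tol = 1e-8, inner_maxit = 100L,
                        outer_tol = 1e-6, outer_maxit = 200L,
                        tau2_floor = 1e-8, tau2_init = 1) {
  structure(list(inner_tol = inner_tol, inner_maxit = as.integer(inner_maxit),
                 outer_tol = outer_tol, outer_maxit = as.integer(outer_maxit),
                 tau2_floor = tau2_floor, tau2_init = tau2_init),
            class = "fit_control")
}

# ---- penalized IWLS engines -------------------------------------------------

solve_spd <- function(H, g) {
  tryCatch(solve(H, g), error = function(e) {
    solve(H + diag(1e-8 * max(diag(H), 1), nrow(H)), g)
  })
}

pirls_binary_ <- function(y, X, Spen, beta, control) {
  ll_of <- function(eta) sum(stats::dbinom(y, 1L, stats::plogis(eta), log = TRUE))
  eta <- drop(X %*% beta)
  pll <- ll_of(eta) - 0.5 * sum(Spen * beta^2)
  converged <- FALSE; it <- 0L
  wgt <- NULL
  while (it < control$inner_maxit) {
    it <- it + 1L
    mu <- stats::plogis(eta)
    wgt <- pmax(mu * (1 - mu), 1e-10)
    grad <- drop(crossprod(X, y - mu)) - Spen * beta
    H <- crossprod(X * wgt, X)
    diag(H) <- diag(H) + Spen
    step <- drop(solve_spd(H, grad))
    tfac <- 1; ok <- FALSE
    for (h in 1:30) {
      beta_new <- beta + tfac * step
      eta_new <- drop(X %*% beta_new)
      pll_new <- ll_of(eta_new) - 0.5 * sum(Spen * beta_new^2)
      if (is.finite(pll_new) && pll_new >= pll - 1e-12) { ok <- TRUE; break }
      tfac <- tfac / 2
    }
    if (!ok) { converged <- TRUE; break }    # no ascent direction left
    rel <- max(abs(beta_new - beta) / (abs(beta) + 1))
    beta <- beta_new; eta <- eta_new; pll <- pll_new
    if (rel < control$inner_tol) { converged <- TRUE; break }
  }
  mu <- stats::plogis(eta)
  wgt <- pmax(mu * (1 - mu), 1e-10)
  list(beta = beta, eta = eta, loglik = ll_of(eta), pll = pll,
       H_unpen = symmetrize(crossprod(X * wgt, X)),
       iters = it, converged = converged)
}

# Proportional-odds Fisher scoring with the full multicategorical weight
# structure; thresholds carried as psi = (theta1, log-increments) so the
# ordering theta_1 < ... < theta_{K-1} is structural.
theta_of_psi <- function(psi) cumsum(c(psi[1L], exp(psi[-1L])))

psi_of_theta <- function(theta) c(theta[1L], log(diff(theta)))

cum_loglik_ <- function(y, theta, w) {
  cp <- stats::plogis(outer(-w, theta, `+`))
  P <- cbind(cp, 1) - cbind(0, cp)
  sum(log(pmax(P[cbind(seq_along(y), y)], 1e-300)))
}

pirls_cumulative_ <- function(y, K, X, Spen, psi, beta, control) {
  n <- length(y); p <- ncol(X)
  Km1 <- K - 1L
  wlin <- if (p) drop(X %*% beta) else numeric(n)
  penv <- function(b) if (p) 0.5 * sum(Spen * b^2) else 0
  pll <- cum_loglik_(y, theta_of_psi(psi), wlin) - penv(beta)
  converged <- FALSE; it <- 0L
  H_unpen <- NULL
  yj <- lapply(seq_len(K), function(j) as.numeric(y == j))
  build <- function(psi, beta, wlin) {
    theta <- theta_of_psi(psi)
    cp <- stats::plogis(outer(-wlin, theta, `+`))        # n x (K-1)
    P <- cbind(cp, 1) - cbind(0, cp)
    Pf <- pmax(P, 1e-10)
    f <- cp * (1 - cp)
    U <- matrix(0, n, Km1); D <- matrix(0, n, Km1)
    O <- if (Km1 > 1L) matrix(0, n, Km1 - 1L) else NULL
    for (j in seq_len(Km1)) {
      U[, j] <- f[, j] * (yj[[j]] / Pf[, j] - yj[[j + 1L]] / Pf[, j + 1L])
      D[, j] <- f[, j]^2 * (1 / Pf[, j] + 1 / Pf[, j + 1L])
      if (j < Km1) O[, j] <- -f[, j] * f[, j + 1L] / Pf[, j + 1L]
    }
    R <- D
    if (Km1 > 1L) {
      R[, -Km1] <- R[, -Km1, drop = FALSE] + O
      R[, -1L] <- R[, -1L, drop = FALSE] + O
    }
    Atheta <- diag(colSums(D), Km1)
    if (Km1 > 1L) for (j in seq_len(Km1 - 1L)) {
      Atheta[j, j + 1L] <- Atheta[j + 1L, j] <- sum(O[, j])
    }
    J <- matrix(0, Km1, Km1); J[, 1L] <- 1
    if (Km1 > 1L) for (m in 2:Km1) J[m:Km1, m] <- exp(psi[m])
    gtheta <- colSums(U)
    Hpp <- crossprod(J, Atheta %*% J)
    gpsi <- drop(crossprod(J, gtheta))
    if (p) {
      s <- rowSums(R)
      Atb <- -crossprod(R, X)                            # (K-1) x p
      Abb <- symmetrize(crossprod(X * s, X))
      diag(Abb) <- diag(Abb) + Spen
      Hpb <- crossprod(J, Atb)
      H <- rbind(cbind(Hpp, Hpb), cbind(t(Hpb), Abb))
      g <- c(gpsi, -drop(crossprod(X, rowSums(U))) - Spen * beta)
      Hu <- rbind(cbind(Hpp, Hpb),
                  cbind(t(Hpb), symmetrize(crossprod(X * s, X))))
    } else {
      H <- Hpp; g <- gpsi; Hu <- Hpp
    }
    list(H = H, g = g, H_unpen = symmetrize(Hu), J = J)
  }
  while (it < control$inner_maxit) {
    it <- it + 1L
    parts <- build(psi, beta, wlin)
    step <- drop(solve_spd(parts$H, parts$g))
    tfac <- 1; ok <- FALSE
    for (h in 1:30) {
      cand <- c(psi, beta) + tfac * step
      psi_new <- cand[seq_len(Km1)]
      beta_new <- if (p) cand[-seq_len(Km1)] else numeric(0)
      wlin_new <- if (p) drop(X %*% beta_new) else wlin
      pll_new <- cum_loglik_(y, theta_of_psi(psi_new), wlin_new) - penv(beta_new)
      if (is.finite(pll_new) && pll_new >= pll - 1e-12) { ok <- TRUE; break }
      tfac <- tfac / 2
    }
    if (!ok) { converged <- TRUE; break }
    rel <- max(abs(cand - c(psi, beta)) / (abs(c(psi, beta)) + 1))
    psi <- psi_new; beta <- beta_new; wlin <- wlin_new; pll <- pll_new
    if (rel < control$inner_tol) { converged <- TRUE; break }
  }
  parts <- build(psi, beta, wlin)
  list(psi = psi, theta = theta_of_psi(psi), beta = beta,
       loglik = cum_loglik_(y, theta_of_psi(psi), wlin), pll = pll,
       H_unpen = parts$H_unpen, J = parts$J,
       iters = it, converged = converged)
}

# ---- outer loop: variance components by working-model REML ------------------

# Schall-type REML update on the working mixed model: for block j with q_j
# whitened coefficients b_j and covariance C = (H + S)^{-1},
#   tau_j <- ||b_j||^2 / (q_j - tr(C_jj) / tau_j),
# clamped at the variance floor.
update_tau2_ <- function(beta, Cdiag, pen, tau2, offset, floor_) {
  out <- tau2
  for (j in seq_along(pen)) {
    b <- beta[pen[[j]]$idx]
    trj <- sum(Cdiag[offset + pen[[j]]$idx])
    nu <- pen[[j]]$q - trj / tau2[[j]]
    out[[j]] <- if (nu <= 1e-10) floor_ else max(sum(b^2) / nu, floor_)
  }
  out
}

fit_core_ <- function(y, design, family, K, tau2, control) {
  X <- design$X; pen <- design$pen
  n <- design$n; p <- ncol(X)
  off <- if (family == "cumulative") K - 1L else 0L
  logl <- character(0)
  reml <- is.null(tau2) && length(pen) > 0L
  if (is.null(tau2)) tau2 <- rep(control$tau2_init, length(pen))
  if (length(tau2) != length(pen))
    stop_("`tau2` must supply one variance per penalized term (",
          length(pen), " needed)")
  tau2 <- pmax(as.numeric(tau2), control$tau2_floor)

  spen_of <- function(tau2) {
    s <- rep(0, p)
    for (j in seq_along(pen)) s[pen[[j]]$idx] <- 1 / tau2[[j]]
    s
  }

  beta <- rep(0, p)
  psi <- NULL
  if (family == "cumulative") {
    cf <- cumsum(tabulate(y, nbins = K)) / n
    theta0 <- stats::qlogis(pmin(pmax(cf[seq_len(K - 1L)], 1e-6), 1 - 1e-6))
    theta0 <- theta0 + cumsum(c(0, pmax(1e-4 - diff(theta0), 0)))  # enforce order
    psi <- psi_of_theta(theta0)
  } else if (length(design$intercept_idx)) {
    beta[design$intercept_idx] <- stats::qlogis(min(max(mean(y), 1e-4), 1 - 1e-4))
  }

  inner <- NULL; outer_it <- 0L; inner_total <- 0L
  outer_conv <- TRUE
  # Aitken acceleration state for the (linearly convergent) variance updates
  acc_step <- NULL; acc_phase <- 0L
  repeat {
    outer_it <- outer_it + 1L
    Spen <- spen_of(tau2)
    inner <- if (family == "binary")
      pirls_binary_(y, X, Spen, beta, control)
    else
      pirls_cumulative_(y, K, X, Spen, psi, beta, control)
    beta <- inner$beta
    if (family == "cumulative") psi <- inner$psi
    inner_total <- inner_total + inner$iters
    if (!reml) break
    Hpen <- inner$H_unpen
    full_idx <- off + seq_len(p)
    diag(Hpen)[full_idx] <- diag(Hpen)[full_idx] + Spen
    C <- tryCatch(chol2inv(chol(Hpen)), error = function(e) solve(Hpen))
    tau2_new <- update_tau2_(beta, diag(C), pen, tau2, off, control$tau2_floor)
    if (any(tau2_new <= control$tau2_floor & tau2 > control$tau2_floor))
      logl <- c(logl, paste0("outer ", outer_it,
                             ": variance component clamped at floor"))
    par_old <- c(psi, beta, log(tau2))
    par_new <- c(psi, beta, log(tau2_new))
    rel <- max(abs(par_new - par_old) / (abs(par_old) + 1))
    logl <- c(logl, sprintf("outer %d: pll=%.6f inner_iters=%d tau2=[%s]",
                            outer_it, inner$pll, inner$iters,
                            paste(signif(tau2_new, 4), collapse = ", ")))
    if (rel < control$outer_tol) { tau2 <- tau2_new; break }
    if (outer_it >= control$outer_maxit) {
      tau2 <- tau2_new; outer_conv <- FALSE; break
    }
    # Aitken extrapolation on log tau2: the Schall map is linearly
    # convergent (near-unit rate when structured/unstructured components
    # compete), so estimate the per-component rate from consecutive raw
    # updates and jump towards the fixed point, capping each jump at 1 on
    # the log scale.  Raw steps drive the convergence checks above.
    step <- log(tau2_new) - log(tau2)
    jump <- step
    if (!is.null(acc_step)) {
      rho <- ifelse(abs(acc_step) > 1e-12, step / acc_step, 0)
      boost <- ifelse(rho > 0 & rho < 0.9999, 1 / (1 - rho), 1)
      jump <- sign(step) * pmin(abs(step) * boost, 1)
    }
    acc_step <- step
    tau2 <- pmax(exp(log(tau2) + jump), control$tau2_floor)
  }

  # separation guard for the binary model: runaway unpenalized coefficients
  if (family == "binary" && p > 0L) {
    unpen <- setdiff(seq_len(p), unlist(lapply(pen, `[[`, "idx")))
    if (length(unpen) && (any(!is.finite(beta)) ||
                          max(abs(inner$eta)) > 20)) {
      logl <- c(logl, "possible complete separation: ridge fallback (1e-4) applied")
      warning("possible complete separation; ridge fallback applied",
              call. = FALSE)
      Spen <- spen_of(tau2)
      Spen[unpen] <- Spen[unpen] + 1e-4
      inner <- pirls_binary_(y, X, Spen, rep(0, p), control)
      beta <- inner$beta
    }
  }

  Spen <- spen_of(tau2)
  Hpen <- inner$H_unpen
  if (p > 0L) {
    full_idx <- off + seq_len(p)
    diag(Hpen)[full_idx] <- diag(Hpen)[full_idx] + Spen
  }
  C <- tryCatch(chol2inv(chol(symmetrize(Hpen))),
                error = function(e) solve(symmetrize(Hpen)))
  edf <- sum(C * inner$H_unpen)
  minus2ll <- -2 * inner$loglik
  crit <- information_criteria(minus2ll, edf, n)

  list(beta = beta, psi = psi,
       theta = if (family == "cumulative") theta_of_psi(psi),
       J = inner$J, tau2 = tau2, C = C, H_unpen = inner$H_unpen,
       minus2ll = minus2ll, df = edf, aic = crit[["AIC"]],
       bic = crit[["BIC"]], gcv = crit[["GCV"]],
       loglik = inner$loglik, offset = off,
       converged = inner$converged && outer_conv,
       iterations = list(outer = outer_it, inner = inner_total),
       log = logl)
}

ci_table_ <- function(est, se) {
  z <- stats::qnorm(0.975)
  data.frame(estimate = est, se = se,
             lower95 = est - z * se, upper95 = est + z * se)
}

assemble_fit_ <- function(core, design, terms, family, K, response, n) {
  off <- core$offset
  Cd <- diag(core$C)
  fixed <- NULL
  if (!is.null(design$fixed_info)) {
    fi <- design$fixed_info
    fixed <- cbind(fi[c("term", "level")],
                   ci_table_(core$beta[fi$idx], sqrt(pmax(Cd[off + fi$idx], 0))))
    rownames(fixed) <- NULL
  }
  thresholds <- NULL; intercept <- NULL
  if (family == "cumulative") {
    Vth <- core$J %*% core$C[seq_len(off), seq_len(off), drop = FALSE] %*% t(core$J)
    thresholds <- cbind(data.frame(par = paste0("theta", seq_len(K - 1L))),
                        ci_table_(core$theta, sqrt(pmax(diag(Vth), 0))))
  } else if (length(design$intercept_idx)) {
    i <- design$intercept_idx
    intercept <- ci_table_(core$beta[i], sqrt(pmax(Cd[i], 0)))
  }
  names(core$tau2) <- vapply(design$pen, `[[`, character(1), "name")
  structure(list(family = family, response = response, n = n, K = K,
                 terms = terms, design = design,
                 beta = core$beta, psi = core$psi,
                 thresholds = thresholds, intercept = intercept,
                 fixed = fixed, tau2 = core$tau2,
                 minus2ll = core$minus2ll, df = core$df, aic = core$aic,
                 bic = core$bic, gcv = core$gcv, loglik = core$loglik,
                 converged = core$converged, iterations = core$iterations,
                 log = core$log, C = core$C, H_unpen = core$H_unpen,
                 offset = off),
            class = "spatord_fit")
}

#' Fit the geoadditive binary logit model
#'
#' Maximizes the penalized Bernoulli-logit log-likelihood
#' `P(y = 1) = F(gamma0 + w)` by IWLS with step-halving; variance
#' components of the penalized (smooth / spatial) blocks are estimated by
#' the working-model REML iteration unless fixed via `tau2`.  Under this
#' convention a *positive* coefficient increases the probability of the
#' `y = 1` (detrimental, low-birth-weight) outcome.
#'
#' @param data a data.frame.
#' @param terms a [model_terms()] declaration.
#' @param response name of the 0/1 response column.
#' @param tau2 `NULL` for REML, or a numeric vector fixing one variance per
#'   penalized term (declaration order: smooths, then spatial).
#' @param control a [fit_control()].
#' @return An object of class `spatord_fit`.
#' @export
fit_binary <- function(data, terms, response = "y", tau2 = NULL,
                       control = fit_control()) {
  y <- data[[response]]
  if (is.null(y)) stop_("response column '", response, "' not in data")
  y <- as.numeric(y)
  if (anyNA(y) || !all(y %in% c(0, 1)))
    stop_("binary response must be coded 0/1 without missing values")
  design <- build_design(data, terms, intercept = TRUE)
  core <- fit_core_(y, design, "binary", K = 2L, tau2 = tau2, control = control)
  assemble_fit_(core, design, terms, "binary", 2L, response, design$n)
}

#' Fit the cumulative (proportional-odds) logit model
#'
#' Maximizes the penalized multinomial likelihood of the cumulative model
#' `P(y <= j) = F(theta_j - w)` by Fisher scoring on the stacked
#' category-indicator working responses with the full multicategorical
#' weight matrix.  Thresholds are kept strictly ordered structurally (first
#' threshold free, increments parameterized on the log scale).  A
#' *positive* coefficient shifts probability mass towards *higher*
#' (larger-size) categories.  `K = 2` delegates to [fit_binary()] on
#' `y == 1` and maps the result back (`theta1 = intercept`, coefficients
#' negated).
#'
#' @inheritParams fit_binary
#' @param response name of the response column, coded `1..K`.
#' @param K number of categories (default: `max(y)`); every category must
#'   be observed.
#' @return An object of class `spatord_fit`.
#' @export
fit_cumulative <- function(data, terms, response = "y", K = NULL, tau2 = NULL,
                           control = fit_control()) {
  y <- data[[response]]
  if (is.null(y)) stop_("response column '", response, "' not in data")
  y <- as.integer(y)
  K <- as.integer(K %||% max(y, na.rm = TRUE))
  if (K < 2L) stop_("need at least 2 categories")
  if (anyNA(y) || any(y < 1L | y > K))
    stop_("ordinal response must be coded 1..K without missing values")
  cnt <- tabulate(y, nbins = K)
  if (any(cnt == 0L))
    stop_("empty response category: ", paste(which(cnt == 0L), collapse = ", "))
  if (K == 2L) {
    dat2 <- data
    dat2[[".y_bin"]] <- as.integer(y == 1L)
    fb <- fit_binary(dat2, terms, response = ".y_bin", tau2 = tau2,
                     control = control)
    return(binary_as_cumulative_(fb, response))
  }
  design <- build_design(data, terms, intercept = FALSE)
  core <- fit_core_(y, design, "cumulative", K = K, tau2 = tau2,
                    control = control)
  assemble_fit_(core, design, terms, "cumulative", K, response, design$n)
}

# K = 2 reduction: P(y<=1) = F(theta1 - w) equals a binary logit on
# (y == 1) with intercept theta1 and negated slope coefficients.
binary_as_cumulative_ <- function(fb, response) {
  i <- fb$design$intercept_idx
  keep <- setdiff(seq_along(fb$beta), i)
  fb$family <- "cumulative"
  fb$response <- response
  fb$psi <- fb$intercept$estimate
  fb$thresholds <- cbind(data.frame(par = "theta1"), fb$intercept)
  fb$intercept <- NULL
  # reorder covariance as (theta | coefficients) and flip coefficient signs
  Sgn <- c(1, rep(-1, length(keep)))
  P <- fb$C[c(i, keep), c(i, keep), drop = FALSE]
  fb$C <- P * tcrossprod(Sgn)
  fb$H_unpen <- fb$H_unpen[c(i, keep), c(i, keep), drop = FALSE] * tcrossprod(Sgn)
  fb$beta <- -fb$beta[keep]
  if (!is.null(fb$fixed)) {
    fb$fixed$estimate <- -fb$fixed$estimate
    lo <- fb$fixed$lower95
    fb$fixed$lower95 <- -fb$fixed$upper95
    fb$fixed$upper95 <- -lo
  }
  fb$offset <- 1L
  # shift stored column indices: intercept removed, theta occupies slot 1
  shift <- function(ix) match(ix, keep)
  if (!is.null(fb$design$fixed_info)) fb$design$fixed_info$idx <- shift(fb$design$fixed_info$idx)
  for (nm in names(fb$design$blocks)) {
    b <- fb$design$blocks[[nm]]
    if (length(b$u_idx)) fb$design$blocks[[nm]]$u_idx <- shift(b$u_idx)
    fb$design$blocks[[nm]]$z_idx <- shift(b$z_idx)
  }
  fb$design$pen <- lapply(fb$design$pen, function(pn) {
    pn$idx <- shift(pn$idx); pn
  })
  fb$design$intercept_idx <- integer(0)
  fb$K <- 2L
  fb$log <- c(fb$log, "K = 2: fitted via the binary reduction")
  fb
}

#' Effective degrees of freedom of a fit
#'
#' Trace of the influence (hat) matrix of the working penalized
#' least-squares problem at convergence:
#' `tr((H + S)^{-1} H)` with `H` the unpenalized information and `S` the
#' penalty at the estimated variance components.  Bounded below by the
#' number of unpenalized coefficients and above by the total count.
#'
#' @param fit a `spatord_fit`.
#' @return A single number.
#' @export
effective_df <- function(fit) {
  stopifnot(inherits(fit, "spatord_fit"))
  sum(fit$C * fit$H_unpen)
}

#' Per-term effective degrees of freedom
#'
#' Splits the hat-matrix trace into additive contributions: thresholds /
#' intercept / fixed effects (`parametric`) and one entry per smooth or
#' spatial term (null-space plus penalized columns).  Entries sum to
#' [effective_df()].
#'
#' @param fit a `spatord_fit`.
#' @return Named numeric vector.
#' @export
term_df <- function(fit) {
  stopifnot(inherits(fit, "spatord_fit"))
  d <- rowSums(fit$C * fit$H_unpen)    # diag((H+S)^{-1} H), H symmetric
  used <- integer(0)
  out <- numeric(0)
  for (nm in names(fit$design$blocks)) {
    b <- fit$design$blocks[[nm]]
    idx <- fit$offset + c(b$u_idx, b$z_idx)
    out[[nm]] <- sum(d[idx])
    used <- c(used, idx)
  }
  c(parametric = sum(d[setdiff(seq_along(d), used)]), out)
}

#' @export
print.spatord_fit <- function(x, ...) {
  cat(sprintf("<spatord_fit> %s model, n = %d%s\n", x$family, x$n,
              if (x$family == "cumulative") paste0(", K = ", x$K) else ""))
  cat(sprintf("  -2LL = %.1f  df = %.1f  AIC = %.1f  BIC = %.1f  GCV = %.3f\n",
              x$minus2ll, x$df, x$aic, x$bic, x$gcv))
  if (length(x$tau2))
    cat("  tau2:", paste(sprintf("%s = %.4g", names(x$tau2), x$tau2),
                         collapse = ", "), "\n")
  cat(sprintf("  converged: %s (%d outer / %d inner iterations)\n",
              x$converged, x$iterations$outer, x$iterations$inner))
  invisible(x)
}

#' @export
summary.spatord_fit <- function(object, ...) {
  print(object)
  if (!is.null(object$thresholds)) {
    cat("\nThresholds:\n"); print(object$thresholds, digits = 4)
  }
  if (!is.null(object$intercept)) {
    cat("\nIntercept:\n"); print(object$intercept, digits = 4)
  }
  if (!is.null(object$fixed)) {
    cat("\nFixed effects (effect coding, +1 own / -1 reference):\n")
    print(object$fixed, digits = 4)
  }
  invisible(object)
}
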