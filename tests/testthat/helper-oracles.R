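# Independent brute-force maximizers used as oracles for the fitters.
# They know nothing about the package internals: plain negative
# log-likelihoods minimized by BFGS, then polished by Newton steps with
# numerical (central-difference) derivatives.

num_grad <- function(f, p, h = 1e-5) {
  vapply(seq_along(p), function(i) {
    e <- replace(numeric(length(p)), i, h)
    (f(p + e) - f(p - e)) / (2 * h)
  }, numeric(1))
}

num_hess <- function(f, p, h = 1e-4) {
  n <- length(p)
  H <- matrix(0, n, n)
  for (i in seq_len(n)) {
    e <- replace(numeric(n), i, h)
    H[, i] <- (num_grad(f, p + e) - num_grad(f, p - e)) / (2 * h)
  }
  (H + t(H)) / 2
}

brute_maximize <- function(nll, start) {
  op <- optim(start, nll, method = "BFGS",
              control = list(reltol = 1e-15, maxit = 5000))
  p <- op$par
  for (k in 1:25) {
    g <- num_grad(nll, p)
    if (max(abs(g)) < 1e-9) break
    H <- num_hess(nll, p)
    step <- tryCatch(solve(H, g), error = function(e) g)
    # backtrack to guarantee descent of the nll
    t <- 1
    while (t > 1e-8 && (!is.finite(nll(p - t * step)) ||
                        nll(p - t * step) > nll(p))) t <- t / 2
    p <- p - t * step
  }
  p
}

# binary logit: P(y = 1) = plogis(X b)
oracle_binary <- function(y, X) {
  nll <- function(b) {
    eta <- drop(X %*% b)
    -sum(y * eta - log1p(exp(eta)))
  }
  brute_maximize(nll, rep(0, ncol(X)))
}

# cumulative logit P(y <= j) = plogis(theta_j - X b); params (theta, b)
oracle_cumulative <- function(y, X, K) {
  n <- length(y)
  nll <- function(p) {
    theta <- p[seq_len(K - 1)]
    if (any(diff(theta) <= 0)) return(1e10)
    b <- p[-seq_len(K - 1)]
    w <- if (ncol(X)) drop(X %*% b) else numeric(n)
    cp <- plogis(outer(-w, theta, `+`))
    P <- cbind(cp, 1) - cbind(0, cp)
    -sum(log(pmax(P[cbind(seq_len(n), y)], 1e-300)))
  }
  cf <- cumsum(tabulate(y, nbins = K))[seq_len(K - 1)] / n
  brute_maximize(nll, c(qlogis(cf), rep(0, ncol(X))))
}

# textbook Cox-de Boor recursion, evaluated pointwise
deboor_basis <- function(x, knots, degree) {
  nb <- length(knots) - degree - 1L
  B0 <- function(i, xx) {
    # right-closed last interval so x = max is representable
    if (i == nb + degree &&
        xx == knots[i + 1L]) return(1)
    as.numeric(xx >= knots[i] & xx < knots[i + 1L])
  }
  rec <- function(i, d, xx) {
    if (d == 0L) return(B0(i, xx))
    a <- if (knots[i + d] > knots[i])
      (xx - knots[i]) / (knots[i + d] - knots[i]) * rec(i, d - 1L, xx) else 0
    b <- if (knots[i + d + 1L] > knots[i + 1L])
      (knots[i + d + 1L] - xx) / (knots[i + d + 1L] - knots[i + 1L]) *
        rec(i + 1L, d - 1L, xx) else 0
    a + b
  }
  out <- matrix(0, length(x), nb)
  for (r in seq_along(x)) for (i in seq_len(nb))
    out[r, i] <- rec(i, degree, x[r])
  out
}

# Moore-Penrose pseudo-inverse via eigendecomposition (oracle for ICAR)
pinv_sym <- function(M, tol = 1e-9) {
  eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
  pos <- eg$values > max(abs(eg$values)) * tol
  V <- eg$vectors[, pos, drop = FALSE]
  V %*% (t(V) / eg$values[pos])
}
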