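#' Odds-ratio transform
#'
#' Componentwise exponential of a coefficient and its interval.  Exact and
#' strictly monotone; rounding (2 decimals in the tables) is presentation
#' only and left to the caller.
#'
#' @param estimate coefficient on the log-odds scale.
#' @param ci optional interval `c(lower, upper)` with `lower <= upper`.
#' @return A list with `or` and, when `ci` is given, `lower` and `upper`.
#' @export
odds_ratio <- function(estimate, ci = NULL) {
  if (!is.finite(estimate)) stop_("`estimate` must be finite")
  out <- list(or = exp(estimate))
  if (!is.null(ci)) {
    ci <- as.numeric(ci)
    if (length(ci) != 2L || !all(is.finite(ci)) || ci[1L] > ci[2L])
      stop_("`ci` must be an ordered finite pair")
    out$lower <- exp(ci[1L]); out$upper <- exp(ci[2L])
  }
  out
}

#' Model comparison criteria
#'
#' `AIC = -2LL + 2 df`, `BIC = -2LL + df log(n)` and the deviance-based
#' generalized cross-validation score `GCV = (-2LL / n) / (1 - df / n)^2`,
#' with `df` the effective degrees of freedom of the penalized fit.
#'
#' @param minus2ll deviance (-2 log-likelihood).
#' @param df effective degrees of freedom, `0 < df < n`.
#' @param n number of observations.
#' @return Named numeric vector `c(AIC, BIC, GCV)`.
#' @export
information_criteria <- function(minus2ll, df, n) {
  if (!is.finite(minus2ll)) stop_("`minus2ll` must be finite")
  if (df <= 0) stop_("`df` must be positive")
  if (df >= n) stop_("`df` must be smaller than `n`")
  c(AIC = minus2ll + 2 * df,
    BIC = minus2ll + df * log(n),
    GCV = (minus2ll / n) / (1 - df / n)^2)
}

#' Smooth-effect curve with 80% and 95% bands
#'
#' Evaluates a fitted P-spline term on a grid spanning its knot range, with
#' pointwise Wald bands at the 80% and 95% levels from the term's posterior
#' covariance block.  The curve satisfies the centering constraint (zero
#' average over the training data).
#'
#' @param fit a `spatord_fit`.
#' @param term name of a smooth covariate in the fit.
#' @param n_grid number of grid points.
#' @return A data.frame of class `smooth_curve` with columns `x`,
#'   `estimate`, `lo80`, `hi80`, `lo95`, `hi95`.
#' @export
smooth_curve <- function(fit, term, n_grid = 100L) {
  stopifnot(inherits(fit, "spatord_fit"))
  b <- fit$design$blocks[[term]]
  avail <- names(Filter(function(z) z$type == "smooth", fit$design$blocks))
  if (is.null(b) || b$type != "smooth")
    stop_("'", term, "' is not a smooth term; available: ",
          paste(avail, collapse = ", "))
  rng <- b$term$range
  grid <- seq(rng[1L], rng[2L], length.out = n_grid)
  Bc <- bspline_basis(grid, b$term) %*% b$Zc
  G <- cbind(Bc %*% b$V0, Bc %*% b$W)
  idx <- fit$offset + c(b$u_idx, b$z_idx)
  coefs <- fit$beta[c(b$u_idx, b$z_idx)]
  est <- drop(G %*% coefs)
  se <- sqrt(pmax(rowSums((G %*% fit$C[idx, idx, drop = FALSE]) * G), 0))
  z80 <- stats::qnorm(0.90); z95 <- stats::qnorm(0.975)
  structure(data.frame(x = grid, estimate = est,
                       lo80 = est - z80 * se, hi80 = est + z80 * se,
                       lo95 = est - z95 * se, hi95 = est + z95 * se),
            class = c("smooth_curve", "data.frame"))
}

# region-level estimate and covariance of a spatial component
spatial_effect_ <- function(fit, which) {
  bs <- fit$design$blocks[["spat_str"]]
  bu <- fit$design$blocks[["spat_unstr"]]
  pick <- switch(which,
    structured = {
      if (is.null(bs)) stop_("no structured spatial term in this fit")
      list(E = bs$Wmat, idx = bs$z_idx, graph = bs$graph)
    },
    unstructured = {
      if (is.null(bu)) stop_("no unstructured spatial term in this fit")
      list(E = diag(bu$graph$n_regions), idx = bu$z_idx, graph = bu$graph)
    },
    total = {
      if (is.null(bs) || is.null(bu))
        stop_("total spatial effect needs both spatial terms")
      list(E = cbind(bs$Wmat, diag(bu$graph$n_regions)),
           idx = c(bs$z_idx, bu$z_idx), graph = bs$graph)
    })
  idx <- fit$offset + pick$idx
  est <- drop(pick$E %*% fit$beta[pick$idx])
  V <- pick$E %*% fit$C[idx, idx, drop = FALSE] %*% t(pick$E)
  list(region = pick$graph$labels, estimate = est,
       se = sqrt(pmax(diag(V), 0)))
}

#' Three-way spatial significance classification
#'
#' Per-region estimate with 95% interval and the map colouring rule:
#' `positive` when the lower bound exceeds 0 (high-risk / white on the
#' paper-style map), `negative` when the upper bound is below 0 (black),
#' `nonsignificant` otherwise (grey).  No multiplicity correction is
#' applied across regions.
#'
#' @param fit a `spatord_fit` with spatial terms.
#' @param which `"structured"` (default), `"unstructured"` or `"total"`.
#' @return A data.frame with columns `region`, `estimate`, `lower95`,
#'   `upper95`, `class`.
#' @export
classify_regions <- function(fit, which = c("structured", "unstructured",
                                            "total")) {
  stopifnot(inherits(fit, "spatord_fit"))
  which <- match.arg(which)
  sp <- spatial_effect_(fit, which)
  z <- stats::qnorm(0.975)
  lower <- sp$estimate - z * sp$se
  upper <- sp$estimate + z * sp$se
  cls <- ifelse(lower > 0, "positive",
                ifelse(upper < 0, "negative", "nonsignificant"))
  data.frame(region = sp$region, estimate = sp$estimate,
             lower95 = lower, upper95 = upper,
             class = factor(cls, levels = c("negative", "nonsignificant",
                                            "positive")),
             stringsAsFactors = FALSE)
}

#' Descriptive frequency table
#'
#' Counts and percentages per outcome category against a stated
#' denominator (by default the classified total, i.e. the sum of the
#' counts; pass e.g. the number of all live births to use a larger base).
#'
#' @param y vector of observed categories, or `NULL` when `counts` is given.
#' @param counts optional vector of per-category counts (used instead of
#'   `y`).
#' @param denominator percentage base; defaults to `sum(counts)`.
#' @param labels optional category labels.
#' @param digits rounding for the percent column (presentation only).
#' @return A data.frame with `category`, `count`, `percent`.
#' @export
descriptive_table <- function(y = NULL, counts = NULL, denominator = NULL,
                              labels = NULL, digits = 2L) {
  if (is.null(counts)) {
    if (is.null(y)) stop_("supply `y` or `counts`")
    tab <- table(y)
    counts <- as.numeric(tab)
    labels <- labels %||% names(tab)
  }
  counts <- as.numeric(counts)
  if (any(counts < 0)) stop_("counts must be non-negative")
  denominator <- denominator %||% sum(counts)
  if (denominator <= 0) stop_("denominator must be positive")
  labels <- labels %||% as.character(seq_along(counts))
  data.frame(category = labels, count = counts,
             percent = round(100 * counts / denominator, digits),
             stringsAsFactors = FALSE)
}

#' Export fit artifacts as delimited text
#'
#' Fixed column orders: coefficient tables are
#' `(term, level, estimate, lower95, upper95, OR, OR_lower, OR_upper)`;
#' curves `(grid, estimate, lo80, hi80, lo95, hi95)`; region tables
#' `(region, estimate, lower95, upper95, class)`.  Tab-separated, no
#' quoting, deterministic bytes.
#'
#' @param fit a `spatord_fit`.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
export_coefficients <- function(fit, path) {
  stopifnot(inherits(fit, "spatord_fit"))
  rows <- NULL
  if (!is.null(fit$thresholds))
    rows <- data.frame(term = "threshold", level = fit$thresholds$par,
                       estimate = fit$thresholds$estimate,
                       lower95 = fit$thresholds$lower95,
                       upper95 = fit$thresholds$upper95)
  if (!is.null(fit$intercept))
    rows <- rbind(rows, data.frame(term = "intercept", level = "",
                                   estimate = fit$intercept$estimate,
                                   lower95 = fit$intercept$lower95,
                                   upper95 = fit$intercept$upper95))
  if (!is.null(fit$fixed))
    rows <- rbind(rows, fit$fixed[c("term", "level", "estimate",
                                    "lower95", "upper95")])
  rows$OR <- exp(rows$estimate)
  rows$OR_lower <- exp(rows$lower95)
  rows$OR_upper <- exp(rows$upper95)
  write_tsv_(rows, path)
}

#' @rdname export_coefficients
#' @param curve a [smooth_curve()].
#' @export
export_curve <- function(curve, path) {
  stopifnot(inherits(curve, "smooth_curve"))
  out <- data.frame(grid = curve$x, estimate = curve$estimate,
                    lo80 = curve$lo80, hi80 = curve$hi80,
                    lo95 = curve$lo95, hi95 = curve$hi95)
  write_tsv_(out, path)
}

#' @rdname export_coefficients
#' @param regions output of [classify_regions()].
#' @export
export_regions <- function(regions, path) {
  write_tsv_(regions[c("region", "estimate", "lower95", "upper95", "class")],
             path)
}

write_tsv_ <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 10, format = "g"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
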