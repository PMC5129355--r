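#' Category probabilities of the cumulative logit model
#'
#' With strictly increasing thresholds `theta` and latent predictor `w`
#' (higher `w` = higher categories), `P(y <= j) = F(theta_j - w)` with `F`
#' the logistic CDF, and `p_j` is the difference of successive cumulative
#' probabilities.
#'
#' @param thresholds strictly increasing numeric vector of length K - 1.
#' @param eta latent predictor value(s) `w`.
#' @return For scalar `eta` a probability vector of length K; otherwise a
#'   `length(eta)` x K matrix.  Rows sum to 1.
#' @export
category_probabilities <- function(thresholds, eta) {
  thresholds <- as.numeric(thresholds)
  if (!length(thresholds) || anyNA(thresholds) || any(diff(thresholds) <= 0))
    stop_("`thresholds` must be strictly increasing")
  eta <- as.numeric(eta)
  cp <- stats::plogis(outer(-eta, thresholds, `+`))
  P <- cbind(cp, 1) - cbind(0, cp)
  colnames(P) <- as.character(seq_len(ncol(P)))
  if (length(eta) == 1L) drop(P) else P
}

# ICAR draw using the *current* RNG stream: spectral pseudo-inverse
# construction, null (per-component constant) directions excluded so each
# component sums to zero exactly.
icar_draw_ <- function(graph, tau2, draws = 1L) {
  if (tau2 < 0) stop_("`tau2` must be non-negative")
  n <- graph$n_regions
  if (tau2 == 0) return(matrix(0, n, draws))
  eg <- eigen(mrf_penalty(graph), symmetric = TRUE)
  pos <- eg$values > max(eg$values, 1e-300) * 1e-9
  if (!any(pos)) return(matrix(0, n, draws))
  V <- eg$vectors[, pos, drop = FALSE]
  sd <- sqrt(tau2 / eg$values[pos])
  Z <- matrix(stats::rnorm(sum(pos) * draws), sum(pos), draws)
  V %*% (Z * sd)
}

#' Sample an intrinsic-CAR (MRF) spatial field
#'
#' Draws from the intrinsic Gaussian Markov random field with precision
#' `K / tau2` (`K` the graph Laplacian), restricted to the orthogonal
#' complement of the per-component constant vectors, i.e. the covariance is
#' `tau2` times the Moore-Penrose pseudo-inverse of `K` and each connected
#' component sums to zero exactly.
#'
#' @param graph an [adjacency_graph()].
#' @param tau2 spatial variance, >= 0 (`0` gives the zero field).
#' @param seed integer seed; the draw is deterministic given the seed and
#'   the caller's RNG state is left untouched.
#' @param draws number of independent fields.
#' @return A numeric vector of length `n_regions` (or an
#'   `n_regions` x `draws` matrix when `draws > 1`).
#' @export
sample_icar_field <- function(graph, tau2, seed, draws = 1L) {
  stopifnot(inherits(graph, "adjacency_graph"))
  out <- with_seed(seed, icar_draw_(graph, tau2, draws))
  if (draws == 1L) drop(out) else out
}

#' Simulation specification for the synthetic-data generator
#'
#' States the world the generator emulates: a 4-category ordered outcome
#' from a cumulative logit with thresholds `theta`, nonlinear smooth effects
#' of continuous maternal covariates (U-shaped age, sigmoid BMI, linear
#' weight by default), effect-coded categorical effects, and a structured
#' (ICAR) plus unstructured region effect on a 37-node graph.  Default
#' thresholds echo the magnitudes reported for intercept-only ordinal fits
#' of birth-size data; default effect sizes are of the order of published
#' fixed-effect estimates for these covariates.
#'
#' @param n_obs number of children (rows).
#' @param thresholds strictly increasing vector, length K - 1.
#' @param continuous named list; each element a list with `range = c(lo,
#'   hi)` and `f`, the true smooth function of the covariate.
#' @param categorical named list; each element a list with `levels`, `ref`,
#'   sampling `probs` (same length as `levels`), and `gamma`, a named
#'   vector of effect-coded coefficients for the non-reference levels.
#' @param tau2_str,tau2_unstr structured / unstructured spatial variances.
#' @param graph an [adjacency_graph()]; regions are assigned with
#'   probabilities `region_weights` (uniform when `NULL`).
#' @param region_weights optional sampling weights over regions.
#' @param seed integer seed.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_obs = 5000L,
                            thresholds = c(-1.9, 0.1, 1.6),
                            continuous = list(
                              mage    = list(range = c(15, 49),
                                             f = function(x) 0.4 * ((x - 32) / 10)^2),
                              mbmi    = list(range = c(15, 35),
                                             f = function(x) 0.5 * tanh((x - 22) / 4)),
                              mweight = list(range = c(40, 80),
                                             f = function(x) -0.012 * (x - 60))),
                            categorical = list(
                              sex      = list(levels = c("female", "male"), ref = "female",
                                              probs = c(0.5, 0.5), gamma = c(male = -0.18)),
                              iron     = list(levels = c("no", "yes"), ref = "no",
                                              probs = c(0.5, 0.5), gamma = c(yes = 0.09)),
                              literate = list(levels = c("no", "yes"), ref = "no",
                                              probs = c(0.55, 0.45), gamma = c(yes = 0.08))),
                            tau2_str = 0.3, tau2_unstr = 0.05,
                            graph = synthetic_nigeria_graph(),
                            region_weights = NULL, seed = 1L) {
  n_obs <- as.integer(n_obs)
  if (n_obs < 1L) stop_("`n_obs` must be positive")
  thresholds <- as.numeric(thresholds)
  if (!length(thresholds) || any(diff(thresholds) <= 0))
    stop_("`thresholds` must be strictly increasing")
  if (tau2_str < 0 || tau2_unstr < 0) stop_("spatial variances must be >= 0")
  stopifnot(inherits(graph, "adjacency_graph"))
  for (nm in names(continuous)) {
    ct <- continuous[[nm]]
    if (!is.function(ct$f))
      stop_("smooth function for covariate '", nm, "' is not a function")
    if (length(ct$range) != 2L || ct$range[1L] >= ct$range[2L])
      stop_("bad range for continuous covariate '", nm, "'")
  }
  for (nm in names(categorical)) {
    ct <- categorical[[nm]]
    if (length(ct$probs) != length(ct$levels))
      stop_("probs/levels length mismatch for '", nm, "'")
    if (!ct$ref %in% ct$levels) stop_("bad reference level for '", nm, "'")
    bad <- setdiff(names(ct$gamma), setdiff(ct$levels, ct$ref))
    if (length(bad))
      stop_("gamma names of '", nm, "' must be non-reference levels; got: ",
            paste(bad, collapse = ", "))
  }
  if (!is.null(region_weights) && length(region_weights) != graph$n_regions)
    stop_("`region_weights` must have one weight per region")
  structure(list(n_obs = n_obs, K = length(thresholds) + 1L,
                 thresholds = thresholds, continuous = continuous,
                 categorical = categorical, tau2_str = tau2_str,
                 tau2_unstr = tau2_unstr, graph = graph,
                 region_weights = region_weights, seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Simulate an ordinal dataset with known truth
#'
#' Draws covariates, spatial fields and outcomes according to a
#' [simulation_spec()].  The latent predictor is
#' `w = sum f(x) + f_str(region) + f_unstr(region) + v' gamma` (smooths
#' centered over the sample) and `y` is drawn from
#' [category_probabilities()]`(theta, w)`.  The binary low-category
#' indicator `y_low = (y == 1)` is included for binary-model work.
#'
#' @param spec a [simulation_spec()].
#' @return A list of class `ordinal_dataset` with `data` (data.frame: `y`,
#'   `y_low`, covariates, `region` label), `graph`, `spec` and `truth`
#'   (centered smooth values per covariate, `f_str`, `f_unstr`, `gamma`,
#'   `thresholds`, and per-observation `w`).
#' @export
simulate_dataset <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  with_seed(spec$seed, {
    n <- spec$n_obs
    g <- spec$graph
    df <- data.frame(row.names = seq_len(n))
    w <- numeric(n)
    smooth_truth <- list()
    for (nm in names(spec$continuous)) {
      ct <- spec$continuous[[nm]]
      x <- stats::runif(n, ct$range[1L], ct$range[2L])
      fx <- ct$f(x)
      fx <- fx - mean(fx)                 # centered, as the model identifies it
      df[[nm]] <- x
      smooth_truth[[nm]] <- fx
      w <- w + fx
    }
    gamma_truth <- list()
    for (nm in names(spec$categorical)) {
      ct <- spec$categorical[[nm]]
      lv <- sample(ct$levels, n, replace = TRUE, prob = ct$probs)
      df[[nm]] <- lv
      tm <- fixed_term(nm, ct$levels, ct$ref)
      gam <- numeric(length(ct$levels) - 1L)
      names(gam) <- setdiff(ct$levels, ct$ref)
      gam[names(ct$gamma)] <- ct$gamma
      w <- w + drop(effect_code(lv, tm) %*% gam)
      gamma_truth[[nm]] <- gam
    }
    reg <- sample.int(g$n_regions, n, replace = TRUE, prob = spec$region_weights)
    f_str <- drop(icar_draw_(g, spec$tau2_str))
    f_unstr <- if (spec$tau2_unstr > 0)
      stats::rnorm(g$n_regions, 0, sqrt(spec$tau2_unstr)) else numeric(g$n_regions)
    w <- w + f_str[reg] + f_unstr[reg]
    df$region <- g$labels[reg]
    cp <- stats::plogis(outer(-w, spec$thresholds, `+`))
    u <- stats::runif(n)
    df$y <- spec$K - as.integer(rowSums(u <= cp))
    df$y_low <- as.integer(df$y == 1L)
    df <- df[c("y", "y_low", names(spec$continuous), names(spec$categorical),
               "region")]
    structure(list(data = df, graph = g, spec = spec,
                   truth = list(smooth = smooth_truth, gamma = gamma_truth,
                                f_str = f_str, f_unstr = f_unstr,
                                thresholds = spec$thresholds, w = w)),
              class = "ordinal_dataset")
  })
}

#' @export
print.ordinal_dataset <- function(x, ...) {
  cat(sprintf("<ordinal_dataset> n = %d, K = %d, %d regions\n",
              nrow(x$data), x$spec$K, x$graph$n_regions))
  print(utils::head(x$data, 4L))
  invisible(x)
}

#' Read / write observation data as delimited text
#'
#' Comma-separated with a header row; categorical columns stored as level
#' labels, the region column as labels matching the graph file.
#'
#' @param data a data.frame (e.g. the `data` element of
#'   [simulate_dataset()]).
#' @param path file path.
#' @param graph optional [adjacency_graph()]; when given, region labels are
#'   validated against it.
#' @param region name of the region column.
#' @return [read_ordinal_data()] returns a data.frame.
#' @export
write_ordinal_data <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ordinal_data
#' @export
read_ordinal_data <- function(path, graph = NULL, region = "region") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(graph) && region %in% names(df)) {
    bad <- setdiff(unique(trimws(as.character(df[[region]]))), graph$labels)
    if (length(bad))
      stop_("region label(s) not in graph: ", paste(bad, collapse = ", "))
  }
  df
}
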