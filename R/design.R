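#' P-spline term specification
#'
#' Describes a penalized B-spline smooth of a continuous covariate: a
#' B-spline basis of the given degree on equidistant knots with a
#' difference penalty on adjacent coefficients.  Defaults (cubic basis, 20
#' inner knots, second-order penalty) follow the conventional choices of
#' structured additive regression software; all are configurable per term.
#'
#' @param name covariate (column) name.
#' @param degree B-spline degree, >= 0.
#' @param inner_knots number of interior knots; the basis has
#'   `inner_knots + degree + 1` functions.
#' @param penalty_order order `d` of the difference penalty, >= 1; must be
#'   smaller than the number of basis functions.
#' @param range optional knot range `c(min, max)` in covariate units;
#'   defaults to the observed range when the design is built.
#' @return An object of class `pspline_term`.
#' @export
pspline_term <- function(name, degree = 3L, inner_knots = 20L,
                         penalty_order = 2L, range = NULL) {
  degree <- as.integer(degree); inner_knots <- as.integer(inner_knots)
  penalty_order <- as.integer(penalty_order)
  if (degree < 0L) stop_("`degree` must be >= 0")
  if (inner_knots < 1L) stop_("`inner_knots` must be >= 1")
  if (penalty_order < 1L) stop_("`penalty_order` must be >= 1")
  n_basis <- inner_knots + degree + 1L
  if (n_basis <= penalty_order)
    stop_("number of basis functions (", n_basis,
          ") must exceed the penalty order (", penalty_order, ")")
  if (!is.null(range)) {
    range <- as.numeric(range)
    if (length(range) != 2L || !all(is.finite(range)) || range[1L] >= range[2L])
      stop_("`range` must be c(min, max) with min < max")
  }
  structure(list(name = name, degree = degree, inner_knots = inner_knots,
                 penalty_order = penalty_order, range = range,
                 n_basis = n_basis),
            class = "pspline_term")
}

#' Effect-coded categorical fixed-effect term
#'
#' One contrast column per non-reference level with the coding +1 at the
#' level's own observations, -1 at the reference level, 0 elsewhere.  Note
#' this differs from treatment dummies: coefficients measure deviations
#' against the (negated) reference, which changes their magnitudes relative
#' to a 0/1 coding.
#'
#' @param name covariate (column) name.
#' @param levels character vector of declared levels (>= 2).
#' @param ref reference level; defaults to the first declared level.
#' @return An object of class `fixed_term`.
#' @export
fixed_term <- function(name, levels, ref = levels[[1L]]) {
  levels <- as.character(levels)
  if (length(levels) < 2L || anyDuplicated(levels))
    stop_("`levels` must be >= 2 unique labels")
  if (!ref %in% levels) stop_("reference level '", ref, "' is not a declared level")
  structure(list(name = name, levels = levels, ref = ref),
            class = "fixed_term")
}

#' Spatial effect term
#'
#' Structured (`kind = "structured"`) terms use the MRF/graph-Laplacian
#' penalty of the supplied graph; unstructured terms (`kind =
#' "unstructured"`) are i.i.d. region-level random effects with an identity
#' (ridge) penalty.
#'
#' @param graph an [adjacency_graph()].
#' @param kind `"structured"` or `"unstructured"`.
#' @return An object of class `spatial_term`.
#' @export
spatial_term <- function(graph, kind = c("structured", "unstructured")) {
  stopifnot(inherits(graph, "adjacency_graph"))
  kind <- match.arg(kind)
  structure(list(graph = graph, kind = kind), class = "spatial_term")
}

#' Both spatial terms for one graph
#' @inheritParams spatial_term
#' @return A list of two [spatial_term()] objects (structured, unstructured).
#' @export
spatial_terms <- function(graph)
  list(spatial_term(graph, "structured"), spatial_term(graph, "unstructured"))

#' B-spline basis matrix for a P-spline term
#'
#' Equidistant knots over the term's range, extended by `degree` extra knots
#' on each side; evaluation outside the range is an error (no silent
#' extrapolation).  Rows form a partition of unity.
#'
#' @param x numeric vector of covariate values.
#' @param term a [pspline_term()]; if its `range` is `NULL` the observed
#'   range of `x` is used.
#' @return A `length(x)` x `n_basis` matrix.
#' @export
bspline_basis <- function(x, term) {
  stopifnot(inherits(term, "pspline_term"))
  x <- as.numeric(x)
  if (anyNA(x)) stop_("missing values in covariate '", term$name, "'")
  rng <- term$range %||% range(x)
  if (any(x < rng[1L] | x > rng[2L]))
    stop_("values of '", term$name, "' outside the knot range [",
          rng[1L], ", ", rng[2L], "]")
  h <- (rng[2L] - rng[1L]) / (term$inner_knots + 1L)
  # inner knots with exact endpoints (seq by=h can undershoot the boundary)
  knots <- c(rng[1L] - h * rev(seq_len(term$degree)),
             seq(rng[1L], rng[2L], length.out = term$inner_knots + 2L),
             rng[2L] + h * seq_len(term$degree))
  B <- splines::splineDesign(knots, x, ord = term$degree + 1L, outer.ok = FALSE)
  stopifnot(ncol(B) == term$n_basis)
  B
}

#' Difference penalty matrix
#'
#' `K = t(D_d) %*% D_d` with `D_d` the d-th order difference operator on the
#' coefficient sequence; rank is `n_basis - order`, and polynomial
#' coefficient sequences of degree below `order` are unpenalized.
#'
#' @param n_basis number of basis coefficients.
#' @param order difference order `d`, with `1 <= d < n_basis`.
#' @return An `n_basis` x `n_basis` symmetric PSD matrix.
#' @export
difference_penalty <- function(n_basis, order) {
  n_basis <- as.integer(n_basis); order <- as.integer(order)
  if (order < 1L) stop_("`order` must be >= 1")
  if (order >= n_basis) stop_("`order` must be smaller than `n_basis`")
  D <- diff(diag(n_basis), differences = order)
  crossprod(D)
}

#' Effect-code a categorical covariate
#'
#' @param labels vector of observed level labels.
#' @param term a [fixed_term()].
#' @return Matrix with one column per non-reference level, entries +1 at the
#'   level's own rows, -1 at reference rows, 0 elsewhere.
#' @export
effect_code <- function(labels, term) {
  stopifnot(inherits(term, "fixed_term"))
  labels <- trimws(as.character(labels))
  unseen <- setdiff(unique(labels), term$levels)
  if (length(unseen))
    stop_("undeclared level(s) in '", term$name, "': ",
          paste(unseen, collapse = ", "))
  nonref <- setdiff(term$levels, term$ref)
  M <- matrix(0, length(labels), length(nonref),
              dimnames = list(NULL, paste0(term$name, ":", nonref)))
  M[labels == term$ref, ] <- -1
  for (k in seq_along(nonref)) M[labels == nonref[[k]], k] <- 1
  M
}

#' Sum-to-zero centering constraint
#'
#' Reparameterizes a basis so that the fitted term sums to zero over the
#' observed data (identifiability against the intercept / thresholds): the
#' coefficient space is restricted to the null space of `colSums(basis)`,
#' reducing the dimension by one, and the penalty is transformed
#' congruently (preserving symmetry and positive semi-definiteness).
#'
#' @param basis n x m basis matrix (m >= 2).
#' @param penalty m x m symmetric PSD penalty.
#' @return A list with `basis` (n x (m-1)), `penalty` ((m-1) x (m-1)) and
#'   `transform` (m x (m-1)), where original coefficients are
#'   `transform %*% constrained coefficients`.
#' @export
center_constraint <- function(basis, penalty) {
  basis <- as.matrix(basis); penalty <- as.matrix(penalty)
  m <- ncol(basis)
  if (m < 2L) stop_("constraint needs at least 2 basis columns")
  stopifnot(nrow(penalty) == m, ncol(penalty) == m)
  cvec <- colSums(basis)
  nrm <- sqrt(sum(cvec^2))
  if (!is.finite(nrm) || nrm < 1e-12 * sqrt(m) * max(1, max(abs(basis))))
    stop_("centering constraint is numerically rank-deficient")
  Q <- qr.Q(qr(matrix(cvec, ncol = 1L)), complete = TRUE)
  Zc <- Q[, -1L, drop = FALSE]
  list(basis = basis %*% Zc,
       penalty = symmetrize(crossprod(Zc, penalty %*% Zc)),
       transform = Zc)
}

#' Mixed-model reparameterization of a penalized term
#'
#' Spectral split of the penalty `K = V diag(lambda) V'`: the unpenalized
#' block spans the null space of `K` (fixed-effect part) and the penalized
#' block is whitened, `Z = basis V+ diag(lambda+^{-1/2})`, so its implied
#' penalty is the identity and the smoothing parameter becomes a variance
#' component.
#'
#' @param basis n x m basis matrix.
#' @param penalty m x m symmetric PSD penalty.
#' @param tol relative eigenvalue tolerance separating the null space.
#' @return A list with `Xu` (unpenalized design, possibly 0 columns), `Z`
#'   (whitened penalized design), `null_basis` (m x p0), `whitener`
#'   (m x q, mapping whitened coefficients back to the original basis) and
#'   `rank` (q).
#' @export
reparameterize <- function(basis, penalty, tol = 1e-9) {
  basis <- as.matrix(basis); penalty <- symmetrize(as.matrix(penalty))
  m <- ncol(basis)
  stopifnot(nrow(penalty) == m)
  eg <- eigen(penalty, symmetric = TRUE)
  lam <- eg$values
  thr <- max(abs(lam), 1e-300) * tol
  if (min(lam) < -thr)
    stop_("penalty is numerically indefinite (smallest eigenvalue ",
          format(min(lam)), ")")
  pos <- lam > thr
  V0 <- eg$vectors[, !pos, drop = FALSE]
  Vp <- eg$vectors[, pos, drop = FALSE]
  W <- sweep(Vp, 2L, sqrt(lam[pos]), `/`)
  list(Xu = basis %*% V0, Z = basis %*% W,
       null_basis = V0, whitener = W, rank = sum(pos))
}
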