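#' Region adjacency graph
#'
#' An undirected neighbourhood structure over administrative regions.  The
#' graph defines the Markov-random-field penalty used for the structured
#' spatial effect: two regions are penalized towards each other exactly when
#' they share an edge.
#'
#' @param n_regions number of regions (positive integer).
#' @param edges two-column integer matrix of region-index pairs (1-based);
#'   may be `NULL` or zero rows for an edgeless graph.  Self-loops are
#'   rejected, duplicate/reversed pairs are collapsed.
#' @param labels optional character vector of region labels (defaults to
#'   `"1"..."n"`); must be unique.
#' @return An object of class `adjacency_graph` with elements `n_regions`,
#'   `edges` (m x 2 matrix, smaller index first) and `labels`.
#' @export
adjacency_graph <- function(n_regions, edges = NULL, labels = NULL) {
  n_regions <- as.integer(n_regions)
  if (length(n_regions) != 1L || is.na(n_regions) || n_regions < 1L)
    stop_("`n_regions` must be a positive integer")
  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- matrix(integer(0), 0L, 2L)
  } else {
    edges <- matrix(as.integer(as.matrix(edges)), ncol = 2L)
    if (anyNA(edges) || any(edges < 1L) || any(edges > n_regions))
      stop_("edge indices must lie in 1..n_regions")
    if (any(edges[, 1L] == edges[, 2L]))
      stop_("self-loops are not allowed in a region graph")
    edges <- cbind(pmin(edges[, 1L], edges[, 2L]),
                   pmax(edges[, 1L], edges[, 2L]))
    edges <- unique(edges)
    edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  }
  labels <- labels %||% as.character(seq_len(n_regions))
  labels <- trimws(as.character(labels))
  if (length(labels) != n_regions || anyDuplicated(labels))
    stop_("`labels` must be ", n_regions, " unique strings")
  structure(list(n_regions = n_regions, edges = edges, labels = labels),
            class = "adjacency_graph")
}

#' @export
print.adjacency_graph <- function(x, ...) {
  comp <- graph_components(x)
  cat(sprintf("<adjacency_graph> %d regions, %d edges, %d component(s)\n",
              x$n_regions, nrow(x$edges), max(comp)))
  invisible(x)
}

#' Node degrees of an adjacency graph
#' @param graph an [adjacency_graph()].
#' @return integer vector of degrees, one per region.
#' @export
graph_degree <- function(graph) {
  stopifnot(inherits(graph, "adjacency_graph"))
  tabulate(c(graph$edges[, 1L], graph$edges[, 2L]), nbins = graph$n_regions)
}

#' Connected-component membership
#' @param graph an [adjacency_graph()].
#' @return integer vector of component ids (1-based), one per region.
#' @export
graph_components <- function(graph) {
  stopifnot(inherits(graph, "adjacency_graph"))
  n <- graph$n_regions
  nbr <- vector("list", n)
  for (k in seq_len(nrow(graph$edges))) {
    i <- graph$edges[k, 1L]; j <- graph$edges[k, 2L]
    nbr[[i]] <- c(nbr[[i]], j); nbr[[j]] <- c(nbr[[j]], i)
  }
  comp <- integer(n)
  id <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    id <- id + 1L
    queue <- s
    comp[s] <- id
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      for (w in nbr[[v]]) if (comp[w] == 0L) { comp[w] <- id; queue <- c(queue, w) }
    }
  }
  comp
}

#' Rook-adjacency lattice graph
#'
#' A `n_rows` x `n_cols` grid with horizontal and vertical neighbour edges;
#' a convenient stand-in for a real administrative map when none is
#' available.  Region index of cell (r, c) is `(r-1) * n_cols + c`.
#'
#' @param n_rows,n_cols grid dimensions, both at least 1.
#' @return An [adjacency_graph()] with `n_rows * n_cols` regions.
#' @export
make_lattice_graph <- function(n_rows, n_cols) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (anyNA(c(n_rows, n_cols)) || n_rows < 1L || n_cols < 1L)
    stop_("lattice dimensions must be positive integers")
  idx <- function(r, c) (r - 1L) * n_cols + c
  e <- list()
  for (r in seq_len(n_rows)) for (c in seq_len(n_cols)) {
    if (c < n_cols) e[[length(e) + 1L]] <- c(idx(r, c), idx(r, c + 1L))
    if (r < n_rows) e[[length(e) + 1L]] <- c(idx(r, c), idx(r + 1L, c))
  }
  edges <- if (length(e)) do.call(rbind, e) else NULL
  adjacency_graph(n_rows * n_cols, edges)
}

#' Synthetic 37-region graph
#'
#' A 6 x 6 rook lattice with one extra node appended (attached to region 36),
#' giving 37 regions: a synthetic stand-in, with the right node count, for a
#' map of 36 states plus a federal capital territory.  It is *not* the real
#' adjacency structure; supply a neighbour-list file via [read_adjacency()]
#' for a real map.
#'
#' @return An [adjacency_graph()] with 37 regions.
#' @export
synthetic_nigeria_graph <- function() {
  g <- make_lattice_graph(6L, 6L)
  adjacency_graph(37L, rbind(g$edges, c(36L, 37L)))
}

#' Read / write a neighbour-list graph file
#'
#' Plain-text dialect: line 1 holds the region count; each following line
#' holds a region label, its neighbour count, then that many neighbour
#' labels, whitespace-separated.  The reader validates symmetry: if region A
#' lists B, region B must list A.
#'
#' @param path file path.
#' @return [read_adjacency()] returns an [adjacency_graph()];
#'   [write_adjacency()] invisibly returns `path`.
#' @export
read_adjacency <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop_("empty graph file: ", path)
  n <- suppressWarnings(as.integer(trimws(lines[[1L]])))
  if (is.na(n) || n < 1L) stop_("first line must hold the region count")
  if (length(lines) != n + 1L)
    stop_("expected ", n, " region lines, found ", length(lines) - 1L)
  toks <- lapply(lines[-1L], function(l) strsplit(trimws(l), "\\s+")[[1L]])
  labels <- vapply(toks, `[[`, character(1), 1L)
  if (anyDuplicated(labels)) stop_("duplicate region labels in graph file")
  index <- seq_len(n); names(index) <- labels
  nbrs <- vector("list", n)
  for (i in seq_len(n)) {
    tk <- toks[[i]]
    cnt <- suppressWarnings(as.integer(tk[[2L]]))
    if (is.na(cnt) || length(tk) != 2L + cnt)
      stop_("malformed neighbour line for region '", labels[[i]], "'")
    if (cnt > 0L) {
      nb <- tk[-(1:2)]
      unknown <- setdiff(nb, labels)
      if (length(unknown))
        stop_("unknown neighbour label(s): ", paste(unknown, collapse = ", "))
      nbrs[[i]] <- unname(index[nb])
    } else nbrs[[i]] <- integer(0)
  }
  # symmetry check before collapsing to an edge set
  for (i in seq_len(n)) for (j in nbrs[[i]])
    if (!(i %in% nbrs[[j]]))
      stop_("asymmetric adjacency: '", labels[[i]], "' lists '", labels[[j]],
            "' but not vice versa")
  edges <- do.call(rbind, lapply(seq_len(n), function(i) {
    j <- nbrs[[i]][nbrs[[i]] > i]
    if (length(j)) cbind(i, j) else NULL
  }))
  adjacency_graph(n, edges, labels)
}

#' @rdname read_adjacency
#' @param graph an [adjacency_graph()].
#' @export
write_adjacency <- function(graph, path) {
  stopifnot(inherits(graph, "adjacency_graph"))
  n <- graph$n_regions
  nbrs <- lapply(seq_len(n), function(i) {
    sort(c(graph$edges[graph$edges[, 1L] == i, 2L],
           graph$edges[graph$edges[, 2L] == i, 1L]))
  })
  out <- c(as.character(n),
           vapply(seq_len(n), function(i) {
             paste(c(graph$labels[[i]], length(nbrs[[i]]),
                     graph$labels[nbrs[[i]]]), collapse = " ")
           }, character(1)))
  writeLines(out, path)
  invisible(path)
}

#' Markov-random-field (graph Laplacian) penalty
#'
#' Returns `K = diag(degree) - adjacency`, the intrinsic-CAR precision
#' structure: `f' K f` equals the sum of squared differences of the effect
#' over all neighbour pairs.  Rows and columns are named by region label.
#'
#' @param graph an [adjacency_graph()].
#' @return A symmetric positive semi-definite matrix with zero row sums and
#'   rank `n_regions - #components`.
#' @export
mrf_penalty <- function(graph) {
  stopifnot(inherits(graph, "adjacency_graph"))
  n <- graph$n_regions
  K <- matrix(0, n, n, dimnames = list(graph$labels, graph$labels))
  for (k in seq_len(nrow(graph$edges))) {
    i <- graph$edges[k, 1L]; j <- graph$edges[k, 2L]
    K[i, j] <- K[i, j] - 1
    K[j, i] <- K[j, i] - 1
  }
  diag(K) <- graph_degree(graph)
  K
}
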