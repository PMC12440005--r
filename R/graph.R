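#' Spatial graphs over spot coordinates
#'
#' The fused penalty smooths coefficients along the edges of a graph over the
#' spot locations. Two constructions are supported: the symmetrized union of
#' each spot's k nearest neighbors, and the Euclidean minimum spanning tree
#' (MST), which carries the penalty with only n-1 edges while keeping all
#' spots connected. Edge weights are Euclidean distances; ties are broken by
#' node index so both constructions are deterministic on gridded coordinates.
#'
#' @param coords numeric n x 2 coordinate matrix.
#' @param k neighbors per spot, `1 <= k <= n-1`.
#' @return An object of class `spatial_graph`: list with `n_nodes`, `edges`
#'   (m x 3 matrix: i, j, weight with 1-based i < j), `kind` and (for KNN)
#'   `k`.
#' @examples
#' g <- build_knn_graph(cbind(0:2, 0), k = 1)
#' g$edges
#' @export
build_knn_graph <- function(coords, k) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  k <- as.integer(k)
  if (k < 1L || k >= n)
    stop("`k` must satisfy 1 <= k <= n-1 (got k=", k, ", n=", n, ")")
  d <- as.matrix(stats::dist(coords))
  pairs <- matrix(0L, 0L, 2L)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    # ties by smaller node index: order() is stable on the secondary key
    nb <- others[order(d[i, others], others)][seq_len(k)]
    pairs <- rbind(pairs, cbind(pmin(i, nb), pmax(i, nb)))
  }
  pairs <- unique(pairs)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  w <- d[cbind(pairs[, 1], pairs[, 2])]
  g <- structure(list(n_nodes = n,
                      edges = cbind(i = pairs[, 1], j = pairs[, 2],
                                    weight = w),
                      kind = "knn", k = k),
                 class = "spatial_graph")
  comp <- graph_components(g)
  if (max(comp) > 1L)
    warning("KNN graph is disconnected (", max(comp), " components); ",
            "the fused penalty smooths within components only")
  g
}

#' @rdname build_knn_graph
#' @details `build_mst` uses Prim's algorithm with lexicographic tie-breaking:
#' among equal-weight frontier edges, the one with the smaller (tree-node,
#' new-node) pair is taken. Duplicate coordinates are allowed (zero-weight
#' edges).
#' @export
build_mst <- function(coords) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 2L) stop("an MST needs at least 2 points")
  in_tree <- logical(n)
  in_tree[1L] <- TRUE
  # best tree neighbor and distance for every non-tree node
  best_from <- rep(1L, n)
  best_d <- sqrt(rowSums((coords - matrix(coords[1L, ], n, 2,
                                          byrow = TRUE))^2))
  best_d[1L] <- Inf
  eds <- matrix(0, n - 1L, 3L)
  for (t in seq_len(n - 1L)) {
    cand <- which(!in_tree)
    dmin <- min(best_d[cand])
    at_min <- cand[best_d[cand] <= dmin]
    # ties: smallest tree-node index, then smallest new-node index
    at_min <- at_min[order(best_from[at_min], at_min)]
    v <- at_min[1L]
    u <- best_from[v]
    eds[t, ] <- c(min(u, v), max(u, v), dmin)
    in_tree[v] <- TRUE
    best_d[v] <- Inf
    dv <- sqrt(rowSums((coords - matrix(coords[v, ], n, 2, byrow = TRUE))^2))
    upd <- !in_tree & (dv < best_d | (dv == best_d & v < best_from))
    best_from[upd] <- v
    best_d[upd] <- dv[upd]
  }
  structure(list(n_nodes = n,
                 edges = cbind(i = as.integer(eds[, 1]),
                               j = as.integer(eds[, 2]), weight = eds[, 3]),
                 kind = "mst"),
            class = "spatial_graph")
}

#' Build the spatial graph a configuration asks for
#'
#' `"auto"` uses a KNN graph (k = `knn_k`) for n <= `auto_threshold` spots
#' and the MST above, which keeps the penalty at n-1 terms on large sections.
#'
#' @param coords numeric n x 2 coordinate matrix.
#' @param config a [run_config()].
#' @return a `spatial_graph`.
#' @export
build_spatial_graph <- function(coords, config = run_config()) {
  n <- nrow(as.matrix(coords))
  kind <- config$graph_kind
  if (kind == "auto") kind <- if (n <= config$auto_threshold) "knn" else "mst"
  if (kind == "knn") build_knn_graph(coords, config$knn_k) else
    build_mst(coords)
}

#' @export
print.spatial_graph <- function(x, ...) {
  cat("spatial_graph (", x$kind, "): ", x$n_nodes, " nodes, ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Edge-node incidence operator of a spatial graph
#'
#' Row r of the returned sparse m x n matrix has +1 at the first endpoint and
#' -1 at the second endpoint of edge r, so `H %*% beta_k` is the vector of
#' edgewise coefficient differences and `sum(abs(H %*% beta_k))` is the fused
#' penalty for one predictor. For an MST the matrix has full row rank n-1.
#'
#' @param graph a `spatial_graph`.
#' @return a [Matrix::sparseMatrix()] (dgCMatrix) with m rows and n columns.
#' @examples
#' g <- build_knn_graph(cbind(0:2, 0), k = 1)
#' as.matrix(incidence_matrix(g))
#' @export
incidence_matrix <- function(graph) {
  stopifnot(inherits(graph, "spatial_graph"))
  m <- nrow(graph$edges)
  Matrix::sparseMatrix(i = rep(seq_len(m), 2L),
                       j = c(graph$edges[, 1], graph$edges[, 2]),
                       x = rep(c(1, -1), each = m),
                       dims = c(m, graph$n_nodes))
}

#' Connected components of a spatial graph
#' @param graph a `spatial_graph`.
#' @return integer component label per node (1-based).
#' @export
graph_components <- function(graph) {
  n <- graph$n_nodes
  parent <- seq_len(n)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  for (e in seq_len(nrow(graph$edges))) {
    ra <- find(graph$edges[e, 1])
    rb <- find(graph$edges[e, 2])
    if (ra != rb) parent[ra] <- rb
  }
  roots <- vapply(seq_len(n), find, numeric(1))
  match(roots, unique(roots))
}

#' Export a graph edge list as delimited text
#' @param graph a `spatial_graph`.
#' @param path output file (TSV: i, j, weight).
#' @return invisibly, the path.
#' @export
write_edge_list <- function(graph, path) {
  utils::write.table(as.data.frame(graph$edges), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Row-standardized spatial weight matrix of a graph
#'
#' Binary adjacency of the graph's edges, each row divided by its row sum
#' (rows of isolated nodes stay zero). This is the weight matrix used by the
#' Moran's I statistic.
#'
#' @param graph a `spatial_graph`.
#' @return a sparse n x n matrix.
#' @export
row_standardized_weights <- function(graph) {
  n <- graph$n_nodes
  A <- Matrix::sparseMatrix(i = c(graph$edges[, 1], graph$edges[, 2]),
                            j = c(graph$edges[, 2], graph$edges[, 1]),
                            x = 1, dims = c(n, n))
  rs <- Matrix::rowSums(A)
  rs[rs == 0] <- 1
  Matrix::Diagonal(x = 1 / rs) %*% A
}
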