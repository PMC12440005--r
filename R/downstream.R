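#' Enforce attribution constraints on a coefficient field
#'
#' Cell types can only contribute non-negatively to a gene's expression, and
#' an absent cell type cannot contribute at all. Negative coefficients are
#' shrunk to zero, and positive coefficients are zeroed wherever the cell
#' type's proportion is zero.
#'
#' @param values numeric n x K coefficient matrix (spots x cell types).
#' @param proportions numeric n x K cell-type proportion matrix.
#' @return n x K matrix satisfying both constraints.
#' @export
apply_attribution_constraints <- function(values, proportions) {
  values <- as.matrix(values)
  proportions <- as.matrix(proportions)
  stopifnot(all(dim(values) == dim(proportions)))
  values[values < 0] <- 0
  values[proportions == 0] <- 0
  values
}

#' Cell-type-attributed expression for one gene
#'
#' Regresses a gene's spot-level expression on deconvolved cell-type
#' proportions with the spatially fused sparse model, applies post-hoc
#' cluster-wise selection, and then the attribution constraints (see
#' [apply_attribution_constraints()]). The resulting n x K field reads as
#' the expression of the gene attributed to each cell type at each spot.
#'
#' Proportions are used on their native scale (no z-scoring, no response
#' centering): they are already commensurate, and the generative reading
#' "expression = sum of proportion x per-cell-type level" has no intercept.
#'
#' @param expression length-n expression vector for the gene.
#' @param proportions n x K proportion matrix, entries in `[0, 1]` (rows
#'   need not sum exactly to 1); colnames are cell-type names.
#' @param coords n x 2 coordinates (used when `graph` is NULL and for
#'   post-hoc clustering).
#' @param graph optional prebuilt `spatial_graph`.
#' @param gene gene name stored in the result.
#' @param penalties a [penalty_config()]. The penalty terms sum over all
#'   spots while the data term is a per-spot average, so useful strengths
#'   are small; the defaults (1e-3, 1e-4, 1e-5) impose light smoothing and
#'   sparsity and leave selection to the post-hoc tests.
#' @param opt an [optimizer_config()].
#' @param n_clusters post-hoc cluster count; default
#'   [default_posthoc_clusters()].
#' @param alpha post-hoc selection level (default 0.05).
#' @param seed integer seed for clustering.
#' @return An object of class `attribution_field`: list with `gene`,
#'   `values` (n x K, non-negative, zero where the cell type is absent),
#'   `proportions`, `selection` (the `svc_selection`), `fit`.
#' @export
attribute_celltypes <- function(expression, proportions, coords,
                                graph = NULL, gene = "gene",
                                penalties = penalty_config(1e-3, 1e-4, 1e-5),
                                opt = optimizer_config(),
                                n_clusters = NULL, alpha = 0.05, seed = 1L) {
  proportions <- as.matrix(proportions)
  coords <- as.matrix(coords)
  n <- nrow(proportions)
  K <- ncol(proportions)
  if (K >= n)
    stop("more cell types (", K, ") than spots (", n,
         "): the attribution regression is under-determined")
  if (any(proportions < 0 | proportions > 1))
    stop("proportions must lie in [0, 1]")
  if (is.null(colnames(proportions)))
    colnames(proportions) <- paste0("celltype", seq_len(K))
  ds <- spatial_dataset(coords, expression, proportions,
                        predictor_names = colnames(proportions))
  if (is.null(graph)) graph <- build_spatial_graph(coords)
  fit <- fit_svc(ds, graph, penalties, opt, standardize = FALSE,
                 center = FALSE)
  field <- hard_threshold(fit$field)
  if (is.null(n_clusters)) n_clusters <- default_posthoc_clusters(n)
  labels <- cluster_spots(coords, n_clusters, seed = seed)
  sel <- refit_and_test(ds, field, labels, alpha = alpha)
  values <- apply_attribution_constraints(apply_selection(field, sel),
                                          proportions)
  structure(list(gene = gene, values = values, proportions = proportions,
                 selection = sel, fit = fit),
            class = "attribution_field")
}

#' @export
print.attribution_field <- function(x, ...) {
  cat("attribution_field for ", x$gene, ": ", nrow(x$values), " spots x ",
      ncol(x$values), " cell types; ", sum(x$values > 0),
      " positive entries\n", sep = "")
  invisible(x)
}

#' Moran's I with a permutation test
#'
#' Global spatial autocorrelation of a spot-level signal:
#' \deqn{I = \frac{n}{S_0}\,\frac{\sum_{ij} w_{ij} z_i z_j}{\sum_i z_i^2}}
#' with z the centered values and W the row-standardized binary adjacency of
#' the spatial graph. Significance for positive autocorrelation is assessed
#' by permuting the values over the spots:
#' `p = (1 + #permuted I >= observed I) / (n_permutations + 1)`.
#'
#' @param values length-n numeric vector with nonzero variance.
#' @param graph a `spatial_graph` over the same spots.
#' @param n_permutations at least 99 (default 999).
#' @param seed integer seed.
#' @return list of class `moran_result`: `statistic`, `perm_pvalue`,
#'   `n_permutations`, `adjusted_pvalue` (NA here; filled by
#'   [detect_svgs()]).
#' @examples
#' g <- build_knn_graph(cbind(0:3, 0), k = 1)
#' morans_i(c(1, 2, 3, 4), g, n_permutations = 99)$statistic  # 0.4
#' @export
morans_i <- function(values, graph, n_permutations = 999, seed = 1L) {
  values <- as.numeric(values)
  n <- graph$n_nodes
  stopifnot(length(values) == n, n_permutations >= 99)
  if (stats::var(values) == 0)
    stop("Moran's I is undefined for a constant vector")
  W <- row_standardized_weights(graph)
  s0 <- sum(W)
  z <- values - mean(values)
  denom <- sum(z^2)
  stat_of <- function(zv) (n / s0) * as.numeric(zv %*% (W %*% zv)) / denom
  obs <- stat_of(z)
  set.seed(seed)
  perm <- vapply(seq_len(n_permutations),
                 function(b) stat_of(z[sample.int(n)]), numeric(1))
  p <- (1 + sum(perm >= obs)) / (n_permutations + 1)
  structure(list(statistic = obs, perm_pvalue = p,
                 n_permutations = as.integer(n_permutations),
                 adjusted_pvalue = NA_real_),
            class = "moran_result")
}

#' Detect spatially variable gene / cell-type pairs
#'
#' Runs the Moran's I permutation test on every column of one or more
#' attribution fields (one column per gene x cell-type pair), adjusts the
#' permutation p-values jointly by Benjamini-Hochberg, and flags a pair as
#' spatially variable iff its adjusted p is below `alpha` and its Moran's I
#' is positive (spatial structure, not dispersion). Columns with fewer than
#' two distinct values are skipped and absent from the output.
#'
#' @param attributions a single `attribution_field` or a list of them; a
#'   plain n x K matrix is also accepted (treated as one gene).
#' @param graph a `spatial_graph` over the same spots.
#' @param alpha significance level on adjusted p-values (default 0.05).
#' @param n_permutations permutations per test (default 999).
#' @param seed integer base seed; tests get seed + column offset.
#' @return data.frame with columns `gene`, `celltype`, `moran_i`, `pvalue`,
#'   `fdr`, `is_svg`.
#' @export
detect_svgs <- function(attributions, graph, alpha = 0.05,
                        n_permutations = 999, seed = 1L) {
  if (inherits(attributions, "attribution_field"))
    attributions <- list(attributions)
  if (is.matrix(attributions))
    attributions <- list(structure(list(gene = "gene", values = attributions),
                                   class = "attribution_field"))
  rows <- list()
  off <- 0L
  for (af in attributions) {
    V <- af$values
    if (is.null(colnames(V))) colnames(V) <- paste0("celltype", seq_len(ncol(V)))
    for (k in seq_len(ncol(V))) {
      off <- off + 1L
      v <- V[, k]
      if (length(unique(v)) < 2L) next
      mr <- morans_i(v, graph, n_permutations = n_permutations,
                     seed = seed + off)
      rows[[length(rows) + 1L]] <-
        data.frame(gene = af$gene, celltype = colnames(V)[k],
                   moran_i = mr$statistic, pvalue = mr$perm_pvalue)
    }
  }
  if (!length(rows))
    return(data.frame(gene = character(), celltype = character(),
                      moran_i = numeric(), pvalue = numeric(),
                      fdr = numeric(), is_svg = logical()))
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$pvalue, method = "BH")
  out$is_svg <- out$fdr < alpha & out$moran_i > 0
  out
}
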