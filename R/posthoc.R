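#' Partition spots into spatial clusters
#'
#' k-means on the coordinates; used to define the neighborhoods over which
#' post-hoc refits assume a shared coefficient scale.
#'
#' @param coords numeric n x 2 coordinate matrix.
#' @param n_clusters number of clusters, `1 <= n_clusters <= n`.
#' @param seed integer seed.
#' @return integer label vector of length n; every cluster is non-empty.
#' @export
cluster_spots <- function(coords, n_clusters, seed = 1L) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  n_clusters <- as.integer(n_clusters)
  if (n_clusters < 1L || n_clusters > n)
    stop("`n_clusters` must be between 1 and n")
  if (n_clusters == 1L) return(rep(1L, n))
  set.seed(seed)
  stats::kmeans(coords, centers = n_clusters, nstart = 10L,
                iter.max = 100L)$cluster
}

#' Default cluster count for post-hoc refitting
#' @param n number of spots.
#' @return `max(10, round(n / 50))`, capped at n.
#' @export
default_posthoc_clusters <- function(n) {
  min(n, max(10L, as.integer(round(n / 50))))
}

#' Post-hoc significance testing of a fitted coefficient field
#'
#' Penalized fits shrink but do not test. Within each spatial cluster, the
#' response is refit by ordinary least squares (with intercept) on the
#' predictors whose coefficient column is nonzero anywhere in that cluster;
#' each tested predictor gets a two-sided t-test p-value, assigned to every
#' spot of the cluster. Benjamini-Hochberg adjustment is applied jointly
#' across all (cluster, predictor) tests, and an entry is selected iff its
#' adjusted p-value is below `alpha` and its fitted coefficient is nonzero
#' at that spot. Clusters with more active predictors than spots are skipped
#' with a warning (rank deficiency), leaving their entries untested (p = 1).
#'
#' @param dataset a [spatial_dataset()].
#' @param field n x p coefficient matrix with exact zeros (run
#'   [hard_threshold()] first).
#' @param labels integer cluster labels from [cluster_spots()].
#' @param alpha selection level in (0, 1), applied to adjusted p-values.
#' @return An object of class `svc_selection`: list with `pvalues`,
#'   `adjusted_pvalues` (n x p, 1 where untested), `selected_mask` (n x p
#'   logical), `cluster_labels`, `alpha`, and `tests` — the long table of
#'   (cluster, predictor, estimate, pvalue, fdr).
#' @export
refit_and_test <- function(dataset, field, labels, alpha = 0.05) {
  stopifnot(inherits(dataset, "spatial_dataset"), alpha > 0, alpha < 1)
  field <- as.matrix(field)
  n <- n_spots(dataset)
  p <- n_predictors(dataset)
  stopifnot(all(dim(field) == c(n, p)), length(labels) == n)

  pmat <- matrix(1, n, p,
                 dimnames = list(dataset$spot_ids, dataset$predictor_names))
  tests <- list()
  for (cl in sort(unique(labels))) {
    rows <- which(labels == cl)
    active <- which(colSums(field[rows, , drop = FALSE] != 0) > 0)
    if (!length(active)) next
    if (length(active) + 1L >= length(rows)) {
      warning("cluster ", cl, " has ", length(active),
              " active predictors for ", length(rows),
              " spots; tests skipped (rank deficiency)")
      next
    }
    X <- dataset$predictors[rows, active, drop = FALSE]
    fit <- stats::lm(dataset$response[rows] ~ X)
    sm <- stats::coef(summary(fit))
    # rows of sm after the intercept follow the columns of X; collinear
    # columns are dropped by lm and stay untested
    keep <- match(paste0("X", colnames(X)), rownames(sm))
    for (a in seq_along(active)) {
      if (is.na(keep[a])) next
      pv <- sm[keep[a], "Pr(>|t|)"]
      if (!is.finite(pv)) pv <- 1
      pmat[rows, active[a]] <- pv
      tests[[length(tests) + 1L]] <-
        data.frame(cluster = cl,
                   predictor = dataset$predictor_names[active[a]],
                   estimate = sm[keep[a], "Estimate"], pvalue = pv)
    }
  }

  adj <- matrix(1, n, p, dimnames = dimnames(pmat))
  if (length(tests)) {
    tab <- do.call(rbind, tests)
    tab$fdr <- stats::p.adjust(tab$pvalue, method = "BH")
    for (r in seq_len(nrow(tab))) {
      rows <- which(labels == tab$cluster[r])
      adj[rows, tab$predictor[r]] <- tab$fdr[r]
    }
  } else {
    tab <- data.frame(cluster = integer(), predictor = character(),
                      estimate = numeric(), pvalue = numeric(),
                      fdr = numeric())
  }
  mask <- adj < alpha & field != 0
  structure(list(pvalues = pmat, adjusted_pvalues = adj,
                 selected_mask = mask, cluster_labels = labels,
                 alpha = alpha, tests = tab),
            class = "svc_selection")
}

#' @export
print.svc_selection <- function(x, ...) {
  cat("svc_selection: ", sum(x$selected_mask), " selected entries across ",
      length(unique(x$cluster_labels)), " clusters (alpha = ", x$alpha,
      ")\n", sep = "")
  invisible(x)
}

#' Apply a selection mask to a coefficient field
#' @param field n x p coefficient matrix.
#' @param selection an `svc_selection`.
#' @return the field with unselected entries set to zero.
#' @export
apply_selection <- function(field, selection) {
  field <- as.matrix(field)
  field[!selection$selected_mask] <- 0
  field
}
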