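#' Simulate a spatially varying coefficient dataset with known truth
#'
#' Coordinates are uniform on the unit square. A spatial partition into
#' `n_clusters` coefficient clusters is drawn from one of three patterns:
#' `"voronoi"` (nearest of `n_clusters` random centers), `"bands"`
#' (horizontal bands stacked along y), or `"checker"` (checkerboard cells
#' labelled cyclically). A random subset of `n_active` predictors is active;
#' for each active predictor and cluster, a coefficient is drawn once from
#' the integer grid `{-coef_scale, ..., coef_scale} \ {0}`, so the true
#' field is piecewise constant over the clusters and identically zero for
#' inactive predictors. Predictors are i.i.d. standard normal and
#' `y = sum_k x_k beta_k + N(0, noise_sd^2)`. Fully reproducible per seed.
#'
#' @param n number of spots.
#' @param p number of predictors.
#' @param n_active number of truly active predictors (<= p).
#' @param n_clusters number of spatial coefficient clusters (>= 1).
#' @param pattern `"voronoi"`, `"bands"` or `"checker"`.
#' @param noise_sd Gaussian noise standard deviation.
#' @param coef_scale coefficient magnitude bound (integer grid).
#' @param seed integer seed.
#' @return list with `dataset` (a [spatial_dataset()]) and `truth`: list
#'   with `cluster_labels`, `true_field` (n x p), `active_set` (indices),
#'   `noise_sd`, `seed`.
#' @export
simulate_dataset <- function(n = 300, p = 20, n_active = 3, n_clusters = 2,
                             pattern = c("voronoi", "bands", "checker"),
                             noise_sd = 0.5, coef_scale = 2, seed = 1L) {
  pattern <- match.arg(pattern)
  stopifnot(n_active <= p, n_active >= 1, n_clusters >= 1, noise_sd >= 0,
            coef_scale >= 1)
  set.seed(seed)
  coords <- cbind(x = stats::runif(n), y = stats::runif(n))
  labels <- switch(pattern,
    voronoi = {
      centers <- cbind(stats::runif(n_clusters), stats::runif(n_clusters))
      d2 <- outer(rowSums(coords^2), rowSums(centers^2), "+") -
        2 * coords %*% t(centers)
      max.col(-d2, ties.method = "first")
    },
    bands = pmin(n_clusters, floor(coords[, 2] * n_clusters) + 1L),
    checker = {
      ix <- pmin(n_clusters, floor(coords[, 1] * n_clusters) + 1L)
      iy <- pmin(n_clusters, floor(coords[, 2] * n_clusters) + 1L)
      ((ix + iy) %% n_clusters) + 1L
    })
  labels <- as.integer(labels)
  active <- sort(sample.int(p, n_active))
  values <- setdiff(seq(-coef_scale, coef_scale), 0)
  cluster_coef <- matrix(sample(values, n_clusters * n_active,
                                replace = TRUE),
                         n_clusters, n_active)
  true_field <- matrix(0, n, p)
  true_field[, active] <- cluster_coef[labels, , drop = FALSE]
  X <- matrix(stats::rnorm(n * p), n, p)
  y <- rowSums(X * true_field) + stats::rnorm(n, 0, noise_sd)
  ds <- spatial_dataset(coords, y, X, section_id = paste0("sim", seed))
  dimnames(true_field) <- dimnames(ds$predictors)
  list(dataset = ds,
       truth = list(cluster_labels = labels, true_field = true_field,
                    active_set = active, n_clusters = as.integer(n_clusters),
                    noise_sd = noise_sd, seed = as.integer(seed)))
}

#' Adjusted Rand Index between two labelings
#'
#' Chance-corrected pair-counting agreement between two partitions of the
#' same items: 1 for identical partitions (up to label renaming), about 0 at
#' chance. Computed from the contingency-table formulation.
#'
#' @param labels_a,labels_b equal-length label vectors (length >= 2).
#' @return a single number in `[-1, 1]`.
#' @examples
#' adjusted_rand_index(c(0, 0, 1, 1), c(0, 1, 0, 1))  # -0.5
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("labelings must have equal length")
  n <- length(labels_a)
  stopifnot(n >= 2)
  tab <- table(labels_a, labels_b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  total <- choose2(n)
  expected <- sum_a * sum_b / total
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(if (sum_ij == expected) 1 else 0)
  (sum_ij - expected) / (max_index - expected)
}

#' Score recovery of a simulated truth
#'
#' Estimated coefficient clusters are obtained by seeded k-means (k = the
#' true cluster count) on the rows of the fitted field restricted to the
#' truly active predictors, and compared to the true clusters by
#' [adjusted_rand_index()]. The post-hoc-selected predictor set (selected
#' anywhere) is compared to the true active set by precision and recall,
#' and RMSE is computed on the truly active entries only.
#'
#' @param truth the `truth` element of [simulate_dataset()].
#' @param fitted n x p fitted coefficient matrix (raw scale).
#' @param selection an `svc_selection` from [refit_and_test()], or NULL to
#'   score selection from the nonzero pattern of `fitted`.
#' @param seed seed for the clustering k-means.
#' @return list of class `recovery_report`: `ari`, `selection_precision`,
#'   `selection_recall`, `coefficient_rmse_active`, `estimated_clusters`.
#' @export
recovery_benchmark <- function(truth, fitted, selection = NULL, seed = 1L) {
  fitted <- as.matrix(fitted)
  stopifnot(all(dim(fitted) == dim(truth$true_field)))
  act <- truth$active_set
  sub <- fitted[, act, drop = FALSE]
  k <- truth$n_clusters
  est <- if (k == 1L || nrow(unique(sub)) < k) rep(1L, nrow(sub)) else {
    set.seed(seed)
    stats::kmeans(sub, centers = k, nstart = 10L, iter.max = 100L)$cluster
  }
  ari <- adjusted_rand_index(truth$cluster_labels, est)
  sel_cols <- if (is.null(selection)) which(colSums(fitted != 0) > 0) else
    which(colSums(selection$selected_mask) > 0)
  tp <- length(intersect(sel_cols, act))
  precision <- if (length(sel_cols)) tp / length(sel_cols) else
    if (length(act)) 0 else 1
  recall <- if (length(act)) tp / length(act) else 1
  rmse <- sqrt(mean((fitted[, act] - truth$true_field[, act])^2))
  structure(list(ari = ari, selection_precision = precision,
                 selection_recall = recall, coefficient_rmse_active = rmse,
                 estimated_clusters = est),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf(paste0("recovery_report: ARI %.3f, precision %.3f, ",
                     "recall %.3f, active-RMSE %.3f\n"),
              x$ari, x$selection_precision, x$selection_recall,
              x$coefficient_rmse_active))
  invisible(x)
}

#' End-to-end simulation benchmark pipeline
#'
#' Simulates a dataset, selects penalties by spatially blocked
#' cross-validation at a reduced budget, fits the final model, applies the
#' hard threshold and post-hoc selection, and scores recovery against the
#' simulated truth. This is the workflow used to validate the method on
#' synthetic data.
#'
#' @param n,p,n_active,n_clusters,pattern,noise_sd,coef_scale passed to
#'   [simulate_dataset()].
#' @param seed integer seed controlling the simulation, tuning and
#'   clustering.
#' @param n_trials tuning trials (default 24; the adaptive sampler spends
#'   half of them refining around the coarse optimum).
#' @param sampler tuning backend, see [tune_hyperparameters()]; the
#'   benchmark defaults to `"adaptive"` because three penalties over eight
#'   orders of magnitude are searched with few trials.
#' @param tune_max_iter optimizer budget per tuning fit (default 400).
#' @param fit_max_iter optimizer budget for the final fit (default 3000).
#' @param n_blocks,n_folds cross-validation layout (defaults 10 blocks,
#'   5 folds).
#' @param alpha post-hoc selection level (default 0.05).
#' @return list with `report` (a `recovery_report`), `tuning`, `fit`,
#'   `selection`, `truth`, `dataset`.
#' @export
recovery_pipeline <- function(n = 300, p = 20, n_active = 3, n_clusters = 2,
                              pattern = "voronoi", noise_sd = 0.5,
                              coef_scale = 2, seed = 1L, n_trials = 24,
                              sampler = "adaptive", tune_max_iter = 400,
                              fit_max_iter = 3000, n_blocks = 10,
                              n_folds = 5, alpha = 0.05) {
  sim <- simulate_dataset(n = n, p = p, n_active = n_active,
                          n_clusters = n_clusters, pattern = pattern,
                          noise_sd = noise_sd, coef_scale = coef_scale,
                          seed = seed)
  ds <- sim$dataset
  graph <- build_spatial_graph(ds$coords)
  scheme <- make_spatial_blocks(ds$coords, n_blocks = n_blocks,
                                n_folds = n_folds, seed = seed)
  tuned <- tune_hyperparameters(ds, graph, scheme, n_trials = n_trials,
                                seed = seed, sampler = sampler,
                                opt = optimizer_config(max_iter =
                                                         tune_max_iter))
  pen <- penalty_config(tuned$best[["lambda1"]], tuned$best[["lambda2"]],
                        tuned$best[["lambda3"]])
  fit <- fit_svc(ds, graph, pen, optimizer_config(max_iter = fit_max_iter))
  field <- hard_threshold(fit$field)
  labels <- cluster_spots(ds$coords, default_posthoc_clusters(n), seed = seed)
  sel <- refit_and_test(ds, field, labels, alpha = alpha)
  report <- recovery_benchmark(sim$truth, field, sel, seed = seed)
  list(report = report, tuning = tuned, fit = fit, selection = sel,
       truth = sim$truth, dataset = ds)
}
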