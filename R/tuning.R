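#' Spatially blocked cross-validation scheme
#'
#' Spots are partitioned into spatially coherent blocks by k-means on the
#' coordinates; whole blocks are then assigned to folds, so validation spots
#' are spatially separated from training spots and spatial autocorrelation
#' cannot leak across the split. Every block appears in exactly one
#' validation set.
#'
#' @param coords numeric n x 2 coordinate matrix.
#' @param n_blocks number of spatial blocks (default 10).
#' @param n_folds number of folds; blocks are dealt to folds as evenly as
#'   possible (default 5).
#' @param seed integer seed (k-means and block shuffling).
#' @return An object of class `cv_scheme`: list with `block_labels`
#'   (length n), `n_blocks`, and `folds` — a list of
#'   `list(train = idx, validation = idx)` index vectors.
#' @export
make_spatial_blocks <- function(coords, n_blocks = 10, n_folds = 5,
                                seed = 1L) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  n_blocks <- as.integer(n_blocks)
  n_folds <- as.integer(n_folds)
  if (n_blocks < 2L || n_blocks > n)
    stop("`n_blocks` must be between 2 and n")
  if (n_folds < 2L || n_folds > n_blocks)
    stop("`n_folds` must be between 2 and n_blocks")
  set.seed(seed)
  km <- stats::kmeans(coords, centers = n_blocks, nstart = 10L,
                      iter.max = 100L)
  labels <- km$cluster
  fold_of_block <- sample(rep_len(seq_len(n_folds), n_blocks))
  folds <- lapply(seq_len(n_folds), function(f) {
    val_blocks <- which(fold_of_block == f)
    val <- which(labels %in% val_blocks)
    list(train = setdiff(seq_len(n), val), validation = val)
  })
  structure(list(block_labels = labels, n_blocks = n_blocks, folds = folds),
            class = "cv_scheme")
}

#' Log-uniform sampler
#'
#' Draws values whose logarithm is uniform on `[log(low), log(high)]`, the
#' sampling law used for penalty search.
#'
#' @param n number of draws.
#' @param low,high positive range endpoints.
#' @return numeric vector of n draws.
#' @export
rloguniform <- function(n, low = 1e-6, high = 1e2) {
  stopifnot(low > 0, high > low)
  exp(stats::runif(n, log(low), log(high)))
}

#' Select penalties by spatially blocked cross-validation
#'
#' Each trial draws `(lambda1, lambda2, lambda3)` independently log-uniform
#' on `[search_low, search_high]`, fits the model on every fold's training
#' blocks, and scores mean squared prediction error on the held-out blocks.
#' Because spatially varying coefficients are undefined at held-out
#' locations, a validation spot is predicted with the coefficients of its
#' nearest training spot — consistent with the smoothness assumption. Trials
#' are independent, so the sequence is reproducible from the seed regardless
#' of execution order. Ties in validation MSE go to the more regularized
#' triple (larger lambda sum).
#'
#' @param dataset a [spatial_dataset()].
#' @param graph a `spatial_graph` on the full coordinates; per-fold training
#'   subgraphs are rebuilt with the same construction (`kind`, `k`).
#' @param scheme a [make_spatial_blocks()] scheme.
#' @param n_trials number of sampled triples (default 50).
#' @param search_low,search_high sampling range (defaults 1e-6, 1e2).
#' @param seed integer seed for the sampler.
#' @param opt an [optimizer_config()] used for every fold fit; use a reduced
#'   `max_iter` here to keep tuning cheap.
#' @param sampler `"random"` — the reference backend, all trials drawn
#'   log-uniform on the full range — or `"adaptive"`, a coarse-to-fine
#'   variant: the first half of the trials are drawn from the full range,
#'   the second half log-uniform from a window (x1/30 to x30, clipped to
#'   the range) around the best triple of the first half. Both backends
#'   record every trial and return the minimum-MSE triple, and both are
#'   deterministic given the seed.
#' @param standardize,center passed to [fit_svc()].
#' @return An object of class `tuning_result`: list with `trials`
#'   (data.frame: lambda1..3, mean_mse), `best` (named numeric triple),
#'   `best_mse`, `seed`.
#' @export
tune_hyperparameters <- function(dataset, graph, scheme, n_trials = 50,
                                 search_low = 1e-6, search_high = 1e2,
                                 seed = 1L, opt = optimizer_config(),
                                 sampler = c("random", "adaptive"),
                                 standardize = TRUE, center = TRUE) {
  stopifnot(inherits(scheme, "cv_scheme"), n_trials >= 1)
  sampler <- match.arg(sampler)
  set.seed(seed)
  lam <- matrix(rloguniform(3L * n_trials, search_low, search_high),
                n_trials, 3L)
  colnames(lam) <- c("lambda1", "lambda2", "lambda3")

  # per-fold fixtures: subgraph on training coords, nearest-training-spot map
  folds <- lapply(scheme$folds, function(f) {
    if (!length(f$train)) stop("cross-validation fold has no training spots")
    if (!length(f$validation)) stop("cross-validation fold has no validation spots")
    tr_co <- dataset$coords[f$train, , drop = FALSE]
    g <- if (graph$kind == "knn")
      build_knn_graph(tr_co, min(graph$k, nrow(tr_co) - 1L))
    else build_mst(tr_co)
    dmat <- outer(rowSums(dataset$coords[f$validation, , drop = FALSE]^2),
                  rowSums(tr_co^2), "+") -
      2 * dataset$coords[f$validation, , drop = FALSE] %*% t(tr_co)
    list(train = f$train, validation = f$validation, graph = g,
         nearest = max.col(-dmat, ties.method = "first"))
  })

  score_triple <- function(l) {
    pen <- penalty_config(l[1], l[2], l[3])
    fold_mse <- vapply(folds, function(f) {
      fit <- fit_svc(dataset[f$train], f$graph, pen, opt,
                     standardize = standardize, center = center)
      yhat <- predict(fit,
                      newdata = dataset$predictors[f$validation, ,
                                                   drop = FALSE],
                      field_rows = f$nearest)
      mean((dataset$response[f$validation] - yhat)^2)
    }, numeric(1))
    mean(fold_mse)
  }

  if (sampler == "adaptive" && n_trials >= 4) {
    n1 <- ceiling(n_trials / 2)
    mse1 <- vapply(seq_len(n1), function(t) score_triple(lam[t, ]),
                   numeric(1))
    anchor <- lam[order(mse1, -rowSums(lam[seq_len(n1), , drop = FALSE]))[1], ]
    lo <- pmax(anchor / 30, search_low)
    hi <- pmin(anchor * 30, search_high)
    for (t in seq(n1 + 1L, n_trials))
      lam[t, ] <- vapply(1:3, function(jj) rloguniform(1, lo[jj], hi[jj]),
                         numeric(1))
    mse <- c(mse1, vapply(seq(n1 + 1L, n_trials),
                          function(t) score_triple(lam[t, ]), numeric(1)))
  } else {
    mse <- vapply(seq_len(n_trials), function(t) score_triple(lam[t, ]),
                  numeric(1))
  }

  trials <- data.frame(lam, mean_mse = mse)
  ord <- order(mse, -rowSums(lam))
  best <- lam[ord[1], ]
  structure(list(trials = trials, best = best, best_mse = mse[ord[1]],
                 seed = as.integer(seed)),
            class = "tuning_result")
}

#' @export
print.tuning_result <- function(x, ...) {
  cat("tuning_result: ", nrow(x$trials), " trials; best (lambda1, lambda2, ",
      "lambda3) = (", paste(signif(x$best, 4), collapse = ", "),
      "), validation MSE ", signif(x$best_mse, 5), "\n", sep = "")
  invisible(x)
}
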