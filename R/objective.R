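#' Decompose the model objective into its four terms
#'
#' The objective being minimized is
#' \deqn{\frac{1}{n}\sum_i \big(y(s_i) - \sum_k x_k(s_i)\beta_k(s_i)\big)^2
#'   + \lambda_1 \sum_k \|H\beta_k\|_1 + \lambda_2 \sum_k \|\beta_k\|_1
#'   + \lambda_3 \sum_k w \|\beta_k\|_2}
#' with \eqn{H} the edge incidence operator of the spatial graph and
#' \eqn{w} the group weight (sqrt(n) by default). The fused term is computed
#' by edgewise gather/difference, i.e. in O(mp) for m edges and p predictors.
#'
#' @param dataset a [spatial_dataset()].
#' @param field numeric n x p coefficient matrix (entry (i,k) =
#'   \eqn{\beta_k(s_i)}).
#' @param graph a `spatial_graph` built on the same coordinates.
#' @param penalties a [penalty_config()].
#' @return `objective_terms`: named numeric vector with elements `data`,
#'   `fused`, `lasso`, `group`. `evaluate_objective`: their sum.
#' @examples
#' d <- spatial_dataset(cbind(c(0, 1), 0), c(1, 2), matrix(1, 2, 1))
#' g <- build_mst(d$coords)
#' evaluate_objective(d, matrix(1, 2, 1), g,
#'                    penalty_config(1, 1, 1))  # 4.5
#' @export
objective_terms <- function(dataset, field, graph, penalties) {
  field <- as.matrix(field)
  n <- n_spots(dataset)
  p <- n_predictors(dataset)
  if (!all(dim(field) == c(n, p)))
    stop("`field` must be ", n, " x ", p, " to match the dataset")
  if (graph$n_nodes != n)
    stop("graph was built on ", graph$n_nodes, " nodes but the dataset has ",
         n, " spots")
  gw <- penalties$group_weight
  if (is.null(gw)) gw <- sqrt(n)
  r <- dataset$response - rowSums(dataset$predictors * field)
  data_term <- sum(r^2) / n
  ei <- graph$edges[, 1]
  ej <- graph$edges[, 2]
  fused <- penalties$lambda1 *
    sum(abs(field[ei, , drop = FALSE] - field[ej, , drop = FALSE]))
  lasso <- penalties$lambda2 * sum(abs(field))
  group <- penalties$lambda3 * gw * sum(sqrt(colSums(field^2)))
  c(data = data_term, fused = fused, lasso = lasso, group = group)
}

#' @rdname objective_terms
#' @export
evaluate_objective <- function(dataset, field, graph, penalties) {
  sum(objective_terms(dataset, field, graph, penalties))
}

#' Fit a sparse spatially varying coefficient field
#'
#' Minimizes the composite objective (see [evaluate_objective()]) by
#' full-batch adaptive-moment (Adam) updates. The group norm is smoothed as
#' \eqn{\sqrt{\|\beta_k\|_2^2+\epsilon}} for gradient purposes; the lasso and
#' fused terms use subgradients (sign(0)=0). Coefficients start at zero, the
#' objective is convex, and the run is fully deterministic: identical inputs
#' give bit-identical traces. The returned field is the incumbent best, so
#' its objective never exceeds the zero-initialization objective.
#'
#' By default predictors are z-scored and the response mean-centered before
#' optimization (penalties are scale-sensitive); the reported `field` is
#' rescaled back to the raw predictor scale, and `field_std` holds the
#' coefficients of the standardized problem whose objective the trace
#' records.
#'
#' @param dataset a [spatial_dataset()].
#' @param graph a `spatial_graph` on the same coordinates.
#' @param penalties a [penalty_config()].
#' @param opt an [optimizer_config()].
#' @param standardize z-score predictors before fitting (default TRUE).
#' @param center mean-center the response before fitting (default TRUE).
#' @return An object of class `svc_fit`: list with `field` (n x p, raw
#'   scale), `field_std`, `dataset_std` (the standardized problem),
#'   `objective`, `objective_trace`, `converged`, `n_iter`, `penalties`,
#'   `opt`, and `scaling` (`x_center`, `x_scale`, `y_center`).
#' @export
fit_svc <- function(dataset, graph, penalties = penalty_config(),
                    opt = optimizer_config(), standardize = TRUE,
                    center = TRUE) {
  stopifnot(inherits(dataset, "spatial_dataset"),
            inherits(graph, "spatial_graph"),
            inherits(penalties, "penalty_config"),
            inherits(opt, "optimizer_config"))
  n <- n_spots(dataset)
  if (graph$n_nodes != n)
    stop("graph node count does not match the dataset")
  X <- dataset$predictors
  y <- dataset$response
  x_center <- rep(0, ncol(X))
  x_scale <- rep(1, ncol(X))
  if (standardize) {
    x_center <- colMeans(X)
    x_scale <- apply(X, 2, stats::sd)
    x_scale[x_scale == 0 | !is.finite(x_scale)] <- 1
    X <- sweep(sweep(X, 2, x_center), 2, x_scale, "/")
  }
  y_center <- if (center) mean(y) else 0
  y <- y - y_center
  gw <- penalties$group_weight
  if (is.null(gw)) gw <- sqrt(n)
  clip <- opt$grad_clip_norm
  if (is.null(clip)) clip <- -1
  sched <- match(opt$schedule, c("constant", "cosine", "step")) - 1L
  res <- fit_svc_adam(X, y, graph$edges[, 1:2, drop = FALSE] - 1L,
                      penalties$lambda1, penalties$lambda2, penalties$lambda3,
                      gw, opt$max_iter, opt$learning_rate, sched, clip,
                      opt$epsilon_stab, opt$early_stop_patience, opt$tol)
  field_std <- res$coefficients
  dimnames(field_std) <- list(dataset$spot_ids, dataset$predictor_names)
  field <- sweep(field_std, 2, x_scale, "/")
  ds_std <- spatial_dataset(dataset$coords, y, X,
                            spot_ids = dataset$spot_ids,
                            predictor_names = dataset$predictor_names,
                            section_id = dataset$section_id)
  structure(list(field = field, field_std = field_std, dataset_std = ds_std,
                 objective = res$objective,
                 objective_trace = as.numeric(res$trace),
                 converged = res$converged, n_iter = res$n_iter,
                 penalties = penalties, opt = opt,
                 scaling = list(x_center = x_center, x_scale = x_scale,
                                y_center = y_center)),
            class = "svc_fit")
}

#' @export
print.svc_fit <- function(x, ...) {
  cat("svc_fit: ", nrow(x$field), " spots x ", ncol(x$field),
      " predictors; objective ", format(x$objective, digits = 6),
      " after ", x$n_iter, " iterations (",
      if (x$converged) "early-stopped" else "hit max_iter", ")\n", sep = "")
  invisible(x)
}

#' Predict the response from a fitted coefficient field
#'
#' @param object an `svc_fit`.
#' @param newdata optional n x p predictor matrix on the raw scale (defaults
#'   to the training predictors implied by the fit).
#' @param field_rows integer index mapping each prediction row to a row of
#'   the coefficient field (defaults to 1:n, i.e. each spot uses its own
#'   coefficients).
#' @param ... unused.
#' @return numeric vector of fitted responses on the raw scale.
#' @export
predict.svc_fit <- function(object, newdata = NULL, field_rows = NULL, ...) {
  B <- object$field
  if (is.null(newdata)) {
    X <- sweep(sweep(object$dataset_std$predictors, 2,
                     object$scaling$x_scale, "*"), 2,
               object$scaling$x_center, "+")
  } else {
    X <- as.matrix(newdata)
  }
  if (is.null(field_rows)) field_rows <- seq_len(nrow(X))
  # raw-scale field absorbs the predictor scaling; centering shifts enter the
  # fitted mean through the centered columns
  Xc <- sweep(X, 2, object$scaling$x_center)
  object$scaling$y_center + rowSums(Xc * B[field_rows, , drop = FALSE])
}

#' Zero out numerically small coefficients
#'
#' Subgradient solvers leave tiny nonzeros where the exact solution is zero;
#' downstream steps (post-hoc testing, attribution, selection scoring) need
#' exact zeros. Entries with `abs(x) < threshold` are set to 0.
#'
#' @param field numeric matrix (or `svc_fit`, whose raw and standardized
#'   fields are both thresholded).
#' @param threshold nonnegative cutoff; `NULL` uses `1e-6 * max(abs(field))`.
#' @return object of the same shape with exact zeros.
#' @export
hard_threshold <- function(field, threshold = NULL) {
  if (inherits(field, "svc_fit")) {
    field$field <- hard_threshold(field$field, threshold)
    field$field_std <- hard_threshold(field$field_std, threshold)
    return(field)
  }
  field <- as.matrix(field)
  if (is.null(threshold)) threshold <- 1e-6 * max(abs(field))
  stopifnot(threshold >= 0)
  field[abs(field) < threshold] <- 0
  field
}
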