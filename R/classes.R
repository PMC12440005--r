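#' Construct a spatial dataset
#'
#' Bundles 2-D spot/cell coordinates, a response vector and a predictor matrix
#' for one tissue section. This is the container every fitting, tuning and
#' downstream function consumes. All slots are validated: dimensions must
#' agree, values must be finite, and spot/predictor names must be unique.
#'
#' @param coords numeric n x 2 matrix of spatial coordinates.
#' @param response length-n numeric response (e.g. a target gene's expression).
#' @param predictors numeric n x p matrix of spatial predictors.
#' @param spot_ids character vector of n unique spot identifiers. Defaults to
#'   rownames of `coords`, or `"s1".."sn"`.
#' @param predictor_names character vector of p unique predictor names.
#'   Defaults to colnames of `predictors`, or `"x1".."xp"`.
#' @param section_id single string labelling the section.
#' @return An object of class `spatial_dataset`: a list with elements
#'   `spot_ids`, `coords`, `response`, `predictors`, `predictor_names`,
#'   `section_id`.
#' @examples
#' d <- spatial_dataset(cbind(runif(5), runif(5)), rnorm(5),
#'                      matrix(rnorm(10), 5, 2))
#' d
#' @export
spatial_dataset <- function(coords, response, predictors,
                            spot_ids = NULL, predictor_names = NULL,
                            section_id = "section1") {
  coords <- as.matrix(coords)
  predictors <- as.matrix(predictors)
  storage.mode(coords) <- "double"
  storage.mode(predictors) <- "double"
  response <- as.numeric(response)
  n <- nrow(coords)
  if (n < 2L) stop("a spatial dataset needs at least 2 spots")
  if (ncol(coords) != 2L) stop("`coords` must have exactly 2 columns")
  if (length(response) != n || nrow(predictors) != n)
    stop("rows of `coords`, `response` and `predictors` must agree")
  if (is.null(spot_ids)) spot_ids <- rownames(coords)
  if (is.null(spot_ids)) spot_ids <- paste0("s", seq_len(n))
  spot_ids <- as.character(spot_ids)
  if (length(spot_ids) != n) stop("`spot_ids` must have length n")
  if (anyDuplicated(spot_ids)) {
    stop("duplicate spot ids: ",
         paste(unique(spot_ids[duplicated(spot_ids)]), collapse = ", "))
  }
  if (is.null(predictor_names)) predictor_names <- colnames(predictors)
  if (is.null(predictor_names))
    predictor_names <- paste0("x", seq_len(ncol(predictors)))
  predictor_names <- as.character(predictor_names)
  if (length(predictor_names) != ncol(predictors))
    stop("`predictor_names` must have length p")
  if (anyDuplicated(predictor_names)) {
    stop("duplicate predictor names: ",
         paste(unique(predictor_names[duplicated(predictor_names)]),
               collapse = ", "))
  }
  if (!all(is.finite(coords)) || !all(is.finite(response)) ||
      !all(is.finite(predictors)))
    stop("non-finite values are not allowed; remove or impute them upstream")
  rownames(coords) <- spot_ids
  rownames(predictors) <- spot_ids
  colnames(predictors) <- predictor_names
  names(response) <- spot_ids
  structure(list(spot_ids = spot_ids, coords = coords, response = response,
                 predictors = predictors, predictor_names = predictor_names,
                 section_id = as.character(section_id)[1]),
            class = "spatial_dataset")
}

#' @export
print.spatial_dataset <- function(x, ...) {
  cat("spatial_dataset: ", length(x$spot_ids), " spots, ",
      length(x$predictor_names), " predictors (section ", x$section_id, ")\n",
      sep = "")
  invisible(x)
}

#' Number of spots / predictors in a spatial dataset
#' @param x a `spatial_dataset`.
#' @return integer count.
#' @export
n_spots <- function(x) length(x$spot_ids)

#' @rdname n_spots
#' @export
n_predictors <- function(x) length(x$predictor_names)

#' Subset a spatial dataset by spot index
#' @param x a `spatial_dataset`.
#' @param i integer or logical index over spots.
#' @param ... unused.
#' @return a `spatial_dataset` restricted to the selected spots.
#' @export
`[.spatial_dataset` <- function(x, i, ...) {
  spatial_dataset(x$coords[i, , drop = FALSE], x$response[i],
                  x$predictors[i, , drop = FALSE],
                  spot_ids = x$spot_ids[i],
                  predictor_names = x$predictor_names,
                  section_id = x$section_id)
}

#' Run configuration for data loading and graph choice
#'
#' Collects the knobs that govern input handling: graph construction mode,
#' the prevalence filter, and standardization defaults. These are recorded in
#' run manifests so that a run can be reproduced exactly.
#'
#' @param graph_kind `"knn"`, `"mst"` or `"auto"`. `"auto"` uses a KNN graph
#'   for n <= `auto_threshold` spots and an MST above that.
#' @param knn_k neighbors per spot for the KNN graph (default 7).
#' @param auto_threshold spot count above which `"auto"` switches to the MST
#'   (default 1000).
#' @param min_expression_fraction predictors nonzero in fewer than this
#'   fraction of spots are dropped at load time (default 0.10; the boundary is
#'   inclusive, a predictor at exactly the fraction is kept).
#' @param standardize_predictors z-score predictors before fitting (default
#'   TRUE); reported coefficients are rescaled back to the raw scale.
#' @param center_response subtract the mean response before fitting (default
#'   TRUE); no intercept is fit.
#' @param orientation `"spots_by_genes"` or `"genes_by_spots"`; orientation of
#'   a dense predictor matrix on disk. Never autodetected.
#' @param log1p_expression apply `log1p` to the predictor matrix at load time
#'   (default FALSE).
#' @param seed integer seed recorded in manifests and used by stochastic
#'   stages.
#' @return a list of class `run_config`.
#' @export
run_config <- function(graph_kind = c("auto", "knn", "mst"), knn_k = 7L,
                       auto_threshold = 1000L, min_expression_fraction = 0.10,
                       standardize_predictors = TRUE, center_response = TRUE,
                       orientation = c("spots_by_genes", "genes_by_spots"),
                       log1p_expression = FALSE, seed = 1L) {
  graph_kind <- match.arg(graph_kind)
  orientation <- match.arg(orientation)
  stopifnot(knn_k >= 1L, auto_threshold >= 1L,
            min_expression_fraction >= 0, min_expression_fraction <= 1)
  structure(list(graph_kind = graph_kind, knn_k = as.integer(knn_k),
                 auto_threshold = as.integer(auto_threshold),
                 min_expression_fraction = min_expression_fraction,
                 standardize_predictors = isTRUE(standardize_predictors),
                 center_response = isTRUE(center_response),
                 orientation = orientation,
                 log1p_expression = isTRUE(log1p_expression),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Penalty configuration
#'
#' The three regularization strengths of the model objective:
#' `lambda1` weighs the graph fused-lasso term (spatial smoothness),
#' `lambda2` the element-wise lasso (per-spot sparsity) and `lambda3` the
#' group lasso over each predictor's whole coefficient field (global
#' predictor removal). The group term is weighted by `group_weight`, which
#' defaults to sqrt(n) at fit time (`NULL`), the usual group-size weight.
#'
#' @param lambda1,lambda2,lambda3 nonnegative penalty strengths.
#' @param group_weight positive multiplier of the group L2 norm, or `NULL`
#'   for sqrt(number of spots).
#' @return a list of class `penalty_config`.
#' @export
penalty_config <- function(lambda1 = 0, lambda2 = 0, lambda3 = 0,
                           group_weight = NULL) {
  stopifnot(lambda1 >= 0, lambda2 >= 0, lambda3 >= 0)
  if (!is.null(group_weight)) stopifnot(group_weight > 0)
  structure(list(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3,
                 group_weight = group_weight),
            class = "penalty_config")
}

#' Optimizer configuration
#'
#' Settings of the adaptive-moment (Adam) solver: iteration budget, base
#' learning rate and schedule, global gradient-norm clipping, the epsilon
#' that smooths the group norm near zero, and early stopping (training stops
#' once the best objective has failed to improve by `tol` for `patience`
#' consecutive iterations).
#'
#' @param max_iter maximum iterations (default 5000).
#' @param learning_rate base step size (default 0.01).
#' @param schedule learning-rate schedule: `"cosine"` (default), `"step"`
#'   (x0.1 at 1/2 and 3/4 of `max_iter`) or `"constant"`.
#' @param grad_clip_norm clip the global gradient Frobenius norm to this
#'   value (default 5); `NULL` disables clipping.
#' @param epsilon_stab smoothing added inside the group-norm square root to
#'   avoid instability at zero (default 1e-8).
#' @param early_stop_patience iterations without improvement before stopping
#'   (default 50).
#' @param tol minimum objective improvement that counts (default 1e-6).
#' @param seed integer seed (the full-batch solver is deterministic; recorded
#'   for provenance).
#' @return a list of class `optimizer_config`.
#' @export
optimizer_config <- function(max_iter = 5000L, learning_rate = 0.01,
                             schedule = c("cosine", "step", "constant"),
                             grad_clip_norm = 5, epsilon_stab = 1e-8,
                             early_stop_patience = 50L, tol = 1e-6,
                             seed = 1L) {
  schedule <- match.arg(schedule)
  stopifnot(max_iter >= 1L, learning_rate > 0, epsilon_stab > 0,
            early_stop_patience >= 1L, tol > 0)
  if (!is.null(grad_clip_norm)) stopifnot(grad_clip_norm > 0)
  structure(list(max_iter = as.integer(max_iter),
                 learning_rate = learning_rate, schedule = schedule,
                 grad_clip_norm = grad_clip_norm, epsilon_stab = epsilon_stab,
                 early_stop_patience = as.integer(early_stop_patience),
                 tol = tol, seed = as.integer(seed)),
            class = "optimizer_config")
}
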