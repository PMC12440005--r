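toy_two_spot <- function() {
  d <- spatial_dataset(cbind(c(0, 1), 0), c(1, 2), matrix(1, 2, 1))
  list(dataset = d, graph = build_mst(d$coords))
}

test_that("the objective matches hand computation and decomposes exactly", {
  tw <- toy_two_spot()
  pen <- penalty_config(1, 1, 1)
  # data (1/2)(0+1)=0.5; fused |1-1|=0; L1 = 2; group sqrt(2)*sqrt(2) = 2
  expect_equal(evaluate_objective(tw$dataset, matrix(1, 2, 1), tw$graph, pen),
               4.5)
  # perfect fit with no penalties
  expect_equal(evaluate_objective(tw$dataset, matrix(c(1, 2), 2, 1),
                                  tw$graph, penalty_config()), 0)
  # null field gives the mean squared response
  expect_equal(evaluate_objective(tw$dataset, matrix(0, 2, 1), tw$graph,
                                  penalty_config()),
               mean(tw$dataset$response^2))
  # term decomposition conserves the total on random instances
  set.seed(31)
  for (rep in 1:5) {
    sim <- simulate_dataset(n = 30, p = 4, seed = rep)
    g <- build_mst(sim$dataset$coords)
    fld <- matrix(rnorm(120), 30, 4)
    pen <- penalty_config(runif(1), runif(1), runif(1))
    terms <- objective_terms(sim$dataset, fld, g, pen)
    expect_equal(sum(terms),
                 evaluate_objective(sim$dataset, fld, g, pen))
    expect_true(all(terms >= 0))
  }
})

test_that("the fitted minimizer matches a dense grid-search oracle on tiny instances", {
  # n = 3 path, p = 1: fused-lasso shrinkage pulls the outlier inward
  d <- spatial_dataset(cbind(0:2, 0), c(0, 0, 3), matrix(1, 3, 1))
  g <- build_mst(d$coords)
  pen <- penalty_config(lambda1 = 0.5)
  oracle <- grid_oracle(d, g, pen, lower = -1, upper = 4)
  fit <- fit_svc(d, g, pen, optimizer_config(max_iter = 4000),
                 standardize = FALSE, center = FALSE)
  expect_lt(max(abs(fit$field - oracle)), 0.02)
  # n = 2, p = 2 with all three penalties active
  d2 <- spatial_dataset(cbind(c(0, 1), 0), c(2, -1),
                        matrix(c(1, 0.5, -0.5, 1), 2, 2))
  g2 <- build_mst(d2$coords)
  pen2 <- penalty_config(0.2, 0.1, 0.05)
  oracle2 <- grid_oracle(d2, g2, pen2, lower = -3, upper = 3)
  fit2 <- fit_svc(d2, g2, pen2, optimizer_config(max_iter = 4000),
                  standardize = FALSE, center = FALSE)
  expect_lt(max(abs(fit2$field - oracle2)), 0.02)
})

test_that("penalty-dominated limits collapse the field as theory predicts", {
  set.seed(17)
  sim <- simulate_dataset(n = 40, p = 3, n_active = 2, noise_sd = 0.2,
                          seed = 17)
  ds <- sim$dataset
  g <- build_mst(ds$coords)
  # huge fusion -> spatially constant columns
  f1 <- fit_svc(ds, g, penalty_config(lambda1 = 1e4),
                optimizer_config(max_iter = 4000), standardize = FALSE,
                center = FALSE)
  expect_lt(max(apply(f1$field, 2, function(b) diff(range(b)))), 1e-3)
  # huge sparsity -> exactly zero after thresholding, objective -> null
  for (pen in list(penalty_config(lambda2 = 1e4),
                   penalty_config(lambda3 = 1e4))) {
    f2 <- fit_svc(ds, g, pen, optimizer_config(max_iter = 2000),
                  standardize = FALSE, center = FALSE)
    expect_lt(max(abs(f2$field)), 1e-6)
    expect_equal(min(f2$objective_trace), mean(ds$response^2),
                 tolerance = 1e-6)
  }
})

test_that("with no penalties and one predictor the per-spot minimizer is recovered", {
  set.seed(23)
  n <- 25
  x <- runif(n, 0.5, 2)
  y <- rnorm(n)
  d <- spatial_dataset(cbind(runif(n), runif(n)), y, matrix(x, n, 1))
  g <- build_mst(d$coords)
  fit <- fit_svc(d, g, penalty_config(),
                 optimizer_config(max_iter = 5000, learning_rate = 0.05),
                 standardize = FALSE, center = FALSE)
  expect_lt(max(abs(fit$field[, 1] - y / x)), 1e-4)
})

test_that("fit bookkeeping: trace ties to the evaluator, incumbents never worsen", {
  sim <- simulate_dataset(n = 50, p = 5, seed = 3)
  ds <- sim$dataset
  g <- build_mst(ds$coords)
  pen <- penalty_config(1e-3, 1e-4, 1e-5)
  fit <- fit_svc(ds, g, pen, optimizer_config(max_iter = 800))
  # recorded best objective equals re-evaluating the returned field
  expect_equal(fit$objective,
               evaluate_objective(fit$dataset_std, fit$field_std, g, pen),
               tolerance = 1e-9)
  expect_equal(fit$objective, min(fit$objective_trace))
  # best-so-far is non-increasing and never exceeds the zero-init objective
  expect_true(all(diff(cummin(fit$objective_trace)) <= 0))
  expect_lte(fit$objective,
             evaluate_objective(fit$dataset_std,
                                matrix(0, 50, 5), g, pen))
  # determinism: identical configs give bit-identical traces
  fit2 <- fit_svc(ds, g, pen, optimizer_config(max_iter = 800))
  expect_identical(fit$objective_trace, fit2$objective_trace)
  expect_identical(fit$field, fit2$field)
})

test_that("doubling the response doubles the unpenalized fitted values", {
  set.seed(41)
  n <- 20
  x <- runif(n, 0.5, 2)
  y <- rnorm(n)
  d1 <- spatial_dataset(cbind(runif(n), runif(n)), y, matrix(x, n, 1))
  g <- build_mst(d1$coords)
  d2 <- spatial_dataset(d1$coords, 2 * y, d1$predictors)
  opt <- optimizer_config(max_iter = 4000, learning_rate = 0.05)
  f1 <- fit_svc(d1, g, penalty_config(), opt, standardize = FALSE,
                center = FALSE)
  f2 <- fit_svc(d2, g, penalty_config(), opt, standardize = FALSE,
                center = FALSE)
  expect_equal(2 * predict(f1), predict(f2), tolerance = 1e-3)
})

test_that("hard thresholding zeroes small entries and barely moves the objective", {
  expect_identical(hard_threshold(matrix(c(1e-9, 0.5), 1, 2), 1e-6),
                   matrix(c(0, 0.5), 1, 2))
  # threshold 0 is the identity
  m <- matrix(rnorm(20), 4, 5)
  expect_identical(hard_threshold(m, 0), m)
  # objective change bounded by the lambda-weighted mass of zeroed entries
  set.seed(29)
  sim <- simulate_dataset(n = 30, p = 4, seed = 29)
  g <- build_mst(sim$dataset$coords)
  pen <- penalty_config(0.5, 0.5, 0.5)
  fld <- matrix(rnorm(120), 30, 4)
  small <- abs(fld) < 0.3
  thr <- hard_threshold(fld, 0.3)
  delta <- abs(evaluate_objective(sim$dataset, thr, g, pen) -
                 evaluate_objective(sim$dataset, fld, g, pen))
  # each zeroed entry can move data/fused/L1/group terms by O(|entry|)
  expect_lt(delta, sum(abs(fld[small])) * 50)
  expect_true(all(thr[small] == 0))
})
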